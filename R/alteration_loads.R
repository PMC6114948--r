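#' Default variant-classification severity map
#'
#' Classifies MAF variant classifications by expected biological effect.
#' Severe: truncating or start-disrupting events; moderate: protein-altering
#' point/in-frame events; everything listed as low does not change the
#' protein (silent, non-coding). The map is a plain named character vector
#' so an alternative table can be supplied to every consumer.
#'
#' @return Named character vector mapping classification to
#'   `"low"`, `"moderate"` or `"severe"`.
#' @export
default_severity_map <- function() {
  c(
    Nonsense_Mutation = "severe", Frame_Shift_Del = "severe",
    Frame_Shift_Ins = "severe", Splice_Site = "severe",
    Nonstop_Mutation = "severe", Translation_Start_Site = "severe",
    Missense_Mutation = "moderate", In_Frame_Del = "moderate",
    In_Frame_Ins = "moderate",
    Silent = "low", `3'UTR` = "low", `5'UTR` = "low", `3'Flank` = "low",
    `5'Flank` = "low", Intron = "low", RNA = "low", IGR = "low",
    Targeted_Region = "low", De_novo_Start_InFrame = "low",
    De_novo_Start_OutOfFrame = "low"
  )
}

.severity_of <- function(classification, severity_map = default_severity_map(),
                         unknown = c("error", "low")) {
  unknown <- match.arg(unknown)
  sev <- severity_map[classification]
  if (anyNA(sev)) {
    if (unknown == "error") {
      stop("unknown variant classification(s): ",
           paste(unique(classification[is.na(sev)]), collapse = ", "))
    }
    sev[is.na(sev)] <- "low"
  }
  unname(sev)
}

#' Per-patient global SNP load
#'
#' Count of retained mutation records per patient (all variant types,
#' post-filtering). Patients absent from `records` are absent from the
#' result unless listed in `patients`, in which case they get 0.
#'
#' @param records Filtered mutation records.
#' @param patients Optional roster for zero-filling.
#' @return Named integer vector of counts.
#' @export
snp_load <- function(records, patients = NULL) {
  counts <- table(records$patient_id)
  if (is.null(patients)) {
    return(setNames(as.integer(counts), names(counts)))
  }
  out <- setNames(integer(length(patients)), patients)
  hit <- intersect(patients, names(counts))
  out[hit] <- as.integer(counts[hit])
  out
}

#' Per-patient count of genes carrying disruptive mutations
#'
#' Number of distinct genes with at least one moderate- or severe-severity
#' mutation per patient.
#'
#' @param records Filtered, single-gene mutation records.
#' @param severity_map Named map, see [default_severity_map()].
#' @param unknown Policy for unmapped classifications: `"error"` (default)
#'   or `"low"` (treat as non-disruptive).
#' @param patients Optional roster for zero-filling.
#' @return Named integer vector.
#' @export
disrupted_gene_count <- function(records, severity_map = default_severity_map(),
                                 unknown = c("error", "low"), patients = NULL) {
  stopifnot(all(records$n_genes == 1L))
  sev <- .severity_of(records$variant_classification, severity_map, unknown)
  hit <- records[sev %in% c("moderate", "severe")]
  counts <- tapply(hit$gene, hit$patient_id, function(g) length(unique(g)))
  counts <- setNames(as.integer(counts), names(counts))
  if (is.null(patients)) return(counts)
  out <- setNames(integer(length(patients)), patients)
  found <- intersect(patients, names(counts))
  out[found] <- counts[found]
  out
}

#' Per-patient copy-number load
#'
#' Sum of the absolute thresholded gene-level copy-number calls per
#' patient, over all genes of the matrix. Values must be GISTIC-style
#' thresholded calls in \{-2, -1, 0, 1, 2\}; missing values are skipped
#' (treated as absent, not imputed).
#'
#' @param cnv_matrix Numeric matrix, genes x patients.
#' @return Named numeric vector of loads, with attribute `n_missing`
#'   (missing values per patient).
#' @export
cnv_load <- function(cnv_matrix) {
  vals <- cnv_matrix[!is.na(cnv_matrix)]
  if (length(vals) > 0L && !all(vals %in% -2:2)) {
    stop("CNV matrix contains values outside {-2,-1,0,1,2}; ",
         "expected thresholded gene-level calls")
  }
  loads <- colSums(abs(cnv_matrix), na.rm = TRUE)
  attr(loads, "n_missing") <- colSums(is.na(cnv_matrix))
  loads
}

# per-gene standardization across patients; zero-variance genes dropped
.methylation_z <- function(beta_matrix) {
  if (ncol(beta_matrix) < 3L) {
    stop("methylation matrix needs >= 3 patients to define per-gene variance")
  }
  mu <- rowMeans(beta_matrix, na.rm = TRUE)
  sdev <- apply(beta_matrix, 1L, sd, na.rm = TRUE)
  keep <- is.finite(sdev) & sdev > 0
  if (any(!keep)) {
    warning(sum(!keep), " gene(s) with zero variance dropped from ",
            "methylation standardization")
  }
  (beta_matrix[keep, , drop = FALSE] - mu[keep]) / sdev[keep]
}

#' Per-patient methylation change rate
#'
#' Gene-level beta values are mean-centered and scaled to unit variance
#' across patients; the per-patient rate is then the sum over genes of the
#' absolute standardized deviation (default) or of the signed z-scores
#' (`mode = "signed"`, which is ~0 for every patient by construction and
#' kept only for comparison).
#'
#' @param beta_matrix Numeric matrix, genes x patients, values in \[0, 1\].
#' @param mode `"absolute"` (default) or `"signed"`.
#' @return Named numeric vector of rates.
#' @export
methylation_change_rate <- function(beta_matrix,
                                    mode = c("absolute", "signed")) {
  mode <- match.arg(mode)
  z <- .methylation_z(beta_matrix)
  if (mode == "absolute") colSums(abs(z), na.rm = TRUE)
  else colSums(z, na.rm = TRUE)
}

#' Assemble the per-patient load table
#'
#' Joins SNP load, disrupted gene count, CNV load and methylation change
#' rate on the clinical roster (zero-fill for mutation-derived counts,
#' `NA` for patients absent from the CNV/methylation matrices).
#'
#' @param clinical Clinical table with a `patient_id` column.
#' @param records Filtered mutation records (optional).
#' @param cnv_matrix Genes x patients CNV matrix (optional).
#' @param beta_matrix Genes x patients methylation matrix (optional).
#' @param severity_map See [default_severity_map()].
#' @return `data.frame` keyed by `patient_id`.
#' @export
patient_loads <- function(clinical, records = NULL, cnv_matrix = NULL,
                          beta_matrix = NULL,
                          severity_map = default_severity_map()) {
  out <- data.frame(patient_id = clinical$patient_id,
                    stringsAsFactors = FALSE)
  roster <- out$patient_id
  if (!is.null(records)) {
    out$snp_load <- snp_load(records, patients = roster)
    out$disrupted_gene_count <-
      disrupted_gene_count(records, severity_map, patients = roster)
  }
  if (!is.null(cnv_matrix)) {
    l <- cnv_load(cnv_matrix)
    out$cnv_load <- unname(l[roster])
  }
  if (!is.null(beta_matrix)) {
    r <- methylation_change_rate(beta_matrix)
    out$methylation_change_rate <- unname(r[roster])
  }
  out
}
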