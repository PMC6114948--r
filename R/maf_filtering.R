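#' somage: age association of somatic genomic alterations
#'
#' Tools to filter somatic mutation tables, build trinucleotide mutation
#' profiles, refit mutational-signature exposures, compute alteration
#' burdens, and run age-association and subgroup statistics, together with
#' a fully seeded synthetic-cohort generator.
#'
#' @importFrom data.table data.table fread fwrite setnames setcolorder as.data.table rbindlist :=
#' @importFrom stats cor cor.test fisher.test median optim p.adjust plogis
#'   qlogis quantile rbinom rlnorm rmultinom rnorm runif sd setNames
#'   wilcox.test complete.cases pnorm qunif rchisq
#' @importFrom utils head modifyList
#' @keywords internal
"_PACKAGE"

# canonical internal column names for mutation records
.maf_internal_cols <- c(
  "patient_id", "sample_id", "gene", "n_genes", "chrom", "pos",
  "ref_allele", "alt_allele", "ref_context", "variant_classification",
  "variant_type"
)

#' Default MAF column mapping
#'
#' Maps the internal field names used throughout the package to the TCGA
#' MAF header names. Override individual entries to read other dialects.
#'
#' @return Named list of column names.
#' @export
default_maf_columns <- function() {
  list(
    sample         = "Tumor_Sample_Barcode",
    gene           = "Hugo_Symbol",
    chrom          = "Chromosome",
    pos            = "Start_position",
    ref            = "Reference_Allele",
    alt            = "Tumor_Seq_Allele2",
    context        = "ref_context",
    classification = "Variant_Classification",
    type           = "Variant_Type"
  )
}

#' Read a MAF-like somatic mutation table
#'
#' Parses a tab-separated mutation table into the package's internal record
#' layout. The patient identifier is derived from the sample barcode by a
#' prefix rule (default: first 12 characters, the TCGA patient barcode).
#' Rows with unparseable mandatory fields (empty gene or sample, or a
#' reference context containing characters outside A/C/G/T/N) are dropped
#' and counted in the `n_dropped` attribute.
#'
#' @param path Path to a tab-separated file with a header.
#' @param columns Column mapping as produced by [default_maf_columns()].
#' @param patient_id_nchar Number of leading barcode characters that form
#'   the patient ID.
#' @param gene_sep Separator used when one row is annotated to several
#'   genes (e.g. `"GENE1;GENE2"`).
#' @return A `data.table` of mutation records with columns
#'   `patient_id, sample_id, gene, n_genes, chrom, pos, ref_allele,
#'   alt_allele, ref_context, variant_classification, variant_type`,
#'   and attribute `n_dropped`.
#' @export
read_maf <- function(path, columns = default_maf_columns(),
                     patient_id_nchar = 12L, gene_sep = ";") {
  stopifnot(file.exists(path))
  raw <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = "character", data.table = TRUE)
  if (nrow(raw) == 0L) {
    warning("empty MAF file: ", path)
    out <- .empty_records()
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  needed <- unlist(columns)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0L) {
    stop("MAF file is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  dt <- data.table::data.table(
    sample_id              = raw[[columns$sample]],
    gene                   = raw[[columns$gene]],
    chrom                  = raw[[columns$chrom]],
    pos                    = suppressWarnings(as.integer(raw[[columns$pos]])),
    ref_allele             = toupper(raw[[columns$ref]]),
    alt_allele             = toupper(raw[[columns$alt]]),
    ref_context            = toupper(raw[[columns$context]]),
    variant_classification = raw[[columns$classification]],
    variant_type           = raw[[columns$type]]
  )
  dt[, `:=`(
    patient_id = substr(sample_id, 1L, patient_id_nchar),
    n_genes = lengths(strsplit(gene, gene_sep, fixed = TRUE))
  )]
  ok <- !is.na(dt$pos) &
    nzchar(dt$sample_id) & nzchar(dt$gene) &
    grepl("^[ACGTN]+$", dt$ref_context)
  n_dropped <- sum(!ok)
  dt <- dt[ok]
  data.table::setcolorder(dt, .maf_internal_cols)
  attr(dt, "n_dropped") <- n_dropped
  dt[]
}

.empty_records <- function() {
  data.table::data.table(
    patient_id = character(), sample_id = character(), gene = character(),
    n_genes = integer(), chrom = character(), pos = integer(),
    ref_allele = character(), alt_allele = character(),
    ref_context = character(), variant_classification = character(),
    variant_type = character()
  )
}

#' Write mutation records as a MAF-like table
#'
#' Inverse of [read_maf()]: writes the internal record layout back out
#' under the supplied (default TCGA) header names.
#'
#' @param records Mutation records.
#' @param path Output path.
#' @param columns Column mapping, see [default_maf_columns()].
#' @return `path`, invisibly.
#' @export
write_maf <- function(records, path, columns = default_maf_columns()) {
  out <- data.table::data.table(
    records$sample_id, records$gene, records$chrom, records$pos,
    records$ref_allele, records$alt_allele, records$ref_context,
    records$variant_classification, records$variant_type
  )
  data.table::setnames(out, unlist(columns[c(
    "sample", "gene", "chrom", "pos", "ref", "alt",
    "context", "classification", "type"
  )]))
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Keep one record per mutation per patient
#'
#' Samples from the same patient share most of their somatic profile, so a
#' mutation observed in several samples of one patient is counted once.
#' Mutation identity is `(patient_id, chrom, pos, ref_allele, alt_allele)`;
#' the first occurrence after a stable sort by `sample_id` wins.
#'
#' @param records Mutation records.
#' @return `list(records = <deduplicated records>, removed = <count>)`.
#' @export
dedup_same_patient <- function(records) {
  if (nrow(records) == 0L) return(list(records = records, removed = 0L))
  ord <- order(records$sample_id)          # stable in R
  dt <- records[ord]
  keep <- !duplicated(dt[, c("patient_id", "chrom", "pos",
                             "ref_allele", "alt_allele"), with = FALSE])
  list(records = dt[keep], removed = sum(!keep))
}

#' Remove mutations annotated to more than one gene
#'
#' A mutation falling on sequence shared by several genes (e.g. paralogs)
#' cannot be assigned to a single gene and is excluded.
#'
#' @param records Mutation records.
#' @return `list(records, removed)`.
#' @export
drop_multi_gene <- function(records) {
  keep <- records$n_genes == 1L
  list(records = records[keep], removed = sum(!keep))
}

#' Tandem-repeat test for a reference context
#'
#' Repetitive reference sequence drives false-positive somatic calls, so a
#' mutation is kept only when its reference context carries, for every unit
#' length 1 to 5 and at every alignment phase, strictly fewer consecutive
#' tandem copies of any unit than the thresholds (default 6 single bases,
#' 4 duplets, 3 triplets, 3 quadruplets, 3 quintuplets). A homopolymer run
#' of k bases counts as floor(k/u) tandem copies at unit length u, so all
#' five unit lengths are always checked. Case-insensitive; `N` never
#' extends a run.
#'
#' @param context Character vector of reference contexts over A/C/G/T/N.
#' @param thresholds Integer vector of length 5: maximal allowed tandem
#'   copy counts are `thresholds - 1` for unit lengths 1..5.
#' @return Logical vector: `TRUE` when the context passes (is kept).
#' @export
repeat_context_pass <- function(context, thresholds = c(6L, 4L, 3L, 3L, 3L)) {
  stopifnot(length(thresholds) == 5L, all(thresholds >= 1L))
  if (any(!grepl("^[ACGTNacgtn]*$", context)) || any(!nzchar(context))) {
    stop("context must be a non-empty string over A, C, G, T, N")
  }
  up <- toupper(context)
  out <- logical(length(up))
  len <- nchar(up)
  for (L in unique(len)) {
    idx <- which(len == L)
    out[idx] <- .repeat_pass_block(up[idx], L, as.integer(thresholds))
  }
  out
}

# vectorized over equal-length contexts; dynamic programming from the
# right at each unit length u: copies[, i] = 1 + copies[, i + u] when the
# u-mer at i equals the u-mer at i + u (and neither contains N)
.repeat_pass_block <- function(s, L, thresholds) {
  ch <- matrix(unlist(strsplit(s, "", fixed = TRUE), use.names = FALSE),
               nrow = length(s), ncol = L, byrow = TRUE)
  is_n <- ch == "N"
  pass <- rep(TRUE, length(s))
  for (u in 1:5) {
    if (L < 2L * u) next
    npos <- L - 2L * u + 1L                 # starts where a next copy fits
    cols <- seq_len(npos)
    eq <- matrix(TRUE, length(s), npos)
    for (off in 0:(u - 1L)) {
      eq <- eq & (ch[, cols + off, drop = FALSE] ==
                    ch[, cols + off + u, drop = FALSE]) &
        !is_n[, cols + off, drop = FALSE] &
        !is_n[, cols + off + u, drop = FALSE]
    }
    ncop <- L - u + 1L
    copies <- matrix(1L, length(s), ncop)
    for (i in npos:1) {
      copies[, i] <- ifelse(eq[, i], copies[, i + u] + 1L, 1L)
    }
    mx <- copies[, 1L]
    if (ncop > 1L) for (j in 2:ncop) mx <- pmax(mx, copies[, j])
    pass <- pass & (mx < thresholds[u])
  }
  pass
}

#' Apply the full mutation exclusion cascade
#'
#' Applies, in order: same-patient deduplication, multi-gene ambiguity
#' removal, the tandem-repeat context filter, and removal of explicitly
#' excluded patients (e.g. hypermutated outliers). Returns the retained
#' records together with a step-by-step accounting report.
#'
#' @param records Mutation records from [read_maf()].
#' @param excluded_patients Character vector of patient IDs to drop after
#'   the three record-level criteria.
#' @param repeat_thresholds Passed to [repeat_context_pass()].
#' @return `list(records, report)` where `report` is a `filter_report`
#'   with the count after each step and per-step removed fractions.
#' @export
run_filters <- function(records, excluded_patients = character(),
                        repeat_thresholds = c(6L, 4L, 3L, 3L, 3L)) {
  n_input <- nrow(records)
  d1 <- dedup_same_patient(records)
  d2 <- drop_multi_gene(d1$records)
  r <- d2$records
  if (nrow(r) > 0L) {
    keep <- repeat_context_pass(r$ref_context, thresholds = repeat_thresholds)
    r3 <- r[keep]
  } else {
    r3 <- r
  }
  r4 <- r3[!r3$patient_id %in% excluded_patients]
  counts <- c(
    n_input               = n_input,
    n_after_dedup         = nrow(d1$records),
    n_after_gene_ambiguity = nrow(d2$records),
    n_after_repeat_filter = nrow(r3),
    n_after_patient_exclusion = nrow(r4)
  )
  fractions <- ifelse(counts[-length(counts)] > 0,
                      1 - counts[-1] / counts[-length(counts)], 0)
  names(fractions) <- paste0("removed_", names(counts)[-1])
  report <- structure(
    list(counts = counts, fractions_removed = fractions,
         excluded_patients = excluded_patients),
    class = "filter_report"
  )
  list(records = r4[], report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Mutation filter report\n")
  steps <- names(x$counts)
  for (i in seq_along(steps)) {
    cat(sprintf("  %-28s %10d", steps[i], x$counts[i]))
    if (i > 1L) cat(sprintf("   (-%.1f%%)", 100 * x$fractions_removed[i - 1L]))
    cat("\n")
  }
  invisible(x)
}

#' Write a filter report as JSON
#'
#' @param report A `filter_report` from [run_filters()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(
    list(counts = as.list(report$counts),
         fractions_removed = as.list(report$fractions_removed),
         excluded_patients = report$excluded_patients),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
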