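#' The 96 trinucleotide substitution channels in canonical order
#'
#' Substitutions in COSMIC order (C>A, C>G, C>T, T>A, T>C, T>G), then the
#' 5' flank A,C,G,T, then the 3' flank A,C,G,T; labels are COSMIC-style,
#' e.g. `"A[C>A]A"`.
#'
#' @return Character vector of 96 channel labels.
#' @export
channel96_labels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  as.vector(vapply(subs, function(s) {
    as.vector(vapply(bases, function(f5) {
      paste0(f5, "[", s, "]", bases)
    }, character(4L)))
  }, character(16L)))
}

.base_complement <- c(A = "T", C = "G", G = "C", T = "A")

#' Map a substitution with flanks to its pyrimidine-normalized channel
#'
#' Every substitution is referred to by the pyrimidine of the mutated
#' Watson-Crick base pair: purine-reference events are reverse-complemented
#' (all three positions complemented, flanks swapped).
#'
#' @param ref,alt,five,three Character vectors of single bases (A/C/G/T).
#'   Recycled to a common length.
#' @return Character vector of channel labels; `NA` where any base is not
#'   one of A/C/G/T or `ref == alt` (unassignable, never an error).
#' @export
normalize_to_pyrimidine <- function(ref, alt, five, three) {
  n <- max(length(ref), length(alt), length(five), length(three))
  ref <- rep_len(toupper(ref), n); alt <- rep_len(toupper(alt), n)
  five <- rep_len(toupper(five), n); three <- rep_len(toupper(three), n)
  ok <- ref %in% names(.base_complement) & alt %in% names(.base_complement) &
    five %in% names(.base_complement) & three %in% names(.base_complement) &
    ref != alt
  out <- rep(NA_character_, n)
  if (!any(ok)) return(out)
  flip <- ok & ref %in% c("A", "G")
  r <- ref; a <- alt; f5 <- five; f3 <- three
  r[flip] <- .base_complement[ref[flip]]
  a[flip] <- .base_complement[alt[flip]]
  f5[flip] <- .base_complement[three[flip]]
  f3[flip] <- .base_complement[five[flip]]
  out[ok] <- paste0(f5[ok], "[", r[ok], ">", a[ok], "]", f3[ok])
  out
}

#' Zero-based index of a channel label in the canonical order
#'
#' @param label Character vector of channel labels such as `"A[C>T]G"`.
#' @return Integer vector of indices in 0..95 (`NA` for unknown labels).
#' @export
channel_index <- function(label) {
  match(label, channel96_labels()) - 1L
}

#' Build per-patient 96-channel mutation count profiles
#'
#' Aggregates filtered single-nucleotide substitution records into one
#' 96-channel count vector per patient. Only `variant_type == "SNP"`
#' records contribute; flanking bases are read from the positions adjacent
#' to the center of `ref_context`. Records whose context cannot supply both
#' flanks, or whose bases fall outside A/C/G/T, are tallied per patient in
#' the `n_unassigned` attribute, so that per patient
#' `sum(counts) + n_unassigned` equals the number of SNP records.
#'
#' @param records Filtered mutation records (see [run_filters()]).
#' @param patients Optional character vector fixing the row set and order
#'   (patients without records get all-zero profiles).
#' @return Integer matrix `patients x 96` with channel-label columns and
#'   attribute `n_unassigned` (named integer vector).
#' @export
build_patient_profiles <- function(records, patients = NULL) {
  if (is.null(patients)) patients <- sort(unique(records$patient_id))
  labels <- channel96_labels()
  prof <- matrix(0L, nrow = length(patients), ncol = 96L,
                 dimnames = list(patients, labels))
  unassigned <- setNames(rep(0L, length(patients)), patients)
  snp <- records[records$variant_type == "SNP" &
                   records$patient_id %in% patients]
  if (nrow(snp) > 0L) {
    w <- nchar(snp$ref_context)
    center <- (w + 1L) %/% 2L
    ok_ctx <- w >= 3L & w %% 2L == 1L
    five <- ifelse(ok_ctx, substr(snp$ref_context, center - 1L, center - 1L), "N")
    three <- ifelse(ok_ctx, substr(snp$ref_context, center + 1L, center + 1L), "N")
    chan <- normalize_to_pyrimidine(snp$ref_allele, snp$alt_allele, five, three)
    assigned <- !is.na(chan)
    if (any(assigned)) {
      tab <- table(factor(snp$patient_id[assigned], levels = patients),
                   factor(chan[assigned], levels = labels))
      prof <- prof + matrix(as.integer(tab), nrow = length(patients),
                            dimnames = dimnames(prof))
    }
    if (any(!assigned)) {
      bad <- table(factor(snp$patient_id[!assigned], levels = patients))
      unassigned <- unassigned + as.integer(bad)
      names(unassigned) <- patients
    }
  }
  attr(prof, "n_unassigned") <- unassigned
  prof
}

#' Write a patients x 96 profile matrix as TSV
#'
#' @param profiles Matrix from [build_patient_profiles()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  dt <- data.table::as.data.table(profiles, keep.rownames = "patient_id")
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
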