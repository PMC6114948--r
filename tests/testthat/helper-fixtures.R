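# shared fixtures built in code

the_catalog <- load_signature_catalog(synthetic_catalog_path())

# one internal-layout mutation record with overridable fields
toy_record <- function(patient = "TCGA-XX-0001", sample = NULL,
                       gene = "GENE1", chrom = "chr1", pos = 100L,
                       ref = "C", alt = "T", context = "ACGTACTGACT",
                       classification = "Missense_Mutation", type = "SNP") {
  # default context center (position 6) is "C"; callers overriding ref
  # should pass a matching context
  data.table::data.table(
    patient_id = patient,
    sample_id = if (is.null(sample)) paste0(patient, "-01A") else sample,
    gene = gene, n_genes = lengths(strsplit(gene, ";", fixed = TRUE)),
    chrom = chrom, pos = as.integer(pos), ref_allele = ref, alt_allele = alt,
    ref_context = context, variant_classification = classification,
    variant_type = type
  )
}

toy_records <- function(...) data.table::rbindlist(list(...))

# write records as a MAF TSV and return the path
toy_maf_file <- function(records, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "toy.maf")
  write_maf(records, path)
  path
}

# literal brute-force tandem-repeat oracle: for every unit length and every
# start, count explicit consecutive copies by substring comparison
oracle_repeat_pass <- function(context, thresholds = c(6L, 4L, 3L, 3L, 3L)) {
  s <- toupper(context)
  n <- nchar(s)
  for (u in 1:5) {
    for (start in seq_len(max(0L, n - u + 1L))) {
      unit <- substr(s, start, start + u - 1L)
      if (grepl("N", unit, fixed = TRUE)) next
      copies <- 1L
      pos <- start + u
      while (pos + u - 1L <= n && substr(s, pos, pos + u - 1L) == unit) {
        copies <- copies + 1L
        pos <- pos + u
      }
      if (copies >= thresholds[u]) return(FALSE)
    }
  }
  TRUE
}

random_contexts <- function(n, min_len = 5L, max_len = 41L) {
  vapply(seq_len(n), function(i) {
    len <- sample(seq(min_len, max_len, by = 2L), 1L)
    paste(sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
                 prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")
  }, character(1L))
}

# literal ECDF-accumulation ssGSEA oracle (term-by-term)
oracle_ssgsea <- function(values, gene_set, alpha = 0.25) {
  n <- length(values)
  r_asc <- rank(values, ties.method = "average")
  ord <- order(values, decreasing = TRUE)
  genes <- names(values)[ord]
  inset <- genes %in% gene_set
  w_total <- 0; out_total <- 0
  for (i in seq_len(n)) {
    if (inset[i]) w_total <- w_total + abs(r_asc[ord][i])^alpha
    else out_total <- out_total + 1
  }
  p_in <- 0; p_out <- 0; score <- 0
  for (i in seq_len(n)) {
    if (inset[i]) p_in <- p_in + abs(r_asc[ord][i])^alpha / w_total
    else p_out <- p_out + 1 / out_total
    score <- score + (p_in - p_out)
  }
  as.numeric(score)
}
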