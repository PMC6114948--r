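#' Classify patients into four signature subgroups by mean thresholds
#'
#' Splits the cohort on two signature exposures (default the two
#' mismatch-repair signatures SI6 and SI26), each thresholded at its
#' cohort arithmetic mean on the raw exposure scale. A patient is "high"
#' when its exposure is strictly greater than the mean (ties go to
#' "low"), producing the four labels `high-A/high-B`, `low-A/high-B`,
#' `high-A/low-B`, `low-A/low-B`.
#'
#' @param exposures Matrix patients x signatures (rownames = patient IDs).
#' @param signatures Character vector of the two signature column names.
#' @return `data.frame`: `patient_id`, `<sig>_class` for each signature,
#'   `label`; attribute `thresholds` holds the two means.
#' @export
classify_signature_subgroups <- function(exposures,
                                         signatures = c("SI6", "SI26")) {
  stopifnot(length(signatures) == 2L,
            all(signatures %in% colnames(exposures)))
  if (nrow(exposures) < 2L) stop("need at least 2 patients to threshold")
  a <- exposures[, signatures[1L]]
  b <- exposures[, signatures[2L]]
  ta <- mean(a); tb <- mean(b)
  ca <- ifelse(a > ta, "high", "low")
  cb <- ifelse(b > tb, "high", "low")
  out <- data.frame(
    patient_id = rownames(exposures),
    ca, cb,
    label = paste0(ca, "-", signatures[1L], "/", cb, "-", signatures[2L]),
    stringsAsFactors = FALSE
  )
  names(out)[2:3] <- paste0(tolower(signatures), "_class")
  attr(out, "thresholds") <- setNames(c(ta, tb), signatures)
  out
}

#' Compare two signature subgroups on clinical and molecular features
#'
#' Wilcoxon rank-sum tests for continuous variables and Fisher's exact
#' tests for categorical variables (including per-gene mutated/wild-type
#' status), between two subgroup labels (default the two discordant
#' mismatch-repair groups), with BH adjustment within each table.
#'
#' @param labels Output of [classify_signature_subgroups()].
#' @param data `data.frame` keyed by `patient_id` holding the variables
#'   (clinical columns and/or load columns).
#' @param group_pair Character vector of the two labels to compare.
#' @param continuous Character vector of continuous column names.
#' @param categorical Character vector of categorical column names.
#' @param gene_status Optional logical genes x patients matrix; each gene
#'   becomes a categorical mutated/wild-type variable.
#' @return List of data.frames `continuous` and `categorical`, each with
#'   `p_value` and `q_value` columns.
#' @export
characterize_subgroups <- function(labels, data, group_pair = NULL,
                                   continuous = character(),
                                   categorical = character(),
                                   gene_status = NULL) {
  if (is.null(group_pair)) {
    lv <- unique(labels$label)
    group_pair <- lv[grepl("^low-.*high-", lv) | grepl("^high-.*low-", lv)]
  }
  stopifnot(length(group_pair) == 2L)
  g1 <- labels$patient_id[labels$label == group_pair[1L]]
  g2 <- labels$patient_id[labels$label == group_pair[2L]]
  if (length(g1) == 0L || length(g2) == 0L) {
    stop("empty subgroup: ", group_pair[which(c(length(g1), length(g2)) == 0L)[1L]])
  }
  rownames(data) <- data$patient_id
  cont <- NULL
  if (length(continuous) > 0L) {
    rows <- lapply(continuous, function(v) {
      a <- data[g1, v]; b <- data[g2, v]
      w <- wilcoxon_rank_sum(a[!is.na(a)], b[!is.na(b)])
      data.frame(variable = v, n1 = sum(!is.na(a)), n2 = sum(!is.na(b)),
                 p_value = w$p_value, flag = w$flag, stringsAsFactors = FALSE)
    })
    cont <- do.call(rbind, rows)
    cont$q_value <- bh_fdr(cont$p_value)
  }
  cat_vars <- list()
  for (v in categorical) {
    cat_vars[[v]] <- setNames(as.character(data[c(g1, g2), v]), c(g1, g2))
  }
  if (!is.null(gene_status)) {
    for (gene in rownames(gene_status)) {
      cat_vars[[paste0("mutated_", gene)]] <- setNames(
        ifelse(gene_status[gene, c(g1, g2)], "mutated", "wild-type"),
        c(g1, g2))
    }
  }
  catg <- NULL
  if (length(cat_vars) > 0L) {
    grp <- factor(c(rep(group_pair[1L], length(g1)),
                    rep(group_pair[2L], length(g2))))
    rows <- lapply(names(cat_vars), function(v) {
      vals <- cat_vars[[v]]
      tab <- table(grp, vals)
      p <- if (any(dim(tab) < 2L)) 1 else
        if (all(dim(tab) == 2L)) fisher_exact(tab) else
          stats::fisher.test(tab)$p.value
      data.frame(variable = v, p_value = p, stringsAsFactors = FALSE)
    })
    catg <- do.call(rbind, rows)
    catg$q_value <- bh_fdr(catg$p_value)
  }
  list(continuous = cont, categorical = catg, group_pair = group_pair)
}

#' Read a GMT gene-set file
#'
#' One set per line: name, description, then gene symbols, tab-separated.
#' Duplicate genes within a set are collapsed; empty sets are an error.
#'
#' @param path GMT file path.
#' @return Named list of character vectors, with attribute `description`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) stop("GMT line(s) without genes: ", which(bad)[1L])
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1L), 1L)
  attr(sets, "description") <- vapply(parts, `[[`, character(1L), 2L)
  sets
}

#' Write a gene-set collection as GMT
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Per-set description column (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(length(sets) > 0L, !is.null(names(sets)))
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Gene-level alteration matrices for pathway projection
#'
#' Builds the three gene x patient layers scored by ssGSEA: the SNP layer
#' counts protein-affecting mutations per gene (silent and other
#' low-severity classes excluded), the CNV layer is the absolute
#' thresholded call, and the methylation layer the absolute per-gene
#' z-score of the beta values.
#'
#' @param records Filtered mutation records (or `NULL`).
#' @param cnv_matrix Genes x patients thresholded CNV matrix (or `NULL`).
#' @param methylation_matrix Genes x patients beta matrix (or `NULL`).
#' @param severity_map See [default_severity_map()].
#' @param patients Optional roster fixing SNP-layer columns.
#' @param gene_universe Optional gene set fixing SNP-layer rows (default:
#'   all genes observed in `records`).
#' @return Named list of matrices (`snp`, `cnv`, `methylation`; absent
#'   layers omitted).
#' @export
gene_level_matrices <- function(records = NULL, cnv_matrix = NULL,
                                methylation_matrix = NULL,
                                severity_map = default_severity_map(),
                                patients = NULL, gene_universe = NULL) {
  out <- list()
  if (!is.null(records)) {
    if (is.null(patients)) patients <- sort(unique(records$patient_id))
    if (is.null(gene_universe)) gene_universe <- sort(unique(records$gene))
    sev <- .severity_of(records$variant_classification, severity_map)
    hit <- records[sev %in% c("moderate", "severe") &
                     records$patient_id %in% patients &
                     records$gene %in% gene_universe]
    tab <- table(factor(hit$gene, levels = gene_universe),
                 factor(hit$patient_id, levels = patients))
    out$snp <- matrix(as.integer(tab), nrow = length(gene_universe),
                      dimnames = list(gene_universe, patients))
  }
  if (!is.null(cnv_matrix)) out$cnv <- abs(cnv_matrix)
  if (!is.null(methylation_matrix)) {
    out$methylation <- abs(.methylation_z(methylation_matrix))
  }
  out
}

#' Single-sample GSEA enrichment score for one patient
#'
#' Genes are ranked by value in decreasing order (ties by mid-rank). The
#' score is the sum over ranked positions of the difference between the
#' weighted in-set cumulative distribution (weights `|rank|^alpha`, where
#' rank is the ascending mid-rank so top genes carry the largest weight,
#' normalized by the in-set total) and the unweighted out-of-set
#' cumulative proportion — the ssGSEA integral of the two empirical
#' distribution functions. `alpha = 0` gives the unweighted
#' Kolmogorov-style statistic.
#'
#' @param values Named numeric vector of per-gene values for one patient.
#' @param gene_set Character vector of gene symbols.
#' @param alpha Rank-weight exponent (ssGSEA default 0.25).
#' @return Numeric score. `NA` with attribute `flag = "disjoint"` when
#'   the set shares no gene with the profile; `0` with
#'   `flag = "degenerate"` when the set covers every profiled gene.
#' @export
ssgsea_score <- function(values, gene_set, alpha = 0.25) {
  stopifnot(!is.null(names(values)), length(values) >= 2L)
  n <- length(values)
  inset <- names(values) %in% gene_set
  if (!any(inset)) return(structure(NA_real_, flag = "disjoint"))
  if (all(inset)) return(structure(0, flag = "degenerate"))
  r_asc <- rank(values, ties.method = "average")   # top gene ~ n
  ord <- order(values, decreasing = TRUE)
  w <- abs(r_asc[ord])^alpha
  in_ord <- inset[ord]
  p_in <- cumsum(w * in_ord) / sum(w * in_ord)
  p_out <- cumsum(!in_ord) / sum(!in_ord)
  sum(p_in - p_out)
}

#' Project alteration layers onto gene sets with ssGSEA
#'
#' Scores every patient column of each gene-level matrix against every
#' gene set. Sets sharing no gene with a layer's universe yield `NA`
#' rows for that layer.
#'
#' @param matrices A single genes x patients matrix or a named list of
#'   them (as from [gene_level_matrices()]).
#' @param gene_sets Named list of gene symbol vectors (see [read_gmt()]).
#' @param alpha Rank-weight exponent.
#' @param normalize When `TRUE`, divide each layer's scores by the range
#'   of scores in that layer (the GenePattern-style normalization);
#'   default off.
#' @return A gene_set x patient matrix, or a named list of them when
#'   `matrices` is a list.
#' @export
project_pathways <- function(matrices, gene_sets, alpha = 0.25,
                             normalize = FALSE) {
  if (is.matrix(matrices)) {
    return(.project_one(matrices, gene_sets, alpha, normalize))
  }
  lapply(matrices, .project_one, gene_sets = gene_sets, alpha = alpha,
         normalize = normalize)
}

.project_one <- function(mat, gene_sets, alpha, normalize) {
  stopifnot(!is.null(rownames(mat)), !is.null(colnames(mat)))
  scores <- matrix(NA_real_, nrow = length(gene_sets), ncol = ncol(mat),
                   dimnames = list(names(gene_sets), colnames(mat)))
  genes <- rownames(mat)
  inset_list <- lapply(gene_sets, function(s) genes %in% s)
  n <- length(genes)
  for (j in seq_len(ncol(mat))) {
    v <- mat[, j]
    r_asc <- rank(v, ties.method = "average")
    ord <- order(v, decreasing = TRUE)
    w <- abs(r_asc[ord])^alpha
    for (i in seq_along(inset_list)) {
      in_ord <- inset_list[[i]][ord]
      n_in <- sum(in_ord)
      if (n_in == 0L) next
      if (n_in == n) { scores[i, j] <- 0; next }
      p_in <- cumsum(w * in_ord) / sum(w * in_ord)
      p_out <- cumsum(!in_ord) / (n - n_in)
      scores[i, j] <- sum(p_in - p_out)
    }
  }
  if (normalize) {
    rng <- range(scores, na.rm = TRUE)
    if (diff(rng) > 0) scores <- scores / diff(rng)
  }
  scores
}

#' Wilcoxon comparison of pathway scores between two subgroups
#'
#' One rank-sum test per gene set between the patients of two subgroup
#' labels, BH-adjusted across sets.
#'
#' @param scores Gene_set x patient score matrix from [project_pathways()].
#' @param labels Output of [classify_signature_subgroups()].
#' @param group_pair The two labels to compare.
#' @return `data.frame`: `gene_set, n1, n2, p_value, q_value, flag`.
#' @export
pathway_subgroup_tests <- function(scores, labels, group_pair) {
  stopifnot(length(group_pair) == 2L)
  g1 <- intersect(labels$patient_id[labels$label == group_pair[1L]],
                  colnames(scores))
  g2 <- intersect(labels$patient_id[labels$label == group_pair[2L]],
                  colnames(scores))
  rows <- lapply(rownames(scores), function(s) {
    a <- scores[s, g1]; b <- scores[s, g2]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) == 0L || length(b) == 0L) {
      return(data.frame(gene_set = s, n1 = length(a), n2 = length(b),
                        p_value = NA_real_, flag = "empty-arm",
                        stringsAsFactors = FALSE))
    }
    w <- wilcoxon_rank_sum(a, b)
    data.frame(gene_set = s, n1 = length(a), n2 = length(b),
               p_value = w$p_value, flag = w$flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_fdr(out$p_value)
  out[, c("gene_set", "n1", "n2", "p_value", "q_value", "flag")]
}

#' Spearman correlation of pathway scores with age
#'
#' One Spearman row per gene set, BH-adjusted across sets (a thin wrapper
#' over [gene_wise_age_correlation()] on the score matrix).
#'
#' @param scores Gene_set x patient score matrix.
#' @param ages Ages aligned with the score columns.
#' @return `data.frame` as in [gene_wise_age_correlation()] with column
#'   `gene_set`.
#' @export
pathway_age_correlation <- function(scores, ages) {
  out <- gene_wise_age_correlation(scores, ages)
  names(out)[names(out) == "gene"] <- "gene_set"
  out
}
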