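#' Spearman rank correlation test
#'
#' Rho is the Pearson correlation of mid-ranks (average ranks on ties).
#' Two-sided p-values follow the permutation distribution as approximated
#' by AS 89 with Edgeworth correction (exact for small tie-free samples);
#' with ties or very large n the t approximation is used, as in
#' `stats::cor.test`.
#'
#' @param x,y Numeric vectors; pairwise-complete observations are used.
#' @param variable Label carried into the result row.
#' @return One-row `data.frame`: `variable, n, rho, p_value, flag`
#'   (`flag` is `"constant"` when either vector is constant and the
#'   statistic undefined, else `""`).
#' @export
spearman_test <- function(x, y, variable = "") {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4L) stop("spearman_test needs at least 4 complete pairs")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    return(data.frame(variable = variable, n = n, rho = NA_real_,
                      p_value = NA_real_, flag = "constant",
                      stringsAsFactors = FALSE))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  data.frame(variable = variable, n = n, rho = unname(ct$estimate),
             p_value = ct$p.value, flag = "", stringsAsFactors = FALSE)
}

#' Percentile bootstrap confidence interval for Spearman's rho
#'
#' Paired resampling with replacement; 95% percentile interval over the
#' replicate rho values. Replicates where either resampled vector is
#' constant (rho undefined) are skipped and counted.
#'
#' @param x,y Numeric vectors (pairwise-complete observations used).
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed; the interval is deterministic given the seed.
#' @param conf Confidence level.
#' @return Numeric `c(low, high)` with attribute `n_degenerate`.
#' @export
bootstrap_rho_ci <- function(x, y, B = 1000L, seed = 1L, conf = 0.95) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4L) stop("bootstrap_rho_ci needs at least 4 complete pairs")
  rhos <- numeric(B)
  ok <- logical(B)
  withr_seed <- .with_seed(seed)
  on.exit(withr_seed(), add = TRUE)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    xb <- x[idx]; yb <- y[idx]
    if (length(unique(xb)) < 2L || length(unique(yb)) < 2L) next
    rhos[b] <- stats::cor(xb, yb, method = "spearman")
    ok[b] <- TRUE
  }
  qs <- stats::quantile(rhos[ok], probs = c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE, na.rm = TRUE)
  structure(qs, n_degenerate = sum(!ok))
}

# save/restore the global RNG state around seeded internals
.with_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values; order-invariant, elementwise `q >= p`.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\]. `NA` is passed
#'   through.
#' @return Numeric vector of q-values.
#' @export
bh_fdr <- function(p_values) {
  pv <- p_values[!is.na(p_values)]
  if (any(pv < 0 | pv > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Wilcoxon rank-sum test
#'
#' Two-sided comparison of two samples: exact enumeration when both groups
#' have at most 25 tie-free observations, otherwise the normal
#' approximation with tie correction and continuity correction.
#'
#' @param a,b Numeric vectors, both non-empty.
#' @return List `statistic`, `p_value`, `method`, `flag` (`"all-tied"`
#'   with `p = 1` when every value is identical).
#' @export
wilcoxon_rank_sum <- function(a, b) {
  stopifnot(length(a) > 0L, length(b) > 0L)
  if (length(unique(c(a, b))) == 1L) {
    return(list(statistic = length(a) * length(b) / 2, p_value = 1,
                method = "degenerate", flag = "all-tied"))
  }
  ties <- any(duplicated(c(a, b)))
  exact <- !ties && length(a) <= 25L && length(b) <= 25L
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = if (exact) "exact" else "normal approximation", flag = "")
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by summation of hypergeometric probabilities no
#' larger than that of the observed table, conditional on fixed margins.
#' A zero margin yields p = 1.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return The two-sided p-value.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)))
  if (any(table < 0) || any(table != round(table))) {
    stop("table must contain non-negative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) return(1)
  stats::fisher.test(table)$p.value
}

#' Local median curve of a variable along age
#'
#' For every grid age (default: all integer ages spanning the data), the
#' median of the values whose age lies within `+/- halfwidth` years, with
#' a 95% percentile bootstrap confidence interval of that median. Grid
#' points with fewer than 3 in-window observations are left undefined.
#'
#' @param ages,values Paired numeric vectors.
#' @param halfwidth Window half-width in years.
#' @param B Bootstrap replicates per grid point.
#' @param seed Integer seed.
#' @param grid Optional explicit grid of ages.
#' @param conf Confidence level.
#' @return `data.frame`: `age, n, median, ci_low, ci_high`.
#' @export
local_median_curve <- function(ages, values, halfwidth = 10, B = 1000L,
                               seed = 1L, grid = NULL, conf = 0.95) {
  keep <- stats::complete.cases(ages, values)
  ages <- ages[keep]; values <- values[keep]
  stopifnot(length(ages) >= 3L)
  if (is.null(grid)) grid <- seq(ceiling(min(ages)), floor(max(ages)))
  restore <- .with_seed(seed)
  on.exit(restore(), add = TRUE)
  probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  rows <- lapply(grid, function(g) {
    inwin <- abs(ages - g) <= halfwidth
    nwin <- sum(inwin)
    if (nwin < 3L) {
      return(data.frame(age = g, n = nwin, median = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_))
    }
    v <- values[inwin]
    meds <- vapply(seq_len(B), function(b) {
      stats::median(v[sample.int(nwin, nwin, replace = TRUE)])
    }, numeric(1L))
    ci <- stats::quantile(meds, probs, names = FALSE)
    data.frame(age = g, n = nwin, median = stats::median(v),
               ci_low = ci[1L], ci_high = ci[2L])
  })
  out <- do.call(rbind, rows)
  attr(out, "halfwidth") <- halfwidth
  out
}

#' Age correlation of a variable, globally and within strata
#'
#' One Spearman test plus bootstrap CI per stratum and for the whole
#' cohort, with Benjamini-Hochberg adjustment across all rows of the
#' table. Strata with fewer than 4 complete pairs get a row with undefined
#' statistics.
#'
#' @param values,ages Paired numeric vectors over the cohort.
#' @param strata Categorical vector (factor or character); `NA` allowed
#'   and reported as excluded from every stratum row.
#' @param B,seed Bootstrap parameters, see [bootstrap_rho_ci()].
#' @return `data.frame`: `stratum, n, rho, ci_low, ci_high, p_value,
#'   q_value, flag`.
#' @export
stratified_age_correlation <- function(values, ages, strata, B = 1000L,
                                       seed = 1L) {
  levels_ <- if (is.factor(strata)) levels(strata) else
    sort(unique(strata[!is.na(strata)]))
  if (length(levels_) == 0L) stop("strata has no non-missing levels")
  groups <- c(list(global = rep(TRUE, length(values))),
              setNames(lapply(levels_, function(l) !is.na(strata) & strata == l),
                       as.character(levels_)))
  rows <- mapply(function(sel, name) {
    v <- values[sel]; a <- ages[sel]
    n <- sum(stats::complete.cases(v, a))
    if (n < 4L) {
      return(data.frame(stratum = name, n = n, rho = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        p_value = NA_real_, flag = "n<4",
                        stringsAsFactors = FALSE))
    }
    st <- spearman_test(v, a, variable = name)
    ci <- if (is.na(st$rho)) c(NA_real_, NA_real_) else
      bootstrap_rho_ci(v, a, B = B, seed = seed)
    data.frame(stratum = name, n = st$n, rho = st$rho, ci_low = ci[1L],
               ci_high = ci[2L], p_value = st$p_value, flag = st$flag,
               stringsAsFactors = FALSE)
  }, groups, names(groups), SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q_value <- bh_fdr(out$p_value)
  out[, c("stratum", "n", "rho", "ci_low", "ci_high", "p_value", "q_value",
          "flag")]
}

#' Row-wise (gene-wise) Spearman correlation with age
#'
#' One Spearman test per row of a gene x patient matrix against patient
#' age, with BH adjustment across rows. Constant rows are flagged with
#' undefined statistics.
#'
#' @param mat Numeric matrix, genes (or gene sets) x patients; columns
#'   must align with `ages`.
#' @param ages Numeric vector, one age per column of `mat`.
#' @return `data.frame`: `gene, n, rho, p_value, q_value, flag`.
#' @export
gene_wise_age_correlation <- function(mat, ages) {
  stopifnot(ncol(mat) == length(ages))
  rows <- lapply(seq_len(nrow(mat)), function(i) {
    spearman_test(mat[i, ], ages,
                  variable = rownames(mat)[i] %||% as.character(i))
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "variable"] <- "gene"
  out$q_value <- bh_fdr(out$p_value)
  rownames(out) <- NULL
  out[, c("gene", "n", "rho", "p_value", "q_value", "flag")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Age-group factor used in subgroup screens
#'
#' Either five classes (`<50`, `50-60`, `60-70`, `70-80`, `>80`; intervals
#' left-open right-closed, so `50-60` is (50, 60]) or the 60-year
#' dichotomy (`<=60`, `>60`).
#'
#' @param ages Numeric vector.
#' @param type `"five"` or `"dichotomy"`.
#' @return Factor of group labels.
#' @export
age_group <- function(ages, type = c("five", "dichotomy")) {
  type <- match.arg(type)
  if (type == "five") {
    cut(ages, breaks = c(-Inf, 50, 60, 70, 80, Inf),
        labels = c("<50", "50-60", "60-70", "70-80", ">80"), right = TRUE)
  } else {
    cut(ages, breaks = c(-Inf, 60, Inf), labels = c("<=60", ">60"),
        right = TRUE)
  }
}

#' Mutational load by per-gene mutation status within age groups
#'
#' For a user-supplied gene list (e.g. frequently mutated DNA repair
#' genes), compares the load of carriers (patients with >= 1 mutation in
#' the gene) against wild-type patients with the Wilcoxon rank-sum test,
#' within each age group, adjusting across genes within each group. Also
#' reports, per group, the fraction of patients carrying at least one of
#' the listed genes mutated.
#'
#' @param loads Named numeric vector of per-patient loads.
#' @param gene_status Logical matrix, genes x patients (`TRUE` = mutated);
#'   column names must match `names(loads)`.
#' @param age_groups Factor over the same patients.
#' @return List with `tests` (data.frame: `gene, age_group, n_mutated,
#'   n_wildtype, p_value, q_value, flag`) and `carrier_fraction`
#'   (named numeric per group).
#' @export
load_by_mutation_status <- function(loads, gene_status, age_groups) {
  patients <- names(loads)
  stopifnot(!is.null(patients),
            identical(sort(colnames(gene_status)), sort(patients)),
            length(age_groups) == length(loads))
  gene_status <- gene_status[, patients, drop = FALSE]
  groups <- levels(as.factor(age_groups))
  rows <- list()
  for (g in groups) {
    in_g <- !is.na(age_groups) & age_groups == g
    for (gene in rownames(gene_status)) {
      mut <- gene_status[gene, ] & in_g
      wt <- !gene_status[gene, ] & in_g
      if (sum(mut) == 0L || sum(wt) == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = gene, age_group = g, n_mutated = sum(mut),
          n_wildtype = sum(wt), p_value = NA_real_, flag = "empty-arm",
          stringsAsFactors = FALSE)
        next
      }
      w <- wilcoxon_rank_sum(loads[mut], loads[wt])
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene, age_group = g, n_mutated = sum(mut),
        n_wildtype = sum(wt), p_value = w$p_value, flag = w$flag,
        stringsAsFactors = FALSE)
    }
  }
  tests <- do.call(rbind, rows)
  tests$q_value <- NA_real_
  for (g in groups) {
    sel <- tests$age_group == g
    tests$q_value[sel] <- bh_fdr(tests$p_value[sel])
  }
  carrier <- vapply(groups, function(g) {
    in_g <- !is.na(age_groups) & age_groups == g
    if (!any(in_g)) return(NA_real_)
    mean(colSums(gene_status[, in_g, drop = FALSE]) > 0)
  }, numeric(1L))
  list(tests = tests[, c("gene", "age_group", "n_mutated", "n_wildtype",
                         "p_value", "q_value", "flag")],
       carrier_fraction = setNames(carrier, groups))
}
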