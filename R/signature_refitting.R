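#' Load a 96 x K mutational signature catalog
#'
#' Reads a tab-separated catalog with a channel-label column (header
#' `SomaticMutationType`, or the first non-numeric column) and one numeric
#' column per signature. Rows are re-ordered to the canonical channel order
#' of [channel96_labels()]. Columns must be non-negative and sum to 1
#' within 1e-3 (column-stochastic probability vectors).
#'
#' The package ships a deterministic synthetic catalog with COSMIC-v2-like
#' structure (see [build_synthetic_catalog()]); a real COSMIC v2
#' `signatures_probabilities`-style TSV with the same layout loads the
#' same way.
#'
#' @param path Path to the catalog TSV.
#' @return A `signature_catalog`: list with `matrix` (96 x K, rownames =
#'   channel labels), `channel_labels`, `signature_labels`.
#' @export
load_signature_catalog <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  lab_col <- if ("SomaticMutationType" %in% names(dt)) {
    "SomaticMutationType"
  } else {
    names(dt)[!vapply(dt, is.numeric, logical(1L))][1L]
  }
  if (is.na(lab_col)) stop("catalog has no channel label column")
  labels <- dt[[lab_col]]
  num_cols <- setdiff(names(dt), lab_col)
  num_cols <- num_cols[vapply(dt[, num_cols, with = FALSE], is.numeric, logical(1L))]
  if (nrow(dt) != 96L) stop("catalog must have exactly 96 rows, got ", nrow(dt))
  canonical <- channel96_labels()
  if (!setequal(labels, canonical)) {
    stop("catalog channel labels do not match the 96 canonical channels")
  }
  mat <- as.matrix(dt[, num_cols, with = FALSE])
  rownames(mat) <- labels
  mat <- mat[canonical, , drop = FALSE]
  if (any(mat < 0)) stop("catalog contains negative entries")
  csums <- colSums(mat)
  if (any(abs(csums - 1) > 1e-3)) {
    bad <- num_cols[abs(csums - 1) > 1e-3]
    stop("catalog column(s) not column-stochastic: ",
         paste(bad, collapse = ", "))
  }
  structure(
    list(matrix = mat, channel_labels = canonical, signature_labels = num_cols),
    class = "signature_catalog"
  )
}

#' @export
print.signature_catalog <- function(x, ...) {
  cat("signature_catalog: 96 channels x", length(x$signature_labels),
      "signatures\n")
  invisible(x)
}

#' Refit signature exposures for one mutation profile
#'
#' Expresses a 96-channel count profile as a non-negative combination of
#' the catalog signatures, minimizing the sum of squared differences
#' between the observed profile and `a1*S1 + ... + aK*SK` over `a >= 0`.
#' The minimization uses bound-constrained quasi-Newton (L-BFGS-B) with
#' the analytic gradient; the problem is convex so the solution does not
#' depend on the (deterministic, scale-aware) initialization
#' `a_i = sum(profile)/K`. Exposures are in mutation-count units:
#' `sum(a)` approximates the profile total when the fit is good.
#'
#' @param profile Numeric vector of 96 non-negative counts (canonical
#'   channel order, or named by channel labels).
#' @param catalog A `signature_catalog`.
#' @param opts Solver options: `maxit` (default 10000) and `factr`
#'   (default 1e7; relative convergence tolerance is `factr * .Machine$double.eps`).
#' @return An `exposure_fit`: list with `a` (named non-negative exposures),
#'   `objective` (residual sum of squares), `reconstruction_cosine`,
#'   `n_mutations`, `convergence`.
#' @export
fit_exposures <- function(profile, catalog, opts = list()) {
  stopifnot(inherits(catalog, "signature_catalog"))
  S <- catalog$matrix
  if (!is.null(names(profile))) profile <- profile[rownames(S)]
  p <- as.numeric(profile)
  if (length(p) != 96L || any(!is.finite(p))) {
    stop("profile must be 96 finite counts")
  }
  k <- ncol(S)
  maxit <- if (is.null(opts$maxit)) 10000L else opts$maxit
  factr <- if (is.null(opts$factr)) 1e7 else opts$factr
  if (all(p == 0)) {
    a <- setNames(rep(0, k), catalog$signature_labels)
    return(structure(list(a = a, objective = 0,
                          reconstruction_cosine = NA_real_,
                          n_mutations = 0, convergence = 0L),
                     class = "exposure_fit"))
  }
  StS <- crossprod(S)
  Stp <- crossprod(S, p)
  fn <- function(a) sum(p^2) - 2 * sum(a * Stp) + drop(crossprod(a, StS %*% a))
  gr <- function(a) drop(2 * (StS %*% a) - 2 * Stp)
  fit <- stats::optim(
    par = rep(sum(p) / k, k), fn = fn, gr = gr,
    method = "L-BFGS-B", lower = rep(0, k),
    control = list(maxit = maxit, factr = factr)
  )
  if (fit$convergence != 0L) {
    # a failed line search at an over-tight tolerance still leaves the
    # iterate essentially at the optimum of this convex problem; retry
    # once with a looser tolerance from the current point
    fit2 <- stats::optim(
      par = pmax(fit$par, 0), fn = fn, gr = gr,
      method = "L-BFGS-B", lower = rep(0, k),
      control = list(maxit = maxit, factr = max(factr, 1e7))
    )
    if (fit2$value <= fit$value) fit <- fit2
    if (fit$convergence != 0L) {
      stop("exposure refit did not converge (optim status ", fit$convergence,
           "): ", fit$message)
    }
  }
  a <- setNames(pmax(fit$par, 0), catalog$signature_labels)
  recon <- drop(S %*% a)
  cosine <- sum(p * recon) / sqrt(sum(p^2) * sum(recon^2))
  structure(
    list(a = a, objective = max(fit$value, 0),
         reconstruction_cosine = cosine,
         n_mutations = sum(p), convergence = fit$convergence),
    class = "exposure_fit"
  )
}

#' @export
print.exposure_fit <- function(x, ...) {
  top <- sort(x$a, decreasing = TRUE)
  top <- top[top > 0][seq_len(min(5L, sum(x$a > 0)))]
  cat("exposure_fit:", x$n_mutations, "mutations, RSS =",
      signif(x$objective, 4), ", cosine =",
      signif(x$reconstruction_cosine, 4), "\n")
  cat("  top exposures:",
      paste(names(top), signif(top, 4), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Refit exposures for a cohort of profiles
#'
#' @param profiles Matrix `patients x 96` from [build_patient_profiles()].
#' @param catalog A `signature_catalog`.
#' @param opts Passed to [fit_exposures()].
#' @return Matrix `patients x K` of exposures, with attribute
#'   `diagnostics`: data.frame of per-patient `objective`,
#'   `reconstruction_cosine`, `n_mutations`.
#' @export
exposure_table <- function(profiles, catalog, opts = list()) {
  stopifnot(nrow(profiles) > 0L)
  fits <- lapply(seq_len(nrow(profiles)), function(i) {
    fit_exposures(profiles[i, ], catalog, opts)
  })
  mat <- do.call(rbind, lapply(fits, function(f) f$a))
  rownames(mat) <- rownames(profiles)
  attr(mat, "diagnostics") <- data.frame(
    patient_id = rownames(profiles),
    objective = vapply(fits, function(f) f$objective, numeric(1L)),
    reconstruction_cosine = vapply(fits, function(f) f$reconstruction_cosine,
                                   numeric(1L)),
    n_mutations = vapply(fits, function(f) f$n_mutations, numeric(1L)),
    stringsAsFactors = FALSE
  )
  mat
}

#' Write an exposure table and its diagnostics
#'
#' @param exposures Matrix from [exposure_table()].
#' @param path Output TSV path; diagnostics go to
#'   `sub("\\\\.tsv$", "_diagnostics.json", path)`.
#' @return `path`, invisibly.
#' @export
write_exposures <- function(exposures, path) {
  dt <- data.table::as.data.table(exposures, keep.rownames = "patient_id")
  data.table::fwrite(dt, path, sep = "\t")
  diag <- attr(exposures, "diagnostics")
  if (!is.null(diag)) {
    jsonlite::write_json(diag, sub("\\.tsv$", "_diagnostics.json", path),
                         digits = NA)
  }
  invisible(path)
}
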