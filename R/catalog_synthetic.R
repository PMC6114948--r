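#' Build the deterministic synthetic signature catalog
#'
#' Constructs a 96 x 30 column-stochastic signature catalog with the
#' qualitative structure of the COSMIC v2 catalog: SI1 concentrates C>T at
#' NpCpG sites (spontaneous 5-methylcytosine deamination), SI2/SI13 are
#' APOBEC-like C>T/C>G at TpCpN, SI4 is the broad C>A tobacco-smoke
#' pattern, SI6 is mismatch-repair-like C>T at NpCpG with a flank profile
#' distinct from SI1 plus a C>A component, SI26 is dominated by T>C
#' transitions, and the remaining signatures are fixed sparse random
#' profiles. This catalog is SYNTHETIC: the numeric values are not the
#' published COSMIC v2 probabilities. It exists so that refitting,
#' subgrouping and simulation are fully testable offline; analyses of real
#' cohorts should load the published catalog with
#' [load_signature_catalog()] instead.
#'
#' The construction is deterministic (fixed internal RNG stream) and
#' matches the shipped fixture
#' `system.file("extdata", "cosmic_v2_like_synthetic_signatures.tsv",
#' package = "somage")`.
#'
#' @return A `signature_catalog` with signatures SI1..SI30.
#' @export
build_synthetic_catalog <- function() {
  labels <- channel96_labels()
  sub_of <- substr(labels, 3L, 5L)
  five_of <- substr(labels, 1L, 1L)
  three_of <- substr(labels, 7L, 7L)

  rng <- .seeded_rng(190681L)
  k <- 30L
  mat <- matrix(0, nrow = 96L, ncol = k,
                dimnames = list(labels, paste0("SI", seq_len(k))))

  # fixed sparse random background for every signature
  for (j in seq_len(k)) {
    g <- rng$rgamma_vec(96L, shape = 0.35)
    mat[, j] <- g / sum(g)
  }

  put_motif <- function(j, mask, weights, mass) {
    w <- weights / sum(weights)
    mat[, j] <<- (1 - mass) * mat[, j] / sum(mat[, j])
    mat[mask, j] <<- mat[mask, j] + mass * w
  }

  ncg <- sub_of == "C>T" & three_of == "G"              # N[C>T]G, 4 channels
  put_motif(1L, ncg, c(A = 0.20, C = 0.30, G = 0.30, T = 0.20)[five_of[ncg]], 0.75)

  tcn_ct <- sub_of == "C>T" & five_of == "T"            # APOBEC-like
  put_motif(2L, tcn_ct, rep(1, sum(tcn_ct)), 0.70)
  tcn_cg <- sub_of == "C>G" & five_of == "T"
  put_motif(13L, tcn_cg, rep(1, sum(tcn_cg)), 0.70)

  ca <- sub_of == "C>A"                                  # tobacco-like
  w_ca <- ifelse(five_of[ca] %in% c("C", "T"), 1.6, 0.7) *
    ifelse(three_of[ca] %in% c("A", "T"), 1.3, 0.8)
  put_motif(4L, ca, w_ca, 0.80)

  # SI5: broad flat profile
  mat[, 5L] <- 0.3 * mat[, 5L] + 0.7 / 96

  # SI6: MMR-like, C>T both at GpCpG and at GpCpN non-CpG sites, plus a
  # C>A tail at CpC; flank profile deliberately distinct from SI1
  gcg <- sub_of == "C>T" & five_of == "G" & three_of == "G"
  put_motif(6L, gcg, rep(1, sum(gcg)), 0.30)
  gcn <- sub_of == "C>T" & five_of == "G" & three_of != "G"
  put_motif(6L, gcn, rep(1, sum(gcn)), 0.30)
  ca_cc <- sub_of == "C>A" & five_of == "C"
  put_motif(6L, ca_cc, rep(1, sum(ca_cc)), 0.20)

  tc <- sub_of == "T>C"                                  # SI26: T>C heavy
  w_tc <- ifelse(three_of[tc] %in% c("A", "G"), 1.4, 0.8)
  put_motif(26L, tc, w_tc, 0.75)

  mat <- sweep(mat, 2L, colSums(mat), "/")
  structure(
    list(matrix = mat, channel_labels = labels,
         signature_labels = colnames(mat)),
    class = "signature_catalog"
  )
}

# self-contained deterministic gamma sampler so the catalog never touches
# (or disturbs) the session RNG stream
.seeded_rng <- function(seed) {
  env <- new.env()
  env$state <- as.double(seed %% 2147483647L)
  nxt <- function() {
    # Lehmer / Park-Miller minimal standard generator
    env$state <- (16807 * env$state) %% 2147483647
    env$state / 2147483647
  }
  runif_vec <- function(n) vapply(seq_len(n), function(i) nxt(), numeric(1L))
  rgamma_one <- function(shape) {
    # Ahrens-Dieter style boost for shape < 1 via shape + 1
    boost <- 1
    a <- shape
    if (a < 1) {
      boost <- nxt()^(1 / a)
      a <- a + 1
    }
    # Marsaglia-Tsang with inverse-CDF normals from the Lehmer stream
    d <- a - 1 / 3
    c <- 1 / sqrt(9 * d)
    repeat {
      x <- stats::qnorm(min(max(nxt(), 1e-12), 1 - 1e-12))
      v <- (1 + c * x)^3
      if (v <= 0) next
      u <- nxt()
      if (log(u) < 0.5 * x^2 + d - d * v + d * log(v)) {
        return(boost * d * v)
      }
    }
  }
  list(
    runif_vec = runif_vec,
    rgamma_vec = function(n, shape) {
      vapply(seq_len(n), function(i) rgamma_one(shape), numeric(1L))
    }
  )
}

#' Write a signature catalog as a TSV fixture
#'
#' @param catalog A `signature_catalog`.
#' @param path Output path; header is
#'   `SomaticMutationType<TAB>SI1...<TAB>SIK`.
#' @return `path`, invisibly.
#' @export
write_signature_catalog <- function(catalog, path) {
  dt <- data.table::as.data.table(catalog$matrix,
                                  keep.rownames = "SomaticMutationType")
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Path to the shipped synthetic signature catalog fixture
#'
#' @return File path of the synthetic COSMIC-v2-like catalog TSV.
#' @export
synthetic_catalog_path <- function() {
  system.file("extdata", "cosmic_v2_like_synthetic_signatures.tsv",
              package = "somage", mustWork = TRUE)
}
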