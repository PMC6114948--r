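test_that("spearman_test recovers perfect monotone association", {
  up <- spearman_test(1:5, c(2, 4, 6, 8, 10))
  expect_equal(up$rho, 1)
  down <- spearman_test(1:5, c(10, 8, 6, 4, 2))
  expect_equal(down$rho, -1)
  # invariant under strictly monotone transforms
  withr::local_seed(2)
  x <- rnorm(40); y <- x + rnorm(40)
  a <- spearman_test(x, y)
  b <- spearman_test(exp(x), y^3 + 5 * y)
  expect_equal(a$rho, b$rho)
  expect_equal(a$p_value, b$p_value)
  # constant input flagged, not an error
  flat <- spearman_test(rep(1, 6), 1:6)
  expect_equal(flat$flag, "constant")
  expect_true(is.na(flat$rho))
  expect_error(spearman_test(1:3, 1:3), "at least 4")
})

test_that("spearman p-values match exhaustive permutation at n = 7", {
  withr::local_seed(31)
  perms <- as.matrix(expand.grid(rep(list(1:7), 7)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 7L), ]
  for (case in 1:5) {
    x <- sample(100, 7)
    y <- sample(100, 7)
    obs <- spearman_test(x, y)
    rx <- rank(x)
    rho_all <- apply(perms, 1, function(py) cor(rx, py))
    p_exact <- mean(abs(rho_all) >= abs(obs$rho) - 1e-12)
    expect_lt(abs(obs$p_value - p_exact), 0.005)
  }
})

test_that("bootstrap rho CI is deterministic, degenerate-safe and well-covered", {
  # y == x: every resample has rho 1
  expect_equal(unname(bootstrap_rho_ci(1:10, 1:10, B = 200, seed = 4)),
               c(1, 1), ignore_attr = TRUE)
  withr::local_seed(6)
  x <- rnorm(60); y <- 0.5 * x + rnorm(60)
  ci1 <- bootstrap_rho_ci(x, y, B = 500, seed = 99)
  ci2 <- bootstrap_rho_ci(x, y, B = 500, seed = 99)
  expect_identical(ci1, ci2)
  rho <- cor(x, y, method = "spearman")
  expect_lte(ci1[1], rho)
  expect_gte(ci1[2], rho)
})

test_that("bootstrap CI coverage is at least ~90% at nominal 95%", {
  # bivariate normal with population Spearman rho targeted at 0.5
  withr::local_seed(123)
  r_lat <- 2 * sin(pi * 0.5 / 6)
  hits <- vapply(1:200, function(i) {
    x <- rnorm(200)
    y <- r_lat * x + sqrt(1 - r_lat^2) * rnorm(200)
    ci <- bootstrap_rho_ci(x, y, B = 400, seed = i)
    ci[1] <= 0.5 && 0.5 <= ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("BH adjustment matches a brute-force step-up oracle", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  oracle_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    pmin(q, 1)[order(o)]
  }
  withr::local_seed(8)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(q >= p))
    # same rejection set as the raw step-up rule at alpha = 0.05 and 0.2
    for (alpha in c(0.05, 0.2)) {
      m <- length(p); ps <- sort(p)
      k <- suppressWarnings(max(which(ps <= alpha * seq_len(m) / m)))
      rej_oracle <- if (is.finite(k)) p <= ps[k] else rep(FALSE, m)
      expect_equal(q <= alpha, rej_oracle)
    }
    # order invariance
    perm <- sample.int(length(p))
    expect_equal(bh_fdr(p[perm]), q[perm])
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("wilcoxon rank-sum handles exact, tied and degenerate cases", {
  # 3 vs 3 extreme split: 2 of the C(6,3)=20 equally likely assignments
  # are at least as extreme, so the two-sided exact p is 0.1
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(10, 11, 12))
  expect_equal(w$p_value, 0.1)
  expect_equal(w$method, "exact")
  same <- wilcoxon_rank_sum(c(1, 2, 3), c(3, 1, 2))
  expect_equal(same$p_value, 1)
  tied <- wilcoxon_rank_sum(rep(2, 4), rep(2, 5))
  expect_equal(tied$p_value, 1)
  expect_equal(tied$flag, "all-tied")
})

test_that("exact and normal-approximate wilcoxon p agree at n = 20/20", {
  withr::local_seed(14)
  for (i in 1:100) {
    a <- rnorm(20); b <- rnorm(20, mean = runif(1, -1, 1))
    p_exact <- stats::wilcox.test(a, b, exact = TRUE)$p.value
    p_norm <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
    expect_lt(abs(p_exact - p_norm), 0.01)
  }
})

test_that("wilcoxon power under a 1-sd shift matches a reference implementation", {
  withr::local_seed(15)
  rej <- vapply(1:500, function(i) {
    a <- rnorm(50); b <- rnorm(50, 1)
    wilcoxon_rank_sum(a, b)$p_value < 0.05
  }, logical(1))
  # reference: stats::wilcox.test on the same generative model
  withr::local_seed(15)
  rej_ref <- vapply(1:500, function(i) {
    a <- rnorm(50); b <- rnorm(50, 1)
    stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - mean(rej_ref)), 0.05)
})

test_that("fisher_exact matches hypergeometric arithmetic", {
  expect_equal(fisher_exact(matrix(c(5, 0, 0, 5), 2)), 2 / choose(10, 5))
  expect_equal(fisher_exact(matrix(c(3, 3, 3, 3), 2)), 1)
  expect_equal(fisher_exact(matrix(c(10, 10, 0, 0), 2)), 1)  # zero margin
  expect_error(fisher_exact(matrix(c(1.5, 2, 3, 4), 2)), "integers")
})

test_that("local median curves window correctly and reproduce under a seed", {
  ages <- c(40, 45, 50, 55, 60, 65, 70, 75, 80, 85)
  # identity values: median at grid age g = median of ages in [g-10, g+10]
  curve <- local_median_curve(ages, ages, halfwidth = 10, B = 50, seed = 2,
                              grid = c(50, 62, 80))
  expect_equal(curve$median[1], median(ages[ages >= 40 & ages <= 60]))
  expect_equal(curve$median[2], median(ages[ages >= 52 & ages <= 72]))
  expect_equal(curve$median[3], median(ages[ages >= 70 & ages <= 90]))
  # constant values: flat curve with zero-width CI
  flat <- local_median_curve(ages, rep(7, 10), halfwidth = 10, B = 50, seed = 2)
  expect_true(all(flat$median == 7))
  expect_true(all(flat$ci_low == 7 & flat$ci_high == 7))
  # same seed -> identical CIs; sparse window -> undefined point
  withr::local_seed(19)
  vals <- rnorm(10)
  c1 <- local_median_curve(ages, vals, B = 100, seed = 5)
  c2 <- local_median_curve(ages, vals, B = 100, seed = 5)
  expect_identical(c1, c2)
  sparse <- local_median_curve(c(40, 41, 80), c(1, 2, 3), halfwidth = 2,
                               B = 20, seed = 1, grid = c(60, 80))
  expect_true(is.na(sparse$median[1]))
})

test_that("stratified correlations recover per-stratum signs and match global", {
  withr::local_seed(22)
  # single stratum equals the global row
  x <- rnorm(50); y <- x + rnorm(50)
  tab <- stratified_age_correlation(x, y, rep("all", 50), B = 100, seed = 3)
  expect_equal(tab$rho[tab$stratum == "all"], tab$rho[tab$stratum == "global"])
  # opposite built-in correlations per stratum
  n <- 150
  a_x <- rnorm(n); a_y <- 0.55 * a_x + sqrt(1 - 0.55^2) * rnorm(n)
  b_x <- rnorm(n); b_y <- -0.55 * b_x + sqrt(1 - 0.55^2) * rnorm(n)
  tab2 <- stratified_age_correlation(c(a_x, b_x), c(a_y, b_y),
                                     rep(c("A", "B"), each = n),
                                     B = 100, seed = 3)
  expect_gt(tab2$rho[tab2$stratum == "A"], 0)
  expect_lt(tab2$rho[tab2$stratum == "B"], 0)
  expect_true(all(tab2$q_value >= tab2$p_value, na.rm = TRUE))
  # small stratum flagged; empty label set errors
  tab3 <- stratified_age_correlation(x, y, c(rep("A", 47), rep("B", 3)),
                                     B = 50, seed = 1)
  expect_equal(tab3$flag[tab3$stratum == "B"], "n<4")
  expect_error(stratified_age_correlation(x, y, rep(NA_character_, 50)),
               "no non-missing")
})

test_that("gene-wise screen flags constants, ranks true signal first, controls FDR", {
  withr::local_seed(33)
  ages <- runif(80, 40, 85)
  mat <- matrix(rnorm(30 * 80), 30, 80,
                dimnames = list(paste0("G", 1:30), NULL))
  mat[1, ] <- ages                 # perfect signal
  mat[2, ] <- 5                    # constant
  tab <- gene_wise_age_correlation(mat, ages)
  expect_equal(tab$rho[tab$gene == "G1"], 1)
  expect_equal(tab$gene[which.min(tab$q_value)], "G1")
  expect_equal(tab$flag[tab$gene == "G2"], "constant")
  # identical rows give identical statistics
  mat2 <- rbind(A = mat[5, ], B = mat[5, ])
  tab2 <- gene_wise_age_correlation(mat2, ages)
  expect_equal(tab2$rho[1], tab2$rho[2])
  expect_equal(tab2$p_value[1], tab2$p_value[2])
  # null matrix: fraction of q <= 0.2 stays inside the FDR sanity band
  null_mat <- matrix(rnorm(500 * 80), 500, 80,
                     dimnames = list(paste0("N", 1:500), NULL))
  null_tab <- gene_wise_age_correlation(null_mat, ages)
  expect_lte(mean(null_tab$q_value <= 0.2), 0.25)
})

test_that("age groups use left-open right-closed boundaries", {
  g <- age_group(c(45, 50, 50.5, 60, 61, 80, 81))
  expect_equal(as.character(g),
               c("<50", "<50", "50-60", "50-60", "60-70", "70-80", ">80"))
  d <- age_group(c(59, 60, 60.1), type = "dichotomy")
  expect_equal(as.character(d), c("<=60", "<=60", ">60"))
})

test_that("load-by-mutation-status screens detect carriers' load shift", {
  withr::local_seed(44)
  n <- 100
  patients <- sprintf("P%03d", 1:n)
  # identical loads in both arms -> p = 1
  status0 <- matrix(rep(c(TRUE, FALSE), each = n / 2), 1, n,
                    dimnames = list("GENEX", patients))
  loads0 <- setNames(rep(3, n), patients)
  r0 <- load_by_mutation_status(loads0, status0,
                                factor(rep("all", n)))
  expect_equal(r0$tests$p_value, 1)
  # simulated mutator effect: +2 sd in carriers, n = 40/60
  hits <- vapply(1:200, function(i) {
    carrier <- c(rep(TRUE, 40), rep(FALSE, 60))[sample.int(n)]
    loads <- setNames(rnorm(n) + 2 * carrier, patients)
    st <- matrix(carrier, 1, n, dimnames = list("GENEX", patients))
    load_by_mutation_status(loads, st, factor(rep("all", n)))$tests$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
  # gene never mutated -> flagged row; carrier fraction reported per group
  st2 <- rbind(GENEX = c(rep(TRUE, 30), rep(FALSE, 70)),
               GENEY = rep(FALSE, n))
  colnames(st2) <- patients
  ages <- c(rep(55, 50), rep(65, 50))
  r2 <- load_by_mutation_status(setNames(rnorm(n), patients), st2,
                                age_group(ages, "dichotomy"))
  expect_true(all(r2$tests$flag[r2$tests$gene == "GENEY"] == "empty-arm"))
  expect_equal(unname(r2$carrier_fraction["<=60"]), mean(st2["GENEX", 1:50]))
})
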