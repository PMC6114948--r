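test_that("mean-threshold subgrouping follows the strict-inequality rule", {
  # ties go to low: identical exposures -> everyone low/low
  expo <- matrix(5, 4, 2, dimnames = list(paste0("P", 1:4), c("SI6", "SI26")))
  lab <- classify_signature_subgroups(expo)
  expect_true(all(lab$label == "low-SI6/low-SI26"))
  # hand-classified 2-patient case: means are (5, 5)
  expo2 <- matrix(c(0, 10, 10, 0), 2, 2,
                  dimnames = list(c("P1", "P2"), c("SI6", "SI26")))
  lab2 <- classify_signature_subgroups(expo2)
  expect_equal(lab2$label, c("low-SI6/high-SI26", "high-SI6/low-SI26"))
  expect_error(classify_signature_subgroups(expo2[1, , drop = FALSE]),
               "at least 2")
})

test_that("subgroup partition sizes sum to n and resist common rescaling", {
  withr::local_seed(7)
  expo <- matrix(rlnorm(200), 100, 2,
                 dimnames = list(sprintf("P%03d", 1:100), c("SI6", "SI26")))
  lab <- classify_signature_subgroups(expo)
  expect_equal(sum(table(lab$label)), 100L)
  lab_scaled <- classify_signature_subgroups(expo * 17.3)
  expect_equal(lab_scaled$label, lab$label)
})

test_that("characterize_subgroups flags shifts and stays quiet under the null", {
  withr::local_seed(77)
  n <- 50
  ids <- sprintf("P%03d", 1:(2 * n))
  labels <- data.frame(patient_id = ids,
                       label = rep(c("low-SI6/high-SI26", "high-SI6/low-SI26"),
                                   each = n))
  # identical subgroups -> p = 1 for a duplicated continuous variable
  dat_same <- data.frame(patient_id = ids, age_years = rep(rnorm(n), 2))
  r_same <- characterize_subgroups(labels, dat_same,
                                   continuous = "age_years")
  expect_equal(r_same$continuous$p_value, 1)
  # +8-year shift in one subgroup detected in >= 90% of replicates
  hits <- vapply(1:50, function(i) {
    dat <- data.frame(patient_id = ids,
                      age_years = c(rnorm(n, 68, 8), rnorm(n, 60, 8)))
    characterize_subgroups(labels, dat,
                           continuous = "age_years")$continuous$p_value < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  # independent categorical variable mostly stays above q = 0.2
  null_hits <- vapply(1:40, function(i) {
    dat <- data.frame(patient_id = ids,
                      gender = sample(c("M", "F"), 2 * n, TRUE))
    characterize_subgroups(labels, dat,
                           categorical = "gender")$categorical$q_value > 0.2
  }, logical(1))
  expect_gte(mean(null_hits), 0.75)
  expect_error(characterize_subgroups(labels, dat_same,
                                      group_pair = c("low-SI6/high-SI26",
                                                     "nonexistent")),
               "empty subgroup")
})

test_that("GMT files round-trip and reject empty sets", {
  sets <- list(SET_A = c("G1", "G2", "G3"), SET_B = c("G4", "G5"))
  path <- file.path(withr::local_tempdir(), "toy.gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_equal(back, sets, ignore_attr = TRUE)
  writeLines(c("SET_A\tna\tG1", "BAD\tna"), path)
  expect_error(read_gmt(path), "without genes")
  # duplicate genes within a set are collapsed
  writeLines("SET_D\tna\tG1\tG1\tG2", path)
  expect_equal(read_gmt(path)$SET_D, c("G1", "G2"))
})

test_that("gene-level matrices exclude silent mutations and tie to loads", {
  recs <- toy_records(
    toy_record(pos = 1, gene = "GENE1"),
    toy_record(pos = 2, gene = "GENE1"),
    toy_record(pos = 3, gene = "GENE1", classification = "Silent"),
    toy_record(pos = 4, gene = "GENE2", classification = "Silent"),
    toy_record(patient = "P2", pos = 1, gene = "GENE2",
               classification = "Nonsense_Mutation")
  )
  m <- gene_level_matrices(records = recs)
  expect_equal(m$snp["GENE1", "TCGA-XX-0001"], 2L)
  expect_equal(m$snp["GENE2", "TCGA-XX-0001"], 0L)
  expect_equal(m$snp["GENE2", "P2"], 1L)
  # column sums equal the non-silent per-patient load
  sev <- default_severity_map()
  nonsilent <- recs[sev[variant_classification] != "low"]
  expect_equal(colSums(m$snp), snp_load(nonsilent,
                                        patients = colnames(m$snp)),
               ignore_attr = TRUE)
  # empty record set over a fixed universe
  m0 <- gene_level_matrices(records = recs[0], patients = "P9",
                            gene_universe = c("GENE1", "GENE2"))
  expect_true(all(m0$snp == 0L))
  # CNV layer is the absolute call; methylation layer the absolute z-score
  cnv <- cbind(P1 = c(-2, 1), P2 = c(0, 2))
  rownames(cnv) <- c("GENE1", "GENE2")
  beta <- rbind(GENE1 = c(0.2, 0.5, 0.8), GENE2 = c(0.3, 0.3, 0.9))
  colnames(beta) <- paste0("P", 1:3)
  m2 <- gene_level_matrices(cnv_matrix = cnv, methylation_matrix = beta)
  expect_equal(m2$cnv, abs(cnv))
  expect_equal(unname(colSums(m2$methylation)),
               unname(methylation_change_rate(beta)))
})

test_that("ssGSEA scores match the literal ECDF-accumulation oracle", {
  withr::local_seed(55)
  for (i in 1:20) {
    vals <- setNames(sample(0:8, 10, replace = TRUE), paste0("G", 1:10))
    set <- sample(names(vals), 3)
    for (alpha in c(0.25, 0)) {
      expect_equal(ssgsea_score(vals, set, alpha = alpha),
                   oracle_ssgsea(vals, set, alpha = alpha))
    }
  }
})

test_that("ssGSEA scoring is rank-based and rewards top-ranked set genes", {
  vals <- setNames(c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1), paste0("G", 1:10))
  # strictly monotone transform leaves the score unchanged
  expect_equal(ssgsea_score(vals, c("G1", "G2", "G3")),
               ssgsea_score(log(vals + 3), c("G1", "G2", "G3")))
  # swapping one set gene downward strictly lowers the score
  top <- ssgsea_score(vals, c("G1", "G2", "G3"))
  for (k in 4:10) {
    expect_gt(top, ssgsea_score(vals, c("G1", "G2", paste0("G", k))))
  }
  # degenerate and disjoint sets are flagged
  all_set <- ssgsea_score(vals, names(vals))
  expect_equal(as.numeric(all_set), 0)
  expect_equal(attr(all_set, "flag"), "degenerate")
  disjoint <- ssgsea_score(vals, c("X1", "X2"))
  expect_true(is.na(disjoint))
  expect_equal(attr(disjoint, "flag"), "disjoint")
})

test_that("pathway projection is column-consistent and matches per-patient scores", {
  withr::local_seed(66)
  genes <- paste0("G", 1:50)
  mat <- matrix(rpois(50 * 4, 2), 50, 4,
                dimnames = list(genes, paste0("P", 1:4)))
  mat[, 4] <- mat[, 3]                     # identical patients
  sets <- list(S1 = genes[1:10], S2 = genes[30:45], S3 = c("ZZ1", "ZZ2"))
  sc <- project_pathways(mat, sets, alpha = 0.25)
  expect_equal(sc[, "P3"], sc[, "P4"])
  expect_true(all(is.na(sc["S3", ])))
  for (j in 1:3) {
    expect_equal(sc["S1", j],
                 as.numeric(ssgsea_score(mat[, j], sets$S1, alpha = 0.25)))
  }
  # list input returns one score matrix per layer
  both <- project_pathways(list(snp = mat, cnv = mat), sets)
  expect_equal(both$snp, both$cnv)
})

test_that("spiked pathways win the subgroup screen in most replicates", {
  withr::local_seed(88)
  genes <- sprintf("G%03d", 1:200)
  sets <- simulate_gene_sets(genes, n_sets = 12L, set_size_range = c(10L, 20L),
                             seed = 9)
  spike <- attr(sets, "spike")
  n <- 30
  ids <- sprintf("P%03d", 1:(2 * n))
  labels <- data.frame(patient_id = ids,
                       label = rep(c("high-SI6/low-SI26", "low-SI6/high-SI26"),
                                   each = n))
  wins <- vapply(1:25, function(i) {
    mat <- matrix(rpois(200 * 2 * n, 1), 200, 2 * n,
                  dimnames = list(genes, ids))
    # inflate the spike set's genes in the first subgroup
    mat[sets[[spike]], 1:n] <- mat[sets[[spike]], 1:n] +
      matrix(rpois(length(sets[[spike]]) * n, 2), ncol = n)
    sc <- project_pathways(mat, sets, alpha = 0.25)
    tst <- pathway_subgroup_tests(sc, labels,
                                  c("high-SI6/low-SI26", "low-SI6/high-SI26"))
    tst$gene_set[which.min(tst$q_value)] == spike
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})
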