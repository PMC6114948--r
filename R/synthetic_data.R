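#' Simulation configuration for synthetic cohorts
#'
#' Bundles and validates the parameters of the synthetic cohort
#' generator. Defaults emulate a tobacco-exposed squamous lung cohort:
#' uniform ages 40-85, log-normal exome mutation counts (median ~300),
#' a smoking-dominated signature mixture, weak opposite-sign age coupling
#' of the two mismatch-repair signatures (rank rho -0.13 for SI6, +0.11
#' for SI26), a weak negative methylation-age coupling (-0.11), no
#' CNV-age coupling, and filter-exercising record fractions matching the
#' removal rates seen in real exome MAFs (same-patient duplicates,
#' multi-gene annotations, repeat-containing contexts).
#'
#' @param n_patients Cohort size.
#' @param age_range `c(min, max)` years, ages sampled uniformly.
#' @param mutation_count_distribution `c(meanlog, sdlog)` of the
#'   log-normal per-patient mutation count.
#' @param active_signatures Named numeric vector of base mixture
#'   fractions (must sum to 1); names must be catalog signature labels.
#' @param age_rho_targets Named numeric vector of target Spearman
#'   correlations between a signature's true exposure fraction and age
#'   (rank coupling via a Gaussian copula; `|rho| < 1`).
#' @param duplicate_fraction Per-record probability of emitting one extra
#'   same-patient duplicate sample record.
#' @param multigene_fraction Per-record probability of a two-gene
#'   annotation.
#' @param repeat_context_fraction Per-record probability of a
#'   threshold-failing (6-base run) reference context.
#' @param indel_fraction Indel records added per SNP record.
#' @param silent_fraction Probability that an SNP is Silent; the rest is
#'   split over Missense/Nonsense/Splice_Site (0.87/0.09/0.04).
#' @param cnv_event_rate Per-gene, per-patient probability of a non-zero
#'   thresholded CNV call.
#' @param cnv_age_rho,methylation_age_rho Target Spearman correlation of
#'   CNV load / methylation change rate with age (0 = uncoupled).
#' @param gene_universe Gene symbols used by all layers.
#' @param tilt_sd Log-odds spread of the age-coupled signature fractions.
#' @param meth_dispersion_sd Log-scale spread of per-patient methylation
#'   dispersion.
#' @return Validated list of class `simulation_config`.
#' @export
simulation_config <- function(
    n_patients = 300L,
    age_range = c(40, 85),
    mutation_count_distribution = c(meanlog = log(300), sdlog = 0.5),
    active_signatures = c(SI4 = 0.45, SI1 = 0.25, SI6 = 0.18, SI26 = 0.12),
    age_rho_targets = c(SI6 = -0.13, SI26 = 0.11),
    duplicate_fraction = 0.2,
    multigene_fraction = 0.001,
    repeat_context_fraction = 0.088,
    indel_fraction = 0.08,
    silent_fraction = 0.25,
    cnv_event_rate = 0.05,
    cnv_age_rho = 0,
    methylation_age_rho = -0.11,
    gene_universe = sprintf("GENE%04d", 1:300),
    tilt_sd = 0.8,
    meth_dispersion_sd = 0.5) {
  cfg <- list(
    n_patients = as.integer(n_patients), age_range = age_range,
    mutation_count_distribution = mutation_count_distribution,
    active_signatures = active_signatures,
    age_rho_targets = age_rho_targets,
    duplicate_fraction = duplicate_fraction,
    multigene_fraction = multigene_fraction,
    repeat_context_fraction = repeat_context_fraction,
    indel_fraction = indel_fraction, silent_fraction = silent_fraction,
    cnv_event_rate = cnv_event_rate, cnv_age_rho = cnv_age_rho,
    methylation_age_rho = methylation_age_rho,
    gene_universe = gene_universe, tilt_sd = tilt_sd,
    meth_dispersion_sd = meth_dispersion_sd
  )
  problems <- character()
  if (cfg$n_patients < 2L) problems <- c(problems, "n_patients must be >= 2")
  if (length(age_range) != 2L || diff(age_range) <= 0) {
    problems <- c(problems, "age_range must be increasing c(min, max)")
  }
  if (abs(sum(active_signatures) - 1) > 1e-8) {
    problems <- c(problems, "active_signatures fractions must sum to 1")
  }
  if (is.null(names(active_signatures)) || any(!nzchar(names(active_signatures)))) {
    problems <- c(problems, "active_signatures must be named")
  }
  if (length(age_rho_targets) > 0) {
    if (any(abs(age_rho_targets) >= 1)) {
      problems <- c(problems, "age_rho_targets must satisfy |rho| < 1")
    }
    if (!all(names(age_rho_targets) %in% names(active_signatures))) {
      problems <- c(problems, "age_rho_targets must name active signatures")
    }
  }
  fracs <- c(duplicate_fraction, multigene_fraction, repeat_context_fraction,
             indel_fraction, silent_fraction, cnv_event_rate)
  if (any(fracs < 0 | fracs > 1)) {
    problems <- c(problems, "all fractions must lie in [0, 1]")
  }
  if (max(abs(c(cnv_age_rho, methylation_age_rho))) >= 1) {
    problems <- c(problems, "matrix age couplings must satisfy |rho| < 1")
  }
  if (length(problems) > 0L) {
    stop("invalid simulation_config:\n  - ",
         paste(problems, collapse = "\n  - "))
  }
  structure(cfg, class = "simulation_config")
}

# Gaussian-copula latent correlation giving a target Spearman rho
.latent_rho <- function(rho_s) 2 * sin(pi * rho_s / 6)

#' Simulate a clinical cohort with ground truth
#'
#' Draws ages uniformly over the configured range; couples the designated
#' signature fractions to age through a Gaussian copula so each attains
#' its target Spearman correlation in expectation (the coupled fraction is
#' a strictly monotone logit-tilt of the latent variable, so the rank
#' coupling is exact up to sampling noise); samples smoking history, tumor
#' stage, transversion status and gender from frequencies typical of a
#' squamous lung cohort; and archives per-patient true exposure fractions,
#' mutation counts and latent variables for recovery tests.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed; output is deterministic given the seed.
#' @return List with `clinical` (data.frame) and `truth` (list:
#'   `fractions` patients x signatures matrix over the active signatures,
#'   `mutation_counts`, `age_z`, `signature_z`).
#' @export
simulate_cohort <- function(config = simulation_config(), seed = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  restore <- .with_seed(seed)
  on.exit(restore(), add = TRUE)
  n <- config$n_patients
  patient_id <- sprintf("SYNT-00-%04d", seq_len(n))
  z_age <- rnorm(n)
  age <- qunif(pnorm(z_age), config$age_range[1L], config$age_range[2L])
  sig_names <- names(config$active_signatures)
  coupled <- names(config$age_rho_targets)
  z_sig <- matrix(NA_real_, n, length(coupled), dimnames = list(NULL, coupled))
  frac <- matrix(0, n, length(sig_names), dimnames = list(patient_id, sig_names))
  for (k in coupled) {
    r <- .latent_rho(config$age_rho_targets[[k]])
    z_sig[, k] <- r * z_age + sqrt(1 - r^2) * rnorm(n)
    frac[, k] <- plogis(qlogis(config$active_signatures[[k]]) +
                          config$tilt_sd * z_sig[, k])
  }
  csum <- rowSums(frac[, coupled, drop = FALSE])
  over <- csum > 0.9
  if (any(over)) {   # rare guard; rescales only the affected patients
    frac[over, coupled] <- frac[over, coupled] * 0.9 / csum[over]
    csum[over] <- 0.9
  }
  uncoupled <- setdiff(sig_names, coupled)
  if (length(uncoupled) > 0L) {
    base_u <- config$active_signatures[uncoupled]
    frac[, uncoupled] <- outer(1 - csum, base_u / sum(base_u))
  } else {
    frac <- frac / rowSums(frac)
  }
  counts <- pmax(1L, round(rlnorm(n, config$mutation_count_distribution[1L],
                                  config$mutation_count_distribution[2L])))
  clinical <- data.frame(
    patient_id = patient_id,
    age_years = round(age, 1),
    gender = sample(c("MALE", "FEMALE"), n, TRUE, prob = c(0.74, 0.26)),
    tobacco_smoking_history_indicator = sample(
      c("Lifelong non-smoker", "Current smoker",
        "Current reformed smoker for > 15 years",
        "Current reformed smoker for < or = 15 years",
        "Current reformed smoker, duration not specified"),
      n, TRUE, prob = c(0.04, 0.28, 0.17, 0.50, 0.01)),
    ajcc_pathologic_tumor_stage = sample(
      c("Stage I", "Stage II", "Stage III", "Stage IV"),
      n, TRUE, prob = c(0.49, 0.32, 0.175, 0.015)),
    transversion_status = sample(c("High", "Low"), n, TRUE,
                                 prob = c(0.82, 0.18)),
    stringsAsFactors = FALSE
  )
  list(clinical = clinical,
       truth = list(fractions = frac, mutation_counts = setNames(counts, patient_id),
                    age_z = z_age, signature_z = z_sig))
}

.rand_bases <- function(n) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE)
}

#' Simulate a MAF-like somatic mutation table
#'
#' Per patient, mutation channels are drawn multinomially from the
#' patient's true signature mixture; each substitution is rendered with
#' its ref/alt alleles and an 11-mer reference context whose center
#' trinucleotide realizes the channel, on a randomly chosen strand (50/50)
#' to exercise pyrimidine normalization. Configured fractions of
#' same-patient duplicate sample records, two-gene annotations, and
#' tandem-repeat-failing contexts are injected, plus frameshift indel
#' records; clean contexts are rejection-sampled to pass the repeat
#' filter so that with all injection fractions at zero [run_filters()]
#' removes nothing.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param catalog A `signature_catalog` supplying the mixture columns.
#' @param config The [simulation_config()] used for the cohort.
#' @param seed Integer seed.
#' @param path Optional path: when given, the table is also written as a
#'   MAF-like TSV with TCGA headers (see [write_maf()]).
#' @return Mutation records in the internal layout of [read_maf()].
#' @export
simulate_maf <- function(cohort, catalog, config = simulation_config(),
                         seed = 1L, path = NULL) {
  stopifnot(inherits(catalog, "signature_catalog"))
  restore <- .with_seed(seed)
  on.exit(restore(), add = TRUE)
  S <- catalog$matrix
  frac <- cohort$truth$fractions
  miss <- setdiff(colnames(frac), colnames(S))
  if (length(miss) > 0L) stop("catalog lacks signature(s): ",
                              paste(miss, collapse = ", "))
  counts <- cohort$truth$mutation_counts
  labels <- channel96_labels()
  sub_of <- substr(labels, 3L, 5L)
  ref_of <- substr(sub_of, 1L, 1L)
  alt_of <- substr(sub_of, 3L, 3L)
  five_of <- substr(labels, 1L, 1L)
  three_of <- substr(labels, 7L, 7L)

  chan_idx <- integer(0); pid <- character(0)
  for (i in seq_len(nrow(frac))) {
    p <- drop(S[, colnames(frac), drop = FALSE] %*% frac[i, ])
    draw <- rmultinom(1L, counts[i], p)[, 1L]
    chan_idx <- c(chan_idx, rep(seq_len(96L), draw))
    pid <- c(pid, rep(rownames(frac)[i], counts[i]))
  }
  m <- length(chan_idx)
  ref <- ref_of[chan_idx]; alt <- alt_of[chan_idx]
  f5 <- five_of[chan_idx]; f3 <- three_of[chan_idx]
  ctx <- .make_contexts(ref, f5, f3)
  flip <- runif(m) < 0.5
  if (any(flip)) {
    ctx[flip] <- .revcomp(ctx[flip])
    ref[flip] <- .base_complement[ref[flip]]
    alt[flip] <- .base_complement[alt[flip]]
  }
  cls_pool <- c("Missense_Mutation", "Nonsense_Mutation", "Splice_Site")
  cls <- ifelse(runif(m) < config$silent_fraction, "Silent",
                sample(cls_pool, m, TRUE, prob = c(0.87, 0.09, 0.04)))
  genes <- sample(config$gene_universe, m, replace = TRUE)
  rec <- data.table::data.table(
    patient_id = pid, sample_id = paste0(pid, "-01A"),
    gene = genes, n_genes = 1L,
    chrom = paste0("chr", sample(1:22, m, TRUE)),
    pos = 100000L + seq_len(m) * 7L,
    ref_allele = ref, alt_allele = alt, ref_context = ctx,
    variant_classification = cls, variant_type = "SNP"
  )
  # frameshift indels (excluded from 96-channel profiling downstream)
  n_ind <- round(config$indel_fraction * m)
  if (n_ind > 0L) {
    ipid <- sample(pid, n_ind, replace = TRUE)
    iref <- .rand_bases(n_ind)
    ins <- runif(n_ind) < 0.5
    rec_ind <- data.table::data.table(
      patient_id = ipid, sample_id = paste0(ipid, "-01A"),
      gene = sample(config$gene_universe, n_ind, TRUE), n_genes = 1L,
      chrom = paste0("chr", sample(1:22, n_ind, TRUE)),
      pos = 100000L + (m + seq_len(n_ind)) * 7L,
      ref_allele = ifelse(ins, "-", iref),
      alt_allele = ifelse(ins, iref, "-"),
      ref_context = .make_contexts(iref, .rand_bases(n_ind), .rand_bases(n_ind)),
      variant_classification = ifelse(ins, "Frame_Shift_Ins", "Frame_Shift_Del"),
      variant_type = ifelse(ins, "INS", "DEL")
    )
    rec <- data.table::rbindlist(list(rec, rec_ind))
  }
  nr <- nrow(rec)
  # two-gene annotations
  mg <- runif(nr) < config$multigene_fraction
  if (any(mg)) {
    rec$gene[mg] <- paste(rec$gene[mg],
                          sample(config$gene_universe, sum(mg), TRUE),
                          sep = ";")
    rec$n_genes[mg] <- 2L
  }
  # repeat-failing contexts: 6-base run of the center base through positions 2-7
  rf <- runif(nr) < config$repeat_context_fraction
  if (any(rf)) {
    center <- ifelse(rec$variant_type[rf] == "SNP", rec$ref_allele[rf],
                     substr(rec$ref_context[rf], 6L, 6L))
    other <- vapply(center, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                    character(1L))
    rec$ref_context[rf] <- paste0(other, strrep(center, 6L), other,
                                  .rand_bases(sum(rf)), .rand_bases(sum(rf)),
                                  .rand_bases(sum(rf)))
  }
  # duplicate same-patient records from a second sample
  dup <- runif(nr) < config$duplicate_fraction
  if (any(dup)) {
    copy <- rec[dup]
    copy$sample_id <- paste0(copy$patient_id, "-06A")
    rec <- data.table::rbindlist(list(rec, copy))
  }
  data.table::setcolorder(rec, .maf_internal_cols)
  if (!is.null(path)) write_maf(rec, path)
  rec[]
}

# 11-mer contexts with fixed center trinucleotide, rejection-sampled to
# pass the tandem-repeat filter
.make_contexts <- function(ref, f5, f3) {
  m <- length(ref)
  ctx <- paste0(.rand_bases(m), .rand_bases(m), .rand_bases(m), .rand_bases(m),
                f5, ref, f3,
                .rand_bases(m), .rand_bases(m), .rand_bases(m), .rand_bases(m))
  for (iter in 1:50) {
    bad <- which(!repeat_context_pass(ctx))
    if (length(bad) == 0L) break
    ctx[bad] <- paste0(.rand_bases(length(bad)), .rand_bases(length(bad)),
                       .rand_bases(length(bad)), .rand_bases(length(bad)),
                       f5[bad], ref[bad], f3[bad],
                       .rand_bases(length(bad)), .rand_bases(length(bad)),
                       .rand_bases(length(bad)), .rand_bases(length(bad)))
  }
  ctx
}

.revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         vapply(s, function(x) paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]),
                                     collapse = ""), character(1L),
                USE.NAMES = FALSE))
}

#' Simulate thresholded CNV and methylation beta matrices
#'
#' CNV: per gene and patient, a non-zero thresholded call in
#' \{-2,-1,1,2\} occurs with the configured event rate, optionally
#' age-coupled through a Gaussian copula on the per-patient rate. DNA
#' methylation: gene-level beta values from a logistic transform of
#' Gaussian deviates whose per-patient dispersion is age-coupled, so the
#' methylation change rate attains the configured target Spearman
#' correlation with age.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param config The [simulation_config()].
#' @param seed Integer seed.
#' @return List `cnv` (genes x patients integer matrix) and
#'   `methylation` (genes x patients beta matrix), plus `truth`
#'   (per-patient latent dispersion and event rates).
#' @export
simulate_matrices <- function(cohort, config = simulation_config(), seed = 1L) {
  restore <- .with_seed(seed)
  on.exit(restore(), add = TRUE)
  patients <- cohort$clinical$patient_id
  n <- length(patients)
  genes <- config$gene_universe
  G <- length(genes)
  z_age <- cohort$truth$age_z

  rate <- rep(config$cnv_event_rate, n)
  if (config$cnv_age_rho != 0) {
    r <- .latent_rho(config$cnv_age_rho)
    z <- r * z_age + sqrt(1 - r^2) * rnorm(n)
    rate <- plogis(qlogis(config$cnv_event_rate) + 0.6 * z)
  }
  cnv <- matrix(0L, G, n, dimnames = list(genes, patients))
  if (config$cnv_event_rate > 0) {
    hit <- matrix(runif(G * n) < rep(rate, each = G), G, n)
    cnv[hit] <- sample(c(-2L, -1L, 1L, 2L), sum(hit), TRUE,
                       prob = c(0.15, 0.35, 0.35, 0.15))
  }

  if (config$methylation_age_rho != 0) {
    r <- .latent_rho(config$methylation_age_rho)
    zm <- r * z_age + sqrt(1 - r^2) * rnorm(n)
  } else {
    zm <- rnorm(n)
  }
  disp <- exp(config$meth_dispersion_sd * zm)
  mu <- rnorm(G, 0, 1.2)
  eps <- matrix(rnorm(G * n), G, n)
  beta <- plogis(mu + sweep(eps, 2L, disp, "*"))
  dimnames(beta) <- list(genes, patients)

  list(cnv = cnv, methylation = beta,
       truth = list(cnv_rate = setNames(rate, patients),
                    methylation_dispersion = setNames(disp, patients)))
}

#' Simulate a toy gene-set collection
#'
#' Random gene sets drawn from the universe; the first set is the
#' designated "spike" set used by enrichment recovery tests.
#'
#' @param gene_universe Character vector of gene symbols.
#' @param n_sets Number of sets.
#' @param set_size_range `c(min, max)` genes per set.
#' @param seed Integer seed.
#' @param path Optional GMT output path.
#' @return Named list of gene vectors with attribute `spike` (the spike
#'   set's name).
#' @export
simulate_gene_sets <- function(gene_universe, n_sets = 20L,
                               set_size_range = c(10L, 40L), seed = 1L,
                               path = NULL) {
  stopifnot(length(gene_universe) >= max(set_size_range),
            set_size_range[1L] >= 1L)
  restore <- .with_seed(seed)
  on.exit(restore(), add = TRUE)
  # sample sizes without the sample(<scalar>) pitfall when min == max
  width <- set_size_range[2L] - set_size_range[1L] + 1L
  sizes <- set_size_range[1L] + sample.int(width, n_sets, replace = TRUE) - 1L
  sets <- lapply(sizes, function(k) sample(gene_universe, k))
  names(sets) <- c("SPIKE_SET", sprintf("PATHWAY_%02d", seq_len(n_sets - 1L)))[
    seq_len(n_sets)]
  attr(sets, "spike") <- names(sets)[1L]
  if (!is.null(path)) write_gmt(sets, path)
  sets
}
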