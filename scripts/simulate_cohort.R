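#!/usr/bin/env Rscript
# Generate a synthetic cohort (MAF, clinical, CNV, methylation, gene sets)
# ready to feed into scripts/run_pipeline.R.
#
# Usage: Rscript scripts/simulate_cohort.R --out <dir> [--n <patients>] [--seed <int>]

suppressPackageStartupMessages(library(somage))

args <- commandArgs(trailingOnly = TRUE)
arg_value <- function(flag, default = NULL) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) {
    if (is.null(default)) stop("missing required argument ", flag)
    return(default)
  }
  args[i + 1L]
}
out_dir <- arg_value("--out")
n <- as.integer(arg_value("--n", "120"))
seed <- as.integer(arg_value("--seed", "1"))
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

catalog <- load_signature_catalog(synthetic_catalog_path())
cfg <- simulation_config(n_patients = n)
cohort <- simulate_cohort(cfg, seed = seed)
maf <- simulate_maf(cohort, catalog, cfg, seed = seed + 1L,
                    path = file.path(out_dir, "cohort.maf"))
mats <- simulate_matrices(cohort, cfg, seed = seed + 2L)
write_gene_matrix(mats$cnv, file.path(out_dir, "cnv.tsv"))
write_gene_matrix(mats$methylation, file.path(out_dir, "methylation.tsv"))
data.table::fwrite(cohort$clinical, file.path(out_dir, "clinical.tsv"),
                   sep = "\t")
sets <- simulate_gene_sets(cfg$gene_universe, n_sets = 20L, seed = seed + 3L,
                           path = file.path(out_dir, "gene_sets.gmt"))

run_yaml <- list(
  maf = file.path(out_dir, "cohort.maf"),
  clinical = file.path(out_dir, "clinical.tsv"),
  cnv = file.path(out_dir, "cnv.tsv"),
  methylation = file.path(out_dir, "methylation.tsv"),
  gmt = file.path(out_dir, "gene_sets.gmt"),
  catalog = synthetic_catalog_path(),
  seed = seed, out_dir = file.path(out_dir, "run")
)
yaml::write_yaml(run_yaml, file.path(out_dir, "run.yaml"))
message("cohort of ", n, " patients written to ", out_dir,
        " (config: ", file.path(out_dir, "run.yaml"), ")")
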