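#' Build or load a pipeline run configuration
#'
#' Accepts a YAML file path or a named list. Statistical constants of the
#' analysis surface here as defaults rather than being hard-coded
#' downstream: 1000 bootstrap replicates, FDR threshold 0.2, a ±10-year
#' local median window, mean-threshold subgrouping on SI6/SI26 and ssGSEA
#' exponent 0.25. Input paths are optional except `maf`, `clinical` and
#' `catalog`; CNV, methylation and gene-set stages run only when their
#' inputs are present.
#'
#' @param config Path to a YAML file or a named list.
#' @return Validated list of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(
    maf = NULL, clinical = NULL, cnv = NULL, methylation = NULL,
    catalog = NULL, gmt = NULL,
    excluded_patients = character(),
    severity_map = NULL,               # path to a 2-column TSV, optional
    bootstrap_replicates = 1000L, seed = 1L, fdr_threshold = 0.2,
    halfwidth = 10, subgroup_signatures = c("SI6", "SI26"),
    ssgsea_alpha = 0.25, solver = list(),
    out_dir = "somage_run"
  )
  cfg <- utils::modifyList(defaults, config)
  for (f in c("maf", "clinical", "catalog")) {
    if (is.null(cfg[[f]])) stop("run_config requires input path: ", f)
  }
  paths <- Filter(Negate(is.null),
                  cfg[c("maf", "clinical", "cnv", "methylation", "catalog",
                        "gmt", "severity_map")])
  missing <- paths[!vapply(paths, file.exists, logical(1L))]
  if (length(missing) > 0L) {
    stop("run_config input path(s) do not exist: ",
         paste(unlist(missing), collapse = ", "))
  }
  if (cfg$fdr_threshold <= 0 || cfg$fdr_threshold >= 1) {
    stop("fdr_threshold must lie in (0, 1)")
  }
  structure(cfg, class = "run_config")
}

.read_severity_map <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  setNames(as.character(dt[[2L]]), dt[[1L]])
}

#' Run the end-to-end age-association pipeline
#'
#' Stages, in order: mutation filtering, 96-channel profiling, signature
#' refitting, per-patient loads, age-association tables (global,
#' stratified by smoking/stage/transversion status, local median curves),
#' signature-age correlations, SI6/SI26 subgroup classification and
#' characterization, and (when a GMT is supplied) ssGSEA pathway
#' projection of the gene-level layers with subgroup and age tests.
#' All result tables are written under `config$out_dir` together with a
#' machine-readable manifest (input checksums, seed, per-stage row
#' counts).
#'
#' @param config A [run_config()] (or list / YAML path coercible to one).
#' @return Invisibly, a list with every stage's in-memory result and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  manifest <- list(
    package_version = as.character(utils::packageVersion("somage")),
    r_version = R.version.string,
    seed = config$seed,
    inputs = lapply(Filter(Negate(is.null),
                           config[c("maf", "clinical", "cnv", "methylation",
                                    "catalog", "gmt")]),
                    function(p) list(path = p,
                                     md5 = unname(tools::md5sum(p)))),
    stages = list()
  )
  note <- function(stage, rows) {
    manifest$stages[[stage]] <<- list(rows = rows)
    message(sprintf("[somage] %-22s %d rows", stage, rows))
  }

  clinical <- as.data.frame(data.table::fread(config$clinical))
  stopifnot("patient_id" %in% names(clinical), "age_years" %in% names(clinical))
  severity <- if (is.null(config$severity_map)) default_severity_map()
              else .read_severity_map(config$severity_map)

  raw <- read_maf(config$maf)
  filt <- run_filters(raw, excluded_patients = config$excluded_patients)
  write_maf(filt$records, out("filtered.maf"))
  write_filter_report(filt$report, out("filter_report.json"))
  note("maf_filtering", nrow(filt$records))

  roster <- intersect(clinical$patient_id, unique(filt$records$patient_id))
  clinical <- clinical[clinical$patient_id %in% roster, , drop = FALSE]
  profiles <- build_patient_profiles(filt$records, patients = roster)
  write_profiles(profiles, out("profiles96.tsv"))
  note("trinucleotide_profiling", nrow(profiles))

  catalog <- load_signature_catalog(config$catalog)
  exposures <- exposure_table(profiles, catalog, opts = config$solver)
  write_exposures(exposures, out("exposures.tsv"))
  note("signature_refitting", nrow(exposures))

  cnv <- meth <- NULL
  if (!is.null(config$cnv)) {
    cnv <- .read_gene_matrix(config$cnv)
  }
  if (!is.null(config$methylation)) {
    meth <- .read_gene_matrix(config$methylation)
  }
  loads <- patient_loads(clinical, records = filt$records, cnv_matrix = cnv,
                         beta_matrix = meth, severity_map = severity)
  data.table::fwrite(loads, out("patient_loads.tsv"), sep = "\t")
  note("alteration_loads", nrow(loads))

  ages <- clinical$age_years[match(loads$patient_id, clinical$patient_id)]
  load_cols <- setdiff(names(loads), "patient_id")
  assoc <- do.call(rbind, lapply(load_cols, function(v) {
    st <- spearman_test(loads[[v]], ages, variable = v)
    ci <- if (is.na(st$rho)) c(NA_real_, NA_real_) else
      bootstrap_rho_ci(loads[[v]], ages, B = config$bootstrap_replicates,
                       seed = config$seed)
    cbind(st[, c("variable", "n", "rho")], ci_low = ci[1L], ci_high = ci[2L],
          st[, c("p_value", "flag")])
  }))
  assoc$q_value <- bh_fdr(assoc$p_value)
  data.table::fwrite(assoc, out("load_age_association.tsv"), sep = "\t")
  note("age_association_global", nrow(assoc))

  strat_vars <- intersect(
    c("tobacco_smoking_history_indicator", "ajcc_pathologic_tumor_stage",
      "transversion_status"), names(clinical))
  strat <- do.call(rbind, lapply(strat_vars, function(sv) {
    tab <- stratified_age_correlation(
      loads$snp_load, ages, clinical[[sv]][match(loads$patient_id,
                                                 clinical$patient_id)],
      B = config$bootstrap_replicates, seed = config$seed)
    cbind(stratifier = sv, tab)
  }))
  if (!is.null(strat)) {
    data.table::fwrite(strat, out("snp_load_stratified.tsv"), sep = "\t")
    note("age_association_strata", nrow(strat))
  }

  curve <- local_median_curve(ages, loads$snp_load,
                              halfwidth = config$halfwidth,
                              B = config$bootstrap_replicates,
                              seed = config$seed)
  data.table::fwrite(curve, out("snp_load_local_median.tsv"), sep = "\t")

  sig_assoc <- gene_wise_age_correlation(t(exposures), ages)
  names(sig_assoc)[1L] <- "signature"
  data.table::fwrite(sig_assoc, out("signature_age_association.tsv"),
                     sep = "\t")
  note("signature_age", nrow(sig_assoc))

  labels <- classify_signature_subgroups(exposures,
                                         signatures = config$subgroup_signatures)
  data.table::fwrite(labels, out("subgroups.tsv"), sep = "\t")
  discordant <- c(
    paste0("low-", config$subgroup_signatures[1L], "/high-",
           config$subgroup_signatures[2L]),
    paste0("high-", config$subgroup_signatures[1L], "/low-",
           config$subgroup_signatures[2L]))
  subchar <- NULL
  if (all(discordant %in% labels$label)) {
    merged <- merge(clinical, loads, by = "patient_id")
    subchar <- characterize_subgroups(
      labels, merged, group_pair = discordant,
      continuous = intersect(c("age_years", load_cols), names(merged)),
      categorical = intersect(c("gender", "tobacco_smoking_history_indicator"),
                              names(merged)))
    if (!is.null(subchar$continuous)) {
      data.table::fwrite(subchar$continuous,
                         out("subgroup_continuous_tests.tsv"), sep = "\t")
    }
    if (!is.null(subchar$categorical)) {
      data.table::fwrite(subchar$categorical,
                         out("subgroup_categorical_tests.tsv"), sep = "\t")
    }
  }
  note("subgrouping", nrow(labels))

  pathways <- NULL
  if (!is.null(config$gmt)) {
    sets <- read_gmt(config$gmt)
    layers <- gene_level_matrices(records = filt$records, cnv_matrix = cnv,
                                  methylation_matrix = meth,
                                  severity_map = severity, patients = roster)
    scores <- project_pathways(layers, sets, alpha = config$ssgsea_alpha)
    pathways <- list(scores = scores)
    for (layer in names(scores)) {
      data.table::fwrite(
        data.table::as.data.table(scores[[layer]], keep.rownames = "gene_set"),
        out(paste0("ssgsea_", layer, ".tsv")), sep = "\t")
      if (all(discordant %in% labels$label)) {
        tst <- pathway_subgroup_tests(scores[[layer]], labels, discordant)
        data.table::fwrite(tst, out(paste0("ssgsea_", layer,
                                           "_subgroup_tests.tsv")), sep = "\t")
        pathways[[paste0(layer, "_subgroup_tests")]] <- tst
      }
      common <- intersect(colnames(scores[[layer]]), loads$patient_id)
      pac <- pathway_age_correlation(
        scores[[layer]][, common, drop = FALSE],
        ages[match(common, loads$patient_id)])
      data.table::fwrite(pac, out(paste0("ssgsea_", layer,
                                         "_age_correlation.tsv")), sep = "\t")
      pathways[[paste0(layer, "_age_correlation")]] <- pac
    }
    note("pathway_projection", length(sets))
  }

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(
    filter_report = filt$report, records = filt$records,
    profiles = profiles, exposures = exposures, loads = loads,
    load_age_association = assoc, stratified = strat,
    local_median = curve, signature_age = sig_assoc, subgroups = labels,
    subgroup_tests = subchar, pathways = pathways, manifest = manifest
  ))
}

.read_gene_matrix <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  genes <- dt[[1L]]
  m <- as.matrix(dt[, -1L, with = FALSE])
  rownames(m) <- genes
  m
}

#' Write a gene x patient matrix as TSV (first column = gene)
#'
#' @param mat Matrix with row and column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_matrix <- function(mat, path) {
  dt <- data.table::as.data.table(mat, keep.rownames = "gene")
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
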