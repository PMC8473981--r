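#' @title Reproducible pipeline stages
#'
#' @description
#' Thin, file-based wrappers tying the stages into a reproducible pipeline:
#' `run_simulate()` writes per-strain observation tables and assay truth,
#' `run_call()` writes tract/CNV/event tables per strain, `run_classify()`
#' writes the per-strain classification and the unselected-event counts.
#' Every stage records its parameters and seed in a manifest.  An
#' `Rscript`-runnable front end over these functions ships in
#' `inst/scripts/ltgc-pipeline.R`.
#'
#' @name pipeline
NULL

write_manifest <- function(dir, stage, params) {
  yaml::write_yaml(c(list(stage = stage, package = "fs2ltgc",
                          version = as.character(utils::packageVersion("fs2ltgc"))),
                     params),
                   file.path(dir, "manifest.yaml"))
}

strain_dirname <- function(nm) gsub("[^A-Za-z0-9._-]", "_", nm)

#' Simulate the cohort to disk
#'
#' @param out_dir output directory (one subdirectory per strain).
#' @param seed RNG seed.
#' @param depth,error_rate,noise_free observation parameters.
#' @param config cohort configuration (default: packaged).
#' @return invisibly, the cohort object.
#' @export
run_simulate <- function(out_dir, seed = 1, depth = NULL, error_rate = 0,
                         noise_free = FALSE, config = cohort_config_path()) {
  if (!file.exists(config)) stop_config("cohort config '%s' not found", config)
  cohort <- generate_fixture_cohort(seed = seed, noise_free = noise_free,
                                    depth = depth, error_rate = error_rate,
                                    config = config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(cohort$strains)) {
    st <- cohort$strains[[nm]]
    d <- file.path(out_dir, strain_dirname(nm))
    dir.create(d, showWarnings = FALSE)
    write_obs(st$obs, file.path(d, "observations.tsv"))
    pr <- chef_band_profile(st$outcome$genome)
    utils::write.table(as.data.frame(pr), file.path(d, "bands.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    truth <- data.frame(strain = nm, mechanism = st$truth$mechanism,
                        truth_group = st$truth$group,
                        separable = st$truth$separable,
                        stringsAsFactors = FALSE)
    utils::write.table(truth, file.path(d, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_manifest(out_dir, "simulate",
                 list(seed = seed, depth = cohort$depth,
                      error_rate = error_rate, noise_free = noise_free,
                      config = normalizePath(config),
                      strains = length(cohort$strains)))
  invisible(cohort)
}

#' Call events from observation tables on disk
#'
#' @param obs_dir directory produced by [run_simulate()].
#' @param out_dir output directory.
#' @param thresholds calling thresholds.
#' @param genome baseline genome (rebuilt from the packaged configs when
#'   NULL; the SNP spacing is taken from the packaged cohort config).
#' @return invisibly, the list of catalogs.
#' @export
run_call <- function(obs_dir, out_dir, thresholds = default_thresholds(),
                     genome = NULL) {
  if (!dir.exists(obs_dir)) stop_config("observation directory '%s' not found", obs_dir)
  dirs <- list.dirs(obs_dir, recursive = FALSE)
  dirs <- dirs[file.exists(file.path(dirs, "observations.tsv"))]
  if (length(dirs) == 0L) stop_config("no observation tables under '%s'", obs_dir)
  if (is.null(genome)) {
    cfg <- yaml::read_yaml(cohort_config_path())
    genome <- baseline_genome(snp_spacing = cfg$cohort$snp_spacing,
                              panel_seed = cfg$cohort$panel_seed)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  catalogs <- list()
  for (d in dirs) {
    nm <- basename(d)
    obs <- read_obs(file.path(d, "observations.tsv"))
    cat_ <- genome_scan(obs, genome, thresholds)
    catalogs[[nm]] <- cat_
    od <- file.path(out_dir, nm)
    dir.create(od, showWarnings = FALSE)
    write_catalog(cat_, tsv = file.path(od, "events.tsv"),
                  bed = file.path(od, "events.bed"))
    utils::write.table(attr(cat_, "tracts"), file.path(od, "tracts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(attr(cat_, "cnvs"), file.path(od, "cnvs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_manifest(out_dir, "call", list(obs_dir = normalizePath(obs_dir),
                                       thresholds = thresholds))
  invisible(catalogs)
}

#' Classify strains from simulated observables and assays
#'
#' Re-runs the molecule-level assays (which need the simulated genomes, so
#' the cohort is regenerated deterministically from the manifest seed) and
#' combines them with the called events.
#'
#' @param sim_dir directory produced by [run_simulate()].
#' @param out_dir output directory.
#' @param thresholds calling thresholds.
#' @return invisibly, the `ltgc_report`.
#' @export
run_classify <- function(sim_dir, out_dir, thresholds = default_thresholds()) {
  man_path <- file.path(sim_dir, "manifest.yaml")
  if (!file.exists(man_path)) stop_config("no manifest under '%s'", sim_dir)
  man <- yaml::read_yaml(man_path)
  cohort <- generate_fixture_cohort(seed = man$seed, noise_free = man$noise_free,
                                    depth = man$depth,
                                    error_rate = man$error_rate,
                                    config = man$config)
  res <- classify_cohort(cohort, thresholds)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(res$report$strains, file.path(out_dir, "classification.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  counts <- data.frame(category = c(names(res$report$unselected),
                                    paste0("group_", names(res$report$groups))),
                       count = c(as.vector(res$report$unselected),
                                 as.vector(res$report$groups)))
  utils::write.table(counts, file.path(out_dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  txt <- utils::capture.output(print(res$report))
  writeLines(txt, file.path(out_dir, "report.txt"))
  write_manifest(out_dir, "classify", list(sim_dir = normalizePath(sim_dir),
                                           seed = man$seed))
  invisible(res$report)
}
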