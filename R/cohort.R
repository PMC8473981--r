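#' @title The 16-strain LTGC fixture cohort
#'
#' @description
#' The packaged cohort configuration encodes, strain by strain, the repair
#' mechanism and breakpoints that reproduce the observed chromosome III
#' homolog size changes (within the ±2 kb CHEF sizing tolerance), the
#' flank-phasing outcomes, the disjoined-arm Southern patterns, and the
#' genome-wide unselected events (15 terminal LOH, of which 5 carry an
#' abrupt allele transition; 8 CNVs; 4 interior gene conversions).
#'
#' @name fixture_cohort
NULL

#' Path to the packaged cohort configuration
#' @export
cohort_config_path <- function() {
  system.file("extdata", "cohort_fs2.yaml", package = "fs2ltgc", mustWork = TRUE)
}

mechanism_truth_group <- function(mech) {
  switch(mech,
         late_template_switch = "Coupling",
         half_crossover = "Repulsion",
         recapture = ,
         dual_bir_anneal = "Coupling",
         dual_bir_half_crossover = "AbruptTransition",
         dual_bir_ectopic = "Disjoined",
         stop_config("unknown mechanism '%s'", mech))
}

split_capture <- function(capture) {
  capture <- capture %||% 0
  list(capture = max(0, capture), trim = max(0, -capture))
}

build_strain <- function(genome, scfg) {
  mech <- scfg$mechanism
  brk <- make_break(genome, list(zero_resection = TRUE))
  brk$proximal_end <- scfg$invasion %||% brk$proximal_end
  if (!is.null(scfg$distal_end)) brk$distal_end <- scfg$distal_end
  cap <- split_capture(scfg$capture)

  out <- switch(
    mech,
    late_template_switch = simulate_late_template_switch(
      genome, brk, scfg$terminus, capture = cap$capture, trim = cap$trim,
      extra_tracts = lapply(scfg$extra_tracts %||% list(), unlist)),
    half_crossover = simulate_half_crossover(
      genome, brk, scfg$cleavage, capture = cap$capture, trim = cap$trim),
    dual_bir_ectopic = {
      # fillers sized from the target CHEF bands of the two products
      inv <- brk$proximal_end; bd <- brk$distal_end
      inv_y <- map_s_to_y(genome, brk$chrom, inv)
      bd_y <- map_s_to_y(genome, brk$chrom, bd)
      szS <- baseline_sizes(genome, brk$chrom)[["S"]]
      base_left <- inv + (bd_y - 1 - inv_y)
      tipf <- genome$features[genome$features$chrom == scfg$attach_chrom &
                                grepl("^telL", genome$features$name), ]
      base_trans <- (szS - bd + 1) +
        (baseline_sizes(genome, scfg$attach_chrom)[["S"]] - tipf$end[1])
      simulate_gap_repair(genome, brk, "dual_bir_ectopic", list(
        attach_chrom = scfg$attach_chrom,
        capture_left = (scfg$cha1_band %||% base_left) - base_left,
        capture_trans = (scfg$pat1_band %||% base_trans) - base_trans))
    },
    simulate_gap_repair(genome, brk, mech, scfg))

  g <- out$genome
  for (cv in scfg$chr3_cnv %||% list()) {
    g <- apply_cnv(g, brk$chrom, unlist(cv$interval), cv$copy_state,
                   molecule_id = paste0(brk$chrom, "_S.rep"),
                   microhomology = cv$microhomology)
  }
  for (ev in scfg$unselected %||% list()) {
    g <- switch(ev$type,
      terminal = simulate_terminal_loh(g, ev$chrom, ev$boundary,
                                       which_origin = normalize_hap(ev$origin %||% "Y"),
                                       abrupt_switch = ev$abrupt_switch)$genome,
      gene_conversion = overlay_gene_conversion(g, ev$chrom, ev$start, ev$end,
                                                normalize_hap(ev$origin %||% "Y")),
      cnv = apply_cnv(g, ev$chrom, unlist(ev$interval), ev$copy_state),
      stop_config("unknown unselected event type '%s'", ev$type))
  }
  out$genome <- g
  out
}

#' Generate the packaged 16-strain fixture cohort
#'
#' Builds one `repair_outcome` and one observation table per strain from the
#' packaged cohort configuration.  The SNP panel is part of the study design
#' and is fixed by the config's panel seed; `seed` only drives read
#' sampling, so noise-free cohorts are identical across seeds.
#'
#' @param seed RNG seed for observation sampling.
#' @param noise_free generate expectation-valued observations (default
#'   TRUE).
#' @param depth sequencing depth (default: config value, 100).
#' @param error_rate per-read miscall rate in sampled mode.
#' @param config path to a cohort YAML (default: packaged).
#' @param genome optional pre-built baseline genome (must match the config's
#'   SNP spacing); built from the packaged baseline config otherwise.
#' @param include_control add an unrearranged control strain.
#' @return an `fs2_cohort`: list with `baseline` genome and `strains`, each
#'   strain holding `name`, `outcome`, `obs`, and a `truth` record
#'   (mechanism, expected group, separability, junction microhomology).
#' @export
generate_fixture_cohort <- function(seed = 1, noise_free = TRUE, depth = NULL,
                                    error_rate = 0, config = cohort_config_path(),
                                    genome = NULL, include_control = FALSE) {
  cfg <- yaml::read_yaml(config)
  depth <- depth %||% cfg$cohort$depth %||% 100
  base <- genome %||% baseline_genome(snp_spacing = cfg$cohort$snp_spacing,
                                      panel_seed = cfg$cohort$panel_seed)
  strains <- list()
  scfgs <- cfg$strains
  if (include_control) {
    scfgs <- c(scfgs, list(list(name = "control", mechanism = "control")))
  }
  for (i in seq_along(scfgs)) {
    sc <- scfgs[[i]]
    if (identical(sc$mechanism, "control")) {
      out <- structure(list(genome = base,
                            event = list(mechanism = "none"),
                            truth_group = "None"), class = "repair_outcome")
    } else {
      out <- build_strain(base, sc)
    }
    obs <- sample_snp_observations(out$genome, depth = depth,
                                   error_rate = error_rate,
                                   seed = child_seed(seed, i),
                                   noise_free = noise_free)
    mh <- NULL
    for (cv in sc$chr3_cnv %||% list()) {
      if (!is.null(cv$microhomology)) mh <- cv$microhomology
    }
    strains[[sc$name]] <- list(
      name = sc$name, outcome = out, obs = obs,
      truth = list(mechanism = sc$mechanism,
                   group = if (identical(sc$mechanism, "control")) "None"
                     else mechanism_truth_group(sc$mechanism),
                   separable = sc$separable %||% TRUE,
                   invasion = sc$invasion, microhomology = mh))
  }
  structure(list(baseline = base, strains = strains, depth = depth,
                 noise_free = noise_free, seed = seed),
            class = "fs2_cohort")
}

#' @export
print.fs2_cohort <- function(x, ...) {
  cat(sprintf("<fs2_cohort: %d strain(s), depth %g, %s observations>\n",
              length(x$strains), x$depth,
              if (x$noise_free) "noise-free" else "sampled"))
  invisible(x)
}

#' Run the full inference pipeline over a cohort
#'
#' For every strain: genome-wide event scan, evidence collection from the
#' in-silico assays plus the chromosome III calls, and group assignment.
#'
#' @param cohort an `fs2_cohort` from [generate_fixture_cohort()].
#' @param thresholds calling thresholds, see [default_thresholds()].
#' @return list: `evidences`, `classifications`, `catalogs`, `report`
#'   (an `ltgc_report`).
#' @export
classify_cohort <- function(cohort, thresholds = default_thresholds()) {
  evidences <- list(); classifications <- list(); catalogs <- list()
  for (nm in names(cohort$strains)) {
    st <- cohort$strains[[nm]]
    ev <- collect_evidence(st$outcome$genome, cohort$baseline, st$obs,
                           thresholds = thresholds,
                           separable = st$truth$separable)
    evidences[[nm]] <- ev
    classifications[[nm]] <- assign_group(ev)
    catalogs[[nm]] <- genome_scan(st$obs, cohort$baseline, thresholds)
  }
  list(evidences = evidences, classifications = classifications,
       catalogs = catalogs,
       report = cohort_report(classifications, evidences, catalogs))
}
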