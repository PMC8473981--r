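#' @title Evidence integration and group assignment
#'
#' @description
#' Per-strain evidence — chromosome III homolog size changes, flank phasing,
#' CHA1/PAT1 arm linkage, coverage anomalies and the called conversion
#' tract — is integrated into one of three evidence groups, each mapped to
#' its compatible repair mechanisms: Repulsion (BIR with half crossover),
#' Disjoined (gap repair with half crossover), Coupling (late template
#' switch or gap repair; the two cannot be distinguished).
#'
#' @name classify
NULL

GROUP_MECHANISMS <- list(
  Coupling = c("late_template_switch", "gap_repair"),
  Repulsion = "half_crossover",
  Disjoined = "gap_repair_with_half_crossover",
  Unclassified = character(0))

#' Collect the evidence bundle for one strain
#'
#' Runs the in-silico assays (CHEF profile, CHA1/PAT1 Southern, PCR-RFLP
#' homolog identification, flank phasing) and combines them with the
#' sequencing calls into the summary consumed by [assign_group()].
#'
#' When the two chromosome III bands cannot be excised individually, the
#' band-to-homolog assignment falls back on band sizing: a band matching the
#' baseline Y size within tolerance is taken as the Y homolog; otherwise the
#' assignment that best matches the half-crossover +6 kb signature is used.
#'
#' @param genome the strain's (rearranged) `fs2_genome`.
#' @param baseline the unrearranged genome (for baseline sizes).
#' @param obs the strain's `snp_obs` table.
#' @param thresholds calling thresholds, see [default_thresholds()].
#' @param separable optional gel-separability override (see
#'   [phase_flanks()]).
#' @param size_tol CHEF sizing tolerance in bp (default 2000).
#' @return an `evidence_bundle`.
#' @export
collect_evidence <- function(genome, baseline, obs,
                             thresholds = default_thresholds(),
                             separable = NULL, size_tol = 2000) {
  th <- utils::modifyList(default_thresholds(), thresholds)
  chrom <- attr(fs2_edges(baseline), "chrom")
  base_sz <- baseline_sizes(baseline, chrom)

  profile <- chef_band_profile(genome)
  cha1 <- southern(profile, genome, "CHA1")
  pat1 <- southern(profile, genome, "PAT1")
  if (nrow(cha1) == 0L) stop_config("no chromosome III bands detected")
  arm_linkage <- if (setequal(cha1$molecule_id, pat1$molecule_id))
    "same_molecule" else "different_molecules"

  obs3 <- obs[obs$chrom == chrom, ]
  calls <- call_zygosity(obs3, th)
  tracts <- segment_tracts(calls, th$min_snps)
  cnv3 <- detect_cnv(obs, th)
  cnv3 <- cnv3[cnv3$chrom == chrom, ]
  pan <- genome$snp_panel[genome$snp_panel$chrom == chrom, ]
  hom <- tracts[tracts$state %in% c("homY", "homS") &
                  tracts$first_snp > min(pan$pos) &
                  tracts$last_snp < max(pan$pos), ]
  # the selected LTGC: the longest interior homozygous tract not explained
  # by a hemizygous deletion
  ltgc <- NULL
  if (nrow(hom)) {
    expl <- vapply(seq_len(nrow(hom)), function(i) {
      any(cnv3$copy_state == 1 & cnv3$start <= hom$first_snp[i] &
            cnv3$end >= hom$last_snp[i])
    }, TRUE)
    hom <- hom[!expl, ]
    if (nrow(hom)) ltgc <- hom[which.max(hom$last_snp - hom$first_snp), ]
  }

  het_outside <- FALSE
  if (!is.null(ltgc)) {
    t3 <- tracts
    het_outside <- any(t3$state == "het" & t3$last_snp < ltgc$first_snp) &&
      any(t3$state == "het" & t3$first_snp > ltgc$last_snp)
  }

  # --- homolog size deltas --------------------------------------------------
  sep_rule <- isolable(cha1, resolution = 10000)
  sep <- separable %||% all(sep_rule)
  diag_snp <- assay_snp(genome)
  y_delta <- s_delta <- NA_real_
  if (isTRUE(sep)) {
    for (i in seq_len(nrow(cha1))) {
      mol <- genome$molecules[[cha1$molecule_id[i]]]
      al <- molecule_allele_at(mol, diag_snp, genome)
      if (al == "Y") y_delta <- cha1$size[i] - base_sz[["Y"]]
      if (al == "S") s_delta <- cha1$size[i] - base_sz[["S"]]
    }
  } else if (nrow(cha1) >= 2L) {
    sz <- sort(cha1$size)
    near_y <- abs(sz - base_sz[["Y"]]) <= size_tol
    if (any(near_y)) {
      ysz <- sz[which(near_y)[1]]
      ssz <- sz[setdiff(seq_along(sz), which(near_y)[1])][1]
    } else {
      # assignment closest to the +6 kb half-crossover signature
      cand <- expand.grid(y = seq_along(sz), s = seq_along(sz))
      cand <- cand[cand$y != cand$s, ]
      score <- abs(sz[cand$y] - base_sz[["Y"]] - 6000)
      best <- cand[which.min(score), ]
      ysz <- sz[best$y]; ssz <- sz[best$s]
    }
    y_delta <- ysz - base_sz[["Y"]]
    s_delta <- ssz - base_sz[["S"]]
  }

  phasing <- if (is.null(ltgc)) {
    structure(list(value = "not_determined", support = NULL),
              class = "phasing_call")
  } else {
    phase_flanks(genome, ltgc, separable = sep)
  }

  # size consistency: S delta predicted from the tract (net hemizygous
  # content replaced by the conversion) plus called chromosome III CNVs
  size_consistency <- NA
  if (!is.null(ltgc) && !is.na(s_delta)) {
    m <- seg_map(baseline, chrom)
    lo <- ltgc$jl_lo %||% ltgc$first_snp; hi <- ltgc$jr_hi %||% ltgc$last_snp
    lo <- ifelse(is.na(lo), ltgc$first_snp, lo)
    hi <- ifelse(is.na(hi), ltgc$last_snp, hi)
    s_only <- sum(pmax(0, pmin(m$s_end, hi) - pmax(m$s_start, lo) + 1)[
      m$type == "s_only" & !is.na(m$s_start)])
    anch <- map_y_to_s_clamped(baseline, chrom, m)
    ysel <- m$type == "y_only"
    y_only <- sum(m$len[ysel][anch[ysel] >= lo & anch[ysel] <= hi])
    pred <- -(s_only - y_only) +
      sum(ifelse(cnv3$copy_state == 3, 1, -1) * (cnv3$end - cnv3$start + 1))
    size_consistency <- abs(s_delta - pred) <= size_tol
  }

  structure(list(chrom = chrom,
                 y_size_delta = y_delta, s_size_delta = s_delta,
                 phasing = phasing$value, phasing_support = phasing$support,
                 arm_linkage = arm_linkage,
                 chr3_cnvs = cnv3, ltgc_tract = ltgc,
                 het_outside = het_outside,
                 size_consistency = size_consistency,
                 separable = isTRUE(sep)),
            class = "evidence_bundle")
}

# Anchor point (S frame) of each y_only segment, for tract-content checks.
map_y_to_s_clamped <- function(genome, chrom, m) {
  vapply(seq_len(nrow(m)), function(i) {
    if (m$type[i] != "y_only") return(NA_real_)
    # position just proximal of the insertion, in the S frame
    prev <- m[seq_len(i - 1L), ]
    prev <- prev[!is.na(prev$s_end), ]
    if (nrow(prev)) max(prev$s_end) else 0
  }, 0)
}

#' @export
print.evidence_bundle <- function(x, ...) {
  cat(sprintf(paste0("<evidence: dY %+d bp, dS %+d bp, phasing %s, arms %s, ",
                     "%d chrIII CNV(s), tract %s>\n"),
              as.integer(x$y_size_delta), as.integer(x$s_size_delta),
              x$phasing, x$arm_linkage, nrow(x$chr3_cnvs),
              if (is.null(x$ltgc_tract)) "none" else
                sprintf("%d-%d", x$ltgc_tract$first_snp, x$ltgc_tract$last_snp)))
  invisible(x)
}

#' Assign a strain to an evidence group
#'
#' Rule order: (1) arm linkage on different molecules with heterozygous
#' flanks and no chromosome III dosage loss is Disjoined (gap repair with
#' half crossover); (2) repulsion phasing — or undetermined phasing with a
#' Y homolog ~6 kb larger — is Repulsion (half crossover); (3) coupling
#' phasing — or undetermined phasing with an unchanged Y homolog — is
#' Coupling (late template switch or gap repair; indistinguishable).
#' Anything else is Unclassified.  Size consistency of the repaired S
#' homolog is advisory: it is recorded in the rationale but only blocks a
#' classification when no rule fires.
#'
#' @param bundle an `evidence_bundle`.
#' @param size_tol tolerance on the size signatures in bp (default 2000,
#'   the CHEF sizing precision).
#' @return an `ltgc_classification`: group, compatible mechanisms, fired
#'   rules.
#' @export
assign_group <- function(bundle, size_tol = 2000) {
  rationale <- character(0)
  has_tract <- !is.null(bundle$ltgc_tract)
  loss3 <- nrow(bundle$chr3_cnvs) > 0 && any(bundle$chr3_cnvs$copy_state == 1)

  group <- NULL
  if (bundle$arm_linkage == "different_molecules" &&
      isTRUE(bundle$het_outside) && !loss3) {
    group <- "Disjoined"
    rationale <- c(rationale,
                   "CHA1/PAT1 hybridize to different molecules",
                   "heterozygous SNPs flank the tract at constant 2x dosage")
  } else if (bundle$phasing == "repulsion" ||
             (bundle$phasing == "not_determined" && has_tract &&
              !is.na(bundle$y_size_delta) &&
              abs(bundle$y_size_delta - 6000) <= size_tol)) {
    group <- "Repulsion"
    rationale <- c(rationale, if (bundle$phasing == "repulsion")
      "flanking SNPs in repulsion" else
        "phasing not determined but Y homolog ~6 kb larger")
  } else if (bundle$phasing == "coupling" ||
             (bundle$phasing == "not_determined" && has_tract &&
              !is.na(bundle$y_size_delta) &&
              abs(bundle$y_size_delta) <= size_tol)) {
    group <- "Coupling"
    rationale <- c(rationale, if (bundle$phasing == "coupling")
      "flanking SNPs in coupling" else
        "phasing not determined but Y homolog unchanged")
    if (isFALSE(bundle$size_consistency)) {
      rationale <- c(rationale,
                     "S-homolog size departs from tract+CNV expectation (advisory)")
    }
  } else {
    group <- "Unclassified"
    rationale <- c(rationale, "no grouping rule fired")
  }
  structure(list(group = group, mechanisms = GROUP_MECHANISMS[[group]],
                 rationale = rationale),
            class = "ltgc_classification")
}

#' @export
print.ltgc_classification <- function(x, ...) {
  cat(sprintf("<%s group; mechanisms: %s>\n", x$group,
              paste(x$mechanisms, collapse = ", ")))
  for (r in x$rationale) cat("  -", r, "\n")
  invisible(x)
}

#' Classify one simulated strain end to end
#'
#' Convenience wrapper: observation sampling, calling, assays, evidence
#' collection and group assignment for a single `repair_outcome`.
#'
#' @param outcome a `repair_outcome`.
#' @param baseline the unrearranged genome.
#' @param depth,error_rate,noise_free,seed observation parameters, see
#'   [sample_snp_observations()].
#' @param separable optional gel-separability override.
#' @param thresholds calling thresholds.
#' @param chrom_only restrict observations to chromosome III (faster when
#'   genome-wide calls are not needed).
#' @return list: `evidence`, `classification`.
#' @export
classify_outcome <- function(outcome, baseline, depth = 100, error_rate = 0,
                             noise_free = FALSE, seed = NULL, separable = NULL,
                             thresholds = default_thresholds(),
                             chrom_only = TRUE) {
  chrom <- if (chrom_only) attr(fs2_edges(baseline), "chrom") else NULL
  obs <- sample_snp_observations(outcome$genome, depth = depth,
                                 error_rate = error_rate, seed = seed,
                                 noise_free = noise_free, chrom = chrom)
  ev <- collect_evidence(outcome$genome, baseline, obs,
                         thresholds = thresholds, separable = separable)
  list(evidence = ev, classification = assign_group(ev))
}

#' Summary report over a classified cohort
#'
#' @param classifications named list of `ltgc_classification` (one per
#'   strain).
#' @param evidences named list of `evidence_bundle`.
#' @param catalogs named list of `event_catalog` (genome-wide scans).
#' @param selected_chrom chromosome carrying the selected events (excluded
#'   from the unselected-event counts; default chrIII).
#' @return an `ltgc_report`: `$strains` (per-strain table), `$groups`
#'   (group counts), `$unselected` (event counts by category).
#' @export
cohort_report <- function(classifications, evidences = NULL, catalogs = NULL,
                          selected_chrom = "chrIII") {
  strains <- data.frame(
    strain = names(classifications),
    group = vapply(classifications, `[[`, "", "group"),
    mechanisms = vapply(classifications, function(x)
      paste(x$mechanisms, collapse = " | "), ""),
    stringsAsFactors = FALSE)
  if (!is.null(evidences)) {
    strains$y_size_delta <- vapply(evidences, function(e)
      as.numeric(e$y_size_delta), 0)[strains$strain]
    strains$s_size_delta <- vapply(evidences, function(e)
      as.numeric(e$s_size_delta), 0)[strains$strain]
    strains$phasing <- vapply(evidences, `[[`, "", "phasing")[strains$strain]
  }
  groups <- table(factor(strains$group,
                         levels = c("Coupling", "Repulsion", "Disjoined",
                                    "Unclassified")))
  unsel <- NULL
  if (!is.null(catalogs)) {
    all_ev <- do.call(rbind, lapply(names(catalogs), function(nm) {
      d <- as.data.frame(catalogs[[nm]])
      if (nrow(d)) d$strain <- nm
      d
    }))
    all_ev <- all_ev[all_ev$chrom != selected_chrom, ]
    unsel <- c(
      terminal_LOH = sum(all_ev$type == "terminal_LOH"),
      CNV = sum(all_ev$type == "CNV"),
      gene_conversion = sum(all_ev$type == "interior_GC"),
      abrupt_transition = sum(all_ev$type == "terminal_LOH" & all_ev$abrupt))
    attr(unsel, "events") <- all_ev
  }
  structure(list(strains = strains, groups = groups, unselected = unsel),
            class = "ltgc_report")
}

#' @export
print.ltgc_report <- function(x, ...) {
  cat("Per-strain classification:\n")
  print.data.frame(x$strains, row.names = FALSE)
  cat("\nGroup counts:\n"); print(x$groups)
  if (!is.null(x$unselected)) {
    cat("\nUnselected events genome-wide (outside the selected chromosome):\n")
    print(x$unselected)
  }
  invisible(x)
}
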