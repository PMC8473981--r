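#' @title Zygosity calling, tract segmentation, CNV and abrupt-transition
#'   detection
#'
#' @description
#' The sequencing inference works entirely from per-SNP Y-allele fractions
#' and coverage.  SNPs are called het / homozygous-Y / homozygous-S by
#' thresholding the Y fraction; maximal runs of identical calls become
#' tracts whose edges ("junctions") are the interval between the last
#' flanking-state SNP and the first in-state SNP; normalized coverage is
#' segmented into 1x/2x/3x copy states; and adjacent opposite homozygous
#' runs with constant coverage are flagged as abrupt allele transitions.
#'
#' @name calling
NULL

#' Default calling thresholds
#' @export
default_thresholds <- function() {
  list(t_high = 0.95, t_low = 0.35, c_min = 10,
       min_snps = 3, cnv_lo = 0.75, cnv_hi = 1.25,
       min_cnv_len = 2000, min_cnv_snps = 5, cnv_smooth = 5)
}

#' Call per-SNP zygosity states
#'
#' @param obs a `snp_obs` table.
#' @param thresholds list with `t_high` (homozygous fraction cut, default
#'   0.95), `t_low` (het window half-width, default 0.35 so het is
#'   0.35–0.65), `c_min` (minimum coverage, default 10 reads).
#' @return data.frame `chrom`, `pos`, `call` in
#'   \{het, homY, homS, ambiguous, low_cov\}.
#' @export
call_zygosity <- function(obs, thresholds = default_thresholds()) {
  th <- utils::modifyList(default_thresholds(), thresholds)
  stopifnot(th$t_low > 0, th$t_low < 0.5, th$t_high > 0.5, th$t_high < 1 + 1e-9)
  f <- obs$y_fraction
  call <- rep("ambiguous", nrow(obs))
  call[!is.na(f) & f >= th$t_high] <- "homY"
  call[!is.na(f) & f <= 1 - th$t_high] <- "homS"
  call[!is.na(f) & f >= th$t_low & f <= 1 - th$t_low] <- "het"
  call[is.na(f) | obs$coverage < th$c_min] <- "low_cov"
  data.frame(chrom = obs$chrom, pos = obs$pos, call = call,
             stringsAsFactors = FALSE)
}

#' Segment zygosity calls into tracts
#'
#' Maximal runs of identical informative calls (het/homY/homS) with at least
#' `min_snps` SNPs.  Ambiguous and low-coverage SNPs are skipped and do not
#' break runs; runs shorter than `min_snps` are treated as noise and
#' absorbed.  Junction intervals span from the last SNP of the neighbouring
#' run to the first SNP of the run (NA at chromosome ends).
#'
#' @param calls output of [call_zygosity()], position-sorted per chromosome.
#' @param min_snps minimum informative SNPs per tract (default 3).
#' @return data.frame of tracts: chrom, state, first_snp, last_snp, n_snps,
#'   junction bounds `jl_lo`,`jl_hi`,`jr_lo`,`jr_hi`.
#' @export
segment_tracts <- function(calls, min_snps = 3) {
  out <- lapply(unique(calls$chrom), function(ch) {
    d <- calls[calls$chrom == ch, ]
    d <- d[order(d$pos), ]
    d <- d[d$call %in% c("het", "homY", "homS"), ]
    if (nrow(d) == 0L) return(NULL)
    st <- d$call
    # absorb sub-threshold runs iteratively
    repeat {
      r <- rle(st)
      short <- which(r$lengths < min_snps)
      if (length(short) == 0L || length(r$lengths) == 1L) break
      k <- short[which.min(r$lengths[short])]
      drop <- sum(r$lengths[seq_len(k - 1L)]) + seq_len(r$lengths[k])
      d <- d[-drop, ]
      st <- d$call
      if (nrow(d) == 0L) return(NULL)
    }
    if (nrow(d) < min_snps) return(NULL)
    r <- rle(st)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    data.frame(chrom = ch, state = r$values,
               first_snp = d$pos[starts], last_snp = d$pos[ends],
               n_snps = r$lengths,
               jl_lo = c(NA, d$pos[ends])[seq_along(starts)],
               jl_hi = d$pos[starts],
               jr_lo = d$pos[ends],
               jr_hi = c(d$pos[starts][-1L], NA),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, Filter(Negate(is.null), out))
  if (is.null(res)) {
    warning("no informative SNPs to segment")
    res <- data.frame(chrom = character(), state = character(),
                      first_snp = numeric(), last_snp = numeric(),
                      n_snps = integer(), jl_lo = numeric(), jl_hi = numeric(),
                      jr_lo = numeric(), jr_hi = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Detect copy-number variants from coverage ratios
#'
#' Per-SNP coverage is normalized by the genome-wide median (the 2x level),
#' lightly median-smoothed, and thresholded into copy states 1/2/3; runs of
#' a non-2 state with enough SNPs and length become calls.  Intervals are
#' reported with flanking-SNP (outer) bounds so the boundary error is at
#' most one inter-SNP gap.
#'
#' @param obs a `snp_obs` table (whole genome preferred, for the median).
#' @param thresholds see [default_thresholds()]: `cnv_lo` (< ratio 0.75 is
#'   1x), `cnv_hi` (> 1.25 is 3x), `min_cnv_len` (2 kb), `min_cnv_snps` (5),
#'   `cnv_smooth` (running-median window, 5).
#' @return data.frame of calls: chrom, start/end (in-state SNP extent),
#'   outer_lo/outer_hi (flanking-SNP bounds), copy_state, n_snps,
#'   mean_ratio.
#' @export
detect_cnv <- function(obs, thresholds = default_thresholds()) {
  th <- utils::modifyList(default_thresholds(), thresholds)
  med <- stats::median(obs$coverage)
  if (!is.finite(med) || med <= 0) stop_config("genome-wide median coverage is zero")
  out <- lapply(unique(obs$chrom), function(ch) {
    d <- obs[obs$chrom == ch, ]
    d <- d[order(d$pos), ]
    ratio <- d$coverage / med
    k <- th$cnv_smooth
    if (k > 1 && nrow(d) >= k) {
      ratio <- stats::runmed(ratio, k = k, endrule = "median")
    }
    state <- ifelse(ratio < th$cnv_lo, 1L, ifelse(ratio > th$cnv_hi, 3L, 2L))
    r <- rle(state)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    keep <- which(r$values != 2L & r$lengths >= th$min_cnv_snps)
    rows <- lapply(keep, function(k2) {
      i1 <- starts[k2]; i2 <- ends[k2]
      lo <- if (i1 > 1L) d$pos[i1 - 1L] else d$pos[i1]
      hi <- if (i2 < nrow(d)) d$pos[i2 + 1L] else d$pos[i2]
      data.frame(chrom = ch, start = d$pos[i1], end = d$pos[i2],
                 outer_lo = lo, outer_hi = hi,
                 copy_state = r$values[k2], n_snps = r$lengths[k2],
                 mean_ratio = mean(d$coverage[i1:i2] / med),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  res <- do.call(rbind, Filter(Negate(is.null), out))
  if (is.null(res)) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      outer_lo = numeric(), outer_hi = numeric(),
                      copy_state = integer(), n_snps = integer(),
                      mean_ratio = numeric(), stringsAsFactors = FALSE))
  }
  # length gate uses the flanking-SNP (outer) extent so short CNVs are not
  # lost to SNP-placement jitter; reported bounds are the in-state extent
  res <- res[res$outer_hi - res$outer_lo + 1 >= th$min_cnv_len, ]
  rownames(res) <- NULL
  res
}

#' Detect abrupt allele transitions
#'
#' Flags junctions where a homozygous-S run and a homozygous-Y run (either
#' order) are directly adjacent — no intervening heterozygous run — and no
#' non-2x CNV call overlaps the junction interval (the coverage stays
#' constant across the transition).
#'
#' @param tracts output of [segment_tracts()].
#' @param cnvs output of [detect_cnv()].
#' @return data.frame: chrom, left_state, right_state, junction bounds.
#' @export
detect_abrupt_transitions <- function(tracts, cnvs = NULL) {
  rows <- list()
  for (ch in unique(tracts$chrom)) {
    t <- tracts[tracts$chrom == ch, ]
    if (nrow(t) < 2L) next
    for (i in seq_len(nrow(t) - 1L)) {
      s1 <- t$state[i]; s2 <- t$state[i + 1L]
      if (!(s1 %in% c("homS", "homY") && s2 %in% c("homS", "homY") && s1 != s2)) next
      j_lo <- t$last_snp[i]; j_hi <- t$first_snp[i + 1L]
      if (!is.null(cnvs) && nrow(cnvs) > 0L) {
        ov <- cnvs$chrom == ch & cnvs$start <= j_hi & cnvs$end >= j_lo
        if (any(ov)) next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, left_state = s1, right_state = s2,
        j_lo = j_lo, j_hi = j_hi, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) res <- data.frame(chrom = character(), left_state = character(),
                                      right_state = character(), j_lo = numeric(),
                                      j_hi = numeric(), stringsAsFactors = FALSE)
  res
}

#' Genome-wide event catalog
#'
#' Runs segmentation, CNV calling and abrupt-transition detection over every
#' chromosome and assembles an event catalog: homozygous runs reaching a
#' chromosome end are terminal LOH (canonical BIR / reciprocal crossover);
#' interior homozygous runs are gene conversions (short < 15 kb vs long
#' >= 15 kb); adjacent opposite homozygous runs joined by an abrupt
#' transition are merged into a single event and flagged; hemizygous runs
#' fully explained by a 1x CNV call are reported as the CNV only.  Events
#' whose interior boundary falls in a configured repeat region (e.g. the
#' chromosome XII rDNA array) are flagged `in_repeat`.
#'
#' @param obs a `snp_obs` table covering the chromosomes of interest.
#' @param genome the `fs2_genome` metadata (panel, features).
#' @param thresholds see [default_thresholds()].
#' @return an `event_catalog` data.frame.
#' @export
genome_scan <- function(obs, genome, thresholds = default_thresholds()) {
  th <- utils::modifyList(default_thresholds(), thresholds)
  calls <- call_zygosity(obs, th)
  tracts <- segment_tracts(calls, th$min_snps)
  cnvs <- detect_cnv(obs, th)
  trans <- detect_abrupt_transitions(tracts, cnvs)
  events <- list()

  rep_feats <- genome$features[genome$features$kind == "repeat_region" &
                                 !grepl("^tel", genome$features$name), ]
  in_repeat <- function(ch, lo, hi) {
    any(rep_feats$chrom == ch & rep_feats$start <= hi & rep_feats$end >= lo)
  }

  for (ch in unique(tracts$chrom)) {
    t <- tracts[tracts$chrom == ch, ]
    pan <- genome$snp_panel[genome$snp_panel$chrom == ch, ]
    first_pos <- min(pan$pos); last_pos <- max(pan$pos)
    hom <- which(t$state %in% c("homS", "homY"))
    if (length(hom) == 0L) next
    # group hom runs linked by an abrupt transition
    grp <- integer(nrow(t)); gid <- 0L
    for (i in hom) {
      linked <- i > 1L && grp[i - 1L] > 0L &&
        any(trans$chrom == ch & trans$j_lo == t$last_snp[i - 1L] &
              trans$j_hi == t$first_snp[i])
      if (linked) grp[i] <- grp[i - 1L] else { gid <- gid + 1L; grp[i] <- gid }
    }
    for (gg in unique(grp[grp > 0L])) {
      idx <- which(grp == gg)
      lo <- t$first_snp[idx[1L]]; hi <- t$last_snp[idx[length(idx)]]
      touches_left <- lo == first_pos
      touches_right <- hi == last_pos
      abrupt <- length(idx) > 1L
      states <- t$state[idx]
      origin <- paste(sub("hom", "", states), collapse = ">")
      # hemizygous runs fully inside a 1x CNV are the CNV, not a conversion
      cnv_cover <- cnvs$chrom == ch & cnvs$copy_state == 1L &
        cnvs$start <= lo & cnvs$end >= hi
      if (!abrupt && !touches_left && !touches_right && any(cnv_cover)) next
      len <- hi - lo + 1
      type <- if (touches_left || touches_right) "terminal_LOH" else "interior_GC"
      # interior-side boundary junction (the event "start")
      if (type == "terminal_LOH" && touches_left) {
        b_lo <- t$jr_lo[idx[length(idx)]]; b_hi <- t$jr_hi[idx[length(idx)]]
      } else {
        b_lo <- t$jl_lo[idx[1L]]; b_hi <- t$jl_hi[idx[1L]]
      }
      events[[length(events) + 1L]] <- data.frame(
        chrom = ch, type = type, start = lo, end = hi, origin = origin,
        copy_state = 2L, length = len,
        length_class = if (type == "interior_GC")
          ifelse(len >= 15000, "long", "short") else NA_character_,
        abrupt = abrupt,
        in_repeat = in_repeat(ch, b_lo %||% lo, b_hi %||% lo),
        stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(nrow(cnvs))) {
    events[[length(events) + 1L]] <- data.frame(
      chrom = cnvs$chrom[i], type = "CNV", start = cnvs$start[i],
      end = cnvs$end[i], origin = NA_character_,
      copy_state = cnvs$copy_state[i],
      length = cnvs$end[i] - cnvs$start[i] + 1,
      length_class = NA_character_, abrupt = FALSE,
      in_repeat = in_repeat(cnvs$chrom[i], cnvs$start[i], cnvs$end[i]),
      stringsAsFactors = FALSE)
  }
  cat_df <- do.call(rbind, events)
  if (is.null(cat_df)) {
    cat_df <- data.frame(chrom = character(), type = character(),
                         start = numeric(), end = numeric(),
                         origin = character(), copy_state = integer(),
                         length = numeric(), length_class = character(),
                         abrupt = logical(), in_repeat = logical(),
                         stringsAsFactors = FALSE)
  }
  cat_df <- cat_df[order(match(cat_df$chrom, genome$chrom_table$chrom),
                         cat_df$start), ]
  rownames(cat_df) <- NULL
  structure(cat_df, class = c("event_catalog", "data.frame"),
            tracts = tracts, cnvs = cnvs, transitions = trans)
}

#' @export
print.event_catalog <- function(x, ...) {
  cat(sprintf("<event catalog: %d event(s)>\n", nrow(x)))
  if (nrow(x)) print.data.frame(x, ...)
  invisible(x)
}

#' Write an event catalog as TSV and BED
#'
#' The BED writer performs the 1-based-inclusive to 0-based-half-open
#' conversion at the boundary only.
#'
#' @param catalog an `event_catalog`.
#' @param tsv,bed output paths (either may be NULL).
#' @export
write_catalog <- function(catalog, tsv = NULL, bed = NULL) {
  if (!is.null(tsv)) {
    utils::write.table(as.data.frame(catalog), tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(bed) && nrow(catalog)) {
    bed_df <- data.frame(catalog$chrom, as.integer(catalog$start - 1),
                         as.integer(catalog$end),
                         paste0(catalog$type, ifelse(catalog$abrupt, "_abrupt", "")))
    utils::write.table(bed_df, bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else if (!is.null(bed)) {
    file.create(bed)
  }
  invisible(catalog)
}
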