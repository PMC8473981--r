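#' @title Forward simulation of repair mechanisms at FS2
#'
#' @description
#' Each simulator takes the baseline diploid plus a break specification and
#' returns the daughter-cell genome predicted by one repair mechanism,
#' together with an event record and the evidence group the mechanism should
#' produce: BIR with a late template switch or gap repair leave flanking SNPs
#' in coupling; half-crossover resolution of BIR leaves them in repulsion and
#' moves the S-specific right-arm terminus onto the Y homolog (+6 kb); gap
#' repair resolved by an ectopic half crossover disjoins the two arms of the
#' S homolog.  Mitotic segregation always delivers the daughter cell that
#' carries the recombinant molecules (the sectored-colony cell); the sister
#' cell is discarded.
#'
#' @name mechanisms
NULL

#' Coordinates of the FS2 fragile site edges
#'
#' @param genome an `fs2_genome` whose configuration declares an FS2
#'   fragile-site feature on the S homolog of chromosome III.
#' @return named vector: `prox` = last shared base centromere-proximal to
#'   FS2, `dist` = first shared base centromere-distal to it.
#' @export
fs2_edges <- function(genome) {
  f <- genome$features[genome$features$kind == "fragile_site", ]
  if (nrow(f) == 0L) stop_config("genome has no fragile_site feature")
  out <- c(prox = f$start[1] - 1, dist = f$end[1] + 1)
  attr(out, "chrom") <- f$chrom[1]
  out
}

rtrunc_exp <- function(n, mean, max) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rexp(n, rate = 1 / mean)
    out <- c(out, x[x <= max])
  }
  round(out[seq_len(n)])
}

#' Specify a double-strand break at FS2
#'
#' Draws 5' resection distances for the two break ends from a truncated
#' exponential (the two ends of the collapsed-fork DSB are separated in time,
#' so each may be resected independently before engaging a template).  In
#' zero-resection mode the conversion-tract ends fall exactly at FS2.
#'
#' @param genome an `fs2_genome`.
#' @param params list: `resect_mean` (bp, default 5000), `resect_max`
#'   (default 30000), `zero_resection` (default FALSE), `lag_model` flag.
#' @param seed RNG seed.
#' @return a `break_spec`: chrom, break position, proximal/distal tract ends.
#' @export
make_break <- function(genome, params = list(), seed = NULL) {
  edges <- fs2_edges(genome)
  chrom <- attr(edges, "chrom")
  sz <- baseline_sizes(genome, chrom)[["S"]]
  if (edges[["prox"]] < 1 || edges[["dist"]] > sz) {
    stop_config("break position outside chromosome")
  }
  zero <- isTRUE(params$zero_resection)
  rmean <- params$resect_mean %||% 5000
  rmax <- params$resect_max %||% 30000
  res <- if (zero) c(0, 0) else with_seed(seed, rtrunc_exp(2L, rmean, rmax))
  prox <- edges[["prox"]] - res[1]
  dist <- edges[["dist"]] + res[2]
  # resection must land in shared sequence for the junction to be mappable
  prox <- snap_shared(genome, chrom, prox, -1L)
  dist <- snap_shared(genome, chrom, dist, +1L)
  structure(list(chrom = chrom, break_pos = round(mean(edges)),
                 proximal_end = prox, distal_end = dist,
                 resect_proximal = res[1], resect_distal = res[2],
                 lag_model = isTRUE(params$lag_model)),
            class = "break_spec")
}

# Walk a position to the nearest shared base in the given direction.
snap_shared <- function(genome, chrom, pos, dir) {
  sz <- baseline_sizes(genome, chrom)[["S"]]
  pos <- max(1, min(sz, pos))
  while (pos >= 1 && pos <= sz && !in_shared(genome, chrom, pos)) pos <- pos + dir
  if (pos < 1 || pos > sz) stop_config("no shared sequence in that direction")
  pos
}

#' @export
print.break_spec <- function(x, ...) {
  cat(sprintf("<break at %s:%d; tract ends %d / %d (resection %d+%d bp)>\n",
              x$chrom, x$break_pos, x$proximal_end, x$distal_end,
              x$resect_proximal, x$resect_distal))
  invisible(x)
}

# Y-origin copy of [from_y..to_y]; `trim` removes that many bases of the
# first Y-only (Ty) segment inside the range (repeat content lost at a
# microhomology-mediated junction, invisible to the SNP panel).
ycopy_blocks <- function(genome, chrom, from_y, to_y, trim = 0) {
  if (to_y < from_y) return(list())
  if (trim <= 0) return(list(new_block("Y", chrom, from_y, to_y)))
  m <- seg_map(genome, chrom)
  yo <- m[m$type == "y_only" & !is.na(m$y_start) &
            m$y_start >= from_y & m$y_end <= to_y, ]
  if (nrow(yo) == 0L || trim > yo$len[1]) {
    stop_config("cannot trim %d bp of repeat content from the copied tract", trim)
  }
  list(new_block("Y", chrom, from_y, yo$y_start[1] - 1),
       new_block("Y", chrom, yo$y_start[1] + trim, to_y))
}

check_position <- function(genome, chrom, pos, what) {
  sz <- baseline_sizes(genome, chrom)[["S"]]
  if (pos < 1 || pos > sz) stop_config("%s beyond chromosome end", what)
  if (!in_shared(genome, chrom, pos)) {
    stop_config("%s (%d) must fall in shared (colinear) sequence", what, pos)
  }
  invisible(pos)
}

new_outcome <- function(genome, mechanism, chrom, invasion, terminus, truth_group,
                        template = "homolog", junction = list()) {
  for (mol in genome$molecules) {
    stopifnot(centromere_count(genome, mol) == 1L)
  }
  structure(list(genome = genome,
                 event = list(mechanism = mechanism, chrom = chrom,
                              invasion_pos = invasion, terminus_pos = terminus,
                              template = template, junction = junction),
                 truth_group = truth_group),
            class = "repair_outcome")
}

#' @export
print.repair_outcome <- function(x, ...) {
  cat(sprintf("<repair outcome: %s at %s:%d-%d, expected group %s>\n",
              x$event$mechanism, x$event$chrom, x$event$invasion_pos,
              x$event$terminus_pos, x$truth_group))
  invisible(x)
}

#' Simulate BIR with a noncanonical late template switch
#'
#' The invading S 3' end copies the Y homolog past the point at which BIR
#' normally becomes processive (>15 kb) and then disengages, re-annealing to
#' its own homolog at `switch_pos`.  The repaired S homolog carries an
#' interior Y-origin tract; the Y homolog is untouched, so flanking SNPs are
#' in coupling and dosage is (2,.) everywhere.
#'
#' @param genome baseline `fs2_genome`.
#' @param brk a `break_spec` from [make_break()].
#' @param switch_pos re-annealing position (S frame), centromere-distal to
#'   the invasion point.
#' @param capture bp of SNP-free repetitive sequence captured at the repair
#'   junction (0 = none).
#' @param trim bp of copied Ty content lost at the junction.
#' @param extra_tracts optional list of further `c(from, to)` switch
#'   intervals for composite events with multiple tracts.
#' @param seed unused (the operation is deterministic); kept for interface
#'   symmetry.
#' @return a `repair_outcome` with `truth_group = "Coupling"`.
#' @export
simulate_late_template_switch <- function(genome, brk, switch_pos, capture = 0,
                                          trim = 0, extra_tracts = NULL,
                                          seed = NULL) {
  chrom <- brk$chrom
  inv <- brk$proximal_end
  if (switch_pos < inv) stop_config("switch position is proximal to the invasion point")
  check_position(genome, chrom, switch_pos, "switch position")
  sz <- baseline_sizes(genome, chrom)[["S"]]
  tracts <- c(list(c(inv, switch_pos)), extra_tracts %||% list())
  blocks <- list()
  cur <- 1
  first <- TRUE
  for (tr in tracts) {
    a <- tr[1]; b <- tr[2]
    if (b > a) {
      check_position(genome, chrom, a, "tract start")
      check_position(genome, chrom, b, "tract end")
      blocks <- c(blocks, list(new_block("S", chrom, cur, a)))
      if (first && capture > 0) blocks <- c(blocks, list(filler_block(capture)))
      ya <- map_s_to_y(genome, chrom, a); yb <- map_s_to_y(genome, chrom, b)
      blocks <- c(blocks, ycopy_blocks(genome, chrom, ya + 1, yb,
                                       trim = if (first) trim else 0))
      cur <- b + 1
      first <- FALSE
    }
  }
  blocks <- c(blocks, list(new_block("S", chrom, cur, sz)))
  m1 <- new_molecule(paste0(chrom, "_S.rep"), blocks)
  g2 <- set_molecules(genome, structure(list(m1, NULL),
                                        names = c(paste0(chrom, "_S.rep"),
                                                  paste0(chrom, "_S"))))
  new_outcome(g2, "late_template_switch", chrom, inv, switch_pos, "Coupling",
              junction = list(capture = capture, trim = trim))
}

#' Simulate BIR resolved by half crossover
#'
#' Endonuclease cleavage of the migrating D-loop at `cleavage_pos` fuses the
#' invading S chromosome to the distal portion of the Y template and
#' transfers the break to the Y homolog, which is then repaired by a second
#' BIR off the remaining S copy.  The daughter genome carries
#' `S[1..invasion] + Y[invasion..telomere]` and
#' `Y[1..cleavage] + S[cleavage..telomere]`; SNPs between invasion and
#' cleavage are homozygous Y, flanking SNPs are in repulsion, and the
#' Y-centromere molecule gains the S-specific right-arm terminus (+6 kb on
#' the baseline configuration).
#'
#' @inheritParams simulate_late_template_switch
#' @param cleavage_pos D-loop cleavage position (S frame), at or distal to
#'   the invasion point.
#' @return a `repair_outcome` with `truth_group = "Repulsion"`.
#' @export
simulate_half_crossover <- function(genome, brk, cleavage_pos, capture = 0,
                                    trim = 0, seed = NULL) {
  chrom <- brk$chrom
  inv <- brk$proximal_end
  sz <- baseline_sizes(genome, chrom)
  if (cleavage_pos < inv) stop_config("cleavage position is proximal to the invasion point")
  if (cleavage_pos > sz[["S"]]) stop_config("cleavage beyond the telomere")
  check_position(genome, chrom, cleavage_pos, "cleavage position")
  inv_y <- map_s_to_y(genome, chrom, inv)
  clv_y <- map_s_to_y(genome, chrom, cleavage_pos)
  m1 <- new_molecule(paste0(chrom, "_S.rep"), c(
    list(new_block("S", chrom, 1, inv)),
    if (capture > 0) list(filler_block(capture)),
    ycopy_blocks(genome, chrom, inv_y + 1, sz[["Y"]], trim = trim)))
  m2 <- new_molecule(paste0(chrom, "_Y.rep"), list(
    if (clv_y >= 1) new_block("Y", chrom, 1, clv_y),
    if (cleavage_pos < sz[["S"]]) new_block("S", chrom, cleavage_pos + 1, sz[["S"]])))
  g2 <- set_molecules(genome, structure(
    list(m1, m2, NULL, NULL),
    names = c(paste0(chrom, "_S.rep"), paste0(chrom, "_Y.rep"),
              paste0(chrom, "_S"), paste0(chrom, "_Y"))))
  new_outcome(g2, "half_crossover", chrom, inv, cleavage_pos, "Repulsion",
              junction = list(capture = capture, trim = trim))
}

#' Simulate gap repair of a two-end DSB
#'
#' The two ends of the FS2 break are separated in time and engage templates
#' independently.  Modes:
#' \describe{
#'   \item{recapture}{the extended first end is re-captured by the second
#'     end: interior Y tract, coupling.}
#'   \item{dual_bir_anneal}{both ends run independent BIR on the Y homolog
#'     and the nascent strands anneal: interior Y tract spanning the gap,
#'     coupling.}
#'   \item{dual_bir_half_crossover}{the centromere-distal D-loop is cleaved:
#'     adjacent homozygous-Y and homozygous-S runs with no intervening
#'     heterozygous SNP and constant (2x) dosage — an abrupt allele
#'     transition, not an LTGC.}
#'   \item{dual_bir_ectopic}{the distal end initiates BIR in a repetitive
#'     element of a nonhomologous chromosome and is resolved by a
#'     centromere-retaining half crossover: the left and right arms of the
#'     S homolog end up on different molecules (Disjoined).}
#' }
#'
#' @inheritParams simulate_late_template_switch
#' @param mode one of `"recapture"`, `"dual_bir_anneal"`,
#'   `"dual_bir_half_crossover"`, `"dual_bir_ectopic"`.
#' @param params mode parameters: `terminus` (tract end / cleavage, S frame);
#'   for `dual_bir_ectopic`: `attach_chrom` (nonhomologous chromosome with a
#'   configured repeat tip), `capture_left` / `capture_trans` (bp of captured
#'   repetitive filler on the two product molecules).
#' @return a `repair_outcome`.
#' @export
simulate_gap_repair <- function(genome, brk, mode, params = list(), seed = NULL) {
  chrom <- brk$chrom
  inv <- brk$proximal_end
  bd <- brk$distal_end
  sz <- baseline_sizes(genome, chrom)
  modes <- c("recapture", "dual_bir_anneal", "dual_bir_half_crossover",
             "dual_bir_ectopic")
  if (!mode %in% modes) stop_config("unknown gap-repair mode '%s'", mode)
  capture <- params$capture %||% 0
  trim <- params$trim %||% 0

  if (mode %in% c("recapture", "dual_bir_anneal")) {
    term <- params$terminus %||% bd
    if (term < bd) stop_config("terminus proximal to the distal break end")
    out <- simulate_late_template_switch(genome, brk, term, capture = capture,
                                         trim = trim)
    out$event$mechanism <- paste0("gap_repair_", mode)
    out$truth_group <- "Coupling"
    return(out)
  }

  if (mode == "dual_bir_half_crossover") {
    term <- params$terminus %||% bd
    check_position(genome, chrom, term, "cleavage position")
    term_y <- map_s_to_y(genome, chrom, term)
    inv_y <- map_s_to_y(genome, chrom, inv)
    # product A: S with an interior Y-copied tract ending at the cleavage;
    # product B: Y fused to an S copy of the distal arm.
    mA <- new_molecule(paste0(chrom, "_S.rep"), c(
      list(new_block("S", chrom, 1, inv)),
      ycopy_blocks(genome, chrom, inv_y + 1, term_y, trim = trim),
      list(new_block("S", chrom, term + 1, sz[["S"]]))))
    mB <- new_molecule(paste0(chrom, "_Y.rep"), list(
      new_block("Y", chrom, 1, term_y),
      new_block("S", chrom, term + 1, sz[["S"]])))
    g2 <- set_molecules(genome, structure(
      list(mA, mB, NULL, NULL),
      names = c(paste0(chrom, "_S.rep"), paste0(chrom, "_Y.rep"),
                paste0(chrom, "_S"), paste0(chrom, "_Y"))))
    return(new_outcome(g2, "gap_repair_dual_bir_half_crossover", chrom, inv,
                       term, "AbruptTransition"))
  }

  # dual_bir_ectopic
  attach_chrom <- params$attach_chrom
  if (is.null(attach_chrom)) {
    stop_config("dual_bir_ectopic requires a configured nonhomologous repeat target")
  }
  tipf <- genome$features[genome$features$chrom == attach_chrom &
                            genome$features$kind == "repeat_region" &
                            grepl("^telL", genome$features$name), ]
  if (nrow(tipf) == 0L) {
    stop_config("no repeat_region target configured on %s", attach_chrom)
  }
  tip <- tipf$end[1]
  inv_y <- map_s_to_y(genome, chrom, inv)
  bd_y <- map_s_to_y(genome, chrom, bd)
  asz <- baseline_sizes(genome, attach_chrom)[["S"]]
  cap_l <- params$capture_left %||% 0
  cap_t <- params$capture_trans %||% 0
  mL <- new_molecule(paste0(chrom, "_SL"), c(
    list(new_block("S", chrom, 1, inv)),
    ycopy_blocks(genome, chrom, inv_y + 1, bd_y - 1, trim = trim),
    if (cap_l > 0) list(filler_block(cap_l))))
  mT <- new_molecule(paste0(chrom, "_ST"), c(
    list(new_block("S", chrom, bd, sz[["S"]])),
    if (cap_t > 0) list(filler_block(cap_t)),
    list(new_block("S", attach_chrom, tip + 1, asz))))
  g2 <- set_molecules(genome, structure(
    list(mL, mT, NULL, NULL),
    names = c(paste0(chrom, "_SL"), paste0(chrom, "_ST"),
              paste0(chrom, "_S"), paste0(attach_chrom, "_S"))))
  new_outcome(g2, "gap_repair_dual_bir_ectopic", chrom, inv, bd, "Disjoined",
              template = c("homolog", attach_chrom),
              junction = list(capture_left = cap_l, capture_trans = cap_t))
}

#' Simulate canonical BIR / reciprocal crossover (terminal LOH)
#'
#' Produces a homozygous run from `start_pos` through the nearer telomere at
#' constant 2x dosage.  With `abrupt_switch`, the copied origin flips at the
#' switch point with no intervening heterozygous SNP — the signature of gap
#' repair resolved by half crossover seen among unselected events.
#'
#' @param genome an `fs2_genome`.
#' @param chrom chromosome.
#' @param start_pos interior boundary of the event (S frame); the event
#'   extends from here through the telomere of the arm `start_pos` is on.
#' @param which_origin `"Y"` or `"S"`: the haplotype that becomes homozygous
#'   at the boundary.
#' @param abrupt_switch optional position between `start_pos` and the
#'   telomere at which the homozygous origin flips to the other haplotype.
#' @param seed unused; interface symmetry.
#' @return a `repair_outcome` with truth label `TerminalLOH` (or
#'   `AbruptTransition` when `abrupt_switch` is set).
#' @export
simulate_terminal_loh <- function(genome, chrom, start_pos, which_origin = "Y",
                                  abrupt_switch = NULL, seed = NULL) {
  which_origin <- normalize_hap(which_origin)
  sz <- baseline_sizes(genome, chrom)
  cen <- genome$chrom_table$centromere[genome$chrom_table$chrom == chrom]
  if (start_pos <= 1 || start_pos >= sz[["S"]]) {
    stop_config("terminal LOH start must be interior to the chromosome")
  }
  check_position(genome, chrom, start_pos, "LOH start")
  right <- start_pos > cen
  b <- start_pos; by <- map_s_to_y(genome, chrom, b)
  idS <- paste0(chrom, "_S"); idY <- paste0(chrom, "_Y")
  molS <- genome$molecules[[idS]]; molY <- genome$molecules[[idY]]
  if (is.null(abrupt_switch)) {
    if (right) {
      if (which_origin == "Y") {
        molS <- new_molecule(idS, list(new_block("S", chrom, 1, b),
                                       new_block("Y", chrom, by + 1, sz[["Y"]])))
      } else {
        molY <- new_molecule(idY, list(new_block("Y", chrom, 1, by),
                                       new_block("S", chrom, b + 1, sz[["S"]])))
      }
    } else {
      if (which_origin == "Y") {
        molS <- new_molecule(idS, list(new_block("Y", chrom, 1, by),
                                       new_block("S", chrom, b + 1, sz[["S"]])))
      } else {
        molY <- new_molecule(idY, list(new_block("S", chrom, 1, b),
                                       new_block("Y", chrom, by + 1, sz[["Y"]])))
      }
    }
    g2 <- set_molecules(genome, structure(list(molS, molY), names = c(idS, idY)))
    return(new_outcome(g2, "terminal_loh", chrom, start_pos,
                       if (right) sz[["S"]] else 1, "TerminalLOH"))
  }
  t <- abrupt_switch
  check_position(genome, chrom, t, "abrupt switch position")
  ty <- map_s_to_y(genome, chrom, t)
  if (right) {
    if (t <= b) stop_config("switch must be distal to the event start")
    # het | homS [b..t] | homY [t..telomere]
    molS <- new_molecule(idS, list(new_block("S", chrom, 1, t),
                                   new_block("Y", chrom, ty + 1, sz[["Y"]])))
    molY <- new_molecule(idY, list(new_block("Y", chrom, 1, by),
                                   new_block("S", chrom, b + 1, t),
                                   new_block("Y", chrom, ty + 1, sz[["Y"]])))
  } else {
    if (t >= b) stop_config("switch must be distal (telomere-ward) to the event start")
    # homY [1..t] | homS [t..b] | het
    molS <- new_molecule(idS, list(new_block("Y", chrom, 1, ty),
                                   new_block("S", chrom, t + 1, sz[["S"]])))
    molY <- new_molecule(idY, list(new_block("Y", chrom, 1, ty),
                                   new_block("S", chrom, t + 1, b),
                                   new_block("Y", chrom, by + 1, sz[["Y"]])))
  }
  g2 <- set_molecules(genome, structure(list(molS, molY), names = c(idS, idY)))
  new_outcome(g2, "terminal_loh_abrupt", chrom, start_pos, t, "AbruptTransition")
}

#' Overlay an interior gene conversion on any chromosome
#'
#' Replaces `[start..end]` of one homolog with a copy of the other haplotype
#' (a short- or long-tract conversion with heterozygous flanks), used for the
#' unselected interior events seen genome-wide.
#'
#' @param genome an `fs2_genome`.
#' @param chrom chromosome.
#' @param start,end tract bounds (S frame).
#' @param which_origin haplotype that becomes homozygous inside the tract.
#' @return the modified genome.
#' @export
overlay_gene_conversion <- function(genome, chrom, start, end, which_origin = "Y") {
  which_origin <- normalize_hap(which_origin)
  check_position(genome, chrom, start, "tract start")
  check_position(genome, chrom, end, "tract end")
  sz <- baseline_sizes(genome, chrom)
  ys <- map_s_to_y(genome, chrom, start); ye <- map_s_to_y(genome, chrom, end)
  if (which_origin == "Y") {
    id <- paste0(chrom, "_S")
    mol <- new_molecule(id, list(new_block("S", chrom, 1, start - 1),
                                 new_block("Y", chrom, ys, ye),
                                 new_block("S", chrom, end + 1, sz[["S"]])))
  } else {
    id <- paste0(chrom, "_Y")
    mol <- new_molecule(id, list(new_block("Y", chrom, 1, ys - 1),
                                 new_block("S", chrom, start, end),
                                 new_block("Y", chrom, ye + 1, sz[["Y"]])))
  }
  set_molecules(genome, structure(list(mol), names = id))
}

#' Apply a copy-number change to one homolog
#'
#' `copy_state = 3` inserts a tandem duplicate of the interval into the
#' carrier molecule; `copy_state = 1` deletes the interval from it.  The
#' junction descriptor (microhomology parameters) is recorded in the
#' genome's CNV log.
#'
#' @param genome an `fs2_genome`.
#' @param chrom chromosome.
#' @param interval `c(start, end)` in the S frame; a zero-length interval
#'   (`end < start`) leaves the genome unchanged.
#' @param copy_state 1 (deletion) or 3 (duplication).
#' @param molecule_id molecule to modify (default: the S homolog of `chrom`).
#' @param microhomology optional list(mh, island) describing the junction.
#' @return the modified `fs2_genome`.
#' @export
apply_cnv <- function(genome, chrom, interval, copy_state,
                      molecule_id = NULL, microhomology = NULL) {
  if (!copy_state %in% c(1, 3)) stop_config("copy_state must be 1 or 3")
  i1 <- interval[1]; i2 <- interval[2]
  if (is.na(i1) || is.na(i2) || i2 < i1) return(genome)
  molecule_id <- molecule_id %||% paste0(chrom, "_S")
  mol <- genome$molecules[[molecule_id]]
  if (is.null(mol)) stop_config("no molecule '%s'", molecule_id)
  cen <- genome$chrom_table$centromere[genome$chrom_table$chrom == chrom]
  if (copy_state == 1 && cen >= i1 && cen <= i2) {
    stop_config("deletion interval crosses the centromere (acentric/dicentric not modeled)")
  }
  y1 <- map_s_to_y(genome, chrom, i1); y2 <- map_s_to_y(genome, chrom, i2)
  b <- mol$blocks
  out <- list()
  done_dup <- FALSE
  for (k in seq_len(nrow(b))) {
    blk <- b[k, ]
    rng <- if (blk$origin == "S") c(i1, i2) else if (blk$origin == "Y") c(y1, y2) else c(NA, NA)
    if (blk$source_chrom != chrom || is.na(rng[1]) ||
        blk$end < rng[1] || blk$start > rng[2]) {
      out <- c(out, list(blk)); next
    }
    os <- max(blk$start, rng[1]); oe <- min(blk$end, rng[2])
    if (copy_state == 1) {
      if (blk$start < os) out <- c(out, list(new_block(blk$origin, chrom, blk$start, os - 1)))
      if (blk$end > oe) out <- c(out, list(new_block(blk$origin, chrom, oe + 1, blk$end)))
    } else {
      if (os > rng[1] || oe < rng[2]) {
        stop_config("duplication interval must lie within one block of %s", molecule_id)
      }
      out <- c(out, list(new_block(blk$origin, chrom, blk$start, oe),
                         new_block(blk$origin, chrom, os, oe)))
      if (blk$end > oe) out <- c(out, list(new_block(blk$origin, chrom, oe + 1, blk$end)))
      done_dup <- TRUE
    }
  }
  if (copy_state == 3 && !done_dup) {
    stop_config("duplication interval not covered by molecule '%s'", molecule_id)
  }
  mol2 <- new_molecule(molecule_id, out)
  g2 <- set_molecules(genome, structure(list(mol2), names = molecule_id))
  g2$cnv_log <- c(genome$cnv_log, list(list(
    chrom = chrom, interval = c(i1, i2), copy_state = copy_state,
    molecule_id = molecule_id, microhomology = microhomology)))
  g2
}

#' Draw a random LTGC-scale event for one mechanism
#'
#' Samples a break (resection from the truncated exponential) and
#' mechanism-specific positions in shared sequence, conditioned on the
#' selection criterion of the screen: the resulting conversion tract spans
#' at least `min_tract` (LTGC events are >= 15 kb by definition).  Used by
#' the simulator-classifier round-trip checks.
#'
#' @param genome baseline `fs2_genome`.
#' @param mechanism one of `"late_template_switch"`, `"half_crossover"`,
#'   `"gap_repair_recapture"`, `"gap_repair_dual_bir_anneal"`,
#'   `"gap_repair_dual_bir_ectopic"`.
#' @param seed RNG seed.
#' @param min_tract minimum tract span in bp (default 15000).
#' @return a `repair_outcome`.
#' @export
sample_mechanism_outcome <- function(genome, mechanism, seed = NULL,
                                     min_tract = 15000) {
  chrom <- attr(fs2_edges(genome), "chrom")
  szS <- baseline_sizes(genome, chrom)[["S"]]
  pan <- genome$snp_panel[genome$snp_panel$chrom == chrom, ]
  distal_cap <- max(pan$pos) - 5000   # keep a phaseable distal flank
  with_seed(seed, {
    for (attempt in 1:50) {
      brk <- make_break(genome)
      inv <- brk$proximal_end
      pick_distal <- function(lo) {
        lo <- max(lo, fs2_edges(genome)[["dist"]])
        snap_shared(genome, chrom,
                    round(stats::runif(1, lo, distal_cap)), +1L)
      }
      out <- switch(mechanism,
        late_template_switch = {
          sw <- pick_distal(inv + min_tract)
          simulate_late_template_switch(genome, brk, sw)
        },
        half_crossover = {
          clv <- pick_distal(inv + min_tract)
          simulate_half_crossover(genome, brk, clv)
        },
        gap_repair_recapture = {
          term <- pick_distal(brk$distal_end + min_tract / 2)
          simulate_gap_repair(genome, brk, "recapture", list(terminus = term))
        },
        gap_repair_dual_bir_anneal =
          simulate_gap_repair(genome, brk, "dual_bir_anneal"),
        gap_repair_dual_bir_ectopic = {
          brk$distal_end <- pick_distal(brk$distal_end + min_tract / 2)
          # keep the PAT1 locus on the translocated right arm
          pat1 <- feature_by_name(genome, "PAT1")
          if (brk$distal_end >= pat1$start - 2000) next
          simulate_gap_repair(genome, brk, "dual_bir_ectopic",
                              list(attach_chrom = sample(c("chrII", "chrV",
                                                           "chrXIII"), 1)))
        },
        stop_config("unknown mechanism '%s'", mechanism))
      z <- zygosity_map(out$genome, chrom)
      n_hom <- sum(z$copies_Y == 2 & z$copies_total == 2)
      if (n_hom >= 10) return(out)
    }
    stop_config("could not sample an LTGC-scale %s event", mechanism)
  })
}
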