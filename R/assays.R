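#' @title In-silico physical assays
#'
#' @description
#' Molecule-level counterparts of the wet-lab assays: CHEF karyotype band
#' profiles (one band per molecule, sized by total block length), Southern
#' hybridization of a probe locus against the profile, band isolability at a
#' gel resolution, PCR-RFLP zygosity typing of single molecules, SNP-phasing
#' of the heterozygous flanks of a conversion tract on isolated homologs,
#' and exact-overlap microhomology analysis of chimeric junction sequences.
#'
#' @name assays
NULL

#' CHEF band profile of a genome
#'
#' @param genome an `fs2_genome`.
#' @return a `band_profile` data.frame (`molecule_id`, `size`), sorted by
#'   decreasing size.
#' @export
chef_band_profile <- function(genome) {
  if (length(genome$molecules) == 0L) stop_config("genome has no molecules")
  d <- data.frame(
    molecule_id = vapply(genome$molecules, `[[`, "", "molecule_id"),
    size = vapply(genome$molecules, chromosome_length, 0),
    stringsAsFactors = FALSE)
  d <- d[order(-d$size), ]
  rownames(d) <- NULL
  structure(d, class = c("band_profile", "data.frame"))
}

#' Southern hybridization of a probe against a band profile
#'
#' @param profile a `band_profile` from [chef_band_profile()].
#' @param genome the genome that produced the profile.
#' @param probe_name name of a configured `probe_locus` feature.
#' @return the subset of `profile` whose molecules carry the probe locus.
#' @export
southern <- function(profile, genome, probe_name) {
  f <- feature_by_name(genome, probe_name)
  if (f$kind != "probe_locus") stop_config("'%s' is not a probe locus", probe_name)
  hit <- vapply(profile$molecule_id, function(id) {
    mol <- genome$molecules[[id]]
    !is.null(mol) && molecule_covers_interval(genome, mol, f$chrom, f$start, f$end)
  }, TRUE)
  out <- profile[hit, ]
  rownames(out) <- NULL
  out
}

#' Band isolability at a gel resolution
#'
#' A band can be excised cleanly iff no other band of the profile lies
#' within `resolution` bp of it.
#'
#' @param profile a `band_profile` (or any data.frame with `molecule_id`,
#'   `size`).
#' @param target_ids molecules to test (default: all).
#' @param resolution minimum separable size difference in bp (default 10 kb).
#' @return named logical vector per target.
#' @export
isolable <- function(profile, target_ids = NULL, resolution = 10000) {
  stopifnot(resolution > 0)
  target_ids <- target_ids %||% profile$molecule_id
  out <- vapply(target_ids, function(id) {
    sz <- profile$size[profile$molecule_id == id]
    if (length(sz) == 0L) return(NA)
    others <- profile$size[profile$molecule_id != id]
    all(abs(others - sz) >= resolution)
  }, TRUE)
  names(out) <- target_ids
  out
}

#' Which allele a molecule carries at a SNP
#'
#' @param molecule an `fs2_molecule`.
#' @param snp one row of the genome's SNP panel (or a position via
#'   `snp = list(chrom =, pos =, pos_Y =)`).
#' @param genome the `fs2_genome` (for coordinate maps).
#' @return `"S"`, `"Y"`, `"S/Y"` (both copies present within one molecule),
#'   or `"PCR_FAIL"` when the locus is absent.
#' @export
molecule_allele_at <- function(molecule, snp, genome) {
  posY <- snp$pos_Y %||% map_s_to_y(genome, snp$chrom, snp$pos)
  b <- molecule$blocks
  hasS <- any(b$origin == "S" & b$source_chrom == snp$chrom &
                b$start <= snp$pos & b$end >= snp$pos)
  hasY <- !is.na(posY) && any(b$origin == "Y" & b$source_chrom == snp$chrom &
                                b$start <= posY & b$end >= posY)
  if (hasS && hasY) "S/Y" else if (hasS) "S" else if (hasY) "Y" else "PCR_FAIL"
}

#' In-silico PCR-RFLP at an assayed SNP
#'
#' Amplifies the SNP locus from a molecule (or from the whole diploid) and
#' digests with the assay's enzyme: the cutting allele yields the cut
#' fragment lengths, the other allele the single uncut amplicon; a
#' heterozygous template yields the union of both (the "three band sizes"
#' case).  `PCR_FAIL` is returned when the locus is absent from the
#' molecule.
#'
#' @param x an `fs2_molecule`, or an `fs2_genome` (unseparated diploid).
#' @param snp a row of the SNP panel carrying an assay spec (see
#'   [assay_snp()]).
#' @param genome required when `x` is a molecule.
#' @return numeric vector of fragment lengths (bp), or the string
#'   `"PCR_FAIL"`.
#' @export
pcr_rflp <- function(x, snp, genome = NULL) {
  if (is.na(snp$amplicon %||% NA)) stop_config("SNP has no RFLP assay spec")
  cuts <- snp$cut_fragments[[1]]
  frag_for <- function(allele) {
    if (allele == snp$cutting_allele) cuts else snp$amplicon
  }
  if (inherits(x, "fs2_genome")) {
    alleles <- unique(unlist(lapply(x$molecules, function(m) {
      a <- molecule_allele_at(m, snp, x)
      if (a == "S/Y") c("S", "Y") else a
    })))
    alleles <- setdiff(alleles, "PCR_FAIL")
    if (length(alleles) == 0L) return("PCR_FAIL")
    return(sort(unique(unlist(lapply(alleles, frag_for))), decreasing = TRUE))
  }
  stopifnot(inherits(x, "fs2_molecule"), !is.null(genome))
  a <- molecule_allele_at(x, snp, genome)
  if (a == "PCR_FAIL") return("PCR_FAIL")
  alleles <- if (a == "S/Y") c("S", "Y") else a
  sort(unique(unlist(lapply(alleles, frag_for))), decreasing = TRUE)
}

#' Retrieve an assayed SNP row from the panel
#'
#' @param genome an `fs2_genome`.
#' @param pos position (default: the first assayed SNP, the diagnostic
#'   left-arm marker).
#' @export
assay_snp <- function(genome, pos = NULL) {
  p <- genome$snp_panel[!is.na(genome$snp_panel$amplicon), ]
  if (nrow(p) == 0L) stop_config("no assayed SNPs in the panel")
  if (!is.null(pos)) p <- p[p$pos == pos, ]
  if (nrow(p) == 0L) stop_config("no assay at that position")
  p[1, ]
}

#' Phase the heterozygous flanks of a conversion tract
#'
#' Emulates the gel-based phasing workflow: the chromosome III bands are
#' located by Southern hybridization; if they can be excised individually,
#' each isolated molecule is typed at the centromere-proximal diagnostic SNP
#' (to identify the S vs Y homolog) and at the nearest informative SNP on
#' each flank of the tract.  Same origin on both flanks of each homolog is
#' coupling; opposite origins on each homolog is repulsion; failure of the
#' distal-flank PCR is the atypical signature of a disjoined chromosome; and
#' bands too close in size to separate give no determination.
#'
#' @param genome the (rearranged) `fs2_genome`.
#' @param tract a tract row from [segment_tracts()] (interior homozygous
#'   tract on chromosome III).
#' @param resolution gel resolution in bp (default 10 kb).
#' @param separable optional logical override of the isolability rule (gel
#'   behaviour of a given strain; observed separability is not a clean
#'   function of the size gap).
#' @return a `phasing_call`: value in \{coupling, repulsion,
#'   atypical_pcr_failure, not_determined\} plus per-molecule support.
#' @export
phase_flanks <- function(genome, tract, resolution = 10000, separable = NULL) {
  chrom <- tract$chrom
  pan <- genome$snp_panel[genome$snp_panel$chrom == chrom, ]
  if (tract$first_snp <= min(pan$pos) || tract$last_snp >= max(pan$pos)) {
    stop_config("tract touches a chromosome end; no flank to phase")
  }
  profile <- chef_band_profile(genome)
  bands <- unique(rbind(southern(profile, genome, "CHA1"),
                        southern(profile, genome, "PAT1")))
  if (is.null(separable)) {
    sz <- bands$size
    separable <- all(vapply(seq_along(sz), function(i)
      all(abs(sz[-i] - sz[i]) >= resolution), TRUE))
  }
  if (!isTRUE(separable)) {
    return(structure(list(value = "not_determined", support = NULL),
                     class = "phasing_call"))
  }
  diag_snp <- assay_snp(genome)
  prox <- pan[pan$pos < tract$first_snp, ]
  dist <- pan[pan$pos > tract$last_snp, ]
  prox_snp <- prox[which.max(prox$pos), ]
  dist_snp <- dist[which.min(dist$pos), ]
  support <- lapply(bands$molecule_id, function(id) {
    mol <- genome$molecules[[id]]
    list(molecule_id = id,
         diagnostic = molecule_allele_at(mol, diag_snp, genome),
         proximal = molecule_allele_at(mol, prox_snp, genome),
         distal = molecule_allele_at(mol, dist_snp, genome))
  })
  # only molecules that amplify the proximal flank carry the left arm/tract
  informative <- Filter(function(s) s$proximal %in% c("S", "Y"), support)
  value <- if (any(vapply(informative, function(s) s$distal == "PCR_FAIL", TRUE))) {
    "atypical_pcr_failure"
  } else {
    pairs <- vapply(informative, function(s) paste0(s$proximal, s$distal), "")
    if (length(pairs) >= 2L && all(pairs %in% c("SS", "YY")) &&
        length(unique(pairs)) == 2L) "coupling"
    else if (length(pairs) >= 2L && all(pairs %in% c("SY", "YS")) &&
             length(unique(pairs)) == 2L) "repulsion"
    else "not_determined"
  }
  structure(list(value = value, support = support), class = "phasing_call")
}

#' @export
print.phasing_call <- function(x, ...) {
  cat(sprintf("<phasing: %s>\n", x$value))
  invisible(x)
}

# ---- microhomology ---------------------------------------------------------

str_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

lcp_len <- function(a, b) {
  n <- min(length(a), length(b))
  if (n == 0L) return(0L)
  neq <- which(a[seq_len(n)] != b[seq_len(n)])
  if (length(neq) == 0L) n else neq[1L] - 1L
}

#' Measure microhomology at a chimeric junction
#'
#' Decomposes `junction` into a prefix of `parent_A` and a suffix of
#' `parent_B`; the maximal exact overlap shared by both parents at the
#' breakpoint is the microhomology.  Nearby "islands" of identity (>= 2
#' exact-matching bases between the parents, aligned at the breakpoint,
#' within `window` bases on either side) are reported separately.
#'
#' @param junction,parent_A,parent_B DNA strings (or a `junction_fixture`
#'   passed as the single first argument).
#' @param window island search window in bases (default 10).
#' @return list: `mh_len`, `islands` (data.frame side/offset/length).
#' @export
find_microhomology <- function(junction, parent_A = NULL, parent_B = NULL,
                               window = 10) {
  if (inherits(junction, "junction_fixture")) {
    parent_A <- junction$parent_A
    parent_B <- junction$parent_B
    junction <- junction$junction
  }
  j <- str_chars(junction); a <- str_chars(parent_A); b <- str_chars(parent_B)
  pA <- lcp_len(j, a)
  sB <- lcp_len(rev(j), rev(b))
  if (pA + sB < length(j)) {
    stop_config("junction does not decompose into a parent-A prefix and a parent-B suffix")
  }
  mh <- pA + sB - length(j)
  # breakpoint at the rightmost admissible split: A position pA aligns with
  # B position bB
  bB <- length(b) - sB + mh
  match_at <- function(da) {
    ia <- pA + da; ib <- bB + da
    ia >= 1 && ia <= length(a) && ib >= 1 && ib <= length(b) && a[ia] == b[ib]
  }
  islands <- list()
  for (side in c(-1L, 1L)) {
    offs <- if (side < 0L) -(mh + seq_len(window)) else seq_len(window)
    m <- vapply(offs, match_at, TRUE)
    r <- rle(m)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= 2L)) {
      islands[[length(islands) + 1L]] <- data.frame(
        side = if (side < 0L) "left" else "right",
        offset = starts[k], length = r$lengths[k], stringsAsFactors = FALSE)
    }
  }
  islands <- do.call(rbind, islands) %||%
    data.frame(side = character(), offset = integer(), length = integer(),
               stringsAsFactors = FALSE)
  list(mh_len = mh, islands = islands)
}
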