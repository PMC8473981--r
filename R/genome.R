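#' @title Block-structured diploid genome model
#'
#' @description
#' The experimental diploid is represented as a set of chromosome-sized
#' molecules, each an ordered list of haplotype-origin blocks.  The two
#' haplotypes ("S", S288c-related, and "Y", YJM789-related) are colinear
#' except where the configuration declares haplotype-specific segments
#' (Ty elements, the hemizygous fragile site FS2, the S-specific right-arm
#' terminus of chromosome III).  SNP markers live in shared (colinear)
#' sequence only; their coordinates are stored in the S-haplotype frame and
#' mapped to the Y frame through the segment map.
#'
#' @name genome_model
NULL

SEG_TYPES <- c("shared", "s_only", "y_only")
SNP_EXCLUDE_KINDS <- c("Ty_element", "repeat_region", "fragile_site", "centromere")

new_block <- function(origin, source_chrom, start, end) {
  stopifnot(length(start) == 1L, length(end) == 1L)
  if (end < start) stop_config("block with end < start (%d < %d)", end, start)
  data.frame(origin = origin, source_chrom = source_chrom,
             start = as.numeric(start), end = as.numeric(end),
             len = as.numeric(end - start + 1), stringsAsFactors = FALSE)
}

filler_block <- function(len, label = "captured_repeat") {
  if (len <= 0) return(NULL)
  data.frame(origin = "filler", source_chrom = label,
             start = 1, end = as.numeric(len), len = as.numeric(len),
             stringsAsFactors = FALSE)
}

new_molecule <- function(id, blocks) {
  blocks <- do.call(rbind, Filter(Negate(is.null), blocks))
  rownames(blocks) <- NULL
  structure(list(molecule_id = id, blocks = blocks), class = "fs2_molecule")
}

#' Physical length of a molecule
#'
#' Sum of the lengths of the haplotype blocks making up a chromosome-sized
#' molecule (the quantity a CHEF gel sizes).
#'
#' @param structure an `fs2_molecule`.
#' @return length in bp.
#' @export
chromosome_length <- function(structure) {
  stopifnot(inherits(structure, "fs2_molecule"))
  sum(structure$blocks$len)
}

#' @export
print.fs2_molecule <- function(x, ...) {
  cat(sprintf("<molecule %s: %s bp, %d block(s)>\n", x$molecule_id,
              format(chromosome_length(x), big.mark = ","), nrow(x$blocks)))
  invisible(x)
}

# ---- segment maps ----------------------------------------------------------

build_seg_map <- function(chrom_cfg) {
  segs <- chrom_cfg$segments
  if (is.null(segs)) {
    segs <- list(list(type = "shared", length = chrom_cfg$size))
  }
  s_pos <- 0; y_pos <- 0
  rows <- lapply(segs, function(s) {
    type <- s$type %||% "shared"
    if (!type %in% SEG_TYPES) stop_config("unknown segment type '%s'", type)
    len <- as.numeric(s$length)
    if (is.null(len) || is.na(len) || len < 1) stop_config("segment needs a positive length")
    r <- data.frame(type = type, len = len,
                    s_start = NA_real_, s_end = NA_real_,
                    y_start = NA_real_, y_end = NA_real_,
                    name = s$name %||% NA_character_,
                    kind = s$kind %||% NA_character_,
                    stringsAsFactors = FALSE)
    if (type %in% c("shared", "s_only")) {
      r$s_start <- s_pos + 1; r$s_end <- s_pos + len; s_pos <<- s_pos + len
    }
    if (type %in% c("shared", "y_only")) {
      r$y_start <- y_pos + 1; r$y_end <- y_pos + len; y_pos <<- y_pos + len
    }
    r
  })
  map <- do.call(rbind, rows)
  attr(map, "size_S") <- s_pos
  attr(map, "size_Y") <- y_pos
  map
}

seg_map <- function(genome, chrom) {
  m <- genome$seg_maps[[chrom]]
  if (is.null(m)) stop_config("unknown chromosome '%s'", chrom)
  m
}

# Map a position between haplotype frames; NA where no counterpart exists.
map_s_to_y <- function(genome, chrom, pos) {
  m <- seg_map(genome, chrom)
  out <- rep(NA_real_, length(pos))
  for (i in which(m$type == "shared")) {
    hit <- !is.na(pos) & pos >= m$s_start[i] & pos <= m$s_end[i]
    out[hit] <- m$y_start[i] + (pos[hit] - m$s_start[i])
  }
  out
}

map_y_to_s <- function(genome, chrom, pos) {
  m <- seg_map(genome, chrom)
  out <- rep(NA_real_, length(pos))
  for (i in which(m$type == "shared")) {
    hit <- !is.na(pos) & pos >= m$y_start[i] & pos <= m$y_end[i]
    out[hit] <- m$s_start[i] + (pos[hit] - m$y_start[i])
  }
  out
}

in_shared <- function(genome, chrom, pos) !is.na(map_s_to_y(genome, chrom, pos))

# ---- configuration ---------------------------------------------------------

#' Load a diploid genome configuration
#'
#' Parses a YAML genome description (chromosome sizes, haplotype-specific
#' segments, features, SNP assay specs) into a validated `fs2_genome` with
#' baseline (unrearranged) molecules and a synthetic SNP marker panel laid
#' down at a configurable density in shared sequence.
#'
#' @param config path to a YAML file, or a YAML string, or a pre-parsed list.
#' @param snp_spacing mean inter-SNP spacing in bp (overrides the config;
#'   default in the packaged baseline config is 1000 bp).
#' @param panel_seed RNG seed for the jittered SNP panel (overrides config).
#'   The panel is part of the study design, so the same config + seed always
#'   yields the identical panel.
#' @return an object of class `fs2_genome`.
#' @export
load_genome_config <- function(config, snp_spacing = NULL, panel_seed = NULL) {
  cfg <- if (is.character(config) && length(config) == 1L) {
    if (file.exists(config)) yaml::read_yaml(config) else yaml::yaml.load(config)
  } else config
  if (!is.list(cfg)) stop_config("genome config must be YAML or a list")
  chroms <- cfg$chromosomes
  if (is.null(chroms) || length(chroms) == 0L) {
    stop_config("genome config declares no chromosomes")
  }

  seg_maps <- list(); chrom_rows <- list(); auto_feats <- list()
  for (cc in chroms) {
    nm <- cc$name
    if (is.null(nm)) stop_config("chromosome without a name")
    m <- build_seg_map(cc)
    seg_maps[[nm]] <- m
    size_S <- attr(m, "size_S"); size_Y <- attr(m, "size_Y")
    chrom_rows[[nm]] <- data.frame(chrom = nm, size_S = size_S, size_Y = size_Y,
                                   centromere = as.numeric(cc$centromere %||% NA),
                                   stringsAsFactors = FALSE)
    if (is.null(cc$centromere)) stop_config("chromosome %s lacks a centromere", nm)
    cen <- as.numeric(cc$centromere)
    if (cen < 1 || cen > size_S) stop_config("centromere outside %s", nm)
    auto_feats[[length(auto_feats) + 1L]] <- data.frame(
      name = paste0("CEN_", nm), chrom = nm, start = cen, end = cen + 119,
      kind = "centromere", haplotype = "both", stringsAsFactors = FALSE)
    # subtelomeric repeat tips (SNP-free; ectopic attachment targets)
    tip <- 1200
    auto_feats[[length(auto_feats) + 1L]] <- data.frame(
      name = paste0("telL_", nm), chrom = nm, start = 1, end = tip,
      kind = "repeat_region", haplotype = "both", stringsAsFactors = FALSE)
    auto_feats[[length(auto_feats) + 1L]] <- data.frame(
      name = paste0("telR_", nm), chrom = nm, start = size_S - tip + 1,
      end = size_S, kind = "repeat_region", haplotype = "both",
      stringsAsFactors = FALSE)
    # named haplotype-specific segments become features in their own frame
    for (i in seq_len(nrow(m))) {
      if (!is.na(m$name[i])) {
        hap <- switch(m$type[i], s_only = "S", y_only = "Y", "both")
        st <- if (m$type[i] == "y_only") m$y_start[i] else m$s_start[i]
        en <- if (m$type[i] == "y_only") m$y_end[i] else m$s_end[i]
        auto_feats[[length(auto_feats) + 1L]] <- data.frame(
          name = m$name[i], chrom = nm, start = st, end = en,
          kind = m$kind[i] %||% "repeat_region", haplotype = hap,
          stringsAsFactors = FALSE)
      }
    }
  }
  chrom_table <- do.call(rbind, chrom_rows)
  rownames(chrom_table) <- NULL

  user_feats <- lapply(cfg$features %||% list(), function(f) {
    data.frame(name = f$name, chrom = f$chrom, start = as.numeric(f$start),
               end = as.numeric(f$end), kind = f$kind,
               haplotype = f$haplotype %||% "both", stringsAsFactors = FALSE)
  })
  features <- do.call(rbind, c(auto_feats, user_feats))
  rownames(features) <- NULL

  bad <- features$start > features$end
  if (any(bad)) stop_config("feature %s has start > end", features$name[bad][1])
  if (anyDuplicated(features$name[features$kind == "probe_locus"])) {
    stop_config("probe loci must have unique names")
  }
  # overlap check among user-declared features on one haplotype
  uf <- do.call(rbind, user_feats)
  if (!is.null(uf) && nrow(uf) > 1L) {
    for (i in seq_len(nrow(uf) - 1L)) for (j in (i + 1L):nrow(uf)) {
      if (uf$chrom[i] == uf$chrom[j] &&
          (uf$haplotype[i] == uf$haplotype[j] || uf$haplotype[i] == "both" ||
           uf$haplotype[j] == "both") &&
          uf$start[i] <= uf$end[j] && uf$start[j] <= uf$end[i]) {
        stop_config("features %s and %s overlap on one haplotype",
                    uf$name[i], uf$name[j])
      }
    }
  }

  g <- structure(list(
    name = cfg$genome$name %||% "diploid",
    divergence = cfg$genome$divergence %||% 0.005,
    chrom_table = chrom_table,
    seg_maps = seg_maps,
    features = features,
    snp_panel = NULL,
    molecules = NULL
  ), class = "fs2_genome")

  g$molecules <- baseline_molecules(g)

  spacing <- snp_spacing %||% cfg$genome$snp_spacing %||% 1000
  jitter <- cfg$genome$snp_jitter %||% floor(spacing / 4)
  pseed <- panel_seed %||% cfg$genome$panel_seed %||% 713
  assays <- cfg$snps$assays %||% list()
  g$snp_panel <- make_snp_panel(g, spacing, jitter, pseed, assays)
  validate_genome(g)
  g
}

baseline_molecules <- function(genome) {
  mols <- list()
  for (i in seq_len(nrow(genome$chrom_table))) {
    ch <- genome$chrom_table$chrom[i]
    mols[[paste0(ch, "_S")]] <- new_molecule(
      paste0(ch, "_S"), list(new_block("S", ch, 1, genome$chrom_table$size_S[i])))
    mols[[paste0(ch, "_Y")]] <- new_molecule(
      paste0(ch, "_Y"), list(new_block("Y", ch, 1, genome$chrom_table$size_Y[i])))
  }
  mols
}

# ---- SNP panel -------------------------------------------------------------

make_snp_panel <- function(genome, spacing, jitter, panel_seed, assays) {
  excl <- genome$features[genome$features$kind %in% SNP_EXCLUDE_KINDS &
                            genome$features$haplotype %in% c("both", "S"), ]
  rows <- with_seed(panel_seed, {
    lapply(seq_len(nrow(genome$chrom_table)), function(i) {
      ch <- genome$chrom_table$chrom[i]
      size <- genome$chrom_table$size_S[i]
      grid <- seq(floor(spacing / 2), size, by = spacing)
      if (jitter > 0) {
        grid <- grid + sample.int(2L * jitter + 1L, length(grid), replace = TRUE) -
          jitter - 1L
      }
      grid <- sort(unique(pmax(1, pmin(size, grid))))
      keep <- in_shared(genome, ch, grid)
      e <- excl[excl$chrom == ch, ]
      for (k in seq_len(nrow(e))) {
        keep <- keep & !(grid >= e$start[k] & grid <= e$end[k])
      }
      if (!any(keep)) return(NULL)
      pos <- grid[keep]
      alle <- matrix(replicate(length(pos), sample(c("A", "C", "G", "T"), 2L)),
                     nrow = 2L)
      data.frame(chrom = ch, pos = pos, allele_S = alle[1, ], allele_Y = alle[2, ],
                 stringsAsFactors = FALSE)
    })
  })
  panel <- do.call(rbind, rows)
  panel$amplicon <- NA_real_
  panel$cutting_allele <- NA_character_
  panel$cut_fragments <- I(vector("list", nrow(panel)))
  for (a in assays) {
    pos <- as.numeric(a$pos)
    if (is.na(pos) || pos < 1) stop_config("assay SNP position must be >= 1")
    sz <- genome$chrom_table$size_S[genome$chrom_table$chrom == a$chrom]
    if (length(sz) == 0L || pos > sz) stop_config("assay SNP outside chromosome %s", a$chrom)
    if (!in_shared(genome, a$chrom, pos)) stop_config("assay SNP %d not in shared sequence", pos)
    cuts <- as.numeric(unlist(a$cut_fragments))
    if (sum(cuts) != as.numeric(a$amplicon)) {
      stop_config("assay at %s:%d: cut fragments must sum to the amplicon length",
                  a$chrom, pos)
    }
    row <- data.frame(chrom = a$chrom, pos = pos, allele_S = "S", allele_Y = "Y",
                      amplicon = as.numeric(a$amplicon),
                      cutting_allele = normalize_hap(a$cutting_allele %||% "Y"),
                      stringsAsFactors = FALSE)
    row$cut_fragments <- I(list(cuts))
    panel <- panel[!(panel$chrom == a$chrom & panel$pos == pos), ]
    panel <- rbind(panel, row)
  }
  panel <- panel[order(match(panel$chrom, genome$chrom_table$chrom), panel$pos), ]
  rownames(panel) <- NULL
  panel$pos_Y <- NA_real_
  for (ch in unique(panel$chrom)) {
    sel <- panel$chrom == ch
    panel$pos_Y[sel] <- map_s_to_y(genome, ch, panel$pos[sel])
  }
  if (anyNA(panel$pos_Y)) stop_config("internal: SNP placed outside shared sequence")
  panel
}

validate_genome <- function(genome) {
  p <- genome$snp_panel
  if (any(p$pos < 1)) stop_config("SNP with position < 1")
  if (any(p$allele_S == p$allele_Y)) stop_config("SNP with identical alleles")
  for (ch in unique(p$chrom)) {
    sz <- genome$chrom_table$size_S[genome$chrom_table$chrom == ch]
    if (length(sz) == 0L) stop_config("SNP on unknown chromosome %s", ch)
    if (any(p$pos[p$chrom == ch] > sz)) stop_config("SNP outside chromosome %s", ch)
  }
  invisible(genome)
}

#' @export
print.fs2_genome <- function(x, ...) {
  cat(sprintf("<fs2_genome '%s': %d chromosomes, %d molecules, %d SNPs>\n",
              x$name, nrow(x$chrom_table), length(x$molecules), nrow(x$snp_panel)))
  invisible(x)
}

#' Baseline homolog sizes
#'
#' @param genome an `fs2_genome`.
#' @param chrom chromosome name.
#' @return named vector `c(S = , Y = )` in bp.
#' @export
baseline_sizes <- function(genome, chrom) {
  i <- match(chrom, genome$chrom_table$chrom)
  if (is.na(i)) stop_config("unknown chromosome '%s'", chrom)
  c(S = genome$chrom_table$size_S[i], Y = genome$chrom_table$size_Y[i])
}

#' Packaged baseline genome configuration
#'
#' Path to the YAML description of the FS2 experimental diploid used
#' throughout the package (chromosome III homologs of 346 kb / 320 kb,
#' hemizygous fragile site FS2 ~1 kb from ARS310, CHA1/PAT1 probe loci,
#' the MnlI PCR-RFLP assay at base 113,543).
#'
#' @return file path.
#' @export
baseline_config_path <- function() {
  system.file("extdata", "baseline_genome.yaml", package = "fs2ltgc", mustWork = TRUE)
}

#' Load the packaged baseline diploid
#'
#' @inheritParams load_genome_config
#' @return an `fs2_genome`.
#' @export
baseline_genome <- function(snp_spacing = NULL, panel_seed = NULL) {
  load_genome_config(baseline_config_path(), snp_spacing = snp_spacing,
                     panel_seed = panel_seed)
}

# ---- dosage ----------------------------------------------------------------

block_cover_counts <- function(genome, chrom, posS, posY) {
  total <- numeric(length(posS)); yc <- numeric(length(posS))
  for (mol in genome$molecules) {
    b <- mol$blocks
    for (k in seq_len(nrow(b))) {
      if (b$source_chrom[k] != chrom) next
      if (b$origin[k] == "S") {
        hit <- posS >= b$start[k] & posS <= b$end[k]
        total <- total + hit
      } else if (b$origin[k] == "Y") {
        hit <- !is.na(posY) & posY >= b$start[k] & posY <= b$end[k]
        total <- total + hit
        yc <- yc + hit
      }
    }
  }
  list(total = total, y = yc)
}

#' Per-SNP copy dosage of a genome
#'
#' Counts, for every SNP of the marker panel, how many molecules carry the
#' SNP's source locus and how many of those copies are Y-origin.  The
#' unrearranged heterozygote is (2,1) everywhere; a homozygous-Y conversion
#' tract is (2,2); a hemizygous deletion totals 1; a duplication totals 3.
#'
#' @param genome an `fs2_genome`.
#' @param chrom optional chromosome restriction.
#' @return data.frame with `chrom`, `pos`, `copies_total`, `copies_Y`.
#' @export
zygosity_map <- function(genome, chrom = NULL) {
  p <- genome$snp_panel
  if (!is.null(chrom)) p <- p[p$chrom %in% chrom, ]
  out <- lapply(unique(p$chrom), function(ch) {
    sel <- p[p$chrom == ch, ]
    cnt <- block_cover_counts(genome, ch, sel$pos, sel$pos_Y)
    data.frame(chrom = ch, pos = sel$pos, copies_total = cnt$total,
               copies_Y = cnt$y, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Does `mol` carry the locus of feature/interval (given in hap frame "both")?
molecule_covers_interval <- function(genome, mol, chrom, start, end) {
  ys <- map_s_to_y(genome, chrom, start); ye <- map_s_to_y(genome, chrom, end)
  b <- mol$blocks
  for (k in seq_len(nrow(b))) {
    if (b$source_chrom[k] != chrom) next
    if (b$origin[k] == "S" && b$start[k] <= end && b$end[k] >= start) return(TRUE)
    if (b$origin[k] == "Y" && !is.na(ys) && !is.na(ye) &&
        b$start[k] <= ye && b$end[k] >= ys) return(TRUE)
  }
  FALSE
}

feature_by_name <- function(genome, name) {
  f <- genome$features[genome$features$name == name, ]
  if (nrow(f) == 0L) stop_config("unknown feature '%s'", name)
  f[1, ]
}

# Number of centromere features covered by a molecule.
centromere_count <- function(genome, mol) {
  cens <- genome$features[genome$features$kind == "centromere", ]
  n <- 0L
  for (i in seq_len(nrow(cens))) {
    if (molecule_covers_interval(genome, mol, cens$chrom[i], cens$start[i],
                                 cens$end[i])) n <- n + 1L
  }
  n
}

# Replace/insert molecules in a genome; NULL drops an id.
set_molecules <- function(genome, ...) {
  upd <- list(...)
  if (length(upd) == 1L && is.null(names(upd)) && is.list(upd[[1]]) &&
      !inherits(upd[[1]], "fs2_molecule")) upd <- upd[[1]]
  for (nm in names(upd)) {
    if (is.null(upd[[nm]])) genome$molecules[[nm]] <- NULL
    else genome$molecules[[nm]] <- upd[[nm]]
  }
  genome
}
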