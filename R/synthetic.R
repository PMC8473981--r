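#' @title Synthetic observables
#'
#' @description
#' Sequencing-level observables are generated at the per-SNP count level:
#' coverage is Poisson around `depth * copies_total / 2` and the Y-allele
#' count is binomial with a symmetric miscall rate, so the heterozygous
#' baseline sits at ~50% Y alleles and 2x coverage, conversion tracts at
#' 100% (or 0%), hemizygous regions at 1x and duplications at 3x.
#' Noise-free mode stores the expectations exactly.
#'
#' @name synthetic_data
NULL

#' Sample per-SNP sequencing observations
#'
#' @param genome an `fs2_genome` (possibly rearranged).
#' @param depth haploid-pair sequencing depth (reads crossing a SNP present
#'   at two copies); default 100.
#' @param error_rate symmetric per-read allele miscall probability
#'   (`0 <= error_rate < 0.5`).
#' @param seed RNG seed (sampled mode).
#' @param noise_free if TRUE, return expectations instead of draws.
#' @param chrom optional chromosome restriction.
#' @return a `snp_obs` data.frame: `chrom`, `pos`, `coverage`, `y_count`,
#'   `y_fraction`, `zero_copy`.
#' @export
sample_snp_observations <- function(genome, depth = 100, error_rate = 0,
                                    seed = NULL, noise_free = FALSE,
                                    chrom = NULL) {
  stopifnot(depth > 0, error_rate >= 0, error_rate < 0.5)
  z <- zygosity_map(genome, chrom)
  lambda <- depth * z$copies_total / 2
  p <- ifelse(z$copies_total > 0, z$copies_Y / z$copies_total, NA_real_)
  p_adj <- p * (1 - error_rate) + (1 - p) * error_rate
  if (noise_free) {
    cov <- lambda
    yc <- ifelse(is.na(p_adj), 0, cov * p_adj)
  } else {
    n <- nrow(z)
    cov <- with_seed(seed, stats::rpois(n, lambda))
    yc <- with_seed(child_seed(seed %||% 0, 1), {
      out <- integer(n)
      ok <- cov > 0 & !is.na(p_adj)
      out[ok] <- stats::rbinom(sum(ok), cov[ok], p_adj[ok])
      out
    })
  }
  obs <- data.frame(chrom = z$chrom, pos = z$pos, coverage = cov, y_count = yc,
                    y_fraction = ifelse(cov > 0, yc / cov, NA_real_),
                    zero_copy = z$copies_total == 0,
                    stringsAsFactors = FALSE)
  structure(obs, class = c("snp_obs", "data.frame"),
            mode = if (noise_free) "noise_free" else "sampled", depth = depth)
}

#' Write / read an observation table (TSV)
#'
#' @param obs a `snp_obs` table.
#' @param path output file.
#' @export
write_obs <- function(obs, path) {
  utils::write.table(obs[, c("chrom", "pos", "coverage", "y_count")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_obs
#' @export
read_obs <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  d$y_fraction <- ifelse(d$coverage > 0, d$y_count / d$coverage, NA_real_)
  d$zero_copy <- d$coverage == 0
  structure(d, class = c("snp_obs", "data.frame"), mode = "sampled")
}

#' Export observations as a minimal VCF-like table
#'
#' CHROM/POS/REF (S allele)/ALT (Y allele)/DP/AD, enough to round-trip the
#' per-SNP counts through standard tooling.
#'
#' @param obs a `snp_obs` table.
#' @param genome the genome whose panel produced `obs`.
#' @param path output file.
#' @export
write_obs_vcf <- function(obs, genome, path) {
  p <- genome$snp_panel
  key <- paste(obs$chrom, obs$pos)
  i <- match(key, paste(p$chrom, p$pos))
  lines <- c("##fileformat=VCFv4.2",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsample")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d\tDP:AD\t%d:%d,%d",
                  obs$chrom, as.integer(obs$pos), p$allele_S[i], p$allele_Y[i],
                  as.integer(round(obs$coverage)), as.integer(round(obs$coverage)),
                  as.integer(round(obs$coverage - obs$y_count)),
                  as.integer(round(obs$y_count)))
  writeLines(c(lines, body), path)
  invisible(path)
}

# ---- junction fixtures -----------------------------------------------------

DNA <- c("A", "C", "G", "T")

rand_seq <- function(n) sample(DNA, n, replace = TRUE)

other_base <- function(b) vapply(b, function(x) sample(setdiff(DNA, x), 1L), "")

#' Generate a chimeric junction fixture with planted microhomology
#'
#' Builds two synthetic parental sequences and a chimeric junction equal to a
#' prefix of parent A joined to a suffix of parent B, overlapping by exactly
#' `mh_len` bases.  Within a guard window around the breakpoint the parents
#' are forced to disagree except at the planted microhomology and at an
#' optional nearby "island" of identity, so the maximal-overlap answer is
#' well defined.
#'
#' @param mh_len planted microhomology length (bases, >= 0).
#' @param island optional `list(length =, offset =)`: an exact-match island
#'   of `length` bases separated from the microhomology by `offset`
#'   mismatched bases on the parent-A side of the breakpoint.
#' @param seq_len length of each parent sequence (default 80).
#' @param seed RNG seed.
#' @return a `junction_fixture`: `parent_A`, `parent_B`, `junction` strings,
#'   the breakpoint offset and the planted spec.
#' @export
generate_junction_fixture <- function(mh_len, island = NULL, seq_len = 80,
                                      seed = NULL) {
  if (mh_len < 0) stop_config("mh_len must be >= 0")
  if (mh_len >= seq_len / 2) stop_config("mh_len too long for the sequence length")
  guard <- 14L
  with_seed(seed, {
    a <- rand_seq(seq_len)
    bp <- floor(seq_len / 2)
    b <- rand_seq(seq_len)
    win <- seq.int(max(1L, bp - guard), min(seq_len, bp + guard))
    b[win] <- other_base(a[win])            # default: disagree near breakpoint
    if (mh_len > 0) {
      idx <- (bp - mh_len + 1):bp
      b[idx] <- a[idx]                      # the microhomology itself
    }
    if (!is.null(island)) {
      il <- island$length %||% 2
      off <- island$offset %||% 2
      if (off < 1) stop_config("island offset must be >= 1")
      idx <- (bp - mh_len - off - il + 1):(bp - mh_len - off)
      if (min(idx) < 1) stop_config("island does not fit in the sequence")
      b[idx] <- a[idx]
    }
    junction <- paste0(paste(a[1:bp], collapse = ""),
                       paste(b[(bp + 1):seq_len], collapse = ""))
    structure(list(parent_A = paste(a, collapse = ""),
                   parent_B = paste(b, collapse = ""),
                   junction = junction, breakpoint = bp,
                   planted = list(mh_len = mh_len, island = island)),
              class = "junction_fixture")
  })
}

#' @export
print.junction_fixture <- function(x, ...) {
  cat(sprintf("<junction fixture: %d bp parents, planted microhomology %d%s>\n",
              nchar(x$parent_A), x$planted$mh_len,
              if (!is.null(x$planted$island))
                sprintf(" + %d-base island", x$planted$island$length) else ""))
  invisible(x)
}

#' Write a junction fixture as FASTA
#'
#' @param fixture a `junction_fixture`.
#' @param path output FASTA path.
#' @export
write_junction_fasta <- function(fixture, path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::DNAStringSet(c(parent_A = fixture$parent_A,
                                     parent_B = fixture$parent_B,
                                     junction = fixture$junction))
    Biostrings::writeXStringSet(ss, path)
  } else {
    writeLines(c(">parent_A", fixture$parent_A, ">parent_B", fixture$parent_B,
                 ">junction", fixture$junction), path)
  }
  invisible(path)
}

#' Read a junction fixture back from FASTA
#'
#' @param path FASTA with records parent_A, parent_B, junction.
#' @export
read_junction_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readDNAStringSet(path)
    v <- as.character(ss)
  } else {
    lines <- readLines(path)
    hd <- grep("^>", lines)
    v <- vapply(seq_along(hd), function(i) {
      to <- if (i < length(hd)) hd[i + 1] - 1L else length(lines)
      paste(lines[(hd[i] + 1L):to], collapse = "")
    }, "")
    names(v) <- sub("^>", "", lines[hd])
  }
  structure(list(parent_A = unname(v[["parent_A"]]),
                 parent_B = unname(v[["parent_B"]]),
                 junction = unname(v[["junction"]]),
                 breakpoint = NA, planted = NULL),
            class = "junction_fixture")
}
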