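# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# Baseline diploid at the default 1 SNP/kb panel density.
get_baseline <- function() {
  if (is.null(.fixture_env$baseline)) {
    .fixture_env$baseline <- baseline_genome()
  }
  .fixture_env$baseline
}

# The packaged 16-strain cohort (noise-free) plus its classification.
get_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- generate_fixture_cohort(seed = 1, noise_free = TRUE)
  }
  .fixture_env$cohort
}

get_cohort_results <- function() {
  if (is.null(.fixture_env$results)) {
    .fixture_env$results <- classify_cohort(get_cohort())
  }
  .fixture_env$results
}

# A small fully colinear diploid with a fragile site, for exact oracles.
tiny_config <- function(size = 50000) {
  sprintf('
genome: {name: tiny, snp_spacing: 1000, snp_jitter: 200, panel_seed: 7}
chromosomes:
  - name: chrA
    size: %d
    centromere: 10000
features:
  - {name: FS_A, chrom: chrA, start: 30000, end: 30400, kind: fragile_site}
  - {name: CHA1, chrom: chrA, start: 4000, end: 4200, kind: probe_locus}
  - {name: PAT1, chrom: chrA, start: 45000, end: 45200, kind: probe_locus}
snps:
  assays:
    - {chrom: chrA, pos: 12000, amplicon: 400, cut_fragments: [250, 150], cutting_allele: "Y"}
', size)
}

get_tiny <- function() {
  if (is.null(.fixture_env$tiny)) {
    .fixture_env$tiny <- load_genome_config(tiny_config())
  }
  .fixture_env$tiny
}

# Independent per-position block-coverage oracle: expands every block of
# every molecule into explicit position vectors (feasible on tiny genomes)
# and tabulates coverage at the SNP positions.
zygosity_oracle <- function(genome, chrom) {
  pan <- genome$snp_panel[genome$snp_panel$chrom == chrom, ]
  tot <- integer(nrow(pan)); yc <- integer(nrow(pan))
  for (mol in genome$molecules) {
    b <- mol$blocks
    for (k in seq_len(nrow(b))) {
      if (b$source_chrom[k] != chrom) next
      covered <- seq(b$start[k], b$end[k])
      if (b$origin[k] == "S") {
        tot <- tot + pan$pos %in% covered
      } else if (b$origin[k] == "Y") {
        hit <- pan$pos_Y %in% covered
        tot <- tot + hit
        yc <- yc + hit
      }
    }
  }
  data.frame(pos = pan$pos, copies_total = tot, copies_Y = yc)
}
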