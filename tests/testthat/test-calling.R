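test_that("zygosity calls match an independent threshold-rule oracle", {
  call_oracle <- function(frac, cov) {
    # independent re-statement of the rule as a lookup over cases
    out <- character(length(frac))
    for (i in seq_along(frac)) {
      out[i] <- if (is.na(frac[i]) || cov[i] < 10) "low_cov"
      else if (frac[i] >= 0.95) "homY"
      else if (frac[i] <= 0.05) "homS"
      else if (frac[i] >= 0.35 && frac[i] <= 0.65) "het"
      else "ambiguous"
    }
    out
  }
  set.seed(99)
  n <- 400
  obs <- data.frame(chrom = "c", pos = seq_len(n) * 100,
                    coverage = sample(0:200, n, replace = TRUE))
  obs$y_count <- rbinom(n, obs$coverage, runif(n))
  obs$y_fraction <- ifelse(obs$coverage > 0, obs$y_count / obs$coverage, NA)
  calls <- call_zygosity(obs)
  expect_equal(calls$call, call_oracle(obs$y_fraction, obs$coverage))
  expect_equal(call_zygosity(data.frame(chrom = "c", pos = 1, coverage = 100,
                                        y_count = 50, y_fraction = 0.5))$call,
               "het")
  expect_equal(call_zygosity(data.frame(chrom = "c", pos = 1, coverage = 100,
                                        y_count = 100, y_fraction = 1))$call,
               "homY")
})

test_that("segmentation finds maximal runs with junction intervals", {
  g <- get_tiny()
  obs <- sample_snp_observations(g, noise_free = TRUE)
  tr <- segment_tracts(call_zygosity(obs))
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$state, "het")
  expect_true(is.na(tr$jl_lo) && is.na(tr$jr_hi))

  # the LTGC 16 strain has exactly one interior homY tract on chrIII
  coh <- get_cohort()
  o16 <- coh$strains[["LTGC 16"]]$obs
  tr16 <- segment_tracts(call_zygosity(o16[o16$chrom == "chrIII", ]))
  hom <- tr16[tr16$state != "het", ]
  expect_equal(nrow(hom), 1L)
  expect_equal(hom$state, "homY")
  pan <- coh$baseline$snp_panel
  p3 <- pan$pos[pan$chrom == "chrIII"]
  expect_gt(hom$first_snp, min(p3))
  expect_lt(hom$last_snp, max(p3))

  # order shuffling then sorting does not change the result; re-running is
  # idempotent
  calls <- call_zygosity(o16[o16$chrom == "chrIII", ])
  shuf <- calls[sample.int(nrow(calls)), ]
  expect_equal(segment_tracts(shuf), tr16)
  expect_equal(segment_tracts(calls), segment_tracts(calls))
  expect_warning(segment_tracts(data.frame(chrom = "c", pos = 1,
                                           call = "low_cov")),
                 "no informative")
})

test_that("junction intervals are narrow and contain the true breakpoints", {
  g <- get_baseline()   # default 1 SNP/kb panel
  m <- fs2ltgc:::seg_map(g, "chrIII")
  in_dense <- function(lo, hi) {
    # junctions not abutting a marker-free hemizygous block
    !any(m$type != "shared" & !is.na(m$s_start) &
           m$s_start <= hi & m$s_end >= lo)
  }
  worst <- 0; n_dense <- 0L
  for (s in 1:25) {
    out <- sample_mechanism_outcome(g, "late_template_switch", seed = 300 + s)
    obs <- sample_snp_observations(out$genome, noise_free = TRUE,
                                   chrom = "chrIII")
    tr <- segment_tracts(call_zygosity(obs))
    hom <- tr[tr$state == "homY", ]
    expect_equal(nrow(hom), 1L)
    inv <- out$event$invasion_pos; sw <- out$event$terminus_pos
    expect_true(hom$jl_lo <= inv && inv <= hom$jl_hi)
    expect_true(hom$jr_lo <= sw && sw <= hom$jr_hi)
    if (in_dense(hom$jr_lo, hom$jr_hi)) {
      worst <- max(worst, hom$jr_hi - hom$jr_lo)
      n_dense <- n_dense + 1L
    }
  }
  expect_gt(n_dense, 10L)
  expect_lt(worst, 4000)
})

test_that("CNV calling recovers planted copy states", {
  coh <- get_cohort()
  base <- coh$baseline
  flat <- detect_cnv(coh$strains[["LTGC 16"]]$obs)
  expect_true(all(flat$chrom != "chrV"))   # no calls on untouched chromosomes
  # LTGC 2: one 3x call of ~40 kb on chrIII
  cnv2 <- detect_cnv(coh$strains[["LTGC 2"]]$obs)
  cnv2 <- cnv2[cnv2$chrom == "chrIII", ]
  expect_equal(nrow(cnv2), 1L)
  expect_equal(cnv2$copy_state, 3L)
  expect_equal(cnv2$end - cnv2$start + 1, 40000, tolerance = 0.05)
  # LTGC 14: one 1x call of ~20 kb inside the conversion tract
  cnv14 <- detect_cnv(coh$strains[["LTGC 14"]]$obs)
  cnv14 <- cnv14[cnv14$chrom == "chrIII", ]
  expect_equal(nrow(cnv14), 1L)
  expect_equal(cnv14$copy_state, 1L)
  expect_equal(cnv14$end - cnv14$start + 1, 20000, tolerance = 0.06)
  expect_error(detect_cnv(data.frame(chrom = "c", pos = 1:10, coverage = 0,
                                     y_count = 0, y_fraction = NA)),
               "median coverage")
  # boundary error at depth 100 stays within one inter-SNP gap
  g <- get_tiny()
  dup <- apply_cnv(g, "chrA", c(20000, 30000), 3)
  o <- sample_snp_observations(dup, depth = 100, seed = 10)
  cc <- detect_cnv(o)
  expect_equal(nrow(cc), 1L)
  gap <- 1200  # max inter-SNP spacing at 1 SNP/kb with 200 bp jitter
  expect_lt(abs(cc$start - 20000), 2 * gap)
  expect_lt(abs(cc$end - 30000), 2 * gap)
})

test_that("abrupt transitions require adjacency and constant coverage", {
  mk <- function(states, cnv = NULL) {
    tr <- data.frame(chrom = "c", state = states,
                     first_snp = seq_along(states) * 1000 + 1,
                     last_snp = seq_along(states) * 1000 + 900,
                     n_snps = 5,
                     jl_lo = NA, jl_hi = NA, jr_lo = NA, jr_hi = NA)
    detect_abrupt_transitions(tr, cnv)
  }
  expect_equal(nrow(mk(c("het", "homS", "homY", "het"))), 1L)
  expect_equal(nrow(mk(c("homS", "het", "homY"))), 0L)
  # a transition coinciding with a CNV boundary is not flagged
  cnv <- data.frame(chrom = "c", start = 2800, end = 3500, copy_state = 1L,
                    n_snps = 5, mean_ratio = 0.5)
  expect_equal(nrow(mk(c("het", "homS", "homY", "het"), cnv)), 0L)
})

test_that("the genome-wide scan assembles the unselected-event catalog", {
  res <- get_cohort_results()
  all_ev <- attr(res$report$unselected, "events")
  expect_equal(sum(all_ev$type == "terminal_LOH"), 15L)
  expect_equal(sum(all_ev$type == "CNV"), 8L)
  expect_equal(sum(all_ev$type == "interior_GC"), 4L)
  # two of the terminal events start in the chrXII rDNA array
  rdna <- all_ev[all_ev$in_repeat & all_ev$type == "terminal_LOH", ]
  expect_equal(nrow(rdna), 2L)
  expect_true(all(rdna$chrom == "chrXII"))
  expect_true(all(abs(rdna$start - 450000) < 25000))
  # an unrearranged genome yields an empty catalog
  g <- get_tiny()
  obs <- sample_snp_observations(g, noise_free = TRUE)
  expect_equal(nrow(genome_scan(obs, g)), 0L)
  # long vs short gene-conversion length classes are recorded
  gc <- all_ev[all_ev$type == "interior_GC", ]
  expect_setequal(gc$length_class, c("short", "long"))
})
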