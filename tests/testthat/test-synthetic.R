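test_that("noise-free observations store the exact expectations", {
  g <- get_tiny()
  obs <- sample_snp_observations(g, depth = 100, noise_free = TRUE)
  expect_true(all(obs$y_fraction == 0.5))
  expect_true(all(obs$coverage == 100))
  brk <- make_break(g, list(zero_resection = TRUE))
  hc <- simulate_half_crossover(g, brk, 40000)
  o2 <- sample_snp_observations(hc$genome, depth = 80, noise_free = TRUE)
  inside <- o2$pos > 30400 & o2$pos <= 40000
  expect_true(all(o2$y_fraction[inside] == 1.0))
  expect_true(all(o2$y_fraction[!inside] == 0.5))
})

test_that("sampled observations converge to their expectations", {
  g <- get_tiny()
  # duplicated region: mean coverage ratio 1.5x over many draws
  dup <- apply_cnv(g, "chrA", c(20000, 30000), 3)
  covs <- replicate(30, {
    o <- sample_snp_observations(dup, depth = 100,
                                 seed = sample.int(1e6, 1))
    c(mean(o$coverage[o$pos >= 20000 & o$pos <= 30000]),
      mean(o$coverage[o$pos < 20000 | o$pos > 30000]))
  })
  expect_equal(mean(covs[1, ]) / mean(covs[2, ]), 1.5, tolerance = 0.02)
  # y_fraction converges to the noise-free expectation at high depth
  o_hi <- sample_snp_observations(dup, depth = 1e4, seed = 3)
  o_nf <- sample_snp_observations(dup, depth = 1e4, noise_free = TRUE)
  expect_lt(max(abs(o_hi$y_fraction - o_nf$y_fraction)), 0.02)
  # symmetric miscalls pull homozygous fractions toward 0.5
  o_err <- sample_snp_observations(g, depth = 1e4, error_rate = 0.1, seed = 4)
  expect_equal(mean(o_err$y_fraction), 0.5, tolerance = 0.01)
})

test_that("junction fixtures plant exactly the requested microhomology", {
  # exhaustive overlap-scan oracle: longest run of parent agreement ending
  # at the breakpoint, parents aligned on the breakpoint
  mh_oracle <- function(fx) {
    a <- strsplit(fx$parent_A, "")[[1]]; b <- strsplit(fx$parent_B, "")[[1]]
    k <- 0L
    while (k < fx$breakpoint && a[fx$breakpoint - k] == b[fx$breakpoint - k]) {
      k <- k + 1L
    }
    k
  }
  for (k in 0:10) {
    fx <- generate_junction_fixture(k, seed = 100 + k)
    expect_equal(mh_oracle(fx), k)
    expect_equal(find_microhomology(fx)$mh_len, k)
  }
  expect_error(generate_junction_fixture(60, seq_len = 80), "too long")
})

test_that("the deletion-junction scenario shows 3 bases plus a 2-base island", {
  fx <- generate_junction_fixture(3, island = list(length = 2, offset = 2),
                                  seed = 8)
  res <- find_microhomology(fx)
  expect_equal(res$mh_len, 3)
  expect_equal(nrow(res$islands), 1L)
  expect_equal(res$islands$length, 2L)
  # blunt junction: no overlap, no islands
  blunt <- generate_junction_fixture(0, seed = 9)
  res0 <- find_microhomology(blunt)
  expect_equal(res0$mh_len, 0)
  expect_equal(nrow(res0$islands), 0L)
})

test_that("junction fixtures survive a FASTA round trip", {
  fx <- generate_junction_fixture(4, seed = 21)
  path <- tempfile(fileext = ".fasta")
  write_junction_fasta(fx, path)
  back <- read_junction_fasta(path)
  expect_equal(back$parent_A, fx$parent_A)
  expect_equal(back$junction, fx$junction)
  expect_equal(find_microhomology(back)$mh_len, 4)
})

test_that("the fixture cohort encodes the study design", {
  coh <- get_cohort()
  expect_length(coh$strains, 16L)
  groups <- table(vapply(coh$strains, function(s) s$truth$group, ""))
  expect_equal(unname(groups[c("Coupling", "Repulsion", "Disjoined")]),
               c(7L, 6L, 3L), ignore_attr = TRUE)
  # LTGC 8: S homolog ~36 kb smaller after the in-tract deletion
  g8 <- coh$strains[["LTGC 8"]]$outcome$genome
  dS <- chromosome_length(g8$molecules$chrIII_S.rep) - 346000
  expect_lt(abs(dS - (-36000)), 2000)
  # an unrearranged control strain stays heterozygous everywhere
  ctl <- generate_fixture_cohort(seed = 2, include_control = TRUE)
  obs <- ctl$strains[["control"]]$obs
  expect_true(all(obs$y_fraction == 0.5))
})

test_that("sampling is seed-deterministic", {
  g <- get_tiny()
  a <- sample_snp_observations(g, depth = 50, seed = 42)
  b <- sample_snp_observations(g, depth = 50, seed = 42)
  c <- sample_snp_observations(g, depth = 50, seed = 43)
  expect_identical(a, b)
  expect_false(identical(a$coverage, c$coverage))
})
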