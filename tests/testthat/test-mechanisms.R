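test_that("break specification respects resection bounds and FS2 anchoring", {
  g <- get_baseline()
  brk0 <- make_break(g, list(zero_resection = TRUE))
  expect_equal(brk0$proximal_end, unname(fs2_edges(g)["prox"]))
  expect_equal(brk0$distal_end, unname(fs2_edges(g)["dist"]))
  draws <- fs2ltgc:::with_seed(11, fs2ltgc:::rtrunc_exp(1e4, 5000, 30000))
  expect_true(all(draws >= 0))
  expect_true(all(draws <= 30000))
})

test_that("late template switch yields an interior coupling tract of the right extent", {
  g <- get_baseline()
  brk <- make_break(g, list(zero_resection = TRUE))
  out <- simulate_late_template_switch(g, brk, 210000)
  expect_equal(out$truth_group, "Coupling")
  z <- zygosity_map(out$genome, "chrIII")
  hom <- z$pos[z$copies_Y == 2]
  pan <- g$snp_panel[g$snp_panel$chrom == "chrIII", ]
  # homozygous SNPs are exactly the panel SNPs inside (invasion, switch]
  expect_equal(sort(hom),
               sort(pan$pos[pan$pos > brk$proximal_end & pan$pos <= 210000]))
  expect_true(all(z$copies_total == 2))
  ph <- phase_flanks(out$genome, data.frame(chrom = "chrIII",
                                            first_snp = min(hom),
                                            last_snp = max(hom)))
  expect_equal(ph$value, "coupling")
  # identity repair: switching back at the invasion point leaves no tract
  id <- simulate_late_template_switch(g, brk, brk$proximal_end)
  zid <- zygosity_map(id$genome, "chrIII")
  expect_true(all(zid$copies_Y == 1))
  expect_error(simulate_late_template_switch(g, brk, brk$proximal_end - 5000),
               "proximal to the invasion")
})

test_that("half crossover shows the repulsion / +6 kb signature", {
  g <- get_baseline()
  brk <- make_break(g, list(zero_resection = TRUE))
  out <- simulate_half_crossover(g, brk, 245000)
  expect_equal(out$truth_group, "Repulsion")
  dy <- chromosome_length(out$genome$molecules$chrIII_Y.rep) -
    baseline_sizes(g, "chrIII")[["Y"]]
  expect_equal(dy, 6000)
  z <- zygosity_map(out$genome, "chrIII")
  hom <- z$pos[z$copies_Y == 2]
  ph <- phase_flanks(out$genome, data.frame(chrom = "chrIII",
                                            first_snp = min(hom),
                                            last_snp = max(hom)),
                     separable = TRUE)
  expect_equal(ph$value, "repulsion")
  # degenerate cleavage at the invasion point: no conversion tract
  z0 <- zygosity_map(simulate_half_crossover(g, brk, brk$proximal_end)$genome,
                     "chrIII")
  expect_true(all(z0$copies_Y[z0$copies_total == 2] == 1))
  expect_error(simulate_half_crossover(g, brk, 400000), "beyond the telomere")
})

test_that("gap-repair modes produce their predicted signatures", {
  g <- get_baseline()
  brk <- make_break(g, list(zero_resection = TRUE))
  expect_error(simulate_gap_repair(g, brk, "weird"), "unknown gap-repair mode")
  expect_error(simulate_gap_repair(g, brk, "dual_bir_ectopic"), "repeat target")

  ann <- simulate_gap_repair(g, brk, "dual_bir_anneal",
                             list(terminus = 200000))
  expect_equal(ann$truth_group, "Coupling")

  ab <- simulate_gap_repair(g, brk, "dual_bir_half_crossover",
                            list(terminus = 230000))
  expect_equal(ab$truth_group, "AbruptTransition")
  z <- zygosity_map(ab$genome, "chrIII")
  expect_true(all(z$copies_total == 2))
  calls <- rle(ifelse(z$copies_Y == 2, "homY", ifelse(z$copies_Y == 0, "homS", "het")))
  # homY run immediately followed by homS run, no intervening het
  i <- which(calls$values == "homY")
  expect_length(i, 1L)
  expect_equal(calls$values[i + 1L], "homS")

  ec <- simulate_gap_repair(g, brk, "dual_bir_ectopic",
                            list(attach_chrom = "chrII"))
  expect_equal(ec$truth_group, "Disjoined")
  pr <- chef_band_profile(ec$genome)
  cha <- southern(pr, ec$genome, "CHA1")
  pat <- southern(pr, ec$genome, "PAT1")
  expect_false(setequal(cha$molecule_id, pat$molecule_id))
  # the probe loci of the S homolog sit on two distinct molecules
  expect_true("chrIII_SL" %in% cha$molecule_id)
  expect_true("chrIII_ST" %in% pat$molecule_id)
})

test_that("terminal LOH converts all SNPs distal to the boundary", {
  g <- get_baseline()
  out <- simulate_terminal_loh(g, "chrV", 355000, "Y")
  z <- zygosity_map(out$genome, "chrV")
  expect_true(all(z$copies_Y[z$pos > 355000] == 2))
  expect_true(all(z$copies_total[z$pos <= 355000] == 2 &
                    z$copies_Y[z$pos <= 355000] == 1))
  expect_error(simulate_terminal_loh(g, "chrV", 577000, "Y"), "interior")
})

test_that("copy-number overlays change dosage as configured", {
  g <- get_tiny()
  dup <- apply_cnv(g, "chrA", c(20000, 30000), 3)
  zd <- zygosity_map(dup, "chrA")
  expect_true(all(zd$copies_total[zd$pos >= 20000 & zd$pos <= 30000] == 3))
  del <- apply_cnv(g, "chrA", c(20000, 30000), 1)
  zl <- zygosity_map(del, "chrA")
  expect_true(all(zl$copies_total[zl$pos >= 20000 & zl$pos <= 30000] == 1))
  expect_identical(apply_cnv(g, "chrA", c(20000, 19999), 3), g)
  expect_error(apply_cnv(g, "chrA", c(5000, 15000), 1), "centromere")
})

test_that("every simulated molecule keeps exactly one centromere and its Fig-style signature", {
  g <- get_baseline()
  mechs <- c("late_template_switch", "half_crossover", "gap_repair_recapture",
             "gap_repair_dual_bir_anneal", "gap_repair_dual_bir_ectopic")
  for (m in mechs) {
    for (s in 1:6) {
      out <- sample_mechanism_outcome(g, m, seed = 1000 * s + match(m, mechs))
      for (mol in out$genome$molecules) {
        expect_equal(fs2ltgc:::centromere_count(out$genome, mol), 1L)
      }
      z <- zygosity_map(out$genome, "chrIII")
      if (m == "gap_repair_dual_bir_ectopic") {
        expect_true(all(z$copies_total == 2))
      } else {
        expect_true(all(z$copies_total == 2))
        # interior tract: heterozygous flanks on both sides
        hom <- range(z$pos[z$copies_Y == 2])
        expect_true(any(z$pos < hom[1] & z$copies_Y == 1))
        expect_true(any(z$pos > hom[2] & z$copies_Y == 1))
      }
    }
  }
})

test_that("round-trip classification recovers the truth group under noise", {
  g <- get_baseline()
  mechs <- c("late_template_switch", "half_crossover", "gap_repair_recapture",
             "gap_repair_dual_bir_anneal", "gap_repair_dual_bir_ectopic")
  n <- 12
  hits <- 0L; tot <- 0L
  for (m in mechs) {
    for (s in seq_len(n)) {
      out <- sample_mechanism_outcome(g, m, seed = 77 + 131 * s + match(m, mechs))
      res <- classify_outcome(out, g, depth = 100, error_rate = 0.01,
                              seed = 900 + s)
      tot <- tot + 1L
      truth <- if (out$truth_group %in% c("Coupling")) "Coupling" else out$truth_group
      if (res$classification$group == truth) hits <- hits + 1L
    }
  }
  expect_gte(hits / tot, 0.95)
})
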