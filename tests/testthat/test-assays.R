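test_that("CHEF band profile sizes every molecule", {
  g <- get_baseline()
  pr <- chef_band_profile(g)
  b3 <- pr$size[pr$molecule_id %in% c("chrIII_S", "chrIII_Y")]
  expect_setequal(b3, c(346000, 320000))
  expect_true(all(diff(pr$size) <= 0))
  # band sizes account for all genome content (block-sum oracle)
  tot <- 0
  for (mol in g$molecules) for (k in seq_len(nrow(mol$blocks))) {
    tot <- tot + (mol$blocks$end[k] - mol$blocks$start[k] + 1)
  }
  expect_equal(sum(pr$size), tot)
  g1 <- g; g1$molecules <- g$molecules["chrI_S"]
  expect_equal(nrow(chef_band_profile(g1)), 1L)
})

test_that("Southern hybridization reproduces the disjoined-arm band patterns", {
  coh <- get_cohort()
  expected <- list(`LTGC 1` = list(cha1 = c(320000, 550000),
                                   pat1 = c(320000, 930000)),
                   `LTGC 3` = list(cha1 = c(320000, 810000),
                                   pat1 = c(320000, 1300000)),
                   `LTGC 5` = list(cha1 = c(320000, 412000),
                                   pat1 = c(320000, 780000)))
  for (nm in names(expected)) {
    g <- coh$strains[[nm]]$outcome$genome
    pr <- chef_band_profile(g)
    expect_setequal(southern(pr, g, "CHA1")$size, expected[[nm]]$cha1)
    expect_setequal(southern(pr, g, "PAT1")$size, expected[[nm]]$pat1)
  }
  # in all other strains the two probes light up the same molecules
  for (nm in setdiff(names(coh$strains), names(expected))) {
    g <- coh$strains[[nm]]$outcome$genome
    pr <- chef_band_profile(g)
    expect_setequal(southern(pr, g, "CHA1")$molecule_id,
                    southern(pr, g, "PAT1")$molecule_id)
  }
  # a probe locus absent from every molecule yields no bands
  g <- get_baseline()
  g2 <- g; g2$molecules <- g$molecules[c("chrI_S", "chrI_Y")]
  expect_equal(nrow(southern(chef_band_profile(g2), g2, "CHA1")), 0L)
  expect_error(southern(chef_band_profile(g), g, "NOPE"), "unknown feature")
})

test_that("isolability matches an all-pairs distance oracle", {
  pr <- data.frame(molecule_id = c("a", "b"), size = c(346000, 320000))
  expect_true(all(isolable(pr, resolution = 10000)))
  set.seed(31)
  for (i in 1:15) {
    sizes <- sample(2e5:1e6, 6)
    pr <- data.frame(molecule_id = letters[1:6], size = sizes)
    got <- isolable(pr, resolution = 15000)
    for (j in 1:6) {
      oracle <- TRUE
      for (k in setdiff(1:6, j)) {
        if (abs(sizes[j] - sizes[k]) < 15000) oracle <- FALSE
      }
      expect_equal(unname(got[j]), oracle)
    }
  }
  # the near-equal chrIII homologs of LTGC 14 cannot be excised
  coh <- get_cohort()
  g14 <- coh$strains[["LTGC 14"]]$outcome$genome
  pr14 <- chef_band_profile(g14)
  b14 <- southern(pr14, g14, "CHA1")
  expect_false(all(isolable(b14[, c("molecule_id", "size")],
                            resolution = 10000)))
})

test_that("PCR-RFLP reproduces the MnlI assay arithmetic", {
  g <- get_baseline()
  snp <- assay_snp(g, 113543)
  expect_equal(pcr_rflp(g$molecules$chrIII_Y, snp, g), c(335, 127))
  expect_equal(pcr_rflp(g$molecules$chrIII_S, snp, g), 462)
  expect_equal(sum(pcr_rflp(g$molecules$chrIII_Y, snp, g)), snp$amplicon)
  # the unseparated heterozygous diploid shows all three bands
  expect_equal(pcr_rflp(g, snp), c(462, 335, 127))
  plain <- g$snp_panel[is.na(g$snp_panel$amplicon), ][1, ]
  expect_error(pcr_rflp(g$molecules$chrIII_S, plain, g), "no RFLP assay")
  # a disjoined left-arm molecule cannot amplify a distal right-arm SNP
  coh <- get_cohort()
  g1 <- coh$strains[["LTGC 1"]]$outcome$genome
  pan <- g1$snp_panel
  distal <- pan[pan$chrom == "chrIII" & pan$pos > 300000, ][1, ]
  expect_equal(molecule_allele_at(g1$molecules$chrIII_SL, distal, g1),
               "PCR_FAIL")
})

test_that("flank phasing reproduces the per-strain determinations", {
  res <- get_cohort_results()
  phasing <- vapply(res$evidences, `[[`, "", "phasing")
  expect_equal(sum(phasing == "coupling"), 6L)
  expect_equal(sum(phasing == "repulsion"), 4L)
  expect_equal(sum(phasing == "atypical_pcr_failure"), 3L)
  expect_equal(sum(phasing == "not_determined"), 3L)
  expect_equal(unname(phasing["LTGC 16"]), "coupling")
  expect_equal(unname(phasing["LTGC 8"]), "repulsion")
  expect_equal(unname(phasing["LTGC 14"]), "not_determined")
  # a tract reaching the chromosome end has no distal flank
  g <- get_baseline()
  expect_error(phase_flanks(g, data.frame(chrom = "chrIII", first_snp = 200,
                                          last_snp = 339999)),
               "chromosome end")
})
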