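test_that("packaged baseline reproduces the experimental diploid geometry", {
  g <- get_baseline()
  expect_equal(unname(baseline_sizes(g, "chrIII")), c(346000, 320000))
  expect_equal(chromosome_length(g$molecules$chrIII_S), 346000)
  expect_equal(chromosome_length(g$molecules$chrIII_Y), 320000)
  # FS2 sits ~1 kb from the ARS310 replication origin
  fs2 <- g$features[g$features$name == "FS2", ]
  ars <- g$features[g$features$name == "ARS310", ]
  expect_lt(abs(fs2$start - ars$end), 1500)
})

test_that("degenerate configurations are rejected", {
  expect_error(load_genome_config("genome: {name: x}\nchromosomes: []"),
               "no chromosomes")
  cfg_snp0 <- '
chromosomes: [{name: c1, size: 10000, centromere: 5000}]
snps:
  assays: [{chrom: c1, pos: 0, amplicon: 10, cut_fragments: [4, 6], cutting_allele: "Y"}]
'
  expect_error(load_genome_config(cfg_snp0), ">= 1")
  cfg_out <- '
chromosomes: [{name: c1, size: 10000, centromere: 5000}]
snps:
  assays: [{chrom: c1, pos: 20000, amplicon: 10, cut_fragments: [4, 6], cutting_allele: "Y"}]
'
  expect_error(load_genome_config(cfg_out), "outside chromosome")
  cfg_overlap <- '
chromosomes: [{name: c1, size: 10000, centromere: 5000}]
features:
  - {name: f1, chrom: c1, start: 2000, end: 3000, kind: gene}
  - {name: f2, chrom: c1, start: 2500, end: 3500, kind: gene}
'
  expect_error(load_genome_config(cfg_overlap), "overlap")
  cfg_badassay <- '
chromosomes: [{name: c1, size: 10000, centromere: 5000}]
snps:
  assays: [{chrom: c1, pos: 100, amplicon: 10, cut_fragments: [4, 5], cutting_allele: "Y"}]
'
  expect_error(load_genome_config(cfg_badassay), "sum to the amplicon")
})

test_that("chromosome_length equals an independent block-sum oracle", {
  expect_equal(chromosome_length(new_molecule("m", list(
    new_block("S", "c", 1, 1000)))), 1000)
  set.seed(42)
  for (i in 1:20) {
    n <- sample(1:6, 1)
    blocks <- lapply(seq_len(n), function(j) {
      s <- sample(1e5, 1); new_block(sample(c("S", "Y"), 1), "c", s,
                                     s + sample(5e4, 1))
    })
    mol <- new_molecule("m", blocks)
    oracle <- 0
    for (b in blocks) oracle <- oracle + (b$end - b$start + 1)
    expect_equal(chromosome_length(mol), oracle)
  }
})

test_that("zygosity_map matches the exhaustive coverage oracle", {
  g <- get_tiny()
  z <- zygosity_map(g, "chrA")
  expect_true(all(z$copies_total == 2) && all(z$copies_Y == 1))
  o <- zygosity_oracle(g, "chrA")
  expect_equal(z$copies_total, o$copies_total)
  expect_equal(z$copies_Y, o$copies_Y)

  # after a deletion on the S homolog, dosage totals 1 inside the deletion
  g2 <- apply_cnv(g, "chrA", c(20000, 25000), 1)
  z2 <- zygosity_map(g2, "chrA")
  o2 <- zygosity_oracle(g2, "chrA")
  expect_equal(z2$copies_total, o2$copies_total)
  expect_equal(z2$copies_Y, o2$copies_Y)
  inside <- z2$pos >= 20000 & z2$pos <= 25000
  expect_true(all(z2$copies_total[inside] == 1))

  # and after a half crossover, hom-Y dosage between invasion and cleavage
  g3 <- get_baseline()
  brk <- make_break(g3, list(zero_resection = TRUE))
  hc <- simulate_half_crossover(g3, brk, 250000)
  z3 <- zygosity_map(hc$genome, "chrIII")
  mid <- z3$pos > 181000 & z3$pos < 249000
  expect_true(all(z3$copies_total[mid] == 2 & z3$copies_Y[mid] == 2))
})

test_that("haplotype coordinate maps round-trip on shared sequence", {
  g <- get_baseline()
  pan <- g$snp_panel[g$snp_panel$chrom == "chrIII", ]
  y <- pan$pos_Y
  back <- fs2ltgc:::map_y_to_s(g, "chrIII", y)
  expect_equal(back, pan$pos)
})

test_that("balanced S/Y block structures conserve baseline size", {
  # reciprocal-exchange products of colinear homologs conserve total length
  g <- get_tiny()
  brk <- make_break(g, list(zero_resection = TRUE))
  hc <- simulate_half_crossover(g, brk, 40000)
  tot0 <- sum(unname(baseline_sizes(g, "chrA")))
  tot1 <- chromosome_length(hc$genome$molecules$chrA_S.rep) +
    chromosome_length(hc$genome$molecules$chrA_Y.rep)
  expect_equal(tot1, tot0)
  g <- get_baseline()
  # terminal LOH on a colinear chromosome conserves each homolog's size
  tl <- simulate_terminal_loh(g, "chrV", 355000, "Y")
  expect_equal(chromosome_length(tl$genome$molecules$chrV_S), 577000)
  expect_equal(chromosome_length(tl$genome$molecules$chrV_Y), 577000)
})
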