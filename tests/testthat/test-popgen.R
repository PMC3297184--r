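test_that("segregating sites separate substitutions from indel events", {
  # 4 x 6 toy: SNPs at columns 2 and 5, one 2-bp gap run at 3-4
  aln <- make_aln(c("AAGGCA", "ATGGCA", "AT--CA", "AA--GA"))
  st <- segregating_sites(aln)
  expect_equal(st$positions, c(2, 5))
  expect_equal(nrow(st$indel_events), 1)
  expect_equal(st$indel_events$start, 3)
  expect_equal(st$indel_events$end, 4)
  expect_setequal(st$indel_events$carriers[[1]], c("s03", "s04"))

  mono <- make_aln(rep("ACGTAC", 3))
  st0 <- segregating_sites(mono)
  expect_equal(length(st0$positions), 0)
  expect_equal(nrow(st0$indel_events), 0)

  # gap runs with different carrier patterns stay separate events
  two <- make_aln(c("A--TTA", "ACGT-A", "ACGTTA"))
  expect_equal(nrow(segregating_sites(two)$indel_events), 2)
})

test_that("parsimony-informative flags need two alleles carried twice", {
  aln <- make_aln(c("AAA", "AAA", "ATC", "ATC"))
  st <- segregating_sites(aln)
  expect_equal(st$positions, c(2, 3))
  expect_equal(st$informative, c(TRUE, TRUE))
  singleton <- segregating_sites(make_aln(c("AT", "AT", "AA", "AT")))
  expect_false(singleton$informative[1])
})

test_that("nucleotide diversity equals the brute-force pairwise oracle", {
  # single pair differing at 1 of 10 sites
  pair <- make_aln(c("AAAAAAAAAA", "AAAAAAAAAC"))
  expect_equal(nucleotide_diversity(pair), 0.1)
  expect_equal(nucleotide_diversity(make_aln(rep("ACGT", 4))), 0)
  expect_true(is.na(nucleotide_diversity(make_aln("ACGT"))))

  for (seed in 1:25) {
    aln <- random_aln(seed, n = 6, L = 30, snps = 5)
    expect_equal(nucleotide_diversity(aln), oracle_pi(aln$seq),
                 tolerance = 1e-12)
  }
})

test_that("Tajima's D matches an independent transcription and has the
           expected sign behaviour", {
  for (seed in 1:15) {
    aln <- random_aln(seed + 100, n = 8, L = 50, snps = 8)
    expect_equal(tajima_d(aln), oracle_tajima(aln$seq), tolerance = 1e-9)
  }

  # intermediate-frequency excess: every variant carried by half the sample
  mid <- make_aln(c(rep("AAAAAAAAAA", 4), rep("CCCCCAAAAA", 4)))
  expect_gt(tajima_d(mid), 0)
  # singleton excess: every variant private to one sample
  sing <- make_aln(c("AAAAAAAAAA", "CAAAAAAAAA", "ACAAAAAAAA",
                     "AACAAAAAAA", "AAACAAAAAA", "AAAACAAAAA"))
  expect_lt(tajima_d(sing), 0)

  expect_true(is.na(tajima_d(make_aln(rep("ACGT", 5)))))
  expect_true(is.na(tajima_d(make_aln(c("AC", "AT", "AC")))))
})

test_that("Fu & Li's D* and F* match an independent transcription", {
  for (seed in 1:15) {
    aln <- random_aln(seed + 200, n = 9, L = 60, snps = 9)
    got <- fu_li_star_tests(aln)
    ref <- oracle_fu_li(aln$seq)
    expect_equal(got$Dstar, ref$Dstar, tolerance = 1e-9)
    expect_equal(got$Fstar, ref$Fstar, tolerance = 1e-9)
  }
  und <- fu_li_star_tests(make_aln(rep("ACGT", 5)))
  expect_true(is.na(und$Dstar) && is.na(und$Fstar))
})

test_that("monomorphic columns never change S, H, or the neutrality tests", {
  aln <- random_aln(42, n = 7, L = 30, snps = 6)
  padded <- make_aln(paste0(apply(aln$seq, 1, paste, collapse = ""),
                            strrep("T", 20)))
  for (f in list(tajima_d,
                 function(a) fu_li_star_tests(a)$Dstar,
                 function(a) fu_li_star_tests(a)$Fstar,
                 haplotype_count,
                 function(a) length(segregating_sites(a)$positions))) {
    expect_equal(f(padded), f(aln), tolerance = 1e-12)
  }
})

test_that("Hudson-Kaplan Rm matches the disjoint-interval oracle", {
  # two crossovers in disjoint intervals
  sq2 <- make_aln(c("AAAAAA", "GGAAAA", "AAGGAA", "GGGGAA",
                    "AAAAGG", "AAGGGG"))
  got <- hudson_kaplan_rm(sq2)
  st <- segregating_sites(sq2)
  expect_equal(got$Rm, oracle_rm(st$states, st$positions))

  # no recombination on tree-generated data
  cfg <- sim_config(seed = 3, L = 300, n_haplotypes = 6,
                    mutations_per_branch = 2, samples_per_haplotype = 1)
  tree_aln <- simulate_alignment(cfg)$alignment
  expect_equal(hudson_kaplan_rm(tree_aln)$Rm, 0)

  for (seed in 1:30) {
    aln <- random_aln(seed + 300, n = 7, L = 12, snps = 8)
    st <- segregating_sites(aln)
    bi <- vapply(st$alleles, length, 1L) == 2
    expect_equal(hudson_kaplan_rm(aln)$Rm,
                 oracle_rm(st$states[, bi, drop = FALSE], st$positions[bi]),
                 info = paste("seed", seed))
  }
})

test_that("four-gamete intervals are reported and reduced correctly", {
  res <- hudson_kaplan_rm(square_aln())
  expect_equal(res$Rm, 1)
  expect_equal(res$intervals$left, 20)
  expect_equal(res$intervals$right, 60)
})

test_that("group/region summaries have the survey-table shape with nd flags", {
  aln <- make_aln(c("AAAAAA", "AATAAA", "AAAAAA", "CAAAAA", "CATAAA"),
                  groups = c("wild", "wild", "wild", "cult", "cult"))
  reg <- hap_regions(c("left", "right"), c(1, 4), c(3, 6), L = 6)
  tab <- group_summary(aln, reg)
  expect_equal(nrow(tab), 3 * 3)  # all + 2 groups, 2 regions + Total
  expect_setequal(unique(tab$region), c("left", "right", "Total"))

  cult <- tab[tab$group == "cult" & tab$region == "Total", ]
  expect_equal(cult$S, 1)
  expect_equal(cult$H, 2)
  # fewer than 4 samples: Tajima's D undefined, printed as nd
  expect_true(is.na(cult$tajima_D))
  expect_equal(cult$tajima_D_band, "nd")

  mono <- diversity_summary(make_aln(rep("ACGTT", 5)))
  expect_equal(mono$S, 0)
  expect_equal(mono$H, 1)
  expect_equal(mono$pi_per_bp, 0)
  expect_true(is.na(mono$tajima_D))

  expect_error(group_summary(aln, groups = "nope"), "unknown group")
})

test_that("the indel event is excluded from substitution statistics", {
  gap <- make_aln(c("AAATTTAA", "AAA---AA", "AAA---AA", "CAATTTAA"))
  st <- segregating_sites(gap)
  expect_equal(st$positions, 1)       # only the SNP at column 1
  expect_equal(nrow(st$indel_events), 1)
  # pi and D computed over the gap-free columns only
  expect_equal(length(st$gap_columns), 3)
})
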