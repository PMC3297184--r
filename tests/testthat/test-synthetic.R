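test_that("simulation output is byte-reproducible under a fixed seed", {
  cfg <- sim_config(seed = 99, L = 300, n_haplotypes = 5,
                    mutations_per_branch = 2, samples_per_haplotype = 2)
  s1 <- simulate_alignment(cfg)
  s2 <- simulate_alignment(cfg)
  expect_identical(s1$alignment$seq, s2$alignment$seq)
  expect_identical(s1$truth$mutations, s2$truth$mutations)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  sim_write(s1, d1); sim_write(s2, d2)
  expect_identical(readLines(file.path(d1, "alignment.fasta")),
                   readLines(file.path(d2, "alignment.fasta")))
  expect_identical(readLines(file.path(d1, "truth.json")),
                   readLines(file.path(d2, "truth.json")))
})

test_that("replaying the truth record regenerates the identical alignment", {
  cfg <- sim_preset_domestication()
  sim <- simulate_alignment(cfg)
  replay <- truth_replay(sim$truth)
  expect_identical(replay$seq, sim$alignment$seq)
  expect_identical(replay$groups, sim$alignment$groups)

  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_alignment(sim$alignment, f1)
  write_alignment(replay, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("degenerate and infeasible configurations are handled", {
  flat <- simulate_alignment(sim_config(seed = 1, L = 100, n_haplotypes = 4,
                                        mutations_per_branch = 0,
                                        samples_per_haplotype = 2))
  expect_equal(length(collapse_haplotypes(flat$alignment)$haplotypes), 1)
  expect_equal(length(segregating_sites(flat$alignment)$positions), 0)

  # two tips: every repeat pair spans all tips, so none is detectable
  expect_error(
    simulate_alignment(sim_config(seed = 2, L = 100, n_haplotypes = 2,
                                  mutations_per_branch = 2,
                                  n_homoplasies = 1)),
    "infeasible")

  expect_error(sim_config(L = 1), "L must be")
  expect_error(sim_config(samples_per_haplotype = 0), ">= 1")
})

test_that("planted repeat mutations are recovered by the network count", {
  for (seed in c(4, 21, 35)) {
    cfg <- sim_config(seed = seed, L = 800, n_haplotypes = 6,
                      mutations_per_branch = 3, n_homoplasies = 2,
                      samples_per_haplotype = 1)
    sim <- simulate_alignment(cfg)
    expect_equal(sum(sim$truth$mutations$homoplasy), 2)
    net <- build_network(collapse_haplotypes(sim$alignment))
    expect_equal(count_homoplasies(net)$H_net, 2, info = paste("seed", seed))
  }
})

test_that("recombinant mosaics are mosaic sequences and raise Rm", {
  cfg <- sim_config(seed = 8, L = 600, n_haplotypes = 5,
                    mutations_per_branch = 3,
                    recombinants = data.frame(parent1 = 1, parent2 = 5,
                                              breakpoint = 300),
                    samples_per_haplotype = 1)
  sim <- simulate_alignment(cfg)
  aln <- sim$alignment
  # the appended haplotype equals parent1 left of the breakpoint and
  # parent2 right of it
  rec <- aln$seq[6, ]
  expect_identical(rec[1:300], aln$seq[1, 1:300])
  expect_identical(rec[301:600], aln$seq[5, 301:600])
  # parents differ on both flanks, and an ancestral-state lineage is
  # sampled, so the four-gamete test must fire
  expect_gte(hudson_kaplan_rm(aln)$Rm, 1)
})

test_that("the domestication preset has the survey-scale structure", {
  cfg <- sim_preset_domestication()
  sim <- simulate_alignment(cfg)
  expect_equal(sim$alignment$n, 113)
  expect_equal(sim$alignment$L, 2560)
  hs <- collapse_haplotypes(sim$alignment)
  expect_equal(length(hs$haplotypes), 11)
  st <- segregating_sites(sim$alignment)
  expect_equal(nrow(st$indel_events), 1)
  expect_equal(st$indel_events$start, 562)
  expect_equal(st$indel_events$length, 46)
  # wild groups are spread over more haplotypes than cultivated groups
  wild_h <- unique(hs$sample_haplotype[sim$alignment$groups %in%
                                         c("wild-turkey", "wild-other")])
  cult_h <- unique(hs$sample_haplotype[sim$alignment$groups %in%
                                         preset_cultivated_groups()])
  expect_gte(length(wild_h), 5)
  # wild diversity exceeds cultivated diversity
  wild_ids <- sim$alignment$sample_ids[sim$alignment$groups %in%
                                         c("wild-turkey", "wild-other")]
  pi_w <- nucleotide_diversity(sim$alignment, group = "wild-turkey")
  pi_d <- nucleotide_diversity(sim$alignment, group = "dehiscent")
  expect_gt(pi_w, pi_d)
})
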