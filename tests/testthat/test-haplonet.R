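test_that("haplotype collapsing is deterministic and conserves membership", {
  aln <- make_aln(c("AAT", "AAT", "CAT", "AAA", "CAT", "AAT"),
                  groups = c("w", "w", "w", "c", "c", "c"))
  hs <- collapse_haplotypes(aln)
  expect_equal(length(hs$haplotypes), 3)
  expect_equal(hs$haplotypes[[1]]$members, c("s01", "s02", "s06"))
  expect_equal(hs$haplotypes[[2]]$members, c("s03", "s05"))
  expect_equal(hs$haplotypes[[3]]$members, "s04")
  expect_equal(hs$haplotypes[[1]]$roman, "I")
  expect_equal(sum(lengths(lapply(hs$haplotypes, `[[`, "members"))), aln$n)

  one <- collapse_haplotypes(make_aln(rep("ACGT", 5)))
  expect_equal(length(one$haplotypes), 1)
  expect_equal(length(one$haplotypes[[1]]$members), 5)
})

test_that("indel_mode controls whether the indel separates haplotypes", {
  aln <- make_aln(c("AATTA", "AATTA", "AA--A", "AA--A"))
  with_indel <- collapse_haplotypes(aln, indel_mode = "include")
  without <- collapse_haplotypes(aln, indel_mode = "exclude")
  expect_equal(length(with_indel$haplotypes), 2)
  expect_equal(length(without$haplotypes), 1)
})

test_that("member conservation holds across simulated datasets", {
  for (seed in c(2, 9, 31)) {
    cfg <- sim_config(seed = seed, L = 400, n_haplotypes = 5,
                      mutations_per_branch = 2, samples_per_haplotype = 3)
    aln <- simulate_alignment(cfg)$alignment
    hs <- collapse_haplotypes(aln)
    expect_equal(sum(lengths(lapply(hs$haplotypes, `[[`, "members"))),
                 aln$n)
  }
})

test_that("tree-generated haplotypes give back the tree: acyclic, one edge
           per planted mutation, no homoplasy", {
  for (seed in c(5, 17, 23, 40)) {
    cfg <- sim_config(seed = seed, L = 500, n_haplotypes = 6,
                      mutations_per_branch = 2, samples_per_haplotype = 1)
    sim <- simulate_alignment(cfg)
    net <- build_network(collapse_haplotypes(sim$alignment))
    n_nodes <- nrow(net$node_states)
    expect_equal(nrow(net$edges), n_nodes - 1)   # connected + acyclic
    expect_equal(net$m, nrow(sim$truth$mutations))
    expect_equal(count_homoplasies(net)$H_net, 0)
    # every planted position appears on exactly one edge
    lab <- unlist(strsplit(net$edges$positions, ","))
    expect_setequal(as.integer(lab), sim$truth$mutations$pos)
    expect_equal(anyDuplicated(lab), 0)
  }
})

test_that("a single haplotype yields a single-node network with m = 0", {
  net <- build_network(collapse_haplotypes(make_aln(rep("ACGT", 3))))
  expect_equal(nrow(net$node_states), 1)
  expect_equal(nrow(net$edges), 0)
  expect_equal(net$m, 0)
  expect_equal(count_homoplasies(net)$H_net, 0)
})

test_that("character conflict is retained as a reticulation cycle", {
  net <- build_network(collapse_haplotypes(square_aln()))
  # 4 sampled nodes, 4 edges: one cycle, no median needed
  expect_equal(nrow(net$edges) - nrow(net$node_states) + 1, 1)
  hp <- count_homoplasies(net)
  expect_equal(hp$H_net, 4)
  # the homoplasy list is exactly the set of repeated edge labels
  lab <- unlist(strsplit(net$edges$positions, ","))
  expect_setequal(names(hp$per_position), unique(lab[duplicated(lab)]))
})

test_that("network construction is deterministic", {
  sim <- simulate_alignment(sim_preset_domestication())
  n1 <- build_network(collapse_haplotypes(sim$alignment))
  n2 <- build_network(collapse_haplotypes(sim$alignment))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_network_dot(n1, f1)
  write_network_dot(n2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(n1$edges$positions, n2$edges$positions)
})

test_that("the DCA is the node with shortest total path to cultivated nodes", {
  # star with sampled ancestor: the centre is the planted ancestor
  aln <- star_aln(k = 4, n_priv = 2)
  net <- build_network(collapse_haplotypes(aln))
  dca <- identify_dca(net, "cultivated")
  expect_equal(dca$node, "H01")  # the sampled ancestral haplotype
  expect_equal(dca$scores$total_length[1], 8)

  expect_error(identify_dca(net, "no-such-group"), "no cultivated")

  single <- build_network(collapse_haplotypes(
    make_aln(rep("AAAA", 2), groups = c("cult", "cult"))))
  expect_equal(identify_dca(single, "cult")$node, "H01")
})

test_that("the haplotype table has the per-sample site-composition layout", {
  aln <- make_aln(c("AATTA", "AATTA", "CA--A", "CA--A", "CATTG"),
                  groups = c("w", "w", "c", "c", "c"))
  hs <- collapse_haplotypes(aln)
  tab <- export_haplotype_table(hs, aln)
  expect_equal(nrow(tab), 5)
  expect_equal(names(tab)[1:3], c("group", "sample_id", "haplotype"))
  expect_true(all(c("pos1", "pos5") %in% names(tab)))
  expect_true(any(grepl("^indel", names(tab))))

  # no segregating sites: id/group/haplotype columns only
  plain <- make_aln(rep("AAAA", 3))
  tab0 <- export_haplotype_table(collapse_haplotypes(plain), plain)
  expect_equal(names(tab0), c("group", "sample_id", "haplotype"))
})

test_that("network exports are readable GraphML/DOT/NEXUS", {
  sim <- simulate_alignment(sim_config(seed = 11, L = 300, n_haplotypes = 4,
                                       mutations_per_branch = 2,
                                       samples_per_haplotype = 2))
  net <- build_network(collapse_haplotypes(sim$alignment))
  g1 <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, g1)
  back <- igraph::read_graph(g1, format = "graphml")
  expect_equal(igraph::vcount(back), nrow(net$node_states))
  expect_equal(igraph::ecount(back), nrow(net$edges))

  d1 <- withr::local_tempfile(fileext = ".dot")
  write_network_dot(net, d1)
  expect_true(any(grepl("label", readLines(d1))))

  nx <- withr::local_tempfile(fileext = ".nex")
  export_nexus(sim$alignment, nx, collapse = TRUE)
  dat <- ape::read.nexus.data(nx)
  expect_equal(length(dat), length(net$hapset$haplotypes))
})
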