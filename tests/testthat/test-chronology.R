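test_that("rate calibration is k / (L * T) with input validation", {
  expect_equal(calibrate_rate(k = 2, L = 1000, age_years = 1000), 2e-6)
  expect_error(calibrate_rate(k = 1, L = 1000, age_years = 0), "age_years")
  expect_error(calibrate_rate(k = 0, L = 1000, age_years = 100),
               "uninformative")
})

test_that("doubling the calibration age halves the rate and doubles ages", {
  aln <- star_aln(k = 4, n_priv = 3, L = 80)
  net <- build_network(collapse_haplotypes(aln))
  a1 <- calibrate_from_network(net, "H01", 1000, L = 80)
  a2 <- calibrate_from_network(net, "H01", 2000, L = 80)
  expect_equal(a2$r, a1$r / 2)
  expect_equal(a2$chronology$age_years, 2 * a1$chronology$age_years)
})

test_that("the calibration node reproduces its age under every depth mode", {
  aln <- square_aln(L = 150, left = c(10, 20), right = c(90, 100, 110))
  net <- build_network(collapse_haplotypes(aln))
  for (mode in c("mean_tip_path", "max_tip_path", "min_tip_path")) {
    res <- calibrate_from_network(net, "H01", 5000, L = 150,
                                  depth_mode = mode)
    chron <- res$chronology
    expect_equal(chron$age_years[chron$node == "H01"], 5000,
                 info = mode)
  }
})

test_that("sampled tip-only nodes get age zero and ages are non-negative", {
  aln <- star_aln(k = 5, n_priv = 2, L = 90)
  net <- build_network(collapse_haplotypes(aln))
  chron <- date_nodes(net, r = 1e-6, L = 90, root = "H01")
  tips <- setdiff(chron$node, "H01")
  expect_true(all(chron$age_years[chron$node %in% tips] == 0))
  expect_true(all(chron$age_years >= 0))
  # the star centre sits n_priv substitutions above every tip
  expect_equal(chron$depth[chron$node == "H01"], 2)
})

test_that("chronology exports round-trip through TSV", {
  aln <- star_aln(k = 3, n_priv = 2, L = 60)
  net <- build_network(collapse_haplotypes(aln))
  chron <- date_nodes(net, r = 2e-5, L = 60, root = "H01")
  f <- withr::local_tempfile(fileext = ".tsv")
  export_chronology(chron, f)
  back <- utils::read.delim(f)
  expect_equal(back$node, chron$node)
  expect_equal(back$depth, chron$depth)
  expect_equal(back$age_years, chron$age_years, tolerance = 1e-9)
  expect_true(all(back$depth_mode == "mean_tip_path"))
})

test_that("recovered ages sharpen as planted mutation counts grow", {
  # star genealogies with Poisson-distributed private mutations: the true
  # centre age is mu/(r*L); the relative error of the recovered age shrinks
  # with increasing mu
  r <- 1e-5; L <- 400
  rel_err <- function(mu, seeds) {
    errs <- vapply(seeds, function(s) {
      set.seed(s)
      k <- 6
      counts <- stats::rpois(k, mu)
      if (all(counts == 0)) return(NA_real_)
      base <- rep("A", L)
      seqs <- paste(base, collapse = "")
      pos <- 1
      for (i in seq_len(k)) {
        sq <- base
        if (counts[i] > 0) {
          sq[pos:(pos + counts[i] - 1)] <- "G"
          pos <- pos + counts[i]
        }
        seqs <- c(seqs, paste(sq, collapse = ""))
      }
      aln <- hap_alignment(c("anc", sprintf("d%d", 1:k)), seqs)
      net <- build_network(collapse_haplotypes(aln))
      chron <- date_nodes(net, r, L, root = "H01")
      est <- chron$age_years[chron$node == "H01"]
      abs(est - mu / (r * L)) / (mu / (r * L))
    }, 0)
    mean(errs, na.rm = TRUE)
  }
  lo <- rel_err(2, 1:12)
  hi <- rel_err(12, 1:12)
  expect_lt(hi, lo)
})
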