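# Fixture builders shared across test files.

# alignment from a vector of equal-length sequence strings
make_aln <- function(seqs, groups = NULL, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("s%02d", seq_along(seqs))
  if (!is.null(groups)) groups <- stats::setNames(groups, ids)
  hap_alignment(ids, seqs, groups)
}

# random gap-free alignment: n samples x L columns over ACGT with a given
# number of planted biallelic SNP columns
random_aln <- function(seed, n = 8, L = 40, snps = 6) {
  set.seed(seed)
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  mat <- matrix(rep(base, each = n), nrow = n)
  cols <- sample(L, snps)
  for (j in cols) {
    alt <- sample(setdiff(c("A", "C", "G", "T"), base[j]), 1)
    carriers <- sample(n, sample(1:(n - 1), 1))
    mat[carriers, j] <- alt
  }
  make_aln(apply(mat, 1, paste, collapse = ""))
}

# the canonical minimal recombination configuration: sampled ancestor, two
# parents diverged on opposite flanks, and their mosaic recombinant
square_aln <- function(L = 100, left = c(10, 20), right = c(60, 70)) {
  base <- rep("A", L)
  mk <- function(cols) { s <- base; s[cols] <- "G"; paste(s, collapse = "") }
  make_aln(c(paste(base, collapse = ""), mk(left), mk(right),
             mk(c(left, right))),
           groups = c("wild", "wild", "wild", "cultivated"),
           ids = c("anc", "p1", "p2", "rec"))
}

# star phylogeny: sampled ancestral haplotype plus k derived haplotypes,
# each carrying n_priv private mutations
star_aln <- function(k = 4, n_priv = 2, L = 60, groups = NULL) {
  base <- rep("A", L)
  seqs <- paste(base, collapse = "")
  pos <- 1
  for (i in seq_len(k)) {
    s <- base
    s[pos:(pos + n_priv - 1)] <- "G"
    pos <- pos + n_priv
    seqs <- c(seqs, paste(s, collapse = ""))
  }
  if (is.null(groups)) groups <- c("wild", rep("cultivated", k))
  make_aln(seqs, groups = groups,
           ids = c("anc", sprintf("d%d", seq_len(k))))
}
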