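# Independent reference computations used to check the package's
# implementations.  These are deliberately naive (double loops, exhaustive
# enumeration, dynamic programming) and share no code with R/.

MISSING <- c("-", "N")

# mean pairwise proportion of differing sites, pairwise deletion
oracle_pi <- function(mat) {
  n <- nrow(mat)
  vals <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- mat[i, ]; b <- mat[j, ]
      ok <- !(a %in% MISSING) & !(b %in% MISSING)
      vals <- c(vals, sum(a[ok] != b[ok]) / sum(ok))
    }
  }
  mean(vals)
}

# Tajima (1989) D, complete deletion, transcribed afresh from the published
# formulas
oracle_tajima <- function(mat) {
  keep <- apply(mat, 2, function(col) !any(col %in% MISSING))
  mat <- mat[, keep, drop = FALSE]
  n <- nrow(mat)
  S <- sum(apply(mat, 2, function(col) length(unique(col)) > 1))
  if (n < 4 || S == 0) return(NA_real_)
  k <- 0
  np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    k <- k + sum(mat[i, ] != mat[j, ]); np <- np + 1
  }
  k <- k / np
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n * n + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / (a1 * a1)
  (k - S / a1) / sqrt((c1 / a1) * S + (c2 / (a1 * a1 + a2)) * S * (S - 1))
}

# Fu & Li (1993) D* and F* without outgroup, corrected variance
# coefficients, transcribed afresh
oracle_fu_li <- function(mat) {
  keep <- apply(mat, 2, function(col) !any(col %in% MISSING))
  mat <- mat[, keep, drop = FALSE]
  n <- nrow(mat)
  eta <- 0; eta_s <- 0
  for (col_i in seq_len(ncol(mat))) {
    tab <- table(mat[, col_i])
    if (length(tab) < 2) next
    eta <- eta + length(tab) - 1
    s <- sum(tab == 1)
    if (s == length(tab)) s <- s - 1
    eta_s <- eta_s + s
  }
  if (n < 4 || eta == 0)
    return(list(Dstar = NA_real_, Fstar = NA_real_))
  k <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    k <- k + sum(mat[i, ] != mat[j, ]); np <- np + 1
  }
  k <- k / np
  a <- sum(1 / seq_len(n - 1))
  b <- sum(1 / seq_len(n - 1)^2)
  a1 <- a + 1 / n
  cn <- 2 * (n * a - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (3 / 2 - (2 * a1 - 3) / (n - 2) - 1 / n)
  vD <- ((n / (n - 1))^2 * b + a^2 * dn -
           2 * (n * a * (a + 1)) / (n - 1)^2) / (a^2 + b)
  uD <- (n / (n - 1)) * (a - n / (n - 1)) - vD
  Dstar <- (n / (n - 1) * eta - a * eta_s) / sqrt(uD * eta + vD * eta^2)
  vF <- (dn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) -
           2 / (n - 1) * (4 * b - 6 + 8 / n)) / (a^2 + b)
  uF <- (n / (n - 1) + (n + 1) / (3 * (n - 1)) - 4 / (n * (n - 1)) +
           2 * (n + 1) / (n - 1)^2 * (a1 - 2 * n / (n + 1))) / a - vF
  Fstar <- (k - (n - 1) / n * eta_s) / sqrt(uF * eta + vF * eta^2)
  list(Dstar = Dstar, Fstar = Fstar)
}

# upper-tail binomial by exhaustive enumeration of outcome sequences
oracle_branch_tail <- function(N, H, p) {
  if (H == 0) return(1)
  total <- 0
  grid <- expand.grid(rep(list(0:1), N))
  for (r in seq_len(nrow(grid))) {
    x <- as.numeric(grid[r, ])
    if (sum(x) >= H)
      total <- total + prod(ifelse(x == 1, p, 1 - p))
  }
  total
}

# maximum number of disjoint four-gamete intervals by dynamic programming
# over all incompatible site pairs (no interval pre-reduction)
oracle_rm <- function(mat, positions) {
  k <- ncol(mat)
  ivl <- NULL
  if (k >= 2) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      a <- mat[, i]; b <- mat[, j]
      ok <- !(a %in% MISSING) & !(b %in% MISSING)
      if (length(unique(paste(a[ok], b[ok]))) == 4)
        ivl <- rbind(ivl, c(positions[i], positions[j]))
    }
  }
  if (is.null(ivl)) return(0L)
  ivl <- ivl[order(ivl[, 2], ivl[, 1]), , drop = FALSE]
  nI <- nrow(ivl)
  best <- function(idx, min_start) {
    if (idx > nI) return(0L)
    skip <- best(idx + 1L, min_start)
    take <- 0L
    if (ivl[idx, 1] >= min_start)
      take <- 1L + best(idx + 1L, ivl[idx, 2])
    max(skip, take)
  }
  best(1L, -Inf)
}
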