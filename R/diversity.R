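## Complete-deletion working matrix: samples restricted to a group, columns to
## a region, then every column containing a gap or ambiguous base dropped.
clean_matrix <- function(aln, regions = NULL, region = NULL, group = NULL) {
  samples <- group_samples(aln, group)
  cols <- region_columns(regions, region, aln$L)
  mat <- aln$seq[samples, cols, drop = FALSE]
  ok <- !apply(mat == "-" | mat == "N", 2, any)
  mat[, ok, drop = FALSE]
}

## Per-site allele count tables for the variable columns of a matrix.
site_allele_tables <- function(mat) {
  tabs <- apply(mat, 2, function(col) table(col), simplify = FALSE)
  tabs[vapply(tabs, length, 1L) >= 2L]
}

#' Nucleotide diversity (Nei's pi per site)
#'
#' Mean proportion of differing sites over all unordered sample pairs, with
#' pairwise deletion of gap/missing positions (each pair is compared over the
#' columns where both samples carry a base).
#'
#' @param aln a [hap_alignment()] object.
#' @param regions,region optional region restriction.
#' @param group optional group label restricting the samples.
#' @return pi per bp (numeric); `NA` when fewer than two samples.
#' @export
nucleotide_diversity <- function(aln, regions = NULL, region = NULL,
                                 group = NULL) {
  samples <- group_samples(aln, group)
  if (length(samples) < 2L) return(NA_real_)
  cols <- region_columns(regions, region, aln$L)
  mat <- aln$seq[samples, cols, drop = FALSE]
  dna <- ape::as.DNAbin(tolower(mat))
  d <- ape::dist.dna(dna, model = "raw", pairwise.deletion = TRUE)
  mean(d)
}

#' Watterson's theta per site
#'
#' `S / (a1 * L_eff)` where `a1 = sum(1/i, i = 1..n-1)` and `L_eff` is the
#' number of complete-deletion columns analysed.
#'
#' @inheritParams nucleotide_diversity
#' @return theta_w per bp; `NA` when fewer than two samples or no sites.
#' @export
watterson_theta <- function(aln, regions = NULL, region = NULL, group = NULL) {
  mat <- clean_matrix(aln, regions, region, group)
  n <- nrow(mat)
  if (n < 2L || ncol(mat) == 0L) return(NA_real_)
  S <- length(site_allele_tables(mat))
  a1 <- sum(1 / seq_len(n - 1L))
  S / (a1 * ncol(mat))
}

## Mean pairwise difference count (not per site) under complete deletion.
mean_pairwise_diffs <- function(mat) {
  n <- nrow(mat)
  total <- 0
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      total <- total + sum(mat[i, ] != mat[j, ])
  total / (n * (n - 1L) / 2)
}

#' Tajima's D
#'
#' Tajima (1989) neutrality statistic contrasting mean pairwise differences
#' with the Watterson estimate, under complete deletion of gap/missing
#' columns.  Undefined cases (fewer than 4 samples, no segregating sites)
#' return `NA` rather than an error: summary tables print them as `"nd"`.
#'
#' @inheritParams nucleotide_diversity
#' @return the D statistic, or `NA` when undefined.
#' @export
tajima_d <- function(aln, regions = NULL, region = NULL, group = NULL) {
  mat <- clean_matrix(aln, regions, region, group)
  n <- nrow(mat)
  if (n < 4L || ncol(mat) == 0L) return(NA_real_)
  S <- length(site_allele_tables(mat))
  if (S == 0L) return(NA_real_)
  k <- mean_pairwise_diffs(mat)
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Fu and Li's D* and F* (no outgroup)
#'
#' Star variants of the Fu & Li (1993) tests, contrasting the total mutation
#' count and mean pairwise differences against the singleton count, using the
#' corrected variance coefficients in standard use.  Complete deletion of
#' gap/missing columns.
#'
#' @inheritParams nucleotide_diversity
#' @return named list with elements `Dstar` and `Fstar` (`NA` when n < 4 or
#'   no segregating sites).
#' @export
fu_li_star_tests <- function(aln, regions = NULL, region = NULL,
                             group = NULL) {
  mat <- clean_matrix(aln, regions, region, group)
  n <- nrow(mat)
  und <- list(Dstar = NA_real_, Fstar = NA_real_)
  if (n < 4L || ncol(mat) == 0L) return(und)
  tabs <- site_allele_tables(mat)
  if (length(tabs) == 0L) return(und)
  ## eta: total mutations (alleles - 1 per site); eta_s: singleton mutations
  eta <- sum(vapply(tabs, function(t) length(t) - 1L, 1L))
  eta_s <- sum(vapply(tabs, function(t) {
    s <- sum(t == 1L)
    if (s == length(t)) s - 1L else s
  }, 1L))
  k <- mean_pairwise_diffs(mat)

  i <- seq_len(n - 1L)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  an1 <- a1 + 1 / n
  cn <- 2 * (n * a1 - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (1.5 - (2 * an1 - 3) / (n - 2) - 1 / n)

  vD <- ((n / (n - 1))^2 * a2 + a1^2 * dn -
           2 * n * a1 * (a1 + 1) / (n - 1)^2) / (a1^2 + a2)
  uD <- (n / (n - 1)) * (a1 - n / (n - 1)) - vD
  Dstar <- ((n / (n - 1)) * eta - a1 * eta_s) /
    sqrt(uD * eta + vD * eta^2)

  vF <- (dn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) -
           (2 / (n - 1)) * (4 * a2 - 6 + 8 / n)) / (a1^2 + a2)
  uF <- (n / (n - 1) + (n + 1) / (3 * (n - 1)) - 4 / (n * (n - 1)) +
           2 * (n + 1) / (n - 1)^2 * (an1 - 2 * n / (n + 1))) / a1 - vF
  Fstar <- (k - ((n - 1) / n) * eta_s) / sqrt(uF * eta + vF * eta^2)

  list(Dstar = Dstar, Fstar = Fstar)
}

#' Significance band for a neutrality statistic
#'
#' Maps a Tajima's D or Fu & Li star statistic onto the conventional
#' reporting bands (`P > 0.10`, `P < 0.05`, `P < 0.02`) using published
#' large-sample critical values (two-sided beta approximation for D;
#' simulation-derived tables for D*/F*).  The bands mirror how such tests are
#' conventionally reported; no resampling is performed.
#'
#' @param stat the observed statistic.
#' @param test one of `"tajima_d"`, `"fu_li_dstar"`, `"fu_li_fstar"`.
#' @return a character band label, `"nd"` for `NA` input.
#' @export
significance_band <- function(stat,
                              test = c("tajima_d", "fu_li_dstar",
                                       "fu_li_fstar")) {
  test <- match.arg(test)
  if (is.na(stat)) return("nd")
  ## approximate two-sided critical magnitudes at P = 0.10 / 0.05 / 0.02
  crit <- switch(test,
    tajima_d   = c(1.57, 1.81, 2.13),
    fu_li_dstar = c(1.34, 1.57, 1.93),
    fu_li_fstar = c(1.38, 1.61, 1.91))
  a <- abs(stat)
  if (a < crit[1]) "P > 0.10"
  else if (a < crit[2]) "P < 0.10"
  else if (a < crit[3]) "P < 0.05"
  else "P < 0.02"
}

#' Haplotype count within a group/region
#'
#' Number of distinct sequences after complete deletion of gap/missing
#' columns, matching how the diversity tables count haplotypes per region.
#'
#' @inheritParams nucleotide_diversity
#' @return integer haplotype count.
#' @export
haplotype_count <- function(aln, regions = NULL, region = NULL,
                            group = NULL) {
  mat <- clean_matrix(aln, regions, region, group)
  if (ncol(mat) == 0L) return(1L)
  length(unique(apply(mat, 1, paste, collapse = "")))
}

#' Full diversity summary for one group/region
#'
#' @inheritParams nucleotide_diversity
#' @return data.frame with one row: `group`, `region`, `n`, `L_effective`,
#'   `S`, `H`, `pi_per_bp`, `theta_w`, `tajima_D`, `fu_li_Dstar`,
#'   `fu_li_Fstar`, `Rm`.  Undefined statistics are `NA`.
#' @export
diversity_summary <- function(aln, regions = NULL, region = NULL,
                              group = NULL) {
  mat <- clean_matrix(aln, regions, region, group)
  fl <- fu_li_star_tests(aln, regions, region, group)
  rm_res <- hudson_kaplan_rm(aln, group = group, regions = regions,
                             region = region)
  data.frame(
    group = if (is.null(group)) "all" else group,
    region = if (is.null(region)) "all" else region,
    n = nrow(mat),
    L_effective = ncol(mat),
    S = length(site_allele_tables(mat)),
    H = haplotype_count(aln, regions, region, group),
    pi_per_bp = nucleotide_diversity(aln, regions, region, group),
    theta_w = watterson_theta(aln, regions, region, group),
    tajima_D = tajima_d(aln, regions, region, group),
    fu_li_Dstar = fl$Dstar,
    fu_li_Fstar = fl$Fstar,
    Rm = rm_res$Rm,
    stringsAsFactors = FALSE
  )
}

#' Group-by-region diversity table
#'
#' Computes the classic locus-survey summary table: for every group and every
#' annotated region (plus `"Total"`), the segregating-site count `S`,
#' haplotype number `H`, nucleotide diversity per bp, and Tajima's D.
#'
#' @param aln a [hap_alignment()] object.
#' @param regions a [hap_regions()] annotation (or `NULL` for total only).
#' @param groups character vector of group labels; defaults to all labels in
#'   the alignment (plus `"all"` first).
#' @param file optional path: writes the long-format table as TSV.
#' @return long data.frame with columns `group`, `region`, `n`, `S`, `H`,
#'   `pi_per_bp`, `tajima_D`, `tajima_D_band`.
#' @export
group_summary <- function(aln, regions = NULL, groups = NULL, file = NULL) {
  stopifnot(inherits(aln, "hap_alignment"))
  if (is.null(groups)) groups <- c("all", sort(unique(aln$groups)))
  unknown <- setdiff(groups, c("all", unique(aln$groups)))
  if (length(unknown))
    stop("unknown group(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  region_names <- c(if (!is.null(regions)) regions$name, "Total")
  rows <- list()
  for (g in groups) {
    for (r in region_names) {
      rr <- if (identical(r, "Total")) NULL else r
      gg <- if (identical(g, "all")) NULL else g
      mat <- clean_matrix(aln, regions, rr, gg)
      D <- tajima_d(aln, regions, rr, gg)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, region = r, n = nrow(mat),
        S = length(site_allele_tables(mat)),
        H = haplotype_count(aln, regions, rr, gg),
        pi_per_bp = nucleotide_diversity(aln, regions, rr, gg),
        tajima_D = D,
        tajima_D_band = significance_band(D, "tajima_d"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(file)) {
    fmt <- out
    fmt$tajima_D <- ifelse(is.na(fmt$tajima_D), "nd",
                           formatC(fmt$tajima_D, digits = 4, format = "f"))
    fmt$pi_per_bp <- ifelse(is.na(fmt$pi_per_bp), "nd",
                            formatC(fmt$pi_per_bp, digits = 5, format = "f"))
    utils::write.table(fmt, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}
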