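# Diversity and differentiation statistics with missing-data-aware
# denominators. Window coordinates are 0-based half-open; site positions
# 1-based.

# restrict to window rows
.window_rows <- function(sites, window) {
  which(sites$chrom == window$chrom & sites$pos > window$start &
          sites$pos <= window$end)
}

#' Nucleotide diversity in a window
#'
#' Ratio-of-sums estimator: pi = sum(d_s) / sum(c_s) over sites, where at
#' a site with n non-missing alleles and allele count a, d_s = a(n-a) and
#' c_s = n(n-1)/2. Monomorphic genotyped sites contribute only c_s. With
#' \code{invariant = "complete"} every unrecorded position in the window
#' is treated as a fully genotyped invariant site (the convention for
#' synthetic data without a depth field); with \code{"none"} only
#' recorded sites enter the denominator.
#'
#' @param gm A \code{\link{genotype_matrix}} restricted to one
#'   population.
#' @param window A list or one-row data frame with \code{chrom},
#'   \code{start}, \code{end} (0-based half-open).
#' @param invariant How unrecorded positions contribute to the
#'   denominator.
#' @return pi per site, or NA when the denominator is zero.
#' @export
pi_window <- function(gm, window, invariant = c("complete", "none")) {
  invariant <- match.arg(invariant)
  rows <- .window_rows(gm$sites, window)
  d <- gm$dosage[rows, , drop = FALSE]
  sc <- .site_counts(d)
  num <- sum(sc$alt * (sc$n_alleles - sc$alt))
  den <- sum(sc$n_alleles * (sc$n_alleles - 1) / 2)
  if (invariant == "complete") {
    n_full <- 2 * length(gm$samples)
    n_unrec <- (window$end - window$start) - length(rows)
    den <- den + n_unrec * n_full * (n_full - 1) / 2
  }
  if (den <= 0) return(NA_real_)
  num / den
}

# Tajima (1989) constants at haplotype count n
.tajima_const <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, e1 = e1, e2 = e2)
}

#' Tajima's D in a window
#'
#' Standard Tajima (1989) statistic over the window's segregating sites:
#' D = (khat - S/a1) / sqrt(e1 S + e2 S (S-1)). Sites contribute with
#' their own non-missing allele count; the constants use the window-modal
#' count.
#'
#' @param gm A \code{\link{genotype_matrix}} restricted to one
#'   population.
#' @param window Window as in \code{\link{pi_window}}.
#' @return D, or NA when S = 0, n < 4, or the variance is undefined.
#' @export
tajima_d_window <- function(gm, window) {
  rows <- .window_rows(gm$sites, window)
  if (!length(rows)) return(NA_real_)
  d <- gm$dosage[rows, , drop = FALSE]
  sc <- .site_counts(d)
  seg <- sc$alt > 0 & sc$alt < sc$n_alleles & sc$n_alleles >= 2
  S <- sum(seg)
  if (S < 1) return(NA_real_)
  n_site <- sc$n_alleles[seg]
  n <- as.integer(names(sort(table(n_site), decreasing = TRUE))[1])
  if (n < 4) return(NA_real_)
  a <- sc$alt[seg]
  khat <- sum(a * (n_site - a) / (n_site * (n_site - 1) / 2))
  k <- .tajima_const(n)
  v <- k$e1 * S + k$e2 * S * (S - 1)
  if (v <= 0) return(NA_real_)
  (khat - S / k$a1) / sqrt(v)
}

#' Watterson's theta in a window
#'
#' Per-site Watterson estimator: S / a1(n) over the comparable-site
#' denominator used by \code{\link{pi_window}}, with n the window-modal
#' non-missing allele count of the segregating sites.
#'
#' @inheritParams pi_window
#' @return Watterson's theta per site, or NA without segregating sites
#'   or comparable sites.
#' @export
theta_w_window <- function(gm, window, invariant = c("complete", "none")) {
  invariant <- match.arg(invariant)
  rows <- .window_rows(gm$sites, window)
  d <- gm$dosage[rows, , drop = FALSE]
  sc <- .site_counts(d)
  seg <- sc$alt > 0 & sc$alt < sc$n_alleles & sc$n_alleles >= 2
  S <- sum(seg)
  # comparable positions: recorded sites plus (optionally) unrecorded
  n_sites <- length(rows)
  if (invariant == "complete")
    n_sites <- n_sites + (window$end - window$start) - length(rows)
  if (S < 1 || n_sites < 1) return(NA_real_)
  n_site <- sc$n_alleles[seg]
  n <- as.integer(names(sort(table(n_site), decreasing = TRUE))[1])
  if (n < 2) return(NA_real_)
  a1 <- sum(1 / seq_len(n - 1))
  (S / a1) / n_sites
}

#' Absolute divergence Dxy in a window
#'
#' Dxy = sum(b_s) / sum(w_s) where b_s = a1 (n2 - a2) + a2 (n1 - a1) is
#' the number of mismatching cross-population allele pairs and w_s =
#' n1 n2 the number of comparable pairs (a_i alt counts, n_i non-missing
#' allele totals). With \code{invariant = "complete"} unrecorded window
#' positions contribute full-weight invariant comparisons.
#'
#' @param gm1,gm2 Genotype matrices of the two populations at matched
#'   sites.
#' @param window Window as in \code{\link{pi_window}}.
#' @param invariant Denominator convention, see \code{\link{pi_window}}.
#' @return Dxy per site, or NA with zero comparable cross pairs.
#' @export
dxy_window <- function(gm1, gm2, window,
                       invariant = c("complete", "none")) {
  invariant <- match.arg(invariant)
  stopifnot(identical(gm1$sites$pos, gm2$sites$pos))
  rows <- .window_rows(gm1$sites, window)
  s1 <- .site_counts(gm1$dosage[rows, , drop = FALSE])
  s2 <- .site_counts(gm2$dosage[rows, , drop = FALSE])
  b <- sum(s1$alt * (s2$n_alleles - s2$alt) +
             s2$alt * (s1$n_alleles - s1$alt))
  w <- sum(s1$n_alleles * s2$n_alleles)
  if (invariant == "complete") {
    nf1 <- 2 * length(gm1$samples)
    nf2 <- 2 * length(gm2$samples)
    n_unrec <- (window$end - window$start) - length(rows)
    w <- w + n_unrec * nf1 * nf2
  }
  if (w <= 0) return(NA_real_)
  b / w
}

#' Weir-Cockerham FST variance components per SNP
#'
#' Computes the Weir & Cockerham (1984) components a (among populations),
#' b (among individuals within populations) and c (within individuals)
#' for two populations at every site.
#'
#' @param gm1,gm2 Genotype matrices of the two populations at matched
#'   sites.
#' @return A data frame with columns \code{a}, \code{b}, \code{c} and the
#'   per-SNP estimate \code{fst} (\code{a/(a+b+c)}, NaN when undefined).
#' @export
wc_fst_components <- function(gm1, gm2) {
  stopifnot(identical(gm1$sites$pos, gm2$sites$pos))
  r <- 2
  n1 <- rowSums(!is.na(gm1$dosage))
  n2 <- rowSums(!is.na(gm2$dosage))
  p1 <- rowSums(gm1$dosage, na.rm = TRUE) / (2 * n1)
  p2 <- rowSums(gm2$dosage, na.rm = TRUE) / (2 * n2)
  h1 <- rowSums(gm1$dosage == 1, na.rm = TRUE) / n1
  h2 <- rowSums(gm2$dosage == 1, na.rm = TRUE) / n2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r -
       hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  data.frame(a = a, b = b, c = cc, fst = a / (a + b + cc))
}

#' Windowed Weir-Cockerham FST
#'
#' Ratio-of-sums window estimate sum(a)/sum(a+b+c) over eligible SNPs;
#' negative or undefined results are clamped to 0. Returns NA (not 0)
#' when no eligible SNP falls in the window.
#'
#' @param gm1,gm2 Genotype matrices of the two populations at matched
#'   sites (pre-filtered to eligible SNPs, e.g. minor allele count >= 4
#'   within the pair).
#' @param window Window as in \code{\link{pi_window}}.
#' @return Clamped window FST in [0, 1], or NA.
#' @export
wc_fst_window <- function(gm1, gm2, window) {
  rows <- .window_rows(gm1$sites, window)
  if (!length(rows)) return(NA_real_)
  comp <- wc_fst_components(
    subset_gm(gm1, sites = rows), subset_gm(gm2, sites = rows))
  den <- sum(comp$a + comp$b + comp$c, na.rm = TRUE)
  if (!is.finite(den) || den == 0) return(NA_real_)
  f <- sum(comp$a, na.rm = TRUE) / den
  max(0, min(1, f))
}

#' Runs of homozygosity
#'
#' Maximal runs of homozygous genotype calls per sample and chromosome.
#' Heterozygous calls terminate a run; missing calls inside a run are
#' tolerated. Length is the 1-based inclusive span between the first and
#' last homozygous site of the run (minimum 1 bp, no minimum SNP count).
#'
#' @param gm A \code{\link{genotype_matrix}}.
#' @return A data frame (\code{sample}, \code{chrom}, \code{start},
#'   \code{end}, \code{length}, \code{n_snps}).
#' @export
roh_scan <- function(gm) {
  out <- list()
  for (ch in unique(gm$sites$chrom)) {
    rows <- which(gm$sites$chrom == ch)
    pos <- gm$sites$pos[rows]
    for (s in gm$samples) {
      dos <- gm$dosage[rows, s]
      hom <- !is.na(dos) & dos != 1L
      het <- !is.na(dos) & dos == 1L
      # segment index increments at each het call
      seg <- cumsum(het)
      for (g in unique(seg[hom])) {
        in_run <- hom & seg == g
        p <- pos[in_run]
        out[[length(out) + 1]] <- data.frame(
          sample = s, chrom = ch, start = min(p), end = max(p),
          length = max(p) - min(p) + 1L, n_snps = sum(in_run),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(sample = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      length = integer(0), n_snps = integer(0)))
  do.call(rbind, out)
}

#' Fraction of long runs of homozygosity
#'
#' @param roh Output of \code{\link{roh_scan}}.
#' @param threshold_bp Length threshold, default 100 kb.
#' @return Fraction of runs strictly longer than the threshold.
#' @export
roh_long_fraction <- function(roh, threshold_bp = 1e5) {
  if (nrow(roh) == 0) return(NA_real_)
  mean(roh$length > threshold_bp)
}

#' Linkage-disequilibrium decay curve
#'
#' Squared Pearson correlation of dosage vectors over complete cases for
#' every SNP pair within \code{max_dist}, after removing SNPs with minor
#' allele frequency below \code{maf_min}; pair r-squared values are
#' averaged in distance bins.
#'
#' @param gm A \code{\link{genotype_matrix}} restricted to one
#'   population.
#' @param maf_min Minimum minor allele frequency (inclusive).
#' @param max_dist Maximum pair distance in bp (inclusive).
#' @param bin_width Distance bin width in bp.
#' @return A data frame (\code{dist_lo}, \code{dist_hi}, \code{mean_r2},
#'   \code{n_pairs}).
#' @export
ld_decay <- function(gm, maf_min = 0.1, max_dist = 100000,
                     bin_width = 1000) {
  sc <- .site_counts(gm$dosage)
  maf <- ifelse(sc$n_alleles > 0, sc$minor / sc$n_alleles, 0)
  gm <- subset_gm(gm, sites = maf >= maf_min)
  dists <- numeric(0)
  r2s <- numeric(0)
  for (ch in unique(gm$sites$chrom)) {
    rows <- which(gm$sites$chrom == ch)
    pos <- gm$sites$pos[rows]
    for (i in seq_along(rows)) {
      j <- i + 1
      while (j <= length(rows) && pos[j] - pos[i] <= max_dist) {
        x <- gm$dosage[rows[i], ]
        y <- gm$dosage[rows[j], ]
        ok <- !is.na(x) & !is.na(y)
        if (sum(ok) >= 2 && sd(x[ok]) > 0 && sd(y[ok]) > 0) {
          dists <- c(dists, pos[j] - pos[i])
          r2s <- c(r2s, cor(x[ok], y[ok])^2)
        }
        j <- j + 1
      }
    }
  }
  if (!length(dists))
    return(data.frame(dist_lo = numeric(0), dist_hi = numeric(0),
                      mean_r2 = numeric(0), n_pairs = integer(0)))
  bin <- pmin(floor((dists - 1) / bin_width), max_dist %/% bin_width)
  agg <- aggregate(r2s, by = list(bin = bin), FUN = mean)
  cnt <- as.vector(table(bin))
  data.frame(dist_lo = agg$bin * bin_width,
             dist_hi = (agg$bin + 1) * bin_width,
             mean_r2 = agg$x, n_pairs = cnt)
}

#' Per-window diversity and differentiation table
#'
#' Computes, for every window: within-cluster pi and Tajima's D, pairwise
#' Dxy and windowed Weir-Cockerham FST, SNP counts, and FST eligibility
#' flags (a window is eligible for a pair when at least
#' \code{min_pair_snps} SNPs pass the \code{mac_min} minor-allele-count
#' filter within that pair).
#'
#' @param gm A \code{\link{genotype_matrix}} over all samples.
#' @param cluster Named character vector mapping sample id to cluster
#'   label.
#' @param windows Data frame from \code{\link{window_tiling}}.
#' @param min_pair_snps FST eligibility floor (default 20).
#' @param mac_min Minor-allele-count filter within each pair (default 4).
#' @param invariant Denominator convention for pi/Dxy, see
#'   \code{\link{pi_window}}.
#' @return The windows data frame extended with per-cluster and per-pair
#'   statistic columns; class \code{window_table}.
#' @export
window_table <- function(gm, cluster, windows, min_pair_snps = 20,
                         mac_min = 4, invariant = "complete") {
  stopifnot(inherits(gm, "genotype_matrix"))
  cls <- sort(unique(cluster))
  gms <- lapply(cls, function(cl)
    subset_gm(gm, samples = names(cluster)[cluster == cl]))
  names(gms) <- cls
  pairs <- utils::combn(cls, 2, simplify = FALSE)
  pair_names <- vapply(pairs, paste, "", collapse = "_")
  # pair-level mac filter applied once, globally
  pair_keep <- lapply(pairs, function(pr) {
    d <- cbind(gms[[pr[1]]]$dosage, gms[[pr[2]]]$dosage)
    sc <- .site_counts(d)
    sc$minor >= mac_min
  })
  names(pair_keep) <- pair_names
  res <- windows
  for (cl in cls) {
    res[[paste0("pi_", cl)]] <- NA_real_
    res[[paste0("theta_", cl)]] <- NA_real_
    res[[paste0("tajd_", cl)]] <- NA_real_
    res[[paste0("n_snps_", cl)]] <- NA_integer_
  }
  for (pn in pair_names) {
    res[[paste0("dxy_", pn)]] <- NA_real_
    res[[paste0("fst_", pn)]] <- NA_real_
    res[[paste0("n_snps_", pn)]] <- NA_integer_
    res[[paste0("eligible_", pn)]] <- FALSE
  }
  for (w in seq_len(nrow(windows))) {
    win <- windows[w, ]
    rows <- .window_rows(gm$sites, win)
    for (cl in cls) {
      g <- gms[[cl]]
      res[w, paste0("pi_", cl)] <- pi_window(g, win, invariant)
      res[w, paste0("theta_", cl)] <- theta_w_window(g, win, invariant)
      res[w, paste0("tajd_", cl)] <- tajima_d_window(g, win)
      sc <- .site_counts(g$dosage[rows, , drop = FALSE])
      res[w, paste0("n_snps_", cl)] <- sum(sc$minor > 0)
    }
    for (k in seq_along(pairs)) {
      pr <- pairs[[k]]
      pn <- pair_names[k]
      res[w, paste0("dxy_", pn)] <-
        dxy_window(gms[[pr[1]]], gms[[pr[2]]], win, invariant)
      keep_rows <- intersect(rows, which(pair_keep[[pn]]))
      n_elig <- length(keep_rows)
      res[w, paste0("n_snps_", pn)] <- n_elig
      res[w, paste0("eligible_", pn)] <- n_elig >= min_pair_snps
      if (n_elig > 0)
        res[w, paste0("fst_", pn)] <- wc_fst_window(
          subset_gm(gms[[pr[1]]], sites = keep_rows),
          subset_gm(gms[[pr[2]]], sites = keep_rows), win)
    }
  }
  class(res) <- c("window_table", "data.frame")
  res
}
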