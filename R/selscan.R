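# Selection scans: cross-population extended haplotype homozygosity,
# composite sweep statistic over 50-SNP stretches, kNN FST-vector
# outliers, quantile tail outliers, Fisher enrichment and the
# integration layer.

# haplotype columns (transposed to haplotypes x snps) for one chromosome
.hap_block <- function(hm, chrom) {
  rows <- which(hm$sites$chrom == chrom)
  list(mat = t(hm$hap[rows, , drop = FALSE]),
       pos = hm$sites$pos[rows], rows = rows)
}

#' Site-EHH profile and integrated EHH at a core SNP
#'
#' Site-EHH at marker x is the probability that two randomly drawn
#' haplotypes are identical over all markers from the core through x
#' (alleles pooled at the core). iES is the trapezoidal integral of the
#' profile over physical position outward in both directions, truncated
#' at the first marker where the profile drops below \code{trunc}.
#'
#' @param hm A \code{\link{haplotype_matrix}} restricted to one
#'   population.
#' @param chrom Chromosome of the core SNP.
#' @param core_pos Position of the core SNP (must be genotyped).
#' @param trunc Truncation threshold (default 0.05).
#' @return A list: \code{ehh} (values at each site of the chromosome, NA
#'   outside the truncation extent), \code{pos}, \code{left},
#'   \code{right} (extent site indices), \code{ies}.
#' @export
ehh_site <- function(hm, chrom, core_pos, trunc = 0.05) {
  blk <- .hap_block(hm, chrom)
  if (nrow(blk$mat) < 2) stop("need at least 2 haplotypes")
  core <- match(core_pos, blk$pos)
  if (is.na(core)) stop("core SNP not found at ", chrom, ":", core_pos)
  pr <- .ehh_profile_cpp(blk$mat, core - 1L, trunc)
  e <- pr$ehh
  ies <- 0
  idx <- pr$left:pr$right
  if (length(idx) >= 1 && !is.na(e[core]) && e[core] >= trunc) {
    p <- blk$pos[idx]
    v <- e[idx]
    if (length(idx) > 1)
      ies <- sum(diff(p) * (head(v, -1) + tail(v, -1)) / 2)
  }
  list(ehh = e, pos = blk$pos, left = pr$left, right = pr$right,
       ies = ies)
}

#' Cross-population EHH scan
#'
#' Computes iES in both populations at every SNP passing the pair
#' minor-allele filter, takes the log-ratio, standardizes genome-wide,
#' and reports two-sided normal p-values. SNPs with a zero or undefined
#' iES in either population are skipped.
#'
#' @param hm1,hm2 Haplotype matrices of the two populations at matched
#'   sites.
#' @param mac_gt Keep SNPs with pooled-pair minor allele count strictly
#'   greater than this (default 4).
#' @param trunc EHH truncation threshold (default 0.05).
#' @param p_out Outlier p-value threshold (default 1e-6).
#' @return A data frame (\code{chrom}, \code{pos}, \code{ies1},
#'   \code{ies2}, \code{raw}, \code{z}, \code{p}, \code{outlier});
#'   positive z means extended homozygosity in population 1.
#' @export
xpehh <- function(hm1, hm2, mac_gt = 4, trunc = 0.05, p_out = 1e-6) {
  stopifnot(identical(hm1$sites$pos, hm2$sites$pos))
  pooled <- cbind(hm1$hap, hm2$hap)
  cnt <- rowSums(pooled)
  minor <- pmin(cnt, ncol(pooled) - cnt)
  keep <- minor > mac_gt
  sites <- hm1$sites[keep, , drop = FALSE]
  h1 <- hm1$hap[keep, , drop = FALSE]
  h2 <- hm2$hap[keep, , drop = FALSE]
  res <- lapply(unique(sites$chrom), function(ch) {
    rows <- which(sites$chrom == ch)
    pos <- sites$pos[rows]
    i1 <- .ies_all_cpp(t(h1[rows, , drop = FALSE]), pos, trunc)
    i2 <- .ies_all_cpp(t(h2[rows, , drop = FALSE]), pos, trunc)
    data.frame(chrom = ch, pos = pos, ies1 = i1, ies2 = i2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  ok <- is.finite(out$ies1) & is.finite(out$ies2) &
    out$ies1 > 0 & out$ies2 > 0
  out$raw <- ifelse(ok, log(out$ies1 / out$ies2), NA_real_)
  mu <- mean(out$raw, na.rm = TRUE)
  s <- sd(out$raw, na.rm = TRUE)
  out$z <- if (is.na(s) || s == 0) NA_real_ else (out$raw - mu) / s
  out$p <- 2 * pnorm(-abs(out$z))
  out$outlier <- !is.na(out$p) & out$p < p_out
  out
}

# merge intervals with gap <= merge_gap (per chrom)
.merge_intervals <- function(df, merge_gap = 0) {
  if (nrow(df) == 0) return(df)
  out <- list()
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    cur <- d[1, c("start", "end")]
    for (i in seq_len(nrow(d))[-1]) {
      if (d$start[i] <= cur$end + merge_gap) {
        cur$end <- max(cur$end, d$end[i])
      } else {
        out[[length(out) + 1]] <- data.frame(chrom = ch, cur)
        cur <- d[i, c("start", "end")]
      }
    }
    out[[length(out) + 1]] <- data.frame(chrom = ch, cur)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' EHH regions around outlier SNPs
#'
#' For each xp-EHH outlier SNP, the region is the maximal span where the
#' focal cluster's site-EHH stays at or above the truncation threshold
#' on both sides of the core; overlapping or adjacent regions (gap at
#' most \code{merge_gap}) are merged.
#'
#' @param hm_focal Haplotype matrix of the focal cluster.
#' @param outliers Data frame with \code{chrom}, \code{pos} of outlier
#'   SNPs (e.g. the outlier rows of \code{\link{xpehh}}).
#' @param trunc EHH truncation threshold.
#' @param merge_gap Maximum merge gap in bp (default 0: only overlapping
#'   or adjacent regions merge).
#' @return A data frame (\code{chrom}, \code{start}, \code{end}) of
#'   merged regions (1-based inclusive).
#' @export
ehh_regions <- function(hm_focal, outliers, trunc = 0.05,
                        merge_gap = 0) {
  if (nrow(outliers) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  spans <- lapply(seq_len(nrow(outliers)), function(i) {
    es <- ehh_site(hm_focal, outliers$chrom[i], outliers$pos[i], trunc)
    data.frame(chrom = outliers$chrom[i], start = es$pos[es$left],
               end = es$pos[es$right], stringsAsFactors = FALSE)
  })
  .merge_intervals(do.call(rbind, spans), merge_gap)
}

#' Regions supported against both other clusters
#'
#' Returns the unions of overlapping regions from two pairwise
#' comparisons; a region found in only one comparison is excluded.
#'
#' @param regions1,regions2 Region data frames from
#'   \code{\link{ehh_regions}} for the focal cluster against each of the
#'   other two clusters.
#' @return A merged region data frame.
#' @export
intersect_both <- function(regions1, regions2) {
  if (nrow(regions1) == 0 || nrow(regions2) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  out <- list()
  for (i in seq_len(nrow(regions1))) {
    r1 <- regions1[i, ]
    hit <- regions2$chrom == r1$chrom & regions2$start <= r1$end &
      regions2$end >= r1$start
    for (j in which(hit)) {
      out[[length(out) + 1]] <- data.frame(
        chrom = r1$chrom, start = min(r1$start, regions2$start[j]),
        end = max(r1$end, regions2$end[j]), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  .merge_intervals(do.call(rbind, out), 0)
}

#' Composite sweep statistic over 50-SNP stretches
#'
#' For each sliding stretch of \code{W} consecutive clean SNPs (no
#' missing genotypes, polymorphic within the population) on a
#' chromosome, computes the product mu = mu_var * mu_sfs * mu_ld:
#' \itemize{
#'   \item mu_var: observed span over the expected span of \code{W} SNPs
#'     given the chromosome's SNP density, span_bp * S_chrom /
#'     (L_chrom * W);
#'   \item mu_sfs: fraction of stretch SNPs that are minor-allele
#'     singletons;
#'   \item mu_ld: mean of the within-half mean r-squared (halves of W/2
#'     SNPs) over the cross-half mean r-squared floored at \code{eps}.
#' }
#'
#' @param gm A \code{\link{genotype_matrix}} restricted to one
#'   population.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param W Stretch size in SNPs (default 50, must be even).
#' @param eps Floor on the cross-half r-squared (default 0.01).
#' @return A data frame (\code{chrom}, \code{first}, \code{last},
#'   \code{mu_var}, \code{mu_sfs}, \code{mu_ld}, \code{mu},
#'   \code{valid}); \code{valid} is all-TRUE until
#'   \code{\link{filter_mu_windows}} is applied.
#' @export
mu_scan <- function(gm, chrom_sizes, W = 50, eps = 0.01) {
  stopifnot(W %% 2 == 0, W >= 4)
  sc <- .site_counts(gm$dosage)
  clean <- sc$n_ind == length(gm$samples) & sc$minor > 0
  gmc <- subset_gm(gm, sites = clean)
  half <- W / 2
  li <- seq_len(half)
  ri <- half + li
  utli <- upper.tri(diag(half))
  out <- list()
  for (ch in unique(gmc$sites$chrom)) {
    rows <- which(gmc$sites$chrom == ch)
    S <- length(rows)
    if (S < W) next
    L <- chrom_sizes[[ch]]
    if (is.null(L)) stop("no chromosome length for ", ch)
    pos <- gmc$sites$pos[rows]
    minor <- .site_counts(gmc$dosage[rows, , drop = FALSE])$minor
    # standardized dosage columns: window correlations via crossprod;
    # zero-variance dosages (e.g. an all-heterozygous site) are treated
    # as uncorrelated
    z <- scale(t(gmc$dosage[rows, , drop = FALSE]))
    z[is.nan(z)] <- 0
    nW <- S - W + 1
    mu_var <- mu_sfs <- mu_ld <- numeric(nW)
    sing <- as.numeric(minor == 1)
    cs <- cumsum(c(0, sing))
    nsamp <- nrow(z)
    for (i in seq_len(nW)) {
      j <- i + W - 1
      mu_var[i] <- (pos[j] - pos[i]) * S / (L * W)
      mu_sfs[i] <- (cs[j + 1] - cs[i]) / W
      cc <- (crossprod(z[, i:j, drop = FALSE]) / (nsamp - 1))^2
      r2l <- mean(cc[li, li][utli])
      r2r <- mean(cc[ri, ri][utli])
      r2x <- mean(cc[li, ri])
      mu_ld[i] <- ((r2l + r2r) / 2) / max(r2x, eps, na.rm = TRUE)
    }
    out[[length(out) + 1]] <- data.frame(
      chrom = ch, first = pos[seq_len(nW)], last = pos[W:S],
      mu_var = mu_var, mu_sfs = mu_sfs, mu_ld = mu_ld,
      mu = mu_var * mu_sfs * mu_ld, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(0), first = integer(0),
                      last = integer(0), mu_var = numeric(0),
                      mu_sfs = numeric(0), mu_ld = numeric(0),
                      mu = numeric(0), valid = logical(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$valid <- TRUE
  res
}

#' Callability filter for composite-statistic windows
#'
#' A stretch is invalid if it overlaps any no-record interval longer
#' than 1 kb, or if no-record intervals of 100-1000 bp cover more than
#' 20 percent of the stretch span.
#'
#' @param mu Data frame from \code{\link{mu_scan}}.
#' @param mask A \code{\link{callability_mask}}.
#' @param long_bp Length defining a long gap (default 1000, exclusive).
#' @param short_range Length range of short gaps (default c(100, 1000),
#'   inclusive).
#' @param max_short_frac Maximum tolerated short-gap coverage fraction
#'   (default 0.2, exclusive).
#' @return \code{mu} with its \code{valid} column updated.
#' @export
filter_mu_windows <- function(mu, mask, long_bp = 1000,
                              short_range = c(100, 1000),
                              max_short_frac = 0.2) {
  if (nrow(mu) == 0 || nrow(mask) == 0) return(mu)
  for (ch in unique(mu$chrom)) {
    wi <- which(mu$chrom == ch)
    m <- mask[mask$chrom == ch, , drop = FALSE]
    # gaps below the short-gap class affect neither rule
    m <- m[m$end - m$start >= short_range[1], , drop = FALSE]
    if (!nrow(m)) next
    ml <- m$end - m$start
    # windows as 0-based half-open [first-1, last)
    ws <- mu$first[wi] - 1
    we <- mu$last[wi]
    # overlap matrix: windows x mask intervals
    ov <- outer(we, m$end, pmin) - outer(ws, m$start, pmax)
    ov[ov < 0] <- 0
    long_hit <- rowSums(ov[, ml > long_bp, drop = FALSE] > 0) > 0
    short <- ml >= short_range[1] & ml <= short_range[2]
    short_bp <- rowSums(ov[, short, drop = FALSE])
    bad <- long_hit | short_bp > max_short_frac * (we - ws)
    mu$valid[wi][bad] <- FALSE
  }
  mu
}

#' Composite-statistic outliers
#'
#' Flags valid stretches whose statistic exceeds the mean plus
#' \code{n_sd} standard deviations of the valid-stretch distribution.
#'
#' @param mu Data frame from \code{\link{mu_scan}} (after
#'   \code{\link{filter_mu_windows}}).
#' @param n_sd Number of standard deviations (default 20).
#' @return \code{mu} with a logical \code{outlier} column.
#' @export
mu_outliers <- function(mu, n_sd = 20) {
  v <- mu$mu[mu$valid]
  thr <- if (length(v) >= 2) mean(v) + n_sd * sd(v) else Inf
  mu$outlier <- mu$valid & mu$mu > thr
  mu
}

# lower/upper tail membership with inclusive ties; exactly
# floor(frac * n) flagged absent ties
.tail_flags <- function(x, frac, lower = TRUE) {
  flags <- rep(FALSE, length(x))
  ok <- which(!is.na(x))
  k <- floor(frac * length(ok))
  if (k < 1) return(flags)
  v <- x[ok]
  thr <- sort(v, decreasing = !lower)[k]
  flags[ok] <- if (lower) v <= thr else v >= thr
  flags
}

#' Quantile tail outlier windows
#'
#' Flags eligible (non-missing) windows in the stated tail of the
#' genome-wide distribution of a statistic; ties at the quantile
#' boundary are all included and missing windows are excluded from the
#' quantile computation.
#'
#' @param wt A \code{\link{window_table}} (or any data frame).
#' @param stat Column name of the statistic.
#' @param tail \code{"lower"} (e.g. pi, Tajima's D) or \code{"upper"}
#'   (e.g. Dxy).
#' @param frac Tail fraction (default 0.05).
#' @return Logical vector of flags over the rows of \code{wt}.
#' @export
tail_outlier_windows <- function(wt, stat, tail = c("lower", "upper"),
                                 frac = 0.05) {
  tail <- match.arg(tail)
  .tail_flags(wt[[stat]], frac, lower = (tail == "lower"))
}

#' kNN FST-vector outlier windows
#'
#' Embeds each window's pairwise-FST 3-vector in Euclidean space; the
#' kNN outlier score of a window is the weighted sum of distances to its
#' k nearest windows with linearly decaying rank weights (or an
#' unweighted mean). delta-FST is the distance to the medoid (the window
#' vector minimizing total distance to all windows). Outliers are
#' windows in the top \code{top_frac} of scores with delta-FST strictly
#' above \code{delta_min}.
#'
#' @param fst_mat Numeric matrix (windows x pairwise FST components).
#' @param k Number of neighbours (default 6993); when the default
#'   exceeds the window count it is rescaled to \code{ceiling(0.35 *
#'   nrow)}; an explicitly supplied k that is >= the window count is an
#'   error.
#' @param top_frac Score tail fraction (default 0.005).
#' @param delta_min Minimum delta-FST (default 0.5, exclusive).
#' @param weighted Use linearly decaying rank weights (default TRUE).
#' @return A data frame (\code{score}, \code{delta_fst},
#'   \code{outlier}).
#' @export
knn_fst_outliers <- function(fst_mat, k = 6993, top_frac = 0.005,
                             delta_min = 0.5, weighted = TRUE) {
  fst_mat <- as.matrix(fst_mat)
  n <- nrow(fst_mat)
  defaulted <- missing(k)
  if (k >= n) {
    if (defaulted) k <- max(1L, as.integer(ceiling(0.35 * n)))
    else stop("k (", k, ") must be smaller than the number of windows (",
              n, "); choose a smaller k")
  }
  if (k >= n) stop("too few windows for any k")
  dm <- as.matrix(dist(fst_mat))
  w <- if (weighted) (k - seq_len(k) + 1) / sum(k - seq_len(k) + 1)
       else rep(1 / k, k)
  score <- vapply(seq_len(n), function(i) {
    dd <- sort(dm[i, -i])[seq_len(k)]
    sum(w * dd)
  }, 0)
  medoid <- which.min(rowSums(dm))
  delta <- dm[, medoid]
  top <- .tail_flags(score, top_frac, lower = FALSE)
  data.frame(score = score, delta_fst = delta,
             outlier = top & delta > delta_min)
}

#' Fisher enrichment of outlier windows in a region
#'
#' One-sided (enrichment) Fisher exact test of the 2x2 table of windows
#' overlapping the region versus not, against outlier versus not.
#'
#' @param region One-row data frame with \code{chrom}, \code{start},
#'   \code{end} (1-based inclusive).
#' @param windows Window data frame (0-based half-open).
#' @param flags Logical outlier flags over the windows.
#' @return The one-sided p-value.
#' @export
enrichment_fisher <- function(region, windows, flags) {
  inreg <- windows$chrom == region$chrom &
    windows$start < region$end & windows$end > region$start - 1
  ok <- !is.na(flags)
  tab <- table(factor(inreg[ok], c(TRUE, FALSE)),
               factor(flags[ok], c(TRUE, FALSE)))
  fisher.test(tab, alternative = "greater")$p.value
}

#' Antagonistic-pleiotropy screen on FST outlier windows
#'
#' For each flagged window, computes the absolute allele-frequency
#' difference between the cluster pair at every eligible SNP and flags
#' the window when strictly more than half of those SNPs differ by more
#' than \code{diff_min}.
#'
#' @param gm1,gm2 Genotype matrices of the cluster pair at matched,
#'   pair-eligible sites.
#' @param windows Window data frame (0-based half-open).
#' @param candidate Logical vector marking the FST outlier windows to
#'   screen.
#' @param diff_min Allele-frequency difference threshold (default 0.95,
#'   exclusive).
#' @return Logical vector over windows: candidate regions with
#'   antagonistic signatures.
#' @export
antagonistic_screen <- function(gm1, gm2, windows, candidate,
                                diff_min = 0.95) {
  stopifnot(identical(gm1$sites$pos, gm2$sites$pos))
  s1 <- .site_counts(gm1$dosage)
  s2 <- .site_counts(gm2$dosage)
  p1 <- ifelse(s1$n_alleles > 0, s1$alt / s1$n_alleles, NA)
  p2 <- ifelse(s2$n_alleles > 0, s2$alt / s2$n_alleles, NA)
  dp <- abs(p1 - p2)
  out <- rep(FALSE, nrow(windows))
  for (i in which(candidate)) {
    rows <- .window_rows(gm1$sites, windows[i, ])
    d <- dp[rows]
    d <- d[!is.na(d)]
    if (length(d) && sum(d > diff_min) > length(d) / 2) out[i] <- TRUE
  }
  out
}

# bp overlap of a region with a set of intervals (1-based inclusive)
.overlap_bp <- function(region, iv) {
  if (nrow(iv) == 0) return(0)
  iv <- iv[iv$chrom == region$chrom, , drop = FALSE]
  if (nrow(iv) == 0) return(0)
  sum(pmax(0, pmin(iv$end, region$end) - pmax(iv$start, region$start) + 1))
}

#' Integrated per-region selection report
#'
#' For each EHH region supported against both other clusters: the number
#' of overlapping windows, per-statistic outlier-window counts with
#' Fisher enrichment stars, the kb overlap with composite-statistic
#' outlier stretches, and a retained flag (at least one corroborating
#' significant signal: any outlier window overlap or composite-statistic
#' overlap).
#'
#' @param regions Region data frame with columns \code{cluster},
#'   \code{chrom}, \code{start}, \code{end} (1-based inclusive).
#' @param wt A \code{\link{window_table}}.
#' @param outlier_flags Named list of logical vectors over the rows of
#'   \code{wt}; names like \code{"pi_P"}, \code{"tajd_P"},
#'   \code{"dxy_G_I"}, \code{"fst_G_I"}.
#' @param mu_regions Data frame (\code{cluster}, \code{chrom},
#'   \code{start}, \code{end}) of merged composite-statistic outlier
#'   stretches.
#' @return A data frame with one row per region: window and outlier
#'   counts per relevant statistic, Fisher p-values, \code{raisd_kb}
#'   overlap, and \code{retained}.
#' @export
integrate_report <- function(regions, wt, outlier_flags, mu_regions) {
  if (nrow(regions) == 0)
    return(data.frame())
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    rg <- regions[i, ]
    cl <- rg$cluster
    inwin <- wt$chrom == rg$chrom & wt$start < rg$end &
      wt$end > rg$start - 1
    rec <- data.frame(cluster = cl, chrom = rg$chrom, start = rg$start,
                      end = rg$end, length = rg$end - rg$start + 1,
                      n_windows = sum(inwin), stringsAsFactors = FALSE)
    relevant <- grep(paste0("(^|_)", cl, "($|_)"), names(outlier_flags),
                     value = TRUE)
    any_signal <- FALSE
    for (nm in relevant) {
      fl <- outlier_flags[[nm]]
      cnt <- sum(fl & inwin, na.rm = TRUE)
      p <- enrichment_fisher(rg, wt, fl)
      rec[[paste0("n_out_", nm)]] <- cnt
      rec[[paste0("p_", nm)]] <- p
      rec[[paste0("star_", nm)]] <-
        if (p < 0.01) "**" else if (p < 0.05) "*" else ""
      if (cnt > 0) any_signal <- TRUE
    }
    mur <- mu_regions[mu_regions$cluster == cl, , drop = FALSE]
    kb <- .overlap_bp(rg, mur) / 1000
    rec$raisd_kb <- kb
    if (kb > 0) any_signal <- TRUE
    rec$retained <- any_signal
    rec
  })
  nm <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (m in setdiff(nm, names(r))) r[[m]] <- NA
    r[nm]
  })
  do.call(rbind, rows)
}
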