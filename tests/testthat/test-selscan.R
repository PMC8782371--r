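test_that("site-EHH follows group enumeration and truncation rules", {
  # 4 identical haplotypes across the chromosome: EHH = 1 everywhere,
  # iES = full physical span
  hap <- matrix(0L, nrow = 6, ncol = 4)
  hap[3, ] <- 1L  # core site must be genotyped; alleles pooled
  hm <- make_hm(hap, pos = c(100L, 200L, 300L, 400L, 500L, 600L))
  es <- ehh_site(hm, "chr1", 300)
  expect_true(all(es$ehh == 1))
  expect_equal(es$ies, 500)  # 600 - 100
  # 4 haplotypes splitting 2+2 immediately beyond the core:
  # EHH at the next marker = (2*1 + 2*1) / (4*3) = 1/3
  hap2 <- matrix(0L, nrow = 2, ncol = 4)
  hap2[2, ] <- c(0L, 0L, 1L, 1L)
  hm2 <- make_hm(hap2, pos = c(100L, 200L))
  es2 <- ehh_site(hm2, "chr1", 100)
  expect_equal(es2$ehh[2], 1 / 3)
  # EHH is non-increasing with distance from the core
  set.seed(9)
  hap3 <- matrix(sample(0:1, 30 * 12, replace = TRUE), nrow = 30)
  hm3 <- make_hm(hap3)
  es3 <- ehh_site(hm3, "chr1", hm3$sites$pos[15], trunc = 0)
  prof <- es3$ehh
  expect_true(all(diff(prof[15:30]) <= 1e-12))
  expect_true(all(diff(prof[1:15]) >= -1e-12))
  expect_error(ehh_site(make_hm(hap3[, 1, drop = FALSE] ), "chr1", 100))
})

test_that("xp-EHH is antisymmetric, standardized, and null on identical pops", {
  set.seed(10)
  hap <- matrix(sample(0:1, 40 * 16, replace = TRUE), nrow = 40)
  hmA <- make_hm(hap[, 1:8])
  hmB <- make_hm(hap[, 9:16])
  xab <- xpehh(hmA, hmB, mac_gt = 0)
  xba <- xpehh(hmB, hmA, mac_gt = 0)
  expect_equal(xab$raw, -xba$raw, tolerance = 1e-12)
  ok <- !is.na(xab$z)
  expect_equal(mean(xab$z[ok]), 0, tolerance = 1e-12)
  expect_equal(sd(xab$z[ok]), 1, tolerance = 1e-12)
  # identical haplotype sets in both populations: raw = 0 everywhere
  xid <- xpehh(make_hm(hap[, 1:8]), make_hm(hap[, 1:8]), mac_gt = 0)
  expect_true(all(abs(xid$raw[!is.na(xid$raw)]) < 1e-12))
})

test_that("EHH regions merge and both-comparison intersection behaves", {
  r1 <- data.frame(chrom = "c", start = c(100L, 250L), end = c(300L, 400L))
  m <- ohia:::.merge_intervals(r1, 0)
  expect_equal(nrow(m), 1)
  expect_equal(m$end, 400)
  # region found only against one cluster is excluded from "both"
  a <- data.frame(chrom = "c", start = 100L, end = 300L)
  b <- data.frame(chrom = "c", start = 500L, end = 700L)
  expect_equal(nrow(intersect_both(a, b)), 0)
  # overlapping regions union
  b2 <- data.frame(chrom = "c", start = 250L, end = 600L)
  u <- intersect_both(a, b2)
  expect_equal(u$start, 100)
  expect_equal(u$end, 600)
})

test_that("the composite statistic reproduces plug-in arithmetic on a constructed stretch", {
  # W = 4 for a hand-checkable case: 2 SNPs per half
  # left half duplicated pair (r2 = 1), right half duplicated pair,
  # cross-half independent; all four SNPs singletons
  n <- 8
  left <- rep(0L, n); left[1] <- 1L
  right <- rep(0L, n); right[2] <- 1L
  d <- rbind(left, left, right, right)
  # choose positions so span = 300 over chromosome of length L with
  # S = 4 clean SNPs: mu_var = span * S / (L * W)
  pos <- c(100L, 200L, 300L, 400L)
  gm <- make_gm(d, pos = pos)
  mu <- mu_scan(gm, c(chr1 = 1000L), W = 4)
  expect_equal(nrow(mu), 1)
  expect_equal(mu$mu_var, 300 * 4 / (1000 * 4))
  expect_equal(mu$mu_sfs, 1)
  # left pair r2 = 1, right pair r2 = 1, cross pairs r2 = 1/49 each
  r2x <- cor(left, right)^2
  expect_equal(mu$mu_ld, 1 / max(r2x, 0.01))
  expect_equal(mu$mu, mu$mu_var * mu$mu_sfs * mu$mu_ld)
})

test_that("callability filtering invalidates windows by the two gap rules", {
  mu <- data.frame(chrom = "c", first = c(1000L, 1000L, 1000L),
                   last = c(11000L, 11000L, 11000L),
                   mu_var = 1, mu_sfs = 1, mu_ld = 1, mu = 1,
                   valid = TRUE)
  # (a) overlap with a 1,500-bp gap -> invalid
  mask_a <- data.frame(chrom = "c", start = 2000L, end = 3500L)
  class(mask_a) <- c("callability_mask", "data.frame")
  expect_false(filter_mu_windows(mu[1, ], mask_a)$valid)
  # (b) two 900-bp gaps in a 10-kb window (18%) -> valid;
  #     three (27%) -> invalid
  gaps2 <- data.frame(chrom = "c", start = c(2000L, 4000L),
                      end = c(2900L, 4900L))
  class(gaps2) <- c("callability_mask", "data.frame")
  expect_true(filter_mu_windows(mu[1, ], gaps2)$valid)
  gaps3 <- data.frame(chrom = "c", start = c(2000L, 4000L, 6000L),
                      end = c(2900L, 4900L, 6900L))
  class(gaps3) <- c("callability_mask", "data.frame")
  expect_false(filter_mu_windows(mu[1, ], gaps3)$valid)
  # a 50-bp gap is below the 100-bp class: valid
  tiny <- data.frame(chrom = "c", start = 2000L, end = 2050L)
  class(tiny) <- c("callability_mask", "data.frame")
  expect_true(filter_mu_windows(mu[1, ], tiny)$valid)
})

test_that("kNN outlier scores match the exhaustive oracle and conjunction rule", {
  set.seed(11)
  m <- matrix(runif(5 * 3, 0, 0.1), ncol = 3)
  m[5, ] <- c(0.9, 0.9, 0.9)  # planted far point
  r <- knn_fst_outliers(m, k = 2, top_frac = 0.2, delta_min = 0.5)
  expect_equal(r$score, oracle_knn(m, 2), tolerance = 1e-12)
  expect_equal(which.max(r$score), 5)
  expect_true(r$outlier[5])
  # identical vectors: all scores zero, no outliers
  r0 <- knn_fst_outliers(matrix(0.2, 10, 3), k = 3, top_frac = 0.2)
  expect_true(all(r0$score == 0))
  expect_false(any(r0$outlier))
  # delta below the floor blocks outlier status despite the top score
  m2 <- matrix(0.0, 10, 3)
  m2[10, ] <- c(0.23, 0.23, 0.23)  # distance to medoid ~0.398 < 0.5
  r2 <- knn_fst_outliers(m2, k = 2, top_frac = 0.2, delta_min = 0.5)
  expect_equal(which.max(r2$score), 10)
  expect_false(r2$outlier[10])
  # explicit k >= windows errors; score invariant under reordering
  expect_error(knn_fst_outliers(m, k = 10), "smaller")
  perm <- c(3, 1, 5, 2, 4)
  rp <- knn_fst_outliers(m[perm, ], k = 2, top_frac = 0.2)
  expect_equal(rp$score, r$score[perm], tolerance = 1e-12)
})

test_that("tail outliers flag exactly the stated fraction with ties included", {
  wt <- data.frame(stat = c(1:100))
  f <- tail_outlier_windows(wt, "stat", "lower", 0.05)
  expect_equal(which(f), 1:5)
  f2 <- tail_outlier_windows(wt, "stat", "upper", 0.05)
  expect_equal(which(f2), 96:100)
  # missing windows excluded from the quantile computation
  wt$stat[1:50] <- NA
  f3 <- tail_outlier_windows(wt, "stat", "lower", 0.05)
  expect_equal(which(f3), 51:52)
  # agrees with a sort-based oracle on random data
  set.seed(12)
  x <- rnorm(200)
  wt2 <- data.frame(stat = x)
  thr <- sort(x)[10]
  expect_equal(which(tail_outlier_windows(wt2, "stat", "lower", 0.05)),
               which(x <= thr))
})

test_that("Fisher enrichment matches the hypergeometric tail", {
  wins <- data.frame(chrom = "c", start = (0:9999) * 20000,
                     end = (1:10000) * 20000)
  flags <- rep(FALSE, 10000)
  flags[sample.int(10000, 500)] <- TRUE  # 5% genome-wide rate
  region <- data.frame(chrom = "c", start = 1, end = 8 * 20000)
  # force 7 of the 8 region windows to be outliers
  flags[1:8] <- c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  p <- enrichment_fisher(region, wins, flags)
  expect_lt(p, 0.01)
  expect_equal(p, oracle_hyper(7, 8, sum(flags), 10000),
               tolerance = 1e-9)
  # region with no outlier windows is not enriched
  flags2 <- rep(FALSE, 10000)
  flags2[9000] <- TRUE
  expect_gte(enrichment_fisher(region, wins, flags2), 0.05)
  # small-table agreement with exact enumeration
  wins_s <- data.frame(chrom = "c", start = (0:19) * 10, end = (1:20) * 10)
  fl <- rep(c(TRUE, FALSE), 10)
  reg <- data.frame(chrom = "c", start = 1, end = 50)
  expect_equal(enrichment_fisher(reg, wins_s, fl),
               oracle_hyper(sum(fl[1:5]), 5, 10, 20), tolerance = 1e-12)
})

test_that("the antagonistic screen requires a strict majority of divergent SNPs", {
  wins <- data.frame(chrom = "chr1", start = 0, end = 1000)
  # 10 SNPs; 6 fixed differences -> flagged
  d1 <- matrix(0L, 10, 5)
  d2 <- matrix(0L, 10, 5)
  d2[1:6, ] <- 2L
  expect_true(antagonistic_screen(make_gm(d1), make_gm(d2), wins, TRUE))
  # exactly half (5 of 10) -> not flagged
  d2b <- matrix(0L, 10, 5)
  d2b[1:5, ] <- 2L
  expect_false(antagonistic_screen(make_gm(d1), make_gm(d2b), wins,
                                   TRUE))
  # equal frequencies -> not flagged
  expect_false(antagonistic_screen(make_gm(d1), make_gm(d1), wins,
                                   TRUE))
})

test_that("the integrated report counts corroborating signals correctly", {
  wins <- data.frame(chrom = "c", start = (0:9) * 20000,
                     end = (1:10) * 20000)
  wt <- wins
  regions <- data.frame(cluster = "P", chrom = "c", start = 30001,
                        end = 70000)
  flags <- list(pi_P = c(FALSE, TRUE, TRUE, FALSE, rep(FALSE, 6)),
                tajd_P = rep(FALSE, 10),
                pi_G = rep(TRUE, 10))  # irrelevant cluster: ignored
  mu_regions <- data.frame(cluster = "P", chrom = "c", start = 35000,
                           end = 42000)
  rep1 <- integrate_report(regions, wt, flags, mu_regions)
  # region 30001..70000 overlaps windows [20000,40000), [40000,60000),
  # [60000,80000); flagged pi_P windows 2 and 3 both overlap
  expect_equal(rep1$n_windows, 3)
  expect_equal(rep1$n_out_pi_P, 2)
  expect_equal(rep1$raisd_kb, 7.001)  # 35000..42000 inclusive span
  expect_true(rep1$retained)
  expect_false("n_out_pi_G" %in% names(rep1))
  # region with no corroborating signal is not retained
  regions2 <- data.frame(cluster = "P", chrom = "c", start = 150001,
                         end = 190000)
  rep2 <- integrate_report(regions2, wt,
                           list(pi_P = rep(FALSE, 10),
                                tajd_P = rep(FALSE, 10)),
                           mu_regions[0, ])
  expect_false(rep2$retained)
  # report column sums match an independent recount
  recount <- sum(flags$pi_P & wt$start < regions$end &
                   wt$end > regions$start - 1)
  expect_equal(rep1$n_out_pi_P, recount)
})
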