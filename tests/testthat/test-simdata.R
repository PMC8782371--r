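test_that("single-deme mean TMRCA matches the 2N coalescent expectation", {
  dem <- demography_config(T1 = 0, T2 = 0, TC = 0, NA_ = 5000)
  samp <- sample_config(n_hap = c(2, 0, 0), n_loci = 1)
  set.seed(11)
  tmrca <- replicate(600, {
    g <- simulate_genealogy(dem, samp)
    # two branches of equal length = TMRCA for n = 2
    g$length[1]
  })
  expect_equal(mean(tmrca), 2 * 5000, tolerance = 3 / sqrt(600))
})

test_that("T1 = T2 = 0 degenerates to a panmictic pooled sample", {
  dem <- demography_config(T1 = 0, T2 = 0, TC = 0, NA_ = 8000)
  samp <- sample_config(n_hap = c(4, 2, 2), n_loci = 1)
  set.seed(5)
  # all 8 lineages should coalesce on the 2 * NA timescale with the
  # unfolded class spectrum proportional to 1/i
  acc <- ohia:::.sim_config_lengths_cpp(ohia:::.coal_cfg(dem, c(4, 2, 2)),
                                        4000L)
  arr <- array(acc, dim = c(5, 3, 3))
  idx <- expand.grid(0:4, 0:2, 0:2)
  marg <- tapply(as.vector(arr), rowSums(idx), sum)
  got <- as.numeric(marg[2:8] / sum(marg[2:8]))
  expect_equal(got, (1 / (1:7)) / sum(1 / (1:7)), tolerance = 0.05)
})

test_that("nested no-migration genealogy matches the naive event oracle", {
  # deme 2 splits from deme 1 at t2, no migration: every branch older
  # than t2 that is ancestral to deme-2 leaves must also be ancestral to
  # deme-1 or have coalesced within deme 2; summary statistics (mean
  # total length, mean singleton-class length) must agree with an
  # independent event-by-event R simulator
  N <- c(1000, 1000, 1000)
  dem <- demography_config(N0 = N[1], N1 = N[2], N2 = N[3], NA_ = 1000,
                           NB = 1000, T1 = 8000, T2 = 500, TC = 0,
                           m01 = 0, m02 = 0, m12 = 0, k01 = 0, k02 = 0,
                           k12 = 0, m3 = 0, shape = "nested")
  samp <- sample_config(n_hap = c(2, 2, 2), n_loci = 1)
  set.seed(21)
  nrep <- 400
  tot_impl <- sing_impl <- numeric(nrep)
  for (i in seq_len(nrep)) {
    g <- simulate_genealogy(dem, samp)
    tot_impl[i] <- sum(g$length)
    sing_impl[i] <- sum(g$length[rowSums(g$config) == 1])
  }
  set.seed(22)
  tot_or <- sing_or <- numeric(nrep)
  for (i in seq_len(nrep)) {
    lens <- oracle_coalescent(c(2, 2, 2), N, matrix(0, 3, 3),
                              t1 = 8000, t2 = 500)
    ln <- vapply(lens, `[[`, 0, "len")
    cfg <- t(vapply(lens, `[[`, integer(3), "cfg"))
    tot_or[i] <- sum(ln)
    sing_or[i] <- sum(ln[rowSums(cfg) == 1])
  }
  se <- sqrt(var(tot_impl) / nrep + var(tot_or) / nrep)
  expect_lt(abs(mean(tot_impl) - mean(tot_or)), 4 * se)
  se_s <- sqrt(var(sing_impl) / nrep + var(sing_or) / nrep)
  expect_lt(abs(mean(sing_impl) - mean(sing_or)), 4 * se_s)
})

test_that("branch configurations respect the nested topology", {
  dem <- demography_config(T1 = 50000, T2 = 500, TC = 0, m01 = 0,
                           m02 = 0, m12 = 0, k01 = 0, k02 = 0, k12 = 0,
                           m3 = 0, shape = "nested")
  samp <- sample_config(n_hap = c(2, 2, 2), n_loci = 1)
  set.seed(31)
  for (i in 1:20) {
    g <- simulate_genealogy(dem, samp)
    birth <- g$t_end - g$length
    mixed <- rowSums(g$config > 0)
    # without migration, branches born below T2 are single-deme
    expect_true(all(mixed[birth < 500 - 1e-9] == 1))
    # between T2 and T1 only demes 1 and 2 may mix (nested shape)
    mid <- birth >= 500 & birth < 50000 - 1e-9
    expect_false(any(g$config[mid, "d0"] > 0 &
                       (g$config[mid, "d1"] > 0 |
                          g$config[mid, "d2"] > 0)))
  }
})

test_that("expected SFS folds the harmonic spectrum correctly", {
  dem <- demography_config(T1 = 0, T2 = 0, TC = 0, NA_ = 10000)
  s <- expected_sfs(dem, sample_config(n_hap = c(4, 0, 0), n_loci = 1),
                    n_sims = 10000, seed = 3)
  idx <- expand.grid(0:4, 0, 0)
  marg <- tapply(as.vector(s$arr), rowSums(idx), sum)
  # unfolded 1/1, 1/2, 1/3 -> folded (1 + 1/3, 1/2) = (8/11, 3/11)
  expect_equal(as.numeric(marg[c("1", "2")]), c(8, 3) / 11,
               tolerance = 0.03)
  expect_equal(sum(s$arr), 1)
})

test_that("expected SFS is invariant under deme-label swap in a symmetric island model", {
  dem <- demography_config(N0 = 5000, N1 = 5000, N2 = 5000, NA_ = 5000,
                           NB = 5000, T1 = 1e8, T2 = 1e8 - 1, TC = 0,
                           m01 = 1e-4, m02 = 0, m12 = 0,
                           k01 = 1e-4, k02 = 0, k12 = 0, m3 = 0)
  samp <- sample_config(n_hap = c(4, 4, 0), n_loci = 1)
  set.seed(17)
  acc <- ohia:::.sim_config_lengths_cpp(ohia:::.coal_cfg(dem, c(4, 4, 0)),
                                        10000L)
  arr <- array(acc, dim = c(5, 5, 1))
  # swap deme labels on the unfolded spectrum, then fold both the same
  # way (folding's lexicographic tie-break is applied after the swap)
  f1 <- fold_sfs3d(arr)
  f2 <- fold_sfs3d(aperm(arr, c(2, 1, 3)))
  expect_lt(0.5 * sum(abs(f1 / sum(f1) - f2 / sum(f2))), 0.05)
})

test_that("coalescent scaling invariance: doubling N and T leaves the SFS unchanged", {
  base <- demography_config(N0 = 2000, N1 = 1500, N2 = 1000,
                            NA_ = 1200, NB = 1800, T1 = 6000, T2 = 2000,
                            TC = 1000, m01 = 1e-4, m02 = 1e-4,
                            m12 = 1e-4, k01 = 1e-5, k02 = 1e-5,
                            k12 = 1e-5, m3 = 1e-5)
  doubled <- demography_config(N0 = 4000, N1 = 3000, N2 = 2000,
                               NA_ = 2400, NB = 3600, T1 = 12000,
                               T2 = 4000, TC = 2000, m01 = 5e-5,
                               m02 = 5e-5, m12 = 5e-5, k01 = 5e-6,
                               k02 = 5e-6, k12 = 5e-6, m3 = 5e-6)
  samp <- sample_config(n_hap = c(4, 4, 4), n_loci = 1)
  s1 <- expected_sfs(base, samp, n_sims = 6000, seed = 7)
  s2 <- expected_sfs(doubled, samp, n_sims = 6000, seed = 8)
  expect_lt(0.5 * sum(abs(s1$arr - s2$arr)), 0.05)
})

test_that("folding ties keep the lexicographically smaller configuration", {
  arr <- array(0, dim = c(3, 3, 1))  # n = (2, 2, 0), total 4
  arr[2, 2, 1] <- 5   # (1,1,0): tot 2 = n/2; complement (1,1,0) itself
  arr[3, 1, 1] <- 2   # (2,0,0): tot 2; complement (0,2,0) is smaller? no:
  # (2,0,0) vs (0,2,0): first index 2 > 0, so (0,2,0) is kept
  f <- fold_sfs3d(arr)
  expect_equal(f[2, 2, 1], 5)
  expect_equal(f[3, 1, 1], 0)
  expect_equal(f[1, 3, 1], 2)
})

test_that("generated datasets are reproducible and internally consistent", {
  dem <- demography_config()
  samp <- sample_config(n_loci = 3, locus_bp = 20000)
  d1 <- tempfile()
  d2 <- tempfile()
  a <- generate_dataset(dem, samp, dir = d1, seed = 42)
  b <- generate_dataset(dem, samp, dir = d2, seed = 42)
  expect_identical(readLines(file.path(d1, "synthetic.vcf")),
                   readLines(file.path(d2, "synthetic.vcf")))
  # VCF round-trip reproduces the haplotype matrix exactly
  rt <- read_vcf(a$paths["vcf"])
  expect_identical(unname(rt$haplotypes$hap), unname(a$haplotypes$hap))
  expect_identical(rt$haplotypes$sites$pos, a$haplotypes$sites$pos)
  # collapsing haplotypes reproduces dosages
  expect_identical(haplotypes_to_genotypes(a$haplotypes)$dosage,
                   a$genotypes$dosage)
  # metadata has cluster-correlated environment and noise columns
  expect_true(all(c("temp", "vpd", "noise1", "noise2") %in%
                    names(a$metadata)))
  expect_identical(sort(unique(a$metadata$cluster)), c("G", "I", "P"))
  # truth file records the demography and seed
  tr <- readLines(a$paths["truth"])
  expect_true(any(grepl("^T1\t", tr)))
})

test_that("divergence without migration yields positive FST downstream", {
  dem <- demography_config(m01 = 0, m02 = 0, m12 = 0, k01 = 0, k02 = 0,
                           k12 = 0, m3 = 0)
  samp <- sample_config(n_hap = c(8, 8, 8), n_loci = 2,
                        locus_bp = 20000)
  d <- generate_dataset(dem, samp, seed = 9)
  cl <- setNames(d$metadata$cluster, d$metadata$sample_id)
  g1 <- subset_gm(d$genotypes, samples = names(cl)[cl == "G"])
  g2 <- subset_gm(d$genotypes, samples = names(cl)[cl == "I"])
  f <- wc_fst_window(g1, g2, list(chrom = "locus001", start = 0,
                                  end = 20000))
  expect_gt(f, 0)
})

test_that("a hard sweep collapses target-deme diversity inside the tract", {
  dem <- demography_config()
  samp <- sample_config(n_loci = 2, locus_bp = 20000)
  sw <- sweep_spec("P", locus = 1, center = 10000, halfwidth = 5000,
                   singleton_rate = 0.02)
  d <- generate_dataset(dem, samp, sweeps = list(sw), seed = 13)
  cl <- setNames(d$metadata$cluster, d$metadata$sample_id)
  gP <- subset_gm(d$genotypes, samples = names(cl)[cl == "P"])
  pi_tract <- pi_window(gP, list(chrom = "locus001", start = 5000,
                                 end = 15000))
  pi_rest <- pi_window(gP, list(chrom = "locus002", start = 0,
                                end = 20000))
  expect_lt(pi_tract, pi_rest)
  # sweep tract outside the sequence fails
  bad <- sweep_spec("P", locus = 1, center = 19900, halfwidth = 500)
  expect_error(generate_dataset(dem, samp, sweeps = list(bad), seed = 1),
               "outside")
})

test_that("neutral constant-size windows have mean Tajima's D near zero", {
  dem <- demography_config(T1 = 0, T2 = 0, TC = 0, NA_ = 50000)
  samp <- sample_config(n_hap = c(20, 0, 0), n_loci = 220,
                        locus_bp = 20000)
  d <- generate_dataset(dem, samp, seed = 101)
  gm <- d$genotypes
  cs <- setNames(rep(20000, 220), sprintf("locus%03d", 1:220))
  wins <- window_tiling(cs, 20000)
  tajd <- vapply(seq_len(nrow(wins)), function(i)
    tajima_d_window(gm, wins[i, ]), 0)
  tajd <- tajd[!is.na(tajd)]
  expect_gte(length(tajd), 200)
  se <- sd(tajd) / sqrt(length(tajd))
  expect_lt(abs(mean(tajd)), 3 * se)
})
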