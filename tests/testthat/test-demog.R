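test_that("observed SFS counts minor-allele configurations by hand rules", {
  # clusters of 1 diploid each; one site with a single alt allele in
  # cluster G -> entry (1, 0, 0)
  d <- matrix(c(1L, 0L, 0L), nrow = 1)
  gm <- make_gm(d, samples = c("g1", "i1", "p1"))
  cl <- c(g1 = "G", i1 = "I", p1 = "P")
  s <- observed_sfs(gm, cl)
  expect_equal(s$arr[2, 1, 1], 1)
  expect_equal(sum(s$arr), 1)
  # all-monomorphic input: zero polymorphic entries
  s0 <- observed_sfs(make_gm(matrix(0L, 4, 3),
                             samples = c("g1", "i1", "p1")), cl)
  expect_equal(sum(s0$arr), 0)
  expect_equal(s0$monomorphic, 4)
  # a site at exactly 50% global frequency takes the lexicographic side
  d5 <- matrix(c(2L, 1L, 0L), nrow = 1)  # alt counts (2,1,0) of 6: tie
  s5 <- observed_sfs(make_gm(d5, samples = c("g1", "i1", "p1")), cl)
  # complement is (0,1,2): lexicographically smaller -> kept
  expect_equal(s5$arr[1, 2, 3], 1)
  expect_equal(s5$n_ties, 1L)
  # missing data is rejected
  dna <- matrix(c(NA, 0L, 0L), nrow = 1)
  expect_error(observed_sfs(make_gm(dna, samples = names(cl)), cl),
               "missing")
})

test_that("composite likelihood obeys the Gibbs inequality and closed forms", {
  set.seed(24)
  n <- c(2L, 2L, 2L)
  p <- array(runif(27), dim = n + 1)
  p[1, 1, 1] <- 0
  p[3, 3, 3] <- 0
  p <- p / sum(p)
  exp_sfs <- sfs3d(p, counts = FALSE)
  o <- array(0, dim = n + 1)
  o[] <- round(p * 1000)
  obs <- sfs3d(o)
  ll_true <- composite_loglik(obs, exp_sfs)
  # any perturbed expected spectrum has lower likelihood
  for (i in 1:10) {
    q <- array(runif(27), dim = n + 1)
    q[1, 1, 1] <- 0; q[3, 3, 3] <- 0
    q <- q / sum(q)
    expect_gte(ll_true, composite_loglik(obs, sfs3d(q, counts = FALSE)))
  }
  # all observed mass on one entry with p = 0.5: log10 L = N log10(0.5)
  o1 <- array(0, dim = n + 1)
  o1[2, 1, 1] <- 200
  p1 <- array(0, dim = n + 1)
  p1[2, 1, 1] <- 0.5
  p1[1, 2, 1] <- 0.5
  expect_equal(composite_loglik(sfs3d(o1), sfs3d(p1, counts = FALSE)),
               200 * log10(0.5))
  # epsilon floor keeps zero-expectation entries finite
  p2 <- array(0, dim = n + 1)
  p2[1, 2, 1] <- 1
  ll <- composite_loglik(sfs3d(o1), sfs3d(p2, counts = FALSE))
  expect_true(is.finite(ll))
  expect_equal(ll, 200 * log10(1e-10))
})

test_that("the model family enumerates 24 distinct specifications", {
  fam <- model_family()
  expect_length(fam, 24)
  key <- vapply(fam, function(s)
    paste(s$hypothesis, s$shape, paste(s$assignment, collapse = "")),
    "")
  expect_equal(anyDuplicated(key), 0L)
  expect_equal(sum(vapply(fam, `[[`, 0, "n_params") == 11), 12)
  expect_equal(sum(vapply(fam, `[[`, 0, "n_params") == 15), 12)
  # M22 carries the printed assignment of the best model
  expect_equal(fam$M22$assignment, c("G", "P", "I"))
  expect_equal(fam$M22$hypothesis, "old")
})

test_that("AIC reproduces the printed model-comparison arithmetic", {
  # the two tabulated anchor rows and the parameter-count identity
  expect_equal(aic(-120826.3, 15), 556455.6, tolerance = 0.3 / 556455)
  expect_equal(aic(-127172.5, 11), 585672.9, tolerance = 0.3 / 585672)
  expect_equal(aic(-1000, 15) - aic(-1000, 11), 8)
  cmp <- compare_models(data.frame(model = c("A", "B"),
                                   loglik10 = c(-1000, -1001),
                                   n_params = c(11, 11)))
  expect_equal(cmp$delta_aic, c(0, 2 * log(10)))
})

test_that("SFS residuals standardize correctly", {
  n <- c(2L, 2L, 2L)
  p <- array(runif(27), dim = n + 1)
  p[1, 1, 1] <- 0; p[3, 3, 3] <- 0
  p <- p / sum(p)
  e <- sfs3d(p, counts = FALSE)
  o <- sfs3d(array(p * 5000, dim = n + 1))
  r <- residual_sfs(o, e)
  expect_true(all(r$residuals[!is.na(r$residuals)] == 0))
  # Poisson-simulated observed: residual sd near 1
  set.seed(25)
  oo <- sfs3d(array(rpois(27, p * 5000), dim = n + 1))
  rr <- residual_sfs(oo, e)
  expect_equal(sd(rr$residuals, na.rm = TRUE), 1, tolerance = 0.4)
  # rescaled expectation makes residual-weighted sums vanish
  res <- rr$residuals
  ee <- p * sum(oo$arr) / sum(p)
  expect_equal(sum(res * sqrt(ee), na.rm = TRUE), 0, tolerance = 1e-8)
})

test_that("unit conversions reproduce the printed split times and rate algebra", {
  expect_equal(convert_time(166784, 30)$mya, 5.00)
  expect_equal(convert_time(163216, 30)$mya, 4.90)
  expect_equal(convert_time(10713, 30)$mya, 0.32)
  # per-generation rate scales linearly with generation time
  expect_equal(per_gen_rate(1e-9, 30) / per_gen_rate(1e-9, 10), 3)
  # msmc conversions
  m <- convert_msmc(7e-4, 1e-5, mu = 7e-9, generation_time_years = 30)
  expect_equal(m$generations, 1e5)
  expect_equal(m$years, 3e6)
  expect_equal(m$ne, 1 / (2 * 1e-5 * 7e-9))
  expect_equal(pop_migration_rate(250000, 2e-5), 10)
})

test_that("bootstrap percentiles follow the sort-based oracle and degenerate case", {
  # percentile mechanics on a fixed replicate matrix
  reps <- matrix(c(1:100, rep(5, 100)), ncol = 2)
  ci <- t(apply(reps, 2, quantile, probs = c(0.025, 0.975)))
  expect_equal(unname(ci[1, ]), unname(quantile(1:100, c(.025, .975))))
  expect_equal(unname(ci[2, ]), c(5, 5))  # zero variance collapses
})

test_that("fit_model honours its contract at zero cycles and validates starts", {
  spec <- model_family("M1")
  set.seed(26)
  # observed spectrum from the generator itself
  truth <- c(N0 = 5e4, N1 = 3e4, N2 = 2e4, NA_ = 2e4, NB = 4e4,
             T1 = 60000, T2 = 8000, m01 = 1e-5, m02 = 1e-5, m12 = 1e-5,
             m3 = 1e-5)
  dem <- ohia:::.spec_demography(spec, truth)
  es <- expected_sfs(dem, sample_config(n_hap = c(6, 6, 6), n_loci = 1),
                     n_sims = 3000, seed = 31)
  obs <- sfs3d(array(rmultinom(1, 5000, as.vector(es$arr)),
                     dim = dim(es$arr)))
  f0 <- fit_model(spec, obs, n_sims = 500, n_cycles = 0, n_runs = 1,
                  seed = 2, start = truth)
  # no optimization: the returned point is the start point
  expect_equal(f0$par, truth[names(f0$par)])
  expect_true(is.finite(f0$loglik10))
  expect_equal(f0$aic, aic(f0$loglik10, 11))
  # out-of-range start fails before any simulation
  bad <- truth; bad["T2"] <- 20000  # beyond the recent-hypothesis range
  expect_error(fit_model(spec, obs, start = bad, n_runs = 1,
                         n_cycles = 0), "range")
  # optimization improves the likelihood from a random start
  f1 <- fit_model(spec, obs, n_sims = 500, n_cycles = 2, n_runs = 1,
                  seed = 3)
  f1b <- fit_model(spec, obs, n_sims = 500, n_cycles = 0, n_runs = 1,
                   seed = 3)
  expect_gte(f1$loglik10, f1b$loglik10)
  # deterministic given seed
  f1c <- fit_model(spec, obs, n_sims = 500, n_cycles = 2, n_runs = 1,
                   seed = 3)
  expect_identical(f1$loglik10, f1c$loglik10)
})

test_that("SFS text files round-trip", {
  n <- c(2L, 4L, 2L)
  arr <- array(rpois(prod(n + 1), 3), dim = n + 1)
  arr[1, 1, 1] <- 0
  s <- sfs3d(arr, monomorphic = 17)
  p <- tempfile()
  write_sfs(s, p)
  r <- read_sfs(p)
  expect_equal(r$arr, s$arr)
  expect_equal(r$monomorphic, 17)
  expect_true(r$folded)
})
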