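# Seeded validation experiments: neutral calibration of the selection
# scans, planted-sweep recovery, demographic parameter recovery, and
# permutation-test calibration. These run the full pipeline machinery on
# generator output and are shared by the test suite and the acceptance
# script.

# scan-scale conditions: 10 independent 100-kb loci of ten freely
# recombining 10-kb segments each (50 windows of 20 kb); large enough
# that a single swept tract stays a small fraction of scored SNPs
.scan_samples <- function() {
  sample_config(n_loci = 10, locus_bp = 100000, n_segments = 10)
}

.scan_one <- function(dataset, config = run_config(vcf = "", metadata = "")) {
  cluster <- setNames(dataset$metadata$cluster,
                      dataset$metadata$sample_id)
  n_loci <- dataset$truth$samples$n_loci
  cs <- setNames(rep(dataset$truth$samples$locus_bp, n_loci),
                 sprintf("locus%03d", seq_len(n_loci)))
  wt <- window_table(dataset$genotypes, cluster,
                     window_tiling(cs, config$window_bp))
  sel <- scan_selection(dataset$genotypes, dataset$haplotypes, cluster,
                        wt, cs, config)
  list(wt = wt, sel = sel)
}

#' Neutral calibration of the selection scans
#'
#' Generates seeded neutral datasets (no sweeps) and summarizes (a) the
#' mean and standard error of windowed Tajima's D under a constant-size
#' panmictic history, (b) how many three-cluster datasets show any
#' composite-statistic outlier at mean + 20 sd, and (c) the total
#' number of xp-EHH outliers at the p < 1e-6 threshold together with
#' the number of SNPs scored.
#'
#' @param n_seeds Number of seeded replicate datasets (default 20).
#' @param base_seed Base seed; replicate s uses base_seed + s.
#' @return A list: \code{tajd_mean}, \code{tajd_se}, \code{n_windows},
#'   \code{mu_outlier_seeds}, \code{xpehh_outliers},
#'   \code{xpehh_snps_scored}.
#' @export
neutral_calibration <- function(n_seeds = 20, base_seed = 1000) {
  # windowed Tajima's D under neutrality: constant-size panmictic demes
  panm <- demography_config(T1 = 0, T2 = 0, TC = 0, NA_ = 50000)
  tajd <- numeric(0)
  for (s in seq_len(n_seeds)) {
    ds <- generate_dataset(panm,
                           sample_config(n_hap = c(20, 0, 0),
                                         n_loci = 15, locus_bp = 20000),
                           seed = base_seed + s)
    cs <- setNames(rep(20000, 15), sprintf("locus%03d", 1:15))
    wins <- window_tiling(cs, 20000)
    td <- vapply(seq_len(nrow(wins)), function(i)
      tajima_d_window(ds$genotypes, wins[i, ]), 0)
    tajd <- c(tajd, td[!is.na(td)])
  }
  # three-cluster neutral datasets for the scan statistics
  dem <- demography_config()
  cfg <- run_config(vcf = "", metadata = "")
  mu_seeds <- 0L
  xp_out <- 0L
  xp_n <- 0L
  # neutral scan datasets are smaller than the sweep-recovery ones (6
  # rather than 10 loci): the calibration claims do not depend on the
  # genome fraction a sweep occupies
  neutral_samples <- sample_config(n_loci = 6, locus_bp = 100000,
                                   n_segments = 10)
  for (s in seq_len(n_seeds)) {
    ds <- generate_dataset(dem, neutral_samples, seed = base_seed + 100 + s)
    sc <- .scan_one(ds, cfg)
    if (any(sc$sel$mu_all$outlier)) mu_seeds <- mu_seeds + 1L
    xp <- sc$sel$xp_all
    xp_out <- xp_out + sum(xp$outlier, na.rm = TRUE)
    xp_n <- xp_n + sum(!is.na(xp$p))
  }
  list(tajd_mean = mean(tajd), tajd_se = sd(tajd) / sqrt(length(tajd)),
       n_windows = length(tajd), mu_outlier_seeds = mu_seeds,
       xpehh_outliers = xp_out, xpehh_snps_scored = xp_n)
}

#' Planted-sweep recovery experiment
#'
#' Injects one hard sweep (complete replacement, residual singleton
#' rate 0.005) into cluster P on locus 1 (tract 30,000-70,000 bp) of a
#' seeded three-cluster dataset and asks whether the integrated
#' selection report recovers it: a retained region for cluster P
#' overlapping the truth tract, i.e. supported by xp-EHH against both
#' other clusters plus at least one corroborating statistic.
#'
#' @param n_seeds Number of seeded replicates (default 20).
#' @param base_seed Base seed.
#' @return A list: \code{successes}, \code{n_seeds}, \code{rate}.
#' @export
sweep_recovery <- function(n_seeds = 20, base_seed = 2000) {
  dem <- demography_config()
  cfg <- run_config(vcf = "", metadata = "")
  sw <- sweep_spec("P", locus = 1, center = 50000, halfwidth = 20000,
                   singleton_rate = 0.005)
  ok <- 0L
  for (s in seq_len(n_seeds)) {
    ds <- generate_dataset(dem, .scan_samples(), sweeps = list(sw),
                           seed = base_seed + s)
    sc <- .scan_one(ds, cfg)
    rep <- sc$sel$report
    hit <- FALSE
    if (NROW(rep) > 0) {
      hit <- any(rep$retained & rep$cluster == "P" &
                   rep$chrom == "locus001" & rep$start <= 70000 &
                   rep$end >= 30000)
    }
    if (hit) ok <- ok + 1L
  }
  list(successes = ok, n_seeds = n_seeds, rate = ok / n_seeds)
}

# the generating truth used by the recovery experiment: a recent-split
# history at comfortably identifiable parameter values
.recovery_truth <- function() {
  c(N0 = 5e4, N1 = 3e4, N2 = 2e4, NA_ = 3e4, NB = 4e4,
    T1 = 40000, T2 = 8000, m01 = 5e-6, m02 = 5e-6, m12 = 5e-6,
    m3 = 5e-6)
}

#' Demographic parameter recovery and model discrimination
#'
#' For each trial, simulates an observed folded 3D SFS over
#' \code{n_sites} surveyed sites (binomial polymorphic-site count, then
#' a multinomial configuration draw) under a known recent-split model,
#' refits that model, and computes parametric-bootstrap 95 percent
#' intervals; coverage is the fraction of parameters whose generating
#' value falls inside its interval. Each trial also fits a
#' wrong-assignment specification to the same data and records whether
#' the true specification achieves the higher composite likelihood.
#'
#' @param n_trials Number of seeded trials (default 10).
#' @param n_sims Simulations per likelihood evaluation (default 2000).
#' @param n_sites Surveyed sites per observed SFS (default 500000).
#' @param n_boot Bootstrap replicates per trial (default 8).
#' @param base_seed Base seed.
#' @return A list: \code{coverage} (fraction over parameters x
#'   trials), \code{discrimination} (fraction of trials won by the
#'   true model), \code{n_trials}, per-trial detail in \code{trials}.
#' @export
demog_recovery <- function(n_trials = 10, n_sims = 2000,
                           n_sites = 500000, n_boot = 8,
                           base_seed = 3000) {
  spec_true <- model_family("M1")   # recent, nested, (G, I, P)
  spec_wrong <- model_family("M2")  # same block, rotated assignment
  truth <- .recovery_truth()
  n_hap <- c(6L, 6L, 6L)
  dem <- .spec_demography(spec_true, truth)
  samp <- sample_config(n_hap = n_hap, n_loci = 1, locus_bp = 1000)
  covered <- 0L
  total <- 0L
  wins <- 0L
  trials <- list()
  for (tr in seq_len(n_trials)) {
    seed <- base_seed + 17 * tr
    es <- expected_sfs(dem, samp, n_sims = 3 * n_sims, seed = seed)
    set.seed(seed + 1)
    np <- rbinom(1, n_sites, es$p_poly)
    obs <- sfs3d(array(rmultinom(1, np, as.vector(es$arr)),
                       dim = dim(es$arr)),
                 monomorphic = n_sites - np)
    fit <- fit_model(spec_true, obs, n_sims = n_sims, n_cycles = 4,
                     n_runs = 1, seed = seed + 2)
    ci <- parametric_bootstrap(spec_true, fit$par, n_hap = n_hap,
                               n_sites = n_sites, n_boot = n_boot,
                               n_sims = n_sims, n_cycles = 4,
                               seed = seed + 3)
    inside <- truth[rownames(ci)] >= ci[, "lo"] &
      truth[rownames(ci)] <= ci[, "hi"]
    covered <- covered + sum(inside)
    total <- total + length(inside)
    fitw <- fit_model(spec_wrong, obs, n_sims = n_sims, n_cycles = 4,
                      n_runs = 1, seed = seed + 4)
    if (fit$loglik10 > fitw$loglik10) wins <- wins + 1L
    trials[[tr]] <- list(fit = fit$par, ci = ci, inside = inside,
                         ll_true = fit$loglik10,
                         ll_wrong = fitw$loglik10)
  }
  list(coverage = covered / total, discrimination = wins / n_trials,
       n_trials = n_trials, trials = trials)
}

#' Permutation-test calibration on pure noise
#'
#' Runs the RDA permutation test on independent Gaussian noise and
#' reports the rejection rate at alpha = 0.05, which should fall in
#' the binomial 95 percent interval around 0.05.
#'
#' @param n_runs Number of noise datasets (default 100).
#' @param n_perm Permutations per test (default 199).
#' @param base_seed Base seed.
#' @return A list: \code{rejections}, \code{n_runs}, \code{rate}.
#' @export
permutation_calibration <- function(n_runs = 100, n_perm = 199,
                                    base_seed = 4000) {
  rej <- 0L
  for (r in seq_len(n_runs)) {
    set.seed(base_seed + r)
    y <- matrix(rnorm(30 * 4), 30, 4)
    x <- matrix(rnorm(30 * 2), 30, 2)
    p <- rda_perm_test(y, x, n_perm = n_perm, seed = base_seed + r)$p
    if (p < 0.05) rej <- rej + 1L
  }
  list(rejections = rej, n_runs = n_runs, rate = rej / n_runs)
}
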