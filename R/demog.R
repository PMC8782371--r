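# SFS-based demographic inference: observed folded 3D SFS, composite
# likelihood against the simulated expected SFS, coordinate-search
# optimization over a 24-model family, AIC comparison, parametric
# bootstrap, residuals and unit conversions.

#' Observed folded 3D site-frequency spectrum
#'
#' Determines the global minor allele per site over the pooled alleles
#' of the three clusters and increments the corresponding
#' minor-allele-count entry. Sites at exactly 50 percent global
#' frequency are assigned by the lexicographic tie-break (the smaller of
#' the configuration and its complement) and counted in the returned
#' object's \code{n_ties}. Selected sites must be free of missing data.
#'
#' @param gm A \code{\link{genotype_matrix}} with zero missing data at
#'   the used sites.
#' @param cluster Named character vector mapping sample id to cluster
#'   label; clusters are ordered alphabetically into dimensions 1-3.
#' @param sites Optional site row indices (e.g. from
#'   \code{\link{select_intergenic_sites}}).
#' @param total_sites Optional total number of surveyed sites; the
#'   difference from the polymorphic tally is added to the monomorphic
#'   count.
#' @return An \code{\link{sfs3d}} of counts (folded).
#' @export
observed_sfs <- function(gm, cluster, sites = NULL, total_sites = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!is.null(sites)) gm <- subset_gm(gm, sites = sites)
  if (anyNA(gm$dosage)) stop("selected sites must have no missing data")
  cls <- sort(unique(cluster))
  stopifnot(length(cls) == 3)
  ids <- lapply(cls, function(cl) names(cluster)[cluster == cl])
  alt <- vapply(ids, function(s)
    rowSums(gm$dosage[, s, drop = FALSE]), numeric(nrow(gm$sites)))
  if (is.null(dim(alt))) alt <- matrix(alt, nrow = 1)
  n_hap <- vapply(ids, function(s) 2L * length(s), integer(1))
  n_tot <- sum(n_hap)
  tot_alt <- rowSums(alt)
  poly <- tot_alt > 0 & tot_alt < n_tot
  mono <- sum(!poly)
  alt <- alt[poly, , drop = FALSE]
  tot_alt <- tot_alt[poly]
  comp <- sweep(-alt, 2, n_hap, "+")  # ref-allele counts
  use_comp <- tot_alt > n_tot / 2
  tie <- tot_alt == n_tot / 2
  n_ties <- 0L
  if (any(tie)) {
    lex_bigger <- (alt[, 1] > comp[, 1]) |
      (alt[, 1] == comp[, 1] & alt[, 2] > comp[, 2]) |
      (alt[, 1] == comp[, 1] & alt[, 2] == comp[, 2] &
         alt[, 3] > comp[, 3])
    use_comp[tie] <- lex_bigger[tie]
    n_ties <- sum(tie)
  }
  cfg <- alt
  cfg[use_comp, ] <- comp[use_comp, ]
  arr <- array(0, dim = n_hap + 1L)
  flat <- 1 + cfg[, 1] + (n_hap[1] + 1) * (cfg[, 2] + (n_hap[2] + 1) * cfg[, 3])
  for (f in flat) arr[f] <- arr[f] + 1
  if (!is.null(total_sites)) mono <- mono + (total_sites - nrow(gm$sites))
  out <- sfs3d(arr, folded = TRUE, counts = TRUE, monomorphic = mono)
  out$n_ties <- n_ties
  out
}

#' Composite log10 likelihood of an observed SFS
#'
#' Composite likelihood over polymorphic entries: log10 L = sum of
#' O_i * log10(max(p_i, eps)) with p the expected
#' polymorphic-conditional probabilities. When the observed spectrum
#' carries a monomorphic-site tally and the expected spectrum carries a
#' per-site polymorphism probability (from \code{\link{expected_sfs}}),
#' the monomorphic term M * log10(1 - p_poly) is added and the
#' polymorphic probabilities are scaled by p_poly; this anchors the
#' absolute parameter scale through the fixed mutation rate. A purely
#' polymorphic-conditional likelihood (no monomorphic tally) leaves the
#' overall coalescent scale unidentified.
#'
#' @param observed An \code{\link{sfs3d}} of counts.
#' @param expected An \code{\link{sfs3d}} of probabilities (e.g. from
#'   \code{\link{expected_sfs}}).
#' @param eps Probability floor (default 1e-10).
#' @return log10 composite likelihood.
#' @export
composite_loglik <- function(observed, expected, eps = 1e-10) {
  stopifnot(inherits(observed, "sfs3d"), inherits(expected, "sfs3d"))
  if (!identical(dim(observed$arr), dim(expected$arr)))
    stop("observed and expected spectra have different shapes")
  o <- as.vector(observed$arr)
  p <- as.vector(expected$arr)
  dm <- dim(observed$arr)
  corners <- c(1, prod(dm))
  o[corners] <- 0
  ll <- sum(o * log10(pmax(p, eps)))
  m <- observed$monomorphic
  if (!is.null(expected$p_poly) && !is.null(m) && m > 0) {
    pp <- min(max(expected$p_poly, eps), 1 - eps)
    ll <- ll + sum(o) * log10(pp) + m * log10(1 - pp)
  }
  ll
}

# Table-2-style assignment cycle shared by both hypothesis blocks
.assign_cycle <- list(c("G", "I", "P"), c("I", "P", "G"), c("P", "G", "I"),
                      c("G", "P", "I"), c("I", "G", "P"), c("P", "I", "G"))

#' The 24-model divergence/migration family
#'
#' Enumerates 24 model specifications: 2 timing hypotheses x 2 topology
#' shapes x 6 cluster-to-deme assignments. Models 1-12 (hypothesis
#' \code{"recent"}) search T2 below 15,000 generations with no
#' migration-rate change (11 free parameters); models 13-24
#' (\code{"old"}) search T2 above 15,000 generations with a rate change
#' at TC below 15,000 (15 free parameters). Within each block, models
#' 1-6 use the nested shape and 7-12 the radiating shape, cycling the
#' six assignments.
#'
#' @param id Optional model id(s) ("M1".."M24") to return.
#' @return A list of \code{model_spec} lists (or a single spec when one
#'   id is given): \code{id}, \code{assignment}, \code{shape},
#'   \code{hypothesis}, \code{n_params}, \code{ranges}.
#' @export
model_family <- function(id = NULL) {
  specs <- list()
  for (i in 0:23) {
    hyp <- if (i < 12) "recent" else "old"
    within <- i %% 12
    shape <- if (within < 6) "nested" else "radiating"
    assignment <- .assign_cycle[[within %% 6 + 1]]
    specs[[i + 1]] <- .model_spec(paste0("M", i + 1), assignment, shape,
                                  hyp)
  }
  names(specs) <- paste0("M", 1:24)
  if (!is.null(id)) {
    if (length(id) == 1) return(specs[[id]])
    return(specs[id])
  }
  specs
}

.model_spec <- function(id, assignment, shape, hypothesis) {
  size_rg <- c(1e2, 1e6)
  mig_rg <- c(1e-8, 1e-2)
  ranges <- list(N0 = size_rg, N1 = size_rg, N2 = size_rg,
                 NA_ = size_rg, NB = size_rg,
                 T1 = c(100, 5e5),
                 T2 = if (hypothesis == "recent") c(10, 15000)
                      else c(15000, 5e5),
                 m01 = mig_rg, m02 = mig_rg, m12 = mig_rg, m3 = mig_rg)
  if (hypothesis == "old")
    ranges <- c(ranges, list(TC = c(10, 15000), k01 = mig_rg,
                             k02 = mig_rg, k12 = mig_rg))
  structure(list(id = id, assignment = assignment, shape = shape,
                 hypothesis = hypothesis, n_params = length(ranges),
                 ranges = ranges), class = "model_spec")
}

# demography_config from a named parameter vector under a spec
.spec_demography <- function(spec, par) {
  recent <- spec$hypothesis == "recent"
  demography_config(
    N0 = par[["N0"]], N1 = par[["N1"]], N2 = par[["N2"]],
    NA_ = par[["NA_"]], NB = par[["NB"]],
    T1 = par[["T1"]], T2 = par[["T2"]],
    # "recent": constant migration over [0, T2): the young-epoch rates
    # run to the split (TC = T2); "old": rate change at the fitted TC
    TC = if (recent) par[["T2"]] else par[["TC"]],
    m01 = par[["m01"]], m02 = par[["m02"]], m12 = par[["m12"]],
    k01 = if (recent) 0 else par[["k01"]],
    k02 = if (recent) 0 else par[["k02"]],
    k12 = if (recent) 0 else par[["k12"]],
    m3 = par[["m3"]], shape = spec$shape,
    assignment = spec$assignment)
}

# moment-based starting point: per-deme nucleotide diversity gives the
# deme sizes (pi = 4 N mu), pairwise divergence minus mean diversity
# gives the split times (dxy = pi_anc + 2 T mu); migration starts at the
# geometric mid-range. Requires a monomorphic tally (absolute scale).
.moment_start <- function(spec, observed, mu = 7e-9) {
  arr <- observed$arr
  n_hap <- observed$n_hap
  total <- sum(arr) + observed$monomorphic
  if (total <= sum(arr)) return(NULL)
  idx <- as.matrix(expand.grid(a0 = 0:n_hap[1], a1 = 0:n_hap[2],
                               a2 = 0:n_hap[3]))
  cnt <- as.vector(arr)
  pi_deme <- vapply(1:3, function(i) {
    a <- idx[, i]
    n <- n_hap[i]
    sum(cnt * 2 * a * (n - a) / (n * (n - 1))) / total
  }, 0)
  dxy <- function(i, j) {
    ai <- idx[, i]; aj <- idx[, j]
    ni <- n_hap[i]; nj <- n_hap[j]
    sum(cnt * (ai * (nj - aj) + aj * (ni - ai)) / (ni * nj)) / total
  }
  N <- pmax(pi_deme / (4 * mu), 200)
  t_est <- function(i, j)
    max((dxy(i, j) - (pi_deme[i] + pi_deme[j]) / 2) / (2 * mu), 200)
  # nested: pair (1,2) splits at T2, pairs with deme 0 at T1;
  # radiating: pair (0,2) splits at T2
  t2 <- if (spec$shape == "nested") t_est(2, 3) else t_est(1, 3)
  t1 <- max(t_est(1, 2), t_est(1, 3), t_est(2, 3), t2)
  par <- c(N0 = N[1], N1 = N[2], N2 = N[3], NA_ = mean(N),
           NB = mean(N), T1 = t1, T2 = t2,
           m01 = 1e-6, m02 = 1e-6, m12 = 1e-6, m3 = 1e-6)
  if (spec$hypothesis == "old")
    par <- c(par, TC = sqrt(10 * 15000), k01 = 1e-6, k02 = 1e-6,
             k12 = 1e-6)
  .clip_params(spec, par[names(spec$ranges)])
}

.random_start <- function(spec) {
  par <- vapply(spec$ranges, function(rg)
    exp(runif(1, log(rg[1]), log(rg[2]))), 0)
  names(par) <- names(spec$ranges)
  if (par[["T1"]] < par[["T2"]]) par[["T1"]] <- par[["T2"]]
  par
}

.clip_params <- function(spec, par) {
  for (nm in names(spec$ranges)) {
    rg <- spec$ranges[[nm]]
    par[[nm]] <- min(max(par[[nm]], rg[1]), rg[2])
  }
  if (par[["T1"]] < par[["T2"]]) par[["T1"]] <- par[["T2"]]
  par
}

#' Fit a demographic model to an observed SFS
#'
#' Composite-likelihood maximization by cyclic coordinate search: each
#' run starts from a log-uniform random point in the search ranges and
#' performs up to \code{n_cycles} cycles; in each cycle every parameter
#' is varied over a multiplicative candidate grid (shrinking with the
#' cycle index) while the expected SFS is re-simulated with common
#' random numbers, so the objective is deterministic within a run. The
#' best run is returned.
#'
#' @param spec A \code{model_spec} from \code{\link{model_family}}.
#' @param observed An observed \code{\link{sfs3d}} of counts; its
#'   dimensions set the haploid sample sizes.
#' @param n_sims Coalescent simulations per likelihood evaluation.
#' @param n_cycles Maximum optimization cycles per run (default 40;
#'   the search stops early when a cycle improves nothing).
#' @param n_runs Independent random starts (default 4).
#' @param seed Seed controlling starts and simulation streams.
#' @param start Optional named start vector; when given, run 1 starts
#'   there (used by the parametric bootstrap).
#' @return A list of class \code{fit_result}: \code{id}, \code{par},
#'   \code{loglik10} (maximum log10 composite likelihood),
#'   \code{n_params}, \code{aic}, \code{runs} (per-run summaries).
#' @export
fit_model <- function(spec, observed, n_sims = 2000, n_cycles = 40,
                      n_runs = 4, seed = 1, start = NULL) {
  stopifnot(inherits(spec, "model_spec"), inherits(observed, "sfs3d"))
  for (nm in names(spec$ranges)) {
    if (!is.null(start) && nm %in% names(start)) {
      rg <- spec$ranges[[nm]]
      if (start[[nm]] < rg[1] || start[[nm]] > rg[2])
        stop("start value for ", nm, " outside its search range")
    }
  }
  n_hap <- observed$n_hap
  samp <- sample_config(n_hap = pmax(n_hap, 2), n_loci = 1,
                        locus_bp = 1000, mu = 7e-9)
  eval_ll <- function(par, eval_seed) {
    dem <- .spec_demography(spec, par)
    es <- expected_sfs(dem, samp, n_sims = n_sims, seed = eval_seed)
    composite_loglik(observed, es)
  }
  runs <- list()
  best <- NULL
  for (r in seq_len(n_runs)) {
    run_seed <- (seed * 131 + r * 7919) %% .Machine$integer.max
    set.seed(run_seed)
    moment <- if (r == 1 && is.null(start))
      .moment_start(spec, observed) else NULL
    par <- if (r == 1 && !is.null(start))
      .clip_params(spec, unlist(start)[names(spec$ranges)])
    else if (!is.null(moment)) moment
    else .random_start(spec)
    eval_seed <- (run_seed + 1) %% .Machine$integer.max
    ll <- eval_ll(par, eval_seed)
    # cyclic coordinate line search on the log scale: the first cycle
    # scans each parameter over its whole search range (7 points), later
    # cycles refine in a multiplicative window shrinking around the
    # current value; a run started from a supplied point (bootstrap
    # refits) skips the global scan
    local_only <- (r == 1 && !is.null(start))
    if (n_cycles > 0) {
      for (cyc in seq_len(n_cycles)) {
        improved <- FALSE
        for (nm in names(spec$ranges)) {
          rg <- spec$ranges[[nm]]
          if (cyc == 1 && !local_only) {
            grid <- exp(seq(log(rg[1]), log(rg[2]), length.out = 7))
          } else {
            f <- 4 ^ (0.5 ^ (cyc - if (local_only) 1 else 2))
            grid <- par[[nm]] * exp(seq(-log(f), log(f),
                                        length.out = 5))
            grid <- pmin(pmax(grid, rg[1]), rg[2])
          }
          for (g in unique(grid)) {
            cand <- par
            cand[[nm]] <- g
            cand <- .clip_params(spec, cand)
            if (identical(cand[[nm]], par[[nm]])) next
            llc <- eval_ll(cand, eval_seed)
            if (llc > ll) {
              par <- cand
              ll <- llc
              improved <- TRUE
            }
          }
        }
        # coalescent-scale move: sizes and times together (migration
        # inverted) — the sloppy direction of SFS models that single
        # coordinates cannot follow
        time_par <- intersect(c("N0", "N1", "N2", "NA_", "NB", "T1",
                                "T2", "TC"), names(spec$ranges))
        mig_par <- intersect(c("m01", "m02", "m12", "m3", "k01", "k02",
                               "k12"), names(spec$ranges))
        sfac <- exp(seq(-log(3), log(3), length.out = 7) *
                      0.6 ^ (cyc - 1))
        for (f in sfac) {
          if (abs(f - 1) < 1e-12) next
          cand <- par
          cand[time_par] <- cand[time_par] * f
          cand[mig_par] <- cand[mig_par] / f
          cand <- .clip_params(spec, cand)
          llc <- eval_ll(cand, eval_seed)
          if (llc > ll) {
            par <- cand
            ll <- llc
            improved <- TRUE
          }
        }
        if (cyc > 1 && !improved) break
      }
    }
    runs[[r]] <- list(run = r, par = par, loglik10 = ll,
                      seed = run_seed)
    if (is.null(best) || ll > best$loglik10)
      best <- list(par = par, loglik10 = ll)
  }
  structure(list(id = spec$id, par = best$par,
                 loglik10 = best$loglik10, n_params = spec$n_params,
                 aic = aic(best$loglik10, spec$n_params), runs = runs),
            class = "fit_result")
}

#' Akaike information criterion from a log10 likelihood
#'
#' AIC = 2 k - 2 ln(10) log10(L): the log10 composite likelihood is
#' converted to natural log before the standard formula.
#'
#' @param loglik10 Maximum log10 likelihood.
#' @param n_params Number of free parameters k.
#' @return AIC.
#' @export
aic <- function(loglik10, n_params) {
  2 * n_params - 2 * log(10) * loglik10
}

#' Compare fitted models by delta AIC
#'
#' @param fits A list of \code{fit_result} objects, or a data frame
#'   with columns \code{id} (or \code{model}), \code{loglik10} and
#'   \code{n_params}.
#' @return A data frame (\code{model}, \code{loglik10},
#'   \code{n_params}, \code{aic}, \code{delta_aic}) with the best model
#'   at delta 0, in input order.
#' @export
compare_models <- function(fits) {
  if (is.data.frame(fits)) {
    id <- if ("model" %in% names(fits)) fits$model else fits$id
    df <- data.frame(model = id, loglik10 = fits$loglik10,
                     n_params = fits$n_params,
                     stringsAsFactors = FALSE)
  } else {
    df <- do.call(rbind, lapply(fits, function(f)
      data.frame(model = f$id, loglik10 = f$loglik10,
                 n_params = f$n_params, stringsAsFactors = FALSE)))
  }
  df$aic <- aic(df$loglik10, df$n_params)
  df$delta_aic <- df$aic - min(df$aic)
  rownames(df) <- NULL
  df
}

#' Parametric bootstrap confidence intervals
#'
#' Simulates \code{n_boot} spectra of \code{n_poly} polymorphic sites
#' from the expected SFS under the fitted parameters, refits each
#' (starting from the fitted values), and returns per-parameter 2.5/97.5
#' percentile intervals.
#'
#' @param spec The fitted \code{model_spec}.
#' @param par Fitted named parameter vector.
#' @param n_hap Haploid sample sizes per cluster (length 3).
#' @param n_poly Number of polymorphic sites per bootstrap SFS (used
#'   when \code{n_sites} is NULL).
#' @param n_sites Total surveyed sites; when given, each bootstrap
#'   draws its polymorphic-site count binomially from the fitted
#'   polymorphism probability and carries the monomorphic remainder,
#'   matching the scale-anchored likelihood.
#' @param n_boot Bootstrap replicates (default 20).
#' @param n_sims Simulations per likelihood evaluation.
#' @param n_cycles Refit cycles (default 3).
#' @param start_at_fit Start each refit at the fitted values (fast but
#'   understates estimator variance); by default refits replicate the
#'   full estimator (moment-based start on the bootstrap data).
#' @param type Interval type: \code{"basic"} (default) reflects the
#'   refit quantiles around the estimate on the log scale, cancelling
#'   first-order estimator bias; \code{"percentile"} reports the raw
#'   2.5/97.5 refit percentiles.
#' @param seed Seed.
#' @return A matrix (parameters x c(lo, hi)) of 95 percent intervals,
#'   with attribute \code{"replicates"} holding the refitted values.
#' @export
parametric_bootstrap <- function(spec, par, n_hap, n_poly = NULL,
                                 n_sites = NULL, n_boot = 20,
                                 n_sims = 2000, n_cycles = 3,
                                 start_at_fit = FALSE,
                                 type = c("basic", "percentile"),
                                 seed = 1) {
  type <- match.arg(type)
  if (is.null(n_poly) && is.null(n_sites))
    stop("give n_poly or n_sites")
  reps <- matrix(NA_real_, nrow = n_boot, ncol = length(par),
                 dimnames = list(NULL, names(par)))
  samp <- sample_config(n_hap = n_hap, n_loci = 1, locus_bp = 1000,
                        mu = 7e-9)
  dem <- .spec_demography(spec, par)
  for (b in seq_len(n_boot)) {
    bs <- (seed * 977 + b * 104729) %% .Machine$integer.max
    set.seed(bs)
    # fresh expected spectrum per replicate, then a site-level draw
    es <- expected_sfs(dem, samp, n_sims = n_sims, seed = bs)
    mono <- 0
    if (!is.null(n_sites)) {
      np <- rbinom(1, n_sites, es$p_poly)
      mono <- n_sites - np
    } else np <- n_poly
    counts <- as.vector(rmultinom(1, np, as.vector(es$arr)))
    obs_b <- sfs3d(array(counts, dim = dim(es$arr)), folded = TRUE,
                   counts = TRUE, monomorphic = mono)
    fit <- fit_model(spec, obs_b, n_sims = n_sims, n_cycles = n_cycles,
                     n_runs = 1, seed = bs,
                     start = if (start_at_fit) par else NULL)
    reps[b, ] <- fit$par[colnames(reps)]
  }
  ci <- t(vapply(colnames(reps), function(nm) {
    q <- quantile(reps[, nm], c(0.025, 0.975), names = FALSE)
    if (type == "basic") {
      # reflected (basic) interval on the log scale: corrects the
      # first-order bias that the refits inherit from the estimator
      th <- par[[nm]]
      if (th > 0 && all(q > 0))
        q <- sort(exp(2 * log(th) - log(q[2:1])))
    }
    q
  }, numeric(2)))
  colnames(ci) <- c("lo", "hi")
  attr(ci, "replicates") <- reps
  ci
}

#' Standardized SFS residuals
#'
#' Per-entry (O - E)/sqrt(E) with E the expected counts rescaled to the
#' observed polymorphic total; entries with E = 0 are returned
#' separately.
#'
#' @param observed \code{\link{sfs3d}} of counts.
#' @param expected \code{\link{sfs3d}} of probabilities or counts.
#' @return A list: \code{residuals} (array, NA where E = 0),
#'   \code{zero_expected} (indices with E = 0 but O > 0).
#' @export
residual_sfs <- function(observed, expected) {
  o <- observed$arr
  e <- expected$arr
  dm <- dim(o)
  o[1, 1, 1] <- 0
  o[dm[1], dm[2], dm[3]] <- 0
  e[1, 1, 1] <- 0
  e[dm[1], dm[2], dm[3]] <- 0
  if (sum(e) > 0) e <- e * sum(o) / sum(e)
  r <- array(NA_real_, dim = dm)
  pos <- e > 0
  r[pos] <- (o[pos] - e[pos]) / sqrt(e[pos])
  list(residuals = r, zero_expected = which(e == 0 & o > 0))
}

#' Time and rate unit conversions
#'
#' \code{convert_time}: generations to years and Mya (Mya reported to 2
#' decimals). \code{convert_msmc}: scaled coalescent output to years and
#' effective size (generations = scaled time / mu, Ne = 1/(2 lambda
#' mu)). \code{per_gen_rate}: a per-year rate times the generation time
#' divided by six (the woody-perennial slowdown applied to
#' annual-calibrated rates). \code{pop_migration_rate}: 2 N m.
#'
#' @param generations Time in generations.
#' @param generation_time_years Generation time (default 30).
#' @return \code{convert_time}: list with \code{years} and \code{mya}.
#' @export
convert_time <- function(generations, generation_time_years = 30) {
  years <- generations * generation_time_years
  list(years = years, mya = round(years / 1e6, 2))
}

#' @rdname convert_time
#' @param scaled_time,scaled_rate MSMC-scaled time and coalescence rate.
#' @param mu Per-site per-generation mutation rate.
#' @export
convert_msmc <- function(scaled_time, scaled_rate, mu,
                         generation_time_years = 30) {
  gens <- scaled_time / mu
  list(generations = gens, years = gens * generation_time_years,
       ne = 1 / (2 * scaled_rate * mu))
}

#' @rdname convert_time
#' @param per_year_rate Mutation rate per site per year.
#' @export
per_gen_rate <- function(per_year_rate, generation_time_years) {
  per_year_rate * generation_time_years / 6
}

#' @rdname convert_time
#' @param n_diploid Effective diploid size.
#' @param m Per-generation migration rate.
#' @export
pop_migration_rate <- function(n_diploid, m) {
  2 * n_diploid * m
}

#' Write / read an SFS text file
#'
#' Plain-text format: a header line \code{n0 n1 n2 folded monomorphic}
#' followed by the flattened counts (dimension 1 fastest).
#'
#' @param sfs An \code{\link{sfs3d}}.
#' @param path File path.
#' @return \code{write_sfs}: the path; \code{read_sfs}: an
#'   \code{\link{sfs3d}}.
#' @export
write_sfs <- function(sfs, path) {
  hdr <- paste(c(sfs$n_hap, as.integer(sfs$folded), sfs$monomorphic),
               collapse = " ")
  writeLines(c(hdr, paste(as.vector(sfs$arr), collapse = " ")), path)
  invisible(path)
}

#' @rdname write_sfs
#' @export
read_sfs <- function(path) {
  ln <- readLines(path)
  hdr <- as.numeric(strsplit(trimws(ln[1]), "\\s+")[[1]])
  vals <- as.numeric(strsplit(trimws(ln[2]), "\\s+")[[1]])
  arr <- array(vals, dim = hdr[1:3] + 1)
  sfs3d(arr, folded = hdr[4] == 1, counts = TRUE, monomorphic = hdr[5])
}
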