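# Population structure and landscape genomics: ancestry-based core
# samples, PCA, distance-based Moran's eigenvector maps, redundancy
# analysis with permutation tests, forward selection and variance
# partitioning.

#' Core samples by ancestry proportion
#'
#' @param q Numeric matrix of ancestry proportions (samples x K), rows
#'   summing to 1 within 1e-6; rownames are sample ids.
#' @param threshold Minimum (exclusive) major ancestry (default 0.9).
#' @return A data frame (\code{sample}, \code{cluster}) of samples whose
#'   maximum ancestry strictly exceeds the threshold; cluster is the
#'   argmax component (column name, or its index).
#' @export
core_samples <- function(q, threshold = 0.9) {
  q <- as.matrix(q)
  if (any(abs(rowSums(q) - 1) > 1e-6))
    stop("ancestry proportions must sum to 1 per sample")
  mx <- apply(q, 1, max)
  keep <- mx > threshold
  cl <- apply(q, 1, which.max)
  lab <- if (!is.null(colnames(q))) colnames(q)[cl] else as.character(cl)
  ids <- if (!is.null(rownames(q))) rownames(q) else
    as.character(seq_len(nrow(q)))
  data.frame(sample = ids[keep], cluster = lab[keep],
             stringsAsFactors = FALSE)
}

#' PCA of genotype dosages
#'
#' Complete-case sites only; dosages are centered per SNP (optionally
#' scaled by the binomial standard deviation sqrt(p(1-p))) and
#' decomposed by SVD.
#'
#' @param gm A \code{\link{genotype_matrix}} (typically after
#'   MAF/missingness/LD filters).
#' @param scale_p Scale each SNP by sqrt(p(1-p)) (default FALSE).
#' @return A list: \code{scores} (samples x PCs), \code{explained}
#'   (variance fractions summing to 1), \code{n_snps}.
#' @export
pca_genotypes <- function(gm, scale_p = FALSE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  complete <- rowSums(is.na(gm$dosage)) == 0
  d <- t(gm$dosage[complete, , drop = FALSE])  # samples x snps
  # drop monomorphic columns (zero variance)
  v <- apply(d, 2, var)
  d <- d[, v > 0, drop = FALSE]
  if (ncol(d) == 0) stop("no polymorphic complete-case SNPs")
  ctr <- scale(d, center = TRUE, scale = FALSE)
  if (scale_p) {
    p <- colMeans(d) / 2
    ctr <- sweep(ctr, 2, sqrt(p * (1 - p)), "/")
  }
  pc <- prcomp(ctr, center = FALSE, scale. = FALSE)
  list(scores = pc$x, explained = pc$sdev^2 / sum(pc$sdev^2),
       n_snps = ncol(d))
}

#' Distance-based Moran's eigenvector maps
#'
#' Builds the great-circle (haversine) distance matrix, truncates it at
#' the longest edge of the minimum spanning tree (larger distances are
#' replaced by four times the truncation distance), Gower-centers
#' -0.5 d^2, and returns the eigenvectors with positive eigenvalues in
#' decreasing eigenvalue order.
#'
#' @param coords Matrix or data frame with columns \code{lon} and
#'   \code{lat} in decimal degrees (in that order for unnamed input).
#' @return Matrix of spatial eigenvectors (columns MEM1, MEM2, ...) with
#'   attribute \code{"values"} (eigenvalues) and \code{"truncation"}.
#' @export
dbmem <- function(coords) {
  coords <- as.matrix(coords)
  if (!is.null(colnames(coords)) &&
      all(c("lon", "lat") %in% colnames(coords)))
    coords <- coords[, c("lon", "lat")]
  n <- nrow(coords)
  if (n < 3) stop("need at least 3 points")
  d <- geosphere::distm(coords, fun = geosphere::distHaversine) / 1000
  st <- vegan::spantree(as.dist(d))
  t_trunc <- max(st$dist)
  dstar <- d
  dstar[dstar > t_trunc] <- 4 * t_trunc
  diag(dstar) <- 0
  a <- -0.5 * dstar^2
  ctr <- diag(n) - matrix(1 / n, n, n)
  g <- ctr %*% a %*% ctr
  eg <- eigen((g + t(g)) / 2, symmetric = TRUE)
  tol <- 1e-8 * max(abs(eg$values))
  keep <- eg$values > tol
  if (!any(keep)) stop("no positive eigenvalues")
  vecs <- eg$vectors[, keep, drop = FALSE]
  colnames(vecs) <- paste0("MEM", seq_len(ncol(vecs)))
  attr(vecs, "values") <- eg$values[keep]
  attr(vecs, "truncation") <- t_trunc
  vecs
}

# center Y; residualize M on covariates (with intercept) via qr
.residualize <- function(m, z) {
  if (is.null(z)) return(scale(m, center = TRUE, scale = FALSE))
  z1 <- cbind(1, as.matrix(z))
  m - qr.fitted(qr(z1), as.matrix(m))
}

#' Redundancy analysis (optionally partial)
#'
#' Least-squares fit of the (centered, optionally
#' covariate-residualized) response matrix on the predictors; canonical
#' axes are the principal components of the fitted values. R-squared is
#' the fitted sum of squares over the total sum of squares of the
#' (residualized) response; adjusted R-squared uses Ezekiel's formula
#' with m = rank of the predictor matrix.
#'
#' @param y Response matrix (samples x variables), e.g. genotype
#'   dosages or PC scores.
#' @param x Predictor matrix or data frame.
#' @param z Optional covariate (conditioning) matrix.
#' @return A list of class \code{ohia_rda}: \code{r2}, \code{adj_r2},
#'   \code{scores} (site scores on canonical axes), \code{rank},
#'   \code{n}, plus internals used by the permutation test.
#' @export
rda_fit <- function(y, x, z = NULL) {
  y <- as.matrix(y)
  x <- as.matrix(x)
  n <- nrow(y)
  yr <- .residualize(y, z)
  xr <- .residualize(x, z)
  qx <- qr(xr)
  m <- qx$rank
  fit <- qr.fitted(qx, yr)
  ss_tot <- sum(yr^2)
  ss_fit <- sum(fit^2)
  # a residualized response that is numerically zero carries no signal
  tol <- 1e-10 * max(sum(scale(y, scale = FALSE)^2), 1)
  r2 <- if (ss_tot > tol) ss_fit / ss_tot else 0
  q_cov <- if (is.null(z)) 0 else qr(as.matrix(z))$rank
  adj <- 1 - (1 - r2) * (n - 1 - q_cov) / (n - m - 1 - q_cov)
  pc <- if (ss_fit > 0) prcomp(fit, center = FALSE) else NULL
  structure(list(r2 = r2, adj_r2 = adj,
                 scores = if (!is.null(pc)) pc$x else NULL,
                 rank = m, n = n, q_cov = q_cov,
                 ss_fit = ss_fit, ss_res = ss_tot - ss_fit,
                 y_res = yr, x_res = xr),
            class = "ohia_rda")
}

#' Permutation test for an RDA model
#'
#' Pseudo-F statistic with rows of the (covariate-residualized) response
#' permuted; for partial models this permutes the residuals of the
#' reduced (covariates-only) model. p = (1 + number of permuted F >=
#' observed F) / (1 + n_perm).
#'
#' @param y,x,z As in \code{\link{rda_fit}}.
#' @param n_perm Number of permutations (default 999).
#' @param seed Seed.
#' @return A list: \code{f}, \code{p}, \code{n_perm}.
#' @export
rda_perm_test <- function(y, x, z = NULL, n_perm = 999, seed = 1) {
  fit <- rda_fit(y, x, z)
  n <- fit$n
  df_res <- n - fit$rank - 1 - fit$q_cov
  if (df_res <= 0) stop("no residual degrees of freedom")
  fstat <- function(yr) {
    f <- qr.fitted(qr(fit$x_res), yr)
    ssf <- sum(f^2)
    ssr <- sum(yr^2) - ssf
    (ssf / fit$rank) / (ssr / df_res)
  }
  f0 <- fstat(fit$y_res)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    yp <- fit$y_res[sample.int(n), , drop = FALSE]
    if (fstat(yp) >= f0) exceed <- exceed + 1L
  }
  list(f = f0, p = (1 + exceed) / (1 + n_perm), n_perm = n_perm)
}

#' Forward selection of constrained-ordination predictors
#'
#' Iteratively adds the candidate with the largest adjusted-R-squared
#' gain, admitting it only if its conditional permutation p-value is
#' below \code{alpha} and the cumulative adjusted R-squared does not
#' exceed that of the all-candidate model; stops otherwise.
#'
#' @param y Response matrix.
#' @param candidates Data frame or matrix of candidate predictors.
#' @param alpha Admission significance level (default 0.05).
#' @param n_perm Permutations per admission test (default 999).
#' @param seed Seed.
#' @return Character vector of selected column names (possibly empty).
#' @export
forward_select <- function(y, candidates, alpha = 0.05, n_perm = 999,
                           seed = 1) {
  candidates <- as.matrix(candidates)
  if (is.null(colnames(candidates)))
    colnames(candidates) <- paste0("V", seq_len(ncol(candidates)))
  global_adj <- rda_fit(y, candidates)$adj_r2
  selected <- character(0)
  remaining <- colnames(candidates)
  current_adj <- -Inf
  step <- 0
  while (length(remaining)) {
    step <- step + 1
    adj <- vapply(remaining, function(v) {
      rda_fit(y, candidates[, c(selected, v), drop = FALSE])$adj_r2
    }, 0)
    best <- remaining[which.max(adj)]
    best_adj <- max(adj)
    if (length(selected) && best_adj <= current_adj) break
    if (best_adj > global_adj + 1e-12) break
    z <- if (length(selected))
      candidates[, selected, drop = FALSE] else NULL
    pt <- rda_perm_test(y, candidates[, best, drop = FALSE], z,
                        n_perm = n_perm, seed = seed + step)
    if (pt$p >= alpha) break
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
    current_adj <- best_adj
  }
  selected
}

#' Variance partitioning between environment and geography
#'
#' Adjusted-R-squared partition from the three models Y~ENV, Y~GEO and
#' Y~ENV+GEO; conditional fractions by subtraction; permutation
#' p-values for the testable fractions (both totals and both
#' conditional fractions).
#'
#' @param y Response matrix.
#' @param env,geo Predictor matrices.
#' @param n_perm Permutations (default 999).
#' @param seed Seed.
#' @return A list of class \code{varpart_result}: adjusted fractions
#'   \code{env_total}, \code{geo_total}, \code{env_given_geo},
#'   \code{geo_given_env}, \code{joint}, \code{residual}, and a
#'   \code{p} vector.
#' @export
varpart_genetic <- function(y, env, geo, n_perm = 999, seed = 1) {
  env <- as.matrix(env)
  geo <- as.matrix(geo)
  a_e <- rda_fit(y, env)$adj_r2
  has_geo <- ncol(geo) > 0
  a_g <- if (has_geo) rda_fit(y, geo)$adj_r2 else 0
  a_eg <- if (has_geo) rda_fit(y, cbind(env, geo))$adj_r2 else a_e
  res <- list(env_total = a_e, geo_total = a_g,
              env_given_geo = a_eg - a_g, geo_given_env = a_eg - a_e,
              joint = a_e + a_g - a_eg, residual = 1 - a_eg)
  p <- c(env_total = rda_perm_test(y, env, NULL, n_perm, seed)$p)
  if (has_geo) {
    p["geo_total"] <- rda_perm_test(y, geo, NULL, n_perm, seed + 1)$p
    p["env_given_geo"] <- rda_perm_test(y, env, geo, n_perm, seed + 2)$p
    p["geo_given_env"] <- rda_perm_test(y, geo, env, n_perm, seed + 3)$p
  }
  res$p <- p
  class(res) <- "varpart_result"
  res
}

#' @export
print.varpart_result <- function(x, ...) {
  cat(sprintf(paste0(
    "adjusted R2 fractions:\n  ENV total      %6.3f (p=%.3g)\n",
    "  GEO total      %6.3f (p=%.3g)\n  ENV | GEO      %6.3f (p=%.3g)\n",
    "  GEO | ENV      %6.3f (p=%.3g)\n  joint          %6.3f\n",
    "  residual       %6.3f\n"),
    x$env_total, x$p["env_total"], x$geo_total, x$p["geo_total"],
    x$env_given_geo, x$p["env_given_geo"],
    x$geo_given_env, x$p["geo_given_env"], x$joint, x$residual))
  invisible(x)
}
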