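# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles enumerate pairs/groups directly and share no code
# with the implementation.

# genotype matrix from a dosage matrix (sites x samples)
make_gm <- function(dosage, chrom = NULL, pos = NULL,
                    samples = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  n_site <- nrow(dosage)
  if (is.null(chrom)) chrom <- rep("chr1", n_site)
  if (is.null(pos)) pos <- seq_len(n_site) * 10L
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(dosage)))
  genotype_matrix(dosage, chrom, pos, rep("A", n_site), rep("T", n_site),
                  samples)
}

# haplotype matrix from a 0/1 matrix (sites x haplotypes)
make_hm <- function(hap, chrom = NULL, pos = NULL) {
  hap <- as.matrix(hap)
  n_site <- nrow(hap)
  if (is.null(chrom)) chrom <- rep("chr1", n_site)
  if (is.null(pos)) pos <- seq_len(n_site) * 100L
  samples <- sprintf("s%02d", seq_len(ncol(hap) / 2))
  haplotype_matrix(hap, chrom, pos, rep("A", n_site), rep("T", n_site),
                   samples)
}

# expand dosages at one site to the multiset of alleles (drop missing)
.alleles <- function(dos) {
  dos <- dos[!is.na(dos)]
  unlist(lapply(dos, function(g) c(rep(1, g), rep(0, 2 - g))))
}

# pi oracle: average pairwise differences over all allele pairs per site
oracle_pi <- function(dosage, n_invariant_full = 0, n_full = NULL) {
  num <- 0
  den <- 0
  for (s in seq_len(nrow(dosage))) {
    al <- .alleles(dosage[s, ])
    n <- length(al)
    if (n < 2) next
    prs <- combn(n, 2)
    num <- num + sum(al[prs[1, ]] != al[prs[2, ]])
    den <- den + ncol(prs)
  }
  if (n_invariant_full > 0)
    den <- den + n_invariant_full * choose(n_full, 2)
  if (den == 0) return(NA_real_)
  num / den
}

# dxy oracle: cross-population allele mismatch fraction
oracle_dxy <- function(d1, d2, n_invariant_full = 0, nf1 = NULL,
                       nf2 = NULL) {
  num <- 0
  den <- 0
  for (s in seq_len(nrow(d1))) {
    a1 <- .alleles(d1[s, ])
    a2 <- .alleles(d2[s, ])
    if (!length(a1) || !length(a2)) next
    num <- num + sum(outer(a1, a2, `!=`))
    den <- den + length(a1) * length(a2)
  }
  if (n_invariant_full > 0) den <- den + n_invariant_full * nf1 * nf2
  if (den == 0) return(NA_real_)
  num / den
}

# Weir-Cockerham (1984) components, independent algebra
oracle_wc <- function(d1, d2) {
  out <- matrix(NA_real_, nrow(d1), 3)
  for (s in seq_len(nrow(d1))) {
    x1 <- d1[s, ][!is.na(d1[s, ])]
    x2 <- d2[s, ][!is.na(d2[s, ])]
    n <- c(length(x1), length(x2))
    p <- c(mean(x1) / 2, mean(x2) / 2)
    h <- c(mean(x1 == 1), mean(x2 == 1))
    r <- 2
    nbar <- mean(n)
    nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
    pbar <- sum(n * p) / sum(n)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / sum(n)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    out[s, ] <- c(a, b, cc)
  }
  out
}

# Tajima's D oracle (independent constant algebra, complete n only)
oracle_tajima <- function(dosage) {
  keep <- rowSums(is.na(dosage)) == 0
  d <- dosage[keep, , drop = FALSE]
  n <- 2 * ncol(d)
  ac <- rowSums(d)
  seg <- ac > 0 & ac < n
  S <- sum(seg)
  if (S == 0 || n < 4) return(NA_real_)
  k <- sum(ac[seg] * (n - ac[seg])) / choose(n, 2)
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  v <- (c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1)
  (k - S / a1) / sqrt(v)
}

# kNN outlier score oracle over all pairwise distances
oracle_knn <- function(m, k, weighted = TRUE) {
  n <- nrow(m)
  dd <- as.matrix(dist(m))
  vapply(seq_len(n), function(i) {
    nb <- sort(dd[i, -i])[1:k]
    w <- if (weighted) (k:1) / sum(k:1) else rep(1 / k, k)
    sum(w * nb)
  }, 0)
}

# hypergeometric enrichment tail oracle
oracle_hyper <- function(x, in_region, outlier, total) {
  # P(X >= x) drawing `in_region` windows from total with `outlier` marked
  sum(dhyper(x:min(in_region, outlier), outlier, total - outlier,
             in_region))
}

# naive event-by-event structured-coalescent simulator (R, independent):
# three demes, sizes N (length 3), symmetric migration matrix mig,
# merges at t2 (deme 2 -> dest2) and t1 (all -> 0); returns per-branch
# lengths with deme-descendant configurations
oracle_coalescent <- function(n_per_deme, N, mig, t1, t2, dest2 = 1,
                              NB = N[dest2 + 1], NA_ = N[1]) {
  lin <- list()
  for (d in 0:2) for (i in seq_len(n_per_deme[d + 1]))
    lin[[length(lin) + 1]] <- list(deme = d, cfg = as.integer(0:2 == d))
  t <- 0
  lens <- list()
  while (length(lin) > 1) {
    demes <- vapply(lin, `[[`, 0, "deme")
    cnt <- vapply(0:2, function(d) sum(demes == d), 0)
    sizes <- N
    if (t >= t1) sizes[1] <- NA_
    else if (t >= t2) sizes[dest2 + 1] <- NB
    rate_c <- cnt * (cnt - 1) / 2 / (2 * sizes)
    mg <- if (t >= t2) matrix(0, 3, 3) else mig
    rate_m <- outer(cnt, rep(1, 3)) * mg
    tot <- sum(rate_c) + sum(rate_m)
    bound <- if (t < t2) t2 else if (t < t1) t1 else Inf
    dt <- if (tot > 0) rexp(1, tot) else Inf
    if (t + dt >= bound) {
      dt <- bound - t
      for (i in seq_along(lin)) {
        lin[[i]]$len <- (lin[[i]]$len %||% 0) + dt
      }
      t <- bound
      if (bound == t2) {
        for (i in seq_along(lin))
          if (lin[[i]]$deme == 2) lin[[i]]$deme <- dest2
      } else {
        for (i in seq_along(lin)) lin[[i]]$deme <- 0
      }
      next
    }
    for (i in seq_along(lin)) lin[[i]]$len <- (lin[[i]]$len %||% 0) + dt
    t <- t + dt
    u <- runif(1) * tot
    done <- FALSE
    for (d in 0:2) {
      if (!done && u < rate_c[d + 1]) {
        cand <- which(demes == d)
        idx <- cand[sample.int(length(cand), 2)]
        a <- lin[[idx[1]]]; b <- lin[[idx[2]]]
        lens[[length(lens) + 1]] <- list(cfg = a$cfg, len = a$len)
        lens[[length(lens) + 1]] <- list(cfg = b$cfg, len = b$len)
        par <- list(deme = d, cfg = a$cfg + b$cfg, len = 0)
        lin <- lin[-idx]
        lin[[length(lin) + 1]] <- par
        done <- TRUE
      }
      u <- u - rate_c[d + 1]
      if (done) break
      for (e in 0:2) {
        if (d != e && u < rate_m[d + 1, e + 1]) {
          cand <- which(demes == d)
          idx <- cand[sample.int(length(cand), 1)]
          lin[[idx]]$deme <- e
          done <- TRUE
          break
        }
        if (d != e) u <- u - rate_m[d + 1, e + 1]
      }
      if (done) break
    }
  }
  lens
}

`%||%` <- function(a, b) if (is.null(a)) b else a
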