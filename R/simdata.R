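# Structured-coalescent synthetic data: three diverged clusters with two
# split times, an epoch-dependent migration change, and optional hard sweeps.

#' Demographic configuration for the three-cluster structured coalescent
#'
#' Parameterizes a three-population divergence history: an ancestral
#' population of diploid size \code{NA_} splits at \code{T1} generations
#' before present; one descendant splits again at \code{T2} (\code{T1 >=
#' T2}); the internal branch between the splits has size \code{NB}.
#' Migration between the three extant demes uses rates \code{k01,k02,k12}
#' older than the change point \code{TC} and \code{m01,m02,m12} younger
#' than it; \code{m3} is the symmetric rate between the two lineages alive
#' during \code{[T2, T1)}.
#'
#' The default values describe an island radiation of a long-lived woody
#' species: three clusters that diverged deeply (about 165,000 generations
#' ago) with low ancient gene flow (population migration rate 2Nk about
#' 0.25), followed by a roughly 40-fold migration increase about 10,700
#' generations ago (2Nm about 10) coinciding with secondary contact.
#' Sizes were chosen so that, at a mutation rate of 7e-9 per site per
#' generation, within-cluster nucleotide diversity is near 0.005,
#' genome-wide pairwise FST near 0.10, and windowed Tajima's D negatively
#' skewed -- the diversity regime of such a radiation.
#'
#' @param N0,N1,N2 Present diploid effective sizes of demes 0, 1, 2.
#' @param NA_ Diploid size of the root population (older than \code{T1}).
#' @param NB Diploid size of the internal branch between \code{T2} and
#'   \code{T1}.
#' @param T1,T2 Split times in generations before present, \code{T1 >= T2}.
#' @param TC Migration-change time in generations (0 disables the change;
#'   must not exceed \code{T2}).
#' @param m01,m02,m12 Per-generation migration rates younger than \code{TC}.
#' @param k01,k02,k12 Per-generation migration rates older than \code{TC}.
#' @param m3 Migration rate between the two surviving lineages in
#'   \code{[T2, T1)}.
#' @param shape \code{"nested"}: deme 2 splits from deme 1 at \code{T2}
#'   (topology ((1,2),0)); \code{"radiating"}: deme 2 splits from deme 0.
#' @param assignment Character vector of length 3 mapping observed cluster
#'   labels onto Pop0, Pop1, Pop2; a permutation of \code{c("G","I","P")}.
#' @return An object of class \code{demography_config}.
#' @export
demography_config <- function(N0 = 250000, N1 = 180000, N2 = 180000,
                              NA_ = 120000, NB = 180000,
                              T1 = 166784, T2 = 163216, TC = 10713,
                              m01 = 2e-5, m02 = 2e-5, m12 = 2e-5,
                              k01 = 5e-7, k02 = 5e-7, k12 = 5e-7,
                              m3 = 5e-7,
                              shape = c("nested", "radiating"),
                              assignment = c("G", "P", "I")) {
  shape <- match.arg(shape)
  sizes <- c(N0 = N0, N1 = N1, N2 = N2, NA_ = NA_, NB = NB)
  if (any(!is.finite(sizes)) || any(sizes <= 0))
    stop("all population sizes must be positive")
  if (!is.finite(T1) || !is.finite(T2) || T1 < T2 || T2 < 0)
    stop("split times must satisfy T1 >= T2 >= 0")
  if (TC < 0 || TC > T2) stop("TC must lie in [0, T2]")
  rates <- c(m01, m02, m12, k01, k02, k12, m3)
  if (any(rates < 0)) stop("migration rates must be >= 0")
  if (length(assignment) != 3 ||
      !setequal(assignment, c("G", "I", "P")))
    stop("assignment must be a permutation of c('G','I','P')")
  structure(list(N0 = N0, N1 = N1, N2 = N2, NA_ = NA_, NB = NB,
                 T1 = T1, T2 = T2, TC = TC,
                 m01 = m01, m02 = m02, m12 = m12,
                 k01 = k01, k02 = k02, k12 = k12, m3 = m3,
                 shape = shape, assignment = assignment),
            class = "demography_config")
}

#' Sampling configuration for the coalescent simulator
#'
#' @param n_hap Haploid sample sizes per deme (each even: diploids are
#'   formed by pairing consecutive haplotypes).
#' @param n_loci Number of independent replicate loci; loci recombine
#'   freely with each other and are emitted as separate contigs.
#' @param locus_bp Sequence length of each locus in bp.
#' @param mu Per-site per-generation mutation rate.
#' @param n_segments Number of freely recombining segments within a locus.
#'   1 (the default) means a locus is a single non-recombining genealogy;
#'   larger values approximate intra-locus recombination by breaking the
#'   locus into independent genealogies of equal length.
#' @return An object of class \code{sample_config}.
#' @export
sample_config <- function(n_hap = c(28, 24, 28), n_loci = 40,
                          locus_bp = 20000, mu = 7e-9, n_segments = 1) {
  if (length(n_hap) != 3 || any(n_hap < 0) || any(n_hap %% 2 != 0) ||
      sum(n_hap) < 2)
    stop("n_hap must be three even haploid counts (diploid samples)")
  if (mu <= 0) stop("mu must be > 0")
  if (n_loci < 1 || locus_bp < 1 || n_segments < 1)
    stop("n_loci, locus_bp, n_segments must be positive")
  if (n_segments > locus_bp) stop("more segments than base pairs")
  structure(list(n_hap = as.integer(n_hap), n_loci = as.integer(n_loci),
                 locus_bp = as.integer(locus_bp), mu = mu,
                 n_segments = as.integer(n_segments)),
            class = "sample_config")
}

#' Hard-sweep specification for synthetic data
#'
#' A deterministic sweep: within the tract, every haplotype of the target
#' deme is replaced by the carrier haplotype, then residual singleton
#' mutations are added at new positions inside the tract (expected count
#' \code{singleton_rate} times the number of pre-sweep tract SNPs, per
#' target haplotype).
#'
#' @param deme Target cluster label ("G", "I" or "P").
#' @param locus Index of the locus carrying the sweep.
#' @param center Sweep center position (bp, 1-based within the locus).
#' @param halfwidth Swept tract half-width in bp.
#' @param carrier Index (within the target deme) of the carrier haplotype.
#' @param singleton_rate Residual-singleton rate in [0, 1].
#' @return An object of class \code{sweep_spec}.
#' @export
sweep_spec <- function(deme, locus = 1L, center, halfwidth,
                       carrier = 1L, singleton_rate = 0.005) {
  if (!deme %in% c("G", "I", "P")) stop("deme must be 'G', 'I' or 'P'")
  if (singleton_rate < 0 || singleton_rate > 1)
    stop("singleton_rate must be in [0, 1]")
  if (center < 1 || halfwidth < 0) stop("invalid tract")
  structure(list(deme = deme, locus = as.integer(locus), center = center,
                 halfwidth = halfwidth, carrier = as.integer(carrier),
                 singleton_rate = singleton_rate),
            class = "sweep_spec")
}

# flatten a demography + haploid counts into the list the C++ core reads
.coal_cfg <- function(demography, n_hap) {
  stopifnot(inherits(demography, "demography_config"))
  list(n = as.integer(n_hap),
       N0 = demography$N0, N1 = demography$N1, N2 = demography$N2,
       `NA` = demography$NA_, NB = demography$NB,
       T1 = demography$T1, T2 = demography$T2, TC = demography$TC,
       m01 = demography$m01, m02 = demography$m02, m12 = demography$m12,
       k01 = demography$k01, k02 = demography$k02, k12 = demography$k12,
       m3 = demography$m3,
       dest2 = if (demography$shape == "nested") 1L else 0L)
}

#' Simulate one genealogy under the structured coalescent
#'
#' Runs a continuous-time (Gillespie) event race over coalescence and
#' migration events, honouring the epoch boundaries \code{TC}, \code{T2}
#' and \code{T1}. Returns all branches (excluding the root) with their
#' lengths in generations, descendant leaf sets, and per-deme descendant
#' counts.
#'
#' @param demography A \code{\link{demography_config}}.
#' @param samples A \code{\link{sample_config}} (only \code{n_hap} is
#'   used).
#' @return A list of class \code{genealogy}: \code{length} (numeric,
#'   generations), \code{t_end} (time of the coalescence ending each
#'   branch; birth time is \code{t_end - length}), \code{leaves} (list
#'   of 1-based leaf indices, leaves ordered deme 0 then 1 then 2),
#'   \code{config} (matrix of per-deme descendant counts),
#'   \code{n_hap}.
#' @export
simulate_genealogy <- function(demography, samples) {
  cfg <- .coal_cfg(demography, samples$n_hap)
  tr <- .sim_tree_cpp(cfg)
  leaves <- lapply(tr$leaves, function(x) x + 1L)
  n <- samples$n_hap
  b0 <- cumsum(c(0L, n))
  config <- t(vapply(leaves, function(lv) {
    c(sum(lv <= b0[2]), sum(lv > b0[2] & lv <= b0[3]), sum(lv > b0[3]))
  }, integer(3)))
  colnames(config) <- c("d0", "d1", "d2")
  structure(list(length = tr$length, t_end = tr$t_end, leaves = leaves,
                 config = config, n_hap = n), class = "genealogy")
}

#' Expected folded 3D site-frequency spectrum
#'
#' Averages total branch length per descendant configuration over
#' \code{n_sims} simulated genealogies, folds to the global minor allele,
#' and normalizes over polymorphic entries. This is the expected-SFS
#' engine used by the demographic fitting routines.
#'
#' Folding pools a configuration with its complement; a configuration at
#' exactly half the total sample keeps the lexicographically smaller
#' member of the pair.
#'
#' @param demography A \code{\link{demography_config}}.
#' @param samples A \code{\link{sample_config}}.
#' @param n_sims Number of genealogies to simulate (>= 1).
#' @param seed Optional seed applied locally for reproducibility.
#' @return An \code{sfs3d} object (see \code{\link{sfs3d}}) with
#'   probabilities summing to 1 over polymorphic entries.
#' @export
expected_sfs <- function(demography, samples, n_sims = 2000, seed = NULL) {
  stopifnot(n_sims >= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  n <- samples$n_hap
  acc <- .sim_config_lengths_cpp(.coal_cfg(demography, n), as.integer(n_sims))
  if (sum(acc) <= 0) stop("all-zero spectrum: no branch length accumulated")
  arr <- array(acc, dim = n + 1L)
  folded <- fold_sfs3d(arr)
  tot <- sum(folded)
  if (tot <= 0) stop("all-zero spectrum after folding")
  out <- sfs3d(folded / tot, folded = TRUE, counts = FALSE)
  # per-site polymorphism probability under the infinite-sites model:
  # anchors the absolute parameter scale through the fixed mutation rate
  out$p_poly <- 1 - exp(-sum(acc) / n_sims * samples$mu)
  out
}

#' Fold a 3D spectrum to the global minor allele
#'
#' Entries whose total derived count exceeds half the pooled sample are
#' pooled into their complementary configuration; exact ties keep the
#' lexicographically smaller configuration of the pair. The monomorphic
#' corners are zeroed.
#'
#' @param arr A numeric array of dimension (n0+1) x (n1+1) x (n2+1).
#' @return A folded array of the same shape.
#' @export
fold_sfs3d <- function(arr) {
  dm <- dim(arr)
  n <- dm - 1L
  idx <- expand.grid(i = 0:n[1], j = 0:n[2], k = 0:n[3])
  tot <- idx$i + idx$j + idx$k
  ntot <- sum(n)
  out <- array(0, dim = dm)
  flat <- as.vector(arr)
  comp <- cbind(n[1] - idx$i, n[2] - idx$j, n[3] - idx$k)
  lex_smaller <- (idx$i < comp[, 1]) |
    (idx$i == comp[, 1] & idx$j < comp[, 2]) |
    (idx$i == comp[, 1] & idx$j == comp[, 2] & idx$k <= comp[, 3])
  target <- ifelse(tot < ntot / 2 | (tot == ntot / 2 & lex_smaller),
                   seq_along(flat),
                   # flat index of the complement
                   1 + comp[, 1] + dm[1] * (comp[, 2] + dm[2] * comp[, 3]))
  acc <- rowsum(flat, target)
  out[as.integer(rownames(acc))] <- acc
  out[1, 1, 1] <- 0
  out[dm[1], dm[2], dm[3]] <- 0
  out
}

#' Construct a 3D site-frequency-spectrum object
#'
#' @param arr Array of counts or probabilities over minor-allele counts,
#'   dimension (n0+1) x (n1+1) x (n2+1).
#' @param folded Logical; folded to global minor allele.
#' @param counts Logical; TRUE for site counts, FALSE for probabilities.
#' @param monomorphic Number of monomorphic sites tallied separately.
#' @return An object of class \code{sfs3d}.
#' @export
sfs3d <- function(arr, folded = TRUE, counts = TRUE, monomorphic = 0) {
  stopifnot(is.array(arr), length(dim(arr)) == 3, all(arr >= 0))
  structure(list(arr = arr, n_hap = dim(arr) - 1L, folded = folded,
                 counts = counts, monomorphic = monomorphic),
            class = "sfs3d")
}

#' @export
print.sfs3d <- function(x, ...) {
  cat(sprintf("3D %s SFS (%s), samples %s, total %g, monomorphic %g\n",
              if (x$folded) "folded" else "unfolded",
              if (x$counts) "counts" else "probabilities",
              paste(x$n_hap, collapse = "/"), sum(x$arr), x$monomorphic))
  invisible(x)
}

# deme label of each haplotype column, via the assignment permutation
.hap_demes <- function(demography, n_hap) {
  rep(demography$assignment, times = n_hap)
}

# simulate one non-recombining segment -> 0/1 haplotype matrix + positions
.sim_segment <- function(cfg, n_tot, mu, seg_start, seg_bp) {
  tr <- .sim_tree_cpp(cfg)
  lens <- tr$length
  n_mut <- rpois(1, sum(lens) * mu * seg_bp)
  if (n_mut == 0)
    return(list(hap = matrix(0L, nrow = 0, ncol = n_tot),
                pos = integer(0)))
  n_mut <- min(n_mut, seg_bp)
  pos <- sort(sample.int(seg_bp, n_mut)) + seg_start
  branch <- sample.int(length(lens), n_mut, replace = TRUE,
                       prob = lens / sum(lens))
  hap <- matrix(0L, nrow = n_mut, ncol = n_tot)
  for (s in seq_len(n_mut)) hap[s, tr$leaves[[branch[s]]] + 1L] <- 1L
  list(hap = hap, pos = pos)
}

#' Generate a synthetic three-cluster dataset
#'
#' Simulates independent locus genealogies, drops mutations at rate
#' \code{mu}, optionally injects hard sweeps, pairs consecutive haplotypes
#' into diploids, and writes a phased VCF (one contig per locus), a
#' tab-separated metadata table (cluster label, synthetic GPS coordinates,
#' six cluster-correlated environmental variables plus two pure-noise
#' variables), and a key-value truth file recording the demographic
#' parameters and sweep tracts.
#'
#' @param demography A \code{\link{demography_config}}.
#' @param samples A \code{\link{sample_config}}.
#' @param sweeps List of \code{\link{sweep_spec}} objects.
#' @param dir Output directory (created if needed); set \code{NULL} to
#'   skip writing files.
#' @param seed Seed; identical configuration and seed give byte-identical
#'   output.
#' @return Invisibly, a list with the \code{haplotype_matrix}, the derived
#'   \code{genotype_matrix}, the metadata data frame, and file paths.
#' @export
generate_dataset <- function(demography, samples, sweeps = list(),
                             dir = NULL, seed = 1) {
  set.seed(seed)
  n_hap <- samples$n_hap
  n_tot <- sum(n_hap)
  demes <- .hap_demes(demography, n_hap)
  cfg <- .coal_cfg(demography, n_hap)
  seg_bp <- samples$locus_bp %/% samples$n_segments
  seg_starts <- (seq_len(samples$n_segments) - 1L) * seg_bp
  hap_list <- vector("list", samples$n_loci)
  pos_list <- vector("list", samples$n_loci)
  for (l in seq_len(samples$n_loci)) {
    segs <- lapply(seg_starts, function(s0)
      .sim_segment(cfg, n_tot, samples$mu, s0, seg_bp))
    hap_list[[l]] <- do.call(rbind, lapply(segs, `[[`, "hap"))
    pos_list[[l]] <- unlist(lapply(segs, `[[`, "pos"))
  }
  # sweep injection
  for (sw in sweeps) {
    stopifnot(inherits(sw, "sweep_spec"))
    if (sw$locus > samples$n_loci) stop("sweep locus out of range")
    lo <- sw$center - sw$halfwidth
    hi <- sw$center + sw$halfwidth
    if (lo < 1 || hi > samples$locus_bp)
      stop("sweep tract outside sequence bounds")
    tgt <- which(demes == sw$deme)
    if (sw$carrier > length(tgt)) stop("carrier index out of range")
    pos <- pos_list[[sw$locus]]
    in_tract <- which(pos >= lo & pos <= hi)
    hap <- hap_list[[sw$locus]]
    carrier_col <- tgt[sw$carrier]
    if (length(in_tract))
      hap[in_tract, tgt] <- hap[in_tract, carrier_col]
    # residual singletons at fresh positions inside the tract
    n_base <- length(in_tract)
    for (h in tgt) {
      k <- rpois(1, sw$singleton_rate * n_base)
      if (k == 0) next
      newpos <- sample(seq(lo, hi), min(k, hi - lo + 1))
      add <- matrix(0L, nrow = length(newpos), ncol = n_tot)
      add[, h] <- 1L
      hap <- rbind(hap, add)
      pos <- c(pos, newpos)
    }
    ord <- order(pos)
    # collapse duplicate positions (keep first)
    keep <- ord[!duplicated(pos[ord])]
    hap_list[[sw$locus]] <- hap[keep, , drop = FALSE]
    pos_list[[sw$locus]] <- pos[keep]
  }
  # assemble matrices
  chrom <- rep(sprintf("locus%03d", seq_len(samples$n_loci)),
               vapply(pos_list, length, integer(1)))
  pos <- unlist(pos_list)
  hap <- do.call(rbind, hap_list)
  # drop monomorphic rows (possible after sweep replacement)
  poly <- rowSums(hap) > 0 & rowSums(hap) < n_tot
  hap <- hap[poly, , drop = FALSE]
  chrom <- chrom[poly]
  pos <- pos[poly]
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nrow(hap), replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  # diploid sample ids: pair consecutive haplotypes per deme
  cl_per_ind <- demes[seq(1, n_tot, by = 2)]
  # ids follow haplotype (deme) order
  sample_id <- sprintf("%s%02d", cl_per_ind,
                       unlist(lapply(rle(cl_per_ind)$lengths, seq_len)))
  hm <- haplotype_matrix(hap, chrom, pos, ref, alt, sample_id,
                         phased = TRUE)
  gm <- haplotypes_to_genotypes(hm)
  meta <- .synth_metadata(sample_id, cl_per_ind)
  out <- list(haplotypes = hm, genotypes = gm, metadata = meta,
              truth = list(demography = demography, samples = samples,
                           sweeps = sweeps, seed = seed))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    vcf <- file.path(dir, "synthetic.vcf")
    write_vcf(hm, vcf,
              contig_lengths = setNames(
                rep(samples$locus_bp, samples$n_loci),
                sprintf("locus%03d", seq_len(samples$n_loci))))
    metaf <- file.path(dir, "metadata.tsv")
    write.table(meta, metaf, sep = "\t", quote = FALSE, row.names = FALSE)
    truthf <- file.path(dir, "truth.txt")
    .write_truth(out$truth, truthf)
    out$paths <- c(vcf = vcf, metadata = metaf, truth = truthf)
  }
  invisible(out)
}

# cluster-specific environmental means (unit-variance noise) plus two
# pure-noise variables; values loosely follow the island's gradients
.synth_metadata <- function(sample_id, cluster) {
  centers <- list(
    G = c(lat = 19.60, lon = -155.10, temp = 18, soil_evapo = 2.0,
          rainfall = 5000, lava_age = 3000, cloud_freq = 0.70, vpd = 250),
    I = c(lat = 19.75, lon = -155.90, temp = 22, soil_evapo = 3.5,
          rainfall = 800, lava_age = 200, cloud_freq = 0.30, vpd = 900),
    P = c(lat = 19.50, lon = -155.45, temp = 10, soil_evapo = 1.0,
          rainfall = 1500, lava_age = 1500, cloud_freq = 0.20, vpd = 500))
  scale_sd <- c(lat = 0.08, lon = 0.08, temp = 1, soil_evapo = 1,
                rainfall = 300, lava_age = 300, cloud_freq = 0.05,
                vpd = 100)
  n <- length(sample_id)
  m <- t(vapply(cluster, function(cl) centers[[cl]], numeric(8)))
  noise <- matrix(rnorm(n * 8), n, 8) * rep(scale_sd, each = n)
  env <- m + noise
  data.frame(sample_id = sample_id, cluster = cluster,
             lat = env[, 1], lon = env[, 2], temp = env[, 3],
             soil_evapo = env[, 4], rainfall = env[, 5],
             lava_age = env[, 6], cloud_freq = env[, 7], vpd = env[, 8],
             noise1 = rnorm(n), noise2 = rnorm(n),
             stringsAsFactors = FALSE)
}

.write_truth <- function(truth, path) {
  d <- truth$demography
  kv <- c(
    vapply(setdiff(names(d), c("shape", "assignment")),
           function(k) sprintf("%s\t%.10g", sub("_$", "", k), d[[k]]), ""),
    sprintf("shape\t%s", d$shape),
    sprintf("assignment\t%s", paste(d$assignment, collapse = ",")),
    sprintf("mu\t%.10g", truth$samples$mu),
    sprintf("seed\t%d", truth$seed))
  for (i in seq_along(truth$sweeps)) {
    sw <- truth$sweeps[[i]]
    kv <- c(kv, sprintf("sweep%d\t%s:locus%03d:%d-%d", i, sw$deme,
                        sw$locus, sw$center - sw$halfwidth,
                        sw$center + sw$halfwidth))
  }
  writeLines(kv, path)
}
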