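# Orchestration: configuration defaults, an end-to-end run over a VCF +
# metadata (synthetic or user-supplied), plain-text stage outputs and a
# JSON-lines log with checksums.

#' Run configuration with field-standard defaults
#'
#' Collects every pipeline threshold with its default: 20-kb windows,
#' per-SNP missingness below 20 percent, minor allele frequency above
#' 0.05, minor allele count of at least 4, a 20-SNP floor for FST
#' windows, xp-EHH outliers at p below 1e-6, composite-statistic
#' outliers at mean + 20 sd, kNN outliers in the top 0.5 percent with
#' delta-FST above 0.5, 5 percent quantile tails, 999 permutations, a
#' generation time of 30 years and a mutation rate of 7e-9.
#'
#' @param vcf,metadata,q_matrix,fasta,gff Input paths (only
#'   \code{vcf} and \code{metadata} are required).
#' @param out_dir Output directory.
#' @param window_bp Window width (default 20000).
#' @param max_missing,min_maf,min_mac SNP filters.
#' @param min_pair_snps FST window eligibility floor.
#' @param xpehh_p xp-EHH outlier p threshold.
#' @param mu_sd Composite-statistic outlier threshold in sd units.
#' @param knn_top,knn_delta kNN outlier thresholds.
#' @param tail_frac Quantile tail fraction.
#' @param n_perm Permutations for RDA tests.
#' @param ancestry_min Core-sample ancestry threshold.
#' @param generation_time,mu Unit-conversion constants.
#' @param seed Seed.
#' @return A list of class \code{run_config}.
#' @export
run_config <- function(vcf, metadata, q_matrix = NULL, fasta = NULL,
                       gff = NULL, out_dir = tempfile("ohia_run"),
                       window_bp = 20000, max_missing = 0.2,
                       min_maf = 0.05, min_mac = 4, min_pair_snps = 20,
                       xpehh_p = 1e-6, mu_sd = 20, knn_top = 0.005,
                       knn_delta = 0.5, tail_frac = 0.05, n_perm = 999,
                       ancestry_min = 0.9, generation_time = 30,
                       mu = 7e-9, seed = 1) {
  structure(as.list(environment()), class = "run_config")
}

.log_line <- function(con, stage, ...) {
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                stage = stage), list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
}

.write_stage <- function(df, dir, name, log_con) {
  path <- file.path(dir, name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  .log_line(log_con, "output", file = name,
            md5 = unname(tools::md5sum(path)))
  path
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input reading and SNP filtering; population
#' structure (core-sample selection from the Q matrix when given, else
#' the metadata cluster labels with a warning; PCA; dbMEM + RDA
#' variance partitioning); windowed diversity/differentiation
#' statistics; the four selection scans with the integrated report; and
#' the observed 3D SFS. Every stage writes plain-text outputs with
#' checksums to the log; any stage failure halts with the stage name.
#'
#' @param config A \code{\link{run_config}}.
#' @return Invisibly, a list with the main stage results and output
#'   paths.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(config$out_dir, "run_log.jsonl"), "w")
  on.exit(close(log_con))
  .log_line(log_con, "start",
            version = as.character(utils::packageVersion("ohia")),
            seed = config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ",
           conditionMessage(e), call. = FALSE))
  }
  set.seed(config$seed)
  ## genio
  res <- stage("genio", {
    vc <- read_vcf(config$vcf)
    meta <- read.table(config$metadata, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
    list(vc = vc, meta = meta)
  })
  vc <- res$vc
  meta <- res$meta
  gm_filt <- stage("genio", filter_snps(vc$genotypes,
                                        max_missing = config$max_missing,
                                        min_maf = config$min_maf,
                                        min_mac = config$min_mac))
  ## structure
  st <- stage("structure", {
    if (!is.null(config$q_matrix)) {
      q <- as.matrix(read.table(config$q_matrix))
      rownames(q) <- meta$sample_id
      core <- core_samples(q, config$ancestry_min)
      # map ancestry components to majority metadata label
      comp_lab <- vapply(unique(core$cluster), function(k) {
        names(which.max(table(
          meta$cluster[match(core$sample[core$cluster == k],
                             meta$sample_id)])))
      }, "")
      core$cluster <- comp_lab[core$cluster]
    } else {
      warning("no Q matrix supplied; using metadata cluster labels")
      core <- data.frame(sample = meta$sample_id,
                         cluster = meta$cluster,
                         stringsAsFactors = FALSE)
    }
    pruned <- ld_prune(gm_filt)
    pca <- pca_genotypes(pruned)
    envv <- as.matrix(meta[, c("temp", "soil_evapo", "rainfall",
                               "lava_age", "cloud_freq", "vpd")])
    mem <- dbmem(meta[, c("lon", "lat")])
    y <- pca$scores
    vp <- varpart_genetic(y, scale(envv), mem, n_perm = config$n_perm,
                          seed = config$seed)
    list(core = core, pca = pca, varpart = vp)
  })
  core <- st$core
  cluster <- setNames(core$cluster, core$sample)
  gm_core <- subset_gm(vc$genotypes, samples = core$sample)
  gm_core <- filter_snps(gm_core, max_missing = config$max_missing)
  ## divstats
  dv <- stage("divstats", {
    chrom_sizes <- vapply(split(gm_core$sites$pos, gm_core$sites$chrom),
                          max, 0)
    windows <- window_tiling(chrom_sizes, config$window_bp)
    wt <- window_table(gm_core, cluster, windows,
                       min_pair_snps = config$min_pair_snps,
                       mac_min = config$min_mac)
    list(windows = windows, wt = wt, chrom_sizes = chrom_sizes)
  })
  wt <- dv$wt
  ## selscan
  sel <- stage("selscan", {
    cls <- sort(unique(cluster))
    hm <- vc$haplotypes
    scan_selection(gm_core, hm, cluster, wt, dv$chrom_sizes, config)
  })
  ## demog (observed spectrum; fitting is run separately at scale)
  dg <- stage("demog", {
    complete <- rowSums(is.na(gm_core$dosage)) == 0
    observed_sfs(subset_gm(gm_core, sites = which(complete)), cluster)
  })
  paths <- c(
    windows = .write_stage(wt, config$out_dir, "window_stats.tsv",
                           log_con),
    xpehh = .write_stage(sel$xp_all, config$out_dir, "xpehh.tsv",
                         log_con),
    mu = .write_stage(sel$mu_all, config$out_dir, "mu_windows.tsv",
                      log_con),
    report = .write_stage(sel$report, config$out_dir,
                          "region_report.tsv", log_con))
  sfs_path <- file.path(config$out_dir, "observed_sfs.txt")
  write_sfs(dg, sfs_path)
  .log_line(log_con, "output", file = "observed_sfs.txt",
            md5 = unname(tools::md5sum(sfs_path)))
  .log_line(log_con, "done")
  invisible(list(structure = st, windows = wt, selscan = sel, sfs = dg,
                 paths = paths, config = config))
}

#' Four-method selection scan with integration
#'
#' Runs xp-EHH for every cluster pair with EHH-region extraction and
#' both-comparison intersection, the composite sweep statistic per
#' cluster with callability filtering, kNN FST-vector outliers,
#' quantile tail outliers for pi/Tajima's D/Dxy, the
#' antagonistic-pleiotropy screen, and the integrated per-region
#' report.
#'
#' @param gm Core-sample \code{\link{genotype_matrix}}.
#' @param hm Matching \code{\link{haplotype_matrix}} (phased), or NULL
#'   to skip the haplotype-based scan.
#' @param cluster Named cluster map.
#' @param wt A \code{\link{window_table}} over the same data.
#' @param chrom_sizes Named chromosome lengths.
#' @param config A \code{\link{run_config}} (thresholds).
#' @return A list: per-pair xp-EHH tables, per-cluster composite
#'   statistic windows, outlier flags, EHH regions and the integrated
#'   report.
#' @export
scan_selection <- function(gm, hm, cluster, wt, chrom_sizes, config) {
  cls <- sort(unique(cluster))
  pairs <- utils::combn(cls, 2, simplify = FALSE)
  mask <- callability_mask(gm)
  ## tail outliers on the window table
  flags <- list()
  for (cl in cls) {
    flags[[paste0("pi_", cl)]] <-
      tail_outlier_windows(wt, paste0("pi_", cl), "lower",
                           config$tail_frac)
    flags[[paste0("tajd_", cl)]] <-
      tail_outlier_windows(wt, paste0("tajd_", cl), "lower",
                           config$tail_frac)
  }
  for (pr in pairs) {
    pn <- paste(pr, collapse = "_")
    flags[[paste0("dxy_", pn)]] <-
      tail_outlier_windows(wt, paste0("dxy_", pn), "upper",
                           config$tail_frac)
  }
  ## kNN FST outliers over eligible windows
  fst_cols <- paste0("fst_", vapply(pairs, paste, "", collapse = "_"))
  elig_cols <- paste0("eligible_",
                      vapply(pairs, paste, "", collapse = "_"))
  eligible <- Reduce(`&`, lapply(elig_cols, function(cc) wt[[cc]]))
  fst_mat <- as.matrix(wt[eligible, fst_cols, drop = FALSE])
  knn_flag <- rep(FALSE, nrow(wt))
  knn <- NULL
  if (sum(eligible) >= 5) {
    knn <- knn_fst_outliers(fst_mat, top_frac = config$knn_top,
                            delta_min = config$knn_delta)
    knn_flag[eligible] <- knn$outlier
  }
  for (pr in pairs) {
    pn <- paste(pr, collapse = "_")
    flags[[paste0("fst_", pn)]] <- knn_flag
  }
  ## antagonistic screen on kNN outlier windows, per pair
  antag <- list()
  for (pr in pairs) {
    pn <- paste(pr, collapse = "_")
    g1 <- subset_gm(gm, samples = names(cluster)[cluster == pr[1]])
    g2 <- subset_gm(gm, samples = names(cluster)[cluster == pr[2]])
    antag[[pn]] <- antagonistic_screen(g1, g2, wt, knn_flag)
  }
  ## composite statistic per cluster
  mu_all <- list()
  mu_regions <- data.frame(cluster = character(0), chrom = character(0),
                           start = integer(0), end = integer(0))
  for (cl in cls) {
    gmc <- subset_gm(gm, samples = names(cluster)[cluster == cl])
    mu <- mu_scan(gmc, chrom_sizes)
    mu <- filter_mu_windows(mu, mask)
    mu <- mu_outliers(mu, config$mu_sd)
    mu$cluster <- cl
    mu_all[[cl]] <- mu
    if (any(mu$outlier)) {
      mr <- .merge_intervals(data.frame(chrom = mu$chrom[mu$outlier],
                                        start = mu$first[mu$outlier],
                                        end = mu$last[mu$outlier]))
      mr$cluster <- cl
      mu_regions <- rbind(mu_regions,
                          mr[, c("cluster", "chrom", "start", "end")])
    }
  }
  ## xp-EHH per pair and EHH regions per focal cluster
  xp_all <- list()
  regions <- data.frame(cluster = character(0), chrom = character(0),
                        start = integer(0), end = integer(0))
  if (!is.null(hm)) {
    hms <- lapply(cls, function(cl) {
      ids <- names(cluster)[cluster == cl]
      cols <- as.vector(rbind(paste0(ids, "_a"), paste0(ids, "_b")))
      haplotype_matrix(hm$hap[, cols, drop = FALSE], hm$sites$chrom,
                       hm$sites$pos, hm$sites$ref, hm$sites$alt, ids,
                       phased = hm$phased)
    })
    names(hms) <- cls
    per_focal <- lapply(cls, function(cl) list())
    names(per_focal) <- cls
    for (pr in pairs) {
      pn <- paste(pr, collapse = "_")
      xp <- xpehh(hms[[pr[1]]], hms[[pr[2]]], trunc = 0.05,
                  p_out = config$xpehh_p)
      xp$pair <- pn
      xp_all[[pn]] <- xp
      # positive z: focal pr[1]; negative: focal pr[2]
      o1 <- xp[xp$outlier & xp$z > 0, c("chrom", "pos")]
      o2 <- xp[xp$outlier & xp$z < 0, c("chrom", "pos")]
      per_focal[[pr[1]]][[pr[2]]] <- ehh_regions(hms[[pr[1]]], o1)
      per_focal[[pr[2]]][[pr[1]]] <- ehh_regions(hms[[pr[2]]], o2)
    }
    for (cl in cls) {
      others <- setdiff(cls, cl)
      both <- intersect_both(per_focal[[cl]][[others[1]]],
                             per_focal[[cl]][[others[2]]])
      if (nrow(both)) {
        both$cluster <- cl
        regions <- rbind(regions,
                         both[, c("cluster", "chrom", "start", "end")])
      }
    }
  }
  report <- integrate_report(regions, wt, flags, mu_regions)
  list(xp_all = if (length(xp_all)) do.call(rbind, xp_all)
       else data.frame(),
       mu_all = do.call(rbind, mu_all), flags = flags, knn = knn,
       antagonistic = antag, regions = regions,
       mu_regions = mu_regions, report = report)
}
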