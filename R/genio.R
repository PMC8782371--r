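# Genotype containers, VCF I/O, SNP filters, degeneracy classification,
# window tiling and callability masks. Internal coordinates are 0-based
# half-open for windows and masks; VCF and site positions are 1-based.

#' Construct a genotype matrix
#'
#' Biallelic diploid dosages (0/1/2, NA for missing) over ordered sites.
#'
#' @param dosage Integer matrix, sites in rows, samples in columns.
#' @param chrom,pos,ref,alt Per-site chromosome, 1-based position and
#'   alleles.
#' @param samples Ordered sample ids (column names).
#' @return An object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(dosage, chrom, pos, ref, alt, samples) {
  dosage <- as.matrix(dosage)
  stopifnot(nrow(dosage) == length(pos), length(chrom) == length(pos),
            ncol(dosage) == length(samples))
  if (any(!dosage %in% c(0L, 1L, 2L, NA)))
    stop("dosages must be 0, 1, 2 or NA")
  ord <- order(chrom, pos)
  dosage <- dosage[ord, , drop = FALSE]
  sites <- data.frame(chrom = chrom[ord], pos = pos[ord],
                      ref = ref[ord], alt = alt[ord],
                      stringsAsFactors = FALSE)
  if (anyDuplicated(sites[c("chrom", "pos")]))
    stop("duplicate site positions within a chromosome")
  colnames(dosage) <- samples
  structure(list(dosage = dosage, sites = sites, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d sites x %d samples (%d chrom)\n",
              nrow(x$sites), length(x$samples),
              length(unique(x$sites$chrom))))
  invisible(x)
}

#' Construct a phased haplotype matrix
#'
#' @param hap 0/1 integer matrix, sites in rows, haplotypes in columns
#'   (two consecutive columns per diploid sample).
#' @param chrom,pos,ref,alt Per-site fields as in
#'   \code{\link{genotype_matrix}}.
#' @param samples Diploid sample ids; haplotype columns are named
#'   \code{<id>_a} and \code{<id>_b}.
#' @param phased Phase provenance flag (TRUE for truth/synthetic or
#'   phased input).
#' @return An object of class \code{haplotype_matrix}.
#' @export
haplotype_matrix <- function(hap, chrom, pos, ref, alt, samples,
                             phased = TRUE) {
  hap <- as.matrix(hap)
  stopifnot(ncol(hap) == 2 * length(samples))
  if (any(!hap %in% c(0L, 1L)))
    stop("haplotypes must be 0/1 with no missing values")
  ord <- order(chrom, pos)
  hap <- hap[ord, , drop = FALSE]
  sites <- data.frame(chrom = chrom[ord], pos = pos[ord],
                      ref = ref[ord], alt = alt[ord],
                      stringsAsFactors = FALSE)
  colnames(hap) <- paste0(rep(samples, each = 2), c("_a", "_b"))
  structure(list(hap = hap, sites = sites, samples = samples,
                 phased = phased), class = "haplotype_matrix")
}

#' Collapse haplotype pairs to a genotype matrix
#'
#' @param hm A \code{\link{haplotype_matrix}}.
#' @return A \code{\link{genotype_matrix}} of dosages.
#' @export
haplotypes_to_genotypes <- function(hm) {
  stopifnot(inherits(hm, "haplotype_matrix"))
  a <- hm$hap[, seq(1, ncol(hm$hap), by = 2), drop = FALSE]
  b <- hm$hap[, seq(2, ncol(hm$hap), by = 2), drop = FALSE]
  genotype_matrix(a + b, hm$sites$chrom, hm$sites$pos, hm$sites$ref,
                  hm$sites$alt, hm$samples)
}

#' Subset a genotype matrix by samples and/or sites
#'
#' @param gm A \code{\link{genotype_matrix}}.
#' @param samples Sample ids to keep (in the given order).
#' @param sites Logical or integer index over site rows.
#' @return A \code{\link{genotype_matrix}}.
#' @export
subset_gm <- function(gm, samples = NULL, sites = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  d <- gm$dosage
  s <- gm$sites
  if (!is.null(sites)) {
    d <- d[sites, , drop = FALSE]
    s <- s[sites, , drop = FALSE]
  }
  ids <- gm$samples
  if (!is.null(samples)) {
    miss <- setdiff(samples, ids)
    if (length(miss))
      stop("unknown samples: ", paste(miss, collapse = ", "))
    d <- d[, samples, drop = FALSE]
    ids <- samples
  }
  genotype_matrix(d, s$chrom, s$pos, s$ref, s$alt, ids)
}

#' Write a VCF 4.2 file
#'
#' Writes phased genotypes (\code{0|1}) for a haplotype matrix or
#' unphased dosage genotypes for a genotype matrix (missing as
#' \code{./.}).
#'
#' @param x A \code{\link{haplotype_matrix}} or
#'   \code{\link{genotype_matrix}}.
#' @param path Output path.
#' @param contig_lengths Optional named vector of contig lengths for the
#'   header.
#' @return The path, invisibly.
#' @export
write_vcf <- function(x, path, contig_lengths = NULL) {
  hdr <- c("##fileformat=VCFv4.2", "##source=ohia")
  if (!is.null(contig_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths),
                          as.integer(contig_lengths)))
  hdr <- c(hdr,
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  if (inherits(x, "haplotype_matrix")) {
    a <- x$hap[, seq(1, ncol(x$hap), by = 2), drop = FALSE]
    b <- x$hap[, seq(2, ncol(x$hap), by = 2), drop = FALSE]
    gt <- matrix(paste0(a, "|", b), nrow = nrow(a))
    sites <- x$sites
  } else if (inherits(x, "genotype_matrix")) {
    code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    gt <- matrix("./.", nrow = nrow(x$dosage), ncol = ncol(x$dosage))
    ok <- !is.na(x$dosage)
    gt[ok] <- code[as.character(x$dosage[ok])]
    sites <- x$sites
  } else stop("x must be a haplotype_matrix or genotype_matrix")
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", x$samples),
                      collapse = "\t"))
  body <- cbind(sites$chrom, sites$pos, ".", sites$ref, sites$alt, ".",
                "PASS", ".", "GT", gt)
  con <- file(path, "wb")  # binary mode: byte-identical across platforms
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  writeLines(apply(body, 1, paste, collapse = "\t"), con, sep = "\n")
  invisible(path)
}

#' Read a VCF into genotype (and haplotype) matrices
#'
#' Multi-allelic records are dropped (sites with more than two alleles are
#' excluded), genotype order follows \code{sample_subset}, and missing
#' genotypes become missing dosages. If every genotype is phased, a
#' haplotype matrix is returned alongside.
#'
#' @param path VCF path.
#' @param sample_subset Optional character vector of samples to keep;
#'   unknown samples are an error, an empty subset is an error.
#' @return A list with \code{genotypes} (a
#'   \code{\link{genotype_matrix}}) and \code{haplotypes} (a
#'   \code{\link{haplotype_matrix}} or NULL).
#' @export
read_vcf <- function(path, sample_subset = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!is.null(sample_subset) && length(sample_subset) == 0)
    stop("sample_subset must not be empty")
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e)
                  stop("malformed VCF '", path, "': ",
                       conditionMessage(e), call. = FALSE))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt_raw <- v@gt[, -1, drop = FALSE]
  samples <- colnames(gt_raw)
  if (!is.null(sample_subset)) {
    miss <- setdiff(sample_subset, samples)
    if (length(miss))
      stop("unknown samples in VCF: ", paste(miss, collapse = ", "))
    gt_raw <- gt_raw[, sample_subset, drop = FALSE]
    samples <- sample_subset
  }
  # biallelic SNP records only
  keep <- !grepl(",", fix[, "ALT"]) & fix[, "ALT"] != "."
  fix <- fix[keep, , drop = FALSE]
  gt_raw <- gt_raw[keep, , drop = FALSE]
  gt <- sub(":.*", "", gt_raw)
  phased <- all(grepl("\\|", gt))
  al1 <- substr(gt, 1, 1)
  al2 <- substr(gt, 3, 3)
  to_int <- function(a) {
    x <- suppressWarnings(as.integer(a))
    x  # "." -> NA
  }
  a1 <- matrix(to_int(al1), nrow = nrow(gt))
  a2 <- matrix(to_int(al2), nrow = nrow(gt))
  dosage <- a1 + a2
  gm <- genotype_matrix(dosage, fix[, "CHROM"],
                        as.integer(fix[, "POS"]), fix[, "REF"],
                        fix[, "ALT"], samples)
  hm <- NULL
  if (phased && !anyNA(dosage)) {
    hap <- matrix(0L, nrow = nrow(gt), ncol = 2 * length(samples))
    hap[, seq(1, ncol(hap), by = 2)] <- a1
    hap[, seq(2, ncol(hap), by = 2)] <- a2
    hm <- haplotype_matrix(hap, fix[, "CHROM"], as.integer(fix[, "POS"]),
                           fix[, "REF"], fix[, "ALT"], samples,
                           phased = TRUE)
  }
  list(genotypes = gm, haplotypes = hm)
}

# per-site allele summaries over non-missing genotypes
.site_counts <- function(dosage) {
  nm <- rowSums(!is.na(dosage))
  alt <- rowSums(dosage, na.rm = TRUE)
  n_alleles <- 2L * nm
  minor <- pmin(alt, n_alleles - alt)
  list(n_ind = nm, n_alleles = n_alleles, alt = alt, minor = minor)
}

#' Filter SNPs on missingness, minor allele frequency and count
#'
#' Keeps SNPs whose missing-genotype fraction is strictly below
#' \code{max_missing}, whose minor allele frequency (over non-missing
#' alleles) is strictly above \code{min_maf}, and whose minor allele
#' count is at least \code{min_mac}. Any threshold may be \code{NULL} to
#' disable it. Idempotent.
#'
#' @param gm A \code{\link{genotype_matrix}}.
#' @param max_missing Maximum missing fraction (exclusive), e.g. 0.2.
#' @param min_maf Minimum minor allele frequency (exclusive), e.g. 0.05.
#' @param min_mac Minimum minor allele count (inclusive), e.g. 4.
#' @return The filtered \code{\link{genotype_matrix}}.
#' @export
filter_snps <- function(gm, max_missing = NULL, min_maf = NULL,
                        min_mac = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  sc <- .site_counts(gm$dosage)
  n_samp <- length(gm$samples)
  keep <- rep(TRUE, nrow(gm$sites))
  if (!is.null(max_missing)) {
    stopifnot(max_missing >= 0, max_missing <= 1)
    keep <- keep & ((n_samp - sc$n_ind) / n_samp < max_missing)
  }
  if (!is.null(min_maf)) {
    stopifnot(min_maf >= 0, min_maf < 0.5)
    maf <- ifelse(sc$n_alleles > 0, sc$minor / sc$n_alleles, 0)
    keep <- keep & (maf > min_maf)
  }
  if (!is.null(min_mac)) keep <- keep & (sc$minor >= min_mac)
  subset_gm(gm, sites = keep)
}

#' Greedy positional LD pruning
#'
#' Left-to-right scan within each chromosome: each kept SNP drops all
#' later SNPs within \code{window_bp} whose squared dosage correlation
#' with it exceeds \code{r2_max} (first-kept wins).
#'
#' @param gm A \code{\link{genotype_matrix}}.
#' @param window_bp Window in bp (default 50).
#' @param r2_max Maximum allowed r-squared (exclusive; default 0.5).
#' @return The pruned \code{\link{genotype_matrix}}.
#' @export
ld_prune <- function(gm, window_bp = 50, r2_max = 0.5) {
  stopifnot(inherits(gm, "genotype_matrix"))
  keep <- rep(TRUE, nrow(gm$sites))
  for (ch in unique(gm$sites$chrom)) {
    idx <- which(gm$sites$chrom == ch)
    pos <- gm$sites$pos[idx]
    for (i in seq_along(idx)) {
      if (!keep[idx[i]]) next
      j <- i + 1
      while (j <= length(idx) && pos[j] - pos[i] <= window_bp) {
        if (keep[idx[j]]) {
          r <- suppressWarnings(
            cor(gm$dosage[idx[i], ], gm$dosage[idx[j], ],
                use = "pairwise.complete.obs"))
          if (!is.na(r) && r^2 > r2_max) keep[idx[j]] <- FALSE
        }
        j <- j + 1
      }
    }
  }
  subset_gm(gm, sites = keep)
}

# codon prefixes whose third position is fourfold degenerate
.ffd_prefixes <- function() {
  gc <- Biostrings::GENETIC_CODE
  pre <- unique(substr(names(gc), 1, 2))
  pre[vapply(pre, function(p) {
    aa <- gc[paste0(p, c("A", "C", "G", "T"))]
    length(unique(aa)) == 1
  }, logical(1))]
}

#' Four-fold degenerate site classification
#'
#' Returns genomic positions that are third codon positions of codons
#' whose amino acid is invariant to the base at that position (standard
#' genetic code), strand-aware. Positions claimed four-fold degenerate by
#' one CDS but covered by a conflicting CDS (where they are not a
#' four-fold third position) are excluded. A CDS whose phase-adjusted
#' length is not a multiple of 3 is skipped with a warning.
#'
#' @param fasta Path to the genome FASTA.
#' @param gff Path to a GFF3 file with CDS features (grouped by their
#'   Parent attribute).
#' @return A data frame with columns \code{chrom} and \code{pos}
#'   (1-based), sorted.
#' @export
fourfold_degenerate_sites <- function(fasta, gff) {
  genome <- Biostrings::readDNAStringSet(fasta)
  names(genome) <- sub("\\s.*", "", names(genome))
  ann <- rtracklayer::import(gff)
  cds <- ann[ann$type == "CDS"]
  if (length(cds) == 0) stop("no CDS features in GFF")
  parent <- as.character(S4Vectors::mcols(cds)$Parent)
  if (all(is.na(parent)) || is.null(parent))
    parent <- as.character(S4Vectors::mcols(cds)$ID)
  ffd_pre <- .ffd_prefixes()
  good <- character(0)    # "chrom:pos" classified 4-fold by some CDS
  covered_bad <- character(0)  # covered but not 4-fold third position
  for (tx in unique(parent)) {
    seg <- cds[parent == tx]
    strand <- as.character(BiocGenerics::strand(seg))[1]
    chrom <- as.character(GenomicRanges::seqnames(seg))[1]
    ord <- order(GenomicRanges::start(seg),
                 decreasing = (strand == "-"))
    seg <- seg[ord]
    # genomic positions of the spliced CDS in transcript order
    posl <- lapply(seq_along(seg), function(i) {
      p <- GenomicRanges::start(seg)[i]:GenomicRanges::end(seg)[i]
      if (strand == "-") rev(p) else p
    })
    gpos <- unlist(posl)
    ph <- S4Vectors::mcols(seg)$phase
    ph1 <- if (!is.null(ph) && !is.na(ph[1])) as.integer(ph[1]) else 0L
    if (ph1 > 0) gpos <- gpos[-seq_len(ph1)]
    if (length(gpos) %% 3 != 0) {
      warning("CDS length of '", tx, "' not a multiple of 3; skipped")
      covered_bad <- c(covered_bad, paste0(chrom, ":", gpos))
      next
    }
    if (chrom %in% names(genome)) {
      bases <- strsplit(as.character(genome[[chrom]]), "")[[1]][gpos]
    } else stop("chromosome '", chrom, "' absent from FASTA")
    if (strand == "-")
      bases <- c(A = "T", C = "G", G = "C", T = "A")[bases]
    ncod <- length(gpos) %/% 3
    pre <- paste0(bases[3 * seq_len(ncod) - 2], bases[3 * seq_len(ncod) - 1])
    third <- gpos[3 * seq_len(ncod)]
    is4 <- pre %in% ffd_pre
    key_all <- paste0(chrom, ":", gpos)
    key_third4 <- paste0(chrom, ":", third[is4], recycle0 = TRUE)
    good <- c(good, key_third4)
    covered_bad <- c(covered_bad, setdiff(key_all, key_third4))
  }
  keys <- setdiff(unique(good), unique(covered_bad))
  if (length(keys) == 0)
    return(data.frame(chrom = character(0), pos = integer(0)))
  parts <- strsplit(keys, ":")
  out <- data.frame(chrom = vapply(parts, `[`, "", 1),
                    pos = as.integer(vapply(parts, `[`, "", 2)),
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Random intergenic site selection
#'
#' Uniformly samples (without replacement) sites that lie strictly more
#' than \code{min_dist_bp} from any exon and have no missing genotype in
#' the target samples. If fewer eligible sites exist than requested, all
#' are returned with a warning.
#'
#' @param gff GFF3 path (exon features; gene/CDS used as fallback) or a
#'   GRanges of exonic intervals.
#' @param gm A \code{\link{genotype_matrix}} providing candidate sites
#'   and missingness.
#' @param n_sites Number of sites to draw (default 500000).
#' @param min_dist_bp Minimum distance from exons, exclusive (default
#'   10000).
#' @param seed Seed for the draw.
#' @return Integer vector of selected site row indices into
#'   \code{gm$sites}, sorted.
#' @export
select_intergenic_sites <- function(gff, gm, n_sites = 500000,
                                    min_dist_bp = 10000, seed = 1) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (inherits(gff, "GRanges")) {
    ex <- gff
  } else {
    ann <- rtracklayer::import(gff)
    ex <- ann[ann$type == "exon"]
    if (length(ex) == 0) ex <- ann[ann$type %in% c("CDS", "gene")]
  }
  sitesGR <- GenomicRanges::GRanges(
    gm$sites$chrom, IRanges::IRanges(gm$sites$pos, gm$sites$pos))
  far <- rep(TRUE, length(sitesGR))
  if (length(ex) > 0) {
    expanded <- GenomicRanges::resize(
      ex, GenomicRanges::width(ex) + 2 * min_dist_bp, fix = "center")
    far <- !IRanges::overlapsAny(sitesGR, expanded, ignore.strand = TRUE)
  }
  complete <- rowSums(is.na(gm$dosage)) == 0
  eligible <- which(far & complete)
  if (length(eligible) <= n_sites) {
    if (length(eligible) < n_sites)
      warning(sprintf("only %d eligible sites for requested %d",
                      length(eligible), n_sites))
    return(eligible)
  }
  set.seed(seed)
  sort(sample(eligible, n_sites))
}

#' Callability mask: no-record regions
#'
#' Gaps of more than 1 bp between consecutive recorded positions on a
#' chromosome, reported as 0-based half-open intervals excluding the
#' recorded endpoints. Regions before the first and after the last record
#' are not reported (chromosome bounds are unknown to the matrix).
#'
#' @param gm A \code{\link{genotype_matrix}} whose sites carry any record
#'   (variant or invariant).
#' @return A data frame (\code{chrom}, \code{start}, \code{end}),
#'   half-open, sorted, disjoint; class \code{callability_mask}.
#' @export
callability_mask <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  out <- do.call(rbind, lapply(unique(gm$sites$chrom), function(ch) {
    p <- sort(gm$sites$pos[gm$sites$chrom == ch])
    if (length(p) < 2) return(NULL)
    gap_len <- diff(p) - 1L
    i <- which(gap_len > 1L)
    if (!length(i)) return(NULL)
    data.frame(chrom = ch, start = p[i], end = p[i + 1] - 1L,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0))
  class(out) <- c("callability_mask", "data.frame")
  out
}

#' Non-overlapping window tiling
#'
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param width Window width in bp (default 20000).
#' @return A data frame (\code{chrom}, \code{start}, \code{end}) of
#'   0-based half-open windows anchored at 0; the last window of a
#'   chromosome may be shorter.
#' @export
window_tiling <- function(chrom_sizes, width = 20000) {
  stopifnot(!is.null(names(chrom_sizes)), width > 0)
  do.call(rbind, lapply(names(chrom_sizes), function(ch) {
    L <- chrom_sizes[[ch]]
    starts <- seq(0, max(0, L - 1), by = width)
    data.frame(chrom = ch, start = starts, end = pmin(starts + width, L),
               stringsAsFactors = FALSE)
  }))
}
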