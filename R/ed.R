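#' Allele frequencies from per-allele depths
#'
#' @param depths Non-negative counts, one per allele.
#' @return Frequencies summing to 1, or all-`NA` of the same length when
#'   total depth is zero (a missing site, excluded downstream).
#' @export
allele_frequencies <- function(depths) {
  if (any(depths < 0)) stop("negative allele depth", call. = FALSE)
  tot <- sum(depths)
  if (tot == 0) return(rep(NA_real_, length(depths)))
  depths / tot
}

#' Euclidean-distance statistic between two pools' allele frequencies
#'
#' ED = sqrt(sum over alleles of (f1 - f2)^2): the frequency distance of a
#' variant between the two bulks.  Bounded by sqrt(2) (pools fixed for
#' opposite alleles) and symmetric in pool order.
#'
#' @param f1,f2 Allele-frequency vectors of equal length, each summing
#'   to 1.
#' @return The ED value.
#' @export
ed_statistic <- function(f1, f2) {
  if (length(f1) != length(f2))
    stop("frequency vectors differ in length", call. = FALSE)
  sqrt(sum((f1 - f2)^2))
}

#' Per-variant ED profile of a two-pool variant table
#'
#' Computes ED and ED^k for every biallelic variant with at least
#' `min_depth` reads in both pools.  SNPs and InDels are profiled jointly;
#' the variant class column is carried through so regions can additionally
#' be reported per class.
#'
#' @param vt A `variant_table` (columns `chrom`, `pos`, `vclass`, `ref1`,
#'   `alt1`, `ref2`, `alt2`).
#' @param k Power applied to ED for noise suppression (default 4).
#' @param min_depth Minimum total depth per pool per site (default 10);
#'   sites failing in either pool are dropped and counted.
#' @return An `ed_profile` data.frame: `chrom`, `pos`, `vclass`, `ed`,
#'   `ed_powered`, sorted by (chrom, pos), with attributes `k`,
#'   `n_dropped`, `pool_names`.
#' @export
ed_profile <- function(vt, k = 4, min_depth = 10) {
  stopifnot(all(c("chrom", "pos", "ref1", "alt1", "ref2", "alt2") %in%
                  names(vt)))
  d1 <- vt$ref1 + vt$alt1
  d2 <- vt$ref2 + vt$alt2
  keep <- d1 >= min_depth & d2 >= min_depth
  n_dropped <- sum(!keep)
  if (!any(keep))
    stop("no variants pass min_depth = ", min_depth, " (dropped ",
         n_dropped, " of ", length(keep), ")", call. = FALSE)
  v <- vt[keep, , drop = FALSE]
  f1 <- v$alt1 / (v$ref1 + v$alt1)
  f2 <- v$alt2 / (v$ref2 + v$alt2)
  # biallelic closed form of the allele-frequency Euclidean distance
  ed <- sqrt(2) * abs(f1 - f2)
  prof <- data.frame(chrom = v$chrom, pos = v$pos,
                     vclass = if ("vclass" %in% names(v)) v$vclass
                              else NA_character_,
                     ed = ed, ed_powered = ed^k,
                     stringsAsFactors = FALSE)
  prof <- prof[order(prof$chrom, prof$pos), ]
  rownames(prof) <- NULL
  structure(prof, k = k, n_dropped = n_dropped,
            pool_names = attr(vt, "pool_names"),
            class = c("ed_profile", "data.frame"))
}

#' Tricube-smoothed ED profile
#'
#' The smoothed value at each variant is the tricube distance-weighted
#' mean of `ed_powered` over variants within +/- `window_bp`/2 on the same
#' chromosome (loess-like weighting; a window holding only the point
#' itself degrades to the identity).
#'
#' @param profile An `ed_profile`.
#' @param window_bp Full window width in bp (default 6 Mb; at the
#'   synthetic marker density of 1/Mb this averages ~7 markers).
#' @return The profile with a `smoothed` column added.
#' @export
smooth_profile <- function(profile, window_bp = 6e6) {
  stopifnot(inherits(profile, "ed_profile"))
  if (window_bp <= 0) stop("window_bp must be positive", call. = FALSE)
  profile$smoothed <- tricube_smooth(profile$chrom, profile$pos,
                                     profile$ed_powered, window_bp)
  attr(profile, "window_bp") <- window_bp
  profile
}

# tricube kernel smoother over (chrom, pos); returns values in row order
tricube_smooth <- function(chrom, pos, y, window_bp) {
  half <- window_bp / 2
  out <- numeric(length(y))
  for (idx in split(seq_along(y), chrom)) {
    p <- pos[idx]
    v <- y[idx]
    out[idx] <- vapply(seq_along(idx), function(i) {
      d <- abs(p - p[i])
      inw <- d <= half
      u <- d[inw] / half
      w <- (1 - u^3)^3
      sum(w * v[inw]) / sum(w)
    }, numeric(1))
  }
  out
}

#' Simulated no-QTL pointwise thresholds for the smoothed ED profile
#'
#' QTL-seq-style null calibration: under no linkage both bulks are random
#' draws of `bulk_size` individuals from the same segregating population,
#' so per site the bulk allele frequency varies by bulk composition
#' (binomial over bulk members) on top of read sampling (binomial over
#' observed depths).  The null genome is simulated `B` times at the
#' observed marker positions and depths and smoothed identically; each
#' variant receives the `q` quantile of its own smoothed null values, so
#' low-depth or sparsely covered markers carry proportionally higher
#' thresholds (the same depth-awareness as QTL-seq confidence intervals).
#'
#' Assumes 1:1 segregation of a heterozygous-by-homozygous cross
#' (offspring alt dosage 0/1); the per-site carrier frequency is
#' estimated from the pooled data so segregation-distorted sites keep
#' their own null.
#'
#' @param vt A `variant_table`.
#' @param bulk_size Individuals per bulk (default 15).
#' @param k ED power (default 4).
#' @param min_depth Depth filter, as in [ed_profile()].
#' @param window_bp Smoothing window, as in [smooth_profile()].
#' @param B Null genomes to simulate (default 1000).
#' @param q Pointwise null quantile (default 0.9995).
#' @return Numeric vector of thresholds, one per variant passing
#'   `min_depth`, in (chrom, pos) order (matching [ed_profile()] rows).
#' @export
ed_null_threshold <- function(vt, bulk_size = 15, k = 4, min_depth = 10,
                              window_bp = 6e6, B = 1000, q = 0.9995) {
  d1 <- vt$ref1 + vt$alt1
  d2 <- vt$ref2 + vt$alt2
  keep <- d1 >= min_depth & d2 >= min_depth
  v <- vt[keep, , drop = FALSE]
  d1 <- d1[keep]; d2 <- d2[keep]
  # pooled alt-read frequency -> dosage-carrier frequency (dosage 0/1
  # gives site frequency = carrier fraction / 2)
  p_carrier <- pmin(2 * (v$alt1 + v$alt2) / (d1 + d2), 1)
  n <- length(d1)
  ord <- order(v$chrom, v$pos)
  chrom <- v$chrom[ord]; pos <- v$pos[ord]
  p_carrier <- p_carrier[ord]; d1 <- d1[ord]; d2 <- d2[ord]
  W <- tricube_weights(chrom, pos, window_bp)
  ed4_null <- matrix(0, n, B)
  for (b in seq_len(B)) {
    fb1 <- rbinom(n, bulk_size, p_carrier) / (2 * bulk_size)
    fb2 <- rbinom(n, bulk_size, p_carrier) / (2 * bulk_size)
    f1 <- rbinom(n, d1, fb1) / d1
    f2 <- rbinom(n, d2, fb2) / d2
    ed4_null[, b] <- (sqrt(2) * abs(f1 - f2))^k
  }
  sm <- W %*% ed4_null
  apply(sm, 1, stats::quantile, probs = q, names = FALSE)
}

# row-normalized tricube weight matrix (zero across chromosomes); dense,
# adequate for marker panels up to a few thousand variants
tricube_weights <- function(chrom, pos, window_bp) {
  half <- window_bp / 2
  n <- length(pos)
  W <- matrix(0, n, n)
  for (idx in split(seq_len(n), chrom)) {
    d <- abs(outer(pos[idx], pos[idx], "-"))
    w <- ifelse(d <= half, (1 - (d / half)^3)^3, 0)
    W[idx, idx] <- w / rowSums(w)
  }
  W
}

#' Call candidate regions from a smoothed ED profile
#'
#' With no explicit `threshold`, threshold = median + `n_sd` SD of the
#' genome-wide smoothed values (the classical ED-profile rule; liberal
#' under the null, see [ed_null_threshold()] for a calibrated
#' alternative, which the pipeline uses by default).  Maximal runs of
#' consecutive above-threshold variants become intervals; adjacent runs
#' closer than `merge_gap` bp are merged.  Output intervals are 0-based
#' half-open; the peak is the variant with the maximum smoothed value
#' inside the interval.
#'
#' @param profile A smoothed `ed_profile`.
#' @param n_sd SD multiplier of the median + SD rule (default 3).
#' @param merge_gap Merge runs separated by less than this many bp
#'   (defaults to the smoothing window).
#' @param vclass Optional variant class (`"SNP"`/`"InDel"`) to restrict
#'   calling to one class, mirroring separate SNP and InDel tracks.
#' @param threshold Optional explicit threshold, scalar or one value per
#'   profile row (e.g. from [ed_null_threshold()]); overrides the
#'   median + SD rule.
#' @return data.frame of intervals: `chrom`, `start`, `end`, `peak_pos`,
#'   `peak_smoothed`, `n_variants`, with attribute `threshold`; zero rows
#'   (with a warning) when the profile is flat.
#' @export
call_regions <- function(profile, n_sd = 3, merge_gap = NULL,
                         vclass = NULL, threshold = NULL) {
  stopifnot(inherits(profile, "ed_profile"))
  if (is.null(profile$smoothed))
    stop("run smooth_profile() first", call. = FALSE)
  if (is.null(merge_gap))
    merge_gap <- attr(profile, "window_bp") %||% 6e6
  if (!is.null(threshold) && length(threshold) > 1) {
    stopifnot(length(threshold) == nrow(profile))
    profile$.thr <- threshold
  }
  if (!is.null(vclass)) profile <- profile[profile$vclass %in% vclass, ]
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), peak_pos = integer(),
                      peak_smoothed = numeric(), n_variants = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(threshold)) {
    s <- stats::sd(profile$smoothed)
    if (!is.finite(s) || s == 0) {
      warning("flat smoothed profile: no regions called")
      return(structure(empty, threshold = NA_real_))
    }
    profile$.thr <- stats::median(profile$smoothed) + n_sd * s
  } else if (length(threshold) == 1) {
    profile$.thr <- threshold
  }
  thr <- profile$.thr
  out <- list()
  for (ch in unique(profile$chrom)) {
    d <- profile[profile$chrom == ch, ]
    above <- d$smoothed > d$.thr
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- c(1L, utils::head(ends, -1) + 1L)
    runs <- data.frame(from = starts[r$values], to = ends[r$values])
    # merge runs whose bp gap is below merge_gap
    if (nrow(runs) > 1) {
      merged <- runs[1, , drop = FALSE]
      for (i in 2:nrow(runs)) {
        gap <- d$pos[runs$from[i]] - d$pos[merged$to[nrow(merged)]]
        if (gap < merge_gap) {
          merged$to[nrow(merged)] <- runs$to[i]
        } else merged <- rbind(merged, runs[i, ])
      }
      runs <- merged
    }
    for (i in seq_len(nrow(runs))) {
      seg <- d[runs$from[i]:runs$to[i], ]
      pk <- which.max(seg$smoothed)
      out[[length(out) + 1]] <- data.frame(
        chrom = ch,
        start = min(seg$pos) - 1L,          # 0-based half-open
        end = max(seg$pos),
        peak_pos = seg$pos[pk],
        peak_smoothed = seg$smoothed[pk],
        n_variants = nrow(seg), stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  structure(res, threshold = if (length(unique(thr)) == 1) thr[1] else thr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Genes overlapping candidate intervals
#'
#' A gene is reported when its span overlaps any interval by at least 1 bp
#' under half-open interval arithmetic (a gene that merely abuts an
#' interval end is excluded).
#'
#' @param intervals data.frame from [call_regions()] (`chrom`, `start`,
#'   `end`, 0-based half-open).
#' @param genes data.frame of gene models (`gene_id`, `chrom`, `start`,
#'   `end`, 1-based inclusive).
#' @return Character vector of gene ids.
#' @export
genes_in_regions <- function(intervals, genes) {
  if (nrow(intervals) == 0) return(character())
  bad <- setdiff(unique(intervals$chrom), unique(genes$chrom))
  if (length(bad))
    stop("interval chromosomes missing from annotation: ",
         paste(bad, collapse = ", "), call. = FALSE)
  iv <- GenomicRanges::GRanges(
    intervals$chrom,
    IRanges::IRanges(start = intervals$start + 1L, end = intervals$end))
  gn <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(start = genes$start, end = genes$end))
  hits <- GenomicRanges::findOverlaps(gn, iv, minoverlap = 1L)
  sort(unique(genes$gene_id[S4Vectors::queryHits(hits)]))
}
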