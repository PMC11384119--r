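#' Median-of-ratios normalization of a pooled count matrix
#'
#' Size factors are the per-sample median of count / geometric-mean ratios
#' over genes with all-positive counts; when fewer than 50 such genes
#' exist the method falls back to total-count scaling.  Factors are
#' rescaled to have geometric mean 1.
#'
#' @param counts Non-negative integer matrix, genes x samples.
#' @return List: `normalized` (counts / size factor), `size_factors`,
#'   `method` (`"median_ratio"` or `"total_count"`).
#' @export
normalize_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  zero_sample <- colSums(counts) == 0
  if (any(zero_sample))
    stop("all-zero sample(s): ",
         paste(colnames(counts)[zero_sample], collapse = ", "),
         call. = FALSE)
  allpos <- rowSums(counts == 0) == 0
  if (sum(allpos) >= 50) {
    lg <- log(counts[allpos, , drop = FALSE])
    geo <- rowMeans(lg)
    sf <- apply(exp(lg - geo), 2, stats::median)
    method <- "median_ratio"
  } else {
    tot <- colSums(counts)
    sf <- tot / exp(mean(log(tot)))
    method <- "total_count"
  }
  sf <- sf / exp(mean(log(sf)))
  list(normalized = sweep(counts, 2, sf, "/"), size_factors = sf,
       method = method)
}

#' Per-gene differential-expression test between colour classes
#'
#' log2 fold change is computed on normalized class means with a 0.5
#' pseudocount, purple over green (green is the control); the p-value is a
#' Welch t-test on log2(normalized + 1) per gene.  Genes with zero
#' variance in both classes get p = 1 when the means agree and p = 0 when
#' they differ.
#'
#' @param normalized Normalized matrix from [normalize_counts()].
#' @param classes Named character vector (`"green"`/`"purple"`) over the
#'   sample columns.
#' @return data.frame: `gene_id`, `mean_green`, `mean_purple`, `log2fc`,
#'   `p`, `q` (Benjamini-Hochberg).
#' @export
de_test <- function(normalized, classes) {
  classes <- classes[colnames(normalized)]
  g <- which(classes == "green")
  p <- which(classes == "purple")
  if (length(g) < 2 || length(p) < 2)
    stop("need >= 2 replicates per class", call. = FALSE)
  mg <- rowMeans(normalized[, g, drop = FALSE])
  mp <- rowMeans(normalized[, p, drop = FALSE])
  lfc <- log2((mp + 0.5) / (mg + 0.5))

  x <- log2(normalized + 1)
  xg <- x[, g, drop = FALSE]
  xp <- x[, p, drop = FALSE]
  ng <- length(g); np <- length(p)
  vg <- rowSums((xg - rowMeans(xg))^2) / (ng - 1)
  vp <- rowSums((xp - rowMeans(xp))^2) / (np - 1)
  se2 <- vg / ng + vp / np
  diff <- rowMeans(xp) - rowMeans(xg)
  tt <- diff / sqrt(se2)
  df <- se2^2 / ((vg / ng)^2 / (ng - 1) + (vp / np)^2 / (np - 1))
  pv <- 2 * stats::pt(-abs(tt), df)
  degen <- se2 == 0
  pv[degen & diff == 0] <- 1
  pv[degen & diff != 0] <- 0
  data.frame(gene_id = rownames(normalized),
             mean_green = mg, mean_purple = mp,
             log2fc = lfc, p = pv,
             q = stats::p.adjust(pv, method = "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter DE results to the DEG set
#'
#' Keeps genes with `|log2fc| > lfc_min` and `p < p_max`, both strict
#' inequalities, and annotates the direction of change.  No multiple-
#' testing correction is applied in this headline filter (q-values remain
#' available in the input).
#'
#' @param results data.frame from [de_test()].
#' @param lfc_min log2 fold-change cutoff (default 1, exclusive).
#' @param p_max p-value cutoff (default 0.05, exclusive).
#' @return The filtered rows with a `direction` column (`"up"`/`"down"`,
#'   purple relative to green).
#' @export
filter_degs <- function(results, lfc_min = 1, p_max = 0.05) {
  if (nrow(results) == 0) stop("empty DE results", call. = FALSE)
  keep <- abs(results$log2fc) > lfc_min & results$p < p_max
  out <- results[keep, , drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  rownames(out) <- NULL
  out
}

#' Sample ordination by principal components
#'
#' PCA of log2(normalized + 1), gene-centred, computed over samples.
#' The sign of each component is fixed so that its largest-magnitude gene
#' loading is positive.
#'
#' @param normalized Normalized matrix.
#' @param n_comp Number of components to report (default 2).
#' @return data.frame of sample scores with attribute `explained`
#'   (variance fractions).
#' @export
pca_scores <- function(normalized, n_comp = 2) {
  if (ncol(normalized) < 3) stop("need >= 3 samples", call. = FALSE)
  x <- t(log2(normalized + 1))
  keep <- apply(x, 2, stats::var) > 0
  if (!any(keep)) stop("constant matrix: zero variance", call. = FALSE)
  pc <- stats::prcomp(x[, keep, drop = FALSE], center = TRUE,
                      scale. = FALSE)
  n_comp <- min(n_comp, ncol(pc$x))
  flip <- vapply(seq_len(n_comp), function(i) {
    l <- pc$rotation[, i]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  scores <- sweep(pc$x[, seq_len(n_comp), drop = FALSE], 2, flip, "*")
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(as.data.frame(scores), explained = ev[seq_len(n_comp)])
}

#' Concordance between RNA-seq fold changes and qPCR ratios
#'
#' @param de data.frame from [de_test()].
#' @param qpcr data.frame with `gene_id` and `ratio` (purple / green
#'   relative expression, e.g. from [relative_expression()]).
#' @return List: per-gene table with `agree` flags and the overall
#'   `agreement` fraction.
#' @export
qpcr_concordance <- function(de, qpcr) {
  shared <- intersect(de$gene_id, qpcr$gene_id)
  if (!length(shared)) stop("no shared genes", call. = FALSE)
  d <- de[match(shared, de$gene_id), ]
  q <- qpcr[match(shared, qpcr$gene_id), ]
  tab <- data.frame(gene_id = shared,
                    rnaseq_log2fc = d$log2fc,
                    qpcr_log2ratio = log2(q$ratio),
                    stringsAsFactors = FALSE)
  tab$agree <- sign(tab$rnaseq_log2fc) == sign(tab$qpcr_log2ratio)
  list(table = tab, agreement = mean(tab$agree))
}
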