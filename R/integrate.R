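#' Seven-region decomposition of three gene sets
#'
#' @param setA,setB,setC Character vectors of gene ids (deduplicated
#'   internally).
#' @param names Labels of the three sets.
#' @return Object of class `venn_partition`: list with `regions` (member
#'   lists for A_only, B_only, C_only, AB, AC, BC, ABC), `counts`, and
#'   `union_size`.  The triple intersection holds the prime candidates.
#' @export
venn_partition <- function(setA, setB, setC,
                           names = c("A", "B", "C")) {
  A <- unique(setA); B <- unique(setB); C <- unique(setC)
  inA <- function(x) x %in% A
  inB <- function(x) x %in% B
  inC <- function(x) x %in% C
  u <- sort(unique(c(A, B, C)))
  key <- paste0(as.integer(inA(u)), as.integer(inB(u)), as.integer(inC(u)))
  regions <- list(
    A_only = u[key == "100"], B_only = u[key == "010"],
    C_only = u[key == "001"], AB = u[key == "110"],
    AC = u[key == "101"], BC = u[key == "011"], ABC = u[key == "111"])
  structure(list(regions = regions,
                 counts = vapply(regions, length, integer(1)),
                 union_size = length(u), set_names = names),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("venn_partition of", paste(x$set_names, collapse = "/"),
      "- union", x$union_size, "genes\n")
  print(x$counts)
  invisible(x)
}

#' Restrict a gene set to listed pathways
#'
#' @param genes Character vector of gene ids.
#' @param annotation data.frame mapping `gene_id` to `pathway`.
#' @param pathways Pathway ids to keep.
#' @return Genes annotated to any listed pathway; unannotated genes are
#'   dropped (count reported via the `n_unannotated` attribute).
#' @export
pathway_filter <- function(genes, annotation, pathways) {
  if (nrow(annotation) == 0) stop("empty annotation map", call. = FALSE)
  ann <- annotation[annotation$gene_id %in% genes, , drop = FALSE]
  n_unann <- sum(!genes %in% annotation$gene_id)
  hit <- unique(ann$gene_id[ann$pathway %in% pathways])
  structure(sort(hit), n_unannotated = n_unann)
}

#' Hypergeometric over-representation test
#'
#' Upper-tail hypergeometric p per term (probability of at least the
#' observed overlap), Benjamini-Hochberg adjusted, ranked by p.
#'
#' @param gene_set Character vector, must be a subset of `universe`.
#' @param universe Character vector of all testable genes.
#' @param term_map data.frame mapping `gene_id` to `term`.
#' @param top_n Rows to keep in the ranked report (default 20).
#' @return data.frame: `term`, `n_term`, `n_overlap`, `p`, `q`, ranked by
#'   p, truncated to `top_n`.
#' @export
enrichment_test <- function(gene_set, universe, term_map, top_n = 20) {
  gene_set <- unique(gene_set)
  universe <- unique(universe)
  if (!all(gene_set %in% universe))
    stop("gene set is not a subset of the universe", call. = FALSE)
  tm <- unique(term_map[term_map$gene_id %in% universe,
                        c("gene_id", "term")])
  terms <- split(tm$gene_id, tm$term)
  N <- length(universe)
  k <- length(gene_set)
  res <- do.call(rbind, lapply(names(terms), function(t) {
    m <- length(terms[[t]])
    ov <- length(intersect(terms[[t]], gene_set))
    p <- stats::phyper(ov - 1, m, N - m, k, lower.tail = FALSE)
    data.frame(term = t, n_term = m, n_overlap = ov, p = p,
               stringsAsFactors = FALSE)
  }))
  res$q <- stats::p.adjust(res$p, method = "BH")
  res <- res[order(res$p, res$term), ]
  rownames(res) <- NULL
  utils::head(res, top_n)
}

#' Pairwise Pearson correlation network over a gene set
#'
#' Correlations are computed across samples on log2(normalized + 1).
#' An edge is retained when `|r| >= r_min` and its t-test p-value
#' (df = n - 2) is below `p_max`.  Zero-variance genes are excluded with
#' a warning.
#'
#' @param normalized Normalized expression matrix (genes x samples).
#' @param genes Gene ids to include.
#' @param r_min Minimum absolute correlation (default 0.8).
#' @param p_max Significance cutoff (default 0.05).
#' @param focal Optional focal gene: its signed partners are reported
#'   separately.
#' @return List: `edges` (data.frame `gene1`, `gene2`, `r`, `p`, `sign`)
#'   and, when `focal` is given, `focal_partners`.
#' @export
correlation_network <- function(normalized, genes, r_min = 0.8,
                                p_max = 0.05, focal = NULL) {
  n <- ncol(normalized)
  if (n < 3) stop("need >= 3 samples", call. = FALSE)
  genes <- intersect(genes, rownames(normalized))
  x <- log2(normalized[genes, , drop = FALSE] + 1)
  v <- apply(x, 1, stats::var)
  if (any(v == 0)) {
    warning("excluding zero-variance gene(s): ",
            paste(genes[v == 0], collapse = ", "))
    x <- x[v > 0, , drop = FALSE]
  }
  if (nrow(x) < 2)
    return(list(edges = data.frame(gene1 = character(),
                                   gene2 = character(), r = numeric(),
                                   p = numeric(), sign = character())))
  r <- stats::cor(t(x))
  ut <- which(upper.tri(r), arr.ind = TRUE)
  rv <- r[ut]
  tv <- rv * sqrt((n - 2) / pmax(1 - rv^2, .Machine$double.eps))
  pv <- 2 * stats::pt(-abs(tv), n - 2)
  edges <- data.frame(gene1 = rownames(r)[ut[, 1]],
                      gene2 = rownames(r)[ut[, 2]],
                      r = rv, p = pv,
                      sign = ifelse(rv >= 0, "positive", "negative"),
                      stringsAsFactors = FALSE)
  edges <- edges[abs(edges$r) >= r_min & edges$p < p_max, , drop = FALSE]
  rownames(edges) <- NULL
  out <- list(edges = edges)
  if (!is.null(focal)) {
    f <- edges[edges$gene1 == focal | edges$gene2 == focal, , drop = FALSE]
    partner <- ifelse(f$gene1 == focal, f$gene2, f$gene1)
    out$focal_partners <- data.frame(gene_id = partner, r = f$r,
                                     sign = f$sign,
                                     stringsAsFactors = FALSE)
  }
  out
}
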