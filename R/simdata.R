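#' Haldane map function: map distance to recombination fraction
#'
#' @param d_cM Map distance in centimorgans.
#' @return Recombination fraction `(1 - exp(-2 d / 100)) / 2`.
#' @export
haldane_r <- function(d_cM) (1 - exp(-2 * d_cM / 100)) / 2

#' Simulate an F1 pseudo-testcross population
#'
#' Gametes of the heterozygous (purple) parent are generated as a Markov
#' chain along each chromosome: the parental haplotype at the first marker
#' is fair-coin, and switches between adjacent markers with the Haldane
#' recombination fraction of their map distance.  The green parent is
#' homozygous reference, so offspring alt dosage equals the purple-parent
#' gamete allele (0 or 1 at every marker).
#'
#' @param config A [cross_config()].
#' @param seed Optional integer seed (set for reproducibility).
#' @return An object of class `sim_population`: list with `genotype`
#'   (individuals x markers dosage matrix), `phase` (purple-parent gamete
#'   haplotype, here identical to `genotype`), `markers`, `config`.
#' @export
simulate_cross <- function(config, seed = NULL) {
  stopifnot(inherits(config, "cross_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_offspring
  mk <- config$markers
  geno <- matrix(0L, nrow = n, ncol = nrow(mk))
  for (ch in unique(mk$chrom)) {
    j <- which(mk$chrom == ch)
    r <- haldane_r(diff(mk$pos_cM[j]))
    H <- matrix(0L, n, length(j))
    H[, 1] <- rbinom(n, 1L, 0.5)
    if (length(j) > 1) {
      for (m in 2:length(j)) {
        switch_ <- rbinom(n, 1L, r[m - 1]) == 1L
        H[, m] <- ifelse(switch_, 1L - H[, m - 1], H[, m - 1])
      }
    }
    geno[, j] <- H
  }
  rownames(geno) <- sprintf("F1_%03d", seq_len(n))
  colnames(geno) <- mk$id
  structure(list(genotype = geno, phase = geno, markers = mk,
                 config = config, liability = NULL, color_class = NULL),
            class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  cat("sim_population:", nrow(x$genotype), "individuals x",
      ncol(x$genotype), "markers\n")
  if (!is.null(x$color_class))
    print(table(x$color_class))
  invisible(x)
}

#' Assign liabilities and colour classes to a simulated population
#'
#' Liability = genotype mean (by causal dosage) + Normal(0, sigma) noise;
#' the four model thresholds bin liability into the five ordered colour
#' classes.
#'
#' @param pop A `sim_population`.
#' @param model A [phenotype_model()].
#' @param overwrite Set `TRUE` to re-assign phenotypes already present.
#' @return The population with `liability` and `color_class` filled in.
#' @export
assign_phenotypes <- function(pop, model = phenotype_model(),
                              overwrite = FALSE) {
  stopifnot(inherits(pop, "sim_population"),
            inherits(model, "phenotype_model"))
  if (!is.null(pop$liability) && !overwrite)
    stop("phenotypes already assigned; use overwrite = TRUE", call. = FALSE)
  dos <- pop$genotype[, pop$config$causal_idx]
  mu <- ifelse(dos >= 1, model$mu_Aa, model$mu_aa)
  liab <- mu + rnorm(length(mu), 0, model$sigma)
  cls <- cut(liab, breaks = c(-Inf, model$thresholds, Inf),
             labels = color_levels(), ordered_result = TRUE)
  pop$liability <- stats::setNames(liab, rownames(pop$genotype))
  pop$color_class <- stats::setNames(cls, rownames(pop$genotype))
  pop
}

#' Select the two phenotypic extremes of a population
#'
#' The `k` lowest-liability individuals form the green group and the `k`
#' highest the purple group.  Ties are broken by individual id (lower id
#' wins), so selection is deterministic.
#'
#' @param pop A phenotyped `sim_population`.
#' @param k Tail size (default 15).
#' @return List with `green` and `purple` character vectors of individual
#'   ids, each ordered from the extreme inwards.
#' @export
select_extremes <- function(pop, k = 15L) {
  stopifnot(inherits(pop, "sim_population"))
  if (is.null(pop$liability))
    stop("assign_phenotypes() must run before select_extremes()",
         call. = FALSE)
  n <- length(pop$liability)
  if (2L * k > n)
    stop("cannot select ", k, " per tail from ", n, " individuals",
         call. = FALSE)
  ids <- names(pop$liability)
  o <- order(pop$liability, ids)        # id breaks liability ties
  list(green = ids[o[seq_len(k)]],
       purple = ids[rev(o)[seq_len(k)]])
}

#' Split a ranked group into sequencing pools
#'
#' Pools are contiguous by rank: the first `pool_size` members form pool 1,
#' and so on.  Each individual lands in exactly one pool.
#'
#' @param group Character vector of individual ids, ranked.
#' @param pool_size Individuals per pool (default 5).
#' @param prefix Pool name prefix (e.g. `"GP"` or `"PP"`).
#' @return Named list of id vectors.
#' @export
form_pools <- function(group, pool_size = 5L, prefix = "P") {
  if (length(group) %% pool_size != 0)
    stop("group size ", length(group), " not divisible by pool size ",
         pool_size, call. = FALSE)
  n_pools <- length(group) %/% pool_size
  pools <- split(group, rep(seq_len(n_pools), each = pool_size))
  stats::setNames(pools, paste0(prefix, seq_len(n_pools)))
}

#' Simulate sequencing depths of one bulk over the marker panel
#'
#' Per marker, total depth is Poisson with the given mean and alt reads are
#' Binomial(depth, f(1-e) + (1-f)e) where f is the mean alt dosage / 2 over
#' the bulk members.  When `expression` is supplied (RNA layer) the Poisson
#' mean is scaled per marker by the containing gene's relative expression;
#' intergenic markers get zero depth — regulatory-region variants are
#' invisible to the RNA layer by construction.
#'
#' @param pop A `sim_population`.
#' @param members Ids of the bulk members.
#' @param lambda Mean depth at an average marker.
#' @param error_rate Per-read error rate.
#' @param expression Optional named numeric vector of relative depth
#'   multipliers per marker id (0 for intergenic), as produced by
#'   [rna_depth_weights()].
#' @return data.frame: `chrom`, `pos`, `vclass`, `depth`, `alt`.
#' @export
simulate_bulk_depths <- function(pop, members, lambda = 50,
                                 error_rate = 0.001, expression = NULL) {
  stopifnot(inherits(pop, "sim_population"))
  if (lambda <= 0) stop("lambda must be positive", call. = FALSE)
  if (length(members) == 0) stop("bulk is empty", call. = FALSE)
  mk <- pop$markers
  G <- pop$genotype[members, , drop = FALSE]
  f <- colMeans(G) / 2
  lam <- rep(lambda, nrow(mk))
  if (!is.null(expression)) {
    w <- expression[mk$id]
    w[is.na(w)] <- 0
    lam <- lambda * w
  }
  depth <- rpois(nrow(mk), lam)
  p_alt <- f * (1 - error_rate) + (1 - f) * error_rate
  alt <- rbinom(nrow(mk), depth, p_alt)
  data.frame(chrom = mk$chrom, pos = mk$pos_bp, vclass = mk$vclass,
             depth = depth, alt = alt, stringsAsFactors = FALSE)
}

#' Combine two per-bulk depth tables into a two-pool variant table
#'
#' @param bulk1,bulk2 data.frames from [simulate_bulk_depths()] over the
#'   same marker panel (pool 1 conventionally the green bulk).
#' @param pool_names Names of the two pools.
#' @return A `variant_table` data.frame: `chrom`, `pos`, `vclass`,
#'   `ref1`, `alt1`, `ref2`, `alt2`.
#' @export
variant_table <- function(bulk1, bulk2, pool_names = c("GP", "PP")) {
  stopifnot(nrow(bulk1) == nrow(bulk2),
            all(bulk1$pos == bulk2$pos), all(bulk1$chrom == bulk2$chrom))
  vt <- data.frame(chrom = bulk1$chrom, pos = bulk1$pos,
                   vclass = bulk1$vclass,
                   ref1 = bulk1$depth - bulk1$alt, alt1 = bulk1$alt,
                   ref2 = bulk2$depth - bulk2$alt, alt2 = bulk2$alt,
                   stringsAsFactors = FALSE)
  attr(vt, "pool_names") <- pool_names
  class(vt) <- c("variant_table", "data.frame")
  vt
}

#' Build gene models over the marker panel
#'
#' Each genic marker receives a 10-kb gene centred on it; one intergenic
#' filler gene is placed halfway to the next marker so the annotation also
#' contains genes with no marker inside.  The causal gene is the gene
#' containing the causal marker.
#'
#' @param config A [cross_config()].
#' @param gene_halfwidth Half-width of each gene in bp.
#' @return data.frame: `gene_id`, `chrom`, `start`, `end` (1-based,
#'   inclusive), `marker_id` (NA for filler genes).
#' @export
make_gene_models <- function(config, gene_halfwidth = 5000L) {
  stopifnot(inherits(config, "cross_config"))
  mk <- config$markers
  genic <- mk[mk$genic, ]
  marker_genes <- data.frame(
    chrom = genic$chrom,
    start = pmax(1L, genic$pos_bp - gene_halfwidth),
    end = genic$pos_bp + gene_halfwidth - 1L,
    marker_id = genic$id, stringsAsFactors = FALSE)
  filler <- data.frame(
    chrom = mk$chrom,
    start = mk$pos_bp + 500000L - gene_halfwidth,
    end = mk$pos_bp + 500000L + gene_halfwidth - 1L,
    marker_id = NA_character_, stringsAsFactors = FALSE)
  genes <- rbind(marker_genes, filler)
  genes <- genes[order(match(genes$chrom, config$chromosomes$name),
                       genes$start), ]
  genes$gene_id <- sprintf("GENE%04d", seq_len(nrow(genes)))
  rownames(genes) <- NULL
  genes <- genes[, c("gene_id", "chrom", "start", "end", "marker_id")]
  causal_marker <- mk$id[config$causal_idx]
  attr(genes, "causal_gene") <-
    genes$gene_id[match(causal_marker, genes$marker_id)]
  genes
}

#' Simulate the pooled expression matrix
#'
#' @param pop A phenotyped `sim_population`.
#' @param pools Named list of pools (ids per pool), e.g.
#'   `c(form_pools(green, 5, "GP"), form_pools(purple, 5, "PP"))`.
#' @param classes Named character vector mapping pool name to
#'   `"green"`/`"purple"`.
#' @param genes Gene models from [make_gene_models()].
#' @param config An [expr_config()].
#' @return List: `counts` (genes x pools integer matrix), `classes`,
#'   `base_mean`, `truth` (planted DEGs with their log2FC and the causal
#'   gene id).
#' @export
simulate_expression <- function(pop, pools, classes, genes,
                                config = expr_config()) {
  stopifnot(inherits(pop, "sim_population"), inherits(config, "expr_config"))
  if (length(pools) < 4 || length(unique(classes[names(pools)])) < 2 ||
      any(table(classes[names(pools)]) < 2))
    stop("need at least 2 pools per class for DE", call. = FALSE)
  ng <- nrow(genes)
  causal_gene <- attr(genes, "causal_gene")
  if (is.null(causal_gene)) causal_gene <- NA_character_
  base <- rlnorm(ng, config$base_meanlog, config$base_sdlog)
  names(base) <- genes$gene_id
  if (!is.na(causal_gene)) base[causal_gene] <- config$causal_base_mean

  eligible <- setdiff(genes$gene_id, causal_gene)
  n_deg <- round(config$deg_fraction * length(eligible))
  planted <- sample(eligible, n_deg)
  lfc <- stats::setNames(rep(0, ng), genes$gene_id)
  lfc[planted] <- rnorm(n_deg, config$lfc_location, config$lfc_scale)

  causal_dos <- pop$genotype[, pop$config$causal_idx]
  counts <- matrix(0L, ng, length(pools),
                   dimnames = list(genes$gene_id, names(pools)))
  size <- 1 / config$dispersion
  for (p in names(pools)) {
    purple <- classes[[p]] == "purple"
    mu <- base
    if (purple) mu <- mu * 2^lfc
    if (!is.na(causal_gene)) {
      pool_dos <- mean(causal_dos[pools[[p]]])
      mu[causal_gene] <- base[causal_gene] * 2^(config$causal_lfc * pool_dos)
    }
    counts[, p] <- rnbinom(ng, mu = mu, size = size)
  }
  truth <- data.frame(gene_id = planted, log2fc = lfc[planted],
                      stringsAsFactors = FALSE)
  list(counts = counts, classes = classes[names(pools)], base_mean = base,
       truth = list(planted = truth, causal_gene = causal_gene))
}

#' Per-marker relative RNA depth weights
#'
#' Weight of a genic marker = containing gene's class-mean expression
#' divided by the mean expression over all genic markers; intergenic
#' markers weigh 0.
#'
#' @param pop A `sim_population`.
#' @param genes Gene models.
#' @param gene_mean Named numeric vector of per-gene mean expression for
#'   the bulk's colour class.
#' @return Named numeric vector over marker ids.
#' @export
rna_depth_weights <- function(pop, genes, gene_mean) {
  mk <- pop$markers
  gene_of <- stats::setNames(genes$gene_id, genes$marker_id)
  w <- rep(0, nrow(mk))
  names(w) <- mk$id
  hit <- mk$id %in% names(gene_of)
  expr <- gene_mean[gene_of[mk$id[hit]]]
  expr[is.na(expr)] <- 0
  w[hit] <- expr
  pos <- w[w > 0]
  if (length(pos)) w <- w / mean(pos)
  w
}

#' Promoter InDel fixture
#'
#' Builds a pair of promoter alleles differing by exactly one insertion
#' inside a fixed window upstream of the start codon, plus one flanking
#' primer pair present once in each allele.  Promoter coordinates are
#' negative and 1-based: -1 is the base immediately 5' of the ATG's A;
#' the window is inclusive on both ends.  With defaults the inserted block
#' occupies -332..-152 of the long allele, i.e. exactly 181 bp.
#'
#' @param insertion_length Length of the inserted block (default 181).
#' @param window Inclusive promoter window `c(-332, -152)` that must
#'   contain the insertion (long-allele coordinates).
#' @param promoter_length Length of the short (insertion-free) allele.
#' @param primer_length Primer length (default 20).
#' @param seed Optional integer seed.
#' @param max_tries Regeneration attempts if a primer happens to multi-map.
#' @return Object of class `promoter_fixture`: `short`, `long` (character
#'   sequences), `fwd`, `rev` (primers, `rev` given 5'->3' on the minus
#'   strand), `insertion_length`, `window`, `insert_coords` (long-allele
#'   coordinates of the inserted block).
#' @export
make_promoter_fixture <- function(insertion_length = 181L,
                                  window = c(-332L, -152L),
                                  promoter_length = 500L,
                                  primer_length = 20L,
                                  seed = NULL, max_tries = 20L) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(window[1] < window[2], window[2] < 0)
  if (insertion_length < 0) stop("insertion_length must be >= 0",
                                 call. = FALSE)
  span <- window[2] - window[1] + 1L
  if (insertion_length > span)
    stop("insertion (", insertion_length, " bp) does not fit the ", span,
         "-bp window", call. = FALSE)
  if (promoter_length < abs(window[1]) + 2L * primer_length + 20L)
    stop("promoter too short for window plus flanking primers",
         call. = FALSE)
  rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
  for (try in seq_len(max_tries)) {
    short <- rand_seq(promoter_length)
    block <- if (insertion_length > 0) rand_seq(insertion_length) else ""
    # inserted block ends at window[2] in long-allele coordinates:
    # short suffix after the insertion point has |window[2]| - 1 bases
    suffix_len <- abs(window[2]) - 1L
    prefix_len <- promoter_length - suffix_len
    long <- paste0(substr(short, 1, prefix_len), block,
                   substr(short, prefix_len + 1, promoter_length))
    # primers flank the window with a safety margin in shared sequence
    up_max <- prefix_len - primer_length - 10L
    f_start <- sample(seq_len(max(1L, up_max)), 1)
    fwd <- substr(short, f_start, f_start + primer_length - 1L)
    down_min <- prefix_len + 1L
    r_start <- sample(down_min:(promoter_length - primer_length + 1L), 1)
    rev_site <- substr(short, r_start, r_start + primer_length - 1L)
    rev <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(rev_site)))
    ok <- function(p, tmpl) {
      length(Biostrings::matchPattern(Biostrings::DNAString(p),
                                      Biostrings::DNAString(tmpl))) == 1
    }
    if (ok(fwd, short) && ok(fwd, long) &&
        ok(rev_site, short) && ok(rev_site, long))
      return(structure(list(short = short, long = long, fwd = fwd,
                            rev = rev,
                            insertion_length = as.integer(insertion_length),
                            window = window,
                            insert_coords = c(window[2] - insertion_length +
                                                1L, window[2])),
                       class = "promoter_fixture"))
  }
  stop("could not place unique primers in ", max_tries, " attempts",
       call. = FALSE)
}
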