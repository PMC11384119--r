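#' Derive a sub-stage seed from the global seed
#'
#' Stable string hash of the stage name folded into the global seed, so
#' adding a stage never shifts another stage's random stream.  Result is
#' kept below 2^31.
#'
#' @param seed Global integer seed.
#' @param stage Stage name.
#' @return Integer seed.
#' @export
stage_seed <- function(seed, stage) {
  h <- 0
  for (b in utf8ToInt(stage)) h <- (h * 131 + b) %% 2147483563
  as.integer((h + as.numeric(seed) * 48271) %% 2147483563)
}

#' Simulate one complete synthetic experiment
#'
#' Runs the generator end to end: F1 cross, liability phenotypes, extreme
#' bulks, RNA pools, DNA- and RNA-layer two-pool depth tables, gene
#' models, and the pooled expression matrix, under one derived seed per
#' stage.
#'
#' @param seed Global seed.
#' @param cross A [cross_config()].
#' @param model A [phenotype_model()].
#' @param design A [bulk_design()].
#' @param expr An [expr_config()].
#' @return List: `pop`, `extremes`, `pools`, `classes`, `genes`,
#'   `vt_dna`, `vt_rna` (two-pool `variant_table`s), `expression`
#'   (counts + truth), `truth` (causal locus and planted DEGs).
#' @export
run_simulation <- function(seed = 1,
                           cross = cross_config(),
                           model = phenotype_model(),
                           design = bulk_design(),
                           expr = expr_config()) {
  pop <- simulate_cross(cross, seed = stage_seed(seed, "cross"))
  set.seed(stage_seed(seed, "phenotype"))
  pop <- assign_phenotypes(pop, model)
  ext <- select_extremes(pop, k = design$k)
  pools <- c(form_pools(ext$green, design$pool_size, "GP"),
             form_pools(ext$purple, design$pool_size, "PP"))
  classes <- stats::setNames(
    ifelse(grepl("^GP", names(pools)), "green", "purple"), names(pools))

  genes <- make_gene_models(cross)
  set.seed(stage_seed(seed, "expression"))
  expression <- simulate_expression(pop, pools, classes, genes, expr)

  set.seed(stage_seed(seed, "dna_depths"))
  dna_g <- simulate_bulk_depths(pop, ext$green, design$lambda_dna,
                                design$error_rate)
  dna_p <- simulate_bulk_depths(pop, ext$purple, design$lambda_dna,
                                design$error_rate)
  vt_dna <- variant_table(dna_g, dna_p, c("GP", "PP"))

  # RNA depth scales with the class-level expression of the containing
  # gene, so regulatory / intergenic variants drop out of the BSR layer
  set.seed(stage_seed(seed, "rna_depths"))
  cls_mean <- function(cl) rowMeans(
    expression$counts[, classes == cl, drop = FALSE])
  w_g <- rna_depth_weights(pop, genes, cls_mean("green"))
  w_p <- rna_depth_weights(pop, genes, cls_mean("purple"))
  rna_g <- simulate_bulk_depths(pop, ext$green, design$lambda_rna,
                                design$error_rate, expression = w_g)
  rna_p <- simulate_bulk_depths(pop, ext$purple, design$lambda_rna,
                                design$error_rate, expression = w_p)
  vt_rna <- variant_table(rna_g, rna_p, c("RGP", "RPP"))

  causal_marker <- cross$markers[cross$causal_idx, ]
  truth <- list(causal_chrom = causal_marker$chrom,
                causal_pos = causal_marker$pos_bp,
                causal_gene = expression$truth$causal_gene,
                planted_degs = expression$truth$planted)
  list(pop = pop, extremes = ext, pools = pools, classes = classes,
       genes = genes, vt_dna = vt_dna, vt_rna = vt_rna,
       expression = expression, truth = truth)
}

#' ED mapping of one variant layer: profile, regions, genes
#'
#' By default the calling threshold is the simulated no-QTL genome-wide
#' excursion level from [ed_null_threshold()] (needs `bulk_size`); set
#' `rule = "median_sd"` for the classical median + `n_sd` SD rule.
#'
#' @param vt A `variant_table`.
#' @param genes Gene models.
#' @param k ED power (default 4).
#' @param min_depth Per-pool depth filter (default 10).
#' @param window_bp Smoothing window (default 6 Mb).
#' @param rule Threshold rule: `"null_sim"` (default) or `"median_sd"`.
#' @param bulk_size Individuals per bulk for the simulated null.
#' @param n_sd SD multiplier for the `"median_sd"` rule.
#' @return List: `profile` (smoothed), `intervals`, `intervals_by_class`,
#'   `genes` (ids overlapped by any interval), `threshold`.
#' @export
run_bsa <- function(vt, genes, k = 4, min_depth = 10, window_bp = 6e6,
                    rule = c("null_sim", "median_sd"), bulk_size = 15,
                    n_sd = 3) {
  rule <- match.arg(rule)
  prof <- smooth_profile(ed_profile(vt, k = k, min_depth = min_depth),
                         window_bp = window_bp)
  thr <- if (rule == "null_sim")
    ed_null_threshold(vt, bulk_size = bulk_size, k = k,
                      min_depth = min_depth, window_bp = window_bp)
  else NULL
  iv <- call_regions(prof, n_sd = n_sd, threshold = thr)
  by_class <- lapply(c(SNP = "SNP", InDel = "InDel"), function(cl)
    suppressWarnings(call_regions(prof, n_sd = n_sd, vclass = cl,
                                  threshold = thr)))
  list(profile = prof, intervals = iv, intervals_by_class = by_class,
       genes = genes_in_regions(iv, genes), threshold = attr(iv, "threshold"))
}

#' Run the full synthetic analysis chain
#'
#' simulate -> ED mapping of the DNA and RNA layers -> DE calling ->
#' three-way integration -> recovery report against the planted truth.
#' When `out_dir` is given, all artifacts are written (VCF, GFF3, BED,
#' TSV, JSON) together with a manifest listing parameters, seeds and a
#' content hash per file.
#'
#' @param seed Global seed.
#' @param out_dir Optional output directory.
#' @param cross,model,design,expr Stage configurations.
#' @param k,min_depth,window_bp,n_sd ED-layer knobs (see [run_bsa()]).
#' @param rule ED threshold rule passed to [run_bsa()].
#' @param lfc_min,p_max DEG thresholds (strict inequalities).
#' @return List: simulation, `bsa`, `bsr`, `de`, `degs`, `venn`,
#'   `recovery` (a recovery report), and `manifest` when writing.
#' @export
run_full <- function(seed = 1, out_dir = NULL,
                     cross = cross_config(),
                     model = phenotype_model(),
                     design = bulk_design(),
                     expr = expr_config(),
                     k = 4, min_depth = 10, window_bp = 6e6, n_sd = 3,
                     rule = c("null_sim", "median_sd"),
                     lfc_min = 1, p_max = 0.05) {
  rule <- match.arg(rule)
  sim <- run_simulation(seed, cross, model, design, expr)
  set.seed(stage_seed(seed, "ed_threshold"))
  bsa <- run_bsa(sim$vt_dna, sim$genes, k, min_depth, window_bp,
                 rule = rule, bulk_size = design$k, n_sd = n_sd)
  bsr <- run_bsa(sim$vt_rna, sim$genes, k, min_depth, window_bp,
                 rule = rule, bulk_size = design$k, n_sd = n_sd)

  norm <- normalize_counts(sim$expression$counts)
  de <- de_test(norm$normalized, sim$classes)
  degs <- filter_degs(de, lfc_min = lfc_min, p_max = p_max)
  venn <- venn_partition(bsa$genes, bsr$genes, degs$gene_id,
                         names = c("BSA", "BSR", "DEG"))
  recovery <- recovery_report(sim$truth, bsa, venn, degs)

  res <- list(sim = sim, bsa = bsa, bsr = bsr, de = de, degs = degs,
              venn = venn, normalized = norm, recovery = recovery)
  if (!is.null(out_dir)) {
    res$manifest <- write_run_outputs(res, out_dir, seed = seed,
                                      params = list(
                                        k = k, min_depth = min_depth,
                                        window_bp = window_bp,
                                        n_sd = n_sd, lfc_min = lfc_min,
                                        p_max = p_max))
  }
  res
}

#' Recovery report against the planted truth
#'
#' @param truth Truth list from [run_simulation()].
#' @param bsa Result of [run_bsa()] on the DNA layer.
#' @param venn `venn_partition` of BSA/BSR/DEG gene sets.
#' @param degs DEG table from [filter_degs()].
#' @return List: `locus_in_top_interval`, `locus_in_any_interval`,
#'   `peak_distance_bp`,
#'   `deg_precision`, `deg_recall`, `causal_in_triple`.
#' @export
recovery_report <- function(truth, bsa, venn, degs) {
  iv <- bsa$intervals
  if (nrow(iv)) {
    top <- iv[which.max(iv$peak_smoothed), ]
    covered <- top$chrom == truth$causal_chrom &&
      truth$causal_pos > top$start && truth$causal_pos <= top$end
    dist <- if (top$chrom == truth$causal_chrom)
      abs(top$peak_pos - truth$causal_pos) else Inf
    any_cover <- any(iv$chrom == truth$causal_chrom &
                       truth$causal_pos > iv$start &
                       truth$causal_pos <= iv$end)
  } else {
    covered <- FALSE
    dist <- Inf
    any_cover <- FALSE
  }
  planted <- truth$planted_degs$gene_id
  called <- degs$gene_id
  tp <- length(intersect(called, c(planted, truth$causal_gene)))
  list(locus_in_top_interval = covered,
       locus_in_any_interval = any_cover,
       peak_distance_bp = dist,
       deg_precision = if (length(called)) tp / length(called) else NA,
       deg_recall = if (length(planted))
         length(intersect(called, planted)) / length(planted) else NA,
       causal_in_triple = truth$causal_gene %in% venn$regions$ABC)
}

#' Write all run artifacts plus a hashed manifest
#' @keywords internal
write_run_outputs <- function(res, out_dir, seed, params) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  chrlen <- stats::setNames(
    as.integer(res$sim$pop$config$chromosomes$length_cM * 1e6 + 1e6),
    res$sim$pop$config$chromosomes$name)
  f <- function(name) file.path(out_dir, name)
  write_variant_vcf(res$sim$vt_dna, f("bsa_pools.vcf"), chrlen)
  write_variant_vcf(res$sim$vt_rna, f("bsr_pools.vcf"), chrlen)
  write_gene_gff3(res$sim$genes, f("genes.gff3"))
  write_counts_tsv(res$sim$expression$counts, f("counts.tsv"))
  write_intervals_bed(res$bsa$intervals, f("bsa_intervals.bed"))
  write_intervals_bed(res$bsr$intervals, f("bsr_intervals.bed"))
  utils::write.table(res$de, f("de_results.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(res$degs, f("degs.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ed_tab <- res$bsa$profile
  utils::write.table(ed_tab, f("bsa_ed_profile.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(causal_chrom = res$sim$truth$causal_chrom,
         causal_pos = res$sim$truth$causal_pos,
         causal_gene = res$sim$truth$causal_gene,
         planted_degs = res$sim$truth$planted_degs),
    f("truth.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(lapply(res$venn$regions, as.character),
                       f("venn.json"), auto_unbox = FALSE)
  jsonlite::write_json(res$recovery, f("recovery.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- list.files(out_dir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(seed = seed, params = params,
                   package_version =
                     as.character(utils::packageVersion("purplemap")),
                   files = lapply(stats::setNames(files, basename(files)),
                                  function(x)
                                    unname(tools::md5sum(x))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}
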