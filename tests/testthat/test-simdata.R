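test_that("simulate_cross produces the configured population", {
  pop <- simulate_cross(cross_config(n_offspring = 127), seed = 1)
  expect_equal(nrow(pop$genotype), 127)
  expect_true(all(pop$genotype %in% 0:1))  # pseudo-testcross dosages
})

test_that("cross_config validates its inputs", {
  expect_error(cross_config(n_offspring = 1), "at least 2")
  expect_error(cross_config(causal_chrom = "chrX"), "undeclared")
  expect_error(cross_config(causal_chrom = "chr1", causal_cM = 999),
               "outside")
  bad <- data.frame(name = "chr1", length_cM = 0, n_markers = 5)
  expect_error(cross_config(chromosomes = bad), "zero-length")
})

test_that("markers 0 cM apart never recombine; Haldane closed form holds", {
  # two markers at identical map position: r(0) = 0
  cfg <- cross_config(
    n_offspring = 200,
    chromosomes = data.frame(name = "chr1", length_cM = 10, n_markers = 2),
    causal_chrom = "chr1", causal_cM = 5)
  cfg$markers$pos_cM <- c(5, 5 + 1e-12)
  pop <- simulate_cross(cfg, seed = 3)
  expect_equal(pop$genotype[, 1], pop$genotype[, 2])

  # markers 50 cM apart: recombinant fraction ~ (1 - exp(-1)) / 2
  cfg2 <- cross_config(
    n_offspring = 10000,
    chromosomes = data.frame(name = "chr1", length_cM = 50, n_markers = 2),
    causal_chrom = "chr1", causal_cM = 25)
  cfg2$markers$pos_cM <- c(0.001, 50)
  pop2 <- simulate_cross(cfg2, seed = 4)
  rf <- mean(pop2$genotype[, 1] != pop2$genotype[, 2])
  expected <- haldane_r(50 - 0.001)
  expect_equal(expected, (1 - exp(-1)) / 2, tolerance = 1e-4)
  expect_lt(abs(rf - expected), 3 * sqrt(expected * (1 - expected) / 1e4))
})

test_that("Haldane consistency across a marker ladder", {
  # simulated recombinant fraction matches the map function at several
  # distances on one long chromosome
  cfg <- cross_config(
    n_offspring = 8000,
    chromosomes = data.frame(name = "chr1", length_cM = 80,
                             n_markers = 9),
    causal_chrom = "chr1", causal_cM = 40)
  pop <- simulate_cross(cfg, seed = 5)
  pos <- cfg$markers$pos_cM
  for (j in c(2, 5, 9)) {
    d <- pos[j] - pos[1]
    rf <- mean(pop$genotype[, 1] != pop$genotype[, j])
    r <- haldane_r(d)
    expect_lt(abs(rf - r), 4 * sqrt(r * (1 - r) / 8000))
  }
})

test_that("seeded determinism: identical seeds give identical output", {
  a <- simulate_cross(cross_config(), seed = 42)
  b <- simulate_cross(cross_config(), seed = 42)
  expect_identical(a$genotype, b$genotype)
})

test_that("assign_phenotypes is deterministic in the noiseless limit", {
  cfg <- tiny_cross()
  pop <- simulate_cross(cfg, seed = 6)
  model <- phenotype_model(mu_aa = -1, mu_Aa = 4, sigma = 0)
  pop <- assign_phenotypes(pop, model)
  dos <- pop$genotype[, cfg$causal_idx]
  expect_true(all(pop$color_class[dos == 0] == "green"))
  expect_true(all(pop$color_class[dos == 1] == "dark_purple"))
  expect_error(assign_phenotypes(pop, model), "already assigned")
})

test_that("phenotype_model rejects bad configurations", {
  expect_error(phenotype_model(thresholds = c(1, 0.5, 2, 3)),
               "increasing")
  expect_error(phenotype_model(mu_aa = 2, mu_Aa = 1), "dominant")
})

test_that("select_extremes ranks by liability with id tie-break", {
  cfg <- tiny_cross()
  pop <- simulate_cross(cfg, seed = 8)
  pop <- assign_phenotypes(pop, phenotype_model())
  ext <- select_extremes(pop, k = 15)
  expect_length(c(ext$green, ext$purple), 30)
  expect_true(max(pop$liability[ext$green]) <=
                min(pop$liability[setdiff(names(pop$liability),
                                          ext$green)]))
  # k = 1 picks the min and max
  e1 <- select_extremes(pop, k = 1)
  expect_equal(e1$green, names(which.min(pop$liability)))
  expect_equal(e1$purple, names(which.max(pop$liability)))
  expect_error(select_extremes(pop, k = 25), "cannot select")

  # tied liabilities resolve by id, stably
  pop$liability[] <- 1
  t1 <- select_extremes(pop, k = 3)
  t2 <- select_extremes(pop, k = 3)
  expect_identical(t1, t2)
  expect_equal(t1$green, sort(names(pop$liability))[1:3])
})

test_that("form_pools partitions the group into contiguous pools", {
  grp <- sprintf("F1_%02d", 1:15)
  pools <- form_pools(grp, 5, "GP")
  expect_length(pools, 3)
  expect_setequal(unlist(pools), grp)
  expect_equal(sum(duplicated(unlist(pools))), 0)
  expect_equal(pools$GP1, grp[1:5])
  expect_length(form_pools(grp, 15), 1)
  expect_error(form_pools(grp, 4), "divisible")
  # six materials from 15 + 15 extremes at 5 per tube
  both <- c(form_pools(grp, 5, "GP"),
            form_pools(sprintf("F1_%02d", 16:30), 5, "PP"))
  expect_length(both, 6)
})

test_that("simulate_bulk_depths follows its noise model", {
  cfg <- tiny_cross()
  pop <- simulate_cross(cfg, seed = 9)
  # error-free reads from a bulk fixed for the alt allele are all alt
  pop$genotype[, ] <- 1L   # dosage 1 => f = 0.5 ... need fixed dosage 2
  pop2 <- pop
  pop2$genotype[, ] <- 2L
  d <- simulate_bulk_depths(pop2, rownames(pop2$genotype)[1:5],
                            lambda = 30, error_rate = 0)
  expect_equal(d$alt, d$depth)
  expect_error(simulate_bulk_depths(pop, rownames(pop$genotype)[1],
                                    lambda = 0), "positive")
  expect_error(simulate_bulk_depths(pop, character(0)), "empty")
})

test_that("alt fraction concentrates at f = 0.5 under high depth", {
  cfg <- tiny_cross(n = 10)
  pop <- simulate_cross(cfg, seed = 10)
  pop$genotype[, ] <- 1L   # every member heterozygous: f = 0.5
  set.seed(11)
  d <- simulate_bulk_depths(pop, rownames(pop$genotype),
                            lambda = 10000, error_rate = 0)
  frac <- d$alt / d$depth
  expect_true(all(abs(frac - 0.5) < 3 * sqrt(0.25 / d$depth)))
})

test_that("intergenic markers get zero RNA-layer depth", {
  cfg <- tiny_cross()
  pop <- simulate_cross(cfg, seed = 12)
  w <- rep(1, nrow(cfg$markers))
  names(w) <- cfg$markers$id
  w[3] <- 0   # marker outside any expressed gene
  d <- simulate_bulk_depths(pop, rownames(pop$genotype)[1:5],
                            lambda = 50, expression = w)
  expect_equal(d$depth[3], 0)
  expect_equal(d$alt[3], 0)
})

test_that("simulate_expression plants the configured structure", {
  cfg <- tiny_cross(n = 30)
  pop <- simulate_cross(cfg, seed = 13)
  pop <- assign_phenotypes(pop, phenotype_model())
  genes <- make_gene_models(cfg)
  ids <- rownames(pop$genotype)
  pools <- c(form_pools(ids[1:15], 5, "GP"), form_pools(ids[16:30], 5, "PP"))
  classes <- setNames(c(rep("green", 3), rep("purple", 3)), names(pools))

  # deg_fraction = 0: no planted DEGs, class means equal in expectation
  set.seed(14)
  e0 <- simulate_expression(pop, pools, classes, genes,
                            expr_config(deg_fraction = 0, causal_lfc = 0))
  expect_equal(nrow(e0$truth$planted), 0)

  # near-Poisson, fold change 4 at the causal gene when purple pools are
  # fixed for the causal allele
  pop$genotype[16:30, cfg$causal_idx] <- 1L
  pop$genotype[1:15, cfg$causal_idx] <- 0L
  set.seed(15)
  e1 <- simulate_expression(pop, pools, classes, genes,
                            expr_config(deg_fraction = 0, causal_lfc = 2,
                                        dispersion = 1e-4,
                                        causal_base_mean = 5000))
  cg <- e1$truth$causal_gene
  ratio <- mean(e1$counts[cg, 4:6]) / mean(e1$counts[cg, 1:3])
  expect_equal(ratio, 4, tolerance = 0.05)

  expect_error(
    simulate_expression(pop, pools[c(1, 4)],
                        classes[c(1, 4)], genes, expr_config()),
    "2 pools per class")
})

test_that("make_gene_models tags the causal gene and spans markers", {
  cfg <- tiny_cross()
  genes <- make_gene_models(cfg)
  cg <- attr(genes, "causal_gene")
  expect_false(is.na(cg))
  row <- genes[genes$gene_id == cg, ]
  causal_bp <- cfg$markers$pos_bp[cfg$causal_idx]
  expect_true(row$start <= causal_bp && causal_bp <= row$end)
  expect_true(all(genes$start <= genes$end))
})

test_that("promoter fixture satisfies its invariants", {
  fx <- make_promoter_fixture(seed = 1)
  expect_equal(nchar(fx$long) - nchar(fx$short), 181)
  # inserted block occupies the printed window exactly
  expect_equal(fx$insert_coords, c(-332L, -152L))
  expect_equal(diff(fx$insert_coords) + 1L, 181L)
  # flanking sequence is shared outside the insertion
  expect_equal(substr(fx$long, 1, 349), substr(fx$short, 1, 349))
  expect_equal(substring(fx$long, 350 + 181), substring(fx$short, 350))

  fx0 <- make_promoter_fixture(insertion_length = 0, seed = 2)
  expect_identical(fx0$short, fx0$long)

  expect_error(make_promoter_fixture(insertion_length = 500), "fit")
})

test_that("in-silico PCR on 20 random fixtures recovers the insertion", {
  for (i in 1:20) {
    len <- sample(c(50, 100, 181), 1)
    fx <- make_promoter_fixture(insertion_length = len, seed = 100 + i)
    a_short <- insilico_pcr(fx$short, fx$fwd, fx$rev)
    a_long <- insilico_pcr(fx$long, fx$fwd, fx$rev)
    expect_length(a_short, 1)
    expect_length(a_long, 1)
    expect_equal(a_long - a_short, len)
  }
})
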