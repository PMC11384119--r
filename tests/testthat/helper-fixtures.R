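# Shared fixtures: all built in code at test time.

# tiny cross: 2 chromosomes, few markers, causal mid-chr1
tiny_cross <- function(n = 40, n_markers = 11, len = 50) {
  cross_config(n_offspring = n,
               chromosomes = data.frame(name = c("chr1", "chr2"),
                                        length_cM = len,
                                        n_markers = n_markers),
               causal_chrom = "chr1", causal_cM = len / 2)
}

# hand-made two-pool variant table
mk_variant_table <- function(chrom, pos, ref1, alt1, ref2, alt2,
                             vclass = NULL) {
  if (is.null(vclass)) vclass <- rep("SNP", length(pos))
  b1 <- data.frame(chrom = chrom, pos = pos, vclass = vclass,
                   depth = ref1 + alt1, alt = alt1)
  b2 <- data.frame(chrom = chrom, pos = pos, vclass = vclass,
                   depth = ref2 + alt2, alt = alt2)
  variant_table(b1, b2)
}

# population whose phenotype ignores genotype: ED null world
null_phenotyped_pop <- function(seed) {
  cfg <- cross_config()
  pop <- simulate_cross(cfg, seed = seed)
  model <- phenotype_model(mu_aa = 0, mu_Aa = 1e-9, sigma = 1,
                           thresholds = c(-0.573101, 0.8, 1.9, 2.993587))
  assign_phenotypes(pop, model)
}
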