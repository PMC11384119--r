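#' Default chromosome layout for the synthetic genome
#'
#' Five chromosomes of 100 cM carrying 100 evenly spaced markers each
#' (1 marker per cM, a typical BSA panel density).  Physical coordinates use
#' the fixed synthetic scale 1 cM = 1 Mb.
#'
#' @return A data.frame with columns `name`, `length_cM`, `n_markers`.
#' @export
default_chromosomes <- function() {
  data.frame(name = paste0("chr", 1:5),
             length_cM = 100,
             n_markers = 100L,
             stringsAsFactors = FALSE)
}

#' Configuration of the simulated F1 cross
#'
#' The cross is a pseudo-testcross: the purple parent is heterozygous
#' (alt/ref, coupling phase) at every marker including the causal locus,
#' the green parent is homozygous reference.  Offspring therefore carry
#' alt-allele dosage 0 or 1 at every marker, segregating 1:1.
#'
#' @param n_offspring Number of F1 individuals (default 127).
#' @param chromosomes data.frame as returned by [default_chromosomes()].
#' @param causal_chrom,causal_cM Chromosome and map position (cM) of the
#'   dominant purple locus.
#' @param genic_fraction Fraction of markers lying inside a gene model
#'   (the causal marker is always genic); intergenic markers receive zero
#'   RNA-layer depth.
#' @param indel_every Every `indel_every`-th marker is emitted as an InDel,
#'   the rest as SNPs.
#' @return An object of class `cross_config`.
#' @export
cross_config <- function(n_offspring = 127L,
                         chromosomes = default_chromosomes(),
                         causal_chrom = "chr3",
                         causal_cM = 50,
                         genic_fraction = 0.8,
                         indel_every = 10L) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length_cM", "n_markers") %in% names(chromosomes)))
  if (n_offspring < 2)
    stop("n_offspring must be at least 2", call. = FALSE)
  if (any(chromosomes$length_cM <= 0))
    stop("zero-length chromosome in configuration", call. = FALSE)
  if (!causal_chrom %in% chromosomes$name)
    stop("causal locus lies on undeclared chromosome: ", causal_chrom,
         call. = FALSE)
  len <- chromosomes$length_cM[chromosomes$name == causal_chrom]
  if (causal_cM < 0 || causal_cM > len)
    stop("causal locus outside chromosome ", causal_chrom, call. = FALSE)

  markers <- do.call(rbind, lapply(seq_len(nrow(chromosomes)), function(i) {
    ch <- chromosomes[i, ]
    pos <- seq(1, ch$length_cM, length.out = ch$n_markers)
    if (any(diff(pos) <= 0))
      stop("marker positions must be strictly increasing on ", ch$name,
           call. = FALSE)
    data.frame(chrom = ch$name, pos_cM = pos, stringsAsFactors = FALSE)
  }))
  markers$pos_bp <- as.integer(round(markers$pos_cM * 1e6))
  markers$id <- sprintf("M%04d", seq_len(nrow(markers)))
  markers$vclass <- ifelse(seq_len(nrow(markers)) %% indel_every == 0,
                           "InDel", "SNP")
  # deterministic genic pattern: drop every k-th marker from gene space
  k <- max(2L, round(1 / (1 - genic_fraction)))
  markers$genic <- seq_len(nrow(markers)) %% k != 0

  # causal marker = nearest marker to the causal map position, forced genic
  on_chr <- which(markers$chrom == causal_chrom)
  causal_idx <- on_chr[which.min(abs(markers$pos_cM[on_chr] - causal_cM))]
  markers$genic[causal_idx] <- TRUE

  structure(list(n_offspring = as.integer(n_offspring),
                 chromosomes = chromosomes,
                 causal_chrom = causal_chrom,
                 causal_cM = causal_cM,
                 causal_idx = causal_idx,
                 markers = markers),
            class = "cross_config")
}

#' Liability threshold model for the leaf-colour gradient
#'
#' Leaf colour is modelled as a latent liability: genotype mean (`mu_aa`
#' for homozygous-reference, `mu_Aa` for carriers of the dominant purple
#' allele) plus Normal(0, `sigma`) noise, binned by four ordered thresholds
#' into five classes: green, three transition grades, dark purple.
#'
#' The default outer thresholds are calibrated constants: with means 0/3 and
#' sigma 1 they solve `P(green) = 18/127` and `P(dark purple) = 32/127`
#' under 1:1 causal segregation, so a population of 127 carries on average
#' 18 totally green and 32 dark-purple individuals.
#'
#' @param mu_aa,mu_Aa Liability means of the two causal genotypes
#'   (`mu_Aa > mu_aa`: purple is dominant).
#' @param sigma Liability standard deviation.
#' @param thresholds Four strictly increasing cut points.
#' @return An object of class `phenotype_model`.
#' @export
phenotype_model <- function(mu_aa = 0, mu_Aa = 3, sigma = 1,
                            thresholds = c(-0.573101, 0.8, 1.9, 2.993587)) {
  if (length(thresholds) != 4 || any(diff(thresholds) <= 0))
    stop("thresholds must be 4 strictly increasing cut points", call. = FALSE)
  if (mu_Aa <= mu_aa)
    stop("mu_Aa must exceed mu_aa (purple is dominant)", call. = FALSE)
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  structure(list(mu_aa = mu_aa, mu_Aa = mu_Aa, sigma = sigma,
                 thresholds = thresholds),
            class = "phenotype_model")
}

#' Colour class labels, ordered green to dark purple
#' @keywords internal
color_levels <- function() {
  c("green", "slight1", "slight2", "slight3", "dark_purple")
}

#' Bulk and sequencing design
#'
#' @param k Tail size per colour class (default 15: the 15 greenest and 15
#'   most purple individuals form the two bulks).
#' @param pool_size RNA pool size (default 5, giving three pools per bulk).
#' @param lambda_dna Mean per-marker read depth of the DNA (BSA) layer.
#' @param lambda_rna Mean per-marker read depth of the RNA (BSR) layer at a
#'   gene of average expression.
#' @param error_rate Per-read sequencing error rate.
#' @return An object of class `bulk_design`.
#' @export
bulk_design <- function(k = 15L, pool_size = 5L,
                        lambda_dna = 50, lambda_rna = 50,
                        error_rate = 0.001) {
  if (lambda_dna <= 0 || lambda_rna <= 0)
    stop("mean depth lambda must be positive", call. = FALSE)
  if (error_rate < 0 || error_rate >= 0.5)
    stop("error_rate must lie in [0, 0.5)", call. = FALSE)
  if (k %% pool_size != 0)
    stop("k must be divisible by pool_size", call. = FALSE)
  structure(list(k = as.integer(k), pool_size = as.integer(pool_size),
                 lambda_dna = lambda_dna, lambda_rna = lambda_rna,
                 error_rate = error_rate),
            class = "bulk_design")
}

#' Expression-layer configuration
#'
#' Null genes share a negative-binomial mean across colour classes; a
#' `deg_fraction` of genes are planted differentially expressed with
#' log2 fold changes drawn from Normal(`lfc_location`, `lfc_scale`); the
#' causal gene's fold change is tied to the mean causal-allele dosage of
#' each pool's members, so purple pools express it ~2^`causal_lfc`-fold
#' higher than green pools.
#'
#' @param deg_fraction Fraction of non-causal genes planted as DEGs.
#' @param lfc_location,lfc_scale Location/scale of the planted log2FC draw.
#' @param dispersion Negative-binomial dispersion (size = 1/dispersion).
#' @param causal_lfc log2 fold change per unit causal dosage at the causal
#'   gene.
#' @param base_meanlog,base_sdlog Log-normal parameters of per-gene base
#'   means.
#' @param causal_base_mean Fixed base mean of the causal gene (kept solidly
#'   expressed so the BSR layer can see its variants).
#' @return An object of class `expr_config`.
#' @export
expr_config <- function(deg_fraction = 0.05,
                        lfc_location = 0, lfc_scale = 2,
                        dispersion = 0.05,
                        causal_lfc = 2,
                        base_meanlog = log(100), base_sdlog = 1,
                        causal_base_mean = 200) {
  if (deg_fraction < 0 || deg_fraction > 1)
    stop("deg_fraction must lie in [0, 1]", call. = FALSE)
  if (dispersion <= 0) stop("dispersion must be positive", call. = FALSE)
  structure(list(deg_fraction = deg_fraction,
                 lfc_location = lfc_location, lfc_scale = lfc_scale,
                 dispersion = dispersion, causal_lfc = causal_lfc,
                 base_meanlog = base_meanlog, base_sdlog = base_sdlog,
                 causal_base_mean = causal_base_mean),
            class = "expr_config")
}
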