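#' Write a two-pool variant table as VCF
#'
#' Emits a minimal VCF 4.2 file with two samples and per-sample AD
#' (allelic depth) fields.  SNPs are written as A>G, InDels as A>AT, so
#' the variant class survives a round trip.
#'
#' @param vt A `variant_table`.
#' @param path Output path.
#' @param chrom_lengths Optional named vector of contig lengths for the
#'   header.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(vt, path, chrom_lengths = NULL) {
  pools <- attr(vt, "pool_names") %||% c("POOL1", "POOL2")
  hdr <- c("##fileformat=VCFv4.2",
           "##source=purplemap")
  if (!is.null(chrom_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(chrom_lengths), chrom_lengths))
  hdr <- c(hdr,
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
           "Description=\"Allelic depths\">"),
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", pools), collapse = "\t"))
  ref <- ifelse(vt$vclass == "InDel", "A", "A")
  alt <- ifelse(vt$vclass == "InDel", "AT", "G")
  body <- paste(vt$chrom, sprintf("%d", as.integer(vt$pos)), ".",
                ref, alt, ".", "PASS", ".",
                "AD:DP",
                paste0(vt$ref1, ",", vt$alt1, ":", vt$ref1 + vt$alt1),
                paste0(vt$ref2, ",", vt$alt2, ":", vt$ref2 + vt$alt2),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a two-sample VCF with AD fields into a variant table
#'
#' Parsed with VariantAnnotation; the two samples become pool 1 and
#' pool 2 in column order.  Variants whose REF/ALT lengths differ are
#' classed as InDels, the rest as SNPs.
#'
#' @param path VCF path.
#' @return A `variant_table`.
#' @export
read_variant_vcf <- function(path) {
  v <- VariantAnnotation::readVcf(path)
  if (ncol(v) != 2)
    stop("expected exactly 2 samples (pools), found ", ncol(v),
         call. = FALSE)
  rr <- SummarizedExperiment::rowRanges(v)
  ad <- VariantAnnotation::geno(v)$AD
  get2 <- function(j) {
    col <- ad[, j]
    if (is.list(col)) t(vapply(col, function(x) x[1:2], numeric(2)))
    else matrix(ad[, j, 1:2], ncol = 2)
  }
  a1 <- get2(1); a2 <- get2(2)
  ref <- as.character(rr$REF)
  alt <- vapply(rr$ALT, function(a) as.character(a)[1], character(1))
  vt <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    vclass = ifelse(nchar(ref) != nchar(alt), "InDel", "SNP"),
    ref1 = a1[, 1], alt1 = a1[, 2],
    ref2 = a2[, 1], alt2 = a2[, 2],
    stringsAsFactors = FALSE)
  rownames(vt) <- NULL
  attr(vt, "pool_names") <- colnames(v)
  class(vt) <- c("variant_table", "data.frame")
  vt
}

#' Write gene models as GFF3
#'
#' @param genes data.frame (`gene_id`, `chrom`, `start`, `end`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end),
    strand = "+", type = "gene", ID = genes$gene_id)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' @param path GFF3 path.
#' @return data.frame (`gene_id`, `chrom`, `start`, `end`).
#' @export
read_gene_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  if (any(GenomicRanges::start(gr) > GenomicRanges::end(gr)))
    stop("GFF3 feature with end < start", call. = FALSE)
  data.frame(gene_id = gr$ID,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}

#' Write candidate intervals as BED (0-based half-open)
#' @param intervals data.frame from [call_regions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals_bed <- function(intervals, path) {
  lines <- sprintf("%s\t%d\t%d\tpeak=%d;smoothed=%.6g",
                   intervals$chrom, intervals$start, intervals$end,
                   intervals$peak_pos, intervals$peak_smoothed)
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a counts matrix as TSV
#'
#' @param counts Integer matrix, genes x samples.
#' @param path TSV path.
#' @return `path` / the counts matrix.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  bad <- which(m < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("negative count at line ", bad[1, 1] + 1L, call. = FALSE)
  storage.mode(m) <- "integer"
  m
}

#' Write the promoter fixture as FASTA
#'
#' Four records: short allele, long allele, forward and reverse primer.
#'
#' @param fixture A `promoter_fixture`.
#' @param path FASTA path.
#' @return `path`, invisibly.
#' @export
write_fixture_fasta <- function(fixture, path) {
  ss <- Biostrings::DNAStringSet(c(promoter_short = fixture$short,
                                   promoter_long = fixture$long,
                                   primer_fwd = fixture$fwd,
                                   primer_rev = fixture$rev))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
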