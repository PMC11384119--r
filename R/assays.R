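#' Spectrophotometric anthocyanin content
#'
#' content = (A x V x n x 465.2) / (epsilon x m) with
#' A = (A530 - A620) - 0.1 (A650 - A620).  The molar extinction
#' coefficient epsilon has no shipped default and must be supplied by the
#' user; without a unit-bearing epsilon the result is in formula units.
#' Note the source protocol reports measuring at 520 nm while the formula
#' uses an A530 slot; readings taken at 520 nm go into the `a530`
#' argument.
#'
#' @param a530,a620,a650 Absorbance readings (A530 slot accepts the
#'   520-nm measurement; see Details).
#' @param volume Extract volume V (ml).
#' @param dilution Dilution factor n.
#' @param epsilon Molar extinction coefficient (required, > 0).
#' @param mass Sample mass m (g).
#' @return Content value(s); a negative corrected absorbance is returned
#'   as-is with a warning.
#' @export
anthocyanin_content <- function(a530, a620, a650, volume, dilution,
                                epsilon, mass) {
  if (any(c(volume, dilution, epsilon, mass) <= 0))
    stop("volume, dilution, epsilon and mass must all be positive",
         call. = FALSE)
  if (any(c(a530, a620, a650) < 0))
    stop("absorbances must be non-negative", call. = FALSE)
  A <- (a530 - a620) - 0.1 * (a650 - a620)
  if (any(A < 0))
    warning("negative corrected absorbance; content reported as-is")
  (A * volume * dilution * 465.2) / (epsilon * mass)
}

#' Relative expression by the 2^-ddCt method
#'
#' ddCt = (Ct_target,sample - Ct_ref,sample) -
#' (Ct_target,calibrator - Ct_ref,calibrator), from replicate-mean Ct
#' values, so the calibrator's relative expression is exactly 1 for every
#' gene.  Replicate spread is summarized as the standard deviation of
#' per-replicate 2^-ddCt values (paired by replicate index within each
#' sample).
#'
#' @param ct data.frame with columns `sample`, `gene`, `ct` (one row per
#'   technical replicate).
#' @param reference_gene Internal-control gene (must be measured in every
#'   sample).
#' @param calibrator Calibrator sample name.
#' @return data.frame: `sample`, `gene`, `rel_expr` (2^-ddCt from mean
#'   Cts), `sd` (across replicates), `n_rep`.
#' @export
relative_expression <- function(ct, reference_gene, calibrator) {
  stopifnot(all(c("sample", "gene", "ct") %in% names(ct)))
  if (any(ct$ct <= 0)) stop("Ct values must be positive", call. = FALSE)
  samples <- unique(ct$sample)
  ref_missing <- samples[!vapply(samples, function(s)
    any(ct$sample == s & ct$gene == reference_gene), logical(1))]
  if (length(ref_missing))
    stop("reference gene missing in sample(s): ",
         paste(ref_missing, collapse = ", "), call. = FALSE)
  if (!calibrator %in% samples)
    stop("calibrator sample not present: ", calibrator, call. = FALSE)

  mean_ct <- stats::aggregate(ct ~ sample + gene, ct, mean)
  get_mean <- function(s, g)
    mean_ct$ct[mean_ct$sample == s & mean_ct$gene == g]
  genes <- setdiff(unique(ct$gene), reference_gene)
  out <- do.call(rbind, lapply(samples, function(s) {
    do.call(rbind, lapply(genes, function(g) {
      tgt <- ct$ct[ct$sample == s & ct$gene == g]
      if (!length(tgt)) return(NULL)
      dct <- get_mean(s, g) - get_mean(s, reference_gene)
      dct_cal <- get_mean(calibrator, g) -
        get_mean(calibrator, reference_gene)
      ddct <- dct - dct_cal
      # replicate-level spread around the sample's mean reference Ct
      rep_ddct <- (tgt - get_mean(s, reference_gene)) - dct_cal
      data.frame(sample = s, gene = g, rel_expr = 2^(-ddct),
                 sd = stats::sd(2^(-rep_ddct)), n_rep = length(tgt),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' GC fraction of a nucleotide sequence
#' @keywords internal
gc_fraction <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  if (!all(chars %in% c("A", "C", "G", "T")))
    stop("non-ACGT character in sequence", call. = FALSE)
  mean(chars %in% c("G", "C"))
}

#' Filter antisense-oligo candidates
#'
#' Selection criteria: GC content between 40 and 60 percent inclusive and
#' binding energy at most -8 kcal/mol.  GC is computed from the sequence;
#' binding energy is an externally computed input.
#'
#' @param candidates data.frame with `sequence` and `binding_energy`
#'   (kcal/mol) columns; an optional `id` column is carried through.
#' @param gc_range Inclusive GC bounds (default `c(0.40, 0.60)`).
#' @param energy_max Maximum binding energy (default -8).
#' @return The input with `gc`, `pass` and `reasons` columns.
#' @export
asodn_filter <- function(candidates, gc_range = c(0.40, 0.60),
                         energy_max = -8) {
  stopifnot(all(c("sequence", "binding_energy") %in% names(candidates)))
  gc <- vapply(candidates$sequence, gc_fraction, numeric(1),
               USE.NAMES = FALSE)
  gc_ok <- gc >= gc_range[1] & gc <= gc_range[2]
  en_ok <- candidates$binding_energy <= energy_max
  reasons <- mapply(function(g, e) {
    r <- c(if (!g) "GC out of range", if (!e) "binding energy too high")
    if (length(r)) paste(r, collapse = "; ") else ""
  }, gc_ok, en_ok)
  out <- candidates
  out$gc <- gc
  out$pass <- gc_ok & en_ok
  out$reasons <- unname(reasons)
  out
}

#' Exact-match in-silico PCR
#'
#' Finds exact occurrences of the forward primer on the plus strand and of
#' the reverse-complemented reverse primer downstream, and reports every
#' productive pairing up to `max_len`.  Amplicon length spans both primer
#' sites inclusive.  No site or ambiguous multi-site pairings are reported
#' as zero or multiple amplicons, not as errors.
#'
#' @param template Template sequence (character or DNAString).
#' @param fwd,rev Primer sequences, each written 5'->3' on its own strand;
#'   at least 15 nt.
#' @param max_len Longest amplicon reported (default 5000).
#' @return Integer vector of amplicon lengths (possibly empty).
#' @export
insilico_pcr <- function(template, fwd, rev, max_len = 5000) {
  if (nchar(fwd) < 15 || nchar(rev) < 15)
    stop("primers must be at least 15 nt", call. = FALSE)
  tmpl <- Biostrings::DNAString(as.character(template))
  f_hits <- Biostrings::matchPattern(Biostrings::DNAString(fwd), tmpl)
  r_site <- Biostrings::reverseComplement(Biostrings::DNAString(rev))
  r_hits <- Biostrings::matchPattern(r_site, tmpl)
  if (length(f_hits) == 0 || length(r_hits) == 0) return(integer())
  lens <- integer()
  for (i in seq_along(f_hits)) {
    fs <- Biostrings::start(f_hits)[i]
    for (j in seq_along(r_hits)) {
      re <- Biostrings::end(r_hits)[j]
      len <- re - fs + 1L
      if (re > Biostrings::end(f_hits)[i] && len <= max_len)
        lens <- c(lens, len)
    }
  }
  sort(lens)
}

#' Co-segregation test of an InDel marker with leaf colour
#'
#' Builds the 2x2 table (long band present / absent x purple / green),
#' runs a two-sided Fisher exact test, and reports the two pattern flags
#' the marker assay looks for: every dark-purple individual carries the
#' long band, and every green individual lacks it.
#'
#' @param table data.frame with `band` (`"long_present"` or
#'   `"short_only"`) and `class` columns per individual.
#' @param purple_classes Colour classes counted as purple (default
#'   `"dark_purple"`).
#' @param green_classes Classes counted as green (default `"green"`);
#'   other classes are excluded from the 2x2.
#' @return List: `contingency`, `p` (Fisher two-sided),
#'   `all_purple_long`, `all_green_short`, `n_excluded`.
#' @export
cosegregation_test <- function(table, purple_classes = "dark_purple",
                               green_classes = "green") {
  stopifnot(all(c("band", "class") %in% names(table)))
  stopifnot(all(table$band %in% c("long_present", "short_only")))
  keep <- table$class %in% c(purple_classes, green_classes)
  t2 <- table[keep, , drop = FALSE]
  pheno <- ifelse(t2$class %in% purple_classes, "purple", "green")
  if (length(unique(pheno)) < 2 || min(table(pheno)) < 2)
    stop("need at least 2 individuals in each phenotype group",
         call. = FALSE)
  cont <- base::table(factor(t2$band,
                             levels = c("long_present", "short_only")),
                      factor(pheno, levels = c("purple", "green")))
  fp <- stats::fisher.test(cont, alternative = "two.sided")$p.value
  list(contingency = cont, p = fp,
       all_purple_long = cont["short_only", "purple"] == 0,
       all_green_short = cont["long_present", "green"] == 0,
       n_excluded = sum(!keep))
}

#' Scan a promoter sequence for IUPAC consensus motifs
#'
#' All exact IUPAC matches on both strands.  Hit positions are promoter
#' coordinates: negative, 1-based, with -1 the base immediately 5' of the
#' start codon; the reported position is the 5'-most template base of the
#' hit.
#'
#' @param sequence Promoter sequence ending at the base adjacent to ATG.
#' @param motifs data.frame with `name` and `iupac` columns.
#' @return data.frame: `motif`, `position` (promoter coordinate),
#'   `strand`, `match` (template-strand sequence of the site).
#' @export
scan_cis_elements <- function(sequence, motifs) {
  stopifnot(all(c("name", "iupac") %in% names(motifs)))
  seq_s <- Biostrings::DNAString(as.character(sequence))
  L <- length(seq_s)
  iupac_ok <- function(m)
    all(strsplit(toupper(m), "")[[1]] %in%
          names(Biostrings::IUPAC_CODE_MAP))
  hits <- list()
  for (i in seq_len(nrow(motifs))) {
    m <- toupper(motifs$iupac[i])
    if (!iupac_ok(m))
      stop("invalid IUPAC character in motif ", motifs$name[i],
           call. = FALSE)
    pat <- Biostrings::DNAString(m)
    for (strand in c("+", "-")) {
      p <- if (strand == "+") pat else Biostrings::reverseComplement(pat)
      mt <- Biostrings::matchPattern(p, seq_s, fixed = FALSE)
      if (length(mt))
        hits[[length(hits) + 1]] <- data.frame(
          motif = motifs$name[i],
          position = Biostrings::start(mt) - L - 1L,
          strand = strand,
          match = as.character(mt), stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(motif = character(), position = integer(),
                      strand = character(), match = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out[order(out$position, out$motif), ]
}
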