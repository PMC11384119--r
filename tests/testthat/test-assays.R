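test_that("anthocyanin_content follows the printed formula", {
  # equal absorbances null out the corrected A
  expect_equal(anthocyanin_content(0.3, 0.3, 0.3, 5, 1, 98.2, 0.1), 0)
  # A = (0.5 - 0.1) - 0.1 * (0.2 - 0.1) = 0.39
  val <- anthocyanin_content(0.5, 0.1, 0.2, 1, 1, 1, 1)
  expect_equal(val, 0.39 * 465.2)
  # linear in V and n, inverse in epsilon and m
  base <- anthocyanin_content(0.5, 0.1, 0.2, 5, 2, 100, 0.1)
  expect_equal(anthocyanin_content(0.5, 0.1, 0.2, 10, 2, 100, 0.1),
               2 * base)
  expect_equal(anthocyanin_content(0.5, 0.1, 0.2, 5, 4, 100, 0.1),
               2 * base)
  expect_equal(anthocyanin_content(0.5, 0.1, 0.2, 5, 2, 200, 0.1),
               base / 2)
  expect_equal(anthocyanin_content(0.5, 0.1, 0.2, 5, 2, 100, 0.2),
               base / 2)
  expect_error(anthocyanin_content(0.5, 0.1, 0.2, 5, 2, 0, 0.1),
               "positive")
  expect_warning(anthocyanin_content(0.1, 0.5, 0.1, 5, 2, 100, 0.1),
                 "negative")
})

ct_fixture <- function() {
  # calibrator GP, sample PP; reference gene GAPDH; 3 replicates each
  rbind(
    data.frame(sample = "GP", gene = "GAPDH", ct = c(20, 20, 20)),
    data.frame(sample = "GP", gene = "MYB75", ct = c(26, 26, 26)),
    data.frame(sample = "PP", gene = "GAPDH", ct = c(20, 20, 20)),
    data.frame(sample = "PP", gene = "MYB75", ct = c(24, 24, 24)))
}

test_that("relative_expression implements 2^-ddCt", {
  out <- relative_expression(ct_fixture(), "GAPDH", "GP")
  # calibrator is exactly 1
  expect_equal(out$rel_expr[out$sample == "GP" & out$gene == "MYB75"], 1)
  # ddCt = (24-20) - (26-20) = -2  ->  4.0
  expect_equal(out$rel_expr[out$sample == "PP" & out$gene == "MYB75"], 4)
  expect_equal(out$n_rep[out$sample == "PP" & out$gene == "MYB75"], 3)

  # ddCt = 1 halves expression
  ct <- ct_fixture()
  ct$ct[ct$sample == "PP" & ct$gene == "MYB75"] <- 27
  out2 <- relative_expression(ct, "GAPDH", "GP")
  expect_equal(out2$rel_expr[out2$sample == "PP" & out2$gene == "MYB75"],
               0.5)

  # calibrator stays exactly 1 even with replicate scatter
  ct3 <- ct_fixture()
  ct3$ct <- ct3$ct + rep(c(-0.2, 0, 0.2), 4)
  out3 <- relative_expression(ct3, "GAPDH", "GP")
  expect_equal(out3$rel_expr[out3$sample == "GP" & out3$gene == "MYB75"],
               1)
  expect_gt(out3$sd[out3$sample == "GP" & out3$gene == "MYB75"], 0)

  expect_error(
    relative_expression(ct_fixture()[-(7:9), ], "GAPDH", "GP"),
    "reference gene missing")
  expect_error(relative_expression(ct_fixture(), "GAPDH", "XX"),
               "calibrator")
})

test_that("asodn_filter applies GC and binding-energy criteria", {
  cand <- data.frame(
    id = c("ok", "gc_high", "energy_high", "gc_border"),
    sequence = c("ATGCATGCATGCATGCATGC",       # GC 0.50
                 "GCGCGCGCGCATGCATGCGC",       # GC 0.80
                 "ATGC",                       # GC 0.50, weak binding
                 "ATGCGCGCATATATATATAT"),      # GC 0.30
    binding_energy = c(-9, -10, -7.5, -12))
  out <- asodn_filter(cand)
  expect_equal(out$pass, c(TRUE, FALSE, FALSE, FALSE))
  expect_match(out$reasons[2], "GC")
  expect_match(out$reasons[3], "energy")
  expect_equal(out$gc, c(0.5, 0.8, 0.5, 0.3))
  # bounds are inclusive: exactly 40% and 60% GC pass
  border <- data.frame(sequence = c("ATATATGCGCGCGCGCGCGC",  # 0.70
                                    "GCGCGCGCGCGCATATATAT",  # 0.60
                                    "GCGCGCGCATATATATATAT"), # 0.40
                       binding_energy = -9)
  expect_equal(asodn_filter(border)$pass, c(FALSE, TRUE, TRUE))
  expect_error(asodn_filter(data.frame(sequence = "ATGN",
                                       binding_energy = -9)),
               "non-ACGT")
})

test_that("insilico_pcr on a constructed template", {
  f <- "ACGTACGTACGTACGTAC"
  r <- "TTGCATGCATGCATGCAT"
  middle <- paste(rep("A", 100), collapse = "")
  tmpl <- paste0(f, middle,
                 as.character(Biostrings::reverseComplement(
                   Biostrings::DNAString(r))))
  expect_equal(insilico_pcr(tmpl, f, r),
               nchar(f) + 100L + nchar(r))
  # absent primer: no amplicon
  expect_length(insilico_pcr(tmpl, "GGGGGGGGGGGGGGGG", r), 0)
  expect_error(insilico_pcr(tmpl, "ACGT", r), "15 nt")
  # fixture allele pair differs by the insertion length
  fx <- make_promoter_fixture(seed = 50)
  expect_equal(insilico_pcr(fx$long, fx$fwd, fx$rev) -
                 insilico_pcr(fx$short, fx$fwd, fx$rev), 181L)
})

band_table <- function(n_long_purple, n_short_purple,
                       n_long_green, n_short_green) {
  data.frame(
    band = c(rep("long_present", n_long_purple),
             rep("short_only", n_short_purple),
             rep("long_present", n_long_green),
             rep("short_only", n_short_green)),
    class = c(rep("dark_purple", n_long_purple + n_short_purple),
              rep("green", n_long_green + n_short_green)))
}

# independent oracle: two-sided Fisher p by full hypergeometric
# enumeration over all tables with the observed margins
fisher_enum <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  x <- max(0, k - n):min(k, m)
  probs <- dhyper(x, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

test_that("cosegregation p matches exact enumeration", {
  # perfect 15/0 vs 0/15 table: p = 2 / C(30, 15)
  res <- cosegregation_test(band_table(15, 0, 0, 15))
  expect_true(res$all_purple_long)
  expect_true(res$all_green_short)
  expect_equal(res$p, 2 / choose(30, 15), tolerance = 1e-10)
  expect_equal(res$p, 1.292e-8, tolerance = 1e-3)

  # checkerboard: no association
  res2 <- cosegregation_test(band_table(5, 5, 5, 5))
  expect_false(res2$all_purple_long)
  expect_false(res2$all_green_short)
  expect_gt(res2$p, 0.9)

  # [[15,0],[5,10]]: purple flag holds, green flag fails
  res3 <- cosegregation_test(band_table(15, 0, 5, 10))
  expect_true(res3$all_purple_long)
  expect_false(res3$all_green_short)
  expect_equal(res3$p, fisher_enum(15, 0, 5, 10), tolerance = 1e-10)

  expect_error(cosegregation_test(band_table(5, 5, 0, 0)),
               "phenotype group")
})

test_that("Fisher p equals enumeration for random tables (total <= 40)", {
  set.seed(51)
  for (i in 1:25) {
    a <- sample(2:12, 1); b <- sample(0:8, 1)
    c <- sample(0:8, 1); d <- sample(2:12, 1)
    res <- cosegregation_test(band_table(a, b, c, d))
    expect_equal(res$p, fisher_enum(a, c, b, d), tolerance = 1e-9,
                 label = sprintf("table %d/%d/%d/%d", a, b, c, d))
  }
})

test_that("scan_cis_elements honours IUPAC degeneracy and coordinates", {
  hits <- scan_cis_elements("AACGTA",
                            data.frame(name = "m", iupac = "ACGT"))
  plus <- hits[hits$strand == "+", ]
  expect_equal(nrow(plus), 1)
  # start index 2 of a 6-mer: promoter coordinate -(6 - 2 + 1) = -5
  expect_equal(plus$position, -5L)
  # ACGT is its own reverse complement: one minus-strand hit too
  expect_equal(nrow(hits), 2)

  # CNGTTR matches CAGTTA and CCGTTG
  for (s in c("CAGTTA", "CCGTTG")) {
    h <- scan_cis_elements(s, data.frame(name = "m", iupac = "CNGTTR"))
    expect_true(any(h$strand == "+"))
  }
  h2 <- scan_cis_elements("CAGTTC",
                          data.frame(name = "m", iupac = "CNGTTR"))
  expect_false(any(h2$strand == "+"))

  # a motif longer than the sequence never matches
  expect_equal(nrow(scan_cis_elements("ACG",
                                      data.frame(name = "m",
                                                 iupac = "ACGTACGT"))), 0)
  expect_error(scan_cis_elements("ACGT",
                                 data.frame(name = "m", iupac = "AXGT")),
               "IUPAC")
})

test_that("motif scan agrees with brute-force matching on random seqs", {
  iupac_match <- function(motif, seq) {
    # position-by-position check against expanded IUPAC codes
    code <- Biostrings::IUPAC_CODE_MAP
    mlen <- nchar(motif); slen <- nchar(seq)
    hits <- integer()
    if (mlen > slen) return(hits)
    for (s in 1:(slen - mlen + 1)) {
      okay <- TRUE
      for (j in 1:mlen) {
        allowed <- strsplit(code[[substr(motif, j, j)]], "")[[1]]
        if (!substr(seq, s + j - 1, s + j - 1) %in% allowed) {
          okay <- FALSE; break
        }
      }
      if (okay) hits <- c(hits, s)
    }
    hits
  }
  set.seed(52)
  for (i in 1:5) {
    seqlen <- sample(200:1000, 1)
    seq <- paste(sample(c("A", "C", "G", "T"), seqlen, TRUE),
                 collapse = "")
    motif <- paste(sample(names(Biostrings::IUPAC_CODE_MAP)[1:14],
                          sample(4:8, 1), TRUE), collapse = "")
    got <- scan_cis_elements(seq, data.frame(name = "m", iupac = motif))
    plus_pos <- sort(got$position[got$strand == "+"])
    brute <- sort(iupac_match(motif, seq) - seqlen - 1L)
    expect_equal(plus_pos, brute, label = motif)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(motif)))
    minus_pos <- sort(got$position[got$strand == "-"])
    brute_m <- sort(iupac_match(rc, seq) - seqlen - 1L)
    expect_equal(minus_pos, brute_m, label = paste("rc", motif))
  }
})
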