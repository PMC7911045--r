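test_that("degenerate codons expand to their Cartesian product", {
  expect_equal(length(expand_degenerate_codon("NNK")), 32L)
  expect_equal(expand_degenerate_codon("TTT"), "TTT")
  expect_equal(length(expand_degenerate_codon("NNN")), 64L)
  expect_error(expand_degenerate_codon("NZK"), "invalid IUPAC")
  expect_error(expand_degenerate_codon("NNKT"), "3-letter")
})

test_that("NNK encodes all 20 amino acids with a single TAG stop", {
  enc <- encoded_amino_acids("NNK")
  expect_equal(sort(names(enc$aa_counts)), sort(scaffpatch:::AA1))
  expect_equal(enc$stop_codons, 1L)
  expect_equal(enc$codons_by_aa[["*"]], "TAG")
  expect_setequal(enc$codons_by_aa[["L"]], c("TTG", "CTT", "CTG"))
  expect_equal(enc$codons_by_aa[["M"]], "ATG")
  # consistency: expansions = sum of amino-acid codons + stops
  for (cod in c("NNK", "NNN", "RNY", "WSK")) {
    e <- encoded_amino_acids(cod)
    expect_equal(e$n_codons, sum(e$aa_counts) + e$stop_codons)
    expect_equal(e$n_codons, length(expand_degenerate_codon(cod)))
  }
})

test_that("ten NNK positions exceed the 1e12 diversity bound, exactly", {
  d <- library_design(strrep("A", 20), 1:10, "NNK")$diversity
  expect_identical(d$protein_diversity_exact, "10240000000000")  # 20^10
  expect_identical(d$dna_diversity_exact, "1125899906842624")    # 32^10
  expect_equal(d$protein_diversity, 20^10)
  expect_gt(d$protein_diversity, 1e12)
  expect_equal(d$stop_free_fraction, (31 / 32)^10, tolerance = 1e-12)

  none <- library_design("AAA", 2, "TTT")$diversity
  expect_equal(none$dna_diversity, 1)
  expect_equal(none$protein_diversity, 1)
  expect_equal(none$stop_free_fraction, 1)
})

test_that("diversity is multiplicative against brute-force enumeration", {
  d <- library_design("AAAA", c(2, 3), "NNK")$diversity
  codons <- expand_degenerate_codon("NNK")
  combos <- expand.grid(codons, codons, stringsAsFactors = FALSE)
  expect_equal(d$dna_diversity, nrow(combos))   # 32^2
  aa <- cbind(Biostrings::GENETIC_CODE[combos[[1]]],
              Biostrings::GENETIC_CODE[combos[[2]]])
  stop_free <- aa[aa[, 1] != "*" & aa[, 2] != "*", , drop = FALSE]
  expect_equal(d$protein_diversity,
               nrow(unique(as.data.frame(stop_free))))  # 20^2
  expect_equal(d$stop_free_fraction, nrow(stop_free) / nrow(combos),
               tolerance = 1e-12)
})

test_that("exact big-integer products agree with double arithmetic in range", {
  expect_identical(scaffpatch:::exact_product(c(7)), "7")
  expect_identical(scaffpatch:::exact_product(rep(32, 10)),
                   format(32^10, scientific = FALSE))
  # beyond 2^53 the string stays exact: 32^20 computed independently by
  # repeated decimal doubling (32^20 = 2^100)
  p100 <- "1"
  for (i in 1:100) {
    digs <- as.integer(rev(strsplit(p100, "")[[1]]))
    carry <- 0; out <- integer(0)
    for (d in digs) { v <- 2 * d + carry; out <- c(out, v %% 10); carry <- v %/% 10 }
    if (carry) out <- c(out, carry)
    p100 <- paste(rev(out), collapse = "")
  }
  expect_identical(scaffpatch:::exact_product(rep(32, 20)), p100)
})

test_that("back-translation round-trips through the genetic code", {
  prot <- "MWSHPQFEKGA"
  expect_equal(scaffpatch:::translate_dna(back_translate(prot)), prot)
  set.seed(31)
  rnd <- paste(sample(scaffpatch:::AA1, 30, replace = TRUE), collapse = "")
  expect_equal(scaffpatch:::translate_dna(back_translate(rnd)), rnd)
})

test_that("the cassette keeps the ribosome-display element order and frame", {
  design <- library_design(paste(rep("ARNDEFHIKL", 3), collapse = ""),
                           11:20, "NNK")
  cass <- assemble_cassette(design)
  expect_equal(cass$coords$element,
               c("t7_promoter", "stem_loop_5p", "rbs", "strep_tag", "orf",
                 "c_myc_tag", "tola_spacer", "stem_loop_3p"))
  expect_equal(scaffpatch:::translate_dna(cass$elements$orf),
               design$scaffold_protein)
  # the tagged fusion ORF must be stop-free through the TolA spacer
  coding <- paste(unlist(cass$elements[c("strep_tag", "orf", "c_myc_tag",
                                         "tola_spacer")]), collapse = "")
  expect_false(grepl("\\*", scaffpatch:::translate_dna(coding)))
  # contiguous 1-based inclusive coordinates
  expect_equal(cass$coords$start[-1], cass$coords$end[-8] + 1L)
  expect_equal(nchar(cass$dna), cass$coords$end[8])
  # degenerate codons appear at randomized positions of the library DNA
  orf_start <- cass$coords$start[cass$coords$element == "orf"]
  expect_equal(substr(cass$library_dna, orf_start + 30, orf_start + 32), "NNK")

  expect_error(assemble_cassette(design,
                                 layout_config = list(c_myc_tag = "GAATAAGAA")),
               "stop codon.*c_myc_tag")
})

test_that("variant sampling is seeded, wild-type-faithful and stop-aware", {
  design <- library_design(paste(rep("ARNDEFHIKL", 2), collapse = ""),
                           c(3, 8, 15), "NNK")
  s1 <- sample_variants(design, 5, seed = 42)
  s2 <- sample_variants(design, 5, seed = 42)
  expect_identical(s1, s2)
  expect_false(any(grepl("\\*", s1$protein)))
  # non-randomized positions stay wild type
  wt <- strsplit(design$scaffold_protein, "")[[1]]
  for (p in s1$protein) {
    v <- strsplit(p, "")[[1]]
    expect_equal(v[-c(3, 8, 15)], wt[-c(3, 8, 15)])
  }
  fixed <- library_design("AAAA", 2, "TTT")
  sf <- sample_variants(fixed, 4, seed = 1)
  expect_equal(unique(sf$protein), "AFAA")

  # TAG frequency at one NNK position ~ 1/32 without stop exclusion
  one <- library_design("AAAA", 2, "NNK")
  draws <- sample_variants(one, 10000, seed = 99, exclude_stops = FALSE)
  frac <- mean(substr(draws$dna, 4, 6) == "TAG")
  sigma <- sqrt((1 / 32) * (31 / 32) / 10000)
  expect_lt(abs(frac - 1 / 32), 3 * sigma)
})
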