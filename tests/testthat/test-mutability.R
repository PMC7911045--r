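test_that("position-scan reader parses both dialects and validates rows", {
  ddg <- synthetic_ddg("GH", planted_mutable = 1, seed = 4)
  f <- tempfile(fileext = ".tsv")
  write_positionscan(ddg, f)
  back <- read_positionscan(f)
  expect_equal(nrow(back$ddg), 2L)
  expect_equal(back$keys$wt_aa, c("G", "H"))
  expect_equal(unname(back$ddg), unname(ddg$ddg), tolerance = 1e-6)
  expect_identical(back$source, "file")

  # two-column dialect: token with the mutant letter appended
  tab <- utils::read.delim(f, colClasses = "character")
  two <- data.frame(token = paste0(tab[[1]], tab[[2]]), ddG = tab[[3]])
  f2 <- tempfile(fileext = ".tsv")
  utils::write.table(two, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_positionscan(f2)$ddg, back$ddg, tolerance = 1e-6)

  # a self row with ddG exactly 0 is accepted without complaint
  expect_no_warning(read_positionscan(f))

  lines <- readLines(f)
  drop_w <- lines[!grepl("^GA1\tW", lines)]
  fw <- tempfile(fileext = ".tsv"); writeLines(drop_w, fw)
  expect_error(read_positionscan(fw), "missing mutant.*W")

  dup <- c(lines, lines[2])
  fd <- tempfile(fileext = ".tsv"); writeLines(dup, fd)
  expect_warning(read_positionscan(fd), "duplicate")

  badtok <- sub("^GA1\t", "G1\t", lines)
  fb <- tempfile(fileext = ".tsv"); writeLines(badtok, fb)
  expect_error(read_positionscan(fb), "token")

  badnum <- sub("^(GA1\tA\t).*$", "\\1oops", lines)
  fn <- tempfile(fileext = ".tsv"); writeLines(badnum, fn)
  expect_error(read_positionscan(fn), "non-numeric")
})

test_that("mutability score counts substitutions under the ddG tolerance", {
  expect_equal(mutability_score(rep(0, 20)), 100)
  expect_equal(mutability_score(c(0, rep(2, 19))), 5)   # only self qualifies
  # 13 of 20 strictly below 0.5 (0.49 counts, 0.5 would not)
  v <- c(0, rep(-0.3, 9), rep(0.49, 3), rep(1.0, 7))
  expect_equal(mutability_score(v), 65)
  expect_equal(mutability_score(c(rep(0.5, 19), 0.499)), 5)  # strict <
  expect_error(mutability_score(rep(0, 19)), "20")
  expect_error(mutability_score(c(rep(0, 19), NaN)), "NaN|NA")
})

test_that("scores match a brute-force oracle and live on the 5% grid", {
  set.seed(99)
  for (i in 1:200) {
    v <- stats::runif(20, -3, 3)
    brute <- 0L
    for (x in v) if (x < 0.5) brute <- brute + 1L   # independent enumeration
    s <- mutability_score(v)
    expect_identical(s, 100 * brute / 20)
    expect_true(s %in% seq(0, 100, by = 5))
  }
})

test_that("score is monotone in the threshold and permutation-invariant", {
  set.seed(7)
  v <- stats::runif(20, -1, 2)
  expect_gte(mutability_score(v, 0.5), mutability_score(v, 0.2))
  expect_gte(mutability_score(v, 0.2), mutability_score(v, 0.0))
  expect_equal(mutability_score(sample(v)), mutability_score(v))
})

test_that("surrogate ddG scales with burial and Grantham distance", {
  m <- synthetic_structure(10, seed = 2, sequence = "WWWWWWWWWW")
  rs <- data.frame(key = residue_key_vec(m), rsasa = c(0, 1.2, rep(0.5, 8)))
  ddg <- surrogate_ddg(m, rs)
  expect_identical(ddg$source, "surrogate")
  expect_true(all(ddg$ddg[, "W"] == 0))              # self always 0
  expect_equal(unname(ddg$ddg[1, "G"]), 1.84)        # buried Trp->Gly
  expect_true(all(ddg$ddg[2, ] == 0))                # fully exposed
  expect_equal(mutability_score(ddg$ddg[2, ]), 100)
  # surrogate mutability never decreases as exposure grows
  scores <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(r) {
    rs$rsasa <- r
    mutability_score(surrogate_ddg(m, rs)$ddg[1, ])
  }, 0)
  expect_true(all(diff(scores) >= 0))
})

test_that("mutable selection applies strict gates and reports gaps", {
  pr <- make_profiles(sprintf("A:%d", 1:6),
                      mutability  = c(60, 60, 50, 60, 60, NA),
                      conservation = c(80, 95, 89, 89, 80, 80),
                      surface = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE))
  sel <- select_mutable(pr)
  expect_equal(as.character(sel), c("A:1", "A:4"))
  expect_equal(attr(sel, "diagnostics"), "A:6")   # missing score, listed
  # surface requirement can be lifted
  sel2 <- select_mutable(pr, require_surface = FALSE)
  expect_true("A:5" %in% sel2)
})

test_that("planted mutable positions are recovered end-to-end", {
  m <- synthetic_structure(40, seed = 21)
  seqs <- structure_sequence(m, "A")
  planted <- c(5:9, 30:34)
  ddg <- synthetic_ddg(seqs, planted, seed = 22)
  mp <- mutability_profile(ddg)
  sub_prob <- rep(0.02, 40); sub_prob[planted] <- 0.5
  cm <- map_to_structure(
    column_conservation(synthetic_msa(seqs, 60, sub_prob, seed = 23)), m)
  rs <- relative_sasa(m, residue_sasa(m, compute_sasa(m, n_points = 240)))
  sel <- select_mutable(residue_profiles(rs, cm, mp))
  expect_setequal(as.character(sel), sprintf("A:%d", planted))
})
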