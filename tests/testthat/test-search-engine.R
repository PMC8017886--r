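test_that("tryptic digestion reproduces the worked examples in both dialects", {
  peps <- function(...) sort(digest_protein(...)$peptide)
  expect_equal(peps("MAKRGYK", 0L, FALSE, "trypsin", 1L, 50L),
               sort(c("MAK", "R", "GYK")))
  expect_equal(peps("MAKRGYK", 1L, FALSE, "trypsin", 1L, 50L),
               sort(c("MAK", "R", "GYK", "MAKR", "RGYK")))
  expect_equal(peps("AKPR", 0L, FALSE, "trypsin", 1L, 50L), "AKPR")
  expect_equal(peps("AKPR", 0L, FALSE, "trypsin/P", 1L, 50L),
               sort(c("AK", "PR")))
})

test_that("digestion equals brute-force enumeration across dialects and settings", {
  set.seed(52)
  for (i in 1:60) {
    s <- random_sequence(sample(8:60, 1L))
    mc <- sample(0:2, 1L)
    semi <- sample(c(TRUE, FALSE), 1L)
    enz <- sample(c("trypsin", "trypsin/P"), 1L)
    minl <- sample(1:4, 1L); maxl <- sample(20:60, 1L)
    got <- sort(digest_protein(s, mc, semi, enz, minl, maxl)$peptide)
    expect_equal(got, oracle_digest(s, mc, semi, enz, minl, maxl),
                 info = sprintf("seq=%s mc=%d semi=%s enz=%s", s, mc, semi,
                                enz))
  }
})

test_that("digestion records missed cleavages and semi-tryptic status", {
  d <- digest_protein("MAKRGYK", 1L, TRUE, "trypsin", 1L, 50L)
  expect_equal(d[peptide == "MAKR", missed_cleavages], 1L)
  expect_false(d[peptide == "MAK", semi_tryptic])
  expect_true(d[peptide == "MA", semi_tryptic])
  # fully tryptic status wins when a peptide arises both ways
  expect_false(d[peptide == "R", semi_tryptic])
})

test_that("peptide masses match an independent residue-table summation", {
  expect_equal(peptide_mass("PEPTIDE"), 799.3600, tolerance = 0.0005)
  expect_equal(peptide_mass("G"), 57.02146 + 18.010565, tolerance = 1e-6)
  cys_fixed <- list(list(residue = "C", delta = 57.02146))
  expect_equal(peptide_mass("C", fixed_mods = cys_fixed),
               103.00919 + 57.02146 + 18.010565, tolerance = 1e-6)
  # additivity: mass(AB) = mass(A) + mass(B) - water
  set.seed(3)
  for (i in 1:10) {
    a <- random_sequence(sample(3:12, 1L))
    b <- random_sequence(sample(3:12, 1L))
    expect_equal(peptide_mass(paste0(a, b)),
                 peptide_mass(a) + peptide_mass(b) - 18.010565,
                 tolerance = 1e-9)
  }
  expect_error(peptide_mass("AXA"), "X")
})

test_that("a perfect ladder spectrum is matched to its own peptide", {
  set.seed(14)
  r <- make_records(c("MAKETTIDERVVLK", vapply(1:5, function(i)
    random_sequence(20L), "")), hap = TRUE)
  db <- build_hapdb(r)
  params <- search_params(min_length = 4L, min_peaks = 4L)
  idx <- build_peptide_index(db, params)
  sp <- ladder_spectrum("ETTIDER")
  psm <- match_spectrum(sp, idx, params)
  expect_equal(psm$peptide, "ETTIDER")
  expect_false(psm$is_decoy)
  # score equals the closed form for a complete singly charged b/y match
  L <- nchar("ETTIDER")
  expect_equal(psm$score,
               2 * lgamma(L) + log1p(1000 * (2 * (L - 1L))),
               tolerance = 1e-6)
})

test_that("precursor filter excludes candidates outside tolerance for all isotopes", {
  r <- make_records("MAKETTIDERVVLK", hap = TRUE)
  db <- build_hapdb(r)
  params <- search_params(min_length = 4L, min_peaks = 4L)
  idx <- build_peptide_index(db, params)
  sp <- ladder_spectrum("ETTIDER")
  sp$precursor_mz <- sp$precursor_mz + 5   # ~10 Da off: outside every isotope
  expect_null(match_spectrum(sp, idx, params))
})

test_that("zero matched fragments score log(1) = 0 and sparse spectra are skipped", {
  r <- make_records("MAKETTIDERVVLK", hap = TRUE)
  db <- build_hapdb(r)
  params <- search_params(min_length = 4L, min_peaks = 10L)
  idx <- build_peptide_index(db, params)
  sp <- ladder_spectrum("ETTIDER")
  sp$peaks <- cbind(mz = seq(2000, 2011), intensity = rep(10, 12))
  psm <- match_spectrum(sp, idx, params)
  expect_equal(psm$score, 0)
  sp$peaks <- sp$peaks[1:3, , drop = FALSE]
  expect_message(expect_null(match_spectrum(sp, idx, params)), "skipping")
})

test_that("search results are deterministic across repeated runs", {
  set.seed(77)
  spec <- community_spec(n_genomes = 3L, proteins_per_genome = 4L,
                         haps_per_genome = 2L, abundance = c(.5, .3, .2),
                         seed = 77)
  comm <- simulate_community(spec)
  sim <- simulate_spectra(comm, 40L, spec)
  db <- build_hapdb(comm$records)
  idx <- build_peptide_index(db, search_params())
  a <- search_spectra(sim$spectra, idx)
  b <- search_spectra(sim$spectra, idx)
  expect_identical(a, b)
})

test_that("external PSM tables are parsed with decoy and best-per-spectrum rules", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("spectrum_id\tpeptide\tscore\tprotein_ids",
               "s1\tPEPTIDEK\t12\tp1",
               "s1\tOTHERK\t9\tp2",
               "s2\tDECOYK\t8\tXXX_p1",
               "s3\tMIXEDK\t7\tp1;XXX_p2"), tsv)
  psms <- parse_external_psms(tsv)
  expect_equal(nrow(psms), 3L)
  expect_equal(psms[spectrum_id == "s1", peptide], "PEPTIDEK")
  expect_true(psms[spectrum_id == "s2", is_decoy])
  expect_false(psms[spectrum_id == "s3", is_decoy])
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("spectrum_id\tpeptide\tscore", "s1\tA\t1"), bad)
  expect_error(parse_external_psms(bad), "protein_ids")
})

test_that("MGF files round-trip through the reader and writer", {
  sp <- list(ladder_spectrum("ETTIDER", id = "one"),
             ladder_spectrum("MAKETTK", id = "two"))
  f <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(sp, f)
  back <- read_mgf(f)
  expect_equal(length(back), 2L)
  expect_equal(back[[1L]]$spectrum_id, "one")
  expect_equal(back[[1L]]$charge, 2L)
  expect_equal(back[[1L]]$precursor_mz, sp[[1L]]$precursor_mz,
               tolerance = 1e-4)
  expect_equal(back[[2L]]$peaks[, "mz"], unname(sp[[2L]]$peaks[, "mz"]),
               tolerance = 1e-4)
})
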