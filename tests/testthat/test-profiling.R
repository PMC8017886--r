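fixture_incidence <- function() {
  data.table::data.table(
    spectrum_id = c("s1", "s2", "s3", "s3", "s4", "s4"),
    genome_id   = c("g1", "g1", "g1", "g2", "g2", "g3"),
    peptide     = c("AAK", "CCK", "DDK", "DDK", "EEK", "EEK"))
}

test_that("incidence maps spectra to all genomes carrying the peptide", {
  reg <- make_records(c("MAAAKR", "MAAAKR", "GGGKR"), c("g1", "g2", "g3"))
  psms <- data.table::data.table(
    spectrum_id = "s1", peptide = "MAAAK", mods = "", score = 10,
    is_decoy = FALSE, proteins = "p01;p02", genomes = "g1;g2")
  inc <- build_incidence(psms, reg)
  expect_setequal(inc$genome_id, c("g1", "g2"))
  expect_equal(unique(inc$spectrum_id), "s1")
})

test_that("incidence expands collapsed duplicates through the dedup map", {
  reg <- make_records(c("MAAAKR", "MAAAKR", "GGGKR"), c("g1", "g3", "g2"))
  dd <- deduplicate_exact(reg)   # p02 (g3) collapses into p01 (g1)
  psms <- data.table::data.table(
    spectrum_id = "s1", peptide = "MAAAK", mods = "", score = 10,
    is_decoy = FALSE, proteins = "p01", genomes = "g1")
  inc <- build_incidence(psms, reg, dd$dedup_map)
  expect_setequal(inc$genome_id, c("g1", "g3"))
})

test_that("incidence rejects decoy PSMs and drops unregistered proteins", {
  reg <- make_records("MAAAKR")
  bad <- data.table::data.table(
    spectrum_id = "s1", peptide = "MAAAK", mods = "", score = 10,
    is_decoy = TRUE, proteins = "XXX_p01", genomes = "g1")
  expect_error(build_incidence(bad, reg), "decoy")
  orphan <- data.table::data.table(
    spectrum_id = c("s1", "s2"), peptide = c("MAAAK", "QQQK"), mods = "",
    score = 10, is_decoy = FALSE, proteins = c("p01", "nope"),
    genomes = c("g1", ""))
  expect_message(inc <- build_incidence(orphan, reg), "dropped")
  expect_equal(unique(inc$spectrum_id), "s1")
})

test_that("greedy cover reproduces the worked example and its verified optimum", {
  inc <- data.table::data.table(
    spectrum_id = c("s1", "s2", "s3", "s3", "s4", "s4"),
    genome_id   = c("g1", "g1", "g1", "g2", "g2", "g3"))
  sel <- greedy_cover(inc, 1.0)
  expect_equal(sel$genome_id, c("g1", "g2"))
  expect_equal(sel$newly_covered, c(3L, 1L))
  expect_equal(sel$cumulative_fraction, c(0.75, 1.0))
  # exhaustive search confirms {g1, g2} is a minimum cover
  expect_equal(oracle_min_cover_size(as.data.frame(inc)), 2L)
  # 75% threshold stops after g1
  sel2 <- greedy_cover(inc, 0.75)
  expect_equal(sel2$genome_id, "g1")
  # single genome covering everything
  one <- data.table::data.table(spectrum_id = c("s1", "s2"),
                                genome_id = "g9")
  sel3 <- greedy_cover(one, 1.0)
  expect_equal(nrow(sel3), 1L)
  expect_equal(sel3$cumulative_fraction, 1.0)
  expect_error(greedy_cover(inc[0L]), "no identified spectra")
  expect_error(greedy_cover(inc, 0), "coverage_threshold")
  # alternative reading: only spectra mapping to exactly one genome count
  selu <- greedy_cover(inc, 1.0, unique_only = TRUE)
  expect_equal(selu$genome_id, "g1")       # s1, s2 are the unique spectra
  expect_equal(selu$newly_covered, 2L)
})

test_that("greedy cover matches the independent oracle on random incidences", {
  set.seed(31)
  for (i in 1:40) {
    inc <- random_incidence(sample(3:12, 1L), sample(5:60, 1L))
    thr <- sample(c(0.6, 0.8, 1.0), 1L)
    sel <- greedy_cover(data.table::as.data.table(inc), thr)
    expect_equal(sel$genome_id, oracle_greedy(inc, thr),
                 info = paste("instance", i))
    # coverage fraction non-decreasing, spectra counted once
    expect_true(all(diff(sel$cumulative_fraction) >= 0))
    expect_lte(max(sel$cumulative_fraction), 1.0)
    expect_equal(sum(sel$newly_covered),
                 sel$cumulative_covered[nrow(sel)])
  }
})

test_that("taxonomic profile rolls spectra up to clades with percentages", {
  tax <- data.table::data.table(
    genome_id = c("g1", "g2", "g3"),
    lineage = c("d__B;p__P1;c__C1;o__O1;f__F1;g__G1;s__S1",
                "d__B;p__P1;c__C1;o__O1;f__F2;g__G2;s__S2",
                "d__B;p__P2;c__C2;o__O2;f__F3;g__G3;s__S3"))
  inc <- fixture_incidence()
  prof <- taxonomic_profile(inc, tax, rank = "order")
  expect_equal(sum(prof$percent), 100, tolerance = 0.01)
  # two genomes in the same order: their spectra pool (s4 counted once in o__O2? no, g3 is o__O2)
  expect_equal(prof[clade == "o__O1", n_spectra], 4L)
  expect_equal(prof[clade == "o__O2", n_spectra], 1L)
  expect_error(taxonomic_profile(inc, tax, rank = "kingdom"), "valid ranks")
})

test_that("minimum-unique-peptide filter excludes weakly supported genomes", {
  tax <- data.table::data.table(
    genome_id = c("g1", "g2", "g3"),
    lineage = rep("d__B;p__P;c__C;o__O;f__F;g__G;s__S", 3L))
  inc <- fixture_incidence()   # g1 has 3 distinct peptides, g2 has 2, g3 has 1
  prof <- taxonomic_profile(inc, tax, rank = "order",
                            min_unique_peptides = 3L)
  expect_equal(prof$n_spectra, 3L)   # only g1 spectra remain
  # restriction to a selection behaves the same way
  prof2 <- taxonomic_profile(inc, tax, rank = "order", genomes = "g2")
  expect_equal(prof2$n_spectra, 2L)
})

test_that("taxonomy tables read from TSV and split lineages by rank", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("genome_id\tlineage",
               "g1\td__B;p__P1;c__C1;o__O1;f__F1;g__G1;s__S1",
               "g2\td__B;p__P1"), f)
  tax <- read_taxonomy_table(f)
  expect_equal(tax[genome_id == "g1", order], "o__O1")
  expect_equal(tax[genome_id == "g2", order], "unclassified")
})
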