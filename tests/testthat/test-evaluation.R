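mini_psms <- function(ids, peptides, scores = 10) {
  data.table::data.table(spectrum_id = ids, peptide = peptides, mods = "",
                         score = scores, is_decoy = FALSE,
                         proteins = "p1", genomes = "g1")
}

test_that("consistency rate compares shared spectra I/L- and mod-blind", {
  a <- mini_psms(sprintf("s%02d", 1:10),
                 c(rep("AAAK", 9), "CCCK"))
  b <- mini_psms(sprintf("s%02d", 1:10),
                 c(rep("AAAK", 9), "DDDK"))
  cr <- consistency_rate(a, b)
  expect_equal(cr$rate, 0.9)
  expect_equal(cr$n_shared, 10L)
  # identical runs are fully consistent
  expect_equal(consistency_rate(a, a)$rate, 1.0)
  # I/L substitution counts as the same peptide
  expect_equal(consistency_rate(mini_psms("s1", "NIK"),
                                mini_psms("s1", "NLK"))$rate, 1.0)
  # modification placement is ignored by default, compared when strict
  am <- mini_psms("s1", "AMAK"); am$mods <- "2"
  bm <- mini_psms("s1", "AMAK"); bm$mods <- ""
  expect_equal(consistency_rate(am, bm)$rate, 1.0)
  expect_equal(consistency_rate(am, bm, strict = TRUE)$rate, 0.0)
  # symmetry over the shared intersection
  expect_equal(consistency_rate(a, b)$rate, consistency_rate(b, a)$rate)
  expect_error(consistency_rate(mini_psms("s1", "AK"),
                                mini_psms("s2", "AK")), "no spectra")
})

test_that("identification rate is the percentage of assigned spectra", {
  expect_equal(identification_rate(39, 100), 39.0)
  expect_equal(identification_rate(0, 100), 0.0)
  # a sample with 57,835 acquired spectra and 22,000 identified
  expect_equal(round(identification_rate(22000, 57835), 2), 38.04)
  expect_error(identification_rate(5, 0), "positive")
  expect_error(identification_rate(11, 10), "between")
})

test_that("peptide overlap canonicalises I/L before set comparison", {
  # an I <-> L substitution is invisible; any other difference separates
  ov <- peptide_overlap("PEPTIDEK", "PEPTVDEK")
  expect_equal(ov, list(only_a = 1L, shared = 0L, only_b = 1L))
  expect_equal(peptide_overlap("PEPTIDEK", "PEPTLDEK")$shared, 1L)
  expect_equal(peptide_overlap("NIK", "NLK")$shared, 1L)
  same <- peptide_overlap(c("AK", "CK"), c("AK", "CK"))
  expect_equal(same$only_a, 0L)
  expect_equal(same$only_b, 0L)
  # canonicalisation is idempotent
  x <- c("NIK", "LIL", "AAA")
  expect_equal(il_collapse(il_collapse(x)), il_collapse(x))
})

test_that("protein support credits shared peptides to every carrier", {
  reg <- make_records(c("MAAAKR", "MAAAKGGGK", "WWWK"), c("g1", "g1", "g2"))
  psms <- data.table::data.table(
    spectrum_id = c("s1", "s2", "s3"),
    peptide = "MAAAK", mods = "", score = 10, is_decoy = FALSE,
    proteins = c("p01;p02", "p01;p02", "p01;p02"), genomes = "g1")
  sup <- protein_support(psms, reg, min_spectra = 3L)
  expect_equal(sup$per_protein[protein_id == "p01", n_spectra], 3L)
  expect_equal(sup$per_protein[protein_id == "p02", n_spectra], 3L)
  expect_equal(sup$per_genome[genome_id == "g1", n_supported], 2L)
  expect_equal(sup$per_genome[genome_id == "g1", percent_supported], 100)
  expect_equal(sup$per_genome[genome_id == "g2", n_supported], 0L)
})

test_that("per-genome support percentage is supported over putative proteins", {
  # genome with 100 proteins of which 19 have support at >= 1 spectrum
  reg <- make_records(vapply(1:100, function(i)
    paste0(random_sequence(8L), "K"), ""), "g1")
  psms <- data.table::data.table(
    spectrum_id = sprintf("s%03d", 1:19), peptide = "ZZZ", mods = "",
    score = 10, is_decoy = FALSE,
    proteins = sprintf("p%02d", c(1:9, 10:19)), genomes = "g1")
  psms$proteins <- sprintf("p%03d", 1:19)
  reg$protein_id <- sprintf("p%03d", 1:100)
  sup <- protein_support(psms, reg, min_spectra = 1L)
  expect_equal(sup$per_genome$percent_supported, 19.0)
})

test_that("expressed-operon detection follows the gap, strand and mean rules", {
  loci <- data.table::data.table(
    gene_id = c("a", "b"), contig_id = "c1",
    start = c(1L, 350L), end = c(300L, 600L),
    strand = "+", spectra_count = c(12, 15))
  got <- detect_expressed_operons(loci)
  expect_equal(nrow(got), 2L)             # one cluster of two genes
  expect_equal(unique(got$mean_spectra), 13.5)
  # gap 49 <= 100; push the second gene out of range
  far <- data.table::copy(loci)[2L, start := 402L]  # gap 101
  expect_equal(nrow(detect_expressed_operons(far)), 0L)
  # opposite strands never chain
  fl <- data.table::copy(loci)[2L, strand := "-"]
  expect_equal(nrow(detect_expressed_operons(fl)), 0L)
  # mean exactly at the threshold is rejected (strictly more than 10)
  lo <- data.table::copy(loci)[, spectra_count := c(10, 10)]
  expect_equal(nrow(detect_expressed_operons(lo)), 0L)
  # overlapping genes chain with gap treated as zero
  ov <- data.table::copy(loci)[2L, start := 250L]
  expect_message(got_ov <- detect_expressed_operons(ov), "overlapping")
  expect_equal(nrow(got_ov), 2L)
})

test_that("operon clusters partition genes and ignore input order", {
  set.seed(17)
  loci <- data.table::data.table(
    gene_id = sprintf("gene%02d", 1:8),
    contig_id = rep(c("c1", "c2"), each = 4L),
    start = rep(c(1L, 200L, 1000L, 1180L), 2L),
    end = rep(c(150L, 900L, 1150L, 1400L), 2L),
    strand = c(rep("+", 4L), "+", "+", "-", "-"),
    spectra_count = c(20, 30, 5, 40, 11, 12, 50, 60))
  got <- detect_expressed_operons(loci)
  expect_equal(anyDuplicated(got$gene_id), 0L)
  shuffled <- loci[sample(.N)]
  got2 <- detect_expressed_operons(shuffled)
  expect_equal(got[order(gene_id)][, !"cluster"],
               got2[order(gene_id)][, !"cluster"])
})

test_that("gene loci load from TSV and GFF3", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tcontig_id\tstart\tend\tstrand\tspectra_count",
               "a\tc1\t1\t300\t+\t12"), tsv)
  x <- read_gene_loci(tsv)
  expect_equal(x$end, 300L)
  gff <- withr::local_tempfile(fileext = ".gff")
  writeLines(c("##gff-version 3",
               "c1\tpred\tCDS\t1\t300\t.\t+\t0\tID=gene1;protein_id=p1",
               "c1\tpred\tCDS\t350\t600\t.\t+\t0\tID=gene2"), gff)
  y <- read_gene_loci(gff)
  expect_equal(y$gene_id, c("gene1", "gene2"))
  expect_equal(y$protein_id, c("p1", "gene2"))
  expect_equal(y$start, c(1L, 350L))
})
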