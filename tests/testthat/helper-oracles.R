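# Independent oracles and fixture builders used across the suite.

# Brute-force digestion oracle: enumerate every substring and test it
# against the cleavage-rule predicate directly.
oracle_digest <- function(sequence, missed_cleavages_max, semi_tryptic,
                          enzyme, min_length, max_length) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(res)
  is_site <- function(i) {
    i >= 1L && i < n && res[i] %in% c("K", "R") &&
      (enzyme == "trypsin/P" || res[i + 1L] != "P")
  }
  valid_nterm <- function(st) st == 1L || is_site(st - 1L)
  valid_cterm <- function(en) en == n || is_site(en)
  peps <- character()
  for (st in seq_len(n)) {
    for (en in st:n) {
      len <- en - st + 1L
      if (len < min_length || len > max_length) next
      internal <- if (en > st)
        sum(vapply(st:(en - 1L), is_site, TRUE)) else 0L
      if (internal > missed_cleavages_max) next
      nt <- valid_nterm(st); ct <- valid_cterm(en)
      keep <- if (semi_tryptic) (nt + ct) >= 1L else nt && ct
      if (keep) peps <- c(peps, substr(sequence, st, en))
    }
  }
  sort(unique(peps))
}

# One-line greedy set-cover oracle over an incidence table
# (columns spectrum_id, genome_id), independent of the package code.
oracle_greedy <- function(inc, threshold = 1.0) {
  inc <- unique(inc[, c("spectrum_id", "genome_id")])
  total <- length(unique(inc$spectrum_id))
  covered <- character(); picked <- character()
  repeat {
    left <- inc[!inc$spectrum_id %in% covered &
                  !inc$genome_id %in% picked, ]
    if (nrow(left) == 0L) break
    cnt <- table(left$genome_id)
    best <- sort(names(cnt)[cnt == max(cnt)])[1L]
    covered <- union(covered, left$spectrum_id[left$genome_id == best])
    picked <- c(picked, best)
    if (length(covered) / total >= threshold) break
  }
  picked
}

# Exhaustive minimum cover over all genome subsets (small instances only).
oracle_min_cover_size <- function(inc) {
  inc <- unique(inc[, c("spectrum_id", "genome_id")])
  genomes <- sort(unique(inc$genome_id))
  spectra <- unique(inc$spectrum_id)
  sets <- split(inc$spectrum_id, inc$genome_id)
  for (k in seq_along(genomes)) {
    combos <- utils::combn(genomes, k, simplify = FALSE)
    for (cm in combos) {
      if (all(spectra %in% unlist(sets[cm], use.names = FALSE)))
        return(k)
    }
  }
  length(genomes)
}

# Random incidence instance.
random_incidence <- function(n_genomes, n_spectra) {
  g <- sprintf("g%02d", seq_len(n_genomes))
  rows <- lapply(seq_len(n_spectra), function(s) {
    k <- sample(1:min(3L, n_genomes), 1L)
    data.frame(spectrum_id = sprintf("s%03d", s),
               genome_id = sample(g, k), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Random amino-acid sequence with K/R present.
random_sequence <- function(len) {
  aa <- c("G","A","S","P","V","T","C","L","I","N","D","Q","K","E","M",
          "H","F","R","Y","W")
  paste(sample(aa, len, replace = TRUE,
               prob = c(rep(1, 12), 2, 1, 1, 1, 1, 2, 1, 1)),
        collapse = "")
}

# Tiny protein record table.
make_records <- function(seqs, genome_ids = "g1", hap = FALSE,
                         annotation = "") {
  data.table::data.table(
    protein_id = sprintf("p%02d", seq_along(seqs)),
    genome_id = rep_len(genome_ids, length(seqs)),
    sequence = seqs,
    annotation = rep_len(annotation, length(seqs)),
    is_hap = rep_len(hap, length(seqs)),
    is_decoy = FALSE)
}

# Noiseless spectrum (perfect singly charged b/y ladder, charge 2) for a
# peptide, built independently from a published residue-mass table.
ORACLE_RESIDUE_MASS <- c(
  G =  57.02146, A =  71.03711, S =  87.03203, P =  97.05276, V =  99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)

ladder_spectrum <- function(peptide, id = "sp1", carbamidomethyl = TRUE,
                            intensity = 1000) {
  r <- ORACLE_RESIDUE_MASS[strsplit(peptide, "", fixed = TRUE)[[1L]]]
  if (carbamidomethyl) r[names(r) == "C"] <- r[names(r) == "C"] + 57.02146
  n <- length(r)
  b <- cumsum(r)[seq_len(n - 1L)] + 1.007276
  y <- rev(sum(r) - cumsum(r)[seq_len(n - 1L)]) + 18.010565 + 1.007276
  mz <- sort(c(b, y))
  list(spectrum_id = id,
       precursor_mz = (sum(r) + 18.010565 + 2 * 1.007276) / 2,
       charge = 2L,
       peaks = cbind(mz = mz, intensity = rep(intensity, length(mz))))
}
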