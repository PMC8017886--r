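#' Specification for a synthetic microbial community
#'
#' Defines the ground-truth conditions the generator emulates: a small
#' community with a skewed abundance vector in which a handful of genomes
#' carry nearly all protein mass (the default vector puts 99% of the mass on
#' the top five of eight genomes, with three trace members), a designated
#' HAP subset per genome expressed `hap_expression_boost` times more than
#' other proteins, m/z measurement noise, and a fraction of unmatchable
#' noise spectra.
#'
#' @param n_genomes number of genomes.
#' @param proteins_per_genome proteins per genome.
#' @param haps_per_genome designated HAPs per genome (must not exceed
#'   `proteins_per_genome`).
#' @param abundance probability vector over genomes (normalised if needed).
#' @param hap_expression_boost expression multiplier for HAPs (>= 1).
#' @param noise_spectrum_fraction fraction of spectra that are random noise,
#'   in \[0, 1).
#' @param mz_noise_ppm standard deviation of m/z perturbation, ppm.
#' @param seed integer seed; all generator randomness derives from it.
#' @param homolog_genomes number of leading genomes whose proteomes are
#'   mutated copies of a shared ancestral proteome (0 = all genomes
#'   independent, the default). Used to emulate communities of related
#'   strains.
#' @param transposition_rate per-residue rate of mass-preserving adjacent
#'   transpositions applied when deriving a homologous proteome; swaps never
#'   cross or involve K/R, so tryptic peptide masses are conserved and
#'   homologous peptides are near-isobaric variants of each other.
#' @return a `community_spec` list.
#' @export
community_spec <- function(n_genomes = 8L, proteins_per_genome = 20L,
                           haps_per_genome = 4L,
                           abundance = c(0.30, 0.22, 0.18, 0.16, 0.13,
                                         0.006, 0.003, 0.001),
                           hap_expression_boost = 5,
                           noise_spectrum_fraction = 0.2,
                           mz_noise_ppm = 5, seed = 1L,
                           homolog_genomes = 0L,
                           transposition_rate = 0.1) {
  stopifnot(n_genomes >= 1L, proteins_per_genome >= 1L,
            haps_per_genome >= 1L,
            haps_per_genome <= proteins_per_genome,
            length(abundance) == n_genomes, all(abundance > 0),
            hap_expression_boost >= 1,
            noise_spectrum_fraction >= 0, noise_spectrum_fraction < 1,
            mz_noise_ppm >= 0, homolog_genomes %in% c(0L, 2:n_genomes))
  structure(list(n_genomes = as.integer(n_genomes),
                 proteins_per_genome = as.integer(proteins_per_genome),
                 haps_per_genome = as.integer(haps_per_genome),
                 abundance = abundance / sum(abundance),
                 hap_expression_boost = hap_expression_boost,
                 noise_spectrum_fraction = noise_spectrum_fraction,
                 mz_noise_ppm = mz_noise_ppm, seed = as.integer(seed),
                 homolog_genomes = as.integer(homolog_genomes),
                 transposition_rate = transposition_rate),
            class = "community_spec")
}

# Residue sampling weights: uniform over the 20 standard amino acids with
# K and R boosted so random proteins yield tryptic peptides of usable length
# (combined K/R frequency ~0.13, mean fully tryptic segment ~7-8 residues).
RESIDUE_WEIGHTS <- local({
  w <- rep(1, 20); names(w) <- names(RESIDUE_MASS)
  w[c("K", "R")] <- 1.5
  w / sum(w)
})

random_protein <- function(len) {
  paste(sample(names(RESIDUE_WEIGHTS), len, replace = TRUE,
               prob = RESIDUE_WEIGHTS), collapse = "")
}

# Mass-preserving within-segment adjacent transpositions: swap positions
# (i, i+1) where neither residue is K or R, so cleavage sites and every
# tryptic peptide's composition (hence mass) are unchanged.
transpose_homolog <- function(sequence, rate) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(res)
  if (n < 2L || rate <= 0) return(sequence)
  ok <- which(!(res[-n] %in% c("K", "R")) & !(res[-1L] %in% c("K", "R")) &
              res[-n] != res[-1L])
  k <- min(length(ok), max(1L, round(n * rate)))
  if (k == 0L || !length(ok)) return(sequence)
  picks <- sort(sample(ok, k))
  picks <- picks[c(TRUE, diff(picks) > 1L)]  # non-overlapping swaps
  for (i in picks) res[c(i, i + 1L)] <- res[c(i + 1L, i)]
  paste(res, collapse = "")
}

#' Generate a synthetic community with ground truth
#'
#' Produces random protein sequences (length 80–400, residue frequencies
#' uniform over the 20 standard amino acids with K/R boosted), flags the
#' designated HAP subset of each genome with ribosomal-protein /
#' elongation-factor annotations, builds a synthetic lineage table in which
#' at least two genomes share an order, and records per-protein expression
#' weights (abundance times the HAP boost). With `homolog_genomes > 0`, the
#' first genomes share a common ancestral proteome diverged by
#' mass-preserving residue transpositions.
#'
#' @param spec a [community_spec()].
#' @return list with `records` (protein table, HAP flags set), `taxonomy`
#'   (`genome_id`, `lineage`), and `ground_truth` (`protein_id`,
#'   `genome_id`, `is_hap`, `weight`, with genome abundances as attribute
#'   `abundance`).
#' @export
simulate_community <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  set.seed(spec$seed)
  g_ids <- sprintf("g%02d", seq_len(spec$n_genomes))
  ancestor <- if (spec$homolog_genomes > 0L) {
    lens <- sample(80:400, spec$proteins_per_genome, replace = TRUE)
    vapply(lens, random_protein, "")
  } else NULL
  recs <- vector("list", spec$n_genomes)
  for (g in seq_len(spec$n_genomes)) {
    seqs <- if (!is.null(ancestor) && g <= spec$homolog_genomes) {
      vapply(ancestor, transpose_homolog, "",
             rate = spec$transposition_rate)
    } else {
      lens <- sample(80:400, spec$proteins_per_genome, replace = TRUE)
      vapply(lens, random_protein, "")
    }
    j <- seq_len(spec$proteins_per_genome)
    is_hap <- j <= spec$haps_per_genome
    ann <- ifelse(is_hap,
                  ifelse(j %% 2L == 1L,
                         sprintf("50S ribosomal protein L%d", j),
                         "elongation factor Tu"),
                  "hypothetical protein")
    recs[[g]] <- data.table(protein_id = sprintf("%s_p%03d", g_ids[g], j),
                            genome_id = g_ids[g], sequence = unname(seqs),
                            annotation = ann, is_hap = is_hap,
                            is_decoy = FALSE)
  }
  records <- rbindlist(recs)
  # lineage: genomes 1 and 2 share an order; the rest get their own
  order_of <- c("o__SharedOrder",
                if (spec$n_genomes >= 2L) "o__SharedOrder",
                if (spec$n_genomes >= 3L)
                  sprintf("o__Order%02d", 3:spec$n_genomes))
  taxonomy <- data.table(
    genome_id = g_ids,
    lineage = sprintf(
      "d__Bacteria;p__Phylum%02d;c__Class%02d;%s;f__Family%02d;g__Genus%02d;s__Species%02d",
      seq_len(spec$n_genomes) %% 3L + 1L, seq_len(spec$n_genomes),
      order_of, seq_len(spec$n_genomes), seq_len(spec$n_genomes),
      seq_len(spec$n_genomes)))
  truth <- records[, .(protein_id, genome_id, is_hap)]
  truth[, weight := spec$abundance[match(genome_id, g_ids)] *
          ifelse(is_hap, spec$hap_expression_boost, 1)]
  setattr(truth, "abundance", setNames(spec$abundance, g_ids))
  list(records = records, taxonomy = taxonomy, ground_truth = truth)
}

#' Generate synthetic MS/MS spectra with ground truth
#'
#' For each true spectrum a protein is sampled proportionally to its
#' expression weight and a tryptic peptide uniformly from its digest; the
#' peptide's singly charged b/y ladder is emitted with m/z values perturbed
#' by `Normal(0, mz_noise_ppm * mz / 1e6)` and lognormal intensities, and
#' the precursor is placed at the true monoisotopic m/z (charge 2) with the
#' same relative noise. A `noise_spectrum_fraction` share of spectra carry
#' random peaks and random precursors and match nothing. Spectrum order is
#' shuffled deterministically under the spec's seed.
#'
#' @param community output of [simulate_community()].
#' @param n_spectra total number of spectra (> 0).
#' @param spec the [community_spec()] used for the community.
#' @param digest_params [search_params()] controlling the peptide pool
#'   sampled from each protein (default: fully tryptic, no missed
#'   cleavages, lengths 6–40).
#' @return list with `spectra` (list of spectrum records) and `truth`
#'   (`data.table`: `spectrum_id`, `peptide`, `protein_id`, `genome_id`;
#'   noise spectra have `NA` peptide).
#' @export
simulate_spectra <- function(community, n_spectra, spec,
                             digest_params = search_params(
                               missed_cleavages_max = 0L,
                               semi_tryptic = FALSE,
                               min_length = 6L, max_length = 40L)) {
  stopifnot(inherits(spec, "community_spec"))
  if (n_spectra <= 0L) stop("n_spectra must be positive")
  set.seed(spec$seed + 10000L)
  truth_tab <- community$ground_truth
  records <- community$records
  tbl <- residue_mass_table(digest_params$fixed_mods)

  # peptide pools per protein (proteins without usable peptides excluded)
  pools <- lapply(records$sequence, function(s)
    digest_protein(s, missed_cleavages_max =
                     digest_params$missed_cleavages_max,
                   semi_tryptic = digest_params$semi_tryptic,
                   enzyme = digest_params$enzyme,
                   min_length = digest_params$min_length,
                   max_length = digest_params$max_length)$peptide)
  pools <- lapply(pools, function(p) p[!grepl("X", p, fixed = TRUE)])
  usable <- which(lengths(pools) > 0L)
  if (!length(usable)) stop("no protein yields any usable tryptic peptide")
  w <- truth_tab$weight[usable]

  n_noise <- round(n_spectra * spec$noise_spectrum_fraction)
  n_true <- n_spectra - n_noise
  ppm <- spec$mz_noise_ppm / 1e6
  jitter <- function(mz) mz * (1 + rnorm(length(mz), 0, ppm))

  make_true <- function(i) {
    p <- sample(usable, 1L, prob = w)
    pep <- sample(pools[[p]], 1L)
    r <- peptide_residue_masses(pep, tbl)
    lad <- fragment_ladders(r)
    frag <- c(lad$b, lad$y)
    prec <- (sum(r) + WATER_MASS + 2 * PROTON_MASS) / 2
    peaks <- cbind(mz = jitter(frag),
                   intensity = rlnorm(length(frag), log(1000), 1))
    peaks <- peaks[order(peaks[, 1L]), , drop = FALSE]
    list(spectrum = list(spectrum_id = NA_character_,
                         precursor_mz = jitter(prec), charge = 2L,
                         peaks = peaks),
         peptide = pep, protein_id = records$protein_id[p],
         genome_id = records$genome_id[p])
  }
  make_noise <- function(i) {
    npk <- sample(20:60, 1L)
    peaks <- cbind(mz = sort(runif(npk, 100, 1500)),
                   intensity = rlnorm(npk, log(1000), 1))
    list(spectrum = list(spectrum_id = NA_character_,
                         precursor_mz = runif(1, 400, 1500), charge = 2L,
                         peaks = peaks),
         peptide = NA_character_, protein_id = NA_character_,
         genome_id = NA_character_)
  }
  items <- c(lapply(seq_len(n_true), make_true),
             lapply(seq_len(n_noise), make_noise))
  items <- items[sample.int(length(items))]
  ids <- sprintf("S%06d", seq_along(items))
  spectra <- vector("list", length(items))
  for (i in seq_along(items)) {
    sp <- items[[i]]$spectrum
    sp$spectrum_id <- ids[i]
    spectra[[i]] <- sp
  }
  truth <- data.table(
    spectrum_id = ids,
    peptide = vapply(items, `[[`, "", "peptide"),
    protein_id = vapply(items, `[[`, "", "protein_id"),
    genome_id = vapply(items, `[[`, "", "genome_id"))
  list(spectra = spectra, truth = truth)
}

#' Write a simulated dataset to a directory
#'
#' Emits the standard file surface: per-genome FASTA, MGF spectra, taxonomy
#' TSV, HAP-flag TSV and ground-truth TSV.
#'
#' @param community output of [simulate_community()].
#' @param sim output of [simulate_spectra()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(community, sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  recs <- community$records
  for (g in unique(recs$genome_id)) {
    sub <- recs[genome_id == g]
    aa <- Biostrings::AAStringSet(sub$sequence)
    names(aa) <- paste(sub$protein_id, sub$annotation)
    Biostrings::writeXStringSet(aa, file.path(dir, paste0(g, ".faa")))
  }
  write_mgf(sim$spectra, file.path(dir, "spectra.mgf"))
  fwrite(community$taxonomy, file.path(dir, "taxonomy.tsv"), sep = "\t")
  fwrite(recs[, .(protein_id, is_hap)], file.path(dir, "hap_flags.tsv"),
         sep = "\t")
  fwrite(sim$truth, file.path(dir, "ground_truth.tsv"), sep = "\t")
  invisible(dir)
}
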