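#' Build the spectrum-to-genome incidence map
#'
#' For each FDR-filtered target PSM, records the set of genomes whose
#' proteins contain the identified peptide. Proteins collapsed during exact
#' deduplication are expanded through the dedup map in both directions, so
#' every genome carrying an identical copy of a shared protein is credited.
#' Spectra whose proteins map to no registered genome are dropped (a count
#' is reported via `message`).
#'
#' @param psms filtered target PSM table (decoys are a precondition
#'   violation and raise an error).
#' @param registry protein record table mapping `protein_id` to `genome_id`
#'   (the pre-deduplication collection).
#' @param dedup_map optional `data.table` (`removed_id`, `kept_id`).
#' @return `data.table` with unique (`spectrum_id`, `genome_id`) pairs, and
#'   a `peptide` column retained for per-genome peptide tallies.
#' @export
build_incidence <- function(psms, registry, dedup_map = NULL) {
  psms <- as.data.table(psms)
  if (any(psms$is_decoy))
    stop("decoy PSMs in input: incidence requires FDR-filtered target PSMs")
  if (nrow(psms) == 0L)
    return(data.table(spectrum_id = character(), genome_id = character(),
                      peptide = character()))
  long <- psms[, .(protein_id = strsplit(proteins, ";", fixed = TRUE)[[1L]]),
               by = .(spectrum_id, peptide)]
  # expand identical-sequence duplicates in both directions
  if (!is.null(dedup_map) && nrow(dedup_map)) {
    add1 <- merge(long, dedup_map, by.x = "protein_id", by.y = "kept_id",
                  allow.cartesian = TRUE)
    add1 <- add1[, .(spectrum_id, peptide, protein_id = removed_id)]
    add2 <- merge(long, dedup_map, by.x = "protein_id", by.y = "removed_id")
    add2 <- add2[, .(spectrum_id, peptide, protein_id = kept_id)]
    long <- unique(rbind(long[, .(spectrum_id, peptide, protein_id)],
                         add1, add2))
  }
  reg <- as.data.table(registry)
  if ("is_decoy" %in% names(reg)) reg <- reg[is_decoy == FALSE]
  reg <- reg[, .(protein_id, genome_id)]
  inc <- merge(long, reg, by = "protein_id")
  mapped <- unique(inc$spectrum_id)
  n_drop <- length(unique(long$spectrum_id)) - length(mapped)
  if (n_drop > 0L)
    message(n_drop, " spectra dropped: peptide maps to no registered genome")
  unique(inc[, .(spectrum_id, genome_id, peptide)])
}

#' Greedy minimal genome cover of identified spectra
#'
#' Iterative greedy set cover: repeatedly pick the genome explaining the
#' largest number of not-yet-covered spectra (ties broken by lexicographic
#' genome id), remove the covered spectra, and stop once the cumulative
#' covered fraction reaches `coverage_threshold` or no genome adds coverage.
#'
#' @param inc incidence table from [build_incidence()].
#' @param coverage_threshold fraction of identified spectra to cover, in
#'   (0, 1]; default 0.8.
#' @param unique_only alternative reading of "unique spectra": restrict the
#'   cover to spectra whose peptide maps to exactly one genome (default
#'   `FALSE`, the set-cover reading in which a shared spectrum is creditable
#'   to any carrier but covered once).
#' @return a `genome_selection`: `data.table` with columns `genome_id`,
#'   `newly_covered`, `cumulative_covered`, `cumulative_fraction`, plus
#'   attributes `n_spectra` and `coverage_threshold`.
#' @export
greedy_cover <- function(inc, coverage_threshold = 0.8,
                         unique_only = FALSE) {
  inc <- unique(as.data.table(inc)[, .(spectrum_id, genome_id)])
  if (unique_only)
    inc <- inc[, if (.N == 1L) .SD, by = spectrum_id]
  if (nrow(inc) == 0L) stop("no identified spectra to profile")
  if (coverage_threshold <= 0 || coverage_threshold > 1)
    stop("coverage_threshold must be in (0, 1]")
  total <- length(unique(inc$spectrum_id))
  sets <- split(inc$spectrum_id, inc$genome_id)
  covered <- character()
  sel_genome <- character(); sel_new <- integer()
  repeat {
    gains <- vapply(sets, function(s) sum(!(s %in% covered)), 0L)
    if (!length(gains) || max(gains) == 0L) break
    best <- sort(names(gains)[gains == max(gains)])[1L]
    covered <- c(covered, setdiff(sets[[best]], covered))
    sel_genome <- c(sel_genome, best)
    sel_new <- c(sel_new, gains[[best]])
    sets[[best]] <- NULL
    if (length(covered) / total >= coverage_threshold) break
  }
  out <- data.table(genome_id = sel_genome, newly_covered = sel_new,
                    cumulative_covered = cumsum(sel_new))
  out[, cumulative_fraction := cumulative_covered / total]
  setattr(out, "n_spectra", total)
  setattr(out, "coverage_threshold", coverage_threshold)
  setattr(out, "class", c("genome_selection", class(out)))
  out[]
}

TAXONOMY_RANKS <- c("domain", "phylum", "class", "order", "family",
                    "genus", "species")

#' Read a genome taxonomy table
#'
#' TSV with columns `genome_id` and `lineage`, the latter a
#' semicolon-delimited rank-ordered lineage
#' (domain;phylum;class;order;family;genus;species).
#'
#' @param path TSV path.
#' @return `data.table` with `genome_id` plus one column per rank.
#' @export
read_taxonomy_table <- function(path) {
  x <- fread(path, sep = "\t", header = TRUE, colClasses = "character")
  miss <- setdiff(c("genome_id", "lineage"), names(x))
  if (length(miss)) stop("taxonomy table is missing column(s): ",
                         paste(miss, collapse = ", "))
  split_lineage(x)
}

# Expand a `lineage` column into one column per rank.
split_lineage <- function(tax) {
  tax <- as.data.table(tax)
  parts <- strsplit(tax$lineage, ";", fixed = TRUE)
  for (i in seq_along(TAXONOMY_RANKS)) {
    tax[, (TAXONOMY_RANKS[i]) := vapply(parts, function(p)
      if (length(p) >= i && nzchar(trimws(p[i]))) trimws(p[i])
      else "unclassified", "")]
  }
  tax[]
}

#' Spectral-count taxonomic composition at a rank
#'
#' Counts distinct identified spectra per clade at the requested rank and
#' reports percentages (normalised to sum to 100). The genome set can be
#' restricted to a greedy selection (`genomes`), and/or to genomes with at
#' least `min_unique_peptides` distinct identified peptides (I/L-blind).
#'
#' @param inc incidence table from [build_incidence()].
#' @param taxonomy taxonomy table (see [read_taxonomy_table()]); genomes
#'   without a lineage fall into an `"unclassified"` bucket.
#' @param rank one of domain, phylum, class, order, family, genus, species.
#' @param min_unique_peptides minimum distinct peptides per genome
#'   (default 0 = no filter).
#' @param genomes optional character vector restricting the genome set
#'   (e.g. `selection$genome_id`).
#' @return `data.table` with `clade`, `n_spectra`, `percent`, sorted by
#'   decreasing count.
#' @export
taxonomic_profile <- function(inc, taxonomy, rank = "order",
                              min_unique_peptides = 0L, genomes = NULL) {
  if (!rank %in% TAXONOMY_RANKS)
    stop("unknown rank '", rank, "'; valid ranks: ",
         paste(TAXONOMY_RANKS, collapse = ", "))
  inc <- as.data.table(inc)
  if (!is.null(genomes)) inc <- inc[genome_id %in% genomes]
  if (min_unique_peptides > 0L) {
    if (!"peptide" %in% names(inc))
      stop("incidence table lacks a peptide column; cannot apply ",
           "min_unique_peptides")
    npep <- inc[, .(n = length(unique(chartr("I", "L", peptide)))),
                by = genome_id]
    inc <- inc[genome_id %in% npep[n >= min_unique_peptides, genome_id]]
  }
  if (nrow(inc) == 0L)
    return(data.table(clade = character(), n_spectra = integer(),
                      percent = numeric()))
  tax <- as.data.table(taxonomy)
  if (!rank %in% names(tax)) tax <- split_lineage(tax)
  inc <- merge(unique(inc[, .(spectrum_id, genome_id)]),
               tax[, c("genome_id", rank), with = FALSE],
               by = "genome_id", all.x = TRUE)
  setnames(inc, rank, "clade")
  inc[is.na(clade), clade := "unclassified"]
  out <- inc[, .(n_spectra = length(unique(spectrum_id))), by = clade]
  out[, percent := 100 * n_spectra / sum(n_spectra)]
  setorder(out, -n_spectra, clade)
  out[]
}

#' Write a greedy selection report as TSV
#' @param selection a `genome_selection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(selection, path) {
  fwrite(as.data.table(selection), path, sep = "\t")
  invisible(path)
}

#' Write a taxonomic composition table as TSV
#' @param composition output of [taxonomic_profile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_composition <- function(composition, path) {
  fwrite(composition, path, sep = "\t")
  invisible(path)
}
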