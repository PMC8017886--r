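#' Isoleucine/leucine-blind peptide canonicalisation
#'
#' Maps every `I` to `L`. Isoleucine and leucine are isobaric and cannot be
#' distinguished by mass spectrometry, so peptide comparisons are performed
#' on this canonical form. Idempotent.
#'
#' @param peptides character vector.
#' @return canonicalised character vector.
#' @export
il_collapse <- function(peptides) chartr("I", "L", peptides)

#' Consistency rate between a small- and a large-database search
#'
#' Over the spectra identified in both runs, the fraction whose peptide is
#' identical. By default peptides are compared I/L-blind and ignoring
#' modification placement; `strict = TRUE` compares the exact modified
#' peptide string instead. The small run's database is assumed to be a
#' subset of the large run's.
#'
#' @param psms_small,psms_big FDR-filtered PSM tables from the nested runs.
#' @param strict compare exact modified peptides (default `FALSE`).
#' @return list with `rate`, `n_shared`, `n_same`.
#' @export
consistency_rate <- function(psms_small, psms_big, strict = FALSE) {
  a <- as.data.table(psms_small); b <- as.data.table(psms_big)
  shared <- intersect(a$spectrum_id, b$spectrum_id)
  if (length(shared) == 0L)
    stop("no spectra identified in both runs; consistency rate is undefined")
  key <- function(x) {
    x <- x[match(shared, spectrum_id)]
    if (strict) paste0(il_collapse(x$peptide), "/", x$mods)
    else il_collapse(x$peptide)
  }
  same <- sum(key(a) == key(b))
  list(rate = same / length(shared), n_shared = length(shared),
       n_same = same)
}

#' Nested-database consistency experiment
#'
#' Searches the same spectra against target databases built from nested
#' genome subsets (each smaller database is a prefix of the larger ones in
#' `genome_order`), filters each run at the FDR target, and reports the
#' consistency rate of every smaller run against the largest. Reproduces the
#' database-size sensitivity analysis: small databases force confident but
#' wrong matches for spectra whose true peptide they lack, so the rate rises
#' with database size.
#'
#' @param spectra list of spectrum records.
#' @param records full protein record table.
#' @param genome_order character vector of genome ids, most abundant first.
#' @param sizes integer vector of nested database sizes (must be
#'   non-decreasing; the last is the reference).
#' @param params a [search_params()].
#' @param fdr FDR target per run.
#' @param decoy_prefix decoy id prefix.
#' @return `data.table` with `size_small`, `size_big`, `rate`, `n_shared`,
#'   `n_same`, plus `n_identified` per run as attribute `runs`.
#' @export
consistency_experiment <- function(spectra, records, genome_order,
                                   sizes = c(5L, 20L, 100L),
                                   params = search_params(), fdr = 0.01,
                                   decoy_prefix = "XXX_") {
  sizes <- sort(unique(as.integer(sizes)))
  stopifnot(length(sizes) >= 2L, max(sizes) <= length(genome_order))
  kept <- lapply(sizes, function(n) {
    db <- build_expanded_db(genome_order[seq_len(n)], character(),
                            records, decoy_prefix)
    psms <- search_spectra(spectra, build_peptide_index(db, params))
    filter_psms(psms, compute_fdr_threshold(psms, fdr))
  })
  names(kept) <- as.character(sizes)
  big <- kept[[length(kept)]]
  out <- rbindlist(lapply(seq_len(length(sizes) - 1L), function(i) {
    cr <- consistency_rate(kept[[i]], big)
    data.table(size_small = sizes[i], size_big = sizes[length(sizes)],
               rate = cr$rate, n_shared = cr$n_shared, n_same = cr$n_same)
  }))
  setattr(out, "runs",
          setNames(vapply(kept, nrow, 0L), names(kept)))
  out[]
}

#' Spectral identification rate
#'
#' Percentage of acquired spectra assigned a peptide passing FDR.
#'
#' @param n_identified number of identified spectra.
#' @param n_spectra total number of acquired spectra (> 0).
#' @return percentage (0–100).
#' @export
identification_rate <- function(n_identified, n_spectra) {
  if (n_spectra <= 0) stop("n_spectra must be positive")
  if (n_identified < 0 || n_identified > n_spectra)
    stop("n_identified must be between 0 and n_spectra")
  100 * n_identified / n_spectra
}

#' I/L-blind peptide set overlap
#'
#' Canonicalises both peptide sets with [il_collapse()] and reports the
#' Venn counts.
#'
#' @param set_a,set_b character vectors of peptide strings.
#' @return list with `only_a`, `shared`, `only_b`.
#' @export
peptide_overlap <- function(set_a, set_b) {
  a <- unique(il_collapse(set_a)); b <- unique(il_collapse(set_b))
  list(only_a = length(setdiff(a, b)),
       shared = length(intersect(a, b)),
       only_b = length(setdiff(b, a)))
}

#' Protein spectral support
#'
#' Counts distinct supporting spectra per protein — a spectrum is credited
#' to every protein containing its peptide — and summarises, per genome, how
#' many proteins reach `min_spectra` support and what fraction of the
#' genome's putative proteins that represents.
#'
#' @param psms FDR-filtered target PSM table.
#' @param registry protein record table (for per-genome protein totals).
#' @param min_spectra support threshold (default 1).
#' @param decoy_prefix decoy ids (dropped from the credit lists).
#' @return list with `per_protein` (`protein_id`, `genome_id`,
#'   `n_spectra`) and `per_genome` (`genome_id`, `n_proteins`,
#'   `n_supported`, `percent_supported`).
#' @export
protein_support <- function(psms, registry, min_spectra = 1L,
                            decoy_prefix = "XXX_") {
  psms <- as.data.table(psms)
  reg <- as.data.table(registry)
  if ("is_decoy" %in% names(reg)) reg <- reg[is_decoy == FALSE]
  long <- if (nrow(psms)) {
    x <- psms[, .(protein_id = strsplit(proteins, ";", fixed = TRUE)[[1L]]),
              by = spectrum_id]
    x[!startsWith(protein_id, decoy_prefix)]
  } else data.table(spectrum_id = character(), protein_id = character())
  per_protein <- long[, .(n_spectra = length(unique(spectrum_id))),
                      by = protein_id]
  per_protein <- merge(per_protein, reg[, .(protein_id, genome_id)],
                       by = "protein_id", all.x = TRUE)
  setorder(per_protein, -n_spectra, protein_id)
  totals <- reg[, .(n_proteins = .N), by = genome_id]
  supp <- per_protein[n_spectra >= min_spectra & !is.na(genome_id),
                      .(n_supported = .N), by = genome_id]
  per_genome <- merge(totals, supp, by = "genome_id", all.x = TRUE)
  per_genome[is.na(n_supported), n_supported := 0L]
  per_genome[, percent_supported := 100 * n_supported / n_proteins]
  setorder(per_genome, -n_supported, genome_id)
  list(per_protein = per_protein[], per_genome = per_genome[])
}

#' Detect expressed operon-like gene clusters
#'
#' Chains consecutive genes on the same contig and strand whose intergenic
#' gap (`start(next) - end(prev) - 1`, 1-based inclusive coordinates;
#' overlaps count as gap 0) is at most `max_gap`, and keeps maximal chains
#' of two or more genes whose mean spectral support is strictly greater than
#' `min_avg_spectra`.
#'
#' @param loci `data.table` with columns `gene_id`, `contig_id`, `start`,
#'   `end`, `strand` (`"+"`/`"-"`), `spectra_count` (and optionally
#'   `protein_id`).
#' @param max_gap maximum intergenic gap in bases (default 100).
#' @param min_avg_spectra mean-support threshold, exclusive (default 10).
#' @return `data.table` of cluster members: `cluster`, `gene_id`,
#'   `contig_id`, `start`, `end`, `strand`, `spectra_count`,
#'   `mean_spectra`, `n_genes`. Empty when no cluster qualifies.
#' @export
detect_expressed_operons <- function(loci, max_gap = 100L,
                                     min_avg_spectra = 10) {
  loci <- as.data.table(loci)
  need <- c("gene_id", "contig_id", "start", "end", "strand",
            "spectra_count")
  miss <- setdiff(need, names(loci))
  if (length(miss)) stop("loci table is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(loci$start > loci$end)) stop("locus with start > end")
  setorder(loci, contig_id, start, end, gene_id)
  n <- nrow(loci)
  if (n == 0L) return(empty_operon_table())
  gap <- c(Inf, loci$start[-1L] - loci$end[-n] - 1L)
  if (any(gap[-1L] < 0)) {
    message(sum(gap[-1L] < 0), " overlapping gene pair(s): gap treated as 0")
    gap <- pmax(gap, 0)
  }
  new_chain <- c(TRUE, loci$contig_id[-1L] != loci$contig_id[-n] |
                   loci$strand[-1L] != loci$strand[-n] |
                   gap[-1L] > max_gap)
  loci[, cluster := cumsum(new_chain)]
  loci[, `:=`(n_genes = .N, mean_spectra = mean(spectra_count)),
       by = cluster]
  out <- loci[n_genes >= 2L & mean_spectra > min_avg_spectra]
  if (nrow(out) == 0L) return(empty_operon_table())
  out[, cluster := as.integer(factor(cluster, levels = unique(cluster)))]
  out[, c(intersect(c("cluster", "gene_id", "protein_id", "contig_id",
                      "start", "end", "strand", "spectra_count",
                      "mean_spectra", "n_genes"), names(out))),
      with = FALSE]
}

empty_operon_table <- function() {
  data.table(cluster = integer(), gene_id = character(),
             contig_id = character(), start = integer(), end = integer(),
             strand = character(), spectra_count = numeric(),
             mean_spectra = numeric(), n_genes = integer())
}

#' Read gene loci from GFF3 or a 6-column TSV
#'
#' For GFF3, CDS features are used; `gene_id` is taken from the `ID`
#' attribute and `protein_id` from `protein_id` or `ID`. Spectral counts are
#' attached afterwards by joining a protein-support table. The TSV form
#' expects a header with `gene_id`, `contig_id`, `start`, `end`, `strand`,
#' `spectra_count` (plus optional `protein_id`).
#'
#' @param path input file.
#' @return loci `data.table` suitable for [detect_expressed_operons()]
#'   (GFF3 input has `spectra_count = NA` until joined).
#' @export
read_gene_loci <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "##gff") || grepl("\t[^\t]*\tCDS\t", first)) {
    ln <- readLines(path)
    ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
    fields <- strsplit(ln, "\t", fixed = TRUE)
    fields <- fields[vapply(fields, function(f)
      length(f) >= 9L && f[3L] == "CDS", TRUE)]
    if (!length(fields))
      stop("no CDS features found in GFF3 file: ", path)
    gff <- data.table(V1 = vapply(fields, `[`, "", 1L),
                      V4 = vapply(fields, `[`, "", 4L),
                      V5 = vapply(fields, `[`, "", 5L),
                      V7 = vapply(fields, `[`, "", 7L),
                      V9 = vapply(fields, `[`, "", 9L))
    ids <- vapply(gff$V9, function(a) {
      m <- regmatches(a, regexpr("ID=[^;]+", a))
      if (length(m)) sub("^ID=", "", m) else NA_character_
    }, "")
    pid <- vapply(gff$V9, function(a) {
      m <- regmatches(a, regexpr("protein_id=[^;]+", a))
      if (length(m)) sub("^protein_id=", "", m) else NA_character_
    }, "")
    return(data.table(gene_id = ids,
                      protein_id = ifelse(is.na(pid), ids, pid),
                      contig_id = as.character(gff$V1),
                      start = as.integer(gff$V4), end = as.integer(gff$V5),
                      strand = as.character(gff$V7),
                      spectra_count = NA_real_))
  }
  x <- fread(path, sep = "\t", header = TRUE)
  need <- c("gene_id", "contig_id", "start", "end", "strand",
            "spectra_count")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("loci TSV is missing column(s): ",
                         paste(miss, collapse = ", "))
  x
}
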