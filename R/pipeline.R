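#' Pipeline configuration
#'
#' Bundles everything the two-step pipeline needs: search parameters, FDR
#' target, greedy coverage threshold, decoy prefix, the minimum step-1
#' spectral support for carrying a HAP into the expanded database, and a
#' seed recorded for provenance.
#'
#' @param params a [search_params()] object.
#' @param fdr PSM-level FDR target for both steps (default 0.01).
#' @param coverage_threshold greedy coverage threshold (default 0.8).
#' @param decoy_prefix decoy protein id prefix.
#' @param min_hap_support minimum FDR-passing step-1 PSMs for a HAP to be
#'   added to the expanded database (default 1).
#' @param seed integer recorded in the result for reproducibility.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(params = search_params(), fdr = 0.01,
                            coverage_threshold = 0.8, decoy_prefix = "XXX_",
                            min_hap_support = 1L, seed = 1L) {
  structure(list(params = params, fdr = fdr,
                 coverage_threshold = coverage_threshold,
                 decoy_prefix = decoy_prefix,
                 min_hap_support = as.integer(min_hap_support),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys mirror [pipeline_config()] and [search_params()]; absent
#' keys keep their defaults.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configurations")
  y <- yaml::read_yaml(path)
  p_args <- y[intersect(names(y), names(formals(search_params)))]
  c_args <- y[intersect(names(y), setdiff(names(formals(pipeline_config)),
                                          "params"))]
  do.call(pipeline_config, c(list(params = do.call(search_params, p_args)),
                             c_args))
}

#' Build the sample-specific expanded search database
#'
#' Step-2 database: all proteins encoded by the genomes chosen in the
#' profiling step, supplemented with every HAP that had spectral support in
#' step 1 (even when its genome was not selected), deduplicated and
#' decoy-augmented.
#'
#' @param selection a `genome_selection` from [greedy_cover()] (or a
#'   character vector of genome ids).
#' @param supported_haps character vector of HAP protein ids with step-1
#'   spectral support (may be empty).
#' @param registry full protein record table (pre-deduplication).
#' @param decoy_prefix decoy id prefix.
#' @return a `search_db`.
#' @export
build_expanded_db <- function(selection, supported_haps, registry,
                              decoy_prefix = "XXX_") {
  sel_genomes <- if (is.character(selection)) selection
                 else selection$genome_id
  if (length(sel_genomes) == 0L) stop("empty genome selection")
  reg <- as.data.table(registry)
  if ("is_decoy" %in% names(reg)) reg <- reg[is_decoy == FALSE]
  pick <- reg[genome_id %in% sel_genomes |
              protein_id %in% supported_haps]
  if (nrow(pick) == 0L) stop("selection matches no registered proteins")
  dd <- deduplicate_exact(pick)
  new_search_db(dd$records, generate_decoys(dd$records, decoy_prefix),
                dd$dedup_map, decoy_prefix)
}

# HAP protein ids with >= min_support FDR-passing PSMs in the step-1 search,
# expanded through the HAPdb dedup map so collapsed twins are carried too.
supported_hap_ids <- function(kept_psms, hapdb, min_support = 1L) {
  if (nrow(kept_psms) == 0L) return(character())
  long <- kept_psms[, .(protein_id =
                          strsplit(proteins, ";", fixed = TRUE)[[1L]]),
                    by = spectrum_id]
  counts <- long[, .(n = length(unique(spectrum_id))), by = protein_id]
  ids <- counts[n >= min_support, protein_id]
  ids <- setdiff(ids, hapdb$decoys$protein_id)
  if (nrow(hapdb$dedup_map)) {
    dm <- hapdb$dedup_map
    ids <- union(ids, dm$removed_id[dm$kept_id %in% ids])
  }
  ids
}

#' Run the full two-step identification pipeline
#'
#' Step 1 (profiling): build the HAPdb from flagged records, search the
#' spectra, filter at the FDR target, and select genomes by greedy cover of
#' the identified spectra. Step 2 (expanded search): build the expanded
#' database from the selected genomes plus spectrally supported HAPs,
#' re-search all spectra, and filter at the FDR target. Only step-2
#' identifications form the final peptide set — step-1 PSMs are never merged
#' into the results, so the final FDR is estimated within a single search.
#'
#' @param spectra list of spectrum records (see [read_mgf()]).
#' @param records full protein record table with HAP flags set.
#' @param config a [pipeline_config()].
#' @param external_psms optional list with elements `profiling` and
#'   `expanded`: pre-computed PSM tables (see [parse_external_psms()]) used
#'   in place of the built-in search engine for the respective steps.
#' @return a `two_step_result` list: `hapdb`, `step1` (psms, fdr, kept),
#'   `incidence`, `selection`, `supported_haps`, `expanded_db`, `step2`,
#'   `peptides` (final table: `peptide`, `n_spectra`, `proteins`, `genomes`,
#'   `best_score`), `config`.
#' @export
run_two_step <- function(spectra, records, config = pipeline_config(),
                         external_psms = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  records <- as.data.table(records)
  hapdb <- stage("build_hapdb", build_hapdb(records, config$decoy_prefix))

  psms1 <- stage("profiling_search", {
    if (!is.null(external_psms$profiling)) external_psms$profiling
    else search_spectra(spectra, build_peptide_index(hapdb, config$params))
  })
  fdr1 <- stage("profiling_fdr", compute_fdr_threshold(psms1, config$fdr))
  kept1 <- filter_psms(psms1, fdr1)

  inc <- stage("incidence", build_incidence(kept1, records, hapdb$dedup_map))
  selection <- stage("greedy_cover",
                     greedy_cover(inc, config$coverage_threshold))
  haps <- supported_hap_ids(kept1, hapdb, config$min_hap_support)

  expanded <- stage("build_expanded_db",
                    build_expanded_db(selection, haps, records,
                                      config$decoy_prefix))
  psms2 <- stage("expanded_search", {
    if (!is.null(external_psms$expanded)) external_psms$expanded
    else search_spectra(spectra, build_peptide_index(expanded, config$params))
  })
  fdr2 <- stage("expanded_fdr", compute_fdr_threshold(psms2, config$fdr))
  kept2 <- filter_psms(psms2, fdr2)

  peptides <- if (nrow(kept2)) {
    tab <- kept2[, .(n_spectra = .N,
                     proteins = paste(sort(unique(unlist(
                       strsplit(proteins, ";", fixed = TRUE)))),
                       collapse = ";"),
                     genomes = paste(sort(unique(unlist(
                       strsplit(genomes, ";", fixed = TRUE)))),
                       collapse = ";"),
                     best_score = max(score)),
                 by = peptide]
    setorder(tab, -n_spectra, peptide)
    tab[]
  } else {
    data.table(peptide = character(), n_spectra = integer(),
               proteins = character(), genomes = character(),
               best_score = numeric())
  }
  structure(list(hapdb = hapdb,
                 step1 = list(psms = psms1, fdr = fdr1, kept = kept1),
                 incidence = inc, selection = selection,
                 supported_haps = haps, expanded_db = expanded,
                 step2 = list(psms = psms2, fdr = fdr2, kept = kept2),
                 peptides = peptides, config = config),
            class = "two_step_result")
}

#' @export
print.two_step_result <- function(x, ...) {
  cat("<two_step_result>\n",
      "  step 1: ", nrow(x$step1$kept), " identified spectra; ",
      nrow(x$selection), " genomes selected (",
      round(100 * x$selection$cumulative_fraction[nrow(x$selection)], 1),
      "% coverage)\n",
      "  step 2: ", nrow(x$step2$kept), " identified spectra, ",
      nrow(x$peptides), " distinct peptides\n", sep = "")
  invisible(x)
}

#' Write the final peptide table as TSV
#' @param result a `two_step_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(result, path) {
  fwrite(result$peptides, path, sep = "\t")
  invisible(path)
}
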