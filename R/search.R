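#' Search parameter set
#'
#' Defaults follow common high-resolution settings for gut metaproteomics:
#' 15 ppm precursor tolerance with isotope error -1..2, 20 ppm fragment
#' tolerance, up to two missed cleavages, semi-tryptic peptides allowed, at
#' most three variable modifications (oxidised methionine) on top of fixed
#' carbamidomethyl cysteine, precursor charges 1 to 7.
#'
#' @param precursor_tol_ppm precursor mass tolerance, ppm.
#' @param isotope_error_range integer vector `c(min, max)` of allowed
#'   isotope-peak mis-assignments.
#' @param fragment_tol_ppm fragment ion tolerance, ppm.
#' @param missed_cleavages_max maximum missed cleavages.
#' @param semi_tryptic allow peptides with one non-tryptic terminus.
#' @param enzyme `"trypsin/P"` or `"trypsin"`.
#' @param min_length,max_length peptide length bounds.
#' @param max_var_mods maximum variable modifications per peptide.
#' @param fixed_mods list of `list(residue =, delta =)`.
#' @param var_mods list of `list(residue =, delta =)`.
#' @param charge_range allowed precursor charge range.
#' @param min_peaks spectra with fewer peaks are skipped.
#' @return a `search_params` list.
#' @export
search_params <- function(precursor_tol_ppm = 15,
                          isotope_error_range = c(-1L, 2L),
                          fragment_tol_ppm = 20,
                          missed_cleavages_max = 2L,
                          semi_tryptic = TRUE,
                          enzyme = c("trypsin/P", "trypsin"),
                          min_length = 6L, max_length = 50L,
                          max_var_mods = 3L,
                          fixed_mods = list(list(residue = "C",
                                                 delta = 57.02146)),
                          var_mods = list(list(residue = "M",
                                               delta = 15.99491)),
                          charge_range = c(1L, 7L),
                          min_peaks = 10L) {
  enzyme <- match.arg(enzyme)
  stopifnot(precursor_tol_ppm > 0, fragment_tol_ppm > 0,
            length(isotope_error_range) == 2L,
            isotope_error_range[1L] <= isotope_error_range[2L],
            charge_range[1L] <= charge_range[2L], charge_range[1L] >= 1L)
  structure(list(precursor_tol_ppm = precursor_tol_ppm,
                 isotope_error_range = as.integer(isotope_error_range),
                 fragment_tol_ppm = fragment_tol_ppm,
                 missed_cleavages_max = as.integer(missed_cleavages_max),
                 semi_tryptic = isTRUE(semi_tryptic),
                 enzyme = enzyme,
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length),
                 max_var_mods = as.integer(max_var_mods),
                 fixed_mods = fixed_mods, var_mods = var_mods,
                 charge_range = as.integer(charge_range),
                 min_peaks = as.integer(min_peaks)),
            class = "search_params")
}

#' Build a mass-indexed peptide candidate set from a search database
#'
#' Digests every target and decoy protein, collapses identical peptide
#' strings while merging protein provenance, computes monoisotopic masses
#' (fixed modifications folded in) and enumerates variable-modification
#' forms up to `max_var_mods`. A peptide is a decoy candidate only when every
#' protein containing it is a decoy.
#'
#' @param db a `search_db` object.
#' @param params a [search_params()] object.
#' @return a `peptide_index`: list with `peptides` (`data.table` sorted by
#'   `mass`, columns `peptide`, `mods` (comma-joined 1-based positions of
#'   oxidised residues, `""` if none), `mass`, `is_decoy`), `prot_map`
#'   (peptide to `protein_id`/`genome_id`), and `params`.
#' @export
build_peptide_index <- function(db, params = search_params()) {
  stopifnot(inherits(db, "search_db"))
  recs <- rbind(db$targets, db$decoys)
  digests <- lapply(seq_len(nrow(recs)), function(i) {
    d <- digest_protein(recs$sequence[i],
                        missed_cleavages_max = params$missed_cleavages_max,
                        semi_tryptic = params$semi_tryptic,
                        enzyme = params$enzyme,
                        min_length = params$min_length,
                        max_length = params$max_length)
    if (nrow(d) == 0L) return(NULL)
    data.table(peptide = d$peptide, protein_id = recs$protein_id[i],
               genome_id = recs$genome_id[i], is_decoy = recs$is_decoy[i])
  })
  long <- rbindlist(digests)
  if (nrow(long) == 0L) stop("digestion produced no peptides")
  prot_map <- unique(long[, .(peptide, protein_id, genome_id)])
  peps <- long[, .(is_decoy = all(is_decoy)), by = peptide]

  # masses via one residue-table lookup over the unlisted characters
  tbl <- residue_mass_table(params$fixed_mods)
  chars <- strsplit(peps$peptide, "", fixed = TRUE)
  u <- unlist(chars, use.names = FALSE)
  idx <- rep.int(seq_len(nrow(peps)), nchar(peps$peptide))
  rm_u <- tbl[u]
  mass <- as.numeric(rowsum(rm_u, idx, reorder = TRUE)) + WATER_MASS
  peps[, `:=`(mods = "", mass = mass)]
  peps <- peps[!is.na(mass)]   # drops peptides containing X

  # variable-modification forms
  if (params$max_var_mods > 0L && length(params$var_mods)) {
    extra <- list()
    for (vm in params$var_mods) {
      has <- grepl(vm$residue, peps$peptide, fixed = TRUE)
      if (!any(has)) next
      sub <- peps[has & mods == ""]
      pos_list <- gregexpr(vm$residue, sub$peptide, fixed = TRUE)
      mod_str <- vector("list", nrow(sub))
      mod_n <- vector("list", nrow(sub))
      for (i in seq_len(nrow(sub))) {
        pos <- as.integer(pos_list[[i]])
        if (length(pos) == 1L) {        # common case: a single modifiable site
          mod_str[[i]] <- as.character(pos)
          mod_n[[i]] <- 1L
          next
        }
        kmax <- min(length(pos), params$max_var_mods)
        combos <- unlist(lapply(seq_len(kmax), function(k)
          utils::combn(pos, k, simplify = FALSE)), recursive = FALSE)
        mod_str[[i]] <- vapply(combos, paste, "", collapse = ",")
        mod_n[[i]] <- lengths(combos)
      }
      reps <- lengths(mod_str)
      extra[[length(extra) + 1L]] <- data.table(
        peptide = rep.int(sub$peptide, reps),
        is_decoy = rep.int(sub$is_decoy, reps),
        mods = unlist(mod_str, use.names = FALSE),
        mass = rep.int(sub$mass, reps) +
          vm$delta * unlist(mod_n, use.names = FALSE))
    }
    if (length(extra))
      peps <- rbind(peps, rbindlist(extra, use.names = TRUE))
  }
  setorder(peps, mass, peptide, mods)
  setkey(prot_map, peptide)
  structure(list(peptides = peps, prot_map = prot_map, params = params),
            class = "peptide_index")
}

#' @export
print.peptide_index <- function(x, ...) {
  cat("<peptide_index> ", nrow(x$peptides), " candidates (",
      sum(!x$peptides$is_decoy), " target / ", sum(x$peptides$is_decoy),
      " decoy) from ", length(unique(x$prot_map$protein_id)),
      " proteins\n", sep = "")
  invisible(x)
}

# Candidate rows of the index within the precursor window of one spectrum.
precursor_candidates <- function(index, obs_neutral, params) {
  masses <- index$peptides$mass
  t <- params$precursor_tol_ppm / 1e6
  rows <- integer()
  for (k in params$isotope_error_range[1L]:params$isotope_error_range[2L]) {
    centre <- obs_neutral - k * ISOTOPE_MASS
    lo <- centre / (1 + t); hi <- centre / (1 - t)
    i1 <- findInterval(lo, masses) + 1L
    i2 <- findInterval(hi, masses)
    if (i2 >= i1) rows <- c(rows, i1:i2)
  }
  sort(unique(rows))
}

# Hyperscore-style fragment match score for candidate rows against one
# spectrum: ln(Nb!) + ln(Ny!) + ln(1 + sum of matched peak intensities),
# singly charged b/y ions only.
score_candidates <- function(cand, peaks, params, tbl) {
  vdelta <- if (length(params$var_mods)) params$var_mods[[1L]]$delta
            else 15.99491
  pk_mz <- peaks[, 1L]; pk_int <- peaks[, 2L]
  scores <- numeric(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    mp <- if (nzchar(cand$mods[i]))
      as.integer(strsplit(cand$mods[i], ",", fixed = TRUE)[[1L]])
    else integer()
    r <- peptide_residue_masses(cand$peptide[i], tbl, mp, vdelta)
    lad <- fragment_ladders(r)
    frag <- c(lad$b, lad$y)
    nb_len <- length(lad$b)
    if (!length(frag) || !length(pk_mz)) { scores[i] <- 0; next }
    j <- findInterval(frag, pk_mz)
    j_lo <- pmax(j, 1L)
    j_hi <- pmin(j + 1L, length(pk_mz))
    d_lo <- abs(frag - pk_mz[j_lo])
    d_hi <- abs(frag - pk_mz[j_hi])
    use_hi <- d_hi < d_lo
    jj <- ifelse(use_hi, j_hi, j_lo)
    dd <- pmin(d_lo, d_hi)
    tol <- params$fragment_tol_ppm * frag / 1e6
    hit <- dd <= tol & j >= 0L
    nb <- sum(hit[seq_len(nb_len)])
    ny <- sum(hit[-seq_len(nb_len)])
    isum <- sum(pk_int[jj[hit]])
    scores[i] <- lgamma(nb + 1) + lgamma(ny + 1) + log1p(isum)
  }
  scores
}

#' Match one spectrum against an indexed candidate set
#'
#' Candidates must satisfy the precursor filter
#' `|M_obs - M_pep - k * 1.00335| <= tol_ppm * M_pep / 1e6` for some isotope
#' error `k` in the configured range, where
#' `M_obs = precursor_mz * z - z * 1.007276`. Matched candidates are scored
#' by counting singly charged b/y fragment ions within the fragment
#' tolerance; the best-scoring candidate is returned, with deterministic
#' tie-breaking by peptide string and then target before decoy.
#'
#' @param spectrum one spectrum record (see [read_mgf()]).
#' @param index a `peptide_index` from [build_peptide_index()].
#' @param params a [search_params()] object.
#' @return one-row PSM `data.table` (`spectrum_id`, `peptide`, `mods`,
#'   `score`, `is_decoy`, `proteins`, `genomes`), or `NULL` when the
#'   spectrum is skipped (too few peaks, charge out of range) or no
#'   candidate passes the precursor filter.
#' @export
match_spectrum <- function(spectrum, index, params = index$params) {
  if (nrow(spectrum$peaks) < params$min_peaks) {
    message("skipping ", spectrum$spectrum_id, ": fewer than ",
            params$min_peaks, " peaks")
    return(NULL)
  }
  z <- spectrum$charge
  if (z < params$charge_range[1L] || z > params$charge_range[2L]) {
    message("skipping ", spectrum$spectrum_id, ": charge ", z,
            " outside configured range")
    return(NULL)
  }
  obs <- spectrum$precursor_mz * z - z * PROTON_MASS
  rows <- precursor_candidates(index, obs, params)
  if (!length(rows)) return(NULL)
  cand <- index$peptides[rows]
  tbl <- residue_mass_table(params$fixed_mods)
  sc <- score_candidates(cand, spectrum$peaks, params, tbl)
  ord <- order(-sc, cand$peptide, cand$is_decoy)
  best <- ord[1L]
  pm <- index$prot_map[J(cand$peptide[best]), on = "peptide"]
  data.table(spectrum_id = spectrum$spectrum_id,
             peptide = cand$peptide[best],
             mods = cand$mods[best],
             score = sc[best],
             is_decoy = cand$is_decoy[best],
             proteins = paste(sort(unique(pm$protein_id)), collapse = ";"),
             genomes = paste(sort(unique(pm$genome_id)), collapse = ";"))
}

#' Search a set of spectra against a peptide index
#'
#' Applies [match_spectrum()] to each spectrum and returns the
#' best-per-spectrum PSM table.
#'
#' @param spectra list of spectrum records.
#' @param index a `peptide_index`.
#' @param params a [search_params()] object (defaults to the index's).
#' @param quiet suppress per-spectrum skip messages.
#' @return PSM `data.table`, one row per matched spectrum.
#' @export
search_spectra <- function(spectra, index, params = index$params,
                           quiet = TRUE) {
  run <- function() rbindlist(
    lapply(spectra, match_spectrum, index = index, params = params))
  psms <- if (quiet) suppressMessages(run()) else run()
  if (nrow(psms) == 0L)
    return(data.table(spectrum_id = character(), peptide = character(),
                      mods = character(), score = numeric(),
                      is_decoy = logical(), proteins = character(),
                      genomes = character()))
  psms
}

#' Read an externally produced PSM table
#'
#' Adapter for driving the pipeline with PSMs from an external search engine.
#' Expects a TSV with columns `spectrum_id`, `peptide`, `score`,
#' `protein_ids` (semicolon-separated). Decoy status is derived from the
#' decoy id prefix: a PSM is a decoy only if every listed protein is a decoy.
#' The best PSM per spectrum is retained (ties broken by peptide string,
#' then target before decoy).
#'
#' @param path TSV file path.
#' @param decoy_prefix decoy protein id prefix.
#' @param registry optional protein record table used to attach genome ids.
#' @return PSM `data.table` in the same layout as [search_spectra()].
#' @export
parse_external_psms <- function(path, decoy_prefix = "XXX_",
                                registry = NULL) {
  x <- fread(path, sep = "\t", header = TRUE)
  need <- c("spectrum_id", "peptide", "score", "protein_ids")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("PSM table is missing column(s): ",
                         paste(miss, collapse = ", "))
  prots <- strsplit(x$protein_ids, ";", fixed = TRUE)
  x[, is_decoy := vapply(prots, function(p)
      all(startsWith(p, decoy_prefix)), TRUE)]
  genomes <- if (!is.null(registry)) {
    reg <- setNames(registry$genome_id, registry$protein_id)
    vapply(prots, function(p) {
      g <- reg[sub(paste0("^", decoy_prefix), "", p)]
      paste(sort(unique(g[!is.na(g)])), collapse = ";")
    }, "")
  } else ""
  out <- data.table(spectrum_id = as.character(x$spectrum_id),
                    peptide = as.character(x$peptide), mods = "",
                    score = as.numeric(x$score), is_decoy = x$is_decoy,
                    proteins = x$protein_ids, genomes = genomes)
  setorder(out, spectrum_id, -score, peptide, is_decoy)
  out[!duplicated(spectrum_id)]
}

#' Write a PSM table as TSV
#' @param psms PSM table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_psms <- function(psms, path) {
  fwrite(psms, path, sep = "\t")
  invisible(path)
}
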