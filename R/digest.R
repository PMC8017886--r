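#' In-silico tryptic digestion
#'
#' Cleaves a protein C-terminal to lysine (K) or arginine (R). Under the
#' `"trypsin/P"` dialect, cleavage occurs even when the next residue is
#' proline; under `"trypsin"` it does not. Fully tryptic peptides with up to
#' `missed_cleavages_max` internal cleavage sites are produced; with
#' `semi_tryptic = TRUE`, peptides with exactly one non-tryptic terminus are
#' added (the protein termini count as tryptic). Duplicate peptide strings
#' are collapsed, keeping the smallest missed-cleavage count and the
#' fully-tryptic status if any occurrence is fully tryptic.
#'
#' @param sequence amino-acid string.
#' @param missed_cleavages_max maximum internal missed cleavages (default 2).
#' @param semi_tryptic also emit semi-tryptic peptides (default `FALSE`).
#' @param enzyme `"trypsin/P"` (default) or `"trypsin"`.
#' @param min_length,max_length peptide length bounds (defaults 6 and 50).
#' @return `data.table` with columns `peptide`, `start`, `end` (1-based in
#'   the parent sequence, first occurrence), `missed_cleavages`,
#'   `semi_tryptic`.
#' @export
digest_protein <- function(sequence, missed_cleavages_max = 2L,
                           semi_tryptic = FALSE,
                           enzyme = c("trypsin/P", "trypsin"),
                           min_length = 6L, max_length = 50L) {
  enzyme <- match.arg(enzyme)
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence),
            missed_cleavages_max >= 0L, min_length >= 1L,
            max_length >= min_length)
  res <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(res)
  sites <- cleavage_sites(res, enzyme)           # positions i: cut after i
  bounds <- c(0L, sites, n)                       # tryptic boundaries
  # cumulative count of cleavage sites at or before each position
  csum <- integer(n)
  if (length(sites)) csum[sites] <- 1L
  csum <- cumsum(csum)
  n_internal <- function(st, en) {                # sites i with st <= i < en
    if (en == 1L) return(0L)
    csum[en - 1L] - (if (st > 1L) csum[st - 1L] else 0L)
  }

  starts <- integer(); ends <- integer(); semis <- logical()
  nb <- length(bounds)
  # fully tryptic: consecutive boundary pairs within the missed-cleavage window
  for (a in seq_len(nb - 1L)) {
    bmax <- min(nb, a + 1L + missed_cleavages_max)
    for (b in (a + 1L):bmax) {
      starts <- c(starts, bounds[a] + 1L); ends <- c(ends, bounds[b])
      semis <- c(semis, FALSE)
    }
  }
  if (semi_tryptic) {
    site_after <- function(k) {   # position of the (k)-th cleavage site, or n
      if (k <= length(sites)) sites[k] else n
    }
    tryptic_start <- bounds[-nb] + 1L
    tryptic_end <- bounds[-1L]
    for (a in seq_len(nb - 1L)) {                 # tryptic N-term, ragged C
      st <- bounds[a] + 1L
      base <- if (st > 1L) csum[st - 1L] else 0L
      emax <- site_after(base + missed_cleavages_max + 1L)
      e <- setdiff(st:emax, tryptic_end)
      if (length(e)) {
        starts <- c(starts, rep(st, length(e))); ends <- c(ends, e)
        semis <- c(semis, rep(TRUE, length(e)))
      }
    }
    site_before <- function(k) {  # k-th site from the end going backwards
      if (k <= length(sites)) sites[length(sites) - k + 1L] else 0L
    }
    for (b in 2L:nb) {                            # tryptic C-term, ragged N
      en <- bounds[b]
      ncut_before_en <- csum[max(en - 1L, 1L)] * (en > 1L)
      # smallest start keeping internal sites <= max
      k_lim <- ncut_before_en - missed_cleavages_max
      smin <- if (k_lim >= 1L) sites[k_lim] + 1L else 1L
      s <- setdiff(smin:en, tryptic_start)
      if (length(s)) {
        starts <- c(starts, s); ends <- c(ends, rep(en, length(s)))
        semis <- c(semis, rep(TRUE, length(s)))
      }
    }
  }
  len <- ends - starts + 1L
  keep <- len >= min_length & len <= max_length & len >= 1L
  starts <- starts[keep]; ends <- ends[keep]; semis <- semis[keep]
  if (length(starts) == 0L)
    return(data.table(peptide = character(), start = integer(),
                      end = integer(), missed_cleavages = integer(),
                      semi_tryptic = logical()))
  out <- data.table(
    peptide = substring(sequence, starts, ends),
    start = starts, end = ends,
    missed_cleavages = mapply(n_internal, starts, ends),
    semi_tryptic = semis)
  # collapse duplicates: prefer fully tryptic, then fewest missed cleavages
  setorder(out, peptide, semi_tryptic, missed_cleavages, start)
  out <- out[!duplicated(peptide)]
  setorder(out, start, end)
  out[]
}

# Cleavage-site positions: cut between i and i+1 when residue i is K/R
# (and, for strict trypsin, residue i+1 is not P).
cleavage_sites <- function(res, enzyme) {
  n <- length(res)
  if (n < 2L) return(integer())
  i <- which(res[-n] %in% c("K", "R"))
  if (enzyme == "trypsin") i <- i[res[i + 1L] != "P"]
  i
}
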