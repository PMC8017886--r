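# Monoisotopic constants (Da)
PROTON_MASS  <- 1.007276
WATER_MASS   <- 18.010565
ISOTOPE_MASS <- 1.00335

# Monoisotopic residue masses for the 20 standard amino acids.
RESIDUE_MASS <- c(
  G =  57.02146, A =  71.03711, S =  87.03203, P =  97.05276, V =  99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

VALID_RESIDUES <- c(names(RESIDUE_MASS), "X")

#' Residue mass table under a set of fixed modifications
#'
#' @param fixed_mods list of `list(residue =, delta =)` entries.
#' @param x_mass optional mass to assign to the ambiguous residue `X`
#'   (default `NA`: peptides containing `X` cannot be massed).
#' @return named numeric vector of residue masses.
#' @keywords internal
residue_mass_table <- function(fixed_mods = list(), x_mass = NA_real_) {
  tbl <- c(RESIDUE_MASS, X = x_mass)
  for (m in fixed_mods) {
    if (!m$residue %in% names(tbl))
      stop("fixed modification on unknown residue: ", m$residue)
    tbl[m$residue] <- tbl[m$residue] + m$delta
  }
  tbl
}

#' Monoisotopic peptide mass
#'
#' Neutral monoisotopic mass: sum of residue masses plus one water, plus the
#' mass deltas of any modifications. Fixed modifications are folded into the
#' residue table; variable modifications are passed as `var_deltas`.
#'
#' @param peptide amino-acid string (uppercase).
#' @param fixed_mods list of fixed modifications, as in [search_params()].
#' @param var_deltas numeric vector of additional modification mass deltas
#'   (positions do not affect the precursor mass).
#' @param x_mass optional mass for residue `X`.
#' @return neutral mass in Da.
#' @examples
#' peptide_mass("PEPTIDE")  # 799.3600
#' @export
peptide_mass <- function(peptide, fixed_mods = list(), var_deltas = numeric(),
                         x_mass = NA_real_) {
  stopifnot(is.character(peptide), length(peptide) == 1L, nzchar(peptide))
  tbl <- residue_mass_table(fixed_mods, x_mass)
  res <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  bad <- setdiff(res, names(tbl))
  if (length(bad))
    stop("unknown residue(s) in peptide: ", paste(unique(bad), collapse = ", "))
  m <- tbl[res]
  if (anyNA(m))
    stop("peptide contains residue X with no configured mass: ", peptide)
  sum(m) + WATER_MASS + sum(var_deltas)
}

# Residue mass vector for one peptide, with fixed mods folded in and
# variable-mod deltas added at 1-based positions. Internal fast path used by
# the scorer and the spectrum simulator.
peptide_residue_masses <- function(peptide, tbl, mod_pos = integer(),
                                   mod_delta = 15.99491) {
  r <- tbl[strsplit(peptide, "", fixed = TRUE)[[1L]]]
  if (length(mod_pos)) r[mod_pos] <- r[mod_pos] + mod_delta
  unname(r)
}

# Singly charged b/y fragment m/z ladders for a residue-mass vector.
fragment_ladders <- function(res_masses) {
  n <- length(res_masses)
  if (n < 2L) return(list(b = numeric(), y = numeric()))
  cs <- cumsum(res_masses)
  b <- cs[seq_len(n - 1L)] + PROTON_MASS
  y <- (cs[n] - cs[seq_len(n - 1L)]) + WATER_MASS + PROTON_MASS
  list(b = b, y = rev(y))  # y ordered y1..y(n-1) (suffix length 1 upward)
}
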