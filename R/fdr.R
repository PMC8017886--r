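#' Target-decoy FDR threshold
#'
#' Estimates the false discovery rate at every distinct score cutoff by the
#' target-decoy approach and returns the lowest cutoff whose estimated FDR
#' is at or below the target — i.e. the cutoff keeping the most target PSMs.
#' The default estimator is `#decoys >= t / max(1, #targets >= t)`; the
#' symmetric variant `2 D / (T + D)` is available via `estimator`.
#'
#' @param psms best-per-spectrum PSM table with `score` and `is_decoy`.
#' @param target_fdr FDR target in (0, 1); default 0.01.
#' @param estimator `"dt"` (decoys over targets, default) or `"combined"`.
#' @return an `fdr_result`: `score_threshold` (`Inf` when no cutoff
#'   qualifies), `n_targets_kept`, `n_decoys_kept`, `estimated_fdr`,
#'   `target_fdr`, `estimator`.
#' @export
compute_fdr_threshold <- function(psms, target_fdr = 0.01,
                                  estimator = c("dt", "combined")) {
  estimator <- match.arg(estimator)
  if (!is.numeric(target_fdr) || target_fdr <= 0 || target_fdr >= 1)
    stop("target_fdr must be in (0, 1)")
  if (nrow(psms) == 0L)
    return(structure(list(score_threshold = Inf, n_targets_kept = 0L,
                          n_decoys_kept = 0L, estimated_fdr = NA_real_,
                          target_fdr = target_fdr, estimator = estimator),
                     class = "fdr_result"))
  if (!any(psms$is_decoy))
    warning("no decoy PSMs present; FDR estimate is uninformative")
  ord <- order(-psms$score)
  sc <- psms$score[ord]
  dec <- psms$is_decoy[ord]
  cum_t <- cumsum(!dec)
  cum_d <- cumsum(dec)
  # evaluate at the last row of each distinct score (all ties included)
  last_of_score <- !duplicated(sc, fromLast = TRUE)
  t_at <- cum_t[last_of_score]; d_at <- cum_d[last_of_score]
  s_at <- sc[last_of_score]
  fdr_at <- switch(estimator,
                   dt = d_at / pmax(1L, t_at),
                   combined = 2 * d_at / pmax(1L, t_at + d_at))
  ok <- which(fdr_at <= target_fdr)
  if (!length(ok))
    return(structure(list(score_threshold = Inf, n_targets_kept = 0L,
                          n_decoys_kept = 0L, estimated_fdr = NA_real_,
                          target_fdr = target_fdr, estimator = estimator),
                     class = "fdr_result"))
  i <- max(ok)   # lowest qualifying score, most targets kept
  structure(list(score_threshold = s_at[i],
                 n_targets_kept = t_at[i],
                 n_decoys_kept = d_at[i],
                 estimated_fdr = fdr_at[i],
                 target_fdr = target_fdr, estimator = estimator),
            class = "fdr_result")
}

#' @export
print.fdr_result <- function(x, ...) {
  cat("<fdr_result> threshold ", format(x$score_threshold), ": ",
      x$n_targets_kept, " targets / ", x$n_decoys_kept,
      " decoys kept (estimated FDR ", format(x$estimated_fdr),
      " at target ", x$target_fdr, ")\n", sep = "")
  invisible(x)
}

#' Filter PSMs at an FDR threshold
#'
#' Returns target PSMs with score at or above the threshold; decoys are
#' excluded from the identified set.
#'
#' @param psms PSM table.
#' @param result an `fdr_result` from [compute_fdr_threshold()] on the same
#'   table.
#' @return filtered PSM table.
#' @export
filter_psms <- function(psms, result) {
  stopifnot(inherits(result, "fdr_result"))
  as.data.table(psms)[!is_decoy & score >= result$score_threshold]
}

#' Write an FDR summary as JSON
#' @param result an `fdr_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fdr_summary <- function(result, path) {
  jsonlite::write_json(unclass(result), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
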