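#' Read MS/MS spectra from a Mascot generic format (MGF) file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks with `TITLE`, `PEPMASS` and
#' `CHARGE` headers. Peak lines carry m/z and intensity; peaks are sorted by
#' m/z on read.
#'
#' @param path MGF file path.
#' @return list of spectrum records, each a list with `spectrum_id`,
#'   `precursor_mz`, `charge`, `peaks` (two-column matrix `mz`, `intensity`).
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("cannot read MGF file: ", path)
  lines <- readLines(path)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins))
    stop("malformed MGF (unbalanced BEGIN IONS/END IONS): ", path)
  out <- vector("list", length(begins))
  for (k in seq_along(begins)) {
    block <- lines[(begins[k] + 1L):(ends[k] - 1L)]
    hdr <- grepl("=", block, fixed = TRUE)
    keys <- sub("=.*$", "", block[hdr])
    vals <- sub("^[^=]*=", "", block[hdr])
    title <- vals[match("TITLE", keys)]
    pepmass <- as.numeric(strsplit(vals[match("PEPMASS", keys)], "\\s+")[[1L]][1L])
    charge_raw <- vals[match("CHARGE", keys)]
    charge <- if (is.na(charge_raw)) 2L
              else as.integer(sub("\\+$", "", charge_raw))
    pk <- block[!hdr & nzchar(trimws(block))]
    peaks <- if (length(pk)) {
      m <- do.call(rbind, lapply(strsplit(trimws(pk), "\\s+"),
                                 function(x) as.numeric(x[1:2])))
      colnames(m) <- c("mz", "intensity")
      m[order(m[, 1L]), , drop = FALSE]
    } else {
      matrix(numeric(), ncol = 2L, dimnames = list(NULL, c("mz", "intensity")))
    }
    out[[k]] <- list(spectrum_id = if (is.na(title)) paste0("spectrum_", k)
                                   else title,
                     precursor_mz = pepmass, charge = charge, peaks = peaks)
  }
  out
}

#' Write spectra to MGF
#'
#' @param spectra list of spectrum records (see [read_mgf()]).
#' @param path output path.
#' @param digits decimal places for m/z and intensity values.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path, digits = 5L) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  fmt <- paste0("%.", digits, "f")
  for (sp in spectra) {
    writeLines(c("BEGIN IONS",
                 paste0("TITLE=", sp$spectrum_id),
                 paste0("PEPMASS=", sprintf(fmt, sp$precursor_mz)),
                 paste0("CHARGE=", sp$charge, "+"),
                 sprintf(paste(fmt, fmt), sp$peaks[, 1L], sp$peaks[, 2L]),
                 "END IONS"), con)
  }
  invisible(path)
}
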