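#' Select HAPs by annotation keyword
#'
#' Flags proteins whose product annotation contains any of the given keywords
#' as a case-insensitive substring. The default keywords are the two phrases
#' that define high-abundance proteins in this pipeline: ribosomal proteins
#' and translation elongation factors.
#'
#' @param records protein record table with an `annotation` column.
#' @param keywords character vector of keywords; must be non-empty.
#' @return character vector of selected `protein_id`s.
#' @export
select_haps_by_keyword <- function(records,
                                   keywords = c("ribosomal protein",
                                                "elongation factor")) {
  if (length(keywords) == 0L || all(!nzchar(keywords)))
    stop("keyword list must be non-empty")
  ann <- tolower(records$annotation)
  hit <- rep(FALSE, length(ann))
  for (kw in tolower(keywords))
    hit <- hit | grepl(kw, ann, fixed = TRUE)
  records$protein_id[hit]
}

#' Select HAPs from HMM domain-scan hits
#'
#' Flags proteins that have at least one domain hit against an allowed
#' profile with E-value at or below the cutoff. The cutoff is applied per
#' reported hit row (the per-domain independent E-value when a HMMER3 domain
#' table is parsed).
#'
#' @param hits `data.table` with columns `protein_id`, `profile_name`,
#'   `e_value` (see [read_domain_hits()]).
#' @param allowed_profiles character vector of profile names to accept; the
#'   package ships a default list of ribosomal-protein and elongation-factor
#'   Pfam family names in
#'   `system.file("extdata", "hap_pfam_profiles.txt", package = "profex")`.
#' @param e_cutoff E-value cutoff (default `1e-10`); must be positive.
#' @return character vector of selected `protein_id`s.
#' @export
select_haps_by_domain <- function(hits, allowed_profiles, e_cutoff = 1e-10) {
  if (!is.numeric(e_cutoff) || length(e_cutoff) != 1L || e_cutoff <= 0)
    stop("e_cutoff must be a positive number")
  if (length(allowed_profiles) == 0L)
    stop("allowed_profiles must be non-empty")
  if (any(hits$e_value <= 0))
    stop("E-values must be positive")
  sel <- hits$profile_name %in% allowed_profiles & hits$e_value <= e_cutoff
  unique(hits$protein_id[sel])
}

#' Read domain-scan hits (HMMER3 domain table or plain TSV)
#'
#' Accepts either the whitespace-delimited HMMER3 `--domtblout` dialect
#' (comment lines start with `#`; the profile name is the target column, the
#' protein the query column, and the per-domain independent E-value is taken)
#' or a simple 3-column TSV with a header `protein_id`, `profile_name`,
#' `e_value`.
#'
#' @param path input file.
#' @param format `"auto"` (default), `"domtbl"` or `"tsv"`.
#' @return `data.table` with columns `protein_id`, `profile_name`, `e_value`.
#' @export
read_domain_hits <- function(path, format = c("auto", "domtbl", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read domain-hit file: ", path)
  lines <- readLines(path)
  if (format == "auto") {
    first <- lines[!startsWith(lines, "#") & nzchar(lines)][1L]
    format <- if (!is.na(first) && grepl("^protein_id\t", first)) "tsv"
              else "domtbl"
  }
  if (format == "tsv") {
    hits <- fread(path, sep = "\t", header = TRUE)
    miss <- setdiff(c("protein_id", "profile_name", "e_value"), names(hits))
    if (length(miss)) stop("domain TSV is missing column(s): ",
                           paste(miss, collapse = ", "))
    return(hits[, .(protein_id = as.character(protein_id),
                    profile_name = as.character(profile_name),
                    e_value = as.numeric(e_value))])
  }
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) == 0L)
    return(data.table(protein_id = character(), profile_name = character(),
                      e_value = numeric()))
  fields <- strsplit(trimws(body), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 13L))
    stop("malformed HMMER3 domain table row: ", body[which(nf < 13L)[1L]])
  # domtblout columns: 1 target (profile), 4 query (protein), 13 i-Evalue
  data.table(protein_id = vapply(fields, `[`, "", 4L),
             profile_name = vapply(fields, `[`, "", 1L),
             e_value = as.numeric(vapply(fields, `[`, "", 13L)))
}

#' Read an allowed-profile list (one profile name per line)
#' @param path text file; blank lines and `#` comments are skipped.
#' @return character vector of profile names.
#' @export
read_profile_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Flag high-abundance proteins on a record table
#'
#' Sets `is_hap` from keyword evidence, domain evidence, or both; when both
#' are supplied the union of the two selections is flagged (the
#' recall-oriented reading: keywords seed the concept, domain profiles
#' generalise it to unannotated MAG proteins).
#'
#' @param records protein record table.
#' @param keywords keyword vector for [select_haps_by_keyword()], or `NULL`
#'   to skip keyword evidence.
#' @param domain_hits domain-hit table for [select_haps_by_domain()], or
#'   `NULL`.
#' @param allowed_profiles profile names, required with `domain_hits`.
#' @param e_cutoff E-value cutoff for domain evidence.
#' @return the record table with `is_hap` updated.
#' @export
apply_hap_flags <- function(records, keywords = c("ribosomal protein",
                                                  "elongation factor"),
                            domain_hits = NULL, allowed_profiles = NULL,
                            e_cutoff = 1e-10) {
  records <- as.data.table(records)
  sel <- character()
  if (!is.null(keywords))
    sel <- select_haps_by_keyword(records, keywords)
  if (!is.null(domain_hits)) {
    if (is.null(allowed_profiles))
      stop("allowed_profiles is required with domain_hits")
    sel <- union(sel, select_haps_by_domain(domain_hits, allowed_profiles,
                                            e_cutoff))
  }
  records[, is_hap := protein_id %in% sel]
  records[]
}
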