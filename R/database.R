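#' Collapse proteins with 100% identical sequences
#'
#' Exact-string deduplication: one record is retained per distinct sequence —
#' the first in input order — and every removed id is mapped to its retained
#' representative. The representative's HAP flag is the logical OR over all
#' records collapsed into it, so a HAP annotated in only one genome keeps its
#' status.
#'
#' @param records protein record table (see [load_fasta_collection()]).
#' @return list with `records` (retained rows) and `dedup_map`
#'   (`data.table` with columns `removed_id`, `kept_id`; empty when all
#'   sequences are distinct).
#' @export
deduplicate_exact <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  records <- as.data.table(records)
  first <- !duplicated(records$sequence)
  kept <- records[first]
  # OR of HAP flags within each identical-sequence group
  grp_hap <- records[, .(hap_any = any(is_hap)), by = sequence]
  kept[, is_hap := grp_hap$hap_any[match(sequence, grp_hap$sequence)]]
  rep_of <- setNames(kept$protein_id, kept$sequence)
  removed <- records[!first]
  dedup_map <- data.table(removed_id = removed$protein_id,
                          kept_id = unname(rep_of[removed$sequence]))
  list(records = kept[], dedup_map = dedup_map)
}

#' Generate reversed-sequence decoys
#'
#' One decoy per target: the decoy sequence is the full reversal of the target
#' sequence, the decoy id is the target id with `decoy_prefix` prepended, and
#' the genome attribution mirrors the target's. Palindromic sequences (equal
#' to their own reversal) are permitted and reported via a message.
#'
#' @param records deduplicated protein record table.
#' @param decoy_prefix id prefix marking decoys (default `"XXX_"`).
#' @return decoy record table with `is_decoy = TRUE`.
#' @export
generate_decoys <- function(records, decoy_prefix = "XXX_") {
  stopifnot(nrow(records) > 0L, nzchar(decoy_prefix))
  if (any(startsWith(records$protein_id, decoy_prefix)))
    stop("decoy prefix '", decoy_prefix,
         "' collides with existing protein id(s); choose another prefix")
  rev_seq <- vapply(strsplit(records$sequence, "", fixed = TRUE),
                    function(x) paste(rev(x), collapse = ""), "")
  n_pal <- sum(rev_seq == records$sequence)
  if (n_pal > 0L)
    message(n_pal, " palindromic sequence(s): decoy equals target")
  data.table(protein_id = paste0(decoy_prefix, records$protein_id),
             genome_id = records$genome_id,
             sequence = rev_seq,
             annotation = records$annotation,
             is_hap = records$is_hap,
             is_decoy = TRUE)
}

new_search_db <- function(targets, decoys, dedup_map, decoy_prefix) {
  structure(list(targets = targets, decoys = decoys, dedup_map = dedup_map,
                 decoy_prefix = decoy_prefix),
            class = "search_db")
}

#' @export
print.search_db <- function(x, ...) {
  cat("<search_db> ", nrow(x$targets), " targets + ", nrow(x$decoys),
      " decoys (", length(unique(x$targets$genome_id)), " genomes, ",
      nrow(x$dedup_map), " collapsed duplicates)\n", sep = "")
  invisible(x)
}

#' Build the high-abundance protein database (HAPdb)
#'
#' Restricts a flagged record collection to HAPs (ribosomal proteins and
#' elongation factors, `is_hap = TRUE`), deduplicates identical sequences and
#' adds reversed decoys. This is the step-1 profiling database.
#'
#' @param records protein record table with HAP flags set (see
#'   [apply_hap_flags()]).
#' @param decoy_prefix decoy id prefix.
#' @return a `search_db` object: `targets`, `decoys`, `dedup_map`,
#'   `decoy_prefix`.
#' @export
build_hapdb <- function(records, decoy_prefix = "XXX_") {
  haps <- as.data.table(records)[is_hap == TRUE]
  if (nrow(haps) == 0L)
    stop("no HAP-flagged records: run HAP extraction (apply_hap_flags) first")
  dd <- deduplicate_exact(haps)
  new_search_db(dd$records, generate_decoys(dd$records, decoy_prefix),
                dd$dedup_map, decoy_prefix)
}

#' Write a dedup map as two-column TSV
#' @param dedup_map table with `removed_id`, `kept_id`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dedup_map <- function(dedup_map, path) {
  fwrite(dedup_map, path, sep = "\t")
  invisible(path)
}
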