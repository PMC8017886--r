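#' Load protein FASTA files into a genome-keyed record table
#'
#' Reads one FASTA file per genome and returns a protein record table with one
#' row per entry. The record id is the header token before the first
#' whitespace; the free-text annotation is everything after it.
#'
#' @param paths character vector of FASTA file paths.
#' @param genome_ids character vector, parallel to `paths`, giving the genome
#'   (or MAG) each file belongs to.
#' @return `data.table` with columns `protein_id`, `genome_id`, `sequence`,
#'   `annotation`, `is_hap` (initialised `FALSE`), `is_decoy` (`FALSE`).
#' @details Sequences must use the 20 standard amino-acid letters plus `X`;
#'   `U`, `O`, `B`, `Z` and other characters are rejected with an error naming
#'   the record and character. Duplicate protein ids across the collection are
#'   an error.
#' @export
load_fasta_collection <- function(paths, genome_ids) {
  stopifnot(length(paths) == length(genome_ids), length(paths) > 0L)
  recs <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    p <- paths[i]
    if (!file.exists(p)) stop("cannot read FASTA file: ", p)
    aa <- tryCatch(Biostrings::readAAStringSet(p),
                   error = function(e) stop("cannot read FASTA file: ", p,
                                            " (", conditionMessage(e), ")"))
    if (length(aa) == 0L) stop("empty FASTA file: ", p)
    hdr <- names(aa)
    ids <- sub("\\s.*$", "", hdr)
    ann <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
    seqs <- toupper(as.character(aa))
    recs[[i]] <- data.table(protein_id = ids, genome_id = genome_ids[i],
                            sequence = seqs, annotation = ann,
                            is_hap = FALSE, is_decoy = FALSE)
  }
  out <- rbindlist(recs)
  validate_protein_records(out)
  out
}

# Shared invariant checks for protein record tables.
validate_protein_records <- function(records) {
  if (anyDuplicated(records$protein_id)) {
    dup <- records$protein_id[duplicated(records$protein_id)][1L]
    stop("duplicate protein_id in collection: ", dup)
  }
  if (any(!nzchar(records$sequence))) {
    stop("empty sequence for record: ",
         records$protein_id[!nzchar(records$sequence)][1L])
  }
  letters_seen <- unique(strsplit(paste(records$sequence, collapse = ""),
                                  "", fixed = TRUE)[[1L]])
  bad <- setdiff(letters_seen, VALID_RESIDUES)
  if (length(bad)) {
    hit <- grepl(bad[1L], records$sequence, fixed = TRUE)
    stop("invalid residue '", bad[1L], "' in record ",
         records$protein_id[hit][1L],
         " (allowed: 20 standard amino acids plus X)")
  }
  invisible(records)
}

#' Read a combined FASTA plus genome map
#'
#' Alternative loader for a single FASTA holding all proteins, with genome
#' attribution supplied as a two-column TSV (`protein_id`, `genome_id`).
#'
#' @param fasta_path path to the combined FASTA.
#' @param map_path path to the tab-separated genome map.
#' @return record table as in [load_fasta_collection()].
#' @export
load_fasta_combined <- function(fasta_path, map_path) {
  recs <- load_fasta_collection(fasta_path, genome_ids = NA_character_)
  map <- fread(map_path, sep = "\t", header = TRUE, colClasses = "character")
  need <- c("protein_id", "genome_id")
  miss <- setdiff(need, names(map))
  if (length(miss)) stop("genome map is missing column(s): ",
                         paste(miss, collapse = ", "))
  recs[, genome_id := NULL]
  out <- merge(recs, map[, need, with = FALSE], by = "protein_id",
               all.x = TRUE, sort = FALSE)
  if (anyNA(out$genome_id))
    stop("no genome mapping for protein(s): ",
         paste(head(out$protein_id[is.na(out$genome_id)], 3L), collapse = ", "))
  setcolorder(out, c("protein_id", "genome_id", "sequence", "annotation",
                     "is_hap", "is_decoy"))
  out[]
}

#' Write a search database (targets and decoys) to FASTA
#'
#' @param db a `search_db` object from [build_hapdb()] or
#'   [build_expanded_db()].
#' @param path output FASTA path.
#' @param width line width for wrapped sequences.
#' @return `path`, invisibly.
#' @export
write_database_fasta <- function(db, path, width = 60L) {
  stopifnot(inherits(db, "search_db"))
  recs <- rbind(db$targets, db$decoys)
  aa <- Biostrings::AAStringSet(recs$sequence)
  names(aa) <- ifelse(nzchar(recs$annotation),
                      paste(recs$protein_id, recs$annotation),
                      recs$protein_id)
  Biostrings::writeXStringSet(aa, path, width = width)
  invisible(path)
}
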