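#' Read a taxonomy-annotated reference database from FASTA
#'
#' Reference FASTA headers carry the taxonomy with the sequence in a
#' pipe-delimited dialect: `id|family|genus|species`. Sequences are
#' uppercased and any record containing a base other than A, C, G or T
#' (e.g. an N) is rejected with a warning, mirroring the exclusion of
#' ambiguous reference sequences during database construction. Records
#' sharing an identical sequence are collected into ambiguity groups;
#' a hit to any member of a non-singleton group can only be resolved
#' to the group's lowest common ancestor.
#'
#' @param path Path to a FASTA file.
#' @param marker Marker name, `"rbcL"` or `"ITS2"`.
#' @param origin Database origin, `"local"` (curated regional database)
#'   or `"global"` (NCBI-like database).
#' @return An object of class `reference_db`: a list with `marker`,
#'   `origin`, `records` (data frame with `id`, `family`, `genus`,
#'   `species`, `sequence`, `group`), and `n_rejected`.
#' @export
read_reference_fasta <- function(path, marker = c("rbcL", "ITS2"),
                                 origin = c("local", "global")) {
  marker <- match.arg(marker)
  origin <- match.arg(origin)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) stop("no records in ", path)
  fields <- strsplit(names(seqs), "|", fixed = TRUE)
  bad <- which(lengths(fields) != 4)
  if (length(bad)) {
    stop("malformed header (expected 'id|family|genus|species'): ",
         names(seqs)[bad[1]])
  }
  records <- data.frame(
    id = vapply(fields, `[`, "", 1),
    family = vapply(fields, `[`, "", 2),
    genus = vapply(fields, `[`, "", 3),
    species = vapply(fields, `[`, "", 4),
    sequence = toupper(as.character(seqs)),
    stringsAsFactors = FALSE)
  rownames(records) <- NULL
  ok <- !grepl("[^ACGT]", records$sequence)
  n_rejected <- sum(!ok)
  if (n_rejected > 0) {
    warning(n_rejected, " record(s) rejected for ambiguous bases: ",
            paste(records$id[!ok], collapse = ", "))
    records <- records[ok, , drop = FALSE]
  }
  if (nrow(records) == 0) stop("all records rejected in ", path)
  if (anyDuplicated(records$id)) {
    stop("duplicated record id(s): ",
         paste(unique(records$id[duplicated(records$id)]), collapse = ", "))
  }
  records <- records[order(records$id), , drop = FALSE]
  rownames(records) <- NULL
  records$group <- match(records$sequence, unique(records$sequence))
  structure(
    list(marker = marker, origin = origin, records = records,
         n_rejected = n_rejected),
    class = "reference_db")
}

#' Write a reference database to FASTA
#'
#' Records are written in canonical order (by id) with the
#' `id|family|genus|species` header dialect, so that reading the file
#' back yields an identical database.
#'
#' @param db A `reference_db` object.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(db, path) {
  rec <- db$records[order(db$records$id), , drop = FALSE]
  seqs <- Biostrings::DNAStringSet(rec$sequence)
  names(seqs) <- paste(rec$id, rec$family, rec$genus, rec$species, sep = "|")
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' @export
print.reference_db <- function(x, ...) {
  groups <- table(x$records$group)
  cat(sprintf("reference_db: %s (%s), %d records, %d ambiguity group(s) of size >= 2\n",
              x$marker, x$origin, nrow(x$records), sum(groups >= 2)))
  invisible(x)
}

#' Ambiguity groups of a reference database
#'
#' @param db A `reference_db` object.
#' @return A list of data frames, one per group of records sharing an
#'   identical sequence; singleton groups included.
#' @export
ambiguity_groups <- function(db) {
  unname(split(db$records, db$records$group))
}

#' Read a regional flora list
#'
#' The flora is a header-bearing TSV with columns `family`, `genus` and
#' `species`, one species-rank entry per row; duplicate rows collapse
#' (set semantics). Identifications sourced from the global database
#' are only adopted when the species appears in this list.
#'
#' @param path Path to the TSV file.
#' @return A data frame of class `flora_list` with columns `family`,
#'   `genus`, `species`, `rank`.
#' @export
read_flora <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("family", "genus", "species")
  if (!all(need %in% names(df))) {
    stop("flora list must have columns: ", paste(need, collapse = ", "))
  }
  df <- unique(df[, need])
  df <- df[nzchar(df$species), , drop = FALSE]
  if (nrow(df) == 0) stop("flora list is empty: ", path)
  df <- df[order(df$family, df$genus, df$species), , drop = FALSE]
  rownames(df) <- NULL
  df$rank <- "species"
  class(df) <- c("flora_list", "data.frame")
  df
}

#' Write a regional flora list
#'
#' @param flora A flora data frame (columns `family`, `genus`, `species`).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_flora <- function(flora, path) {
  df <- as.data.frame(flora)[, c("family", "genus", "species")]
  df <- unique(df[order(df$family, df$genus, df$species), , drop = FALSE])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

flora_key <- function(x) paste(x$family, x$genus, x$species, sep = "\r")

#' Test flora membership of species-rank taxa
#'
#' @param taxa Data frame with `family`, `genus`, `species` columns.
#' @param flora A flora list from [read_flora()] or the generator.
#' @return Logical vector, `TRUE` where the row is a species present in
#'   the flora.
#' @export
in_flora <- function(taxa, flora) {
  flora_key(taxa) %in% flora_key(flora)
}
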