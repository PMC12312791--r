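#' @importFrom Biostrings readBStringSet
NULL

# 20 standard amino-acid one-letter codes, and the extended letters that are
# tolerated (flagged in the record metadata) but excluded from composition
# statistics.
STANDARD_AA <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)
EXTENDED_AA <- c("B", "J", "O", "U", "X", "Z")

#' Create a protein record
#'
#' The unit of data moved through the pipeline: an identifier, an amino-acid
#' sequence, a set of GO annotations and an optional binary druggability label
#' (1 = drug target, 0 = non-drug target).
#'
#' @param id Unique, non-empty protein identifier.
#' @param sequence Amino-acid sequence (upper-case one-letter codes).
#'   Extended letters (B, J, O, U, X, Z) are tolerated and recorded in
#'   `meta$extended_letters`; anything else is rejected.
#' @param go_terms Character vector of GO identifiers (`"GO:"` + 7 digits).
#' @param label Optional binary label, `1` (drug target), `0` (non-target) or
#'   `NA` (unlabeled).
#' @param meta Named list of free-form metadata.
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(id, sequence, go_terms = character(),
                           label = NA_integer_, meta = list()) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stopf("protein id must be a non-empty string")
  }
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stopf("sequence for '%s' is empty", id)
  check_sequence(sequence, id)
  ext <- intersect(unique(strsplit(sequence, "")[[1]]), EXTENDED_AA)
  if (length(ext)) meta$extended_letters <- ext
  if (!is.na(label) && !label %in% c(0L, 1L)) {
    stopf("label for '%s' must be 0, 1 or NA", id)
  }
  structure(
    list(id = id, sequence = sequence, go_terms = unique(as.character(go_terms)),
         label = if (is.na(label)) NA_integer_ else as.integer(label),
         meta = meta),
    class = "protein_record"
  )
}

# Reject any character outside the standard + tolerated extended alphabet,
# reporting the first offending position.
check_sequence <- function(sequence, id = "?") {
  ok <- c(STANDARD_AA, EXTENDED_AA)
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% ok)
  if (length(bad)) {
    stopf("invalid character '%s' at position %d in sequence '%s'",
          chars[bad[1]], bad[1], id)
  }
  invisible(TRUE)
}

#' Read protein records from a FASTA file
#'
#' The token before the first whitespace in each header becomes the record id;
#' sequences are upper-cased. Gap (`-`) and stop (`*`) characters are
#' rejected with the offending position.
#'
#' @param path Path to a FASTA file.
#' @return A list of [protein_record()] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stopf("FASTA file is empty: %s", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stopf("duplicate FASTA id: '%s'", dup[1])
  seqs <- as.character(set)
  mapply(function(id, s) protein_record(id, s), ids, seqs,
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write protein records to a FASTA file
#'
#' @param records List of [protein_record()] objects.
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  lines <- unlist(lapply(records, function(r) {
    body <- substring(r$sequence,
                      seq(1L, nchar(r$sequence), by = width),
                      pmin(seq(1L, nchar(r$sequence), by = width) + width - 1L,
                           nchar(r$sequence)))
    c(paste0(">", r$id), body)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read GO annotations
#'
#' Reads either a two-column TSV (`protein_id<TAB>GO_id`) or a GAF 2.x file
#' (17 tab-separated columns, `!`-prefixed comment lines; the protein id is
#' column 2, the GO id column 5, and rows whose qualifier contains `NOT` are
#' dropped). Rows are unioned into one GO-term set per protein; ids absent
#' from any dataset are retained (filtering happens downstream).
#'
#' @param path Path to the annotation file.
#' @param format `"tsv"` or `"gaf"`.
#' @return Named list mapping protein id to a character vector of GO ids.
#' @export
read_go_annotations <- function(path, format = c("tsv", "gaf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  lines <- readLines(path)
  ids <- character(0)
  gos <- character(0)
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(line)) next
    if (format == "gaf" && startsWith(line, "!")) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (format == "tsv") {
      if (length(fields) < 2L) stopf("line %d: expected 2 tab-separated columns", i)
      pid <- fields[1]
      go <- fields[2]
    } else {
      if (length(fields) < 5L) stopf("line %d: malformed GAF row", i)
      if (grepl("NOT", fields[4], fixed = TRUE)) next
      pid <- fields[2]
      go <- fields[5]
    }
    if (!grepl("^GO:[0-9]{7}$", go)) {
      stopf("line %d: malformed GO id '%s'", i, go)
    }
    ids <- c(ids, pid)
    gos <- c(gos, go)
  }
  lapply(split(gos, factor(ids, levels = unique(ids))), unique)
}

#' Read a dataset manifest
#'
#' CSV with columns `id`, `label` and optionally `split`; ids must be unique.
#'
#' @param path Path to the manifest CSV.
#' @return A data.frame with columns `id`, `label`, `split`.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "label") %in% names(df))) {
    stopf("manifest must have columns 'id' and 'label'")
  }
  dup <- df$id[duplicated(df$id)]
  if (length(dup)) stopf("duplicate manifest id: '%s'", dup[1])
  bad <- !(is.na(df$label) | df$label %in% c(0, 1))
  if (any(bad)) stopf("manifest labels must be 0, 1 or NA (row %d)", which(bad)[1])
  if (is.null(df$split)) df$split <- NA_character_
  df[, c("id", "label", "split")]
}

#' @rdname read_manifest
#' @param manifest Data.frame with columns `id`, `label`, `split`.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
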