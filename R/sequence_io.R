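#' Protein sequence records and domain-string notation
#'
#' Coordinates are 1-based inclusive throughout the package, matching the
#' residue numbering used in the CaM-binding literature (e.g. a domain at
#' 1221-1240 spans 20 residues).
#'
#' @name sequence_io
NULL

# Validate an amino-acid string: 20 standard letters plus X (unknown).
# Returns the upper-cased sequence or signals an error naming the offending
# position.  U (selenocysteine) and ambiguity codes (B, J, Z, O) are
# rejected: none occur in the shipped corpus and silent acceptance would
# risk miscounted anchors.
validate_sequence <- function(sequence, id = "<sequence>", allow_empty = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) {
    if (allow_empty) return(sequence)
    stop("empty sequence in record '", id, "'", call. = FALSE)
  }
  chars <- strsplit(sequence, "")[[1]]
  ok <- chars %in% c(AA_STANDARD, "X")
  if (!all(ok)) {
    pos <- which(!ok)[1]
    stop("invalid residue '", chars[pos], "' at position ", pos,
         " in record '", id, "'", call. = FALSE)
  }
  sequence
}

#' Create a validated protein record
#'
#' @param id free-text identifier.
#' @param sequence amino-acid string; the 20 standard letters plus `X`
#'   (unknown) are accepted, anything else is rejected with the record and
#'   position named.  Case is normalized to upper.
#' @return an object of class `protein_record` with fields `id`, `sequence`
#'   and `length`.
#' @export
protein_record <- function(id, sequence) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- validate_sequence(sequence, id = id)
  structure(list(id = id, sequence = sequence, length = nchar(sequence)),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  preview <- if (x$length > 40L) paste0(substr(x$sequence, 1L, 40L), "...")
             else x$sequence
  cat("<protein_record> ", x$id, " (", x$length, " aa)\n  ", preview, "\n",
      sep = "")
  invisible(x)
}

# Accept a protein_record or a bare string; return the sequence string.
as_sequence <- function(x, allow_empty = TRUE) {
  if (inherits(x, "protein_record")) return(x$sequence)
  validate_sequence(x, allow_empty = allow_empty)
}

#' Parse FASTA input into protein records
#'
#' @param input path to a FASTA file, or FASTA-formatted text (a single
#'   string containing newlines, or a character vector of lines).
#' @return list of [protein_record()] objects, order preserved.
#' @export
parse_fasta <- function(input) {
  stopifnot(is.character(input), length(input) >= 1L)
  if (length(input) == 1L && !grepl("\n", input) && file.exists(input)) {
    path <- input
  } else {
    path <- tempfile(fileext = ".fasta")
    on.exit(unlink(path), add = TRUE)
    writeLines(input, path)
  }
  aas <- Biostrings::readAAStringSet(path)
  if (length(aas) == 0L) {
    stop("no records found in FASTA input", call. = FALSE)
  }
  ids <- names(aas)
  ids[!nzchar(ids)] <- sprintf("record%d", which(!nzchar(ids)))
  mapply(protein_record, ids, as.character(aas),
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write protein records to FASTA
#'
#' @param records list of [protein_record()] objects (a single record is
#'   also accepted).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "protein_record")) records <- list(records)
  seqs <- vapply(records, function(r) r$sequence, character(1))
  ids <- vapply(records, function(r) r$id, character(1))
  aas <- Biostrings::AAStringSet(seqs)
  names(aas) <- ids
  Biostrings::writeXStringSet(aas, path)
  invisible(path)
}

#' Parse printed domain-string notation
#'
#' The CaM-binding literature prints domains as the literal residue string
#' flanked by its 1-based start and end coordinates in the full protein,
#' e.g. `"1221LQALLLKRFLLARRSRRGLF1240"`.  Either or both coordinates may be
#' absent.  The literal residue letters are always authoritative: they are
#' never altered, truncated or padded.  When both coordinates are present,
#' `coordinate_flag` records whether `end - start + 1` equals the literal
#' sequence length (`"consistent"` / `"inconsistent"`); when either is
#' missing the flag is `"absent"`.  Printed coordinate typos therefore
#' surface as `"inconsistent"` rather than being silently corrected.
#'
#' @param text the printed notation.
#' @param protein_id optional protein identifier to attach.
#' @return an object of class `domain_annotation` with fields `protein_id`,
#'   `start`, `end`, `sequence`, `length` and `coordinate_flag`.
#' @examples
#' parse_domain_string("1221LQALLLKRFLLARRSRRGLF1240")
#' parse_domain_string("LQALL")
#' @export
parse_domain_string <- function(text, protein_id = NA_character_) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  m <- regexec("^([0-9]*)([A-Za-z]+)([0-9]*)$", text)[[1]]
  if (m[1] == -1L) {
    stop("cannot parse domain string (no residue letters found): '",
         text, "'", call. = FALSE)
  }
  parts <- regmatches(text, regexec("^([0-9]*)([A-Za-z]+)([0-9]*)$", text))[[1]]
  start <- if (nzchar(parts[2])) as.integer(parts[2]) else NA_integer_
  end <- if (nzchar(parts[4])) as.integer(parts[4]) else NA_integer_
  sequence <- validate_sequence(parts[3], id = text)
  flag <- if (is.na(start) || is.na(end)) {
    "absent"
  } else if (end - start + 1L == nchar(sequence)) {
    "consistent"
  } else {
    "inconsistent"
  }
  structure(list(protein_id = protein_id, start = start, end = end,
                 sequence = sequence, length = nchar(sequence),
                 coordinate_flag = flag),
            class = "domain_annotation")
}

#' @export
print.domain_annotation <- function(x, ...) {
  coord <- if (is.na(x$start) && is.na(x$end)) "coords absent"
           else paste0(x$start, "-", x$end, " (", x$coordinate_flag, ")")
  cat("<domain_annotation> ",
      if (!is.na(x$protein_id)) paste0(x$protein_id, " ") else "",
      x$sequence, " [", x$length, " aa, ", coord, "]\n", sep = "")
  invisible(x)
}
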