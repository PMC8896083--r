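#' Enumerate calcium-dependent and IQ-family CaM-binding motifs
#'
#' The engine is an exhaustive, deterministic replacement for the "visual
#' scan" step of CaMBD annotation: every start position is tested, all
#' overlapping hits are reported, and no deduplication is performed across
#' classes (shared anchor pairs are counted once per class, as the
#' literature does).  Scanning is N-to-C only: motif nomenclature is
#' defined on the forward chain.
#'
#' @name motif_engine
NULL

empty_hits <- function() {
  data.frame(class = character(0), start = integer(0), end = integer(0),
             anchor_positions = character(0), anchor_residues = character(0),
             stringsAsFactors = FALSE)
}

#' Enumerate anchor-spacing motif hits in a sequence
#'
#' Reports one hit for every start position `i` such that the residue at
#' `i + offset` is in the anchor alphabet for every offset of the class.
#' Sequences shorter than the class span (including the empty sequence)
#' yield zero hits rather than an error, which keeps whole-proteome sweeps
#' simple.  `X` (unknown) is never an anchor.
#'
#' @param sequence amino-acid string or [protein_record()].
#' @param class a [motif_class()].
#' @param alphabet an [anchor_alphabet()] or preset name; default strict
#'   \{F, I, L, V, W\}.
#' @return data frame with one row per hit: `class`, `start`, `end` (first
#'   and last anchor position, 1-based), `anchor_positions`
#'   (comma-separated), `anchor_residues` (pasted letters); sorted by
#'   `start`.
#' @examples
#' enumerate_anchor_motifs("LQALLLKRFLLARRSRRGLF",
#'                         default_motif_classes()[["1-10"]])
#' @export
enumerate_anchor_motifs <- function(sequence, class,
                                    alphabet = anchor_alphabet("strict")) {
  stopifnot(inherits(class, "motif_class"))
  alphabet <- as_anchor_alphabet(alphabet)
  sequence <- as_sequence(sequence)
  n <- nchar(sequence)
  if (n < class$span) return(empty_hits())
  chars <- strsplit(sequence, "")[[1]]
  is_anchor <- chars %in% alphabet$residues
  n_start <- n - class$span + 1L
  ok <- rep(TRUE, n_start)
  for (off in class$offsets) {
    ok <- ok & is_anchor[seq_len(n_start) + off]
  }
  starts <- which(ok)
  if (length(starts) == 0L) return(empty_hits())
  pos <- lapply(starts, function(s) s + class$offsets)
  data.frame(
    class = class$name,
    start = starts,
    end = starts + class$span - 1L,
    anchor_positions = vapply(pos, paste, character(1), collapse = ","),
    anchor_residues = vapply(pos, function(p) paste(chars[p], collapse = ""),
                             character(1)),
    stringsAsFactors = FALSE
  )
}

#' Scan a sequence against a roster of motif classes
#'
#' @inheritParams enumerate_anchor_motifs
#' @param classes named list of [motif_class()] objects (or default class
#'   names); duplicate class names are a configuration error.
#' @return named list of hit data frames, one element per class (possibly
#'   zero-row), in roster order.
#' @export
scan_all_classes <- function(sequence, classes = default_motif_classes(),
                             alphabet = anchor_alphabet("strict")) {
  classes <- as_motif_classes(classes)
  lapply(classes, function(k) enumerate_anchor_motifs(sequence, k, alphabet))
}

#' Tally motif hits per class
#'
#' @param hits either the named list returned by [scan_all_classes()] or a
#'   single hit data frame (as from [enumerate_anchor_motifs()]).
#' @param classes optional character vector of class names that must appear
#'   in the result (with zero counts where absent from `hits`).
#' @return named integer vector of per-class counts; the sum equals the
#'   total number of hits.
#' @export
count_by_class <- function(hits, classes = NULL) {
  if (is.data.frame(hits)) {
    tab <- table(hits$class)
    counts <- stats::setNames(as.integer(tab), names(tab))
  } else {
    counts <- vapply(hits, nrow, integer(1))
  }
  if (!is.null(classes)) {
    out <- stats::setNames(integer(length(classes)), classes)
    shared <- intersect(names(counts), classes)
    out[shared] <- counts[shared]
    extra <- setdiff(names(counts), classes)
    if (length(extra) > 0L) out <- c(out, counts[extra])
    counts <- out
  }
  counts
}

# IQ-family patterns.  The canonical calcium-independent IQ motif is
# [FILV]Qxxx[RK]Gxxx[RK]xx[FILVWY] (14 residues); "IQ-like" is the relaxed
# head-only pattern [FILVWY]Qxxx[RK]G (7 residues), which accepts the
# incomplete variants reported in the literature (e.g. a W at position 1
# and no anchor at position 14).
.IQ_CANONICAL <- "[FILV]Q[A-Z]{3}[RK]G[A-Z]{3}[RK][A-Z]{2}[FILVWY]"
.IQ_RELAXED <- "[FILVWY]Q[A-Z]{3}[RK]G"
.IQ_CANONICAL_LEN <- 14L
.IQ_RELAXED_LEN <- 7L

# All (overlapping) start positions of a regex in a string.
regex_starts <- function(sequence, pattern) {
  m <- gregexpr(paste0("(?=", pattern, ")"), sequence, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Scan a sequence for IQ and IQ-like motifs
#'
#' Positions matching the canonical pattern are reported as variant `"IQ"`;
#' positions matching only the relaxed head pattern as `"IQ-like"`.
#' Overlapping matches are all reported.
#'
#' @inheritParams enumerate_anchor_motifs
#' @return data frame with columns `variant`, `start`, `end`,
#'   `matched_text`, sorted by `start`.
#' @examples
#' scan_iq("WQKAERGDILLSSL")  # one IQ-like hit, no canonical IQ
#' @export
scan_iq <- function(sequence) {
  sequence <- as_sequence(sequence)
  canonical <- regex_starts(sequence, .IQ_CANONICAL)
  relaxed <- setdiff(regex_starts(sequence, .IQ_RELAXED), canonical)
  out <- rbind(
    if (length(canonical) > 0L) data.frame(
      variant = "IQ", start = canonical,
      end = canonical + .IQ_CANONICAL_LEN - 1L,
      matched_text = substring(sequence, canonical,
                               canonical + .IQ_CANONICAL_LEN - 1L),
      stringsAsFactors = FALSE),
    if (length(relaxed) > 0L) data.frame(
      variant = "IQ-like", start = relaxed,
      end = relaxed + .IQ_RELAXED_LEN - 1L,
      matched_text = substring(sequence, relaxed,
                               relaxed + .IQ_RELAXED_LEN - 1L),
      stringsAsFactors = FALSE)
  )
  if (is.null(out)) {
    out <- data.frame(variant = character(0), start = integer(0),
                      end = integer(0), matched_text = character(0),
                      stringsAsFactors = FALSE)
  }
  out[order(out$start, out$variant), , drop = FALSE]
}
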