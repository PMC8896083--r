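#' The 20 standard amino-acid one-letter codes
#'
#' Order follows the conventional A/R/N/D/... listing.  `X` (unknown residue)
#' is accepted by the sequence validators but is never a member of this set
#' and can therefore never serve as a motif anchor.
#'
#' @export
AA_STANDARD <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

.ALPHABET_PRESETS <- list(
  "strict"   = c("F", "I", "L", "V", "W"),
  "strict+M" = c("F", "I", "L", "V", "W", "M"),
  "strict+A" = c("F", "I", "L", "V", "W", "A"),
  "strict+Y" = c("F", "I", "L", "V", "W", "Y")
)

#' Hydrophobic anchor alphabet
#'
#' An anchor alphabet is the residue set treated as a bulky hydrophobic
#' "anchor" when enumerating calcium-dependent CaM-binding motifs.  The
#' default, `"strict"`, is \{F, I, L, V, W\}; the presets `"strict+M"`,
#' `"strict+A"` and `"strict+Y"` extend it by one residue each.  A fully
#' custom set can be given either as `"custom:<letters>"` (e.g.
#' `"custom:FILMVWY"`) or via the `residues` argument.
#'
#' @param name preset name, `"custom:<letters>"` string, or a free label
#'   when `residues` is supplied.
#' @param residues optional character vector of one-letter codes overriding
#'   the preset lookup.
#' @return an object of class `anchor_alphabet` with fields `name` and
#'   `residues`.
#' @examples
#' anchor_alphabet()
#' anchor_alphabet("custom:FILV")
#' @export
anchor_alphabet <- function(name = "strict", residues = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (is.null(residues)) {
    if (name %in% names(.ALPHABET_PRESETS)) {
      residues <- .ALPHABET_PRESETS[[name]]
    } else if (grepl("^custom:", name)) {
      residues <- strsplit(toupper(sub("^custom:", "", name)), "")[[1]]
    } else {
      stop("unknown anchor alphabet '", name, "'; known presets: ",
           paste(names(.ALPHABET_PRESETS), collapse = ", "),
           " or 'custom:<letters>'", call. = FALSE)
    }
  }
  residues <- unique(toupper(residues))
  if (length(residues) == 0L) {
    stop("anchor alphabet must contain at least one residue", call. = FALSE)
  }
  bad <- setdiff(residues, AA_STANDARD)
  if (length(bad) > 0L) {
    stop("anchor alphabet contains non-standard residues: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(name = name, residues = residues),
            class = "anchor_alphabet")
}

#' @export
print.anchor_alphabet <- function(x, ...) {
  cat("<anchor_alphabet> ", x$name, ": {",
      paste(x$residues, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

# Coerce a preset name or anchor_alphabet object to anchor_alphabet.
as_anchor_alphabet <- function(x) {
  if (inherits(x, "anchor_alphabet")) return(x)
  anchor_alphabet(x)
}
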