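#' Synthetic protein backgrounds and planted-motif benchmarks
#'
#' Every pipeline stage is testable without downloads: i.i.d. random
#' backgrounds of a specified residue composition, motif planting with
#' recorded ground truth, and benchmark datasets (FASTA + truth TSV)
#' suitable for sensitivity and background-rate measurement.
#'
#' @name synthetic_data
NULL

#' Uniform background composition
#'
#' Equal probability 1/20 for each standard residue — the simplest null.
#'
#' @return named numeric vector over [AA_STANDARD] summing to 1.
#' @export
uniform_composition <- function() {
  stats::setNames(rep(1 / 20, 20), AA_STANDARD)
}

#' Average human proteome residue composition
#'
#' Swiss-Prot average amino-acid frequencies, renormalized over the 20
#' standard residues; a more realistic null than [uniform_composition()].
#'
#' @return named numeric vector over [AA_STANDARD] summing to 1.
#' @export
human_proteome_composition <- function() {
  f <- c(A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.37, Q = 3.93,
         E = 6.75, G = 7.07, H = 2.27, I = 5.96, L = 9.66, K = 5.84,
         M = 2.42, F = 3.86, P = 4.70, S = 6.56, T = 5.34, W = 1.08,
         Y = 2.92, V = 6.87)
  (f / sum(f))[AA_STANDARD]
}

resolve_composition <- function(composition) {
  if (is.character(composition) && length(composition) == 1L) {
    composition <- switch(composition,
      uniform = uniform_composition(),
      human = human_proteome_composition(),
      stop("unknown composition preset '", composition,
           "' (use 'uniform' or 'human')", call. = FALSE))
  }
  if (!is.numeric(composition) ||
      !setequal(names(composition), AA_STANDARD) ||
      any(composition < 0) || any(!is.finite(composition))) {
    stop("composition must be a non-negative numeric vector named by the ",
         "20 standard residues", call. = FALSE)
  }
  composition <- composition[AA_STANDARD]
  if (abs(sum(composition) - 1) > 1e-6) {
    stop("composition probabilities must sum to 1 (got ",
         format(sum(composition)), ")", call. = FALSE)
  }
  composition
}

#' Specify a synthetic dataset
#'
#' @param n_sequences number of sequences to generate.
#' @param length residue length of every sequence.
#' @param composition `"uniform"` (default), `"human"`, or a named numeric
#'   probability vector over the 20 standard residues summing to 1.
#' @param planted `NULL` for pure background, or a character vector of
#'   motif class names (recycled over sequences) naming the class planted
#'   in each sequence.
#' @param positions optional integer vector of planting positions (recycled);
#'   when `NULL` positions are drawn uniformly among the feasible starts.
#' @param seed integer seed; generation is fully deterministic given the
#'   spec.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_sequences, length, composition = "uniform",
                           planted = NULL, positions = NULL, seed = 1L) {
  stopifnot(n_sequences >= 1L, length >= 1L)
  composition <- resolve_composition(composition)
  if (!is.null(planted)) {
    classes <- as_motif_classes(unique(planted))
    spans <- vapply(classes, function(k) k$span, integer(1))
    if (any(spans > length)) {
      stop("planted class span exceeds sequence length", call. = FALSE)
    }
    if (!is.null(positions)) {
      maxspan <- max(spans[unique(planted)])
      if (any(positions < 1L) || any(positions + maxspan - 1L > length)) {
        stop("planted positions do not fit within sequence length",
             call. = FALSE)
      }
    }
  }
  structure(list(n_sequences = as.integer(n_sequences),
                 length = as.integer(length),
                 composition = composition,
                 planted = planted, positions = positions,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Draw one i.i.d. background sequence using the current RNG state.
draw_background <- function(length, composition) {
  paste(sample(AA_STANDARD, length, replace = TRUE, prob = composition),
        collapse = "")
}

#' Generate random protein backgrounds
#'
#' @param spec a [synthetic_spec()]; `planted` is ignored here.
#' @return list of [protein_record()] objects with ids `syn0001`, ...
#' @export
generate_background <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  lapply(seq_len(spec$n_sequences), function(i) {
    protein_record(sprintf("syn%04d", i),
                   draw_background(spec$length, spec$composition))
  })
}

#' Plant an anchor motif into a record
#'
#' Overwrites (never inserts, so coordinates stay stable) the window
#' `[position, position + span - 1]`: anchor offsets receive residues
#' sampled from the anchor alphabet, all other positions in the window
#' receive residues sampled from outside it.  By construction the scanned
#' class then has a hit at exactly the planted position within the window
#' (background chance hits outside it may still occur).
#'
#' Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param record a [protein_record()].
#' @param class a [motif_class()].
#' @param position 1-based planting position.
#' @param alphabet anchor alphabet used for the planted anchors.
#' @return list with `record` (modified) and `truth`
#'   (data frame: `id`, `class`, `position`).
#' @export
plant_motif <- function(record, class, position,
                        alphabet = anchor_alphabet("strict")) {
  stopifnot(inherits(record, "protein_record"),
            inherits(class, "motif_class"))
  alphabet <- as_anchor_alphabet(alphabet)
  position <- as.integer(position)
  if (position < 1L || position + class$span - 1L > record$length) {
    stop("planted motif span [", position, ", ",
         position + class$span - 1L, "] overflows sequence of length ",
         record$length, call. = FALSE)
  }
  non_anchor <- setdiff(AA_STANDARD, alphabet$residues)
  chars <- strsplit(record$sequence, "")[[1]]
  window <- position:(position + class$span - 1L)
  anchors <- position + class$offsets
  filler <- setdiff(window, anchors)
  chars[anchors] <- sample(alphabet$residues, length(anchors), replace = TRUE)
  chars[filler] <- sample(non_anchor, length(filler), replace = TRUE)
  list(record = protein_record(record$id, paste(chars, collapse = "")),
       truth = data.frame(id = record$id, class = class$name,
                          position = position, stringsAsFactors = FALSE))
}

#' Build a planted-motif benchmark dataset
#'
#' Generates `spec$n_sequences` backgrounds and, if `spec$planted` is set,
#' plants one motif per sequence, recording ground truth.  Deterministic
#' given `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @param alphabet anchor alphabet for planted anchors.
#' @return list with `records` (list of [protein_record()]) and `truth`
#'   (data frame `id`, `class`, `position`; zero rows when nothing is
#'   planted).
#' @export
make_benchmark <- function(spec, alphabet = anchor_alphabet("strict")) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  records <- lapply(seq_len(spec$n_sequences), function(i) {
    protein_record(sprintf("syn%04d", i),
                   draw_background(spec$length, spec$composition))
  })
  truth <- data.frame(id = character(0), class = character(0),
                      position = integer(0), stringsAsFactors = FALSE)
  if (!is.null(spec$planted)) {
    classes <- as_motif_classes(unique(spec$planted))
    planted <- rep_len(spec$planted, spec$n_sequences)
    positions <- if (!is.null(spec$positions)) {
      rep_len(as.integer(spec$positions), spec$n_sequences)
    }
    rows <- vector("list", spec$n_sequences)
    for (i in seq_len(spec$n_sequences)) {
      k <- classes[[planted[i]]]
      pos <- if (is.null(positions)) {
        sample.int(spec$length - k$span + 1L, 1L)
      } else positions[i]
      res <- plant_motif(records[[i]], k, pos, alphabet)
      records[[i]] <- res$record
      rows[[i]] <- res$truth
    }
    truth <- do.call(rbind, rows)
  }
  list(records = records, truth = truth)
}

#' Write a benchmark to FASTA + truth TSV
#'
#' @param benchmark result of [make_benchmark()].
#' @param fasta_path,truth_path output file paths.
#' @return invisibly, a list of the two paths.
#' @export
write_benchmark <- function(benchmark, fasta_path, truth_path) {
  write_fasta(benchmark$records, fasta_path)
  utils::write.table(benchmark$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(fasta = fasta_path, truth = truth_path))
}

#' Expected background hit count for a two-anchor class
#'
#' Under an i.i.d. background, a two-anchor class of span `s` has hit
#' probability `p^2` at each of the `L - s + 1` start positions, where `p`
#' is the total probability of the anchor residues; the expected hit count
#' per sequence is therefore `p^2 * (L - s + 1)`.
#'
#' @param length sequence length `L`.
#' @param class a two-anchor [motif_class()].
#' @param composition background composition (name or vector).
#' @param alphabet anchor alphabet.
#' @return expected hits per sequence.
#' @export
expected_background_hits <- function(length, class,
                                     composition = "uniform",
                                     alphabet = anchor_alphabet("strict")) {
  stopifnot(inherits(class, "motif_class"), length(class$offsets) == 2L)
  composition <- resolve_composition(composition)
  alphabet <- as_anchor_alphabet(alphabet)
  p <- sum(composition[alphabet$residues])
  p^2 * max(length - class$span + 1L, 0L)
}
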