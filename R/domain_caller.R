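#' Heuristic CaMBD window caller
#'
#' Canonical calcium-dependent CaMBDs are short basic amphipathic helices.
#' This module proposes candidate domain windows in a full-length sequence
#' by scoring each window for motif density, net positive charge, mean
#' hydropathy and hydrophobic moment, then greedily resolving overlaps.
#' It is an explicitly heuristic caller: it approximates the functional
#' role of profile-HMM CaMBD predictors without reproducing any particular
#' predictor's boundaries, and the corpus-reproduction path of this package
#' does not depend on it (the shipped domains are scanned directly).
#'
#' @name domain_caller
NULL

#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy values (Kyte & Doolittle 1982).  `X` (unknown) is
#' scored 0 (neutral).
#'
#' @export
KD_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2, X = 0
)

# Hydrophobic moment: magnitude of the helical-wheel vector sum of
# window-centred hydropathies at `angle` degrees per residue.  Centring on
# the window mean makes compositionally uniform windows score exactly 0 —
# the moment then measures periodic hydropathy variation (amphipathicity),
# not bulk composition.
hydrophobic_moment <- function(h, angle = 100) {
  if (length(h) == 0L) return(0)
  theta <- (seq_along(h) - 1L) * angle * pi / 180
  Mod(sum((h - mean(h)) * exp(1i * theta)))
}

#' Default weights for the window composite score
#'
#' The composite is
#' `motif * motif_density + charge * max(net_charge, 0) +
#'  hydropathy * mean_hydropathy + moment * hydrophobic_moment -
#'  proline * proline_count`.
#' Motif density (hits per residue, typically 0-0.3) carries the largest
#' weight since motif content is the primary evidence; net positive charge
#' and amphipathic moment reward basic amphipathic helix character; the
#' proline term penalizes helix breakers.
#'
#' @return named numeric vector of weights.
#' @export
caller_weights <- function() {
  c(motif = 10, charge = 0.5, hydropathy = 0.5, moment = 0.3, proline = 1)
}

#' Configuration for the domain caller
#'
#' @param window_min,window_max inclusive window-length range; the default
#'   15-27 covers the 14-27 residue range typical of reported CaMBDs.
#' @param threshold minimum composite score for a window to be retained;
#'   may be `-Inf` to retain everything.
#' @param weights named numeric vector as in [caller_weights()].
#' @param alphabet anchor alphabet (object or preset name) for the motif
#'   density term.
#' @param classes motif class roster for the motif density term.
#' @param angle helical twist in degrees per residue (100 for an ideal
#'   alpha helix).
#' @return list of class `caller_config`.
#' @export
caller_config <- function(window_min = 15L, window_max = 27L,
                          threshold = 5,
                          weights = caller_weights(),
                          alphabet = "strict",
                          classes = default_motif_classes(),
                          angle = 100) {
  window_min <- as.integer(window_min)
  window_max <- as.integer(window_max)
  if (is.na(window_min) || is.na(window_max) || window_min < 1L ||
      window_min > window_max) {
    stop("invalid window-length range: need 1 <= window_min <= window_max",
         call. = FALSE)
  }
  needed <- c("motif", "charge", "hydropathy", "moment", "proline")
  if (!all(needed %in% names(weights)) || !all(is.finite(weights[needed]))) {
    stop("weights must be finite and named ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(threshold) || length(threshold) != 1L || is.nan(threshold)) {
    stop("threshold must be a single number (possibly -Inf)", call. = FALSE)
  }
  structure(list(window_min = window_min, window_max = window_max,
                 threshold = threshold, weights = weights[needed],
                 alphabet = as_anchor_alphabet(alphabet),
                 classes = as_motif_classes(classes),
                 angle = angle),
            class = "caller_config")
}

window_charge <- function(chars) {
  sum(chars %in% c("R", "K")) - sum(chars %in% c("D", "E"))
}

#' Score a single sequence window
#'
#' @param sequence amino-acid string or [protein_record()].
#' @param start,end 1-based inclusive window bounds.
#' @param config a [caller_config()]; its threshold is ignored here.
#' @return list of class `window_score` with fields `start`, `end`,
#'   `motif_density`, `n_motifs`, `net_charge`, `mean_hydropathy`,
#'   `hydrophobic_moment`, `proline_count`, `composite`.
#' @export
score_window <- function(sequence, start, end, config = caller_config()) {
  stopifnot(inherits(config, "caller_config"))
  sequence <- as_sequence(sequence, allow_empty = FALSE)
  n <- nchar(sequence)
  if (start < 1L || end > n || start > end) {
    stop("window [", start, ", ", end, "] out of bounds for sequence of ",
         "length ", n, call. = FALSE)
  }
  win <- substr(sequence, start, end)
  chars <- strsplit(win, "")[[1]]
  len <- length(chars)
  n_motifs <- sum(vapply(config$classes, function(k) {
    nrow(enumerate_anchor_motifs(win, k, config$alphabet))
  }, integer(1)))
  h <- unname(KD_HYDROPATHY[chars])
  comp <- list(
    start = start, end = end,
    motif_density = n_motifs / len,
    n_motifs = n_motifs,
    net_charge = window_charge(chars),
    mean_hydropathy = mean(h),
    hydrophobic_moment = hydrophobic_moment(h, config$angle),
    proline_count = sum(chars == "P")
  )
  w <- config$weights
  comp$composite <- unname(
    w["motif"] * comp$motif_density +
    w["charge"] * max(comp$net_charge, 0) +
    w["hydropathy"] * comp$mean_hydropathy +
    w["moment"] * comp$hydrophobic_moment -
    w["proline"] * comp$proline_count
  )
  structure(comp, class = "window_score")
}

# Vectorized scoring of every window of every length in range, via prefix
# sums.  The hydrophobic moment uses global-phase complex prefix sums: the
# centred windowed vector sum is S1 - mean(h) * S2 where S1, S2 are
# windowed sums of h * exp(i*theta) and exp(i*theta); the magnitude is
# invariant to the global phase rotation relative to the window start.
all_window_scores <- function(sequence, config) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  if (n < config$window_min) {
    return(data.frame(start = integer(0), end = integer(0),
                      n_motifs = integer(0), composite = numeric(0)))
  }
  h <- unname(KD_HYDROPATHY[chars])
  chg <- (chars %in% c("R", "K")) - (chars %in% c("D", "E"))
  pro <- chars == "P"
  theta <- (seq_len(n) - 1L) * config$angle * pi / 180
  z <- exp(1i * theta)
  cs_h <- c(0, cumsum(h)); cs_chg <- c(0, cumsum(chg))
  cs_pro <- c(0, cumsum(pro))
  cs_z <- c(0, cumsum(z)); cs_hz <- c(0, cumsum(h * z))
  is_anchor <- chars %in% config$alphabet$residues
  hit_cs <- lapply(config$classes, function(k) {
    if (n < k$span) return(NULL)
    n_start <- n - k$span + 1L
    ok <- rep(TRUE, n_start)
    for (off in k$offsets) ok <- ok & is_anchor[seq_len(n_start) + off]
    c(0, cumsum(ok))
  })
  spans <- vapply(config$classes, function(k) k$span, integer(1))
  w <- config$weights
  lens <- seq(config$window_min, min(config$window_max, n))
  out <- lapply(lens, function(L) {
    s <- seq_len(n - L + 1L)
    e <- s + L - 1L
    n_mot <- rep(0L, length(s))
    for (j in seq_along(hit_cs)) {
      if (is.null(hit_cs[[j]]) || spans[j] > L) next
      last_start <- e - spans[j] + 1L
      n_mot <- n_mot + as.integer(hit_cs[[j]][last_start + 1L] - hit_cs[[j]][s])
    }
    mean_h <- (cs_h[e + 1L] - cs_h[s]) / L
    mom <- Mod((cs_hz[e + 1L] - cs_hz[s]) - mean_h * (cs_z[e + 1L] - cs_z[s]))
    composite <- w["motif"] * (n_mot / L) +
      w["charge"] * pmax(cs_chg[e + 1L] - cs_chg[s], 0) +
      w["hydropathy"] * mean_h +
      w["moment"] * mom -
      w["proline"] * (cs_pro[e + 1L] - cs_pro[s])
    data.frame(start = s, end = e, n_motifs = n_mot,
               composite = unname(composite))
  })
  do.call(rbind, out)
}

#' Call candidate CaMBD windows in a protein
#'
#' Slides every window length in the configured range over the sequence,
#' retains windows whose composite score meets the threshold, and resolves
#' overlaps greedily by descending composite (ties broken by smaller start,
#' then shorter window).  Deterministic for a fixed configuration.
#'
#' @param record a [protein_record()] (or bare sequence string, in which
#'   case the id is `"<sequence>"`).
#' @param config a [caller_config()].
#' @return data frame of non-overlapping candidates sorted by `start`:
#'   `protein_id`, `start`, `end`, `score`, `n_motifs`.
#' @export
call_domains <- function(record, config = caller_config()) {
  stopifnot(inherits(config, "caller_config"))
  if (!inherits(record, "protein_record")) {
    record <- protein_record("<sequence>", record)
  }
  scores <- all_window_scores(record$sequence, config)
  scores <- scores[scores$composite >= config$threshold, , drop = FALSE]
  empty <- data.frame(protein_id = character(0), start = integer(0),
                      end = integer(0), score = numeric(0),
                      n_motifs = integer(0), stringsAsFactors = FALSE)
  if (nrow(scores) == 0L) return(empty)
  ord <- order(-scores$composite, scores$start, scores$end - scores$start)
  scores <- scores[ord, , drop = FALSE]
  taken <- logical(record$length)
  keep <- logical(nrow(scores))
  for (i in seq_len(nrow(scores))) {
    idx <- scores$start[i]:scores$end[i]
    if (!any(taken[idx])) {
      keep[i] <- TRUE
      taken[idx] <- TRUE
    }
  }
  out <- scores[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  data.frame(protein_id = record$id, start = out$start, end = out$end,
             score = out$composite, n_motifs = out$n_motifs,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write domain candidates as BED-like TSV
#'
#' Columns: protein id, 0-based half-open start, end, score — the usual
#' BED coordinate convention.
#'
#' @param candidates data frame from [call_domains()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_candidates_bed <- function(candidates, path) {
  bed <- data.frame(chrom = candidates$protein_id,
                    chromStart = candidates$start - 1L,
                    chromEnd = candidates$end,
                    score = candidates$score)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
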