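#' Scan configuration and report rendering
#'
#' The analysis drivers under `analysis/` are thin wrappers over these
#' functions: `scan_report()` runs the motif scan over FASTA or printed
#' domain-string input, `concordance_report()` reproduces the corpus
#' tallies and inventory, and the writers render TSV (grep-able default)
#' and JSON (machine consumption).
#'
#' @name cli_report
NULL

#' Build a scan configuration
#'
#' Unknown alphabet or class names are rejected at construction time.
#'
#' @param alphabet anchor alphabet preset name, `"custom:<letters>"`, or an
#'   [anchor_alphabet()] object.
#' @param classes character vector of default class names, or a list of
#'   [motif_class()] objects.
#' @param iq logical: also scan for IQ/IQ-like motifs?
#' @param caller a [caller_config()] for the domain-calling stage.
#' @param format `"tsv"` or `"json"`.
#' @param seed optional integer seed for stages that draw random numbers.
#' @return list of class `scan_config`.
#' @export
scan_config <- function(alphabet = "strict",
                        classes = names(default_motif_classes()),
                        iq = TRUE,
                        caller = caller_config(),
                        format = c("tsv", "json"),
                        seed = NULL) {
  format <- match.arg(format)
  stopifnot(is.logical(iq), length(iq) == 1L,
            inherits(caller, "caller_config"))
  structure(list(alphabet = as_anchor_alphabet(alphabet),
                 classes = as_motif_classes(classes),
                 iq = iq, caller = caller, format = format,
                 seed = if (!is.null(seed)) as.integer(seed)),
            class = "scan_config")
}

#' Read a scan configuration from YAML
#'
#' Recognized keys: `alphabet` (string), `classes` (list of names, or a
#' map name -> offsets for custom classes), `iq` (logical), `format`,
#' `seed`, and a `caller` map with `window_min`, `window_max`, `threshold`
#' and `weights`.
#'
#' @param path YAML file path.
#' @return a [scan_config()].
#' @export
read_scan_config <- function(path) {
  y <- yaml::read_yaml(path)
  classes <- if (is.null(y$classes)) {
    names(default_motif_classes())
  } else if (is.character(y$classes) ||
             (is.list(y$classes) && is.null(names(y$classes)))) {
    unlist(y$classes)
  } else {
    mapply(motif_class, names(y$classes), y$classes, SIMPLIFY = FALSE)
  }
  caller_args <- y$caller %||% list()
  if (!is.null(caller_args$weights)) {
    caller_args$weights <- unlist(caller_args$weights)
  }
  caller <- do.call(caller_config, caller_args)
  scan_config(alphabet = y$alphabet %||% "strict",
              classes = classes,
              iq = y$iq %||% TRUE,
              caller = caller,
              format = y$format %||% "tsv",
              seed = y$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scan sequences and assemble a motif report
#'
#' @param input a FASTA file path, FASTA text, a list of
#'   [protein_record()]s, or a character vector of printed domain strings
#'   (notation of [parse_domain_string()]).
#' @param config a [scan_config()].
#' @return object of class `scan_report`: list with `hits` (one row per
#'   anchor-motif hit: `protein_id`, `class`, `start`, `end`,
#'   `anchor_positions`, `anchor_residues`), `counts` (per protein x class,
#'   zero-count classes included) and `iq` (IQ hits, or `NULL` when IQ
#'   scanning is off).
#' @export
scan_report <- function(input, config = scan_config()) {
  stopifnot(inherits(config, "scan_config"))
  records <- resolve_scan_input(input)
  if (length(records) == 0L) {
    warning("no sequences to scan; returning an empty report")
  }
  class_names <- names(config$classes)
  hits <- list(); counts <- list(); iq <- list()
  for (rec in records) {
    scans <- scan_all_classes(rec$sequence, config$classes, config$alphabet)
    per_class <- count_by_class(scans)
    h <- do.call(rbind, scans)
    if (!is.null(h) && nrow(h) > 0L) {
      hits[[length(hits) + 1L]] <-
        cbind(protein_id = rec$id, h, stringsAsFactors = FALSE)
    }
    counts[[length(counts) + 1L]] <- data.frame(
      protein_id = rec$id, class = class_names,
      n = unname(per_class[class_names]),
      stringsAsFactors = FALSE)
    if (config$iq) {
      q <- scan_iq(rec$sequence)
      if (nrow(q) > 0L) {
        iq[[length(iq) + 1L]] <-
          cbind(protein_id = rec$id, q, stringsAsFactors = FALSE)
      }
    }
  }
  bind <- function(x, proto) {
    if (length(x) == 0L) proto else
      `rownames<-`(do.call(rbind, x), NULL)
  }
  structure(list(
    hits = bind(hits, cbind(protein_id = character(0), empty_hits())),
    counts = bind(counts, data.frame(protein_id = character(0),
                                     class = character(0), n = integer(0))),
    iq = if (config$iq) {
      bind(iq, data.frame(protein_id = character(0), variant = character(0),
                          start = integer(0), end = integer(0),
                          matched_text = character(0)))
    },
    alphabet = config$alphabet$name
  ), class = "scan_report")
}

resolve_scan_input <- function(input) {
  if (inherits(input, "protein_record")) return(list(input))
  if (is.list(input)) {
    stopifnot(all(vapply(input, inherits, logical(1), "protein_record")))
    return(input)
  }
  stopifnot(is.character(input))
  is_fasta_text <- any(grepl("^>", trimws(input))) || any(grepl("\n>", input))
  if ((length(input) == 1L && !grepl("\n", input) && file.exists(input)) ||
      is_fasta_text) {
    return(parse_fasta(input))
  }
  # printed domain-string notation, one string per element
  lapply(seq_along(input), function(i) {
    ann <- parse_domain_string(input[i])
    id <- if (is.na(ann$start)) sprintf("domain%d", i) else
      paste0("domain", i, "_", ann$start, "-", ann$end)
    protein_record(id, ann$sequence)
  })
}

#' @export
print.scan_report <- function(x, ...) {
  n_prot <- length(unique(x$counts$protein_id))
  cat("<scan_report> ", n_prot, " sequence(s), alphabet ", x$alphabet,
      "\n", sep = "")
  for (cl in unique(x$counts$class)) {
    cat("  ", format(cl, width = 9), sum(x$counts$n[x$counts$class == cl]),
        "hit(s)\n")
  }
  if (!is.null(x$iq)) cat("  IQ/IQ-like:", nrow(x$iq), "hit(s)\n")
  invisible(x)
}

#' Write a scan report as TSV
#'
#' One row per anchor-motif hit; IQ hits (if scanned) are appended with
#' the variant in the `class` column and the matched text in
#' `anchor_residues`.
#'
#' @param report a [scan_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(report, path) {
  tab <- report$hits
  if (!is.null(report$iq) && nrow(report$iq) > 0L) {
    iq <- data.frame(protein_id = report$iq$protein_id,
                     class = report$iq$variant,
                     start = report$iq$start, end = report$iq$end,
                     anchor_positions = as.character(report$iq$start),
                     anchor_residues = report$iq$matched_text,
                     stringsAsFactors = FALSE)
    tab <- rbind(tab, iq)
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a scan report as JSON
#'
#' Nested per-protein report: per-class counts plus the individual hits.
#'
#' @inheritParams write_scan_tsv
#' @return `path`, invisibly.
#' @export
write_scan_json <- function(report, path) {
  proteins <- unique(report$counts$protein_id)
  out <- lapply(proteins, function(p) {
    cnt <- report$counts[report$counts$protein_id == p, ]
    h <- report$hits[report$hits$protein_id == p, -1, drop = FALSE]
    obj <- list(counts = stats::setNames(as.list(cnt$n), cnt$class),
                hits = h)
    if (!is.null(report$iq)) {
      obj$iq <- report$iq[report$iq$protein_id == p, -1, drop = FALSE]
    }
    obj
  })
  jsonlite::write_json(stats::setNames(out, proteins), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Full concordance report over the packaged corpus
#'
#' Runs [motif_concordance()] with the given alphabet, verifies the
#' reported IQ-family motif, and assembles the inventory union and the
#' disease-matrix marginals.
#'
#' @param alphabet anchor alphabet (object or preset name).
#' @return object of class `concordance_report`: list with `concordance`,
#'   `iq` (reported vs computed IQ hits), `inventory`, `disease`.
#' @export
concordance_report <- function(alphabet = "strict") {
  conc <- motif_concordance(alphabet = alphabet)
  iq_corpus <- load_iq_corpus()
  iq_corpus$computed <- vapply(iq_corpus$sequence, function(s) {
    q <- scan_iq(s)
    sum(q$variant == "IQ-like")
  }, integer(1))
  iq_corpus$match <- iq_corpus$computed == iq_corpus$reported_count
  structure(list(concordance = conc,
                 iq = iq_corpus,
                 inventory = cambp_inventory(),
                 disease = disease_matrix(),
                 alphabet = as_anchor_alphabet(alphabet)$name),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  conc <- x$concordance
  inv <- x$inventory
  cat("CaMBD corpus concordance (alphabet: ", x$alphabet, ")\n", sep = "")
  cat("  scanned proteins: ", inv$n_scanned, "\n", sep = "")
  cat("  previously identified CaMBPs: ", inv$n_prior, "\n", sep = "")
  cat("  union inventory: ", inv$n_union, " proteins\n", sep = "")
  cat("  reported counts compared: ", nrow(conc),
      " (", sum(conc$match), " match, ", sum(!conc$match),
      " mismatch)\n", sep = "")
  mism <- conc[!conc$match, , drop = FALSE]
  if (nrow(mism) > 0L) {
    cat("  mismatches (reported vs computed):\n")
    for (i in seq_len(nrow(mism))) {
      cat(sprintf("    %s %s %s: reported %d, computed %d\n",
                  mism$protein[i], mism$domain_label[i], mism$class[i],
                  mism$reported[i], mism$computed[i]))
    }
  }
  cat("  IQ-family: ", sum(x$iq$match), "/", nrow(x$iq),
      " reported motifs reproduced\n", sep = "")
  marg <- attr(x$disease, "col_marginals")
  cat("  disease links (stated only): ",
      paste(sprintf("%s=%d", names(marg), marg), collapse = " "), "\n",
      sep = "")
  invisible(x)
}

#' Write a concordance table as TSV
#'
#' @param report a [concordance_report()] or the data frame from
#'   [motif_concordance()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_concordance_tsv <- function(report, path) {
  tab <- if (inherits(report, "concordance_report")) report$concordance
         else report
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
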