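# Independent brute-force oracles, deliberately naive: every start position
# and every offset is tested with scalar loops, with no code shared with the
# package's scanning path.

brute_anchor_motifs <- function(sequence, offsets, residues) {
  chars <- strsplit(sequence, "")[[1]]
  span <- offsets[length(offsets)] + 1L
  starts <- integer(0)
  if (length(chars) >= span) {
    for (i in seq_len(length(chars) - span + 1L)) {
      all_anchored <- TRUE
      for (off in offsets) {
        if (!(chars[i + off] %in% residues)) {
          all_anchored <- FALSE
          break
        }
      }
      if (all_anchored) starts <- c(starts, i)
    }
  }
  starts
}

# Position-by-position check of the canonical IQ pattern at position i.
brute_iq_canonical_at <- function(sequence, i) {
  chars <- strsplit(sequence, "")[[1]]
  if (i + 13L > length(chars)) return(FALSE)
  w <- chars[i:(i + 13L)]
  w[1] %in% c("F", "I", "L", "V") && w[2] == "Q" &&
    w[6] %in% c("R", "K") && w[7] == "G" &&
    w[11] %in% c("R", "K") && w[14] %in% c("F", "I", "L", "V", "W", "Y")
}

brute_iq_relaxed_at <- function(sequence, i) {
  chars <- strsplit(sequence, "")[[1]]
  if (i + 6L > length(chars)) return(FALSE)
  w <- chars[i:(i + 6L)]
  w[1] %in% c("F", "I", "L", "V", "W", "Y") && w[2] == "Q" &&
    w[6] %in% c("R", "K") && w[7] == "G"
}

random_aa_seq <- function(len, letters = AA_STANDARD) {
  paste(sample(letters, len, replace = TRUE), collapse = "")
}

# Frozen copies of the corpus domain strings; the fixture must stay
# byte-identical to these.
CORPUS_DOMAIN_STRINGS <- c(
  "ABCA7 CaMBD1" = "1221LQALLLKRFLLARRSRRGLF1240",
  "ABCA7 CaMBD2" = "1401QGLKTKKWVNEVRYGGFSLG1420",
  "CH3L1 CaMBD1" = "333SVKSKVQYLKDRQLAGAMVW352",
  "CLU CaMBD1" = "33VAERLTRKYNELLKSYQWKM352",
  "CR1 CaMBD1" = "1090VVTYRCNLGSRGRKVFEL1107",
  "EPHA1 CaMBD1" = "167NVERCSLGRLTRRGLYLA184",
  "MS4A4E CaMBD1" = "28HSYLCKGLQEKFFKRKPKV6",
  "MS4A4E CaMBD2" = "107NYLKNLSWRIMGSYLCF123",
  "MS4A6A CaMBD1" = "101LSIATEKRLTKLLVH115",
  "NLRP3 CaMBD1" = "564ENYGKFEKGYLIFVVRFLFGLVNQERT589",
  "NLRP3 CaMBD2" = "603QIRLELLKWIEVKAKAKKLQIQ624",
  "PILRA CaMBD1" = "208IMILGLICLLRWRRRKGQQRT229",
  "TREM2 CaMBD1" = "62RVVSTHNLWLLSFLRRWNG80"
)

hit_starts <- function(hits) hits$start
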