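---
title: "Scanning for calmodulin-binding domains and motifs"
author: "cambscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning for calmodulin-binding domains and motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cambscan)
```

## The problem

Calmodulin (CaM) is a small calcium-sensing regulatory protein that binds
short helical peptides — calmodulin-binding domains (CaMBDs), typically
14–27 residues forming a basic amphipathic helix — in several hundred
target proteins (CaMBPs). Canonical calcium-dependent CaMBDs are
recognized by the spacing of bulky hydrophobic *anchor* residues within
the binding window: the classes 1–10, 1–12, 1–14 and 1–16 place two
anchors at those 1-based positions, while 1–5–10 and 1–5–8–14 add interior
anchors. Calcium-independent binding instead uses the IQ motif family,
canonically `[FILV]Qxxx[RK]Gxxx[RK]xx[FILVWY]`.

In the neuroinflammation literature, thirteen putative CaMBDs across
eleven risk-factor and biomarker proteins (ABCA7, CD33, CH3L1/YKL-40,
CLU, CR1, EPHA1, MS4A4E, MS4A6A, NLRP3, PILRA, TREM2) have been reported
with per-class motif counts obtained by *visual* scanning. `cambscan`
makes that second stage systematic: it enumerates motif occurrences
exhaustively and deterministically, ships the reported domains and counts
as a corpus, and reports agreement and disagreement explicitly.

## The scanning model

A motif class is a tuple of anchor offsets (1–10 ≡ offsets `{0, 9}`;
1–5–10 ≡ `{0, 4, 9}`, and so on); an anchor alphabet is the residue set
allowed at those offsets. A hit exists at start `i` (1-based) when the
residue at `i + offset` is in the alphabet for **every** offset:

```{r}
enumerate_anchor_motifs("LQALLLKRFLLARRSRRGLF",
                        default_motif_classes()[["1-10"]])
```

Deliberate properties of the enumeration:

* **Exhaustive and overlapping.** Every start position is tested;
  overlapping hits are all reported, and no deduplication is done across
  classes — the literature itself counts an anchor pair once per class
  (the same (1,10) pair above supports both a 1–10 and a 1–5–10 motif).
* **Forward strand only.** Motif nomenclature is defined N→C; no
  reverse-orientation scan exists.
* **Degenerate inputs return empty.** Sequences shorter than a class
  span, including the empty sequence, yield zero hits rather than an
  error, which keeps whole-proteome sweeps unconditional.
* **`X` never anchors.** Unknown residues are accepted in input but are
  not members of any alphabet.

IQ scanning distinguishes the canonical 14-residue pattern (`IQ`) from
the relaxed head-only pattern `[FILVWY]Qxxx[RK]G` (`IQ-like`). The
relaxed pattern is defined this way because the one IQ-family motif in
the corpus, `WQKAERGDILLSSL`, fails the canonical pattern at position 1
(W) and position 11 (L) yet is a reported IQ-like match; the head-only
pattern accepts exactly such incomplete variants.

### Choice of anchor alphabet

The default alphabet is **strict {F, I, L, V, W}**. Across the 35
per-class counts stated for the corpus, this is the uniform choice that
reproduces the largest subset (24 of 35); extensions by M, A or Y are
available as presets (`"strict+M"`, `"strict+A"`, `"strict+Y"`) because a
few individual reported counts are only attainable with them, but no
single uniform alphabet reproduces all reported counts. The concordance
report therefore surfaces the residual disagreements as explicit
mismatches instead of forcing agreement:

```{r}
report <- concordance_report(alphabet = "strict")
report
```

Only classes whose count the source text states are compared; unstated
classes are *not* asserted to be zero, because the visual-scan tallies
are not guaranteed exhaustive per class.

## Coordinates and the printed domain-string notation

Coordinates are 1-based inclusive throughout. Domains are parsed from
the printed notation `1221LQALLLKRFLLARRSRRGLF1240` (optional flanking
integers around the literal residue string). The literal residues are
always authoritative: when printed coordinates conflict with the
sequence length — the corpus contains four such typos (CLU `33…352`,
MS4A4E `28…6`, and off-by-one spans for NLRP3 CaMBD1 and PILRA) — the
record is flagged `inconsistent` rather than silently corrected, since
the intended coordinates are not stated. Extended residue codes (U, B,
Z, J, O) are rejected at parse time; none occur in the corpus, and silent
acceptance would risk miscounted anchors.

## The inventory and disease links

The eleven distinct corpus proteins form the scanned set; thirteen
previously identified neuroinflammation-linked CaMBPs (BACE1, BIN1,
CaMKII, PP2B, PMCA, NOS, NMDAR, AchR, Ado A2AR, Aβ, APOE, SNCA, TMEM175)
form the prior set; their union of 24 is the CaMBP inventory. A protein
appearing in both lists would be flagged and counted once. The
protein–disease incidence matrix is built only from links stated in
running text (status `"stated"`); associations that appear only in a
figure are not encoded, and any row with another status is excluded from
counts.

## The heuristic domain caller

The upstream stage that originally proposed the corpus domains is an
external profile-HMM web service whose algorithm is unpublished.
`call_domains()` is an explicitly heuristic stand-in for that functional
role — proposing candidate CaMBD windows in a full-length sequence — and
the corpus-reproduction path never uses it (the printed domains are
scanned directly).

Each window of length 15–27 (the typical CaMBD size range) receives a
composite score

\[
S = w_m \frac{\text{motif hits}}{\text{window length}}
  + w_c \max(\text{net charge}, 0)
  + w_h \overline{h}
  + w_\mu \mu_H
  - w_p \cdot \#\text{Pro}
\]

with net charge `+1` per R/K and `−1` per D/E, mean Kyte–Doolittle
hydropathy \(\overline{h}\), and hydrophobic moment \(\mu_H\) — the
magnitude of the helical-wheel vector sum of *window-centred*
hydropathies at 100°/residue. Centring on the window mean is a
deliberate numerical choice: the uncentred sum is nonzero even for
compositionally uniform windows (the geometric phase sum rarely
cancels), whereas the centred moment measures periodic hydropathy
variation — amphipathicity — and is exactly zero for an all-glycine
window. Proline is penalized as a helix breaker.

Default weights are `(motif 10, charge 0.5, hydropathy 0.5, moment 0.3,
proline 1)` with threshold 5: motif density is the primary evidence
(a single hit in a 20-mer contributes 0.5 to the density, hence 5 to the
score), charge and moment reward basic amphipathic character, and the
threshold sits far above anything an anchor-free, negatively charged
background window can reach while idealized planted domains score ~10.
Windows at or above threshold are resolved greedily by descending score,
ties broken by smaller start then shorter window — simple, deterministic
and testable. No attempt is made to infer the external service's scoring
or boundaries; candidate boundaries here are approximate by construction.

## The synthetic-data generator

`generate_background()` draws i.i.d. sequences from a residue
composition (uniform by default — the simplest null; an average human
proteome composition ships as the `"human"` preset), with an integer
seed making every dataset reproducible. `plant_motif()` overwrites —
never inserts, so truth coordinates stay stable — a window with anchors
from the alphabet at the class offsets and non-anchor residues elsewhere
in the window, which guarantees a hit at exactly the planted position.
`make_benchmark()` combines the two into FASTA + truth tables.

Two analytic checks anchor the generator: planted-motif sensitivity is
1.0 by construction, and for a two-anchor class the background hit rate
per sequence has the closed form \(p^2 (L - s + 1)\), where `p` is the
total anchor probability and `s` the span; simulations agree within
three standard errors (`analysis/03_simulation_benchmark.R` runs this at
10,000 sequences of length 50).

What the generator does *not* emulate: residue autocorrelation,
secondary-structure constraints, domain architecture, and evolutionary
conservation of real proteins. Passing benchmarks therefore demonstrate
correctness of the scanning and calling machinery under an i.i.d. null,
not predictive accuracy for real proteomes.

## Problem sizes used in the shipped analyses

The analysis drivers and the test suite use: the 13-domain corpus
(deterministic, instantaneous); 1,000 random sequences of length ≤ 40
for brute-force oracle equivalence; 10,000 sequences of length 50 for
sensitivity and background-rate checks; and 50 planted-domain trials of
length 200 for the caller benchmark. These sizes give sub-percent Monte
Carlo error on the quantities checked.

## Known limitations

* CD33's reported counts cannot be recomputed — its domain sequence was
  never printed; the entry is flagged `sequence-unavailable` and skipped
  with a notice.
* Eleven of the 35 stated counts disagree with strict-alphabet
  enumeration in either direction (extra strict pairs the visual scan did
  not count, or counts needing extended alphabets); they are reported as
  mismatches, not errors.
* The caller is a labelled heuristic; its boundaries should not be
  compared against any external predictor's.
* Disease links cover only text-stated associations; the matrix is a
  floor, not the full association landscape.
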