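# cambscan

Systematic scanning of protein sequences for calmodulin-binding domains
(CaMBDs) and motifs, built around the neuroinflammation CaMBP corpus.

## The problem

Calmodulin (CaM) transduces calcium signals by binding short helical
peptides in its target proteins (CaMBPs). Canonical calcium-dependent
CaMBDs — 14–27 residue basic amphipathic helices — are recognized by the
spacing of bulky hydrophobic **anchor** residues: the classes 1–10, 1–12,
1–14, 1–16 place two anchors at those positions of the motif window, and
1–5–10 / 1–5–8–14 add interior anchors. Calcium-independent binding uses
the IQ family, canonically `[FILV]Qxxx[RK]Gxxx[RK]xx[FILVWY]`.

Reported CaMBD annotations for neuroinflammation-linked proteins (TREM2,
CD33, PILRA, CR1, MS4A4E/MS4A6A, CLU, ABCA7, EPHA1, CH3L1/YKL-40, NLRP3)
were produced by *visual* scanning of candidate domains. `cambscan`
replaces that step with exhaustive, deterministic enumeration: a hit of a
class with offsets `{o1..ok}` exists at start `i` iff the residue at
`i + oj` is in the anchor alphabet (default strict `{F,I,L,V,W}`) for
every offset; all overlapping hits are reported and nothing is
deduplicated across classes. The package ships the thirteen reported
domains across eleven proteins as a corpus with their stated per-class
counts, reproduces what a uniform alphabet can reproduce, and surfaces
the rest as explicit mismatches. It also provides a heuristic
basic-amphipathic-helix window caller (motif density, net charge, mean
Kyte–Doolittle hydropathy, hydrophobic moment at 100°/residue), and a
seeded synthetic-data generator for planted-motif benchmarking.

Audience: anyone annotating CaM-binding potential in protein sequences or
auditing visually curated CaMBD motif tallies.

## Worked example

Scan the ABCA7 CaMBD `1221LQALLLKRFLLARRSRRGLF1240` for 1–10 motifs:

```r
library(cambscan)
enumerate_anchor_motifs("LQALLLKRFLLARRSRRGLF", default_motif_classes()[["1-10"]])
#>   class start end anchor_positions anchor_residues
#> 1  1-10     1  10             1,10              LL
#> 2  1-10    10  19            10,19              LL
#> 3  1-10    11  20            11,20              LF
```

Three 1–10 motifs: anchor pairs (L1,L10), (L10,L19), (L11,F20) — note the
overlap at L10, which is counted, not collapsed. Tallying the full roster:

```r
count_by_class(scan_all_classes("LQALLLKRFLLARRSRRGLF"))
#>     1-10     1-12     1-14     1-16   1-5-10 1-5-8-14
#>        3        1        1        2        1        0
```

The domain's reported annotation (three 1–10, one 1–5–10, one 1–14) is
reproduced; the scanner additionally finds strict 1–12/1–16 pairs that
the visual annotation did not state. The IQ scanner separates canonical
from relaxed matches:

```r
scan_iq("WQKAERGDILLSSL")   # the reported NLRP3 IQ-like motif
#>   variant start end matched_text
#> 1 IQ-like     1   7      WQKAERG
```

`concordance_report()` runs the whole corpus: 24 of the 35 stated counts
are reproduced exactly under the strict alphabet; the 11 disagreements
(e.g. TREM2 1–12: reported 1, computed 2) are printed individually. The
CaMBP inventory arithmetic — 11 scanned proteins + 13 previously
identified CaMBPs = 24 — and the text-stated protein–disease matrix are
included in the same report.

## Analysis workflow

The numbered drivers under `analysis/` reproduce the shipped analyses and
write tables to `results/`:

| script | what it does |
| --- | --- |
| `01_reproduce_counts.R` | corpus concordance (`results/concordance.tsv`) |
| `02_inventory_and_diseases.R` | CaMBP inventory and disease matrix |
| `03_simulation_benchmark.R` | planted-motif sensitivity, background rate vs closed form |
| `04_domain_caller_benchmark.R` | planted-domain recovery by the window caller |

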