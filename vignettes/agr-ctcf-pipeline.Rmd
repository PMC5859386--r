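---
title: "Models and methods: CTCF occupancy, orientation and loop geometry in antigen-receptor loci"
author: "agrpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Antigen-receptor (AgR) loci — Igh, Igκ, Igλ, TCRβ, TCRα/δ, TCRγ — are up to
several megabases long, with large arrays of V gene segments far from the
small D-J-C cluster at one end. V(D)J recombination requires distal V
segments to reach the (D)J segments, which is thought to be mediated by
CTCF/cohesin chromatin loops: cohesin extrudes chromatin until it is halted
at CTCF sites, preferentially when two sites face each other ("convergent"
orientation). Because the CTCF motif is non-palindromic, every bound site
has an orientation, and the genome-wide orientation pattern of a locus
predicts which loops can form.

`agrpipe` implements the computational chain needed to characterise this
from ChIP-seq-like data:

1. **Multi-mapping-aware read placement** (`place_reads`). AgR loci arose by
   extensive duplication; reads from near-identical repeats are discarded by
   unique-only mapping, which makes duplicated copies look unbound. The
   placement contract is: report all placements with at most `v_max`
   mismatches, keep only the best (minimal-mismatch) stratum, retain the
   read if it has at most `m_max` best-stratum placements, otherwise discard
   it. The defaults `v_max = 2`, `m_max = 3` are the permissive policy the
   field uses for loci containing a triplicated segment.
2. **Confident peak calling** (`call_peaks`) against a local Poisson
   background, with a p-value cutoff of `1e-5` and a Benjamini–Hochberg
   FDR cutoff of 1% — the conventional "confident peak" thresholds.
3. **Cross-cell-type merging and specificity classification**
   (`merge_peak_sets`, `classify_specificity`): literal (≥ 1 bp) overlap,
   transitively closed, defines merged reference sites; presence patterns
   over a nine-state panel (pre-pro-B, pro-B, pre-B, DN, DP, mature B,
   mature T, MEF, ES) are classified as ubiquitous, lymphocyte-specific,
   B-/T-lineage, stage-specific, or mixed.
4. **Hypergeometric locus enrichment** (`locus_enrichment`): the genome is
   cut into fixed bins (default 1 kb); with `N` genome bins, `K` locus
   bins, `n` peak-bearing bins and `k` of them in the locus, the
   enrichment p-value is the exact upper tail `P(X >= k)` of
   Hypergeometric(N, K, n).
5. **Motif-orientation calling** (`orient_peak_set`): each confident peak
   is scanned on both strands against a nine-entry CTCF motif library;
   every collapsed motif instance votes with its strand; the consensus
   sign gives a forward/reverse call; ties are ambiguous and discarded
   from the stranded output.
6. **Loop geometry** (`predict_extrusion_loops`, `geometry_census`,
   `detect_flanked_domains`): ordered anchor pairs are convergent (+,−),
   tandem (equal signs) or divergent (−,+); under the convergent-stop
   extrusion rule each forward anchor is predicted to loop to its nearest
   downstream reverse anchor.

All of it runs end to end on a synthetic locus panel, so the package needs
no external data.

## The synthetic-data model

`build_genome` draws a uniform random background sequence and writes each
planted motif instance (the library consensus, reverse-complemented for
minus-strand sites) at its recorded position. An optional duplication
clones a template segment into `n_copies − 1` adjacent copies with
independent per-base substitutions at the stated divergence (substitutions
only, so copy coordinates remain exactly alignable and the truth map stays
exact). Template sites are projected into every copy, and the projections
inherit the template's occupancy — duplicated CTCF sites are bound in every
copy, which is what ChIP-qPCR shows for near-identical locus repeats.

`simulate_reads` models occupancy as the fraction of cell-equivalents with
the site bound: a site with occupancy `p` emits
`Poisson(reads_per_bound_site × p)` reads, so expected peak height is
proportional to occupancy — the mechanism behind cell-type differences in
peak intensity. Fragment midpoints are `Normal(site centre, frag_len / 4)`;
the default `frag_len = 147` bp mirrors the nucleosome-scale fragment
extension conventionally used when building signal tracks. A uniform
Poisson background (default 0.02 reads/bp) is added. Every operation takes
an explicit seed and uses a private RNG stream; `run_pipeline` derives all
stage seeds deterministically from one master seed.

### The default panel

`default_agr_panel()` encodes four scaled-down locus designs plus a
site-free 500 kb background chromosome (the "rest of the genome" against
which locus enrichment is measured):

| locus        | size   | V sites | design point |
|--------------|--------|---------|--------------|
| `igh_like`   | 60 kb  | 12, all `+` | superanchor pattern: every V-region site faces the D-J-C end; a cluster of reverse sites at the far end |
| `igk_like`   | 60 kb  | 10, mixed   | stage-specific: V occupancy 0.9 in pre-B, 0.05 in pro-B, 0 elsewhere; distal half toward the J end, proximal half away |
| `tcrb_like`  | 40 kb  | 8, all `+`  | small locus, T-restricted D-J-C sites |
| `tcrad_like` | 90 kb  | 20, 85% `+` | triplicated 8 kb segment (0.5% divergence) and a minority of reverse V sites |

Occupancies are design values, not estimates: 0.9 for "bound", 0.05 for
"marginal", 0 for "unbound"; D-J-C-end sites are occupied in every panel
label (including MEF and ES), V-region sites only in lymphoid labels. Locus
sizes are scaled ~50-fold below the real loci so the full panel (5
chromosomes × 9 cell types) simulates, places and calls in about three
minutes on one core; every qualitative contrast of the real loci
(triplication, mixed orientation, majority-toward-J, stage-specificity) is
preserved at this scale. Planted sites are spaced ≥ 1 kb apart so peaks do
not merge across sites.

Two deliberate simplifications: the Igκ-like V occupancy is confined to
pre-B (in vivo the pre-B pattern persists into mature B cells; confining
it to one label makes the locus a clean test of the `stage_specific`
class), and ES occupancy of the TCRα/δ-like V region is set to 0.5 to
exercise the `mixed` class.

### What the generator does *not* model

No ChIP fragment-size distribution, GC bias, chromatin accessibility or
mappability structure beyond the duplication construct; no indels in
duplication copies; no motif-affinity heterogeneity (all planted sites use
the library consensus). Passing tests therefore demonstrate the internal
consistency and statistical calibration of the pipeline under this model,
not performance on real ChIP-seq libraries.

## Numerical and design choices

**Motif scoring.** Scores are log-odds in bits against a uniform 0.25
background; `N` in a scanned sequence contributes 0 bits. Zero
probabilities in user motif files are rejected (log-odds would be −∞)
rather than silently pseudocounted. `consensus_to_matrix` gives allowed
bases 0.997 probability mass (split across degenerate codes) and places
the threshold midway between the worst score attainable within the
mismatch budget and the best score attainable with one extra mismatch; the
tested contract is that separation, not the constants. With strongly
unequal per-position information content such additive separation can be
impossible, in which case conversion fails loudly.

**The default library** is synthetic: five consensus-derived entries
("database"-style, exact-match thresholds) and four profile-style entries
("discovered"-style, dominant base 0.85, threshold at 80% of the maximal
score) — mirroring the usual 5 + 4 library design for CTCF orientation
annotation. The nine consensi are CTCF-like, non-palindromic 15–16-mers,
verified non-cross-hybridising: no consensus (or its reverse complement)
reaches any other entry's threshold on the wrong strand, so a planted site
can never produce an opposing vote.

**Peak caller.** Window coverage sums are converted to fragment-count
equivalents (`sum / frag_len`) and tested against
`Poisson(rate × window / frag_len)`, where the rate is the most
conservative of the global mean, a 10 kb local mean, and the control track
mean — the local-background idea of standard callers, reduced to its
Poisson core. Windows (200 bp, step 100) passing both `p <= 1e-5` and
BH `q <= 0.01` are merged by overlap; the summit is the coverage argmax.
Because partially overlapping fragments contribute fractional mass, the
count statistic is slightly under-dispersed relative to Poisson, making
the test conservative; the calibration suite verifies empirical FDR ≤ 3×
nominal on 200 pure-null tracks.

**Specificity precedence.** The classes are applied in order: ubiquitous
(present in all labels) → lymphocyte_specific (no non-lymphoid, ≥ 1 B and
≥ 1 T label) → B_/T_lineage (one lineage only, ≥ 2 labels) →
stage_specific (exactly one lymphoid label) → mixed. Lymphocyte
specificity deliberately does not require *all* lymphoid labels (early
pre-pro-B progenitors often lack sites that every later stage carries).

**Enrichment urn.** Whether enrichment should count peaks, base pairs or
bins is underdetermined; bins (default 1 kb, configurable) make the urn
model well-defined — a bin either contains a peak summit or not, and
`N`, `K`, `n`, `k` are all bin counts. The upper tail is computed by
`stats::phyper` (exact, log-gamma-stable); the test suite verifies it
against direct combinatorial enumeration over every grid with `N ≤ 60`
(1.2 million cases, agreement to 4e-15).

**Orientation voting.** "Consensus sign" is read as strict majority over
motif instances — the weakest reading under which ties are ambiguous and
discarded. Overlapping hits of the same motif on the same strand collapse
to the best-scoring instance first (one physical site, one vote), which
prevents wide peaks from inflating vote counts. A per-motif-model voting
mode (`mode = "per_motif_best"`) is provided for users who prefer counting
models rather than instances; the default is per-instance.

**Loop rule.** Anchors are fully blocking (permeability 0): each forward
anchor pairs with its nearest downstream reverse anchor, and the
intervening-anchor count is reported so users can relax blocking
downstream. This is a model, not a claim — tandem-loop exceptions are
documented in vivo. One subtlety: this per-forward-anchor rule is *not*
mirror-symmetric (reflecting the genome and complementing strands turns it
into a per-reverse-anchor rule; an array `(+,+,−)` predicts two loops, its
mirror `(+,−,−)` one). The pairwise geometry census *is* exactly
mirror-symmetric, and that is the invariant the tests assert.

**Multimap weighting and deduplication.** `coverage_from_placements`
defaults to full weight 1 per retained placement, mirroring
report-all-up-to-m aligner semantics; a `1/k` fractional mode is provided.
`compare_mapping_policies` — the diagnostic that contrasts coverage over
duplication copies with a unique control — uses fractional weighting and
disables sequence-level duplicate removal, for two reasons established
during design: (i) under full weight every ambiguous read is replicated
into all copies, so repeat coverage scales with copy number rather than
occupancy; (ii) dedup removes cross-copy sequence collisions, depressing
repeat coverage by a depth-dependent factor (~13% at the depths used here)
even when every copy is equally bound. Both effects would confound the
question the diagnostic asks — how much signal the placement *cap*
destroys over repeats. How duplicate removal should interact with
multi-placement retention is genuinely underdetermined in standard
pipelines; `place_reads` itself keeps dedup on (one contribution per
distinct sequence), and the interaction is exposed through the `dedup`
argument.

**Degenerate inputs.** Empty interval files parse to empty tables; peaks
shorter than every motif scan to zero hits (not an error); an empty peak
set makes the motif-match fraction undefined (error) and is reported as
`NA` by `make_report`; a site-free, repeat-free chromosome skips placement
(every background read is its own unique placement) — an exact shortcut
used for the background chromosome.

## Running the pipeline

```{r}
library(agrpipe)
cfg <- pipeline_config(seed = 1)
bundle <- run_pipeline(cfg)
report <- make_report(bundle)
head(report)
```

The bundle holds, per locus: per-cell-type confident peaks, the merged
presence matrix and specificity classes, V-region peak counts, oriented
peaks with vote counts, toward/away tallies relative to the D-J-C end,
bin-based enrichment against the synthetic genome, and predicted extrusion
loops with a geometry census. `scripts/acceptance.R` reruns the whole
chain from a seed and writes the headline numbers as JSON.

## Known limitations

- The placement engine is exact and index-free; it is meant for
  synthetic-scale genomes (≤ a few Mb), not real reference genomes.
- The peak caller is a single-scale Poisson window scan: no fragment-model
  estimation, no broad-peak mode, no per-1M rescaling beyond a constant.
- Orientation calls depend on the motif library; with real data the
  library is an input and its miscalibration propagates directly.
- The extrusion rule ignores loading sites, permeability and extrusion
  kinetics; it predicts the convergent-pair skeleton only.
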