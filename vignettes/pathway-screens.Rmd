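---
title: "Pathway-centric pooled resistance screens: model, parameters, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-centric pooled resistance screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathscreen)
```

## What this package models

A pathway-activation screen introduces a pooled lentiviral library of
activating cDNA constructs — each tagged with a 4-nt DNA barcode — into a
cancer cell line, selects the transduced pool under a targeted drug at
several doses alongside vehicle-treated wells, and reads construct
abundances out by amplicon sequencing. Constructs whose activation rescues
growth under drug become over-represented relative to inert controls; the
pathways they activate are nominated as resistance drivers.

`pathscreen` implements this as two halves sharing one set of contracts:

1. **Forward model** (`simulate_infection()`, `simulate_arm()`,
   `simulate_sequencing()`, `generate_screen()`): a generative simulation
   of the screen with a known truth table of planted resistance effects.
2. **Inverse pipeline** (`count_barcodes()`, `compute_enrichment()`,
   `call_hits()`): the deconvolution that turns raw reads back into
   pathway-level calls.

Because the forward model is explicit, the inverse pipeline can be tested
as a parameter-recovery problem: plant effects, run the whole loop, and ask
whether the calls equal the truth.

## The library manifest

The packaged manifest (`default_manifest()`) holds 36 pathway-activating
constructs across 17 canonical signaling pathways plus HcRed and luciferase
(negative controls) and a MEK1-DD spike-in flagged as positive control — 39
records. Three apoptosis sub-groupings (intrinsic, extrinsic, common
effector) are collapsed into a single BCL-2-family apoptosis pathway so the
17-pathway count holds; the sub-grouping is retained in `variant_note`.

The true 4-nt barcode sequences of such libraries are not public, so the
packaged barcodes are **synthetic**, generated by
`assign_barcodes(min_hamming = 2, seed = 0)`. The distance-2 construction
uses a parity code (letter values summing to 0 mod 4), which has exactly
`4^3 = 64` words — any single substitution changes the parity, so no two
barcodes are single-error neighbours and exact matching is collision-free.
The 17-nt linker is likewise a synthetic stand-in: any fixed 17-mer ending
in the ATG start codon satisfies the layout, because linker matching is
against this same constant.

## The forward model and its assumptions

**Infection.** Each of `n_cells` cells receives Poisson(`moi`) lentiviral
integrations; untransduced cells are removed (puromycin). Each integration
draws a construct uniformly (the pooled library is titered for equal
representation). At the default MOI of 0.3, the expected fraction of
transduced cells with a single construct is
$\lambda e^{-\lambda} / (1 - e^{-\lambda}) \approx 0.857$.

**Design.** The surviving pool is split into 7 equal populations: a frozen
t0 pool, three drug doses with nominal growth inhibitions 0.2 / 0.5 / 0.8
(GI20–GI80; labelled 150 nM / 750 nM / 1.5 µM in the bundled MEK-inhibitor
preset), and three paired vehicle wells.

**Selection.** Growth is discretised daily. A genotype carrying resistance
factor $\rho \in [0,1]$ at dose $d$ grows at
$r = g_0 \,(1 - \mathrm{GI}(d)\,\rho)$ net divisions/day, where $g_0$ is the
uninhibited growth rate ($\rho = 1$: fully sensitive; $\rho = 0$: fully
resistant). Cells carrying several constructs use the strongest (minimum)
$\rho$ — the dominant-effect assumption usual for gain-of-function
constructs. Counts are stochastically rounded each day; when a population
exceeds `capacity` it is passaged by a 1:10 multinomial subsample.

**Sequencing.** Templates are drawn multinomially over integrations (a
two-construct cell contributes two templates), each read is
barcode + linker + index (27 nt exactly), and i.i.d. substitutions are
applied at `error_rate` per base. Qualities are constant (Phred Q40); PCR
amplification bias, indels, and quality-dependent errors are not modelled.

## The inverse pipeline

**Counting.** Reads are sliced at fixed offsets (0-based half-open):
barcode [0,4), linker [4,21), index [21,27). The index must match one
sample uniquely within `max_index_mm` (default 0; ties reject), the linker
within `max_linker_mm` (default 2) of the constant, and the barcode must
match exactly — 4-nt barcodes at pairwise distance 2 cannot support error
correction, since a distance-1 neighbour would be ambiguous. Longer reads
are truncated to 27 nt; shorter reads are rejected. Every read is either
assigned or tallied under a rejection reason, so assigned + rejected always
equals the input count. Counting streams FASTQ in chunks; memory does not
grow with file size.

**Enrichment.** Fractions are counts over the per-sample total; averaging
is technical-then-biological arithmetic mean (the order is a convention —
the two levels are named but not ordered in the underlying protocol; a
geometric-mean variant sits behind `geometric = TRUE`). All vehicle wells
are averaged into a single reference. The pseudocount $\alpha = 10^{-6}$ is
applied symmetrically to numerator and denominator: it keeps ratios finite
on dropout while being ~4 orders of magnitude below the 1/39 abundance of
any library member, so abundant constructs are undistorted and
vehicle-vs-itself is exactly 1 for any $\alpha$.

**Hit calling.** Enrichment is expressed relative to the mean of the
negative-control constructs per dose, and a pathway is called when at least
one of its activating constructs exceeds 1.5 (strictly) at ≥ 2 doses. The
"same construct at ≥ 2 doses" reading is the default; the pooled-across-
constructs alternative is available (`per_construct = FALSE`) for
sensitivity analysis. The MEK1-DD spike-in is excluded from the baseline
(flagged `positive_control`): in a MEK-inhibitor screen its behaviour is
ambiguous, and the baseline should contain only constructs with no expected
effect. Missing enrichment at a dose fails that dose. Raising the
threshold or the dose requirement can only shrink the hit set.

## Default parameters

| parameter | default | why |
|---|---|---|
| `n_cells` | 5×10⁵ | cells exposed to virus (one seeded well) |
| `moi` | 0.3 | keeps ~86 % of transduced cells single-construct |
| `doses` | GI 0.2/0.5/0.8 | three doses spanning GI20–GI80 |
| `days` | 21 | middle of the 2–4 week selection window |
| `split_fraction` | 0.1 | 1:10 passage at confluence |
| `capacity` | 2×10⁵ | confluent-well scale; gives a passage every ~3 days at 1 division/day |
| `baseline_growth` | 1 division/day | typical doubling time of cultured cancer lines |
| `read_depth` | 10⁵/sample | ~2,500× mean coverage per construct |
| `error_rate` | 10⁻³/base | short-read substitution scale |
| `n_tech_reps` | 2 | two index primers per sample |
| `alpha` | 10⁻⁶ | pseudocount, see above |
| `threshold`, `min_doses` | 1.5, 2 | the calling rule |

All randomness flows from one scenario seed through per-operation sub-seeds
(`seed`, operation tag), so any arm or sample is independently
reproducible and a fixed seed reproduces a byte-identical screen.
Genotype bookkeeping is ordered by manifest index / byte order, so results
do not depend on the session locale.

## What a green test establishes — and what it does not

The simulator emulates: Poisson integration statistics, equal library
representation, dose-dependent positive selection with planted effects,
passage bottlenecks, index/barcode read structure, and multinomial
sequencing with substitution errors. It deliberately omits: clonal
evolution and de novo mutation, PCR bias beyond multinomial sampling,
drug pharmacokinetics, quality-dependent or indel errors, and any
cell-line-specific biology. Recovery of planted effects therefore
validates the *pipeline's arithmetic and the design's statistical power*,
not the biological conclusions of any real screen.

**The hitchhiker limit.** At MOI 0.3, ~13 % of transduced cells carry two
constructs. Under strong selection a passenger construct sharing a cell
with a resistant one rides upward with it. With 5×10⁵ infected cells split
7 ways, a given (resistant, passenger) pair is founded by only ~16 cells
per arm, so passenger enrichment relative to the two-control baseline
carries ~30 % founder noise; occasionally (roughly one seed in six) a
passenger clears the 1.5× bar at two doses and a spurious pathway is
called alongside the planted ones. This is intrinsic to the design scale,
not an artifact of the pipeline: it shrinks with more infected cells,
more controls in the baseline, or a lower MOI, and it is why marginal
calls just above threshold deserve scrutiny while the planted pathways sit
at 25–30×.

## Numerical conventions

Coordinates are 0-based half-open; strict inequality at the hit threshold;
tied index matches are rejections; zero-read samples are excluded from
fraction tables with a warning; replicate concordance (`r²`, squared
Pearson correlation of paired fractions) is computed on plain fractions
and reported as missing for zero-variance inputs. Capacity errors in
barcode design are raised before any assignment happens (the distance-2
4-mer code has exactly 64 words; greedy packing is used for larger
distances).
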