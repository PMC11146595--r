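---
title: "Ribosome decision graphs: model, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ribosome decision graphs: model, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdgraph)
```

## The model

A ribosome decision graph (RDG) describes everything a single
small-subunit-containing ribosomal complex can do on one mRNA, from loading
at the 5' cap to final dissociation. The graph is rooted at an `ENTRY` node,
every maximal path ends at a single `EXIT` node, and each root-to-exit path
(a *RiboPath*) is one complete, mutually exclusive behavior of one ribosome.
Edges are either `SCAN` (movement without synthesis) or `TRANSLATE`
(elongation through a *translon* — the region translated from initiation
through termination, which unlike an ORF may span several reading frames
after a frameshift or cross recoded stops). Branch nodes carry the
nondeterminism:

* `BRANCH_INIT` — leaky scanning at a start codon: commit (initiate) with
  probability $p$, continue scanning with $1-p$;
* `BRANCH_REINIT` — after terminating a sufficiently short translon, resume
  scanning downstream versus leave the mRNA;
* `BRANCH_READTHROUGH` — at a recoded stop (including selenocysteine UGA):
  decode through versus terminate;
* `BRANCH_FRAMESHIFT` — at a programmed frameshift site: slip into the
  shifted frame versus stay.

Stop codons without an annotated event are deterministic ends of translons,
and the final leaky continue edge ends at `EXIT` — the unproductive path of
a ribosome that never initiated. The graph is a DAG because scanning and
elongation are strictly 5'→3'; post-termination 3'→5' movement is outside
the model.

Probabilities are attached to branches, not baked into topology (with one
exception below), so the same graph serves structural queries (path counts,
mutual exclusivity, variant effects) and quantitative ones (path
probabilities, synthesis rates) under any assignment.

## Semantics decided during design

**Reinitiation is a policy, not a per-site event.** The biology is a
property of the terminating ribosome (initiation factors still attached
after a short elongation), so every termination is screened against a
`reinitiation_policy()`: translons longer than `max_translon_nt` (default
100 nt, a conventional "short uORF" scale) never reinitiate. The *recharge
model* expresses delayed reinitiation — the distance needed to re-acquire
the ternary complex: `NONE` (immediately competent), `STEP`
(`recharge_distance_nt`; closer starts deterministically skipped) or
`EXPONENTIAL` (competent at distance $x$ with probability
$1-e^{-x/\lambda}$).

**A committed reinitiating ribosome initiates at the first eligible
downstream start.** Under `NONE`/`STEP` the reinitiation branch is binary:
exit, or resume and initiate at the 5'-most start beyond the recharge
window, *strictly downstream of the termination site* (a start inside the
terminated translon, like the CUG of the three-start example, is never a
reinitiation target). We considered giving the post-termination ribosome a
second leaky decision at that start; that model produces six structural
paths on the three-start example instead of the five distinct ribosome
behaviors the scenario actually admits, so it was rejected. Under
`EXPONENTIAL` recharge the post-termination route does branch per start,
with competence probabilities assigned at build time. Chained reinitiation
(a reinitiated short translon reinitiating again) is behind
`allow_chained`, off by default: the canonical examples never chain, and we
prefer the conservative graph.

**Deterministic starts truncate the scanning route.** An initiation event
with `probability = 1` (the usual treatment of an annotated CDS start) is
built with a commit edge only. This is a deliberate structural choice: a
"leak" edge carrying probability zero would still create paths, and the
variant analyses below are *structural* statements ("no path reaches the
CDS"). Consequence: events downstream of a deterministic start that no
reinitiation can reach are pruned from the graph entirely.

**Shared elongation prefixes.** A readthrough or frameshift decision happens
mid-elongation, so the short and extended product variants share their 5'
`TRANSLATE` edges. Each edge stores the id of its base (all-continue)
variant; the authoritative translon attribution of a path is the set of
`TERMINATION` nodes it traverses. Co-located events are ordered
initiation < frameshift < readthrough, and two elongation events in one
codon are rejected as ambiguous.

## Quantification

The flux of a translon is its length-normalized footprint density: under
uniform elongation a ribosome deposits footprints along the whole translon,
so initiations per unit time are proportional to (summed A-site density) /
(translon length). No smoothing or end-trimming is applied by default
(`trim_codons = 0`) so the estimator stays auditable.

**Overlap decomposition.** Translons overlap — trans-frame products overlap
in different frames, and N-terminally extended proteoforms overlap in the
*same* frame, where sub-codon phase carries no information. `translon_fluxes()`
therefore solves the linear model in which each translon contributes a
constant per-codon deposit on its codon-phase positions, by least squares
over the whole track; unique regions separate the overlapping contributions,
and frame-aware attribution falls out as the special case of disjoint
phases. Negative estimates (possible under noise) are clamped to zero with a
warning. The plain per-translon mean (`translon_flux()`, method `"naive"`)
is kept for audit.

**Flux balance.** On the scanning route, the flux arriving at a branch is
the commit flux plus everything committed downstream; the commit probability
is commit/arriving, computed 3'→5' in closed form. Two stated assumptions:

* the unproductive exit flux is unobservable in Ribo-seq and is set to zero,
  so the inferred probability of the 3'-most branch on a route is an upper
  bound — exact when that start is deterministic, which is why the worked
  examples treat the CDS start as probability 1;
* each translon must be entered by exactly one edge. A translon fed by both
  reinitiation and leaky scanning (the main translon of the three-start
  example) is not identifiable from one density track: the estimator stops
  and asks the user to fix one probability (`fixed =`), then subtracts the
  reinitiated flux and solves the rest. We deliberately do not fall back to
  a least-squares fit over non-identifiable graphs — a silently
  ill-conditioned estimate is worse than an explicit error. Elongation
  (readthrough/frameshift) branches share prefix density between their
  variants and are likewise outside this estimator's scope.

`path_probabilities()` multiplies edge probabilities along each path (sums
to 1 within 1e-9 by construction); `relative_synthesis_rates()` sums path
probabilities per translon and also reports them as a percentage of the
productive total. On noise-free data the loop flux → probabilities → rates
reproduces the normalized input fluxes exactly on identifiable graphs.

## The simulator and what the fixtures represent

`simulate_footprints()` samples one decision per branch per ribosome
(multinomially over path probabilities), then deposits
`footprints_per_codon` (default 1) expected footprints per traversed codon
on the codon's first nucleotide, preserving sub-codon phase. Noise models:
`none` (exact expectation — useful for algebraic identities), `multinomial`
(sampled path choices, footprint totals scattered uniformly over codons) and
`poisson` (per-codon counts). Elongation is uniform — no codon-specific
dwell times — deliberately matching the flux estimator's assumption so
recovery tests are exact in expectation; dwell-time heterogeneity, library
biases, footprint-length distributions and multimapping are not emulated,
so passing recovery tests demonstrate estimator correctness under the
model, not robustness to real-library artifacts.

The fixture transcripts are deterministic codon-block constructions (the
`GGA` filler repeat is AUG- and stop-free in all frames), so all structural
counts are exact:

* `make_fig3_transcript()` — three starts in two frames; five RiboPaths;
  canonical probabilities 0.5 (uAUG), 0.3 (CUG), 0.9 (reinitiation), CDS
  deterministic. These values are the package's reference simulation
  conditions; the recovery loop runs at 100,000 ribosomes, where multinomial
  noise leaves each re-estimated probability within ±0.02 of truth.
* `make_delayed_reinit_transcript()` — short uORF (12 nt), long uORF
  (192 nt) overlapping the CDS start, CDS; `STEP` recharge of 10 nt
  ("normal") reaches the long uORF start, 60 nt ("stress") carries the
  ribosome past it to the CDS — chosen so the two presets bracket the
  15 nt/61 nt start distances.
* `make_readthrough_transcript()` / `make_frameshift_transcript()` — one
  recoded UGA (two products sharing a start); one −1 slip site (a
  two-segment trans-frame translon beside the in-frame product).
* `make_variant_fixture()` — leaky uAUG (p = 0.25), strong in-frame AUG
  (p = 1) whose short leader translons feed the CDS by reinitiation; a
  single-U insertion inside the leader ORFs shifts their frame, extends both
  past the CDS start (removing reinitiation eligibility) and creates a new
  AUG at the edit site. The rebuilt graph has no path through the CDS.

## Variants

Variants are applied in transcript coordinates (`ref` validated in place);
events are *re-derived* on the edited sequence rather than shifted — edits
create and destroy codons. Rediscovered starts inherit probability and name
from offset-corrected matches; destroyed non-initiation events are dropped
with a warning. `diff_rdg()` matches translons across graphs in two stages
after offset correction: first by terminal stop and frame (N-terminal
variation keeps the stop), then by start and start codon (frame shifts and
stop losses move the stop but keep the start — stop-anchoring alone would
misreport a 3' extension as loss plus gain). Length decides
`EXTENDED`/`TRUNCATED`; equal length with a different terminal frame is
`FRAME_CHANGED`. Multi-variant input is applied left to right with
re-anchoring; overlapping edits are rejected.

## Numerical and interface choices

* Coordinates are 0-based, half-open, transcript-space everywhere; BED and
  bedGraph share that convention, wiggle input (1-based) is converted on
  read, VCF positions likewise with anchor-base stripping.
* A START_STOP ORF interval includes its terminating stop codon; peptide
  length is `(end − start)/3 − 1`. Starts without an in-frame stop are
  retained and flagged `open_ended` (they matter for stop-loss variants);
  open-ended translons never reinitiate (they do not terminate).
* The Kozak context score is the matched fraction of the seven scored
  consensus positions (`gccRccAUGG`, −6..−1 and +4) with a fixed
  denominator; out-of-transcript positions contribute zero. It is a
  consensus match, not a trained model.
* Stable ids: nodes are named by role and coordinate (`init@6`,
  `reinit@15:T1`), edges sequentially in construction order, paths in
  commit-first depth-first order — rebuilds are bit-identical, DOT and JSON
  output diff-stable. Probabilities serialize at 6 significant digits;
  test comparisons use 1e-9 absolute.
* `enumerate_paths()` refuses more than `max_paths` (default 1e6) paths and
  reports the exact count from the dynamic-programming counter; conceptual
  graphs over exhaustive start sets should be queried with `count_paths()`.

## Known limitations

One RDG describes one mRNA sequence: multi-isoform loci need one graph per
isoform (splice-graph integration is out of scope), and genomic variants
must be lifted to transcript coordinates by the caller. Kinetic phenomena —
ribosome queuing and stall-mediated regulation — are not representable as
single-ribosome path properties; a stall site can only be carried as an
inert annotation. Raw Ribo-seq processing (alignment, A-site offset
calibration) is upstream of this package: the density input is already
A-site-assigned, per-nucleotide, transcript-space signal. The
flux-balance estimator is exact on trees of initiation/reinitiation
decisions; quantifying readthrough/frameshift commitment from density would
require segment-wise estimators that are deliberately left out.
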