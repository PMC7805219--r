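---
title: "Curating transposable element family models with tefamkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating transposable element family models with tefamkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tefamkit)
```

## The problem

Transposable element (TE) copies decay neutrally after insertion, so a
family in a genome is a cloud of diverged, fragmented instances. A
curated family is represented by a *seed alignment* — a multiple
alignment of representative instances — from which two models are
derived: a consensus sequence (usable by string-based tools) and a
profile hidden Markov model (more sensitive to diverged copies).
`tefamkit` implements this dual-model workflow: CpG-aware consensus
calling, profile-HMM construction and alignment with a maintained
consensus-to-model position correspondence, termini-based
classification of DNA transposons, a tandem-repeat import filter, an
HDF5 family store with an embedded organismal taxonomy, and a TE
evolution simulator that provides ground truth for every component.

## The consensus model

A naive consensus takes the per-column majority base. That fails
systematically at ancestral CpG dinucleotides: methylated cytosines
deaminate at highly elevated rates, so an ancestral `CG` surfaces in
descendants mostly as `TG` (plus-strand C→T) and `CA` (minus-strand
G→A). At realistic ages a majority vote sees a `T` column followed by
an `A`-rich column and destroys the CpG.

`tefamkit` instead scores each candidate ancestral base $b$ for a
column with observed counts $c_{obs}$ by a log-odds sum

$$S(b) = \sum_{obs} c_{obs}\,\log_2 \frac{P(obs \mid b)}{0.25},$$

where $P(obs \mid b)$ comes from a Kimura-style neutral substitution
model: a per-site substitution mass equal to the `divergence`
parameter, transition:transversion weights 4:1:1 (a ts/tv ratio of 2),
and the mammalian GC→AT asymmetry applied by multiplying the C→T and
G→A transition *weight* by `gcToAtBias` (default 2) while holding the
per-site substitution mass fixed, so the bias redistributes rather
than inflates divergence. Scores are floored at −30 bits so the matrix
stays finite at vanishing divergence. Ties break in the fixed order
A < C < G < T, compared at a 10⁻⁹ tolerance so that exact rational
ties are not decided by floating-point summation order.

### Ancestral CpG inference

A second pass considers each adjacent pair of retained columns under
the joint hypothesis of an ancestral `CG`. Under that hypothesis the
C→T and G→A probabilities are multiplied by `cpgMultiplier` (default
10) and the rows renormalized, so retained ancestral bases are
penalized exactly as much as the decay model predicts. If the joint
`CG` score beats the sum of the two independent best calls, the pair
is emitted as `C,G` and recorded as an inferred CpG site. A largely
intact CpG cannot beat its own independent `C,G` calls (the elevated
model predicts more decay than observed), so pairs already called
`C,G` are additionally recorded as CpG sites whenever at least one
intact `CG` dimer is observed — chemically, any ancestral `CG` *is* a
CpG site. Accepted pairs are consumed left to right, so overlapping
dimers cannot both be annotated.

The decision rule is deliberately conservative for non-CpG columns: a
conserved `T`/`A` pair scores higher under its own ancestral bases
than under the elevated CpG model, because renormalization caps the
elevated C→T probability well below a conserved column's match score.

### Occupancy

Columns with fewer than `minOccupancy` (default 0.3) non-gap residues
are excluded from the consensus. The HMM uses a stricter match-column
threshold (`symfrac`, default 0.5, boundary inclusive): the consensus
should extend into low-coverage flanks that a probabilistic model
should not claim to model. When both models are built together, match
columns are forced into the consensus so every match state maps to
exactly one consensus position; the bijection is stored in the model
and used by `projectAlignment()` to compare HMM and consensus
alignments directly.

## The profile HMM

`buildHMM()` estimates a Plan7-like nucleotide profile HMM without the
multi-hit (J) state. Emissions are pseudocounted,
$(c + pc \cdot 0.25)/(n + pc)$ with `pseudocount = 1`. Transitions are
counted from each row's observed state path and smoothed toward a
sparse prior (one pseudo-observation split 0.9/0.05/0.05 across
M→M/M→I/M→D, and 0.5/0.5 for insert and delete states): a uniform
add-one scheme would cost roughly one bit per transition in models
built from one or two sequences, crippling single-consensus models,
while the sparse prior keeps match-to-match dominant yet still learns
indel propensities from deep alignments. Rows are treated as
fragments: leading and trailing gaps contribute neither delete states
nor begin/end transitions, matching the biology of truncated TE
copies. Sequence weighting is uniform in this version — a declared
limitation; entropy weighting would reduce the influence of clusters
of near-identical copies.

Decoding is *glocal* — global in the model, local in the sequence —
via Viterbi in log₂-odds space (implemented in C++). Flanking sequence
is emitted at background frequency with no transition cost, so its
log-odds contribution is exactly zero and bit scores are invariant
under appended background flanks. `N` scores zero bits in every state.
The dynamic program is validated against an exhaustive enumeration of
all legal paths on small random models (up to 4 match states, 5
residues).

The text serialization is an HMMER3-like layout (negative natural
logs, one match state per block, `%.17g` precision so round trips are
exact to ~10⁻¹⁶) with an added `CMAP` line carrying the
consensus-position map. It is an interchange format of this package,
not bit-exact HMMER.

## Termini signatures and TSDs

DNA transposons with similar transposases have similar terminal
sequences, because the transposase binds them. The signature of a
classification category is built by piling up the terminal 60 bp of
its member consensi (N-padded when shorter), ungapped, anchored at the
element boundary with an exhaustive 0–3 bp shift search that maximizes
total column information content — a deterministic stand-in for the
hand-alignment a curator would do. Each end yields a pseudocounted
position probability profile with per-column information content
$IC = 2 + \sum_b p_b \log_2 p_b$; for TIR categories a combined
profile pools the 5′ rows with reverse-complemented 3′ rows (pooling,
not concatenation, is this package's recorded choice of "combined").

Classification scores a query's termini against every signature in
both orientations over placements within ±3 bp, and reports a category
only when the 5′ and 3′ matches agree in orientation and each exceeds
`minBits` (default 8 bits ≈ one chance hit per 256 placements). The
positional and orientation filters are what make such short homologies
trustworthy.

Target site duplications are detected as the longest exact match
(k = 2…20) between the end of the left flank and the start of the
right flank, with one mismatch tolerated for k ≥ 8. A solo-LTR
heuristic flags consensi with `TG…CA` termini, an `AATAAA`
poly-adenylation signal and a 4–6 bp TSD.

## Tandem filter

The uncurated-import rule drops a family if and only if more than 80%
of its consensus is tandemly repetitive *and* less than 100 bp of
contiguous sequence is tandem-free; both inequalities are strict, so
boundary cases are kept. The detector is a bounded-period self-match
scan (period ≤ 20 bp by default; windowed match fraction ≥ 0.8
spanning ≥ 3 repeat units; runs extended left by one period to include
the seed copy). Periods above the bound are invisible by construction,
which is what preserves long and complex satellites. This detector is
a functional stand-in for an external tandem repeat finder: the
contract implemented here is the filter rule, not parity with any
specific tool, and interval boundaries can differ from a
character-exact annotation by a few bases at repeat edges.

## The family store

`famdbCreate()` builds an HDF5-backed store holding families
(consensus, optional HMM, classification path, metadata) and an
immutable embedded taxonomy, with two indexes: taxon → family
accessions and lowercase name token → taxon ids. Root paths are
precomputed at creation, so ancestor queries cost O(depth); all
lookups are hashed, which keeps query time essentially independent of
store size. Uncurated families get `DR` accessions auto-assigned in
strictly increasing order (`DRnnnnnnn.1`); curated families use `DF`,
and the accession prefix must agree with the curated flag. The on-disk
layout is versioned in a root attribute and is this package's own
design honoring the stated contracts (offline, taxonomy-aware, fast
subtree queries) — it is not byte-compatible with any external tool.
Exports: FASTA, EMBL flat entries (1-based coordinates, as that format
requires) and concatenated HMM text.

## The simulator

`simulateTE()` generates ground truth for everything above. Class II
(TIR) copies mutate independently from the ancestor — a star
phylogeny, the regime in which a consensus converges on the original
element. Class I families evolve along a master lineage: each
subfamily inherits at least three diagnostic mutations, which are
protected from further mutation in descendants so they co-segregate
perfectly with subfamily labels (a construction guarantee used by the
tests; real diagnostic sites can be overwritten by later hits).
Structural features per kind: TIRs (15 bp, 3′ = reverse complement of
5′), LINE poly-A tails with geometric 5′ truncation and variable 5–15
bp TSDs, identical 150 bp LTRs with `TG…CA` ends, and solo LTRs with
`TG…CA`, `AATAAA` and 4–6 bp TSDs.

Substitutions follow the same parameterization as the consensus
matrix. CpG decay is modeled on both strands explicitly: each strand
of an ancestral CpG deaminates independently with probability
$q = 1 - e^{-m \cdot r_{ts}}$, where $r_{ts}$ is the baseline
(unbiased) transition hazard and $m$ the CpG multiplier — the
multiplier is defined against baseline transitions rather than on top
of the GC→AT bias, since that bias already reflects aggregate
deamination and stacking the two would double-count. The hazard form
saturates below 1; at the default 15% divergence and m = 10 roughly
two thirds of CpG strands have decayed, producing the TG/CA/TA dimer
mixture the CpG-aware caller is designed to invert. Indels are
Poisson-placed at 0.1 events per substitution with geometric lengths
(mean 1.7 bp), enough to exercise the HMM's insert and delete states.
Insertions are placed without nesting; each gets a target site
duplication copied from the insertion point. A single seed fixes all
randomness; identical seeds give byte-identical output.

What the simulator does *not* emulate: GC isochores or genic
background, nested insertions, horizontal transfer, segmental
duplication, and sequencing artifacts. Passing tests therefore show
that the algorithms invert the stated generative model, not that they
are robust to every feature of real genomes.

## Study conditions and problem sizes

The validation suite runs at the scale the methods are designed for,
chosen once as realistic for a young TE family: consensus recovery
uses a 1000 bp class II ancestor, 50 copies, 15% mean divergence,
CpG ×10, GC→AT bias 2, over 20 replicates; copy-number sweeps use
n ∈ {5, 10, 20, 50}; termini experiments use 5 categories × 20
families at 10% terminus divergence with an 80/20 split; the store
experiments use a 1000-node taxonomy with 10,000 families; the
end-to-end import uses the default five-family configuration (two
TIRs, a two-subfamily LINE, an LTR element, a solo LTR; 50 copies
each) in a 300 kb genome. Under these conditions the CpG-aware caller
reaches ≥99% ancestor identity and recovers the large majority of
true CpG dinucleotides, while a majority vote recovers essentially
none — the qualitative gap the log-odds caller exists to close.

## Numerical choices and degenerate inputs

* Log-odds scores are floored at −30 bits (probabilities below
  ~10⁻⁹ against a 0.25 background); `-Inf` never enters arithmetic.
* Column-call ties are resolved at a 10⁻⁹ tolerance in fixed base
  order; the Viterbi traceback prefers match over insert over delete
  on exact ties.
* A single-row alignment is a legal seed: it yields a model with
  pseudocounted emissions and prior-dominated transitions (this is how
  library consensi are turned into search models in the import
  pipeline).
* Empty columns (all gaps or all N) are dropped from the consensus;
  an alignment whose every column fails occupancy raises an error
  rather than returning an empty string.
* The GC→AT bias saturates at the stay probability at extreme
  divergence so the score matrix remains diagonally dominant.

## Known limitations

Uniform sequence weights; no E-value calibration or genome-scale
search thresholds (the import pipeline's instance gathering is
fixture-scale, windowed Viterbi — not a replacement for a production
annotator); the shipped classification tree is a curated ~60-node
skeleton of the major class I/II divisions, not a complete taxonomy
of TE diversity; the termini signature library must be built from the
user's own classified consensi rather than shipped curated data; and
the tandem detector is a bounded-period self-match scan, not a full
tandem-repeat aligner.
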