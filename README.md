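# tefamkit

Tools for building and curating transposable element (TE) family
models from seed alignments, for people who assemble and maintain
repeat libraries: from a multiple alignment of family instances (the
*seed alignment*) it derives both a CpG-aware consensus sequence and a
profile hidden Markov model with a maintained positional
correspondence between the two, classifies families by an unranked
path-string taxonomy and by the terminal-sequence signatures of DNA
transposons, applies the tandem-repeat import filter used for
uncurated libraries, and persists families together with an embedded
organismal taxonomy in an indexed HDF5 store with FASTA/EMBL/HMM
export. A TE evolution simulator with full ground truth makes every
component testable without downloading any external data.

## The models

**Consensus.** For a column with base counts `c(obs)` each candidate
ancestral base `b` is scored by the log-odds sum

    S(b) = sum_obs c(obs) * log2( P(obs | b) / 0.25 )

with `P(obs | b)` from a Kimura-style neutral model (per-site
substitution mass = `divergence`, ts/tv = 2, C→T / G→A transition
weight multiplied by `gcToAtBias`). A second pass infers ancestral CpG
dinucleotides: each adjacent column pair is rescored under the joint
hypothesis of an ancestral `CG` with the C→T and G→A rates multiplied
by `cpgMultiplier` (rows renormalized); where decayed `TG`/`CA`/`TA`
dimers dominate, the joint hypothesis beats the independent calls and
the pair is restored to `C,G`. A plain majority vote destroys these
sites; the log-odds caller recovers them.

**Profile HMM.** Plan7-like match/insert/delete architecture without
the multi-hit state, built with pseudocounted emissions
`(counts + 0.25) / (n + 1)` and sparse-prior transition smoothing,
decoded *glocally* (model-global, sequence-local) by a C++ Viterbi in
log2-odds space. Every match state maps to exactly one consensus
position, so alignments against either model can be compared directly
via `projectAlignment()`.

**Termini signatures.** Position probability profiles of the terminal
60 bp of a classification category's consensi (5′, 3′, and pooled
5′ + revcomp(3′) for TIR categories), with per-column information
content `2 + sum_b p_b log2 p_b`; classification requires 5′ and 3′
matches consistent in orientation and position, plus target-site
duplication detection (longest k = 2–20 flank match, one mismatch
allowed for k ≥ 8).

## Worked example

Simulate a young class II (TIR) family — 500 bp ancestor, 30 copies at
15% divergence with 10× CpG decay — then rebuild its models from the
seed alignment:

```r
library(tefamkit)

sim <- simulateTE(simConfig(seed = 7, genomeLength = 60000L,
  families = list(familySpec("demo", "class2_tir",
                             ancestralLength = 500L, copyNumber = 30L,
                             meanDivergence = 0.15, tsdLength = 8L))))
aln <- sim$truth$seedAlignments$demo
aln
#> SeedAlignment 'demo': 30 instances x 666 columns

mat <- neutralSubstitutionMatrix(divergence = 0.15, gcToAtBias = 2,
                                 cpgMultiplier = 10)
cc <- callConsensus(aln, mat)
cc
#> ConsensusCall: 500 bp, 29 inferred ancestral CpG site(s)
```

The called consensus is 99.6% identical to the true ancestor,
including the CpG dinucleotides that a majority vote would report as
`TG`/`CA`. The paired profile HMM finds and maps an instance back to
consensus coordinates:

```r
hmm <- buildHMM(aln, name = "demo")
hmm
#> ProfileHMM 'demo': 500 match states

ins <- sim$truth$insertions
k <- which(ins$strand == "+")[1]
ma <- viterbiAlign(hmm, substr(sim$genome, ins$start[k] - 50,
                               ins$end[k] + 50))
ma
#> ModelAlignment: score 542.52 bits, sequence 51-544
head(projectAlignment(hmm, ma), 3)
#>   consensusPos seqPos
#> 1            1     51
#> 2            2     52
#> 3            3     53
```

542 bits over a 500-state model is an unambiguous full-length hit (a
shuffled sequence scores far below zero under the glocal model); the
projection pairs each consensus position with its genomic position.
The 8 bp target site duplication flanking the insertion is recovered
exactly:

```r
detectTSD(substr(sim$genome, ins$start[k] - 20, ins$start[k] - 1),
          substr(sim$genome, ins$end[k] + 1, ins$end[k] + 20))
#> $length
#> [1] 8
#> $motif
#> [1] "AGAAGTTA"
```

The end-to-end intake for uncurated libraries —
`pipelineUncuratedImport()` — chains the tandem filter, windowed
glocal search of a genome with single assignment of each interval to
its best family, seed-alignment construction, consensus + HMM
building, optional termini classification, and storage as `DR`
families in a FamDB-style HDF5 store. A thin command-line wrapper
lives in `inst/scripts/tefamkit.R`
(`Rscript tefamkit.R import lib.fa --genome genome.fa --store out.h5`).

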