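---
title: "Screening plant and algal sequence libraries for vitamin B12-associated metabolism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening plant and algal sequence libraries for vitamin B12-associated metabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Vitamin B12 (cobalamin) is synthesised only by some prokaryotes, yet many
eukaryotic algae depend on it: the B12-dependent methionine synthase METH
requires the cofactor, while the B12-independent isoform METE does not.
Which of the two a species encodes — together with the METH reactivator
MTRR, the adenosylcobalamin-dependent enzymes MCM and RNR-II, the Cbl
uptake/trafficking proteins and the acquisition protein CBA1 — determines
whether its methionine metabolism is B12-dependent, facultative, or fully
B12-independent, and whether it has dispensed with known B12-associated
metabolism altogether.

Scoring these families across hundreds of mixed genome and transcriptome
libraries is error-prone in exactly four ways, and the pipeline in this
package is organised around those four failure modes:

1. **Spurious similarity.** A permissive forward search (local alignment at
   an E-value threshold of 1e-5) is followed by reciprocal best-hit
   validation against a decoy proteome supplemented with the query set: a
   candidate is kept only when its best match is a query of the same
   family.  For METE, best hits to any of the three characterised
   Arabidopsis methionine synthases also validate, because plants uniquely
   retain METE.
2. **Misassembled or wildly divergent sequences.** Candidates are screened
   on neighbour-joining trees; tips whose terminal branch exceeds 1.0
   expected substitutions per site are removed one per iteration with full
   realignment, and alignments are trimmed to columns with at least half
   the rows ungapped.
3. **Bacterial contamination versus genuine horizontal transfer.**
   Candidate trees include a prokaryotic reference panel and distant
   eukaryotic outgroup references.  A eukaryotic tip is a contaminant when
   it is near-identical (>= 99%) to a prokaryotic sequence, or when its
   smallest local clade is otherwise entirely prokaryotic and it is the
   only strain of its lineage group there; when two or more distinct
   strains of one lineage group share that position the acquisition is
   treated as a transfer and retained.  Single-strain transfers are
   therefore *deliberately* discarded as contamination — the conservative
   choice for presence calling.
4. **Incomplete transcripts and split gene models.** Every surviving
   candidate must carry its family's required domain models (position
   specific scoring models scanned at E ≤ 1e-5).  In genome libraries,
   records that are individually incomplete but jointly complete *on the
   same scaffold* are rescued as a split gene model; unions across
   scaffolds are reported but not rescued.

Presence calls are aggregated per strain (libraries of one strain are
merged; a genome anywhere marks the strain genome-backed) and classified:
METH and METE together mean facultative B12 use, METH alone B12
dependence, METE alone B12 independence.  Because transcriptomes
under-report METE (it is repressed under B12-replete growth), loss calls —
METE retained with METH, MTRR, MCM and RNR-II all absent — are made only
for genome-backed strains; METH-only calls without a genome carry a
low-confidence flag.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `forward_evalue_threshold` | 1e-5 | E-value | permissive retrieval; later filters do the real work |
| `domain_evalue_threshold` | 1e-5 | E-value | domain hit acceptance |
| `branch_length_threshold` | 1.0 | substitutions/site | strictly-greater rule; terminal branches only |
| `gap_threshold` | 0.5 | fraction | columns at exactly 0.5 ungapped are kept |
| `contaminant_identity_threshold` | 0.99 | fraction | near-identity to a prokaryotic tip |
| `nj_replicates` | 100 | count | column-bootstrap support on the screening trees |

Distances are Poisson-corrected mismatch fractions, `d = -ln(1 - p)`,
computed over mutually ungapped columns so truncated transcripts do not
inflate divergence; `p` is capped at 0.95 (`d` ≈ 3.0) to keep saturated
pairs finite.  The units make the 1.0 substitutions-per-site pruning rule
meaningful.

## Numerical and design choices

* The pairwise aligner is an exact affine-gap dynamic programme
  (BLOSUM62, gap open 11, extend 1; a gap of length L costs
  `11 + L`).  Tie-breaks prefer the diagonal, then the vertical, then the
  horizontal move, so tracebacks are deterministic.  `X` scores zero
  against everything: transcriptome data is noisy and unknown residues
  should neither reward nor punish.
* E-values use the Karlin-Altschul form `K·m·n·exp(-λS)` with fixed
  λ = 0.267, K = 0.041 — no per-query recalibration, since only a coarse
  1e-5 cutoff is consumed.
* Neighbour joining follows the Saitou-Nei Q-criterion with two
  determinism rules: Q-ties resolve to the lexicographically smallest
  label pair, and negative branch estimates are clamped to zero with the
  deficit moved to the sibling so the pair's path length is preserved.  On
  additive matrices the algorithm is exact, which is what the test suite
  asserts against path-length recomputation.
* The default multiple aligner is centre-star progressive alignment
  (centre = maximal summed global score; sequences merged against the
  growing profile, new gap columns propagated).  It is deliberately
  simple: the simulated data contain no indels other than transcript
  truncation, so gaps arise only at truncated ends.  An external aligner
  can be substituted upstream of the same `b12_msa` contract.
* Domain models are additive-pseudocount position-specific scoring models
  in natural-log units, scanned with the same affine dynamic programme
  (gap open 4 nats, extend 0.5 nats) and scored with λ = 1.  CBA1, which
  has no shared domain model, is validated by a two-sequence consensus
  profile built from its two characterised seed proteins after
  end-extension of their local alignment.
* Long *internal* branches are logged but never trigger removal — only
  terminal branches are acted on.  Iterative pruning removes a single
  worst offender per cycle with full realignment, because one rogue
  sequence inflates its neighbours' branch estimates.

## The synthetic cohort

The generator produces desk-scale cohorts with complete evolutionary
ground truth.  Its defaults define the package's reference benchmark: 30
species on a Yule tree (birth rate 1, so the expected root-to-tip depth is
`sum(1/k, k=2..30)` ≈ 3 time units), six families (METE, METH, MTRR, MCM,
RNR-II, CblB), per-branch loss probability 0.3, per-branch transfer
probability 0.05, per-library contamination probability 0.05, transcript
truncation probability 0.2 (a uniform 20-60% prefix or suffix is lost),
transcriptome dropout 0.2, and half the species transcriptome-only.
Sequences evolve by per-site Poisson substitution with uniform replacement
(the 20-state analogue of the Jukes-Cantor model, so the observed
divergence has a checkable closed form); domain segments evolve at 0.3
times the background rate, which is what keeps domain hits detectable at
realistic divergence.  Each family carries a bacterial pool (20 lineages
on a long stem) supplying transfer donors, contaminants and the
prokaryotic reference panel, and a smaller eukaryotic outgroup panel
standing in for the distantly related eukaryote reference libraries a real
screen aligns against; without the latter, lone vertical survivors have no
eukaryotic context and drift into the bacterial radiation.

What the generator does **not** emulate: indels (alignments are gapless
except for truncation), rate heterogeneity across lineages, compositional
bias, assembly chimeras, and paralogy within a family.  Passing the
benchmark therefore shows the decision logic is correct under the stated
noise processes, not that the pipeline is robust to every artefact of real
transcriptome assemblies.

## Benchmark behaviour and known limitations

On the reference cohort the screen attains presence precision 1.0,
contaminant recall 1.0 with zero contaminant-driven false presences, and
zero false positives on vertically inherited records.  Status accuracy
against truth is 0.80 at the reference seed, and every misclassification
is attributable to a rule the pipeline applies on purpose: transfers with
a *single* recipient strain are flagged as contamination (the
conservative reading of the single-library rule — with the default
transfer rate roughly half of all transfer events have one surviving
recipient), and transcriptome dropout removes a truly present gene from
the library entirely.  Both are properties of the screening policy and the
data model, not defects of the implementation; raising the multi-strain
evidence bar is exactly what keeps contaminant false presences at zero.

Other limitations worth knowing: maximum-likelihood tree inference is out
of scope (curation operates on neighbour-joining trees; externally
computed trees can be supplied in newick through the same functions);
profile models are not hidden Markov models — presence/absence at a coarse
E-value threshold is all the downstream logic consumes; and strain-level
genome gating is a conservative interpretation of the lineage-level rule
used descriptively in the field.

## Problem sizes

The shipped tests and the acceptance script run the reference cohort (30
species, 6 families, ≈ 320 library records plus reference panels), 500
random alignment-oracle cases, 200 random additive-matrix neighbour-joining
cases, and three seeded replicates of the curation-stage discrimination
benchmark.
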