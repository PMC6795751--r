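---
title: "Detecting translated circRNAs from Ribo-seq: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting translated circRNAs from Ribo-seq: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboloop)
```

## The problem

Circular RNAs (circRNAs) are covalently closed transcripts produced by
back-splicing: the 3' end of an exon joins an upstream 5' end, so the
molecule has no free ends and its diagnostic signature is the back-splice
junction. A subset of circRNAs is translated, often without a canonical AUG
start. Ribosome profiling (Ribo-seq) sequences the ~25-35 nt fragments
protected by elongating ribosomes (RPFs), so an RPF that can only be
explained by a read spanning the back-splice junction is direct evidence
that ribosomes traverse the junction — evidence a linear transcript cannot
produce.

`riboloop` turns this idea into a five-stage pipeline:

1. **Read preparation** — adapter/quality trimming, rRNA depletion, and
   removal of every read perfectly explained by the linear genome. What
   survives are the "final unique" Ribo-seq reads: fragments the linear
   transcriptome cannot account for.
2. **Virtual genome** — each candidate circRNA sequence is written twice in
   tandem, so its junction lies at the unit midpoint; units are separated
   by 100 N bases.
3. **Junction mapping** — gap-free alignment of the retained reads to the
   virtual genome; per circRNA, the junction-spanning placements are
   counted (NMJ) and merged into a junction-covered region (RMRJ) when
   NMJ > 3.
4. **Classification** — each RMRJ sequence is mapped to a k-mer
   co-occurrence network, topological features are extracted under
   iterative edge thresholding, and a decision-tree/forest model trained on
   coding vs noncoding material labels it; a circRNA whose RMRJ is labeled
   coding is reported as translated.
5. **Peptides** — the translated product is predicted as the longest
   junction-covering stop-free codon run, with no start-codon requirement.

## The virtual genome

Writing each circRNA `c` of length `L` as `cc` makes every rotation of the
monomer — in particular every junction-spanning fragment shorter than `L` —
a contiguous substring of the unit. The junction of unit `i` sits at layout
coordinate `J_i = offset_i + L_i`, exactly mid-unit. The 100-N spacers are
longer than any RPF, and the aligner rejects placements that touch an N, so
no alignment can bridge two circRNAs. All coordinates in the package are
0-based and half-open; a junction coordinate `J` denotes the boundary
between layout positions `J-1` and `J`, and conversion to 1-based happens
only when SAM or BED is written.

## Alignment: gap-free seed-and-verify

RPFs are short and the reference is a concatenation of short units, so the
aligner is deliberately gap-free (substitutions only). For a mismatch
budget `m` the read is partitioned into `m + 1` disjoint chunks; if the
read has a placement with at most `m` substitutions, at least one chunk is
error-free (pigeonhole), so looking up each chunk's leading k-mer in an
exact index and verifying every candidate diagonal end-to-end finds *all*
valid placements whenever the read length is at least `(m + 1) * k`. The
pipeline default is `k = 8`, which preserves this guarantee for 25-nt
reads at the default budget of 2 mismatches. Reads whose placements fall in
two different units are discarded as ambiguous; the tandem-duplication
shadow inside one unit (a monomer-interior read appears at `s` and
`s + L`) is collapsed, preferring the junction-spanning placement.
The aligner is verified in the test suite against an independent
brute-force Hamming scan (both strands, every offset) on randomized
instances.

An RMRJ is emitted per circRNA when the number of junction-spanning
placements (NMJ, counted with at least `min_overhang = 1` base on each side
of the junction) strictly exceeds `nmj_min = 3`; its interval is the union
of those placements, which necessarily is one contiguous interval
containing the junction. Minus-strand placements count toward NMJ by
default (library strandedness is often unknown); a flag restricts counting
to the plus strand, and another collapses duplicate placements as a
PCR-duplicate guard (off by default, since NMJ thresholds in the
literature are defined on raw read counts).

## Classification: word networks and thresholded features

An RMRJ sequence is mapped to an undirected weighted network whose nodes
are its length-`w` words (default `w = 3`) and whose edge weights count
adjacent word pairs. Coding sequence, with its biased codon and codon-pair
usage, concentrates weight on few recurrent transitions; random or
shuffled sequence spreads it. Six measures summarise the topology: mean
degree, mean local clustering (degree < 2 maps to 0), degree assortativity
(Pearson correlation of endpoint degrees over both edge orientations, 0
when undefined), mean betweenness normalised by `(n-1)(n-2)/2`, mean
unweighted shortest path over the largest component, and edge/node ratio.
Recomputing them after retaining only edges with weight > t for
`t = 0 ... T-1` (default `T = 10`) yields a 60-dimensional feature vector
whose tail iterations see only the heavily repeated core — the part random
sequence does not have. Features are min-max scaled on the training bounds
and fed to either an information-gain decision tree or, by default, a
25-tree random forest behind the same interface.

Two design points matter here:

* **Length and geometry matching.** The thresholded features are strongly
  length-dependent (a 60-nt fragment cannot reach the edge weights of a
  600-nt transcript), and what the pipeline classifies are RMRJs — short
  junction-centered windows. The training stage therefore converts each
  training transcript into one *junction-coverage window*: the merged
  interval of eight simulated junction-spanning read placements on the
  doubled sequence, i.e. an object with exactly the RMRJ's geometry
  (`train_window = "junction"`). Uniform windows and whole-sequence
  training remain available (`train_window = c(min, max)` or `NULL`), and
  a flag classifies full circRNA sequences instead of RMRJs.
* **Determinism.** Training rows are canonically ordered (label, features,
  sequence) before the seeded fold assignment and forest fit, so permuting
  the training input cannot change the model; two runs with one seed are
  bit-identical, which the test suite asserts end to end.

Reported model quality is stratified cross-validation accuracy (default 5
folds) computed with the same window construction.

## Peptide prediction without a start codon

Because circRNA translation frequently initiates without AUG, open reading
frames are not anchored at start codons. For each frame of the RMRJ the
translation is split at stops into maximal stop-free runs; runs covering
the junction with at least one base on both sides and at least `min_aa =
10` residues qualify, and the longest wins (ties: lowest frame, then
leftmost). The emitted call records the frame, the nucleotide interval
(which re-translates exactly to the reported peptide), and its coordinates
in doubled-unit space. Codons containing N translate to `X`; trailing
partial codons are dropped. Frameshift-aware gene models are out of scope:
the caller is an exact, enumerable rule, which makes the truth-table
comparison in the tests sharp.

## The synthetic benchmark generator

Real Ribo-seq studies need genome-scale references and public read
archives; the package instead ships a fully seeded generator that emulates
every input at desk scale, with a truth table tying each claim to the
emitted records.

* **Coding model.** Coding sequence is a stylised codon grammar: each
  coding region draws six sense codons (always including the four
  junction-motif codons) and follows a random cyclic order over them with
  probability 0.9 per codon, jumping uniformly otherwise. This is codon
  and codon-pair bias pushed far enough that a ribosome-footprint-sized
  fragment is unambiguously coding-like through network topology alone —
  the signature is topological (recurrent transitions), not tied to which
  codons a region uses. Because every region has its own vocabulary and
  order, regions are globally distinct and short reads do not cross-map
  between circRNAs. Real coding sequence is far less regular; passing
  tests therefore demonstrate pipeline correctness on separable data, not
  classifier performance on real transcriptomes.
* **Planted translated circRNAs.** A translated circRNA is a random
  monomer (200-800 nt) carrying a grammar codon run of 60-300 nt centered
  on the back-splice junction, flanked by in-frame TAA stops. The fixed
  five-codon junction motif `CTA GAT | AAC CTA AAG` places a TAG stop 2 nt
  5' of the junction and a TAA stop 7 nt 3' of it in the +1 frame and a
  TAA stop directly across the junction in the +2 frame, so the planted
  frame is provably the unique junction-covering stop-free run of 10+
  amino acids — the truth table's frame claim is exact, not probabilistic.
  Centering the run keeps junction-local read windows inside coding
  sequence.
* **Reads.** Translated circRNAs receive a configured number of
  junction-spanning reads (default 8) with at least 1 nt overhang,
  sampled across the doubled junction; untranslated circRNAs receive only
  monomer-interior reads. Contaminants are substrings of a synthetic rRNA
  reference (a third with one substitution — still within the 2-mismatch
  depletion budget) and of the synthetic linear genome (half reverse
  complemented), at 10% of the total each by default. 30% of reads carry
  3' adapter read-through truncated at a 50-nt cycle limit. Base
  qualities follow a linear decay model (Q36, 0.15/cycle) — high enough
  that quality truncation is exercised by dedicated unit tests rather
  than by the bundle. Per-base sequencing errors beyond the rRNA
  substitutions and realistic P-site periodicity are deliberately not
  modelled.
* **Null model.** The GenRGenS-style null is a visible order-k Markov
  chain (default order 1, pseudo-count smoothing only for unseen
  contexts, lengths resampled from the training set). Fitted to coding
  sequences it preserves their nucleotide and neighbour frequencies while
  destroying the in-frame structure — the correct null for asking whether
  the classifier reacts to coding structure rather than composition.

## The false-discovery experiment

The package's headline check (recomputed by `scripts/acceptance.R`) trains
the classifier on 500 synthetic coding circRNA sequences against 500
order-1 Markov negatives fitted to them, emits 10,000 fresh null sequences
from the same chain, hands every null *passing* junction coverage (8
spanning reads, NMJ above threshold), classifies the resulting
junction-covered regions, and reports the fraction labeled translated.
Supplying coverage directly isolates the classifier as the only
discriminator — the mapping stage is verified separately against its
brute-force oracle. Typical runs give a false-positive fraction well
below the 0.05 credibility line.

## Parameters at a glance

| parameter | default | meaning |
|---|---|---|
| `spacer` | 100 nt | N run between virtual-genome units; exceeds any RPF |
| `k` | 8 | seed length; keeps full sensitivity for 25-nt reads at 2 mismatches |
| `max_mismatch` | 2 | substitution budget on the virtual genome |
| `rrna_max_mismatch` | 2 | depletion budget against the rRNA reference |
| `nmj_min` | 3 | RMRJ requires NMJ > 3, i.e. at least 4 junction reads |
| `min_overhang` | 1 nt | bases required on each side of the junction |
| `w`, `T` | 3, 10 | word size and threshold iterations (60 features) |
| `trees` | 25 | forest size; `classifier = "tree"` for a single tree |
| `train_window` | "junction" | training instances use RMRJ geometry |
| `min_aa` | 10 | minimum peptide length |

## Problem sizes and numerical conventions

The shipped tests run the generator at its default study conditions: the
end-to-end bundle uses 5 translated and 5 untranslated circRNAs at 8
junction reads each with contaminants on; the depth titration uses 20
translated and 10 untranslated circRNAs at depths 2, 4, 8 and 16; the
false-discovery experiment uses 500 + 500 training sequences and 10,000
nulls. Degenerate network cases (empty graphs, isolated nodes, undefined
assortativity) map to 0 by convention so feature vectors are always
finite. Trimming iterates its four-step pass to a fixpoint, which makes it
idempotent even in corner cases where one pass exposes new low-quality
tail bases. The pigeonhole sensitivity guarantee is conditional on
`read length >= (max_mismatch + 1) * k`; the reference filters choose `k`
automatically from the shortest read so the guarantee holds during rRNA
depletion and genome filtering.

## Known limitations

* The synthetic coding grammar is an idealisation; nothing here measures
  performance on real transcriptomes, where coding/noncoding separation
  is weaker and BASiNET-class tools are typically trained on curated
  mRNA/ncRNA sets.
* Alignment is strictly gap-free: indel sequencing errors cost a read.
* P-site offsets and 3-nt periodicity are not used as evidence — RPF
  periodicity over back-splice junctions is typically too noisy to
  exploit.
* Rolling-circle translation beyond the doubled unit, frameshifts and
  mass-spectrometry integration are out of scope.
* NMJ counts do not deduplicate PCR duplicates by default (flag
  available); the threshold semantics follow raw read counts.
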