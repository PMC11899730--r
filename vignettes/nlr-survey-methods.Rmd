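---
title: "Methods: surveying NBS-LRR resistance genes with nlrsurvey"
author: "nlrsurvey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surveying NBS-LRR resistance genes with nlrsurvey}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nlrsurvey)
```

# Scope

`nlrsurvey` implements a genome-wide survey pipeline for the NBS-LRR
(NLR) family of plant disease-resistance genes, of the kind routinely
reported for crop genomes. The pipeline takes three inputs — gene models
(GFF3), protein sequences (FASTA), and per-gene TIR/NB-ARC/LRR/RPW8
domain hits (a minimal five-column TSV emulating Pfam/InterPro output) —
and produces:

1. a **domain-architecture classification** of every NBS gene into the
   subclass grammar used by pepper-style surveys (`N`, `NL`, `NLL`,
   `NLN`, `NLNLN`, `NN`, `CN`, `CNL`, `CNN`, `CNLN`, `CNLNLN`, `TN`,
   `RN`) and the nTNL/TNL subfamily split;
2. a **genomic landscape**: physical gene clusters under a 250-kb
   chaining rule and tandem-duplication arrays under a 150-kb span rule;
3. **motif models** of the six conserved NBS motifs (P-loop, RNBS-A,
   kinase-2, RNBS-B, RNBS-C, GLPL), with log-odds scanning, canonical
   order checks and de novo ZOOPS EM discovery;
4. a **conserved-NBS phylogeny**: p-distance neighbor joining with
   column-bootstrap support over the P-loop→GLPL region.

Upstream homology searching (BLAST/HMMER against a real genome) is out
of scope: domain hits are an input contract. To make every stage
testable without downloads, the package ships a synthetic-survey
generator (`simulate_survey()`) whose defaults emulate the published
pepper (*Capsicum annuum*) survey profile and whose ground truth is
recorded exactly.

# Domain-architecture classification

Domain hits become tokens (`T`, `N`, `L`, `R`) ordered by their protein
start coordinate; a predicted coiled-coil contributes a `C` token only
when it begins before the first NB-ARC domain, matching the N-terminal
CC semantics of the CNL literature. Design choices where the convention
is genuinely open:

* **Overlapping same-type hits** (overlap > 50% of the shorter hit) are
  merged into one token. Distinct LRR hits are counted individually —
  that is what distinguishes `NL` from `NLL`.
* **TIR dominance.** If both TIR and a coiled-coil are present the
  subfamily is TNL and the `C` is dropped from the class name (the
  taxonomy has no `CT*` classes); the gene still counts as
  "CC-containing" in the summary, which is why the CC tally is exposed
  separately from the per-class table.
* **RPW8 dominance.** Any RPW8-containing gene is classed `RN`.
* Genes with no NB-ARC hit are outside the NBS-gene definition; they are
  excluded with an explicit signal (`nlr_not_nbs`), never silently.
* Token strings outside the recognized grammar map to `OTHER`; the
  classifier is total.

The kinase-2 terminal residue is a subfamily marker (W → nTNL,
D → TNL). `kinase2_marker()` applies exactly that rule and reports any
other terminal residue as `unknown` — notably the TN-class consensus in
the reference inventory ends in E and is deliberately not guessed.

# Coiled-coil prediction

Pfam does not model coiled-coils reliably, so surveys use a dedicated
scanner with a probability threshold of 0.8. `predict_coiled_coil()` is
a heptad-register scorer: a sliding window (default 21 residues, three
heptads) is scored under all seven registers with the geometric mean of
per-residue, per-heptad-position propensities from the package's own
20×7 table (`cc_heptad_propensity`); the per-residue probability is a
logistic transform (midpoint 0.48, slope 25 on the log scale — fixed
package constants) of the best covering-window score, and runs of
residues at or above the threshold become segments.

The propensity table is a documented constant built from the qualitative
structure of coiled coils — hydrophobics favored at core positions a/d,
charged and polar residues at the solvent-exposed positions, and strong
penalties for the helix breakers G and P. Its contract, which the tests
enforce, is behavioral: canonical leucine-zipper-like heptad repeats
exceed the 0.8 threshold, poly-glycine and uniform-random sequence do
not, and inserting additional ideal repeats never decreases a segment's
probability. It is a self-contained scorer with its own calibration, and
its numerical output is not comparable to any particular legacy
coiled-coil program.

# Genomic landscape

"Within a 250-kb region" is implemented as single-linkage chaining on
the start-to-start distance between coordinate-sorted genes of one
chromosome: a fixed sliding window would make cluster membership depend
on window placement, while chaining is the protocol used by the legume
surveys this rule descends from. Strand is ignored, and unassigned
scaffolds (`chr00`) are clustered like any chromosome. Chains of ≥ 2
genes are clusters; the rest are singletons.

Tandem arrays are maximal runs of ≥ 2 *consecutive* cluster members
whose span (last end − first start + 1) is strictly below 150 kb. The
"two to eight genes" phrasing of published surveys is treated as an
observation, not a ceiling: longer runs are flagged `over_limit`, not
split. No sequence-similarity condition is applied — the rule is purely
positional.

Headline percentages are rounded half-up to whole percent (54%, 31%),
per-class fractions to one decimal (69.4%, 0.8%), matching the printed
precision of the surveys this package emulates. Because published
tallies have used both the full gene count and the nTNL-only count as
denominators, `summarize_survey()` reports both
(`per_class_pct_total`, `per_class_pct_ntnl`). The CNL:TNL ratio is the
CC-containing count over the TNL count and is reported as `NA` when no
TNL exists.

# Motif kit

PWMs are built from printed consensus strings: `match_prob` (default
0.7) on the consensus letter, the remainder spread evenly; the
ambiguity codes J (I/L), Z (E/Q), B (N/D) split the match mass 50/50;
`X` takes the background row. The background is uniform 1/20 by default
and overridable. Scanning sums per-position log2 odds and returns the
best window, ties going to the smallest start; a best score below zero
means "no hit".

`discover_motif_em()` is a MEME-style ZOOPS (zero-or-one occurrence per
sequence) EM: the E-step computes each sequence's posterior over "no
site" and every offset, the M-step re-estimates the PWM (pseudocount
0.01) and the site prior λ. Convergence is a relative log-likelihood
change below 1e-6 or 500 iterations. Initialization seeds the PWM from
randomly chosen data substrings (`n_starts` restarts, deterministic
given `seed`), followed by a *phase-shift refinement*: EM restarted from
the current site alignment shifted by up to half the motif width, kept
when the likelihood improves. Without this step EM frequently converges
to a column-shifted copy of the planted motif; with it, planted-site
localization on the package's standard benchmark (20 sequences of 100
residues, 10% per-residue substitution) is essentially perfect.

Two honest limitations, verified by simulation and worth knowing:

* On signal-free data a converged ZOOPS maximizer still finds *some*
  motif — the best spurious alignment — and its site prior settles well
  above zero (≈ 0.5 in our null simulations). λ alone is therefore not a
  significance measure; significance requires comparing likelihoods
  against a null, exactly as MEME's E-values do. The tests assert the
  honest discriminator: planted signal saturates λ ≈ 1 with a far larger
  likelihood, the null does not.
* The log-likelihood trace is non-decreasing up to floating-point noise
  (~1e-8 on magnitudes of hundreds); tests allow that tolerance.

`pwm_similarity()` is the package's own defined measure — best-offset
mean per-column Pearson correlation with negatives floored at zero —
because the similarity matrix printed alongside published motif tables
has no documented method; no attempt is made to reproduce those printed
values.

# Conserved-NBS phylogeny

The region entering the phylogeny runs from the P-loop hit start to the
GLPL hit end. Genes missing either motif or with them out of order are
excluded with per-gene reason codes — this filtering is why published
surveys place only a subset of their genes in the tree, and the package
reports reasons rather than asserting any target count.

Alignment is an in-package progressive aligner: affine-gap global
(Needleman–Wunsch) pairwise alignment over BLOSUM62 (gap open 10,
extend 0.5; deterministic tie-breaks preferring substitutions over
gaps), a UPGMA guide tree from pairwise p-distances, and affine-gap
profile–profile merges up the guide tree. Its acceptance surface is
homology recovery on synthetic data with a known homology map, not
bit-compatibility with any external aligner.

p-distances use pairwise gap deletion by default (complete deletion is a
trivial pre-filter away); a pair with zero comparable sites is an error
naming the pair. Neighbor joining is the canonical Saitou–Nei
agglomeration with two determinism/safety conventions: Q-matrix ties are
broken toward the lexicographically smallest pair of subtree labels, and
negative branch lengths are clamped to zero with the deficit moved to
the sister branch (preserving the pair's path length). On additive
matrices the implementation reproduces the generating topology and
path-length matrix to 1e-9, which the test suite checks against an
exhaustive-topology oracle.

Bootstrap support resamples alignment columns with replacement, rebuilds
the NJ tree per replicate, and reports per-edge bipartition frequencies
on the full-data tree (majority-rule consensus attached as an
attribute). The survey convention is 1000 replicates (the pipeline
default); tests and the acceptance script use 50–200 so the whole suite
runs at desk scale.

# The synthetic generator and what passing means

`simulate_survey()` is first-class, tested code. Its defaults *are* the
package's study conditions, chosen once to mirror the published pepper
survey profile:

* 252 genes mixed over the 11 reference subclasses in proportion to the
  published per-class counts (`pepper_class_inventory`);
* 12 chromosomes plus an unassigned `chr00` (singletons only there);
* 47 planted clusters holding 136 genes: within-cluster start-to-start
  spacing 200 kb (inside the 250-kb rule), between-unit spacing 400 kb
  (outside it); 30 planted tandem runs totalling 77 genes at 20-kb
  spacing (spans < 150 kb) — 18 pairs, 11 triples and one eight-gene
  array, every one inside a cluster;
* proteins assembled module by module: TIR/RPW8 stubs or a 42-residue
  ideal heptad repeat at the N-terminus as the class dictates, NBS
  blocks carrying the six motif instances in canonical order separated
  by random 15–40-residue linkers, LRR stubs; matching domain hits are
  emitted for TIR/NB-ARC/LRR/RPW8 but deliberately **not** for
  coiled-coils, so `predict_coiled_coil()` is exercised end to end;
* `motif_divergence` (default 0.1) is the per-residue substitution
  probability applied to motif instances *and* to the N-terminal
  modules. Applying it to the modules is what makes the noisy-recovery
  condition meaningful: domain hits are exact inputs, so coiled-coil
  detection is the only classification step noise can break.

Sequences for phylogeny benchmarks are evolved on
coalescent-style random trees (`random_tree()`: exponential branch
lengths above a 0.03 floor — zero-length internal branches are
unrecoverable by any method, so the floor keeps simulated topologies
identifiable) under per-site substitution with uniform replacement,
indel-free so the true homology map is the identity. Benchmark problem
sizes, stated here as the package's chosen conditions: 10-leaf trees,
1000-site roots, rate 0.25 (mean p-distance ≈ 0.1), 20 trials; the
TNL-monophyly benchmark uses independent random roots for the two
subfamilies (between-family p-distance ≈ 0.95, within ≈ 0.1–0.3).

What passing does and does not show: the generator plants exactly the
structures the rules detect, with clean spacing margins and i.i.d.
linker sequence. Real genomes add pseudogenes, fragmented gene models,
nested and overlapping domain hits, compositional bias that degrades PWM
scanning, and alignment-difficult indel variation — none of which the
default generator emulates (an indel mode exists for aligner stress
tests). Recovery rates on synthetic data are a correctness check of the
implementation, not an accuracy claim about any real genome.

# Numerical and degenerate-input conventions

* Rounding of printed percentages is half-up, not banker's.
* `X` residues score neutrally (0 bits) in scanning, neutrally low in
  coiled-coil prediction, and 0 in BLOSUM62 alignment.
* Empty surveys are valid: all counts zero, no errors.
* Proteins shorter than a motif width yield "no hit" with a warning;
  shorter than the coiled-coil window, an empty segment table.
* EM requires ≥ 2 sequences at least as long as the motif width;
  shorter sequences participate as "no site" only.
* All stage randomness is seeded; the pipeline fans one global seed out
  to per-stage seeds by fixed offsets, so stages are independently
  reproducible and identical configurations give byte-identical
  `summary.json` and Newick outputs.
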