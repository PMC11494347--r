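---
title: "Alignment-free homology detection for disordered sequences with shark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free homology detection for disordered sequences with shark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shark)
```

## The problem

Intrinsically disordered regions (IDRs) evolve fast: they accumulate
substitutions and insertions/deletions at rates that defeat sequence
alignment, yet they often conserve function through short linear motifs,
repeats, and bulk amino-acid composition. Alignment-based homology tools
(Smith–Waterman, BLAST, HMMER) assume a collinear residue correspondence
and therefore miss most remote homology among such "unalignable"
sequences. This package implements an alignment-free alternative: sequences
are compared through their k-mer inventories, with non-identical k-mers
allowed to match according to amino-acid physicochemistry, and a small
ensemble classifier aggregates the evidence across k-mer lengths.

## Physicochemical residue similarity

The foundation is Grantham's amino-acid distance, which combines side-chain
chemical composition $c$, polarity $p$, and molecular volume $v$:

$$D(a,b) = \rho\left[\alpha\,(c_a-c_b)^2 + \beta\,(p_a-p_b)^2 +
  \gamma\,(v_a-v_b)^2\right]^{1/2}$$

with the published constants $\alpha = 1.833$, $\beta = 0.1018$,
$\gamma = 0.000399$ and $\rho$ fixed so the mean over the 190 residue pairs
is 100. The property triples ship with the package
(`grantham_properties()`) and match the AAindex entries
GRAR740101–GRAR740103; the classical integer table is reproduced by
rounding (maximum 215 for Cys–Trp; the 1974 print differs by at most one
unit in a few cells because of rounding of intermediates in the original).

Distances are converted to a bounded similarity linearly,

$$\mathrm{sim}(a,b) = 1 - D(a,b)/215,$$

so identical residues score 1 and the Cys–Trp extreme scores (essentially)
0. The linear map is a package choice: it is bounded, order-preserving, and
keeps "high score = high similarity". The normalization constant is an
argument of `build_similarity_matrix()`, so alternative transforms are one
constant away.

## SHARK-scores

Both scores are computed from the k-mer similarity matrix
$w_{ij} = \frac1k\sum_{p=1}^{k}\mathrm{sim}(x_{i+p}, y_{j+p})$ over all
overlapping k-mers of the two sequences. The arithmetic per-position mean
is ungapped and collinear *within* the k-mer only; there is no positional
constraint between k-mers, which is what removes the alignment assumption.

* **SHARK-score (best)** — for each k-mer of one sequence take its best
  match in the other, average these maxima, and symmetrize as the mean of
  the two directions (homology is symmetric, the directional score is not).
  Identical sequences score exactly 1.
* **SHARK-score (T)** — sum all $w_{ij} \ge T$ and divide by the number of
  k-mer pairs $n_1 n_2$, giving a length-normalized score in $[0,1]$ that
  is non-increasing in $T$.

The classical alignment-free baselines are included with their standard
definitions over k-mer count vectors / sets: Euclidean distance, the cosine
Similarity Ratio, and the Normalized Google Distance (NGD) with the corpus
size fixed at $N = 20^k$, an empty intersection defined as distance 1, and
clamping to $[0,1]$. The set-based convention (distinct k-mers, not counts)
and the $N$ convention are package choices; both are isolated in one
function.

## The SHARK-dive ensemble

A sequence pair is summarized by 10 features, one per k-mer length
$k = 1..10$ (short-linear-motif scale). The default map is:

| k | feature |
|---|---------|
| 1 | cosine Similarity Ratio over residue counts (pure composition) |
| 2–4 | $1 - \mathrm{NGD}$ (so higher = more similar) |
| 5–10 | SHARK-score (best) |

The k = 1 entry deserves a note. A thresholded SHARK-score with $T = 0$
also aggregates composition, but it equals the *mean* pairwise residue
similarity and is therefore below 1 even for a self-comparison. Several
contracts of the package (a self-comparison attains the feature-space
maximum; a database query finds itself first) require every feature to be
maximal at identity, so the cosine composition similarity is used instead.
The map is a plain data frame argument and is archived inside every trained
model.

The classifier is a 10-fold ensemble of gradient-boosted decision trees
(xgboost; 200 rounds, depth 3, learning rate 0.1 — a deliberately small
model for a 10-dimensional feature space). Folds are formed from
*families*, not pairs: families are shuffled with the seed and dealt
round-robin into 10 folds, and submodel $i$ never sees a pair touching
fold $i$. This prevents information leakage between related pairs, mirrors
the family-wise train/validation/test split, and is asserted by the tests.
The ensemble probability is the mean of the 10 submodel probabilities;
pairs at or above the default threshold 0.5 are called homologous (ties
count as positive).

All submodels are fitted with a monotonicity constraint: every feature is a
similarity, so the probability of homology is constrained to be
non-decreasing in each feature. Besides being the scientifically sensible
shape, this makes a guarantee out of an otherwise empirical property — no
pair can outscore a self-comparison, whose features all sit at the maximum
1 — at no measurable cost in held-out performance. The constraint can be
dropped via `hyperparams = list(monotone = FALSE)`.

Feature importance is the gain-based importance of each submodel,
normalized to sum 1 within a submodel, summarized as mean ± SD across the
ensemble (`feature_importance()`, `plot()` on the fitted model).

## The synthetic homolog families

No curated IDR ortholog collection is bundled, so training and evaluation
run on a generator (`generate_dataset()`) that emulates the *structure* of
such data: families of diverged segments that share motifs and composition
but are barely alignable.

Each family draws a composition profile by perturbing a disordered-like
base composition (enriched S, G, P, Q, E, K; depleted W, C, F and other
order-promoting residues) with log-normal noise (`spread`), draws a set of
motifs from that profile, implants them at random non-overlapping positions
in an ancestor sequence, and derives each member by independent mutation:
per-residue substitutions biased toward Grantham-similar residues,
geometric-length insertions and deletions that spare the motif spans (so
motifs drift in position but keep their physicochemical character). Members
are re-mutated until all pairwise identities are at or below 0.5 —
the identity cap mirrors the "maximum 50% identity" filtering used when
curating remote-homolog benchmarks, and identity is measured the
conventional way (global Needleman–Wunsch with BLOSUM62, gap open 10 /
extend 1, identities over alignment length including gaps).

Defaults: 50 families, 5–20 members, ancestor lengths 50–300, 5 motifs of
length 6–10, substitution rate 0.38, insertion/deletion rate 0.08 with
indel lengths geometric and capped at 5, `spread = 1`. The structural
defaults (family counts, sizes, lengths, identity cap, split ratios) define
the study conditions; the divergence and separation knobs were calibrated
once so that the default dataset carries a learnable but non-trivial
homology signal — the ensemble recovers held-out-family homology at
auPRC ≥ 0.9 and F1 ≥ 0.8, the recovery level the package's acceptance
properties assert — and they are not adjusted thereafter. Every generator
output is a pure function of its parameters and the seed.

What the generator does *not* emulate: real length/family-size
distributions of curated ortholog sets, repeat expansions, compositional
drift along a phylogeny (members are independent draws from one ancestor,
a star phylogeny), and true disorder (composition bias is a proxy). Passing
the recovery tests therefore shows the pipeline is correct and the signal
types (motifs + composition) are learnable — it does not certify
performance on real proteome data.

## Search and interpretation

`shark_search()` scores a query against every database entry and returns
ranked hits (probability descending, ties broken by target id — fully
deterministic). The interpretation layer answers *why* a pair scored well:

* `build_background()` samples unrelated (cross-family) pairs and stores
  their per-k feature samples; `score_context()` places a pair's features
  at their empirical percentiles among unrelated pairs.
* `extract_matches()` lists all k-mer pairs with similarity at or above a
  threshold, mapped back onto both sequences (0-based offsets internally;
  the text panel prints 1-based inclusive coordinates and says so). The
  defaults k = 8, T = 0.85 give motif-scale, high-stringency matches;
  both are exposed everywhere. One k-mer may match many, so repeated and
  swapped motifs appear as multiple spans.

## Evaluation harness

`run_benchmark()` performs the all-vs-all comparison of the test-split
families with any mix of methods (a fitted ensemble, or any
`function(s1, s2) -> score` such as the bundled Smith–Waterman). The
conventions are fixed and documented rather than configurable:

* PR curves are computed at every distinct score (ties grouped); the area
  is the step-wise average-precision sum with no interpolation. A constant
  scorer yields the positive prevalence; perfect separation yields 1.
* F1 is reported at the method's stated threshold (the ensemble's 0.5)
  or, for raw scores with no natural scale, at the best-F1 threshold
  (ties resolved toward the lower threshold) — the convention under which
  alignment baselines are usually given their best case.
* Sensitivity is binned by pairwise identity in half-open bins (last bin
  closed), by default 10-point bins over [0, 0.5] plus a ≥ 0.5 bin;
  empty bins are undefined (`NA`), never 0.
* The Smith–Waterman baseline is an affine-gap Gotoh DP (a gap of length
  $L$ costs `gap_open` $+ (L-1)\,$`gap_extend`); substitution matrices are
  pluggable by name (Biostrings data) or from NCBI/EMBOSS-layout text
  files. External search tools are never executed — only their tabular
  outputs (BLAST outfmt-6, HMMER tblout) are parsed, with malformed lines
  collected in a rejects table.

## Numerical and engineering choices

* The k-mer similarity matrix and the alignment DP are small C++ kernels;
  the matrix fill uses rolling window sums along diagonals, so a score is
  $O(L_1 L_2)$ for any k. Agreement with nested-loop brute-force
  recomputation is part of the test suite (tolerance $10^{-12}$; the
  rolling sums differ from naive summation only at floating-point
  round-off).
* Non-canonical residue codes (X, B, Z, U, O, `*`) are rejected by default;
  with `sanitize = TRUE` the k-mers containing them are dropped rather than
  silently recoded, because coercion would corrupt composition features.
* Sequences shorter than k raise an error in standalone score calls, but
  inside a feature vector the affected feature is set to 0 with a warning,
  so database-scale scoring never aborts on short entries.
* One user-facing seed is fanned out deterministically to every random
  component (`derive_seed()`); re-running any command with the same seed
  and inputs is byte-identical, and model archives restore predictions
  bit-exactly.
* Problem sizes in the bundled tests are chosen to keep a full run small:
  the recovery property trains on the default 50-family dataset (three
  seeds), everything else runs on 6–15 family fixtures generated in code.

## Known limitations

* The ensemble probability is calibrated on balanced training pairs; under
  all-vs-all prevalence the 0.5 threshold is conservative for precision.
  The percentile machinery (`score_context()`) is the recommended lens for
  individual pairs.
* SHARK-score (T) normalizes by $n_1 n_2$, which penalizes long unrelated
  stretches; alternative normalizations can be swapped in by changing one
  constant but are not exposed as options.
* The classifier detects homology *or* analogy — shared motifs and
  composition do not distinguish common ancestry from convergence, and no
  attempt is made to.
* Scores compare two sequences; there is no profile or iterative search
  mode.
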