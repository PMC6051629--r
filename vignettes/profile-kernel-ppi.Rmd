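---
title: "Profile-kernel SVMs for protein-protein interaction prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profile-kernel SVMs for PPI prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(kernppi)
```

This vignette is the package's own account of the method: the model, the
data-quality pipeline around it, the numerical choices, and what the
synthetic-data experiments do and do not demonstrate.

## The prediction problem

Given an organism's proteome and a set of experimentally supported physical
protein-protein interactions (PPIs), the task is to rank all unseen protein
pairs by their probability of physical interaction, using nothing but each
protein's sequence and its evolutionary profile. Two properties of PPI data
shape everything downstream: most database evidence is weak (methods such as
co-localization imply no direct contact), and homologous proteins inherit
interactions, so a naive train/test split leaks information through sequence
similarity.

## Evidence scoring and curation

Every detection method is assigned a reliability score from 1 (lowest) to 10
(highest); an interaction's score is the **maximum** over its evidence, and
interactions below 5 are discarded. The threshold is inclusive: a single
ELISA (score 5) keeps a pair, while blue native page (3) plus pull down
(2.5) together do not — a deliberate design in which many weak assays never
substitute for one adequate one. Methods missing from the score table
default to 1 with a warning, so unknown annotation quality can never promote
a pair past the filter. Interaction partners can be mapped onto a reference
proteome when a global alignment reaches at least 95% identity; unmappable
pairs are dropped and reported, with no fuzzy identifier resolution
attempted.

## Sequence similarity, the HSSP curve, and redundancy

All pairwise comparisons in the package use one aligner: global
Needleman-Wunsch with BLOSUM62, gap open 10, gap extension 0.5
(`Biostrings::pairwiseAlignment`). Percent identity is computed over **all**
alignment columns, gap columns included. Neither the alignment flavour nor
the gap costs are dictated by the method itself; they are package defaults,
chosen because the HSSP convention is whole-chain, and they are exposed
nowhere else so the mapping step and the redundancy step can never disagree.

The HSSP-curve threshold

$$ t(L) = \begin{cases} 100 & L \le 11 \\
480\,L^{-0.32\,(1+e^{-L/1000})} & 11 < L \le 450 \\
19.5 & L > 450 \end{cases} $$

separates reliably homologous alignments from the twilight zone as a
function of alignment length $L$; `hval(a, b)` is the identity of the
alignment minus $t(L)$. The curve is continuous to within 0.1 percentage
points at the 450-column breakpoint and evaluates to 20.7 at $L = 250$, so
HVAL = 20 corresponds to roughly 40.7% identity for 250-column alignments.

Redundancy reduction is a greedy single pass that retains an interaction
only if both of its proteins have HVAL ≤ 20 to every protein of every
previously retained interaction. The visit order — descending evidence
score, then lexicographic pair id — is a package decision: it keeps the
best-evidenced representative of each homology cluster and makes the result
independent of input file order. Two boundary conventions are implemented
exactly as specified per operation even though they are mutually
inconsistent at the knife's edge: reduction removes pairs *above* 20
(HVAL exactly 20 is retained), while negative sampling requires *strictly
below* 20 (HVAL exactly 20 is excluded from the pool).

## Negative sampling

True non-interactions are essentially never annotated, so negatives are
sampled: 10 per positive, uniformly over all unordered pairs of proteins
whose HVAL stays below 20 against **every** protein of the positive set,
excluding the positive pairs themselves. The sampler draws pair *ranks*
without replacement and unranks them, so uniformity is exact and the draw is
reproducible from a recorded seed. If the eligible pool cannot supply the
request, the sampler fails loudly with the shortfall rather than silently
relaxing the constraint. The 10:1 ratio is the only treatment of class
imbalance anywhere in the pipeline — the SVM itself uses no class weights.

## The profile kernel

A profile assigns position $i$ a distribution $p_i(\cdot)$ over the 20
residues. For k-mer length $k$ and conservation threshold $\sigma$, window
$i$'s **mutation neighborhood** is

$$ N_i = \{\beta \in \Sigma^k : \textstyle\sum_{j=0}^{k-1}
   -\ln p_{i+j}(\beta_j) < \sigma \}. $$

Each k-mer in each window's neighborhood contributes count 1 to the
protein's sparse feature vector. Numerical conventions the method statement
leaves open, fixed here:

* **Log base.** Natural log. The searched range σ = 4…11 brackets the cost
  of an uninformative position, $-\ln(1/20) \approx 3.0$ nats, which is the
  behaviour the grid implies.
* **Probability floor.** Every profile row is clamped at ε = 1e−4 and
  renormalized, so $-\ln p$ is always finite. A delta profile therefore
  gives its query residue probability $1/(1+19\varepsilon) \approx 0.998$.
* **Boundary.** Strict inequality (score < σ). A "conservation exceeding σ"
  phrasing maps to a *score below* σ under −log scoring.
* **Nonstandard residues.** `X` positions get uniform rows: an unknown
  residue should not manufacture conserved k-mers.
* **All-zero PSSM rows** (positions with no aligned homologs) fall back to a
  delta on the query residue, with a message, rather than failing.

The traversal expands prefixes breadth-first and prunes on the running
score, so only viable prefixes are visited; a brute-force enumerator
(`kmer_features_oracle`, guarded at k ≤ 4) exists solely to verify it, and
the equivalence is asserted exactly, not approximately, on randomized
instances. With delta profiles the features reduce to classic spectrum
counts, which gives a second, independent reference implementation in the
tests.

**Pair construction.** A pair's vector is the element-wise sum of the two
individually L2-normalized protein vectors. This choice is symmetric in the
partners and keeps the pair kernel positive semidefinite; the pair Gram
matrix is then cosine-normalized, giving $\|x\|^2_{pair} = 2 + 2\cos(a,b)$
on the diagonal before normalization. Tensor-product pair kernels were
considered out of scope.

**Profiles without PSSMs.** When no PSI-BLAST profile exists, a
pseudo-profile mixes a point mass on the query residue with the BLOSUM62
conditional substitution distribution, $p_i = (1-\alpha)\delta(q_i) +
\alpha\, q(\cdot\mid q_i)$, where $q(b \mid a) \propto f(b)\,2^{s(a,b)/2}$
from the half-bit BLOSUM62 scores and Robinson-Robinson background
frequencies. α = 0 yields delta profiles (exact spectrum limit); the
default α = 0.1 keeps the query residue dominant while admitting
conservative substitutions. This fallback is a testability device and a
profile-free operating mode, not an approximation of PSI-BLAST output.

## SVM training and calibration

The classifier is a soft-margin C-SVM on the precomputed normalized pair
kernel, optimized by libsvm in both of the package's two training routes,
which are kept provably interchangeable:

* `train_svm(K, labels)` takes the kernel matrix, factorizes it by symmetric
  eigendecomposition ($K = FF^\top$, negative eigenvalues clipped at zero)
  and fits a linear SVM on the rows of $F$ — an exact reformulation of the
  precomputed-kernel problem.
* The pipeline internally trains the same linear SVM on the explicit
  L2-normalized sparse pair vectors directly, skipping the dense kernel
  factorization. Because the normalized pair kernel *is* the linear kernel
  on those vectors, both routes solve the same dual problem; a test asserts
  their decision functions agree to 1e−6 at tight optimizer tolerance. The
  sparse route is used in cross-validation because it is several-fold faster
  on the near-diagonal kernels this problem produces (most random protein
  pairs share almost no k-mers).

The cost parameter is not part of the method statement; the default is
C = 1 on the unit-diagonal kernel, exposed in every training function.
Decision values are oriented so that positives score high (the underlying
solvers' sign conventions depend on label order), and probabilities come
from a Platt-style sigmoid $P(y=1\mid f) = 1/(1+e^{Af+B})$ fitted on the
training decision values with the usual smoothed targets
$t_+ = (N_+ + 1)/(N_+ + 2)$, $t_- = 1/(N_- + 2)$, minimized by BFGS. The
smoothing keeps the fit finite even when training is perfectly separable.
Reported probabilities are clamped to (1e−12, 1 − 1e−12), so they are
strictly inside (0, 1).

## Precision-recall evaluation and model selection

Scores are swept from high to low; at each recall on a fixed grid (100
evenly spaced points, 0.01…1.00 — the grid density is a package choice) the
precision of the **smallest** prediction set achieving at least that recall
is reported. At full recall the precision equals the positive prevalence by
construction, which the tests assert. Error bars:

* **Cross-validation:** the standard deviation of precision across all fold
  curves at each grid recall.
* **Single hold-out curves:** a binomial error. Two modes are implemented
  because the method statement's printed formula, $e = n\,p(1-p)$, is
  dimensionally a variance-scaled count rather than an error on a
  proportion — a square root and a division appear to have been dropped.
  `binomial_error(p, n, "as_printed")` evaluates the formula literally;
  `"standard_error"` gives $\sqrt{p(1-p)/n}$ and is the default for plots.
  No attempt is made to guess the intended form beyond offering both.

A parameter combination is condensed to one number: the mean of the mean
precisions over grid recalls ≤ 20%. The cross-validation protocol is 5-fold,
repeated 5 times **from the start** — each repetition re-splits the
positives and resamples the negatives — giving 25 fits per combination.
Negatives are resampled per repetition (not per fold); the repetition is the
unit at which sampling noise is averaged. Fold splitting is on positive
interactions, not proteins: redundancy reduction has already guaranteed that
no two interactions share or resemble proteins, which is what makes
interaction-level splitting leak-free, and the code asserts the protein
disjointness at run time rather than trusting it.

Organism gating follows the printed boundaries exactly: fewer than 200
non-redundant PPIs — no model; 200 to 500 inclusive — fixed hyperparameters
(k = 5, σ = 11), evaluated by repeated cross-validation only; strictly more
than 500 — full grid search (k ∈ {3,4,5,6} × σ ∈ {4,…,11}) on a seeded
two-thirds training split, scored by the early-recall statistic with ties
broken toward smaller k then smaller σ, and a final model confirmed once on
the held-out third.

## Interactome prediction

The final model scores all pairs of proteins dissimilar (HVAL < 20) to every
positive-set protein — the same constraint as negative sampling, applied
consistently even though the method statement's wording varies between
sections. Per-protein feature vectors are computed once; pairs are
enumerated in index batches and never materialized wholesale; output is
sorted by descending calibrated probability with lexicographic tie-breaks,
and batch size provably does not affect the result. The published set keeps
the global top `10 × n_proteins` records; an optional rounding granularity
mimics round published sizes, treated as presentation rather than method.
When predictions are compared against an external reference, a prediction
counts as positive at probability ≥ 0.5 and accuracy is
`100 × correct / evidenced` — the ratio orientation that reproduces every
published percentage.

## The synthetic generator: what it does and does not show

`simulate_organism()` draws founder sequences i.i.d. uniform over the 20
residues (default lengths 150-250), derives family members by per-residue
substitution at rate 0.15 — which keeps within-family HVAL comfortably above
20 at those lengths while unrelated sequences sit far below 0 — and plants
each interaction as a pair of k-mer motifs written into the two partners at
random positions. Evidence is drawn from a bundled miniature score table
(blue native page 3, pull down 2.5, ELISA 5, X-ray crystallography 10), with
a configurable fraction of positives receiving only sub-threshold evidence
so the curation filter has something to do. One master seed drives every
sub-stream.

This emulates exactly the statistical structure the pipeline assumes —
homology clusters, planted learnable signal, mixed evidence quality — and
nothing else. Real interactomes have hub degree distributions, domain-level
interaction grammars, compositional bias and study bias, none of which are
modelled (the method itself ignores network structure, so their absence does
not favour the package). Passing the planted-signal tests demonstrates that
the machinery recovers a shared-k-mer signal at the designed 10:1 imbalance;
it says nothing about precision attainable on real organisms, which depends
on database snapshots and PSI-BLAST profiles outside this package's scope.

Problem sizes used in the shipped experiments: the end-to-end planted-signal
run uses 600 proteins and 200 positives with motif length 4 and one 5-fold
cross-validation at (k = 4, σ = 4); the negative-sampling contract run uses
500 proteins and 50 positives. Unit tests run the same operations at smaller
sizes with the brute-force oracles.

## Known limitations

* The aligner and gap parameters behind HVAL are package defaults, not part
  of the method statement; absolute HVAL values near the cut can shift
  slightly under other conventions.
* Platt calibration is fitted on training-fold decision values, not a held
  aside calibration split; with small positive sets a dedicated split would
  cost more than it buys, but probabilities near 0.5 should be read loosely.
* `kmer_features` enumerates neighborhoods exactly; for flat profiles with
  large σ and k the neighborhoods grow combinatorially. The traversal prunes
  well in realistic regimes (profiles with informative positions) but offers
  no approximate mode.
* MITAB support is the minimal column subset (ids and detection method);
  full PSI-MI controlled-vocabulary resolution is out of scope, as is any
  database access.
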