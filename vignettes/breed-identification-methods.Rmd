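---
title: "Methods and design of the breedkit pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the breedkit pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical models behind each breedkit stage,
the tunable parameters and their defaults, the numerical choices, and what
the simulation-based tests do and do not demonstrate about real data.

## Genotype encoding

Genotypes enter as HapMap text in either the two-letter (`AG`) or IUPAC
single-character (`R`) dialect; `auto` sniffs the dialect from call width.
Each call becomes the dosage of the alternate allele — the second allele of
the `alleles` column. When that column is malformed, the minor allele
observed in the data is taken as alternate, with a count tie broken toward
the ASCII-greater character so dosages are deterministic. `NN`, `N`, `--`
and `-` are missing. The strand column is ignored and alleles are used as
written; positions stay 1-based and unsorted. Monomorphic SNPs are kept at
read time — they carry no association information and are excluded (with a
warning) by the per-SNP statistics instead, so the container remains a
faithful image of the file.

## Sample-size guidance

The power model is a per-SNP two-proportion z-test on allele frequencies:
n individuals per breed contribute 2n alleles per group. For a detectable
frequency difference δ between p and p − δ at two-sided size α and target
power 1 − β, the normal approximation gives

n_alleles = (z~1−α/2~ + z~1−β~)² (p₁q₁ + p₂q₂) / δ²,

rounded up and halved into individuals. By default the recommendation is
then *verified by exact power evaluation* — the rejection probability is
summed over both binomial allele-count distributions — and raised until the
exact power reaches the target. The approximation and the exact rule can
disagree by an individual or two near the boundary (at δ = 0.25, p = 0.5,
α = 0.05, power = 0.8 the approximation gives 28 individuals, the exact
rule 30); `exact = FALSE` exposes the pure formula. Defaults δ = 0.2,
α = 0.05, power = 0.8 are a conventional effect size for breed-informative
SNPs; the power model itself is this package's choice, as tools in this
space typically do not publish theirs.

Class balancing resamples with replacement up to the largest class
(duplicate IDs suffixed `__dupK`) or subsamples without replacement down to
the smallest, always seeded.

## Embeddings

PCA operates on column-centered (optionally unit-variance standardized)
dosages; missing dosages are imputed by the per-SNP mean by default, or the
SNP is dropped. Centering-only is the default because dosage variance is
itself informative about allele frequency; standardization is a flag.
Explained variance is the usual eigenvalue share. Classical MDS is
Torgerson double-centering with negative eigenvalues truncated to zero;
UMAP is delegated to `uwot` (a published algorithm this package merely
invokes), single-threaded and seeded so coordinates are reproducible.
Every component's sign is fixed by making the largest-magnitude loading
(or coordinate) positive, which makes embeddings invariant to individual
ordering. Outlier curation is a pure operation: dropping individuals
returns a new dataset and analyses are simply re-run.

## Distances and trees

The individual-by-individual distance is allele sharing, d(i,j) = mean over
shared non-missing SNPs of |gᵢ − gⱼ|/2 — i.e. 1 − IBS similarity. It is the
simplest distance consistent with dosage data; the tree builders accept any
user-supplied matrix. Neighbor-joining and BioNJ come from `ape`, UPGMA
from average-linkage `hclust` (node height = half the merge distance).
Negative NJ branch lengths are clamped to zero with the deficit moved to
the sibling edge, the common convention; raw lengths are preserved as an
attribute. Agglomeration ties are resolved by the deterministic behaviour
of the underlying implementations, so repeated runs are identical, though
the tie order is theirs rather than a lowest-index rule. Two numerical
notes: `ape`'s NJ is exact to machine precision on additive matrices, while
its BioNJ runs in single precision internally (path-length errors around
10⁻⁶, and near-tied merge choices that can depend on taxon order on
non-additive input). Bootstrap support resamples SNP columns with
replacement B times and labels each internal edge with the percentage of
replicate trees containing the same bipartition; SNP bootstrap is the
natural resampling unit for unlinked markers. FastME-style minimum
evolution is not provided.

## Admixture model

Ancestry inference maximizes the classic binomial admixture likelihood

ℓ = Σᵢⱼ [ gᵢⱼ log Σₖ qᵢₖ fₖⱼ + (2 − gᵢⱼ) log Σₖ qᵢₖ (1 − fₖⱼ) ]

by EM on both the ancestry proportions Q (rows on the simplex) and cluster
allele frequencies F, skipping missing entries. K = 1 is closed form.
Frequencies are clamped to [10⁻⁶, 1 − 10⁻⁶] each iteration to keep the
log-likelihood finite; convergence is |Δℓ| < 10⁻⁶ or 500 iterations, and
the best of 5 seeded random restarts is returned. The per-iteration
log-likelihood trace is stored, and EM's monotonicity is asserted in the
tests (to a 10⁻⁶ relative tolerance, allowing for the clamp).

K is chosen by masked-entry cross-validation: a random 10% of non-missing
entries is masked, the model refitted, and masked dosages predicted as
2 Σₖ q̂ᵢₖ f̂ₖⱼ; the error is the mean squared deviation averaged over 3
replicates and the chosen K is the argmin (lowest K on ties). Inside CV
the EM runs lighter (2 restarts, tolerance 10⁻⁵, 200 iterations) — the CV
surface needs relative, not absolute, precision. Label switching is
resolved by Hungarian assignment on column correlations against a
reference fit or a label vector.

## Panel selection

Association statistics use the 2 × C allele-count-by-breed table for the
chi-square (Pearson, no continuity correction, C − 1 df) and Fisher's
exact test (exact for C ≤ 3 and ≤ 60 alleles, else seeded Monte-Carlo with
10⁵ tables); allele-level tables keep exact enumeration tractable and match
standard population-genetics practice. Mutual information and information
gain use the 3-genotype-class × breed table in bits, retaining
non-additive genotype signal; the two are the same quantity computed two
ways (I(X;Y) = H(Y) − H(Y|X)) and both tags are provided for interface
completeness. Ranking is by ascending p (test methods) or descending
statistic, ties by SNP ID; no multiple-testing correction is applied
because selection is by rank, not significance — raw p-values are reported
for transparency. Redundancy pruning is a greedy scan in rank order
dropping any SNP whose squared Pearson correlation with an already-kept
SNP exceeds the threshold (default r² = 0.9). The panel is the top
fraction or count of the pruned ranking.

## Classifiers, metrics, one-class screen, z-score

Four classifiers are wrapped behind one interface: KNN (k = 5), random
forest (500 trees), RBF SVM with probability outputs, and XGBoost (200
rounds, depth 6, learning rate 0.3, single thread). None are tuned
automatically; hyperparameters are plain arguments. Cross-validation is
stratified k-fold (per-breed fold sizes within one), repeated k-fold with
re-randomized splits, or leave-one-out (refused above 10,000 individuals).
Missing dosages are imputed with training-fold means inside CV and
full-data means in the final refit, so no test information leaks into
training. Metrics: pooled accuracy; Cohen's unweighted kappa
(p₀ − p_e)/(1 − p_e) with chance agreement from marginal products (defined
as 1 for a perfect degenerate margin and 0 otherwise); macro AUC as the
unweighted mean of one-vs-rest rank AUCs with midpoint tie handling,
excluding classes absent from the truth with a warning. The multi-class
AUC reduction had to be fixed somewhere; macro one-vs-rest is the most
common convention.

The one-class screen scores a query's panel dosages under the predicted
breed's allele frequencies (add-one smoothed, so the floor is
1/(2n_b + 2)) as the mean per-SNP binomial log-likelihood, and passes it
if the score reaches the breed's threshold — the 1st percentile
(inverse-ECDF) of the breed's *training* scores. Training scores are
jackknifed: each individual's alleles are removed from its breed's
frequency estimate before scoring. Without this the threshold inherits the
in-sample bias of the frequencies and rejects over half of genuinely new
own-breed individuals; with it, held-out true-breed individuals pass at
the same ≈99% rate as training rows while uniform-random genotypes score
far below any threshold. Queries with more than 50% missing panel SNPs
fail outright as low-quality. Validation runs after assignment, under the
predicted breed.

The confidence z-score transforms the top-class probability P through
t = P^α/(P^α + (1−P)^α), returning t when P > 0.5 and t + α(0.5 − t)
otherwise (α > 0, default 2 — the transform needs a fixed default and 2
gives a symmetric, gently sharpening curve). The two branches agree at
P = 0.5. The low-P branch is implemented verbatim even though it is not
monotone in P for α > 1 — a near-zero P can map to a high z — and can
exceed 1 for large α, so the returned value is clamped to [0, 1] with the
raw value kept as an attribute. Because of the low-branch behaviour the
z-score should always be read together with the one-class flag, which is
what actually rejects implausible genotypes.

## Simulator

The generator is the Balding–Nichols island model: per SNP an ancestral
frequency p ~ Uniform(0.05, 0.95); per breed a frequency
f ~ Beta(p(1−F)/F, (1−p)(1−F)/F) with F the target FST (so E[f] = p,
Var[f] = p(1−p)F); dosages are Binomial(2, f), admixed individuals draw
from the mixture frequency Σ qₖ fₖ, and missing calls are masked uniformly.
This prior matches the admixture likelihood, making parameter-recovery
tests coherent. Default conditions — 10 breeds × 20 individuals, 2,000
SNPs, FST 0.15 — are the study shape the package's benchmarks use: a
desk-scale analog of a medium-density SNP-chip multi-breed panel with
moderate differentiation. Alleles are fixed A/G with synthetic positions,
since nothing downstream uses positional information; geography points are
a decorative grid within valid coordinate ranges.

What the simulations do *not* contain: linkage disequilibrium, genotyping
batch effects, within-breed substructure or relatedness, and ascertainment
bias of chip SNPs. Perfect benchmark metrics on strongly differentiated
unlinked simulated markers therefore demonstrate correctness of the
pipeline's machinery, not expected field performance — real panels with
close breeds, LD-correlated markers and small samples will sit below these
figures, which is exactly why the CV report and one-class screen exist.

## Benchmark problem sizes

The package's benchmark suite uses: the 10 × 20 × 2,000 classification
analog above (pooled 5-fold CV accuracy, macro AUC, kappa — all 1.0 under
these conditions); admixture recovery at K = 3, FST 0.2, 60 individuals,
1,000 SNPs (mean |Q̂ − Q_true| ≈ 0.008; the F̂ error is bounded below by
the binomial sampling floor √(E[f(1−f)]/40) ≈ 0.058, so F̂ is checked
against realized sample frequencies instead); K selection over K = 1..4 in
10 seeded replicates; and the one-class benchmark at 5 breeds, FST 0.3,
1,000-SNP panel with 20 train / 5 held-out per breed. These sizes were
chosen so the statistical signal is unambiguous while the whole suite
stays comfortable on a laptop.
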