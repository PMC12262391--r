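---
title: "Information-theoretic saliency of multi-biosample chromatin states: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information-theoretic saliency of multi-biosample chromatin states: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Chromatin-state segmentations (ChromHMM-style) assign one categorical label
— promoter, enhancer, transcribed, repressed, quiescent, … — to each
fixed-width genomic bin (200 bp by default) in each biosample. With dozens
to hundreds of biosamples, the result is a large categorical matrix of
biosamples × bins, and the practical questions are: *where* is this matrix
surprising (region prioritization), *how do two groups of biosamples
differ*, and *where else does a given local state architecture recur*?
`chromsaliency` answers these with relative-entropy scores, a signed
squared-distance differential statistic with a permutation null, a greedy
region recommender, and a scale-normalized similarity search, plus a
seed-deterministic simulator so everything is testable without external
data.

```{r setup}
library(chromsaliency)
```

# Saliency scores

Let $p_i$ be the observed frequency of state $i$ at a bin (fraction of
biosamples carrying it) and $q_i$ its expected genome-wide frequency,
estimated from all (biosample, bin) entries. The basic per-state saliency
level, in bits, is

$$s_{1,i} = p_i \log_2 \frac{p_i}{q_i},$$

the contribution of state $i$ to the Kullback–Leibler divergence
$\mathrm{KL}(p\,\|\,q)$. The per-bin total is therefore nonnegative
whenever the background is estimated from the same matrix, and zero
exactly when the bin's state distribution matches the background. Because
$s_{1,i}$ decreases in $q_i$ at fixed $p_i$, rare states — enhancers,
promoters, typically a few percent of the genome — are upweighted, while
quiescent and broadly transcribed states, which cover most of the genome,
are downweighted. Per-state levels can be negative (a state seen *less*
often than expected); we report them unclipped and only the totals are
sign-guaranteed.

Two refinements replace the background of single states with backgrounds
of state co-occurrence:

* the **pair metric** scores each bin's distribution of ordered state
  pairs across distinct biosample pairs against its genome-wide mean,
  $s_{2,i} = \sum_j p_{ij} \log_2 (p_{ij}/q_{ij})$. This distinguishes
  states by their sharing behavior: recurrent enhancer states, which are
  normally biosample-specific, become more surprising than equally
  recurrent promoter states, which are normally shared.
* the **biosample-pair metric** further conditions on *which* pair of
  biosamples shares the states,
  $s_{3,i} = \sum_j \sum_{\alpha \neq \beta} p_{ij}^{\alpha\beta}
  \log_2 (p_{ij}^{\alpha\beta} / q_{ij}^{\alpha\beta})$, so agreement
  between biosamples that rarely agree counts for more than agreement
  between near-replicates.

Numerical conventions, stated once and used everywhere:

* logarithms are base 2; all scores are in bits;
* $0 \cdot \log_2(0/q) = 0$ (the standard KL convention);
* pair distributions run over **ordered distinct** biosample pairs
  ($\alpha \neq \beta$, normalizer $m(m-1)$). Self-pairs carry no
  co-occurrence information and would inflate diagonal mass; ordered
  pairs keep the algebra symmetric without halving conventions;
* backgrounds are computed over **all** bins, including all-quiescent
  ones (the quiescent exclusion below applies only to the differential
  null fit);
* an observed state with zero background frequency is an error unless a
  pseudocount is requested (`expected_frequencies(x, pseudocount = )`);
  this only arises when scoring one dataset against another dataset's
  background, and the default pseudocount is 0 so same-matrix scoring is
  exact.

The biosample-pair background is $O(n^2 m^2)$ in memory and both it and
the scores stream over ordered biosample pairs; no per-bin joint tensor
is ever materialized genome-wide.

## Consensus versus dominant states

The **consensus** track takes, at each bin, the state with maximal
per-state saliency; the **dominant** track takes the most frequent state.
The two differ exactly where the information weighting matters: a rare
state carried by a minority of biosamples can out-score a common state
carried by the majority, because its per-observation weight
$\log_2(p/q)$ is large. On quiescent-dominated genomes the dominant track
is mostly quiescent while the consensus track over-represents regulatory
states. Ties (rare in continuous scores, common in degenerate fixtures)
break toward the lowest state index, deterministically, and are reported
via a message.

```{r consensus-demo}
spec <- simulation_spec(3, 10, 2000, state_freqs = c(0.89, 0.10, 0.01),
                        seed = 5, quiescent = 1L)
spec <- plant_rare_state_island(spec, rows = 1:2,
                                bins_at = c(300, 900, 1500), state = 3L)
x <- simulate_matrix(spec)
s <- s1_scores(x)
rbind(consensus = consensus_states(s)[c(300, 900, 1500)],
      dominant  = dominant_states(x)[c(300, 900, 1500)])
```

# Pairwise differential analysis

For two disjoint biosample groups $A$ and $B$, both groups' per-state
saliency vectors are computed against a **joint** background pooled over
$A \cup B$ (so neither group is scored against the other's composition),
and each bin receives the signed squared Euclidean distance

$$\mathrm{SSED}_{A,B} = \pm \sum_i
  \left( p_i^A \log_2 \tfrac{p_i^A}{q_i^{AB}}
       - p_i^B \log_2 \tfrac{p_i^B}{q_i^{AB}} \right)^2,$$

signed positive when $A$'s total saliency is at least $B$'s. An exact tie
with nonzero distance is signed positive — arbitrary but deterministic,
and it affects only exactly-tied bins. Swapping the groups negates the
track. Group sizes may differ; each group's $p$ is normalized by its own
size, so size enters only through estimation noise.

## The permutation null

Significance comes from a permutation null: group labels are reassigned
uniformly at random (preserving the original group sizes), the statistic
is recomputed genome-wide, and the permuted values are pooled. Bins at
which **every biosample of both groups** is quiescent are excluded from
the pool — they would otherwise flood it with structural zeros. (The
alternative reading, "quiescent across the full dataset", would also
exclude bins where a biosample outside both groups is non-quiescent;
we exclude on the compared biosamples only, since only they enter the
statistic.)

A three-parameter generalized normal (exponential power) distribution

$$f(x) = \frac{\beta}{2\alpha\,\Gamma(1/\beta)}
  \exp\!\left\{-\left(\tfrac{|x-\mu|}{\alpha}\right)^{\beta}\right\}$$

is fitted to the pool by maximum likelihood. The family contains the
Laplace ($\beta = 1$) and the normal ($\beta = 2$, $\alpha = \sigma\sqrt 2$)
and accommodates the sharply peaked, heavy-tailed shape of the null.
Fitting details: initialization by the method of moments (location from
the median, shape by inverting the family's kurtosis
$\Gamma(5/\beta)\Gamma(1/\beta)/\Gamma(3/\beta)^2$, scale from
$\mathrm{Var} = \alpha^2 \Gamma(3/\beta)/\Gamma(1/\beta)$); Nelder–Mead on
$(\mu, \log\alpha, \log\beta)$ with $\beta$ confined to $[0.2, 10]$,
retried with L-BFGS-B on non-convergence. Rather than fitting the full
multi-million-value pool once, `sample_size` values (default 100,000) are
drawn `n_fits` times (default 11, odd so the median is a single fit) and
the fit with the median negative log-likelihood is kept — robustness
against an unlucky subsample at bounded cost.

Two-sided p-values follow from the closed-form tail
$P(|X-\mu| \ge t) = Q\!\left(1/\beta, (t/\alpha)^{\beta}\right)$ (upper
regularized incomplete gamma; direction is reported separately via the
sign), excluded bins are assigned $p = 1$, and Benjamini–Hochberg FDR
control is applied over the non-excluded bins only. The number of
permutations (default 100), the subsample size, and the number of fits
are all configurable; one user seed drives permutation assignment and
subsampling, making every run reproducible.

Known limitation: the generalized normal is a *smooth* family fitted to a
*discrete* permutation distribution (the statistic takes finitely many
values given the group sizes). Its small-tail probabilities are
accordingly approximate — calibration checks on simulated exchangeable
groups find the realized $P(p \le \alpha)$ within roughly ten percent
relative of the nominal $\alpha$ at $\alpha \in \{0.01, 0.05\}$, with the
direction of the deviation depending on the state-frequency profile.
Downstream FDR calls at conventional thresholds are insensitive to this,
but exact error-rate guarantees should not be read into the tails.

# Region recommendation

High-saliency regions of a fixed size (default 10 kb for single-group
scores, 25 kb for differential magnitudes) are curated greedily: take the
highest-scoring available bin (ties toward the lower coordinate), grow
the window one bin at a time toward whichever side adds the larger score
(ties extend right), and stop at the target size; then retire the
window's bins and repeat, up to `k` regions (default 100) or until no
strictly positive seed remains. A chromosome edge — or a bin already
claimed by an earlier region, which we treat identically — forces growth
to the other side; a seed squeezed so that no full-size window fits is
discarded. Windows never cross chromosome boundaries. Ranks are assigned
by descending aggregate score after collection (the greedy order follows
seed height, which need not order the aggregates). The greedy extension
equals the exhaustive maximum-sum window on unimodal score profiles but
is not globally optimal in general; it is deterministic and linear-time.
Note that regions are *admitted* in seed-height order and only *ranked*
by aggregate: with a small `k`, a flat region of moderate bins can be cut
off by sharper single-bin peaks, so when aggregate ordering matters, ask
for generous `k` and truncate by rank afterwards.

Differential regions additionally carry the signed aggregate, the
direction (which group is more salient), and the state contributing most
squared distance within the region — the label a browser display would
color by.

# Similarity search

To compare regions of different sizes, every region is reduced to exactly
**25 blocks**: its bins are split into 25 consecutive equal groups and
each state's block value is the *maximum* of its per-bin levels within
the group. Pooling is per state — not on totals — because which states
are strongly present anywhere in a block is exactly the pattern identity
a search should preserve; pooling totals would conflate, say, a strong
promoter block with a strong enhancer block. Max pooling also grants
shift tolerance: displacing a pattern by up to about one block leaves the
representation nearly unchanged. Supported query sizes are multiples of
25 bins between 5 kb and 100 kb at the default 200-bp bin.

The genome is tiled into windows of the query's size at a stride of half
the window (rounded down to a bin multiple) — a compromise between index
size and alignment tolerance — and windows are ranked by Euclidean
distance between flattened $25 \times n$ block matrices. A hit must be
*more similar than dissimilar*: its distance must fall strictly below
half the mode of the query's genome-wide distance distribution. The mode
is estimated as the midpoint of the tallest Freedman–Diaconis histogram
bin (ties toward the lower bin); with fewer than 10 indexed windows the
histogram is meaningless and half the median is used instead, with a
warning. Windows overlapping the query are excluded from the hits, and at
most `max_hits` (default 5) are returned in ascending distance order.

# The simulator

`simulation_spec()` + `simulate_matrix()` generate annotation matrices
with known structure: background labels drawn i.i.d. per (biosample, bin)
from target genome-wide frequencies, optionally with geometric run
lengths (`mean_run_length`) to mimic the segment-length structure of real
tracks, and three kinds of planted features overwriting their bins
deterministically — recurring multi-biosample patterns (for search
tests), group-differential regions (for pairwise tests), and rare-state
islands (for consensus-vs-dominant tests). Overlapping plants are
rejected. Everything is a pure function of the spec, including its seed.
Matrices can be written as per-biosample BED segmentations plus a JSON
state model and read back, exercising the full I/O path.

Where a realistic profile is needed, we use a quiescent-dominant one —
the designated quiescent state at 70% and the remaining mass decaying
geometrically across the other states — mirroring the rarity gradient of
real chromatin-state genomes in which quiescent plus transcribed states
cover the large majority of positions and regulatory states a few
percent. What the simulator deliberately does **not** emulate: correlated
biosample groups (cell-type trees), position-dependent state composition,
assembly gaps, or realistic emission noise. Passing tests on simulated
data therefore demonstrate correctness of the computations and
recoverability of planted structure, not biological performance on any
particular consortium dataset.

Test and check problem sizes are chosen to keep the whole suite fast on a
laptop: oracle comparisons run on matrices up to 4 biosamples × 8 bins ×
4 states against brute-force enumeration (tolerance $10^{-9}$);
calibration and planted-recovery checks use simulated genomes of
20,000–100,000 bins, 5–10 biosamples, and 50 permutations.

# Input handling notes

* Coordinates are 0-based half-open (BED) everywhere; bin index =
  `start %/% bin_size`.
* Interval starts must be bin-aligned; a chromosome's final interval may
  end off-grid, in which case the partial terminal bin is truncated with
  a message (chromosome lengths are rarely bin multiples).
* Bins uncovered by a segmentation are filled with the model's designated
  quiescent state (segmentations are normally genome-covering, so gaps
  indicate truncated inputs), with an explicit `fill_state` override;
  without any fill state, uncovered bins are an error.
* State labels are matched against the model's labels, abbreviations,
  and the `"E7"` / `"7"` numeric dialects (following the number embedded
  in `"7_Enh"`-style labels), covering the dialects of published
  ChromHMM outputs.
* The chromosome universe is the union across files, ordered by first
  appearance starting from the first file.
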