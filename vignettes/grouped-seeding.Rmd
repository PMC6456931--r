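---
title: "Grouped short k-mer seeding for long-read overlap detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grouped short k-mer seeding for long-read overlap detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groupseed)
```

## The problem

All-vs-all overlap detection is the first step of overlap-graph assembly
from third-generation (PacBio/ONT-like) reads. These reads carry 10--15%
errors dominated by insertions and deletions, so two reads sequenced from
the same genomic locus agree, per aligned base, only with probability
around 0.7--0.85. Overlappers that seed with a single long exact match
(15-mers, minimizers, minHash sketches) lose sensitivity precisely where
long reads matter most: small overlaps, which determine the irreducible
edges of the overlap graph and hence assembly contiguity, especially at
the low coverage typical of metagenomes.

`groupseed` instead seeds with *groups* of short exact matches (9-mers by
default). A single 9-mer hit is weak evidence, but several 9-mer hits
packed closely together and lying on nearly the same alignment diagonal
are strong evidence. "Closely" and "nearly" are not tuning knobs: both
thresholds are calibrated from an explicit error model at a chosen
confidence level.

## Statistical calibration

### Inter-seed distance: the waiting-time model

Along the implied alignment of two overlapping reads, base agreement is
modeled as independent Bernoulli trials with match probability $p$
(default 0.85). A $k$-mer match is a run of $k$ successes, so the distance
$D_k$ from one seed to the completion of the next follows the first-run
waiting-time law

$$
P[D_k = x] =
\begin{cases}
0 & 0 \le x < k \\
p^k & x = k \\
(1-p)\,p^k\bigl(1 - \sum_{i=0}^{x-k-1} P[D_k = i]\bigr) & x > k,
\end{cases}
$$

which `waiting_time_distribution()` tabulates. The recursion is the exact
law: the package's tests verify it against the absorbing Markov chain over
run lengths (to $10^{-12}$) and against Monte-Carlo run sampling (within
three standard errors at $10^5$ samples).

`solve_rho()` converts the law into a grouping threshold: the smallest
integer bound $\rho$ with $P[D_k < \rho] \ge 1 - \alpha$. The bound is
deliberately *exclusive-strict* ("the distance falls below $\rho$ with 95%
confidence"). At the defaults ($p = 0.85$, $k = 9$, $\alpha = 0.05$) the
cumulative probability at 53 is 0.95030 --- within $4\times10^{-4}$ of the
level --- so the inclusive and strict conventions land on adjacent
integers (53 vs 54). We commit to the strict bound, which gives
$\rho = 54$; grouping itself then applies the inclusive test
$D \le \rho$, so the strict calibration is the sensitivity-preserving
choice of the two. A side effect worth knowing: for a degenerate $p = 1$
the strict bound is $k + 1$, one above the deterministic distance.

### Diagonal shift: the lazy random-walk model

Indels move hits across alignment diagonals. With per-base indel
probability $q$ (default 0.06; insertions and deletions are
interchangeable when comparing two reads), the diagonal drift over $l$
aligned positions is a lazy random walk with steps $+1$, $-1$, $0$ at
probabilities $q$, $q$, $1-2q$. `diagonal_shift_distribution()` computes
the exact $l$-step law; the iterative convolution is the reference
implementation, and an equivalent closed form (a sum over deletion counts
with two binomial coefficients) is evaluated in log-space --- the
coefficients overflow doubles near $l \approx 50$ --- and cross-checked
against the convolution to $10^{-12}$ for all $l \le 60$.

`solve_delta()` accumulates mass over $i = 0, \pm 1, \pm 2, \dots$ until
it reaches $1-\alpha$ (the inclusive summation is unambiguous here). The
number of steps is taken as $l = \rho$, the largest tolerated inter-seed
distance. Defaults give $\delta = 5$:

```{r calibrate}
calibrate()
```

## The pipeline

### Filtration by positional shared k-mer counts

Counting shared 15-mers between all read pairs removes the vast majority
of pairs before any per-pair work. Counts are *positional* --- each
position pair counts once, so a repeated k-mer occurring $n_1$ and $n_2$
times contributes $n_1 n_2$ --- which makes expectations analyzable:
between unrelated reads $E[X_r] = |\Sigma|^{-k} L_1 L_2$, and within an
overlap of size $M$, $E[X_o] = P_o M + |\Sigma|^{-k} L_1 L_2$ with
$P_o = \bigl((1-\varepsilon)^2 + \varepsilon^2/(|\Sigma|-1)\bigr)^k$.
For 8 kb reads at 15% error, $E[X_r] \approx 0.06$ while a 500-base
overlap already contributes $\approx 4.5$ expected hits, so the default
threshold of **two shared 15-mers** discards almost all unrelated pairs at
negligible sensitivity cost. `recommend_filter_threshold()` automates the
choice for other length/error profiles: it takes the smallest integer
above $E[X_r]$ for the longest read pair that still sits at or below
$E[X_o]$ for the shortest considered read (floor 2000 by default) with the
overlap set to a quarter of its length --- the hard small-overlap regime
--- and never goes below 2. For a short-read profile (mean $\approx$ 1.7 kb)
with 11-mers it yields 3.

The counts come from a generalized suffix array over all reads and their
reverse complements (prefix doubling, then Kasai's LCP construction), with
read-id and orientation arrays aligned to suffix rank. Every maximal run
of suffixes sharing a prefix of length $\ge k$ contributes the product of
per-read occurrence counts to each read pair in the run. Each read is
indexed in both orientations; forward$\times$forward products are counted
as `+` hits and forward($a$)$\times$reverse($b$) products as `-` hits,
which counts every positional hit exactly once because the mirrored
occurrences lie in the reverse-complement k-mer's run. Terminators and
ambiguous bases are encoded as unique symbols, so k-mers containing `N`
never match. Orientations are thresholded independently, since a true
overlap exists in one relative orientation.

### Group seeding

For each surviving pair, all exact 9-mer hits are enumerated (hash index,
two-bit encoding) and clustered by single linkage under the two calibrated
constraints: inter-seed distance $\max(|i_2-i_1|, |j_2-j_1|) \le \rho$ and
diagonal shift $|(j_2-i_2) - (j_1-i_1)| \le \delta$, closed transitively.
The implementation sorts hits by $i$ and probes only the $\rho$-window ---
an optimization that cannot change the connected components, and the tests
verify exact component equality against a full pairwise closure. A group's
score is its *matched bases*: the union of member $[i, i+k)$ intervals on
read 1, so overlapping seeds are not double-counted. Read 1 is the fixed
reference side; the read-2 union can differ by indels, and using one fixed
side keeps the acceptance rule scale-consistent.

### Chaining and acceptance

Groups are chained by sparse dynamic programming maximizing total matched
bases under strict precedence in both reads, with no gap penalty and
deterministic tie-breaks. Because an optimal chain occasionally captures a
far-off-diagonal group at an end and inflates the implied overlap,
`trim_collinear()` keeps the best-scoring contiguous sub-chain whose
diagonals stay within $\delta + \lceil q \cdot \mathrm{span} \rceil$ of
the sub-chain's median diagonal: $\delta$ bounds drift between neighboring
seeds, and $q \cdot \mathrm{span}$ bounds the cumulative drift across the
sub-chain. The overlap region is then the chain's bounding box extended to
the read ends along the alignment direction, clipped at whichever read
boundary comes first, and $L_O$ is the extended span on read 1.

A chain is reported as an overlap when

$$ n \;\ge\; n_e = \frac{1}{c} \cdot \frac{L_O}{\rho} \cdot k $$

(one group at least every $\rho$ bases, each worth at least $k$ matched
bases, relaxed by the coefficient $c$) *and* the chained spans on the two
reads agree within a relative tolerance $\tau$ (default 0.3). $c$ is the
sensitivity/precision dial: raising it only ever adds acceptances. The
default $c = 2$ sits in the middle of the useful range; $\tau = 0.3$
tolerates the span asymmetry that 6% indel rates produce while rejecting
repeat-induced chains whose extents disagree badly.

## The simulator and what it does (not) show

`simulate_reads()` provides the test bed: a uniform random genome, uniform
read starts, truncated-normal read lengths (floor 200), uniform strands,
and a single-pass error channel --- at each consumed genome base, a
geometric number of inserted bases (no advance), then substitution,
deletion or copy. At the default 8.6%/4.4%/1.4% rates a read emits about
$0.086/0.914 + 0.870/0.914 \approx 1.046$ bases per consumed genome base,
which the tests verify. Ground truth comes from the sampling coordinates:
every pair of reads whose genomic intervals intersect by at least
`min_truth_overlap` (default 100 bases --- a floor has to be chosen, and
100 is well below anything an assembler would use) is a true overlap, and
consecutive reads by start coordinate mark irreducible edges.

A uniform random genome has no repeats, skewed composition, chimeras or
quality ramps; real data has all four. Passing the synthetic recovery
tests therefore demonstrates the method's statistical machinery --- that
calibrated grouping plus chaining finds indel-riddled overlaps down to a
few hundred bases --- not robustness to repeat structure, which is
deliberately out of scope (no minimizers, no repeat masking, and the
optional suffix-run cap is off by default).

## Problem sizes and numerical choices

The shipped tests run a 100 kb genome at 10X with 8 kb reads (about 125
reads and 1200 true pairs) for the end-to-end recovery check --- large
enough that filtration, grouping, chaining and the acceptance rule all
operate in their intended regimes, small enough to re-run routinely.
Oracle-equivalence suites use 200 random instances per kernel; Monte-Carlo
distribution checks use $10^5$ samples and a three-standard-error band.

Numerical conventions worth recording: all coordinates are 0-based with
half-open intervals (PAF's convention); the waiting-time support grows
geometrically until the cumulative reaches the confidence level, with a
hard cap that turns "p far too small for k" into an error; the closed-form
walk mass is summed in log-space; medians of even-sized diagonal sets are
midpoint medians; chain ties resolve to the earliest group in
$(a_\mathrm{start}, b_\mathrm{start})$ order; and duplicate hits are
deduplicated defensively even though exact enumeration cannot produce
them.

## A worked example

```{r example}
cfg <- simulation_config(genome_length = 30000, coverage = 8,
                         mean_read_length = 3000, seed = 7)
sim <- simulate_reads(cfg)
calls <- run_pipeline(sim$reads, pipeline_config())
score_calls(calls, sim$truth, min_overlap = 500)
```

```{r binned}
head(binned_sensitivity(calls, sim$truth, bin_width = 500))
```

## Limitations

- Coordinates in PAF output are approximate (seed-bounding-box extension,
  not base-level alignment); downstream consumers should re-align.
- The per-pair stage is quadratic in candidate pairs; the package targets
  low-coverage datasets (metagenomes, small genomes), not 50X mammalian
  runs.
- `p` and `q` are user parameters, not estimated from the data; calibrate
  them from a quality report or an alignment sample.
- Repeat-dense genomes will produce repeat-induced candidate pairs that
  only the size-similarity rule and $n_e$ partially suppress.
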