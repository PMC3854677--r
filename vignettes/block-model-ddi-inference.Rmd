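---
title: "Predicting drug-drug interaction types with stochastic block models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting drug-drug interaction types with stochastic block models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The inference problem

A drug interaction network has one node per drug and one typed link per
reported pairwise interaction — synergistic, additive, antagonistic,
suppressing, or simply "adverse interaction present" in the binary case.
Exhaustive screens type every pair of a small panel; large interaction
databases list thousands of positive links and are silent about the
rest.  In both settings the practical question is the same: given the
observed network $A^O$, what is the probability that an untested (or
untrusted) pair $(i, j)$ interacts with each type $k$?

`ddiblock` answers this with Bayesian model averaging over stochastic
block models.  The modeling assumption is that interactions are driven
by what the drugs act on: drugs can be partitioned into groups (in
practice these align with mechanism of action) such that the probability
of each interaction type depends only on the groups of the two drugs.  A
model is therefore a partition $P$ of the drugs plus, for every group
pair $(\alpha, \beta)$, a probability vector $q_{\alpha\beta}$ over the
$K$ types.  No pharmacological covariates enter anywhere; reported
interactions are the only input, and the procedure has no free
parameters to tune.

## Marginalizing the type probabilities

Conditioned on a partition, the likelihood of the observed counts
$n^k_{\alpha\beta}$ (interactions of type $k$ between groups $\alpha$
and $\beta$, $n_{\alpha\beta} = \sum_k n^k_{\alpha\beta}$) factorizes
over group pairs, and each $q_{\alpha\beta}$ can be integrated out
analytically under a uniform prior on the $K$-simplex:

$$\int_{\Delta_K} (K-1)!\ \prod_k q_k^{n^k}\, dq
  \;=\; \frac{(K-1)!\ \prod_k n^k!}{(n + K - 1)!}.$$

`log_pair_factor()` implements the logarithm of this factor (with
log-gamma, never large factorials), and the partition weight is

$$H(P) \;=\; \sum_{\alpha \le \beta}
  \Big[\ln\big((n_{\alpha\beta}+K-1)!\big)
  - \sum_k \ln\big(n^k_{\alpha\beta}!\big) - \ln\big((K-1)!\big)\Big],$$

so that the posterior weight of a partition is $e^{-H(P)}$: partitions
whose group pairs interact near-monochromatically get low $H$ and
dominate.  Within-group pairs ($\alpha = \beta$) are included; a group
pair with no observations contributes exactly zero.  Because the
$(K-1)!$ prior-density constant does not cancel between partitions with
different numbers of occupied groups, it is kept by default and exposed
as the `include_prior_constant` switch; the closed form was verified
against numeric simplex integration (quadrature at $K = 2$, Monte-Carlo
at $K = 3, 4$) in the test suite.

The posterior probability that pair $(i, j)$ has type $k$ is then the
average over partitions of a Laplace-smoothed cell estimate,

$$p(x_{ij} = k \mid A^O) \;=\;
  \frac{1}{Z}\sum_P
  \frac{n^k_{\sigma_i \sigma_j} + 1}{n_{\sigma_i \sigma_j} + K}\,
  e^{-H(P)},$$

with $\sigma_i$ the group of $i$ under $P$.  For up to ten drugs this
sum is computed exhaustively over all set partitions
(`exact_link_posterior()`, Bell(8) = 4140 terms); beyond that it is
estimated by Markov chain Monte Carlo.

## The partition sampler

`run_sampler()` follows the classic recipe: propose moving one uniformly
chosen drug to one of the other $N - 1$ group labels ($N$ labels are
maintained so every partition is reachable and the proposal is symmetric
on labeled assignments), and accept downhill moves always, uphill moves
with probability $e^{H - H'}$.  One subtlety is handled explicitly: a
set partition with $b$ occupied groups corresponds to $N!/(N-b)!$
labeled assignments, so a chain that is uncorrected on labels would
oversample finer partitions by exactly that multiplicity.  The
acceptance ratio therefore carries the factor $(N)_b / (N)_{b'}$, which
makes the stationary distribution over *set partitions* exactly
$e^{-H}/Z$ — the weight the model average requires, with each partition
counted once.  The test suite checks this directly: the empirical visit
frequencies of a chain on a 5-drug network match $e^{-H}/Z$ over all 52
set partitions by a chi-squared test, and the sampled posterior matches
the exhaustive 203-partition sum on a 6-drug toy to better than 0.02.

Default protocol, reproduced from the sampling scheme the method was
validated with: **50 independent chains, 200 recorded partitions each**
(10,000 pooled samples).  Each chain starts from an independent
uniformly random assignment; many short chains pool better than one long
one and parallelize trivially.  Two automatic decisions keep the run
unsupervised:

* **Thermalization.**  A chain burns in until the means of $H$ over two
  consecutive 20-sweep windows differ by less than one pooled standard
  error (a sweep is $N$ elementary moves), with a hard cap of 10,000
  sweeps; failing the cap is a warning by default and an error in
  `strict` mode.
* **Thinning.**  After burn-in the decorrelation time of $H$ is
  estimated from its autocorrelation over 200 probe sweeps (first lag
  below $1/e$, capped at 50), and one partition is recorded per that
  many sweeps.

All randomness derives from the configured seed (each chain gets an
independent stream derived from it), so runs are bit-reproducible and
independent of how chains would be scheduled.

Incremental count bookkeeping uses the one-observation identities
$\Delta = \log(n + K) - \log(n^k + 1)$ (add) and
$\log(n^k) - \log(n + K - 1)$ (remove); since every argument is a small
integer, logarithms come from a precomputed table, and the running $H$
is refreshed from scratch every 4096 sweeps to keep floating-point
drift below $10^{-10}$.

## Observation semantics

Two views of a network are supported, matching the two data settings:

* **heldout** — unobserved pairs are missing data and contribute to no
  counts.  This is the right view for partially observed exhaustive
  screens, where "not measured" carries no information.
* **fully_observed** — for binary none/interaction networks, every pair
  is an observation and an unstored pair means "no interaction".  This
  is the right view for database snapshots, and it lets a single
  sampler run score all $\binom{N}{2}$ pairs.  When a stored pair is
  itself scored, its own observation is first removed from the counts
  (leave-one-out), so an edge is judged by the rest of its block only.

## Comparison predictors

Three reference predictors share the same interface
(`predict_pairs()`), so every protocol runs all methods under identical
conditions:

* **Baseline** — the global rate of each type among observed
  interactions; the same vector for every query.  It calibrates how
  hard prediction is (a 60/40 type split is harder than 95/5).
* **Neighbor-based** — profile similarity $S_{ij}$ = fraction of equal
  interactions among partners reported for both drugs; the prediction
  for $(i, j)$ copies the known interaction $x_{kl}$ with the largest
  product $S_{ik} S_{jl}$.  Self-similarity is 1 (so a known $x_{lj}$
  with $l$ similar to $i$ is a valid candidate), undefined similarities
  are skipped rather than zeroed, ties break on the larger minimum
  similarity and then lexicographically, and with no usable candidate
  the baseline is returned.
* **Prism II** — agglomerative monochromatic clustering.  Groups merge
  greedily by a distance combining the mean normalized profile distance
  $D_{ij} = 1 - S_{ij}$ (undefined pairs maximally distant) with the
  increase in total monochromaticity entropy
  $S(v) = (v_- + v_+)\,h(v_-/(v_-+v_+))$ summed over all group pairs
  (within-group included — otherwise the single-group reference of the
  cut rule would be zero), weighted by `entropy_weight`.  The tree is
  cut at the fewest-groups partition whose total entropy is at most
  `cut_threshold` times the single-group entropy; predictions then use
  the same Laplace cell estimator as the block model, evaluated at that
  one partition (the test suite asserts this estimator identity).  For
  $K > 2$ alphabets only synergistic-like and antagonistic-like types
  enter the entropy vector; additive is neutral and suppressing counts
  as antagonistic-like by default (`type_polarity`).  Defaults
  `entropy_weight = 1`, `cut_threshold = 0.1` were fixed by requiring
  exact recovery of perfectly monochromatic planted blocks; results are
  not sensitive to moderate changes, and both are exposed in
  `prism_config()`.

## Evaluation protocols

* **Sub-sampling validation** (`subsample_validate()`): keep a uniform
  random $\lceil f M \rceil$-subset of the observed pairs, fit on it,
  predict the complement; report exact accuracy and, on ordered
  alphabets, within-one-level accuracy (±1 on the severity scale:
  synergistic predicted as additive counts as correct, as antagonistic
  or suppressing as wrong), with standard errors over repetitions.
  Sub-sampling is uniform over pairs, not stratified by type; additive
  interactions are observations like any other.
  `relative_improvement()` expresses accuracy gaps relative to the
  baseline: $(F_{SBM} - F_X)/(F_X - F_B)$.
* **Snapshot detection** (`evaluate_snapshots()`): score every pair of
  the earlier snapshot in fully-observed mode; novel-link detection
  ranks added pairs against never-added pairs by $p(\text{interaction})$,
  spurious-link detection ranks removed pairs against persistent pairs
  by the negated score (so one rank-based AUROC implementation serves
  both; ties count one half, and the trapezoid area of the
  sensitivity-specificity curve equals the rank AUROC identically).
* **Discovery simulation** (`discovery_simulation()`): a target drug
  enters the database with a single seed interaction; at each iteration
  the block model scores all unqueried target pairs (database
  semantics: unqueried and confirmed-negative pairs are both non-edges;
  the candidate's own non-edge is left out of its counts) and the top
  candidate is tested against the truth.  The trace is reported against
  a feasible region: the oracle line $\min(q, d)$ above, the expected
  random-querying line $q\,d/(N-2)$ below.  An early design used the
  heldout view here; it fails in an instructive way — once the target
  drifts to a singleton group, never-explored group pairs score the
  Laplace prior mean $1/K$, which beats every informed estimate, and
  querying degenerates to random.  The database view has no empty
  cells and does not suffer from this.

## The synthetic generator

`generate_planted_network()` draws every pair's type from a planted
partition and per-group-pair type distributions — the generative reading
of the inference model — and `make_exhaustive_fixture()` instantiates
two screen-sized designs (13 drugs / K = 3 and 21 drugs / K = 4, all
pairs typed, three resp. four planted mechanism groups, dominant type
probability 0.8).  `perturb_snapshot()` builds snapshot pairs with known
novel/spurious sets; perturbing the *true* network into the earlier
snapshot makes the hidden links structure-consistent and hence
detectable, which is the property the snapshot benchmark needs
(uniformly random "novel" links would be undetectable by any method, by
construction).

What the generator does **not** emulate: degree heterogeneity within
groups, overlapping or hierarchical mechanisms, systematic measurement
error, and the empirical type matrices of real screens.  Passing the
planted benchmarks therefore demonstrates correctness of the machinery
and identifiability under the model's own assumptions, not performance
on any real database.

## Problem sizes and numerical choices

The verification suite uses: exhaustive enumeration at 5–6 drugs;
a $10^5$-sweep chain (thinned to every 10th sweep for the chi-squared
statistic, which assumes independent draws); planted recovery at 60
drugs / 3 groups / dominant probability 0.9 / half observed / 10
repetitions; snapshot detection and discovery at 100 drugs / 4 groups
(within-group interaction probability 0.7, between 0.03), 5% of edges
moved, a degree-10 target and 20 queries.  The discovery loop re-runs
the sampler from scratch every iteration with 10 chains × 100 samples —
a ranking of ~100 candidates does not need the full 50 × 200 protocol,
which is used everywhere else.  Degenerate inputs are defined
deliberately: empty networks have $H \equiv 0$ and uniform posteriors;
empty count cells contribute zero to $H$; classification ties resolve
to the lowest type index; an unsatisfiable Prism cut returns singletons
with a warning.

## Limitations

Plain (not degree-corrected) block models; two-drug interactions only;
one partition ensemble per network rather than hierarchical priors over
the number of groups (the uniform-assignment ceiling of $N$ groups is
the implicit prior); Prism II as implemented scales to screen-sized
panels, not thousand-drug databases.  Headline performance on real,
version-dated interaction databases depends on those external datasets
and is outside what the synthetic benchmarks can certify.
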