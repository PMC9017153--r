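---
title: "Quantitative analysis of RNA Bind-n-Seq binding experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative analysis of RNA Bind-n-Seq binding experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

RNA Bind-n-Seq (RBNS) incubates a protein with a large random-sequence
RNA pool, recovers the protein-bound RNA, and sequences both the input
pool and the bound fractions. `rbnskit` turns those libraries into
quantitative binding parameters. It covers, in order of the analysis
flow:

1. read quality control and adapter-anchored trimming;
2. k-mer counting, enrichment ratios, and Z-score significance;
3. a target-site grammar for miRNA-guided binding (site types, labels,
   motif enumeration, k-mer classification);
4. iterative de novo site discovery with read masking;
5. assignment of reads to site categories and conversion to
   concentrations;
6. maximum-likelihood estimation of absolute dissociation constants
   from an equilibrium dilution series;
7. maximum-likelihood estimation of association and dissociation rate
   constants from a kinetic time course;
8. a generative simulator used for validation;
9. bench-planning calculators (titration, equilibration time, pool
   copy numbers); and
10. configuration-driven end-to-end pipelines with a small CLI.

This vignette documents the models, their assumptions, the numerical
choices, and the known limitations. The worked example lives in the
README; the formal behavior is specified by the test suite.

# The measurement model

## Equilibrium dilution series

A binding reaction $j$ contains total RNA at fixed concentration
(100 nM by convention) partitioned into site categories $i$ with pool
concentrations $P_i$ (the categories are the modeled binding sites plus
a catch-all "no-site" category), and active protein at $\mathrm{DF}_j
\cdot [\mathrm{stock}]$, where $\mathrm{DF}_j$ is the dilution factor
of sample $j$ and one sample is a no-protein control
($\mathrm{DF}=0$).

Each category binds with a single dissociation constant $K_i$. At
equilibrium the free protein $A_j$ satisfies the mass balance

$$\mathrm{DF}_j\,[\mathrm{stock}] - A_j -
  \sum_i \frac{A_j P_i}{K_i + A_j} = 0,$$

and the specifically bound concentration of category $i$ is
$s_{ij} = A_j P_i / (K_i + A_j)$. Recovery is not perfectly specific: a
fixed total concentration $b$ of RNA comes down non-specifically,
apportioned among categories in proportion to their *free*
concentrations. The recovered concentration is therefore

$$x_{ij} = s_{ij} + b\,\frac{P_i - s_{ij}}{\sum_k (P_k - s_{kj})}.$$

Sequencing draws a fixed number of reads per sample, so only the
proportions $x_{ij}/\sum_i x_{ij}$ are observable. Counts are modeled
as multinomial per sample; dropping data-only constants, the cost
minimized is

$$f = \sum_j \Big[\ln\big(\textstyle\sum_i x_{ij}\big)\sum_i n_{ij}
      - \sum_i n_{ij} \ln x_{ij}\Big],$$

which depends on each sample's $x_{\cdot j}$ only through its
proportions (scale invariance per sample; the test suite checks this
against `dmultinom`).

Free parameters: one $K_i$ per category (including no-site), the active
stock concentration, and the background $b$. All are optimized in log
space with box constraints (site $K_D$ 0.1 pM–100 nM, no-site
0.1–10^4 nM, stock 0.1–100 nM, background 5 pM–5 nM) using `optim`'s
L-BFGS-B with an analytic gradient.

The gradient is fully analytic, including the implicit dependence of
$A_j$ on the parameters obtained by differentiating the mass balance.
This matters: finite-difference gradients at this cost scale (tens of
millions of reads) are noise-limited, and the implicit term is not
negligible because the experiment operates in the ligand-depletion
regime.

## Kinetic time course

For a time course at total protein $T$, each category relaxes as

$$s_i(t) = u_i - v_i e^{-w_i t},\qquad
  u_i = \frac{k_{\mathrm{on},i} P_i A}{k_{\mathrm{on},i} A +
  k_{\mathrm{off},i}},\quad
  v_i = \frac{k_{\mathrm{on},i} P_i T}{k_{\mathrm{on},i} T +
  k_{\mathrm{off},i}},\quad
  w_i = k_{\mathrm{on},i} A + k_{\mathrm{off},i},$$

with the free protein $A(t)$ determined self-consistently from
$T - A - \sum_i s_i(A, t) = 0$. This is a quasi-static
pseudo-first-order approximation: it is exact when protein is in
excess, and the test suite verifies agreement with a full mass-action
ODE integration (deSolve) to better than $10^{-3}$ relative in that
regime. At $t \to \infty$ it reduces exactly to the equilibrium model
with $K_i = k_{\mathrm{off},i}/k_{\mathrm{on},i}$ (verified to
$10^{-6}$). Non-specific recovery mixes in exactly as at equilibrium,
and the likelihood is the same multinomial form over time points.

Because every $s_i$ is strictly increasing in $A$, the balance is
strictly decreasing in $A$ and the root is unique; it is bracketed on
$(0, T]$ and polished by Newton steps.

# Estimation protocol

`estimate_kd()` and `estimate_kinetics()` share one protocol:

* **Resampling.** Each of `n_boot` replicates subsamples 95% of every
  sample's reads *without replacement* (multivariate hypergeometric),
  mirroring how sequencing samples a finite library.
* **Multi-start.** Each replicate is fit from `n_starts` starting
  points. Equilibrium starts pair a log-spaced grid of stock-protein
  guesses (0.5–25 nM) with a grid of no-site $K_D$ guesses (0.5–10 nM);
  site $K_D$s are initialized at 1/mean-enrichment and the background at
  0.1 nM, all jittered with $\mathcal{N}(0, 0.1)$ noise in log space.
* **Retention.** A fit is retained when the Pearson correlation between
  predicted and observed counts exceeds 0.90. Reported estimates are
  medians over retained fits with 2.5/97.5 percentile intervals.

Kinetic starting values derive from moment matching. At early times
recovery is background-dominated, so a category's enrichment is
approximately $1 + (s_i/P_i)\,(\mathrm{pool}/b)$; converting the
enrichment slope between the first two time points into a bound-fraction
slope with the background's initial guess gives

$$k_{\mathrm{on},i}^{(0)} =
  \frac{\big(E_i(t_2)-E_i(t_1)\big)\, b_0 / \sum_k P_k}{(t_2-t_1)\,T}.$$

The $b_0/\sum_k P_k$ factor is essential: without it the initializer is
three orders of magnitude too large, every start clamps at the upper
$k_{\mathrm{on}}$ bound, and the optimizer can settle in a local
minimum with excellent predicted-count correlation but wrong rank
order — exactly the failure mode retention cannot catch.
$k_{\mathrm{off}}$ is initialized from late-time enrichment so the
implied $K_D$ matches the equilibrium initializer.

## Numerical choices

* **Optimizer tolerance.** L-BFGS-B's default `factr` ($10^7$) stops
  when the cost improvement falls below roughly $10^7 \cdot
  \epsilon_{\mathrm{mach}} \cdot |f| \approx 0.4$ units at $2\times10^7$
  reads — the same order as the entire depth of the likelihood's soft
  direction (below), so fits would freeze near their starting values.
  The package uses `factr = 10`.
* **Root solving.** Free-protein balances are solved by `uniroot`
  bracketing plus Newton polish to a residual below $10^{-10}$ relative;
  the equilibrium solver raises an error rather than returning an
  unconverged root.
* **Degenerate predictions.** Parameter vectors that predict zero
  concentration for an observed category receive a large finite penalty
  instead of an infinite cost, keeping line searches well-defined.
* **Large urns.** Hypergeometric subsampling falls back to a multinomial
  draw when molecule counts exceed integer range; at that size the
  sampling fraction makes the two indistinguishable.

## Identifiability

The equilibrium likelihood has one soft direction: scaling **all**
$K_D$s jointly (with a compensating small change in stock protein)
changes the cost very little, because only composition proportions are
observed and the absolute scale is pinned only weakly through the
dilution series' depletion nonlinearity. A Fisher-information analysis
at the default study conditions puts the marginal standard deviation of
$\log K_D$ near 0.7 at $2\times10^7$ reads per sample — i.e. the
*absolute* $K_D$ scale of a single simulated dataset can wander by up to
about two-fold even for an exact maximum-likelihood fit, while
*relative* affinities, the stock concentration (±3%), and the
background (±1%) are sharp. Test tolerances on absolute recovery are
set at two-fold for this reason; they reflect the information content
of the experiment, not the quality of the optimizer. The kinetic
likelihood is harder still: absolute rate constants are generally not
recoverable at realistic depth, so the package's validation asserts
rank-order recovery across sites, not absolute values.

# Site grammar and discovery

## Grammar

A site is described by the guide positions it pairs ($gX$–$gY$,
numbered from the miRNA 5′ end), an optional t1 identity (the target
nucleotide opposite $g1$, read by a protein pocket rather than by
pairing), and at most a small set of single-nucleotide edits: G:U
wobbles, one non-wobble mismatch, one bulged target nucleotide, or a
deleted guide position. Canonical names (8mer, 7mer-m8, 7mer-A1, 6mer,
6mer-A1, 5mer-A1, `kmer-mX.Y`, `-wN`, `bX.YN`) follow the field's
nomenclature; mismatch (`-xNnt`) and deletion (`-dN`) suffixes are this
package's convention. Deletions at adjacent identical guide bases are
indistinguishable at the motif level and are merged into `-dN/N+1`
labels.

## Classification cascade

`classify_kmer()` classifies a k-mer by trying, at each sub-length from
$k$ down to 4: perfect complementarity, then a single bulged target
nucleotide, then wobbles, then one mismatch — accepting the first stage
with a candidate and breaking ties by fewest edits, then
seed-proximity, then 5′-most position. Two design rules are worth
stating explicitly:

* **Edits must be internal to the paired span.** A wobble or mismatch
  at a span boundary is indistinguishable from a shorter perfectly
  paired site with an unpaired flanking nucleotide, so the cascade
  canonicalizes such k-mers to the shorter perfect site. Without this
  rule, discovery reports a halo of spurious boundary-edit variants
  around every strong site.
* **A 3′-terminal nucleotide adjacent to a g2-anchored span is the t1
  identity**, so `UACCUCA` is a 7mer-A1, not a seven-nucleotide paired
  span.

## Discovery

Site discovery iterates: rank k-mers by enrichment (bound over pool
frequency), classify the top set, select the site type whose best
member k-mer is most enriched, and accept it only if (a) that member's
Z-score **in the original, unmasked enrichment table** reaches the
99.9th-percentile threshold and (b) the site is not significantly
enriched in the no-protein control. Accepted motifs are then masked —
every read containing the motif is removed from both bound and pool —
and enrichments recomputed, so "shadow" k-mers that were enriched only
by co-occurring with a true site fall away. Acceptance against the
original table (rather than the masked one) keeps the significance
reference frame fixed across iterations.

# Simulator

The simulator generates data strictly from the fixed study conditions;
it is a validation instrument, not a tuning knob.

* **Equilibrium series**: a 100 nM pool with four specific sites at
  15 pM each ($K_D$ = 5, 20, 100, 500 pM), a 5 nM no-site background
  category, 2.1 nM stock protein diluted 3.2-fold from DF = 0.4 across
  five samples plus a no-protein control, and 0.1 nM non-specific
  recovery.
* **Kinetic series**: 150 pM protein, 14 time points from 0 to 7200 s;
  dataset 1 varies $k_{\mathrm{on}}$ across sites ($10^{-1}$ to
  $10^{-4}$ nM⁻¹s⁻¹), dataset 2 fixes $k_{\mathrm{on}}$ and varies
  $k_{\mathrm{off}}$ ($10^{-5}$ to $10^{-1}$ s⁻¹).

Realism choices: expected category concentrations are converted to
molecule counts in the 20 µL reaction volume, and sequencing is drawn
*without replacement* from that finite molecule population
(multivariate hypergeometric), giving the correct sub-multinomial
counting variance. Read-level synthesis (`generate_synthetic_reads`)
plants motifs at uniformly random positions in uniform random
sequence, records per-read ground truth, and is used for the QC,
counting, discovery and assignment round trips, where a read-level —
not category-level — channel is what is being tested.

# Bench-planning calculators

* `fit_titration()` fits the quadratic ligand-depletion binding
  equation to an active-protein titration; in the tight-binding limit
  the curve degenerates to a piecewise-linear breakpoint at the
  stoichiometric equivalence point, which the fit recovers with a
  near-zero apparent $K_D$.
* `equilibration_time()` computes $k_{\mathrm{eq}} = k_{\mathrm{on}}
  [\mathrm{protein}][\mathrm{site}] + k_{\mathrm{off}}$, the
  conventional planning formula. The first term multiplies two
  concentrations and is therefore not dimensionally standard, but at
  picomolar concentrations it is numerically negligible against
  $k_{\mathrm{off}}$; `pseudo_first_order = TRUE` selects the
  dimensionally consistent relaxation rate
  $k_{\mathrm{on}}([\mathrm{protein}]+[\mathrm{site}]) +
  k_{\mathrm{off}}$. Five half-lives (analytically 96.875% complete)
  are reported as the conservative equilibration time.
* `pool_copy_number()` gives the expected copies of a k-mer in a random
  pool: $(L-k+1)$ windows per molecule, each matching with probability
  $4^{-k}$.

# Pipelines

`run_equilibrium_pipeline()` and `run_kinetics_pipeline()` sequence
QC → discovery (skipped when sites are given explicitly) →
assignment → estimation from a single configuration list or YAML/JSON
file. Configuration validation runs before any compute (exactly one
pool; equilibrium runs need exactly one no-protein control; kinetic
runs need at least four time points). Each stage logs timing to stderr
and failures abort with a stage label. Every run is deterministic given
`config$seed`, and all written artifacts embed a short content hash of
the configuration (32-bit FNV-1a over the serialized object, skipping
the serialization header so the hash is independent of the writing R
version). A thin CLI (`inst/cli/rbns.R`) exposes the individual stages
and the end-to-end runs.

# Test-scale choices

The shipped tests run discovery at $k = 8$ on libraries of
$3\times10^4$ reads rather than the $k = 10$ / $10^7$-read scale of a
real experiment: the Z-score reference distribution over $4^8$ k-mers
is already well-formed at that depth, and the behavior under test
(ranking, classification, masking, control rejection) is
scale-independent. Estimation tests use reduced protocols (tens of
starts, a few resamples); the defaults (100 starts × 10 resamples)
simply tighten the percentile intervals.

# Limitations

* The equilibrium and kinetic models assume one dissociation constant
  (or rate pair) per category; position or flanking-sequence effects
  within a category are averaged over.
* The kinetic closed form is quasi-static; far from the excess-protein
  regime it is an approximation to the full mass-action system (the
  estimators and simulator share it, so validation round trips remain
  internally consistent).
* Absolute-scale recovery is limited by experimental information, not
  by the code (see *Identifiability*); plan on interpreting relative
  affinities unless the dilution series is deep and well-placed.
* The discovery procedure judges significance against an empirical
  Z-score percentile; on data with no true signal the top fraction of
  noise k-mers is, by construction, above any fixed percentile, so the
  no-protein control filter is the principal guard against false
  positives and should always be provided.
* Non-specific recovery is modeled as a single concentration shared
  across samples; protein-dependent background is not modeled.
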