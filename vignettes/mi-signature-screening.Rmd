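---
title: "Mutual-information screening of gene-set signatures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutual-information screening of gene-set signatures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redirectomics)
```

## The problem

Cancer cell redirection is the adoption of a normal phenotype by tumor cells
co-cultured with an excess of normal mammary epithelial cells. An expression
study of this system contrasts six sorted cell groups — normal (A), tumor
(B), redirected (E), and intermediate mixing controls (C, D, F) — each with
three replicate microarray columns on a log2 intensity scale. The screening
question is polygenic: which curated gene sets (MSigDB-style molecular
signatures) behave as one unit whose expression in redirected cells
resembles normal cells and diverges from tumor cells?

`redirectomics` answers this with a mutual-information (MI) statistic. For a
signature projected onto the probes of the expression matrix, each sample
column restricted to those probes is a discrete random variable after
binning, and for two cell groups the MI between their columns measures how
predictable one group's expression pattern over the signature is from the
other's — sensitive to any reproducible relationship, not only linear ones.
The screen statistic is the ratio

$$ R = \frac{\mathrm{MI}(\text{normal}, \text{redirected})}
            {\mathrm{MI}(\text{redirected}, \text{tumor})} , $$

large when the signature's pattern is shared between normal and redirected
groups but scrambled in the tumor group.

## Discretization

MI is estimated by the plug-in (maximum-likelihood) estimator on binned
intensities, in bits, with no bias correction. The default scheme uses
unit-width bins on the log2 scale anchored at the floored global minimum of
the matrix. Two considerations drive this choice:

* post-RMA log2 intensities for this design span roughly 3.6–14, so unit
  bins yield about 11 occupied states; the maximum entropy $\log_2 n$ for an
  $n$-gene set then crosses the number of states near $n = 11$, which is
  exactly where the screen's size filter sits (sets of 10 or fewer members
  are excluded as too small for reliable MI);
* unit bins make the estimator deterministic and interpretable (one bin per
  two-fold expression change), with no tuning parameter fit to the data.

A `fixed_bins` alternative (equal-width partition of the global range) is
provided for sensitivity analysis. Because the default origin is a function
of the global minimum, analyses that must be invariant to probes outside a
signature should fix `origin` explicitly.

The plug-in estimator is biased upward at small sample size — with $a$ and
$b$ occupied marginal states the expected spurious MI is roughly
$(a-1)(b-1)/(2 n \ln 2)$ bits for $n$ genes — which is the practical reason
for the minimum-set-size filter rather than any correction term.

## Replicate aggregation

The ratio needs one MI value per pair of groups, but each group has three
replicate columns. Two aggregations are implemented:

* `pairwise_mean` (default): the mean of MI over all cross-group replicate
  column pairs (nine pairs for 3×3). This uses every column, is invariant to
  replicate ordering, and does not inflate the state space.
* `concatenate`: MI of the two vectors formed by stacking each group's
  replicates. This estimates MI on 3× the sample size but treats replicates
  as exchangeable draws of the same variable.

With one replicate per group the two coincide. The choice matters little on
the synthetic designs below; `pairwise_mean` is the default because its
estimate is an average of identically constructed terms rather than a single
estimate on a mixture.

## The screen and its null model

Each signature is translated gene → probe (all probes of a gene are
retained; the mapping is an explicit input table), the size filter is
applied, and signatures with zero numerator MI are excluded; a zero
denominator with positive numerator is excluded as undefined rather than
treated as infinite, so the null distribution stays finite. The testable
ratios themselves form the null distribution: the screen fits a normal by
mean and standard deviation to all testable ratios (`gaussian_fit`) and
assigns each signature the upper-tail probability of its ratio. Bonferroni
control at family-wise level $\alpha$ (default 0.01) calls a signature
significant when $p \le \alpha / N_{\text{tested}}$; inverting the fitted
normal at that per-test threshold gives the equivalent minimum significant
ratio, which `mi_screen()` reports as `ratio_cutoff`.

Two caveats are intentional and documented rather than hidden. First,
fitting the null to all ratios (including any true positives) is
conservative: real signal inflates the fitted spread. Second, a ratio
distribution is right-skewed in principle; the Gaussian tail is a
reconstruction, so an `empirical` null
$(1 + \#\{r_i \ge r\})/(1 + N)$ is provided as a robustness check — its
resolution ($\approx 1/N$) cannot reach Bonferroni thresholds at realistic
database sizes, which is itself the reason a parametric tail is needed at
all. Testing is one-sided (upper tail) because only maximal ratios mark
redirection-like signatures; the low-ratio tail is reported descriptively.

## Sample geometry by inverse MI

For visualization, every pair of sample columns gets the dissimilarity
$\log_2(n)/\mathrm{MI}$, maximum entropy for the probe-set size over observed
MI (1 for identical uniform columns, growing as dependence decays). Classical
(Torgerson) multidimensional scaling — double-centering of squared
dissimilarities and eigendecomposition, via `stats::cmdscale` — embeds the
columns; `order_samples_1d()` uses all probes and one dimension, oriented so
the tumor group sits on the positive side. Numerical conventions: negative
eigenvalues (inverse-MI dissimilarities need not be Euclidean) are clamped
to zero with a warning; each dimension is reflected so its largest-magnitude
coordinate is positive, making output deterministic; a zero-MI pair aborts
construction rather than being capped, because any finite stand-in distance
would be an invention.

## Differential expression and the core biomarker rule

Single-probe contrasts use a moderated two-sample t statistic: per-probe
pooled variances $s_g^2$ (df $d_g$) are shrunk toward a prior $s_0^2$ with
prior df $d_0$ estimated by moment matching on $\log s_g^2$ (mean and
variance of a log-F distribution; $d_0$ via the inverse trigamma). The
posterior variance $(d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ enters the t
statistic, whose df is $d_g + d_0$ capped at the pooled residual df; when
the observed log-variances show no excess dispersion beyond chi-square
sampling noise, $d_0 = \infty$ and the common variance is estimated by the
mean sample variance. p-values are Benjamini–Hochberg adjusted within each
contrast. The machinery is implemented from these defining formulas because
the biomarker selection rule sits directly on it and must be self-contained;
a Welch t option serves as an internal cross-check, and the test suite
verifies the implementation against an independent reference implementation
of the moderated t.

The core rule reduces significant signatures to core biomarker genes: a
candidate gene (member of a significant signature) is core when at least one
of its probes is significant (adjusted $p < 10^{-4}$) in both
normal-vs-tumor and redirected-vs-tumor while not significant in
normal-vs-redirected, and none of its probes is significant in
normal-vs-redirected. This "any-qualifying, none-contradicting" collapse is
a design choice — the probe→gene direction of the rule is genuinely open —
chosen so that a single discordant probe cannot both qualify and disqualify
a gene.

## Interaction-based extension

Each significant signature is extended by its one-hop neighbors in a
user-supplied interaction table (genetic, physical, or co-expression edges;
a local stand-in for an online interaction service, whose internal
significance filter is not reproducible offline). A neighbor is added when
at least one of its probes passes both tumor-contrast gates at the chosen
stringency; extension never removes original members, and a stricter
stringency can only shrink the added set. `extension_sweep()` rescores
original and extended signatures under one configuration and reports
per-(signature, stringency) rows with an `improved` flag.

## What the synthetic generator emulates

`simulate_bundle()` produces the whole input bundle — expression matrix with
design, GMT database, probe-gene map, interaction table — from one seeded
stream, with ground truth. Its defaults are the study conditions the
package is tested under:

* six groups × 3 replicates, 2,000 probes, values truncated to
  [3.582, 14.052] log2 units;
* per-probe baseline means from a two-component Gaussian mixture (components
  at the low/high thirds of the range, sd 1.0, weight 0.5), giving the
  weakly bimodal pooled distributions of normal/redirected groups;
* in tumor-like groups (B, F) unplanted high-mode probes drift down by half
  the inter-mode gap, merging the pooled distribution into a single peak —
  the "highly expressed genes shift to a lower state" picture — while
  preserving the probe-to-probe correspondence with normal columns, so null
  signatures keep ratios near 1;
* planted signatures (5 × 50 genes, drawn from high-mode genes) instead
  receive a mean-preserving, variance-shrunk (factor 0.5) permutation of
  their member means minus a 3.0 log2 planted effect in tumor-like groups.
  The permutation is the essential device: a constant shift would leave MI
  unchanged, whereas scrambling destroys the tumor-normal correspondence
  exactly for planted members, and mean preservation keeps the realized
  shift at −3.0 independent of the draw;
* intermediate groups C, D interpolate all tumor effects at 0.5 without
  scrambling; replicate noise is i.i.d. Gaussian, sd 0.3;
* per planted signature, 3 extension genes outside the database carry the
  same tumor treatment and are wired to members in the interaction table,
  with low-mode decoy neighbors that must fail the DE gates.

Effect sizes and noise levels are the generator's own realistic choices (a
3 log2-unit shift with 0.3 replicate noise is a strong but unremarkable
microarray effect); the source study reports no magnitudes for them. The
generator does not emulate probe-level array artifacts (background,
cross-hybridization), probe-level variance heterogeneity within genes,
correlated noise between replicates, or realistic signature overlap
structure; passing tests therefore demonstrate correctness and calibration
of the machinery under the declared generative model, not performance on any
particular real data set.

A bimodality diagnostic (`bimodality_score()`, a per-observation
log-likelihood-ratio of a two-component Gaussian mixture fitted by a small
deterministic EM against a single Gaussian) verifies the generated shape
contrast; constant input returns the defined minimal score 0.

## Problem sizes and numerical choices

The package's own verification uses 2,000 probes, 200 null + 5 planted
signatures, and 20 simulation repeats for the recovery, calibration, and
extension summaries (smaller 400-probe bundles for unit tests); at these
sizes a full simulate–screen–embed–DE–core–extend pass takes about a second.
Other numerical conventions collected in one place: MI is clamped at 0
against floating-point residue; entropy uses $0 \log 0 = 0$; discretization
boundary values fall in the right-closed last bin (fixed-bin scheme);
degenerate null distributions (all ratios equal) produce no significant
calls rather than an error; ties in the ranked screen output are broken
lexicographically by signature name; the inverse trigamma is solved by
Newton iteration.

## Limitations

* The per-test threshold and ratio cutoff inherit the Gaussian-tail
  reconstruction; with a heavy-tailed true null the screen is anticonservative
  in the extreme tail. The planted/null separation the package verifies is
  rank-based and does not depend on the tail model.
* The screen treats the three roles (normal, redirected, tumor) as given;
  intermediate groups never enter filtering.
* All inputs are assumed RMA-normalized, log2-transformed upstream; the
  package performs no normalization and no probe summarization.
* Extension trusts the supplied edge list; no edge-significance model is
  applied beyond the optional weight floor.
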