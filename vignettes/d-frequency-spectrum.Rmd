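---
title: "Methods: the D frequency spectrum and its simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the D frequency spectrum and its simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfspectrum)
```

## The statistic

Consider four populations related as (((P1, P2), P3), O), with O an outgroup
used only to orient alleles as ancestral/derived. At a biallelic site with
derived-allele frequencies $p_1, p_2, p_3$ (the outgroup fixed ancestral),
the expected weights of the two informative patterns are

$$C_\mathrm{ABBA} = (1 - p_1)\,p_2\,p_3, \qquad
  C_\mathrm{BABA} = p_1\,(1 - p_2)\,p_3,$$

and the D-statistic over a set of sites is

$$D = \frac{\sum C_\mathrm{ABBA} - \sum C_\mathrm{BABA}}
           {\sum C_\mathrm{ABBA} + \sum C_\mathrm{BABA}}.$$

Under the null of no gene flow (any amount of incomplete lineage sorting,
any population-size history shared by P1 and P2), ABBA and BABA are equally
likely and $E[D] = 0$. A nonzero $D$ indicates excess derived-allele sharing
between P3 and one of P1/P2 — but it says nothing about *when* the excess
arose, and some non-introgression histories (e.g. a bottleneck in one
ingroup, or structure in the common ancestor) distort the site patterns in
ways that an aggregate $D$ either hides or mimics.

The **D frequency spectrum** stratifies the same sums by the derived-allele
count of the "B-sharing" ingroup population: an ABBA site with $k$ derived
copies in P2 contributes to bin $k$, a BABA site with $k$ derived copies in
P1 contributes to bin $k$ (with $n$ haploid copies sampled per ingroup
population, $k = 1, \dots, n$; $k = 0$ sites carry no pattern weight by
construction). Each bin reports

$$D_k = \frac{A_k - B_k}{A_k + B_k}, \qquad
  w_k = \frac{A_k + B_k}{\sum_j (A_j + B_j)},$$

where $A_k, B_k$ are the binned ABBA/BABA mass. Two exact identities hold
and are enforced to $10^{-12}$ in the test suite: $\sum_k w_k = 1$ and
$\sum_k w_k D_k = D$. A bin with no mass has an *undefined* $D_k$ (reported
as `NA`, never 0) and $w_k = 0$.

The interpretive value is that the *time* of gene flow leaves a frequency
signature: recent introgression piles excess sharing into low-frequency
bins, older flow shifts it toward higher frequencies, and confounders have
their own shapes (a bottleneck in P2 produces negative low bins balanced by
a positive top bin with $D \approx 0$ overall; ancestral structure produces
positive intermediate/high bins with near-zero low bins).

## Computing the spectrum

`dfs()` consumes a polarized joint site frequency spectrum — a
$(n_1{+}1) \times (n_2{+}1) \times (n_3{+}1)$ tensor of site counts indexed
by derived-allele counts — and performs the binned sums as tensor
contractions. Two input routes are provided:

* `read_sfs()` reads the dadi/moments plain-text format (shape line with
  `unfolded`, flattened counts in C order, optional mask line). A 4-D
  spectrum including an outgroup axis is polarized by `polarize_sfs()`:
  outgroup-ancestral slices are kept, outgroup-fixed-derived slices are
  flipped on all three ingroup axes, outgroup-polymorphic cells are
  discarded (and accounted for).
* `dfs_from_vcf()` reads a VCF and a sample→population map, counts allele
  copies from GT strings (any ploidy; `.` and `*` are missing), filters
  non-SNPs, non-biallelic sites, and sites below a call-fraction threshold
  (default 0.8), polarizes against the outgroup sample(s) (sites where the
  outgroup is polymorphic or uncalled are discarded), and bins sites into a
  spectrum at a fixed target sample size.

Unequal or incomplete sampling is handled by exact hypergeometric
projection (`project_sfs()`): a cell with $i$ derived of $n$ sampled copies
is spread over counts $c$ of a smaller target $m$ with weight
$\binom{i}{c}\binom{n-i}{m-c}/\binom{n}{m}$, computed with `stats::dhyper`.
Projection conserves mass and commutes with scaling; `dfs()` requires
$n_1 = n_2$ (the bins must align) and projects the larger ingroup down
automatically if needed. Per-site missing data uses the same weights
(`missing = "project"`), or drops incomplete sites (`missing = "drop"`).

Uncertainty comes from a site-level bootstrap (`dfs_bootstrap()`):
multinomial resampling of sites over the SFS cells, holding the total count
fixed, recomputing $D$ and every $D_k$ per replicate. This treats sites as
unlinked — appropriate for the simulator output below; for dense genomic
data with linkage, a block resampling scheme would be needed and is out of
scope here.

## The simulator

`simulate_joint_sfs()` is a Monte Carlo structured-coalescent generator of
*unlinked* sites: each site gets an independent genealogy, one mutation, and
one SFS cell increment.

**Model.** Time runs backward in units of $2N_\mathrm{ref}$ generations.
A `demographic_model` holds: per-population relative sizes $\nu$ (piecewise
constant; pairwise coalescence rate $1/\nu$), merge events (population A's
lineages join population B at time $t$), and migration epochs. Migration is
specified forward in time as $M = 2Nm$ from a donor into a recipient; in
the backward process this is the per-lineage rate at which a lineage
currently in the *recipient* jumps into the donor pool, because a lineage
sampled in the recipient traces its ancestry to the donor at the rate
forward migrants arrive. The engine precomputes breakpoints (merge times,
epoch edges, size changes) and runs a standard exponential race within each
interval — total rate $\sum_p \binom{k_p}{2}/\nu_p + \sum_e k_{\mathrm{dest}(e)} M_e$ —
choosing a coalescence or a migration, executing merges at breakpoints.

**Mutation placement.** With genealogy in hand, one mutation is placed
uniformly at random on total branch length, optionally restricted to the
parts of branches inside a *mutation window* $[a, b)$ (used by the
ancient-mutations-only scenario, window $[t_{123}, \infty)$). Genealogies
with zero branch length inside the window are redrawn; the redraw count is
returned as the `resampled` attribute. The derived-allele counts of the
subtended leaves in the three sampled populations index the SFS cell. No
outgroup is simulated: the spectrum is polarized by construction, emulating
an analysis with a perfect outgroup.

**Presets.** `presets()` names the scenarios used throughout. The shared
topology is $t_{12} = 0.5$, $t_{123} = 1.0$, $\nu = 1$ everywhere unless a
scenario says otherwise — round values in coalescent units chosen as
package defaults so that ILS is substantial (splits well under $2N$
generations apart) and signatures are visible at modest sample sizes.
Gene-flow windows: recent $[0, 0.1]$, old $[0.2, 0.3]$, ancient
$[0.4, 0.5]$ (just before $t_{12}$); rates $M$ of 0.5–3 depending on the
scenario; bottleneck: $\nu = 0.05$ for 0.05 time units in P2. The
ancestral-structure scenario is the one place defaults were chosen by
mechanism rather than round numbers: the ancestor of all three populations
is split into two demes exchanging migrants at $M = 1$ from $t_{12} = 0.1$
back to $t_{\mathrm{end}} = 4.0$, with P3 branching from one deme at
$t_{123} = 1.0$. Moderate deme exchange lets once-common declining alleles
equilibrate across demes (so low-frequency bins show no asymmetry) while
the recent P1/P2 split leaves no time for post-split drift to refill low
bins — producing the characteristic near-zero low bins with positive
intermediate/high bins. Longer post-split histories or weaker deme exchange
wash out or invert that shape.

**Determinism.** All engine randomness flows from one
`std::mt19937_64` stream seeded (via `seed_seq`) from two values derived
from the user's seed; a run is a pure function of (model, samples, sites,
seed). There is no parallel mode. `dfs_grid()` derives one sub-seed per
grid row from the master seed.

## Numerical choices

* The decomposition and weight identities are exact in exact arithmetic;
  tests enforce them at $10^{-12}$ to allow floating-point summation error.
* Undefined bins are `NA`, excluded from plots, written as empty fields in
  the TSV export, and re-read as `NA`.
* Projection uses `dhyper` directly rather than factorials, for stability at
  larger sample sizes.
* Bootstrap standard errors use 100 replicates by default — enough for the
  3-SE significance convention used throughout; raise `n_boot` for finer
  quantiles.

## A worked run

```{r example}
model <- presets("fig2a_recent_geneflow")
sfs <- simulate_joint_sfs(model, samples = c(8, 8, 8),
                          n_sites = 2e4, seed = 1)
res <- dfs(sfs)
res
glance(res)
```

```{r plot, fig.width = 5, fig.height = 3.5}
autoplot(res)
```

Recent P3→P2 flow concentrates positive $D_k$ at low $k$ with a negative
top bin — the signature that distinguishes it from old flow (signal shifted
toward high $k$) and from confounders with $D \approx 0$ overall.

## Limitations

* Sites are unlinked by construction; the simulator makes no attempt at
  recombination along chromosomes, and the bootstrap assumes exchangeable
  sites. No block-jackknife is provided.
* Scenario presets are calibrated qualitatively (shape of the spectrum),
  not to any empirical system.
* The outgroup is assumed informative: polarization discards sites where it
  is polymorphic or uncalled rather than modelling ancestral-state error.
* A mutation window far above any plausible TMRCA makes the rejection
  sampler slow; the windows reachable through presets are all benign.
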