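---
title: "From ASV tables to predicted metabolic reaction capacity: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From ASV tables to predicted metabolic reaction capacity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reactocap)
```

## The analysis model

`reactocap` covers the downstream arc of a multi-diet amplicon study of a
host gut community (the motivating setting is Atlantic salmon fed
fishmeal, soybean-meal and yeast-based diets, but nothing in the code is
host-specific). The pipeline has two halves.

**Community structure.** Counts are treated as compositional. After
taxonomy- and prevalence-based filtering, the package computes relative
abundances, genus-or-lowest-rank aggregates, core ASVs by prevalence,
compartment overlap by a presence threshold, four alpha indices and four
beta-diversity distances, with PERMANOVA and PERMDISP permutation tests
on the distances and PCoA for ordination.

**Predicted metabolic capacity.** Each ASV is matched to a collection of
genome-scale metabolic models (GSMMs) at its lowest assigned rank among
species, genus and family. Writing $E(i,j)$ for the fraction of ASV $j$'s
models containing reaction $i$, the per-sample normalized reaction
abundance is

$$a_r(i) = \frac{\sum_j a_{\mathrm{ASV}}(j)\,E(i,j)}
                {\sum_j a_{\mathrm{ASV}}(j)},$$

with both sums over the *mapped* ASVs. $a_r(i)$ is a probability-weighted
community fraction, so it is bounded by the smallest and largest
contributing $E(i,j)$ and is invariant to sequencing depth. Reactions are
compared between diet pairs with two-sample t-tests and BH correction;
subsystems (pathways) are then tested for over-representation among the
significantly different reactions, separately for each direction of
change, with one-sided Fisher's exact tests.

### Assumptions worth stating

- Taxonomic identity is an adequate proxy for gene content at the rank
  where the ASV maps. Family-level matches average over very diverse
  genomes; $E(i,j)$ quantifies that uncertainty but cannot remove it.
- The mapped sub-community represents the whole community's metabolic
  potential. The default denominator excludes unmapped ASVs (for which
  $E$ is undefined); `denominator = "all"` exposes the literal
  all-ASV reading for sensitivity analysis — it shrinks every $a_r$
  toward 0 by the unmapped mass.
- t-tests on $a_r$ assume approximate normality within diet groups;
  $a_r$ is an average of many bounded terms, which in practice makes it
  much better behaved than raw counts.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| rarefaction depth | 1,604 | reads | the study protocol's minimum library size; applied only to Jaccard and unweighted UniFrac |
| core prevalence | 0.80 | fraction of samples | the protocol's core-microbiota definition |
| overlap presence | 0.0005 | relative abundance | 0.05% floor for an ASV to count as present in a compartment |
| prevalence filter | 3 | samples | ASVs in fewer biological samples are removed |
| permutations | 999 | — | PERMANOVA/PERMDISP; with the (1+b)/(1+n) convention the minimum p is 0.001 |
| CLR/PhILR pseudocount | 1 | counts | the most common convention; the analysis is silent on it, so it is a flag |
| group-test threshold | adjusted p < 0.05 | — | strict inequality for Kruskal–Wallis/Wilcoxon calls |
| reaction/subsystem threshold | adjusted p ≤ 0.05 | — | inclusive, as used for the capacity analysis |

Shannon entropy is in nats so that Pielou's evenness is exactly
$H/\ln S$. Faith's PD uses the rooted convention (the path to the root is
included); a sample containing a single tip therefore has PD equal to its
root-to-tip path length, not zero.

## What the synthetic generator emulates — and what it does not

`simulate_community()` draws one baseline composition from a symmetric
Dirichlet (concentration 0.5 over 60 ASVs by default, giving realistically
uneven communities), applies group "dominance" effects as deterministic
mass reallocation (a designated ASV set to, say, 0.9 of the composition —
the single-taxon dominance seen in fermented-feed diets), perturbs the
group composition per sample with a Dirichlet of concentration
$\theta = 200$, and draws counts as a multinomial at a log-normal library
size (log-mean 10, log-sd 1, spanning roughly 1.6k–180k reads like the
motivating dataset). Because the effect is a deterministic reallocation,
the planted effect size is exact in expectation, which is what makes the
recovery tests sharp. Taxonomy is generated tree-consistently: the random
bifurcating tree is built by binary merging within genera first, so
genus-level clades are monophyletic and Faith's PD/UniFrac never
contradict the taxonomy. Lineages are truncated at genus or family with
probability 0.25, and species names are present for 15% of ASVs,
mirroring the fraction typically resolvable from V3–V4 amplicons.

`simulate_gsmm_collection()` gives every mapped taxon a fixed number of
models containing a shared core (30% of reactions) plus accessory
reactions at probability 0.3; models of one designated taxon include the
reactions of a designated subsystem with probability raised by the
signature strength. `unmapped_taxon_frac` leaves a fraction of taxa with
no models, exercising the exclusion path.

The generator does **not** emulate sequencing error, chimeras,
contamination, batch effects between runs, or phylogenetic signal in
reaction content beyond the single planted taxon. A green end-to-end test
therefore establishes that the *statistical machinery* recovers a planted
functional signal at realistic depths and group sizes — not that any
particular biological claim is true, and not that real GSMM collections
are accurate.

## Numerical choices

- **Permutation p-values** use $(1+b)/(1+n_{\mathrm{perm}})$ and an
  observed-statistic comparison with a $10^{-12}$ slack so ties count as
  exceedances; p can never be 0.
- **PERMDISP** embeds by PCoA, discards axes with negative eigenvalues
  (the count is reported), and measures distances to the group *spatial
  median* computed by Weiszfeld iteration (tolerance $10^{-9}$, guarded
  against points landing on the median).
- **Wilcoxon tests** are exact by subset enumeration when both groups
  have ≤ 8 observations (ties handled by enumerating the actual pooled
  ranks), otherwise a tie-corrected normal approximation with continuity
  correction.
- **BH** is the step-up rule implemented directly (sort, scale by
  $m/\mathrm{rank}$, cumulative minimum from the top, cap at 1).
- **Aitchison/PhILR** add a pseudocount of 1 before closure. This breaks
  exact scale invariance (the CLR of $x+1$ is not that of $2x+1$), so the
  scale-invariance property is asserted at pseudocount 0 on strictly
  positive data; with the default pseudocount the distances remain
  *approximately* scale-invariant at realistic depths. PhILR uses unit
  taxon and branch weights — with those weights the balances are an
  orthonormal ILR basis, so PhILR distances equal Aitchison distances on
  any bifurcating tree; the tests exploit this isometry as an oracle.
  Multifurcations are resolved with zero-length edges and reported.
- **Rarefaction** subsamples reads without replacement (exact
  multivariate hypergeometric via index sampling); under-depth samples
  are dropped with a warning rather than erroring, because rarefying "to
  the minimum depth" may still exclude samples in simulated data.
- **Degenerate inputs**: all-zero samples are errors everywhere;
  reactions with zero variance in both groups and equal means are
  excluded from testing *and* from the enrichment universe (a
  zero-variance feature has an undefined t and would dilute Fisher's
  margins with uninformative rows).

## Design decisions that were genuinely open

- **Denominator of $a_r$**: "total number of ASVs" is read as the mapped
  ASVs, since only mapped ASVs are included in the reaction analysis and
  $E$ is undefined for the rest; the literal reading is available by
  flag.
- **Enrichment directionality**: the Fisher test is run separately on
  each direction's significant set (higher in diet 1 / higher in diet 2)
  against all remaining tested reactions. This makes the two directions
  symmetric and the signed heat-table antisymmetric under pair
  relabelling, which the tests assert.
- **t-test form**: pooled-variance Student by default — the plain
  reading of "two-sample t-test" — with Welch behind a flag; group sizes
  are equal by design in the motivating study, where the two coincide
  closely.
- **Core prevalence scope**: computed over the supplied sample set, with
  per-group cores and their intersection also reported, since the study
  presents both a pooled count and a per-diet Venn diagram and the text
  does not disambiguate.
- **Alpha diversity input**: computed on the table as given; the
  protocol prescribes rarefaction only for Jaccard/UniFrac, so rarefying
  before the alpha indices is the caller's choice (the CLI exposes
  `--rarefy`).
- **Taxon matching is exact** (case-sensitive, whitespace-trimmed).
  Fuzzy matching would silently change results between runs of the same
  data and is deliberately absent.

## Known limitations

- Family-level model averaging can make $E$ nearly uniform across ASVs
  of the same family, deflating between-sample variance in $a_r$.
- The enrichment test conditions on the BH-significant set; with very
  many significant reactions (as in strong planted runs) the Fisher
  margins are dominated by the significant row, and power comes from the
  subsystem's concentration in one direction.
- PERMDISP with discarded imaginary axes slightly underestimates
  dispersion for strongly non-Euclidean distances (Jaccard/UniFrac);
  the discarded count is reported so users can judge severity.
- The synthetic tree has exponential branch lengths with no clock or
  rate model; phylogenetic alpha/beta values are internally consistent
  but not calibrated to real 16S divergence.
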