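---
title: "Prioritizing candidate driver genes in small leukemia cohorts"
author: "CoMutNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing candidate driver genes in small leukemia cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CoMutNet)
```

## The problem

Acute promyelocytic leukemia (APL) is defined by the *PML/RARA* fusion, but
the fusion alone does not produce the leukemic phenotype: cooperating
somatic mutations are spread thinly over many genes, mostly non-recurrent,
so cohort sizes reachable in a rare disease (tens of patients) give little
power for classical per-gene recurrence tests. CoMutNet implements the
analysis strategy appropriate to that regime: filter variants to a
high-confidence somatic set with an auditable cascade, test per-gene
carrier frequencies against a large reference population, look for
*combinations* — co-occurring mutations and functional-category burden —
and finally ask whether the recurrently mutated genes sit unusually close
to each other in the protein–protein interactome. A gene that is both
recurrence-enriched and embedded in a significantly connected subnetwork
is a far stronger driver candidate than either signal alone supports.

Every stage consumes and produces plain interoperable formats (VCF, TSV,
SIF/GraphML), and a synthetic-data generator with planted truth makes the
whole pipeline testable offline.

## The filter cascade

`runCascade()` applies seven stages in fixed order, recording per-patient
surviving counts in a `FilterAudit`:

1. **Detected** — all calls in the diagnostic sample.
2. **Somatic** — population-database screen: calls with a catalogued
   carrier frequency at or above `max_pop_freq` (default 1%) are treated
   as germline. In *unmatched* mode this stage is the full germinality
   test: additionally, calls whose variant allele fraction (VAF) falls in
   a germline band — heterozygous `[0.45, 0.55]` or homozygous
   `[0.95, 1]` by default — are removed. Calls with no catalogued
   frequency are kept: a novel variant is exactly what a somatic screen
   must not discard.
3. **AbsentInCR** — matched mode only: subtraction of the
   complete-remission (CR) sample, the patient's germline proxy.
   "Absent" is thresholded (at most 1 supporting read *and* VAF < 0.02 by
   default) rather than literal zero, because at ~60x exome coverage a
   single stray read is expected noise. Variant identity is
   `(chrom, pos, ref, alt)` after reference-free parsimony trimming of
   shared allele padding; full left-alignment would need the reference
   genome, which this pipeline deliberately does not consume.
4. **HighQuality** — site filters: depth ≥ 10 (the
   covered-by-ten-reads convention; configurable), call quality ≥ 30,
   strand-bias probability ≤ 0.9, VAF ≥ 0.05.
5. **Coding** — consequence classes {nonsynonymous, stop gain,
   frameshift, in-frame indel, splice site}.
6. **Deleterious** — the upstream annotation flag, with truncating and
   splice-disrupting consequences deleterious unconditionally.
   Deleteriousness is consumed, never computed: predictors are external
   tools with their own validation.
7. **UnknownInDbSNP** — removal of catalogued (known) variants.

Each stage output is a subset of its input, so audit rows are
non-increasing — a property the tests exercise on random cohorts. The
high-quality thresholds are package defaults, not reconstructions of any
particular study's (unpublished) settings; all are exposed in
`cascadeConfig()`.

Two summary conventions worth noting: `tiTvRatio()` counts transitions
strand-symmetrically (C>T and G>A are the same event), and
`toMutationMatrix()` lets gene-level diagnostic events (fusion partners,
FLT3-ITD) enter the binary matrix alongside point mutations, because the
downstream network analysis treats them as first-class lesions.

## Recurrence enrichment

For gene $g$ carried by $k$ of $n$ cohort patients, with reference carrier
frequency $f_0$ in a population of $N_{\mathrm{ref}}$ individuals
(default 2504), `screenCohort()` computes the one-sided exact binomial
tail

$$p = P(X \ge k), \qquad X \sim \mathrm{Binomial}(n, \max(f_0,
\tfrac{1}{N_{\mathrm{ref}}+1})).$$

The binomial is the minimal model consistent with asking whether the
cohort frequency exceeds the population expectation; a two-proportion
Fisher variant (`method = "fisher"`) is provided for sensitivity
analysis. The zero-frequency floor $1/(N_{\mathrm{ref}}+1)$ — the largest
frequency compatible with observing zero carriers among
$N_{\mathrm{ref}}$ — prevents degenerate $p = 0$ for genes absent from
the reference. Raw-p thresholding at $\alpha$ is the default decision
rule (matching how small-cohort screens are usually reported);
Benjamini–Hochberg q-values are always emitted alongside for modern use.
Reference frequencies are carrier (per-individual) frequencies; tables in
percent are converted at parse time based on the header unit token, never
on magnitude.

```{r screen}
apl <- aplEnrichedGenes()
screen <- screenCohort(aplCohortMatrix(), apl$ref, alpha = 0.05)
head(screen[, c("gene", "k", "f0_used", "p_value", "significant")])
```

## Co-occurrence networks

`buildCooccurrenceNetwork()` tests every unordered gene pair (both genes
mutated in ≥ 1 patient) on its 2×2 patient table with the chi-square test
of independence, one degree of freedom, **no** continuity correction:
with $n = 25$ a Yates correction would materially change which pairs
reach $p \le 0.05$, and the statistic then obeys the exact identity
$\chi^2 = n\varphi^2$ used as a regression oracle in the tests. When any
margin is zero the statistic is 0 and $p = 1$. Fisher's exact test is
available both as an option and as the small-count cross-check. Edges
with $p \le \alpha$ are kept, annotated with the joint carrier count
(edge label), direction (above/below the independence expectation
$n p_1 p_2$), and BH q-values; nodes carry their significant-degree.

A subtlety worth stating: at these sample sizes the chi-square's exact
size is slightly *below* nominal (enumerable as 0.046 at $n = 25$,
carrier rate 0.2), because 2×2 tables are discrete. The calibration tests
therefore compare the simulated type-I rate against the enumerated exact
size, and additionally verify it never exceeds $\alpha$ beyond
Monte-Carlo noise.

## Functional categories

`assignCategories()` lifts the gene matrix to a patient × category matrix
under a user-supplied gene→category map (live ontology lookups are
deliberately out of scope — they are irreproducible). Multi-label genes
count once per label; this inflates cross-category co-mutation, which is
why `categoryExcess()` offers a patient-preserving gene-label permutation
null (1000 shuffles by default) beside the default gene-count-share
binomial margin test: hit-events are modelled as multinomial over
categories with probabilities proportional to category gene counts, and
each category is tested one-sided against its share.
`categoryVsReference()` compares per-category mutation rates against a
reference population with two-proportion tests in both directions, and
`categoryComutation()` reuses the pairwise chi-square machinery on
category columns.

## Minimal connected network analysis

`buildMCN()` maps a seed gene set (the recurrently mutated genes plus
known disease genes) onto an undirected interactome and retains

* every edge between two seeds, and
* every non-seed node adjacent to ≥ 2 seeds of which some pair lacks a
  direct edge — a *single intermediate* on a length-2 path — together
  with its seed-incident edges.

Optional minimality pruning removes intermediates without changing how
the seeds partition into connected components. The pruned set is found by
exact search over connector subsets in increasing size (lexicographic
tie-break, so construction is deterministic and order-invariant); a
greedy most-redundant-first pass takes over above 20 intermediates per
component. Pruning cannot change the seed-component partition, so it is
off by default in the statistics path.

Significance comes from a resampling null (`sampleNull()`): M random seed
sets of the same size — uniform over interactome nodes by default, or
matched to the observed seeds' degree bins, since uniform nulls overstate
significance for high-degree seeds — each scored by the same
construction, with the add-one empirical p-value
$(1 + \#\{\text{null} \ge \text{obs}\})/(M+1)$. Three statistics are
computed: `connected_seed_count` (seeds in components of size ≥ 2; the
primary report statistic), `components` (fewer = more connected; the
comparison reverses), and `mean_seed_degree` (mean seed degree within the
MCN). The statistics differ in resolution: `connected_seed_count` takes
a handful of integer values on sparse graphs, which makes its p-value
distribution strongly atomic; `mean_seed_degree` is nearly continuous.
Calibration checks (p-values uniform when seeds are drawn from the null
itself) therefore use `mean_seed_degree`; a KS uniformity test on the
atomic statistic would reject for any correct implementation, which is a
property of the statistic, not of the sampler.

`prioritizeCandidates()` finally intersects the signals: candidates are
seeds lying in an MCN component of size ≥ 2, given a globally significant
MCN, that are also enrichment-significant — sorted by enrichment p-value
and annotated with their co-occurrence significant-degree.
Enrichment-significant genes absent from the interactome are reported
separately rather than silently dropped.

```{r mcn}
g <- generateInteractome(interactomeSpec(
  n_nodes = 50, background_p = 0.03,
  node_names = c("PTPN11", "PML", "STAT1", sprintf("N%02d", 1:47)),
  seed = 1))
g <- igraph::add_edges(g, c("PTPN11", "STAT1", "STAT1", "PML"))
buildMCN(c("PTPN11", "PML"), igraph::simplify(g))
```

## What the synthetic generator emulates

`generateCohort()` draws independent Bernoulli gene columns (default: 25
patients × 72 genes, background carrier rate 0.08 — the scale and
recurrence range of a targeted-resequencing APL cohort), with planted
enriched genes (multiplied rates) and planted co-occurring pairs realized
by *forcing* joint carriers in a chosen number of patients, so the
truth value of the joint count is exact rather than distributional.
`generateInteractome()` overlays a dense planted module (default
within-module edge probability 0.8) on an Erdős–Rényi background
(default 300 nodes, edge probability 0.01).
`generateVariantFixtures()` writes matched diagnosis/remission VCF pairs
in which every variant carries a truth tag naming the stage that must
remove it; each planted failure violates exactly one stage's predicate
and passes all earlier ones, so the cascade audit must reproduce the
planted counts exactly. `generateUnmatchedCalls()` emulates a
panel-sequenced cohort without germline controls: 30% germline calls of
which 85% are catalogued above 1% population frequency (most germline
variation is common and known), heterozygous VAF binomial around 0.5 at
~220x panel coverage, 20% homozygous near 1.

What the generator does **not** emulate: mutational signatures, subclonal
VAF structure, read-level artifacts, linkage between genes, and the
scale-free degree structure of real interactomes. Passing tests on
planted data therefore demonstrate correctness of the statistics and
recovery at the stated effect sizes — not performance on real cohorts,
where coverage heterogeneity and annotation error dominate.

## Validation design and problem sizes

The test-suite validation scenarios are fixed as follows, chosen once as
realistic for the cohort scale the package targets:

* **Oracle equivalence.** Binomial tails against log-space direct
  summation over a $(k, n \le 50, p_0)$ grid at $10^{-10}$ relative
  tolerance; $\chi^2 = n\varphi^2$ on random tables; MCN pruning against
  exhaustive connector-subset search on 200 random graphs of ≤ 12 nodes.
* **Calibration.** 500 independent null cohorts (50 genes, $n = 25$,
  rate 0.2) for the co-occurrence type-I rate, compared to the
  enumerated exact size; 500 repetitions of null-drawn seed sets
  ($M = 99$, 12 seeds, 300-node background-0.03 interactome) for KS
  uniformity of the `mean_seed_degree` empirical p-value.
* **Recovery.** Planted enrichment at carrier rate 0.2 vs reference 0.01
  ($n = 25$; power ≥ 0.8 over 200 simulations, null false-positive rate
  ≤ 2α); forced pairs with joint counts 2 and 3 on low-carrier genes;
  and a full planted-module scenario — 8 driver genes at carrier rate
  0.3 (the upper recurrence range observed in APL cohorts) forming a
  dense interactome module, 42 passengers at the population rate —
  prioritized at the strict α = 0.01 that small-cohort candidate lists
  are reported at, requiring exact recovery of the planted set in ≥ 80%
  of 100 simulations.

Numerical conventions: p-values never reported as exactly zero (add-one
convention for resampling; the reference-frequency floor for the
binomial); ties in all orderings broken by gene symbol; every writer
emits one header line, tab delimiters, `.` decimal, and provenance
comments (config hash + RNG seed), so reruns at a fixed seed are
byte-identical.

## Known limitations

* The binomial screen treats the reference frequency as known; for genes
  estimated from small reference panels the Fisher option is the more
  honest comparison.
* Chi-square co-occurrence at $n = 25$ is slightly conservative
  (exact size 0.046 at nominal 0.05) and loses calibration entirely for
  margins of 1; the Fisher method is the fallback there.
* The uniform MCN null overstates significance for high-degree seed
  sets; degree-matched mode mitigates but bins coarsely (powers of two).
* Reference-free parsimony cannot canonicalize every equivalent padded
  indel representation the way reference-aware left-alignment can;
  calls from a single consistent caller are unaffected.
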