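---
title: "Models and methods behind omicsfunnel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind omicsfunnel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omicsfunnel)
```

omicsfunnel implements an integrative case-control strategy for separating
disease-causing variants ("putative mutations") from variants that act only
through interactions with other variants ("putative effect modifiers"), and
for prioritising the pathways they sit in. The pipeline chains a
transcriptome-level significance filter, pathway over-representation, a
cross-case variant intersection, verification-cohort rules, a chi-square
association battery, linkage-disequilibrium estimation and hub-gene ranking.
This vignette documents the statistical models, the tunable parameters, the
synthetic-cohort generator that the test suite exercises, and the design
decisions taken where the method left genuine freedom.

## Differential expression filter

The expression arm consumes a per-gene differential-expression table (FPKM in
cases and controls, a log2 expression ratio, a test statistic, p and
BH-adjusted q, and a status code). The filter retains a gene iff `q < q_max`
(strictly; a gene at exactly the threshold is dropped) and, by default, the
status is `OK` — the `LOWDATA` (too few reads), `HIDATA` (too many fragments
in a locus) and `FAIL` (test did not run) codes mark genes whose test output
is not trustworthy. Defaults: `q_max = 0.05`.

The ratio `log2(FPKM_case / FPKM_control)` is kept as stated, including its
degenerate cases: a transcript expressed in cases but absent from controls
yields `+Inf` with a `case_only` flag rather than being silently dropped,
because case-only expression is itself a finding (e.g. an intronic microRNA
detected only in the disease group).

## Pathway over-representation

Enrichment of the retained genes against each pathway gene set is the
right-tailed hypergeometric (one-sided Fisher) test:
$P(X \ge x)$ where $x$ is the observed overlap, with `pathway_size` draws
from a universe containing `query_size` successes. Choices worth noting:

* **Universe.** The background defaults to the genes actually testable in
  the experiment (status-`OK` genes of the DE table), not the genome.
  Commercial pathway suites keep their background private; an
  experiment-derived universe is reproducible and conservative.
* **No multiple-testing correction on pathways.** Significance is called on
  raw p at `alpha_pathway = 0.05` (−log10 p ≥ 1.301), matching the practice
  of the pathway tools this step stands in for; a BH-adjusted column is
  reported alongside so readers can apply a stricter rule.
* Results are sorted by ascending p with ties broken by pathway name, so
  reports are byte-stable.

## The integration funnel

Variants called in the discovery cases are intersected on their locus key
(chromosome, position, ref, alt) — *presence* is intersected, not genotype;
genotypes are analysed later by the association battery. Quality
stratification then requires every non-missing discovery call to satisfy
`GQ >= 20` and `DP >= 10` (configurable; calls without the annotations pass
by default, because a missing annotation is not evidence of poor quality).
A candidate is emitted for every intersected variant whose annotated gene
both survived the DE filter and belongs to at least one significant pathway.

The funnel report counts: total → intersection → dbSNP-known (rsID present)
→ in DE genes, and then two *parallel* refinements of the in-DE set — rare
(population MAF < `rare_maf = 0.01`) and in-significant-pathways. The last
two are siblings rather than nested stages, so only the four-stage prefix is
monotone non-increasing. A variant without a population MAF keeps an
undefined rare flag: unknown frequency is not evidence of commonness.

Verification applies a presence rule over pedigree cohorts and population
controls: a candidate found with the required genotype (`carrier` by
default, `hom_alt` for recessive hypotheses) in at least one member of at
least one case pedigree and in **no** control is a *possible putative
mutation*; found in a pedigree and also in a control it is a *potential
putative effect modifier*; otherwise *unsupported*. "Some members" is
operationalised as ≥ 1 member (`min_carriers`).

## The chi-square battery and classification

All association tests are Pearson chi-square tests computed from first
principles, with Yates' continuity correction on 2×2 tables:
$$X^2 = \sum_{ij} \frac{(|O_{ij} - E_{ij}| - c_{ij})^2}{E_{ij}},
\qquad c_{ij} = \min(0.5,\ |O_{ij} - E_{ij}|),$$
the clamp ensuring a perfectly proportional table scores exactly 0. The
p-value is the upper chi-square tail on $(r-1)(c-1)$ degrees of freedom.
A goodness-of-fit variant ("test for probabilities") compares observed
counts with stated category probabilities on $k - 1$ df. Expected cell
counts below 5 raise a flag in the output but do not switch to an exact
test: the battery reports sparse joint tables (degrees of freedom like 7, 11
or 17 arise from dropping unobserved joint genotype categories) exactly as
the chi-square framework sees them.

Table constructions per variant:

* `carrier` — carrier (dosage ≥ 1) vs non-carrier × disease (2×2);
* `genotype` — observed genotype classes × disease (up to 3×2);
* `stratum` — one focus genotype vs all others × disease (2×2);
* `joint2` — genotype classes of variant A × those of variant B (pooled
  sample; the variant–variant dependence test);
* `joint3` — observed joint (A, B) genotype combinations × disease.

Missing genotypes are excluded pairwise-complete throughout.

**Classification rules.** A variant's *direct family* is the carrier test
plus one stratum test per observed non-reference genotype class (the hom-ref
stratum is the row-swapped carrier table and would duplicate its p-value, so
it is counted once). If the family shows a significant direct association,
the variant is a `putative_mutation`. Otherwise partners are searched: if
for some partner both the `joint2` dependence test and the `joint3`
joint-genotype-by-disease test fall below `alpha_assoc = 0.05`, the variant
is a `putative_effect_modifier`, recording the partner with the smallest
joint-test p. Everything else is `unclassified`. Direct effects take
precedence: a variant that satisfies both sets of conditions is a mutation.

**Why the direct verdict uses BH within the family.** The direct family
contains up to three correlated 2×2 tests. Comparing each to raw alpha
makes the family-wise false "mutation" rate roughly two- to threefold the
nominal level (~0.09–0.11 at n = 500/500 for a common null variant, by
simulation), which would contaminate the modifier search — a modifier is
only reachable when no direct test fires. The default therefore
Benjamini–Hochberg-adjusts the p-values *within each variant's family*
before comparing to alpha, which restores the per-variant false-positive
rate to ≈ 0.04 while leaving the power for genuinely penetrant variants
essentially unchanged (their p-values are many orders below alpha).
`direct_adjust = "none"` switches back to the literal raw-alpha behaviour;
raw and adjusted values are always both reported.

## Linkage disequilibrium

Two-locus haplotype frequencies are estimated from unphased genotypes by
expectation–maximisation over the double-heterozygote phase ambiguity. The
chain starts from linkage-equilibrium frequencies (products of the sample
allele frequencies): a deterministic initialisation that needs no seed and
that leaves the estimator at the symmetric point when the data carry no
phase information (e.g. a cohort of pure double heterozygotes). Iteration
stops when the largest frequency change drops below `tol = 1e-8` (or at
`max_iter = 1000`); the log-likelihood is non-decreasing at every step, and
the test suite asserts it.

From the haplotype frequencies $(f_{AB}, f_{Ab}, f_{aB}, f_{ab})$:
$D = f_{AB} f_{ab} - f_{Ab} f_{aB}$;
$D' = |D| / D_{max}$ with $D_{max} = \min(p_A q_b,\ p_a q_B)$ for $D > 0$
and $\min(p_A q_B,\ p_a q_b)$ otherwise; and
$r^2 = D^2 / (p_A p_a q_B q_b)$. For a monomorphic locus $D'$ and $r^2$ are
reported as *undefined* (NA), not 0, so a degenerate cohort stays visible in
reports instead of masquerading as equilibrium.

## Seed-site scanner

The scanner classifies microRNA target sites in 3′UTRs by the canonical
seed-match taxonomy. With the 6mer *core* defined as the reverse complement
of miRNA positions 2–7, a site on the UTR (5′→3′) is

* `8mer`: m8 complement + core + A,
* `7mer-m8`: m8 complement + core (an exact match to positions 2–8),
* `7mer-1A`: core + A,

where the A at target position 1 is required as a literal adenine in the
UTR — the established convention — rather than as a complement of miRNA
position 1. Each core occurrence reports only its strongest type
(8mer > 7mer-m8 > 7mer-1A); overlapping sites at *different* core offsets
are all reported. Coordinates are 1-based inclusive on the input sequence;
the BED exporter converts to 0-based half-open. U and T are interchangeable
on input; the reported site sequence echoes the input alphabet.

## The synthetic-cohort generator

The generator produces a full study — discovery expression arm (6 cases vs
4 controls, the size of the RNA-seq design it emulates), verification
pedigrees (3 + 5 + 5 cases) with 11 population controls, and a replication
association arm of 500 cases and 500 controls — together with a ground-truth
manifest, so every pipeline stage has a planted-recovery test without any
external downloads.

**Genotypes.** Independent loci are drawn under Hardy–Weinberg equilibrium.
The designated LD pair is drawn by constructing two-locus haplotype
frequencies with a target $D'$ (allele frequencies 0.4/0.3, $D' = 1$ by
default) and sampling two haplotypes per subject; the phased haplotypes are
retained so the EM estimator can be checked against phased truth.

**Penetrance model.** Disease probability is logistic:
$$\mathrm{logit}\,P(D) = \mathrm{logit}(p_0)
 + \log(m)\,\mathbb{1}[\text{mutation genotype}]
 + \log(w)\,\mathbb{1}[\text{both modifiers carried}]
 + h_A(g_A) + h_B(g_B),$$
with baseline $p_0 = 0.1$, a recessive mutation ($m = 6$ for the hom-alt
genotype, allele frequency 0.5) and an interaction multiplier $w = 6$
applied only when both modifier loci (allele frequencies 0.3) are carriers.
Case/control labels are Bernoulli draws followed by rejection sampling until
the quotas are met (case-control ascertainment, as in the real designs the
generator emulates).

The terms $h_A, h_B$ are the *marginal balancing* terms, solved numerically
(fixed-point iteration over the 27-cell effect-locus grid, residual
< 1e-12) so that each modifier locus has exactly flat marginal penetrance.
They matter because an "interaction-only" multiplier is not marginally
silent: under case-control ascertainment, an AND-type interaction induces a
marginal genotype-disease association at each partner locus of the same
order as the joint signal, and a noncentrality scan over the whole
(frequency, effect, baseline) space shows no setting in which the joint
test is powered while the marginals stay undetectable. A variant whose
definition is "no direct association with disease, but its interaction with
a partner is associated" must therefore be *constructed* marginally flat —
the classic pure-epistasis construction — and that is what the balancing
terms do. `balance_modifier_margins = FALSE` restores the raw multiplier
model for readers who want to study the induced marginal association
itself.

**Designed operating characteristics.** The defaults were fixed by a power
analysis before the test suite was written: at n = 500/500, the recessive
mutation's stratum test is expected to fire essentially always; the
modifier pair's joint and dependence tests are expected significant with
probability ≈ 0.99 while all direct-family tests stay null, giving a
designed pair-recovery probability of ≈ 0.9; and a null locus is falsely
labelled a mutation at ≈ 0.04. The acceptance suite measures exactly these
rates over 200 seeded cohorts (thresholds: mutation recovery ≥ 0.95,
pair recovery ≥ 0.80, null rate ≤ 0.05 + 2 Monte-Carlo SE).

**Expression and pathways.** Per-gene log2 FPKM baselines are N(5, 1) with
within-group noise sd 0.35; the 30 planted genes are shifted by
log2(fold change 4) in cases; the per-gene test is a two-sample t-test on
log2(FPKM + 1) with BH adjustment. At these settings the planted effect is
≈ 8–9 within-group standard errors, so the five candidate genes pass the
q-filter with probability ≈ 1 — deliberately high, because the end-to-end
recovery test conditions on the candidates reaching the association stage.
Pathway sets are 10 sets of 20 genes: three *enriched* sets containing the
hub gene (the mutation's gene) and the other candidate genes plus planted
DE genes, and seven null sets drawn from a reserved non-DE pool that is
never assigned to variants — so candidate membership is by construction,
not by accident of sampling. The funnel plantings follow the documented
default counts (100 variants, 40 shared, 38 dbSNP-known, 12 in DE genes, 3
rare); the truth manifest evaluates its expected funnel on the emitted
tables, so the realised BH filter is reflected exactly.

**What the generator does not emulate.** Reads and alignment artefacts
(inputs begin at called genotypes and FPKM tables); LD between the effect
loci and anything else (each planted locus is independent except the
designated pair, whereas real modifier candidates are often discovered
*because* they sit in LD blocks); population stratification and relatedness
within the replication arm; covariates; and gene-gene expression
correlation. Passing the recovery tests therefore demonstrates that the
statistical machinery is correct under its stated model, not that the
thresholds are robust to confounding in real cohorts.

## Determinism and numerical choices

Every simulation is a pure function of its configuration (`withr::with_seed`
around an integer seed; no time, locale or platform dependence). Reports are
written with fixed column orders and fixed float formatting, so identical
inputs give byte-identical files; the provenance block records the
parameters and package version but no timestamps. Pathway ties break by
name; hub ties break by (pathway count, minimal pathway p, gene name);
chi-square degeneracies (a collapsed margin after dropping empty rows or
columns) raise errors naming the margin rather than returning NaN. The EM
tolerance (1e-8 on frequencies) means a cohort in perfect coupling with
double heterozygotes present can report $D'$ a hair below 1; the
no-ambiguity fixtures in the tests recover 1 exactly.

The problem sizes used by the test and acceptance suites — 200 seeded
cohorts of 1 000 subjects for the classification operating characteristics,
100 seeds for LD recovery, 1 000 random tables for the chi-square
cross-check, 100 random UTRs for the scanner — were chosen so the whole
suite completes in a couple of minutes on a single core while keeping every
Monte-Carlo standard error well below the margins being asserted.

## Known limitations

* The classification engine tests marginal and pairwise structures only; a
  three-locus pure interaction with pairwise-null projections would be
  missed by design.
* The modifier search is over candidate pairs at raw alpha; with many
  candidates the partner family grows and a BH step across partners (not
  implemented, to stay faithful to the method) would be warranted.
* Chi-square p-values are asymptotic; sparse joint tables are flagged via
  the expected-count warning but not switched to exact tests.
* The enrichment universe is experiment-derived; numbers are not comparable
  with tools that use a proprietary background.
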