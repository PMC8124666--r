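---
title: "Models and methods behind clonepair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind clonepair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonepair)
```

## The study design the package targets

`clonepair` analyses multi-region tumour sequencing studies in which every
patient contributes two spatially separated biopsies of the primary tumour
(`TU1`, `TU2`) and one matched normal sample (`N`). Such designs are the
standard way to quantify intra-tumour heterogeneity (ITH): a somatic
mutation detected in both biopsies is *shared*, one detected in a single
biopsy is *private*, and the private fraction of a patient's mutations is
a direct measure of how spatially structured the tumour's clonal
architecture is. Deep targeted panels with unique molecular identifiers
(UMIs) push detection down to variant allele frequencies (VAFs) of a few
percent, where sequencing errors and fixation artifacts dominate unless
they are explicitly corrected — which is what the package's consensus and
filtering stages do before any biology is interpreted.

The pipeline is `simulate/ingest -> filter -> shared/private -> clone
assignment -> clonal exclusivity`, with each stage usable on its own.

## UMI consensus

Reads with an identical UMI and an identical mapping position derive from
one original DNA molecule. `group_reads()` groups by the exact
`(umi, chrom, pos)` key — no edit-distance merging of near-identical UMIs
is attempted (directional adjacency clustering is a deliberate non-goal) —
and `consensus_sequence()` collapses each family by **strict per-position
unanimity**: a position keeps its base only if every read in the family
agrees; any contradiction, including an input `N` (which cannot certify
unanimity), is masked with `N`. There is no minimum family size: a
singleton family passes through unchanged.

Strict unanimity is intentionally conservative. A 2-vs-1 disagreement is
masked rather than resolved by majority, because at the low VAFs this
assay targets a single polymerase or sequencing error is indistinguishable
from a real low-frequency allele at the level of one family. A plurality
mode exists behind `majority = TRUE` (ties still mask) for users who
prefer throughput over caution. For a family of size $k$ and per-base
error rate $e$, a position stays unmasked with probability
$(1-e)^k + 3(e/3)^k$, and a *wrong* unmasked call requires all $k$ reads
to make the same error — probability $3(e/3)^k$, far below the single-read
error rate for $k \ge 2$. Both identities are exercised by the tests
against simulated families.

## Variant filters

**FFPE artifacts.** Formalin fixation deaminates cytosine, producing
spurious C>T (and, read on the other strand, G>A) calls. Because the
damage hits different positions in different cells, artifacts concentrate
at low VAF (1–10%). `ffpe_filter()` removes a variant iff its substitution
is C>T or G>A **and** its VAF is strictly below 0.10; a C>T at exactly 10%
is retained. Indels are exempt (deamination cannot produce them), and the
filter is applied per sample — an artifact arises in one FFPE block, not
in both biopsies at once. The filter is strand-agnostic; orientation-aware
(FoxoG-style) modelling is out of scope.

**Copy-number neutrality.** Downstream clone assignment assumes diploid,
copy-number-neutral loci, so variants in likely CNV regions must go. The
signal is allelic imbalance of heterozygous germline SNPs: a SNP with
normal-sample VAF inside $[0.40, 0.60]$ (inclusive — the heterozygosity
call) whose tumour VAF falls strictly outside those bounds indicates a
local copy-number change. `cn_neutral_filter()` removes every variant
within 4000 bp (inclusive: distance 4000 is removed, 4001 retained;
positions are 1-based and distance is $|pos_1 - pos_2|$) of such a SNP on
the same chromosome. The two boundary conventions — inclusive
heterozygosity bounds, strict complement for "out of bounds", inclusive
window — are chosen so the two clauses partition VAF space consistently,
and every boundary is pinned by a test so the choice is explicit and
changeable.

**Impact categories.** For clonal-interaction analysis only variants that
can plausibly change a clone's phenotype are informative.
`impact_filter()` keeps all HIGH (frameshift, gained stop/start) and
MODERATE (missense, inframe indel) impact variants, keeps LOW impact
variants *except* synonymous changes and retained start/stop codons, and
drops all MODIFIER variants (intronic, UTR, other non-coding). Silent
variants remain useful upstream (they carry signal for clone inference),
which is why this filter is applied only when building the entity-by-clone
matrices, not before clustering.

## Shared/private classification

`merge_samples()` joins the two biopsies' post-filter call sets on the
canonical `(chrom, pos, ref, alt)` key. Presence means presence in the
call set: no VAF re-thresholding happens at merge time, because detection
thresholds belong to calling and filtering, and no "rescue" of a variant
by sub-threshold read evidence in the other biopsy is attempted.
`private_fraction()`, `gene_frequency()` (patient-level indicator, so a
patient with three mutations in one gene counts once) and
`detect_convergence()` (a gene hit by distinct mutations with differing
biopsy patterns — the signature of convergent evolution) summarise the
cohort.

## Clone assignment from paired VAFs

Full phylogenetic latent-feature inference is out of scope; the package
instead clusters mutations in the two-dimensional space of per-sample
read counts under a binomial mixture:

$$ alt_{is} \sim \mathrm{Binomial}(depth_{is},\ \theta_{c(i),s}), \qquad s \in \{TU1, TU2\}. $$

EM with k-means++ seeding is restarted `n_restarts` (default 20) times
per candidate $K$, the best restart is kept by log-likelihood, and $K$ is
selected by BIC with ties broken toward smaller $K$ (parsimony,
deterministic). All randomness flows from one integer seed. Numerical
guards: $\theta$ is clamped to $[10^{-6}, 1-10^{-6}]$ so zero-VAF private
clusters remain finite in the likelihood; EM stops when the log-likelihood
improves by less than $10^{-8}$ or after 300 iterations.

Two modelling choices deserve emphasis:

* **Absent-side depth imputation.** A variant absent from one biopsy's
  call set has no recorded counts there, but on a deep panel the locus
  *was* covered, and observing zero alt reads at depth ~500–900 is strong
  evidence of a near-zero clone fraction — it is what separates a private
  cluster at $(0.26, 0)$ from a shared one at $(0.26, 0.11)$. By default
  the absent side's depth is imputed as the median depth of that sample's
  present calls with alt = 0 (`impute_absent_depth = "median"`).
* **From cluster centres to clone fractions.** In a pure, diploid,
  copy-number-neutral setting the cancer cell fraction of cluster $c$ in
  sample $s$ is $\min(1, 2\theta_{cs})$. Reported per-clone fractions map
  the CCFs to a linear chain ordered by mean CCF (largest = ancestral):
  clone $i$'s fraction is $CCF_i - CCF_{i+1}$ and the normal row is
  $1 - \max_i CCF_i$. This is exact when the true tree is a chain and an
  approximation otherwise; per-sample order inversions (pigeonhole
  violations) are reported in `$chain_violations`, never silently
  corrected, because topology inference is out of scope. Recovery
  benchmarks therefore score CCF matrices, the topology-free quantity the
  VAFs actually identify.

`to_entity_clone_matrix()` collapses the assignment to a binary
entity-by-clone matrix at gene or pathway level. A mutation marks its
assigned clone only, matching how deposited clone matrices are
represented; `propagate = TRUE` with a clone-tree parent vector instead
marks all descendant clones, which inherit ancestral mutations.

## Pathway over-representation

`build_background()` applies the expressed-gene rule: a gene enters the
background iff its total fragment count across the compared tumour and
normal samples is at least 10 (inclusive). `ora_test()` is the one-sided
hypergeometric upper tail $P(X \ge k)$ with pathway membership intersected
with the background first, $P(X \ge 0) = 1$ by convention, and
Benjamini–Hochberg q-values across tested pathways. Differential
expression calling itself is an input contract — the module consumes gene
lists, never count matrices. No pruning of the pathway hierarchy is
performed.

## Clonal exclusivity

Two entities (genes or pathways) altered in the same tumour but never in
the same clone suggest a clonal interaction. For a patient with $K$
clones in which entity $A$ occupies $|A|$ clones and $B$ occupies $|B|$,
the null model fixes both set sizes (the mutation-burden confounder) and
the clone count, and randomises placement uniformly:

$$ P_{excl} = \frac{\binom{K - |A|}{|B|}}{\binom{K}{|B|}}, $$

symmetric in $A,B$ and exactly 0 when $|A|+|B| > K$. Across the
comparable patients (both entities altered), the statistic $T$ = number of
exclusive patients follows a Poisson-binomial null, which the package
convolves **exactly**, so $p = P(T \ge T_{obs})$ is deterministic; a
seeded Monte-Carlo permutation mode exists purely as a cross-check.
`test_all_pairs()` tests every pair altered together in at least
`min_patients` (default 2) patients and applies BH across that family.

This null deliberately replaces likelihood-ratio machinery with
patient-specific background rates of exclusivity; the divergence matters
in both directions. With small clone sets relative to $K$, exclusivity is
*likely* under the null — two singleton sets among four clones are
disjoint with probability $3/4$, so even a pair exclusive in all four of
four patients has $p = (3/4)^4 \approx 0.32$. The size-conditioned test
can therefore only flag pairs whose clone sets are large enough (or
cohorts large enough) that joint exclusivity is genuinely surprising;
detecting few-patient singleton patterns at high significance requires
the background-rate modelling this package intentionally does not
re-implement. The bundled worked-example matrices
(`inst/extdata/synthetic_clone_matrix_patient{8,14}.tsv`) are synthetic
reconstructions of a published qualitative pattern — pathway 1 in clones
1+2 / clone 2, pathways 2 and 3 in clone 3 — and under this null give
$p = \tfrac13 \cdot \tfrac23 = 2/9$ per pair: correctly labelled
exclusive in both patients, and correctly not significant with two
patients of evidence under a size-conditioned null.

**Calibration design.** Because the exact test is discrete, its rejection
rate at nominal $\alpha$ equals the largest attainable tail $\le \alpha$,
which for most small configurations is far below $\alpha$ (extreme
conservatism, rejection rate near 0). The calibration experiment uses 18
patients with $K = 4$ and set sizes $(1, 2)$, giving $P_{excl} = 1/2$ per
patient and a null $T \sim \mathrm{Bin}(18, 1/2)$ whose attainable level
is $P(T \ge 13) = 0.048$ — close enough to nominal that a simulation can
distinguish a calibrated test from a broken one. The acceptance suite
verifies a rejection rate in $[0.03, 0.07]$ over 1000 simulated null
cohorts.

## The synthetic cohort generator

`simulate_cohort()` is first-class, tested code, not a fixture. Per
patient it draws a uniform random labelled rooted clone tree ($K$ uniform
on `n_clones_range`, default 2–4; topology only enters through cumulative
clone fractions), per-sample clone fractions from a Dirichlet over
(present clones, normal) with the normal component floored at
$1 - purity$ (default purity 0.7, the usual tumour-cell-content inclusion
threshold), and assigns `n_mutations_per_clone` (default 8) mutations to
each clone. A mutation's expected VAF in sample $s$ is
$0.5 \sum_{c \in carriers} F_{cs}$ with carriers = assigned clone plus
descendants (diploid, copy-number neutral), and observed alt counts are
$\mathrm{Binomial}(depth, VAF)$ at default depth 933, a deep-panel raw
coverage. Spatial structure — the thing that makes mutations private —
comes from `p_clone_absent` (default 0.6): each non-founding clone is
confined to a single random biopsy with that probability. Founding-clone
mutations are thus always shared (truncal), and cohort private fractions
land broadly in the 30–60% range reported by paired-biopsy studies, with
wide per-seed variance at 16 patients.

Layered on top are the nuisance channels each filter needs:
per-sample FFPE artifacts (C>T/G>A, true VAF uniform in (0.01, 0.10),
present in one biopsy only), germline heterozygous SNPs (normal VAF
uniform in (0.45, 0.55)) of which those inside CNV regions are displaced
outside $[0.4, 0.6]$ in both tumour samples, somatic mutations placed
inside CNV regions with probability `p_mut_in_cnv` (so the window filter
has true positives, placed clear of region margins otherwise), and
planted clonally exclusive pathway pairs realised by assigning
pathway-private genes to two distinct clones while excluding those genes
from the general gene pool.

Choices made for testability, which are also the generator's main
departures from real data:

* True somatic mutations never use the C>T / G>A substitution pair; it is
  reserved for the artifact channel. Otherwise a low-fraction true
  clone's deamination-like mutations would be (correctly, per the rule)
  removed by the FFPE filter and no planted-negative control could exist.
  Real tumours of course carry true C>T mutations, and the real filter
  pays a sensitivity price the simulation does not measure.
* `noise = "none"` emits a variant in a sample exactly when its carrier
  clones have positive fraction, with `alt = max(1, round(VAF * depth))`,
  so detection equals ground truth and classification can be tested for
  exact agreement.
* `min_clone_spacing` (default 0 = off) rejection-samples fraction draws
  until every clone pair is separated by at least the given expected-VAF
  distance in some sample and every clone is detectable somewhere. The
  clone-recovery benchmark sets 0.05 — about 2.5 binomial standard
  deviations at depth 500 — because without it a fraction of replicates
  are information-theoretically unrecoverable (two clones can draw
  near-identical fractions) and the benchmark would measure chance
  geometry, not the algorithm.
* Not emulated at all: read-level alignment artifacts, strand bias, indel
  error models, subclonal copy number beyond the imbalanced-SNP signal,
  real genome coordinates (loci are uniform on one synthetic contig so
  window distances are controllable), and family-size distributions of
  real UMI libraries (geometric with mean 3 by default).

Passing tests on this generator therefore demonstrate that each stage
implements its stated rule and that the stages compose correctly — not
that the pipeline's cohort-level numbers reproduce any particular real
cohort, which depends on raw data and a multi-caller stack outside this
package's scope.

## Problem sizes used by the test and acceptance suites

Chosen to exercise each property at meaningful resolution: 1000 UMI
families against the consensus oracle; 16-patient default cohorts for
filter and heterogeneity properties (8 patients for noise-free exactness
checks); 50 replicates of the clone-recovery benchmark (depth 500, 3
clones, 15 mutations/clone, 20 restarts); 1000 simulated cohorts for test
calibration and 200 for the planted-pair power setting; exhaustive
enumeration oracles up to 6 patients with $K \le 5$ and backgrounds up to
25 genes.

## Known limitations

* The exclusivity null conditions on clone-set sizes only; it does not
  model patient-specific propensities for exclusivity, so its p-values
  are conservative for small clone sets (see above) and it cannot
  reproduce published significance levels that derive from
  likelihood-ratio tests with estimated background rates.
* CCFs assume purity-corrected, diploid, copy-number-neutral loci; the
  CN filter enforces this only as well as germline SNP density allows.
* The chain mapping from CCFs to clone fractions is a reporting
  convention, not an inference; branching topologies make it approximate.
* VCF support is deliberately minimal (AD/DP counts, ANN-style
  annotation, both AD dialects); BCF, phased genotypes and symbolic
  alleles are out of scope.
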