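---
title: "Isoform-level systems genetics in a recombinant inbred panel"
author: "isoqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isoform-level systems genetics in a recombinant inbred panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoqtl)
```

## The problem

Reference transcript annotation for non-model organisms under-represents
alternative splicing and alternative polyadenylation (APA), so analyses
that link brain gene expression to behavioral traits can miss the isoform
actually carrying the signal. `isoqtl` implements the analysis chain that
addresses this in a recombinant inbred (RI) panel: a merged multi-source
transcript annotation (reference transcripts, splice-reconstruction
isoforms, 3'-terminus extension isoforms) is quantified per transcript,
filtered to a detected-above-background (DABG) set, normalized, reduced to
heritable dominant isoforms, organized into coexpression modules, and
mapped against strain genotypes and a strain-level phenotype. Candidate
transcripts and candidate modules must satisfy three criteria
simultaneously: phenotype correlation, a genome-wide significant QTL for
their own expression, and co-location of that QTL with a phenotype QTL.

Because every stage is exercised on synthetic data with planted truths,
the synthetic-data module is first-class, tested code: it defines the
statistical structure the analysis assumes, and the test suite measures
whether the pipeline recovers what was planted.

## The genetic model

RI strains are fully inbred mosaics of two progenitor genomes, coded 0/1
at every marker. Chromosomes are simulated as two-state Markov chains over
ordered markers; the inter-marker switch probability applies the
sib-mating RI map expansion

$$R = \frac{4r}{1 + 6r},$$

where $r$ is the per-interval meiotic recombination fraction. RI panels
accumulate recombinations over many generations of sib mating, so the
effective map is denser than a single meiosis; $r = 0.5$ is a fixed point
(free recombination stays free), and a unit-test switch
(`map_expansion = "identity"`) disables the expansion. Markers with
identical or complemented allele vectors across strains are statistically
indistinguishable in single-marker regression, so they are collapsed to
strain distribution patterns (SDPs); scans run on SDP representatives and
peaks are reported at the representative's genomic position.

## Expression model and heritability calibration

Counts are negative binomial with a log link:

$$\log \mu_{tl} = b_t + u_{t,s(l)} + \beta_t g_{s(l)} + \gamma_{t,b(l)} + \log d_l,$$

with transcript baseline $b_t$, strain effect $u$, optional planted eQTL
allele effect $\beta$, batch effect $\gamma$ (a global per-batch shift
plus per-transcript wobble), and library depth offset $d_l$. Negative
binomial with dispersion $\to 0$ recovers Poisson, which the tests use.

Panel heritability is the $R^2$ of a one-way ANOVA of per-animal
expression with strain as the factor. At the default design (30 strains
$\times$ 3 libraries) this estimator has a null floor near
$(k-1)/(kn-1) \approx 0.33$: even pure noise yields $R^2$ around a third.
The generator therefore calibrates the strain-effect variance against the
design by inverting the ANOVA expectation

$$E[R^2] \approx \frac{(k-1)(\sigma_w^2 + n\sigma_b^2)}
 {(k-1)(\sigma_w^2 + n\sigma_b^2) + k(n-1)\sigma_w^2},$$

and folds the counting-noise floor ($1/\mu + \phi$ on the log scale, by
the delta method) into the within-strain budget, so the *realized* $R^2$
distribution tracks the configured `heritability_range`. The default
range `c(0.34, 0.66)` was chosen once so that the realized median sits
near 0.5, consistent with the kind of brain transcriptome panel this
models; the acceptance checks verify the mean calibration error is below
0.05 and the Kolmogorov distance between realized and target
distributions is below 0.1 at 2,000 transcripts.

## Quantitation and the DABG cascade

Reads are represented by equivalence classes (the set of transcripts a
read is compatible with). The quantifier iterates the classical EM rate
update

$$\alpha_t \leftarrow \sum_c n_c
 \frac{\alpha_t/\ell_t}{\sum_{t' \in c} \alpha_{t'}/\ell_{t'}}$$

to a fixed point (tolerance $10^{-8}$ on abundance proportions, at most
1,000 iterations). Effective length equals transcript length — no
fragment-length correction — a documented simplification isolated behind
the length accessor. The DABG cascade runs in order: (1) drop libraries
under 10 million raw read pairs; (2) drop transcripts off the
autosomal/sex chromosomes; (3) quantify; (4) drop transcripts with zero
estimated counts in at least a third of the designated quantitation
libraries (ceiling rule: `ceiling(N/3)` with `>=`) or 200 nucleotides or
shorter, simultaneously (the order of these two rules is not separable in
the procedure's description; they are applied as one step); (5)
re-quantify everything against the survivors so reads from removed
transcripts flow to retained ones; (6) re-apply the zero rule. Because
the EM stops at a finite tolerance, a starved transcript can retain a
vanishing fraction of a read; counts at or below `zero_tol` (default
$10^{-3}$ reads) count as zero. A ledger records genes, transcripts and
per-source counts at every step and asserts monotonicity.

## Normalization

Depth is equalized by upper-quartile scaling: each library's 75th
percentile of counts (over transcripts expressed somewhere) is scaled to
the across-library mean of those percentiles, so adding a library moves
all factors smoothly rather than re-anchoring to a fixed reference. The
variance-stabilizing step is a moderated log: $\log_2(c + 1)$ followed by
per-transcript shrinkage of library values toward the transcript mean
with weight $\lambda/(\lambda + n)$. The GLM-based regularized log is
deliberately not re-implemented: every downstream statistic here (rank
correlation, ANOVA $R^2$, regression LOD) depends only on a monotone
variance-stabilized scale, and the transform records its provenance in an
attribute. Batch adjustment is parametric empirical-Bayes location/scale
adjustment via `sva::ComBat`, applied at library level before strain
means; a single batch is an identity, and batches confounded 1:1 with
strain trigger a warning because the effect is not identifiable then.

## Prefiltering

Three ordered reductions mirror the analysis this package supports: keep
the top three isoforms per gene by mean TPM over the RI-panel libraries
(ties break lexicographically so results are order-independent); drop
transcripts at or below the median heritability of the post-top-3 set
(the boundary is inclusive — a transcript exactly at the median is
dropped); drop transcripts that share no exact splice junction with a
reference transcript. Junction equality is exact by design: single-base
junction shifts are biologically meaningful in this context and fuzzing
would erase them. Single-exon transcripts have no junctions; by default
they are unassociated, with an opt-in exonic-overlap fallback.

## Coexpression network

The network is unsigned: $a_{ij} = |\mathrm{cor}(x_i, x_j)|^\beta$ across
strain means, with the soft threshold $\beta = 7$ as default. Topological
overlap is the standard
$(\ell_{ij} + a_{ij}) / (\min(k_i, k_j) + 1 - a_{ij})$. Modules come from
average-linkage clustering of $1 - \mathrm{TOM}$ with a simplified
recursive branch cut (the reference dynamic hybrid cut has many unstated
internals): a branch whose internal merge height exceeds the cohesion
ceiling (`merge_height`, default 0.99) must split further; a cohesive
branch splits only when both children reach `min_module_size` (default 5)
and the height gap to the taller child exceeds
$(1 - s/5)(h_{max} - h_{min})$, where $s$ is `split_sensitivity` (default
4; larger splits more aggressively). Branches smaller than the minimum
size fall into an explicitly labeled unassigned pool. Module labels are
size-ranked (`M1`, `M2`, ...) rather than palette colors. Divergence from
the reference implementation's module boundaries is expected; the tested
surface is properties: planted two-block structure is recovered exactly,
pure noise stays unassigned, eigengene variance explained matches a full
spectral decomposition.

The module eigengene is the first principal component of the
standardized members-by-strains matrix, sign-fixed so its mean
correlation with members is positive. Intra-modular connectivity is the
within-module adjacency row sum; the maximum defines the hub, ties
breaking lexicographically.

## QTL mapping

Single-marker regression gives $\mathrm{LOD} =
(n/2)\log_{10}(RSS_0/RSS_1)$, equal to $-(n/2)\log_{10}(1 - r^2)$; the
tests hold the two routes together to $10^{-10}$ absolute. Perfect fits
are capped (default 50). Genome-wide empirical p-values come from
permuting strain labels jointly across markers (preserving LD), with
$p = (1 + \#\{max_{perm} \ge obs\})/(N+1)$; thresholds are empirical
quantiles at $\alpha \in \{0.01, 0.05, 0.63\}$ — the 0.63 level is the
conventional "suggestive" tier. Credible intervals place posterior mass
$\propto 10^{\mathrm{LOD}}$ on the chromosome's markers, accumulate
markers by decreasing mass until coverage, and expand one flanking marker
each side. Covariate scans re-fit both models with the conditioning
marker's allele term, so a linked tag of the same QTL collapses while an
independent QTL persists. Local versus distal classification uses an
explicit convention — same chromosome and within 10 Mb of the transcript
midpoint, inclusive — since no biological constant defines "local".

## Candidate selection

A feature (transcript or module eigengene) is a candidate only if all
three hold: Spearman correlation with the phenotype at $p < 0.01$
(two-sided, t-approximation on $n-2$ df — adequate at 20–30 strains);
best QTL genome-wide empirical $p < 0.01$; and the QTL peak marker inside
the 95% credible interval of any significant-or-suggestive phenotype QTL
(inclusive endpoints, same chromosome). No multiple-testing correction is
applied to the criteria themselves, mirroring the practice this package
supports; an informational Benjamini–Hochberg column is emitted. Records
are ordered by correlation p-value. Candidacy is monotone in the
thresholds, and on all-null data the expected candidate count is bounded
by the product of the two p-value thresholds — both tested.

## Design choices made where the design was open

- **Sources of transcripts.** The source label is authoritative from a
  GTF attribute (`source_label`); inference from id conventions (an id
  equal to an existing id plus `.N` is a 3'-extension duplicate, `ENS*`
  reference, `MSTRG*` splice reconstruction) is a fallback only.
- **Coordinates.** 1-based inclusive throughout (native GTF); BED export
  converts to 0-based half-open at the boundary and is tested at the
  off-by-one.
- **Median convention.** Even-count medians are the mean of the central
  order statistics; the heritability boundary rule is "at or below the
  median is dropped".
- **Zero-count rule scope.** The rule is evaluated on the designated
  RI-panel quantitation libraries, never on loading-control libraries.
- **Phenotype replicates.** Six animals per strain by default; the strain
  mean over animals is what feeds QTL mapping. Animal counts are a free
  parameter of the design.
- **Seed fan-out.** One configuration seed derives per-stage child seeds
  through a fixed integer derivation, so stages can be rerun in
  isolation and full runs are byte-identical.

## What the simulations do and do not show

The synthetic panel emulates: biallelic homozygous genotypes with RI map
expansion, SDP redundancy, strain/batch/depth structure across 100
libraries (90 RI + 10 loading controls, one deliberately under the depth
threshold), ambiguous read assignment through exon sharing,
heritability spanning a configured range, and planted local/distal eQTL
and phenotype QTL. It does not emulate read sequences, alignment error,
GC/length bias, spike-ins, or strain-specific genome construction —
passing tests therefore validate the statistical machinery, not
sequencing artifacts.

Problem sizes used by the test suite and acceptance script are the
package's own choices for a compact, convincing demonstration: the
permutation calibration uses 500 null traits on a 30-strain map of about
200 SDPs with 1,000 permutations each; QTL recovery uses 200 replicates
of a 50%-variance QTL in 21 strains on a sparse framework map (4
chromosomes × 8 markers, $r = 0.4$ per interval) — sparse because on a
tightly linked map the argmax lands on a linked neighbor often enough
that peak-identity recovery is not a meaningful target, which is exactly
why credible intervals exist; the end-to-end candidate check runs 100
pipeline replicates of a 60-transcript panel with a 10-transcript module
sharing an eQTL at a marker that also explains 70% of strain-level
phenotype variance — a strong planted signal, chosen so that detection at
21 phenotyped strains under the stringent 0.01 correlation threshold is
statistically attainable, with 100 matching all-null replicates.

## Known limitations

- The EM has no fragment-length model and no uncertainty quantification
  (no posterior sampling); expected counts only.
- The moderated log is not the GLM-based regularized log; provenance is
  recorded and downstream statistics are insensitive to the difference by
  construction.
- The branch cut is a documented simplification of the reference
  dendrogram cutter; module boundaries will differ from it in edge cases.
- Spearman p-values are t-approximate, not exact permutation values.
- Batch adjustment inherits the identifiability limits of location/scale
  empirical Bayes: near-confounded designs are warned about, not fixed.
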