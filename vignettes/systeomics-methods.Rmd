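---
title: "Methods and design of the systeomics pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the systeomics pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(systeomics)
```

This vignette documents the statistical model behind each stage of the
pipeline, the parameters a user can turn, what the synthetic-data generator
does and does not emulate, and the design decisions taken where the
underlying methodology is genuinely open.

## Quantification

**NSAF.** Spectral counting measures a protein's MS/MS evidence, which grows
with both abundance and protein length; the normalized spectral abundance
factor divides counts by length in amino acids and renormalizes per sample,

$$\mathrm{NSAF}_i = \frac{SpC_i / L_i}{\sum_j SpC_j / L_j},$$

so NSAF is a *relative* abundance over the identified proteome. Two
consequences drive the implementation: the denominator runs over exactly the
features present in the table (adding or removing proteins changes every
NSAF), and per-sample NSAF sums to 1 by construction — the package asserts
this to 1e-9 and tests that rescaling a sample's counts by any positive
constant leaves NSAF unchanged. Zero counts give NSAF 0 and propagate; no
pseudocount is applied inside quantification. When spectral counts come from
multiple chromatographic fractions or duplicate runs of one sample, they are
summed into that sample's column before quantification. For protein groups
we take the length of the first-listed (representative) accession, the usual
convention when a group-level length rule is not otherwise defined.

**FPKM** is the closed form $f_i \cdot 10^9 / (T \cdot L_i)$ with $L_i$ in
nucleotides and $T$ the sample's total mapped fragments (defaulting to the
column sum). **Size factors** implement the median-of-ratios estimator: the
per-gene reference is the geometric mean across samples, computed in log
space and restricted to genes with a nonzero count in every sample (a
numerical-stability and well-definedness requirement), and the factor is the
sample's median count/reference ratio. For the matrix $(X, cX)$ this yields
$(1/\sqrt{c}, \sqrt{c})$ exactly. The test suite cross-checks the estimator
against the Bioconductor reference implementation; the two differ only when
the reference gene set has even size, where the reference averages the two
middle genes in log space while the definition used here averages the ratios.

## Detection integration and differential flagging

A *detection profile* is the set of identifiers seen in one dataset (cell
line × phase × omics layer). A gene counts as detected at the mRNA level
when its FPKM is positive and at the protein level when it has at least one
identified peptide row (count > 0); both thresholds are configurable.
Overlap accounting partitions the union of two profiles into
only-A/both/only-B; identifier maps (many-to-one allowed) move profiles
between namespaces, and unmapped identifiers are counted and either dropped
or passed through.

`compare_abundance()` flags outliers on the log2 ratio of pseudocounted
abundances. How such confidence bands should be drawn is genuinely open; the
package standardizes each gene's log2 ratio by a center and spread estimated
*across genes* and flags genes outside two-sided normal quantiles at the
requested levels (90% and 95% by default). The default estimator is robust —
median and MAD scaled by 1.4826 so the spread estimates the normal sd — on
the argument that the band should describe the unchanged majority and not be
inflated by the very outliers it is meant to expose; `estimator =
"parametric"` (mean/sd) is available for comparison, and the choice is
recorded in the output attributes and the run manifest. The pseudocount
defaults to half the smallest nonzero abundance in the pair, a conventional
detection-limit surrogate; fold-change selection (`max(r, 1/r) ≥ 1.8` by
default) operates on the same pseudocounted linear ratio. Degenerate cases
are defined explicitly: zero spread flags nothing, fewer than three shared
features is an error, and swapping the inputs negates every log ratio and
flips the direction labels.

Under an exchangeable null with a common noise scale the flagged fractions
converge to the nominal 5%/10%; this is verified by simulation at 10,000
genes. When per-gene noise scales differ strongly — e.g. Poisson counting
noise at very different depths — a single global band is conservative for
precise genes and liberal for noisy ones; this heteroscedasticity is a known
limitation of the global-band design, inherent to flagging on a scatter of
ratios rather than fitting a per-gene error model.

## Enrichment and depletion

Annotation terms are tested by the exact hypergeometric model: conditioned
on its size, a detection profile is a draw of $n$ genes without replacement
from the $N$-gene universe, and a term with $K$ annotated genes yields
$k$ detected members. Both tails are *inclusive* of the observed count,
$p_\mathrm{enrich} = P(X \ge k)$ and $p_\mathrm{deplete} = P(X \le k)$, so
$p_\mathrm{enrich} + p_\mathrm{deplete} - P(X = k) = 1$; the test suite
checks both tails against exhaustive enumeration of all $\binom{N}{n}$ draws
for every feasible tuple with $N \le 12$ and the identity on random tuples
up to $N = 20{,}000$. Tail probabilities are computed through R's
hypergeometric distribution functions, which work on log scale internally
and remain accurate at genome-scale $N$.

The universe choice materially changes $N$ and is therefore an explicit
policy: `annotation` (all genes annotated in the loaded collection; the
default, appropriate when detection is compared against what *could* be
annotated), `detected_union`, or an explicit list. Bonferroni adjustment
multiplies by the number of tested terms in the collection, applied to each
direction separately, since enrichment and depletion are reported as
separate analyses. Because the exact test is discrete, the achieved level of
`p_deplete < 0.05` under a random-detection null sits slightly below 5%
(about 3.5% at the generator's default term sizes); the calibration test's
tolerance covers this conditional-test effect.

Cross-dataset comparison keys KEGG terms by their trailing map number so the
same pathway tested against two species' annotations counts once; GO and
custom terms key by term id. Significance matrices hold
$-\log_{10}(\max(p, p_\mathrm{floor}))$ with a floor of 1e-16 (display
ceiling 16); ranked term tables order by p-value with ties broken by the
larger deviation $|k - nK/N|$ and then term id, making the order fully
deterministic.

## Localization consensus

The membrane/secreted caller consumes one normalized evidence row per
protein and applies a union rule: any TM predictor reporting at least one
helix (threshold configurable), or a plasma-membrane compartment call, sets
`membrane`; any signal-peptide call, a secretory TargetP call, or an
extracellular compartment call sets `secreted`. A union was chosen over a
majority vote because the per-method catalog counts such pipelines report
are inclusive by nature, and because the union is the transparent choice
when the output lists the firing predictors — stricter policies are one
`min_votes` away, applied downstream without recomputation. Missing
predictor outputs are `NA` and never fire, and the WoLF PSORT compartment
mapping (plasma membrane → membrane, extracellular → secreted) is explicit.
Catalog merging is order-aware set union with first-seen accounting, and RNA
cross-checking is an exact set difference.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, not
any particular instrument: per-gene detection is independent Bernoulli with
a baseline probability (default 0.8, giving the ~80% detected universes
typical of deep proteome/transcriptome studies) overridden for genes of
planted terms; abundance is log-normal (meanlog 2, sdlog 1 — a right-skewed
distribution spanning ~3 orders of magnitude, the shape label-free
proteomics reports); condition B multiplies abundance by $2^{\mathrm{lfc}}$
for planted fold-change genes; spectral and fragment counts are Poisson with
mean abundance × (length/1000) × depth, the simplest generative model whose
expectation NSAF and FPKM invert; and membrane/secreted labels are drawn
with marginal fractions 20%/20% including 5% doubly labeled, matching the
study conditions used in validation. Universes default to 1,000 genes with
50 terms of 10–100 genes, a realistic term-size spread relative to the
universe. A single global seed expands into named substreams (universe,
labels, detection, abundance, predictors), so identical seeds give
byte-identical output files and adding a stage never perturbs earlier draws.

What the generator does *not* emulate — correlated detection within
complexes, peptide-level identification and FDR filtering, protein-group
roll-up, batch structure, over-dispersed counts, and predictor errors that
correlate across tools (a real TM segment missed by TMHMM is often missed by
Phobius too) — bounds what passing tests show: they validate the statistical
machinery under its own assumptions, not performance on any real proteome.
The independence of per-predictor errors, in particular, makes the union
rule's measured sensitivity an upper bound.

## Validation problem sizes

The shipped tests and acceptance script use: exhaustive tail enumeration for
all universes up to $N = 12$ (1,650 tuples) plus 1,000 random large tuples;
100 random count tables for NSAF properties; 100 simulation seeds for
planted-term recovery (1,000 genes, 50 terms of 50, baseline 0.8, planted
detection 0.1); 200 null universes for depletion calibration; 10,000 genes
for CI calibration; 1,000 proteins for localization recovery; and two full
pipeline runs for byte-level determinism. These sizes make the whole suite
run in well under a minute while leaving Monte-Carlo error far smaller than
the tested tolerances.

## Known limitations

Beyond the generator caveats above: the pipeline consumes already-identified
feature tables and never revisits identification error; NSAF comparisons
across samples assume comparable identified proteomes (the denominator is
per-sample); the hypergeometric model treats detection as exchangeable
across genes, which real abundance-dependent detection violates; and
Bonferroni control is deliberately conservative for the strongly overlapping
term families typical of GO.
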