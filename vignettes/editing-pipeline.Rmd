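---
title: "Detecting A-to-I RNA editing and downstream clinical quantities with editomekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting A-to-I RNA editing and downstream clinical quantities with editomekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editomekit)
```

## The problem

Adenosine-to-inosine (A-to-I) editing is the most prevalent form of RNA
editing in human cells. Inosine pairs like guanosine, so an edited site
appears in RNA sequencing reads as an A>G substitution on the transcribed
strand — or, when the transcript comes from the minus genomic strand, as a
T>C substitution in genomic coordinates. Because the DNA itself is
unchanged, a candidate editing site is an RNA-only variant: distinguishing
genuine editing from germline variation, sequencing error and alignment
artifact is a filtering problem, and this package implements that filtering
as two explicit cascades, together with the downstream quantities a study
of editing-driven chemoresistance needs: a paired hyper-editing caller, an
expression/editing z-score signature with survival strata, single-hit
limiting-dilution frequency estimation, and a handful of small clinical
formulas.

Every stage is testable at desk scale because the package also ships the
synthetic-data generators that produce each input with known ground truth.

## The two calling cascades

**Matched-exome ("organoid") cascade.** When whole-exome sequencing of the
same sample is available, DNA evidence does the heavy lifting:

1. *Candidate calling.* A site enters as a candidate when its RNA pileup
   shows an A>G (plus strand) or T>C (minus strand) change with read depth
   strictly greater than 7 and alternative-allele depth strictly greater
   than 2. The thresholds are exclusive — depth ≥ 8 and alt ≥ 3 — and are
   kept verbatim rather than harmonized with the inclusive de novo rule
   below, because the two cascades are documented side by side.
2. *DNA subtraction.* Sites with variant evidence in the matched DNA are
   removed. The DNA evidence rule is: any non-reference base supported by
   at least 2 reads (configurable). The rule is symmetric with the de novo
   support threshold.
3. *Known-resource filtering.* A site is removed iff it is absent from
   RADAR **and** absent from DARNED **and** not recorded as edited in the
   relevant tissue (default `"stomach"`) by the inosinome-atlas style
   database. This is the literal conjunctive reading of the removal rule;
   the stricter alternative — keep only sites present in at least one
   editing database *and* tissue-edited — is available as
   `mode = "any_resource"` and is never chosen silently.

**De novo ("cohort") cascade.** Without matched DNA, read-level and
annotation filters substitute for DNA evidence:

1. Observations with mapping quality < 20 are discarded (mapq 255 =
   "unavailable" passes, logged); sites with at least 2 supporting reads —
   inclusive — are kept.
2. Sites reported as SNPs in any provided population database (1000
   Genomes / ESP style) are removed, with union semantics, so the order of
   databases never matters.
3. Alternative reads whose site lies within the first 6 bases of the read
   are censored (the imperfect random-hexamer priming artifact), and the
   site is re-tested against the support threshold with depths and editing
   level recomputed. Censoring is observation-level rather than wholesale
   site deletion because the artifact affects individual read ends.
4. Sites inside Alu elements bypass the artifact filter; other sites are
   removed when within 4 bases of a splice junction on the intronic side,
   inside a reference homopolymer run of ≥ 5 bases (the run length is our
   choice — common editing-pipeline practice — since "homopolymeric
   region" has no universal definition), or inside a simple repeat.
5. Sites outside the precomputed uniquely-alignable mask are removed. By
   default this applies to Alu sites too (the unconditional reading);
   `aluExemptUniqueness` scopes it to non-Alu sites.

Both cascades are subset operations stage by stage, and `runCascade()`
emits a `CascadeReport` whose per-stage counts are verified non-increasing.

```{r cascade-example}
study <- simulateOrganoidStudy(nPlanted = 15, nNull = 80, nSnps = 8,
                               nLines = 1, refLength = 40000L, seed = 11)
res <- runCascade(list(cascade = "organoid",
                       rna = study$samples$L1_resistant$rna,
                       dna = study$samples$L1_resistant$dna,
                       radar = study$radar, darned = study$darned,
                       atlas = study$atlas))
cascadeStages(res$report)
```

## Differential hyper-editing

For each site the editing level is the fraction of reads carrying the
edited base, in transcript orientation. Levels are compared between paired
parental and resistant lines; a site contributes to a pair only when its
depth passes the measurability criterion (the same depth > 7 rule) in
*both* members, and a pair in which it does not is reported as
non-evaluable (`NA`) rather than dropped. The hyper-editing call is a
threshold rule, not a statistical test: a site is hyper-edited when

\[
\Delta_\ell = \text{level}_{\text{resistant},\ell} -
\text{level}_{\text{parental},\ell} \ge 0.10
\]

in at least 2 of the 3 paired lines. "10% change" is read as an absolute
editing-fraction difference of 0.10 (the relative-change reading was
rejected: levels are themselves fractions, and the rule is applied to their
signed difference, resistance relative to parental). The threshold is
inclusive ("at least"). Sites measurable in fewer than `minLines` pairs can
never be called and are visible as non-evaluable rows. Raising either
threshold provably never enlarges the called set, and the caller is tested
exactly against a brute-force double loop.

Called sites are summarized by transcript region (3'UTR, 5'UTR, CDS,
noncoding exon, intron, intergenic; precedence 3'UTR > 5'UTR > CDS >
noncoding exon > intron when gene models conflict) and grouped by
biological process, counting per gene by default (a gene with several
called sites counts once per process) with a site-level mode available.

## The expression/editing signature

For a cohort, the signature score of patient \(i\) is

\[
s_i = \tfrac{1}{2}\left( z(\text{ADAR1 expr})_i + z(\text{SCD1 editing})_i \right),
\]

with z-scores using the sample standard deviation (n − 1; the convention of
standard statistical environments). Strata follow the sign: HIGH for
\(s_i > 0\), LOW for \(s_i < 0\); an exact zero is excluded from both
strata, since a ">0 versus <0" comparison leaves zero undefined. The score
is invariant to any positive affine transform of either raw component —
z-scoring absorbs it — which also means any consistent per-cohort
expression normalization is acceptable. Survival model fitting is
deliberately out of scope: the package emits strata labels for standard
survival tooling.

IHC-based stratification uses the immunoreactive score IRS = intensity
(0–3) × percentage category (0: 0%, 1: (0,10]%, 2: (10,50]%, 3: (50,80]%,
4: >80%), with quartile cutoffs computed by the nearest-rank rule and ties
included in the extreme group, making the stratification deterministic.

## Limiting-dilution frequency estimation

The single-hit model says a well seeded with \(d\) cells is negative with
probability \(\exp(-f d)\), where \(f\) is the initiating-cell frequency —
the complementary log-log link makes the model linear in \(\log d\). The
binomial log-likelihood is maximized over \(\log f\) (the likelihood is
unimodal and concave there) by bracketed one-dimensional optimization with
tolerance 1e−10; the 95% CI is Wald on \(\log f\), back-transformed, and
is labeled as such in output since likelihood-based intervals are a
reasonable alternative construction. Single-dose designs admit the closed
form \(\hat f = -\ln(\text{negative fraction})/d\), which the optimizer is
tested against to 1e−6 relative. Degenerate designs are handled
explicitly: all-negative gives \(\hat f = 0\) with a one-sided profile
upper bound at a log-likelihood drop of \(\chi^2_1(0.95)/2\) (closed form
\(1.92/\sum n_i d_i\)); all-positive is symmetric.

Group comparison is a likelihood-ratio test (separate versus shared
frequency) against \(\chi^2_1\); one-sided p-values halve the tail when
the observed direction matches the stated alternative, else complement the
half-tail. The direction must always be supplied by the caller — no
default direction is assumed.

## What the generators emulate, and what they do not

`simulateReference()` draws an i.i.d. base sequence with planted
homopolymer runs and labeled Alu-like, repeat, intron and uniqueness-mask
intervals. `simulatePileupPair()` draws per-site depths from a Poisson,
edited-base counts from a binomial at the planted editing fraction, a
uniform per-base sequencing error (default 0.005, a typical post-filter
Illumina substitution rate), uniform read offsets, and matched DNA pileups
carrying heterozygous germline SNPs but no edits. `simulateCohort()`
couples log-normal expression to a beta-distributed editing fraction
through a latent bivariate Gaussian whose correlation is calibrated — by
deterministic common-random-number search, independent of the user's seed —
so the realized Pearson correlation hits the requested target;
survival is exponential in the signature score with uniform censoring.
`simulateLda()` is the single-hit binomial itself.

The default study conditions are three paired parental/resistant lines,
200 planted hyper-edited sites at an editing-level increase of 0.3 over a
parental level of 0, 2000 covered null sites, 50 germline SNPs, mean depth
50 and error rate 0.005 — and at these conditions the full cascade +
differential pipeline recovers ≥ 95% of planted sites with ≤ 5% false
calls in the test suite.

What the generators do **not** model: alignment artifacts beyond the
uniform error + read-offset scheme (no splice-junction misalignment, no
strand bias, no PCR duplicates), base-quality scores (the pileup dialect
deliberately omits them, as the upstream base-quality provenance of the
matched-exome cascade is unspecified), linkage between nearby sites, or
overdispersed well counts in the limiting-dilution model. Passing tests on
these simulations therefore demonstrate correctness of the *filtering
logic and estimators*, not robustness to every artifact of real
sequencing data.

## Numerical and design choices

- Positions are 1-based throughout site reports; interval files are BED
  half-open on disk and converted once, at the reader boundary, to 1-based
  closed `GRanges`. Converting a position to interval space and back is the
  identity.
- Chromosome naming is never normalized silently; mixing `chr1` with `1`
  between RNA and DNA inputs is a hard error.
- De novo alternative-base ties are broken deterministically in base order
  A < C < G < T.
- The editing level is recomputed exactly as alt/depth after every
  observation-censoring step; `N` observations count toward depth but can
  never be the alternative.
- Seeds: every generator is a pure function of (parameters, seed); a
  single seed is folded with a per-generator stream index so adding one
  generator call never perturbs another's draws, and the caller's RNG
  state is restored afterwards.
- Test problem sizes (200 + 2000 sites, 3 lines, 500 limiting-dilution
  replicates, cohorts of 500) were chosen as the smallest scales at which
  the binomial/Poisson noise floors sit comfortably below the thresholds
  being verified, keeping the default suite runnable on a laptop in a few
  minutes.

## Known limitations

Indels and multi-allelic sites are out of scope (A-to-I editing is a
single-base substitution); alignment, duplicate marking and BLAT-style
uniqueness computation are upstream concerns consumed as inputs; survival
modeling beyond strata labels, per-site statistical testing of editing
differences and enrichment analysis are deliberately not provided.
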