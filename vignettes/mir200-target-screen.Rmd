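---
title: "Anti-correlation screening and consensus nomination of microRNA targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anti-correlation screening and consensus nomination of microRNA targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mircorr)
```

## The problem

A microRNA represses its target mRNAs, so across a cohort of tumors a
genuine miRNA–target pair should show *negative* correlation between the
miRNA's abundance and the target's mRNA signal. Sequence-based prediction
tools (TargetScan, PicTar, miRDB, microRNA.org) nominate thousands of
candidate pairs from seed-match complementarity alone, most of which are
not functional in any given tissue. `mircorr` implements the
expression-guided intersection of the two evidence streams: a Pearson
screen over every marker-probe × miRNA pair in a matched expression
cohort, followed by a consensus rule that keeps a (miRNA, gene) pair only
when (i) at least one tool predicts it and (ii) at least one probe of the
gene is significantly *negatively* correlated with the miRNA. Downstream,
the package implements the arithmetic used to confirm nominated targets at
the bench: 2^−ΔΔCt relative expression, densitometric relative protein
levels, and the confirmed-target decision rule.

## The screening model

For probe $x$ and miRNA $y$ measured on $n$ matched samples, the screen
computes the Pearson coefficient $r$ and attaches the exact null
transform

$$ t = \frac{r\sqrt{n-2}}{\sqrt{1-r^2}}, \qquad t \sim t_{n-2}
\text{ under } H_0: \rho = 0, $$

giving a two-sided p-value. Missing cells are handled pairwise-complete
and the per-pair $n$ is stored with each result, never assumed equal to
the cohort size. A constant probe or miRNA yields an explicit undefined
record (`r = NA`, never significant) rather than a silent zero.

The selection rule is a conjunction by default: a pair passes when
$|r| \ge r_{\min}$ **and** $p \le \alpha$, with defaults
$r_{\min} = 0.258$ and $\alpha = 0.05$. These two conditions are close
but not identical at typical cohort sizes: at $n = 57$,
`critical_r(57, 0.05)` is ≈ 0.261, slightly above the pinned 0.258, so
the p-value condition binds. The profile keeps both knobs explicit
(`analysis_thresholds()`), with `alpha_only` and `r_only` modes for
sensitivity analysis. Benjamini–Hochberg adjusted p-values are reported
alongside every raw p, but by default the significance flag gates on the
raw p — screening pipelines of this design applied no multiplicity
correction, and the adjusted column lets a user impose one
(`adjust_gate = TRUE`) without code changes.

Because microarray designs measure one gene with several partially
discordant probe sets, the consensus rule asks for a significant negative
correlation in *at least one* probe of the gene; pairs whose only
significant correlations are positive are excluded. Per-source support is
retained in the output so a stricter k-of-4 consensus is a configuration
choice, not a code change. Validation status against a TarBase-style
catalogue is annotation only — it never gates inclusion. Binding-site
records are filtered inclusively at mirSVR ≤ 0 (more negative = stronger
predicted repression) and PhastCons ≥ 0, and sites are counted per
(gene, miRNA) with identical coordinates collapsed and overlapping but
distinct sites counted separately.

### Scale of the correlated values

Whether the mRNA signal enters the correlation linearly or after a log
transform is left to the caller: `log_transform()` applies
$\log_2(x + \text{offset})$ with an explicit offset (default 1) and
refuses double transforms. Pearson on raw linear microarray signal is
dominated by high-signal outliers, so the workflow default is log2;
running on the linear scale reproduces the alternative convention. The
direction of every correlation also depends on whether miRNA abundance is
supplied as an expression value or as a raw Ct (which is *inversely*
related to abundance); the package takes whatever matrix it is given and
documents the expectation that callers supply abundance-scale values, so
a Ct-scale matrix should be negated or linearized first.

## Quantification arithmetic

Relative expression follows the Livak method exactly:
$\Delta Ct = Ct_{\text{target}} - Ct_{\text{control gene}}$ per
replicate, averaged per condition;
$\Delta\Delta Ct = \overline{\Delta Ct}_{\text{treated}} -
\overline{\Delta Ct}_{\text{control}}$; fold $= 2^{-\Delta\Delta Ct}$.
Replicate ΔCt values are retained for an unpaired two-sided t-test
(Welch by default; a pooled-variance option exists because the original
description does not say which was used). Endogenous controls are
parameters (`UBC` for mRNA, `U47` for miRNA are the conventional
choices), never hard-coded. Ct values at the assay ceiling (default 40
cycles) mark the result `censored`: the fold is then a bound, not a
point estimate. No amplification-efficiency correction is applied — the
method is pure 2^−ΔΔCt by design.

Protein levels divide each band by its lane's loading control (tubulin)
and then by the reference condition (the scrambled-miRNA control), making
the result invariant to per-lane exposure scaling; `percent_change`
$= 100\,(1 - \text{relative level})$. A predicted gene is **confirmed**
when the mRNA is significantly downregulated (fold < 1, $p \le 0.05$) *or*
the protein falls by at least 15% — a disjunction with a strict boundary
(14.9% does not confirm).

Tumor-vs-normal fold changes are ratios of group means on the linear
scale (log2 matrices are back-transformed for the ratio only), with the
unpaired t-test run on the analysis scale.

## What the generator emulates

`simulate_cohort()` produces a matched cohort with the statistical
structure the screen assumes, all on the log2 scale:

* miRNA$_i$ ~ Normal(`mirna_mean` + `tumor_shift`$_i$ · 1[tumor],
  `mirna_sd`);
* for a planted pair $(i, g)$ with target probe-level correlation $r$:
  gene signal $= \mu - \beta\,(\text{miRNA}_i - E[\text{miRNA}_i]) +
  \varepsilon$ with $\beta = -r\,\sigma_{\text{gene}}/\sigma_{\text{miRNA}}$,
  and the residual variance chosen so the **total** probe variance equals
  `baseline_sd`²;
* each gene carries 1–3 probes (uniform), each adding independent
  Normal(0, `noise_sd`) probe noise.

Pinning the total probe variance makes the planted $r$ the exact
population correlation between any probe of $g$ and the miRNA, and gives
a hard feasibility bound
$|r| \le \sqrt{1 - \text{noise\_sd}^2/\text{baseline\_sd}^2}$
(`attainable_r()`); an infeasible request errors with that bound rather
than silently attenuating.

Defaults are the study-scale conditions used by the tests, the analysis
scripts and the acceptance script: 57 matched tumor samples, 200 genes,
20 miRNAs, 30 planted pairs at $r = -0.5$, per-source prediction error
rates fn = 0.2 / fp = 0.01, probe noise sd 0.3 against total probe sd 1,
and baseline means 8 (mRNA) and 6 (miRNA) — magnitudes typical of log2
microarray signal. The tumor shifts of the first three miRNAs
(log2 of 2.56, 2.94 and 3.16) emulate the overexpression a squamous-cell
lung cohort shows for the miR-200 family, so `group_fold_change()` is
testable against known truth. The benchmark problem sizes (50 seeds for
the recovery benchmark, 30 for the fold-change recovery, 2,000 pairs for
the null calibration, 200 replicated assays for the ΔΔCt Monte Carlo)
were chosen as the smallest runs whose Monte-Carlo error is well inside
the margins being checked.

What the generator deliberately does **not** emulate: MAS5 probe-level
chemistry, TaqMan amplification curves, heavy-tailed or batch-structured
noise, correlated miRNAs, or genes regulated by several miRNAs at once
(each gene is planted for at most one miRNA so the planted correlation is
exact). Passing tests therefore demonstrate that the pipeline's logic and
arithmetic are correct and well calibrated under its own statistical
assumptions — not that those assumptions hold for any particular real
platform.

## Numerical and design choices

* `correlation_pvalue(±1, n)` returns an exact 0 with an `exactness`
  attribute instead of dividing by zero.
* Pairs with fewer than 3 complete samples are excluded from the
  correlation output and listed in a skip log (attribute `"skipped"`);
  they are neither errors nor silent omissions.
* A replicate t-test on constant (e.g. noiselessly simulated) ΔCt values
  leaves `p = NA` rather than failing the fold computation.
* Probe ids match case-sensitively; gene symbols and miRNA names match
  case-insensitively after normalization (`normalize_mirna_id()` maps
  `MIR-200A`, `miR-200a`, `hsa-miR-200a` to one key), because public
  prediction exports mix conventions.
* Stable ordering: `filter_significant()` preserves input order;
  consensus rows come out in first-prediction order, making outputs
  diff-able across runs.
* Seeds compose deterministically: the cohort, the prediction tables and
  each Ct table take explicit seeds, and a fixed seed yields identical
  output.

## Known limitations

* Gene identity is by official symbol; an alias table is out of scope, so
  renamed symbols in third-party exports will not join unless
  pre-normalized.
* The screen is strictly pairwise Pearson — no rank-based or partial
  correlation, and no network inference.
* Binding-site handling consumes database exports; the package does not
  scan sequences or compute duplex energies.
* Historical candidate counts from any specific database era cannot be
  reproduced without those exact snapshots; the pipeline reports what the
  supplied tables contain.
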