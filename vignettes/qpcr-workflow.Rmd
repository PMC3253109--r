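---
title: "Methods: the qpcrkit RT-qPCR analysis workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the qpcrkit RT-qPCR analysis workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpcrkit)
```

# The model

RT-qPCR quantification rests on the exponential growth of PCR product:
after n cycles a template at initial concentration $C_0$ reaches
$C = C_0 (1+E)^n$, where the efficiency $E \in (0, 1]$ is the fraction of
template successfully duplicated per cycle ($E = 1$: perfect doubling).
The threshold cycle Ct is the cycle at which product crosses a fixed
fluorescence threshold, so Ct is linear in $-\log C_0$ and one cycle
corresponds to a $(1+E)$-fold difference in starting material.

Every stage of this package is an elaboration of that identity.

## Stage 1 — standard-curve efficiency

Serially diluted standard cDNA (dilution factor `dilut`, `grad` levels,
serial 1 = undiluted) gives known relative concentrations
$c_l = \mathrm{dilut}^{-(l-1)}$. Ordinary least squares of Ct on
$x = \log_{10} c$ yields a slope of $-1/\log_{10}(1+E)$, inverted as

$$E = 10^{-1/\mathrm{slope}} - 1 .$$

Assumptions: efficiency is constant over the quantifiable range, and the
standards amplify like the unknowns. The regression base is immaterial:
any base rescales slope and its inverse identically, so base 10 is used
with arbitrary `dilut`. Replicates within a dilution level are averaged to
a mean Ct before the fit, weighting all levels equally (an
`average_replicates = FALSE` switch regresses on all points instead). A
non-negative slope means the series did not dilute as designed; the fit is
still reported but the efficiency is `NA` with a warning. Fewer than three
distinct levels, or zero variance in $x$, are hard errors.

## Stage 2 — reference stability (M value)

Relative quantities are reconstructed per gene as
$q[g, s] = (1+E_g)^{\,Ct_{cal}(g) - Ct[g, s]}$. The stability statistic of
gene $g$ within a candidate panel is the arithmetic mean, over the other
panel members $k$, of the sample standard deviation across samples of
$\log_2(q_g/q_k)$. A perfectly co-regulated (or perfectly stable) pair has
a constant ratio, hence SD 0. The least stable gene — highest M — is
excluded and M recomputed on the shrinking panel until three genes remain.

The reported rank is the *reverse exclusion order*, with the final trio
ordered by its final-panel M, so a single best gene is always identified.
Because each M is reported "as of exclusion time" (a different panel each
round), the rank order and the M-value sort order can disagree; selection
should follow the rank. This is deliberate and surfaced in the output
rather than hidden.

Numerical conventions: log base 2 throughout (the geNorm convention; the
base rescales all M and V values uniformly and can never change a
ranking). Ties on the maximal M exclude the lexicographically later gene
name; final-trio M ties rank the lexicographically earlier name better.
Both tie-breaks exist purely for deterministic reproducibility. Stability
uses all *unknown* samples across all treatment types — standards are
never mixed into expression statistics — and the min-Ct calibrator, whose
choice cancels in every log-ratio SD anyway.

## Stage 3 — normalizer optimization (V series)

The normalization factor over a reference subset is the per-sample
geometric mean of their quantities. With references added in rank order,

$$V_{n/n+1} = \mathrm{SD}_s\!\left[\log_2 \frac{NF_n[s]}{NF_{n+1}[s]}\right]$$

measures how much the normalizer still moves when the (n+1)-th gene
arrives. The series is computed from $V_{1/2}$ upward — preserving the
possibility that one or two validated genes suffice — and the optimal
count is the argmin, ties to the smaller n (parsimony). Note
$V_{n/n+1} = 0$ exactly when the incoming gene's quantity profile is
proportional to $NF_n$; duplicating an already-included gene does *not*
generally zero the next V, since the duplicate shifts the geometric mean
unless it already equals it.

The dispersion metric is the standard deviation by default (geNorm
convention); a `variance` option is provided because the two are sometimes
conflated in the literature. The configured metric travels with the series
as metadata. SD and variance are monotone transforms of each other, so the
argmin — the only thing consumed downstream — is identical under either.

## Stages 4–5 — ΔΔCt normalization and ratio statistics

For targets, quantities use the *control-mean* calibrator: each gene's Ct
is referenced to its mean Ct over control-type samples, which makes the
control geometric mean of $q$ — and of the normalized value
$q_t[s]/NF[s]$ — exactly 1 by construction. This is the
efficiency-corrected ΔΔCt scheme: the target's Ct shift between treated
and control, net of the references' shift, on the fold-change scale.

Per (target, treatment): $d$ = difference of log2-value group means,
fold change $R = 2^d$, and a two-tailed two-sample t-test on the log2
values. Defaults: classical pooled-variance Student's t (Welch via
`var_equal = FALSE`), reflecting the small, usually balanced group sizes
of qPCR designs. The SE of $R$ is the delta-method back-transform
$SE_R = R \ln 2\, SE(d)$; the symmetric log-scale SE (`se_log2`) is also
exported since fold-change uncertainty is symmetric only in log space.
Benjamini–Hochberg adjustment is applied across *all* rows produced by one
call — the natural multiple-testing family is the set of gene × treatment
comparisons reported together. Each sample is one biological replicate:
technical replicates were collapsed by mean Ct in data handling, and the
t-test degrees of freedom derive from sample counts.

# Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `dilut`, `grad` | 10, 5 | fold, levels | a 5-step 10-fold series spans 4 decades, the common design |
| `e_excluded` | 0.95 | fraction | assays below 95% efficiency are unreliable for ΔΔCt; a gene at exactly the threshold is retained |
| `calibrator` | min-Ct (stability), control-mean (normalization) | — | cancels in log-ratio SDs; control-mean makes values read as fold-of-control |
| V metric | SD | log2 units | geNorm convention; `variance` available |
| `n_refs` | V-series argmin | genes | overridable; user reference lists are honored in given order |
| t-test | pooled | — | Student's t as the default named method; Welch by flag |
| missing Ct | excluded + warning | — | "Undetermined" instrument flags; a group left with < 2 usable samples errors downstream |

Efficiency is stored as a fraction (1.0 = 100%) everywhere in code; the
`Efficiency` sheet additionally prints `efficiency_pct` to avoid the
0.95-vs-95% ambiguity.

Standards are distinguished from unknowns explicitly — an input `role`
column, or a `standard_type` label matched against `type` (default
`"standard"`) — rather than by guessing naming conventions. Serial index 1
is the undiluted standard; increasing serial means further dilution.

# The synthetic generator

`generate_dataset()` draws, per sample, a loading offset
$L_s \sim N(0, \sigma_{load})$ shared by **all** genes — the confounding
variation normalization exists to remove — and per (gene, sample) a
biological noise term on the log2-quantity scale with gene-specific SD.
Designed fold changes enter as Ct shifts $-\log_{1+E_g}(F)$; technical
replicates add Gaussian Ct noise; standards follow the dilution design
with the slope implied by each gene's true efficiency.

Stated-world defaults, chosen once:

* 19 candidate references + 9 targets, 3 treatment types (control `C05`),
  3 samples per type, duplicate reactions — the shape of a realistic
  validation panel (~260 standard and ~500 unknown reactions).
* true efficiencies evenly spaced over 0.97–1.05: assays that pass a
  standard 95% QC cut with margin, so the whole candidate panel
  participates after the efficiency filter, as in a well-run study.
* reference noise SDs strictly increasing 0.05–0.6 log2 units (a designed
  stability order), target noise 0.25, replicate noise 0.1 cycles.
* $\sigma_{load} = 0.5$ cycles — large enough that unnormalized analysis
  visibly fails, making cancellation tests meaningful.
* one designed effect: 6-fold induction of `Hsp70` under `T05`.

What it does **not** emulate: amplification and melt curves, inhibitors or
efficiency drift across the dynamic range, inter-run batch structure,
non-Gaussian dropout of low-expression wells, and truly co-regulated
reference modules (noise is independent across genes, which flatters the
M-value's independence assumption). A green recovery test therefore
establishes that the algorithms invert the generator's (standard,
multiplicative-error) model — not that any particular wet-lab dataset
meets that model. One subtlety is tested explicitly: the loading offset is
additive in Ct, so with *unequal* efficiencies it is not exactly a common
quantity factor; exact-cancellation checks use equal efficiencies or
inject the offset in quantity space, and the residual inexactness with
heterogeneous E is a property of ΔΔCt itself, not of this implementation.

# Degenerate inputs and numerics

Duplicate (gene, sample, serial) triples within a role are validation
errors; technical replication uses distinct serials (unknowns) or distinct
standard sample series and is collapsed by arithmetic mean of Ct at each
stage boundary. Genes missing any sample are dropped from a quantity
matrix with a warning before construction, so matrices are always
complete. All stage sheets are TSV with numerics printed at 17 significant
digits, which round-trips IEEE doubles exactly — reruns and stage-wise
composition are byte-identical, and that is asserted, not assumed. The
pipeline's provenance sidecar (`run_info.json`) records package version,
parameters and the selected references.

# Known limitations

* No alternative stability statistics (NormFinder/BestKeeper), no ANOVA /
  permutation / rank tests, no RDML or plate-layout parsing, and no
  fluorescence-curve efficiency estimation — all outside this workflow's
  scope.
* The V-series argmin rule always returns some n; on panels with a flat
  series the choice among near-equal minima is statistically arbitrary
  (ties break toward fewer genes by design).
* Stability ranks and optimized reference sets are data-specific by
  construction and should never be carried from one experiment to another;
  the package recomputes them per dataset and offers no mechanism to reuse
  them, on purpose.
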