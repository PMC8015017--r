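---
title: "Disproportionality screening of spontaneous adverse-event reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality screening of spontaneous adverse-event reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvscreen)
```

## The problem

Spontaneous reporting systems such as Japan's JADER collect voluntary
reports of suspected adverse drug reactions. Each case links a patient
record (DEMO) to the drugs mentioned in the report (DRUG, each with a
participation role: suspected, concomitant or interacting) and to the
adverse events coded as MedDRA preferred terms (REAC). Because there is no
denominator of drug users, the standard screening approach is
*disproportionality analysis*: for a drug $x$ and an event $y$, compare how
often the pair is reported against the rate expected if $x$ and $y$ were
reported independently. The screening unit here is the 2×2 table

|              | event $y$ | no event |
|--------------|-----------|----------|
| drug $x$     | $a$       | $b$      |
| no drug $x$  | $c$       | $d$      |

with $N = a+b+c+d$ the size of the analysed cohort. `pvscreen` builds these
tables from JADER-dialect extracts and scores them with three detectors.

The counting unit is the case within each drug row: a case reporting two
suspected drugs contributes to both drugs' tables (the screen counts drug
mentions across rows), but contributes exactly once within a row, and the
composite-event indicator is binary per case no matter how many member PTs
the case reports. Every table on the same cohort therefore sums to the same
$N$.

## The three detectors

**Reporting odds ratio (ROR).** $\mathrm{ROR} = ad/bc$, with the Woolf
log-scale interval
$\exp\!\big(\ln \mathrm{ROR} \pm z\sqrt{1/a+1/b+1/c+1/d}\big)$, $z = 1.96$.
A signal is declared when the interval's lower bound exceeds 1. With any
zero cell the ROR is reported as undefined and cannot signal; the
Haldane–Anscombe 0.5 continuity correction is available as an explicit
option (`haldane = TRUE`) but is off by default, since a screen should
expose rather than mask degenerate tables.

**Proportional reporting ratio (PRR).**
$\mathrm{PRR} = \frac{a/(a+b)}{c/(c+d)}$, accompanied by the
continuity-corrected chi-square with margin-fixed expectations
$E = \text{row}\cdot\text{col}/N$:
$\chi^2 = \sum_{\text{cells}} \big(\max(|O - E| - 0.5,\, 0)\big)^2 / E .$
Flooring each cell's $|O-E|-0.5$ at zero is the standard convention for the
Yates correction; it makes $\chi^2$ exactly 0 on the symmetric unit table.
A signal requires all three of $\mathrm{PRR} \ge 2$, $\chi^2 \ge 4$ and
$n = a \ge 3$.

**BCPNN information component (IC).** The Bayesian confidence propagation
neural network estimate of $\log_2$ of the observed-over-expected reporting
ratio, with priors shrinking small-count estimates toward 0. With
$C = N$, $c_x = a+b$, $c_y = a+c$, $c_{xy} = a$ and priors
$\alpha = \beta = 2$, $\alpha_1 = \beta_1 = 1$, $\gamma_{11} = 1$,
$\gamma$ is derived from the margins,

$$\gamma = \gamma_{11}\frac{(C+\alpha)(C+\beta)}{(c_x+\alpha_1)(c_y+\beta_1)},$$

$$E(\mathrm{IC}) = \log_2 \frac{(c_{xy}+\gamma_{11})(C+\alpha)(C+\beta)}
  {(C+\gamma)(c_x+\alpha_1)(c_y+\beta_1)},$$

and $V(\mathrm{IC})$ is the matching posterior variance (see
`?compute_ic`). The IC is defined for every nonnegative table, zero cells
included — that is the point of the shrinkage. A signal requires the 95%
interval's lower bound to exceed 0.

Two anchors pin the implementation down: on the table $(1,1,1,1)$ the IC is
exactly 0, and as all cells grow proportionally the IC converges to the raw
$\log_2\!\big(aN/((a+b)(a+c))\big)$; both are asserted in the test suite at
×10/×100/×1000 scalings. For rare events ($c/d \to 0$) the PRR converges to
the ROR, with relative gap bounded by $a/b + c/d$.

### The IC interval: delta method versus posterior sampling

The default interval is $E(\mathrm{IC}) \pm z\sqrt{V(\mathrm{IC})}$ (delta
method). `ci_method = "monte_carlo"` instead samples the joint and margin
reporting probabilities from their Beta posteriors and takes the percentile
interval of $\log_2\big(p_{xy}/(p_x p_y)\big)$; on tables with all cells
≥ 100 the two lower bounds agree to better than 0.1 (tested). We flag this
choice prominently because published antipsychotic screens of JADER print
IC intervals substantially *wider* than either method produces — e.g. a
printed interval of (−0.16, 3.56) around an IC of 1.70 at $n = 12$ implies
a standard deviation near 0.95 where the Bate variance gives about 0.40 —
and the construction behind such intervals cannot be identified from the
published text. IC point estimates reproduce to the printed precision; IC
interval bounds, and therefore the IC signal/no-signal calls near the
boundary, may not. The interval method is a configurable, documented choice
rather than a claim of equivalence.

## Cohort construction

The screen follows the usual JADER preprocessing: keep female cases only
(sex is one of female/male/unknown), keep the study window (April 2004 to
April 2019 by default in quarter labels), count only *suspected* drug
mentions as exposure, and deduplicate re-reports. Two rules are deliberate
interpretations where the field's practice is not fully standardized:

* **Deduplication** keeps, per case id, the record with the highest report
  sequence — a re-report supersedes earlier versions of the same case. The
  operation is idempotent and is exercised round-trip against the
  generator's duplicate injection.
* **Participation filtering never drops cases.** Removing a case's
  non-suspected mentions can leave it with no mentions at all; the case
  stays in the cohort and contributes to $c$ or $d$. Anything else would
  shrink $N$ below the female-cohort size and make tables on the same
  cohort sum to different totals.

Drug names are matched exactly after trimming, whitespace collapsing,
full-width→half-width folding and case folding (public JADER files mix
widths); an optional user synonym map handles brand/generic variants. No
fuzzy matching is attempted.

Composite events are named sets of preferred terms. The packaged
`benign_and_malignant_breast_neoplasms` set carries the 60 PTs (with
MedDRA v22.0 codes) of the breast-neoplasm high level term grouping;
`hyperprolactinaemia` is a single-PT set, user-extensible to related terms
(e.g. blood prolactin increased) via a two-column file. Matching prefers PT
codes when both the report and the set entry carry one, falling back to
normalized names — public extracts often carry names only.

## The synthetic generator

`generate_cases()` emulates the four-table structure so the whole pipeline
is testable without the real database. The generative model is the simplest
one with a controllable ground truth: independent Bernoulli exposures per
drug; each composite event tied to one drug by a two-point model with
baseline probability $p_0$ among the unexposed and
$p_1 = \mathrm{OR}\,p_0/(1-p_0+\mathrm{OR}\,p_0)$ among the exposed, so the
population odds ratio equals the configured value; exposed drugs recorded
with role "suspected"; unexposed filler cases carrying no drug mention, so
a drug's report total equals its exposure count. Duplicate re-reports are
injected as a second DEMO row with incremented sequence sharing the case's
DRUG/REAC rows.

Defaults that are not dictated by the screening method itself were fixed
once: `female_fraction = 0.55` (a typical spontaneous-report sex balance),
report quarters uniform over 2004Q2–2019Q1 (the screen's default study
window), `duplicate_rate = 0` unless exercising deduplication. What the
generator does **not** model — reporting-time trends, drug–drug
interactions, correlated multi-event structure, real name variants,
informative missingness — bounds what green tests mean: they validate the
counting and the estimators under clean conditions, not robustness to the
messiness of real extracts.

Calibration of the generator itself is checked statistically: across 200
replicates of 500,000 cases at exposure probability 0.002, $p_0 = 0.002$
and true OR 4 (realistic rare-exposure, rare-event screening scale), the
Woolf 95% interval covers the configured OR at the nominal rate (the test
accepts 90–98%) and the mean log-ROR sits within three standard errors of
$\log 4$. `generate_from_counts()` is the exact-margin counterpart: it
builds a cohort that recounts to a requested $(a,b,c,d)$ exactly, which is
how published rows are turned back into case-level data.

## Reconstructing published screen tables

Published per-drug screen tables typically print $n = a$, the drug total
$a+b$, the statistics and one grand total $N$ — but not the event marginal
$a+c$. Given one printed ROR the marginal has the closed form

$$c = \frac{N - (a+b)}{1 + \mathrm{ROR}\cdot b/a}, \qquad
  \text{marginal} = c + a,$$

strictly decreasing in the printed ROR. `consistency_report()` inverts
every row, takes the median of the implied marginals as a robust consensus
(rounded to an integer), and flags rows deviating by more than 5% — the
median is used precisely so that a minority of anomalous rows cannot drag
the consensus. On the packaged breast-neoplasm table the consensus is
**1515** of 703,846 female cases, eight of the ten nonzero rows agree with
it to within 1%, and with that single marginal the package reproduces their
printed ROR, PRR, Woolf bounds and $\chi^2$ to printed precision, and the
IC for six rows (see below). Reconstruction of the hyperprolactinaemia
table is shipped as a diagnostic only: its rows imply mutually inconsistent
marginals (roughly 26 to 225), so no single marginal can reproduce it, and
the consistency report is the honest output.

Known irreproducible printed values in the packaged breast table, all
flagged rather than silently absorbed:

* the paliperidone and aripiprazole rows imply marginals of ≈770 and ≈1343,
  inconsistent with the other eight (different data cut or transcription
  error; undecidable from the published text);
* the olanzapine ROR interval repeats the haloperidol row's interval
  verbatim and disagrees with its own point estimate;
* the bromperidol and zotepine printed ICs (0.58, 1.94) are not reproduced
  by the Bate formula on their own reconstructed tables (0.68, 1.90), under
  any marginal consistent with their printed RORs.

## Numerical and design notes

* All cell arithmetic is done in doubles: margin products overflow 32-bit
  integers at realistic database sizes.
* Zero-cell policy: ROR and PRR report `defined = FALSE` (and never
  signal); IC is always defined. No silent continuity corrections.
* Screen output retains full precision; only the print method rounds to two
  decimals.
* Determinism: generators take explicit seeds and restore the caller's RNG
  state; `run_screen()` is byte-identical for a fixed config and seed.
* Orphan DRUG/REAC rows (case ids missing from DEMO) are dropped and
  counted, not errors — real extracts contain them. Unknown vocabulary
  values (an unexpected sex or participation string) *are* errors naming
  the value and row, because silently dropping them would bias counts.
* Problem sizes in the test suite were chosen for tight statistical checks
  at interactive runtimes: the oracle recount runs on cohorts of a few
  hundred cases, the null-OR check on 200,000, the coverage study on
  200 × 500,000.

## Limitations

Stratified or adjusted analyses (age, concomitant drugs), EBGM/MGPS,
sequence-symmetry and time-to-onset methods, multiple-testing control, and
MedDRA hierarchy traversal beyond user-supplied PT lists are out of scope.
Disproportionality signals are reporting disproportions, not incidence
estimates and not causal claims.
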