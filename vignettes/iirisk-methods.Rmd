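---
title: "Methods: the initiation-inactivation-repopulation risk model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the initiation-inactivation-repopulation risk model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(iirisk)
```

## The model

`iirisk` estimates the excess relative risk (ERR) of secondary malignancies
in cancer survivors from a mechanistic two-compartment model of normal cells
$n(t)$ and therapy-induced premalignant cells $m(t)$:

$$
\frac{dn}{dt} = \lambda n \left(1 - \frac{n}{N}\right) - k(t)\,n - \mu(t)\,n,
\qquad
\frac{dm}{dt} = r \lambda m \left(1 - \frac{n}{N}\right) - k(t)\,m + \mu(t)\,n.
$$

Both compartments repopulate logistically toward the homeostatic cell number
$N$, coupled through the normal-cell occupancy $n/N$; premalignant cells
grow a factor $r$ faster (or slower) than normal cells. Treatment enters
through the cell-kill rate $k(t)$ and the mutation-induction rate $\mu(t)$,
which move cells out of both compartments and from $n$ into $m$,
respectively. After the last treatment event both compartments regrow freely
and the premalignant count settles at a plateau value $M$; risk is reported
as $\mathrm{ERR} = g \cdot M$ and $\mathrm{RR} = 1 + \mathrm{ERR}$, where $g$
is an organ-specific proportionality factor absorbing demographic modifiers.

Along the untreated flow $d\log m = r\, d\log n$, so the plateau is available
in closed form from any post-treatment state:
$M = m \,(N/n)^{r}$. `risk()` uses this identity by default
(`evaluation = "plateau"`); `evaluation = "treatment_end"` reports $m$ at the
last treatment event instead. The regrowth window matters: premalignant
cells keep proliferating while the depleted normal compartment refills, and
the reported risks are only reached with this regrowth included.

## Treatment representation

**Radiotherapy.** A course of $K_R$ fractions of $d_R$ Gy is delivered on a
weekday calendar (day 0 is a Monday; `fractions_per_week = 5` skips
weekends, so 20 fractions span 26 calendar days). Each fraction is treated
as an instantaneous impulse — the exact limit of a pulse of width
$\tau \to 0$ at dose rate $d_R/\tau$:

$$
n^+ = n_0\, e^{-(\alpha_R d_R + \gamma_R d_R)}, \qquad
m^+ = m_0\, e^{-\alpha_R d_R} + \gamma_R d_R\, n_0\, e^{-\alpha_R d_R}.
$$

Newly created premalignant cells carry the factor $e^{-\alpha_R d_R}$
because, within the pulse, cells that mutate are still exposed to the
remainder of the pulse's kill. This map is *exact*, not a first-order
approximation; the package also ships a finite-pulse continuous integrator
(`integrator = "continuous"`, built on `deSolve::lsoda()`) as an
independent oracle, and the two agree to well below 0.5% (this is enforced
by the test suite).

**Chemotherapy.** A course of $K_C$ cycles of $d_C$ mg/m² (mechlorethamine
dose-equivalent), one cycle every $L = 30$ days. Within a cycle the
cytotoxic effect decays with the drug clearance rate $\alpha_d$, with the
decay clock reset at each cycle start $t_i$:

$$
k_C(t) = \frac{\alpha_C d_C}{L} e^{-\alpha_d (t - t_i)}, \qquad
\mu_C(t) = \frac{\gamma_C d_C}{L},
$$

i.e. the per-cycle coefficients $\alpha_C d_C$ and $\gamma_C d_C$ are spread
over the cycle as daily rates: kill front-loaded by the clearance decay,
mutation induction as a constant flux over the cycle. This convention is a
deliberate design choice — interpreting $\alpha_C d_C$ as an instantaneous
daily rate rather than a per-cycle budget collapses the normal compartment
and cannot reproduce the published cohort risks, whereas the spread-out form
matches the published chemotherapy-only tables to about 1%.

**Concurrent therapy and interaction.** Radiotherapy starts with the first
chemotherapy cycle. Radio-sensitization by the drug is modeled per fraction,
active only when a fraction is delivered during an ongoing cycle, in one of
two modes:

* `dose_multiplier` (default, the calibrated mode): the interaction factor
  $\varepsilon$ multiplies the radiation dose *in the cell-kill exponent
  only* ($d_{kill} = \varepsilon d_R$), while mutation induction keeps the
  physical dose. $\varepsilon = 0$ disables the interaction.
* `extra_kill_rate`: each interacting fraction applies an extra kill impulse
  $e^{-\varepsilon}$ to both compartments; $\varepsilon = 0$ is the additive
  limit.

## Parameters, units and defaults

`organ_params()` carries the full parameterization:

| field | meaning | unit | breast | lung | thyroid |
|---|---|---|---|---|---|
| `lam` | normal-cell proliferation rate | /day | 0.4 | 0.4 | 0.4 |
| `r` | relative premalignant growth rate | — | 0.76 | 0.96 | 0.68 |
| `N` | homeostatic cell number | cells | 1e6 | 1e6 | 1e6 |
| `alpha_R` | radiation cell kill | /Gy | 0.18 | 0.18 | 0.25 |
| `gamma_R` | radiation mutation induction | /Gy | 1e-6 | 1e-6 | 1e-6 |
| `alpha_C` | chemo cell kill | per mg/m² | 0.2 | 0.2 | 0.2 |
| `gamma_C` | chemo mutation induction | per mg/m² | 1e-9 | 0.5e-6 | 0.9e-7 |
| `alpha_d` | drug clearance | /day | 0.1333 | 0.1333 | 0.1333 |
| `g` | ERR proportionality | — | 1.2 | 0.18 | 1.0 |

Course defaults: 2 Gy per fraction, 5 fractions/week, 12 mg/m² per 30-day
cycle. Total doses are converted to whole fractions with
`K = round(D / d_R)` (banker's rounding, so 25 Gy gives 12 fractions).

```{r}
p <- organ_params("thyroid")
course <- concurrent_course(radiation_course(K_R = 10),
                            chemo_course(K_C = 5), epsilon = 2.6)
risk(p, simulate_course(p, course))
```

## Dose-response shapes

Because fractions kill premalignant cells as well as create them, the
radiotherapy-only dose response is bell-shaped for thyroid parameters (kill
eventually outweighs initiation plus repopulation) and still rising over the
clinical range for breast and lung:

```{r}
dose_response_curve(organ_params("thyroid"), seq(0, 40, by = 10),
                    fractions_per_week = 7)
```

On the weekday calendar the weekend gaps superimpose small phase wiggles on
the bell; the single-sign-change property of the derivative is therefore
stated (and tested) on the daily schedule, while the weekday schedule keeps
an interior maximum.

## Parameter extraction

Fitting is deterministic bounded 1-D least squares: a fixed grid pre-scan
followed by `stats::optimize()` refinement inside the bracketing cells,
with an explicit non-identifiability flag when the objective is flat. The
three pipeline steps are

1. `fit_relative_growth()` — $r$ from ERR-vs-dose data,
2. `fit_chemo_mutation_rate()` — $\gamma_C$ from RR-vs-cycles data
   (log10-scale search, since extracted rates span 1e-9 to 1e-6),
3. `fit_interaction()` — $\varepsilon$ from concurrent RR data, optionally
   shared across organs.

Unweighted SSE is the default; `weights = "inverse_variance"` derives
weights from the log-width of the reported 95% intervals.
`sensitivity_scan()` refits $\gamma_C$ across assumed values of another
parameter (by default `alpha_C` over 0.1–0.3) to check that the extracted
order of magnitude is robust.

```{r}
lung <- organ_params("lung")
fit_chemo_mutation_rate(data.frame(cycles = c(3, 6, 10),
                                   rr = c(4.0, 6.2, 13.0)), lung)
```

## Synthetic cohorts

`synthetic_spec()` + `generate_err_dataset()` / `generate_rr_dataset()`
produce cohort-style summaries with known ground truth for
parameter-recovery studies. Noise is multiplicative lognormal on the
*excess* risk with a stated coefficient of variation
($\sigma = \sqrt{\log(1 + cv^2)}$, median 1), so observed RR can fall below
1 as real cohort estimates do. A seed is mandatory whenever noise is
requested, generation is bitwise reproducible, and the generating
parameters plus the noise-free model curve travel with the data (the
`truth` attribute, written as a JSON sidecar by
`write_synthetic_dataset()`). The generator only produces summary-level
ERR/RR tables — not individual-level cohort data.

## Numerical choices

* Pulse-free segments are integrated with an adaptive Dormand–Prince 5(4)
  scheme implemented in C++ (relative tolerance 1e-8, absolute 1e-10 by
  default); integration failures raise errors rather than returning partial
  results.
* Treatment events are breakpoints: the integrator never steps across a
  fraction or a cycle boundary.
* The continuous finite-pulse integrator exists purely as a cross-check
  oracle and is about two orders of magnitude slower.
* All fits are deterministic; repeated calls are bitwise identical.

## Limitations

* The model tracks expected cell counts only — no stochastic extinction,
  no inter-patient variability beyond the `g` factor.
* Risks are evaluated at the regrowth plateau; age-at-exposure and
  attained-age dependence are absorbed into `g` rather than modeled.
* The chemotherapy description uses a single drug-equivalent dose scale;
  multi-agent pharmacokinetics are out of scope.
* Weekend-phase effects make shape statements schedule-dependent; see the
  dose-response section.
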