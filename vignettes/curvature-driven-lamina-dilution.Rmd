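---
title: "Curvature-driven lamina dilution: models, measurements and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curvature-driven lamina dilution: models, measurements and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curvlamina)
```

## The scientific problem

Nuclear envelope rupture spills genomic DNA into the cytoplasm and is a
hallmark of confined cell migration, laminopathies and cancer. Two
physical observations organise this package. First, the lamin-B meshwork —
stiff, farnesylated, membrane-anchored filaments — thins specifically at
envelope sites of high *positive Gaussian* curvature: nuclear poles,
constricting pores, micropipette tips, but not at the saddle-shaped cusp
where a pipette wall meets the nucleus. Second, the lamin-A meshwork is
mobile and behaves viscously: it dilutes only when curvature is imposed
*fast*, above a critical extension rate, and otherwise fortifies the
envelope even where lamin-B has thinned.

## The single-filament detachment model

We treat one lamin-B filament of in-situ length $L_{fil}$ and persistence
length $\ell_p$ as a two-state system, attached to or detached from the
inner nuclear membrane. Taking the detached state as energy reference, the
attached state at membrane curvature $1/R$ costs

$$E_{att} = -E + \frac{a}{R} + \frac{k}{2R^2}, \qquad
  k = \ell_p L_{fil}\ [k_BT\,\mu m^2],$$

where $E \ (k_BT)$ is the flat-membrane binding energy, $a \ (k_BT\,\mu m)$
converts curvature into lost filament–membrane contact area, and the
quadratic term is the bending cost of conforming a stiff filament to the
membrane. The Boltzmann occupancy of the detached state is logistic in
curvature:

$$P_{det} = \frac{1}{1 + e^{\,E - a/R - k/2R^2}},$$

rising from $1/(1+e^{E}) \approx 0$ on flat membrane (for $E \gg k_BT$)
to 1 at high curvature. All energies are expressed in $k_BT$ units so
temperature never appears explicitly, and the curvature argument is
$1/R\ (\mu m^{-1})$ rather than $R$, which keeps the flat limit
representable as exactly zero.

With the measured filament geometry, $\ell_p = 0.5\,\mu m$ and
$L_{fil} = 0.38\,\mu m$, the bending constant is
$k = 0.19\,k_BT\,\mu m^2$:

```{r}
bending_constant(0.5, 0.38)
```

At physiological curvatures ($\lesssim 1\,\mu m^{-1}$) this term shifts
detachment probabilities by less than 0.05 across a broad grid of
$(E, a)$ (a property the test suite asserts), so fits routinely drop it.
Responses are therefore fitted with the three-parameter sigmoid

$$y = \frac{B}{1 + e^{\varepsilon - \alpha x}},$$

whose amplitude $B$ carries the units of the response (a percentage for
rupture frequencies, a ratio for pole intensities) while
$\varepsilon, \alpha$ play the roles of $E, a$.

### Fitting: modes, multi-starts, degeneracies

`fit_sigmoid()` exposes two modes. *B_only* keeps
$(\varepsilon, \alpha)$ fixed — they were determined in earlier work and
are **not** hard-coded here; the user must supply them — and solves the
amplitude in closed form, $B = \sum w s y / \sum w s^2$ with
$s = 1/(1+e^{\varepsilon - \alpha x})$. *full* mode estimates all three
parameters by Levenberg–Marquardt least squares from five deterministic
multi-starts with log-spaced initial $\alpha$ (spanning three decades
scaled to the design range); the best residual wins and ties go to the
smallest $\alpha$, which prefers the shallowest curve among equivalent
optima. Whether the original cohort fits weighted points by trial count is
not documented, so both weighted (`n_trials`) and unweighted routes exist.
All-zero responses return $B = 0$ with zero residual rather than an
error; logistic exponents are clipped at $\pm 700$ before exponentiation
because saturated probabilities are physically meaningful limits, not
failures.

## Curvature measurement

Curvature along a nuclear contour is measured exactly as in the imaging
procedure: a least-squares circle is fitted to the contour within an
arc-length window and $1/R_{fit}$ reported, signed positive where the
contour bulges outward. The algebraic (Kåsa) fit is refined by one
geometric Gauss–Newton step — deterministic, robust, and adequate at
segmentation noise scales. Exactly collinear windows return curvature 0
(infinite radius). Pore and pipette curvatures are simply $2/D$.

Two ambiguities required decisions:

* **Window placement.** The experimental description ("overlap the surface
  for a distance of 2 µm") does not say whether the window is one-sided.
  We centre it on the query point: symmetric windows are unbiased at the
  extrema (poles) where curvature is actually read off.
* **Window vs feature scale.** The 2 µm default matches nuclear pole radii
  of order 1–2 µm. On shapes whose curvature varies strongly within 2 µm
  of arc (the poles of a 10:3 ellipse, say) any fixed window averages the
  peak down; validation against analytic extrema therefore uses windows
  small relative to the curvature-variation scale. For very small closed
  contours the window is clamped to half the perimeter so the fit never
  wraps onto itself.

Regime thresholds (low/medium/high) are configuration, not constants —
the published shading boundaries are graphical. Boundaries classify
upward, and negative (concave) curvatures classify as `low` with a
warning, since the detachment model concerns positive Gaussian curvature;
`gaussian_sign()` handles the saddle/cylinder bookkeeping when a second
principal curvature is available.

## Intensity metrics

Line profiles are min–max normalised and pole intensities averaged over
the first 1 µm. The window average is a trapezoidal integral divided by
the window width rather than a raw sample mean: the experimental profiles
were uniform pixel grids, but CSV inputs need not be, and trapezoidal
averaging is exact for linear interpolants on any grid. Dilution is
$\varphi = \text{inside}/\text{tip} - 1$ (zero when the tip has lost
nothing), with `relative_tip_intensity()` its reciprocal view
$1/(1+\varphi)$; spindle-pole measurements reuse the same measure with
(centre, pole) in place of (inside, tip). Background subtraction is an
explicit upstream step — mirrored from the experimental procedure, which
subtracts background for pipette measurements only.

## Rupture statistics

**Multi-site independence.** The observed fractions of migrated nuclei
with 2 and 3+ blebs/scars match powers of the single-rupture probability.
We read that model as $P(N \ge k) = p_1^k$ — a $k$-th rupture occurs with
probability $p_1$ given $k-1$ already have. This chain reading is
self-consistent with the 2 and 3+ classes; a fixed-site binomial model
would instead predict $3p^2(1-p)$ for "exactly 2" and contradict the
printed functional form. The published comparison was visual; the formal
goodness-of-fit test here is an extension: classes $\{0, 1, 2, 3+\}$ with
expected counts below 5 pooled downward, an exact multinomial tail
(likelihood ordering, vectorised enumeration) for cohorts under 200 cells
and Pearson's chi-square above, plus Holm adjustment when testing several
pore diameters at once.

**Regime enrichment** divides the fraction of rupture-site curvatures in
each regime by the regime's perimeter occupancy, so 1 means "no
preference"; regimes absent from the perimeter yield a flagged `NA`
rather than an error, and an empty rupture list yields enrichment 0.

**Critical-rate hinge.** Lamin-A dilution versus extension rate is fitted
with $\varphi = c\,\max(0, \text{rate} - r_{crit})$. At fixed breakpoint
the slope is a closed-form projection, so the fit is a 1-D search over
$r_{crit}$: a deterministic 201-point grid over the observed rate range
refined by local optimisation between the flanking grid points. The
objective is piecewise smooth with kinks at the data rates; the
coarse-to-fine scheme avoids both local minima and stochastic seeds. If
no positive dilution is observed the fit returns the maximum observed
rate flagged `"no dilution detected"`. For lamin-B, which dilutes in
proportion to rate from zero, the recovered $r_{crit}$ is ~0.

## What the synthetic generators emulate

`generator_config()` fixes the study conditions once:

| parameter | default | rationale |
|---|---|---|
| pore diameters | 2.25, 3, 4, 5, 6, 8 µm | etched + commercial pore range; curvatures 0.25–0.89 µm⁻¹ |
| cells per pore | 500 | cohort size at which the sigmoid refit is tested |
| sigmoid $(B, \varepsilon, \alpha)$ | 102, 4, 8 | $B$ from the overall rupture-frequency fit (percent scale); $\varepsilon/\alpha = 0.5\,\mu m^{-1}$ places the half-rise at the pipette curvature, central in the pore range — the published $\varepsilon, \alpha$ values are not printed, so these are the package's single choice |
| hinge (slope, $r_{crit}$) | 1 per (µm/s), 0.2 µm/s | no numeric value is printed; 0.2 µm/s sits inside the probed 0.05–1 µm/s rate range |
| noise sd | 0.05 a.u. | additive Gaussian, the scale used in recovery tests |
| myosin-inhibition factor | 0.5 on $p$ | rupture roughly halves under myosin-II inhibition; an approximation knob, not a fitted constant |
| lamin-A relaxation | onset 60 s, $\tau$ 60 s | the long-time convergence of lamin-A toward lamin-B dilution is qualitative in the data; both constants are explicit config with no claim of realism |

Amplitudes above 1 are interpreted as percentages and divided by 100 when
converted to simulation probabilities. Cohorts draw site counts by
sequential Bernoulli trials (capped at the 3+ class), so the independence
structure holds by construction; aspiration traces hold the hinge law
exactly until the relaxation onset, which makes the generator/estimator
round trip exact at the standard 60 s readout. Noise is additive Gaussian
(not Poisson) because the emulated profiles are background-subtracted
averages over many pixels. The mapping from detachment probability to
fractional intensity loss assumes simple proportionality — a single
filament standing in for local meshwork density — and is the generator's
main idealisation.

What passing tests therefore show: the estimators recover the generating
model under realistic sampling noise at the stated problem sizes. What
they do not show: segmentation error, uneven illumination, bleaching,
cell-to-cell parameter variability, or any mechanical computation of
nuclear shape in a pore (geometry is imposed, never simulated). Contours
here are inputs; no image segmentation or 3-D surface reconstruction is
attempted.

## Problem sizes and determinism

The test suite exercises: 256-point contours for curvature oracles
(circles 0.5–10 µm, 10:3 ellipses); 20 replicate cohorts of 6 × 500 cells
for sigmoid recovery; a 10,000-cell cohort for the independence fractions;
500 null replicates of 100-cell cohorts for the test's empirical size;
20,000 perimeter samples for the enrichment null; and 30 aspiration traces
for hinge recovery. Every stochastic step runs under an explicit seed, and
a fixed `generator_config()` reproduces its CSV outputs byte for byte —
the manifest written next to each pipeline output records config, seed and
a config hash.

## Known limitations

* $\varepsilon$ and $\alpha$ have no defaults in the fitting layer; B-only
  fits require the user to supply values from prior calibration.
* The independence test conditions on a supplied $p_1$; estimating $p_1$
  from the same cohort (the published convention of using the one-bleb
  fraction) makes the test mildly conservative.
* 2-D contours carry one principal curvature; Gaussian-sign classification
  at poles assumes rotational symmetry unless the second curvature is
  supplied.
* Condition effects (myosin inhibition, hypotonic stress) act only as
  multiplicative modifiers on rupture probability — there is no
  intranuclear pressure model, by design.
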