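---
title: "Models and methods behind g4fold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind g4fold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4fold)
```

g4fold quantifies how a G-quadruplex (G4) folds and how a binding protein
shifts that equilibrium, from three kinds of measurements: single-molecule
FRET trajectories of surface-immobilized molecules, circular-dichroism (CD)
spectra/kinetics/melting curves, and binding titrations. This vignette
explains the models, the tunable parameters and their defaults, the numerical
choices, and what the synthetic-data generator does and does not emulate.

## The two-state FRET model

A molecule interconverts between a *compacted* low-FRET conformer (mean
apparent efficiency `e_low`, default 0.49) and a *folded* high-FRET G4
conformer (`e_high`, default 0.81), with first-order rates `k_lh` (folding)
and `k_hl` (unfolding). On a camera running at frame interval $\Delta t$ the
continuous-time chain is embedded in discrete time: the state is constant
within a frame and switches at a frame boundary with probability
$p = 1 - e^{-k\Delta t}$. The stationary folded occupancy is
$k_{lh}/(k_{lh}+k_{hl})$; the initial state is drawn from `p_init_high`,
which defaults to that stationary value but is a free parameter, because
refolded samples can sit far from equilibrium (a sample refolded in situ by
potassium addition shows only a few percent folded molecules even when the
rates alone would predict ~18%).

Per frame, donor and acceptor intensities are

$$ I_D = b_D + (1-E)\,I_{tot} + \varepsilon, \qquad
   I_A = b_A + E\,I_{tot} + \varepsilon, $$

with $E$ the state mean plus Gaussian state noise (`sigma_e_*`, default
0.06), $I_{tot}$ the shared total intensity (default 500 counts), constant
backgrounds (default 50 counts) and additive Gaussian channel noise (default
15 counts), an EMCCD read-noise-like model. Photobleaching is one
exponential lifetime per fluorophore with a single-step intensity change:
after the acceptor bleaches, the acceptor collapses to background and the
donor gains the acceptor's share (the anticorrelated step used to certify
single molecules); after the donor bleaches both channels collapse. Shot
noise, spectral crosstalk, gamma factors, triplet blinking and within-frame
motion blurring are deliberately not modeled: they change calibration, not
the structure of the estimation problem the package exercises.

## Trace processing

Photobleach detection looks for the largest single-frame acceptor drop
exceeding 5 robust noise SDs (noise estimated from the median absolute
frame-to-frame difference), requires an anticorrelated donor rise of at
least half the step within one frame, and then requires the acceptor's share
of the signal to stay collapsed (post-step raw ratio $I_A/(I_A+I_D)$ below
0.25, and no recovery above half the step). The last two conditions are what
separate a genuine bleach from a high-to-low FRET transition of the molecule
itself, which produces the same anticorrelated signature but leaves the
acceptor at its low-state level. Donor bleaching is a donor drop of the same
significance with no anticorrelated rise and the summed intensity collapsing
below 30% of its pre-step level.

FRET efficiency is $E = I_A/(I_A+I_D)$ after channel-wise background
subtraction. Corrected intensities are not clipped at zero and $E$ is not
clipped to $[0,1]$ — clipping would bias the Gaussian population fits — so
histograms extend over $[-0.1, 1.1]$. Frames with total intensity below 10%
of the ensemble median are marked invalid. Per-molecule population values
average the first 15 valid frames; molecules with fewer valid frames are
excluded from histograms (with a logged count) but keep contributing dwells
up to their bleach.

## Population decomposition

Histograms (0.02-wide bins) are fitted with a sum of one or two Gaussians by
least squares; the reported percent contributions are the component areas
$a_i\sigma_i / \sum_j a_j\sigma_j$. Initialization is a small multi-start:
component means from the modes of a fixed-bandwidth (0.025 E units) kernel
density of the values — robust to bin-width choice and able to seed minority
populations down to a few percent — plus, when visible, the raw histogram
peaks; the best residual wins. Component SDs are bounded below by half a bin
(a narrower "population" is indistinguishable from a single noisy bin) and
above by half the histogram range. A maximum-likelihood mixture fit on the
values themselves (EM, via mclust) is kept as an internal cross-check; the
two routes agree within a few points on the fixtures the tests run, which is
why the histogram fit — the convention in the smFRET literature — is the
primary route.

Model selection between one and two components uses an F-test on the
residual sum of squares at $\alpha = 0.01$, and additionally requires the
means to be separated by more than the larger SD and both components to
carry at least 5% of the area. The last rule is not classical: without it, a
two-bin sliver component can "significantly" absorb Poisson lumpiness of a
unimodal histogram. Five percent is below any population the analyses here
interpret, and the type-I behavior of the combined rule is tested.

## Dwell-time kinetics

States are assigned by thresholding at the midpoint of the two fitted
component means, after an optional (default on) width-3 median filter that
suppresses single-frame excursions; with the default noise and a 0.3 E-unit
separation, fewer than 1% of frames are misassigned. Maximal runs become
dwells; the first and last dwell of each molecule are flagged censored.

Three rate estimators are provided. The histogram estimator — least-squares
fit of $A e^{-kt}$ to the dwell-time histogram (2-frame bins), censored
dwells excluded — mirrors how such figures are conventionally produced. The
plain MLE, $k = 1/\overline{t}$ on uncensored dwells, is its closed-form
check. Both are accurate only when dwells are short compared to the
observation window. At this system's own operating point they are not: at
$k_{lh} = 0.011\,\mathrm{s^{-1}}$ the mean low dwell (~91 s) matches the
90 s trace (300 frames at 0.3 s), so discarding censored dwells keeps only
window-sized dwells and inflates the naive estimates several-fold — no
tuning can fix a length-biased sample. The default for pipeline rate
estimates is therefore the censoring-aware `"survival"` estimator: the exact
MLE of the discrete chain, $\hat p =$ transitions / frames-at-risk over
*all* dwells (censored dwells contribute exposure but no event), converted
through $k = -\log(1-\hat p)/\Delta t$. Start-censored dwells are valid
events by memorylessness. The residual discretization bias is below
$k\Delta t/2$ in this regime and is documented rather than corrected.
Minimum dwell is one frame; no missed-event correction is applied since
$k\Delta t \ll 1$.

Equilibrium folding free energy is $\Delta G = -RT\ln K_{eq}$ with $K_{eq}$
computed both from population fractions ($p_{high}/p_{low}$) and from rates
($k_{lh}/k_{hl}$); their ratio is reported as a two-state consistency check.

## CD analysis

Spectra are smoothed with a Savitzky–Golay filter (window 11 points, order
3; polynomials up to the order pass unchanged). Topology calls are
rule-based on smoothed-spectrum extrema: parallel G4s show a positive band
near 264 nm with a negative band near 240 nm; antiparallel G4s a positive
band near 295 nm with a negative 260 nm signal; two positive bands (264 and
290 nm) indicate a hybrid fold or a mixture of topologies. The windows
(255–270, 235–248, 285–300 nm) bracket those landmarks and are fixed
constants; bands below the noise floor (3 robust SDs of the smoothing
residual by default) are ignored, so a flat spectrum is `undetermined`, and
calls are invariant to positive rescaling.

Folding kinetics at a fixed wavelength are fitted with
$f(t) = a(1-e^{-bt})$ or $f(t) = a(1-e^{-bt}) + c(1-e^{-dt})$. Automatic
model selection takes the biphasic model only when the F-test at
$\alpha=0.01$ supports it *and* $b/d \ge 3$: the bi-exponential form is
unidentifiable as $b \to d$, and the guard prevents the degenerate
equal-rate solution. Rates are fitted in the time unit of the data and
reported in both s^-1 and min^-1. Melting curves are fitted with the
Boltzmann sigmoid
$\theta(T) = \theta_f + (\theta_u-\theta_f)/(1+e^{(T_m-T)/w})$ — the
functional form is the package's choice of "sigmoid"; sloping baselines are
out of scope, and the acceptance tolerances on $T_m$ are wide enough for
either convention. The sigmoid (and the isotherm below) are fitted with
`minpack.lm::nls.lm` on explicit residual functions, which proved more
robust than the formula interface on noiseless data.

## Binding and chemical shift perturbations

Titrations are fitted with
$r = r_{free} + (r_{bound}-r_{free}) f_{bound}$, where $f_{bound}$ comes
from the exact single-site depletion quadratic

$$ f = \frac{(P + D + K_D) - \sqrt{(P + D + K_D)^2 - 4PD}}{2D}. $$

The depletion form is the default even though the labeled DNA here (20 nM)
is far below the fitted $K_D$ (where it coincides with the hyperbola to
about one part in $10^3$), so the same code remains valid for tight
binders; the hyperbolic approximation is available as an option. A fit whose
$r_{bound}$ overshoots the maximum observed response by more than 20% of the
fitted amplitude is flagged `saturation_reached = FALSE`, reproducing the
qualitative behavior of a weak binder that never saturates within the
dilution range. CSPs are $\sqrt{(0.102\,\Delta\delta_N)^2 +
\Delta\delta_H^2}$; residues above mean + 1 SD are flagged as maximal.

## What the generator emulates, and the sizes the checks run at

The synthetic-data module generates every input the pipeline consumes, with
ground truth retained, so each stage is validated by parameter recovery:
stationary occupancy and exponential dwells of the simulated chain,
noiseless fits recovered to relative 1e-6, bleach lifetimes recovered from
detected steps, mixture fractions recovered within a few points, rates
recovered within the reported experimental uncertainties. Default condition
presets (`g4ix_conditions()`) encode the studied regimes: population centers
0.41 / 0.49 / 0.81 / 0.85 with 7% vs 63% folded, rates 0.011 / 0.050 and
0.021 / 0.036 s^-1 at 0.3 s frames, melting midpoints 41.2 and 52.8 °C, a
9.7 min^-1 CD folding rate, and a 16-point 1:1 dilution from 200 µM with
20 nM DNA at $K_D$ = 4.9 µM (weak-binder analog 85 µM). The population
widths (0.07 for the compacted state, 0.05 for the folded state) are chosen
once as typical smFRET histogram widths, since only the centers and their
fit uncertainties are reported experimentally. Kinetic CD traces for the
fast regime are sampled at 0.1 s over one minute, a realistic
single-wavelength acquisition rate.

Recovery runs use 150–300 molecules for populations, 200 molecules × 300
frames for kinetics, 141-point melting curves and 16-point titrations —
desk-scale sizes at which every documented tolerance holds. Because all
molecules share the same state means, simulated ensembles lack the static
heterogeneity that broadens real histograms, and the noise model omits shot
noise and photophysics beyond single-step bleaching; passing tests therefore
demonstrate correctness of the estimators under the stated model, not
instrument calibration on real data.

## Worked example

```{r example, eval = FALSE}
m <- two_state_model(k_lh = 0.011, k_hl = 0.050,
                     frame_interval = 0.3, n_frames = 300)
report <- run_smfret_workflow(model = m, n_molecules = 200, seed = 1)
report$rates$low_to_high$rate   # ~0.010 s^-1
report$rates$high_to_low$rate   # ~0.055 s^-1
report$fractions                # area percent of the two populations
```

## Known limitations

Two FRET states only (no hidden-Markov or Bayesian state inference);
thresholding-based assignment with optional hysteresis left off by default;
no quantitative CD basis-spectrum deconvolution or van't Hoff analysis; no
Hill or multi-site binding models; no transition-path or barrier-height
analysis — only equilibrium $\Delta G$ is computed.
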