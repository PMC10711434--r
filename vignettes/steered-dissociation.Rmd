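---
title: "Contact-map steered dissociation: models, estimators and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact-map steered dissociation: models, estimators and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pullpmf)
```

`pullpmf` turns ensembles of steered-MD work curves into dissociation
free-energy profiles for protein–DNA complexes, and builds the contact-map
collective variables that the steering engine pulls on. This vignette is
the package's own account of the science: the models, their assumptions,
the tunable parameters, and the numerical decisions — including the ones
where the design was genuinely open.

## The contact-map collective variable

The reaction coordinate is a count of hydrogen-bond-like contacts between
protein donor atoms and DNA groove acceptor atoms. Each donor–acceptor
pair at distance $r$ (nm) contributes a weight from the rational switching
function

$$c(r) = \begin{cases} 1, & r < d_0,\\[2pt]
\dfrac{1 - x^{nn}}{1 - x^{mm}}, & x = (r - d_0)/r_0 \ge 0,\end{cases}$$

which is continuous, non-increasing, and decays to zero whenever
$mm > nn$. Two parameter sets serve two purposes:

| set | $r_0$ (nm) | $d_0$ (nm) | $nn$ | $mm$ | role |
|---|---|---|---|---|---|
| descriptive (`contact_switching()`) | 0.4 | 0.25 | 2 | 4 | counts a hydrogen bond (< 0.35 nm) as 1 and a 0.7 nm contact as 0.5; resolves binding modes |
| steering (`steering_switching()`) | 3.0 | 0.3 | 1 | 12 | decays near-linearly over 0.3–3.0 nm ($R^2 > 0.998$), so the moving restraint displaces every contact at a near-constant rate |

The total count $C$ sums over all pairs; per-donor counts $C_j$ (Q112,
G113, R114, R93 for the H-NS DNA-binding domain) partition it exactly and
drive the mechanism analysis. Selection conventions keep counts comparable
between sequences: exactly one acceptor atom per nucleobase — minor groove
N3 (purines) / O2 (pyrimidines); major groove O6 (G), N7 (A), O4 (T), with
cytosine contributing none by default because its major-groove face
presents only the N4 amino *donor*. Both tables are user-overridable,
because contact maps for new systems (e.g. major-groove binders like the
ETS domain) are expected to be adjusted.

The steering coordinate is the affine map
$\lambda = (C - c_\mathrm{end})/(c_\mathrm{start} - c_\mathrm{end})$;
the H-NS study conditions steer from 108 to 65 contacts in linear-map
units. $\lambda$ is deliberately not clamped: excursions outside $[0,1]$
are physically meaningful (deeper binding, further dissociation) and are
flagged with a warning instead. A comparison of two sequences is only
valid under a *shared* `lambda_map()`, which the functions therefore take
explicitly.

Two geometry decisions follow the steering protocol rather than general
MD practice. Distances feeding the contact map are computed **without**
minimum-image wrapping by default: as the complex is pulled apart, a
periodic image of the partner can come closer than the real partner and
would corrupt the coordinate; `pbc = TRUE` restores minimum-image
behaviour for other uses. And the paper-style donor list names an NZ atom
on arginine, which does not exist in arginine topology; the preset remaps
NZ → NE with a warning rather than failing or silently dropping a donor.

## Work accumulation and engine interchange

The moving harmonic restraint of stiffness $k_f$ (kJ/mol per squared
contact count — the CV is dimensionless, so the printed engine unit
"kJ/mol" is interpreted per contact²) does discrete work

$$w(t_k) = \sum_{j \le k} k_f\,\bigl(c_\mathrm{ref}(t_j) - C(t_j)\bigr)\,
\Delta c_\mathrm{ref}(t_j),$$

accumulated on the restraint-center grid. Attributing work to
$\lambda(c_\mathrm{ref})$ rather than to the instantaneous $C$ puts every
run of an ensemble on a common λ axis by construction, which the
exponential average needs. Engines that report their own work column are
used as-is; otherwise the package re-accumulates from the CV series, and
the two routes agree exactly at full output resolution (they differ only
by the stride discretization of the stored series). A curve whose first
work value is non-zero is shifted to zero — the work origin is a gauge
choice — with a warning.

## The Jarzynski estimator and its error band

Pointwise over the shared grid,

$$\Phi(\lambda) = -\tfrac{1}{\beta}\Bigl[\operatorname{logsumexp}\bigl(-\beta w_i(\lambda)\bigr) - \ln N\Bigr],$$

evaluated with log-sum-exp stabilization (the exponential average is
dominated by rare low-work trajectories; naive exponentials underflow).
Free energies are reported in kcal/mol with $k_B = 0.0019872041$
kcal/(mol K) and a fixed 4.184 kJ/kcal conversion; reduced-unit toy data
pass `work_unit = "kT"`, which sets $\beta = 1$.

The error band is the work standard deviation across runs, emitted in two
forms: the dimensionless $(\beta/2)\sqrt{\langle w^2\rangle - \langle
w\rangle^2}$ exactly as conventionally printed, and the plain SD in
kcal/mol, because the band is drawn on an energy axis. **Population**
variance is used, matching the closed formula rather than the $n-1$
sample convention; with 20 runs the difference is 2.5% of the band and
immaterial, but the choice is fixed and documented here.

$\Delta W = \max\Phi - \min\Phi$ over the grid (not endpoint-to-endpoint:
an interior extremum wins when present), and
$\Delta\Delta W = |\Delta W_A - \Delta W_B|$ is symmetric.

Useful invariants, all enforced in the test suite: $\Phi$ equals the work
curve when all runs are identical; $\Phi \le \langle w\rangle$ pointwise
(Jensen), with equality only for identical curves; and for Gaussian work
with SD $s$, $\Phi \to \mu - \beta s^2/2$ — the sharpest closed-form
oracle available, provided by `gaussian_work_ensemble()`.

## Mechanism surfaces and pathway classes

The 2D mechanism surface bins all (C_Q112, C_R114, work) samples of an
ensemble on a 100 × 100 grid (the default; configurable) and assigns each
occupied bin the Boltzmann-weighted mean work
$z = \sum w_k e^{-\beta w_k} / \sum e^{-\beta w_k}$, again log-sum-exp
stabilized. Empty bins receive a fill strictly above the maximum observed
work — 1.05 × max by default, with a fallback of
$\max + 0.05(|\max| + 1)$ when the maximum is not positive, so the
"fill > max" invariant survives degenerate inputs. The binned construction
is authoritative; `smooth_surface()` offers optional least-squares
polynomial smoothing of occupied bins as a cosmetic post-process, off by
default. The temperature entering β for the surface defaults to the
simulation temperature (298 K), since nothing else is defensible without
further information.

Pathway classification reads the glutamine count at the first downward
crossing of total = 30 contacts (linear interpolation between bracketing
samples): `R-G-Q` below 5, `Q-G-R` above. The rule as usually stated
covers both $\le 5$ and $\ge 5$, double-counting exactly 5; ties are
labeled `R-G-Q` — the branch conventionally written first — and flagged
in a `tie` column rather than silently absorbed. First-crossing semantics
make the label invariant to recrossings and to uniform time-resampling.

## Groove geometry and deformation

The minor-groove width is a deliberate simplification of curvilinear
helical-axis definitions: for the strand-1 phosphate at base-pair index
$i$, the width is the minimum distance to strand-2 phosphates at base-pair
indices $i-3$, $i-2$, $i-1$ (the registers spanning the minor groove in
B-DNA), minus 0.58 nm (twice the phosphate van-der-Waals radius). No
helical axis is fitted. This preserves the relative narrowing/widening
trends the protocol interprets — AT-tracts narrow, GC widens — at the cost
of absolute accuracy; positions without phosphates (5′ termini) are
reported absent (`NA`), never zero. DNA deformation is tracked as
optimal-superposition RMSD (Kabsch, via SVD with reflection correction),
and `correlate_max_work_rmsd()` quantifies the diagnostic that high-work
runs coincide with large DNA deformation.

## The toy simulator: what it emulates and what it does not

`simulate_steered_langevin()` integrates a scalar coordinate in a flat,
harmonic or double-well potential with the Euler–Maruyama overdamped
update

$$x \leftarrow x - \frac{\Delta t}{\gamma}\,\partial_x\bigl(V + \tfrac{k}{2}(x - c)^2\bigr) + \sqrt{2 k_B T \Delta t/\gamma}\,\eta,$$

the trap center $c$ moving linearly from $x_0$ to $x_1$, work accumulated
with exactly the discrete rule above, output written as the same
COLVAR-style tables the engine pipeline reads. Reduced units ($k_B T = 1$
by default) keep the oracles analytic: a translated trap over a flat
potential has $\Delta F = 0$ with strictly positive mean (dissipated)
work; a stiff trap dragged across a harmonic well recovers
$\tfrac{\kappa}{2}(x_1^2 - x_0^2)$; a static trap preserves the Boltzmann
distribution.

What it does *not* emulate: the toy coordinate has no molecular
structure, so passing tests demonstrates that the estimators, file
formats and work bookkeeping are correct — not that a particular
force field, contact map or pulling speed samples a real complex
adequately. Run-to-run variance is tunable through the friction,
temperature and drag speed, but the heavy-tailed work distributions of
strongly deformed DNA (the high-RMSD runs) have no toy counterpart.

Numerical guardrails: the stability bound
$\Delta t\,(\kappa + k_\mathrm{trap})/\gamma < 0.1$ is enforced at entry
and divergence aborts with the bound in the message. Euler–Maruyama
inflates the stationary variance by $O(\Delta t\, K/\gamma)$, so
quantitative checks run at $\Delta t\,K/\gamma \lesssim 0.04$ — e.g. the
stiff-spring recovery uses $\Delta t = 2\times10^{-4}$ with $10^5$ steps.
Initial positions are drawn from the exact trap-plus-potential stationary
distribution, so no burn-in is wasted. Every trajectory is
bit-reproducible from its integer seed (R's default Mersenne Twister via
an isolated `withr::with_seed()` scope).

## Numerical choices, tolerances, degenerate inputs

* The switching function's $x = 1$ point is a 0/0 form; the analytic
  limit $nn/mm$ is substituted within $|x - 1| < 10^{-6}$ to avoid
  catastrophic cancellation.
* Contact counts are dimensionless floats end to end; nothing rounds.
* `read_work_curves()` linearly interpolates all runs onto the densest
  λ grid present; inconsistent pull direction or NaNs are per-file
  errors, a non-zero starting work is a gauge shift with warning.
* A single-curve "ensemble" degrades to $\Phi = w$ with a warning rather
  than an error, since it is occasionally useful for inspection.
* Zero variance in either coordinate makes the Pearson correlation
  undefined; it is reported `NA`, never 0.
* Start-frame selection applies all contact windows jointly (logical
  AND), draws uniformly without replacement, and errors with the
  qualifying count when too few frames qualify.

## Study conditions baked into defaults

Defaults mirror the H-NS protocol: 20 runs per ensemble, 108 → 65 contact
steering range, 500 kJ/mol restraint (per contact²), 100 ns pulls at a
2 fs step for input emission, start-frame windows Q112: 10.25 ± 0.125 and
R114: 23 ± 0.25, 298 K, 100 surface bins per axis, classification
thresholds 30 (total) and 5 (Q112). Desk-scale test and acceptance runs
use toy problem sizes chosen to finish in seconds while leaving the
statistical checks sharp: 500-run flat drags, 200-run stiff-spring drags,
$10^5$-sample Gaussian ensembles, 20-run file-pipeline comparisons.

## Known limitations

* Trajectory readers cover DCD and multi-model PDB; XTC is not parsed.
* The groove-width dialect is the phosphate-distance approximation
  described above, not a helical-axis definition; absolute widths carry
  that caveat.
* No bidirectional estimators (Crooks/BAR), no bootstrap error beyond the
  work SD, no reweighting to other temperatures: the package estimates
  exactly what the unidirectional protocol provides.
* Steering-input emission targets the PLUMED dialect only.
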