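---
title: "A minimal neural model of foraging choice, reward, and addiction-like dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A minimal neural model of foraging choice, reward, and addiction-like dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slugforage)
```

## The model

`slugforage` simulates a single generalist forager, modeled on the predatory
sea slug *Pleurobranchaea californica*, choosing between approach and
avoidance of odor sources in a toroidal arena. Three item types share the
world: a benign, nutritive prey (hermi), a noxious, nutritive prey (flab),
and a drug-like item that delivers a large positive reward but no nutrition.
Every behavioral claim the package makes is produced by the interaction of
four small components; there are no special-case rules for "addiction".

**Odor environment.** Each live item deposits its own signature odor, and
prey additionally deposit betaine, a resource signal predicting nutritional
content. Fields diffuse by an 8-neighbor toroidal kernel (a fraction
`diffusion_fraction` of each cell's content is shared equally with its
neighbors each tick) and evaporate multiplicatively. The defaults
(`diffusion_fraction` 0.5, `evaporation_fraction` 0.05/tick, deposits
0.5/tick) give quasi-static plumes with an e-fold length of about 2 patches
and a sensing horizon of roughly 25-30 patches under the logarithmic
transduction below — large enough to support chemotaxis, small enough that
search matters.

**Sensing and turning.** Two sensors sit at `heading ± 40°`, 3 patches from
the body center. Transduction is logarithmic,
`s = max(0, 7 + log10(c + 1e-7))`, so a plume is usable over five orders of
magnitude of concentration. The somatic map is a body-referenced place code:
the side with the larger summed input defines the stimulus side, and
`gain_turn × |left − right|` (capped at `max_turn`) sets the turn amplitude.
Direction is set separately by appetitive state: at or above
`approach_threshold` the turn is toward the stimulus, below it away. This
separation — amplitude from the place code, sign from central state — is the
model's core decision motif.

**Incentive and appetitive state.** Learned positive and negative values
(`V+`, `V−` per signature, both in [0, 1]) weight the side-summed sensor
inputs into a scalar incentive

    I = Σ V+_k s_k + w_betaine s_betaine − Σ V−_k s_k .

Appetitive state is a logistic readout of a linear drive integrating
incentive, hunger, satiation, reward experience (RE), and pain (P):

    AS = σ( I + h0 (1 − S)(1 + c_w max(0, −RE))
              − c_s S (1 + c_re max(0, RE)) − Q(RE, P) − θ )

with `Q` the net suppression from the reciprocal inhibition of reward
experience and pain (below). Hunger (`1 − S`) drives appetite and is
amplified in withdrawal (negative RE); satiation suppresses it, more
strongly under positive RE; large positive RE or unopposed pain suppresses
it directly. Consumption requires appetitive state at or above
`bite_threshold` within `capture_radius`.

**Reward learning.** Each consumption event applies one Rescorla-Wagner
update to the consumed signature only: rewarding events drive `V+` toward
`min(1, reward / r_norm)`, noxious events drive `V−` toward
`min(1, |reward| / r_norm)`, and reward-free consumption extinguishes `V+`
toward zero. The learning rate α = 0.3 is pinned by the pre-feeding
calibration: fifteen feedings must reach the maximum of 1 at two-decimal
reporting, and `1 − (1 − α)^15 ≥ 0.995` requires `α ≥ 0.298`.

**Homeostatic reward circuit.** Rewards enter a pulse trace `u` (decay
`τ_u` = 50 ticks) feeding neuron R on top of a tonic baseline
(`x_R = max(0, r0 + u)`, `r0 = 1`). Neuron M multiplies R by a plastic
weight, `x_M = W x_R`, and W follows a homeostatic setpoint rule,
`W ← W + η_W (M_set − x_M)`, clamped to [0.05, 2]. Reward experience is the
linear readout `RE = k_RE (x_M − M_set)`. The tonic baseline is what makes
withdrawal possible at all in a multiplicative synapse: after sustained
reward has depressed W, removing input leaves `x_M = W r0 < M_set`, i.e.
negative RE, which then relaxes back as W recovers. One parameter pair sets
the two addiction timescales: desensitization tracks `1 / (η_W x_R)` (fast
under strong input) and resensitization tracks `1 / (η_W r0)` (2000 ticks at
the default `η_W` = 5e-4), so withdrawal outlasts the binge that caused it.

**Pain.** A pain center integrates applied stimuli with decay `τ_P` = 30
ticks and contributes an aversive-side input to the somatic map at its
body-relative bearing. Pain and positive reward experience are reciprocally
inhibitory: `P_eff = max(0, P (1 + c_p max(0, −RE)) − k_pr max(0, RE))`,
`RE_eff = max(0, max(0, RE) − k_rp P)`, `Q = P_eff + RE_eff`. Matched pain
and positive RE cancel — which is why a pain stimulus can *disinhibit*
appetitive state and evoke an approach turn in a forager with high reward
experience — while negative RE amplifies pain.

## Experiment protocols

**Presentation mode** immobilizes the forager (translation off, turning
free), clamps satiation and/or reward experience ("fixation of variables"),
places one item 5 patches ahead at bearing +30°, and classifies the net
heading change toward the stimulus over 300 ticks (after 200 ticks of field
equilibration) with a 5° dead zone. The item sits at +30° rather than dead
ahead because the two-sensor geometry makes bearing 0° a permanent
left-right tie: the somatic amplitude would be identically zero and no trial
could ever classify. Selectivity maps run one presentation per cell of a
10 × 9 grid (satiation `seq(0.01, 1, length.out = 10)` spanning the
clamped satiation range; reward experience −20…20 in steps of 5). The
drug-free state sets `V+`(hermi) = `V−`(flab) = 1 with the drug naive; the
addicted state additionally sets `V+`(drug) = 1, by direct assignment (the
pre-feeding route to the same values is exercised separately). The pain map
applies a sustained stimulus of strength 10 to the right anterior region
(bearing −45°) over a 10 × 11 grid with reward experience −10…10. A
sustained stimulus of strength A is maintained by applying `A/τ_P` per tick,
which holds the pain output at A in steady state — keeping P on the same
scale as the reward-experience axis it is traded off against
(`k_rp = k_pr = 1`).

**Addiction cycle mode** is a free run through four phases (5000 / 10000 /
5000 / 10000 ticks): prey only (3 hermi + 3 flab, respawning at uniform
random sites when eaten); drug introduced (6 respawning drug items, full
reward); drug removed; drug without reward (drug present with unchanged
odor, zero reward). The forager starts naive with nutrition at its fed
baseline. Ten trials with derived child seeds are aggregated into per-tick
mean ± SEM (sample SD / √n; SEM with one trial is reported as missing, not
zero).

## Free-running locomotion

Two purely locomotor rules apply only in free runs (never in presentation
mode, whose trials stay deterministic):

- *Heading jitter*: Gaussian noise (SD 4°/tick) on the executed turn. A
  deterministic straight-line search on a torus revisits a measure-zero set
  of tracks; real foragers' paths are noisy.
- *Escape bouts*: an avoidance decision made while a stimulus is present
  commits the forager to its avoidance orientation for 50 ticks
  (~37 patches at default speed). Without this, a hungry forager stalls
  indefinitely on the radius around a noxious plume where hunger-driven
  approach and learned aversion balance exactly — a deterministic limit
  cycle with no biological counterpart, since real avoidance is expressed as
  a ballistic bout, not an instantaneous re-decision.

## Calibration of the decision constants

The model's qualitative claims pin the constants tightly; the shipped
defaults were chosen to satisfy all of them jointly, by the following
arithmetic rather than by fitting:

- The pain map requires approach toward a strength-10 stimulus at minimal
  satiation and neutral RE: `h0 > P + θ = 11`, hence `h0 = 12`. Avoidance at
  S ≥ 0.8 then follows for any `c_s > 0`.
- Approach toward pain at some S ≥ 0.5 under high positive RE (where matched
  pain and RE cancel, Q = 0) bounds the satiated suppression:
  `c_s (1 + 10 c_re) < h0 − 2θ` at S = 0.5; `c_s = 2`, `c_re = 0.1` leave a
  3-unit margin.
- Avoidance of pain at *all* satiation under withdrawal couples the two
  amplification gains: `h0 (1 + c_w |RE|) < P (1 + c_p |RE|) + θ` for
  |RE| ≥ 5 requires `c_w ≲ 0.08 + 0.83 c_p`. The withdrawal-overeating
  dynamics of the addiction cycle want `c_w` large; `c_w = 0.9` with
  `c_p = 1.2` satisfies both sides.
- The drug's odor deposit (5/tick versus 0.5 for prey) realizes "drug valued
  above all prey" within the incentive formula: learned values cap at 1 for
  both drug and hermi, and hermi additionally collects the betaine term, so
  only a stronger drug signature (log-sensing adds ~2 to its side-summed
  input) makes drug incentive exceed hermi incentive everywhere
  (`w_betaine = 0.02` keeps the betaine term from reversing it).
- `k_RE = 10` scales the readout so that free-running reward experience
  spans roughly the −20…20 band the selectivity maps sweep: a fresh drug
  consumption peaks near +40 and desensitized consumption near +20, while
  the deepest attainable withdrawal (`W` at its floor) reaches −9.5.

## What the defaults produce

At these defaults the package's own test suite verifies, end to end: the
two-decimal pre-feeding calibration; the four-phase opponent-process shape
of the reward-experience timecourse (onset peak, adaptation under input,
negative undershoot at offset, recovery); the selectivity-map patterns
(corner avoidance at maximal satiation and RE, strict containment of the
hermi-approach set inside the drug-approach set in the addicted state,
withdrawal disinhibition, flab avoided at S ≥ 0.5 while hermi is approached
there); the pain-map patterns (approach at starvation, avoidance when fed,
reward analgesia, withdrawal hyperalgesia); and, over ten seeded trials of
the addiction cycle, withdrawal overeating, mini-withdrawals, cravings
(faster drug re-engagement after reintroduction), and extinction of the
drug's learned value below 0.1 under reward-free consumption.

## Numerical and design notes

- Within a tick: deposit → diffuse → evaporate → sense → decide → move →
  consume → learn → satiation update. Any fixed order is defensible; this
  one is documented and tested.
- Ties in the somatic map (equal side sums) map to "center" and a zero turn:
  the decision path contains no randomness.
- One root seed drives everything; trial k uses a child seed derived by a
  fixed offset, so trial k is invariant to the trial count.
- Grid experiments are deterministic given the configuration; the seed is
  recorded in the output manifest for provenance.
- The diffusion kernel is compiled (Rcpp); everything else is plain R.
- Problem sizes used by the shipped tests: the end-to-end behavioral suite
  runs at the full 200 × 200 defaults; unit tests use 30-60 patch arenas and
  shortened phases.

## Limitations

The agent has no body mechanics, no feeding motor pattern, and no episodic
or sequence memory; learning is single-cue (no compound-stimulus
competition, blocking, or overshadowing); all rewards share one circuit
channel, so noxious and rewarding inputs interact only through the pulse
trace; the odor physics is patch diffusion, not fluid dynamics. The
synthetic environment emulates plume structure, respawning prey, and
reward/nutrition contingencies, but not turbulence, prey motion, or
multi-animal competition — passing tests show the *decision architecture*
produces the claimed phenomena, not that a real forager's kinematics are
reproduced.
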