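# slugforage

An agent-based simulator of cost-benefit foraging decisions in a generalist
predator modeled on the sea slug *Pleurobranchaea californica* — and of the
addiction-like dynamics that emerge when a high-reward, non-nutritive
"drug" item enters its world.

A single forager tracks odor plumes on a toroidal arena. Turn *amplitude*
comes from a body-referenced somatic map of stimulation; turn *direction* is
set centrally by **appetitive state**, a logistic readout of the drive

```
AS = σ( I + h0·(1−S)·(1 + c_w·max(0,−RE)) − c_s·S·(1 + c_re·max(0,RE)) − Q(RE,P) − θ )
```

where `I` is incentive (learned positive/negative odor values `V±` weighting
the sensed signatures, plus an innate resource-signal term), `S` satiation,
`RE` reward experience, `P` pain, and `Q` the net suppression from the
reciprocal inhibition of reward experience and pain. Above threshold the
forager turns toward stimuli and can consume; below it, away.

Three mechanisms interact around that decision:

- **Rescorla-Wagner learning**: each consumption updates the consumed
  signature's value by `V' = V + α·(λ − V)`, with `λ` set by the event's
  reward (and `λ = 0` for reward-free consumption — extinction).
- **A homeostatic reward circuit**: rewards pulse neuron R
  (`x_R = max(0, r0 + u)`); neuron M reads `x_M = W·x_R` through a plastic
  weight under the setpoint rule `W ← W + η_W·(M_set − x_M)`; reward
  experience is `RE = k_RE·(x_M − M_set)`. Sustained reward desensitizes
  (`W` falls, highs shrink); removing it produces withdrawal (`RE < 0` on
  the tonic baseline) and slow resensitization — the opponent-process
  timecourse.
- **Pain–reward reciprocal inhibition**: matched pain and positive reward
  experience cancel each other's suppression of appetite, so strong reward
  experience can convert a painful stimulus into a target of approach.

The package implements the environment (diffusing/evaporating odor fields,
respawning prey), the forager, the circuit, the learning rule, and the three
experiment protocols: **selectivity maps** over fixed (satiation, reward
experience) grids, **pain-response maps**, and the four-phase free-running
**addiction cycle** (prey only → drug introduced → drug removed → drug
without reward) with multi-trial mean ± SEM aggregation.

## Worked example

Present each item to an immobilized, addicted-state forager (all learned
values at maximum) at mid satiation:

```r
library(slugforage)
cfg <- default_config()
V <- state_associations("addicted")
for (item in c("hermi", "flab", "drug")) {
  out <- run_presentation(item, list(S = 0.56, RE = 0), cfg, V)
  cat(sprintf("%-6s S=0.56 RE=0  ->  %-8s (net turn %+.1f deg)\n",
              item, out$outcome, out$net_turn))
}
```

```
hermi  S=0.56 RE=0  ->  approach (net turn +31.8 deg)
flab   S=0.56 RE=0  ->  avoid    (net turn -150.0 deg)
drug   S=0.56 RE=0  ->  approach (net turn +30.6 deg)
```

The forager turns onto the benign prey and the drug (the net turn settles on
the item's +30° bearing) and spins away from the noxious prey. Full grids,
cycle runs, and figures are available from R
(`build_selectivity_map()`, `run_pain_map()`, `run_addiction_cycle()`,
`aggregate_trials()`, `write_outputs()`) or from the bundled CLI:

```sh
inst/cli/slugforage selectivity-map --state addicted --seed 1 --out results/
inst/cli/slugforage addiction-cycle --trials 10 --seed 42 --out results/ --plots
```

Every run is reproducible from (config, seed): trial k derives its stream
from the root seed by a fixed offset, and `write_outputs()` records a JSON
manifest with the config hash, the seed, and per-file checksums.

See `vignettes/foraging-addiction-model.Rmd` for the model's assumptions,
the calibration of the decision constants, and known limitations.

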