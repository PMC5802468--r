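# pleiosim

Many genes that shape the electrical behaviour of cortical neurons —
voltage-gated Na⁺ and Ca²⁺ channel subunits, HCN channels, the SERCA
calcium pump — are also expressed in the sinoatrial node, the heart's
pacemaker. A variant that subtly changes such a channel therefore acts in
both organs at once. `pleiosim` is an R package for simulating this
cross-tissue pleiotropy: it asks, variant by variant, whether the effect
on neuronal firing and the effect on cardiac pacemaking point in the same
direction (analogous) or in opposite directions (non-analogous), and what
the consequences are for impulse propagation in sinoatrial tissue.

The package provides:

* **Cell models** — a reduced two-compartment layer-V pyramidal neuron
  with the standard detailed-model channel repertoire (transient and
  persistent Na, fast/slow K, SK, L- and T-type Ca, HCN, leak, somatic Ca
  pool), and two single-compartment sinoatrial node cells ("mouse-type"
  and "rabbit-type") whose funny currents carry the published HCN4-like
  (V½ = −106.8 mV, slope 16.3 mV, reversal −24 mV) and HCN1/4-mixture
  (V½ = −52.5 mV, 9.0 mV, −4 mV) characteristics, calibrated so the
  control cells pace at the published 4.76 Hz and 2.90 Hz with peak
  inward I_f of about 0.006 and 0.0067 nA.
* **Variant algebra** — variant effects as sets of additive (mV offsets)
  or multiplicative (factors) parameter modifications, with the scaling
  rules Δ → sΔ and Γ → Γˢ, and a calibration that shrinks each variant to
  the largest scale c ∈ [0, 1] at which the cell still preserves its
  behaviour (equal spike counts, bounded frequency and AP-shape changes).
* **Protocols** — f–I curves, rheobase by bisection, pacemaking-rate
  measurement, AP shape metrics.
* **Tissue** — a 1D diffusively coupled pacemaker-cell chain (conduction
  velocity) and a 2D monodomain sinoatrial-disc-in-atrium simulation with
  exit-block and silencing detection.
* **Analysis** — per-variant outcome tables, cross-model Pearson
  correlations per gene class, and analogous / non-analogous / neutral
  classification.
* **A seeded synthetic variant generator** emulating the structure of a
  curated functional-genomics variant table (7 genes, 80:14 class
  mixture), so the full pipeline is reproducible without restricted data.

The scientific core in one sentence: in the neuron, extra Ca²⁺ influx
activates SK channels and *lowers* the firing rate, while in the
pacemaker the same influx accelerates the diastolic depolarisation and
*raises* the beating rate — so Ca²⁺-channel/transporter variants act
non-analogously (negative cross-model correlation), whereas Na⁺ and HCN
variants act analogously (positive correlation).

## Worked example

```r
library(pleiosim)

# control mouse-type pacemaker: 20 s, discard 2 s settling
mouse <- build_san("mouse")
run <- integrate_cell(mouse, duration = 20000)
pacemaking_frequency(run, settle = 2000)
#> <pacemaking_summary> 4.756 Hz over 86 cycles

# a Cav1.3 gain-of-function variant: conductance x3, activation -8 mV
eff <- variant_effect("demo", "CACNA1D", list(
  parameter_modification("CaL13.gbar", "mult", 3),
  parameter_modification("CaL13.act.vhalf", "add", -8)))

# shrink it until the cell barely keeps its control behaviour
cs <- condition_set("san", record = 5000, settle = 1500)
cal <- find_threshold_c(mouse, eff, cs, step = 0.2, tol = 0.02)
cal$c
#> [1] 0.65

# apply at epsilon = -1/2 and +1/2 of the calibrated threshold
for (eps in c(-0.5, 0.5)) {
  vm <- apply_variant(mouse, eff, epsilon = eps, c_scale = cal$c)
  pf <- pacemaking_frequency(vm, record = 8000, settle = 2000,
                             control_frequency = 4.756)
  cat(sprintf("epsilon %+.2f: %.3f Hz (%+.1f%%)\n",
              eps, pf$frequency, 100 * pf$relative_difference))
}
#> epsilon -0.50: 4.566 Hz (-4.0%)
#> epsilon +0.50: 5.168 Hz (+8.7%)
```

The reversed (loss-of-function) application slows pacemaking, the
gain-of-function application speeds it — while the same variant, applied
to the neuron model, *lowers* the firing rate through SK activation.
`run_pipeline()` automates this over a whole variant table and both cell
types:

```r
cfg <- run_config(n_variants = 30, seed = 7, epsilon = c(-0.25),
                  outdir = "run1")
res <- run_pipeline(cfg)
res$analysis$correlations   # Pearson r per gene class, neuron vs SAN rate
```

For tissue-level consequences:

```r
rabbit <- build_san("rabbit")
res2d <- simulate_tissue_2d(rabbit, tissue_config(san_radius_cm = 0.27),
                            duration = 3500)
detect_exit_block(res2d)    # SAN cycles, atrial beats, blocked beats
```

## Package layout

```
R/                 model builders, variant algebra, calibration,
                   protocols, tissue wrappers, pipeline
src/               compiled cell right-hand sides and tissue steppers
tests/testthat/    unit, property and acceptance tests
scripts/           acceptance.R
vignettes/         pleiosim-methods.Rmd (models, assumptions, numerics)
```

See `vignettes/pleiosim-methods.Rmd` for the full account of the models,
their assumptions and limitations, and every numerical choice.
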