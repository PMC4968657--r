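# fretnc — ratiometric FRET imaging of lipid nanocarrier integrity

Lipid nano-emulsion droplets loaded with a near-infrared FRET dye pair
(donor ≈ 700 nm, acceptor ≈ 820–840 nm) report on their own integrity:
intact droplets emit mostly in the acceptor channel (efficient FRET),
disintegrated ones in the donor channel. Imaging both channels in a
whole-animal setup and dividing them pixel by pixel yields a
concentration- and illumination-independent readout that can be
calibrated into **percent of intact carriers** — directly in the blood
circulation, liver and tumors of living mice.

`fretnc` is for researchers doing such two-channel NIR FRET imaging who
need the quantification chain, and for method developers who want to
stress-test it on synthetic phantoms with known ground truth.

## The model

* **Calibration law** (fitted from well-plate mixture series of intact and
  dye-separated carriers, ≥ 4 integrity levels):

  y = a + b·e^(c·x),  y the proximity ratio A/(A+D), x integrity in %.

  Default constants a = 0.14572, b = 0.1254, c = 0.01748 (reference
  two-channel setup). Inversion x = ln((y−a)/b)/c is clamped to [0, 100]
  with `below_floor` / `above_ceiling` flags.
* **Quantification**: per ROI, time and channel — mean intensity →
  background correction against the pre-injection frame of the same ROI →
  E = A/(A+D) → inversion into integrity.
* **Kinetics**: logistic y(t) = a₂ + (a₁−a₂)/(1+(t/x₀)^p) fitted per
  region; half-life = smallest t with y(t) = 50 (closed form); blood
  clearance I(t) = I₀·2^(−t/h) for donor-only controls.
* **Phantom generator**: stylized mouse (256×256) with region-specific
  concentration and integrity kinetics, channel-specific backgrounds
  (donor 40 / acceptor 4 counts), Poisson shot + Gaussian read noise,
  16-bit quantization. The built-in `healthy`, `tumor_bearing` and
  `donor_only` scenarios encode the study endpoints (93% blood / 66%
  liver at 6 h, 8.2 h liver half-life; 77% tumor at 2 h, 4.4 h tumor
  half-life; 3 h circulation half-time) as ground truth.

## Worked example

```r
library(fretnc)

cal <- calibration_params()                 # reference calibration law
tcs <- lapply(1:3, function(s)              # n = 3 phantom mice
  integrity_timecourse(simulate_study(builtin_scenario("healthy"), seed = s),
                       cal))
summ <- summarize_replicates(lapply(tcs, function(tc)
  tc[, c("region", "quantity", "time_h", "value")]))
subset(summ, time_h == 6)
#>       region  quantity time_h    value         sem n
#> 5      liver integrity      6 66.00702 0.009413227 3
#> 11 tail_vein integrity      6 92.93279 0.070074679 3

fit <- fit_logistic(tcs[[1]][tcs[[1]]$region == "liver", ])
half_life(fit)
#> [1] 8.20257
```

At 6 h the phantom mice show carriers still 93% intact in the blood but
down to 66% in the liver, with a liver disintegration half-life of
8.2 h — the pipeline recovering, through noise, background correction and
calibration inversion, exactly the kinetics the scenario encodes.

## Analysis workflow

Numbered drivers under `analysis/` run the study end to end, writing
tables to `results/` and images to `scratch/`:

```sh
Rscript analysis/01_simulate.R    # phantom studies (TIFF + manifests) + ground truth
Rscript analysis/02_calibrate.R   # noisy plate -> fitted calibration law
Rscript analysis/03_quantify.R    # integrity time courses + ratio images
Rscript analysis/04_kinetics.R    # logistic fits, half-lives, clearance, t-test
```

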