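# dropnet

Quantification of patterned gene expression induced in bacterial lawns by
3D-printed picoliter droplet networks.

Droplet networks — hundreds of ~150 pL aqueous droplets joined by lipid
bilayers — can release a chemical inducer (arabinose, through α-hemolysin
pores) onto an *E. coli*-laden hydrogel, switching on reporter expression in
a spatial pattern set by which droplets carry cargo. `dropnet` implements
the image-analysis side of such experiments: given a two-channel
epi-fluorescence micrograph pair — a reporter channel (mCherry or sfGFP) and
a cascade-blue-dextran (CBD) tracer channel outlining the network footprint
— it scores how faithfully the induced expression reproduces the intended
pattern.

## The pattern-fidelity index

Both channels are 12-bit images (0–4095 a.u.). With the activation
threshold *I*<sub>B</sub> (the mean baseline intensity of never-induced
lawns; 179 a.u. for mCherry, 200 a.u. for sfGFP) and the footprint
threshold *I*<sub>CBD</sub> = 500 a.u., each pixel is classified as
activated (≥ *I*<sub>B</sub>) and/or footprint (≥ *I*<sub>CBD</sub>).
Multiplying pixel counts by the pixel area *A*<sub>pix</sub> gives

- *A*<sub>I</sub> — intended expression area (the footprint),
- *A*<sub>U</sub> — unintended expression area (activated outside the
  footprint),
- *A*<sub>N</sub> — no-expression area inside the footprint,

and the pattern-fidelity index

&nbsp;&nbsp;&nbsp;&nbsp;PF = (*A*<sub>I</sub> − *A*<sub>U</sub>) / *A*<sub>I</sub>.

PF approaches 1 when expression is confined to the footprint and can go
negative when stray expression dominates; it is reported as computed, never
clamped. Alongside PF the package reports the activated-pixel count
*N*<sub>a</sub>, the total and mean activated intensities *I*<sub>T</sub>
and *I*<sub>M</sub>, and the volume-to-surface-area ratio
*R*<sub>VSA</sub> = *V* / *A*<sub>I</sub> of the network (storage volume per
release area).

Because the raw study micrographs are not deposited, the package ships a
synthetic micrograph generator with exact geometric ground truth
(`simulate_image_pair()`): printing maps are rasterized as hex-packed
droplet disks, a diffusion halo is modelled as an exact dilation of the
footprint, and droplet–hydrogel contact failures as whole missing droplets.
Every stage of the pipeline is verified against this ground truth and
against brute-force per-pixel oracles. Supporting modules cover
heat-induced network shrinkage analysis, micro-colony density counting, and
the normality-gated two-group statistics used for competition outcomes.

## Worked example

Simulate a cross-patterned network with a 40 µm expression halo and 15% of
bottom droplets failing bilayer contact, then quantify it:

```r
library(dropnet)

p <- synth_params(builtin_pattern("cross"), halo_width_um = 40,
                  hole_fraction = 0.15, seed = 42)
sim <- simulate_image_pair(p)
m <- compute_metrics(sim$expr, sim$cbd)
m
#> <pattern_metrics> PF = 0.3266 | A_I = 0.2199, A_U = 0.1481, A_N = 0.03142 mm^2 |
#>                   I_M = 633.9 a.u., I_T = 1.27e+08 a.u., N_a = 200394
sim$truth$PF_true
#> [1] 0.3265509
```

The cross footprint covers 0.2199 mm²; the 40 µm halo pushes 0.1481 mm² of
expression outside it (the cross has a long perimeter, so halos are
punishing), giving PF ≈ 0.33, and the failed droplets leave 0.031 mm² of
the footprint silent. The measured PF matches the geometric ground truth to
four decimals because intensity noise never crosses the thresholds.

A grid of experiments runs through the pipeline layer:

```r
cfg <- run_config(seed = 1)
specs <- lapply(c(0, 50, 100), function(h)
  synth_params(builtin_pattern("full"), halo_width_um = h))
run_pipeline(cfg, specs)[, c("id", "PF", "PF_true", "PF_error")]
#>        id     PF PF_true PF_error
#> 1 sim_001 1.0000  1.0000        0
#> 2 sim_002 0.5604  0.5604        0
#> 3 sim_003 0.2030  0.2030        0
```

Fidelity degrades monotonically with halo width — the trend the index is
designed to expose.

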