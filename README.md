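# retinasim

Scene enhancement and degenerate-retina simulation for low vision.

Retinal degenerations — age-related macular degeneration (AMD) and
retinitis pigmentosa above all — destroy photoreceptors and leave
patients with blurred central vision or a frank scotoma. Electronic
visual aids can pre-process the scene to make its remaining structure
easier to use, but testing candidate algorithms on patients is slow and
expensive. `retinasim` provides both sides of the desk-scale
alternative, for vision scientists and assistive-technology engineers:

* **Three enhancement algorithms.** *TRON* (Tinted Reduced Outlined
  Nature) multiplies the scene by a floored, normalized multi-scale
  gradient map, `W = max(G, K)`, keeping tinted color at boundaries
  while dimming homogeneous regions to a fraction `K`. *Cartoonization*
  soft-quantizes the luminance into `N = 8` bins,
  `Q = q + (Δq/2)·tanh(φ·(y − q)/Δq)` with the transition sharpness `φ`
  driven by the local gradient (clamped to `[0.1, 0.4]`, mapped to
  `[3, 25]`), and darkens edges by the negative gradient map.
  *Edge overlay* recolors significant edges (binarized at `τ_min`) over
  the original, smoothed, or cartoonized scene. All three build on
  Perona–Malik anisotropic diffusion (`c(g) = exp(−(g/κ)²)`, 8-neighbour
  explicit scheme, `Δt ≤ 1/7`) and a rotation-consistent four-direction
  `[-1, 0, 1]` gradient operator with a dyadic pyramid for
  low-frequency derivatives.

* **A degenerate-retina model.** Foveated space-variant blur
  (`σ(r) = log r` per one-pixel eccentricity ring; a 20 × 20 px fovea on
  an 800 px frame under the 1 mm / 6 mm / 42 mm fovea/macula/retina
  geometry), cone and CIE-Lab color-opponent separation, horizontal-cell
  Gaussian smoothing, five bipolar centre–surround
  difference-of-Gaussians signals (`σ_s = 2σ_c`, surround kernel 5×),
  parametric clustered scotomata (fixation, size `S` in macula
  diameters, loss fraction `D`, seeded), and spectral Neumann–Poisson
  reconstruction of the luminance and the two chromatic channels sent
  to the cortex.

* **Evaluation metrics.** Extracted-edge percentage
  `E = 100·ΣG_scaled/(255·M·N)`, Pelli–Robson-style contrast stimuli
  (16 contrasts × 14 eccentricities, Weber contrast `10^(−logCS)`),
  a face-detection degeneration sweep with a pluggable detector
  interface, and a frame-difference motion metric averaged over frame
  gaps 1–4.

## Worked example

```r
library(retinasim)

# a synthetic low-contrast scene, its TRON enhancement, and the
# retina's view of it with a central macula-sized scotoma
img <- make_fixture("low_contrast_shapes", size = 128, seed = 1)
enh <- tron(img, tron_params())
sim <- retina_pipeline(enh, spec = scotoma_spec(c(64, 64), size_s = 1,
                                                degree_d = 1, seed = 7))
edge_percentage(img)
#> Extracted edges: 6.248% of a 128 x 128 image
edge_percentage(sim)
#> Extracted edges: 10.094% of a 128 x 128 image

# motion perception: TRON raises the frame-difference motion score
frames <- make_fixture("moving_square_video", size = 96, n_frames = 6)
motion_percentage(frames, gaps = 1:2)
#> [1] 1.287659
tp <- tron_params(diffusion = diffusion_params(iterations = 3),
                  pyramid_levels = 2)
motion_percentage(lapply(frames, tron, params = tp), gaps = 1:2)
#> [1] 1.598771

retina_geometry(c(800, 800))
#> Retina geometry for 800 x 800 image: fovea 20 px, macula 114.3 px
#> (retina 42 mm, fovea 1 mm, macula 6 mm)
```

The edge percentages quantify how much boundary signal a scene carries
(0 for a constant image, 100 for a maximal-gradient image); the motion
numbers show the enhanced sequence carrying about 24% more perceivable
frame-to-frame change than the raw one.

## Package layout

| Where | What |
| --- | --- |
| `R/filters.R` | diffusion, directional derivatives, gradient field, pyramid |
| `R/enhance.R` | TRON, soft quantization, cartoonization, edge overlay |
| `R/retina.R` | geometry, foveation, opponency, DoG, Poisson solver, scotoma, pipeline |
| `R/evaluate.R` | edge/motion metrics, contrast stimuli, face sweep |
| `R/io.R`, `R/config.R`, `R/cli.R` | image/video I/O, fixtures, YAML config, CLI |
| `vignettes/retinasim-methods.Rmd` | model assumptions, parameter choices, limitations |
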