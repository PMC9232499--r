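# gliomotion

Quantitative analysis of collective glioma cell migration from time-lapse
tracking data and histology-derived masks.

High-grade gliomas contain *oncostreams*: fascicles of elongated,
nematically aligned tumor cells that move collectively and drive invasion.
`gliomotion` is aimed at researchers analyzing such data — cell tracks from
tumor explant or intravital movies, labeled nuclei masks from H&E sections,
and two-phase tumor/brain border images. It provides:

* **Motion-pattern classification.** The per-step headings
  θ ∈ [0, 2π) of a tumor zone are fitted by maximum likelihood under three
  circular families — uniform (*swarm*), von Mises (*flock*,
  ρ(θ) = e^{κ cos(θ−μ)} / 2π I₀(κ)), and an equal-weight antipodal von
  Mises mixture (*stream*, ½ vM(μ, κ) + ½ vM(μ+π, κ)) — and compared by
  Akaike weights w_i = exp(−Δᵢ/2) / Σ exp(−Δⱼ/2) with
  Δᵢ = AICᵢ − min AIC. The zone label is the family with maximal weight.
* **Kinematics**: headings and speeds (µm/h) per step from TrackMate-dialect
  XML or plain CSV tracks; rectangular analysis zones; speed summaries.
* **Spatial order**: pair directional correlation C(r) = ⟨cos(θᵢ−θⱼ)⟩ by
  distance bin (optionally by front/right/back/left sector or with the
  nematic kernel cos 2Δθ), relative-position maps in the focal heading
  frame, nearest-neighbour distances.
* **Shape and alignment**: per-nucleus area, Crofton perimeter, moment
  aspect ratio, circularity 4πA/P², Feret (orientation) angle, nematic
  order S = |⟨e^{2iα}⟩|, and the elongated/round split at aspect ratio 2.
* **Border sinuosity**: Allen–Cahn relaxation ∂u/∂t = ε²∇²u + u − u³ of a
  ±1 phase image, marching-squares interface extraction, and
  S = L/D (curve length over endpoint distance).
* **Synthetic data with ground truth** for all of the above, fully
  seeded, plus a YAML-configured pipeline (`run_zone_analysis()`) and a
  thin CLI (`inst/cli/gliomotion`).

## Worked example

Simulate a stream-patterned explant zone and classify it:

```r
library(gliomotion)

sim <- simulate_trajectories("stream", n_cells = 60, n_frames = 60, seed = 42)
kin <- compute_kinematics(sim$tracks)

summarize_speeds(kin)$summary
#>   group    n     mean       sd
#> 1   all 3540 4.194045 1.312052

classify_pattern(kin$theta[kin$valid], zone_id = "explant-zone-B")
#> Zone: explant-zone-B
#> N = 3540 headings; pattern: stream
#>             logL      AIC     dAIC AW
#> swarm  -6506.085 13012.17 1880.669  0
#> stream -5563.750 11131.50    0.000  1
#> flock  -6504.538 13013.08 1881.577  0

nearest_neighbor_distances(build_snapshots(kin))$summary
#>      n   median       q1       q3
#> 1 3540 37.74416 26.78598 56.69512
```

The mean step speed (4.19 µm/h) recovers the configured stream speed of
4.26 µm/h; the classifier puts essentially all Akaike weight on the
bimodal (stream) family, whose fitted axis (`fit$fits[[2]]$mu`) is 44.9°,
matching the generating axis of 45°; and nearest neighbours sit in the
tens of micrometres, as set by the arena density. A reported `AW` of 1 or
0 mirrors the saturated weights typical of well-sampled zones.

Border analysis works the same way from an image:

```r
border <- simulate_border_image(amplitude = 40, wavelength = 200,
                                image_size = c(400, 400),
                                noise_flip_prob = 0.01, seed = 7)
field <- allen_cahn_smooth(binarize_tumor_image(border$image, 0.5), 200)
extract_border_curve(field)
#> border_curve: 686 points, L = 509.181 um, D = 399.374 um, S = 1.2749
border$truth$sinuosity
#> [1] 1.319937
```

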