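---
title: "Voxel Monte Carlo photon transport: model, conventions and validation"
author: "voxmc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel Monte Carlo photon transport: model, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxmc)
```

## The model

voxmc simulates light propagation in turbid media — tissue, phantoms,
any strongly scattering material — with the weighted-packet Monte Carlo
method on a regular voxel grid. Each packet carries a statistical weight
`w` that decays continuously with absorption instead of the packet
terminating at each interaction:

* **Hop.** A dimensionless scattering pathlength `s* = -log(u)` is drawn
  (`u` uniform on (0,1]); the physical hop in a voxel with scattering
  coefficient `mus` is `s*/mus`, giving a mean free path of `1/mus`.
* **Segment-accurate deposition.** The hop is split at every voxel
  boundary it crosses (incremental grid marching with per-direction
  reciprocals). Along a segment of length `l` in a voxel with absorption
  `mua`, the packet deposits `w (1 - exp(-mua l))` into that voxel's
  current time gate and its weight is attenuated accordingly
  (Beer–Lambert). Elapsed time advances by `l n / c` with the voxel's
  refractive index `n`, so time gates are correct in mismatched media.
* **Scatter.** At the hop's end the new direction is drawn from the
  Henyey–Greenstein phase function with the voxel's anisotropy `g`
  (`g = 0` reduces to isotropic; the mean deflection cosine equals `g`).
  The accumulated momentum transfer `sum(1 - cos(theta))` is tracked per
  packet.
* **Boundaries.** Each face of the bounding box carries one of four
  conditions: total absorption (escape), unpolarized Fresnel
  reflection/refraction against the exterior index, total (mirror)
  reflection, or cyclic wrap-around to the opposite face, which emulates
  an infinite medium. With `DoMismatch` enabled the same Fresnel/Snell
  physics applies at every interior voxel face where the refractive index
  changes, including total internal reflection beyond the critical angle.
* **Termination.** Packets end by escaping, by reaching the end of the
  time window (`T1`), or by Russian roulette: once `w` falls below a
  threshold fraction of its launch weight the packet survives with
  probability `p` and is reweighted by `1/p`, which preserves the
  expectation exactly.

Media are either integer **labels** indexing a table of
`(mua, mus, g, n)` — label 0 is reserved for the background/outside, and
a packet crossing into a 0-labelled voxel leaves the medium there — or a
per-voxel float table of `(mua, mus)` pairs with global `g` and `n`
("continuously varying" media).

### Units and conventions

Optical coefficients are **per mm**; `LengthUnit` (mm per grid unit,
default 1) converts them to grid units internally. Positions are
continuous grid coordinates with voxel `(i, j, k)` (0-based) owning the
half-open box `[i, i+1) x [j, j+1) x [k, k+1)`. Shape membership during
rasterization is evaluated at the voxel **center** `(i+0.5, j+0.5,
k+0.5)` with closed inequalities, so a center exactly on a surface is
inside; this convention is a dialect decision and is pinned down by the
brute-force oracle tests. Detected-photon partial pathlengths are
recorded in **mm**, stated in the output metadata.

### Fluence normalization

Raw per-voxel, per-gate deposited energy `E` is converted to fluence
rate via `E / (mua V Dt W)` with voxel volume `V` (mm^3), gate width
`Dt` (s) and total launched weight `W`, yielding units of 1/mm^2/s per
unit delivered energy. Voxels with `mua = 0` cannot use this estimator;
there the kernel accumulates weighted pathlength `w l` (mm) instead,
normalized by `V Dt W` — the two estimators agree in the limit
`mua -> 0`. Summing gates times `Dt` gives the CW fluence (1/mm^2),
which is what the diffusion validation compares.

## Reproducibility and replay

Every photon owns a private random substream: its 64-bit stream key is
derived from `(seed, worker, photon index)` with a splitmix64-style
mixer, and the stream itself is xorshift128+. Consequences, all tested:

* identical `(input, seed, workers)` reproduces fluence and
  detected-photon files byte for byte;
* logical workers use disjoint substreams, so a 4-worker run is a
  statistically independent but individually reproducible estimate of
  the 1-worker run, and merging just adds raw grids and concatenates
  detection tables;
* a detected photon stores its key (two 32-bit halves), and **replay**
  re-simulates exactly the recorded trajectory from the key alone,
  accumulating pathlength x detected weight per voxel into a sensitivity
  (Jacobian) grid. Replay verifies bit-exact agreement of the replayed
  exit state with the recorded one and refuses to proceed otherwise.
  Because a roulette event consumes a random draw, the roulette settings
  of the forward run are carried on the result and reused at replay.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `Forward.T0/T1/Dt` | — | time window and gate width, s; `(T1-T0)/Dt` gates |
| `Domain.LengthUnit` | 1 | mm per grid unit |
| `Session.DoMismatch` | off | interior Fresnel/Snell physics |
| `Session.DoNormalize` | on | convert energy to fluence rate |
| `roulette_threshold` | `1e-4` | roulette trigger, fraction of launch weight |
| `roulette_p` | 0.1 | survival probability (survivors reweighted by 10x) |
| `Focus` | `Inf` | focal length of area sources; >0 convergent, <0 divergent |

The roulette defaults are the conventional ones for tissue optics;
unbiasedness does not depend on them (tested), only variance and runtime
do.

## The synthetic scenes and what they do (not) show

`make_fixture()` generates the package's study conditions:

* `homogeneous_cube` — 60 mm cube, `mua 0.005, mus 1, g 0.01, n 1`,
  pencil beam, absorbing faces: the minimal end-to-end scene.
* `layered_slab` — three z-layers with tissue-like optics
  (epidermis/dermis-scale `mua 0.004–0.02/mm`, `mus 6–9/mm`, `g ~0.9`,
  `n 1.37`), two surface detectors: exercises heterogeneous labels,
  detection and replay.
* `embedded_sphere` — an absorbing, scattering sphere (r = 10 mm) in a
  clear-ish background: exercises the rasterizer inside the transport
  path.
* `infinite_cyclic` — `mua 0.005, mus 10, g 0.9, n 1` (so
  `mus' = 1/mm`), isotropic point source at the center of a 60 mm cube
  with cyclic faces: the quantitative physics benchmark.

For `infinite_cyclic` the window is a single 3 ns gate. At
`mua = 0.005/mm` a 3 ns window caps photon paths at ~900 mm, where the
remaining packet weight is `e^-4.5` (~1%), so the truncation bias on CW
fluence inside r = 15 mm is well below the diffusion-theory comparison
band; the choice trades a negligible bias for a much shorter run.
Validation runs transport 1e6 photons (the profile below is reported by
`scripts/acceptance.R`); the unit-test suite uses smaller photon counts
(2e3–2e5) chosen so each block answers its question in seconds.

These scenes emulate the geometry and optics of layered and embedded
tissue structures, not real anatomies: they have axis-aligned interfaces
(except the sphere/cylinder), piecewise-constant optics, and no noise
floor, detector response, or index-matched coupling gel. Passing tests
show the transport physics, bookkeeping and I/O are right — not that any
particular biological prediction is.

## Validation against diffusion theory

For an isotropic point source in an infinite homogeneous medium,
diffusion theory gives the CW Green's function

$$\Phi(r) = \frac{\exp(-\mu_{eff}\, r)}{4 \pi D r}, \qquad
D = \frac{1}{3(\mu_a + \mu_s')}, \quad
\mu_{eff} = \sqrt{3 \mu_a (\mu_a + \mu_s')}.$$

The cyclic boundary makes the 60 mm cube periodic, a standard stand-in
for the infinite medium at these attenuation lengths. The comparison
shell-averages MC fluence in 1 mm radial bins and excludes radii inside
3 transport mean free paths (`3/(mua + mus')` = 3 mm here), where
diffusion theory itself is invalid; shells with fewer than 1000
deposition events are flagged as statistically inadequate rather than
compared. Over r = 5–15 mm the maximum shell error measured by the
acceptance run at 10⁶ photons is ~0.5% (the residual is dominated by
the diffusion approximation, not MC noise) against the 10% acceptance
band.

## Numerical choices

* **Attenuation.** `1 - exp(-x)` uses a 4-term series below `x = 0.01`
  (relative error < 1e-9 at the switch point) and the exact exponential
  above, so per-segment deposition is cheap in fine grids and still
  exact for optically thick segments (the Beer–Lambert test asserts
  1e-6 on a 10 mm path).
* **Grid marching.** The next boundary distance per axis uses
  precomputed direction reciprocals; the smallest distance wins and
  exact ties advance both indices (corner crossing). The chord-length
  oracle (body-diagonal path, 1e-9 tolerance) pins this down.
* **Azimuth sampling.** The scattering azimuth unit vector is drawn by
  rejection from the unit disk (double-angle identity) rather than
  sin/cos; directions are renormalized to first order each scatter,
  keeping |dir| within ~1e-12 of 1 over any trajectory length.
* **Degenerate media.** `mus = 0` gives straight-line transport capped
  at the domain boundary; `mua = mus = 0` (vacuum) advances with pure
  time delay; both are guarded against infinite loops by the time-gate
  cap, which is also what terminates lossless mirror boxes.
* **Ties and half-open boxes.** A position exactly on a voxel's lower
  face belongs to that voxel; cyclic wrap clamps re-entry positions into
  the half-open domain so indices stay valid.
* **Exact bookkeeping.** The weight ledger tracks absorbed, escaped,
  time-expired and the roulette net (kill − boost); their sum equals
  launched weight to ~1e-13 relative in all fixtures. Roulette makes a
  three-term ledger balance only in expectation, which is why the net
  term exists.

## Design choices where the design was open

* **JSON dialect.** Key names follow the established
  Session/Forward/Optode/Domain/Shapes layout; unknown keys warn rather
  than fail, for forward compatibility. Boundary conditions are a
  6-letter string (`a`bsorb/`r`=Fresnel/`m`irror/`c`yclic) in face order
  x-,x+,y-,y+,z-,z+ — the letter spelling is this package's dialect and
  is fixed in the shipped JSON Schema (`vmc_schema_path()`). With no
  JSON-Schema engine among the package's dependencies, `validate_config()`
  enforces the same rules in code and reports path-addressed violations;
  the schema file is the normative, machine-readable statement of the
  dialect and the tests keep the two in agreement.
* **Array annotations.** `_ArraySize_` is declared row-major; the stream
  runs the last declared dimension fastest, and a 3D volume declared
  `[nx, ny, nz]` decodes so that index `(i, j, k)` addresses
  `x = i, y = j, z = k`. Only zlib is accepted for `_ArrayZipType_`;
  anything else errors loudly. Both compressed and uncompressed forms
  are accepted on input. Uncompressed `single` arrays are quantized
  through IEEE float32 so even the decimal JSON form round-trips
  bit-exactly.
* **Fourier source packing.** `param1[4] = kx + phase/(2*pi)` (integer
  part the x spatial frequency, fractional part the phase),
  `param2[4] = ky`; the launch weight `(1 + cos(2*pi*(kx u + ky v) +
  phase))/2` is intrinsically in [0, 1], so no clamping is needed.
* **Specular launch.** A source outside the box is advanced to the
  entry face; under `DoMismatch` the specular loss `(1 - R)` is applied
  deterministically at entry and the direction refracted.
* **Interior Fresnel handling** is per voxel face (the face normal is
  the axis crossed); no smoothed normals.

## Known limitations

* Sub-voxel boundary geometry (split-voxel / mesh methods), polarization,
  and user-defined phase functions are out of scope; curved interfaces
  are staircase-approximated at the voxel size.
* The diffusion validation covers the diffusive regime
  (`mus' >> mua`); no time-domain or semi-infinite analytic comparisons
  are bundled.
* Per-voxel continuous media carry `(mua, mus)` only; `g` and `n` are
  global in that mode.
* Workers are logical (sequential) — the point is reproducible stream
  splitting and merging, not wall-clock parallelism.

## A minimal session

```{r example}
doc <- make_fixture("homogeneous_cube", photons = 5000)
res <- run_simulation(doc, seed = 7, workers = 2)
res
cw <- cw_fluence(res)
signif(cw[31, 31, 1:5], 3) # fluence (1/mm^2) along the beam axis
```

The same simulation runs from a shell via the installed script:

```
Rscript $(Rscript -e 'cat(system.file("cli","voxmc",package="voxmc"))') \
  -f cube.json --seed 7 -t 2 -o out
```

writing `out.jnii` (time-gated fluence volume), `out_detp.json`
(detected photons) and `out_summary.json` (run accounting).
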