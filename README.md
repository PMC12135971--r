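# harddisk2d

Structure factors of randomly packed hard disks in two dimensions, computed
by explicit Metropolis Monte Carlo simulation, for interpreting small-angle
X-ray and neutron scattering from densely packed parallel fibrils —
cellulose microfibrils in wood cell walls, collagen fibrils, aligned
colloidal rods.  In such systems the single-fibril form factor and the
packing structure factor overlap on the same length scale; an explicit
hard-disk model of the cross-section plane gives a physically grounded
interference function where paracrystalline lattice models over-structure
the problem.

## The model

Unit-radius hard disks in a square periodic box of side `l` are sampled by
Metropolis Monte Carlo (normal steps, tuned step size, tile-grid collision
checks).  The pair distribution function g(r) is estimated from all pair
distances inside the circle of diameter `l` inscribed in the box,
normalized by the exact distance density of random points in a circle
(so no periodic minimum-image is needed), and the structure factor follows
as the zero-order Hankel transform of the correlation function
h = g − 1:

    S(Q) = 1 + 2πν ∫₀^rmax h(r) J₀(Qr) r dr,        ν = φ/π

with a linear taper of h from `l/4` to `l/2`, parabolic replacement of the
oscillatory region below Q = 0.6, and Savitzky–Golay smoothing (window 29).
Curves for area fractions φ = 0.05 … 0.65 are tabulated as a bivariate
degree-2 B-spline over (φ, Q).  The Rosenfeld scaled-particle closed form
and the infinite-cylinder form factor P(x) = (2J₁(x)/x)² complete the
intensity product model I(Q) = scale · S(QR) · P(QR) + background.

All Q values are on the dimensionless QR scale (lengths in disk radii);
divide by the physical radius to get inverse length.

## Worked example

```r
library(harddisk2d)

# simulate a phi = 0.3 fluid and compare with the analytic reference
s <- simulate_sq(0.3, l = 100, n_samples = 40, sample_interval = 20,
                 burn_in = 100, seed = 2)
s
#> Structure factor S(Q): 1001 points on Q in [0, 10], phi = 0.2903, r_max = 50 radii
#>   main peak at Q = 2.687 with S = 1.306

locate_peaks(s, q_window = c(1, 6))
#>          q        s
#> 1 2.687127 1.306223
#> 2 5.542774 1.079689

max(abs(s$s[s$q >= 1] / rosenfeld_sq(s$phi, s$q[s$q >= 1]) - 1))
#> [1] 0.06085856
```

The realized area fraction 0.2903 is below the target 0.3 because an
integer hexagonal lattice initializes a small (100-radius) box.  The first
structure peak sits at QR ≈ 2.7 — for 13 Å cellulose microfibrils that is
Q ≈ 0.21 Å⁻¹ — with a shallow second oscillation near √3 times that
position.  The ~6% disagreement with the Rosenfeld closed form at this
density is dominated by the analytic form under-predicting the emerging
structure peak (it shrinks below 2% for φ ≤ 0.15; see the methods
vignette).  Multiplying by the cylinder form factor shifts the apparent
scattering peak to lower Q than the structure-factor peak 2.85/13 = 0.22:

```r
m <- cylinder_model(radius = 13, phi = 0.4)
prof <- saxs_intensity(seq(0.01, 0.6, 0.001), m)
prof$q[which.max(prof$intensity)]
#> [1] 0.166
```

A command-line front end mirrors the pipeline
(`exec/hd2d simulate|pdf|sq|tabulate|compare|saxs`), e.g.

```sh
Rscript exec/hd2d sq --phi 0.6 --box 200 --samples 100 --rmax 25 --seed 1 --out sq060.tsv
```

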