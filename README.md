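# photonrestore

Single-photon counting, camera-noise elimination, 4D coordinate assignment
and probability-based super-resolution restoration for high-speed confocal
imaging — with a full forward simulator so every stage can be validated
against known ground truth.

## The problem

When a spinning-disk confocal microscope is pushed to ~1000 frames/s and its
signal is amplified 10⁵–10⁶-fold by a cooled image intensifier, each detected
fluorescence photon appears on the camera as an isolated, spatially resolved
cluster of counts.  Instead of integrating intensity images, one can *count*
those photons: record each one's sub-pixel position, its frame time, and —
because a piezo actuator sweeps the focal plane — its z coordinate.  The
acquisition then yields a table of photons with 4D coordinates (x, y, z, t)
from which camera noise has been removed essentially completely, since
genuine single-photon clusters are separable from read noise by a per-pixel
threshold plus a cluster-shape test.

From the binned photon density the original object is restored by maximising
the Poisson likelihood of the counts given the object convolved with the
(known, separable Gaussian) point-spread function

```
counts_v ~ Poisson( (object ⊗ PSF)_v ),   PSF = N(0, σ_xy²) ⊗ N(0, σ_xy²) ⊗ N(0, σ_z²)
```

via multiplicative Richardson–Lucy updates, run on a finite field with a
renormalised (non-circulant) forward model and an optional compact object
support — the finiteness is what licenses restoration beyond the optical
transmission band.  Because a point estimate cannot carry its own
reliability, the package reports interval estimates: the in-window photon
list is bootstrap-resampled, each replicate deconvolved, and the result is
an expected-value image with voxelwise confidence bounds.

The package is for microscopists and methods developers who want to
prototype, test or audit this computational chain without the instrument:
every stage (fluorophore geometry, Poisson emission, intensifier gain
clusters, camera noise, saw/triangular z scanning) has a forward model, and
resolution metrology (line profiles, Rayleigh dip criterion, FWHM, bead PSF
estimation) closes the loop.

## Worked example: resolving a 71-nm nano-ruler

Two parallel dye lines 71 nm apart (a DNA-origami-style ruler) are simulated
through the full chain — emission, intensifier, camera, dark-frame
calibration, single-photon counting, restoration — and the spacing is
measured on the restored profile:

```r
library(photonrestore)
run <- nanoruler_experiment(seed = 1001)
run$n_detected
#> [1] 8171
run$resolved
#> [1] TRUE
round(run$separation, 1)
#> [1] 82.1
round(run$dip_ratio, 2)
#> [1] 0.04
```

About 8000 photons survive counting; the restored line profile shows two
clear peaks with a deep dip between them (82 nm apart in this seed) — far below the ~260 nm
FWHM of the simulated PSF.  (`separation` is the distance between
parabolically refined peak positions; `dip_ratio` is the minimum between the
peaks as a fraction of the lower peak, resolved when ≤ 0.735.  Individual
seeds scatter by some tens of nm — at 8000 photons the separation estimate
is information-limited — while the median over seeds sits on the true
spacing; see the methods vignette.)

The same API drives the standard pipeline pieces directly:

```r
wf   <- scan_waveform("triangular", z_range = 4500, pitch = 90, plane_interval = 1)
plan <- plan_volumes(wf, duration = 1000, pattern = "pattern1")  # 19 windows, 100 ms each
rec  <- interval_reconstruct(photons, grid, psf, window = c(0, 100), B = 50)
tidy(rec)      # voxel table with mean / lower / upper
glance(rec)    # one-row summary
autoplot(rec)  # max-intensity projection
```

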