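# pcmfrap

Radial-profiling FRAP analysis of pericentriolar material (PCM)
assembly, with a mechanistic simulator of the two recovery modes it is
designed to distinguish.

## The problem

Centrioles build a matrix of pericentriolar material around themselves,
and that matrix expands dramatically in mitosis. For a given PCM protein,
fluorescence recovery after photobleaching (FRAP) answers a mechanistic
question: is the protein recruited by **binding sites distributed
throughout the PCM** (recovery is even — the recovering intensity profile
always has the pre-bleach shape), or is it incorporated **only next to
the centriole and then moved slowly outward** (inside-out assembly —
recovery profiles start narrow and spread, peripheral recovery starts
slow and accelerates, and a re-bleach resets all rates)?

`pcmfrap` is for cell biologists and image analysts who want that
readout to be quantitative and testable. It implements:

* **Radial profiling** — 5× pixel upsampling, thresholded
  centre-of-mass detection, mean intensity over concentric rings
  (0.028 µm spacing over 3.02 µm by default, 107 rings), cytosolic
  background subtraction, peak normalization, mirroring and averaging
  over ≥ 10 centrosomes.
* **Recovery kinetics** — central (0.028–0.14 µm) and peripheral
  (0.62–0.73 µm) ROI curves, least-squares initial rates over the first
  60 s, a quadratic acceleration index, a FWHM-versus-time spreading
  statistic, double-bleach rate comparisons, and a rule-based
  classification into `distributed` / `inside_out` / `indeterminate`.
* **A two-pool ring-chain simulator** of both mechanisms. Inside-out
  flux: dC_i/dt = [i=1]·J + a·C_{i−1} − [i<N]·a·C_i − k_loss·C_i, with
  closed-form steady state C_1 = J/(a+k_loss), geometric interior decay
  and total mass J/k_loss. Distributed exchange: per-ring relaxation to
  ρ_i at rate k_ex, giving the even recovery 1 − exp(−k_ex·t).
  Bleaches scale the fluorescent pool only; integration is exact
  (matrix exponential / closed form). A Gaussian-PSF camera model with
  Poisson and read noise renders movies, 170 nm bead references, and
  fixed-cell quantification tables.
* **Population statistics** — boxed-region centrosome quantification,
  per-brain averaging, an exact/approximate Mann–Whitney U test, paired
  control-vs-experimental rate comparison with percent reduction, and
  binary aster scoring.

## Worked example

```r
library(pcmfrap)

## simulate an inside-out (flux) movie: 10 centrosomes, bleach at t = 0
movie <- simulate_frap_movie(mechanistic_params("flux"), seed = 1)
ana <- analyze_frap(movie)
print(ana)
#> FRAP analysis
#> Profile set: 16 time points (t = -20..295 s), 10 centrosomes averaged, 1 bleach event(s)
#>   central rate 0.01129 /s, peripheral rate 0.001981 /s (ratio 5.7)
#>   FWHM slope 0.000981 um/s (t = 7.46)
#> Recovery mode: inside_out
#>   early FWHM ratio 0.711 (< 0.8?), FWHM slope 0.000981 um/s (t = 7.46), shape dev 0.688 (< 0.05?)

## the distributed mechanism, same optics and pre-bleach image
movie2 <- simulate_frap_movie(mechanistic_params("distributed"), seed = 2)
analyze_frap(movie2)$mode
#> Recovery mode: distributed
#>   early FWHM ratio 1 (< 0.8?), FWHM slope -7.08e-06 um/s (t = -1.53), shape dev 0.00687 (< 0.05?)
```

Reading the numbers: for the flux movie the central ROI recovers ~5.7×
faster than the peripheral ROI in the first minute; the earliest
recovery profile is 0.71× as wide as the pre-bleach profile and widens
at ~0.001 µm/s (t = 7.5), so the movie is called `inside_out`. The
distributed movie's recovery profiles deviate from the pre-bleach shape
by < 0.7% of peak at every time point, so it is called `distributed`.

`run_frap_pipeline()` wraps the same analysis with strict YAML/JSON
configuration, TIFF + JSON-sidecar movie output, a kinetics report and
a checksummed run manifest; `run_fixed_pipeline()` does the same for
fixed-cell tables (per-brain averages, Mann–Whitney comparisons).

## Package layout

| file | contents |
|---|---|
| `R/params.R`, `R/ring_chain.R` | mechanistic parameters, exact two-pool ring-chain integration, closed forms |
| `R/render.R` | Gaussian-PSF optical model, movie and bead rendering |
| `R/fixed_cells.R` | synthetic fixed-cell tables and paired-rate generator |
| `R/profiling.R`, `R/profile_set.R` | ring grids, upsampling, centre finding, radial profiles, movie profiling |
| `R/kinetics.R` | ROI curves, rates, acceleration, spreading, mode classification |
| `R/population_stats.R` | box quantification, brain averages, Mann–Whitney, paired t, aster scoring |
| `R/analyze.R`, `R/pipeline.R`, `R/io.R` | end-to-end analysis, configured pipelines, TIFF/CSV/JSON I/O |
| `vignettes/pcmfrap-methods.Rmd` | models, defaults, design decisions, limitations |
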