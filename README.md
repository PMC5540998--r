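# simi — similarity unmixing for spectrally multiplexed fluorescence microscopy

Intravital multiphoton imaging routinely records many fluorescently labeled
cell populations at once, but neighboring emission spectra bleed into each
other's detection channels, and classical linear spectral unmixing cannot
separate more fluorophores than there are detectors. `simi` implements
**similarity unmixing (SIMI)**: instead of solving for fluorophore
abundances, it classifies every pixel by spectral signature, which keeps
working when fluorophores outnumber channels. It is aimed at microscopists
and image analysts working with multichannel (PMT-filter) detection systems
under single-label-per-cell staining designs.

## The method

The detected signal on channel *i* of an *n*-channel system is modeled as a
linear combination of the contributing fluorophores, `S_i = Σ_j a_ij F_j`,
where column *j* of the mixing matrix is fluorophore *j*'s **fingerprint**
`a_j = (a_1j, …, a_nj)` — its relative emission intensity per detection
channel, normalized so `Σ_i a_ij = 1`. Fingerprints are measured empirically
from single-label reference images (per-channel mean over foreground,
background-subtracted, unit-normalized), or annotated directly on a mixed
image for signals never available in isolation (e.g. macrophage
autofluorescence).

For each pixel, SIMI normalizes the measured channel vector to `b` with
`Σ_i b_i = 1` and assigns the fluorophore minimizing the squared difference

```
R²_j = Σ_i (b_i − a_ij)² ,   label = argmin_j R²_j
```

evaluated exhaustively over all fingerprints. Because only the *ratios*
between channels matter, any number of fluorophores with pairwise distinct
fingerprints can be separated — including `m > n` — as long as their
signatures are not negligibly close. The correctness condition is
one-fluorophore-per-cell: the classifier reports identity, not fractional
abundance. A linear-unmixing baseline (OLS and non-negative least squares)
is included for the determined regime `m ≤ n`, where the two methods agree
on the dominant fluorophore for pure pixels.

The package also ships a synthetic scene simulator (disk-shaped cells, one
fingerprint each, lognormal brightness spread, Poisson shot noise, Gaussian
read noise, optional mixed-signature "phagocyte" objects), evaluation
tooling (confusion matrices, per-object majority accuracy, recovered-class
counts), multichannel/OME TIFF I/O, and small excitation-planning helpers
for two-laser wavelength mixing (virtual wavelength, photon-flux totals).

## Worked example

Seven fluorophore signatures, six detection channels — the underdetermined
case where linear unmixing is impossible:

```r
library(simi)

ps    <- preset_scenario("six_channel_seven_class", seed = 11)
scene <- simulate_scene(ps$config)              # noisy image + ground truth
res   <- unmix_image(scene$image, ps$fingerprints)
res
#> <unmix_result> 128 x 128 pixels, threshold 51.66 , intensity mode: total
#> background         F1         F2         F3         F4         F5         F6  autofluor
#>      12693        373        921        515        583        732        274        293

confusion_and_accuracy(res, scene$truth)
#> <evaluation_report>
#>   pixel accuracy (foreground): 1
#>   object majority accuracy:    1
#>   recovered classes:           7 of 7
#>   per-class recall:            1 1 1 1 1 1 1
#>   30 objects evaluated; 3691 truth-foreground pixels
```

The per-pixel table counts how many pixels landed in each fluorophore
channel (the scene is mostly background); the report shows that every one
of the seven classes — six dominant-channel signatures plus one broad
autofluorescence-like signature — is recovered from only six channels, with
every foreground pixel correctly labeled at ~200 expected counts per pixel.

The same pipeline is scriptable from a shell (see `inst/exec/simi`):

```sh
simi simulate --preset six_channel_seven_class --seed 11 \
     --out scene.tif --truth truth.tif --prints prints.csv
simi unmix    --input scene.tif --prints prints.csv \
     --out-labels labels.tif --out-channels unmixed/
simi evaluate --pred labels.tif --truth truth.tif --out report.json
simi plan     --lambda1 850 --lambda2 1230     # prints 1005
```

File formats: images are TIFF (float32; layouts `pages` = one page per
channel, `samples` = channel-interleaved, `ome` = pages plus OME-XML channel
names/wavelengths), labels are 16-bit TIFF, fingerprints are CSV (one row
per fluorophore: `name, ch1, …, chn` in ascending-wavelength order) or JSON
(with channel metadata). Every CLI run writes a `<output>.run.json` sidecar
recording its full parameter set.

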