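---
title: "Mapping spawning redds from UAV imagery: models, operators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping spawning redds from UAV imagery: models, operators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reddmap)
```

## The problem

Salmonid females dig spawning nests (redds) in lake and river gravel,
clearing silt and algae as they do. The cleared gravel is darker than the
undisturbed substrate around it, so at survey altitude a redd is a dark,
irregular blob in an ordinary RGB photograph. `reddmap` turns such a
photograph into a thematic map: every pixel is assigned to one of a small
number of endmember classes (spawning redds, vegetation, underwater rocks,
deep water, and so on), the map is cleaned of isolated misclassified pixels,
and its quality is scored against ground-truth pixels the analyst reserved
for validation. Mapping the redd *area* this way sidesteps the classic
failure modes of manual redd counting — observer bias and superimposed,
uncountable nests.

The package operates downstream of data acquisition: it assumes a single
georeferenced or plain RGB image per site, with training and ground-truth
ROIs chosen by someone who knows the site. Flight planning, photogrammetry,
georectification and multi-temporal change detection are out of scope.

## Classifiers

### Gaussian maximum likelihood

Training ROIs give, per class $c$, the band mean $\mu_c$ and the unbiased
($n-1$) sample covariance $\Sigma_c$ of the training pixels, computed on the
unit scale (intensities divided by $2^{\text{bits}}-1$, so 8- and 16-bit
cameras behave identically). Each pixel $x$ maximises

$$ g_c(x) = \ln p_c - \tfrac12 \ln\lvert\Sigma_c\rvert
            - \tfrac12 (x-\mu_c)^\top \Sigma_c^{-1} (x-\mu_c), $$

with equal priors $p_c = 1/K$ by default — classification is then driven by
spectra alone, which matches how the method is used in the field. No
probability threshold is applied by default, so every pixel receives a
class; setting `probability_threshold` in `mlc_config()` leaves pixels below
that posterior unclassified instead.

Two numerical choices matter. A constant-colour training area produces a
singular covariance; such classes are flagged during training and the
classifier adds a relative ridge $\varepsilon \cdot \mathrm{tr}(\Sigma)/3$
(default $\varepsilon = 10^{-6}$, escalated tenfold until the Cholesky
factorisation succeeds; $\varepsilon$ itself when the trace is zero) to the
diagonal before inversion. Discriminant ties break to the lowest class id,
making the classifier deterministic and invariant to pixel order.

### Logistic neural network

The second classifier is a 3-input, one-hidden-layer, $K$-output perceptron
with logistic activations throughout, trained on one-hot targets by
full-batch gradient descent with momentum:

$$ \Delta w(t) = -\eta \, \nabla E + \alpha \, \Delta w(t-1), $$

where $E$ is the sum-of-squares output error averaged over training pixels.
The defaults are the settings used in the lake surveys: training rate
$\eta = 0.2$, momentum $\alpha = 0.9$, threshold contribution 0.9, RMS exit
criterion 0.1, one hidden layer, 1000 iterations.

Several aspects of that parameterisation are under-specified in common
remote-sensing practice, and this package fixes them as follows:

* **Threshold contribution** is implemented as a multiplier on the gradient
  part of the bias ("threshold") weight updates: biases learn at
  $0.9\,\eta$ while interconnection weights learn at $\eta$. This is an
  interpretation of the conventional parameter name, stated here rather
  than hidden.
* **Batch versus per-sample updates**: full batch, for determinism — the
  trained model is a pure function of the data and `rng_seed`.
* **Gradient scale**: the batch gradient is averaged over training pixels,
  so the meaning of $\eta$ does not depend on how many ROI pixels were
  drawn.
* **Initialisation**: weights uniform in $[-0.05, 0.05]$ from the seeded
  generator; hidden width defaults to $K$.

Training stops when the RMS output error reaches the exit criterion or the
iteration cap, whichever is first; a model that has not converged is still
returned, with a warning. On a six-class scene the default 1000 iterations
are typically not enough for full convergence (two- or three-class problems
converge comfortably within them); users who want a converged six-class fit
should raise `max_iterations` to a few thousand. The cap is part of the
standard configuration, so the package keeps it as the default rather than
silently training longer.

## Post-classification operators

Raw per-pixel classification leaves salt-and-pepper noise: isolated pixels
classified differently from their surroundings. Three operators, applied by
default in the order majority → sieve → clump, clean this up. The defaults
(3×3 majority kernel with centre weight 1; sieve at 4-connectivity, minimum
size 2; clump size 3) are the settings used in the lake surveys.

* **Majority analysis** replaces each pixel by the label holding the
  largest vote in its kernel window, the centre counted `center_weight`
  times and windows clipped at image borders. Unclassified (label 0) votes
  like any other label, so the filter never invents classes in unclassified
  regions. Ties that include the centre's label keep the centre; other
  ties go to the lowest class id. With `center_weight >= kernel²` the
  filter is the identity.
* **Sieve** labels connected components of equal nonzero class (4- or
  8-connectivity) and sets components smaller than `min_size` to
  unclassified. With the default minimum size 2, exactly the isolated
  single pixels disappear — which is why an otherwise fully classified map
  can contain a stray unclassified pixel after clean-up.
* **Clump** closes each class mask morphologically (dilate then erode,
  square element of width `size`, background padding at borders), bridging
  thin gaps between fragments of the same class. Classes are processed in
  descending order of pixel count; a pixel gained by a closing adopts the
  class only where the input map was unclassified or held a class processed
  earlier, later gains overriding earlier ones. This precedence rule is the
  package's own deterministic resolution of inter-class conflicts, which
  the standard descriptions of the operator leave open; original pixels of
  not-yet-processed classes are never destroyed.

The operators do not commute — a majority pass can erode a small component
below the sieve threshold that would otherwise have survived — so the order
is configurable and logged, and `apply_postclassification()` records the
pixels changed by each step.

## Accuracy assessment

Ground-truth ROIs, chosen pixel-disjoint from the training ROIs (enforced
when both are supplied), yield a $(K{+}1) \times K$ confusion matrix: rows
are predictions with an extra unclassified row, columns are true classes.
From it:

* producer's accuracy $\mathrm{PA}_c$ = diagonal / column total (omission
  complement);
* user's accuracy $\mathrm{UA}_c$ = diagonal / row total (commission
  complement);
* overall accuracy $p_o$ = trace / grand total, the unclassified row
  counting in the total but never in the trace;
* kappa $\kappa = (p_o - p_e)/(1 - p_e)$ with
  $p_e = \sum_c \text{row}_c \,\text{col}_c / N^2$ over the named classes
  only — the unclassified row has no matching column, so it contributes to
  $N$ but not to expected agreement.

This unclassified-row convention is exactly what reproduces the published
figures of the two bundled surveys (for example κ = 0.89 and 0.84 for the
two Thingvallavatn classifiers) from their raw counts. Kappa is often read
on a 0–1 scale, but the statistic itself can be negative for
worse-than-chance maps and the package does not clamp it. A class that never
occurs in the ground truth (empty column) or is never predicted (empty row)
has an undefined PA or UA; the package returns `NA` with a warning rather
than reporting a misleading zero. Display rounding is half-up at two
decimals, matching how such tables are conventionally printed; stored values
are exact fractions.

## The synthetic scene generator

`generate_scene()` emulates the structure of a subarctic lake spawning
ground without claiming colorimetric fidelity to any real site: four
horizontal zone bands (vegetated land 18%, pale shoreline 14%, shallow
water 43%, deep water 25% of image height by default), yellow-brown surface
rocks scattered in the shoreline band, and dark redd blobs — unions of six
jittered discs, so their boundaries are irregular like real redds — inside
the shallow band. Every pixel's colour is drawn from its class's Gaussian
colour model (default isotropic sd 0.02) plus sensor noise (default sd
0.02) and quantized to 8 bits. Training and ground-truth ROIs are sampled
without replacement from class interiors (one pixel in from any class
border, mimicking analyst-drawn interior polygons) and are pixel-disjoint by
construction. The default ROI sizes mirror a realistic survey design: 975
training pixels per class (fifteen samples of ~65 pixels) and 1000
ground-truth pixels per class.

`corrupt_labels()` complements the generator for testing the clean-up
operators: it flips each pixel independently with a given probability to a
uniformly random other class — the idealised salt-and-pepper error model
the majority and sieve filters target.

What passing tests on these scenes does and does not show: the generator
produces exactly the statistical structure the classifiers assume
(per-class Gaussian colours, spatially uncorrelated noise), so synthetic
recovery demonstrates correctness of the implementation, not performance on
real imagery. Real scenes add water-surface glint, ripples, depth-dependent
attenuation and spatially correlated texture, none of which are rendered;
accuracy on real surveys must be established with real ground truth, as in
the bundled error matrices.

## Problem sizes and determinism

The test suite and the acceptance script run the full-scene checks at
512×512 pixels (the scale at which per-class ROI sizes of ~1000 pixels are
realistic) and oracle-equivalence checks at 8×8–16×16, where brute-force
reference implementations are exact and fast. All stochastic components —
scene layout, colour draws, ROI sampling, label corruption, network
initialisation — flow from explicit integer seeds, and the maximum
likelihood path is fully deterministic, so a pipeline run is reproducible
byte for byte from its manifest.

## Conventions and limitations

* Coordinates are 1-based `(row, col)` with row 1 at the top throughout,
  the native R matrix convention; ROI formats carrying x/y are converted on
  read (x = column, y = row).
* Raster formats are TIFF and PNG. GeoTIFF georeferencing tags are carried
  opaquely (the package does no geodesy) and JPEG input is not supported.
* Class maps persist as single-band 8-bit rasters, limiting file-backed
  schemes to 255 classes.
* The two classifiers here are the two that performed best on the original
  lake surveys; the package deliberately implements no further classifiers
  and no object-based or convolutional segmentation — it is pixel-based by
  design.
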