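---
title: "Methods: from scale nanostructure images to phylogenetic inference"
author: "nanophylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from scale nanostructure images to phylogenetic inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanophylo)
```

# Overview

Snakes carry sub-micron surface structures ("nanogratings") on the apical
face of their oberhautchen cells: holes, straight or labyrinthine channels,
border digitations, sawteeth, and cranio-caudal ridges. These structures
confer hydrophobicity and sometimes structural iridescence, and their
distribution across species is a classic discrete-character comparative
problem. nanophylo implements both halves of such an analysis:

1. **imaging** — classifying SEM-like grayscale images of cell surfaces into
   the four discrete surface states (smooth, holes, straight channels,
   labyrinthine channels) with a contour-geometry algorithm, plus the
   measurement-based rules for cell shape and cell border;
2. **phylogenetics** — Mk models of discrete-character evolution with Pagel
   tree transformations and AICc model selection, a likelihood-ratio test of
   phylogenetic signal, stochastic character mapping, and phylogenetic
   regression (PGLS and a Bayesian multinomial-logit mixed model).

A synthetic-data module generates every input — images with known ground
truth, birth-death trees, Mk-simulated characters — so the entire pipeline
is testable without any external download.

# The imaging algorithm

An image passes through five stages.

**Contrast equalization.** Contrast limited adaptive histogram equalization
(CLAHE, via EBImage) removes large-scale illumination inhomogeneity while
capping noise amplification. Parameters: `clip_limit` (default 2) and the
tile side (default 64 px).

**Tiled thresholding.** The image is cut into 100 x 100 px tiles; each
tile's intensities are clustered by k-means with k = 3, seeded
deterministically at the intensity quartiles so the imaging path needs no
RNG. The tile threshold is the mean of the two lowest cluster centres —
dark structures fall below it. Two degenerate cases get documented
treatment. A tile with fewer than three distinct intensities degrades its
cluster count gracefully (a two-level tile thresholds at the midpoint); a
tile whose cluster-centre spread is below `min_contrast` (default 40
intensity units) is treated as structure-free and contributes no threshold.
Without the second guard, the two-lowest-centres rule would mark roughly a
third of the pixels of a *smooth* (pure noise) image as foreground; real
structured tiles separate their centres by the structure/background contrast
(~115 units in our synthetic material), so the guard at 40 is far from both
regimes. Tile thresholds are then Gaussian-smoothed across tiles
(`smooth_sigma` = 1 tile; NA-aware normalized convolution so structure-free
tiles inherit neighbouring thresholds) and interpolated bilinearly to pixel
resolution, which suppresses tile-border artifacts.

**Contour detection.** Connected foreground components (8-connectivity,
speckle guard `min_area` = 20 px) become contours with the three ASR
descriptors: **A**, pixel area normalized by image area; **S**, solidity —
pixel count over the area of the convex hull of the boundary-pixel corners
(taking corners rather than centres guarantees S <= 1 and makes a 60 x 5 px
rectangle measure exactly 60 x 5); **R**, side ratio of the minimum-area
bounding rectangle found by rotating calipers (>= 1); and the long-axis
orientation in [0, 180).

**Contour classification**, in fixed order: (1) a *hole* needs S > 0.8 and
R < 6, and its area must lie within 2 SD of the mean area of the
provisional holes of the same image — the mean/SD are computed once from
the S/R-provisional holes and applied once (a two-pass scheme; iterating
the filter would make the result order-dependent); (2) a *straight channel*
needs S > 0.5 and R >= 6, with no area constraint; (3) remaining contours
adopt the label of their nearest Hu-moment match in a training library when
the log-magnitude distance is below 0.3 — the default library is built from
canonical synthetic shapes (disk, ellipses, elongated rectangles), the
cutoff chosen so a shape always matches itself (distance 0) while a disk
never matches a 12:1 rectangle (distance ~1); (4) a contour that can be cut
at its convexity defects (depth >= 4 px; each cut runs from the deepest
defect vertex to the nearest boundary vertex at least n/6 positions away,
recursively) into two or more pieces that each satisfy the straight-channel
rule becomes a *labyrinthine channel*, with per-piece orientations
recorded; (5) anything else is unclassified. An optional JSON override
table (contour id to label) replaces interactive manual correction; the
pipeline is fully runnable without it.

**Surface decision tree.** If the total contour area fraction is below 3%
the surface is *smooth*. Otherwise *holes* win when they have the largest
covering surface (exact ties prefer holes, matching the order in which the
states are checked). When channels cover more, the standard deviation of
the channel orientations decides: above 25 degrees *labyrinthine*,
otherwise *straight*. Orientations are axial (0-180); the SD is taken after
re-centring on the circular mean of the doubled angles, avoiding the
179-versus-1 degree wrap artifact a naive SD would create. The published
distribution of per-species orientation SDs shows an empirical gap between
22 and 26 degrees, so the cutoff is robust to this choice of statistic.

**Cell shape and border.** These consume measurement tables, not pixels
(digit lengths are measured by hand in practice). A cell is *polygonal*
when mean width / mean length <= 2 (boundary inclusive), *wide* otherwise;
lengths supplied as (min, max) pairs are averaged per cell, the convention
for sawtooth borders. Digit states use the digit-to-cell length ratio:
< 0.3 short, [0.3, 0.5] mild, > 0.5 long. Regular versus sawteeth is a
caller-supplied flag: sawteeth are recognized descriptively (larger,
5-10 um, irregular, imbricating) and no algorithmic criterion is published,
so the package records the flag rather than guessing one.

# Trees and transformations

Newick I/O, pruning, and polytomy resolution delegate to ape; pruning keeps
root-to-tip depths of retained taxa, and multifurcations are resolved
deterministically (children sorted by label) with new branches of
`1e-6` x tree height, the conventional dodge for comparative methods that
require strictly binary trees.

Subspecies deduplication collapses rows sharing a binomial prefix (first
two tokens of the label): first drop partially scored subspecies when a
fully scored one exists; then, among disagreeing subspecies, keep the one
whose states best match the most closely related other species (nearest
cophenetic neighbour; ties broken alphabetically); finally keep the
alphabetically first. Every removal is logged with the rule that fired.

Pagel's transformations are implemented directly. **lambda** multiplies
internal branches by the coefficient; by default pendant branches are then
extended to restore each tip's depth, which makes the transformed tree's
Brownian covariance equal the textbook lambda-scaled covariance
(off-diagonals x lambda) on ultrametric trees — the behaviour implied by
likelihood-based lambda estimates. A `pendant = "strict"` flag provides
pure internal compression for users who want the literal reading; which
variant underlies any particular published estimate is generally not
recoverable from a methods section, so both are exposed and the
covariance-faithful one is the default. **delta** raises node heights to a
power after normalizing total height to one (and rescales back; the
normalization makes the coefficient scale-free). **kappa** raises each
branch length to a power, with kappa = 0 giving unit branches (purely
punctuated change).

# Mk likelihood machinery

Rate matrices come in ER (one rate), SYM (symmetric), and ARD (all rates
distinct) structures. Transition probabilities use the eigendecomposition
of Q when it is diagonalizable and well-conditioned (condition estimate
< 1e8) — one matrix multiply covers all branches — falling back to
scaling-and-squaring otherwise; SYM matrices are always well-behaved, ARD
need not be. The likelihood is Felsenstein pruning with per-node rescaling;
unknown tip states enter as all-ones partials, and taxa unknown for a
character are pruned before fitting. Root priors: uniform (the fitting
default), stationary, or the scaled-conditional-likelihood convention used
by stochastic mapping.

Fitting maximizes over log-rates (bounds [1e-8, 1e3]) and, optionally, one
transformation coefficient (lambda in [0, 1]; delta, kappa in [0.01, 3],
matching common practice) by multi-start L-BFGS-B with log-spaced rate
starts — 25 by default, configurable; the λ-profile is occasionally
multimodal, and at least three starts (cycling coefficient starts 0.9 /
0.5 / 0.2) are advisable for transformed fits. Model comparison uses
`AICc = -2 lnL + 2p + 2p(p+1)/(n-p-1)` with n = number of tips, and Akaike
weights normalized within the comparison set. The phylogenetic-signal test
profiles the Mk likelihood over the lambda transformation and compares the
ML fit against lambda = 0 (star phylogeny: trait evolution independent of
the tree) with a one-degree chi-square LRT.

A note on attainable precision: a single binary character on a 300-tip tree
carries limited information about its own rate — the ML estimator's
relative SD is about 20-30% regardless of tree scale (we verified the
likelihood itself against an independent implementation, so this is
sampling variance, not optimizer error). Recovery harnesses therefore
check the median relative error for rates; the lambda coefficient is much
better determined and is checked seed-by-seed.

# Stochastic mapping

Exact marginal ancestral posteriors come from the up-down (inside-outside)
pruning recursion and serve as the reference for validating the sampler.
Each sampled history draws the root from the scaled conditional likelihoods
(equivalently: flat root prior), draws node states down the tree from their
conditional distributions, then fills every branch with an
endpoint-conditioned path by **uniformization**: the number of jumps of the
embedded chain is drawn from its Poisson mixture conditioned on the
endpoints, the jump chain is bridged by forward sampling against powers of
the uniformized transition matrix, jump times are uniform order statistics,
and virtual (self) jumps collapse into segments. Uniformization has bounded
runtime even for improbable endpoint pairs, where rejection sampling stalls.
For a 2-state equal-rates chain the uniformized jump chain flips
deterministically, so the change count follows a parity-truncated Poisson —
a closed form the tests exploit.

By default the rate matrix stays fixed at its ML estimate (empirical
Bayes). A full-Bayes mode resamples the free rates between draws by
Metropolis-Hastings under independent exponential priors centred on the ML
rates (the reference implementations leave this prior implicit; ours is
stated), with configurable burn-in and sampling frequency — the published
configuration (1e4 draws, burn-in 1e3, frequency 100) is directly
expressible. Summaries give node posterior frequencies, mean transition
counts, and optional per-clade time-in-state proportions.

# Correlations among characters

**PGLS** regresses one character's integer codes on another's
(pseudo-continuous coding — the codes are used verbatim, which is what
fitting a linear model to coded states means; the approach has documented
good statistical behaviour for discrete data) under error covariance
sigma^2 V, where V_ij is the root-to-MRCA distance and the tree is used
untransformed (all Pagel coefficients fixed at 1). The solve whitens
through the Cholesky factor of V — no explicit inverse — and reports
per-coefficient t tests plus a global F test against the intercept-only GLS
model; estimates are invariant to scaling V.

**PGLMM** is a Bayesian multinomial-logit mixed model sampled by a
compiled blocked Gibbs sampler. For a J-state response (reference = lowest
code) there are J-1 latent variables per species; a 2-state response gets a
single latent with intercept and slope, J > 2 gets per-latent intercepts
and slopes with no global intercept. Priors: fixed effects
N(0, (1.7 + pi^2/3) I); residual covariance fixed at (I + 11')/J
throughout the run; the phylogenetic random effect has covariance
Sigma_a (x) A with A the Brownian covariance normalized to unit height,
an inverse-Wishart law on the working covariance, and genuine parameter
expansion (a = alpha u with alpha ~ N(0, 1e3), i.e. alpha.mu = 0,
alpha.V = 1e3) for mixing. The inverse-Wishart's (V, nu) are not pinned
down by any published default, so V = I, nu = J-1 is used and stated here.
The sampler works in the eigenbasis of A, where the random-effect rows
decouple and each sweep is O(n) — no dense n x n solve; latents are updated
by random-walk Metropolis and clipped to +/- 20 against overflow (the
truncation value is our choice). Two reporting conventions matter:
coefficient p-values are two-sided minimum-tail doubled (the tail
convention is otherwise ambiguous), and because the residual variance is
fixed, latent-scale coefficients are also reported rescaled by
1/sqrt(1 + c^2 sigma_e^2) with c = 16 sqrt(3)/(15 pi) — the standard
correction that makes them comparable to a marginal logit fit. With the
random effect forced off on a star tree, the rescaled slope reproduces the
multinomial-logit MLE to within a few percent (validated against
`nnet::multinom`); with A = I the random effect is confounded with the
residual, which is why that limit, not a star-tree fit with the random
effect on, is the sampler's oracle.

The all-pairs screen tests every unordered character pair (10 pairs for 5
characters), pruning to jointly scored taxa per pair, skipping pairs with
fewer than 10, and calling significance at alpha = 0.05.

# The synthetic-data generator

`generate_tree()` simulates constant-rate birth-death trees conditioned on
the tip count (ape's `rphylo`). `simulate_character()` samples states
root-to-tip through `expm(Q t)` on the optionally lambda-transformed tree.
`generate_character_matrix()` emulates the five scored characters — cell
shape (2 states), cell border (5), cell surface (4), ridge (2), life habit
(7: four pure habits plus the three combination states) — with ER rates
scaled to about 1.5 expected changes per character across the tree, a
regime with clear but unsaturated signal. Coupling two characters makes
both deterministic functions of one latent Mk character (the second equals
the latent; the first is the monotone collapse floor(latent k1/k2)), giving
the correlation tests a known positive with a known effect size; the
collapse is monotone in the codes deliberately, since the tests consume
pseudo-continuous codes.

`generate_surface_image()` draws dark structures on a brighter background
(default 175 vs 60, 8-bit), adds a linear illumination gradient of random
direction (amplitude 25 — the stage the CLAHE + local thresholding pipeline
exists to cope with) and Gaussian pixel noise (default SD 5). Holes are
ellipses (semi-axes 5-9 px, axis ratio up to 2); straight channels are
50-80 x 4-5 px rectangles with orientations N(base, angle_sd); labyrinthine
chains concatenate 2-3 rectangles (32-42 x 3.5 px) joined at turns of at
least 35 degrees, guaranteeing convexity defects and a known decomposition,
with one truth polygon recorded per segment. Default densities give 8-12%
surface coverage, the regime of structured SEM images. Structures are
placed with overlap rejection. What the generator does **not** emulate:
real SEM texture (graininess, charging artifacts, partial cell borders,
depth-of-field blur), within-image mixtures of states, and the faint
sub-threshold pits that real smooth-but-dimpled species show. Passing the
panel therefore demonstrates that the geometry, thresholds and decision
tree are implemented correctly — not that the classifier would reach the
same accuracy on raw micrographs.

One state per species per character is assumed throughout; within-species
variability is not modelled anywhere in the synthetic matrices.

# Reproducibility, problem sizes and numerical choices

Every stochastic operation takes an integer seed and threads it through R's
default Mersenne-Twister generator, restoring the caller's RNG state on
exit; images are bit-identical given the seed. The test-suite problem sizes
are chosen to exercise each statistical claim at meaningful power on one
desktop CPU: 200-image panels for the end-to-end imaging accuracy check,
300-tip trees and 20 seeds for lambda recovery, 1e4 draws for
sampler-versus-exact comparisons, 200 replicates for the PGLS size check
(each on a fresh tree, avoiding tree-specific heaping of the discrete-code
p distribution), and 1.2e4-3e4-iteration PGLMM chains, which the compiled
sampler traverses in seconds. The pipeline's own defaults (e.g. `n_starts`,
mapping draws, chain lengths) are configurable up to the published-scale
settings (1e4 starting points, 1e4 mapping simulations, 1e7-iteration
chains) for production runs.

Degenerate inputs are handled explicitly: monomorphic characters error with
advice (their likelihood is flat in the rates); constant predictors error
naming the offender; impossible endpoint pairs in branch-path sampling
error rather than loop; empty training sets skip Hu matching with a
warning; a constant image passes through equalization unchanged.

# Known limitations

* The imaging module classifies surfaces only; cell borders and digits are
  measured, not detected, matching how the characters are defined.
* The "dense network of elevations" phenotype is outside the four-state
  scheme and should be coded unknown.
* PGLS on pseudo-continuous codes inherits the usual caveats of treating
  ordered codes as metric; the screen reports it alongside PGLMM for that
  reason.
* The PGLMM convergence flag (Geweke |z| < 3 on >= 80% of parameters) is a
  screen, not a guarantee; long chains remain the user's responsibility.
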