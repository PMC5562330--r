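---
title: "Detecting and tracking local calcium releases in submembrane image stacks"
author: "lcrtracker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and tracking local calcium releases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcrtracker)
```

## The problem

Cardiac pacemaker (sinoatrial-node) cells generate their spontaneous beat
partly through local Ca releases (LCRs): spatially confined discharges of
sarcoplasmic-reticulum Ca into the thin cytosolic layer under the cell
membrane during diastole. There, released Ca activates the electrogenic
Na/Ca exchanger and accelerates diastolic depolarization. Unlike the
stereotyped Ca sparks of ventricular myocytes, LCRs propagate, recruit
neighbouring release sites, merge with each other and split into multiple
fronts, so single-threshold spark detectors mischaracterise them.
`lcrtracker` implements an event-based analysis of this behaviour: it
segments every frame of a submembrane [Ca] movie into release footprints,
links the footprints through time into dynamic LCRs with explicit
birth/collision/separation/death bookkeeping, and reduces each LCR to the
statistics used to compare conditions (signal mass, path area, maximum
amplitude, duration, birth time).

The sole required input is a `FrameStack`: a time-ordered series of 2D
matrices of instantaneous [Ca] (micromolar) in the voxel layer under the
membrane, with a frame interval (default 5 ms) and voxel edge length
(default 100 nm). Such stacks typically come from stochastic
reaction-diffusion simulations of pacemaker cells; the package reads them
as multi-page 32-bit float TIFF or delimited text.

## Single-frame segmentation

For each frame `f` the algorithm computes the arithmetic mean and the
*intensity increment*

\[ \Delta_f = \frac{\max_f - \mathrm{mean}_f}{n_\mathrm{bins}}, \qquad
   n_\mathrm{bins} = 50 \text{ by default,} \]

and slices the frame into nested Boolean *intensity bins*: bin *i*
(1-based) holds the voxels with \([Ca] > \mathrm{mean}_f + \Delta_f\,(i-1)\),
strict inequality at every level. Bin 1 — everything strictly above the
frame mean — separates releases from background. Each maximal connected
component of bin 1 is one *LCR image*; the *intensity peaks* inside a
component are its plateau-grouped local maxima, and an image with two or
more peaks is *complex* (it embraces several release sites). The *signal
mass* of an image is the summed voxel [Ca] converted to moles:
concentration (nmol/L) times voxel volume in litres, 1e-18 L for a 100 nm
voxel edge, so one voxel at 1 uM carries 1e-15 nmol.

Two connectivity choices are deliberately different:

* **cluster connectivity is 4** (edge-sharing): two voxels belong to the
  same cluster only when they have a common border, which corner-only
  contact does not provide;
* **peak neighbourhood is 8**: diagonal neighbours suppress what would
  otherwise be counted as twin peaks on a discrete diagonal ridge.

Both are configurable (`lcrConfig`). A connected plateau of equal-valued
local maxima counts as a single peak, represented by its smallest
(row, col) voxel — without this rule, quantised data would double-count
peaks. A spatially uniform frame has \(\Delta_f = 0\) and yields zero LCR
images rather than an error.

Because the mean and increment are recomputed per frame, segmentation
levels drift with the global Ca transient. That is intentional — the
threshold adapts as the transient decays — and it implies that the
absolute segmentation level of an LCR is not comparable across distant
frames. The package documents this behaviour rather than "correcting" it.

## Frame-to-frame tracking

Two images in consecutive frames form an *image pair* when their bin-1
footprints share at least one voxel. Per frame, the tracker resolves the
pair graph in a fixed order:

1. **Collisions first.** A current image paired with previous images of
   two or more distinct live tracks is a collision. The signal masses of
   the *previous-frame* images of each pair are compared; the track with
   the largest previous-image mass survives and adopts the current image,
   every other participant is terminated (`death_collision`), and all of a
   loser's pairs are deleted before separations are considered — collision
   has priority over separation. Ties go to the older track (smaller id),
   keeping the algorithm deterministic. Simultaneous multi-way collisions
   leave a single largest-mass survivor.
2. **Adoption.** Each remaining current image joins the unique live track
   it still pairs with. A previous image feeding several current images is
   a *separation*: all those images stay in the same LCR, which now has
   several *threads*. A current image fed by several previous images of
   the same track is an intra-track thread merge (`intra_thread_merge`),
   not a collision — only distinct LCRs can collide.
3. **Births.** Current images with no remaining pair start new tracks.
   Images of the very first analysed frame are all births; they represent
   pre-existing releases, so birth-time statistics can exclude them
   (`excludeFrame0Births`, on by default).
4. **Attrition.** A live track that adopted nothing is terminated by
   stochastic attrition. A multi-thread track dies only when *all* its
   threads have ended; losing one front does not kill the LCR.

Tracks still alive on the last frame are labelled `alive_at_end` — in a
correctly windowed diastolic recording this means the LCR was absorbed by
the upstroke-induced Ca transient rather than dying on its own.

Threads are represented implicitly: every current-frame image a track
holds is one live thread tip, so the thread count of a frame is the number
of images the track holds in it. The per-track `nThreads` reported is the
peak concurrent thread count over the track's life. Explicit per-thread
image chains are not materialised because no downstream statistic consumes
them; the event log (separations, merges, collisions with participants)
retains the full branching history if a user needs to reconstruct it.

A dynamic LCR is *complex* if at least one of its member images is
complex, independent of its thread history: multi-peak images indicate
multiple recruited release sites even when the footprint never splits.

## Per-LCR metrics and summaries

* **Signal mass** (nmol ms): sum of member-image masses times the frame
  interval.
* **Path area** (um^2): area of the *union* of all voxels the LCR ever
  occupied — a static release has the same path area whether it lives one
  frame or a hundred.
* **Max amplitude** (uM): highest voxel [Ca] over the track's life.
* **Duration** (ms): inclusive frame count times the frame interval, so a
  single-frame LCR lasts one frame interval (5 ms), not zero. The
  inclusive convention is a documented choice; short-lived releases have
  nonzero durations under it.
* **Birth time** (ms): birth frame relative to the analysis-window start.

`summarizeLCRs` aggregates these per class (all / complex / simple) with
exact additivity — counts and total masses for "all" equal simple plus
complex by construction. "Total complex collisions" counts collision
events whose *surviving* track is complex at finalisation; the alternative
reading (either participant complex) is available via
`complexCollisionRule = "either"`, since the informal definition admits
both. Histogram defaults: 25 ms birth-time bins and log-spaced decade bins
for signal mass; both are configurable, as no canonical binning exists.

## The diastolic analysis window

LCR statistics are meaningful during diastole, between the maximal
diastolic potential (MDP) and the activation of L-type Ca channels.
`selectWindow` locates the MDP as the minimum Vm of the selected cycle
(earliest sample on ties) and the window end as the first upward crossing
of the threshold (default -50 mV) after it, linearly interpolated between
samples and rounded (half-up) to the stack's frame grid. Cycles are
delimited by action-potential peaks, found as local Vm maxima above 0 mV
(boundary samples included, so traces cut at a spike still delimit their
cycles); the caller picks the cycle index. The minimum-Vm rule for the MDP
is a documented choice — any sub-sample refinement would be spurious at a
5 ms output interval.

## The synthetic generator and what passing tests mean

`lcrScenario`/`renderScenario` produce stacks of scripted isotropic
Gaussian blobs,

\[ \mathrm{frame}_t = B(t) + \sum_e A_e(t)\,
   e^{-d_e^2 / 2\sigma_e(t)^2} + \varepsilon, \qquad
   B(t) = B_\mathrm{rest} + (B_0 - B_\mathrm{rest})\,e^{-t/\tau}, \]

with exact ground truth (birth/end frames, amplitudes, footprints) and
seeded determinism. Defaults emulate a diastolic recording: resting
background 0.1 uM (~100 nM), initial background 0.6 uM decaying with
\(\tau = 150\) ms (the tail of the action-potential-induced transient),
zero noise — the simulation output this analysis targets is noise-free,
so noise exists only as an explicit knob. Additive noise is clamped at
zero because concentrations cannot be negative.

Scenario builders script the three behaviours the tracker must get right:

* `makeMergeScenario`: a smaller blob drifts into a static larger one;
  the footprints fuse and the collision must be won by the larger
  previous-image mass.
* `makeSplitScenario`: two components separate from a common centre; one
  separation event, two threads, and the track must survive the first
  thread's fade and die with the second.
* `makePopulationScenario`: by default 30 static events on a 64 x 64 grid
  over 200 frames, placed on a regular lattice whose spacing guarantees
  that no two supra-mean footprints can touch (given the default
  amplitude 1.5–4 uM and width 0.9–1.2 voxel ranges), with seeded random
  amplitudes, widths, birth frames and durations. Zero noise plus
  guaranteed isolation makes recovery exact: the validation suite demands
  the scripted event count, exact birth frames and all-simple
  classification. Event durations sampled beyond what a short stack can
  hold are truncated so every event is born after the first frame and
  fades before the last.

The blobs are Gaussians, not solutions of a reaction-diffusion problem:
the generator tests the *detector*, not the cell's physics. Passing these
tests therefore shows that segmentation, linking and bookkeeping are
correct on well-posed inputs; it does not show robustness to photon
noise, motion, anisotropic point-spread functions or the irregular
footprints of real recruited release clusters — none of which the
generator emulates. On noisy input the adaptive mean threshold will
produce spurious small detections (the test suite demonstrates the
direction of this effect without asserting a rate).

## Numerical and interface choices

* Rows, columns and frames are 1-based; frame *k* is at time
  \((k-1)\,\Delta t\). Units are fixed (uM, ms, nm) and never guessed
  from the data.
* Mass conservation of the segmentation (sum of image masses = direct
  supra-mean summation times voxel volume) holds to floating-point
  round-off; the suite checks a 1e-12 relative tolerance.
* Stacks are written as uncompressed baseline float32 grayscale TIFF by
  the package's own encoder, one page per frame; reading accepts LZW as
  well. Round trips are exact at float32 precision.
* The optional `periodicX` flag wraps the column dimension for cells
  approximated as a toroid; it affects cluster connectivity, peak
  neighbourhoods and blob rendering, and is off by default because the
  wrap-around is a modelling convention, not an observation.
* Detection and tracking contain no randomness: identical stack and
  configuration give byte-identical outputs, which the pipeline writes
  atomically together with the exact configuration used.

## Validation problem sizes

The shipped test-suite and acceptance checks run, per invocation: bin
nesting on 100 random frames up to 64 x 64; clustering against an
independent flood-fill oracle on 200 random 16 x 16 masks at both
connectivities; partition/conservation on 25 multi-blob frames; the
30-event 64 x 64 x 200 population recovery; the merge and split
scenarios; the ensemble-table consistency checks; and a byte-identity
rerun of the full pipeline on an 8-event stack. These sizes were chosen
to exercise every code path in seconds while keeping recovery conditions
exact; larger stacks change runtimes, not outcomes, since the algorithms
are deterministic per frame.

## Known limitations

* The adaptive per-frame threshold makes detection sensitive to the
  global transient phase: early diastolic frames with a high mean detect
  only the strongest releases.
* No gap closing: a release that dips below the frame mean for one frame
  is two tracks (a death and a birth). This mirrors the strict overlap
  definition of an image pair.
* No sub-voxel localisation, smoothing or denoising; inputs are assumed
  noise-free or pre-processed.
* Collision resolution compares single previous-frame image masses, not
  whole-track cumulative masses; the informal "larger LCR wins" reading
  is interpreted at the image level, where the comparison is defined per
  pair.
* Proprietary microscope formats, motion correction and dye calibration
  are out of scope.

## A worked run

```{r example}
scn <- makePopulationScenario(nEvents = 8, height = 32, width = 32,
                              nFrames = 60, seed = 11)
out <- renderScenario(scn)
trackSet <- trackLCRs(out$stack)
trackSet
head(trackTable(trackSet))
met <- lcrMetrics(trackSet)
summarizeLCRs(met, eventLog(trackSet))$summary
```
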