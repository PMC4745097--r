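# widecal

Wide-field single-photon calcium imaging records hundreds of neurons at
once — at the price of movies that are tens of gigabytes, contaminated by
respiratory motion and illumination non-uniformity, and too large for
manual ROI curation. `widecal` is an R package for neuroscientists running
such experiments (e.g. GCaMP6f imaging of hippocampal CA1 through a
cannula window during trace eyeblink conditioning). It processes a session
end to end:

1. **Motion correction** — homomorphic (log-domain) contrast enhancement
   to remove the static multiplicative illumination field, then rigid
   registration by regularized phase correlation against a running-mean
   template, with sub-pixel peak interpolation.
2. **ROI detection** — per-pixel z-scoring over the session,
   `z = (x - mean)/sd`, an adaptive threshold starting at 1.5 SD,
   morphological cleanup, and 8-connected component labeling into
   single-frame ROIs bounded by soma morphology (30-300 px at
   1.312 µm/px).
3. **ROI merging** — single-linkage clustering of detections by centroid
   and bounding-box proximity in overlapping image blocks, a redundancy
   pass across blocks, and a greedy mask-overlap filter (IoU cap) in
   place of manual curation.
4. **Traces** — per-ROI mean fluorescence; dF/F as
   `(f - f_avg)/f_avg`, rescaled so each trace's maximum is exactly
   100%; SNR as max trace intensity over the mean temporal SD of
   non-ROI pixels; whole-field photobleaching percent.
5. **Behavior** — tone-puff trial schedules (350 ms CS, 250 ms trace
   interval, 100 ms US) and trial scoring from an eyelid-reflection
   trace: correct iff any sample within 600 ms of tone onset exceeds
   `baseline mean + k * SD` (baseline = 3 s pre-tone).
6. **Task statistics** — trial-aligned dF/F; per-ROI paired t-test of
   task-window ([0, 2) s) vs baseline-window ([-2, 0) s) area under the
   curve over correct trials; positive/negative labels by the sign of
   the difference at α = 0.05; latency to the peak of the trial average
   within 8 s; population percentages.
7. **Spatial statistics** — median pairwise centroid distance with a
   500-draw resampling null, 50 µm adjacency counts by modulation type,
   and a tie-corrected Mann-Whitney rank-sum comparison.

A **simulator** (`simParams()`, `makeGroundTruth()`, `renderMovie()`,
`renderEyelid()`, `renderCellTraces()`) generates movies with known
ground truth — planted somata, GCaMP6f-like transients, respiratory
motion with rare biphasic jumps, vignetting, photobleaching, shot + read
noise, and a 40-trial conditioning schedule with positively/negatively
modulated cells — so every stage is tested against what was planted.
See `vignettes/widecal-methods.Rmd` for the models and parameter
rationale.

## Worked example

Simulate a small session, correct it, detect and merge ROIs, and extract
normalized traces:

```r
library(widecal)

p  <- simParams(frameHeight = 128, frameWidth = 128, nFrames = 300,
                nCells = 8, seed = 19)
gt    <- makeGroundTruth(p)
movie <- renderMovie(gt, p)

res       <- correctSequence(movie, registrationParams(maxShift = 10))
corrected <- res$video
summarizeDisplacement(res$displacement)
#> $meanUm
#> [1] 1.437511
#> $sdUm
#> [1] 0.7356981

stats  <- computePixelStats(corrected)
sfrois <- detectRois(corrected, stats, detectionParams())
rois   <- filterSeparated(clusterRois(sfrois, frameDim(corrected)))
rois
#> RoiSet: 7 multi-frame ROIs in a 128 x 128 px frame
#>   area 137-150 px, appearances 11-24 frames

scoreRecovery(rois, gt)[c("recall", "precision")]
#> $recall
#> [1] 0.875
#> $precision
#> [1] 1

traces <- normalizeTraces(extractTraces(corrected, rois))
quality <- computeSnr(corrected, rois, traces, stats)
round(quality$meanSnr, 2)
#> [1] 47.47
photobleachingPercent(corrected)
#> [1] 6.383189
```

The displacement summary is the per-frame motion magnitude in µm,
measured relative to the first frame (the planted respiratory amplitude
is 0.8 px ≈ 1 µm); 7 of the 8 planted cells are recovered with no false
positives — in a 15 s movie one sparsely firing cell does not reach the
5-appearance survival threshold, which is exactly the behavior the
full-length run is scored on; SNR is each ROI's peak intensity over the background noise SD;
the bleaching percent reflects the simulator's 6.7% whole-session decay
sampled over this shorter movie.

Task statistics run on a full-length session; at the trace level:

```r
p2  <- simParams(frameHeight = 256, frameWidth = 256, nFrames = 27500,
                 nCells = 50, seed = 73)
gt2 <- makeGroundTruth(p2)
tr2 <- normalizeTraces(renderCellTraces(gt2, p2))
mod <- analyzeTaskModulation(tr2, gt2@schedule)
summarizePopulation(mod$label)
#>      label count percent
#> 1 positive    11      22
#> 2 negative    15      30
#> 3     none    24      48
mean(mod$label == gt2@modulationLabel)
#> [1] 0.92
```

`runPipeline(pipelineConfig(...), outDir)` chains every stage, writes the
intermediate TIFF/CSV/JSON artifacts, and records per-stage summary
numbers in a `manifest.json` that reproduces bit-exactly under the same
configuration and seed. A thin command-line wrapper lives at
`inst/scripts/widecal.R`:

```sh
Rscript inst/scripts/widecal.R run --config inst/extdata/example-config.yaml \
    --out outdir --seed 1
```

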