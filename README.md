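# dwiseg

Fully automatic segmentation of acute ischemic stroke lesions in
diffusion-weighted MRI (DWI), implemented as a two-stage convolutional
cascade with its own self-contained neural-network engine
(Rcpp/RcppArmadillo), NIfTI preprocessing, patch sampling, component-level
evaluation metrics, and a synthetic phantom generator so that the whole
pipeline can be trained and tested without clinical data.

**Who it is for.** Medical-image-analysis researchers who want a fully
inspectable, dependency-light R implementation of the cascade — for
method study, teaching, and phantom-scale experimentation — and anyone
needing the component-level evaluation suite (Dice, FP/FN component
counts and sizes, detection rate, small/large stratification) for lesion
segmentations.

## The method

Acute ischemic lesions are hyperintense in DWI but vary from a few
pixels to hundreds, and bright air-interface artefacts mimic small
lesions. The cascade:

**Stage 1 — EDD-style ensemble encoder-decoder.** Each branch is an
encoder of 3×3 stride-1 convolution stacks (batch norm + ReLU) with 2×2
max poolings that record the argmax location **m** of every window, and
a mirrored decoder that upsamples by *unpooling*: each pooled value is
scattered back to its recorded position,

```
x̃, m = f_D(x),   y = g_D(x̃, m)
```

so weak small-lesion activations are reconstructed in place instead of
being smeared by interpolation. N independently initialised branches are
fused by the pixel-wise mean (the naive ensemble)

```
h(x) = g_D1(f_D1(x)) ⊕ … ⊕ g_DN(f_DN(x)),      ⊕ = mean
```

and a refinement head conditions on the original image,
`H(x) = r(h(x), x)`. Training minimises the deeply supervised loss

```
ℓ = λ1 CE(H(x), y) + λ2 CE(h(x), y) + Σ_i λ_{i+2} CE(branch_i(x), y)
```

by SGD (learning rate 0.05, momentum 0.9, weight decay 0, Xavier
initialisation, all λ = 1).

**Stage 2 — MUSCLE-style candidate evaluation.** The stage-1 map is
thresholded at 0.5; slice-wise 8-connected components of ≤ 60 px become
candidates. Around each candidate, image windows at scales s, 2s, 4s
(s = max(bbox side, 8)) plus the probability window are resized to
16×16 and stacked; a mini-VGG classifier (4 convs, 1 pooling, 3 FC
layers) yields an instance probability q, fused into the pixel odds as
independent evidence: `p' = p·q̃ / (p·q̃ + (1−p)(1−q̃))`. Re-binarising
at the same threshold removes rejected components; large components
always bypass. Per-subject evaluation reports Dice = 2|X∩Y|/(|X|+|Y|),
mean FP/FN component counts (m#FP, m#FN) and pooled sizes (mSFP, mSFN),
and the detection rate DR = N_TP/N, optionally stratified at a 37 px
mean lesion size.

## Worked example

Train the scaled-down cascade on a 20-subject phantom cohort and segment
a fresh test cohort (about three minutes on one CPU):

```r
library(dwiseg)

pcfg <- phantomConfig(imageSize = 128L, nSlices = 3L,
                      lesionCountRange = c(1L, 3L),
                      lesionSizeMeanlog = log(18), lesionSizeSdlog = 0.6,
                      fractionSmall = 0.6, artefactCountRange = c(2L, 4L),
                      lesionContrast = 2, artefactContrast = 1.8, seed = 7L)
cohort <- generateCohort(pcfg, 20L)

sets <- buildTrainingSet(cohort$subjects, patchSize = 32L, seed = 5L)
net  <- networkConfig(convStacks = 3L, convsPerStack = 1L,
                      baseChannels = 8L, patchSize = 32L)
edd  <- trainEDD(sets$train, sets$val, net,
                 trainConfig(maxEpochs = 10L, seed = 1L))

## stage-2 training data: stage-1 detections on the training subjects
trainIDs <- sets$split$subject[sets$split$set == "train"]
subs <- Filter(function(s) s@manifestRow$subject_id %in% trainIDs,
               cohort$subjects)
td <- dwiseg:::.muscleTrainingData(edd, subs, muscleConfig())
muscle <- trainMuscle(td$stacks, td$labels,
                      trainCfg = trainConfig(maxEpochs = 15L, seed = 2L))

## evaluate both stages on ten fresh subjects
test <- generateCohort(pcfg, 10L, firstSeed = 21L)
ev1 <- list(); ev2 <- list()
for (s in test$subjects) {
  vol <- normalizeIntensity(resampleInPlane(s@volume))
  p   <- predictVolume(edd, vol)
  sid <- s@manifestRow$subject_id
  ev1[[sid]] <- evaluateSubject(binarize(p), s@lesionMask, sid)
  ev2[[sid]] <- evaluateSubject(refineSegmentation(p, muscle, vol)$mask,
                                s@lesionMask, sid)
}
cohortReport(ev1)   # stage 1 alone
cohortReport(ev2)   # full cascade
```

Output of the two reports:

```
EvalReport over 10 subject(s)
 n_subjects mean_dice m_fp m_fn    ms_fp ms_fn dr
         10  0.786195  3.4    0 9.323529   NaN  1
EvalReport over 10 subject(s)
 n_subjects mean_dice m_fp m_fn ms_fp ms_fn dr
         10 0.9993711    0    0   NaN   NaN  1
```

Reading it: stage 1 finds every lesion subject (DR = 1) and misses no
lesion component (m#FN = 0), but leaves on average 3.4 false-positive
components per subject (mean size 9.3 px) — the phantom's boundary
artefacts. The candidate-evaluation stage removes all of them without
losing a single detected subject, and the mean Dice rises from 0.79 to
0.999 (mSFP/mSFN are NaN-flagged where no such component exists). This
is the cascade's designed behaviour: a large m#FP drop at an unchanged
detection rate.

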