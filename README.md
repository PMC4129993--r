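# hierbg

Hierarchical block-pixel background modeling for detecting moving objects in
underwater video.

Underwater footage defeats classic background subtraction three ways at
once: artificial lighting drifts slowly across the scene, patches of the
background oscillate on their own (caustic flicker, swaying material), and
attenuation leaves objects at such low contrast that parts of them are
nearly identical to the background in raw intensity. `hierbg` implements a
two-stage background model for this regime, together with the classic
per-pixel Gaussian baseline it is compared against, coverage / false-alarm
quality metrics, and a seeded synthetic-scene generator with ground truth.

## The model

**Coarse stage (per subblock).** Each frame is tiled into `M x N` subblocks.
A tile is summarized by its block-truncation-coding intensity vector
`v = (mu_ht, mu_hb, mu_lt, mu_lb)` — the tile is thresholded at its mean
`mu` into high/low sides with means `mu_h`, `mu_l`, and each side is
thresholded again at its own mean. Every tile keeps `K` weighted candidate
vectors (weights sum to 1). An incoming tile matches the nearest stored
vector within the adaptive threshold

    T_D = T_D_base * (alpha + S),      0.7 <= alpha <= 0.8,

where `S in [0, 1]` is the normalized correlation of the mean-absolute-
deviation profiles of the tile and its running background exemplar — a tile
that merely brightened keeps `S ~ 1` and a permissive threshold. Matches
within the smallest weight-prefix exceeding `T` are background; everything
else is the *rough object region*. Matched weights follow
`w <- (1 - alpha_w) w + alpha_w M_k` (renormalized), matched background
features follow an EMA at rate `alpha_b`, and unmatched tiles replace the
minimum-weight entry at weight `alpha_w`.

**Fine stage (per pixel, rough region only).** Each pixel is described by a
moderated local binary pattern: `P` neighbors on a radius-`R` circle each
contribute the bit `s(g_p - g_c + beta)`, packed into a code
`sum_p bit_p 2^p`. The offset `beta = 3` keeps near-flat neighborhoods from
flipping bits on noise, and the code depends only on differences, so it is
exactly invariant under additive illumination change. A pixel is background
iff some entry of its FIFO history of the last `K_pix` background codes lies
within Euclidean bit-distance `T_D_pix` of the current code; only
background-classified pixels update their history. Object-classified pixels
form the refined mask, which is always contained in the rough mask.

**Evaluation.** For a detection `D` against truth object region `O` on an
image with background `B`:

    C_good  = |D ∩ O| / |O|        (coverage of the true object)
    C_false = |D ∩ B| / |B|        (false-alarm ratio over the background)

## Worked example

```r
library(hierbg)

suite <- standardSuite()                  # 8 fixed, seeded scene configs
scene <- generateScene(suite$close_degraded)
scene
#> SyntheticScene: 60 frames of 96 x 96
#>   objects: 1  illumination: additive_ramp  noise sd: 2  seed: 908

det <- detectSequence(scene)              # hierarchical detector, defaults
det
#> DetectionSet: 60 frames; refined foreground px per frame: median 743 max 965

evaluateMasks(det, scene, frames = 11:60) # skip 10 burn-in frames
#> EvalReport over 50 frames: mean C_good = 0.9362, mean C_false = 0.0468

baseline <- gaussianBaselineDetect(scene)
evaluateMasks(baseline, truthMasks(scene), frames = 11:60)
#> EvalReport over 50 frames: mean C_good = 0.9272, mean C_false = 0.1204
```

The scene is a textured disk at low contrast crossing a drifting, noisy,
locally oscillating background. After burn-in the hierarchical detector
covers ~94% of the object while flagging ~4.7% of the background; the
per-pixel Gaussian baseline covers slightly less of the object while
flagging 2.6x more background — the oscillating region and the block rim
that the texture stage removes.

Masks can be written and re-read with `writeMasks()` / `loadMasks()`
(PNG/TIFF/PGM, `0 = background, 255 = foreground`), and frame directories
loaded with `loadFrames()`. A command-line front end with `detect`,
`baseline`, `evaluate` and `synth` subcommands is installed at
`system.file("scripts", "hierbg", package = "hierbg")`.

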