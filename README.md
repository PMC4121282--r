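# brainmatch

Identity verification from structural brain MRI, using the shape of
cortical gray matter as the biometric trait.

Two T1 volumes of the same head acquired on different days differ in pose,
global intensity gain and noise — but the *structure* of the gray matter is
stable and highly individual. `brainmatch` decides whether two volumes come
from the same person by reducing each to a binary gray-matter shape and
comparing shapes:

1. **Rigid registration** to a tissue-prior template: the 6-parameter
   transform `M = T(t) R_x R_y R_z` is estimated by damped Gauss–Newton
   minimisation of the sum of squared intensity differences, after 5 mm
   FWHM Gaussian smoothing.
2. **Segmentation**: a prior-initialised Gaussian mixture model classifies
   every voxel into GM/WM/CSF/other. Probabilities start from template
   priors `p_nk = P_T(k, M x_n)` and are iteratively updated with
   `q_nk = g_nk p_nk` (class density times current membership),
   renormalised per voxel.
3. **Binarisation**: Otsu's 256-bin threshold on the GM probability map.
4. **Matching**: two binary GM volumes are aligned through the template
   bridge (`M12 = M2^{-1} M1`, no extra estimation) and scored by the
   directed chamfer distance
   `d = Σ_x min_y { ‖x − y‖ : B1'(x) = 1, B2'(y) = 1 }` (mm, exact
   distance-transform evaluation), normalised to a similarity
   `s = (1 − (d − d_min)/(d_max − d_min)) × 100` with `(d_min, d_max)`
   learned from training pair distances.
5. **Evaluation**: genuine/imposter score sets, FAR/FRR/TAR threshold
   tables, and the equal error rate (EER).

A seeded phantom generator produces multi-subject, multi-visit cohorts
with ground-truth anatomy, motion and gain, so the entire pipeline is
testable without any external imaging data. See the vignette
(`vignettes/gray-matter-verification.Rmd`) for the models, numerical
choices and limitations.

## Worked example

Score a synthetic cohort of 4 subjects × 2 visits end to end:

```r
library(brainmatch)

co <- generate_cohort(4, 2, phantom_config(seed = 7))
ss <- score_cohort(co$manifest, co$template, co$priors)
ss
#> score_set: 4 genuine pairs (scores 97.92-100), 6 imposter pairs (scores 0-53.75)

rate_table(ss, seq(60, 80, by = 10))
#>   threshold far frr tar
#> 1        60   0   0   1
#> 2        70   0   0   1
#> 3        80   0   0   1

equal_error_rate(ss)
#> [1] 0
```

Same-subject pairs score 97.9–100, different-subject pairs 0–53.8: the
score distributions are disjoint, every threshold between them verifies
with zero false acceptances and zero false rejections, and the EER is 0.
The normaliser trained on this cohort's pair distances spans
`d_min ≈ 749 mm` (best genuine pair) to `d_max ≈ 9064 mm` (worst imposter
pair), summed over ~10⁴ gray-matter surface voxels.

The same operations are available from the shell via the installed
`exec/brainmatch` script:

```sh
brainmatch simulate --subjects 4 --visits 2 --seed 7 --out cohort/
brainmatch evaluate --cohort cohort/manifest.csv --out report/
brainmatch match --moving a.nii.gz --fixed b.nii.gz \
  --template t.nii.gz --priors p.nii.gz --normalizer norm.json --out m.json
```

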