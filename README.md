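# coregkit

Automated MEG-MRI co-registration with an inter-method reliability
analysis, plus a synthetic head-cohort generator with known ground truth.

## The problem

MEG source analysis depends on a rigid-body transform aligning the
participant's anatomical MRI with the MEG head coordinate frame defined by
the digitized fiducials (nasion, left/right preauricular points). The
alignment can be done by an operator nudging the fit by eye or by an
automated procedure; `coregkit` implements the automated procedure and the
statistics used to ask whether the two approaches agree. It is aimed at
MEG methodologists who want to study co-registration behaviour — error
metrics, outlier rules, de-facing effects, inter-method reliability —
under controlled conditions where the true transform is known.

The automated pipeline is the standard five-step design:

1. transfer template-space fiducial coordinates into the subject's MRI
   frame,
2. initial rigid fit from those three landmarks (SVD/Kabsch orthogonal
   Procrustes, reflection-safe),
3. iterative closest points (ICP) against the triangulated scalp, using
   exact point-to-triangle distances,
4. removal of outlier headshape points (> 5 mm from the surface),
5. a final ICP pass on the retained points.

The **co-registration error** of any candidate transform `T` is

```
error(T) = median_i  dist( T^{-1} p_i , S )
```

the median over headshape points `p_i` (head frame) of the exact Euclidean
distance to the scalp surface `S` (MRI frame); medians above 2 mm raise a
quality flag. Two methods are compared per measure (error, translations
x/y/z, rotations pitch/roll/yaw) with medians and IQRs, mean paired
difference ± SD, Pearson *r* (converted to Cohen's *d* via
`d = 2r / sqrt(1 - r²)`), and the intra-class correlation ICC(3,1),

```
ICC(3,1) = (MS_B - MS_E) / (MS_B + (k - 1) MS_E)
```

from the subjects-by-methods ANOVA mean squares, banded after Cicchetti
(poor / fair / good / excellent).

## Worked example

Generate a small synthetic cohort, co-register one subject, then run the
manual-versus-automated comparison:

```r
library(coregkit)

coh <- generate_cohort(6, master_seed = 7)
s <- coh$subjects[[1]]
s$surface
#> <head_surface> 2562 vertices, 5120 triangles, fiducials nasion/lpa/rpa
s$headshape
#> <headshape_set> 143 headshape points, 4 hpi, 3 fiducials

res <- auto_coregister(s$headshape, s$surface, s$fiducial_estimates)
res
#> <coreg_result> median error 1.566 mm (IQR 0.874-2.412), 143 points, 5 outliers
res$transform
#> <rigid_transform>  (MRI -> head unless stated otherwise)
#>   translation (mm): x +3.434  y -7.739  z -63.146
#>   rotation  (deg) : pitch +4.080  roll +4.384  yaw -2.763
```

The median error of 1.57 mm says that half of this subject's digitized
scalp points lie within 1.57 mm of the MRI scalp under the fitted
transform — a usable fit (below the 2 mm quality heuristic); 5 points were
dropped as > 5 mm outliers during fitting but still count in the error.

```r
study <- run_cohort_study(coh)   # automated arm + simulated manual operator
compare_methods(study$manual, study$auto, study$headshape_counts)
#> <comparison_report> 6 subjects
#>   error: median a 1.629 mm, b 1.470 mm; mean diff -0.534 (SD 0.645)
#>   error ICC -0.199 (poor); after >2.0 mm exclusion (0 dropped): -0.199
#>   error r = -0.249 (p = 0.634), Cohen's d = -0.51
#>   parameter ICCs:  tx 0.791, ty 0.997, tz 0.985, pitch 0.991, roll 0.908, yaw 0.976
```

Transform parameters agree strongly between the methods (ICCs 0.79-1.00,
good to excellent) because between-subject head-position variance dwarfs
both methods' errors; the error ICC is noisy at n = 6 and stabilizes on
larger cohorts. `run_cohort_study(coh, defaced = TRUE)` adds a third arm
in which the automated method runs against geometrically de-faced
surfaces.

A command-line interface wraps the same functions
(`exec/coregkit simulate | coregister | evaluate | compare | report`); see
`cli_main()`.

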