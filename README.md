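# thinseg

Semi-supervised brain-ventricle segmentation that is agnostic to slice
thickness. Clinical CT and MR volumes are split by acquisition spacing
into **thick-slice** (spacing > 3 mm, common in routine practice, cheap to
annotate) and **thin-slice** (<= 3 mm, where most research models live).
The package trains one 2-D encoder–decoder on *labeled thick-slice*
volumes together with *unlabeled thin-slice* volumes, so a single model
segments both regimes, and measures everything with the Dice overlap
`2|A∩B| / (|A|+|B|)` — the basis of ventricle volumetry for hydrocephalus
and atrophy assessment.

Who it is for: researchers in medical image analysis who want a small,
fully reproducible, CPU-friendly implementation of this training scheme —
network, objectives, trainer, evaluation harness, and a synthetic
thick/thin phantom cohort to exercise it end-to-end — in plain R.

## The method

The network is a residual convolutional encoder with a decoder built from
**sub-pixel convolution** stages,

&nbsp;&nbsp;&nbsp;&nbsp;F<sup>L</sup> = SP(W<sub>L</sub> ∗ F<sup>L−1</sup> + b<sub>L</sub>),

where SP rearranges an H×W×(C·r²) tensor into rH×rW×C by tiling each
pixel's r² channels over an r×r block. Training minimizes

&nbsp;&nbsp;&nbsp;&nbsp;L(x<sub>s</sub>, x<sub>t</sub>) = L<sub>S</sub>(p<sub>s</sub>, y<sub>s</sub>) + λ·L<sub>T</sub>(p<sub>t</sub>),

with L<sub>S</sub> the pixel-mean cross-entropy on labeled thick-slice
predictions and L<sub>T</sub> the negated f-divergence between each
unlabeled thin-slice pixel's class distribution and the uniform
distribution U = 1/C:

&nbsp;&nbsp;&nbsp;&nbsp;L<sub>T</sub> = −(1/C) Σ<sub>c</sub> f(C·p<sup>c</sup>).

Minimizing L<sub>T</sub> pushes unlabeled predictions away from the
decision boundary. The default generator is the Pearson χ² divergence
f(x) = x² − 1, whose binary reference gradient 2 − 4p is bounded by 2, in
contrast to the KL choice f(x) = x·log x whose gradient
log(1−p) − log(p) explodes at confident pixels (both are implemented;
see `binary_gradient_reference()`).

There is no torch here: convolution forward/backward runs through
compiled im2col kernels (RcppArmadillo) under a ~40-line reverse-mode
tape, with Adam, instance normalization, and gradient clipping in base R.

## Worked example

```r
library(thinseg)

# a paired thin/thick phantom with ground truth
ph <- generate_phantom(phantom_spec(ventricle_scale = 2.2, seed = 42))
ph$thick
#> <labeled_volume 'phantom_thick'> CT thick, 8 x 64 x 64 voxels, spacing 5.00 x 3.00 x 3.00 mm, with mask

# a full cohort on disk: 16 labeled thick + 16 unlabeled thin + 5 test subjects
dir <- tempfile()
manifest <- cmd_generate(out_dir = dir)

# train the semi-supervised model and evaluate on the held-out volumes
ck  <- cmd_train(manifest = manifest, out_dir = file.path(dir, "run"))
rep <- cmd_evaluate(ck, manifest, out_dir = file.path(dir, "eval"))
cmd_report(rep)
```

On the default configuration (small encoder, 64×64 slices, χ² objective,
seed 1) the evaluation prints:

```
Dice report over 10 volumes (mean Dice 0.9229)
  CT     thick 0.9445  thin 0.9387  mixed 0.9416
  MR_T1  thick 0.9009  thin 0.9200  mixed 0.9105
```

Mean Dice above 0.9 on held-out volumes of both domains and modalities,
from thick-slice labels only. The run takes a few minutes on one CPU.
The three-arm ablation (`run_ablation()` / `cmd_ablate`) contrasts
thick-only supervised training (Exp 1), the unlabeled objective alone
(Exp 2 — collapses to confident near-constant predictions, Dice ≈ 0), and
the combined objective (Exp 3), all from identical initialization.

Lower-level interfaces: `thinseg()` is the fitting function (returns a
classed object with `print`/`summary`/`coef`/`plot`/`predict` methods),
`predict()` segments whole volumes slice-wise, `evaluate_volumes()` /
`evaluate_manifest()` produce grouped Dice reports, and
`inst/cli/thinseg.R` wraps everything for the shell.

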