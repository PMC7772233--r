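#' Specify a synthetic head phantom
#'
#' A phantom is an axial slab through a head-shaped ellipsoid containing a
#' bilateral, branched ventricle-like foreground (two mirrored unions of
#' anterior-horn / body / posterior-horn / inferior-horn ellipsoids plus a
#' midline third-ventricle bridge). The same underlying anatomy is rendered
#' twice: a thin-slice volume sampled at `thin_spacing`, and a thick-slice
#' volume obtained from it by partial-volume averaging of `thick_factor`
#' consecutive slices, so the derived thick spacing
#' `thin_spacing * thick_factor` always exceeds the 3 mm thick/thin cut-off.
#'
#' @param head_radii Numeric triple, head ellipsoid semi-axes in mm along
#'   (slice, row, column) = (z, anterior-posterior, left-right).
#' @param ventricle_scale Dimensionless severity factor (>= 0.5). 1 is a
#'   normal-sized ventricular system; values towards 3 emulate the enlarged,
#'   distorted ventricles of atrophy, normal-pressure hydrocephalus and
#'   acquired hydrocephalus. Ventricle volume grows monotonically with it.
#' @param modality `"CT"` or `"MR_T1"`. Only the intensity triple changes;
#'   in both, ventricular CSF is darker than brain parenchyma.
#' @param thin_spacing Thin-slice spacing in mm, in (0, 3].
#' @param thick_factor Integer >= 2; number of thin slices averaged into one
#'   thick slice. `thin_spacing * thick_factor` must exceed 3 mm.
#' @param intensity_means Numeric triple (background, brain, ventricle) in
#'   arbitrary units; ventricle mean must be below brain mean.
#' @param noise_sd Additive Gaussian noise standard deviation (same units) on
#'   thin-slice images. Thick-slice noise is drawn independently at
#'   `noise_sd / sqrt(thick_factor)`, the level implied by averaging
#'   `thick_factor` independently-noisy acquisitions.
#' @param in_plane_size Integer pair (rows, columns) of each slice.
#' @param in_plane_spacing In-plane voxel size in mm.
#' @param n_slices Number of thin slices in the slab.
#' @param n_distractors Number of dark non-ventricular confounder
#'   structures (sulcus / cistern-like, intermediate attenuation, elongated
#'   in z). They are part of what makes thick-slice supervision ambiguous:
#'   on thick slices they resemble partial-volume-washed ventricle horns.
#' @param seed Integer seed; the phantom is fully deterministic given it.
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()], [make_cohort()]
#' @export
phantom_spec <- function(head_radii = c(65, 85, 70),
                         ventricle_scale = 1,
                         modality = c("CT", "MR_T1"),
                         thin_spacing = 1,
                         thick_factor = 5L,
                         intensity_means = NULL,
                         noise_sd = NULL,
                         in_plane_size = c(64L, 64L),
                         in_plane_spacing = 3,
                         n_slices = 40L,
                         n_distractors = 8L,
                         seed = 1L) {
  modality <- match.arg(modality)
  if (is.null(intensity_means))
    intensity_means <- if (modality == "CT") c(0, 30, 4) else c(0, 110, 35)
  if (is.null(noise_sd))
    noise_sd <- if (modality == "CT") 7 else 18
  spec <- structure(list(
    head_radii = as.numeric(head_radii),
    ventricle_scale = as.numeric(ventricle_scale),
    modality = modality,
    thin_spacing = as.numeric(thin_spacing),
    thick_factor = as.integer(thick_factor),
    intensity_means = as.numeric(intensity_means),
    noise_sd = as.numeric(noise_sd),
    in_plane_size = as.integer(in_plane_size),
    in_plane_spacing = as.numeric(in_plane_spacing),
    n_slices = as.integer(n_slices),
    n_distractors = as.integer(n_distractors),
    seed = as.integer(seed)
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (length(spec$head_radii) != 3L || any(spec$head_radii <= 0))
    stopf("head_radii must be three positive lengths (mm)")
  if (spec$ventricle_scale < 0.5)
    stopf("ventricle_scale must be >= 0.5")
  if (spec$thin_spacing <= 0 || spec$thin_spacing > 3)
    stopf("thin_spacing must lie in (0, 3] mm (thin-slice definition)")
  if (spec$thick_factor < 2L)
    stopf("thick_factor must be an integer >= 2")
  if (spec$thin_spacing * spec$thick_factor <= 3)
    stopf("thin_spacing * thick_factor must exceed 3 mm so the derived thick volume is thick-slice")
  if (spec$intensity_means[3] >= spec$intensity_means[2])
    stopf("ventricle intensity mean must be below brain mean (CSF is dark on CT and T1)")
  if (spec$noise_sd < 0) stopf("noise_sd must be >= 0")
  if (length(spec$in_plane_size) != 2L || any(spec$in_plane_size < 8L))
    stopf("in_plane_size must be two integers >= 8")
  if (spec$n_slices < spec$thick_factor)
    stopf("n_slices must be at least thick_factor")
  invisible(spec)
}

# Ellipsoid atlas of the ventricular system at severity 1, in mm, for one
# hemisphere at lateral offset `side` (+1/-1); the third ventricle sits on
# the midline. Columns: cz, cy, cx, az, ay, ax. The horns are deliberately
# flat in z (semi-axis about one thick slice), so thick-slice partial-volume
# averaging washes them out while thin slices show them crisply — the main
# morphological source of the thick-vs-thin domain gap.
ventricle_atlas <- function(side) {
  rbind(
    anterior  = c(0,  -28, side * 11,  3, 14, 4.5),
    body      = c(6,   -4, side * 14, 11, 22, 5.0),
    posterior = c(-2,  22, side * 16,  3, 16, 4.5),
    inferior  = c(-11, 12, side * 21,  3, 12, 4.0)
  )
}

# Boolean (S, H, W) array: union of jittered ellipsoids. `ell` is a matrix
# with columns cz, cy, cx, az, ay, ax.
ellipsoid_union <- function(z, y, x, ell) {
  out <- array(FALSE, c(length(z), length(y), length(x)))
  for (r in seq_len(nrow(ell))) {
    qz <- ((z - ell[r, 1]) / ell[r, 4])^2
    qy <- ((y - ell[r, 2]) / ell[r, 5])^2
    qx <- ((x - ell[r, 3]) / ell[r, 6])^2
    out <- out | (outer(outer(qz, qy, `+`), qx, `+`) <= 1)
  }
  out
}

#' Generate a paired thin-slice / thick-slice labeled phantom
#'
#' Renders the phantom described by `spec` on the thin grid, then derives the
#' thick volume by non-overlapping block averaging of `thick_factor`
#' consecutive noiseless thin slices (the partial-volume model); the thick
#' mask is a per-block majority vote (ties count as foreground). Noise is
#' drawn independently for the two volumes, emulating separate acquisitions.
#' When `n_slices` is not divisible by `thick_factor` the trailing remainder
#' slices are dropped from the thick volume and recorded in its
#' `truncated_slices` attribute.
#'
#' @param spec A [phantom_spec()].
#' @param id Stem used for the two volume ids (`<id>_thin`, `<id>_thick`).
#' @return A list with elements `thin` and `thick`, both [labeled_volume()]s
#'   carrying ground-truth ventricle masks.
#' @examples
#' ph <- generate_phantom(phantom_spec(n_slices = 20L, seed = 42L))
#' dim(ph$thin$intensity)   # 20 x 64 x 64
#' dim(ph$thick$intensity)  # 4 x 64 x 64
#' @export
generate_phantom <- function(spec, id = "phantom") {
  validate_phantom_spec(spec)
  S <- spec$n_slices
  H <- spec$in_plane_size[1]
  W <- spec$in_plane_size[2]
  k <- spec$thick_factor
  dz <- spec$thin_spacing
  dp <- spec$in_plane_spacing

  z <- (seq_len(S) - (S + 1) / 2) * dz
  y <- (seq_len(H) - (H + 1) / 2) * dp
  x <- (seq_len(W) - (W + 1) / 2) * dp

  vols <- with_seed(spec$seed, {
    head <- ellipsoid_union(z, y, x, matrix(c(0, 0, 0, spec$head_radii), 1))

    # Per-volume anatomical variability: jitter ellipsoid centers and axes.
    s_lin <- spec$ventricle_scale^(1 / 3)
    ell <- rbind(ventricle_atlas(+1), ventricle_atlas(-1),
                 third = c(-2, -6, 0, 8, 12, 2.2))
    jc <- matrix(stats::runif(nrow(ell) * 3, -3, 3), ncol = 3)
    ja <- matrix(stats::runif(nrow(ell) * 3, 0.9, 1.1), ncol = 3)
    ell[, 1:3] <- ell[, 1:3] + jc
    ell[, 4:6] <- ell[, 4:6] * ja * s_lin
    vent <- ellipsoid_union(z, y, x, ell) & head

    im <- spec$intensity_means
    clean <- array(im[1], c(S, H, W))
    clean[head] <- im[2]

    # Dark non-ventricular confounders (sulci / cisterns / periventricular
    # hypodensities): elongated in z, so they look the same on thick and
    # thin slices, with intermediate attenuation between brain and CSF. On
    # thick slices they are confusable with partial-volume-averaged horns;
    # on thin slices the full-contrast horns separate cleanly from them.
    nd <- spec$n_distractors
    if (nd > 0L) {
      # two populations: intermediate-attenuation streaks (sulci, partially
      # averaged cisterns) and full CSF-dark dots (perivascular spaces /
      # small cisterns); both elongated in z so they look alike on thick
      # and thin slices.
      dell <- cbind(stats::runif(2 * nd, -12, 12),        # cz
                    stats::runif(2 * nd, -45, 45),        # cy
                    stats::runif(2 * nd, -45, 45),        # cx
                    stats::runif(2 * nd, 12, 20),         # az
                    c(stats::runif(nd, 3, 6),
                      stats::runif(nd, 2.5, 4)),          # ay
                    c(stats::runif(nd, 3, 6),
                      stats::runif(nd, 2.5, 4)))          # ax
      depth <- c(stats::runif(nd, 0.4, 0.7),
                 stats::runif(nd, 0.85, 1))
      for (di in seq_len(2 * nd)) {
        blob <- ellipsoid_union(z, y, x, dell[di, , drop = FALSE]) &
          head & !vent
        clean[blob] <- im[2] - depth[di] * (im[2] - im[3])
      }
    }
    clean[vent] <- im[3]

    thin_int <- clean
    nh <- sum(head)
    if (spec$noise_sd > 0)
      thin_int[head] <- thin_int[head] + stats::rnorm(nh, 0, spec$noise_sd)

    St <- S %/% k
    used <- St * k
    blk <- function(a) array(a[seq_len(used), , , drop = FALSE], c(k, St, H, W))
    thick_int <- colMeans(blk(clean), dims = 1)
    counts <- colSums(blk(vent), dims = 1)
    thick_mask <- counts >= k / 2           # majority vote, ties -> foreground
    head_frac <- colMeans(blk(head), dims = 1)
    if (spec$noise_sd > 0) {
      idx <- head_frac > 0
      thick_int[idx] <- thick_int[idx] +
        stats::rnorm(sum(idx), 0, spec$noise_sd / sqrt(k))
    }
    list(thin_int = thin_int, thin_mask = vent,
         thick_int = thick_int, thick_mask = thick_mask,
         truncated = S - used)
  })

  thin <- labeled_volume(vols$thin_int, mask = vols$thin_mask,
                         spacing = c(dz, dp, dp), modality = spec$modality,
                         volume_id = paste0(id, "_thin"))
  thick <- labeled_volume(vols$thick_int, mask = vols$thick_mask * 1,
                          spacing = c(dz * k, dp, dp),
                          modality = spec$modality,
                          volume_id = paste0(id, "_thick"))
  thick$truncated_slices <- vols$truncated
  list(thin = thin, thick = thick)
}

#' Write a synthetic thick/thin training-and-test cohort to disk
#'
#' Emulates the cohort structure the semi-supervised setting assumes: labeled
#' thick-slice training volumes, unlabeled thin-slice training volumes (their
#' ground truth is withheld from the manifest and kept in a hidden file used
#' only for evaluation), and held-out test subjects contributing one thick
#' and one thin volume each. Subjects draw a ventricle severity from
#' `severity_mix` and a modality from `modality_mix`.
#'
#' @param n_train_labeled_thick,n_train_unlabeled_thin Numbers of training
#'   volumes of each kind.
#' @param n_test Number of held-out subjects; each contributes a thick and a
#'   thin volume, so the test split holds `2 * n_test` volumes.
#' @param severity_mix Numeric vector of `ventricle_scale` values sampled
#'   uniformly per subject (or a `list(values =, prob =)` for weights).
#' @param modality_mix Named probabilities for `c(CT =, MR_T1 =)`.
#' @param seed Integer master seed; the cohort (files and manifest) is
#'   byte-reproducible given it.
#' @param out_dir Output directory, created if needed.
#' @param base_spec A [phantom_spec()] supplying geometry, spacing, noise and
#'   intensity defaults; per-subject severity/modality/seed override it.
#' @return Invisibly, the manifest `data.frame` (columns `volume_id`, `path`,
#'   `mask_path`, `modality`, `domain`, `split`) with attribute `"path"`
#'   giving the manifest CSV location.
#' @export
make_cohort <- function(n_train_labeled_thick, n_train_unlabeled_thin, n_test,
                        severity_mix = c(0.8, 1, 1.4, 2.2, 3),
                        modality_mix = c(CT = 0.5, MR_T1 = 0.5),
                        seed = 1L,
                        out_dir,
                        base_spec = phantom_spec()) {
  nL <- as.integer(n_train_labeled_thick)
  nU <- as.integer(n_train_unlabeled_thin)
  nT <- as.integer(n_test)
  if (any(c(nL, nU, nT) < 0)) stopf("cohort counts must be >= 0")
  if (is.list(severity_mix)) {
    sev_values <- severity_mix$values
    sev_prob <- severity_mix$prob
  } else {
    sev_values <- severity_mix
    sev_prob <- NULL
  }
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2L) != 0L)
    stopf("cannot write cohort to '%s'", out_dir)
  hidden_dir <- file.path(out_dir, "hidden_truth")
  dir.create(hidden_dir, showWarnings = FALSE)

  n_sub <- nL + nU + nT
  draws <- with_seed(seed, list(
    sev = sample(sev_values, n_sub, replace = TRUE, prob = sev_prob),
    mod = sample(names(modality_mix), n_sub, replace = TRUE,
                 prob = as.numeric(modality_mix)),
    seeds = sample.int(.Machine$integer.max - 1L, n_sub)
  ))

  rows <- list()
  hidden <- list()
  add_row <- function(volume_id, path, mask_path, modality, domain, split) {
    rows[[length(rows) + 1L]] <<- data.frame(
      volume_id = volume_id, path = path, mask_path = mask_path,
      modality = modality, domain = domain, split = split,
      stringsAsFactors = FALSE)
  }
  write_pair <- function(vol, stem, with_mask) {
    path <- file.path(out_dir, paste0(stem, ".nii.gz"))
    mask_path <- if (with_mask) file.path(out_dir, paste0(stem, "_mask.nii.gz")) else ""
    write_volume(vol, path, mask_path = if (with_mask) mask_path else NULL)
    c(path = basename(path), mask_path = if (with_mask) basename(mask_path) else "")
  }
  # Noise scales across modalities: the base spec's noise relative to its
  # modality default is applied as a multiplier to each subject's modality
  # default, so one base spec sets a cohort-wide noise level coherently.
  noise_ratio <- base_spec$noise_sd /
    phantom_spec(modality = base_spec$modality)$noise_sd
  subj_spec <- function(i) {
    sp <- base_spec
    sp$ventricle_scale <- draws$sev[i]
    sp$modality <- draws$mod[i]
    defaults <- phantom_spec(modality = sp$modality)
    sp$intensity_means <- defaults$intensity_means
    sp$noise_sd <- defaults$noise_sd * noise_ratio
    sp$seed <- draws$seeds[i]
    sp
  }

  i <- 0L
  for (j in seq_len(nL)) {
    i <- i + 1L
    ph <- generate_phantom(subj_spec(i), id = sprintf("trainL%03d", j))
    p <- write_pair(ph$thick, sprintf("trainL%03d_thick", j), with_mask = TRUE)
    add_row(ph$thick$volume_id, p["path"], p["mask_path"],
            draws$mod[i], "thick", "train_labeled")
  }
  for (j in seq_len(nU)) {
    i <- i + 1L
    ph <- generate_phantom(subj_spec(i), id = sprintf("trainU%03d", j))
    p <- write_pair(ph$thin, sprintf("trainU%03d_thin", j), with_mask = FALSE)
    hp <- file.path(hidden_dir, sprintf("trainU%03d_thin_mask.nii.gz", j))
    write_mask_nifti(ph$thin$mask, ph$thin$spacing, hp)
    hidden[[length(hidden) + 1L]] <- data.frame(
      volume_id = ph$thin$volume_id,
      mask_path = file.path("hidden_truth", basename(hp)),
      stringsAsFactors = FALSE)
    add_row(ph$thin$volume_id, p["path"], "", draws$mod[i], "thin",
            "train_unlabeled")
  }
  for (j in seq_len(nT)) {
    i <- i + 1L
    ph <- generate_phantom(subj_spec(i), id = sprintf("test%03d", j))
    p <- write_pair(ph$thick, sprintf("test%03d_thick", j), with_mask = TRUE)
    add_row(ph$thick$volume_id, p["path"], p["mask_path"],
            draws$mod[i], "thick", "test")
    p <- write_pair(ph$thin, sprintf("test%03d_thin", j), with_mask = TRUE)
    add_row(ph$thin$volume_id, p["path"], p["mask_path"],
            draws$mod[i], "thin", "test")
  }

  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(volume_id = character(), path = character(),
               mask_path = character(), modality = character(),
               domain = character(), split = character())
  mpath <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  if (length(hidden))
    utils::write.csv(do.call(rbind, hidden),
                     file.path(out_dir, "hidden_truth", "hidden_truth.csv"),
                     row.names = FALSE)
  attr(manifest, "path") <- mpath
  invisible(manifest)
}
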