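test_that("phantom_spec enforces the thick/thin slice-spacing contract", {
  expect_error(phantom_spec(thin_spacing = 4), "thin_spacing")
  expect_error(phantom_spec(thin_spacing = 1, thick_factor = 3), "exceed 3 mm")
  expect_error(phantom_spec(ventricle_scale = 0.2), "ventricle_scale")
  expect_error(phantom_spec(intensity_means = c(0, 10, 20)), "below brain")
  sp <- phantom_spec(thin_spacing = 1.5, thick_factor = 3L)
  expect_s3_class(sp, "phantom_spec")
  expect_gt(sp$thin_spacing * sp$thick_factor, 3)
})

test_that("thick volume has n_slices / thick_factor slices and correct tags", {
  ph <- generate_phantom(tiny_spec(seed = 2L, n_slices = 25L))
  expect_identical(dim(ph$thick$intensity)[1], 5L)
  expect_identical(ph$thin$domain, "thin")
  expect_identical(ph$thick$domain, "thick")
  expect_equal(ph$thick$spacing[1], ph$thin$spacing[1] * 5)
  expect_identical(ph$thick$truncated_slices, 0L)
})

test_that("non-divisible slice counts truncate trailing slices with a record", {
  ph <- generate_phantom(tiny_spec(seed = 2L, n_slices = 13L))
  expect_identical(dim(ph$thick$intensity)[1], 2L)
  expect_identical(ph$thick$truncated_slices, 3L)
})

test_that("noiseless thick voxels equal block means of thin voxels", {
  ph <- generate_phantom(tiny_spec(seed = 3L, noise_sd = 0))
  k <- 5L
  thin <- ph$thin$intensity
  thick <- ph$thick$intensity
  # brute-force oracle over every thick voxel
  for (i in seq_len(dim(thick)[1])) {
    blk <- thin[((i - 1L) * k + 1L):(i * k), , , drop = FALSE]
    expect_equal(thick[i, , ], colMeans(blk, dims = 1), tolerance = 1e-12)
  }
  # conservation: totals match over the covered slices
  expect_equal(sum(thick) * k, sum(thin), tolerance = 1e-8)
})

test_that("ventricle volume grows monotonically with severity", {
  scales <- c(0.7, 1, 1.5, 2.2, 3)
  vox <- vapply(scales, function(s)
    sum(generate_phantom(tiny_spec(seed = 9L, ventricle_scale = s))$thin$mask),
    1)
  expect_true(all(diff(vox) >= 0))
  expect_gt(vox[5], vox[1])
  # strict increase for a doubling of severity
  v1 <- sum(generate_phantom(tiny_spec(seed = 4L))$thin$mask)
  v2 <- sum(generate_phantom(tiny_spec(seed = 4L,
                                       ventricle_scale = 2))$thin$mask)
  expect_gt(v2, v1)
})

test_that("phantom anatomy satisfies containment and contrast invariants", {
  for (mod in c("CT", "MR_T1")) {
    ph <- generate_phantom(tiny_spec(seed = 6L, modality = mod,
                                     noise_sd = 0))
    v <- ph$thin
    head <- v$intensity != 0
    expect_true(all(head[v$mask == 1]))       # ventricle inside head
    expect_lt(sum(v$mask), sum(head))         # strict subset
    expect_lt(sum(head), length(head))        # head strictly inside volume
    im <- phantom_spec(modality = mod)$intensity_means
    expect_lt(mean(v$intensity[v$mask == 1]), mean(v$intensity[head & !v$mask]))
    expect_equal(unique(as.vector(v$intensity[v$mask == 1])), im[3])
  }
})

test_that("the thick-derived mask differs from the thin truth (domain gap)", {
  ph <- generate_phantom(tiny_spec(seed = 7L))
  k <- 5L
  up <- ph$thick$mask[rep(seq_len(dim(ph$thick$mask)[1]), each = k), , ]
  expect_lt(dice(up, ph$thin$mask), 1)
})

test_that("phantom generation is deterministic given the seed", {
  a <- generate_phantom(tiny_spec(seed = 11L))
  b <- generate_phantom(tiny_spec(seed = 11L))
  expect_identical(a$thin$intensity, b$thin$intensity)
  expect_identical(a$thick$mask, b$thick$mask)
  c <- generate_phantom(tiny_spec(seed = 12L))
  expect_false(identical(a$thin$intensity, c$thin$intensity))
})

test_that("make_cohort writes a consistent, reproducible manifest", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- tiny_cohort(d1)
  m2 <- tiny_cohort(d2)
  expect_identical(readLines(file.path(d1, "manifest.csv")),
                   readLines(file.path(d2, "manifest.csv")))
  expect_setequal(unique(m1$split), c("train_labeled", "train_unlabeled", "test"))
  expect_identical(sum(m1$split == "test"), 2L)  # one thick + one thin subject
  # unlabeled training masks are withheld from the manifest but kept hidden
  expect_true(all(m1$mask_path[m1$split == "train_unlabeled"] == ""))
  expect_true(file.exists(file.path(d1, "hidden_truth", "hidden_truth.csv")))
  # every row's domain tag agrees with the written file's slice spacing
  for (i in seq_len(nrow(m1))) {
    v <- read_volume(file.path(d1, m1$path[i]), modality = m1$modality[i])
    expect_identical(v$domain, m1$domain[i])
    expect_identical(v$domain == "thick", v$spacing[1] > 3)
  }
})

test_that("empty cohort splits are allowed", {
  d <- withr::local_tempdir()
  m <- make_cohort(1, 0, 0, seed = 3L, out_dir = d, base_spec = tiny_spec())
  expect_identical(nrow(m), 1L)
  expect_false(any(m$split == "test"))
})
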