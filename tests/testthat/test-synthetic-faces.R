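test_that("rendering is deterministic and geometrically consistent", {
  p <- list(rot_deg = 10, tx = 4, ty = -6, noise_seed = 11)
  r1 <- render_face(p, 256)
  r2 <- render_face(p, 256)
  expect_identical(r1, r2)
  expect_equal(dim(r1$image), c(256, 256))
  expect_true(all(r1$mask %in% c(0, 255)))
  expect_gt(sum(r1$mask == 255), 0)

  # landmark rotation matches the requested jitter
  ec <- eye_centers(r1$landmarks)
  expect_equal(interocular_angle(ec$left, ec$right), 10, tolerance = 0.05)

  # eye-group centroids sit at the rendered eye-ellipse centres: the eye
  # pixels around each centroid must be dark (eye intensity 0.15 + noise)
  for (e in list(ec$left, ec$right)) {
    patch <- r1$image[round(e[2]) + 1 + (-2:2), round(e[1]) + 1 + (-2:2)]
    expect_lt(mean(patch), 0.3)
  }
})

test_that("fat-pad mask lies below the eyes and above the mouth, off the eyes", {
  r <- render_face(list(noise_seed = 3), 512)
  idx <- which(r$mask == 255, arr.ind = TRUE)
  ys <- idx[, 1] - 1 # 0-based y
  eye_lms <- r$landmarks[37:48, ]
  mouth_lms <- r$landmarks[49:68, ]
  expect_true(all(ys > max(eye_lms[, 2])))
  expect_true(all(ys < min(mouth_lms[, 2])))
  # no overlap with the (dark) eye ellipses: mask pixels must be bright
  expect_true(all(r$image[r$mask == 255] > 0.3))
})

test_that("no-jitter cohorts render horizontal eye lines", {
  spec <- cohort_spec(6, jitter_rotation_deg = 0, jitter_translation_px = 0,
                      seed = 3, canvas_size = 256)
  objs <- attr(generate_cohort(spec), "objects")
  for (o in objs) {
    ec <- eye_centers(o$landmarks)
    expect_lt(abs(ec$left[2] - ec$right[2]), 0.5)
  }
})

test_that("cohort generation writes a complete, reloadable fixture set", {
  dir <- withr::local_tempdir()
  spec <- cohort_spec(4, seed = 2, canvas_size = 128)
  meta <- generate_cohort(spec, out_dir = dir)
  expect_equal(nrow(meta), 4)
  expect_true(file.exists(file.path(dir, "metadata.csv")))
  for (i in seq_len(4)) {
    expect_true(file.exists(meta$image_path[i]))
    m <- read_mask(meta$mask_path[i])
    expect_true(all(m %in% c(0, 255)))
    lm <- read_landmarks(meta$landmarks_path[i])
    expect_equal(dim(lm), c(68, 2))
  }
  # round trip matches the in-memory render up to 8-bit quantisation
  objs <- attr(generate_cohort(spec), "objects")
  img <- png::readPNG(meta$image_path[1])
  expect_equal(img, objs[[1]]$image, tolerance = 1 / 255)
  expect_equal(read_landmarks(meta$landmarks_path[1]), objs[[1]]$landmarks,
               ignore_attr = TRUE)
})

test_that("label prevalence and subgroup fractions match the specification", {
  spec <- cohort_spec(5000, seed = 9)
  att <- cohort_attributes(spec)
  # binomial 3-SD band around the nominal prevalence
  p <- spec$prevalence
  band <- 3 * sqrt(p * (1 - p) / 5000)
  expect_lt(abs(mean(att$risk) - p), band)
  expect_lt(abs(mean(att$gender == "male") - spec$male_fraction),
            3 * sqrt(0.615 * 0.385 / 5000))
  expect_lt(abs(mean(att$age_group == "elderly") - spec$elderly_fraction),
            3 * sqrt(0.165 * 0.835 / 5000))
  # the risk label is equivalent to the NRS >= 3 cut
  expect_identical(att$risk == 1, att$nrs_score >= 3)
  expect_true(all(att$nrs_score %in% 0:5))

  # a cohort of the clinical size: risk count within the central 99%
  # binomial interval of Binom(515, 0.239)
  att515 <- cohort_attributes(cohort_spec(515, seed = 1))
  n_risk <- sum(att515$nrs_score >= 3)
  expect_gte(n_risk, qbinom(0.005, 515, 0.239))
  expect_lte(n_risk, qbinom(0.995, 515, 0.239))
})

test_that("zero effect size leaves class-conditional appearance identical", {
  spec <- cohort_spec(10, effect_size = 0, seed = 7, canvas_size = 256)
  coh <- generate_cohort(spec)
  objs <- attr(coh, "objects")
  roi_mean <- vapply(objs, function(o) mean(o$image[o$mask == 255]),
                     numeric(1))
  cls <- coh$risk
  if (length(unique(cls)) == 2) {
    obs <- abs(mean(roi_mean[cls == 1]) - mean(roi_mean[cls == 0]))
    set.seed(1)
    null <- replicate(999, {
      pc <- sample(cls)
      abs(mean(roi_mean[pc == 1]) - mean(roi_mean[pc == 0]))
    })
    pval <- (1 + sum(null >= obs)) / 1000
    expect_gt(pval, 0.01)
  }
  # masks remain valid
  for (o in objs) expect_true(all(o$mask %in% c(0, 255)))
})

test_that("effect size 2 is recoverable from mean ROI intensity alone", {
  spec <- cohort_spec(200, effect_size = 2, seed = 11, canvas_size = 256)
  coh <- generate_cohort(spec)
  objs <- attr(coh, "objects")
  roi_mean <- vapply(objs, function(o) mean(o$image[o$mask == 255]),
                     numeric(1))
  cls <- coh$risk
  acc <- max(vapply(sort(roi_mean), function(th)
    max(mean((roi_mean > th) == cls), mean((roi_mean <= th) == cls)),
    numeric(1)))
  expect_gte(acc, 0.8)
})

test_that("invalid cohort specifications are rejected", {
  expect_error(cohort_spec(1), "n_subjects")
  expect_error(cohort_spec(10, prevalence = 0), "prevalence")
  expect_error(cohort_spec(10, prevalence = 1), "prevalence")
  expect_error(cohort_spec(10, effect_size = -1), "effect_size")
  expect_error(render_face(canvas_size = 64), "canvas_size")
})
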