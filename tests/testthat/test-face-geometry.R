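# builds a 68-point landmark set with prescribed eye/mouth/jaw positions
make_landmarks <- function(left_eye = c(100, 150), right_eye = c(160, 150),
                           mouth = c(130, 220), jaw_x = c(60, 200)) {
  lm <- matrix(rep(c(130, 180), each = 68), 68, 2)
  lm[37:42, ] <- matrix(left_eye, 6, 2, byrow = TRUE)
  lm[43:48, ] <- matrix(right_eye, 6, 2, byrow = TRUE)
  lm[49:68, ] <- matrix(mouth, 20, 2, byrow = TRUE)
  lm[1, ] <- c(jaw_x[1], 180); lm[17, ] <- c(jaw_x[2], 180)
  colnames(lm) <- c("x", "y")
  lm
}

test_that("eye centres are the centroids of the eye landmark groups", {
  lm <- make_landmarks()
  ec <- eye_centers(lm)
  expect_equal(ec$left, c(100, 150))
  expect_equal(ec$right, c(160, 150))

  # symmetric scatter around (100, 150) averages back to the centre
  lm[37:42, ] <- rbind(c(99, 149), c(101, 151), c(100, 150), c(98, 150),
                       c(102, 150), c(100, 150))
  expect_equal(eye_centers(lm)$left, c(100, 150))

  # image-left is enforced by x-order, not by index group
  lm2 <- make_landmarks(left_eye = c(160, 150), right_eye = c(100, 140))
  ec2 <- eye_centers(lm2)
  expect_lt(ec2$left[1], ec2$right[1])
})

test_that("interocular angle follows atan2 with the y-down sign convention", {
  expect_equal(interocular_angle(c(100, 150), c(160, 150)), 0)
  expect_equal(interocular_angle(c(0, 0), c(10, 10)), 45)
  expect_equal(interocular_angle(c(0, 10), c(10, 0)), -45)
  expect_error(interocular_angle(c(1, 1), c(1, 1)), "coincident")
})

test_that("eye centroids of rendered faces match the drawn ellipse centres", {
  r <- render_face(list(rot_deg = 7, tx = 3, ty = 2, noise_seed = 2), 512)
  ec <- eye_centers(r$landmarks)
  # the drawn centres are the rotated/translated template eye centres
  ctr <- (512 - 1) / 2
  a <- 7 * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  truth_l <- as.vector(R %*% c(-62, -40)) + c(ctr + 3, ctr + 2)
  truth_r <- as.vector(R %*% c(62, -40)) + c(ctr + 3, ctr + 2)
  expect_lt(sqrt(sum((ec$left - truth_l)^2)), 2)
  expect_lt(sqrt(sum((ec$right - truth_r)^2)), 2)
})

test_that("alignment levels the eye line and is idempotent", {
  r <- render_face(list(rot_deg = 10, tx = 5, ty = -4, noise_seed = 8), 256)
  al <- align_face(r$image, r$landmarks)
  ec <- eye_centers(al$landmarks)
  expect_lt(abs(interocular_angle(ec$left, ec$right)), 0.2)
  expect_lt(abs(ec$left[2] - ec$right[2]), 0.5)
  # second application is the identity on landmarks (within resampling noise)
  al2 <- align_face(al$image, al$landmarks)
  expect_lt(max(abs(al2$landmarks - al$landmarks)), 0.5)
})

test_that("aligning an already-horizontal face changes nothing", {
  r <- render_face(list(noise_seed = 5), 256)
  al <- align_face(r$image, r$landmarks)
  expect_equal(al$landmarks, r$landmarks, tolerance = 1e-10)
  expect_equal(al$image, r$image, tolerance = 1e-10)
})

test_that("crop solves the 30%/35% placement with one similarity transform", {
  lm <- make_landmarks(left_eye = c(180, 300), right_eye = c(220, 300),
                       mouth = c(200, 370), jaw_x = c(100, 300))
  img <- matrix(0.5, 420, 420)
  cr <- crop_face(img, lm, size = 300)
  # scale = (0.35*300) / (370 - 300) = 1.5
  expect_equal(unname(cr$transform[1, 1]), 1.5)
  ec <- eye_centers(cr$landmarks)
  eye_mid <- (ec$left + ec$right) / 2
  mouth <- colMeans(cr$landmarks[49:68, ])
  expect_equal(unname(eye_mid), c(150, 90))
  expect_equal(unname(mouth), c(150, 195))
  expect_equal(dim(cr$image), c(300, 300))
  expect_error(crop_face(img, make_landmarks(mouth = c(130, 100))), "below")
})

test_that("align-then-crop places eyes and mouth on the canonical rows", {
  for (seed in 1:3) {
    spec <- cohort_spec(2, seed = seed)
    o <- attr(generate_cohort(spec), "objects")[[1]]
    al <- align_face(o$image, o$landmarks)
    cr <- crop_face(al$image, al$landmarks)
    ec <- eye_centers(cr$landmarks)
    mouth <- colMeans(cr$landmarks[49:68, ])
    expect_lt(abs((ec$left[2] + ec$right[2]) / 2 - 90), 1)
    expect_lt(abs(mouth[2] - 195), 1)
    # the warped ground-truth mask stays inside the 300x300 frame
    pp <- preprocess_sample(o$image, o$landmarks, o$mask)
    expect_gt(sum(pp$mask == 255), 0)
    border <- c(pp$mask[1, ], pp$mask[300, ], pp$mask[, 1], pp$mask[, 300])
    expect_true(all(border == 0))
  }
})

test_that("raster warping and landmark transforms stay consistent", {
  r <- render_face(list(rot_deg = 9, noise_seed = 1), 256)
  # delta impulse at the nose-tip landmark must land on the transformed point
  lm_pt <- r$landmarks[31, ]
  img <- matrix(0, 256, 256)
  img[round(lm_pt[2]) + 1, round(lm_pt[1]) + 1] <- 1
  pp <- preprocess_sample(img, r$landmarks, size = 300)
  peak <- which(pp$face == max(pp$face), arr.ind = TRUE)[1, ]
  moved <- pp$landmarks[31, ]
  expect_lt(abs(peak[2] - 1 - moved[1]), 1.6)
  expect_lt(abs(peak[1] - 1 - moved[2]), 1.6)
})

test_that("joint translation of image and landmarks leaves the crop unchanged", {
  r <- render_face(list(rot_deg = 4, noise_seed = 6), 256)
  big <- matrix(0, 320, 320)
  big[1:256, 1:256] <- r$image
  shifted <- matrix(0, 320, 320)
  shifted[31:286, 21:276] <- r$image
  lm0 <- r$landmarks
  lm1 <- sweep(r$landmarks, 2, c(20, 30), "+")
  p0 <- preprocess_sample(big, lm0, size = 200)
  p1 <- preprocess_sample(shifted, lm1, size = 200)
  expect_equal(p0$landmarks, p1$landmarks, tolerance = 1e-8)
  expect_lt(max(abs(p0$face - p1$face)), 1e-8)
})
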