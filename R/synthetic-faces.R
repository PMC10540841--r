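#' Cohort specification for the synthetic face generator
#'
#' Defines the statistical structure of a generated cohort. The defaults
#' mirror the clinical cohort the pipeline was designed around: 23.9%
#' prevalence of nutritional risk (NRS-2002 >= 3), 61.5% men, 16.5% elderly
#' (age >= 65), and a 37.7% share of subjects recruited at remote sites.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param prevalence probability that a subject is at nutritional risk
#'   (NRS-2002 >= 3); must lie strictly in (0, 1).
#' @param elderly_fraction probability of the elderly age group.
#' @param male_fraction probability of male gender.
#' @param remote_fraction probability of a remote collection site.
#' @param effect_size separation of fat-pad appearance (brightness and
#'   thickness) between risk classes, in units of the between-subject
#'   appearance standard deviation. 0 means no signal.
#' @param jitter_rotation_deg maximum absolute in-plane head rotation (deg).
#' @param jitter_translation_px maximum absolute translation (px).
#' @param split_fraction fraction of subjects assigned to the training split.
#' @param canvas_size side length of the square canvas in pixels (>= 128).
#' @param seed integer master seed; every subject derives its own stream.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects,
                        prevalence = 0.239,
                        elderly_fraction = 0.165,
                        male_fraction = 0.615,
                        remote_fraction = 0.377,
                        effect_size = 2,
                        jitter_rotation_deg = 5,
                        jitter_translation_px = 10,
                        split_fraction = 0.74,
                        canvas_size = 512,
                        seed = 1L) {
  if (n_subjects < 2) stop("n_subjects must be >= 2", call. = FALSE)
  if (prevalence <= 0 || prevalence >= 1) {
    stop("prevalence must lie strictly in (0, 1)", call. = FALSE)
  }
  fr <- c(elderly_fraction, male_fraction, remote_fraction, split_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]", call. = FALSE)
  if (effect_size < 0) stop("effect_size must be non-negative", call. = FALSE)
  if (canvas_size < 128) stop("canvas_size must be >= 128", call. = FALSE)
  structure(list(
    n_subjects = as.integer(n_subjects), prevalence = prevalence,
    elderly_fraction = elderly_fraction, male_fraction = male_fraction,
    remote_fraction = remote_fraction, effect_size = effect_size,
    jitter_rotation_deg = jitter_rotation_deg,
    jitter_translation_px = jitter_translation_px,
    split_fraction = split_fraction, canvas_size = as.integer(canvas_size),
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

# 68-point landmark template in the face frame (origin at face centre,
# x rightward, y downward, units of a 512-px canvas; scaled at render time).
# Indexing follows the standard 68-point scheme: jaw 0-16, brows 17-26,
# nose 27-35, image-left eye 36-41, image-right eye 42-47, mouth 48-67.
face_template <- function() {
  jaw_phi <- seq(pi - 0.35, 0.35, length.out = 17)
  jaw <- cbind(0.98 * 150 * cos(jaw_phi), 0.98 * 190 * sin(jaw_phi))
  brow_t <- seq(0, 1, length.out = 5)
  brow_l <- cbind(-92 + 58 * brow_t, -68 - 8 * sin(pi * brow_t))
  brow_r <- cbind(34 + 58 * brow_t, -68 - 8 * sin(pi * rev(brow_t)))
  nose <- rbind(cbind(0, seq(-40, 12, length.out = 4)),
                cbind(seq(-16, 16, length.out = 5), 24))
  eye_ang <- seq(0, 300, by = 60) * pi / 180
  eye_pts <- function(cx) cbind(cx + 16 * cos(eye_ang), -40 + 8 * sin(eye_ang))
  mouth_out <- (seq_len(12) - 1) * 30 * pi / 180
  mouth_in <- (seq_len(8) - 1) * 45 * pi / 180
  mouth <- rbind(cbind(40 * cos(mouth_out), 95 + 14 * sin(mouth_out)),
                 cbind(24 * cos(mouth_in), 95 + 7 * sin(mouth_in)))
  rbind(jaw, brow_l, brow_r, nose, eye_pts(-62), eye_pts(62), mouth)
}

# Geometry constants of the schematic face (512-canvas units).
.face_geom <- list(
  eye_cx = 62, eye_cy = -40, eye_a = 16, eye_b = 8,
  pad_gap = 3, pad_a = 36, pad_b0 = 28, # pad_b = pad_b0 + thickness
  mouth_cy = 95, mouth_a = 40, mouth_b = 14
)

#' Render one schematic face
#'
#' Draws a schematic face (ellipse primitives, not photorealistic) on a
#' square canvas together with the matching 68-point landmarks and the
#' ground-truth binary mask of the sub-orbital fat-pad crescents. The
#' crescents sit strictly below the eye ellipses; their brightness and
#' thickness carry the class signal.
#'
#' @param params list with elements `pad_level` (crescent brightness in
#'   \[0,1\]), `pad_thick` (crescent thickness, px at 512 scale),
#'   `rot_deg` (in-plane rotation), `tx`, `ty` (translation, px), and
#'   `noise_seed` (integer seed for pixel noise). Missing elements default
#'   to an upright, centred, baseline face.
#' @param canvas_size square canvas side, >= 128.
#' @return list with `image` (canvas x canvas matrix in \[0,1\]),
#'   `landmarks` (68 x 2 matrix, columns x, y, 0-based pixel coordinates),
#'   and `mask` (matrix with values 0/255).
#' @export
render_face <- function(params = list(), canvas_size = 512) {
  if (canvas_size < 128) stop("canvas_size must be >= 128", call. = FALSE)
  p <- list(pad_level = 0.55, pad_thick = 5, rot_deg = 0, tx = 0, ty = 0,
            noise_seed = 0L)
  p[names(params)] <- params
  g <- .face_geom
  n <- as.integer(canvas_size)
  s <- n / 512
  ctr <- (n - 1) / 2
  a <- p$rot_deg * pi / 180
  ca <- cos(a); sa <- sin(a)

  # map canvas pixel coords into the face frame (inverse rigid transform)
  X <- matrix(0:(n - 1), n, n, byrow = TRUE) - ctr - p$tx
  Y <- matrix(0:(n - 1), n, n) - ctr - p$ty
  xf <- (ca * X + sa * Y) / s
  yf <- (-sa * X + ca * Y) / s

  in_ell <- function(cx, cy, ea, eb) {
    ((xf - cx) / ea)^2 + ((yf - cy) / eb)^2 <= 1
  }
  img <- matrix(0.08, n, n)
  img[in_ell(0, 0, 150, 190)] <- 0.72
  img[in_ell(-63, -70, 30, 5) | in_ell(63, -70, 30, 5)] <- 0.30      # brows
  img[abs(xf) <= 2.5 & yf >= -40 & yf <= 16] <- 0.60                 # nose
  img[in_ell(0, 20, 18, 4)] <- 0.55
  img[in_ell(0, g$mouth_cy, g$mouth_a, g$mouth_b)] <- 0.30           # mouth
  eye_l <- in_ell(-g$eye_cx, g$eye_cy, g$eye_a, g$eye_b)
  eye_r <- in_ell(g$eye_cx, g$eye_cy, g$eye_a, g$eye_b)
  img[eye_l | eye_r] <- 0.15

  pb <- g$pad_b0 + p$pad_thick
  below <- yf >= g$eye_cy + g$eye_b + g$pad_gap
  pad <- (in_ell(-g$eye_cx, g$eye_cy, g$pad_a, pb) |
            in_ell(g$eye_cx, g$eye_cy, g$pad_a, pb)) & below
  img[pad] <- p$pad_level

  set.seed(as.integer(p$noise_seed))
  img <- img + matrix(rnorm(n * n, sd = 0.012), n, n)
  img[pad] <- img[pad] + rnorm(sum(pad), sd = 0.03)
  img <- pmin(pmax(img, 0), 1)
  img <- round(img * 255) / 255  # 8-bit quantization, as stored on disk

  lm <- face_template() * s
  R <- matrix(c(ca, sa, -sa, ca), 2, 2)  # y-down rotation by rot_deg
  lm <- t(R %*% t(lm)) +
    matrix(c(ctr + p$tx, ctr + p$ty), 68, 2, byrow = TRUE)
  colnames(lm) <- c("x", "y")

  mask <- matrix(0, n, n)
  mask[pad] <- 255
  list(image = img, landmarks = lm, mask = mask)
}

# Draws the per-subject attributes and rendering parameters for subject i.
# Pure function of (spec, i): each subject re-seeds from a derived stream.
draw_subject <- function(spec, i) {
  subject_seed <- derive_seed(spec$seed, i)
  set.seed(subject_seed)
  risk <- rbinom(1, 1, spec$prevalence)
  nrs_score <- if (risk == 1) sample(3:5, 1) else sample(0:2, 1)
  age_group <- if (rbinom(1, 1, spec$elderly_fraction) == 1) "elderly" else "non_elderly"
  gender <- if (rbinom(1, 1, spec$male_fraction) == 1) "male" else "female"
  site <- if (rbinom(1, 1, spec$remote_fraction) == 1) "remote" else "non_remote"
  # appearance: nutritional risk depletes the fat pad, so the risk class
  # shifts DOWN in both brightness and thickness by effect_size units of
  # the between-subject noise sd. Levels are clamped below the skin tone
  # (0.72) so the crescent boundary never vanishes.
  pad_level <- 0.55 - 0.06 * (spec$effect_size * risk + rnorm(1))
  pad_thick <- 12 - 1.5 * (spec$effect_size * risk + rnorm(1))
  list(
    sample_id = sprintf("s%04d", i), risk = risk, nrs_score = nrs_score,
    age_group = age_group, gender = gender, site = site,
    pad_level = min(max(pad_level, 0.25), 0.66),
    pad_thick = min(max(pad_thick, 5), 18),
    rot_deg = runif(1, -spec$jitter_rotation_deg, spec$jitter_rotation_deg),
    tx = runif(1, -spec$jitter_translation_px, spec$jitter_translation_px),
    ty = runif(1, -spec$jitter_translation_px, spec$jitter_translation_px),
    noise_seed = derive_seed(subject_seed, 99)
  )
}

#' Subject attributes of a synthetic cohort (no rendering)
#'
#' Returns the subject-level attribute table that [generate_cohort()] would
#' produce, without rendering any images. Useful for checking the label and
#' covariate distributions at large n.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with one row per subject.
#' @export
cohort_attributes <- function(spec) {
  rows <- lapply(seq_len(spec$n_subjects), function(i) {
    d <- draw_subject(spec, i)
    data.frame(sample_id = d$sample_id, nrs_score = d$nrs_score,
               risk = d$risk, age_group = d$age_group, gender = d$gender,
               site = d$site, pad_level = d$pad_level,
               pad_thick = d$pad_thick, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  n_train <- round(spec$split_fraction * spec$n_subjects)
  df$split <- c(rep("train", n_train),
                rep("test", spec$n_subjects - n_train))
  df
}

#' Generate a synthetic face cohort
#'
#' Renders `spec$n_subjects` schematic faces with consistent 68-point
#' landmarks, ground-truth fat-pad masks, NRS-2002 scores, and subgroup
#' attributes (age group, gender, site). Attributes are sampled
#' independently of the risk label except for the fat-pad appearance,
#' which shifts by `effect_size` appearance-noise standard deviations in
#' the risk class. Fully deterministic given `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir output directory; when given, per-subject PNG images,
#'   PNG masks and landmark CSVs are written under `images/`, `masks/`,
#'   `landmarks/`, together with a `metadata.csv`. When `NULL`, nothing is
#'   written and the rendered objects are kept in memory.
#' @param keep_objects keep the rendered image/landmarks/mask of every
#'   subject in memory (attached as attribute `"objects"`).
#' @return data.frame of sample records (id, paths, NRS score, attributes,
#'   split); when `keep_objects`, attribute `"objects"` is a list of
#'   [render_face()] results parallel to the rows.
#' @export
generate_cohort <- function(spec, out_dir = NULL,
                            keep_objects = is.null(out_dir)) {
  stopifnot(inherits(spec, "cohort_spec"))
  write_files <- !is.null(out_dir)
  if (write_files) {
    for (d in file.path(out_dir, c("images", "masks", "landmarks"))) {
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
    }
    if (!dir.exists(out_dir)) stop("cannot create out_dir: ", out_dir, call. = FALSE)
  }
  meta <- cohort_attributes(spec)
  meta$image_path <- NA_character_
  meta$mask_path <- NA_character_
  meta$landmarks_path <- NA_character_
  objects <- if (keep_objects) vector("list", spec$n_subjects) else NULL

  for (i in seq_len(spec$n_subjects)) {
    d <- draw_subject(spec, i)
    r <- render_face(d, spec$canvas_size)
    if (keep_objects) objects[[i]] <- r
    if (write_files) {
      ip <- file.path(out_dir, "images", paste0(d$sample_id, ".png"))
      mp <- file.path(out_dir, "masks", paste0(d$sample_id, ".png"))
      lp <- file.path(out_dir, "landmarks", paste0(d$sample_id, ".csv"))
      png::writePNG(r$image, ip)
      write_mask(r$mask, mp)
      write_landmarks(r$landmarks, lp)
      meta$image_path[i] <- ip; meta$mask_path[i] <- mp
      meta$landmarks_path[i] <- lp
    }
  }
  cols <- c("sample_id", "image_path", "mask_path", "landmarks_path",
            "nrs_score", "age_group", "gender", "site", "split")
  meta <- meta[, c(cols, setdiff(names(meta), cols))]
  if (write_files) {
    write.csv(meta[, cols], file.path(out_dir, "metadata.csv"),
              row.names = FALSE)
  }
  if (keep_objects) attr(meta, "objects") <- objects
  meta
}

#' Read and write landmark CSV files
#'
#' Landmarks are stored as CSV with header `index,x,y`, 68 rows, 0-based
#' point index, pixel units, origin at the top-left pixel centre, x
#' rightward, y downward.
#'
#' @param path CSV path.
#' @return `read_landmarks` returns a 68 x 2 matrix with columns x, y.
#' @export
read_landmarks <- function(path) {
  df <- read.csv(path)
  stopifnot(nrow(df) == 68, all(c("index", "x", "y") %in% names(df)))
  lm <- as.matrix(df[order(df$index), c("x", "y")])
  rownames(lm) <- NULL
  lm
}

#' @rdname read_landmarks
#' @param landmarks 68 x 2 matrix (columns x, y).
#' @export
write_landmarks <- function(landmarks, path) {
  stopifnot(nrow(landmarks) == 68)
  write.csv(data.frame(index = 0:67, x = landmarks[, 1], y = landmarks[, 2]),
            path, row.names = FALSE)
}

#' Read and write binary mask PNGs
#'
#' Masks are 8-bit PNGs whose pixels are exactly 0 (background) or 255
#' (orbital fat pad).
#'
#' @param path PNG path.
#' @return `read_mask` returns a matrix with values 0/255.
#' @export
read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m <- round(m * 255)
  stopifnot_binary_mask(m)
  m
}

#' @rdname read_mask
#' @param mask matrix with values 0/255.
#' @export
write_mask <- function(mask, path) {
  stopifnot_binary_mask(mask)
  png::writePNG(mask / 255, path)
}
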