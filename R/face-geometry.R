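#' Eye centre points from 68-point landmarks
#'
#' The eye centres are the centroids of the six landmarks of each eye
#' (standard 68-point indexing: image-left eye points 36-41, image-right
#' eye points 42-47, 0-based). The pair is returned so that `left` is the
#' image-left eye (smaller x), swapping if needed.
#'
#' @param landmarks 68 x 2 matrix (columns x, y, pixels, y down).
#' @return list with numeric `left` and `right` points `c(x, y)`.
#' @export
eye_centers <- function(landmarks) {
  stopifnot(is.matrix(landmarks), nrow(landmarks) == 68,
            all(is.finite(landmarks)))
  left <- colMeans(landmarks[37:42, , drop = FALSE])   # points 36-41
  right <- colMeans(landmarks[43:48, , drop = FALSE])  # points 42-47
  if (isTRUE(all.equal(left, right, tolerance = 1e-12))) {
    stop("degenerate landmarks: coincident eye centroids", call. = FALSE)
  }
  if (left[1] > right[1]) { tmp <- left; left <- right; right <- tmp }
  list(left = unname(left), right = unname(right))
}

#' Angle of the interocular line
#'
#' Angle between the line joining the two eye centres and the horizontal,
#' in degrees, in (-90, 90]. In the y-down image frame the angle is
#' positive when the image-right eye sits lower than the image-left eye.
#'
#' @param left,right eye centre points `c(x, y)`.
#' @return angle in degrees.
#' @export
interocular_angle <- function(left, right) {
  if (all(left == right)) stop("coincident eye centres", call. = FALSE)
  theta <- atan2(right[2] - left[2], right[1] - left[1]) * 180 / pi
  # fold to (-90, 90] (the eye line is undirected)
  if (theta > 90) theta <- theta - 180
  if (theta <= -90) theta <- theta + 180
  theta
}

# Applies a forward 2x3 affine [A | t] (point' = A p + t) to an n x 2 matrix.
transform_points <- function(points, m) {
  out <- points %*% t(m[, 1:2]) +
    matrix(m[, 3], nrow(points), 2, byrow = TRUE)
  colnames(out) <- colnames(points)
  out
}

#' Warp a raster by a forward affine transform
#'
#' Resamples `image` under the forward transform `m` (a 2 x 3 matrix
#' mapping source pixel coordinates to output coordinates; 0-based, pixel
#' centres at integers) using bilinear interpolation; pixels that map from
#' outside the source are filled with black (0).
#'
#' @param image matrix (grayscale) or H x W x C array.
#' @param m forward 2 x 3 affine matrix.
#' @param out_h,out_w output raster size.
#' @return warped raster, same number of channels as the input.
#' @export
warp_image <- function(image, m, out_h, out_w) {
  A <- m[, 1:2, drop = FALSE]
  Ainv <- solve(A)
  minv <- cbind(Ainv, -Ainv %*% m[, 3])
  was_matrix <- is.matrix(image)
  out <- .warp_bilinear(as_cube(image), minv, as.integer(out_h),
                        as.integer(out_w))
  if (was_matrix) out <- out[, , 1] else out
}

#' Rigid transform that levels the interocular line
#'
#' The forward 2 x 3 affine matrix that rotates by minus the interocular
#' angle about the midpoint between the eye centres (so that after applying
#' it the line connecting the eyes is horizontal).
#'
#' @param landmarks 68 x 2 landmark matrix.
#' @return 2 x 3 forward affine matrix.
#' @export
align_transform <- function(landmarks) {
  ec <- eye_centers(landmarks)
  theta <- interocular_angle(ec$left, ec$right) * pi / 180
  mid <- (ec$left + ec$right) / 2
  ca <- cos(-theta); sa <- sin(-theta)
  A <- matrix(c(ca, sa, -sa, ca), 2, 2)
  cbind(A, mid - A %*% mid)
}

#' Compose two forward affine transforms
#'
#' Returns the 2 x 3 matrix of `m2 o m1` (apply `m1` first).
#'
#' @param m2,m1 2 x 3 forward affine matrices.
#' @return 2 x 3 forward affine matrix.
#' @export
compose_affine <- function(m2, m1) {
  A <- m2[, 1:2] %*% m1[, 1:2]
  cbind(A, m2[, 1:2] %*% m1[, 3] + m2[, 3])
}

#' Align a face so the interocular line is horizontal
#'
#' Rotates the image and its 68 landmarks rigidly by minus the interocular
#' angle about the midpoint between the two eye centres, so that the line
#' connecting the eyes becomes horizontal. Raster resampling is bilinear
#' with black fill outside the source frame.
#'
#' @param image matrix or H x W x C array with values in \[0,1\].
#' @param landmarks 68 x 2 landmark matrix.
#' @return list with rotated `image` (same size) and `landmarks`.
#' @export
align_face <- function(image, landmarks) {
  if (length(image) == 0) stop("empty image", call. = FALSE)
  m <- align_transform(landmarks)
  img <- as_cube(image)
  list(image = warp_image(image, m, nrow(img), ncol(img)),
       landmarks = transform_points(landmarks, m))
}

#' Crop and rescale an aligned face to the canonical 300 x 300 frame
#'
#' Applies the single similarity transform (uniform scale plus translation,
#' no rotation) that places the face centre (midpoint of the leftmost and
#' rightmost landmarks) at the horizontal centre, the eye centre at 30% of
#' the output height from the top, and the mouth centre (centroid of
#' landmarks 48-67) at 35% of the output height from the bottom. For the
#' default `size = 300` the eye row is 90 and the mouth row is 195. Call
#' after [align_face()].
#'
#' @param image matrix or H x W x C array.
#' @param landmarks 68 x 2 landmark matrix (eye line horizontal).
#' @param size output side length in pixels.
#' @return list with `image` (`size` x `size`), `landmarks` transformed to
#'   the output frame, and `transform` (the forward 2 x 3 matrix, reusable
#'   to warp e.g. a paired mask with [warp_image()]).
#' @export
crop_face <- function(image, landmarks, size = 300) {
  ec <- eye_centers(landmarks)
  eye_mid <- (ec$left + ec$right) / 2
  mouth <- colMeans(landmarks[49:68, , drop = FALSE])  # points 48-67
  span <- mouth[2] - eye_mid[2]
  if (span <= 0) {
    stop("mouth centre must lie below the eye centre", call. = FALSE)
  }
  # eye row at 0.30*size, mouth row at size - 0.35*size
  s <- (size - 0.35 * size - 0.30 * size) / span
  cx <- mean(range(landmarks[, 1]))
  m <- cbind(diag(c(s, s)),
             c(size / 2 - s * cx, 0.30 * size - s * eye_mid[2]))
  list(image = warp_image(image, m, size, size),
       landmarks = transform_points(landmarks, m),
       transform = m)
}
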