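#' Grayscale conversion (ITU-R BT.601 luma)
#'
#' @param image matrix (returned unchanged) or H x W x 3 array.
#' @return matrix of luma values on the input's scale.
#' @export
luma <- function(image) {
  if (is.matrix(image)) return(image)
  d <- dim(image)
  if (length(d) == 3 && d[3] == 1) return(image[, , 1])
  stopifnot(length(d) == 3, d[3] >= 3)
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

#' Restrict a face image to the fat-pad region of interest
#'
#' Merges the aligned, cropped face with its fat-pad mask: the face is
#' converted to grayscale (BT.601 luma) and scaled to \[0,1\], pixels where
#' the mask is 0 are set to 0, pixels where the mask is 255 keep the face
#' value.
#'
#' @param face matrix or H x W x C array, values in \[0,1\].
#' @param mask 0/255 mask matrix of the same height/width.
#' @return ROI matrix in \[0,1\] with zeros outside the mask.
#' @export
apply_mask <- function(face, mask) {
  g <- luma(face)
  if (!all(dim(g) == dim(mask))) stop("face/mask shape mismatch", call. = FALSE)
  stopifnot_binary_mask(mask)
  g <- pmin(pmax(g, 0), 1)
  g[mask == 0] <- 0
  g
}

#' HOG descriptor parameters
#'
#' Defaults are the dense Dalal-Triggs configuration used throughout the
#' pipeline: 8 x 8-pixel cells, 2 x 2-cell blocks advanced with a 1-cell
#' stride, 9 unsigned orientation bins with centres at i*pi/9 (i = 0..8),
#' and L2-Hys block normalization (L2-normalize, clip at 0.2, renormalize).
#'
#' @param cell_px cell side in pixels.
#' @param cells_per_block_side cells per block side (blocks are square).
#' @param bins orientation bins over \[0, pi).
#' @param clip L2-Hys clipping threshold.
#' @return object of class `hog_params`.
#' @export
hog_params <- function(cell_px = 8, cells_per_block_side = 2, bins = 9,
                       clip = 0.2) {
  stopifnot(cell_px >= 2, bins >= 2, cells_per_block_side >= 1)
  structure(list(cell_px = as.integer(cell_px),
                 cells_per_block_side = as.integer(cells_per_block_side),
                 bins = as.integer(bins), clip = clip),
            class = "hog_params")
}

#' Length of the HOG descriptor
#'
#' Cells are whole `cell_px` squares (partial border cells are dropped);
#' blocks of `cells_per_block_side`^2 cells slide with a 1-cell stride, so
#' an image of 37 x 37 cells has 36 x 36 overlapping blocks. Each block
#' contributes `cells_per_block_side`^2 * `bins` features; for a 300 x 300
#' image under the defaults this gives 36 * 36 * 36 = 46,656.
#'
#' @param width,height image size in pixels.
#' @param params a [hog_params()].
#' @return integer descriptor length.
#' @export
hog_length <- function(width, height, params = hog_params()) {
  ncx <- floor(width / params$cell_px)
  ncy <- floor(height / params$cell_px)
  nbx <- ncx - params$cells_per_block_side + 1
  nby <- ncy - params$cells_per_block_side + 1
  if (nbx < 1 || nby < 1) {
    stop("image smaller than one block", call. = FALSE)
  }
  as.integer(nbx * nby * params$cells_per_block_side^2 * params$bins)
}

#' Histogram-of-oriented-gradients descriptor
#'
#' Dense HOG of a grayscale image in \[0,1\]: centred-difference gradients
#' (`[-1, 0, 1]`, borders replicated), unsigned orientation folded to
#' \[0, pi), per-pixel magnitude votes split linearly between the two
#' nearest bin centres (centres at i*pi/bins), per-cell histograms,
#' 2 x 2-cell blocks at 1-cell stride normalized with L2-Hys. Blocks are
#' concatenated row-major (block rows outer, columns inner), cells within a
#' block row-major, bins ascending.
#'
#' @param image grayscale matrix, values in \[0,1\].
#' @param params a [hog_params()].
#' @return numeric vector of length `hog_length(ncol(image), nrow(image))`.
#' @export
hog_features <- function(image, params = hog_params()) {
  stopifnot(is.matrix(image))
  if (!all(is.finite(image))) stop("non-finite pixels", call. = FALSE)
  H <- nrow(image); W <- ncol(image)
  cp <- params$cell_px; nbin <- params$bins; cbs <- params$cells_per_block_side
  len <- hog_length(W, H, params)  # validates size

  # centred differences with replicated borders; x = columns, y = rows (down)
  gx <- image[, c(2:W, W)] - image[, c(1, 1:(W - 1))]
  gy <- image[c(2:H, H), ] - image[c(1, 1:(H - 1)), ]
  mag <- sqrt(gx^2 + gy^2)
  theta <- atan2(gy, gx) %% pi
  pos <- theta / (pi / nbin)
  b0 <- floor(pos) %% nbin
  f <- pos - floor(pos)

  ncy <- floor(H / cp); ncx <- floor(W / cp)
  hu <- ncy * cp; wu <- ncx * cp
  # block-sum operators: Sy (ncy x hu), Sx (ncx x wu)
  Sy <- matrix(0, ncy, hu); Sy[cbind(rep(1:ncy, each = cp), 1:hu)] <- 1
  Sx <- matrix(0, ncx, wu); Sx[cbind(rep(1:ncx, each = cp), 1:wu)] <- 1
  hist <- array(0, c(ncy, ncx, nbin))
  for (b in 0:(nbin - 1)) {
    wmat <- matrix(0, H, W)
    sel0 <- b0 == b
    wmat[sel0] <- mag[sel0] * (1 - f[sel0])
    sel1 <- (b0 + 1) %% nbin == b
    wmat[sel1] <- wmat[sel1] + mag[sel1] * f[sel1]
    hist[, , b + 1] <- Sy %*% wmat[1:hu, 1:wu, drop = FALSE] %*% t(Sx)
  }

  nby <- ncy - cbs + 1; nbx <- ncx - cbs + 1
  blk_len <- cbs * cbs * nbin
  out <- numeric(len)
  pos_out <- 0L
  for (by in seq_len(nby)) {
    for (bx in seq_len(nbx)) {
      v <- numeric(blk_len)
      k <- 0L
      for (cy in 0:(cbs - 1)) {
        for (cx in 0:(cbs - 1)) {
          v[k + 1:nbin] <- hist[by + cy, bx + cx, ]
          k <- k + nbin
        }
      }
      nrm <- sqrt(sum(v^2))
      if (nrm > 0) {
        v <- v / nrm
        v[v > params$clip] <- params$clip
        v <- v / sqrt(sum(v^2))
      }
      out[pos_out + seq_len(blk_len)] <- v
      pos_out <- pos_out + blk_len
    }
  }
  out
}

#' Per-feature z-score standardizer
#'
#' Fits per-feature mean and population standard deviation (divide by n) on
#' the training matrix; constant features get sd 1 so they standardize to 0.
#' Fit on training data only and reuse on test data.
#'
#' @param x numeric matrix, rows = samples.
#' @return object of class `standardizer` with `mean` and `sd`.
#' @export
fit_standardizer <- function(x) {
  if (nrow(x) < 2) stop("need >= 2 training vectors", call. = FALSE)
  mu <- colMeans(x)
  sdv <- sqrt(colMeans(sweep(x, 2, mu)^2))
  sdv[sdv < 1e-12] <- 1
  structure(list(mean = mu, sd = sdv), class = "standardizer")
}

#' @rdname fit_standardizer
#' @param st a fitted `standardizer`.
#' @export
standardize <- function(st, x) {
  stopifnot(inherits(st, "standardizer"), ncol(x) == length(st$mean))
  sweep(sweep(x, 2, st$mean), 2, st$sd, "/")
}

#' Principal component analysis for feature reduction
#'
#' Computes the top-`k` principal components of the training matrix
#' (eigenvectors of the covariance of centred rows, via SVD). Component
#' signs are fixed so the largest-magnitude loading of each component is
#' positive. Fit on training data only.
#'
#' @param x numeric matrix, rows = samples.
#' @param k number of components to keep; must satisfy
#'   `k <= min(nrow(x), ncol(x))`.
#' @return object of class `pca_model` with `components` (k x d, orthonormal
#'   rows), `center`, and `explained_variance`.
#' @export
fit_pca <- function(x, k = 100) {
  n <- nrow(x); d <- ncol(x)
  if (n < 2) stop("need >= 2 training vectors", call. = FALSE)
  if (k > min(n, d)) {
    stop(sprintf("k = %d exceeds min(n_samples, n_features) = %d",
                 k, min(n, d)), call. = FALSE)
  }
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  sv <- svd(xc, nu = 0, nv = k)
  comp <- t(sv$v[, seq_len(k), drop = FALSE])
  flip <- apply(comp, 1, function(r) sign(r[which.max(abs(r))]))
  comp <- comp * flip
  structure(list(components = comp, center = ctr,
                 explained_variance = sv$d[seq_len(k)]^2 / (n - 1),
                 total_variance = sum(sv$d^2) / (n - 1)),
            class = "pca_model")
}

#' @rdname fit_pca
#' @param model a fitted `pca_model`.
#' @export
pca_reduce <- function(model, x) {
  stopifnot(inherits(model, "pca_model"), ncol(x) == length(model$center))
  sweep(x, 2, model$center) %*% t(model$components)
}

#' @rdname fit_pca
#' @param scores n x k matrix of projected coordinates.
#' @export
pca_reconstruct <- function(model, scores) {
  sweep(scores %*% model$components, 2, model$center, "+")
}
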