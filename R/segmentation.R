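#' Training configuration for the fat-pad segmentation model
#'
#' Defaults follow the full-scale training recipe used for the clinical
#' model: batch size 1, 50 epochs, binary cross-entropy loss, RMSProp with
#' learning rate 1e-5, weight decay 1e-8 and momentum 0.9. For desk-scale
#' runs on synthetic fixtures the architecture is shrunk via
#' `base_channels`/`depth`/`image_size`, the learning rate raised to ~5e-4
#' and `rms_alpha` lowered to 0.9 (RMSProp's normalised steps travel
#' roughly lr x steps, and the full-recipe values are calibrated to a
#' ~20,000-step schedule).
#'
#' @param epochs number of passes over the training set.
#' @param learning_rate RMSProp learning rate.
#' @param weight_decay L2 penalty added to gradients.
#' @param momentum RMSProp momentum.
#' @param rms_alpha RMSProp smoothing constant of the running mean square
#'   (framework default 0.99; small-step desk runs track curvature faster
#'   with 0.9).
#' @param base_channels channels of the first encoder level (doubled per
#'   level); 64 reproduces the classic U-net, 16 is the desk-scale default.
#' @param depth number of pooling levels.
#' @param in_channels input channels (1 = grayscale).
#' @param image_size expected square input side; must be divisible by
#'   `2^depth`.
#' @param split_fraction train fraction used by [split_dataset()].
#' @param seed integer seed (weight init and epoch shuffling).
#' @return object of class `seg_train_config`.
#' @export
seg_train_config <- function(epochs = 50, learning_rate = 1e-5,
                             weight_decay = 1e-8, momentum = 0.9,
                             rms_alpha = 0.99,
                             base_channels = 64, depth = 4,
                             in_channels = 1, image_size = 300,
                             split_fraction = 0.8, seed = 1L) {
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (split_fraction <= 0 || split_fraction >= 1) {
    stop("split_fraction must lie in (0, 1)", call. = FALSE)
  }
  structure(list(
    batch_size = 1L, epochs = as.integer(epochs),
    learning_rate = learning_rate, weight_decay = weight_decay,
    momentum = momentum, rms_alpha = rms_alpha,
    base_channels = as.integer(base_channels),
    depth = as.integer(depth), in_channels = as.integer(in_channels),
    image_size = as.integer(image_size), split_fraction = split_fraction,
    seed = as.integer(seed)
  ), class = "seg_train_config")
}

#' Random train/test split
#'
#' Splits records (a data.frame or list) into disjoint, exhaustive train
#' and test subsets with `|train| = round(fraction * n)`, deterministically
#' for a given seed and unstratified.
#'
#' @param records data.frame (split by row) or list.
#' @param fraction train fraction in (0, 1).
#' @param seed integer seed.
#' @return list with elements `train` and `test`.
#' @export
split_dataset <- function(records, fraction = 0.8, seed = 1L) {
  n <- if (is.data.frame(records)) nrow(records) else length(records)
  if (n < 2) stop("need at least 2 records to split", call. = FALSE)
  n_train <- round(fraction * n)
  if (n_train == 0 || n_train == n) {
    stop("split would leave an empty train or test set", call. = FALSE)
  }
  set.seed(as.integer(seed))
  idx <- sample.int(n, n_train)
  take <- function(i) if (is.data.frame(records)) records[i, , drop = FALSE]
    else records[i]
  list(train = take(sort(idx)), test = take(setdiff(seq_len(n), sort(idx))))
}

# zero-pads H and W up to the next multiple of m (bottom/right), so any
# input size works with 2^depth pooling levels; predictions are cropped back
pad_to_multiple <- function(x, m) {
  d <- dim(x)
  H <- ceiling(d[1] / m) * m
  W <- ceiling(d[2] / m) * m
  if (H == d[1] && W == d[2]) return(x)
  out <- array(0, c(H, W, d[3]))
  out[seq_len(d[1]), seq_len(d[2]), ] <- x
  out
}

prep_face_input <- function(face, in_channels) {
  x <- as_cube(face)
  if (dim(x)[3] != in_channels) {
    if (in_channels == 1) x <- array(luma(face), c(dim(x)[1], dim(x)[2], 1))
    else stop("face has ", dim(x)[3], " channels; model expects ",
              in_channels, call. = FALSE)
  }
  x
}

#' Train the orbital-fat-pad segmentation U-net
#'
#' Trains the encoder-decoder on (face, mask) pairs with binary
#' cross-entropy and RMSProp at batch size 1. Masks are stored as 0/255
#' rasters and converted internally to 0/1 targets. Deterministic given
#' `config$seed` (single-threaded BLAS assumed).
#'
#' @param pairs list of `list(face =, mask =)` pairs; faces are matrices or
#'   H x W x C arrays in \[0,1\], masks 0/255 matrices of the same size.
#' @param config a [seg_train_config()].
#' @param val_pairs optional held-out pairs; mean Dice is recorded per epoch.
#' @return object of class `seg_model` with elements `params`,
#'   `config`, and `history` (data.frame: epoch, loss, and `val_dice` when
#'   validation pairs were given).
#' @export
train_seg <- function(pairs, config = seg_train_config(),
                      val_pairs = NULL) {
  if (length(pairs) < 1) stop("no training pairs", call. = FALSE)
  sz <- config$image_size
  for (p in pairs) {
    f <- as_cube(p$face)
    if (!all(dim(p$mask)[1:2] == dim(f)[1:2]) || any(dim(f)[1:2] != sz)) {
      stop("face/mask shape mismatch with configured image_size",
           call. = FALSE)
    }
    stopifnot_binary_mask(p$mask)
  }
  params <- unet_init(config$in_channels, config$base_channels,
                      config$depth, seed = config$seed)
  state <- list(sq = lapply(params, function(p) p * 0),
                buf = lapply(params, function(p) p * 0))
  m2 <- 2^config$depth
  xs <- lapply(pairs, function(p)
    pad_to_multiple(prep_face_input(p$face, config$in_channels), m2))
  ts <- lapply(pairs, function(p)
    pad_to_multiple(as_cube(p$mask / 255), m2)[, , 1])
  history <- data.frame(epoch = integer(), loss = numeric())
  val_dice <- numeric()
  for (epoch in seq_len(config$epochs)) {
    set.seed(derive_seed(config$seed, epoch))
    ord <- sample.int(length(pairs))
    ep_loss <- 0
    for (i in ord) {
      fw <- unet_forward(params, xs[[i]], config$depth)
      lo <- bce_with_logits(fw$logits, ts[[i]])
      ep_loss <- ep_loss + lo$loss
      grads <- unet_backward(params, fw$cache, lo$dlogits, config$depth)
      st <- rmsprop_step(params, grads, state, config$learning_rate,
                         alpha = config$rms_alpha %||% 0.99,
                         weight_decay = config$weight_decay,
                         momentum = config$momentum)
      params <- st$params; state <- st$state
    }
    history <- rbind(history,
                     data.frame(epoch = epoch, loss = ep_loss / length(pairs)))
    if (!is.null(val_pairs)) {
      model_now <- structure(list(params = params, config = config),
                             class = "seg_model")
      dd <- vapply(val_pairs, function(p) {
        dice(predict_mask(model_now, p$face), p$mask)
      }, numeric(1))
      val_dice <- c(val_dice, mean(dd))
    }
  }
  if (!is.null(val_pairs)) history$val_dice <- val_dice
  structure(list(params = params, config = config, history = history),
            class = "seg_model")
}

#' Predict a binary fat-pad mask
#'
#' Runs the trained U-net on one face and thresholds the per-pixel sigmoid
#' probability map.
#'
#' @param model a `seg_model` from [train_seg()].
#' @param face matrix or array matching the model's configured input size.
#' @param threshold probability cut in (0, 1); pixels whose probability
#'   exceeds `threshold` become foreground (255).
#' @return mask matrix with values 0/255.
#' @export
predict_mask <- function(model, face, threshold = 0.5) {
  prob <- predict_prob(model, face)
  mask <- matrix(0, nrow(prob), ncol(prob))
  mask[prob > threshold] <- 255
  mask
}

#' Probability map of the fat-pad segmentation
#'
#' @inheritParams predict_mask
#' @return matrix of per-pixel foreground probabilities in \[0,1\].
#' @export
predict_prob <- function(model, face) {
  x <- prep_face_input(face, model$config$in_channels)
  if (any(dim(x)[1:2] != model$config$image_size)) {
    stop("face size does not match the model's image_size", call. = FALSE)
  }
  d <- dim(x)
  x <- pad_to_multiple(x, 2^model$config$depth)
  logits <- unet_forward(model$params, x, model$config$depth)$logits
  sigmoid(logits[seq_len(d[1]), seq_len(d[2])])
}

#' Save / load a segmentation checkpoint
#'
#' Single-file checkpoint containing the parameters, the architecture
#' descriptor (config) and the training history.
#'
#' @param model a `seg_model`.
#' @param path file path.
#' @export
save_seg_model <- function(model, path) {
  stopifnot(inherits(model, "seg_model"))
  saveRDS(model, path)
}

#' @rdname save_seg_model
#' @export
load_seg_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "seg_model"))
  model
}

#' Overlap metrics between binary masks
#'
#' `dice()` computes the Dice coefficient 2|A∩B|/(|A|+|B|) over the
#' foreground (255) pixel sets; `iou()` the intersection-over-union of the
#' chosen class; `miou()` the unweighted mean IoU over foreground and
#' background. A class empty in both masks scores 1.
#'
#' @param a,b mask matrices with values 0/255 and equal shape.
#' @return a fraction in \[0, 1\].
#' @export
dice <- function(a, b) {
  check_mask_pair(a, b)
  na <- sum(a == 255); nb <- sum(b == 255)
  if (na + nb == 0) return(1)
  2 * sum(a == 255 & b == 255) / (na + nb)
}

#' @rdname dice
#' @param cls `"foreground"` (255) or `"background"` (0).
#' @export
iou <- function(a, b, cls = c("foreground", "background")) {
  check_mask_pair(a, b)
  cls <- match.arg(cls)
  v <- if (cls == "foreground") 255 else 0
  uni <- sum(a == v | b == v)
  if (uni == 0) return(1)
  sum(a == v & b == v) / uni
}

#' @rdname dice
#' @export
miou <- function(a, b) {
  (iou(a, b, "foreground") + iou(a, b, "background")) / 2
}

check_mask_pair <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("mask shape mismatch", call. = FALSE)
  stopifnot_binary_mask(a, "a")
  stopifnot_binary_mask(b, "b")
  invisible(NULL)
}
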