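# Independent brute-force oracles used to cross-check the vectorized
# implementations. Deliberately naive: per-pixel loops, no shared code with
# the package internals.

# naive dense HOG: per-pixel gradient/vote loop, per-cell accumulation,
# per-block L2-Hys
hog_naive <- function(img, params = hog_params()) {
  H <- nrow(img); W <- ncol(img)
  cp <- params$cell_px; nb <- params$bins; cbs <- params$cells_per_block_side
  ncy <- floor(H / cp); ncx <- floor(W / cp)
  hist <- array(0, c(ncy, ncx, nb))
  for (i in 1:H) for (j in 1:W) {
    jm <- max(j - 1, 1); jp <- min(j + 1, W)
    im <- max(i - 1, 1); ip <- min(i + 1, H)
    gx <- img[i, jp] - img[i, jm]
    gy <- img[ip, j] - img[im, j]
    mag <- sqrt(gx^2 + gy^2)
    th <- atan2(gy, gx) %% pi
    pos <- th / (pi / nb); b0 <- floor(pos) %% nb; f <- pos - floor(pos)
    cy <- ceiling(i / cp); cx <- ceiling(j / cp)
    if (cy > ncy || cx > ncx) next
    hist[cy, cx, b0 + 1] <- hist[cy, cx, b0 + 1] + mag * (1 - f)
    hist[cy, cx, (b0 + 1) %% nb + 1] <- hist[cy, cx, (b0 + 1) %% nb + 1] + mag * f
  }
  out <- c()
  for (by in 1:(ncy - cbs + 1)) for (bx in 1:(ncx - cbs + 1)) {
    v <- c()
    for (cy in 0:(cbs - 1)) for (cx in 0:(cbs - 1)) v <- c(v, hist[by + cy, bx + cx, ])
    nrm <- sqrt(sum(v^2))
    if (nrm > 0) {
      v <- v / nrm; v[v > params$clip] <- params$clip; v <- v / sqrt(sum(v^2))
    }
    out <- c(out, v)
  }
  out
}

# Yates-corrected Pearson chi-square computed straight from the definition
chi2_yates_naive <- function(tbl) {
  E <- outer(rowSums(tbl), colSums(tbl)) / sum(tbl)
  stat <- sum(pmax(abs(tbl - E) - 0.5, 0)^2 / E)
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

# random binary mask helper
random_mask <- function(n = 12, p = 0.4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(0, n, n)
  m[matrix(runif(n * n) < p, n, n)] <- 255
  m
}

# renders a small cohort and preprocesses it to (face, mask) pairs at `size`
make_seg_pairs <- function(n, size = 64, seed = 5, canvas = 256) {
  spec <- cohort_spec(max(n, 2), seed = seed, canvas_size = canvas)
  coh <- generate_cohort(spec)
  objs <- attr(coh, "objects")[seq_len(n)]
  lapply(objs, function(o) {
    pp <- preprocess_sample(o$image, o$landmarks, o$mask, size = size)
    list(face = pp$face, mask = pp$mask)
  })
}
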