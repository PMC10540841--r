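#' Pipeline configuration
#'
#' Bundles the per-stage settings of the end-to-end run: alignment/crop
#' size, segmentation training, HOG parameters, PCA dimensionality, and
#' SVM hyper-parameters. All stage seeds derive from the single master
#' `seed`.
#'
#' @param crop_size canonical aligned-face side (px).
#' @param use_true_masks use the cohort's ground-truth masks instead of
#'   training/applying the segmentation model.
#' @param seg a [seg_train_config()] (ignored when `use_true_masks`).
#' @param seg_model optional pre-trained `seg_model` to apply instead of
#'   training.
#' @param hog a [hog_params()].
#' @param pca_k PCA dimensionality (reduced feature length).
#' @param svm an [svm_config()].
#' @param seed master integer seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(crop_size = 300, use_true_masks = FALSE,
                            seg = seg_train_config(), seg_model = NULL,
                            hog = hog_params(), pca_k = 100,
                            svm = svm_config(), seed = 1L) {
  structure(list(crop_size = as.integer(crop_size),
                 use_true_masks = use_true_masks, seg = seg,
                 seg_model = seg_model, hog = hog,
                 pca_k = as.integer(pca_k), svm = svm,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Align, crop and mask-warp one sample
#'
#' Computes the alignment rotation and the canonical-crop similarity from
#' the landmarks, composes them into a single transform, and applies it to
#' the face (bilinear) and, when given, to the paired mask (bilinear then
#' re-binarized at 0.5).
#'
#' @param image face raster in \[0,1\].
#' @param landmarks 68 x 2 landmark matrix.
#' @param mask optional 0/255 mask aligned with `image`.
#' @param size output side (px).
#' @return list with `face`, `landmarks`, `mask` (or NULL), `transform`.
#' @export
preprocess_sample <- function(image, landmarks, mask = NULL, size = 300) {
  m1 <- align_transform(landmarks)
  lm1 <- transform_points(landmarks, m1)
  cr <- crop_face(image * 0, lm1, size = size)  # transform only; cheap raster
  m <- compose_affine(cr$transform, m1)
  out_mask <- NULL
  if (!is.null(mask)) {
    stopifnot_binary_mask(mask)
    wm <- warp_image(mask / 255, m, size, size)
    out_mask <- matrix(0, size, size)
    out_mask[wm > 0.5] <- 255
  }
  list(face = warp_image(image, m, size, size),
       landmarks = transform_points(landmarks, m),
       mask = out_mask, transform = m)
}

load_sample <- function(rec, objects = NULL, i = NULL) {
  if (!is.null(objects)) {
    return(objects[[i]])
  }
  for (f in c("image_path", "landmarks_path", "mask_path")) {
    if (is.na(rec[[f]]) || !file.exists(rec[[f]])) {
      stop("missing file for sample ", rec$sample_id, ": ", rec[[f]],
           call. = FALSE)
    }
  }
  img <- png::readPNG(rec$image_path)
  if (length(dim(img)) == 3) img <- luma(img)
  list(image = img, landmarks = read_landmarks(rec$landmarks_path),
       mask = read_mask(rec$mask_path))
}

#' Run the full screening pipeline on a cohort
#'
#' Executes align -> crop -> (ground-truth or U-net) fat-pad masks ->
#' ROI-restricted HOG -> z-score standardization -> PCA -> RBF-SVM ->
#' evaluation. The standardizer, PCA basis and SVM are fitted on the
#' training split only; the held-out split yields confusion counts, the
#' four classification metrics, and per-attribute subgroup reports (age
#' group, gender, site).
#'
#' @param records cohort metadata data.frame as from [generate_cohort()]
#'   (columns sample_id, paths or in-memory objects, nrs_score, age_group,
#'   gender, site, split).
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for the JSON report and manifest.
#' @return list of class `nutriface_report`: confusion counts, metrics,
#'   subgroup reports, split sizes, and (when segmentation was trained)
#'   validation Dice summary.
#' @export
run_pipeline <- function(records, config = pipeline_config(),
                         out_dir = NULL) {
  objects <- attr(records, "objects")
  n <- nrow(records)
  size <- config$crop_size

  pre <- vector("list", n)
  for (i in seq_len(n)) {
    s <- load_sample(records[i, ], objects, i)
    pre[[i]] <- tryCatch(
      preprocess_sample(s$image, s$landmarks, s$mask, size = size),
      error = function(e) stop("stage align/crop failed for sample ",
                               records$sample_id[i], ": ", conditionMessage(e),
                               call. = FALSE))
  }

  is_train <- records$split == "train"
  seg_summary <- NULL
  if (config$use_true_masks) {
    masks <- lapply(pre, `[[`, "mask")
  } else {
    model <- config$seg_model
    if (is.null(model)) {
      cfg <- config$seg
      cfg$image_size <- size
      cfg$seed <- derive_seed(config$seed, 11L)
      train_pairs <- lapply(which(is_train), function(i)
        list(face = pre[[i]]$face, mask = pre[[i]]$mask))
      model <- train_seg(train_pairs, cfg)
    }
    masks <- lapply(pre, function(p) predict_mask(model, p$face))
    dvals <- vapply(which(!is_train), function(i)
      dice(masks[[i]], pre[[i]]$mask), numeric(1))
    seg_summary <- list(test_dice_mean = mean(dvals))
  }

  feats <- t(vapply(seq_len(n), function(i) {
    hog_features(apply_mask(pre[[i]]$face, masks[[i]]), config$hog)
  }, numeric(hog_length(size, size, config$hog))))

  labels <- nrs_class(records$nrs_score)
  st <- fit_standardizer(feats[is_train, , drop = FALSE])
  ztr <- standardize(st, feats[is_train, , drop = FALSE])
  zte <- standardize(st, feats[!is_train, , drop = FALSE])
  k <- min(config$pca_k, nrow(ztr), ncol(ztr))
  pca <- fit_pca(ztr, k = k)
  xtr <- pca_reduce(pca, ztr)
  xte <- pca_reduce(pca, zte)
  svm_cfg <- config$svm
  svm_cfg$seed <- derive_seed(config$seed, 21L)
  model_svm <- train_svm(xtr, labels[is_train], svm_cfg)
  pred <- predict(model_svm, xte)

  cc <- confusion(labels[!is_train], pred)
  metrics <- classification_metrics(cc)
  test_records <- records[!is_train, , drop = FALSE]
  subgroups <- lapply(c("age_group", "gender", "site"), function(a) {
    tryCatch(subgroup_report(test_records, pred, a),
             warning = function(w) suppressWarnings(
               subgroup_report(test_records, pred, a)))
  })
  names(subgroups) <- c("age_group", "gender", "site")

  report <- structure(list(
    n = n, n_train = sum(is_train), n_test = sum(!is_train),
    pca_k = k, confusion = cc, metrics = metrics,
    segmentation = seg_summary, subgroups = subgroups,
    seed = config$seed
  ), class = "nutriface_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    rp <- file.path(out_dir, "report.json")
    jsonlite::write_json(unclass(report), rp, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
    files <- rp
    manifest <- data.frame(file = basename(files),
                           md5 = unname(tools::md5sum(files)),
                           stringsAsFactors = FALSE)
    write.csv(manifest, file.path(out_dir, "manifest.csv"),
              row.names = FALSE)
  }
  report
}

#' @export
print.nutriface_report <- function(x, ...) {
  cat(sprintf("nutriface run: %d samples (%d train / %d test), PCA k = %d\n",
              x$n, x$n_train, x$n_test, x$pca_k))
  with(x$confusion, cat(sprintf(
    "confusion: TP=%d TN=%d FP=%d FN=%d\n", TP, TN, FP, FN)))
  m <- x$metrics
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f%%", 100 * v)
  cat(sprintf("accuracy %s | precision %s | recall %s | F1 %s\n",
              fmt(m$accuracy), fmt(m$precision), fmt(m$recall), fmt(m$f1)))
  if (!is.null(x$segmentation)) {
    cat(sprintf("segmentation test Dice: %.3f\n",
                x$segmentation$test_dice_mean))
  }
  for (sg in x$subgroups) {
    cat(sprintf("subgroup %s (p = %s):\n", sg$attribute,
                ifelse(is.na(sg$p_value), "NA", sprintf("%.3f", sg$p_value))))
    print(format_subgroup_report(sg), row.names = FALSE)
  }
  invisible(x)
}
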