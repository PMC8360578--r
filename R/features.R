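#' Assemble a labeled mask dataset
#'
#' @param masks List of 64 x 64 logical masks (e.g. from
#'   [normalize_series()] or [normalize_shapes()]).
#' @param class Character/factor vector of class labels, one per mask.
#' @param series Optional series identifier per mask (used for
#'   per-timeseries averaging downstream); defaults to the class label.
#' @return A tibble with columns `mask` (list), `class` (factor), `series`.
#' @export
labeled_masks <- function(masks, class, series = NULL) {
  stopifnot(length(masks) == length(class))
  if (is.null(series)) series <- as.character(class)
  tibble::tibble(mask = masks, class = factor(class),
                 series = as.character(series))
}

#' Rotation-augment a dataset to equal class sizes
#'
#' Pads every class to `target_count` masks by adding copies rotated by
#' angles drawn uniformly from `(-max_angle, +max_angle)` degrees
#' (seeded, deterministic). With `max_angle = 0` the copies are identical
#' to their originals.
#'
#' @param data A tibble from [labeled_masks()].
#' @param max_angle Maximum rotation (degrees), default 5.
#' @param target_count Per-class size after augmentation; defaults to the
#'   largest class.
#' @param seed Integer seed.
#' @return The augmented tibble (original rows first, then copies, with a
#'   logical `augmented` column).
#' @export
augment_dataset <- function(data, max_angle = 5, target_count = NULL,
                            seed = 1L) {
  counts <- table(data$class)
  if (any(counts == 0)) stop("empty class in dataset")
  if (is.null(target_count)) target_count <- max(counts)
  if (target_count < max(counts)) {
    stop("target_count must be >= the largest class size")
  }
  set.seed(seed)
  data$augmented <- FALSE
  extra <- list()
  for (cl in names(counts)) {
    need <- target_count - counts[[cl]]
    if (need == 0) next
    src <- which(data$class == cl)
    pick <- src[(seq_len(need) - 1L) %% length(src) + 1L]
    angles <- stats::runif(need, -max_angle, max_angle) * pi / 180
    rows <- data[pick, ]
    rows$mask <- lapply(seq_len(need), function(i) {
      m <- rows$mask[[i]]
      if (angles[i] == 0) m else
        affine_mask(m, angle = angles[i], scale = 1, out_dim = nrow(m),
                    center = c((nrow(m) - 1) / 2, (ncol(m) - 1) / 2))
    })
    rows$augmented <- TRUE
    extra[[cl]] <- rows
  }
  dplyr::bind_rows(c(list(data), unname(extra)))
}

#' Classifier configuration
#'
#' The frozen reference architecture: 64 x 64 x 1 input, conv(16, 3x3,
#' relu), max-pool 3x3, conv(32, 3x3, relu), max-pool 3x3, dense(256, relu)
#' whose activations are the 256-dim intermediate features, dense(32, tanh),
#' dense(n_classes, linear) whose pre-softmax activations are the feature
#' vector F, then softmax. Optimizer is Adam.
#'
#' @param n_classes Number of classes (3 for the reference task).
#' @param epochs Training epochs (reference default 2000; desk-scale runs
#'   use far fewer).
#' @param lr Learning rate. @param batch_size Mini-batch size.
#' @param conv_filters,kernel,pool,dense Architecture knobs.
#' @param val_frac Validation fraction for the train/validation split.
#' @param seed Integer seed controlling initialization, split and shuffling.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(n_classes = 3L, epochs = 2000L, lr = 1e-4,
                              batch_size = 64L, conv_filters = c(16L, 32L),
                              kernel = 3L, pool = 3L, dense = c(256L, 32L),
                              val_frac = 0.25, seed = 1L) {
  stopifnot(n_classes >= 2, epochs >= 1, lr > 0, batch_size >= 1,
            length(conv_filters) == 2, length(dense) == 2,
            pool == 3L, val_frac > 0, val_frac < 1)
  structure(list(n_classes = as.integer(n_classes),
                 epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size),
                 conv_filters = as.integer(conv_filters),
                 kernel = as.integer(kernel), pool = as.integer(pool),
                 dense = as.integer(dense), input_dim = 64L,
                 val_frac = val_frac, seed = as.integer(seed)),
            class = "classifier_config")
}

as_mask_tensor <- function(masks) {
  d <- dim(masks[[1]])
  if (!all(d == 64L)) stop("classifier inputs must be 64 x 64 masks")
  X <- array(0, c(64L, 64L, 1L, length(masks)))
  for (i in seq_along(masks)) X[, , 1L, i] <- masks[[i]] * 1.0
  X
}

#' Train the convolutional shape classifier
#'
#' Splits the dataset into train/validation (stratified by class, seeded),
#' then trains the reference architecture with softmax cross-entropy and
#' Adam. Per-epoch train/validation accuracy and loss are recorded; the
#' summary reports the mean over the last 10 epochs. Fully deterministic
#' for a fixed seed.
#'
#' @param data A tibble from [labeled_masks()] (>= 2 classes, 64x64 masks).
#' @param config A [classifier_config()]; its `n_classes` must match.
#' @return An object of class `shape_classifier` with elements `params`,
#'   `classes`, `config`, `history` (tibble epoch/loss/accuracy/val_...).
#' @export
train_shape_classifier <- function(data, config = classifier_config()) {
  classes <- levels(droplevels(factor(data$class)))
  if (length(classes) < 2) stop("training needs at least 2 classes")
  if (length(classes) != config$n_classes) {
    stop("config$n_classes = ", config$n_classes, " but data has ",
         length(classes), " classes")
  }
  set.seed(config$seed)
  y <- as.integer(factor(data$class, levels = classes))
  # stratified split
  val_idx <- unlist(lapply(seq_along(classes), function(k) {
    idx <- which(y == k)
    sample(idx, max(1L, round(length(idx) * config$val_frac)))
  }))
  tr_idx <- setdiff(seq_along(y), val_idx)

  Xtr <- as_mask_tensor(data$mask[tr_idx]); ytr <- y[tr_idx]
  Xva <- as_mask_tensor(data$mask[val_idx]); yva <- y[val_idx]
  ntr <- length(ytr)
  onehot <- function(yy) {
    o <- matrix(0, length(yy), config$n_classes)
    o[cbind(seq_along(yy), yy)] <- 1
    o
  }
  par <- cnn_init_params(config)
  layouts <- new.env(parent = emptyenv())
  layout_for <- function(n) {
    key <- as.character(n)
    if (is.null(layouts[[key]])) layouts[[key]] <- cnn_layout(n, config)
    layouts[[key]]
  }
  st <- adam_state(lapply(par, function(p) dim(p) %||% length(p)))
  t_adam <- 0L
  hist <- vector("list", config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample(ntr)
    ep_loss <- 0; ep_hits <- 0
    for (b0 in seq(1L, ntr, by = config$batch_size)) {
      bi <- ord[b0:min(b0 + config$batch_size - 1L, ntr)]
      fwd <- cnn_forward(par, Xtr[, , , bi, drop = FALSE], config,
                         layout_for(length(bi)))
      yb <- onehot(ytr[bi])
      p_true <- rowSums(fwd$probs * yb)
      ep_loss <- ep_loss - sum(log(pmax(p_true, 1e-12)))
      ep_hits <- ep_hits + sum(max.col(fwd$probs) == ytr[bi])
      g <- cnn_backward(par, fwd, yb, config, layout_for(length(bi)))
      t_adam <- t_adam + 1L
      upd <- adam_update(par, g, st, config$lr, t_adam)
      par <- upd$par; st <- upd$st
    }
    va <- cnn_forward(par, Xva, config, layout_for(length(yva)),
                      keep_cache = FALSE)
    va_p <- rowSums(va$probs * onehot(yva))
    hist[[ep]] <- tibble::tibble(
      epoch = ep, loss = ep_loss / ntr, accuracy = ep_hits / ntr,
      val_loss = -mean(log(pmax(va_p, 1e-12))),
      val_accuracy = mean(max.col(va$probs) == yva))
  }
  structure(list(params = par, classes = classes, config = config,
                 history = dplyr::bind_rows(hist),
                 n_train = ntr, n_val = length(yva)),
            class = "shape_classifier")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.shape_classifier <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<shape_classifier> %d classes (%s); %d epochs\n",
    length(x$classes), paste(x$classes, collapse = ", "),
    nrow(x$history)))
  cat(sprintf("  last-10-epoch mean accuracy: train %.3f, validation %.3f\n",
              g$accuracy_last10, g$val_accuracy_last10))
  invisible(x)
}

#' @method tidy shape_classifier
#' @export
tidy.shape_classifier <- function(x, ...) x$history

#' @method glance shape_classifier
#' @export
glance.shape_classifier <- function(x, ...) {
  h <- utils::tail(x$history, 10)
  tibble::tibble(
    epochs = nrow(x$history), n_train = x$n_train, n_val = x$n_val,
    accuracy_last10 = mean(h$accuracy),
    val_accuracy_last10 = mean(h$val_accuracy),
    loss_final = x$history$loss[nrow(x$history)],
    val_loss_final = x$history$val_loss[nrow(x$history)])
}

#' Extract feature vectors from masks
#'
#' Runs masks through a trained classifier and returns either the 3-node
#' pre-softmax feature vector F (`layer = "feature3"`, columns `F1..Fk`) or
#' the 256-dim intermediate dense activations (`layer = "intermediate256"`,
#' columns `X1..X256`), together with softmax class probabilities and the
#' argmax predicted class.
#'
#' @param classifier A trained `shape_classifier`.
#' @param masks List of 64 x 64 masks, a `normalized_series`, or a tibble
#'   with a `mask` list-column (extra columns are carried through).
#' @param layer `"feature3"` or `"intermediate256"`.
#' @return A tibble, one row per mask.
#' @export
extract_features <- function(classifier, masks,
                             layer = c("feature3", "intermediate256")) {
  stopifnot(inherits(classifier, "shape_classifier"))
  layer <- match.arg(layer)
  carry <- NULL
  if (inherits(masks, "normalized_series")) {
    masks <- masks$masks
  } else if (is.data.frame(masks)) {
    carry <- dplyr::select(masks, -"mask")
    masks <- masks$mask
  }
  X <- as_mask_tensor(masks)
  cfg <- classifier$config
  fwd <- cnn_forward(classifier$params, X, cfg,
                     cnn_layout(dim(X)[4], cfg), keep_cache = FALSE)
  feats <- if (layer == "feature3") {
    f <- as.data.frame(fwd$F)
    names(f) <- paste0("F", seq_len(ncol(f)))
    f
  } else {
    f <- as.data.frame(fwd$intermediate)
    names(f) <- paste0("X", seq_len(ncol(f)))
    f
  }
  probs <- as.data.frame(fwd$probs)
  names(probs) <- paste0("p_", classifier$classes)
  out <- tibble::as_tibble(cbind(feats, probs))
  out$predicted <- factor(classifier$classes[max.col(fwd$probs)],
                          levels = classifier$classes)
  if (!is.null(carry) && ncol(carry)) out <- dplyr::bind_cols(carry, out)
  out
}

#' Principal-component shape space
#'
#' PCA (centered, unscaled) of per-timeseries time-averaged feature
#' vectors. The fitted object projects any feature table into (PC1, PC2).
#'
#' @param mean_features A tibble whose numeric `F*` columns hold one
#'   time-averaged feature vector per timeseries (>= 3 rows).
#' @return An object of class `shape_pca` with `rotation` (orthonormal
#'   loadings), `center`, `latencies` (explained-variance fractions).
#' @export
fit_shape_pca <- function(mean_features) {
  fm <- as.matrix(dplyr::select(mean_features, dplyr::matches("^F\\d+$")))
  if (nrow(fm) < 3) stop("PCA needs at least 3 feature vectors")
  if (all(apply(fm, 2, stats::var) < 1e-15)) stop("zero-variance features")
  pc <- stats::prcomp(fm, center = TRUE, scale. = FALSE)
  lat <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(rotation = pc$rotation, center = pc$center,
                 latencies = lat, n = nrow(fm)),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  cat("<shape_pca> latencies:",
      paste(sprintf("%.1f%%", 100 * x$latencies), collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy shape_pca
#' @export
tidy.shape_pca <- function(x, ...) {
  r <- x$rotation
  tibble::as_tibble(r, rownames = "feature")
}

#' @method glance shape_pca
#' @export
glance.shape_pca <- function(x, ...) {
  out <- as.list(x$latencies)
  names(out) <- paste0("latency_PC", seq_along(out))
  tibble::as_tibble(out)
}

#' Project feature vectors into the PCA shape space
#'
#' @param pca A `shape_pca`.
#' @param features A tibble with the same `F*` columns the PCA was fitted
#'   on.
#' @param n_components Number of PCs appended (default 2).
#' @return `features` with `PC1`, `PC2`, ... columns appended.
#' @export
project_features <- function(pca, features, n_components = 2L) {
  fm <- as.matrix(dplyr::select(features, dplyr::matches("^F\\d+$")))
  sc <- sweep(fm, 2, pca$center) %*% pca$rotation[, seq_len(n_components),
                                                  drop = FALSE]
  for (j in seq_len(n_components)) {
    features[[paste0("PC", j)]] <- sc[, j]
  }
  features
}

#' Hand-crafted shape features
#'
#' For an aligned (normalized) mask: `h1` is the vertical extent (along the
#' front-tail axis) over the equivalent-circle diameter, `h2` the
#' horizontal extent over the equivalent-circle diameter, and `h3` the
#' circularity `4 pi A / P^2` with `P` the traced contour perimeter.
#'
#' @param mask A 64 x 64 (or any) binary mask, foreground aligned.
#' @return A tibble with `h1`, `h2`, `h3`.
#' @export
handcrafted_features <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask")
  a <- nrow(idx)
  deq <- 2 * sqrt(a / pi)
  # 16 harmonics suppress pixelation of the traced outline; at the 25-px
  # working scale this keeps a disk's circularity near 1 while rounding
  # polygon corners by only a few percent
  ct <- extract_contour(mask, n_points = 256L, harmonics = 16L)
  tibble::tibble(
    h1 = (max(idx[, 1]) - min(idx[, 1]) + 1) / deq,
    h2 = (max(idx[, 2]) - min(idx[, 2]) + 1) / deq,
    h3 = min(1, 4 * pi * a / ct$perimeter^2))
}
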