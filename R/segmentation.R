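#' Segmentation training configuration
#'
#' Defaults follow the reference training recipe (512 x 512 x 3 inputs, 100
#' epochs, learning rate 1e-5); toy-scale experiments on phantoms override
#' `input_size`, `epochs`, `learning_rate`, `depth` and `base_channels`. The
#' three input channels are the axial slice and its superior and inferior
#' neighbors, integrating information across adjacent image layers.
#'
#' @param input_size `(H, W, C)`; C must be 3.
#' @param epochs Training epochs (>= 1).
#' @param learning_rate Adam learning rate (> 0).
#' @param num_classes Output classes including background (default 6:
#'   background + LV, RV, PA, AA, lung).
#' @param loss `"cross_entropy"`, `"dice"` or `"combined"`.
#' @param batch_size Gradient-accumulation batch size.
#' @param depth Number of resolution levels (2x2 pools).
#' @param base_channels Channels at the first level (doubling per level).
#' @param seed Seed for weight initialization and epoch shuffling.
#' @param checkpoint_dir Optional directory; when set, [seg_train()] writes
#'   the best checkpoint there.
#' @return A list of class `seg_train_config`.
#' @export
seg_train_config <- function(input_size = c(512L, 512L, 3L), epochs = 100L,
                             learning_rate = 1e-5, num_classes = 6L,
                             loss = c("cross_entropy", "dice", "combined"),
                             batch_size = 4L, depth = 4L, base_channels = 32L,
                             seed = 1L, checkpoint_dir = NULL) {
  loss <- match.arg(loss)
  input_size <- as.integer(input_size)
  if (length(input_size) != 3L || input_size[3] != 3L)
    abort_ctpa("input_size must be (H, W, 3)", "ctpa_value_error")
  if (epochs < 1L) abort_ctpa("epochs must be >= 1", "ctpa_value_error")
  if (learning_rate <= 0) abort_ctpa("learning_rate must be > 0", "ctpa_value_error")
  structure(list(input_size = input_size, epochs = as.integer(epochs),
                 learning_rate = learning_rate, num_classes = as.integer(num_classes),
                 loss = loss, batch_size = as.integer(batch_size),
                 depth = as.integer(depth), base_channels = as.integer(base_channels),
                 seed = as.integer(seed), checkpoint_dir = checkpoint_dir),
            class = "seg_train_config")
}

resize_nearest <- function(mat, H, W) {
  if (nrow(mat) == H && ncol(mat) == W) return(mat)
  ri <- pmin(pmax(ceiling(seq_len(H) / H * nrow(mat)), 1L), nrow(mat))
  ci <- pmin(pmax(ceiling(seq_len(W) / W * ncol(mat)), 1L), ncol(mat))
  mat[ri, ci, drop = FALSE]
}

# Per-volume intensity standardization applied identically at train and
# predict time.
standardize_ct <- function(img) (img - mean(img)) / max(stats::sd(img), 1e-8)

#' Build per-slice training pairs from a CT volume and its labels
#'
#' Each axial slice becomes one training pair: a 3-channel image holding the
#' previous, current and next slice (edge slices replicate the center slice)
#' and the center slice's label map. Images are standardized per volume and
#' resized (nearest-neighbor) to the configured input size; labels are
#' resized nearest-neighbor so no new codes appear.
#'
#' @param ct A `ct_volume` from [render_pseudo_ct()] (or any list with an
#'   `image` (z, y, x) array).
#' @param labels A [labeled_volume()] congruent with `ct`.
#' @param input_size `(H, W, 3)` target size (default: native slice size).
#' @return List of `list(x = H x W x 3 array, y = H x W integer matrix)`.
#' @export
make_training_slices <- function(ct, labels, input_size = NULL) {
  img <- ct$image
  if (!identical(dim(img), dim(labels$labels)))
    abort_ctpa("CT volume and label volume have different shapes", "ctpa_value_error")
  nz <- dim(img)[1]
  H <- if (is.null(input_size)) dim(img)[2] else input_size[1]
  W <- if (is.null(input_size)) dim(img)[3] else input_size[2]
  img <- standardize_ct(img)
  lapply(seq_len(nz), function(z) {
    zs <- pmin(pmax(c(z - 1L, z, z + 1L), 1L), nz)
    x <- array(0, c(H, W, 3L))
    for (c in 1:3) x[, , c] <- resize_nearest(img[zs[c], , ], H, W)
    list(x = x, y = resize_nearest(labels$labels[z, , ], H, W))
  })
}

#' Train a U-Net on slice pairs
#'
#' Adam optimization of the configured loss with gradient accumulation over
#' `batch_size` slices. After each epoch the validation loss is evaluated;
#' the returned model carries the weights of the epoch with minimal
#' validation loss (the "optimal checkpoint"). Training aborts with a
#' diagnostic if the loss becomes non-finite. Reproducible from the config
#' seed.
#'
#' @param model A [build_unet()] model.
#' @param train_pairs,val_pairs Non-empty lists from
#'   [make_training_slices()].
#' @param config The [seg_train_config()].
#' @return List of class `seg_fit`: `model` (best weights), `history`
#'   (data frame epoch / train_loss / val_loss), `best_epoch`, and
#'   `checkpoint` (RDS path or `NULL`).
#' @export
seg_train <- function(model, train_pairs, val_pairs, config) {
  if (length(train_pairs) < 1L || length(val_pairs) < 1L)
    abort_ctpa("need at least one training and one validation pair", "ctpa_value_error")
  params <- model$params
  state <- adam_init(params)
  eval_loss <- function(prm, pairs) {
    m <- model; m$params <- prm
    mean(vapply(pairs, function(pr) {
      fw <- unet_forward(m, pr$x, train = FALSE)
      seg_loss(fw$logits, pr$y, config$loss)$loss
    }, numeric(1)))
  }
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best <- list(loss = Inf, params = params, epoch = 0L)
  orders <- with_seed(config$seed + 1L,
    lapply(seq_len(config$epochs), function(e) sample.int(length(train_pairs))))
  for (epoch in seq_len(config$epochs)) {
    ord <- orders[[epoch]]
    ep_loss <- 0
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    for (bt in batches) {
      acc <- NULL
      bl <- 0
      m <- model; m$params <- params
      for (j in bt) {
        pr <- train_pairs[[j]]
        fw <- unet_forward(m, pr$x, train = TRUE)
        ls <- seg_loss(fw$logits, pr$y, config$loss)
        if (!is.finite(ls$loss))
          abort_ctpa(sprintf("non-finite loss at epoch %d: check learning rate",
                             epoch), "seg_train_error")
        bl <- bl + ls$loss
        g <- unet_backward(m, fw$cache, ls$dlogits)
        acc <- if (is.null(acc)) g else
          Map(`+`, acc, g)
      }
      acc <- lapply(acc, function(g) g / length(bt))
      upd <- adam_step(params, acc, state, config$learning_rate)
      params <- upd$params; state <- upd$state
      ep_loss <- ep_loss + bl
    }
    vl <- eval_loss(params, val_pairs)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = ep_loss / length(train_pairs), val_loss = vl))
    if (vl < best$loss) best <- list(loss = vl, params = params, epoch = epoch)
  }
  model$params <- best$params
  ckpt <- NULL
  if (!is.null(config$checkpoint_dir)) {
    dir.create(config$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
    ckpt <- file.path(config$checkpoint_dir, "unet_best.rds")
    saveRDS(list(model = model, config = config, best_epoch = best$epoch), ckpt)
  }
  structure(list(model = model, history = history, best_epoch = best$epoch,
                 checkpoint = ckpt), class = "seg_fit")
}

#' Predict a labeled volume from a CT volume
#'
#' Runs the network slice by slice (same 3-neighbor channel construction and
#' standardization as training), takes the per-pixel argmax class, resizes
#' back to the native slice size, and reassembles a [labeled_volume()] with
#' the input's spacing. Deterministic for a fixed model.
#'
#' @param model A trained `unet_model` (e.g. `fit$model` from [seg_train()]).
#' @param ct A `ct_volume`.
#' @param label_map Label map attached to the output volume.
#' @return A [labeled_volume()].
#' @export
seg_predict <- function(model, ct, label_map = canonical_label_map()) {
  d <- dim(ct$image)
  H <- model$input_size[1]; W <- model$input_size[2]
  img <- standardize_ct(ct$image)
  labels <- array(0L, dim = d)
  for (z in seq_len(d[1])) {
    zs <- pmin(pmax(c(z - 1L, z, z + 1L), 1L), d[1])
    x <- array(0, c(H, W, 3L))
    for (c in 1:3) x[, , c] <- resize_nearest(img[zs[c], , ], H, W)
    logits <- unet_forward(model, x)$logits
    cls <- matrix(max.col(matrix(logits, H * W, dim(logits)[3]),
                          ties.method = "first") - 1L, H, W)
    labels[z, , ] <- resize_nearest(cls, d[2], d[3])
  }
  labeled_volume(labels, ct$spacing, label_map)
}

#' Per-structure Dice between a predicted and a reference labeled volume
#'
#' @param pred,ref [labeled_volume()]s with the same label map and shape.
#' @param structures Structure names to score (default: all in the map).
#' @return Named numeric vector of Dice coefficients (NA where a structure is
#'   empty in both volumes).
#' @export
dice_per_structure <- function(pred, ref, structures = names(ref$label_map)) {
  vapply(structures, function(nm) {
    code <- structure_code(ref, nm)
    x <- pred$labels == code
    y <- ref$labels == code
    if (!any(x) && !any(y)) return(NA_real_)
    dice(x, y)
  }, numeric(1))
}
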