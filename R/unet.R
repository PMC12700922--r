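# A small, dependency-free U-Net: encoder/decoder with skip connections at
# every resolution level, 3x3 convolutions via im2col + BLAS matrix products,
# hand-written backpropagation and Adam. Feature maps are (H, W, C) arrays;
# one image per forward pass (batching = gradient accumulation).

im2col3 <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  pad <- array(0, c(H + 2L, W + 2L, C))
  pad[2:(H + 1L), 2:(W + 1L), ] <- x
  cols <- matrix(0, H * W, 9L * C)
  k <- 0L
  for (ox in 0:2) for (oy in 0:2) {
    cols[, k * C + seq_len(C)] <-
      matrix(pad[(1L + oy):(H + oy), (1L + ox):(W + ox), , drop = FALSE], H * W, C)
    k <- k + 1L
  }
  cols
}

col2im3 <- function(cols, H, W, C) {
  pad <- array(0, c(H + 2L, W + 2L, C))
  k <- 0L
  for (ox in 0:2) for (oy in 0:2) {
    ys <- (1L + oy):(H + oy); xs <- (1L + ox):(W + ox)
    pad[ys, xs, ] <- pad[ys, xs, ] +
      array(cols[, k * C + seq_len(C)], c(H, W, C))
    k <- k + 1L
  }
  pad[2:(H + 1L), 2:(W + 1L), , drop = FALSE]
}

# 2x2 max pool with deterministic tie-breaking (fixed candidate order).
maxpool2_fwd <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  oi <- seq(1L, H, 2L); ei <- seq(2L, H, 2L)
  oj <- seq(1L, W, 2L); ej <- seq(2L, W, 2L)
  cand <- list(x[oi, oj, , drop = FALSE], x[ei, oj, , drop = FALSE],
               x[oi, ej, , drop = FALSE], x[ei, ej, , drop = FALSE])
  m <- pmax(cand[[1]], cand[[2]], cand[[3]], cand[[4]])
  arg <- 1L * (cand[[1]] == m)
  arg[arg == 0 & cand[[2]] == m] <- 2L
  arg[arg == 0 & cand[[3]] == m] <- 3L
  arg[arg == 0] <- 4L
  list(out = m, arg = arg, dim_in = d)
}

maxpool2_bwd <- function(cache, dout) {
  d <- cache$dim_in
  dx <- array(0, d)
  oi <- seq(1L, d[1], 2L); ei <- seq(2L, d[1], 2L)
  oj <- seq(1L, d[2], 2L); ej <- seq(2L, d[2], 2L)
  sel <- function(k) dout * (cache$arg == k)
  dx[oi, oj, ] <- sel(1L); dx[ei, oj, ] <- dx[ei, oj, ] + sel(2L)
  dx[oi, ej, ] <- dx[oi, ej, ] + sel(3L); dx[ei, ej, ] <- dx[ei, ej, ] + sel(4L)
  dx
}

upsample2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , drop = FALSE]
}

upsample2_bwd <- function(dout) {
  d <- dim(dout)
  oi <- seq(1L, d[1], 2L); ei <- seq(2L, d[1], 2L)
  oj <- seq(1L, d[2], 2L); ej <- seq(2L, d[2], 2L)
  dout[oi, oj, , drop = FALSE] + dout[ei, oj, , drop = FALSE] +
    dout[oi, ej, , drop = FALSE] + dout[ei, ej, , drop = FALSE]
}

unet_layer_names <- function(depth) {
  nms <- character(0)
  for (i in seq_len(depth)) nms <- c(nms, sprintf("enc%d_1", i), sprintf("enc%d_2", i))
  nms <- c(nms, "mid_1", "mid_2")
  for (i in rev(seq_len(depth)))
    nms <- c(nms, sprintf("up%d", i), sprintf("dec%d_1", i), sprintf("dec%d_2", i))
  c(nms, "head")
}

#' Build a U-Net model
#'
#' Constructs the encoder-decoder segmentation network: `depth` resolution
#' levels of two 3x3 convolution + ReLU blocks with 2x2 max pooling on the
#' way down, a two-convolution bottleneck, nearest-neighbor upsampling with a
#' channel-halving convolution and a skip-connection concatenation at each
#' level on the way up, and a final 1x1 convolution producing per-pixel class
#' scores. Weights use seeded He-normal initialization.
#'
#' @param config A [seg_train_config()].
#' @return A `unet_model`: list of parameter arrays plus architecture
#'   metadata.
#' @export
build_unet <- function(config) {
  H <- config$input_size[1]; W <- config$input_size[2]; Cin <- config$input_size[3]
  depth <- config$depth
  if (H %% 2^depth != 0L || W %% 2^depth != 0L)
    abort_ctpa(sprintf("input size %dx%d not divisible by 2^depth = %d",
                       H, W, 2^depth), "ctpa_value_error")
  base <- config$base_channels
  feats <- base * 2^(0:depth)
  params <- list()
  he_conv <- function(cin, cout, k = 3L)
    list(W = matrix(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
                    k * k * cin, cout),
         b = numeric(cout))
  with_seed(config$seed, {
    add <- function(nm, cin, cout, k = 3L) {
      p <- he_conv(cin, cout, k)
      params[[paste0(nm, "_W")]] <<- p$W
      params[[paste0(nm, "_b")]] <<- p$b
    }
    cin <- Cin
    for (i in seq_len(depth)) {
      add(sprintf("enc%d_1", i), cin, feats[i])
      add(sprintf("enc%d_2", i), feats[i], feats[i])
      cin <- feats[i]
    }
    add("mid_1", feats[depth], feats[depth + 1])
    add("mid_2", feats[depth + 1], feats[depth + 1])
    for (i in rev(seq_len(depth))) {
      above <- if (i == depth) feats[depth + 1] else feats[i + 1]
      add(sprintf("up%d", i), above, feats[i])
      add(sprintf("dec%d_1", i), 2L * feats[i], feats[i])
      add(sprintf("dec%d_2", i), feats[i], feats[i])
    }
    add("head", feats[1], config$num_classes, k = 1L)
  })
  structure(list(params = params, depth = depth, input_size = config$input_size,
                 num_classes = config$num_classes, base_channels = base),
            class = "unet_model")
}

# Forward pass; when train = TRUE caches everything backward needs.
unet_forward <- function(model, x, train = FALSE) {
  p <- model$params
  cache <- if (train) new.env(parent = emptyenv())
  conv3 <- function(h, nm) {
    d <- dim(h)
    Xcol <- im2col3(h)
    out <- sweep(Xcol %*% p[[paste0(nm, "_W")]], 2, p[[paste0(nm, "_b")]], "+")
    if (train) assign(nm, list(Xcol = Xcol, d = d), envir = cache)
    array(out, c(d[1], d[2], length(p[[paste0(nm, "_b")]])))
  }
  relu <- function(h, nm) {
    if (train) assign(paste0(nm, ".relu"), h > 0, envir = cache)
    h * (h > 0)
  }
  block <- function(h, nm) relu(conv3(h, nm), nm)
  skips <- vector("list", model$depth)
  h <- x
  for (i in seq_len(model$depth)) {
    h <- block(h, sprintf("enc%d_1", i))
    h <- block(h, sprintf("enc%d_2", i))
    skips[[i]] <- h
    pool <- maxpool2_fwd(h)
    if (train) assign(sprintf("pool%d", i), pool[c("arg", "dim_in")], envir = cache)
    h <- pool$out
  }
  h <- block(h, "mid_1")
  h <- block(h, "mid_2")
  for (i in rev(seq_len(model$depth))) {
    h <- upsample2_fwd(h)
    h <- block(h, sprintf("up%d", i))
    nc_skip <- dim(skips[[i]])[3]
    h <- array(c(skips[[i]], h), c(dim(h)[1], dim(h)[2], nc_skip + dim(h)[3]))
    if (train) assign(sprintf("cat%d", i), nc_skip, envir = cache)
    h <- block(h, sprintf("dec%d_1", i))
    h <- block(h, sprintf("dec%d_2", i))
  }
  d <- dim(h)
  hm <- matrix(h, d[1] * d[2], d[3])
  if (train) assign("head", list(X = hm, d = d), envir = cache)
  logits <- sweep(hm %*% p$head_W, 2, p$head_b, "+")
  list(logits = array(logits, c(d[1], d[2], model$num_classes)), cache = cache)
}

# Backward pass: returns gradients named like the parameters.
unet_backward <- function(model, cache, dlogits) {
  p <- model$params
  grads <- list()
  dconv3_in <- function(dout, nm) {
    cc <- get(nm, envir = cache)
    dmat <- matrix(dout, prod(dim(dout)[1:2]), dim(dout)[3])
    grads[[paste0(nm, "_W")]] <<- crossprod(cc$Xcol, dmat)
    grads[[paste0(nm, "_b")]] <<- colSums(dmat)
    col2im3(dmat %*% t(p[[paste0(nm, "_W")]]), cc$d[1], cc$d[2], cc$d[3])
  }
  dblock <- function(dout, nm) dconv3_in(dout * get(paste0(nm, ".relu"), envir = cache), nm)

  hd <- get("head", envir = cache)
  dmat <- matrix(dlogits, prod(dim(dlogits)[1:2]), dim(dlogits)[3])
  grads$head_W <- crossprod(hd$X, dmat)
  grads$head_b <- colSums(dmat)
  dh <- array(dmat %*% t(p$head_W), hd$d)
  dskips <- vector("list", model$depth)
  for (i in seq_len(model$depth)) {
    dh <- dblock(dh, sprintf("dec%d_2", i))
    dh <- dblock(dh, sprintf("dec%d_1", i))
    nc_skip <- get(sprintf("cat%d", i), envir = cache)
    dskips[[i]] <- dh[, , seq_len(nc_skip), drop = FALSE]
    dh <- dh[, , (nc_skip + 1L):dim(dh)[3], drop = FALSE]
    dh <- dblock(dh, sprintf("up%d", i))
    dh <- upsample2_bwd(dh)
  }
  dh <- dblock(dh, "mid_2")
  dh <- dblock(dh, "mid_1")
  for (i in rev(seq_len(model$depth))) {
    dh <- maxpool2_bwd(get(sprintf("pool%d", i), envir = cache), dh)
    dh <- dh + dskips[[i]]
    dh <- dblock(dh, sprintf("enc%d_2", i))
    dh <- dblock(dh, sprintf("enc%d_1", i))
  }
  grads
}

# Softmax cross-entropy over pixels; y holds integer classes 0..K-1.
# Returns loss and the gradient w.r.t. the logits. With loss = "dice" or
# "combined", adds a soft-Dice term averaged over classes present in y.
seg_loss <- function(logits, y, loss = "cross_entropy") {
  d <- dim(logits); n <- d[1] * d[2]; K <- d[3]
  lm <- matrix(logits, n, K)
  lm <- lm - apply(lm, 1, max)
  el <- exp(lm)
  prob <- el / rowSums(el)
  yi <- as.integer(y) + 1L
  onehot <- matrix(0, n, K)
  onehot[cbind(seq_len(n), yi)] <- 1
  ce <- -mean(log(pmax(prob[cbind(seq_len(n), yi)], 1e-12)))
  dce <- (prob - onehot) / n
  if (loss == "cross_entropy")
    return(list(loss = ce, dlogits = array(dce, d)))
  eps <- 1e-7
  present <- sort(unique(yi))
  inter <- colSums(prob * onehot)
  denom <- colSums(prob) + colSums(onehot)
  dice_k <- (2 * inter + eps) / (denom + eps)
  dice_loss <- 1 - mean(dice_k[present])
  # d(dice_k)/d(prob) then through the softmax Jacobian
  dprob <- matrix(0, n, K)
  for (k in present) {
    ddk <- (2 * onehot[, k] * (denom[k] + eps) - (2 * inter[k] + eps)) / (denom[k] + eps)^2
    dprob[, k] <- dprob[, k] - ddk / length(present)
  }
  dots <- rowSums(dprob * prob)
  ddice <- prob * (dprob - dots)
  if (loss == "dice")
    return(list(loss = dice_loss, dlogits = array(ddice, d)))
  list(loss = ce + dice_loss, dlogits = array(dce + ddice, d))
}

adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
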