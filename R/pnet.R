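#' Configuration for the dilated fully convolutional segmenter
#'
#' The network follows the P-Net design: 13 dilated 3x3 convolution
#' layers grouped into five blocks of (2, 2, 3, 3, 3) layers with
#' dilation rates (1, 2, 4, 8, 16), no spatial downsampling anywhere,
#' block outputs concatenated channel-wise and classified by two 1x1
#' layers with dropout between them.  Training minimizes a weighted
#' cross-entropy (background:foreground 1:10 by default) with ADAM at
#' learning rate 1e-4 for up to 20 epochs.
#'
#' @param channels feature channels per block (64 by default; smaller
#'   values give a reduced network that trains quickly on a CPU).
#' @param input_size side length images are resized to before
#'   segmentation (512 by default; 128 for the reduced test-scale
#'   configuration).
#' @param dropout_rate dropout probability between the two 1x1
#'   classifier layers, in `[0, 1)`.
#' @param class_weights length-2 vector `c(background, foreground)` of
#'   cross-entropy weights; both must be positive.
#' @param learning_rate ADAM learning rate.
#' @param max_epochs maximum training epochs.
#' @param batch_size images per ADAM step.
#' @param early_stop_rel stop when the relative epoch-loss improvement
#'   falls below this value (0 disables early stopping).
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout.
#' @return An object of class `"PNetConfig"`.
#' @export
pnet_config <- function(channels = 64, input_size = 512,
                        dropout_rate = 0.5,
                        class_weights = c(background = 1, foreground = 10),
                        learning_rate = 1e-4, max_epochs = 20,
                        batch_size = 2, early_stop_rel = 0, seed = 1) {
  stopifnot(
    "channels must be a positive integer" = channels >= 1,
    "input_size must be >= 32" = input_size >= 32,
    "dropout_rate must be in [0, 1)" =
      dropout_rate >= 0 && dropout_rate < 1,
    "class_weights must be two positive values" =
      length(class_weights) == 2 && all(class_weights > 0),
    "learning_rate must be > 0" = learning_rate > 0,
    "max_epochs must be >= 1" = max_epochs >= 1,
    "batch_size must be >= 1" = batch_size >= 1
  )
  structure(
    list(n_blocks = 5L,
         convs_per_block = c(2L, 2L, 3L, 3L, 3L),
         dilation_per_block = c(1L, 2L, 4L, 8L, 16L),
         kernel_size = 3L, n_classes = 2L,
         channels = as.integer(channels),
         input_size = as.integer(input_size),
         dropout_rate = dropout_rate,
         class_weights = c(background = class_weights[[1]],
                           foreground = class_weights[[2]]),
         learning_rate = learning_rate,
         max_epochs = as.integer(max_epochs),
         batch_size = as.integer(batch_size),
         early_stop_rel = early_stop_rel,
         seed = as.integer(seed)),
    class = "PNetConfig"
  )
}

# Per-conv-layer metadata: input channels, output channels, dilation.
pnet_layer_table <- function(config) {
  C <- config$channels
  layers <- data.frame(layer = integer(), block = integer(),
                       cin = integer(), cout = integer(),
                       dilation = integer())
  l <- 0L
  for (b in seq_len(config$n_blocks)) {
    for (k in seq_len(config$convs_per_block[b])) {
      l <- l + 1L
      layers <- rbind(layers, data.frame(
        layer = l, block = b,
        cin = if (l == 1L) 1L else C, cout = C,
        dilation = config$dilation_per_block[b]))
    }
  }
  stopifnot(nrow(layers) == 13L)  # 13 conv layers in 5 blocks
  layers
}

#' Build (initialize) the segmentation network
#'
#' Allocates He-initialized parameters for the architecture described in
#' [pnet_config()].  Initialization is a pure function of
#' `config$seed`.
#'
#' @param config a [pnet_config()].
#' @return An object of class `"pnet_model"`.
#' @export
build_pnet <- function(config) {
  stopifnot(inherits(config, "PNetConfig"))
  layers <- pnet_layer_table(config)
  C <- config$channels
  params <- withr::with_seed(config$seed, {
    p <- list()
    for (i in seq_len(nrow(layers))) {
      cin <- layers$cin[i]; cout <- layers$cout[i]
      p[[sprintf("conv%02d_W", i)]] <-
        matrix(rnorm(9 * cin * cout, sd = sqrt(2 / (9 * cin))),
               9 * cin, cout)
      p[[sprintf("conv%02d_b", i)]] <- numeric(cout)
    }
    p$fc1_W <- matrix(rnorm(5 * C * C, sd = sqrt(2 / (5 * C))), 5 * C, C)
    p$fc1_b <- numeric(C)
    p$fc2_W <- matrix(rnorm(C * 2, sd = sqrt(2 / C)), C, 2)
    p$fc2_b <- numeric(2)
    p
  })
  structure(list(config = config, layers = layers, params = params),
            class = "pnet_model")
}

#' Trainable parameter count
#' @param model a [build_pnet()] model.
#' @return Total number of trainable parameters.
#' @export
pnet_n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

# Forward pass on one standardized frame (H x W matrix).
# Returns per-pixel class scores ((H*W) x 2) and, when keep_cache, the
# activations needed for backprop.
pnet_forward <- function(model, x, dropout_mask = NULL,
                         keep_cache = FALSE) {
  p <- model$params; layers <- model$layers
  H <- nrow(x); W <- ncol(x); C <- model$config$channels
  a <- array(x, dim = c(H, W, 1))
  inputs <- if (keep_cache) vector("list", 13L) else NULL
  block_out <- vector("list", 5L)
  for (i in seq_len(13L)) {
    if (keep_cache) inputs[[i]] <- a
    a <- conv2d_fw(a, p[[sprintf("conv%02d_W", i)]],
                   p[[sprintf("conv%02d_b", i)]], layers$dilation[i],
                   relu = TRUE)
    if (i == max(layers$layer[layers$block == layers$block[i]]))
      block_out[[layers$block[i]]] <- a
  }
  Fm <- matrix(0, H * W, 5 * C)
  for (b in 1:5)
    Fm[, ((b - 1) * C + 1):(b * C)] <- matrix(block_out[[b]], H * W, C)
  h_pre <- sweep(Fm %*% p$fc1_W, 2, p$fc1_b, "+")
  h <- pmax(h_pre, 0)
  if (!is.null(dropout_mask)) h <- h * dropout_mask
  scores <- sweep(h %*% p$fc2_W, 2, p$fc2_b, "+")
  out <- list(scores = scores, dim = c(H, W))
  if (keep_cache)
    out$cache <- list(inputs = inputs, final = a, Fm = Fm, h_pre = h_pre,
                      h = h, dropout_mask = dropout_mask)
  out
}

# Stable per-pixel log-softmax probabilities for 2-class score rows.
softmax2 <- function(scores) {
  m <- pmax(scores[, 1], scores[, 2])
  e1 <- exp(scores[, 1] - m); e2 <- exp(scores[, 2] - m)
  z <- e1 + e2
  cbind(e1 / z, e2 / z)
}

#' Weighted per-pixel cross-entropy loss
#'
#' Mean over pixels of `-w[class] * log p[class]`, where class 1 is
#' background and class 2 foreground and probabilities come from a
#' softmax over the two score maps.  Probabilities are clamped at 1e-7
#' before the log.  The default 1:10 background:foreground weighting
#' counteracts the strong class imbalance of spheroid images.
#'
#' @param scores `H x W x 2` score array (or `(H*W) x 2` matrix).
#' @param truth a [seg_mask()] or binary matrix of foreground labels.
#' @param class_weights length-2 positive vector
#'   `c(background, foreground)`.
#' @return Scalar loss.
#' @export
weighted_cross_entropy <- function(scores, truth,
                                   class_weights = c(1, 10)) {
  y <- as.vector(mask_pixels(truth))
  s <- if (length(dim(scores)) == 3) matrix(scores, ncol = 2) else scores
  if (nrow(s) != length(y))
    stop("weighted_cross_entropy: score/truth shapes do not match")
  prob <- softmax2(s)
  p_true <- ifelse(y == 1, prob[, 2], prob[, 1])
  w <- ifelse(y == 1, class_weights[2], class_weights[1])
  mean(-w * log(pmax(p_true, 1e-7)))
}

# Loss gradient wrt scores: (1/N) * w_y * (p - onehot_y).
wce_grad <- function(scores, y, class_weights) {
  prob <- softmax2(scores)
  n <- length(y)
  w <- ifelse(y == 1, class_weights[2], class_weights[1])
  g <- prob
  g[cbind(seq_len(n), y + 1L)] <- g[cbind(seq_len(n), y + 1L)] - 1
  g * (w / n)
}

# Backward pass; returns gradient list matching model$params.
pnet_backward <- function(model, fwd, gscores) {
  p <- model$params; layers <- model$layers
  C <- model$config$channels
  H <- fwd$dim[1]; W <- fwd$dim[2]
  cache <- fwd$cache
  grads <- list()
  gh <- tcrossprod(gscores, p$fc2_W)
  grads$fc2_W <- crossprod(cache$h, gscores)
  grads$fc2_b <- colSums(gscores)
  if (!is.null(cache$dropout_mask)) gh <- gh * cache$dropout_mask
  gh_pre <- gh * (cache$h_pre > 0)
  grads$fc1_W <- crossprod(cache$Fm, gh_pre)
  grads$fc1_b <- colSums(gh_pre)
  gF <- tcrossprod(gh_pre, p$fc1_W)
  carry <- NULL  # gradient flowing into the output of the current block
  for (b in 5:1) {
    gb <- array(gF[, ((b - 1) * C + 1):(b * C)], dim = c(H, W, C))
    g_out <- if (is.null(carry)) gb else gb + carry
    idx <- rev(layers$layer[layers$block == b])
    for (i in idx) {
      act <- if (i == 13L) cache$final else cache$inputs[[i + 1L]]
      bw <- conv2d_bw(cache$inputs[[i]], p[[sprintf("conv%02d_W", i)]],
                      g_out, act, layers$dilation[i])
      grads[[sprintf("conv%02d_W", i)]] <- bw$gW
      grads[[sprintf("conv%02d_b", i)]] <- as.numeric(bw$gb)
      g_out <- bw$gx
    }
    carry <- g_out
  }
  grads
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# The 8 dihedral transforms (identity, 3 rotations, and their mirrored
# versions) used for training augmentation.
dihedral_transform <- function(m, k) {
  stopifnot(k >= 0, k <= 7)
  if (k >= 4) m <- m[, ncol(m):1, drop = FALSE]
  r <- k %% 4
  for (i in seq_len(r)) m <- t(m[nrow(m):1, , drop = FALSE])
  m
}

resize_frame <- function(m, size, nearest = FALSE) {
  if (all(dim(m) == size)) return(m)
  img <- EBImage::resize(EBImage::Image(m), w = size, h = size,
                         filter = if (nearest) "none" else "bilinear")
  EBImage::imageData(img)
}

standardize_frame <- function(m) {
  s <- sd(m)
  if (s == 0) s <- 1
  (m - mean(m)) / s
}

#' Train the segmentation network
#'
#' Resizes frames and masks to `config$input_size` (bilinear for images,
#' nearest-neighbour for masks), expands the training set 8-fold with
#' flip/rotation augmentation, and minimizes the weighted cross-entropy
#' with ADAM at the configured learning rate, dropout active.  The whole
#' run (initialization, shuffling, dropout) is a pure function of
#' `config$seed`.
#'
#' @param images list of single-channel matrices (phase-contrast
#'   frames).
#' @param masks list of matching ground-truth masks ([seg_mask()] or
#'   binary matrices).
#' @param config a [pnet_config()].
#' @param val_images,val_masks optional held-out frames on which a mean
#'   Dice score is recorded each epoch.
#' @param verbose print per-epoch losses.
#' @return List with `model` (trained `pnet_model`) and `report`
#'   (per-epoch mean training loss, augmentation count, validation
#'   Dice).
#' @export
train_pnet <- function(images, masks, config, val_images = NULL,
                       val_masks = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "PNetConfig"))
  if (length(images) == 0 || length(images) != length(masks))
    stop("train_pnet: need a non-empty, matched image/mask set")
  size <- config$input_size
  xs <- lapply(images, function(m)
    standardize_frame(resize_frame(m, size)))
  ys <- lapply(masks, function(m)
    resize_frame(mask_pixels(m), size, nearest = TRUE))

  aug_x <- list(); aug_y <- list()
  for (i in seq_along(xs)) {
    for (k in 0:7) {
      aug_x[[length(aug_x) + 1L]] <- dihedral_transform(xs[[i]], k)
      aug_y[[length(aug_y) + 1L]] <- dihedral_transform(ys[[i]], k)
    }
  }
  n_aug <- length(aug_x)
  cw <- config$class_weights
  keep <- 1 - config$dropout_rate

  model <- build_pnet(config)
  losses <- numeric(0); val_dice <- numeric(0)
  withr::with_seed(config$seed + 1L, {
    state <- adam_init(model$params)
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n_aug)
      step_losses <- numeric(0)
      for (start in seq(1, n_aug, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n_aug)]
        gacc <- NULL; bl <- 0
        for (j in idx) {
          dm <- if (keep < 1)
            matrix((runif(size * size * config$channels) < keep) / keep,
                   size * size, config$channels)
          else NULL
          fwd <- pnet_forward(model, aug_x[[j]], dropout_mask = dm,
                              keep_cache = TRUE)
          yv <- as.integer(as.vector(aug_y[[j]]) != 0)
          bl <- bl + weighted_cross_entropy(fwd$scores, aug_y[[j]], cw)
          gs <- wce_grad(fwd$scores, yv, cw)
          g <- pnet_backward(model, fwd, gs)
          gacc <- if (is.null(gacc)) g
                  else Map(`+`, gacc, g[names(gacc)])
        }
        gacc <- lapply(gacc, function(g) g / length(idx))
        upd <- adam_step(model$params, gacc, state, config$learning_rate)
        model$params <- upd$params; state <- upd$state
        step_losses <- c(step_losses, bl / length(idx))
      }
      losses <- c(losses, mean(step_losses))
      if (!is.null(val_images)) {
        vd <- mean(mapply(function(im, mk)
          dice(segment(model, im), mk), val_images, val_masks))
        val_dice <- c(val_dice, vd)
      }
      if (verbose)
        message(sprintf("epoch %d: loss %.5f%s", epoch, mean(step_losses),
                        if (length(val_dice)) sprintf(" val Dice %.3f",
                                                      val_dice[epoch]) else ""))
      if (config$early_stop_rel > 0 && epoch > 1) {
        rel <- (losses[epoch - 1] - losses[epoch]) /
          max(losses[epoch - 1], 1e-12)
        if (rel < config$early_stop_rel) break
      }
    }
  })
  list(model = model,
       report = list(loss = losses, n_train_augmented = n_aug,
                     val_dice = val_dice))
}

# Largest connected component + hole filling; spheroid masks are single
# simply connected objects.
postprocess_mask <- function(bin) {
  if (sum(bin) == 0) return(bin)
  lab <- EBImage::bwlabel(EBImage::Image(bin))
  tab <- tabulate(as.integer(EBImage::imageData(lab)))
  keep <- which.max(tab)
  m <- EBImage::Image(matrix(as.integer(EBImage::imageData(lab) == keep),
                             nrow(bin), ncol(bin)))
  EBImage::imageData(EBImage::fillHull(m))
}

#' Segment one frame with a trained network
#'
#' Resizes the frame to the network input size, computes per-pixel class
#' scores, takes the argmax, keeps the largest connected foreground
#' component, fills holes, and maps the mask back to the original
#' resolution with nearest-neighbour interpolation.
#'
#' @param model a trained (or freshly built) `pnet_model`.
#' @param frame single-channel matrix.
#' @return A [seg_mask()] with source `"pnet"`; if the network predicts
#'   no foreground the mask is empty and `empty_flag` is set (with a
#'   warning).
#' @export
segment <- function(model, frame) {
  stopifnot(inherits(model, "pnet_model"))
  size <- model$config$input_size
  x <- standardize_frame(resize_frame(frame, size))
  fwd <- pnet_forward(model, x)
  bin <- matrix(as.integer(fwd$scores[, 2] > fwd$scores[, 1]), size, size)
  empty <- sum(bin) == 0
  if (empty) warning("segment: network predicted no foreground")
  bin <- postprocess_mask(bin)
  full <- resize_frame(bin, nrow(frame), nearest = TRUE)
  if (!all(dim(frame) == nrow(frame)))
    full <- EBImage::imageData(EBImage::resize(
      EBImage::Image(bin), w = nrow(frame), h = ncol(frame),
      filter = "none"))
  seg_mask(full, source = "pnet", empty_flag = empty)
}
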