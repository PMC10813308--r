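# Compact 2D convolutional network for specklegram classification.
#
# Layers: [conv(k x k, valid) -> ReLU -> maxpool(p x p)] per block, flatten,
# dense -> ReLU, dense -> softmax over the concentration panel. Convolutions
# are evaluated as im2col patch-matrix products so all heavy lifting is BLAS
# matrix multiplication; gradients follow the same route (transposed products
# plus an index scatter-add for the input gradient).

#' CNN configuration
#'
#' @param input_shape integer `c(height, width)` of the (single-channel)
#'   input images; default the desk-scale 64 x 80 grid.
#' @param panel concentration panel in ng/mL; the network has one output
#'   class per panel entry.
#' @param conv_filters filter counts per conv block.
#' @param kernel square kernel size (valid convolution).
#' @param pool square max-pool size/stride.
#' @param dense_width width of the fully connected layer.
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param epochs epoch budget.
#' @param patience early-stopping patience on validation loss.
#' @param seed integer seed for initialization and batch shuffling.
#' @return an object of class `cnn_config`.
#' @export
cnn_config <- function(input_shape = c(64L, 80L),
                       panel = c(1, 5, 10, 20, 30, 50, 100, 500, 1000),
                       conv_filters = c(16L, 32L, 64L), kernel = 3L,
                       pool = 2L, dense_width = 128L, learning_rate = 1e-3,
                       batch_size = 32L, epochs = 30L, patience = 5L,
                       seed = 1L) {
  if (epochs < 1L) stop_with("config", "epoch budget must be >= 1")
  cfg <- structure(
    list(input_shape = as.integer(input_shape), panel = panel,
         class_count = length(panel), conv_filters = as.integer(conv_filters),
         kernel = as.integer(kernel), pool = as.integer(pool),
         dense_width = as.integer(dense_width),
         learning_rate = learning_rate, batch_size = as.integer(batch_size),
         epochs = as.integer(epochs), patience = as.integer(patience),
         seed = as.integer(seed)),
    class = "cnn_config"
  )
  cnn_shapes(cfg)  # validates feasibility
  cfg
}

# shape of the feature map after each block; errors if pooling exhausts it
cnn_shapes <- function(config) {
  h <- config$input_shape[1]; w <- config$input_shape[2]; ch <- 1L
  shapes <- list()
  for (f in config$conv_filters) {
    h <- h - config$kernel + 1L
    w <- w - config$kernel + 1L
    if (h < 1L || w < 1L) {
      stop_with("architecture",
                "input shape incompatible with convolution/pooling depth")
    }
    h <- h %/% config$pool
    w <- w %/% config$pool
    if (h < 1L || w < 1L) {
      stop_with("architecture",
                "input shape incompatible with convolution/pooling depth")
    }
    shapes[[length(shapes) + 1L]] <- c(h, w, f)
    ch <- f
  }
  shapes
}

#' Build (initialize) the CNN
#'
#' He-normal seeded initialization; two calls with the same config produce
#' identical parameters.
#'
#' @param config a [cnn_config()].
#' @return an object of class `cnn_model`.
#' @export
build_model <- function(config) {
  shapes <- cnn_shapes(config)
  k <- config$kernel
  params <- list()
  with_seed(config$seed, {
    cin <- 1L
    for (l in seq_along(config$conv_filters)) {
      f <- config$conv_filters[l]
      fan_in <- k * k * cin
      params[[paste0("conv", l, "_W")]] <-
        matrix(stats::rnorm(fan_in * f, 0, sqrt(2 / fan_in)), fan_in, f)
      params[[paste0("conv", l, "_b")]] <- numeric(f)
      cin <- f
    }
    feat <- prod(shapes[[length(shapes)]])
    dw <- config$dense_width
    params[["dense_W"]] <-
      matrix(stats::rnorm(dw * feat, 0, sqrt(2 / feat)), dw, feat)
    params[["dense_b"]] <- numeric(dw)
    params[["out_W"]] <-
      matrix(stats::rnorm(config$class_count * dw, 0, sqrt(2 / dw)),
             config$class_count, dw)
    params[["out_b"]] <- numeric(config$class_count)
  })
  structure(list(config = config, params = params, trained = FALSE),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<cnn_model> %d x %d input, blocks [%s], %d classes, %s (%d parameters)\n",
              x$config$input_shape[1], x$config$input_shape[2],
              paste(x$config$conv_filters, collapse = ","),
              x$config$class_count,
              if (x$trained) "trained" else "untrained", np))
  invisible(x)
}

# ---- im2col machinery -------------------------------------------------------

.idx_cache <- new.env(parent = emptyenv())

conv_idx <- function(h, w, ch, n, k) {
  key <- paste(h, w, ch, n, k, sep = "_")
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  oh <- h - k + 1L; ow <- w - k + 1L
  patch_starts <- as.vector(outer(seq_len(oh), (seq_len(ow) - 1L) * h, `+`))
  offsets <- as.vector(outer(
    as.vector(outer(0:(k - 1L), (0:(k - 1L)) * h, `+`)),
    (seq_len(ch) - 1L) * h * w, `+`))
  starts <- as.vector(outer(patch_starts,
                            (seq_len(n) - 1L) * h * w * ch, `+`))
  out <- list(starts = starts, offsets = offsets, oh = oh, ow = ow)
  if (length(.idx_cache) > 24L) rm(list = ls(.idx_cache), envir = .idx_cache)
  .idx_cache[[key]] <- out
  out
}

conv_forward <- function(x, wmat, b) {
  d <- dim(x)  # h, w, ch, n
  k <- as.integer(sqrt(nrow(wmat) / d[3]))
  ii <- conv_idx(d[1], d[2], d[3], d[4], k)
  xv <- as.vector(x)
  col <- matrix(0, length(ii$starts), length(ii$offsets))
  for (o in seq_along(ii$offsets)) {
    col[, o] <- xv[ii$starts + ii$offsets[o]]
  }
  y <- col %*% wmat
  y <- y + rep(b, each = nrow(y))
  dim(y) <- c(ii$oh, ii$ow, d[4], ncol(wmat))
  list(out = aperm(y, c(1, 2, 4, 3)), col = col, ii = ii, xdim = d)
}

conv_backward <- function(dy, cache, wmat, need_dx = TRUE) {
  dym <- aperm(dy, c(1, 2, 4, 3))
  dim(dym) <- c(dim(cache$col)[1], dim(wmat)[2])
  dw <- crossprod(cache$col, dym)
  db <- colSums(dym)
  dx <- NULL
  if (need_dx) {
    dcol <- dym %*% t(wmat)
    ii <- cache$ii
    dx <- numeric(prod(cache$xdim))
    for (o in seq_along(ii$offsets)) {
      ix <- ii$starts + ii$offsets[o]
      dx[ix] <- dx[ix] + dcol[, o]
    }
    dim(dx) <- cache$xdim
  }
  list(dw = dw, db = db, dx = dx)
}

pool_forward <- function(x, p) {
  d <- dim(x)
  oh <- d[1] %/% p; ow <- d[2] %/% p
  rows <- function(di) seq(di, oh * p, by = p)
  cols <- function(dj) seq(dj, ow * p, by = p)
  m <- x[rows(1), cols(1), , , drop = FALSE]
  wi <- array(1L, dim = dim(m))
  q <- 1L
  for (dj in seq_len(p)) for (di in seq_len(p)) {
    if (di == 1L && dj == 1L) { q <- q + 0L; next }
    q <- q + 1L
    sub <- x[rows(di), cols(dj), , , drop = FALSE]
    upd <- sub > m
    m[upd] <- sub[upd]
    wi[upd] <- q
  }
  list(out = m, wi = wi, xdim = d, p = p, oh = oh, ow = ow)
}

pool_backward <- function(dy, cache) {
  p <- cache$p
  dx <- array(0, dim = cache$xdim)
  rows <- function(di) seq(di, cache$oh * p, by = p)
  cols <- function(dj) seq(dj, cache$ow * p, by = p)
  q <- 0L
  for (dj in seq_len(p)) for (di in seq_len(p)) {
    q <- q + 1L
    mask <- cache$wi == q
    if (!any(mask)) next
    tmp <- dx[rows(di), cols(dj), , , drop = FALSE]
    tmp[mask] <- dy[mask]
    dx[rows(di), cols(dj), , ] <- tmp
  }
  dx
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max), `-`)
  e <- exp(z)
  sweep(e, 2, colSums(e), `/`)
}

cnn_forward <- function(model, x, keep_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  caches <- list()
  a <- x
  for (l in seq_along(cfg$conv_filters)) {
    cv <- conv_forward(a, p[[paste0("conv", l, "_W")]],
                       p[[paste0("conv", l, "_b")]])
    r <- pmax(cv$out, 0)
    pl <- pool_forward(r, cfg$pool)
    if (keep_cache) {
      caches[[l]] <- list(conv = cv, relu_mask = cv$out > 0, pool = pl)
    }
    a <- pl$out
  }
  featdim <- dim(a)
  n <- featdim[4]
  xm <- a
  dim(xm) <- c(prod(featdim[1:3]), n)
  z1 <- p$dense_W %*% xm + p$dense_b
  r1 <- pmax(z1, 0)
  z2 <- p$out_W %*% r1 + p$out_b
  probs <- softmax_cols(z2)
  list(probs = probs,
       cache = if (keep_cache) {
         list(blocks = caches, xm = xm, z1 = z1, r1 = r1, featdim = featdim)
       })
}

cnn_loss_grads <- function(model, x, y) {
  cfg <- model$config
  p <- model$params
  fw <- cnn_forward(model, x, keep_cache = TRUE)
  probs <- fw$probs
  n <- ncol(probs)
  loss <- -mean(log(pmax(probs[cbind(y, seq_len(n))], 1e-300)))
  acc <- mean(max.col(t(probs)) == y)
  grads <- list()
  dz2 <- probs
  dz2[cbind(y, seq_len(n))] <- dz2[cbind(y, seq_len(n))] - 1
  dz2 <- dz2 / n
  ch <- fw$cache
  grads$out_W <- dz2 %*% t(ch$r1)
  grads$out_b <- rowSums(dz2)
  dr1 <- t(p$out_W) %*% dz2
  dz1 <- dr1 * (ch$z1 > 0)
  grads$dense_W <- dz1 %*% t(ch$xm)
  grads$dense_b <- rowSums(dz1)
  da <- t(p$dense_W) %*% dz1
  dim(da) <- ch$featdim
  for (l in rev(seq_along(cfg$conv_filters))) {
    blk <- ch$blocks[[l]]
    dr <- pool_backward(da, blk$pool)
    dcv <- dr * blk$relu_mask
    bw <- conv_backward(dcv, blk$conv, p[[paste0("conv", l, "_W")]],
                        need_dx = l > 1L)
    grads[[paste0("conv", l, "_W")]] <- bw$dw
    grads[[paste0("conv", l, "_b")]] <- bw$db
    if (l > 1L) da <- bw$dx
  }
  list(loss = loss, acc = acc, grads = grads)
}

#' Train the CNN on a labeled specklegram set
#'
#' Minimizes cross-entropy with Adam on the training split, tracks loss and
#' accuracy on the validation split each epoch, stops early when the
#' validation loss has not improved for `patience` epochs, and returns the
#' parameters of the best validation epoch. All shuffling and
#' initialization-independent randomness is derived from the config seed.
#'
#' @param model a [build_model()] result.
#' @param x training images, array `height x width x 1 x n`.
#' @param y integer class labels in `1..class_count`.
#' @param x_val,y_val validation split (same formats).
#' @param verbose print per-epoch progress.
#' @return the trained `cnn_model`, with a `history` data.frame (epoch,
#'   train_loss, train_accuracy, val_loss, val_accuracy) attached.
#' @export
train_cnn <- function(model, x, y, x_val, y_val, verbose = FALSE) {
  cfg <- model$config
  n <- dim(x)[4]
  if (n < 1L || dim(x_val)[4] < 1L) {
    stop_with("data", "train and validation splits must be non-empty")
  }
  mom <- lapply(model$params, function(p) p * 0)
  vel <- mom
  lr <- cfg$learning_rate; b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     train_accuracy = numeric(), val_loss = numeric(),
                     val_accuracy = numeric())
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  stale <- 0L
  for (e in seq_len(cfg$epochs)) {
    ord <- with_seed(fan_seed(cfg$seed, "epoch", e), sample.int(n))
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    tl <- 0; ta <- 0
    for (bi in batches) {
      step <- step + 1L
      lg <- cnn_loss_grads(model, x[, , , bi, drop = FALSE], y[bi])
      if (!is.finite(lg$loss)) {
        stop_with("divergence", "non-finite loss at epoch %d, step %d",
                  e, step)
      }
      tl <- tl + lg$loss * length(bi); ta <- ta + lg$acc * length(bi)
      for (nm in names(lg$grads)) {
        g <- lg$grads[[nm]]
        mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * g
        vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * g * g
        mhat <- mom[[nm]] / (1 - b1^step)
        vhat <- vel[[nm]] / (1 - b2^step)
        model$params[[nm]] <- model$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    vl <- cnn_eval_loss(model, x_val, y_val)
    hist <- rbind(hist, data.frame(
      epoch = e, train_loss = tl / n, train_accuracy = ta / n,
      val_loss = vl$loss, val_accuracy = vl$acc))
    if (verbose) {
      message(sprintf("epoch %2d  train loss %.4f acc %.3f | val loss %.4f acc %.3f",
                      e, tl / n, ta / n, vl$loss, vl$acc))
    }
    if (vl$loss < best$loss - 1e-12) {
      best <- list(loss = vl$loss, params = model$params, epoch = e)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= cfg$patience) break
    }
  }
  model$params <- best$params
  model$trained <- TRUE
  model$history <- hist
  model$best_epoch <- best$epoch
  model
}

cnn_eval_loss <- function(model, x, y, batch = 64L) {
  n <- dim(x)[4]
  loss <- 0; correct <- 0
  for (bi in split(seq_len(n), ceiling(seq_len(n) / batch))) {
    probs <- cnn_forward(model, x[, , , bi, drop = FALSE])$probs
    loss <- loss - sum(log(pmax(probs[cbind(y[bi], seq_along(bi))], 1e-300)))
    correct <- correct + sum(max.col(t(probs)) == y[bi])
  }
  list(loss = loss / n, acc = correct / n)
}

#' Class probabilities for a batch of images
#'
#' @param model a trained `cnn_model`.
#' @param x array `height x width x 1 x n` (or a single `height x width`
#'   matrix).
#' @param batch evaluation batch size.
#' @return a `class_count x n` matrix of probabilities (columns sum to 1).
#' @export
predict_proba <- function(model, x, batch = 64L) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L, 1L))
  n <- dim(x)[4]
  out <- matrix(NA_real_, model$config$class_count, n)
  for (bi in split(seq_len(n), ceiling(seq_len(n) / batch))) {
    out[, bi] <- cnn_forward(model, x[, , , bi, drop = FALSE])$probs
  }
  out
}
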