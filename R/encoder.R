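#' Convolutional encoder configuration
#'
#' Architecture and training settings for the pair-descriptor encoder:
#' one valid (no padding) convolution layer with sigmoid activation, one
#' 2 x 2 max-pooling layer, a sigmoid dense layer whose activations are the
#' extracted features, and a single sigmoid output unit. Training minimises
#' binary cross-entropy plus an L2 weight penalty `lambda/2 * ||W||^2`
#' (biases are not penalised), by Adam (default) or plain SGD.
#'
#' @param conv_kernel Convolution kernel side; `NULL` (default) picks
#'   `min(16, grid side)` at training time. The canonical choice is 16.
#' @param pool Max-pooling window side (default 2). A feature map smaller
#'   than the window passes through unchanged; odd trailing rows/columns are
#'   dropped.
#' @param n_filters Number of convolution filters (default 16).
#' @param dense_units Width of the feature layer (default 64).
#' @param epochs,batch_size Training schedule (defaults 50, 32).
#' @param learning_rate Step size eta (default 1e-3).
#' @param lambda L2 penalty weight (default 2e-4); 0 recovers plain binary
#'   cross-entropy.
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @param standardize Standardise grids cell-wise (training mean/SD, SD
#'   floored at `sd_floor`) before the convolution. Similarity values are
#'   small in magnitude (kernel entries rarely exceed 0.2), which leaves
#'   sigmoid units in a flat region; the affine rescaling is estimated from
#'   the training descriptors only and is stored with the encoder.
#' @param sd_floor Lower bound on the per-cell SD used for standardisation
#'   (default 0.05), so near-constant cells (e.g. padding) are not blown up.
#' @return A list of class `"encoder_config"`.
#' @export
encoder_config <- function(conv_kernel = NULL, pool = 2L, n_filters = 32L,
                           dense_units = 128L, epochs = 80L, batch_size = 32L,
                           learning_rate = 0.01, lambda = 2e-4,
                           optimizer = c("adam", "sgd"),
                           standardize = TRUE, sd_floor = 0.05) {
  optimizer <- match.arg(optimizer)
  stopifnot(is.null(conv_kernel) || conv_kernel >= 1,
            n_filters >= 1, dense_units >= 1, epochs >= 0, batch_size >= 1,
            learning_rate > 0, lambda >= 0, sd_floor > 0)
  structure(list(conv_kernel = conv_kernel, pool = as.integer(pool),
                 n_filters = as.integer(n_filters),
                 dense_units = as.integer(dense_units),
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, lambda = lambda,
                 optimizer = optimizer, standardize = isTRUE(standardize),
                 sd_floor = sd_floor),
            class = "encoder_config")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# im2col: rows = output positions (row-major), cols = kernel cells
# (column-major within the k x k patch, matching as.vector of a submatrix)
im2col <- function(grid, k) {
  s <- nrow(grid)
  q <- s - k + 1L
  out <- matrix(0, q * q, k * k)
  r <- 1L
  for (a in seq_len(q)) {
    for (b in seq_len(q)) {
      out[r, ] <- as.vector(grid[a:(a + k - 1L), b:(b + k - 1L)])
      r <- r + 1L
    }
  }
  out
}

# non-overlapping max-pool index sets over a q x q map stored row-major;
# returns a list of integer vectors (one per pooled cell, row-major)
pool_index_sets <- function(q, pool) {
  if (q < pool) return(as.list(seq_len(q * q)))  # map smaller than window: identity
  p <- q %/% pool
  idx <- vector("list", p * p)
  cell <- 1L
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      rows <- ((i - 1L) * pool + 1L):(i * pool)
      cols <- ((j - 1L) * pool + 1L):(j * pool)
      idx[[cell]] <- as.integer(outer(rows - 1L, cols, function(a, b) a * q + b))
      cell <- cell + 1L
    }
  }
  idx
}

#' Brute-force valid convolution of a grid with one kernel
#'
#' Reference sliding-window implementation used as an independent check of
#' the encoder's vectorised convolution: output cell (a, b) is the plain dot
#' product of the kernel with the grid window anchored at (a, b).
#'
#' @param grid Square numeric matrix.
#' @param kernel Square numeric kernel, side not larger than the grid's.
#' @return The `(s - k + 1)` square matrix of window dot products.
#' @export
conv2d_valid <- function(grid, kernel) {
  k <- nrow(kernel)
  q <- nrow(grid) - k + 1L
  P <- im2col(grid, k)
  matrix(P %*% as.vector(kernel), q, q, byrow = TRUE)
}

#' Brute-force non-overlapping max-pooling
#'
#' @param map Numeric matrix.
#' @param pool Window side (default 2). Trailing rows/columns that do not
#'   fill a window are dropped; a map smaller than the window is returned
#'   unchanged.
#' @return The pooled matrix.
#' @export
max_pool <- function(map, pool = 2L) {
  q <- nrow(map)
  if (q < pool) return(map)
  p <- q %/% pool
  out <- matrix(0, p, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      out[i, j] <- max(map[((i - 1) * pool + 1):(i * pool),
                           ((j - 1) * pool + 1):(j * pool)])
    }
  }
  out
}

#' Binary cross-entropy with optional L2 weight penalty
#'
#' `-mean(y log p + (1 - y) log(1 - p)) + lambda/2 * sum(w^2)`; with
#' `lambda = 0` this is plain binary cross-entropy.
#'
#' @param y Binary labels.
#' @param p Predicted probabilities.
#' @param lambda Penalty weight.
#' @param weights Numeric vector (or list of arrays) of penalised weights.
#' @return The scalar loss.
#' @export
bce_loss <- function(y, p, lambda = 0, weights = numeric()) {
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  base <- -mean(y * log(p) + (1 - y) * log(1 - p))
  base + lambda / 2 * sum(unlist(weights)^2)
}

init_encoder_weights <- function(k, q, pool, n_filters, dense_units, seed) {
  set.seed(seed)
  p <- if (q < pool) q else q %/% pool
  m <- p * p * n_filters
  glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(runif(nr * nc, -lim, lim), nr, nc)
  }
  list(Wc = glorot(k * k, n_filters), bc = rep(0, n_filters),
       W2 = glorot(dense_units, m), b2 = rep(0, dense_units),
       w3 = glorot(1, dense_units), b3 = 0,
       p = p, m = m)
}

# forward pass for a batch; Plist = list of im2col matrices
encoder_forward <- function(w, Plist, n_filters, pool_idx, keep_cache = FALSE) {
  B <- length(Plist)
  qsq <- nrow(Plist[[1]])
  n_cells <- length(pool_idx)
  H <- matrix(0, w$m, B)
  A1l <- if (keep_cache) vector("list", B) else NULL
  arg <- if (keep_cache) vector("list", B) else NULL
  for (s in seq_len(B)) {
    A1 <- sigmoid(sweep(Plist[[s]] %*% w$Wc, 2L, w$bc, `+`))
    pooled <- matrix(0, n_cells, n_filters)
    am <- matrix(0L, n_cells, n_filters)
    for (f in seq_len(n_filters)) {
      col <- A1[, f]
      for (c in seq_len(n_cells)) {
        ids <- pool_idx[[c]]
        k <- which.max(col[ids])
        pooled[c, f] <- col[ids[k]]
        am[c, f] <- ids[k]
      }
    }
    H[, s] <- as.vector(pooled)
    if (keep_cache) { A1l[[s]] <- A1; arg[[s]] <- am }
  }
  Z2 <- w$W2 %*% H + w$b2
  A2 <- sigmoid(Z2)
  yhat <- as.vector(sigmoid(w$w3 %*% A2 + w$b3))
  list(H = H, A2 = A2, yhat = yhat, A1 = A1l, argmax = arg)
}

#' Train the convolutional pair-descriptor encoder
#'
#' Fits the encoder defined by [encoder_config()] on labelled pair
#' descriptors. Training is deterministic given `seed` (seeded weight
#' initialisation and epoch shuffling); the per-epoch training loss is
#' recorded in `$loss_history`. With `epochs = 0` the encoder keeps its
#' seeded initial weights, which is still a valid (untrained) feature map.
#'
#' @param descriptors List of [build_pair_descriptor()] results (or bare
#'   square grids).
#' @param labels Binary labels, one per descriptor.
#' @param config An [encoder_config()].
#' @param seed Integer seed.
#' @return An object of class `"cnn_encoder"`.
#' @export
train_encoder <- function(descriptors, labels, config = encoder_config(),
                          seed = 1L) {
  grids <- purrr::map(descriptors, descriptor_to_grid)
  labels <- as.numeric(labels)
  stopifnot(length(grids) == length(labels), all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2L && config$epochs > 0L) {
    stop("encoder training needs both classes present", call. = FALSE)
  }
  side <- nrow(grids[[1]])
  if (any(vapply(grids, nrow, 1L) != side)) {
    stop("all descriptor grids must share one side length", call. = FALSE)
  }
  k <- config$conv_kernel %||% default_conv_kernel(side)
  if (k > side) {
    stop(sprintf("conv kernel (%d) larger than descriptor grid side (%d)",
                 k, side), call. = FALSE)
  }
  if (config$standardize) {
    centre <- Reduce(`+`, grids) / length(grids)
    spread <- sqrt(Reduce(`+`, lapply(grids, function(g) (g - centre)^2)) /
                     length(grids))
    spread <- pmax(spread, config$sd_floor)
  } else {
    centre <- matrix(0, side, side)
    spread <- matrix(1, side, side)
  }
  grids <- lapply(grids, function(g) (g - centre) / spread)
  q <- side - k + 1L
  pool_idx <- pool_index_sets(q, config$pool)
  w <- init_encoder_weights(k, q, config$pool, config$n_filters,
                            config$dense_units, derive_seed(seed, "encoder-init"))
  Plist <- purrr::map(grids, im2col, k = k)

  opt <- adam_state(w)
  loss_history <- numeric(0)
  n <- length(grids)
  set.seed(derive_seed(seed, "encoder-shuffle"))
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    for (batch in batches) {
      g <- encoder_gradients(w, Plist[batch], labels[batch], config, pool_idx)
      upd <- if (config$optimizer == "adam") {
        adam_update(w, g, opt, config$learning_rate)
      } else {
        sgd_update(w, g, config$learning_rate)
      }
      w <- upd$w
      opt <- upd$opt %||% opt
    }
    fw <- encoder_forward(w, Plist, config$n_filters, pool_idx)
    loss_history <- c(loss_history,
                      bce_loss(labels, fw$yhat, config$lambda,
                               list(w$Wc, w$W2, w$w3)))
  }
  structure(list(weights = w, config = config, conv_kernel = k, side = side,
                 pool_idx = pool_idx, centre = centre, spread = spread,
                 loss_history = loss_history, seed = seed),
            class = "cnn_encoder")
}

# 16 x 16 is the canonical kernel; on grids too small for it, use half the
# side so the conv keeps a genuine sliding window
default_conv_kernel <- function(side) {
  if (side >= 16L) 16L else max(2L, side %/% 2L)
}

descriptor_to_grid <- function(d) {
  if (inherits(d, "pair_descriptor")) d$grid else as.matrix(d)
}

encoder_gradients <- function(w, Plist, y, config, pool_idx) {
  B <- length(Plist)
  nf <- config$n_filters
  fw <- encoder_forward(w, Plist, nf, pool_idx, keep_cache = TRUE)
  dz3 <- matrix(fw$yhat - y, 1L, B)                       # d loss / d z3
  dw3 <- dz3 %*% t(fw$A2) / B + config$lambda * w$w3
  db3 <- mean(dz3)
  dZ2 <- (t(w$w3) %*% dz3) * fw$A2 * (1 - fw$A2)
  dW2 <- dZ2 %*% t(fw$H) / B + config$lambda * w$W2
  db2 <- rowMeans(dZ2)
  dH <- t(w$W2) %*% dZ2
  dWc <- matrix(0, nrow(w$Wc), ncol(w$Wc))
  dbc <- rep(0, nf)
  n_cells <- length(pool_idx)
  for (s in seq_len(B)) {
    dA1 <- matrix(0, nrow(Plist[[s]]), nf)
    dpool <- matrix(dH[, s], n_cells, nf)
    am <- fw$argmax[[s]]
    for (f in seq_len(nf)) {
      dA1[am[, f], f] <- dA1[am[, f], f] + dpool[, f]
    }
    dZ1 <- dA1 * fw$A1[[s]] * (1 - fw$A1[[s]])
    dWc <- dWc + t(Plist[[s]]) %*% dZ1
    dbc <- dbc + colSums(dZ1)
  }
  list(Wc = dWc / B + config$lambda * w$Wc, bc = dbc / B,
       W2 = dW2, b2 = db2, w3 = dw3, b3 = db3)
}

adam_state <- function(w) {
  zero_like <- function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else rep(0, length(x))
  nm <- c("Wc", "bc", "W2", "b2", "w3", "b3")
  list(m = purrr::map(setNames(nm, nm), ~ zero_like(w[[.x]])),
       v = purrr::map(setNames(nm, nm), ~ zero_like(w[[.x]])),
       t = 0L)
}

adam_update <- function(w, g, opt, eta, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  for (nm in names(g)) {
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g[[nm]]
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g[[nm]]^2
    mhat <- opt$m[[nm]] / (1 - beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - beta2^opt$t)
    w[[nm]] <- w[[nm]] - eta * mhat / (sqrt(vhat) + eps)
  }
  list(w = w, opt = opt)
}

sgd_update <- function(w, g, eta) {
  for (nm in names(g)) w[[nm]] <- w[[nm]] - eta * g[[nm]]
  list(w = w, opt = NULL)
}

#' Encode descriptors into learned feature vectors
#'
#' Runs the forward pass and returns the feature-layer activations (the
#' dense layer before the output unit), one row per descriptor. Values lie
#' in (0, 1) under the sigmoid activation. `encode()` is pure: repeated
#' calls on the same input agree exactly.
#'
#' @param encoder A trained [train_encoder()] object.
#' @param descriptors List of descriptors or grids with the training side
#'   length.
#' @return A numeric matrix, `length(descriptors)` x `dense_units`.
#' @export
encode <- function(encoder, descriptors) {
  stopifnot(inherits(encoder, "cnn_encoder"))
  grids <- purrr::map(descriptors, descriptor_to_grid)
  if (any(vapply(grids, nrow, 1L) != encoder$side)) {
    stop("descriptor grid side does not match the encoder's training side",
         call. = FALSE)
  }
  grids <- lapply(grids, function(g) (g - encoder$centre) / encoder$spread)
  Plist <- purrr::map(grids, im2col, k = encoder$conv_kernel)
  fw <- encoder_forward(encoder$weights, Plist, encoder$config$n_filters,
                        encoder$pool_idx)
  t(fw$A2)
}

#' @rdname encode
#' @return `encoder_predict()`: the output unit's probabilities.
#' @export
encoder_predict <- function(encoder, descriptors) {
  grids <- purrr::map(descriptors, descriptor_to_grid)
  grids <- lapply(grids, function(g) (g - encoder$centre) / encoder$spread)
  Plist <- purrr::map(grids, im2col, k = encoder$conv_kernel)
  encoder_forward(encoder$weights, Plist, encoder$config$n_filters,
                  encoder$pool_idx)$yhat
}

#' @export
print.cnn_encoder <- function(x, ...) {
  cat(sprintf(paste0("<cnn_encoder> conv %dx%d (%d filters) -> pool %dx%d -> ",
                     "dense %d -> 1; %d epoch(s), final loss %s\n"),
              x$conv_kernel, x$conv_kernel, x$config$n_filters,
              x$config$pool, x$config$pool, x$config$dense_units,
              length(x$loss_history),
              if (length(x$loss_history)) sprintf("%.4f", x$loss_history[length(x$loss_history)]) else "NA"))
  invisible(x)
}
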