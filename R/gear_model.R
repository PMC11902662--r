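# CNN-LSTM gear classifier, implemented directly on BLAS-backed base-R
# matrix operations (the deployment environment provides no deep-learning
# framework). Layer sequence: Conv1D x4 (ReLU, same padding, stride 1,
# dropout after layers 2 and 4) -> LSTM (sequence-returning) -> LSTM ->
# dropout -> dense ReLU x2 -> dense softmax. Conv layers use im2col + GEMM;
# LSTMs use full backpropagation through time. Correctness of every
# gradient is pinned by a numeric-vs-analytic gradient-check test.

#' Architecture specification for the gear classifier
#'
#' Defaults follow the published architecture: four Conv1D layers with 16,
#' 32, 64 and 128 filters and kernel sizes alternating 2 and 3, dropout
#' 0.25 after the second and fourth convolutions and after the LSTM stack,
#' two LSTM layers of 256 units (the first sequence-returning), dense
#' layers of 2048 and 1024 units, and a 3-class softmax output. All widths
#' are configurable; desk-scale runs use a narrower spec for CPU budgets.
#'
#' @param conv_filters four filter counts.
#' @param kernel_sizes four kernel sizes from \{2, 3\} (default alternates
#'   2, 3, 2, 3).
#' @param dropout dropout rate after conv-2, conv-4 and the LSTM stack.
#' @param lstm_units two LSTM widths.
#' @param dense_units two hidden dense widths.
#' @param n_classes number of output classes (3 gears).
#' @return a `model_spec`.
#' @export
model_spec <- function(conv_filters = c(16, 32, 64, 128),
                       kernel_sizes = c(2, 3, 2, 3),
                       dropout = 0.25,
                       lstm_units = c(256, 256),
                       dense_units = c(2048, 1024),
                       n_classes = 3) {
  stopifnot(length(conv_filters) == 4, all(conv_filters >= 1),
            length(kernel_sizes) == 4, all(kernel_sizes %in% c(2, 3)),
            length(lstm_units) == 2, all(lstm_units >= 1),
            length(dense_units) == 2, all(dense_units >= 1),
            dropout >= 0, dropout < 1, n_classes >= 2)
  structure(list(conv_filters = as.integer(conv_filters),
                 kernel_sizes = as.integer(kernel_sizes),
                 dropout = dropout,
                 lstm_units = as.integer(lstm_units),
                 dense_units = as.integer(dense_units),
                 n_classes = as.integer(n_classes)),
            class = "model_spec")
}

#' Training specification
#'
#' Categorical cross-entropy optimized with RMSprop, 50 epochs with batch
#' size 64 by default, and early stopping on validation loss with
#' best-weight restoration. The RMSprop learning rate defaults to the
#' common 1e-3.
#'
#' @param epochs maximum epochs (>= 1).
#' @param batch_size minibatch size (>= 1).
#' @param patience early-stopping patience in epochs (`Inf` disables).
#' @param lr RMSprop learning rate.
#' @param rho RMSprop decay.
#' @param clipnorm global gradient-norm clip (stabilizes BPTT).
#' @param seed RNG seed controlling initialization order of shuffling and
#'   dropout; fixed seed reproduces training bit-for-bit.
#' @param verbose print per-epoch progress.
#' @return a `train_spec`.
#' @export
train_spec <- function(epochs = 50, batch_size = 64, patience = 10,
                       lr = 1e-3, rho = 0.9, clipnorm = 5, seed = 1L,
                       verbose = FALSE) {
  stopifnot(epochs >= 1, batch_size >= 1, patience >= 1, lr > 0,
            rho > 0, rho < 1)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 patience = patience, lr = lr, rho = rho, clipnorm = clipnorm,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_spec")
}

# ---- shape helpers -------------------------------------------------------

# (B,T,C) array <-> (B*T, C) matrix with row index (b, t), b fastest
.mat3 <- function(a) { d <- dim(a); dim(a) <- c(d[1] * d[2], d[3]); a }
.arr3 <- function(m, B, T) { dim(m) <- c(B, T, ncol(m)); m }

.addb <- function(Z, b) Z + rep(b, each = nrow(Z))

.glorot <- function(fan_in, fan_out, nrow_, ncol_) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow_ * ncol_, -lim, lim), nrow_, ncol_)
}

# ---- layer primitives ----------------------------------------------------

# im2col: (B,T,C) -> (B*T, C*k) with keras-style "same" padding, stride 1
.im2col <- function(X, k) {
  B <- dim(X)[1]; T <- dim(X)[2]; C <- dim(X)[3]
  left <- (k - 1L) %/% 2L
  Xpad <- array(0, c(B, T + k - 1L, C))
  Xpad[, (left + 1L):(left + T), ] <- X
  cols <- vector("list", k)
  for (o in seq_len(k)) {
    cols[[o]] <- .mat3(Xpad[, o:(o + T - 1L), , drop = FALSE])
  }
  do.call(cbind, cols)
}

# scatter dXcol (B*T, C*k) back to dX (B,T,C)
.col2im <- function(dXcol, B, T, C, k) {
  left <- (k - 1L) %/% 2L
  dXpad <- array(0, c(B, T + k - 1L, C))
  for (o in seq_len(k)) {
    block <- dXcol[, ((o - 1L) * C + 1L):(o * C), drop = FALSE]
    dXpad[, o:(o + T - 1L), ] <- dXpad[, o:(o + T - 1L), , drop = FALSE] +
      .arr3(block, B, T)
  }
  dXpad[, (left + 1L):(left + T), , drop = FALSE]
}

.conv_fwd <- function(X, layer) {
  B <- dim(X)[1]; T <- dim(X)[2]
  Xcol <- .im2col(X, layer$k)
  Z <- .addb(Xcol %*% layer$W, layer$b)
  A <- Z * (Z > 0)
  list(out = .arr3(A, B, T), Xcol = Xcol, mask = Z > 0,
       C = dim(X)[3], B = B, T = T)
}

.conv_bwd <- function(dY, cache, layer) {
  dZ <- .mat3(dY) * cache$mask
  dW <- crossprod(cache$Xcol, dZ)
  db <- colSums(dZ)
  dXcol <- tcrossprod(dZ, layer$W)
  dX <- .col2im(dXcol, cache$B, cache$T, cache$C, layer$k)
  list(dX = dX, dW = dW, db = db)
}

.sigm <- function(x) 1 / (1 + exp(-x))

# LSTM forward over (B,T,D); returns full hidden sequence + caches
.lstm_fwd <- function(X, layer) {
  B <- dim(X)[1]; T <- dim(X)[2]; D <- dim(X)[3]; H <- layer$units
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  gates <- vector("list", T); cs <- vector("list", T)
  hs <- vector("list", T); tanhc <- vector("list", T)
  Hseq <- array(0, c(B, T, H))
  for (t in seq_len(T)) {
    xt <- X[, t, , drop = FALSE]; dim(xt) <- c(B, D)
    z <- .addb(cbind(xt, h) %*% layer$W, layer$b)
    i <- .sigm(z[, 1:H, drop = FALSE])
    f <- .sigm(z[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- .sigm(z[, (3 * H + 1):(4 * H), drop = FALSE])
    cc <- f * cc + i * g
    tc <- tanh(cc)
    h <- o * tc
    gates[[t]] <- list(i = i, f = f, g = g, o = o)
    cs[[t]] <- cc; hs[[t]] <- h; tanhc[[t]] <- tc
    Hseq[, t, ] <- h
  }
  list(out = Hseq, gates = gates, cs = cs, hs = hs, tanhc = tanhc,
       X = X, B = B, T = T, D = D, H = H)
}

# BPTT; dH: (B,T,H) gradient on the hidden sequence (zeros allowed)
.lstm_bwd <- function(dH, cache, layer) {
  B <- cache$B; T <- cache$T; D <- cache$D; H <- cache$H
  dW <- matrix(0, nrow(layer$W), ncol(layer$W))
  db <- numeric(4 * H)
  dX <- array(0, c(B, T, D))
  dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)
  for (t in rev(seq_len(T))) {
    g <- cache$gates[[t]]
    tc <- cache$tanhc[[t]]
    c_prev <- if (t > 1) cache$cs[[t - 1]] else matrix(0, B, H)
    h_prev <- if (t > 1) cache$hs[[t - 1]] else matrix(0, B, H)
    dh <- dh_next + dH[, t, , drop = TRUE]
    if (is.null(dim(dh))) dim(dh) <- c(B, H)
    dc <- dc_next + dh * g$o * (1 - tc^2)
    di <- dc * g$g; df <- dc * c_prev; dg <- dc * g$i; do_ <- dh * tc
    dz <- cbind(di * g$i * (1 - g$i),
                df * g$f * (1 - g$f),
                dg * (1 - g$g^2),
                do_ * g$o * (1 - g$o))
    xt <- cache$X[, t, , drop = FALSE]; dim(xt) <- c(B, D)
    dW <- dW + crossprod(cbind(xt, h_prev), dz)
    db <- db + colSums(dz)
    dxh <- tcrossprod(dz, layer$W)
    dX[, t, ] <- dxh[, 1:D, drop = FALSE]
    dh_next <- dxh[, (D + 1):(D + H), drop = FALSE]
    dc_next <- dc * g$f
  }
  list(dX = dX, dW = dW, db = db)
}

.softmax <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# ---- model construction --------------------------------------------------

#' Build an untrained gear classifier
#'
#' Initializes all weights (Glorot-uniform, LSTM forget-gate bias 1) for a
#' given input shape. Same padding and stride 1 preserve the step axis
#' through the convolutional stack, so the LSTMs see the full temporal
#' resolution.
#'
#' @param steps time steps per window (e.g. 100 for 5000 ms windows with
#'   50 ms subframes); must be >= 4 to cover the convolutional receptive
#'   field.
#' @param n_channels input channels per step.
#' @param spec a [model_spec()].
#' @param seed RNG seed for initialization.
#' @param channel_names optional channel names; recorded for mismatch
#'   checking at train/predict time.
#' @return an untrained `gear_model`.
#' @export
build_model <- function(steps, n_channels, spec = model_spec(), seed = 1L,
                        channel_names = NULL) {
  stopifnot(inherits(spec, "model_spec"), n_channels >= 1)
  if (steps < 4) {
    stop("steps must be >= 4 for the convolutional receptive field",
         call. = FALSE)
  }
  if (!is.null(channel_names)) stopifnot(length(channel_names) == n_channels)
  params <- with_seed(seed, {
    p <- list(conv = list(), lstm = list(), dense = list())
    cin <- n_channels
    for (i in 1:4) {
      f <- spec$conv_filters[i]; k <- spec$kernel_sizes[i]
      p$conv[[i]] <- list(W = .glorot(cin * k, f * k, cin * k, f),
                          b = numeric(f), k = k)
      cin <- f
    }
    din <- cin
    for (j in 1:2) {
      H <- spec$lstm_units[j]
      b <- numeric(4 * H)
      b[(H + 1):(2 * H)] <- 1      # forget-gate bias
      p$lstm[[j]] <- list(W = .glorot(din + H, 4 * H, din + H, 4 * H),
                          b = b, units = H)
      din <- H
    }
    widths <- c(spec$dense_units, spec$n_classes)
    for (d in 1:3) {
      p$dense[[d]] <- list(W = .glorot(din, widths[d], din, widths[d]),
                           b = numeric(widths[d]))
      din <- widths[d]
    }
    p
  })
  structure(list(spec = spec, steps = as.integer(steps),
                 n_channels = as.integer(n_channels),
                 channel_names = channel_names,
                 classes = gear_levels()[seq_len(spec$n_classes)],
                 params = params, trained = FALSE, history = NULL),
            class = "gear_model")
}

#' @export
print.gear_model <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<gear_model> %s: input %d steps x %d channels\n",
              if (x$trained) "trained" else "untrained",
              x$steps, x$n_channels))
  cat(sprintf("  Conv1D %s (kernels %s) -> LSTM %s -> dense %s -> softmax %d\n",
              paste(s$conv_filters, collapse = "/"),
              paste(s$kernel_sizes, collapse = "/"),
              paste(s$lstm_units, collapse = "/"),
              paste(s$dense_units, collapse = "/"), s$n_classes))
  invisible(x)
}

# full forward pass; training = TRUE applies inverted dropout
.forward <- function(model, X, training = FALSE, keep_cache = FALSE) {
  p <- model$params; rate <- model$spec$dropout
  B <- dim(X)[1]
  caches <- list(); drop <- list()
  a <- X
  for (i in 1:4) {
    cc <- .conv_fwd(a, p$conv[[i]])
    a <- cc$out
    if (keep_cache) caches[[paste0("conv", i)]] <- cc
    if (training && rate > 0 && i %in% c(2L, 4L)) {
      m <- (matrix(stats::runif(length(a)), dim(a)[1] * dim(a)[2],
                   dim(a)[3]) >= rate) / (1 - rate)
      a <- .arr3(.mat3(a) * m, dim(a)[1], dim(a)[2])
      drop[[paste0("conv", i)]] <- m
    }
  }
  l1 <- .lstm_fwd(a, p$lstm[[1]])
  l2 <- .lstm_fwd(l1$out, p$lstm[[2]])
  h <- l2$out[, dim(l2$out)[2], , drop = TRUE]
  if (is.null(dim(h))) dim(h) <- c(B, p$lstm[[2]]$units)
  if (keep_cache) { caches$lstm1 <- l1; caches$lstm2 <- l2 }
  if (training && rate > 0) {
    m <- (matrix(stats::runif(length(h)), nrow(h), ncol(h)) >= rate) / (1 - rate)
    h <- h * m
    drop$lstm <- m
  }
  z1 <- .addb(h %*% p$dense[[1]]$W, p$dense[[1]]$b); a1 <- z1 * (z1 > 0)
  z2 <- .addb(a1 %*% p$dense[[2]]$W, p$dense[[2]]$b); a2 <- z2 * (z2 > 0)
  logits <- .addb(a2 %*% p$dense[[3]]$W, p$dense[[3]]$b)
  probs <- .softmax(logits)
  if (keep_cache) {
    caches$dense <- list(h = h, a1 = a1, a2 = a2, m1 = z1 > 0, m2 = z2 > 0)
    caches$drop <- drop
  }
  list(probs = probs, caches = if (keep_cache) caches else NULL)
}

# backward pass; returns gradients in the same structure as params
.backward <- function(model, fw, Y) {
  p <- model$params; caches <- fw$caches
  B <- nrow(Y)
  g <- list(conv = vector("list", 4), lstm = vector("list", 2),
            dense = vector("list", 3))
  dZ <- (fw$probs - Y) / B
  dn <- caches$dense
  g$dense[[3]] <- list(dW = crossprod(dn$a2, dZ), db = colSums(dZ))
  dA2 <- tcrossprod(dZ, p$dense[[3]]$W) * dn$m2
  g$dense[[2]] <- list(dW = crossprod(dn$a1, dA2), db = colSums(dA2))
  dA1 <- tcrossprod(dA2, p$dense[[2]]$W) * dn$m1
  g$dense[[1]] <- list(dW = crossprod(dn$h, dA1), db = colSums(dA1))
  dh <- tcrossprod(dA1, p$dense[[1]]$W)
  if (!is.null(caches$drop$lstm)) dh <- dh * caches$drop$lstm
  T2 <- caches$lstm2$T
  dH2 <- array(0, c(B, T2, p$lstm[[2]]$units))
  dH2[, T2, ] <- dh
  b2 <- .lstm_bwd(dH2, caches$lstm2, p$lstm[[2]])
  g$lstm[[2]] <- list(dW = b2$dW, db = b2$db)
  b1 <- .lstm_bwd(b2$dX, caches$lstm1, p$lstm[[1]])
  g$lstm[[1]] <- list(dW = b1$dW, db = b1$db)
  dA <- b1$dX
  for (i in 4:1) {
    key <- paste0("conv", i)
    if (!is.null(caches$drop[[key]])) {
      dA <- .arr3(.mat3(dA) * caches$drop[[key]], dim(dA)[1], dim(dA)[2])
    }
    bb <- .conv_bwd(dA, caches[[key]], p$conv[[i]])
    g$conv[[i]] <- list(dW = bb$dW, db = bb$db)
    dA <- bb$dX
  }
  g
}

# iterate (params, grads, rmsprop state) leaves in lockstep
.walk_params <- function(params, fn) {
  for (grp in c("conv", "lstm", "dense")) {
    for (i in seq_along(params[[grp]])) {
      for (leaf in c("W", "b")) fn(grp, i, leaf)
    }
  }
}

.global_norm <- function(grads) {
  s <- 0
  .walk_params(grads, function(grp, i, leaf) {
    gname <- if (leaf == "W") "dW" else "db"
    s <<- s + sum(grads[[grp]][[i]][[gname]]^2)
  })
  sqrt(s)
}

# ---- training ------------------------------------------------------------

.one_hot <- function(labels, classes) {
  Y <- matrix(0, length(labels), length(classes))
  Y[cbind(seq_along(labels), match(as.character(labels), classes))] <- 1
  Y
}

.batch_probs <- function(model, X, batch_size = 512L) {
  n <- dim(X)[1]
  out <- matrix(0, n, model$spec$n_classes)
  at <- 1L
  while (at <= n) {
    idx <- at:min(at + batch_size - 1L, n)
    out[idx, ] <- .forward(model, X[idx, , , drop = FALSE])$probs
    at <- at + batch_size
  }
  out
}

.check_ws_for_model <- function(model, ws, what) {
  if (dim(ws$tensor)[2] != model$steps ||
      dim(ws$tensor)[3] != model$n_channels) {
    stop(what, " window set shape (", dim(ws$tensor)[2], " steps x ",
         dim(ws$tensor)[3], " channels) does not match the model (",
         model$steps, " x ", model$n_channels, ")", call. = FALSE)
  }
  if (!is.null(model$channel_names) &&
      !identical(ws$channel_names, model$channel_names)) {
    stop(what, " channel names do not match the model", call. = FALSE)
  }
}

#' Train the gear classifier
#'
#' Minibatch RMSprop on categorical cross-entropy with per-epoch validation
#' monitoring, early stopping on validation loss and best-weight
#' restoration. The validation set must be normalized with the *training*
#' fold's statistics (see [fit_norm()]); this function never touches
#' normalization. History records per-epoch cumulative elapsed seconds and
#' validation weighted average accuracy.
#'
#' @param model an untrained (or previously trained) `gear_model`.
#' @param train_ws,val_ws normalized `window_set`s sharing the model's
#'   channel set.
#' @param tspec a [train_spec()].
#' @return the trained `gear_model`, with a `history` data frame
#'   (`epoch`, `elapsed_s`, `train_loss`, `val_loss`, `waa`).
#' @export
train_model <- function(model, train_ws, val_ws, tspec = train_spec()) {
  stopifnot(inherits(model, "gear_model"), inherits(tspec, "train_spec"))
  .check_ws_for_model(model, train_ws, "training")
  .check_ws_for_model(model, val_ws, "validation")
  if (!identical(train_ws$channel_names, val_ws$channel_names)) {
    stop("training and validation channel sets differ", call. = FALSE)
  }
  classes <- model$classes
  present <- classes %in% as.character(unique(train_ws$labels))
  if (!all(present)) {
    stop("class(es) absent from training labels: ",
         paste(classes[!present], collapse = ", "), call. = FALSE)
  }
  X <- train_ws$tensor
  Y <- .one_hot(train_ws$labels, classes)
  Xv <- val_ws$tensor
  yv <- match(as.character(val_ws$labels), classes)
  n <- dim(X)[1]
  state <- NULL   # rmsprop caches, lazily initialized
  best <- list(loss = Inf, params = NULL, epoch = 0L)
  hist <- vector("list", tspec$epochs)
  t0 <- proc.time()[["elapsed"]]
  with_seed(tspec$seed, {
    for (epoch in seq_len(tspec$epochs)) {
      ord <- sample.int(n)
      losses <- c()
      at <- 1L
      while (at <= n) {
        idx <- ord[at:min(at + tspec$batch_size - 1L, n)]
        Xb <- X[idx, , , drop = FALSE]
        Yb <- Y[idx, , drop = FALSE]
        fw <- .forward(model, Xb, training = TRUE, keep_cache = TRUE)
        eps <- 1e-12
        losses <- c(losses, -mean(log(pmax(rowSums(fw$probs * Yb), eps))))
        grads <- .backward(model, fw, Yb)
        gn <- .global_norm(grads)
        scale <- if (is.finite(tspec$clipnorm) && gn > tspec$clipnorm)
          tspec$clipnorm / gn else 1
        if (is.null(state)) {
          state <- grads  # same shapes; zero it
          .walk_params(state, function(grp, i, leaf) {
            gname <- if (leaf == "W") "dW" else "db"
            state[[grp]][[i]][[gname]] <<- 0 * state[[grp]][[i]][[gname]]
          })
        }
        .walk_params(model$params, function(grp, i, leaf) {
          gname <- if (leaf == "W") "dW" else "db"
          gmat <- grads[[grp]][[i]][[gname]] * scale
          s <- tspec$rho * state[[grp]][[i]][[gname]] + (1 - tspec$rho) * gmat^2
          state[[grp]][[i]][[gname]] <<- s
          model$params[[grp]][[i]][[leaf]] <<-
            model$params[[grp]][[i]][[leaf]] - tspec$lr * gmat / (sqrt(s) + 1e-7)
        })
        at <- at + tspec$batch_size
      }
      pv <- .batch_probs(model, Xv)
      val_loss <- -mean(log(pmax(pv[cbind(seq_along(yv), yv)], 1e-12)))
      waa <- mean(max.col(pv, ties.method = "first") == yv)
      hist[[epoch]] <- data.frame(
        epoch = epoch, elapsed_s = proc.time()[["elapsed"]] - t0,
        train_loss = mean(losses), val_loss = val_loss, waa = waa)
      if (tspec$verbose) {
        message(sprintf("epoch %3d  loss %.4f  val_loss %.4f  val WAA %.4f  (%.1fs)",
                        epoch, mean(losses), val_loss, waa,
                        hist[[epoch]]$elapsed_s))
      }
      if (val_loss < best$loss) {
        best <- list(loss = val_loss, params = model$params, epoch = epoch)
      } else if (epoch - best$epoch >= tspec$patience) {
        break
      }
    }
  })
  if (!is.null(best$params)) model$params <- best$params
  model$trained <- TRUE
  model$history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  model$best_epoch <- best$epoch
  model
}

#' Predict gear probabilities for a window set
#'
#' @param object a trained `gear_model`.
#' @param ws a normalized `window_set` matching the model's channels.
#' @param batch_size forward-pass batch size (result is batch-size
#'   invariant).
#' @param ... unused.
#' @return list with `prob` (rows sum to 1, columns in canonical class
#'   order) and `gear` (argmax labels; ties broken toward the earlier
#'   canonical class).
#' @export
predict.gear_model <- function(object, ws, batch_size = 512L, ...) {
  stopifnot(inherits(ws, "window_set"))
  .check_ws_for_model(object, ws, "prediction")
  prob <- .batch_probs(object, ws$tensor, as.integer(batch_size))
  colnames(prob) <- object$classes
  gear <- factor(object$classes[max.col(prob, ties.method = "first")],
                 levels = gear_levels())
  list(prob = prob, gear = gear)
}
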