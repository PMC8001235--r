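# Feed-forward multilayer perceptron for binary classification.
# Written in plain matrix algebra: ReLU hidden layers, sigmoid output,
# binary cross-entropy loss, Adam updates, early stopping on a validation
# fraction of the training data. Inputs are standardized on training
# statistics; all randomness flows from `seed`.

#' Fit a multilayer perceptron classifier
#'
#' @param x Samples x features numeric matrix.
#' @param y Binary labels.
#' @param hidden Integer vector of hidden-layer sizes (default two layers of
#'   128 units).
#' @param learning_rate Adam step size.
#' @param epochs Maximum training epochs.
#' @param batch_size Minibatch size.
#' @param val_fraction Fraction of the training data held out for early
#'   stopping.
#' @param patience Epochs without validation improvement before stopping.
#' @param l2 L2 weight penalty.
#' @param seed Integer seed (initialisation, shuffling, validation split).
#' @return An `edison_mlp` model.
#' @export
mlp_fit <- function(x, y, hidden = c(128, 128), learning_rate = 1e-3,
                    epochs = 200, batch_size = 32, val_fraction = 0.15,
                    patience = 20, l2 = 1e-4, seed = 1L) {
  y <- as_binary(y)
  check_both_classes(y)
  x <- as.matrix(x)
  withr::with_seed(as.integer(seed), {
    ctr <- colMeans(x)
    scl <- apply(x, 2, sd)
    scl[scl < 1e-12] <- 1
    xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")

    n <- nrow(xs)
    n_val <- max(2L, round(val_fraction * n))
    val_idx <- integer(0)
    for (cl in 0:1) {
      idx <- which(y == cl)
      take <- max(1L, round(length(idx) * val_fraction))
      val_idx <- c(val_idx, sample(idx, min(take, length(idx) - 1L)))
    }
    tr_idx <- setdiff(seq_len(n), val_idx)
    xt <- xs[tr_idx, , drop = FALSE]; yt <- y[tr_idx]
    xv <- xs[val_idx, , drop = FALSE]; yv <- y[val_idx]

    sizes <- c(ncol(xs), hidden, 1L)
    L <- length(sizes) - 1L
    W <- lapply(seq_len(L), function(l) {
      matrix(rnorm(sizes[l] * sizes[l + 1], 0, sqrt(2 / sizes[l])),
             sizes[l], sizes[l + 1])
    })
    b <- lapply(seq_len(L), function(l) rep(0, sizes[l + 1]))
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(bb) bb * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t_step <- 0

    forward <- function(xm) {
      a <- list(xm)
      for (l in seq_len(L)) {
        z <- sweep(a[[l]] %*% W[[l]], 2, b[[l]], "+")
        a[[l + 1]] <- if (l < L) pmax(z, 0) else plogis(z)
      }
      a
    }
    val_loss <- function() {
      p <- forward(xv)[[L + 1]][, 1]
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      -mean(yv * log(p) + (1 - yv) * log(1 - p))
    }

    best <- list(loss = Inf, W = W, b = b, epoch = 0L)
    stale <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample(length(yt))
      for (start in seq(1, length(yt), by = batch_size)) {
        bi <- ord[start:min(start + batch_size - 1L, length(yt))]
        a <- forward(xt[bi, , drop = FALSE])
        nb <- length(bi)
        delta <- (a[[L + 1]] - yt[bi]) / nb      # dL/dz at the sigmoid
        t_step <- t_step + 1
        for (l in rev(seq_len(L))) {
          gW <- crossprod(a[[l]], delta) + l2 * W[[l]]
          gb <- colSums(delta)
          if (l > 1) {
            delta <- (delta %*% t(W[[l]])) * (a[[l]] > 0)
          }
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
          mhW <- mW[[l]] / (1 - beta1^t_step)
          vhW <- vW[[l]] / (1 - beta2^t_step)
          mhb <- mb[[l]] / (1 - beta1^t_step)
          vhb <- vb[[l]] / (1 - beta2^t_step)
          W[[l]] <- W[[l]] - learning_rate * mhW / (sqrt(vhW) + eps)
          b[[l]] <- b[[l]] - learning_rate * mhb / (sqrt(vhb) + eps)
        }
      }
      vl <- val_loss()
      if (vl < best$loss - 1e-6) {
        best <- list(loss = vl, W = W, b = b, epoch = ep)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= patience) break
      }
    }
    structure(list(W = best$W, b = best$b, center = ctr, scale = scl,
                   hidden = hidden, val_loss = best$loss,
                   epochs_trained = best$epoch, seed = as.integer(seed)),
              class = "edison_mlp")
  })
}

#' @export
predict.edison_mlp <- function(object, newdata, ...) {
  xm <- as.matrix(newdata)
  xm <- sweep(sweep(xm, 2, object$center), 2, object$scale, "/")
  L <- length(object$W)
  a <- xm
  for (l in seq_len(L)) {
    z <- sweep(a %*% object$W[[l]], 2, object$b[[l]], "+")
    a <- if (l < L) pmax(z, 0) else plogis(z)
  }
  a[, 1]
}

#' @export
print.edison_mlp <- function(x, ...) {
  cat(sprintf("<edison_mlp> %s, best val loss %.4f at epoch %d\n",
              paste(c(length(x$center), x$hidden, 1), collapse = "-"),
              x$val_loss, x$epochs_trained))
  invisible(x)
}
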