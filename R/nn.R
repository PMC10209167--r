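#' Fit a small feed-forward network
#'
#' A compact multilayer perceptron used throughout the package for pairwise
#' link prediction and clinical-score regression: ReLU hidden layers (0, 1
#' or 2 of them in the tuning grids), inverted dropout, the Adam optimiser,
#' a class-balanced loss for imbalanced labels, and early stopping when the
#' validation loss has not improved for `patience` epochs (the best-epoch
#' weights are kept). Inputs are standardized per column on the training
#' statistics (embedding features share a large common component and raw
#' coordinates condition badly); the statistics travel with the model and
#' are applied at prediction time. Training is deterministic for a given
#' seed.
#'
#' @param x numeric feature matrix (rows = examples).
#' @param y targets: a 0/1 vector or matrix for classification (one column
#'   per task), a numeric vector for regression.
#' @param hidden integer vector of hidden-layer sizes (`integer(0)` gives a
#'   linear / logistic model).
#' @param dropout dropout probability applied to hidden activations.
#' @param task `"classification"` (sigmoid outputs, cross-entropy) or
#'   `"regression"` (linear output, squared error).
#' @param balanced if `TRUE`, classification examples are weighted inversely
#'   to their class frequency per output column.
#' @param lr Adam learning rate.
#' @param epochs maximum epochs.
#' @param batch_size minibatch size.
#' @param patience early-stopping patience in epochs.
#' @param x_val,y_val optional validation set; if absent, `val_fraction` of
#'   the rows is held out (seeded).
#' @param val_fraction fraction held out when no validation set is given.
#' @param seed RNG seed covering initialisation, shuffling and dropout.
#' @return a `pwas_mlp` model.
#' @export
mlp_fit <- function(x, y, hidden = c(100L), dropout = 0,
                    task = c("classification", "regression"),
                    balanced = TRUE, lr = 0.01, epochs = 100L,
                    batch_size = 32L, patience = 2L,
                    x_val = NULL, y_val = NULL, val_fraction = 0.2,
                    seed = 1L) {
  task <- match.arg(task)
  x <- as.matrix(x)
  if (is.vector(y)) y <- matrix(as.numeric(y), ncol = 1L)
  y <- as.matrix(y)
  stopifnot(nrow(x) == nrow(y), dropout >= 0, dropout < 1)
  if (task == "classification") {
    for (j in seq_len(ncol(y)))
      if (length(unique(y[, j])) < 2L)
        stop("labels are single-class in column ", j)
  }
  with_seed(seed, {
    if (is.null(x_val)) {
      n <- nrow(x)
      n_val <- max(1L, floor(val_fraction * n))
      vi <- sample.int(n, n_val)
      x_val <- x[vi, , drop = FALSE]
      y_val <- y[vi, , drop = FALSE]
      x <- x[-vi, , drop = FALSE]
      y <- y[-vi, , drop = FALSE]
    } else {
      if (is.vector(y_val)) y_val <- matrix(as.numeric(y_val), ncol = 1L)
    }
    # standardize inputs on training statistics; word-embedding features
    # share a large common component and raw coordinates condition badly
    center <- colMeans(x)
    scale_ <- apply(x, 2L, sd)
    scale_[scale_ == 0 | !is.finite(scale_)] <- 1
    x <- sweep(sweep(x, 2L, center), 2L, scale_, `/`)
    x_val <- sweep(sweep(x_val, 2L, center), 2L, scale_, `/`)
    n <- nrow(x)
    n_out <- ncol(y)
    # per-column class weights: n / (2 * n_class)
    w <- matrix(1, n, n_out)
    w_val <- matrix(1, nrow(y_val), n_out)
    if (task == "classification" && balanced) {
      for (j in seq_len(n_out)) {
        n1 <- sum(y[, j] == 1)
        n0 <- n - n1
        if (n1 > 0 && n0 > 0) {
          w[, j] <- ifelse(y[, j] == 1, n / (2 * n1), n / (2 * n0))
          w_val[, j] <- ifelse(y_val[, j] == 1, n / (2 * n1), n / (2 * n0))
        }
      }
    }
    sizes <- c(ncol(x), hidden, n_out)
    L <- length(sizes) - 1L
    W <- vector("list", L); b <- vector("list", L)
    for (l in seq_len(L)) {
      W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                    sd = sqrt(2 / sizes[l])),
                       sizes[l], sizes[l + 1L])
      b[[l]] <- rep(0, sizes[l + 1L])
    }
    mW <- lapply(W, function(m) m * 0); vW <- mW
    mb <- lapply(b, function(v) v * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; tstep <- 0L

    forward <- function(xx, train = FALSE) {
      act <- list(xx)
      masks <- vector("list", L)
      h <- xx
      for (l in seq_len(L)) {
        z <- sweep(h %*% W[[l]], 2L, b[[l]], `+`)
        if (l < L) {
          h <- pmax(z, 0)
          if (train && dropout > 0) {
            m <- matrix(stats::runif(length(h)) >= dropout, nrow(h), ncol(h))
            h <- h * m / (1 - dropout)
            masks[[l]] <- m
          }
        } else {
          h <- if (task == "classification") 1 / (1 + exp(-z)) else z
        }
        act[[l + 1L]] <- h
      }
      list(act = act, masks = masks)
    }
    loss_fn <- function(p, yy, ww) {
      if (task == "classification") {
        p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
        -sum(ww * (yy * log(p) + (1 - yy) * log(1 - p))) / nrow(yy)
      } else {
        sum(ww * (p - yy)^2) / nrow(yy)
      }
    }
    best <- list(loss = Inf, W = W, b = b)
    wait <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        bi <- ord[start:min(start + batch_size - 1L, n)]
        xb <- x[bi, , drop = FALSE]
        yb <- y[bi, , drop = FALSE]
        wb <- w[bi, , drop = FALSE]
        fw <- forward(xb, train = TRUE)
        act <- fw$act
        # output delta: (p - y) * w / n works for both sigmoid-BCE and
        # 0.5*MSE up to a constant absorbed by the learning rate
        delta <- (act[[L + 1L]] - yb) * wb / nrow(yb)
        tstep <- tstep + 1L
        for (l in rev(seq_len(L))) {
          gW <- crossprod(act[[l]], delta)
          gb <- colSums(delta)
          if (l > 1L) {
            delta <- delta %*% t(W[[l]])
            delta <- delta * (act[[l]] > 0)
            if (dropout > 0 && !is.null(fw$masks[[l - 1L]]))
              delta <- delta * fw$masks[[l - 1L]] / (1 - dropout)
          }
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
          mhW <- mW[[l]] / (1 - beta1^tstep)
          vhW <- vW[[l]] / (1 - beta2^tstep)
          mhb <- mb[[l]] / (1 - beta1^tstep)
          vhb <- vb[[l]] / (1 - beta2^tstep)
          W[[l]] <- W[[l]] - lr * mhW / (sqrt(vhW) + eps)
          b[[l]] <- b[[l]] - lr * mhb / (sqrt(vhb) + eps)
        }
      }
      val_p <- forward(x_val, train = FALSE)$act[[L + 1L]]
      vl <- loss_fn(val_p, y_val, w_val)
      if (vl < best$loss - 1e-9) {
        best <- list(loss = vl, W = W, b = b)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait > patience) break
      }
    }
    structure(list(W = best$W, b = best$b, center = center, scale = scale_,
                   task = task, hidden = hidden,
                   dropout = dropout, n_out = n_out, val_loss = best$loss,
                   epochs_run = ep, seed = seed),
              class = "pwas_mlp")
  })
}

#' Predict from a fitted network
#'
#' @param object a `pwas_mlp`.
#' @param x feature matrix.
#' @param ... unused.
#' @return matrix of probabilities (classification) or values (regression);
#'   a vector when the model has a single output.
#' @export
predict.pwas_mlp <- function(object, x, ...) {
  h <- as.matrix(x)
  if (!is.null(object$center))
    h <- sweep(sweep(h, 2L, object$center), 2L, object$scale, `/`)
  L <- length(object$W)
  for (l in seq_len(L)) {
    z <- sweep(h %*% object$W[[l]], 2L, object$b[[l]], `+`)
    h <- if (l < L) pmax(z, 0)
    else if (object$task == "classification") 1 / (1 + exp(-z)) else z
  }
  if (ncol(h) == 1L) as.numeric(h) else h
}

#' @export
print.pwas_mlp <- function(x, ...) {
  cat("<pwas_mlp>", x$task, "- hidden [", paste(x$hidden, collapse = ","),
      "] dropout", x$dropout, "- val loss", signif(x$val_loss, 4),
      "after", x$epochs_run, "epochs\n")
  invisible(x)
}
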