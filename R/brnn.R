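#' Train a Bayesian-regularized neural network for methane prediction
#'
#' A single-hidden-layer network with `hidden` tanh neurons and a linear
#' output, trained by Levenberg-Marquardt minimization of
#' `F = beta * E_D + alpha * E_W` (E_D = error sum of squares, E_W = sum
#' of squared weights). After each epoch the regularization pair is
#' updated by the Gauss-Newton approximation to the Bayesian evidence:
#' `gamma = npar - 2 * alpha * tr(H^-1)` effective parameters,
#' `alpha = gamma / (2 E_W)`, `beta = (n - gamma) / (2 E_D)`. Inputs are
#' z-scored and targets centered and scaled internally; weights are
#' initialized N(0, sd 0.1) under the seed, so training is deterministic.
#'
#' @param x spectra matrix (rows = samples).
#' @param y numeric target (methane, g/d).
#' @param hidden hidden neurons (default 2).
#' @param epochs training epochs (default 100).
#' @param seed integer seed for weight initialization.
#' @param init_sd standard deviation of the initial weights.
#' @return A `brnn_fit` object: weights, regularization pair, effective
#'   number of parameters, scaling constants, training history.
#' @export
train_brnn <- function(x, y, hidden = 2, epochs = 100, seed = 1L,
                       init_sd = 0.1) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 10) stop("at least 10 training pairs are required")
  if (length(y) != n) stop("x and y disagree in length")
  xm <- colMeans(x)
  xs <- apply(x, 2, stats::sd)
  xs[xs == 0 | !is.finite(xs)] <- 1
  X <- sweep(sweep(x, 2, xm), 2, xs, `/`)
  ym <- mean(y)
  ys <- stats::sd(y)
  if (is.na(ys) || ys == 0) ys <- 1
  yz <- (y - ym) / ys
  d <- ncol(X)
  h <- hidden
  npar <- h * (d + 1) + h + 1
  set.seed(seed)
  theta <- stats::rnorm(npar, sd = init_sd)

  unpack <- function(th) {
    v <- matrix(th[seq_len(d * h)], d, h)
    bh <- th[d * h + seq_len(h)]
    w <- th[d * h + h + seq_len(h)]
    b0 <- th[npar]
    list(v = v, bh = bh, w = w, b0 = b0)
  }
  forward <- function(th) {
    p <- unpack(th)
    A <- tanh(sweep(X %*% p$v, 2, p$bh, `+`))
    list(pred = as.numeric(A %*% p$w + p$b0), A = A, p = p)
  }
  jacobian <- function(fw) {
    A <- fw$A; p <- fw$p
    dA <- 1 - A^2
    J <- matrix(0, n, npar)
    for (j in seq_len(h)) {
      cols <- (j - 1) * d + seq_len(d)
      J[, cols] <- X * (p$w[j] * dA[, j])
      J[, d * h + j] <- p$w[j] * dA[, j]
      J[, d * h + h + j] <- A[, j]
    }
    J[, npar] <- 1
    J
  }

  alpha <- 0.01
  beta <- 1
  mu <- 0.005
  history <- matrix(NA_real_, epochs, 4,
                    dimnames = list(NULL, c("ed", "ew", "alpha", "beta")))
  fw <- forward(theta)
  for (ep in seq_len(epochs)) {
    e <- yz - fw$pred
    ed <- sum(e^2)
    ew <- sum(theta^2)
    Fobj <- beta * ed + alpha * ew
    J <- jacobian(fw)
    JtJ <- crossprod(J)
    g <- -2 * beta * crossprod(J, e)[, 1] + 2 * alpha * theta
    accepted <- FALSE
    for (try in 1:12) {
      H <- 2 * beta * JtJ + diag(2 * alpha + mu, npar)
      delta <- tryCatch(solve(H, -g), error = function(err) NULL)
      if (!is.null(delta)) {
        cand <- theta + delta
        fw_c <- forward(cand)
        e_c <- yz - fw_c$pred
        F_c <- beta * sum(e_c^2) + alpha * sum(cand^2)
        if (is.finite(F_c) && F_c < Fobj) {
          theta <- cand
          fw <- fw_c
          mu <- max(mu * 0.1, 1e-12)
          accepted <- TRUE
          break
        }
      }
      mu <- mu * 10
      if (mu > 1e10) break
    }
    e <- yz - fw$pred
    ed <- sum(e^2)
    ew <- sum(theta^2)
    if (!is.finite(ed) || !is.finite(ew)) {
      stop("non-finite training loss at epoch ", ep,
           " (ed = ", ed, ", ew = ", ew, ")")
    }
    # evidence update of the regularization pair
    Hreg <- 2 * beta * JtJ + diag(2 * alpha, npar)
    trHinv <- tryCatch(sum(diag(chol2inv(chol(Hreg)))),
                       error = function(err) NA_real_)
    if (is.finite(trHinv)) {
      gamma <- npar - 2 * alpha * trHinv
      gamma <- min(max(gamma, 1e-6), npar - 1e-6)
      alpha <- gamma / (2 * max(ew, 1e-12))
      beta <- max((n - gamma), 1e-6) / (2 * max(ed, 1e-12))
    }
    history[ep, ] <- c(ed, ew, alpha, beta)
    if (!accepted && mu > 1e10) {
      history <- history[seq_len(ep), , drop = FALSE]
      break
    }
  }
  gamma <- npar - 2 * alpha * sum(diag(chol2inv(chol(
    2 * beta * crossprod(jacobian(fw)) + diag(2 * alpha, npar)))))
  structure(
    list(theta = theta, hidden = h, input_dim = d, npar = npar,
         alpha = alpha, beta = beta, gamma = gamma,
         x_center = xm, x_scale = xs, y_center = ym, y_scale = ys,
         epochs = nrow(stats::na.omit(history)), seed = seed,
         history = tibble::as_tibble(stats::na.omit(history))),
    class = "brnn_fit"
  )
}

#' @export
print.brnn_fit <- function(x, ...) {
  cat("<brnn_fit>", x$hidden, "tanh neurons,", x$input_dim, "inputs,",
      x$npar, "weights\n")
  cat(sprintf("alpha = %.4g, beta = %.4g, effective parameters = %.1f\n",
              x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' Predict methane from spectra with a trained network
#'
#' Deterministic forward pass; the training-time input standardization and
#' target scaling are applied and inverted.
#'
#' @param model a `brnn_fit` from [train_brnn()].
#' @param spectra matrix (rows = samples) with the training input
#'   dimension.
#' @return Numeric vector of predicted methane (g/d).
#' @export
predict_ch4 <- function(model, spectra) {
  x <- as.matrix(spectra)
  if (ncol(x) != model$input_dim) {
    stop("input has ", ncol(x), " columns; the model expects ",
         model$input_dim)
  }
  X <- sweep(sweep(x, 2, model$x_center), 2, model$x_scale, `/`)
  d <- model$input_dim; h <- model$hidden
  v <- matrix(model$theta[seq_len(d * h)], d, h)
  bh <- model$theta[d * h + seq_len(h)]
  w <- model$theta[d * h + h + seq_len(h)]
  b0 <- model$theta[model$npar]
  A <- tanh(sweep(X %*% v, 2, bh, `+`))
  as.numeric(A %*% w + b0) * model$y_scale + model$y_center
}

#' @export
predict.brnn_fit <- function(object, newdata, ...) {
  predict_ch4(object, newdata)
}

#' Prediction accuracy and error
#'
#' Pearson correlation between observed and predicted values, and the
#' root-mean-square error.
#'
#' @param predicted,observed numeric vectors of equal length (>= 3).
#' @return Tibble with `r`, `rmse`, `n`.
#' @export
prediction_metrics <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(observed) < 3) {
    stop("predicted and observed must have equal length >= 3")
  }
  r <- if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) {
    warning("zero variance; correlation undefined")
    NA_real_
  } else {
    stats::cor(predicted, observed)
  }
  tibble::tibble(r = r,
                 rmse = sqrt(mean((predicted - observed)^2)),
                 n = length(observed))
}
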