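#' Fit the reference multilayer perceptron
#'
#' A small fully connected network with two hidden layers (10 and 2 nodes
#' by default) and logistic activations everywhere, trained by full-batch
#' Adam on the binary cross-entropy with a light L2 penalty.  Training
#' stops when the infinity norm of the gradient drops below `tol`
#' (convergence) or after `max_iter` epochs; initial weights are drawn
#' `N(0, 0.5)` under `seed`, so fits are fully reproducible.
#'
#' @param x Numeric matrix of standardized predictors, one row per example.
#' @param y 0/1 vector (1 = active).
#' @param hidden Integer vector of the two hidden-layer widths.
#' @param seed Integer seed for the weight initialization.
#' @param max_iter Epoch cap.
#' @param learn_rate Adam step size.
#' @param tol Gradient infinity-norm convergence threshold.
#' @param l2 L2 penalty on the weights (keeps the optimum finite on
#'   separable data).
#' @return List of class `fam_mlp` with the weights, `converged`,
#'   `iterations`, `loss` and the training feature names.
#' @export
mlp_fit <- function(x, y, hidden = c(10, 2), seed = 1L, max_iter = 2000,
                    learn_rate = 0.02, tol = 0.01, l2 = 1e-4) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(x), all(y %in% c(0, 1)))
  if (length(hidden) != 2 || any(hidden < 1)) {
    stop("hidden must give two positive layer widths", call. = FALSE)
  }
  if (length(unique(y)) < 2) {
    stop("training data must contain both classes", call. = FALSE)
  }
  p <- ncol(x)
  init <- with_substream(as.integer(seed), list(
    W1 = matrix(rnorm(p * hidden[1], sd = 0.5), p, hidden[1]),
    b1 = rnorm(hidden[1], sd = 0.5),
    W2 = matrix(rnorm(hidden[1] * hidden[2], sd = 0.5), hidden[1], hidden[2]),
    b2 = rnorm(hidden[2], sd = 0.5),
    w3 = rnorm(hidden[2], sd = 0.5),
    b3 = rnorm(1, sd = 0.5)
  ))
  fit <- mlp_train_cpp(
    x, y, init$W1, init$b1, init$W2, init$b2, init$w3, init$b3,
    as.integer(max_iter), learn_rate, tol, l2
  )
  structure(
    list(
      W1 = fit$W1, b1 = as.numeric(fit$b1), W2 = fit$W2,
      b2 = as.numeric(fit$b2), w3 = as.numeric(fit$w3), b3 = fit$b3,
      converged = fit$converged, iterations = fit$iterations,
      loss = fit$loss, features = colnames(x), hidden = hidden
    ),
    class = "fam_mlp"
  )
}

#' @rdname mlp_fit
#' @param model A fitted `fam_mlp`.
#' @param newdata Matrix with the same feature columns as at training.
#' @return `mlp_predict()` returns scores in `[0, 1]` (probability of the
#'   active class).
#' @export
mlp_predict <- function(model, newdata) {
  stopifnot(inherits(model, "fam_mlp"))
  newdata <- as.matrix(newdata)
  if (!is.null(model$features) && !is.null(colnames(newdata)) &&
    !identical(colnames(newdata), model$features)) {
    stop("feature schema of newdata does not match the training schema",
      call. = FALSE
    )
  }
  as.numeric(mlp_forward_cpp(
    newdata, model$W1, model$b1, model$W2, model$b2, model$w3, model$b3
  ))
}

#' @export
print.fam_mlp <- function(x, ...) {
  cat(
    "<fam_mlp> ", length(x$features), "-", x$hidden[1], "-", x$hidden[2],
    "-1 logistic network; ", x$iterations, " epochs; ",
    if (isTRUE(x$converged)) "converged" else "max_iter reached",
    "; loss ", signif(x$loss, 4), "\n",
    sep = ""
  )
  invisible(x)
}
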