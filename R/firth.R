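#' Firth-penalized logistic regression
#'
#' Fits a logistic regression by maximizing the Jeffreys-penalized
#' log-likelihood `l(beta) + 0.5 * log det I(beta)` (Firth 1993), which removes
#' the first-order bias of the MLE and yields finite coefficients even under
#' complete separation. Newton-Raphson iterations use the hat-diagonal-adjusted
#' score `U*(beta) = X' (y - p + h (0.5 - p))`, with step-halving whenever a
#' step would decrease the penalized likelihood. Predictors are standardized
#' internally and coefficients back-transformed.
#'
#' @param x numeric matrix (or data.frame) of predictors, one row per subject;
#'   an intercept column is added internally.
#' @param y binary outcome (0/1, logical, or two-level factor/character;
#'   coerced with [as_binary_labels()]).
#' @param max_iter maximum Newton iterations (default 50).
#' @param tol convergence when the largest coefficient change drops below this
#'   (default 1e-8, on the standardized scale).
#' @return list of class `"firth_fit"`: `coefficients` (named, original
#'   scale, `"(Intercept)"` first), `standard_errors`,
#'   `log_likelihood_penalized`, `converged`, `iterations`, `probabilities`
#'   (fitted, in (0,1)), `y`, `vcov`.
#' @references Firth, D. (1993) Bias reduction of maximum likelihood
#'   estimates. Biometrika 80, 27-38.
#' @export
firth_fit <- function(x, y, max_iter = 50L, tol = 1e-8) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as_binary_labels(y)
  if (nrow(x) != length(y)) stop("x and y dimensions disagree")
  if (nrow(x) < ncol(x) + 1L) stop("need n >= number of predictors + 1")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))

  mu <- colMeans(x)
  sg <- apply(x, 2L, stats::sd)
  if (any(sg == 0)) stop("constant predictor column: ", paste(colnames(x)[sg == 0], collapse = ", "))
  z <- sweep(sweep(x, 2L, mu), 2L, sg, "/")
  X <- cbind(`(Intercept)` = 1, z)
  p_dim <- ncol(X)
  qr_x <- qr(X)
  if (qr_x$rank < p_dim) stop("design matrix is rank-deficient after standardization")

  pen_ll <- function(beta) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    info <- crossprod(X, X * w)
    ll <- sum(y * eta - log1p(exp(eta)))
    ll + 0.5 * determinant(info, logarithm = TRUE)$modulus
  }

  beta <- rep(0, p_dim)
  ll_old <- pen_ll(beta)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    Xw <- X * sqrt(w)
    info <- crossprod(Xw)
    # hat diagonals of W^(1/2) X (X'WX)^-1 X' W^(1/2)
    h <- rowSums((Xw %*% solve(info)) * Xw)
    u_star <- drop(crossprod(X, y - p + h * (0.5 - p)))
    delta <- solve(info, u_star)
    step <- 1
    repeat {
      beta_new <- beta + step * delta
      ll_new <- pen_ll(beta_new)
      if (is.finite(ll_new) && ll_new >= ll_old - 1e-12) break
      step <- step / 2
      if (step < 1e-10) { beta_new <- beta; ll_new <- ll_old; break }
    }
    moved <- max(abs(beta_new - beta))
    beta <- beta_new
    ll_old <- ll_new
    if (moved < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("Firth fit did not converge in ", max_iter,
            " iterations; returning the current iterate")

  eta <- drop(X %*% beta)
  p_fit <- stats::plogis(eta)
  w <- p_fit * (1 - p_fit)
  info <- crossprod(X, X * w)
  vcov_std <- solve(info)

  # back-transform: beta_j = beta_std_j / s_j ; b0 = b0_std - sum(beta_std_j mu_j / s_j)
  k <- length(sg)
  Tm <- diag(p_dim)
  Tm[1L, 1L + seq_len(k)] <- -mu / sg
  for (j in seq_len(k)) Tm[1L + j, 1L + j] <- 1 / sg[j]
  coef_orig <- drop(Tm %*% beta)
  vcov_orig <- Tm %*% vcov_std %*% t(Tm)
  nms <- c("(Intercept)", colnames(x))
  names(coef_orig) <- nms
  dimnames(vcov_orig) <- list(nms, nms)

  # the standardized design shifts log det I by 2*log|det T|; report the
  # penalized likelihood on the original scale
  structure(list(coefficients = coef_orig,
                 standard_errors = sqrt(diag(vcov_orig)),
                 log_likelihood_penalized = as.numeric(ll_old) + sum(log(sg)),
                 converged = converged, iterations = iter,
                 probabilities = p_fit, y = y, vcov = vcov_orig),
            class = "firth_fit")
}

#' @export
print.firth_fit <- function(x, ...) {
  cat(sprintf("Firth-penalized logistic regression (%d iterations, %sconverged)\n",
              x$iterations, if (x$converged) "" else "NOT "))
  print(round(cbind(coef = x$coefficients, se = x$standard_errors), 4))
  cat(sprintf("penalized log-likelihood: %.4f\n", x$log_likelihood_penalized))
  invisible(x)
}

#' Classify subjects from a fitted Firth model
#'
#' Labels a subject positive when its fitted probability is at or above
#' `cutoff`. With `cutoff = NULL` the least-squares optimal probability
#' cut-off ([best_cutoff()]) on the fitted probabilities is used.
#'
#' @param fit a [firth_fit()] result.
#' @param cutoff probability threshold in \[0, 1\] (0 labels everyone
#'   positive, 1 everyone negative), or `NULL` for the least-squares
#'   optimum.
#' @return list: `labels` (0/1), `cutoff`, `sensitivity`, `specificity`.
#' @export
classify <- function(fit, cutoff = NULL) {
  stopifnot(inherits(fit, "firth_fit"))
  p <- fit$probabilities
  if (is.null(cutoff)) {
    co <- best_cutoff(p, fit$y, positive = 1L)
    cutoff <- co$cutoff
  } else if (!is.numeric(cutoff) || cutoff < 0 || cutoff > 1) {
    stop("cutoff must lie in [0, 1]")
  }
  lab <- as.integer(p >= cutoff)
  list(labels = lab, cutoff = cutoff,
       sensitivity = mean(lab[fit$y == 1L] == 1L),
       specificity = mean(lab[fit$y == 0L] == 0L))
}
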