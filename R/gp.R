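# Gaussian-process regression with an anisotropic squared-exponential kernel
# and a fitted nugget. Features are standardized and the target centred and
# scaled before hyperparameters (log lengthscales, log signal sd, log noise
# sd) are chosen by marginal-likelihood maximization (L-BFGS-B with seeded
# restarts). Small-n exact GP: O(n^3) Cholesky per likelihood evaluation.

sq_dist <- function(X1, X2, ls) {
  X1 <- sweep(X1, 2, ls, "/")
  X2 <- sweep(X2, 2, ls, "/")
  outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * tcrossprod(X1, X2)
}

gp_nll <- function(theta, X, y) {
  d <- ncol(X)
  ls <- exp(theta[1:d])
  sf2 <- exp(2 * theta[d + 1])
  sn2 <- exp(2 * theta[d + 2])
  n <- nrow(X)
  K <- sf2 * exp(-0.5 * pmax(sq_dist(X, X, ls), 0)) + diag(sn2 + 1e-10, n)
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(1e10)
  alpha <- backsolve(L, forwardsolve(t(L), y))
  as.numeric(0.5 * crossprod(y, alpha) + sum(log(diag(L))) +
               0.5 * n * log(2 * pi))
}

#' Fit a Gaussian-process regression
#'
#' @param X Numeric matrix or data frame of inputs (n x d).
#' @param y Numeric response vector of length n.
#' @param seed Seed for the hyperparameter restarts.
#' @param n_restarts Number of seeded random restarts in addition to the
#'   default start.
#' @param noise If FALSE the noise sd is pinned near zero (interpolating GP).
#' @return An object of class `lv_gp` supporting [gp_predict()].
#' @export
gp_fit <- function(X, y, seed = 1L, n_restarts = 3, noise = TRUE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  d <- ncol(X)
  if (length(y) != n) abort("X and y sizes disagree")
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  if (qr(cbind(1, Xs))$rank < min(n, d + 1))
    abort("rank-deficient inputs: cannot fit the emulator")
  y_ctr <- mean(y)
  y_scl <- sd(y)
  constant <- !is.finite(y_scl) || y_scl < 1e-12 * (abs(y_ctr) + 1)
  if (constant) {
    return(structure(list(constant = TRUE, y_ctr = y_ctr, ctr = ctr,
                          scl = scl), class = "lv_gp"))
  }
  ys <- (y - y_ctr) / y_scl

  lb <- c(rep(log(0.05), d), log(1e-2), log(1e-6))
  ub <- c(rep(log(100), d), log(10), log(2))
  if (!noise) ub[d + 2] <- log(1e-5)
  start0 <- c(rep(log(1), d), log(1), if (noise) log(0.1) else log(1e-6))
  starts <- list(start0)
  withr::with_seed(seed, {
    for (i in seq_len(n_restarts))
      starts[[i + 1]] <- runif(d + 2, lb, ub)
  })
  best <- NULL
  for (s in starts) {
    op <- tryCatch(
      optim(s, gp_nll, X = Xs, y = ys, method = "L-BFGS-B",
            lower = lb, upper = ub, control = list(maxit = 200)),
      error = function(e) NULL)
    if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
  }
  if (is.null(best)) abort("GP hyperparameter optimization failed")
  theta <- best$par
  ls <- exp(theta[1:d])
  sf2 <- exp(2 * theta[d + 1])
  sn2 <- exp(2 * theta[d + 2])
  K <- sf2 * exp(-0.5 * pmax(sq_dist(Xs, Xs, ls), 0)) + diag(sn2 + 1e-10, n)
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), ys))
  structure(list(constant = FALSE, X = Xs, ctr = ctr, scl = scl,
                 y_ctr = y_ctr, y_scl = y_scl, ls = ls, sf2 = sf2, sn2 = sn2,
                 L = L, alpha = alpha, nll = best$value),
            class = "lv_gp")
}

#' Predict from a fitted Gaussian process
#'
#' @param fit An `lv_gp` object from [gp_fit()].
#' @param Xnew Matrix or data frame of prediction inputs.
#' @return A list with `mean` and `sd` (posterior sd of the latent mean).
#' @export
gp_predict <- function(fit, Xnew) {
  stopifnot(inherits(fit, "lv_gp"))
  Xnew <- as.matrix(Xnew)
  storage.mode(Xnew) <- "double"
  if (isTRUE(fit$constant)) {
    return(list(mean = rep(fit$y_ctr, nrow(Xnew)),
                sd = rep(0, nrow(Xnew))))
  }
  Xs <- sweep(sweep(Xnew, 2, fit$ctr), 2, fit$scl, "/")
  Ks <- fit$sf2 * exp(-0.5 * pmax(sq_dist(Xs, fit$X, fit$ls), 0))
  mu <- as.numeric(Ks %*% fit$alpha)
  v <- forwardsolve(t(fit$L), t(Ks))
  var <- pmax(fit$sf2 - colSums(v^2), 0)
  list(mean = fit$y_ctr + fit$y_scl * mu,
       sd = fit$y_scl * sqrt(var))
}
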