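#' Mesh-adaptive direct search with orthogonal poll directions
#'
#' Derivative-free box-constrained minimizer in the OrthoMADS family: at each
#' iteration the incumbent is polled along an orthogonal basis (a seeded
#' Householder reflection of a random unit direction) and its negation,
#' scaled by the current mesh size. The mesh is held on success and contracts
#' on failure; the incumbent objective is monotone non-increasing and the
#' whole evaluation sequence is reproducible under a fixed seed.
#'
#' @param objective Function of a numeric vector returning a finite scalar.
#' @param lower,upper Finite bound vectors of equal length.
#' @param seed Integer seed controlling the poll directions.
#' @param budget Maximum number of objective evaluations
#'   (>= length(lower) + 1).
#' @param x0 Optional start point (default: box midpoint).
#' @param mesh_tol Mesh size below which the search is declared converged.
#' @param search_frac Fraction of the budget spent on an initial seeded
#'   Latin-hypercube search step (global exploration) before polling starts
#'   from the best point found.
#' @return A list with `par`, `value`, `evaluations`, `converged`, `seed`,
#'   and the monotone `history` of incumbent values.
#' @export
mads_minimize <- function(objective, lower, upper, seed = 1L, budget = 200,
                          x0 = NULL, mesh_tol = 1e-7, search_frac = 0.15) {
  d <- length(lower)
  if (length(upper) != d || any(!is.finite(c(lower, upper))) ||
      any(upper < lower))
    abort("bounds must be finite with lower <= upper")
  if (budget < d + 1) abort("budget must be at least dimension + 1")
  span <- upper - lower
  fixed <- span == 0
  unscale <- function(u) lower + u * span
  u0 <- if (is.null(x0)) rep(0.5, d) else (x0 - lower) / ifelse(fixed, 1, span)
  u0[fixed] <- 0
  u0 <- pmin(pmax(u0, 0), 1)

  f0 <- objective(unscale(u0))
  if (!is.finite(f0))
    abort("objective is not finite at the initial point")
  evals <- 1L
  inc_u <- u0
  inc_f <- f0
  history <- f0
  delta <- 0.25
  converged <- FALSE

  if (all(fixed) || all(span[!fixed] == 0)) {
    return(list(par = unscale(inc_u), value = inc_f, evaluations = evals,
                converged = TRUE, seed = seed, history = history))
  }

  last_dir <- NULL
  withr::with_seed(seed, {
    # search step: seeded space-filling exploration, then poll from the best
    n_search <- min(floor(search_frac * budget), max(0, budget - 4 * d - 1))
    if (n_search >= 2 && any(!fixed)) {
      S <- lhs::randomLHS(n_search, d)
      for (i in seq_len(n_search)) {
        cand <- S[i, ]
        cand[fixed] <- 0
        fc <- objective(unscale(cand))
        evals <- evals + 1L
        if (is.finite(fc) && fc < inc_f) {
          inc_u <- cand
          inc_f <- fc
        }
        history <- c(history, inc_f)
      }
    }
    while (evals < budget) {
      if (delta < mesh_tol) { converged <- TRUE; break }
      v <- rnorm(d)
      v[fixed] <- 0
      nv <- sqrt(sum(v^2))
      if (nv == 0) next
      v <- v / nv
      H <- diag(d) - 2 * tcrossprod(v)
      D <- cbind(H, -H)
      if (!is.null(last_dir)) {
        # dynamic ordering: poll the direction closest to the last
        # successful step first
        D <- D[, order(-crossprod(D, last_dir)), drop = FALSE]
      }
      success <- FALSE
      for (j in seq_len(ncol(D))) {
        if (evals >= budget) break
        cand <- pmin(pmax(inc_u + delta * D[, j], 0), 1)
        cand[fixed] <- 0
        if (all(cand == inc_u)) next
        fc <- objective(unscale(cand))
        evals <- evals + 1L
        if (is.finite(fc) && fc < inc_f) {
          last_dir <- (cand - inc_u) / max(sqrt(sum((cand - inc_u)^2)), 1e-300)
          inc_u <- cand
          inc_f <- fc
          history <- c(history, fc)
          success <- TRUE
          break # opportunistic poll
        }
        history <- c(history, inc_f)
      }
      delta <- if (success) delta else delta / 2
    }
  })
  list(par = unscale(inc_u), value = inc_f, evaluations = evals,
       converged = converged, seed = seed, history = history)
}
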