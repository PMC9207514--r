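#' Salp swarm algorithm for bounded continuous minimization
#'
#' The salp swarm algorithm (SSA) models a chain of salps: the first
#' individual (the leader) searches globally around the best-known solution
#' (the "food" position) while every follower moves to the midpoint between
#' itself and its predecessor, so the chain contracts toward the food as
#' iterations proceed.  The leader's step size is governed by the
#' convergence factor \eqn{c_1 = 2 e^{-(4t/T)^2}}, which decays from 2 at
#' the first iteration to nearly 0 at the last, trading exploration for
#' exploitation.
#'
#' Per dimension \eqn{i}, the leader moves to
#' \eqn{F_i \pm c_1 ((X^{max}_i - X^{min}_i) c_2 + X^{min}_i)} with fresh
#' uniform \eqn{c_2, c_3 \in [0,1]} and the sign taken positive when
#' \eqn{c_3 \ge 0.5}.  Followers update sequentially, each seeing its
#' predecessor's already-updated position.  All positions are clamped to
#' the box after every move, and the food position/fitness is the best
#' solution seen so far, so the fitness trace is non-increasing.
#'
#' @param fn objective function taking a numeric vector of length
#'   `length(lower)` and returning a finite scalar; minimized.
#' @param lower,upper numeric vectors of box bounds, `lower < upper`
#'   elementwise (scalars are recycled to a common length).
#' @param n_pop population size, at least 2.
#' @param max_iter number of iterations, at least 1.
#' @param init optional matrix of starting positions (rows), e.g. a known
#'   good solution; rows are clamped to the box and the remaining
#'   `n_pop - nrow(init)` salps are drawn uniformly.
#' @param seed optional integer; when given, `set.seed(seed)` is called
#'   first.  When `NULL` the current RNG stream is used (so callers can
#'   manage seeding themselves).
#' @return A list with `par` (best position found), `value` (its fitness)
#'   and `trace` (food fitness after initialization and after each
#'   iteration, length `max_iter + 1`, non-increasing).
#' @examples
#' out <- ssa_optimize(function(v) sum(v^2), lower = -5, upper = 5,
#'                     n_pop = 30, max_iter = 50, seed = 1)
#' out$value
#' @export
ssa_optimize <- function(fn, lower, upper, n_pop = 30L, max_iter = 100L,
                         init = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- max(length(lower), length(upper))
  lower <- rep_len(as.numeric(lower), n)
  upper <- rep_len(as.numeric(upper), n)
  if (any(!is.finite(lower)) || any(!is.finite(upper)) ||
      any(lower >= upper))
    stop("bounds must be finite with lower < upper elementwise")
  n_pop <- as.integer(n_pop)
  max_iter <- as.integer(max_iter)
  if (n_pop < 2L) stop("'n_pop' must be >= 2")
  if (max_iter < 1L) stop("'max_iter' must be >= 1")

  pos <- ssa_init_population(n_pop, lower, upper)
  if (!is.null(init)) {
    init <- matrix(as.numeric(init), ncol = n)
    k <- min(nrow(init), n_pop)
    pos[seq_len(k), ] <- clamp_rows(init[seq_len(k), , drop = FALSE],
                                    lower, upper)
  }

  evaluate <- function(P) {
    f <- apply(P, 1L, fn)
    if (any(!is.finite(f))) {
      bad <- which(!is.finite(f))[[1L]]
      stop("fitness function returned a non-finite value at position (",
           paste(signif(P[bad, ], 6), collapse = ", "), ")")
    }
    f
  }

  fit <- evaluate(pos)
  best <- which.min(fit)
  food <- pos[best, ]
  food_fit <- fit[[best]]
  trace <- numeric(max_iter + 1L)
  trace[[1L]] <- food_fit

  for (t in seq_len(max_iter)) {
    c1 <- ssa_convergence_factor(t, max_iter)
    pos[1L, ] <- ssa_update_leader(food, lower, upper, c1)
    pos <- ssa_update_followers(pos)
    pos <- clamp_rows(pos, lower, upper)
    fit <- evaluate(pos)
    best <- which.min(fit)
    if (fit[[best]] < food_fit) {
      food_fit <- fit[[best]]
      food <- pos[best, ]
    }
    trace[[t + 1L]] <- food_fit
  }
  list(par = food, value = food_fit, trace = trace)
}

#' SSA building blocks
#'
#' `ssa_convergence_factor()` computes \eqn{c_1 = 2 e^{-(4t/T)^2}}.
#' `ssa_init_population()` draws `n_pop` positions uniformly in the box.
#' `ssa_update_leader()` performs the leader move around the food position
#' (fresh `c2`, `c3` per dimension) and clamps to the box.
#' `ssa_update_followers()` replaces each row `j >= 2` by the midpoint of
#' itself and the already-updated row `j - 1`, in order; row 1 (the
#' leader) is untouched.
#'
#' @param t current iteration, `0 <= t <= max_iter`.
#' @param max_iter total number of iterations, at least 1.
#' @param n_pop population size.
#' @param lower,upper numeric bound vectors of equal length.
#' @param food current food (best-so-far) position.
#' @param c1 convergence factor, `>= 0`.
#' @param positions numeric matrix, one salp per row.
#' @return `ssa_convergence_factor()`: scalar; `ssa_init_population()` and
#'   `ssa_update_followers()`: a matrix; `ssa_update_leader()`: a vector.
#' @export
ssa_convergence_factor <- function(t, max_iter) {
  if (max_iter < 1L) stop("'max_iter' must be >= 1")
  if (t < 0 || t > max_iter) stop("'t' must lie in [0, max_iter]")
  2 * exp(-(4 * t / max_iter)^2)
}

#' @rdname ssa_convergence_factor
#' @export
ssa_init_population <- function(n_pop, lower, upper) {
  n <- length(lower)
  r <- matrix(stats::runif(n_pop * n), nrow = n_pop)
  sweep(sweep(r, 2L, upper - lower, `*`), 2L, lower, `+`)
}

#' @rdname ssa_convergence_factor
#' @export
ssa_update_leader <- function(food, lower, upper, c1) {
  n <- length(food)
  c2 <- stats::runif(n)
  c3 <- stats::runif(n)
  step <- c1 * ((upper - lower) * c2 + lower)
  out <- ifelse(c3 >= 0.5, food + step, food - step)
  pmin(pmax(out, lower), upper)
}

#' @rdname ssa_convergence_factor
#' @export
ssa_update_followers <- function(positions) {
  m <- nrow(positions)
  if (m < 2L) return(positions)
  for (j in 2:m)
    positions[j, ] <- (positions[j, ] + positions[j - 1L, ]) / 2
  positions
}

clamp_rows <- function(P, lower, upper) {
  P <- sweep(P, 2L, lower, pmax)
  sweep(P, 2L, upper, pmin)
}
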