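#' L-BFGS optimizer configuration
#'
#' Controls the limited-memory quasi-Newton engine used to solve for the
#' fusion weight and to fit the sigmoid brightness model.
#'
#' @param h0 Initial iterate for the 1-D weight solve (default 0.5).
#' @param epsilon Gradient-norm stopping threshold (default 1e-5).
#' @param num Memory size: number of stored (step, gradient-change) vector
#'   pairs (default 10).
#' @param max_iter Iteration cap (default 200).
#' @return An object of class `lbfgs_config`.
#' @export
lbfgs_config <- function(h0 = 0.5, epsilon = 1e-5, num = 10, max_iter = 200) {
  if (!is.finite(epsilon) || epsilon <= 0) stop("epsilon must be > 0")
  if (num < 1) stop("memory size num must be >= 1")
  if (max_iter < 1) stop("max_iter must be >= 1")
  structure(list(h0 = h0, epsilon = epsilon, num = as.integer(num),
                 max_iter = as.integer(max_iter)),
            class = "lbfgs_config")
}

#' Minimize a smooth function by limited-memory BFGS
#'
#' A self-contained L-BFGS implementation: the search direction is obtained
#' from the classical two-loop recursion over the newest `num` stored
#' (s, t) = (step, gradient-change) pairs, with the standard
#' `(s.t / t.t) I` initial Hessian scaling; the step length comes from
#' backtracking line search under the Armijo sufficient-decrease condition.
#' Pairs with non-positive curvature `s.t` are discarded to keep the
#' inverse-Hessian approximation positive definite. Iteration stops when the
#' gradient max-norm falls to `epsilon` or `max_iter` is reached.
#'
#' @param fn Objective function of a numeric vector.
#' @param gr Gradient function (same signature, returns a vector).
#' @param x0 Numeric start vector.
#' @param cfg An [lbfgs_config()].
#' @return List with `par`, `value`, `grad_norm`, `iterations`, `converged`.
#' @export
lbfgs_minimize <- function(fn, gr, x0, cfg = lbfgs_config()) {
  x <- as.numeric(x0)
  g <- gr(x)
  fx <- fn(x)
  if (!all(is.finite(c(fx, g)))) stop("non-finite objective or gradient at start")
  S <- list()  # steps s_k
  Tt <- list() # gradient changes t_k
  k <- 0L
  while (max(abs(g)) > cfg$epsilon && k < cfg$max_iter) {
    p <- -two_loop_direction(g, S, Tt)
    if (sum(p * g) >= 0) p <- -g  # not a descent direction: steepest-descent reset
    # Armijo backtracking
    alpha <- 1
    c1 <- 1e-4
    slope <- sum(g * p)
    repeat {
      x_new <- x + alpha * p
      f_new <- fn(x_new)
      if (is.finite(f_new) && f_new <= fx + c1 * alpha * slope) break
      alpha <- alpha / 2
      if (alpha < 1e-20) { x_new <- x; f_new <- fx; break }
    }
    if (identical(x_new, x)) break  # line search failed; give up
    g_new <- gr(x_new)
    s <- x_new - x
    t <- g_new - g
    if (sum(s * t) > 1e-12 * sum(t * t)) {  # curvature condition
      S[[length(S) + 1L]] <- s
      Tt[[length(Tt) + 1L]] <- t
      if (length(S) > cfg$num) { S <- S[-1]; Tt <- Tt[-1] }
    }
    x <- x_new; g <- g_new; fx <- f_new
    k <- k + 1L
  }
  list(par = x, value = fx, grad_norm = max(abs(g)),
       iterations = k, converged = max(abs(g)) <= cfg$epsilon)
}

# Two-loop recursion: returns B g, the inverse-Hessian approximation applied
# to the gradient, from the stored pair history.
two_loop_direction <- function(g, S, Tt) {
  m <- length(S)
  if (m == 0L) return(g)
  q <- g
  rho <- numeric(m)
  a <- numeric(m)
  for (i in m:1) {
    rho[i] <- 1 / sum(Tt[[i]] * S[[i]])
    a[i] <- rho[i] * sum(S[[i]] * q)
    q <- q - a[i] * Tt[[i]]
  }
  gamma <- sum(S[[m]] * Tt[[m]]) / sum(Tt[[m]] * Tt[[m]])
  r <- gamma * q
  for (i in 1:m) {
    b <- rho[i] * sum(Tt[[i]] * r)
    r <- r + S[[i]] * (a[i] - b)
  }
  r
}
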