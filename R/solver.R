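#' Squared spectral norm of a matrix
#'
#' Returns the square of the largest singular value, computed from the Gram
#' matrix of the smaller side for efficiency.
#'
#' @param D A nonempty numeric matrix with finite entries.
#' @return A nonnegative scalar.
#' @export
spectral_norm_sq <- function(D) {
  D <- as.matrix(D)
  if (length(D) == 0L) stop("spectral_norm_sq: empty matrix", call. = FALSE)
  if (!all(is.finite(D)))
    stop("spectral_norm_sq: non-finite entries", call. = FALSE)
  G <- if (nrow(D) <= ncol(D)) tcrossprod(D) else crossprod(D)
  # largest eigenvalue of the Gram matrix = squared largest singular value
  max(0, eigen(G, symmetric = TRUE, only.values = TRUE)$values[1])
}

#' Define a joint low-rank and sparse representation problem
#'
#' Bundles the feature matrix `Y`, the background dictionary `D` and the two
#' regularization weights of the program
#' \deqn{\min_{A,E} \|A\|_* + \beta \|A\|_1 + \alpha \|E\|_{2,1}
#'       \quad \mathrm{s.t.}\quad Y = DA + E.}
#' Setting `beta = 0` recovers the plain low-rank representation model.
#'
#' @param Y Feature matrix, one column per pixel (`k * omega^2` rows).
#' @param D Background dictionary with the same number of rows as `Y`.
#' @param alpha Weight of the column-sparse abnormality term, `> 0`.
#' @param beta Weight of the element-wise sparsity term, `>= 0`.
#' @return An object of class `jclrrsr_problem`.
#' @export
jclrrsr_problem <- function(Y, D, alpha, beta = 0) {
  Y <- as.matrix(Y); D <- as.matrix(D)
  if (nrow(Y) != nrow(D))
    stop("jclrrsr_problem: 'Y' and 'D' must have the same number of rows",
         call. = FALSE)
  if (!all(is.finite(Y)) || !all(is.finite(D)))
    stop("jclrrsr_problem: non-finite entries", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("jclrrsr_problem: 'alpha' must be > 0", call. = FALSE)
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0)
    stop("jclrrsr_problem: 'beta' must be >= 0", call. = FALSE)
  structure(list(Y = Y, D = D, alpha = alpha, beta = beta),
            class = "jclrrsr_problem")
}

#' Control parameters for the LADMAP solver
#'
#' @param gamma0 Initial penalty. `NULL` (default) chooses `0.1 / ||Y||_2`,
#'   which makes the schedule invariant to a global rescaling of the data.
#' @param gamma_max Cap on the penalty.
#' @param rho0 Penalty growth factor (`> 1`), applied only on iterations where
#'   the scaled iterate change falls below `eps2`.
#' @param eps1 Tolerance on the relative constraint residual
#'   `||Y - DA - E||_F / ||Y||_F`.
#' @param eps2 Tolerance on the penalty-scaled iterate change
#'   `gamma * max(||dA||_F, ||dU||_F, ||dE||_F) / ||Y||_F`.
#' @param max_iter Iteration cap.
#' @param theta_mode `"safe"` (default) sets the linearization constant to
#'   `||D||_2^2 + 1`, accounting for the auxiliary-variable coupling term in
#'   the smoothed Lagrangian; `"paper"` uses `||D||_2^2` exactly.
#' @param verbose Integer; `> 0` prints progress every `verbose` iterations.
#' @return A list of class `ladmap_control`.
#' @export
ladmap_control <- function(gamma0 = NULL, gamma_max = 1e10, rho0 = 1.9,
                           eps1 = 1e-6, eps2 = 1e-4, max_iter = 500L,
                           theta_mode = c("safe", "paper"), verbose = 0L) {
  theta_mode <- match.arg(theta_mode)
  if (!is.null(gamma0) && gamma0 <= 0)
    stop("ladmap_control: 'gamma0' must be > 0", call. = FALSE)
  if (gamma_max <= 0 || (!is.null(gamma0) && gamma_max < gamma0))
    stop("ladmap_control: 'gamma_max' must be >= gamma0", call. = FALSE)
  if (rho0 <= 1) stop("ladmap_control: 'rho0' must be > 1", call. = FALSE)
  if (eps1 <= 0 || eps2 <= 0)
    stop("ladmap_control: tolerances must be > 0", call. = FALSE)
  if (max_iter < 1) stop("ladmap_control: 'max_iter' must be >= 1",
                         call. = FALSE)
  structure(list(gamma0 = gamma0, gamma_max = gamma_max, rho0 = rho0,
                 eps1 = eps1, eps2 = eps2, max_iter = as.integer(max_iter),
                 theta_mode = theta_mode, verbose = as.integer(verbose)),
            class = "ladmap_control")
}

# One linearized proximal step on A: singular value thresholding of
# A - G / theta at level 1 / (theta * gamma), where G is the gradient of the
# smoothed quadratic (divided by gamma). Returns the new A and its singular
# values (free by-product of the thresholding).
#' @noRd
ladmap_update_A <- function(state, problem) {
  with(state, {
    R1 <- problem$Y - problem$D %*% A - E + Z1 / gamma
    G <- -crossprod(problem$D, R1) + (A - U + Z2 / gamma)
    M <- A - G / theta
    s <- svd(M)
    d <- pmax(s$d - 1 / (theta * gamma), 0)
    keep <- d > 0
    A_new <- if (any(keep))
      s$u[, keep, drop = FALSE] %*% (d[keep] * t(s$v[, keep, drop = FALSE]))
    else array(0, dim(A))
    list(A = A_new, sv = d)
  })
}

# Element-wise soft threshold on the auxiliary copy U; exact pass-through
# when beta = 0.
#' @noRd
ladmap_update_U <- function(state, problem) {
  V <- state$A + state$Z2 / state$gamma
  if (problem$beta == 0) V else soft_threshold(V, problem$beta / state$gamma)
}

# Column-wise l2,1 shrinkage on Q = Y - D A + Z1 / gamma.
#' @noRd
ladmap_update_E <- function(state, problem) {
  Qk <- problem$Y - problem$D %*% state$A + state$Z1 / state$gamma
  column_l21_shrink(Qk, problem$alpha / state$gamma)
}

# Multiplier ascent and adaptive penalty growth. `deltas` are the Frobenius
# norms of the iterate changes from this sweep.
#' @noRd
ladmap_update_multipliers <- function(state, problem, control, deltas) {
  resid <- problem$Y - problem$D %*% state$A - state$E
  Z1 <- state$Z1 + state$gamma * resid
  Z2 <- state$Z2 + state$gamma * (state$A - state$U)
  crit2 <- state$gamma * max(deltas) / state$ny
  rho <- if (crit2 < control$eps2) control$rho0 else 1
  gamma <- min(control$gamma_max, rho * state$gamma)
  list(Z1 = Z1, Z2 = Z2, gamma = gamma, resid = resid, crit2 = crit2)
}

#' Solve the joint low-rank and sparse representation program by LADMAP
#'
#' Linearized alternating direction method with adaptive penalty. The `A`
#' subproblem is solved by singular value thresholding of a linearized
#' quadratic, the auxiliary `U` by element-wise soft thresholding, and the
#' abnormality matrix `E` by column-wise l2,1 shrinkage; Lagrange multipliers
#' are then updated and the penalty grows whenever the iterates have
#' stabilized. Iterations run in the fixed order A, U, E. All variables start
#' at zero, so a solve is fully deterministic.
#'
#' Convergence is declared when both the relative constraint residual
#' `||Y - DA - E||_F / ||Y||_F <= eps1` and the penalty-scaled iterate change
#' fall below `eps2`.
#'
#' @param problem A [jclrrsr_problem()].
#' @param control A [ladmap_control()].
#' @return A list of class `jclrrsr_fit` with `A_star`, `E_star`, `converged`,
#'   `iterations`, `residual_history` (relative constraint residuals),
#'   `objective_history` (`||A||_* + beta ||A||_1 + alpha ||E||_{2,1}`),
#'   `gamma_history` and `theta`.
#' @examples
#' D <- qr.Q(qr(matrix(rnorm(20), 5, 4)))
#' Y <- D %*% matrix(rnorm(12), 4, 3)
#' fit <- solve_jclrrsr(jclrrsr_problem(Y, D, alpha = 0.5, beta = 0.05))
#' fit$converged
#' @export
solve_jclrrsr <- function(problem, control = ladmap_control()) {
  stopifnot(inherits(problem, "jclrrsr_problem"))
  stopifnot(inherits(control, "ladmap_control"))
  Y <- problem$Y; D <- problem$D
  N <- nrow(Y); M <- ncol(Y); S <- ncol(D)
  ny <- fnorm(Y)
  if (ny == 0) ny <- 1
  nD2 <- spectral_norm_sq(D)
  theta <- if (control$theta_mode == "paper") nD2 else nD2 + 1
  if (theta <= 0) stop("solve_jclrrsr: zero dictionary", call. = FALSE)
  gamma0 <- control$gamma0
  if (is.null(gamma0)) {
    sy <- sqrt(spectral_norm_sq(Y))
    gamma0 <- if (sy > 0) 0.1 / sy else 0.1
  }

  state <- list(A = matrix(0, S, M), U = matrix(0, S, M),
                E = matrix(0, N, M), Z1 = matrix(0, N, M),
                Z2 = matrix(0, S, M), gamma = gamma0, theta = theta, ny = ny)

  resid_hist <- numeric(0)
  obj_hist <- numeric(0)
  gamma_hist <- numeric(0)
  converged <- FALSE
  k <- 0L
  while (k < control$max_iter) {
    k <- k + 1L
    A_prev <- state$A; U_prev <- state$U; E_prev <- state$E
    upA <- ladmap_update_A(state, problem)
    state$A <- upA$A
    state$U <- ladmap_update_U(state, problem)
    state$E <- ladmap_update_E(state, problem)
    if (anyNA(state$A) || anyNA(state$U) || anyNA(state$E))
      stop(sprintf("solve_jclrrsr: solver diverged (NaN) at iteration %d", k),
           call. = FALSE)
    deltas <- c(fnorm(state$A - A_prev), fnorm(state$U - U_prev),
                fnorm(state$E - E_prev))
    up <- ladmap_update_multipliers(state, problem, control, deltas)
    relres <- fnorm(up$resid) / ny
    obj <- sum(upA$sv) + problem$beta * sum(abs(state$A)) +
      problem$alpha * l21_norm(state$E)
    resid_hist[k] <- relres
    obj_hist[k] <- obj
    gamma_hist[k] <- state$gamma
    if (control$verbose > 0 && k %% control$verbose == 0)
      message(sprintf("iter %4d  relres %.3e  crit2 %.3e  gamma %.3e  obj %.6g",
                      k, relres, up$crit2, state$gamma, obj))
    done <- relres <= control$eps1 && up$crit2 <= control$eps2
    state$Z1 <- up$Z1; state$Z2 <- up$Z2; state$gamma <- up$gamma
    if (done) { converged <- TRUE; break }
  }

  structure(list(A_star = state$A, E_star = state$E, converged = converged,
                 iterations = k, residual_history = resid_hist,
                 objective_history = obj_hist, gamma_history = gamma_hist,
                 theta = theta, gamma0 = gamma0),
            class = "jclrrsr_fit")
}

#' @export
print.jclrrsr_fit <- function(x, ...) {
  cat(sprintf(
    "JCLRRSR fit: %d iterations, %s (final rel. residual %.3e)\n",
    x$iterations, if (x$converged) "converged" else "NOT converged",
    utils::tail(x$residual_history, 1)))
  cat(sprintf("  A*: %d x %d   E*: %d x %d   objective %.6g\n",
              nrow(x$A_star), ncol(x$A_star), nrow(x$E_star), ncol(x$E_star),
              utils::tail(x$objective_history, 1)))
  invisible(x)
}
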