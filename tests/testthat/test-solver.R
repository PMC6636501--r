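make_state <- function(problem, gamma = 1, theta = NULL) {
  N <- nrow(problem$Y); M <- ncol(problem$Y); S <- ncol(problem$D)
  if (is.null(theta)) theta <- spectral_norm_sq(problem$D) + 1
  list(A = matrix(0, S, M), U = matrix(0, S, M), E = matrix(0, N, M),
       Z1 = matrix(0, N, M), Z2 = matrix(0, S, M), gamma = gamma,
       theta = theta, ny = max(sqrt(sum(problem$Y^2)), 1))
}

test_that("squared spectral norm matches a full SVD", {
  expect_equal(spectral_norm_sq(diag(3)), 1)
  expect_equal(spectral_norm_sq(diag(c(2, 1))), 4)
  set.seed(2)
  D <- matrix(rnorm(40), 5, 8)
  expect_equal(spectral_norm_sq(D), svd(D, nu = 0, nv = 0)$d[1]^2,
               tolerance = 1e-10)
  expect_error(spectral_norm_sq(matrix(numeric(0), 0, 0)), "empty")
})

test_that("the A update composes the stated gradient with the SVT prox", {
  set.seed(13)
  D <- matrix(rnorm(4 * 3), 4, 3)
  Y <- matrix(rnorm(4 * 4), 4, 4)
  prob <- jclrrsr_problem(Y, D, alpha = 0.3, beta = 0.1)
  # zero iterate with E = Y has zero gradient, so A stays zero
  st <- make_state(prob, gamma = 2)
  st$E <- Y
  expect_equal(jclrrsr:::ladmap_update_A(st, prob)$A, matrix(0, 3, 4))
  # random state: recompute the step independently
  st <- make_state(prob, gamma = 1.7)
  st$A <- matrix(rnorm(12), 3, 4); st$U <- matrix(rnorm(12), 3, 4)
  st$E <- matrix(rnorm(16), 4, 4)
  st$Z1 <- matrix(rnorm(16), 4, 4); st$Z2 <- matrix(rnorm(12), 3, 4)
  G <- -crossprod(D, Y - D %*% st$A - st$E + st$Z1 / st$gamma) +
    (st$A - st$U + st$Z2 / st$gamma)
  expected <- singular_value_threshold(st$A - G / st$theta,
                                       1 / (st$theta * st$gamma))
  expect_equal(jclrrsr:::ladmap_update_A(st, prob)$A, expected,
               tolerance = 1e-12)
  # full shrinkage: a tiny penalty makes the SVT threshold dominate the
  # (small) linearized step, collapsing A to zero
  st2 <- make_state(prob, gamma = 1e-6)
  st2$E <- Y - 0.01 * matrix(rnorm(16), 4, 4)
  expect_equal(jclrrsr:::ladmap_update_A(st2, prob)$A, matrix(0, 3, 4))
})

test_that("the U update soft-thresholds, passing through when beta is zero", {
  D <- diag(3); Y <- diag(3)
  st <- make_state(jclrrsr_problem(Y, D, alpha = 1, beta = 0), gamma = 2)
  st$A <- matrix(rnorm(9), 3, 3); st$Z2 <- matrix(rnorm(9), 3, 3)
  prob0 <- jclrrsr_problem(Y, D, alpha = 1, beta = 0)
  expect_equal(jclrrsr:::ladmap_update_U(st, prob0),
               st$A + st$Z2 / st$gamma)
  # beta / gamma = 0.5 on constant entries 1.2 gives 0.7
  prob1 <- jclrrsr_problem(Y, D, alpha = 1, beta = 1)
  st$A <- matrix(1.2, 3, 3); st$Z2 <- matrix(0, 3, 3)
  expect_equal(jclrrsr:::ladmap_update_U(st, prob1), matrix(0.7, 3, 3))
  # entries inside the dead zone vanish
  st$A <- matrix(0.4, 3, 3)
  expect_equal(jclrrsr:::ladmap_update_U(st, prob1), matrix(0, 3, 3))
})

test_that("the E update shrinks columns of the constraint residual", {
  set.seed(17)
  D <- matrix(rnorm(12), 4, 3)
  A <- matrix(rnorm(15), 3, 5)
  Y <- D %*% A
  prob <- jclrrsr_problem(Y, D, alpha = 1, beta = 0)
  st <- make_state(prob, gamma = 1)
  st$A <- A
  expect_equal(jclrrsr:::ladmap_update_E(st, prob), matrix(0, 4, 5))
  # one column of norm 5 above the threshold alpha / gamma = 1
  st$Z1 <- matrix(0, 4, 5)
  st$Z1[, 2] <- c(3, 4, 0, 0)   # makes Q's column 2 equal (3,4,0,0)
  E <- jclrrsr:::ladmap_update_E(st, prob)
  expect_equal(E[, 2], c(2.4, 3.2, 0, 0))
  expect_equal(E[, -2], matrix(0, 4, 4))
  # threshold above every column norm zeroes E
  prob_big <- jclrrsr_problem(Y, D, alpha = 100, beta = 0)
  expect_equal(jclrrsr:::ladmap_update_E(st, prob_big), matrix(0, 4, 5))
})

test_that("multiplier updates follow gradient ascent with a capped penalty", {
  set.seed(19)
  D <- matrix(rnorm(12), 4, 3)
  A <- matrix(rnorm(15), 3, 5)
  Y <- D %*% A
  prob <- jclrrsr_problem(Y, D, alpha = 1, beta = 0)
  ctl <- ladmap_control(gamma_max = 2, rho0 = 1.9, eps2 = 1e-4)
  # exact feasibility leaves the multipliers unchanged
  st <- make_state(prob, gamma = 1.5)
  st$A <- A; st$U <- A; st$E <- matrix(0, 4, 5)
  up <- jclrrsr:::ladmap_update_multipliers(st, prob, ctl, deltas = c(1, 1, 1))
  expect_equal(up$Z1, st$Z1)
  expect_equal(up$Z2, st$Z2)
  # hand-recomputed ascent step
  st$E <- matrix(rnorm(20), 4, 5); st$U <- matrix(rnorm(15), 3, 5)
  up <- jclrrsr:::ladmap_update_multipliers(st, prob, ctl, deltas = c(1, 1, 1))
  expect_equal(up$Z1, st$Z1 + st$gamma * (Y - D %*% st$A - st$E),
               tolerance = 1e-12)
  expect_equal(up$Z2, st$Z2 + st$gamma * (st$A - st$U), tolerance = 1e-12)
  # large iterate change keeps gamma fixed; tiny change grows it to the cap
  expect_equal(up$gamma, st$gamma)
  up2 <- jclrrsr:::ladmap_update_multipliers(st, prob, ctl,
                                             deltas = c(0, 0, 0))
  expect_equal(up2$gamma, 2)   # 1.5 * 1.9 capped at gamma_max
})

test_that("a representable feature matrix yields a vanishing abnormality part", {
  set.seed(23)
  D <- matrix(rnorm(6 * 8), 6, 8)
  # alpha large enough that declaring any column abnormal is never cheaper
  # than representing it over the dictionary (columns of Y are atoms of D)
  prob <- jclrrsr_problem(D, D, alpha = 4, beta = 0.05)
  fit <- solve_jclrrsr(prob, ladmap_control(max_iter = 1500))
  maxcol <- max(sqrt(colSums(D^2)))
  expect_lte(max(sqrt(colSums(fit$E_star^2))), 1e-3 * maxcol)
  expect_lte(utils::tail(fit$residual_history, 1), 1e-4)
})

test_that("solver bookkeeping: histories, penalty monotonicity, residuals", {
  set.seed(29)
  D <- matrix(rnorm(5 * 4), 5, 4)
  Y <- matrix(rnorm(5 * 6), 5, 6)
  fit <- solve_jclrrsr(jclrrsr_problem(Y, D, alpha = 0.5, beta = 0.05),
                       ladmap_control(max_iter = 2000))
  expect_true(fit$converged)
  expect_length(fit$residual_history, fit$iterations)
  expect_length(fit$objective_history, fit$iterations)
  expect_true(all(diff(fit$gamma_history) >= 0))
  expect_lte(max(fit$gamma_history), 1e10)
  expect_lte(utils::tail(fit$residual_history, 1), 1e-6)
  # the recorded final iterates reproduce the recorded residual
  relres <- sqrt(sum((Y - D %*% fit$A_star - fit$E_star)^2)) /
    sqrt(sum(Y^2))
  expect_equal(relres, utils::tail(fit$residual_history, 1),
               tolerance = 1e-12)
  # a max_iter budget of 1 reports non-convergence without error
  fit1 <- solve_jclrrsr(jclrrsr_problem(Y, D, alpha = 0.5, beta = 0.05),
                        ladmap_control(max_iter = 1))
  expect_false(fit1$converged)
  expect_equal(fit1$iterations, 1L)
})

test_that("the beta = 0 path solves the plain low-rank representation program", {
  set.seed(37)
  D <- matrix(rnorm(5 * 3), 5, 3)
  Y <- matrix(rnorm(5 * 5), 5, 5)
  fit <- solve_jclrrsr(jclrrsr_problem(Y, D, alpha = 0.5, beta = 0),
                       ladmap_control(max_iter = 3000))
  orc <- oracle_jclrrsr(Y, D, alpha = 0.5, beta = 0)
  obj_fit <- oracle_objective(fit$A_star, Y, D, 0.5, 0)
  expect_lte(abs(obj_fit - orc$obj) / orc$obj, 1e-3)
})

test_that("solving is deterministic", {
  set.seed(43)
  D <- matrix(rnorm(5 * 3), 5, 3)
  Y <- matrix(rnorm(5 * 6), 5, 6)
  prob <- jclrrsr_problem(Y, D, alpha = 0.3, beta = 0.1)
  f1 <- solve_jclrrsr(prob)
  f2 <- solve_jclrrsr(prob)
  expect_identical(f1$A_star, f2$A_star)
  expect_identical(f1$E_star, f2$E_star)
})

test_that("problem construction validates shapes and weights", {
  expect_error(jclrrsr_problem(matrix(0, 3, 2), matrix(0, 4, 2), 1),
               "same number of rows")
  expect_error(jclrrsr_problem(diag(2), diag(2), alpha = 0), "> 0")
  expect_error(jclrrsr_problem(diag(2), diag(2), alpha = 1, beta = -1),
               ">= 0")
  expect_error(ladmap_control(rho0 = 1), "> 1")
  expect_error(ladmap_control(max_iter = 0), ">= 1")
})
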