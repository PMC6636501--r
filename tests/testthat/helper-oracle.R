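# Independent convex-programming oracles used to verify the proximal
# operators and the LADMAP solver. They minimize Huber-smoothed surrogates
# of the nonsmooth objectives with L-BFGS and contain their own norm code,
# so they share nothing with the package's solution path.

or_huber <- function(t, mu) ifelse(t >= mu, t - mu / 2, t^2 / (2 * mu))
or_dhuber <- function(t, mu) pmin(t / mu, 1)

# Exact (unsmoothed) value of h(X) for the three regularizers.
or_hval <- function(X, type, w) {
  switch(type,
         nuclear = w * sum(svd(X, nu = 0, nv = 0)$d),
         l1 = w * sum(abs(X)),
         l21 = w * sum(sqrt(colSums(X^2))))
}

# Oracle for the proximal problem min_X h(X) + 0.5 ||X - Y||_F^2.
# Returns the minimizer found and the exact objective there.
oracle_prox <- function(Y, w, type = c("nuclear", "l1", "l21"), mu = 1e-7,
                        maxit = 5000) {
  type <- match.arg(type)
  n <- nrow(Y); m <- ncol(Y)
  obj <- function(x) {
    X <- matrix(x, n, m)
    h <- switch(type,
                nuclear = sum(or_huber(svd(X, nu = 0, nv = 0)$d, mu)),
                l1 = sum(or_huber(abs(X), mu)),
                l21 = sum(or_huber(sqrt(colSums(X^2)), mu)))
    w * h + 0.5 * sum((X - Y)^2)
  }
  grad <- function(x) {
    X <- matrix(x, n, m)
    g <- switch(type,
                nuclear = {
                  s <- svd(X)
                  s$u %*% (or_dhuber(s$d, mu) * t(s$v))
                },
                l1 = sign(X) * or_dhuber(abs(X), mu),
                l21 = {
                  cn <- sqrt(colSums(X^2))
                  X * rep(ifelse(cn >= mu, 1 / cn, 1 / mu), each = n)
                })
    as.vector(w * g + (X - Y))
  }
  op <- stats::optim(as.vector(Y), obj, grad, method = "L-BFGS-B",
                     control = list(maxit = maxit, factr = 10))
  X <- matrix(op$par, n, m)
  list(X = X, obj = or_hval(X, type, w) + 0.5 * sum((X - Y)^2))
}

# Exact objective of the joint program at coefficient matrix A, with the
# abnormality part eliminated through the equality constraint E = Y - DA:
# ||A||_* + beta ||A||_1 + alpha ||Y - DA||_{2,1}.
oracle_objective <- function(A, Y, D, alpha, beta) {
  sum(svd(A, nu = 0, nv = 0)$d) + beta * sum(abs(A)) +
    alpha * sum(sqrt(colSums((Y - D %*% A)^2)))
}

# Oracle for the full joint program: smoothed eliminated form minimized by
# L-BFGS from a zero start. beta = 0 gives the plain low-rank representation
# program.
oracle_jclrrsr <- function(Y, D, alpha, beta, mu = 1e-6, maxit = 5000) {
  S <- ncol(D); M <- ncol(Y)
  obj <- function(a) {
    A <- matrix(a, S, M)
    R <- Y - D %*% A
    sum(or_huber(svd(A, nu = 0, nv = 0)$d, mu)) +
      beta * sum(or_huber(abs(A), mu)) +
      alpha * sum(or_huber(sqrt(colSums(R^2)), mu))
  }
  grad <- function(a) {
    A <- matrix(a, S, M)
    s <- svd(A)
    Gnuc <- s$u %*% (or_dhuber(s$d, mu) * t(s$v))
    Gl1 <- beta * sign(A) * or_dhuber(abs(A), mu)
    R <- Y - D %*% A
    cn <- sqrt(colSums(R^2))
    Gl21 <- -alpha * crossprod(D, R * rep(ifelse(cn >= mu, 1 / cn, 1 / mu),
                                          each = nrow(R)))
    as.vector(Gnuc + Gl1 + Gl21)
  }
  op <- stats::optim(rep(0, S * M), obj, grad, method = "L-BFGS-B",
                     control = list(maxit = maxit, factr = 10))
  A <- matrix(op$par, S, M)
  list(A = A, obj = oracle_objective(A, Y, D, alpha, beta))
}

# Exhaustive Otsu oracle: scan every bin edge of a fixed-width histogram and
# maximize the between-class variance directly.
oracle_otsu <- function(v, levels = 256L) {
  r <- range(v)
  edges <- seq(r[1], r[2], length.out = levels + 1L)
  best <- -Inf; best_t <- edges[2]
  for (t in edges[2:levels]) {
    lo <- v <= t; hi <- !lo
    if (!any(lo) || !any(hi)) next
    w0 <- mean(lo)
    bcv <- w0 * (1 - w0) * (mean(v[lo]) - mean(v[hi]))^2
    if (bcv > best) { best <- bcv; best_t <- t }
  }
  best_t
}

# Brute-force count of integer lattice points in a disc of radius `radius`
# centered at integer coordinates.
oracle_disc_count <- function(radius) {
  r <- ceiling(radius)
  sum(outer((-r):r, (-r):r, function(x, y) x^2 + y^2 <= radius^2))
}
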