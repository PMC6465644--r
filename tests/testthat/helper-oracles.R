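# Independent oracles used to cross-check the package's implementations.

# PLS1 via SVD of the cross-covariance with explicit deflation, written
# independently of the package's NIPALS loop.
svd_pls1_oracle <- function(X, y, ncomp, center = TRUE) {
  X <- scale(as.matrix(X), center = center, scale = FALSE)
  y <- as.numeric(y)
  if (center) y <- y - mean(y)
  W <- P <- matrix(0, ncol(X), ncomp)
  Tm <- matrix(0, nrow(X), ncomp)
  q <- numeric(ncomp)
  for (k in seq_len(ncomp)) {
    M <- crossprod(X, matrix(y, ncol = 1))
    u <- svd(M)$u[, 1]
    t_k <- X %*% u
    P[, k] <- crossprod(X, t_k) / sum(t_k^2)
    q[k] <- crossprod(y, t_k) / sum(t_k^2)
    W[, k] <- u
    Tm[, k] <- t_k
    X <- X - t_k %*% t(P[, k])
    y <- y - t_k * q[k]
  }
  list(W = W, P = P, q = q, T = Tm)
}

# Newton-Raphson logistic MLE, independent of stats::glm's IRLS.
newton_logistic_oracle <- function(x, y, tol = 1e-12, maxit = 200) {
  X <- cbind(1, x)
  beta <- c(0, 0)
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    Wd <- p * (1 - p)
    step <- solve(crossprod(X, X * Wd), crossprod(X, y - p))
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  beta <- unname(beta)
  c(intercept = beta[1], slope = beta[2])
}

# brute-force grid search for the shortest interval of a quantile function
grid_hdi_oracle <- function(qfun, mass = 0.95, grid_n = 20001) {
  p <- seq(0, 1 - mass, length.out = grid_n)
  w <- qfun(p + mass) - qfun(p)
  i <- which.min(w)
  c(qfun(p[i]), qfun(p[i] + mass))
}

# full enumeration of the two-sided exact rank-sum p-value
enum_wilcoxon_oracle <- function(a, b) {
  r <- rank(c(a, b))
  na <- length(a)
  w <- sum(r[seq_len(na)])
  sums <- combn(r, na, sum)
  min(1, 2 * min(mean(sums <= w + 1e-9), mean(sums >= w - 1e-9)))
}

rotate_xy <- function(xy, angle) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  xy %*% t(R)
}

# small synthetic study + downstream analysis used by several test files
make_small_study <- function(seed = 11, n_flow = 3000L, profiles = NULL) {
  if (is.null(profiles)) profiles <- reference_profiles()
  cfg <- study_config(profiles, n_flow_events = n_flow, seed = seed)
  gen_study(cfg)
}

analyse_study <- function(study, B = 0) {
  gates <- lapply(names(study$flow), function(id) {
    gate_sample(study$flow[[id]]$test, study$flow[[id]]$control)
  })
  names(gates) <- names(study$flow)
  behaviors <- lapply(study$cohorts, behavior_summary, B = B)
  list(gates = gates, behaviors = behaviors, clinical = study$clinical)
}
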