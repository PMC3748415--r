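# Brute-force QP oracle: projected gradient descent on the SVM dual
#   min 1/2 a'Qa - 1'a,  0 <= a <= C,  sum(a * y) = 0
# independent of the SMO path it is used to check. Projection onto the
# box-plus-hyperplane set is computed by bisection on the hyperplane
# multiplier (clip(z - theta*y) has monotone label-weighted sum in theta).

project_box_hyperplane <- function(z, y, box_c) {
  val <- function(theta) sum(y * pmin(pmax(z - theta * y, 0), box_c))
  lo <- -1
  hi <- 1
  while (val(lo) < 0) lo <- lo * 2
  while (val(hi) > 0) hi <- hi * 2
  for (k in 1:200) {
    mid <- (lo + hi) / 2
    if (val(mid) > 0) lo <- mid else hi <- mid
  }
  pmin(pmax(z - ((lo + hi) / 2) * y, 0), box_c)
}

oracle_qp_solve <- function(q, y, box_c, max_iter = 50000, tol = 1e-12) {
  m <- nrow(q)
  lmax <- max(eigen(q, symmetric = TRUE, only.values = TRUE)$values, 1e-8)
  eta <- 1 / lmax
  alpha <- project_box_hyperplane(rep(0, m), y, box_c)
  for (k in seq_len(max_iter)) {
    g <- drop(q %*% alpha) - 1
    alpha_new <- project_box_hyperplane(alpha - eta * g, y, box_c)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }
  alpha
}

qp_objective <- function(q, alpha) {
  0.5 * drop(crossprod(alpha, q %*% alpha)) - sum(alpha)
}

# random tiny dual problem (m <= 6, n <= 4, random positive reweighting)
random_tiny_problem <- function(seed) {
  set.seed(seed)
  m <- sample(3:6, 1)
  n <- sample(2:4, 1)
  y <- c(-1, 1, sample(c(-1, 1), m - 2, replace = TRUE))
  x <- matrix(rnorm(m * n), m, n)
  v <- exp(runif(n, -2, 2))
  box_c <- sample(c(1, 5, 25), 1)
  q <- dual_q_matrix(x, y, v)
  list(x = x, y = y, v = v, box_c = box_c, q = q, m = m, n = n)
}
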