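test_that("two-point toy dual is solved exactly in one update", {
  d <- toy_1d()
  sol <- solve_weighted_dual(d, v = 1, control = hard_margin_control())
  expect_equal(sol$alpha, c(0.5, 0.5), tolerance = 1e-10)
  expect_equal(sol$dual_objective, -0.5, tolerance = 1e-10)
  expect_equal(sol$n_passes, 1L)
  expect_true(sol$converged)
  w <- primal_from_dual(d, alpha = sol$alpha, v = 1)
  expect_equal(w, 1, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(compute_bias(d, w = w, alpha = sol$alpha), 0,
               tolerance = 1e-10)
})

test_that("box constraint clips the toy solution", {
  d <- toy_1d()
  sol <- solve_weighted_dual(d, v = 1, control = irwp_control(box_c = 0.3))
  expect_equal(sol$alpha, c(0.3, 0.3), tolerance = 1e-12)
})

test_that("solutions are dual-feasible and never worse than the zero start", {
  set.seed(7)
  for (k in 1:10) {
    pr <- random_tiny_problem(1000 + k)
    ctl <- irwp_control(box_c = pr$box_c)
    sol <- solve_weighted_dual(pr$x, pr$y, pr$v, ctl)
    expect_lte(sol$dual_objective, 0) # alpha = 0 is feasible with value 0
    expect_true(all(sol$alpha >= 0))
    expect_true(all(sol$alpha <= pr$box_c + 1e-12))
    expect_lte(abs(sum(sol$alpha * pr$y)), ctl$smo_tol)
  }
})

test_that("SMO matches the projected-gradient oracle on tiny problems", {
  for (k in 1:50) {
    pr <- random_tiny_problem(2000 + k)
    sol <- solve_weighted_dual(pr$x, pr$y, pr$v,
                               irwp_control(box_c = pr$box_c))
    a_star <- oracle_qp_solve(pr$q, pr$y, pr$box_c)
    expect_equal(sol$dual_objective, qp_objective(pr$q, a_star),
                 tolerance = 1e-6)
  }
})

test_that("4-point separable toy matches the oracle in alpha and objective", {
  d <- toy_2d()
  q <- dual_q_matrix(d$x, d$y, c(1, 1))
  sol <- solve_weighted_dual(d, v = c(1, 1), control = irwp_control(box_c = 100))
  a_star <- oracle_qp_solve(q, d$y, 100)
  expect_equal(sol$alpha, a_star, tolerance = 1e-4)
  expect_equal(sol$dual_objective, qp_objective(q, a_star), tolerance = 1e-6)
})

test_that("duplicate points split alpha mass but preserve the objective", {
  x <- rbind(c(1, 0), c(1, 0), c(-1, 0.5))
  y <- c(1, 1, -1)
  sol_dup <- solve_weighted_dual(x, y, c(1, 1), irwp_control(box_c = 50))
  sol_ded <- solve_weighted_dual(x[2:3, ], y[2:3], c(1, 1),
                                 irwp_control(box_c = 50))
  expect_equal(sol_dup$dual_objective, sol_ded$dual_objective,
               tolerance = 1e-6)
})

test_that("primal-dual bookkeeping: alpha'Q alpha equals w'Vw", {
  for (k in 1:10) {
    pr <- random_tiny_problem(3000 + k)
    sol <- solve_weighted_dual(pr$x, pr$y, pr$v,
                               irwp_control(box_c = pr$box_c))
    w <- primal_from_dual(pr$x, pr$y, sol$alpha, pr$v)
    aqa <- drop(crossprod(sol$alpha, pr$q %*% sol$alpha))
    expect_equal(0.5 * aqa, 0.5 * sum(pr$v * w^2), tolerance = 1e-8)
  }
})

test_that("hard margin on non-separable data asks for a finite box", {
  expect_error(
    solve_weighted_dual(toy_nonseparable(), v = 1,
                        control = hard_margin_control()),
    "box_c")
})

test_that("warm-started solves recover the same primal weights", {
  pr <- random_tiny_problem(42)
  ctl <- irwp_control(box_c = pr$box_c)
  cold <- solve_weighted_dual(pr$x, pr$y, pr$v, ctl)
  # start from a feasible but suboptimal point: the clipped cold solution
  a0 <- pmin(cold$alpha, pr$box_c / 2)
  a0 <- project_box_hyperplane(a0, pr$y, pr$box_c)
  warm <- solve_weighted_dual(pr$x, pr$y, pr$v, ctl, alpha0 = a0)
  w_cold <- primal_from_dual(pr$x, pr$y, cold$alpha, pr$v)
  w_warm <- primal_from_dual(pr$x, pr$y, warm$alpha, pr$v)
  expect_equal(w_warm, w_cold, tolerance = 1e-5)
  expect_equal(warm$dual_objective, cold$dual_objective, tolerance = 1e-8)
})

test_that("working-set primitives reproduce the compiled solver on the toy", {
  d <- toy_1d()
  q <- dual_q_matrix(d$x, d$y, 1)
  alpha <- c(0, 0)
  grad <- c(-1, -1)
  pair <- max_violating_pair(alpha, grad, d$y, Inf, 1e-6)
  expect_equal(sort(pair), c(1L, 2L))
  st <- two_variable_update(alpha, grad, q, d$y, Inf, pair[1], pair[2])
  expect_equal(st$alpha, c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(st$grad, drop(q %*% st$alpha) - 1, tolerance = 1e-12)
  # converged state yields no pair; a violation at the tolerance does not
  # count as a violation
  expect_null(max_violating_pair(st$alpha, st$grad, d$y, Inf, 1e-6))
  expect_null(max_violating_pair(alpha, grad, d$y, Inf, 2))
  # zero-violation update is a no-op
  st2 <- two_variable_update(st$alpha, st$grad, q, d$y, Inf, 1, 2)
  expect_identical(st2$alpha, st$alpha)
})

test_that("pair updates never increase the objective and keep sum(alpha*y)", {
  pr <- random_tiny_problem(77)
  alpha <- rep(0, pr$m)
  grad <- rep(-1, pr$m)
  obj <- function(a) qp_objective(pr$q, a)
  last <- obj(alpha)
  for (k in 1:100) {
    pair <- max_violating_pair(alpha, grad, pr$y, pr$box_c, 1e-9)
    if (is.null(pair)) break
    st <- two_variable_update(alpha, grad, pr$q, pr$y, pr$box_c,
                              pair[1], pair[2])
    alpha <- st$alpha
    grad <- st$grad
    cur <- obj(alpha)
    expect_lte(cur, last + 1e-12 * max(1, abs(last)))
    expect_equal(sum(alpha * pr$y), 0, tolerance = 1e-13)
    last <- cur
  }
  expect_null(max_violating_pair(alpha, grad, pr$y, pr$box_c, 1e-6))
})
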