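test_that("p = 2 is a fixed point: plain L2 SVM in at most two outer passes", {
  for (seed in c(11, 12)) {
    pr <- random_tiny_problem(seed)
    fit <- irwp_svm(pr$x, pr$y, p = 2, control = irwp_control(box_c = pr$box_c))
    expect_lte(fit$n_outer_iters, 2L)
    expect_true(fit$converged)
    # reference: brute-force QP at V = I
    q <- dual_q_matrix(pr$x, pr$y, rep(1, pr$n))
    a_star <- oracle_qp_solve(q, pr$y, pr$box_c)
    w_star <- primal_from_dual(pr$x, pr$y, a_star, rep(1, pr$n))
    expect_equal(fit$weights, w_star, tolerance = 1e-4, ignore_attr = TRUE)
  }
})

test_that("p = 2 fit agrees with an established SVM implementation", {
  set.seed(5)
  m <- 40
  x <- rbind(matrix(rnorm(m * 2, 1.2), m / 2),
             matrix(rnorm(m * 2, -1.2), m / 2))
  y <- rep(c(1, -1), each = m / 2)
  fit <- irwp_svm(x, y, p = 2, control = irwp_control(box_c = 10))
  ref <- e1071::svm(x, factor(y, levels = c(1, -1)), scale = FALSE,
                    kernel = "linear", cost = 10)
  w_ref <- drop(crossprod(ref$SV, ref$coefs))
  expect_equal(fit$weights, w_ref, tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(fit$bias, ref$rho, tolerance = 1e-2)
  expect_equal(predict(fit, x), y)
})

test_that("single-feature toy is pinned at w = 1, b = 0 for every p", {
  d <- toy_1d()
  for (p in c(0.2, 0.5, 1, 1.5, 2)) {
    fit <- irwp_svm(d, p = p, control = hard_margin_control())
    expect_equal(fit$weights, 1, tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(fit$bias, 0, tolerance = 1e-6)
    expect_true(fit$converged)
  }
})

test_that("KKT complementarity and margins hold on separable hard-margin fits", {
  d <- toy_2d()
  ctl <- hard_margin_control()
  for (p in c(0.8, 1.3, 2)) {
    fit <- irwp_svm(d, p = p, control = ctl)
    marg <- d$y * (drop(d$x %*% fit$weights) - fit$bias)
    expect_true(all(marg >= 1 - 1e-5))
    sv <- fit$support_indices
    expect_gte(length(sv), 1L)
    expect_true(all(abs(marg[sv] - 1) <= 10 * ctl$smo_tol + 1e-8))
    # support vectors sit on the margin: y_k (w'x_k - b) = 1
    expect_equal(d$y[sv] * (decision_function(fit, d$x[sv, , drop = FALSE])),
                 rep(1, length(sv)), tolerance = 1e-5)
  }
})

test_that("the smoothed penalty is non-increasing along the reweighting path", {
  ws <- weston_split_std(301, n_samples = 160, n_train = 80, n_features = 25)
  eps <- 1e-8
  for (p in c(0.5, 0.8, 1.5)) {
    fit <- irwp_svm(ws$train, p = p)
    pen <- vapply(fit$weight_trajectory,
                  function(w) 0.5 * sum((abs(w) + eps)^p), numeric(1))
    expect_true(all(diff(pen) <= 1e-6 * pmax(1, abs(pen[-length(pen)]))))
  }
})

test_that("uniform feature scaling rescales weights and fixes predictions", {
  d <- toy_2d()
  fit1 <- irwp_svm(d, p = 0.8, control = hard_margin_control())
  cc <- 4
  fit2 <- irwp_svm(d$x * cc, d$y, p = 0.8, control = hard_margin_control())
  expect_equal(fit2$weights, fit1$weights / cc, tolerance = 1e-4,
               ignore_attr = TRUE)
  xnew <- rbind(c(1, 2), c(-0.5, 3), c(0.3, -4))
  expect_equal(predict(fit2, xnew * cc), predict(fit1, xnew))
})

test_that("prediction is the sign of the margin, with ties going to +1", {
  d <- toy_1d()
  fit <- irwp_svm(d, p = 1, control = hard_margin_control())
  expect_equal(decision_function(fit, 3), 3, tolerance = 1e-6)
  expect_equal(decision_function(fit, 0), -fit$bias)
  expect_equal(predict(fit, matrix(c(3, -3), 2, 1)), c(1, -1))
  # b = 0 here, so the zero vector has margin exactly 0 -> +1
  expect_equal(predict(fit, matrix(0, 1, 1)), 1)
  expect_error(decision_function(fit, c(1, 2)), "mismatch")
})

test_that("separable training points are all refit correctly", {
  d <- toy_2d()
  fit <- irwp_svm(d, p = 1.2, control = hard_margin_control())
  expect_equal(predict(fit, d$x), d$y)
})

test_that("selected_features applies the relative magnitude rule", {
  fake <- structure(list(weights = c(1, 1e-9, 0.5), bias = 0, p = 1,
                         control = irwp_control()),
                    class = "irwp_svm")
  expect_equal(selected_features(fake, feature_threshold = 1e-3), c(1L, 3L))
  expect_equal(selected_features(fake, feature_threshold = 0), 1:3)
  fake$weights <- c(0, 0, 0)
  expect_error(selected_features(fake), "zero")
})

test_that("bridge-penalty fit silences nearly all noise features", {
  ws <- weston_split_std(1001, n_samples = 1000, n_train = 500)
  fit <- irwp_svm(ws$train, p = 0.8)
  aw <- abs(fit$weights)
  thr <- fit$control$feature_threshold * max(aw)
  expect_gte(sum(aw[7:100] < thr), 88)
  # and the selected set is essentially the true relevant set
  expect_lte(feature_selection_error_rate(selected_features(fit),
                                          ws$relevant, 100), 3)
})

test_that("degenerate inputs are rejected", {
  expect_error(irwp_svm(matrix(1:4, 2, 2), c(1, 1), p = 1), "single class")
  expect_error(irwp_svm(toy_1d(), p = 0), "p must lie")
  expect_error(irwp_svm(toy_1d(), p = 2.1), "p must lie")
})
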