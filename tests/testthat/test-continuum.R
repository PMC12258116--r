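test_that("closed-form eigenvalues match a numeric eigensolver", {
  set.seed(7)
  for (i in 1:100) {
    p <- continuous_params(k1 = runif(1, 0.1, 2), k2 = runif(1, 0, 2),
                           k3 = runif(1, 0, 2), k4 = runif(1, 0, 2),
                           k5 = runif(1, 0, 2), k6 = runif(1, 0, 2))
    ev_closed <- sort(unname(ode_eigenvalues(p)))
    ev_num <- sort(Re(eigen(system_matrix(p), only.values = TRUE)$values))
    expect_equal(ev_closed, ev_num, tolerance = 1e-10)
  }
})

test_that("the dominant eigenvalue follows the balance of the rate products", {
  # no differentiation: pure growth at sqrt(k1 k2)
  p <- continuous_params(k2 = 0.25)
  expect_equal(unname(ode_eigenvalues(p)["lambda1"]), 0.5)
  expect_equal(round(unname(ode_eigenvalues(
    continuous_params(k2 = k2_from_c(6)))["lambda1"]), 6), 0.285199)
  # balanced: lambda1 = 0 exactly
  pb <- continuous_params(k2 = 0.5, k3 = 1, k4 = 0.5)
  expect_equal(unname(ode_eigenvalues(pb)["lambda1"]), 0, tolerance = 1e-14)
  expect_equal(classify_regime(pb), "steady")
  # decoupled death rates
  expect_equal(unname(ode_eigenvalues(continuous_params(k2 = 1, k5 = 0.3))["lambda3"]),
               -0.3)
})

test_that("regime classification follows the sign of k1 k2 - k3 k4", {
  expect_equal(classify_regime(continuous_params(k2 = 0.3)), "growth")
  expect_equal(classify_regime(continuous_params(k2 = 0, k3 = 1, k4 = 1)),
               "decay")
  set.seed(11)
  for (i in 1:50) {
    k <- runif(4, 0, 2)
    p <- continuous_params(k1 = k[1], k2 = k[2], k3 = k[3], k4 = k[4])
    bal <- k[1] * k[2] - k[3] * k[4]
    expected <- if (bal > 0) "growth" else if (bal < 0) "decay" else "steady"
    expect_equal(classify_regime(p), expected)
    expect_equal(sign(unname(ode_eigenvalues(p)["lambda1"])), sign(bal),
                 tolerance = 1e-12)
  }
})

test_that("one differentiation lineage cannot balance a dividing system", {
  set.seed(13)
  for (i in 1:20) {
    p <- continuous_params(k1 = runif(1, 0.1, 2), k2 = runif(1, 0.1, 2),
                           k3 = 0, k4 = runif(1, 0.1, 2))
    expect_gt(unname(ode_eigenvalues(p)["lambda1"]), 0)
    expect_equal(classify_regime(p), "growth")
  }
})

test_that("steady-state ratios are k2/k4, k4/k6, k3/k5 and attract trajectories", {
  p <- continuous_params(k1 = 1, k2 = 0.381966, k3 = 0.381966 / 0.618034,
                         k4 = 0.618034, k5 = 0.4, k6 = 0.7)
  r <- steady_state_ratios(p)
  expect_equal(round(r$value[r$ratio == "M/I"], 6), 0.618034)
  expect_equal(r$value[r$ratio == "W2/M"], 0.618034 / 0.7, tolerance = 1e-9)
  expect_equal(r$value[r$ratio == "W1/I"], (0.381966 / 0.618034) / 0.4,
               tolerance = 1e-9)

  expect_error(steady_state_ratios(continuous_params(k2 = 1)), "balance")
  expect_error(
    steady_state_ratios(continuous_params(k2 = 0, k3 = 0, k4 = 1, k5 = 0, k6 = 1)),
    "positive")

  set.seed(17)
  for (i in 1:20) {
    k4 <- runif(1, 0.2, 1); k3 <- runif(1, 0.2, 1)
    p <- continuous_params(k1 = 1, k2 = k3 * k4, k3 = k3, k4 = k4,
                           k5 = runif(1, 0.2, 1), k6 = runif(1, 0.2, 1))
    traj <- integrate_compartments(p, c(M = 1, I = 1, W1 = 0.1, W2 = 0.1),
                                   times = c(0, 100, 200))
    fin <- traj[nrow(traj), ]
    r <- steady_state_ratios(p)
    expect_equal(fin$M / fin$I, r$value[1], tolerance = 1e-6)
    expect_equal(fin$W2 / fin$M, r$value[2], tolerance = 1e-6)
    expect_equal(fin$W1 / fin$I, r$value[3], tolerance = 1e-6)
  }
})

test_that("trajectories are accurate and preserve nonnegativity", {
  # nothing to produce or drain (k1 sets the clock but M = 0): constant
  traj <- integrate_compartments(continuous_params(k2 = 0),
                                 c(I = 1, W1 = 2), times = 0:5)
  expect_equal(traj$I, rep(1, 6), tolerance = 1e-9)
  expect_equal(traj$W1, rep(2, 6), tolerance = 1e-9)
  expect_equal(traj$M, rep(0, 6), tolerance = 1e-12)

  # pure growth: M/I tends to sqrt(k2/k1) and matches the closed form
  p <- continuous_params(k2 = 0.25)
  traj <- integrate_compartments(p, c(M = 1), times = seq(0, 40, 5))
  expect_equal(traj$M[9] / traj$I[9], 0.5, tolerance = 1e-7)
  # closed-form check of M(t) for the 2x2 block: cosh/sinh growth
  lam <- 0.5
  expect_equal(traj$M, cosh(lam * traj$time), tolerance = 1e-7)
  expect_true(all(as.matrix(traj[, -1]) >= -1e-12))

  expect_error(integrate_compartments(p, c(M = 1), times = c(1, 0)),
               "increasing")
  expect_error(integrate_compartments(p, c(M = -1), times = 0:2),
               "nonnegative")
})

test_that("the discrete-continuous correspondence closes the loop", {
  for (c in 1:6) {
    p <- continuous_params(k2 = k2_from_c(c))
    traj <- integrate_compartments(p, c(M = 1), times = c(0, 60, 120))
    mi <- traj$M[3] / traj$I[3]
    expect_lt(abs(mi - solve_lambda(c)), 1e-6)
    expect_lt(abs(mi - table3_printed$M_over_I[c]), 1e-6)  # printed: 6 dp
  }
})

test_that("tidy and glance summarize the fitted system", {
  m <- ode_model(continuous_params(k2 = 0.5, k3 = 1, k4 = 0.5, k5 = 0.2,
                                   k6 = 0.3))
  td <- tidy(m)
  expect_equal(td$term, paste0("lambda", 1:4))
  expect_equal(td$eigenvalue[3:4], c(-0.2, -0.3))
  gl <- glance(m)
  expect_equal(gl$regime, "steady")
  expect_equal(gl$balance, 0)
})
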