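# Dense grid-search oracles, kept deliberately independent of the
# optimizer path they check.
grid_null <- function(theta_hat, tau, mu_grid, sigma_grid) {
  ll <- function(mu, sigma)
    sum(dnorm(theta_hat, mu, sqrt(sigma^2 + tau^2), log = TRUE))
  vals <- outer(mu_grid, sigma_grid, Vectorize(ll))
  idx <- arrayInd(which.max(vals), dim(vals))
  c(mu = mu_grid[idx[1]], sigma = sigma_grid[idx[2]],
    log_lik = max(vals))
}

sys_ll <- function(par, theta, theta_hat, tau) {
  m <- theta + par[1] + par[2] * theta
  s <- par[3] + par[4] * abs(theta)
  sum(dnorm(theta_hat, m, sqrt(s^2 + tau^2), log = TRUE))
}

test_that("fit_null handles the degenerate common-estimate case", {
  fit <- fit_null(rep(0.3, 5), rep(0.05, 5))
  expect_equal(fit$mu, 0.3, tolerance = 1e-6)
  expect_lt(fit$sigma, 1e-4)
  expect_error(fit_null(0.3, 0.05), "at least 2")
})

test_that("fit_null matches a dense grid-search oracle", {
  theta_hat <- c(-0.2, 0, 0.2)
  tau <- rep(0.01, 3)
  fit <- fit_null(theta_hat, tau)
  oracle <- grid_null(theta_hat, tau,
                      mu_grid = seq(-0.3, 0.3, by = 1e-3),
                      sigma_grid = seq(1e-4, 0.5, by = 1e-3))
  expect_lt(abs(fit$mu - oracle["mu"]), 2e-3)
  expect_lt(abs(fit$sigma - oracle["sigma"]), 2e-3)
  expect_gte(fit$log_lik, oracle["log_lik"] - 1e-4)
})

test_that("fit_null recovers generating parameters at large control counts", {
  set.seed(51)
  mu <- 0.1; sigma <- 0.15
  n <- 1000
  tau <- runif(n, 0.02, 0.1)
  theta_hat <- rnorm(n, mu, sqrt(sigma^2 + tau^2))
  fit <- fit_null(theta_hat, tau)
  boot <- replicate(200, {
    i <- sample.int(n, n, replace = TRUE)
    f <- fit_null(theta_hat[i], tau[i])
    c(f$mu, f$sigma)
  })
  expect_lt(abs(fit$mu - mu), 3 * sd(boot[1, ]))
  expect_lt(abs(fit$sigma - sigma), 3 * sd(boot[2, ]))
})

test_that("systematic error model fits exact and simulated control sets", {
  # exact controls with tiny noise: no systematic error at all
  theta <- rep(c(0, log(2), log(4)), each = 3)
  fit <- fit_systematic_error_model(theta, theta, rep(1e-3, 9))
  expect_lt(abs(fit$a), 1e-3)
  expect_lt(abs(fit$b), 1e-2)
  expect_lt(fit$c, 1e-3)
  expect_lt(fit$d, 1e-2)

  expect_error(fit_systematic_error_model(rep(0, 5), rnorm(5), rep(0.1, 5)),
               "fit_null")

  # parameter recovery at 500 controls
  set.seed(52)
  a <- 0.1; b <- 0.2; cc <- 0.05; d <- 0.05
  th <- rep(c(0, log(1.5), log(2), log(4)), length.out = 500)
  tau <- runif(500, 0.02, 0.05)
  th_hat <- rnorm(500, th + a + b * th, sqrt((cc + d * abs(th))^2 + tau^2))
  f <- fit_systematic_error_model(th, th_hat, tau)
  boot <- replicate(100, {
    i <- sample.int(500, 500, replace = TRUE)
    g <- fit_systematic_error_model(th[i], th_hat[i], tau[i])
    c(g$a, g$b, g$c, g$d)
  })
  expect_lt(abs(f$a - a), 3 * sd(boot[1, ]))
  expect_lt(abs(f$b - b), 3 * sd(boot[2, ]))
  expect_lt(abs(f$c - cc), 3 * sd(boot[3, ]))
  expect_lt(abs(f$d - d), 3 * sd(boot[4, ]))
})

test_that("systematic-model optimum beats a coarse 4-D grid", {
  set.seed(53)
  theta <- c(0, 0, 0, log(1.5), log(2), log(4))
  theta_hat <- theta + rnorm(6, 0.05, 0.05)
  tau <- rep(0.04, 6)
  fit <- fit_systematic_error_model(theta, theta_hat, tau)
  grid <- expand.grid(a = seq(-0.2, 0.3, by = 0.025),
                      b = seq(-0.4, 0.4, by = 0.05),
                      cc = c(1e-4, seq(0.01, 0.2, by = 0.01)),
                      d = c(1e-4, seq(0.01, 0.2, by = 0.01)))
  grid_best <- max(apply(grid, 1, sys_ll, theta = theta,
                         theta_hat = theta_hat, tau = tau))
  expect_gte(fit$log_lik, grid_best - 1e-4)
})

test_that("zero-error calibration reproduces the Wald interval", {
  est <- structure(list(log_or = 0.31, se = 0.07), class = "effect_estimate")
  null0 <- structure(list(mu = 0, sigma = 0), class = "null_distribution")
  cal <- calibrate_ci(est, null0)
  expect_equal(cal$ci_lo, 0.31 - qnorm(0.975) * 0.07, tolerance = 1e-6)
  expect_equal(cal$ci_hi, 0.31 + qnorm(0.975) * 0.07, tolerance = 1e-6)
  expect_equal(cal$log_or, 0.31, tolerance = 1e-6)

  sys0 <- structure(list(a = 0, b = 0, c = 0, d = 0),
                    class = "systematic_error_model")
  cal2 <- calibrate_ci(est, sys0)
  expect_equal(cal2$ci_lo, cal$ci_lo, tolerance = 1e-6)
  expect_equal(cal2$ci_hi, cal$ci_hi, tolerance = 1e-6)
})

test_that("a pure-shift null model shifts the interval by mu exactly", {
  est <- structure(list(log_or = 0.5, se = 0.1), class = "effect_estimate")
  null_shift <- structure(list(mu = 0.2, sigma = 0),
                          class = "null_distribution")
  cal <- calibrate_ci(est, null_shift)
  expect_equal(cal$log_or, 0.3, tolerance = 1e-6)
  expect_equal(cal$ci_lo, 0.3 - qnorm(0.975) * 0.1, tolerance = 1e-6)
  expect_equal(cal$ci_hi, 0.3 + qnorm(0.975) * 0.1, tolerance = 1e-6)
})

test_that("null-model calibrated width is never below the Wald width", {
  est <- structure(list(log_or = 0.2, se = 0.05), class = "effect_estimate")
  for (sigma in c(0, 0.02, 0.1, 0.5)) {
    nm <- structure(list(mu = 0.1, sigma = sigma),
                    class = "null_distribution")
    cal <- calibrate_ci(est, nm)
    expect_equal(cal$ci_hi - cal$ci_lo,
                 2 * qnorm(0.975) * sqrt(sigma^2 + est$se^2),
                 tolerance = 1e-5)
    expect_gte(cal$ci_hi - cal$ci_lo + 1e-7,
               2 * qnorm(0.975) * est$se)
  }
})

test_that("calibrated endpoints satisfy tail-probability self-consistency", {
  set.seed(54)
  for (rep in 1:20) {
    model <- structure(list(a = rnorm(1, 0, 0.2), b = rnorm(1, 0, 0.2),
                            c = runif(1, 0, 0.2), d = runif(1, 0, 0.2)),
                       class = "systematic_error_model")
    est <- structure(list(log_or = rnorm(1, 0, 0.5),
                          se = runif(1, 0.02, 0.2)),
                     class = "effect_estimate")
    cal <- calibrate_ci(est, model)
    tail_at <- function(theta) {
      m <- theta + model$a + model$b * theta
      s <- model$c + model$d * abs(theta)
      pnorm(est$log_or, m, sqrt(s^2 + est$se^2))
    }
    expect_equal(tail_at(cal$ci_lo), 0.975, tolerance = 1e-6)
    expect_equal(tail_at(cal$ci_hi), 0.025, tolerance = 1e-6)
    expect_equal(tail_at(cal$log_or), 0.5, tolerance = 1e-6)
    expect_lt(cal$ci_lo, cal$ci_hi)
  }
})

test_that("calibration is equivariant under sign flip", {
  set.seed(55)
  theta <- rep(c(0, log(2)), each = 5)
  theta_hat <- theta + rnorm(10, 0.1, 0.08)
  tau <- runif(10, 0.03, 0.08)
  est <- structure(list(log_or = 0.4, se = 0.06), class = "effect_estimate")

  f_pos <- fit_systematic_error_model(theta, theta_hat, tau)
  f_neg <- fit_systematic_error_model(-theta, -theta_hat, tau)
  expect_equal(f_neg$a, -f_pos$a, tolerance = 1e-4)
  expect_equal(f_neg$b, f_pos$b, tolerance = 1e-4)
  expect_equal(f_neg$c, f_pos$c, tolerance = 1e-4)

  cal_pos <- calibrate_ci(est, f_pos)
  est_neg <- structure(list(log_or = -0.4, se = 0.06),
                       class = "effect_estimate")
  cal_neg <- calibrate_ci(est_neg, f_neg)
  expect_equal(cal_neg$ci_lo, -cal_pos$ci_hi, tolerance = 1e-5)
  expect_equal(cal_neg$ci_hi, -cal_pos$ci_lo, tolerance = 1e-5)
})

test_that("calibrated p-values behave at the anchors and under the null", {
  est <- structure(list(log_or = 0.2, se = 0.1), class = "effect_estimate")
  null_at <- structure(list(mu = 0.2, sigma = 0.3),
                       class = "null_distribution")
  expect_equal(calibrate_p(est, null_at), 1)
  null0 <- structure(list(mu = 0, sigma = 0), class = "null_distribution")
  wald_p <- 2 * pnorm(-abs(est$log_or / est$se))
  expect_equal(calibrate_p(est, null0), wald_p, tolerance = 1e-10)

  # probability integral transform: p-values uniform when the null model
  # is the generating law
  set.seed(56)
  mu <- 0.2; sigma <- 0.1
  tau <- runif(1000, 0.02, 0.1)
  th <- rnorm(1000, mu, sqrt(sigma^2 + tau^2))
  nm <- structure(list(mu = mu, sigma = sigma), class = "null_distribution")
  pv <- vapply(seq_len(1000), function(i)
    calibrate_p(structure(list(log_or = th[i], se = tau[i]),
                          class = "effect_estimate"), nm), numeric(1))
  expect_gt(ks.test(pv, "punif")$p.value, 0.01)
})

test_that("clean controls keep calibrated coverage nominal (no harm)", {
  # control estimates with zero systematic error: calibrating a clean
  # estimate against a model fitted to them must not break coverage
  set.seed(57)
  n_iter <- 300
  covered <- logical(n_iter)
  for (i in seq_len(n_iter)) {
    theta <- rep(c(0, log(1.5), log(2), log(4)), each = 5)
    tau <- runif(20, 0.02, 0.05)
    th_hat <- rnorm(20, theta, tau)
    model <- fit_systematic_error_model(theta, th_hat, tau)
    truth <- 0.1
    est <- structure(list(log_or = rnorm(1, truth, 0.04), se = 0.04),
                     class = "effect_estimate")
    cal <- calibrate_ci(est, model)
    covered[i] <- truth >= cal$ci_lo && truth <= cal$ci_hi
  }
  expect_gte(mean(covered), 0.92)
  expect_lte(mean(covered), 0.995)
})
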