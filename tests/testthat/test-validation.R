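test_that("residual vectors match the objective exactly", {
  b <- make_benchmark("oscillator", noise = noise_spec(15),
                      missing_fraction = 0.2, seed = 4)
  pred <- integrate_model(b$model)
  r <- residual_vectors(pred, b$data)
  expect_named(r, colnames(b$data$observations))
  # cross-module identity: sum of squares equals the fitness
  expect_equal(sum(unlist(r)^2), fitness(pred, b$data),
               tolerance = 1e-12)

  # perfect fit -> all-zero residuals
  full <- make_dataset(pred$times, pred$states)
  expect_true(all(unlist(residual_vectors(pred, full)) == 0))

  # a single observed entry
  obs <- pred$states
  mask <- matrix(FALSE, nrow(obs), ncol(obs))
  obs[5, 2] <- pred$states[5, 2] + 1
  mask[5, 2] <- TRUE
  one <- make_dataset(pred$times, obs, mask = mask)
  r1 <- residual_vectors(pred, one)
  expect_equal(unname(unlist(r1)), 1)
})

test_that("the variance point estimate is the unbiased sample variance", {
  expect_identical(variance_point(c(0, 0, 0, 0)), 0)
  expect_equal(variance_point(c(1, -1, 1, -1)), 4 / 3)
  expect_equal(variance_point(c(1, -1, 1, -1), center = "zero"), 4 / 3)
  # centring matters when the mean is nonzero
  expect_equal(variance_point(c(2, 0), center = "zero"), 4)
  expect_equal(variance_point(c(2, 0)), 2)
  expect_error(variance_point(1), "two")

  set.seed(20)
  z <- rnorm(1e5, sd = 3)
  expect_lt(abs(variance_point(z) - 9) / 9, 0.02)
})

test_that("the chi-square interval brackets the point estimate", {
  expect_equal(unname(variance_interval(0, 10)), c(0, 0))
  set.seed(21)
  for (i in 1:200) {
    s2 <- runif(1, 0, 10); n <- sample(3:500, 1); g <- runif(1, 0.5, 0.99)
    ci <- variance_interval(s2, n, g)
    expect_lte(ci[["lower"]], s2 + 1e-12)
    expect_gte(ci[["upper"]], s2 - 1e-12)
  }
  # width shrinks to zero with growing N at fixed s2
  w <- vapply(c(10, 100, 1000, 10000), function(n)
    diff(variance_interval(2, n)), numeric(1))
  expect_true(all(diff(w) < 0))
  expect_error(variance_interval(1, 1), "two")
})

test_that("interval coverage is calibrated at the nominal level", {
  set.seed(22)
  n <- 50; sigma2 <- 4
  hits <- vapply(1:2000, function(i) {
    s2 <- variance_point(rnorm(n, sd = sqrt(sigma2)))
    ci <- variance_interval(s2, n, 0.95)
    sigma2 >= ci[["lower"]] && sigma2 <= ci[["upper"]]
  }, logical(1))
  expect_gte(mean(hits), 0.935)
  expect_lte(mean(hits), 0.965)
})

test_that("a truth fit passes and the test degenerates sensibly with gamma", {
  b <- make_benchmark("oscillator", noise = noise_spec(15), seed = 5)
  idt <- identifiability_test(b$model, data = b$data,
                              params = b$model$param_space$values)
  expect_s3_class(idt, "identifiability_test")
  expect_true(all(idt$lower <= idt$variance_point + 1e-12))
  expect_true(all(idt$upper >= idt$variance_point - 1e-12))
  expect_true(attr(idt, "passed"))

  # gamma close to 1 widens the interval until anything plausible passes
  rough <- identifiability_test(b$model, data = b$data,
                                params = b$model$param_space$values,
                                gamma = 0.999999)
  expect_true(all(rough$upper / rough$lower >
                  idt$upper / idt$lower))
})

test_that("truth fits pass at roughly the confidence level against the
           theoretical variance", {
  # homoscedastic per-state noise (absolute scheme) so the chi-square
  # calibration applies exactly
  m <- decay_model(0.5)
  truth <- integrate_model(m, 0.5)
  sd_x <- sd(truth$states[, 1])
  theo <- c(x = (0.10 * sd_x)^2)
  set.seed(23)
  pass <- vapply(1:400, function(i) {
    d <- add_noise(truth, noise_spec(10, scheme = "absolute",
                                     seed = 30000 + i))
    attr(identifiability_test(m, data = d, params = 0.5,
                              real_variance = theo), "passed")
  }, logical(1))
  expect_gte(mean(pass), 0.90)
  expect_lte(mean(pass), 0.99)
})

test_that("the AIC formula and its monotonicity hold", {
  # MSE = 1 -> AIC = 2D
  expect_equal(aic_score(100, 100, 3), 6)
  # doubling D at fixed MSE raises AIC by 2D
  expect_equal(aic_score(100, 100, 6) - aic_score(100, 100, 3), 6)
  # lower MSE at equal D always wins
  f <- seq(1, 50, by = 0.5)
  a <- vapply(f, aic_score, numeric(1), n_obs = 40, n_par = 4)
  expect_true(all(diff(a) > 0))
  # perfect fits are floored, not an error
  expect_true(is.finite(aic_score(0, 10, 2)))
  expect_error(aic_score(-1, 10, 2), ">= 0")
})

test_that("model comparison declares the AIC-minimal candidate", {
  m <- benchmark_model("simulated_nonlinear")
  b <- make_benchmark(m, noise = noise_spec(0), seed = 6)
  ctl <- optimizer_control(NP = 8, iterations = 10, initial_ke = 1)
  ablated <- fix_parameters(m, c(b = 0))

  sel <- compare_models(list(original = m, reduced = ablated), b$data,
                        control = ctl, seed = 3)
  expect_identical(sel$winner, "original")
  expect_lt(sel$aic[["original"]], sel$aic[["reduced"]])

  # identical candidates tie; declaration order breaks the tie
  tie <- compare_models(list(first = m, second = m), b$data,
                        control = optimizer_control(NP = 4, iterations = 2,
                                                    initial_ke = 1),
                        seed = 3)
  expect_identical(tie$winner,
                   names(tie$aic)[which.min(tie$aic)])

  # winner invariant under candidate reordering
  sel2 <- compare_models(list(reduced = ablated, original = m), b$data,
                         control = ctl, seed = 3)
  expect_identical(sel2$winner, "original")
})
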