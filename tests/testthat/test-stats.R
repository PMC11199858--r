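test_that("degree and strength count rows and columns correctly", {
  W <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  W["a", "b"] <- 2; W["a", "c"] <- 3
  con <- connectome(data.frame(label = letters[1:3]), W, "LNe")
  expect_equal(node_degree(con, "out")[["a"]], 2)
  expect_equal(node_degree(con, "out", weighted = TRUE)[["a"]], 5)
  expect_equal(node_degree(con, "in")[["b"]], 1)
  empty <- connectome(data.frame(label = letters[1:3]),
                      matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3])),
                      "LNe")
  expect_true(all(node_degree(empty, "in") == 0))

  # handshake invariants
  con2 <- random_connectome(25, seed = 3)
  expect_equal(sum(node_degree(con2, "in")), sum(node_degree(con2, "out")))
  expect_equal(sum(node_degree(con2, "in")), n_links(con2))
  expect_equal(sum(node_degree(con2, "in", weighted = TRUE)),
               sum(node_degree(con2, "out", weighted = TRUE)))
})

test_that("weighted in-degree of an FLNe network is exactly 0 or 1", {
  con <- censor(random_connectome(30, seed = 6), sprintf("v%02d", 1:12))
  flne <- to_flne(con)$connectome
  s_in <- node_degree(flne, "in", weighted = TRUE)
  expect_true(all(abs(s_in) < 1e-9 | abs(s_in - 1) < 1e-9))
})

test_that("closed-form MLE fits and degeneracy errors", {
  f <- fit_family(c(1, 2, 3), "exponential")
  expect_equal(unname(f$params["rate"]), 0.5)   # 1 / mean
  expect_equal(f$log_likelihood, sum(dexp(1:3, 0.5, log = TRUE)))
  g <- fit_family(c(1, 2, 3, 4), "normal")
  expect_equal(unname(g$params["mean"]), 2.5)
  expect_equal(unname(g$params["sd"]), sqrt(mean((1:4 - 2.5)^2)))  # MLE sd
  h <- fit_family(exp(c(0, 1, 2)), "lognormal")
  expect_equal(unname(h$params["meanlog"]), 1)
  expect_error(fit_family(rep(2, 10), "normal"), "degenerate")
  expect_error(fit_family(1, "normal"), ">= 2")
  # zeros excluded with count for log families
  z <- fit_family(c(0, 0, 1, 2, 3), "exponential")
  expect_equal(z$n_excluded, 2L)
  expect_equal(z$n, 3L)
})

test_that("MLE parameters agree with an independent optimiser", {
  skip_if_not_installed("MASS")
  set.seed(77)
  x <- rlnorm(200, 1, 0.7)
  ours <- fit_family(x, "lognormal")
  ref <- MASS::fitdistr(x, "lognormal")
  expect_equal(unname(ours$params["meanlog"]), unname(ref$estimate["meanlog"]),
               tolerance = 1e-6)
  expect_equal(ours$log_likelihood, as.numeric(ref$loglik), tolerance = 1e-6)
})

test_that("family comparison ranks the generating family first", {
  set.seed(31)
  exp_wins <- 0; lnorm_wins <- 0
  for (i in 1:20) {
    xe <- rexp(200, 0.3)
    if (compare_families(xe, c("exponential", "normal"))$family[1] ==
        "exponential") exp_wins <- exp_wins + 1
    xl <- rlnorm(500, 0, 1)
    if (compare_families(xl)$family[1] == "lognormal")
      lnorm_wins <- lnorm_wins + 1
  }
  expect_gte(exp_wins, 19)
  expect_gte(lnorm_wins, 19)
  # identical families in, stable order and identical likelihoods out
  two <- compare_families(rexp(50, 1), c("normal", "normal"))
  expect_equal(two$log_likelihood[1], two$log_likelihood[2])
})

test_that("noise-free exponential decay is recovered exactly", {
  con <- random_connectome(50, seed = 12, coords = TRUE)
  con$W[con$W > 0] <- 10 * exp(-con$D[con$W > 0] / 5)
  fit <- weight_distance_fit(con, "exponential")
  expect_equal(fit$lambda, 5, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$intercept, log(10), tolerance = 1e-9)
  # power law on exact power-law data
  con$W[con$W > 0] <- 3 * con$D[con$W > 0]^-2
  pfit <- weight_distance_fit(con, "powerlaw")
  expect_equal(pfit$gamma, 2, tolerance = 1e-9)
  expect_equal(pfit$r_squared, 1, tolerance = 1e-9)
})

test_that("decay parameters are invariant to global weight rescaling", {
  sim <- generate_connectome(synth_config(n_nodes = 40, n_measured = 40,
                                          log_sigma = 0.3, seed = 4))
  con <- sim$connectome
  f1 <- weight_distance_fit(con)
  con$W <- con$W * 1e4
  f2 <- weight_distance_fit(con)
  expect_equal(f1$lambda, f2$lambda, tolerance = 1e-9)
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-9)
  expect_equal(f2$intercept - f1$intercept, log(1e4), tolerance = 1e-6)
})
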