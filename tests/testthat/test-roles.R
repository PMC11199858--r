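test_that("participation limits: all-local gives 0, even split gives 0.5", {
  con <- two_cliques(bridge = 0)
  z <- stats::setNames(rep(1:2, each = 5), con$nodes$label)
  P <- participation(con, z, "out")
  expect_true(all(P == 0))
  # node with links split equally over two modules
  W <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  W["a", "b"] <- 1; W["a", "c"] <- 1
  con2 <- connectome(data.frame(label = letters[1:3]), W, "LNe")
  z2 <- stats::setNames(c(1, 1, 2), letters[1:3])
  expect_equal(participation(con2, z2, "out")[["a"]], 0.5)
  # single-module partition: P = 0 everywhere
  con3 <- random_connectome(10, seed = 5)
  expect_true(all(participation(con3, rep(1, 10), "in") == 0))
})

test_that("P and z match brute-force recomputation to 1e-12", {
  for (s in 1:4) {
    con <- random_connectome(30, seed = 70 + s)
    set.seed(s)
    z <- sample(1:4, 30, replace = TRUE)
    for (dir in c("in", "out")) for (wt in c(TRUE, FALSE)) {
      P <- participation(con, z, dir, weighted = wt)
      zz <- within_module_z(con, z, dir, weighted = wt)
      expect_lt(max(abs(P - brute_participation(con$W, z, dir, wt))), 1e-12)
      expect_lt(max(abs(zz - brute_z(con$W, z, dir, wt))), 1e-12)
      expect_true(all(P >= 0 & P <= 1))
    }
  }
})

test_that("within-module z uses population sd and the sigma = 0 rule", {
  # one module with out-kappas (1, 1, 4):
  # z = (kappa - 2) / sd_pop, sd_pop = sqrt(2), so (-0.707, -0.707, 1.414)
  W2 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  W2["a", "b"] <- 1; W2["b", "a"] <- 1; W2["c", "a"] <- 2; W2["c", "b"] <- 2
  con2 <- connectome(data.frame(label = letters[1:3]), W2, "LNe")
  zz <- within_module_z(con2, rep(1, 3), "out", weighted = TRUE)
  expect_equal(unname(zz), c(-1, -1, 2) / sqrt(2), tolerance = 1e-9)
  # uniform kappa: sigma = 0 gives z = 0, not NaN
  conu <- two_cliques(bridge = 0)
  zu <- within_module_z(conu, rep(1:2, each = 5), "out")
  expect_true(all(zu == 0))
})

test_that("role boundaries reproduce the R1-R7 table on a probe grid", {
  b <- role_boundaries()
  probes <- expand.grid(P = c(0, 0.03, 0.05, 0.06, 0.3, 0.62, 0.63,
                              0.75, 0.8, 0.81, 1),
                        z = c(-1, 0, 2, 2.4, 2.5, 2.51, 3, 5))
  expected <- with(probes, ifelse(z > 2.5,
    ifelse(P <= 0.30, "R5", ifelse(P <= 0.75, "R6", "R7")),
    ifelse(P <= 0.05, "R1", ifelse(P <= 0.62, "R2",
                                   ifelse(P <= 0.80, "R3", "R4")))))
  expect_equal(classify_role(probes$P, probes$z, b), expected)
  expect_equal(classify_role(0.1, 3), "R5")
  expect_equal(classify_role(0, 0), "R1")
  expect_error(classify_role(1.2, 0), "outside")
  # marginal-hub band is flagged but stays a non-hub role
  con <- random_connectome(10, seed = 1)
  tb <- role_table(con, rep(1:2, 5), "out")
  expect_true(all(tb$role[tb$marginal_hub] %in% c("R1", "R2", "R3", "R4")))
})

test_that("a planted cross-module hub tops the extracted hub list", {
  # three 10-cliques, plus one node wired strongly into every module
  # (an outlier among n_m module members caps at z = sqrt(n_m - 1), so the
  # module must be large enough for the hub band z > 2.5 to be reachable)
  m <- 10; K <- 3; n <- K * m + 1
  W <- matrix(0, n, n)
  for (k in 1:K) {
    idx <- ((k - 1) * m + 1):(k * m)
    W[idx, idx] <- 1
  }
  hub <- n
  W[hub, 1:(n - 1)] <- 3   # strong out-links everywhere
  W[1:(n - 1), hub] <- 0.2
  diag(W) <- 0
  labels <- c(sprintf("n%02d", 1:(n - 1)), "HUB")
  dimnames(W) <- list(labels, labels)
  con <- connectome(data.frame(label = labels), W, "LNe")
  z <- stats::setNames(c(rep(1:K, each = m), 1), labels)
  roles_in <- role_table(con, z, "in")
  roles_out <- role_table(con, z, "out")
  res <- extract_hubs_and_connectors(roles_in, roles_out)
  expect_equal(res$hubs$label[1], "HUB")
  expect_false("HUB" %in% res$connectors$label)
  # with no z > 2.5 nodes the hub list is empty but connectors may exist
  res2 <- extract_hubs_and_connectors(roles_in[roles_in$z < 2, ],
                                      roles_out[roles_out$z < 2, ])
  expect_equal(nrow(res2$hubs), 0)
})

test_that("P and z are invariant under global weight rescaling", {
  con <- random_connectome(20, seed = 91)
  z <- rep(1:4, 5)
  P1 <- participation(con, z, "in"); z1 <- within_module_z(con, z, "in")
  con$W <- con$W * 500
  expect_equal(participation(con, z, "in"), P1, tolerance = 1e-12)
  expect_equal(within_module_z(con, z, "in"), z1, tolerance = 1e-12)
})
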