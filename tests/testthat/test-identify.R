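test_that("pattern coefficients reproduce the joint log-odds exactly", {
  # two items sharing one operation, full-credit pattern
  W2 <- matrix(1, 2, 1)
  pc <- pattern_coefficients("osdclm", W2, c(1, 1))
  expect_equal(pc$s, 2L)
  expect_equal(unname(pc$r), c(-2, 1, 0))

  # all-zero pattern carries no information
  pc0 <- pattern_coefficients("osdclm", W2, c(0, 0))
  expect_equal(pc0$s, 0L)
  expect_true(all(pc0$r == 0))

  expect_error(pattern_coefficients("oslm", W2, c(1, 0)), "contingent")

  # s*theta + r'xi equals the sum of response-weighted logits for random
  # parameter values (the identity defining the coefficients)
  set.seed(31)
  for (model in c("osclm", "osdclm")) {
    J <- 6; M <- 2
    W <- random_weights(J, M)
    for (r in 1:20) {
      x <- rbinom(J, 1, 0.5)
      params <- random_params(model, J, M)
      theta <- rnorm(1)
      pc <- pattern_coefficients(model, W, x)
      xi <- unlist(params)
      lam <- pc$s * theta + sum(pc$r * xi)
      direct <- sum(vapply(seq_len(J), function(j)
        x[j] * item_logit(model, theta, params, W, x[seq_len(j - 1)], j),
        numeric(1)))
      expect_equal(lam, direct, tolerance = 1e-12)
    }
  }
})

test_that("rank conditions distinguish identified from deficient designs", {
  # OSLM with two items on one operation: Q = (W; V) has rank 2
  rep1 <- check_identification("oslm", matrix(1, 2, 1))
  expect_true(rep1$identified)
  expect_equal(rep1$achieved_rank, 2L)

  # duplicated operation columns break the LLTM rank condition
  Wdup <- cbind(c(1, 1, 1), c(1, 1, 1))
  rep2 <- check_identification("lltm", Wdup)
  expect_false(rep2$identified)

  # the fraction-subtraction design identifies the full differential model:
  # the realized-pattern coefficient matrix reaches rank 3M + 1 = 16
  W <- fraction_weights()
  expect_true(check_identification("osdclm", W)$identified)
  X <- simulate_responses("osdclm", generate_theta(536, seed = 2),
                          fraction_true_params(), W, seed = 3)
  emp <- check_identification("osdclm", W, X)
  expect_true(emp$identified)
  expect_equal(emp$achieved_rank, 16L)

  # duplicating response patterns cannot change the empirical verdict
  emp2 <- check_identification("osdclm", W, rbind(X, X[1:50, ]))
  expect_equal(emp$identified, emp2$identified)
  expect_equal(emp$achieved_rank, emp2$achieved_rank)
})

test_that("marginal pattern probabilities normalize and match simulation", {
  # single Rasch item at beta = 0: symmetry gives probability one half
  p1 <- pattern_probabilities("rasch", structural_params("rasch", beta = 0),
                              matrix(1, 1, 1))
  expect_equal(sum(p1$probability), 1, tolerance = 1e-10)
  expect_equal(p1$probability[p1$pattern == "1"], 0.5, tolerance = 1e-8)

  set.seed(17)
  W3 <- matrix(c(1, 1, 1, 0, 1, 1), 3, 2)
  for (model in c("lltm", "oslm", "osclm", "osdclm")) {
    params <- random_params(model, 3, 2)
    p <- pattern_probabilities(model, params, W3)
    expect_true(all(p$probability >= 0))
    expect_equal(sum(p$probability), 1, tolerance = 1e-10)
  }

  # enumeration agrees with forward simulation of the differential model
  params <- structural_params("osdclm", alpha = c(-0.5, 0.8),
                              delta = c(0.6, -0.3), gamma = c(0.2, -0.5))
  p <- pattern_probabilities("osdclm", params, W3)
  n_sim <- 1e6
  X <- simulate_responses("osdclm", generate_theta(n_sim, seed = 5), params,
                          W3, seed = 6)
  key <- apply(X, 1, paste0, collapse = "")
  freq <- as.numeric(table(factor(key, levels = p$pattern))) / n_sim
  se <- sqrt(p$probability * (1 - p$probability) / n_sim)
  expect_true(all(abs(freq - p$probability) < 4 * se))
})

test_that("the pattern-level Jacobian identity holds and flags deficiency", {
  set.seed(41)
  W3 <- matrix(c(1, 1, 1), 3, 1)
  params <- structural_params("osdclm", alpha = -0.5, delta = 0.7, gamma = 0.04)
  jb <- pattern_jacobian("osdclm", params, W3, theta = 0.3)

  # centering operator annihilates the vector of ones
  Tn <- length(jb$p)
  centering <- diag(Tn) - matrix(1, Tn, 1) %*% t(jb$p)
  expect_equal(max(abs(centering %*% rep(1, Tn))), 0, tolerance = 1e-12)

  # central differences of log p against the analytic Jacobian
  xi <- unlist(params)
  h <- 1e-6
  num <- sapply(seq_along(xi), function(k) {
    up <- xi; up[k] <- up[k] + h
    dn <- xi; dn[k] <- dn[k] - h
    (log(opirt:::pattern_softmax("osdclm", up, W3, theta = 0.3)) -
     log(opirt:::pattern_softmax("osdclm", dn, W3, theta = 0.3))) / (2 * h)
  })
  expect_equal(max(abs(num - jb$jacobian)), 0, tolerance = 1e-5)

  # information rank equals Jacobian rank, and a constant column in R
  # produces the predicted deficiency
  expect_equal(opirt:::numerical_rank(jb$information),
               opirt:::numerical_rank(jb$jacobian))
  Rbad <- cbind(jb$R, 1)
  Jbad <- centering %*% Rbad
  Ibad <- t(Jbad) %*% (jb$p * Jbad)
  expect_lt(opirt:::numerical_rank(Ibad), ncol(Rbad))
})

test_that("information-matrix and coefficient-rank verdicts agree", {
  set.seed(53)
  for (r in 1:5) {
    J <- sample(3:5, 1); M <- sample(1:2, 1)
    W <- random_weights(J, M, max_w = 1)
    params <- random_params("osdclm", J, M)
    jb <- pattern_jacobian("osdclm", params, W, theta = 0)
    info_full <- opirt:::numerical_rank(jb$information) == ncol(jb$R)
    rplus_full <- check_identification("osdclm", W)$identified
    expect_equal(info_full, rplus_full)
  }
})
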