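test_that("draw summaries compute EAP, SD and ordered intervals", {
  d <- matrix(5, 10, 1, dimnames = list(NULL, "a"))
  s <- draw_summary(d)
  expect_equal(s$eap, 5); expect_equal(s$sd, 0)
  expect_equal(s$q2.5, 5); expect_equal(s$q97.5, 5)

  s2 <- draw_summary(matrix(1:4, 4, 1))
  expect_equal(s2$eap, 2.5)
  expect_true(s2$q2.5 <= s2$q97.5)
  expect_error(draw_summary(matrix(numeric(0), 0, 1)), "no draws")
})

test_that("practice differences are zero when both practice effects agree", {
  M <- 3
  draws <- matrix(rnorm(50 * 3 * M), 50, 3 * M)
  draws[, 2 * M + seq_len(M)] <- draws[, M + seq_len(M)]  # gamma == delta
  fake <- structure(list(model = "osdclm", W = matrix(1, 4, M),
                         xi_draws = draws), class = "opl_fit")
  d <- practice_difference(fake)
  expect_true(all(d$eap == 0))
  expect_true(all(!d$credible))

  fake$model <- "oslm"
  expect_error(practice_difference(fake), "OSDCLM")
})

test_that("difficulty trajectories follow accumulated practice", {
  W <- fraction_weights()
  params <- fraction_true_params()

  # all-correct person: operation difficulty falls by delta per occurrence
  tr <- difficulty_trajectory(params, W, rep(1, 15))
  op1 <- dplyr::filter(tr, operation == 1)
  expect_equal(op1$difficulty,
               params$alpha[1] - params$delta[1] * (op1$occurrence - 1))
  expect_equal(tr$difficulty[tr$occurrence == 1],
               params$alpha)  # practice is zero at first appearance

  # no practice effects: flat at alpha
  flat <- difficulty_trajectory(structural_params("lltm", alpha = params$alpha),
                                W, rbinom(15, 1, 0.5))
  expect_true(all(flat$difficulty == params$alpha[flat$operation]))

  # two persons with the same sub-pattern on the items using an operation
  # share that operation's trajectory
  x1 <- as.integer(strsplit("010101111110111", "")[[1]])
  x2 <- rep(1L, 15)
  t1 <- difficulty_trajectory(params, W, x1)
  t2 <- difficulty_trajectory(params, W, x2)
  for (m in c(2, 5)) {  # identical responses on the items involving m
    expect_equal(dplyr::filter(t1, operation == m)$difficulty,
                 dplyr::filter(t2, operation == m)$difficulty)
  }
  expect_false(isTRUE(all.equal(dplyr::filter(t1, operation == 3)$difficulty,
                                dplyr::filter(t2, operation == 3)$difficulty)))
})

test_that("the sampler recovers Rasch difficulties on simulated data", {
  set.seed(71)
  J <- 10; I <- 300
  beta <- seq(-1.5, 1.5, length.out = J)
  theta <- rnorm(I)
  X <- simulate_responses("rasch", theta,
                          structural_params("rasch", beta = beta),
                          diag(J), seed = 72)
  fit <- fit_oplm(X, diag(J), "rasch", config = quick_config(seed = 73, iter = 600))
  est <- tidy(fit)
  expect_gt(cor(est$eap, beta), 0.9)
  expect_lt(mean(abs(est$eap - beta)), 0.25)
  expect_true(all(est$rhat < 1.2))
  expect_true(all(est$q2.5 < est$q97.5))
})

test_that("Rasch and identity-weight LLTM give matching difficulty estimates", {
  set.seed(81)
  J <- 8; I <- 250
  beta <- rnorm(J, sd = 1)
  X <- simulate_responses("rasch", rnorm(I),
                          structural_params("rasch", beta = beta),
                          diag(J), seed = 82)
  f1 <- fit_oplm(X, diag(J), "rasch", config = quick_config(seed = 83, iter = 800))
  f2 <- fit_oplm(X, diag(J), "lltm", config = quick_config(seed = 84, iter = 800))
  expect_lt(max(abs(tidy(f1)$eap - tidy(f2)$eap)), 0.15)
})

test_that("posterior estimates are robust to the structural prior", {
  set.seed(91)
  W <- W_toy()
  params <- structural_params("osclm", alpha = c(-0.5, 0.7), delta = c(0.4, 0.1))
  X <- simulate_responses("osclm", rnorm(400), params, W, seed = 92)
  f_weak <- fit_oplm(X, W, "osclm", config = quick_config(seed = 93, iter = 800),
                     prior_var = 100)
  f_flat <- fit_oplm(X, W, "osclm", config = quick_config(seed = 94, iter = 800),
                     prior_var = 1e6)
  expect_lt(mean(abs(tidy(f_weak)$eap - tidy(f_flat)$eap)), 0.06)
  # a shifted prior mean barely moves weakly informed estimates
  f_mean <- fit_oplm(X, W, "osclm", config = quick_config(seed = 95, iter = 800),
                     prior_mean = 1, prior_var = 100)
  expect_lt(mean(abs(tidy(f_weak)$eap - tidy(f_mean)$eap)), 0.06)
})

test_that("the posterior matches an independent Gibbs sampler", {
  set.seed(101)
  J <- 6; M <- 2; I <- 120
  W <- random_weights(J, M, max_w = 1)
  params <- structural_params("osdclm", alpha = c(-0.4, 0.6),
                              delta = c(0.5, -0.2), gamma = c(0.1, 0.3))
  X <- simulate_responses("osdclm", rnorm(I), params, W, seed = 102)
  fit <- fit_oplm(X, W, "osdclm",
                  config = mcmc_config(chains = 2, iter = 3000, seed = 103))
  des <- opirt:::structural_design("osdclm", X, W)

  library(rjags)
  data <- list(y = des$y, Z = des$Z, person = des$person,
               n = length(des$y), P = ncol(des$Z), I = I)
  spec <- "model {
    for (k in 1:n) {
      logit(p[k]) <- inprod(Z[k,], xi) + theta[person[k]]
      y[k] ~ dbern(p[k])
    }
    for (j in 1:P) { xi[j] ~ dnorm(0, 0.01) }
    for (i in 1:I) { theta[i] ~ dnorm(0, 1) }
  }"
  jm <- jags.model(textConnection(spec), data = data, n.chains = 2,
                   n.adapt = 500, quiet = TRUE,
                   inits = list(.RNG.name = "base::Mersenne-Twister",
                                .RNG.seed = 104))
  update(jm, 500)
  samp <- coda.samples(jm, "xi", n.iter = 4000)
  ref <- summary(samp)$statistics
  ours <- tidy(fit)
  expect_lt(max(abs(ours$eap - ref[, "Mean"])), 0.12)
  expect_lt(max(abs(ours$sd - ref[, "SD"])), 0.08)
})
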