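test_that("non-contingent practice counts accumulate previous operation use", {
  # running count for a single always-used operation
  expect_equal(unname(noncontingent_practice(matrix(1, 4, 1))[, 1]),
               c(0, 1, 2, 3))

  # operation 5 of the fraction-subtraction matrix appears on items 4, 10, 14
  V <- noncontingent_practice(fraction_weights())
  expect_equal(unname(V[c(4, 10, 14), 5]), c(0, 1, 2))
  expect_true(all(V[-c(4, 10, 14), 5] == 0))

  # counts vanish where the current item does not use the operation
  W <- W_toy()
  V <- noncontingent_practice(W)
  expect_true(all(V[W == 0] == 0))
})

test_that("contingent practice splits by correctness and conserves the total", {
  W <- fraction_weights()
  x <- rep(1, 15); x[4] <- 0   # miss the first operation-5 item
  cp <- contingent_practice(W, x)
  expect_equal(cp$V[10, 5], 0)  # only incorrect practice of op 5 before item 10
  expect_equal(cp$U[10, 5], 1)
  expect_equal(cp$V[14, 5], 1)
  expect_equal(cp$U[14, 5], 1)

  # all-correct and all-wrong degenerate cases
  V <- noncontingent_practice(W)
  allc <- contingent_practice(W, rep(1, 15))
  expect_equal(allc$V, V); expect_true(all(allc$U == 0))
  allw <- contingent_practice(W, rep(0, 15))
  expect_true(all(allw$V == 0)); expect_equal(allw$U, V)

  # conservation V + U = total practice for random response vectors
  set.seed(42)
  for (r in 1:20) {
    J <- sample(3:10, 1); M <- sample(1:3, 1)
    Wr <- random_weights(J, M)
    x <- rbinom(J, 1, 0.5)
    cp <- contingent_practice(Wr, x)
    expect_equal(cp$V + cp$U, noncontingent_practice(Wr))
    expect_true(all(cp$V[1, ] == 0) && all(cp$U[1, ] == 0))
  }
})

test_that("item logits follow the model definitions", {
  W1 <- matrix(1, 3, 1)
  expect_equal(item_logit("rasch", 0, structural_params("rasch", beta = rep(0, 3)),
                          W1, j = 1), 0)
  # differential contingent learning, direct substitution
  p <- structural_params("osdclm", alpha = 1, delta = 0.5, gamma = 0.2)
  expect_equal(item_logit("osdclm", 0, p, W1, history = c(1, 0), j = 3), -0.3)
  # history must match the item position
  expect_error(item_logit("osdclm", 0, p, W1, history = c(1), j = 3), "history")

  # equal delta and gamma collapse the differential model onto the OSLM
  set.seed(7)
  for (r in 1:10) {
    J <- 6; M <- 2
    W <- random_weights(J, M)
    d <- rnorm(M) / 2; a <- rnorm(M)
    posd <- structural_params("osdclm", alpha = a, delta = d, gamma = d)
    posl <- structural_params("oslm", alpha = a, delta = d)
    x <- rbinom(J, 1, 0.5)
    for (j in seq_len(J))
      expect_equal(item_logit("osdclm", 0.3, posd, W, x[seq_len(j - 1)], j),
                   item_logit("oslm", 0.3, posl, W, x[seq_len(j - 1)], j))
  }
})

test_that("vectorized predictors agree with the item-wise oracle", {
  set.seed(11)
  for (model in model_tags()) {
    J <- 7; M <- 3; I <- 9
    W <- random_weights(J, M)
    params <- random_params(model, J, M)
    theta <- rnorm(I)
    X <- matrix(rbinom(I * J, 1, 0.5), I, J)
    eta <- linear_predictor(model, X, theta, params, W)
    for (i in c(1, 5, 9)) for (j in seq_len(J))
      expect_equal(eta[i, j],
                   naive_logit(model, theta[i], params, W, X[i, ], j),
                   tolerance = 1e-12)
  }
})

test_that("log-likelihood nests collapse exactly and match a loop oracle", {
  set.seed(23)
  J <- 8; M <- 2; I <- 15
  W <- random_weights(J, M)
  theta <- rnorm(I)
  X <- matrix(rbinom(I * J, 1, 0.5), I, J)
  a <- rnorm(M); d <- rnorm(M) / 2; g <- rnorm(M) / 2

  ll <- function(model, params) response_loglik(model, X, theta, params, W)$total
  # gamma = delta -> OSLM; gamma = 0 -> OSCLM; both zero -> LLTM
  expect_equal(ll("osdclm", structural_params("osdclm", alpha = a, delta = d, gamma = d)),
               ll("oslm", structural_params("oslm", alpha = a, delta = d)))
  expect_equal(ll("osdclm", structural_params("osdclm", alpha = a, delta = d, gamma = rep(0, M))),
               ll("osclm", structural_params("osclm", alpha = a, delta = d)))
  expect_equal(ll("osdclm", structural_params("osdclm", alpha = a, delta = rep(0, M), gamma = rep(0, M))),
               ll("lltm", structural_params("lltm", alpha = a)))
  # LLTM with an identity weight matrix is the Rasch model
  bI <- rnorm(J)
  expect_equal(response_loglik("lltm", X, theta,
                               structural_params("lltm", alpha = bI), diag(J))$total,
               response_loglik("rasch", X, theta,
                               structural_params("rasch", beta = bI), W = diag(J))$total)

  # loop-oracle equivalence
  for (model in model_tags()) {
    params <- random_params(model, J, M)
    expect_equal(ll(model, params), naive_loglik(model, X, theta, params, W),
                 tolerance = 1e-10)
  }
})

test_that("log-likelihood stays finite for extreme parameters", {
  W <- W_toy()
  X <- matrix(rbinom(40, 1, 0.5), 10, 4)
  p <- structural_params("osdclm", alpha = c(50, -50), delta = c(50, -50),
                         gamma = c(-50, 50))
  out <- response_loglik("osdclm", X, rep(c(-10, 10), 5), p, W)
  expect_true(is.finite(out$total))
  expect_true(all(is.finite(out$pointwise)))
})

test_that("input validation catches malformed responses and weights", {
  expect_error(validate_responses(matrix(c(0, 2, 1, 0), 2, 2)), "row 2, column 1")
  expect_error(validate_responses(matrix(c(0, 1, NA, 0), 2, 2)), "row 1, column 2")
  expect_error(validate_responses(matrix(1, 2, 1)), "at least 2 items")
  expect_error(validate_weights(matrix(c(1, 0, 0, 0), 2, 2)), "all-zero")
  expect_error(validate_weights(matrix(c(1, 1, 0, 0), 2, 2)), "operation 2")
  expect_warning(validate_weights(matrix(c(1, 0.5, 1, 1), 2, 2)), "counts")
})
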