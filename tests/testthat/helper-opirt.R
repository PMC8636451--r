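# shared fixtures and independent reference implementations

W_toy <- function() {
  W <- matrix(c(1, 1, 0, 1,
                0, 1, 1, 1), 4, 2)
  colnames(W) <- c("opA", "opB")
  W
}

random_weights <- function(J, M, max_w = 2) {
  repeat {
    W <- matrix(sample(0:max_w, J * M, replace = TRUE), J, M)
    if (all(rowSums(W) > 0) && all(colSums(W) > 0)) return(W)
  }
}

random_params <- function(model, J, M, scale = 0.8) {
  r <- function(n) round(rnorm(n, sd = scale), 2)
  switch(model,
    rasch  = structural_params("rasch", beta = r(J)),
    lltm   = structural_params("lltm", alpha = r(M)),
    oslm   = structural_params("oslm", alpha = r(M), delta = r(M) / 2),
    osclm  = structural_params("osclm", alpha = r(M), delta = r(M) / 2),
    osdclm = structural_params("osdclm", alpha = r(M), delta = r(M) / 2,
                               gamma = r(M) / 2))
}

# literal loop transcription of the model logits, independent of the
# vectorized implementation
naive_logit <- function(model, theta, params, W, x, j) {
  M <- ncol(W)
  if (model == "rasch") return(theta - params$beta[j])
  eta <- theta
  for (m in seq_len(M)) {
    corr <- incorr <- tot <- 0
    if (j > 1) for (k in seq_len(j - 1)) {
      tot <- tot + W[k, m]
      corr <- corr + x[k] * W[k, m]
      incorr <- incorr + (1 - x[k]) * W[k, m]
    }
    d <- params$alpha[m]
    if (model == "oslm") d <- d - params$delta[m] * tot
    if (model == "osclm") d <- d - params$delta[m] * corr
    if (model == "osdclm") d <- d - params$delta[m] * corr - params$gamma[m] * incorr
    eta <- eta - W[j, m] * d
  }
  eta
}

naive_loglik <- function(model, X, theta, params, W) {
  total <- 0
  for (i in seq_len(nrow(X))) for (j in seq_len(ncol(X))) {
    eta <- naive_logit(model, theta[i], params, W, X[i, ], j)
    p <- plogis(eta)
    total <- total + ifelse(X[i, j] == 1, log(p), log(1 - p))
  }
  total
}

quick_config <- function(seed = 1, iter = 400, chains = 2) {
  mcmc_config(chains = chains, iter = iter, seed = seed)
}
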