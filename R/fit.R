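#' MCMC configuration
#'
#' Defaults follow the estimation protocol used throughout the package's
#' reference analyses: four chains of 2,000 iterations each, the first half
#' discarded as burn-in, weakly informative N(0, 100) priors on structural
#' parameters (variance 100), standard normal priors on abilities, and a
#' convergence check on the potential scale reduction statistic.
#'
#' @param chains number of chains (>= 2).
#' @param iter iterations per chain (>= 200).
#' @param burnin fraction of each chain discarded (default 0.5).
#' @param seed master seed; per-chain seeds are derived deterministically.
#' @param rhat_threshold convergence cutoff for split-R-hat (default 1.1).
#' @param target_accept dual-averaging acceptance target.
#' @param leapfrog integer range (min, max) of leapfrog steps per iteration.
#' @return List of class `"opl_mcmc_config"`.
#' @export
mcmc_config <- function(chains = 4, iter = 2000, burnin = 0.5, seed = NULL,
                        rhat_threshold = 1.1, target_accept = 0.8,
                        leapfrog = c(4, 12)) {
  stopifnot(chains >= 2, iter >= 200, burnin > 0, burnin < 1,
            length(leapfrog) == 2, leapfrog[1] >= 1, leapfrog[2] >= leapfrog[1])
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 burnin = burnin, seed = seed,
                 rhat_threshold = rhat_threshold,
                 target_accept = target_accept,
                 leapfrog = as.integer(leapfrog)),
            class = "opl_mcmc_config")
}

## ---- design for estimation ------------------------------------------------

## Long-format structural design: observation n = (i-1)*J + j.
## eta_n = Z[n, ] %*% xi + theta[person[n]]
structural_design <- function(model, X, W) {
  model <- match_model(model)
  I <- nrow(X); J <- nrow(W); M <- ncol(W)
  rep_rows <- function(A) A[rep(seq_len(J), I), , drop = FALSE]
  flat <- function(mat) as.vector(t(mat))  # I x J -> person-major vector
  if (model == "rasch") {
    Z <- rep_rows(-diag(J))
  } else if (model == "lltm") {
    Z <- rep_rows(-W)
  } else if (model == "oslm") {
    Z <- cbind(rep_rows(-W), rep_rows(noncontingent_practice(W)))
  } else {
    S <- cum_lower(J)
    Vcols <- matrix(0, I * J, M)
    Ucols <- if (model == "osdclm") matrix(0, I * J, M) else NULL
    for (m in seq_len(M)) {
      Cm <- sweep(X, 2, W[, m], `*`) %*% S
      Vcols[, m] <- flat(sweep(Cm, 2, W[, m], `*`))
      if (model == "osdclm") {
        Em <- sweep(1 - X, 2, W[, m], `*`) %*% S
        Ucols[, m] <- flat(sweep(Em, 2, W[, m], `*`))
      }
    }
    Z <- cbind(rep_rows(-W), Vcols, Ucols)
  }
  colnames(Z) <- param_names(model, W)
  list(Z = Z, y = flat(X), person = rep(seq_len(I), each = J))
}

## Newton mode + diagonal Hessian of the log posterior (Laplace
## approximation), exploiting the block structure: the theta block of the
## Hessian is diagonal, so each step solves only a P x P system.
laplace_mode <- function(Z, y, person, I, prec_xi, prec_theta = 1,
                         offset = 0, max_iter = 25, tol = 1e-8) {
  P <- ncol(Z)
  xi <- numeric(P); theta <- numeric(I)
  A <- NULL; cth <- NULL; B <- NULL; Sc <- NULL
  for (it in seq_len(max_iter)) {
    eta <- drop(Z %*% xi) + theta[person] + offset
    p <- plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    g <- y - p
    g_xi <- drop(crossprod(Z, g)) - prec_xi * xi
    g_th <- drop(rowsum(g, person)) - prec_theta * theta
    A <- crossprod(Z, Z * w) + diag(prec_xi, P)
    cth <- drop(rowsum(w, person)) + prec_theta
    B <- t(rowsum(Z * w, person))               # P x I
    Sc <- A - B %*% (t(B) / cth)
    d_xi <- solve(Sc, g_xi - B %*% (g_th / cth))
    d_th <- (g_th - drop(crossprod(B, d_xi))) / cth
    xi <- xi + drop(d_xi); theta <- theta + d_th
    if (max(abs(c(d_xi, d_th))) < tol) break
  }
  list(xi = xi, theta = theta,
       chol_schur = chol(Sc), cross = B, theta_prec = cth)
}

## ---- convergence ----------------------------------------------------------

## split-half potential scale reduction, one value per column of draws
split_rhat <- function(draws, chain) {
  grp <- character(length(chain))
  for (ch in unique(chain)) {
    idx <- which(chain == ch)
    grp[idx] <- paste0(ch, ".", rep(1:2, each = ceiling(length(idx) / 2))[seq_along(idx)])
  }
  apply(draws, 2, function(x) {
    m <- tapply(x, grp, mean)
    v <- tapply(x, grp, var)
    n <- min(table(grp))
    W <- mean(v)
    B <- n * var(as.numeric(m))
    if (W <= 0) return(1)
    sqrt((n - 1) / n + B / (n * W))
  })
}

## ---- fitting --------------------------------------------------------------

#' Fit an operation-specific learning model by Hamiltonian Monte Carlo
#'
#' Samples the joint posterior of the structural parameters and the person
#' abilities.  Conditional on the observed response histories, every model
#' in the family is a Bernoulli-logit regression with a fixed design, which
#' the sampler exploits: a Laplace approximation supplies the starting
#' values and the full curvature metric, and a fixed-metric HMC transition with
#' dual-averaging step-size adaptation does the sampling.  Chains are
#' reproducible from the `seed` in `config`.
#'
#' Structural parameters get independent `N(prior_mean, prior_var)` priors;
#' abilities get standard normal priors, which also fix the latent scale.
#' The identifiability of the structural block is checked up front with
#' [check_identification()]; a failed check warns but does not stop.
#'
#' @param X person-by-item binary response matrix (administration order).
#' @param W item-by-operation weight matrix (ignored for the Rasch model,
#'   where it only provides dimensions).
#' @param model model tag; see [model_tags()].
#' @param config an [mcmc_config()].
#' @param prior_mean,prior_var normal prior for structural parameters
#'   (defaults 0 and 100).
#' @param check_id run the identification check (default TRUE).
#' @return An object of class `"opl_fit"`; see [tidy.opl_fit()],
#'   [glance.opl_fit()], [posterior_summary()], [ppmc()], [waic()].
#' @examples
#' \donttest{
#' W <- fraction_weights()
#' truth <- fraction_true_params()
#' X <- simulate_responses("osdclm", generate_theta(150, seed = 1), truth, W,
#'                         seed = 2)
#' fit <- fit_oplm(X, W, "osdclm",
#'                 config = mcmc_config(chains = 2, iter = 500, seed = 3))
#' tidy(fit)
#' }
#' @export
fit_oplm <- function(X, W, model, config = mcmc_config(),
                     prior_mean = 0, prior_var = 100, check_id = TRUE) {
  model <- match_model(model)
  X <- validate_responses(X)
  W <- validate_weights(W)
  if (ncol(X) != nrow(W))
    stop("X and W disagree on the number of items", call. = FALSE)
  stopifnot(inherits(config, "opl_mcmc_config"), prior_var > 0)

  if (check_id) {
    id <- check_identification(model, W, X = if (is_contingent(model)) X else NULL)
    if (!id$identified)
      warning(sprintf("structural parameters of the %s may not be identified (rank %d < %d)",
                      model, id$achieved_rank, id$required_rank), call. = FALSE)
  } else id <- NULL

  des <- structural_design(model, X, W)
  I <- nrow(X); P <- ncol(des$Z)
  prec_xi <- rep(1 / prior_var, P)
  offset <- drop(des$Z %*% rep(prior_mean, P))
  map <- laplace_mode(des$Z, des$y, des$person, I, prec_xi, offset = offset)

  seed <- if (is.null(config$seed)) sample.int(.Machine$integer.max, 1) else config$seed
  warmup <- floor(config$iter * config$burnin)
  keep <- config$iter - warmup
  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1, config$chains)

  draws <- vector("list", config$chains)
  accept <- div <- numeric(config$chains)
  D <- P + I
  sqc <- sqrt(map$theta_prec)
  for (ch in seq_len(config$chains)) {
    set.seed(chain_seeds[ch])
    ## jitter the mode by a draw from the Laplace approximation
    z <- rnorm(D)
    j_xi <- backsolve(map$chol_schur, z[seq_len(P)])
    j_th <- z[P + seq_len(I)] / sqc -
      drop(crossprod(map$cross, j_xi)) / map$theta_prec
    init <- c(map$xi + j_xi, map$theta + j_th)
    res <- .hmc_chain(des$Z, des$y, des$person - 1L, I, c(prec_xi, rep(1, I)),
                      offset, init, map$chol_schur, map$cross, map$theta_prec,
                      config$iter, warmup,
                      config$target_accept, config$leapfrog[1],
                      config$leapfrog[2], 0.2)
    draws[[ch]] <- res$draws
    accept[ch] <- res$accept_rate
    div[ch] <- res$divergences
  }
  all_draws <- do.call(rbind, draws)
  chain_id <- rep(seq_len(config$chains), each = keep)
  ## shift the structural block back to its prior-mean parameterization
  if (prior_mean != 0) all_draws[, seq_len(P)] <- all_draws[, seq_len(P)] + prior_mean

  nm <- param_names(model, W)
  xi_draws <- all_draws[, seq_len(P), drop = FALSE]
  colnames(xi_draws) <- nm
  theta_draws <- all_draws[, P + seq_len(I), drop = FALSE]
  colnames(theta_draws) <- paste0("theta[", seq_len(I), "]")

  rhat <- c(split_rhat(xi_draws, chain_id), split_rhat(theta_draws, chain_id))
  conv_ok <- all(rhat <= config$rhat_threshold, na.rm = TRUE)
  if (!conv_ok)
    warning(sprintf("convergence warning: max split-R-hat = %.3f (threshold %.2f)",
                    max(rhat, na.rm = TRUE), config$rhat_threshold), call. = FALSE)

  structure(list(
    model = model, X = X, W = W,
    xi_draws = xi_draws, theta_draws = theta_draws, chain = chain_id,
    rhat = rhat, converged = conv_ok,
    accept_rate = accept, divergences = sum(div),
    config = config, seed = seed, prior_mean = prior_mean,
    prior_var = prior_var, mode = map, identification = id
  ), class = "opl_fit")
}

#' @export
print.opl_fit <- function(x, ...) {
  cat(sprintf("<opl_fit> %s model: %d persons x %d items, %d retained draws (%d chains)\n",
              toupper(x$model), nrow(x$X), ncol(x$X), nrow(x$xi_draws),
              x$config$chains))
  cat(sprintf("  max R-hat %.3f | divergences %d | mean accept %.2f\n",
              max(x$rhat, na.rm = TRUE), x$divergences, mean(x$accept_rate)))
  print(tidy(x), n = 15)
  invisible(x)
}

## ---- summaries ------------------------------------------------------------

#' Summarize a matrix of posterior draws
#'
#' @param draws L x P matrix, one column per parameter.
#' @return Tibble with EAP (posterior mean), posterior SD and the central
#'   95% probability interval per parameter.
#' @export
draw_summary <- function(draws) {
  draws <- as.matrix(draws)
  if (nrow(draws) == 0) stop("no draws to summarize", call. = FALSE)
  qs <- apply(draws, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  tibble::tibble(
    parameter = colnames(draws) %||% paste0("par", seq_len(ncol(draws))),
    eap = unname(colMeans(draws)),
    sd = unname(apply(draws, 2, sd)),
    q2.5 = unname(qs[1, ]), q97.5 = unname(qs[2, ])
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Posterior summary of a fitted model
#'
#' @param fit an `"opl_fit"`.
#' @param pars `"structural"`, `"theta"`, or `"all"`.
#' @return Tibble: parameter, EAP, SD, 2.5% and 97.5% quantiles, R-hat.
#' @export
posterior_summary <- function(fit, pars = c("structural", "theta", "all")) {
  pars <- match.arg(pars)
  stopifnot(inherits(fit, "opl_fit"))
  draws <- switch(pars,
    structural = fit$xi_draws,
    theta = fit$theta_draws,
    all = cbind(fit$xi_draws, fit$theta_draws))
  out <- draw_summary(draws)
  out$rhat <- unname(fit$rhat[out$parameter])
  out
}

#' Tidy method for fitted models: the structural parameter table
#'
#' @param x an `"opl_fit"`.
#' @param ... unused.
#' @return Tibble of structural-parameter summaries (EAP, SD, interval,
#'   R-hat).
#' @export
tidy.opl_fit <- function(x, ...) posterior_summary(x, "structural")

#' Glance method for fitted models
#'
#' @param x an `"opl_fit"`.
#' @param ... unused.
#' @return One-row tibble with model tag, data dimensions, draw count,
#'   max R-hat, divergence count and mean acceptance rate.
#' @export
glance.opl_fit <- function(x, ...) {
  tibble::tibble(model = x$model, n_persons = nrow(x$X), n_items = ncol(x$X),
                 n_structural = ncol(x$xi_draws), n_draws = nrow(x$xi_draws),
                 max_rhat = max(x$rhat, na.rm = TRUE),
                 converged = x$converged,
                 divergences = x$divergences,
                 accept_rate = mean(x$accept_rate))
}

## EAP structural parameters of a fit, as an opl_params object
eap_params <- function(fit) {
  vector_params(fit$model, colMeans(fit$xi_draws))
}

#' Practice-parameter differences of the OSDCLM
#'
#' Summarizes `d_m = delta_m - gamma_m`, the difference between the
#' learning derived from correct and from incorrect practice of operation
#' `m`, computed draw-wise.  A difference is flagged credible when its 95%
#' posterior interval excludes zero.
#'
#' @param fit an OSDCLM `"opl_fit"`.
#' @return Tibble: operation, EAP, SD, interval, `credible` flag.
#' @export
practice_difference <- function(fit) {
  stopifnot(inherits(fit, "opl_fit"))
  if (fit$model != "osdclm")
    stop("practice differences are defined for the OSDCLM", call. = FALSE)
  M <- ncol(fit$W)
  d <- fit$xi_draws[, M + seq_len(M), drop = FALSE] -
    fit$xi_draws[, 2 * M + seq_len(M), drop = FALSE]
  colnames(d) <- paste0("d[", seq_len(M), "]")
  out <- draw_summary(d)
  out$operation <- seq_len(M)
  out$credible <- out$q2.5 > 0 | out$q97.5 < 0
  out[, c("operation", "parameter", "eap", "sd", "q2.5", "q97.5", "credible")]
}

#' Effective operation difficulty along the test
#'
#' Tracks, for one person, how the difficulty of each operation evolves
#' over the items that involve it: at each occurrence the effective
#' difficulty is `alpha_m - delta_m * (correct previous practice) -
#' gamma_m * (incorrect previous practice)`, evaluated from the person's
#' own responses.  Previous practice is zero the first time an operation
#' appears.  Nested models follow by setting `gamma = delta` (OSLM, with
#' total practice), `gamma = 0` (OSCLM) or both to zero (LLTM, flat
#' trajectory).
#'
#' @param object an `"opl_fit"` (EAPs are used) or an `"opl_params"`.
#' @param W weight matrix (taken from the fit when omitted).
#' @param x the person's 0/1 response vector.
#' @return Tibble of class `"opl_trajectory"`: operation, item, occurrence,
#'   practice counts and effective difficulty.
#' @export
difficulty_trajectory <- function(object, W = NULL, x) {
  if (inherits(object, "opl_fit")) {
    W <- W %||% object$W
    params <- eap_params(object)
    model <- object$model
  } else {
    params <- object
    model <- attr(params, "model")
  }
  if (model == "rasch")
    stop("operation trajectories require an operation-level model", call. = FALSE)
  W <- validate_weights(W)
  if (length(x) != nrow(W))
    stop("response vector length does not match number of items", call. = FALSE)
  delta <- switch(model, lltm = rep(0, ncol(W)), params$delta)
  gamma <- switch(model,
    lltm = rep(0, ncol(W)),
    oslm = params$delta,   # non-contingent: any practice counts equally
    osclm = rep(0, ncol(W)),
    osdclm = params$gamma)
  J <- nrow(W); M <- ncol(W)
  rows <- list()
  for (m in seq_len(M)) {
    items <- which(W[, m] > 0)
    corr <- c(0, cumsum(x * W[, m]))[items]
    incorr <- c(0, cumsum((1 - x) * W[, m]))[items]
    if (model == "oslm") {
      tot <- c(0, cumsum(W[, m]))[items]
      corr <- tot; incorr <- 0 * tot; gamma[m] <- 0
    }
    rows[[m]] <- tibble::tibble(
      operation = m, item = unname(items), occurrence = seq_along(items),
      correct_practice = unname(corr), incorrect_practice = unname(incorr),
      difficulty = unname(params$alpha[m] - delta[m] * corr - gamma[m] * incorr)
    )
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("opl_trajectory", class(out))
  out
}

#' Plot an operation-difficulty trajectory
#'
#' @param object an `"opl_trajectory"` from [difficulty_trajectory()].
#' @param ... unused.
#' @return A ggplot: effective difficulty against occurrence, one line per
#'   operation.
#' @export
autoplot.opl_trajectory <- function(object, ...) {
  ggplot2::ggplot(object,
    ggplot2::aes(x = .data$occurrence, y = .data$difficulty,
                 colour = factor(.data$operation))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "occurrence of the operation",
                  y = "effective difficulty", colour = "operation") +
    ggplot2::theme_minimal()
}
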