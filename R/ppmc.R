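#' Pairwise, item-level and test-level odds ratios
#'
#' The odds ratio `OR = n11 * n00 / (n10 * n01)` over the 2 x 2 table of
#' each unordered item pair is a model-free measure of local dependence.
#' Item-level values sum the ORs of the pairs containing the item; the
#' test-level value sums over all unordered pairs (so item-level values
#' add up to twice the test-level value).
#'
#' Pairs whose 2 x 2 table contains an empty cell (common in replicated
#' data with easy or hard items) get the Haldane-Anscombe correction:
#' 0.5 is added to all four cells of that table only, and the pair is
#' flagged.  Keeping the corrected pair (rather than dropping it) keeps
#' realized and replicated sums comparable over the identical pair set.
#'
#' @param X binary response matrix.
#' @return List with `pair` (tibble: item1, item2, or, corrected), `item`
#'   (named numeric vector of length J) and `test` (scalar).
#' @export
odds_ratio_stats <- function(X) {
  X <- validate_responses(X)
  J <- ncol(X)
  n11 <- crossprod(X)
  n00 <- crossprod(1 - X)
  n10 <- crossprod(X, 1 - X)   # [j, j'] = #(x_j = 1, x_j' = 0)
  ut <- which(upper.tri(n11), arr.ind = TRUE)
  a <- n11[ut]; b <- n10[ut]; cc <- t(n10)[ut]; d <- n00[ut]
  corrected <- (a == 0) | (b == 0) | (cc == 0) | (d == 0)
  h <- 0.5 * corrected
  or <- (a + h) * (d + h) / ((b + h) * (cc + h))
  pair <- tibble::tibble(item1 = ut[, 1], item2 = ut[, 2],
                         or = or, corrected = corrected)
  item <- vapply(seq_len(J), function(j)
    sum(or[ut[, 1] == j | ut[, 2] == j]), numeric(1))
  names(item) <- colnames(X)
  list(pair = pair, item = item, test = sum(or))
}

## truncated latent residuals for one parameter draw.
## Z is drawn from a standard normal (default) or logistic distribution
## centred at the linear predictor, truncated to (0, Inf) when x = 1 and
## (-Inf, 0] when x = 0; eps = Z - eta.  Inverse-CDF sampling on the log
## scale keeps extreme |eta| finite.
latent_residuals <- function(eta, X, latent = "normal") {
  u <- matrix(runif(length(eta)), nrow(eta), ncol(eta))
  lcdf0 <- if (latent == "normal") pnorm(-eta, log.p = TRUE)
           else plogis(-eta, log.p = TRUE)   # log P(Z <= 0)
  lsf0 <- if (latent == "normal") pnorm(eta, log.p = TRUE)
          else plogis(eta, log.p = TRUE)     # log P(Z > 0)
  qfun <- if (latent == "normal") qnorm else qlogis
  eps <- matrix(0, nrow(eta), ncol(eta))
  pos <- X == 1
  ## x = 1: upper tail mass; x = 0: lower tail mass
  eps[pos] <- -qfun(log1p(-u[pos]) + lsf0[pos], log.p = TRUE)
  eps[!pos] <- qfun(log(u[!pos]) + lcdf0[!pos], log.p = TRUE)
  eps
}

#' Bayesian latent residual statistics
#'
#' For one posterior draw, augments each observation with a latent
#' response `Z_ij` centred at the model logit `eta_ij` and truncated by
#' the response (`Z > 0` when correct, `Z <= 0` when incorrect), and
#' returns the sums of squared residuals `eps_ij = Z_ij - eta_ij` per item
#' and for the whole test.  One latent draw is taken per posterior draw.
#'
#' @param model model tag.
#' @param X binary response matrix (observed or replicated).
#' @param theta ability vector for the draw.
#' @param params structural parameters for the draw.
#' @param W weight matrix.
#' @param latent `"normal"` (Albert-Chib-style augmentation, default) or
#'   `"logistic"` latent scale.
#' @return List with `item` (length-J vector of summed squared residuals)
#'   and `test` (their total).
#' @export
blr_stats <- function(model, X, theta, params, W,
                      latent = c("normal", "logistic")) {
  latent <- match.arg(latent)
  X <- validate_responses(X)
  eta <- linear_predictor(model, X, theta, params, W)
  eps <- latent_residuals(eta, X, latent)
  item <- colSums(eps^2)
  names(item) <- colnames(X)
  list(item = item, test = sum(item))
}

#' Posterior predictive p value
#'
#' The proportion of posterior draws in which the replicated discrepancy is
#' greater than or equal to the realized discrepancy (ties count).
#'
#' @param realized,replicated equal-length vectors, paired per draw.
#' @return Scalar in `[0, 1]`.
#' @export
ppp_value <- function(realized, replicated) {
  if (length(realized) == 0 || length(realized) != length(replicated))
    stop("realized and replicated must be non-empty and of equal length",
         call. = FALSE)
  mean(replicated >= realized)
}

#' Posterior predictive model checking
#'
#' For each retained posterior draw, generates a replicated data set from
#' the fitted model (sequentially within person for contingent models, so
#' replicated histories feed the practice terms), computes the requested
#' discrepancy statistics on the observed and replicated data, and
#' summarizes them as posterior predictive p values at the pair, item and
#' test level.  The hypothesis of fit is rejected at the test level when a
#' PPP value is below `alpha` or above `1 - alpha`.
#'
#' The odds ratio is data-only, so its realized value is a single number;
#' the latent-residual statistic depends on the parameter draw, so its
#' realized value is summarized by a posterior mean and SD.
#'
#' @param fit an `"opl_fit"`.
#' @param statistics subset of `c("or", "blr")`.
#' @param ndraws number of posterior draws to use (default: all retained
#'   draws, thinned deterministically when fewer are requested).
#' @param seed seed for replication and latent-residual noise.
#' @param alpha tail probability defining rejection (default 0.05).
#' @param latent latent scale for the BLR, see [blr_stats()].
#' @return Object of class `"opl_ppmc"` with tibbles `test`, `item` and
#'   `pair`.
#' @export
ppmc <- function(fit, statistics = c("or", "blr"), ndraws = NULL, seed = NULL,
                 alpha = 0.05, latent = c("normal", "logistic")) {
  stopifnot(inherits(fit, "opl_fit"))
  statistics <- match.arg(statistics, c("or", "blr"), several.ok = TRUE)
  latent <- match.arg(latent)
  L <- nrow(fit$xi_draws)
  idx <- if (is.null(ndraws) || ndraws >= L) seq_len(L)
         else unique(round(seq(1, L, length.out = ndraws)))
  if (!is.null(seed)) set.seed(seed)

  X <- fit$X; W <- fit$W; J <- ncol(X)
  use_or <- "or" %in% statistics
  use_blr <- "blr" %in% statistics
  if (use_or) {
    or_obs <- odds_ratio_stats(X)
    npair <- nrow(or_obs$pair)
    or_rep_test <- numeric(length(idx))
    or_rep_item <- matrix(0, length(idx), J)
    or_rep_pair <- matrix(0, length(idx), npair)
  }
  if (use_blr) {
    blr_real_test <- blr_rep_test <- numeric(length(idx))
    blr_real_item <- blr_rep_item <- matrix(0, length(idx), J)
  }

  ## fixed design of the observed data: realized linear predictors per
  ## draw are a matrix product rather than a full predictor rebuild
  des <- structural_design(fit$model, X, W)
  I <- nrow(X)
  for (k in seq_along(idx)) {
    l <- idx[k]
    params_l <- vector_params(fit$model, fit$xi_draws[l, ])
    theta_l <- fit$theta_draws[l, ]
    eta_obs <- matrix(drop(des$Z %*% fit$xi_draws[l, ]) + theta_l[des$person],
                      I, J, byrow = TRUE)
    rep_l <- .simulate_with_eta(fit$model, theta_l, params_l, W,
                                eta_fixed = if (!is_contingent(fit$model)) eta_obs)
    X_rep <- rep_l$X
    if (use_or) {
      o <- odds_ratio_stats(X_rep)
      or_rep_test[k] <- o$test
      or_rep_item[k, ] <- o$item
      or_rep_pair[k, ] <- o$pair$or
    }
    if (use_blr) {
      er <- latent_residuals(eta_obs, X, latent)
      ep <- latent_residuals(rep_l$eta, X_rep, latent)
      blr_real_item[k, ] <- colSums(er^2); blr_real_test[k] <- sum(er^2)
      blr_rep_item[k, ] <- colSums(ep^2); blr_rep_test[k] <- sum(ep^2)
    }
  }

  test <- item <- pair <- NULL
  if (use_or) {
    test <- dplyr::bind_rows(test, tibble::tibble(
      statistic = "OR", observed = or_obs$test, observed_sd = NA_real_,
      simulated = mean(or_rep_test), simulated_sd = sd(or_rep_test),
      ppp = ppp_value(rep(or_obs$test, length(idx)), or_rep_test)))
    item <- dplyr::bind_rows(item, tibble::tibble(
      statistic = "OR", item = seq_len(J), observed = unname(or_obs$item),
      observed_sd = NA_real_,
      simulated = colMeans(or_rep_item),
      simulated_sd = apply(or_rep_item, 2, sd),
      ppp = vapply(seq_len(J), function(j)
        ppp_value(rep(or_obs$item[j], length(idx)), or_rep_item[, j]),
        numeric(1))))
    pair <- tibble::tibble(
      statistic = "OR",
      item1 = or_obs$pair$item1, item2 = or_obs$pair$item2,
      observed = or_obs$pair$or, corrected = or_obs$pair$corrected,
      simulated = colMeans(or_rep_pair),
      ppp = vapply(seq_len(ncol(or_rep_pair)), function(p)
        ppp_value(rep(or_obs$pair$or[p], length(idx)), or_rep_pair[, p]),
        numeric(1)))
  }
  if (use_blr) {
    test <- dplyr::bind_rows(test, tibble::tibble(
      statistic = "BLR", observed = mean(blr_real_test),
      observed_sd = sd(blr_real_test),
      simulated = mean(blr_rep_test), simulated_sd = sd(blr_rep_test),
      ppp = ppp_value(blr_real_test, blr_rep_test)))
    item <- dplyr::bind_rows(item, tibble::tibble(
      statistic = "BLR", item = seq_len(J),
      observed = colMeans(blr_real_item),
      observed_sd = apply(blr_real_item, 2, sd),
      simulated = colMeans(blr_rep_item),
      simulated_sd = apply(blr_rep_item, 2, sd),
      ppp = vapply(seq_len(J), function(j)
        ppp_value(blr_real_item[, j], blr_rep_item[, j]), numeric(1))))
  }
  test$reject <- test$ppp < alpha | test$ppp > 1 - alpha

  structure(list(test = test, item = item, pair = pair,
                 model = fit$model, ndraws = length(idx), alpha = alpha,
                 latent = latent),
            class = "opl_ppmc")
}

#' @export
print.opl_ppmc <- function(x, ...) {
  cat(sprintf("<opl_ppmc> %s model, %d draws\n", toupper(x$model), x$ndraws))
  print(x$test)
  invisible(x)
}

#' Tidy method for PPMC results: the test-level table
#'
#' @param x an `"opl_ppmc"`.
#' @param level `"test"`, `"item"` or `"pair"`.
#' @param ... unused.
#' @return The requested tibble of discrepancy summaries.
#' @export
tidy.opl_ppmc <- function(x, level = c("test", "item", "pair"), ...) {
  x[[match.arg(level)]]
}

#' Plot item-level posterior predictive p values
#'
#' @param object an `"opl_ppmc"`.
#' @param ... unused.
#' @return A ggplot with items on the x axis, PPP on the y axis, one panel
#'   per statistic, and the rejection band marked.
#' @export
autoplot.opl_ppmc <- function(object, ...) {
  ggplot2::ggplot(object$item,
    ggplot2::aes(x = .data$item, y = .data$ppp)) +
    ggplot2::geom_hline(yintercept = c(object$alpha, 1 - object$alpha),
                        linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~ .data$statistic) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(y = "posterior predictive p value") +
    ggplot2::theme_minimal()
}
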