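#' Pointwise log-likelihood over posterior draws
#'
#' Evaluates `log p(x_ij | theta^l, xi^l)` for every retained draw and
#' every observation, the input to [waic()] and [loo_psis()].  The unit of
#' prediction is a single response `x_ij`; contingent models condition on
#' the person's observed history (consistent with estimation).
#'
#' @param fit an `"opl_fit"`.
#' @param ndraws optional number of draws (deterministic thinning).
#' @return L x (I*J) matrix; observations are ordered person-major
#'   (person 1 items 1..J, then person 2, ...), with attribute `dim_ij`.
#' @export
pointwise_loglik <- function(fit, ndraws = NULL) {
  stopifnot(inherits(fit, "opl_fit"))
  L <- nrow(fit$xi_draws)
  idx <- if (is.null(ndraws) || ndraws >= L) seq_len(L)
         else unique(round(seq(1, L, length.out = ndraws)))
  des <- structural_design(fit$model, fit$X, fit$W)
  ll <- .pointwise_ll_draws(des$Z, des$y, des$person - 1L,
                            fit$xi_draws[idx, , drop = FALSE],
                            fit$theta_draws[idx, , drop = FALSE])
  attr(ll, "dim_ij") <- c(nrow(fit$X), ncol(fit$X))
  ll
}

logmeanexp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

## column-wise logmeanexp and variance without per-column apply()
col_logmeanexp <- function(ll) {
  tll <- t(ll)
  m <- tll[cbind(seq_len(nrow(tll)), max.col(tll, ties.method = "first"))]
  m + log(colMeans(exp(sweep(ll, 2, m))))
}

col_var <- function(ll) {
  L <- nrow(ll)
  (colSums(ll^2) - L * colMeans(ll)^2) / (L - 1)
}

#' Widely applicable information criterion
#'
#' `elpd_waic = lpd - p_waic`, with `lpd` the log pointwise predictive
#' density (log of the draw-averaged density per observation) and `p_waic`
#' the summed posterior variance of the log predictive density;
#' `WAIC = -2 * elpd_waic`.
#'
#' @param ll L x n pointwise log-likelihood matrix (draws in rows), e.g.
#'   from [pointwise_loglik()].
#' @return One-row tibble: `lpd`, `elpd_waic`, `p_waic`, `waic`.
#' @export
waic <- function(ll) {
  ll <- as.matrix(ll)
  if (nrow(ll) < 2)
    stop("WAIC needs at least two draws (pointwise variance)", call. = FALSE)
  lpd_i <- col_logmeanexp(ll)
  p_i <- col_var(ll)
  tibble::tibble(lpd = sum(lpd_i), elpd_waic = sum(lpd_i) - sum(p_i),
                 p_waic = sum(p_i), waic = -2 * (sum(lpd_i) - sum(p_i)))
}

## Zhang & Stephens (2009) empirical-Bayes fit of the generalized Pareto
## distribution to positive exceedances, with the mild prior
## regularization toward k = 0.5 used in Pareto-smoothed importance
## sampling.
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  m <- 30L + floor(sqrt(n))
  j <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (j - 0.5))) / (3 * xstar)
  kf <- vapply(theta, function(t) mean(log1p(-t * x)), numeric(1))
  l <- n * (log(-theta / kf) - kf - 1)
  wts <- 1 / vapply(seq_len(m), function(i) sum(exp(l - l[i])), numeric(1))
  theta_hat <- sum(theta * wts)
  khat <- mean(log1p(-theta_hat * x))
  sigma <- -khat / theta_hat
  khat_reg <- (n * khat + 10 * 0.5) / (n + 10)
  list(k = khat_reg, sigma = sigma)
}

psis_smooth <- function(lw) {
  L <- length(lw)
  lw <- lw - max(lw)
  tail_n <- ceiling(min(0.2 * L, 3 * sqrt(L)))
  if (tail_n < 5) return(list(lw = lw, k = Inf))
  ord <- order(lw)
  tail_ids <- ord[(L - tail_n + 1):L]
  cutoff <- exp(lw[ord[L - tail_n]])
  exceed <- exp(lw[tail_ids]) - cutoff
  if (max(exceed) <= 0) return(list(lw = lw, k = -Inf))
  fit <- gpd_fit(exceed)
  p <- (seq_len(tail_n) - 0.5) / tail_n
  q <- if (abs(fit$k) < 1e-12) -fit$sigma * log(1 - p)
       else fit$sigma / fit$k * ((1 - p)^(-fit$k) - 1)
  smoothed <- sort(log(cutoff + q))
  ## assign sorted smoothed values to the sorted tail positions, then
  ## truncate at the largest raw weight
  lw[tail_ids] <- pmin(smoothed, max(lw))
  list(lw = lw, k = fit$k)
}

#' Pareto-smoothed importance-sampling leave-one-out cross validation
#'
#' Per observation, the leave-one-out predictive density is estimated by
#' importance sampling with ratios `1 / p(x_ij | theta^l, xi^l)`; the
#' largest 20% of the ratios are replaced by expected order statistics of
#' a generalized Pareto distribution fitted to them and truncated at the
#' raw maximum.  `p_loo = lpd - elpd_loo`, `LOOIC = -2 * elpd_loo`.
#' Estimated Pareto shape parameters above 0.7 are flagged with a warning.
#'
#' @param ll L x n pointwise log-likelihood matrix.
#' @return One-row tibble: `lpd`, `elpd_loo`, `p_loo`, `looic`,
#'   `n_high_k`; per-point shapes in attribute `pareto_k`.
#' @export
loo_psis <- function(ll) {
  ll <- as.matrix(ll)
  L <- nrow(ll); n <- ncol(ll)
  if (L < 2) stop("LOO needs at least two draws", call. = FALSE)
  elpd_i <- numeric(n); k_i <- numeric(n); lpd_i <- numeric(n)
  for (i in seq_len(n)) {
    lli <- ll[, i]
    sm <- psis_smooth(-lli)
    lw <- sm$lw
    elpd_i[i] <- logmeanexp(lw + lli) - logmeanexp(lw)
    k_i[i] <- sm$k
    lpd_i[i] <- logmeanexp(lli)
  }
  n_high <- sum(is.finite(k_i) & k_i > 0.7)
  if (n_high > 0)
    warning(sprintf("%d of %d observations have Pareto k > 0.7; LOO may be unreliable",
                    n_high, n), call. = FALSE)
  out <- tibble::tibble(lpd = sum(lpd_i), elpd_loo = sum(elpd_i),
                        p_loo = sum(lpd_i) - sum(elpd_i),
                        looic = -2 * sum(elpd_i), n_high_k = n_high)
  attr(out, "pareto_k") <- k_i
  out
}

#' Fit and compare several models on one data set
#'
#' Fits each requested model and tabulates WAIC and PSIS-LOO.  Lower WAIC /
#' LOOIC indicates better out-of-sample predictive accuracy.
#'
#' @param X response matrix.
#' @param W weight matrix.
#' @param models model tags to compare (default all five).
#' @param config shared [mcmc_config()].
#' @param keep_fits retain the fitted objects in the result (default FALSE).
#' @param ... passed to [fit_oplm()].
#' @return Object of class `"opl_compare"`: a comparison tibble (one row
#'   per model, best model first according to WAIC) plus the fits if kept.
#' @export
compare_models <- function(X, W, models = model_tags(),
                           config = mcmc_config(), keep_fits = FALSE, ...) {
  models <- vapply(models, match_model, character(1))
  fits <- list()
  rows <- lapply(models, function(m) {
    fit <- fit_oplm(X, W, m, config = config, ...)
    if (keep_fits) fits[[m]] <<- fit
    ll <- pointwise_loglik(fit)
    w <- waic(ll)
    lo <- suppressWarnings(loo_psis(ll))
    tibble::tibble(model = m, lpd = w$lpd,
                   elpd_waic = w$elpd_waic, p_waic = w$p_waic, waic = w$waic,
                   elpd_loo = lo$elpd_loo, p_loo = lo$p_loo, looic = lo$looic,
                   n_high_k = lo$n_high_k)
  })
  tab <- dplyr::arrange(dplyr::bind_rows(rows), .data$waic)
  structure(list(table = tab, fits = if (keep_fits) fits,
                 J = ncol(X), M = ncol(W)),
            class = "opl_compare")
}

#' @export
print.opl_compare <- function(x, ...) {
  cat(sprintf("<opl_compare> best model by WAIC: %s\n", select_model(x)))
  print(x$table)
  invisible(x)
}

#' Tidy method for model comparisons
#'
#' @param x an `"opl_compare"`.
#' @param ... unused.
#' @return The comparison tibble.
#' @export
tidy.opl_compare <- function(x, ...) x$table

## parsimony order used to break exact criterion ties (fewest structural
## parameters first; operation-level counts when J, M known)
model_complexity <- function(models, J = NULL, M = NULL) {
  if (!is.null(J) && !is.null(M)) {
    vapply(models, n_structural, integer(1), J = J, M = M) +
      match(models, model_tags()) / 10  # stable residual order
  } else {
    match(models, c("lltm", "oslm", "osclm", "osdclm", "rasch"))
  }
}

#' Select the best model from a comparison
#'
#' Returns the model with the lowest criterion value; exact ties go to the
#' model with the fewest structural parameters.
#'
#' @param comparison an `"opl_compare"` or a data frame with a `model`
#'   column and the criterion column.
#' @param criterion `"waic"` or `"looic"`.
#' @param J,M dimensions used to count structural parameters for
#'   tie-breaking (taken from an `"opl_compare"` automatically).
#' @return The selected model tag.
#' @export
select_model <- function(comparison, criterion = c("waic", "looic"),
                         J = NULL, M = NULL) {
  criterion <- match.arg(criterion)
  if (inherits(comparison, "opl_compare")) {
    J <- J %||% comparison$J; M <- M %||% comparison$M
    comparison <- comparison$table
  }
  if (!criterion %in% names(comparison))
    stop(sprintf("comparison has no '%s' column", criterion), call. = FALSE)
  vals <- comparison[[criterion]]
  best <- which(vals == min(vals))
  if (length(best) > 1) {
    cx <- model_complexity(comparison$model[best], J, M)
    best <- best[which.min(cx)]
  }
  comparison$model[best[1]]
}
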