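#' Draw person abilities
#'
#' Abilities are i.i.d. standard normal, the distribution assumed by every
#' model in the family.
#'
#' @param I number of persons.
#' @param seed optional seed for reproducibility.
#' @return Numeric vector of length `I`.
#' @export
generate_theta <- function(I, seed = NULL) {
  stopifnot(I >= 1)
  if (!is.null(seed)) set.seed(seed)
  rnorm(I)
}

#' Simulate (or replicate) a response matrix
#'
#' Forward-simulates binary responses from any model of the family.
#' Contingent models are generated sequentially item by item within each
#' person, feeding the person's own realized responses into the practice
#' terms; this is also the replication scheme used by [ppmc()], where
#' replicated histories (not observed ones) drive the practice effects.
#'
#' @param model model tag.
#' @param theta length-I ability vector.
#' @param params structural parameters (see [structural_params()]).
#' @param W item-by-operation weight matrix.
#' @param seed optional seed.
#' @return I x J integer response matrix.
#' @export
simulate_responses <- function(model, theta, params, W, seed = NULL) {
  W <- validate_weights(W)
  if (!is.null(seed)) set.seed(seed)
  .simulate_with_eta(match_model(model), theta, params, W)$X
}

## forward simulation that also returns the linear predictors actually
## used (for replicated-data discrepancies); assumes validated inputs and
## the current RNG stream
.simulate_with_eta <- function(model, theta, params, W, eta_fixed = NULL) {
  I <- length(theta); J <- nrow(W); M <- ncol(W)
  X <- matrix(0L, I, J)
  if (!is_contingent(model)) {
    eta <- eta_fixed %||% .linear_predictor(model, X, theta, params, W)
    X[] <- rbinom(I * J, 1, plogis(eta))
    colnames(X) <- rownames(W)
    return(list(X = X, eta = eta))
  }
  ## sequential generation: accumulated correct / incorrect practice per
  ## operation, updated after each item
  corr <- matrix(0, I, M)
  incorr <- matrix(0, I, M)
  eta_out <- matrix(0, I, J)
  use_gamma <- model == "osdclm"
  for (j in seq_len(J)) {
    w <- W[j, ]
    eta <- theta - sum(w * params$alpha) + drop(corr %*% (w * params$delta))
    if (use_gamma) eta <- eta + drop(incorr %*% (w * params$gamma))
    eta_out[, j] <- eta
    X[, j] <- rbinom(I, 1, plogis(eta))
    corr <- corr + outer(as.numeric(X[, j]), w)
    incorr <- incorr + outer(as.numeric(1L - X[, j]), w)
  }
  colnames(X) <- rownames(W)
  list(X = X, eta = eta_out)
}

## ---- reference fixtures ---------------------------------------------------

#' Weight matrix of the fraction-subtraction test
#'
#' The 15-item, 5-operation weight matrix defined by de la Torre for
#' Tatsuoka's fraction-subtraction data, read from the CSV bundled with the
#' package (stored operation-by-item, as commonly printed, and transposed
#' on reading).
#'
#' @return 15 x 5 binary matrix, items in rows.
#' @export
fraction_weights <- function() {
  path <- system.file("extdata", "fraction_subtraction_weights.csv",
                      package = "opirt")
  read_weight_matrix(path, transposed = TRUE)
}

#' Reference structural parameters for the fraction-subtraction analysis
#'
#' EAP estimates of the OSDCLM on the fraction-subtraction data, used as
#' the true generating values in the simulation-study harness.  Nested
#' generating models drop the blocks they do not define (`gamma` for the
#' OSCLM, both contingency distinctions for the OSLM, all practice blocks
#' for the LLTM).
#'
#' @param model generating model tag (default `"osdclm"`).
#' @return An `"opl_params"` object for the requested model.
#' @export
fraction_true_params <- function(model = "osdclm") {
  model <- match_model(model)
  alpha <- c(-0.564, 3.527, -2.014, -0.443, 1.073)
  delta <- c(0.680, 0.724, -0.851, -0.222, 0.329)
  gamma <- c(0.040, 0.676, -0.548, -0.490, -0.695)
  switch(model,
    rasch = stop("reference values are operation-level; no Rasch block",
                 call. = FALSE),
    lltm = structural_params("lltm", alpha = alpha),
    oslm = structural_params("oslm", alpha = alpha, delta = delta),
    osclm = structural_params("osclm", alpha = alpha, delta = delta),
    osdclm = structural_params("osdclm", alpha = alpha, delta = delta,
                               gamma = gamma))
}

## ---- recovery metrics -----------------------------------------------------

#' Recovery metrics over replicated estimates
#'
#' Given `N` replicate estimates of an M-vector of parameters and the true
#' values, computes the three recovery summaries used in factorial
#' simulation studies:
#' \describe{
#'   \item{SE}{`sqrt( (1/(N-1)) sum_n mean_m (est_nm - mean_n est_m)^2 )`,
#'     precision, independent of the truth.}
#'   \item{Bias}{`mean_m | mean_n est_nm - truth_m |`, absolute bias of the
#'     replicate-averaged estimates.}
#'   \item{RMSE}{`(1/N) sum_n sqrt( mean_m (est_nm - truth_m)^2 )`,
#'     accuracy per replicate, averaged.}
#' }
#'
#' @param estimates N x M matrix of estimates (one row per replicate).
#' @param truth length-M vector of true values.
#' @return One-row tibble with `se`, `bias`, `rmse` and `n_replicates`.
#' @export
recovery_metrics <- function(estimates, truth) {
  estimates <- as.matrix(estimates)
  N <- nrow(estimates); M <- ncol(estimates)
  if (length(truth) != M) stop("truth length must match columns", call. = FALSE)
  if (N < 2) stop("at least two replicates are required for the SE", call. = FALSE)
  center <- colMeans(estimates)
  dev <- sweep(estimates, 2, center)
  se <- sqrt(sum(rowSums(dev^2) / M) / (N - 1))
  bias <- mean(abs(center - truth))
  err <- sweep(estimates, 2, truth)
  rmse <- mean(sqrt(rowSums(err^2) / M))
  tibble::tibble(se = se, bias = bias, rmse = rmse, n_replicates = N)
}

## ---- factorial study ------------------------------------------------------

derive_seeds <- function(master, n) {
  set.seed(master)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Factorial simulation study: generating models x fitted models
#'
#' For each generating model, simulates `n_reps` data sets (standard normal
#' abilities, the supplied weight matrix and true parameters), fits each
#' model in `fitted`, and tabulates: mean PPP and empirical proportion of
#' rejections (EPR) per discrepancy statistic, mean WAIC/LOOIC and
#' empirical proportion of selections (EPS) over the fitted set, and
#' SE/Bias/RMSE recovery metrics per parameter block.  Replicate seeds are
#' derived deterministically from the master seed, so any cell can be
#' recomputed independently.  A failed fit is recorded with a warning and
#' excluded from the summaries.
#'
#' @param generating character vector of generating model tags (no rasch).
#' @param fitted character vector of fitted model tags.
#' @param n_reps replicates per generating model.
#' @param I persons per data set.
#' @param W weight matrix (default [fraction_weights()]).
#' @param true_params named list of `"opl_params"` per generating model
#'   (default: [fraction_true_params()] blocks).
#' @param config [mcmc_config()] used for every fit.
#' @param seed master seed.
#' @param statistics PPMC statistics (default both).
#' @param ppmc_draws posterior draws used by PPMC (default 500).
#' @param criterion selection criterion, `"waic"` or `"looic"`.
#' @param compute_loo also compute PSIS-LOO (default TRUE; WAIC is always
#'   computed).
#' @param alpha PPMC rejection tail (default 0.05).
#' @return Object of class `"opl_study"` with tibbles `ppmc`, `selection`,
#'   `recovery` and `replicates`, plus the seed table.
#' @export
run_study <- function(generating = c("osdclm", "osclm", "oslm", "lltm"),
                      fitted = model_tags(),
                      n_reps = 20, I = 536,
                      W = fraction_weights(),
                      true_params = NULL,
                      config = mcmc_config(chains = 2, iter = 1000),
                      seed = 1, statistics = c("or", "blr"),
                      ppmc_draws = 500, criterion = c("waic", "looic"),
                      compute_loo = TRUE, alpha = 0.05) {
  criterion <- match.arg(criterion)
  generating <- vapply(generating, match_model, character(1))
  fitted <- vapply(fitted, match_model, character(1))
  W <- validate_weights(W)
  if (is.null(true_params))
    true_params <- setNames(lapply(generating, fraction_true_params), generating)

  seeds <- derive_seeds(seed, 3L * length(generating) * n_reps)
  sidx <- 0L
  rows <- list()
  for (g in generating) {
    truth <- true_params[[g]]
    for (n in seq_len(n_reps)) {
      sidx <- sidx + 1L
      th_seed <- seeds[3 * (sidx - 1) + 1]
      x_seed <- seeds[3 * (sidx - 1) + 2]
      fit_seed <- seeds[3 * (sidx - 1) + 3]
      theta <- generate_theta(I, seed = th_seed)
      X <- simulate_responses(g, theta, truth, W, seed = x_seed)
      for (f in fitted) {
        res <- tryCatch({
          cfg <- config; cfg$seed <- fit_seed
          fit <- suppressWarnings(fit_oplm(X, W, f, config = cfg))
          pc <- if (length(statistics))
            ppmc(fit, statistics = statistics, ndraws = ppmc_draws,
                 seed = fit_seed, alpha = alpha)
          ll <- pointwise_loglik(fit)
          w <- waic(ll)
          lo <- if (compute_loo) suppressWarnings(loo_psis(ll)) else NULL
          est <- tidy(fit)
          row <- tibble::tibble(
            generating = g, fitted = f, rep = n,
            converged = fit$converged,
            max_rhat = max(fit$rhat, na.rm = TRUE),
            waic = w$waic, looic = if (compute_loo) lo$looic else NA_real_,
            estimates = list(est), ppmc_test = list(if (is.null(pc)) tibble::tibble() else pc$test))
          row
        }, error = function(e) {
          warning(sprintf("fit failed (%s data, %s fit, rep %d): %s",
                          g, f, n, conditionMessage(e)), call. = FALSE)
          NULL
        })
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  reps <- dplyr::bind_rows(rows)
  out <- structure(list(
    replicates = reps,
    ppmc = if (length(statistics)) summarize_study_ppmc(reps, alpha) else tibble::tibble(),
    selection = summarize_study_selection(reps, criterion, compute_loo),
    recovery = summarize_study_recovery(reps, true_params, W),
    generating = generating, fitted = fitted, n_reps = n_reps, I = I,
    seed = seed, criterion = criterion
  ), class = "opl_study")
  out
}

summarize_study_ppmc <- function(reps, alpha) {
  if (nrow(reps) == 0) return(tibble::tibble())
  reps |>
    dplyr::select("generating", "fitted", "rep", "ppmc_test") |>
    tidyr::unnest("ppmc_test") |>
    dplyr::group_by(.data$generating, .data$fitted, .data$statistic) |>
    dplyr::summarise(mean_ppp = mean(.data$ppp), epr = mean(.data$reject),
                     n = dplyr::n(), .groups = "drop")
}

summarize_study_selection <- function(reps, criterion, compute_loo) {
  if (nrow(reps) == 0) return(tibble::tibble())
  crits <- c("waic", if (compute_loo) "looic")
  purrr::map_dfr(crits, function(cr) {
    sel <- dplyr::bind_rows(lapply(
      split(reps, interaction(reps$generating, reps$rep), drop = TRUE),
      function(d) {
        tab <- tibble::tibble(model = d$fitted)
        tab[[cr]] <- d[[cr]]
        tibble::tibble(generating = d$generating[1], rep = d$rep[1],
                       selected = select_model(tab, criterion = cr))
      }))
    reps |>
      dplyr::left_join(sel, by = c("generating", "rep")) |>
      dplyr::group_by(.data$generating, .data$fitted) |>
      dplyr::summarise(criterion = cr, mean_ic = mean(.data[[cr]]),
                       eps = mean(.data$fitted == .data$selected),
                       n = dplyr::n(), .groups = "drop")
  })
}

summarize_study_recovery <- function(reps, true_params, W) {
  if (nrow(reps) == 0) return(tibble::tibble())
  M <- ncol(W)
  cells <- dplyr::distinct(reps, .data$generating, .data$fitted)
  out <- list()
  for (k in seq_len(nrow(cells))) {
    g <- cells$generating[k]; f <- cells$fitted[k]
    truth <- true_params[[g]]
    blocks <- intersect(param_blocks(f), names(truth))
    blocks <- setdiff(blocks, "beta")
    if (!length(blocks)) next
    sub <- dplyr::filter(reps, .data$generating == g, .data$fitted == f)
    for (b in blocks) {
      est <- t(vapply(sub$estimates, function(e) {
        e$eap[grepl(paste0("^", b, "\\["), e$parameter)]
      }, numeric(M)))
      met <- recovery_metrics(est, truth[[b]])
      out[[length(out) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(generating = g, fitted = f, block = b), met)
    }
  }
  dplyr::bind_rows(out)
}

#' @export
print.opl_study <- function(x, ...) {
  cat(sprintf("<opl_study> %d replicates x %d generating x %d fitted models (I = %d)\n",
              x$n_reps, length(x$generating), length(x$fitted), x$I))
  cat("PPMC summary:\n"); print(x$ppmc, n = 20)
  cat("Selection summary:\n"); print(x$selection, n = 20)
  invisible(x)
}

#' Tidy method for simulation studies
#'
#' @param x an `"opl_study"`.
#' @param table which summary: `"ppmc"`, `"selection"`, `"recovery"` or
#'   `"replicates"`.
#' @param ... unused.
#' @return The requested tibble.
#' @export
tidy.opl_study <- function(x, table = c("ppmc", "selection", "recovery",
                                        "replicates"), ...) {
  x[[match.arg(table)]]
}

#' Plot empirical rejection proportions of a study
#'
#' @param object an `"opl_study"`.
#' @param ... unused.
#' @return A ggplot tile map of EPR by generating and fitted model.
#' @export
autoplot.opl_study <- function(object, ...) {
  ggplot2::ggplot(object$ppmc,
    ggplot2::aes(x = .data$fitted, y = .data$generating, fill = .data$epr)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$mean_ppp)), colour = "white") +
    ggplot2::facet_wrap(~ .data$statistic) +
    ggplot2::scale_fill_gradient(low = "#2c7fb8", high = "#d7301f",
                                 limits = c(0, 1)) +
    ggplot2::labs(fill = "EPR (PPP shown)") +
    ggplot2::theme_minimal()
}
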