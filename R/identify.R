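#' Pattern-level coefficients of a contingent model
#'
#' For a contingent model, the joint log-odds of a response pattern `x`
#' collapses to `lambda = s*theta + r'xi`, where `s` is the number-right
#' score and `r` collects, per operation, the pattern's total operation
#' weight (with negative sign, multiplying `alpha`), its accumulated
#' correct practice (multiplying `delta`) and, for the OSDCLM, its
#' accumulated incorrect practice (multiplying `gamma`).  The identity
#' `s*theta + r'xi = sum_j x_j eta_j` holds for every `theta` and every
#' parameter vector.
#'
#' @param model `"osclm"` or `"osdclm"`.
#' @param W weight matrix.
#' @param x a single 0/1 response pattern.
#' @return List with `s` (integer score) and `r` (length 2M or 3M vector).
#' @export
pattern_coefficients <- function(model, W, x) {
  model <- match_model(model)
  if (!is_contingent(model))
    stop("pattern coefficients are defined for contingent models only",
         call. = FALSE)
  W <- validate_weights(W)
  if (length(x) != nrow(W))
    stop("pattern length does not match number of items", call. = FALSE)
  cp <- contingent_practice(W, x)
  r <- c(-drop(x %*% W), drop(x %*% cp$V))
  if (model == "osdclm") r <- c(r, drop(x %*% cp$U))
  nm <- param_names(model, W)
  list(s = as.integer(sum(x)), r = setNames(r, nm))
}

## all 2^J patterns as a T x J matrix, administration order in columns
all_patterns <- function(J) {
  stopifnot(J <= 20)
  T_ <- 2^J
  m <- matrix(0L, T_, J)
  for (j in seq_len(J)) m[, j] <- rep(rep(0:1, each = 2^(J - j)), length.out = T_)
  m
}

#' Coefficient matrix R over a set of response patterns
#'
#' Stacks [pattern_coefficients()] row-wise; one row per pattern.
#'
#' @param model contingent model tag.
#' @param W weight matrix.
#' @param patterns T x J 0/1 matrix; defaults to all `2^J` patterns.
#' @return List with `s` (T-vector of scores) and `R` (T x 2M or T x 3M).
#' @export
pattern_coef_matrix <- function(model, W, patterns = NULL) {
  W <- validate_weights(W)
  if (is.null(patterns)) patterns <- all_patterns(nrow(W))
  patterns <- as.matrix(patterns)
  out <- apply(patterns, 1, function(x) pattern_coefficients(model, W, x)$r)
  R <- t(out)
  colnames(R) <- param_names(model, W)
  list(s = as.integer(rowSums(patterns)), R = R)
}

numerical_rank <- function(A) {
  if (length(A) == 0) return(0L)
  sv <- svd(A, nu = 0, nv = 0)$d
  tol <- max(dim(A), 1) * .Machine$double.eps * max(sv, 0)
  sum(sv > tol)
}

#' Identifiability check for the structural parameters
#'
#' Applies the rank condition appropriate to each model:
#' * LLTM: `rank(W) = M` (the Bayesian condition; the prior fixes the
#'   ability scale, so the classical `M <= J - 1` bound relaxes to
#'   `M <= J`).
#' * OSLM: `rank(Q) = 2M` with `Q = (W; V)`, `V` the non-contingent
#'   practice counts.
#' * OSCLM / OSDCLM: full column rank of `R+ = (R; 1)` over response
#'   patterns, checked through the rank of the (2M+1 or 3M+1)-square
#'   matrix `R+'R+`.  When a response matrix is supplied the check uses the
#'   realized patterns (empirical identifiability); otherwise all `2^J`
#'   patterns are enumerated.
#' * Rasch: identified by construction under the ability prior.
#'
#' @param model model tag.
#' @param W weight matrix.
#' @param X optional response matrix for the empirical check.
#' @return A one-row tibble: model, matrix checked, required and achieved
#'   rank, and the logical verdict `identified`.
#' @export
check_identification <- function(model, W, X = NULL) {
  model <- match_model(model)
  W <- validate_weights(W)
  J <- nrow(W); M <- ncol(W)
  if (model == "rasch") {
    mat <- "none"; req <- ach <- J
  } else if (model == "lltm") {
    mat <- "W"; req <- M; ach <- numerical_rank(W)
  } else if (model == "oslm") {
    mat <- "Q = (W; V)"; req <- 2L * M
    ach <- numerical_rank(cbind(W, noncontingent_practice(W)))
  } else {
    patterns <- if (is.null(X)) {
      mat <- "R+ (all patterns)"
      all_patterns(J)
    } else {
      mat <- "R+ (realized patterns)"
      unique(validate_responses(X))
    }
    R <- pattern_coef_matrix(model, W, patterns)$R
    Rp <- cbind(R, 1)
    req <- ncol(Rp)
    ach <- numerical_rank(crossprod(Rp))
  }
  tibble::tibble(model = model, matrix = mat,
                 required_rank = as.integer(req),
                 achieved_rank = as.integer(ach),
                 identified = ach == req)
}

gh_nodes <- function(n) {
  q <- statmod::gauss.quad(n, kind = "hermite")
  ## integrate g(theta) phi(theta) dtheta = sum w_i/sqrt(pi) g(sqrt(2) x_i)
  list(theta = sqrt(2) * q$nodes, weight = q$weights / sqrt(pi))
}

#' Marginal response-pattern probabilities
#'
#' The probability of each of the `2^J` response patterns under the
#' generative model, with ability integrated over its standard normal
#' distribution by Gauss-Hermite quadrature.  Contingent models are
#' evaluated as the product of the sequential conditional probabilities, so
#' these are exactly the probabilities from which [simulate_responses()]
#' draws.
#'
#' @param model model tag.
#' @param params structural parameters.
#' @param W weight matrix.
#' @param nodes number of Gauss-Hermite nodes (default 41).
#' @return Tibble with the pattern (as a string), score and probability;
#'   probabilities sum to one.
#' @export
pattern_probabilities <- function(model, params, W, nodes = 41) {
  W <- validate_weights(W)
  J <- nrow(W)
  if (J > 12) stop("pattern enumeration supported for J <= 12 only", call. = FALSE)
  patterns <- all_patterns(J)
  gh <- gh_nodes(nodes)
  p <- numeric(nrow(patterns))
  for (q in seq_along(gh$theta)) {
    ll <- .pointwise_ll(model, patterns, rep(gh$theta[q], nrow(patterns)),
                        params, W)
    p <- p + gh$weight[q] * exp(rowSums(ll))
  }
  tibble::tibble(
    pattern = apply(patterns, 1, paste0, collapse = ""),
    score = as.integer(rowSums(patterns)),
    probability = p
  )
}

#' Pattern-level Jacobian and information matrix
#'
#' Uses the pattern-level multinomial parameterization of a contingent
#' model: at a fixed ability value, pattern probabilities are
#' `p = softmax(s*theta + R xi)`, the Jacobian of `log p` with respect to
#' `xi` is `(I - 1 p') R`, and the Fisher information is `J' diag(p) J`.
#' A rank-deficient information matrix (equivalently, the vector of ones
#' lying in the column space of `R`) signals non-identifiability.
#'
#' @param model contingent model tag.
#' @param params structural parameters.
#' @param W weight matrix.
#' @param theta ability value at which the multinomial is evaluated
#'   (default 0).
#' @return List with `p`, `jacobian`, `information`, `R` and `s`.
#' @export
pattern_jacobian <- function(model, params, W, theta = 0) {
  model <- match_model(model)
  if (!is_contingent(model))
    stop("pattern-level Jacobian is defined for contingent models", call. = FALSE)
  W <- validate_weights(W)
  if (nrow(W) > 12) stop("pattern enumeration supported for J <= 12 only",
                         call. = FALSE)
  cm <- pattern_coef_matrix(model, W)
  xi <- params_vector(structural_params(model,
          alpha = params$alpha, delta = params$delta, gamma = params$gamma))
  lam <- cm$s * theta + drop(cm$R %*% xi)
  lam <- lam - max(lam)
  p <- exp(lam) / sum(exp(lam))
  Jac <- cm$R - matrix(drop(crossprod(p, cm$R)), nrow(cm$R), ncol(cm$R),
                       byrow = TRUE)
  info <- crossprod(Jac, p * Jac)
  list(p = p, jacobian = Jac, information = info, R = cm$R, s = cm$s)
}

## softmax pattern probabilities at fixed theta; used by tests to
## finite-difference the Jacobian identity
pattern_softmax <- function(model, xi, W, theta = 0) {
  cm <- pattern_coef_matrix(model, W)
  lam <- cm$s * theta + drop(cm$R %*% xi)
  lam <- lam - max(lam)
  exp(lam) / sum(exp(lam))
}
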