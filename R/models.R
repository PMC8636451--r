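#' opirt: explanatory item response models with operation-specific learning
#'
#' Fits and evaluates a nested family of logistic latent-trait models for
#' binary test data in which the difficulty of the cognitive operations
#' required by the items may change with practice accumulated during the
#' test.  The family contains, from most restrictive to most general:
#'
#' * **Rasch**: `logit P(X_ij = 1) = theta_i - beta_j`.
#' * **LLTM**: item difficulty decomposed as `beta_j = sum_m w_jm alpha_m`,
#'   with `W = (w_jm)` a J x M matrix counting how often operation `m` is
#'   used when solving item `j`.
#' * **OSLM**: each operation difficulty decreases by `delta_m` per previous
#'   practice of the operation, regardless of response correctness
#'   (non-contingent learning).
#' * **OSCLM**: practice counts only when the previous item was answered
#'   correctly (contingent learning), which induces local dependence among
#'   items.
#' * **OSDCLM**: correct and incorrect previous practice carry separate
#'   effects `delta_m` and `gamma_m` (differential contingent learning).
#'
#' Estimation is full Bayes via Hamiltonian Monte Carlo; model evaluation
#' uses posterior predictive checks (odds ratio, Bayesian latent residuals)
#' and WAIC / PSIS-LOO comparison.  A simulation-study harness measures
#' parameter recovery and model-selection operating characteristics.
#'
#' @docType package
#' @name opirt-package
#' @aliases opirt
#' @useDynLib opirt, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats plogis qlogis pnorm qnorm rnorm rbinom runif var
#'   quantile sd integrate dlogis setNames
#' @importFrom utils head read.csv write.csv
#' @importFrom rlang .data
#' @keywords internal
"_PACKAGE"

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Model tags of the operation-specific learning family
#'
#' @return Character vector `c("rasch", "lltm", "oslm", "osclm", "osdclm")`,
#'   ordered from most restrictive to most general.
#' @export
model_tags <- function() c("rasch", "lltm", "oslm", "osclm", "osdclm")

match_model <- function(model) {
  match.arg(tolower(model), model_tags())
}

#' Does a model tag denote a contingent-learning model?
#'
#' Contingent models (OSCLM, OSDCLM) condition the practice effect on the
#' correctness of earlier responses and therefore induce local item
#' dependence.
#'
#' @param model model tag.
#' @return Logical scalar.
#' @export
is_contingent <- function(model) {
  match_model(model) %in% c("osclm", "osdclm")
}

#' Which structural parameter blocks does a model have?
#'
#' @param model model tag.
#' @return Character vector among `"beta"`, `"alpha"`, `"delta"`, `"gamma"`.
#' @export
param_blocks <- function(model) {
  switch(match_model(model),
    rasch  = "beta",
    lltm   = "alpha",
    oslm   = c("alpha", "delta"),
    osclm  = c("alpha", "delta"),
    osdclm = c("alpha", "delta", "gamma")
  )
}

#' Number of structural parameters of a model
#'
#' @param model model tag.
#' @param J number of items.
#' @param M number of operations.
#' @return Integer count (J for Rasch, M per block otherwise).
#' @export
n_structural <- function(model, J, M) {
  if (match_model(model) == "rasch") as.integer(J) else
    as.integer(M * length(param_blocks(model)))
}

## ---- validation -----------------------------------------------------------

#' Validate a binary response matrix
#'
#' Responses must be complete (no missing entries), coded 0/1, with items in
#' administration order along the columns.
#'
#' @param X matrix or data frame of person-by-item responses.
#' @return The validated integer matrix (invisibly classed input passed
#'   through).
#' @export
validate_responses <- function(X) {
  X <- as.matrix(X)
  if (length(X) == 0L) stop("response matrix is empty", call. = FALSE)
  if (ncol(X) < 2L) stop("response matrix needs at least 2 items", call. = FALSE)
  bad <- which(!(X %in% c(0, 1)) | is.na(X))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(X)) + 1
    j <- ((bad[1] - 1) %/% nrow(X)) + 1
    stop(sprintf("non-binary or missing response at row %d, column %d (value '%s')",
                 i, j, as.character(X[bad[1]])), call. = FALSE)
  }
  storage.mode(X) <- "integer"
  if (is.null(colnames(X))) colnames(X) <- paste0("item", seq_len(ncol(X)))
  X
}

#' Validate an item-by-operation weight matrix
#'
#' Weights count how often each operation is used in solving each item; they
#' must be nonnegative, every item must use at least one operation, and
#' every operation must be used by at least one item.  Non-integer weights
#' are accepted with a warning, since the practice bookkeeping presumes
#' counts.
#'
#' @param W matrix or data frame, J items by M operations.
#' @return Validated numeric matrix with operation column names.
#' @export
validate_weights <- function(W) {
  W <- as.matrix(W)
  storage.mode(W) <- "double"
  if (any(is.na(W)) || any(W < 0))
    stop("weights must be nonnegative and complete", call. = FALSE)
  if (any(colSums(W) == 0))
    stop(sprintf("operation %d has all-zero weights", which(colSums(W) == 0)[1]),
         call. = FALSE)
  if (any(rowSums(W) == 0))
    stop(sprintf("item %d has all-zero weights", which(rowSums(W) == 0)[1]),
         call. = FALSE)
  if (any(W != round(W)))
    warning("non-integer weights supplied; practice terms assume counts",
            call. = FALSE)
  if (is.null(colnames(W))) colnames(W) <- paste0("op", seq_len(ncol(W)))
  if (is.null(rownames(W))) rownames(W) <- paste0("item", seq_len(nrow(W)))
  W
}

#' Structural parameter set for a model
#'
#' Bundles the parameter blocks a model needs: `beta` (item difficulties,
#' Rasch only), `alpha` (initial operation difficulties), `delta` (change in
#' operation difficulty per previous correct practice, or per any practice
#' for the OSLM), and `gamma` (change per previous incorrect practice,
#' OSDCLM only).
#'
#' @param model model tag.
#' @param alpha,delta,gamma,beta numeric vectors; only the blocks the model
#'   uses may be supplied.
#' @return A list of class `"opl_params"` with exactly the blocks the model
#'   defines.
#' @examples
#' structural_params("oslm", alpha = c(-1, 2), delta = c(0.3, 0))
#' @export
structural_params <- function(model, alpha = NULL, delta = NULL, gamma = NULL,
                              beta = NULL) {
  model <- match_model(model)
  blocks <- param_blocks(model)
  supplied <- list(beta = beta, alpha = alpha, delta = delta, gamma = gamma)
  extra <- setdiff(names(supplied)[!vapply(supplied, is.null, logical(1))], blocks)
  if (length(extra))
    stop(sprintf("model '%s' has no '%s' block", model, extra[1]), call. = FALSE)
  out <- supplied[blocks]
  if (any(vapply(out, is.null, logical(1))))
    stop(sprintf("model '%s' requires blocks: %s", model,
                 paste(blocks, collapse = ", ")), call. = FALSE)
  len <- lengths(out)
  if (model != "rasch" && length(unique(len)) != 1L)
    stop("all operation-level blocks must have the same length M", call. = FALSE)
  structure(lapply(out, as.numeric), model = model, class = "opl_params")
}

params_vector <- function(params) unlist(params, use.names = FALSE)

vector_params <- function(model, xi, J = NULL, M = NULL) {
  model <- match_model(model)
  if (model == "rasch") return(structural_params(model, beta = xi))
  blocks <- param_blocks(model)
  M <- length(xi) / length(blocks)
  sp <- split(xi, rep(seq_along(blocks), each = M))
  names(sp) <- blocks
  do.call(structural_params, c(list(model = model), sp))
}

#' Names of the structural parameters
#'
#' @param model model tag.
#' @param W weight matrix (used for dimensions and operation labels).
#' @return Character vector like `c("alpha[1]", ..., "gamma[M]")`.
#' @export
param_names <- function(model, W) {
  model <- match_model(model)
  if (model == "rasch") return(paste0("beta[", seq_len(nrow(W)), "]"))
  unlist(lapply(param_blocks(model),
                function(b) paste0(b, "[", seq_len(ncol(W)), "]")))
}

## ---- practice bookkeeping -------------------------------------------------

## strictly-lower-triangular accumulator: (A %*% cum_lower(J))[, j] =
## rowSums over columns k < j of A
cum_lower <- function(J) {
  S <- matrix(0, J, J)
  S[upper.tri(S)] <- 1  # S[k, j] = 1 iff k < j
  S
}

#' Non-contingent practice counts
#'
#' The total previous practice of operation `m` before item `j`,
#' `v_jm = w_jm * sum_{k<j} w_km`, independent of any responses.  This is
#' the practice design of the OSLM, and the sum of the correct and
#' incorrect contingent counts for any response vector.
#'
#' @param W item-by-operation weight matrix.
#' @return J x M numeric matrix of counts.
#' @examples
#' noncontingent_practice(matrix(1, 4, 1))  # running count 0,1,2,3
#' @export
noncontingent_practice <- function(W) {
  W <- validate_weights(W)
  J <- nrow(W)
  prior <- apply(W, 2, function(w) c(0, cumsum(w))[seq_len(J)])
  if (J == 1L) prior <- matrix(prior, nrow = 1)
  V <- W * prior
  dimnames(V) <- dimnames(W)
  V
}

#' Contingent practice counts for one person
#'
#' Splits previous practice by the correctness of the person's earlier
#' responses: `v_jm = w_jm * sum_{k<j} x_k w_km` (correct practice) and
#' `u_jm = w_jm * sum_{k<j} (1 - x_k) w_km` (incorrect practice).  Their sum
#' equals [noncontingent_practice()] for every response vector.
#'
#' @param W item-by-operation weight matrix.
#' @param x a single person's full 0/1 response vector, administration order.
#' @return List with J x M matrices `V` (correct) and `U` (incorrect).
#' @export
contingent_practice <- function(W, x) {
  W <- validate_weights(W)
  if (length(x) != nrow(W))
    stop("response vector length does not match number of items", call. = FALSE)
  if (!all(x %in% c(0, 1))) stop("responses must be 0/1", call. = FALSE)
  J <- nrow(W)
  csum <- function(z) if (J == 1L) matrix(z, 1) else z
  prior_c <- apply(W * x, 2, function(w) c(0, cumsum(w))[seq_len(J)])
  prior_i <- apply(W * (1 - x), 2, function(w) c(0, cumsum(w))[seq_len(J)])
  V <- W * csum(prior_c)
  U <- W * csum(prior_i)
  dimnames(V) <- dimnames(U) <- dimnames(W)
  list(V = V, U = U)
}

## cumulative practice counts for all persons at once:
## list(correct = I x J matrix C with C[i, j] = sum_{k<j} x_ik w_km, per m)
## returned as I x J x M arrays collapsed into a list over m
practice_cube <- function(W, X, contingent_on = X) {
  J <- nrow(W); M <- ncol(W)
  S <- cum_lower(J)
  lapply(seq_len(M), function(m) {
    A <- sweep(contingent_on, 2, W[, m], `*`)
    A %*% S
  })
}

## ---- linear predictors ----------------------------------------------------

#' Linear predictor (logit) for one observation
#'
#' Evaluates the model's logit of a correct response for a person with
#' ability `theta` on item `j`, given the person's responses to the earlier
#' items.  For the OSDCLM this is
#' `theta - sum_m w_jm [alpha_m - delta_m C_jm - gamma_m E_jm]`, with
#' `C_jm` and `E_jm` the correct and incorrect previous practice counts of
#' operation `m`.
#'
#' @param model model tag.
#' @param theta person ability.
#' @param params [structural_params()] for the model.
#' @param W weight matrix.
#' @param history responses to items `1..j-1` (ignored by rasch/lltm/oslm).
#' @param j item index (1-based, administration order).
#' @return The logit (a real number).
#' @export
item_logit <- function(model, theta, params, W, history = numeric(0), j) {
  model <- match_model(model)
  W <- validate_weights(W)
  if (j < 1 || j > nrow(W)) stop("item index out of range", call. = FALSE)
  if (model == "rasch") return(theta - params$beta[j])
  w <- W[j, ]
  base <- sum(w * params$alpha)
  if (model == "lltm") return(theta - base)
  if (model == "oslm") {
    prior <- if (j == 1L) rep(0, ncol(W)) else colSums(W[seq_len(j - 1), , drop = FALSE])
    return(theta - base + sum(w * params$delta * prior))
  }
  if (length(history) != j - 1)
    stop("history must contain the responses to the previous j-1 items",
         call. = FALSE)
  Wp <- W[seq_len(j - 1), , drop = FALSE]
  corr <- if (j == 1L) rep(0, ncol(W)) else colSums(Wp * history)
  incorr <- if (j == 1L) rep(0, ncol(W)) else colSums(Wp * (1 - history))
  eta <- theta - base + sum(w * params$delta * corr)
  if (model == "osdclm") eta <- eta + sum(w * params$gamma * incorr)
  eta
}

#' Matrix of linear predictors for a full response matrix
#'
#' For contingent models the practice terms condition on each person's
#' observed earlier responses in `X`.
#'
#' @param model model tag.
#' @param X I x J binary response matrix supplying the histories.
#' @param theta length-I ability vector.
#' @param params structural parameters.
#' @param W weight matrix.
#' @return I x J matrix of logits.
#' @export
linear_predictor <- function(model, X, theta, params, W) {
  X <- validate_responses(X)
  W <- validate_weights(W)
  if (ncol(X) != nrow(W))
    stop("X and W disagree on the number of items", call. = FALSE)
  if (length(theta) != nrow(X))
    stop("theta length must equal nrow(X)", call. = FALSE)
  .linear_predictor(model, X, theta, params, W)
}

.linear_predictor <- function(model, X, theta, params, W) {
  model <- match_model(model)
  I <- nrow(X); J <- nrow(W); M <- ncol(W)
  eta <- matrix(theta, I, J)
  if (model == "rasch") return(eta - matrix(params$beta, I, J, byrow = TRUE))
  eta <- eta - matrix(drop(W %*% params$alpha), I, J, byrow = TRUE)
  if (model == "lltm") return(eta)
  if (model == "oslm") {
    V <- noncontingent_practice(W)
    return(eta + matrix(drop(V %*% params$delta), I, J, byrow = TRUE))
  }
  S <- cum_lower(J)
  for (m in seq_len(M)) {
    Cm <- (sweep(X, 2, W[, m], `*`) %*% S)            # correct prior practice
    eta <- eta + params$delta[m] * sweep(Cm, 2, W[, m], `*`)
    if (model == "osdclm") {
      Em <- (sweep(1 - X, 2, W[, m], `*`) %*% S)      # incorrect prior practice
      eta <- eta + params$gamma[m] * sweep(Em, 2, W[, m], `*`)
    }
  }
  eta
}

## numerically stable log(1 + exp(x))
log1pexp <- function(x) {
  out <- x
  lo <- x <= 18
  out[lo] <- log1p(exp(x[lo]))
  mid <- x > 18 & x <= 33.3
  out[mid] <- x[mid] + exp(-x[mid])
  out
}

#' Observed-data log-likelihood
#'
#' Bernoulli log-likelihood of a response matrix under any model of the
#' family, with contingent models conditioning on each person's observed
#' earlier responses.  Uses the stable `x*eta - log(1 + exp(eta))`
#' formulation, finite for very large `|eta|`.
#'
#' @inheritParams linear_predictor
#' @return List with `total` (scalar) and `pointwise` (I x J matrix of
#'   log-densities, the unit of prediction used by WAIC/LOO).
#' @export
response_loglik <- function(model, X, theta, params, W) {
  eta <- linear_predictor(model, X, theta, params, W)
  X <- validate_responses(X)
  pw <- X * eta - log1pexp(eta)
  list(total = sum(pw), pointwise = pw)
}

## log-likelihood without input validation (internal; tolerates J = 1)
.pointwise_ll <- function(model, X, theta, params, W) {
  eta <- .linear_predictor(model, X, theta, params, W)
  X * eta - log1pexp(eta)
}
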