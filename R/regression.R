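#' Build the network regression design matrix
#'
#' Assembles the model matrix of the network logistic regression, with
#' columns ordered `[intercept | covariates | nodes | edges]`. Only edges
#' present in the topology contribute a column (the indicator \eqn{I_{ij}}
#' gates edge terms).
#'
#' @param data Data frame with one numeric column per topology node, the
#'   binary response column, and any covariate columns.
#' @param topology A [network_topology()].
#' @param edge_features Tibble of per-individual edge features, as returned
#'   by [pmi_features()] or [pmnr_features()], with rows matching `data`.
#' @param response Name of the binary (0/1 or two-level) response column.
#' @param covariates Character vector of covariate column names (may be
#'   empty).
#' @return A list with `x` (numeric design matrix), `y` (0/1 integer
#'   response), and `spec`, a tibble with columns `term` and `role`
#'   (`"intercept"`, `"covariate"`, `"node"`, `"edge"`) describing each
#'   design column in order.
#' @export
build_design <- function(data, topology, edge_features, response,
                         covariates = character()) {
  stopifnot(inherits(topology, "network_topology"))
  data <- as.data.frame(data)
  if (!response %in% names(data)) {
    abort(sprintf("Response column '%s' not found in data.", response))
  }
  y_raw <- data[[response]]
  lev <- sort(unique(y_raw))
  if (length(lev) != 2L) {
    abort(sprintf(
      "Response '%s' must be binary; found %d distinct value(s).",
      response, length(lev)
    ))
  }
  y <- as.integer(y_raw == lev[2L])
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov) > 0L) {
    abort(sprintf(
      "Covariate column(s) not found: %s", paste(missing_cov, collapse = ", ")
    ))
  }
  X <- node_matrix(data, topology)
  Efm <- as.matrix(edge_features)
  if (nrow(Efm) != nrow(X) || length(y) != nrow(X)) {
    abort("Row counts of data and edge features disagree.")
  }
  Zc <- if (length(covariates) > 0L) as.matrix(data[covariates]) else
    matrix(numeric(0), nrow(X), 0L)
  design <- cbind(`(Intercept)` = 1, Zc, X, Efm)
  spec <- tibble(
    term = colnames(design),
    role = c("intercept", rep("covariate", ncol(Zc)),
             rep("node", ncol(X)), rep("edge", ncol(Efm)))
  )
  if (anyDuplicated(spec$term)) abort("Design term names are not unique.")
  list(x = design, y = y, spec = spec)
}

#' Fit a logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit used by the network regression. The
#' fitter is deliberately self-contained: Newton/IRLS steps until the
#' largest score component falls below `tol_score` or the relative change
#' in log-likelihood falls below `tol_loglik`, up to `max_iter` iterations.
#' The coefficient covariance is the inverse observed information at the
#' optimum (which for the canonical logit link equals the expected
#' information).
#'
#' Complete or quasi-complete separation is flagged rather than silently
#' penalized: a fit is marked non-converged (with a warning) when the
#' iteration limit is reached or any coefficient exceeds 15 on the
#' per-standard-deviation scale. Setting `ridge` to a small positive value
#' adds an L2 penalty as an optional rescue.
#'
#' @param x Numeric design matrix (including any intercept column).
#' @param y Integer 0/1 response vector.
#' @param tol_score,tol_loglik,max_iter Convergence controls.
#' @param ridge Optional L2 penalty (0 = plain MLE).
#' @return A list with `coefficients`, `vcov`, `loglik`, `converged`,
#'   `iterations`, `fitted`, `n`.
#' @export
fit_logistic <- function(x, y, tol_score = 1e-8, tol_loglik = 1e-10,
                         max_iter = 100L, ridge = 0) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) abort("`y` must be coded 0/1.")
  n <- nrow(x); k <- ncol(x)
  if (n != length(y)) abort("`x` and `y` have different lengths.")
  if (n <= k) {
    warn(sprintf("Fewer observations (%d) than parameters (%d): fit unstable.",
                 n, k))
  }
  qrx <- qr(x)
  if (qrx$rank < k) {
    dropped <- colnames(x)[qrx$pivot[(qrx$rank + 1L):k]]
    abort(sprintf(
      "Singular design matrix; collinear term(s): %s",
      paste(dropped, collapse = ", ")
    ))
  }
  beta <- rep(0, k)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- drop(x %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    score <- drop(crossprod(x, y - mu)) - ridge * beta
    info <- crossprod(x * w, x)
    if (ridge > 0) info <- info + diag(ridge, k)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + step
    eta <- drop(x %*% beta)
    ll <- sum(y * eta - log1p(exp(eta))) - ridge * sum(beta^2) / 2
    mu <- plogis(eta)
    score_new <- drop(crossprod(x, y - mu)) - ridge * beta
    if (max(abs(score_new)) < tol_score ||
        abs(ll - ll_old) < tol_loglik * (abs(ll_old) + tol_loglik)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    if (iter >= max_iter) break
  }
  eta <- drop(x %*% beta)
  mu <- plogis(eta)
  w <- mu * (1 - mu)
  info <- crossprod(x * w, x)
  if (ridge > 0) info <- info + diag(ridge, k)
  vcov <- tryCatch(solve(info), error = function(e) matrix(NA_real_, k, k))
  # separation screen: coefficient magnitude on the per-SD scale
  sds <- apply(x, 2L, sd)
  sds[sds == 0] <- 1 # intercept-like columns judged on raw scale
  if (any(abs(beta * sds) > 15)) converged <- FALSE
  if (!converged) {
    warn("Logistic fit did not converge (possible complete or quasi-separation).")
  }
  ll <- sum(y * eta - log1p(exp(eta)))
  list(
    coefficients = setNames(beta, colnames(x)),
    vcov = structure(vcov, dimnames = list(colnames(x), colnames(x))),
    loglik = ll,
    converged = converged,
    iterations = iter,
    fitted = mu,
    n = n
  )
}

#' Wald tests for each model term
#'
#' For each coefficient, `z = estimate / se` with `se` from the inverse
#' observed information, and a two-sided p-value from the standard normal
#' reference. For a non-converged fit the p-values are still reported but
#' flagged with a warning.
#'
#' @param fit Result of [fit_logistic()].
#' @param spec Optional term-role tibble from [build_design()].
#' @return A tibble with columns `term`, `role` (if `spec` given),
#'   `estimate`, `std.error`, `statistic`, `p.value`.
#' @export
wald_tests <- function(fit, spec = NULL) {
  if (!isTRUE(fit$converged)) {
    warn("Wald tests from a non-converged fit; interpret with caution.")
  }
  est <- fit$coefficients
  se <- sqrt(diag(fit$vcov))
  z <- est / se
  out <- tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(z),
    p.value = 2 * pnorm(-abs(unname(z)))
  )
  if (!is.null(spec)) {
    out <- dplyr::left_join(out, spec, by = "term")
    out <- dplyr::relocate(out, "role", .after = "term")
  }
  out
}

#' Global likelihood-ratio test for whole-network association
#'
#' Compares the full network model (covariates + nodes + edges) with the
#' reduced model containing only the intercept and covariates, on the same
#' rows. The statistic is twice the log-likelihood difference, referred to
#' a chi-square distribution with `p + |edges|` degrees of freedom; it
#' tests whether the network as a whole is associated with the outcome.
#'
#' @param full_fit,reduced_fit Results of [fit_logistic()] for the nested
#'   pair.
#' @param df Degrees of freedom (number of node + edge terms dropped).
#' @return A tibble with `statistic`, `df`, `p.value`, `converged`.
#' @export
lrt_global <- function(full_fit, reduced_fit, df) {
  ok <- isTRUE(full_fit$converged) && isTRUE(reduced_fit$converged)
  if (!ok) warn("Likelihood-ratio test involves a non-converged fit.")
  stat <- max(0, 2 * (full_fit$loglik - reduced_fit$loglik))
  tibble(
    statistic = stat,
    df = as.integer(df),
    p.value = if (df > 0L) pchisq(stat, df = df, lower.tail = FALSE) else 1,
    converged = ok
  )
}
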