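#' Fit a network regression with PMI or product-moment edge features
#'
#' The main entry point. Converts every edge of `topology` into a
#' per-individual feature — the kernel pointwise mutual information of the
#' node pair (`method = "pmi"`) or the standardized node cross-product
#' (`method = "product"`, the linear-correlation baseline) — then fits the
#' logistic model
#' \deqn{\mathrm{logit}\,P(Y=1) = \beta_0 + \sum_s \alpha_s Z_s +
#'   \sum_i \beta_i x_i + \sum_{i<j} I_{ij}\, \gamma_{ij} E_{ij}}
#' and performs per-term Wald tests plus a global likelihood-ratio test of
#' the whole network against the intercept + covariates model.
#'
#' @param data Data frame holding the node columns named as in `topology`,
#'   the binary response, and any covariates.
#' @param topology A [network_topology()].
#' @param response Name of the binary response column.
#' @param covariates Character vector of covariate column names.
#' @param method `"pmi"` for PMI edge features, `"product"` for the
#'   product-moment baseline.
#' @param standardize_edges If `TRUE`, center and scale each edge-feature
#'   column before fitting (default leaves features on their natural
#'   scale).
#' @param bonferroni If `TRUE`, add a Bonferroni-adjusted p-value column
#'   over the `p + |edges|` node and edge tests.
#' @param grid_mode,grid_size,eps Passed to [pmi_features()].
#' @param ridge Optional L2 penalty passed to [fit_logistic()] as a
#'   separation rescue (default 0 = plain maximum likelihood).
#' @return An object of class `pminr_fit`; see [tidy.pminr_fit()] and
#'   [glance.pminr_fit()].
#' @examples
#' net <- network_topology(data.frame(from = c("A", "A"), to = c("B", "C")))
#' set.seed(1)
#' d <- data.frame(A = rnorm(150), B = rnorm(150), C = rnorm(150),
#'                 case = rbinom(150, 1, 0.5))
#' fit <- fit_pminr(d, net, response = "case", method = "product")
#' tidy(fit)
#' glance(fit)
#' @export
fit_pminr <- function(data, topology, response, covariates = character(),
                      method = c("pmi", "product"), standardize_edges = FALSE,
                      bonferroni = FALSE, grid_mode = FALSE, grid_size = 80L,
                      eps = 1e-12, ridge = 0) {
  method <- match.arg(method)
  stopifnot(inherits(topology, "network_topology"))
  ef <- switch(
    method,
    pmi = pmi_features(data, topology, grid_mode = grid_mode,
                       grid_size = grid_size, eps = eps),
    product = pmnr_features(data, topology)
  )
  if (standardize_edges && nrow(topology$edges) > 0L) {
    ef <- as_tibble(as.data.frame(scale(as.matrix(ef))))
  }
  des <- build_design(data, topology, ef, response, covariates)
  fit <- fit_logistic(des$x, des$y, ridge = ridge)
  terms <- withCallingHandlers(
    wald_tests(fit, des$spec),
    warning = function(w) invokeRestart("muffleWarning")
  )
  m_tests <- sum(des$spec$role %in% c("node", "edge"))
  if (bonferroni) {
    terms$p.bonferroni <- ifelse(
      terms$role %in% c("node", "edge"),
      pmin(1, terms$p.value * m_tests), NA_real_
    )
  }
  reduced_cols <- des$spec$role %in% c("intercept", "covariate")
  reduced <- fit_logistic(des$x[, reduced_cols, drop = FALSE], des$y,
                          ridge = ridge)
  lrt <- withCallingHandlers(
    lrt_global(fit, reduced, df = m_tests),
    warning = function(w) invokeRestart("muffleWarning")
  )
  structure(
    list(
      method = method,
      topology = topology,
      response = response,
      covariates = covariates,
      spec = des$spec,
      fit = fit,
      reduced_fit = reduced,
      terms = terms,
      lrt = lrt,
      floor_hits = attr(ef, "floor_hits"),
      n = fit$n
    ),
    class = "pminr_fit"
  )
}

#' @export
print.pminr_fit <- function(x, ...) {
  cat(sprintf(
    "<pminr_fit: %s edge features, %d individuals, %d nodes, %d edges>\n",
    if (x$method == "pmi") "PMI" else "product-moment",
    x$n, length(x$topology$nodes), nrow(x$topology$edges)
  ))
  if (!x$fit$converged) cat("warning: fit did not converge\n")
  cat(sprintf(
    "global network LRT: statistic %.3f on %d df, p = %.4g\n",
    x$lrt$statistic, x$lrt$df, x$lrt$p.value
  ))
  sig <- dplyr::filter(x$terms, .data$role %in% c("node", "edge"),
                       .data$p.value < 0.05)
  cat(sprintf("%d node/edge term(s) with Wald p < 0.05\n", nrow(sig)))
  invisible(x)
}

#' Tidy the per-term results of a network regression
#'
#' One row per model term (intercept, covariates, nodes, edges) with the
#' coefficient, its standard error, the Wald z statistic and two-sided
#' p-value (plus a Bonferroni column if requested at fit time).
#'
#' @param x A `pminr_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `role`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @export
tidy.pminr_fit <- function(x, ...) {
  x$terms
}

#' One-row summary of a network regression
#'
#' @param x A `pminr_fit`.
#' @param ... Unused.
#' @return A tibble with the global likelihood-ratio statistic, degrees of
#'   freedom and p-value, log-likelihoods, convergence flag, counts of
#'   model terms and the sample size.
#' @export
glance.pminr_fit <- function(x, ...) {
  tibble(
    method = x$method,
    n = x$n,
    n_nodes = length(x$topology$nodes),
    n_edges = nrow(x$topology$edges),
    logLik = x$fit$loglik,
    logLik_reduced = x$reduced_fit$loglik,
    lrt_statistic = x$lrt$statistic,
    lrt_df = x$lrt$df,
    lrt_p.value = x$lrt$p.value,
    converged = x$fit$converged,
    floor_hits = x$floor_hits
  )
}

#' Plot the per-term evidence of a network regression
#'
#' Dot plot of -log10 Wald p-values for node and edge terms, with the 0.05
#' reference line.
#'
#' @param object A `pminr_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pminr_fit <- function(object, ...) {
  d <- dplyr::filter(tidy(object), .data$role %in% c("node", "edge"))
  d$term <- factor(d$term, levels = d$term)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$term, y = -log10(.data$p.value),
                                  colour = .data$role)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed") +
    ggplot2::labs(x = NULL, y = expression(-log[10] ~ p),
                  colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' Write a fitted network regression as tidy tables
#'
#' Writes the per-term Wald table as TSV and returns the paths. The global
#' likelihood-ratio record is appended as a final row with role
#' `"global"`.
#'
#' @param fit A `pminr_fit`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_fit_tsv <- function(fit, path) {
  stopifnot(inherits(fit, "pminr_fit"))
  tab <- tidy(fit)
  glob <- tibble(
    term = "global_network", role = "global",
    estimate = NA_real_, std.error = NA_real_,
    statistic = fit$lrt$statistic, p.value = fit$lrt$p.value
  )
  extra <- setdiff(names(tab), names(glob))
  for (nm in extra) glob[[nm]] <- NA_real_
  readr::write_tsv(dplyr::bind_rows(tab, glob[names(tab)]), path)
  invisible(path)
}
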