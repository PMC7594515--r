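#' Monte-Carlo operating characteristics of the network regression
#'
#' Runs the full simulation loop for one configuration cell: per replicate
#' it draws the node covariance, selects the effecting targets (or, under
#' the null, a no-effect node and edge to test), generates node values and
#' the binary response, fits the network regression with each requested
#' edge-feature method, and records whether the targeted node Wald test,
#' edge Wald test, and global likelihood-ratio test reject at the nominal
#' level. Under a null configuration the rejection proportions estimate
#' type-I error; otherwise they estimate power.
#'
#' Replicate seeds are derived deterministically from `seed`, so a rerun
#' with the same configuration and seed reproduces the table exactly.
#' Replicates whose fit fails or does not converge are excluded from the
#' denominator and tallied; a warning is raised if more than 5% of
#' replicates fail for any method.
#'
#' @param config A [sim_config()].
#' @param seed Master seed for the whole run.
#' @return A `pminr_oc` tibble with one row per method x test
#'   (`node`, `edge`, `global`): columns `scenario`, `situation`, `n`,
#'   `method`, `test`, `rejections`, `replicates`, `proportion`, `se`
#'   (Monte-Carlo standard error \eqn{\sqrt{\hat p (1-\hat p)/R}}), plus a
#'   `failures` attribute with the per-method tally.
#' @examples
#' \donttest{
#' cfg <- sim_config("linear", "null", n = 300, replicates = 20)
#' run_operating_characteristics(cfg, seed = 1)
#' }
#' @export
run_operating_characteristics <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  topo <- config$topology
  ne <- nrow(topo$edges)
  R <- config$replicates
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, R)
  sigma_fixed <- if (!config$redraw_sigma) sample_covariance(topo) else NULL

  methods <- config$methods
  counts <- matrix(0L, length(methods), 3L,
                   dimnames = list(methods, c("node", "edge", "global")))
  rejections <- matrix(0L, length(methods), 3L,
                       dimnames = list(methods, c("node", "edge", "global")))
  failures <- setNames(integer(length(methods)), methods)

  for (r in seq_len(R)) {
    set.seed(rep_seeds[r])
    sigma <- sigma_fixed %||% sample_covariance(topo)
    targets <- config$fixed_targets %||% pick_targets(topo, config$situation)
    # tests always target a node and an edge: the effecting ones when they
    # exist, otherwise a randomly selected no-effect target
    node_t <- targets$node %||% sample.int(length(topo$nodes), 1L)
    edge_t <- targets$edge %||% (if (ne > 0L) sample.int(ne, 1L) else NULL)
    nl_edge <- if (config$scenario != "linear") edge_t else NULL
    X <- simulate_nodes(config$n, sigma, topo, config$scenario,
                        nonlinear_edge = nl_edge, alpha = config$alpha)
    eff <- effect_map(topo, targets, beta = config$beta, gamma = config$gamma)
    y <- simulate_response(X, topo, eff, config$scenario,
                           alpha = config$alpha)
    d <- as.data.frame(X)
    d$y <- y
    node_term <- topo$nodes[node_t]
    edge_term <- if (!is.null(edge_t)) edge_names(topo)[edge_t] else NULL
    for (m in methods) {
      fit <- tryCatch(
        suppressWarnings(fit_pminr(d, topo, response = "y", method = m,
                                   grid_mode = config$grid_mode)),
        error = function(e) NULL
      )
      if (is.null(fit) || !fit$fit$converged || !fit$reduced_fit$converged) {
        failures[m] <- failures[m] + 1L
        next
      }
      tt <- fit$terms
      p_node <- tt$p.value[tt$term == node_term]
      p_edge <- if (!is.null(edge_term)) tt$p.value[tt$term == edge_term]
                else NA_real_
      p_glob <- fit$lrt$p.value
      ps <- c(node = p_node,
              edge = if (is.null(edge_term)) NA_real_ else p_edge,
              global = p_glob)
      for (tst in c("node", "edge", "global")) {
        if (!is.na(ps[[tst]])) {
          counts[m, tst] <- counts[m, tst] + 1L
          if (ps[[tst]] < config$level) {
            rejections[m, tst] <- rejections[m, tst] + 1L
          }
        }
      }
    }
  }
  frac_fail <- failures / R
  if (any(frac_fail > 0.05)) {
    warn(sprintf(
      "More than 5%% of replicates failed for: %s",
      paste(sprintf("%s (%d/%d)", names(failures)[frac_fail > 0.05],
                    failures[frac_fail > 0.05], R), collapse = ", ")
    ))
  }
  out <- tidyr::expand_grid(method = methods,
                            test = c("node", "edge", "global"))
  out$rejections <- mapply(function(m, t) rejections[m, t],
                           out$method, out$test)
  out$replicates <- mapply(function(m, t) counts[m, t],
                           out$method, out$test)
  out$proportion <- ifelse(out$replicates > 0,
                           out$rejections / out$replicates, NA_real_)
  out$se <- ifelse(out$replicates > 0,
                   sqrt(out$proportion * (1 - out$proportion) /
                          out$replicates), NA_real_)
  out <- dplyr::bind_cols(
    tibble(scenario = config$scenario, situation = config$situation,
           n = config$n),
    out
  )
  attr(out, "failures") <- failures
  attr(out, "seed") <- seed
  attr(out, "level") <- config$level
  class(out) <- c("pminr_oc", class(out))
  out
}

#' Operating characteristics over a grid of sample sizes
#'
#' Convenience wrapper running [run_operating_characteristics()] for each
#' sample size in `n`, with per-cell seeds derived from the master seed,
#' and binding the results. All other settings come from `config`.
#'
#' @param config A [sim_config()] (its `n` is ignored).
#' @param n Integer vector of sample sizes.
#' @param seed Master seed.
#' @return A `pminr_oc` tibble with one block per sample size.
#' @export
run_oc_grid <- function(config, n, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  cell_seeds <- sample.int(.Machine$integer.max, length(n))
  res <- purrr::map2(n, cell_seeds, function(ni, si) {
    cfg <- config
    cfg$n <- as.integer(ni)
    run_operating_characteristics(cfg, seed = si)
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("pminr_oc", class(out))
  out
}

#' Plot rejection proportions from a simulation run
#'
#' Line plot of rejection proportion against sample size, one colour per
#' method, faceted by test type, with the nominal level as a reference
#' line. Matches the layout used to compare type-I error and power curves.
#'
#' @param object A `pminr_oc` tibble.
#' @param level Nominal level reference line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pminr_oc <- function(object, level = attr(object, "level") %||% 0.05,
                              ...) {
  d <- dplyr::filter(as_tibble(object), !is.na(.data$proportion))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n, y = .data$proportion,
                                  colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(0, .data$proportion -
                                                      2 * .data$se),
                                        ymax = pmin(1, .data$proportion +
                                                      2 * .data$se)),
                           width = 0) +
    ggplot2::geom_hline(yintercept = level, linetype = "dashed") +
    ggplot2::facet_grid(test ~ scenario + situation) +
    ggplot2::labs(x = "sample size", y = "rejection proportion",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
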