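SCENARIOS <- c("linear", "quadratic", "sine", "sine_squared")
SITUATIONS <- c("null", "node_only", "edge_only",
                "node_edge_on_edge", "node_edge_off_edge")

# nonlinear inter-node link functions, one per non-linear scenario
scenario_g <- function(scenario) {
  switch(scenario,
    linear = identity,
    quadratic = function(x) x^2,
    sine = sin,
    sine_squared = function(x) sin(x)^2,
    abort(sprintf("Unknown scenario '%s'.", scenario))
  )
}

default_gamma <- function(scenario) {
  if (scenario %in% c("linear", "quadratic")) 0.2 else 0.6
}

#' Simulation configuration
#'
#' Bundles the settings of one simulation cell: the inter-node dependence
#' pattern (`scenario`), which effects are present (`situation`), the
#' sample size, replicate count, effect sizes and the topology. Defaults
#' follow the study design the harness reproduces: node effect
#' `beta = 0.3`; edge effect `gamma = 0.2` for the linear and quadratic
#' scenarios and `0.6` for the sine-type scenarios; nonlinear connection
#' strength `alpha = 1`; edge correlations drawn from \{0.10, 0.15, ...,
#' 0.55\}; intercept fixed at zero so the two outcome groups are balanced
#' under the null.
#'
#' @param scenario One of `"linear"`, `"quadratic"`, `"sine"`,
#'   `"sine_squared"` — the dependence pattern placed on the designated
#'   edge (`x_j = alpha * g(x_i) + eps` for the nonlinear patterns).
#' @param situation One of `"null"`, `"node_only"`, `"edge_only"`,
#'   `"node_edge_on_edge"`, `"node_edge_off_edge"` — which effects drive
#'   the response, and whether the effecting node is an endpoint of the
#'   effecting edge.
#' @param n Sample size per replicate (at least 50).
#' @param replicates Number of Monte-Carlo replicates (at least 1).
#' @param topology A [network_topology()]; defaults to the packaged
#'   26-node / 37-edge simulation topology.
#' @param beta,gamma Node and edge effect sizes on the logit scale.
#' @param alpha Nonlinear connection strength.
#' @param methods Which edge-feature methods to evaluate.
#' @param level Nominal test level for rejection counting.
#' @param fixed_targets Optional effect-target list (as returned by
#'   [pick_targets()]) to reuse in every replicate instead of random
#'   selection.
#' @param redraw_sigma If `TRUE` (default) the covariance matrix is redrawn
#'   every replicate; if `FALSE` it is drawn once from the master seed.
#' @param grid_mode Use the grid-interpolation PMI path in the fits.
#' @return A `sim_config` list.
#' @export
sim_config <- function(scenario = "linear", situation = "null",
                       n = 500L, replicates = 100L,
                       topology = insulin_resistance_network(),
                       beta = 0.3, gamma = default_gamma(scenario),
                       alpha = 1, methods = c("pmi", "product"),
                       level = 0.05, fixed_targets = NULL,
                       redraw_sigma = TRUE, grid_mode = FALSE) {
  scenario <- match.arg(scenario, SCENARIOS)
  situation <- match.arg(situation, SITUATIONS)
  methods <- match.arg(methods, c("pmi", "product"), several.ok = TRUE)
  stopifnot(inherits(topology, "network_topology"))
  n <- as.integer(n)
  replicates <- as.integer(replicates)
  if (is.na(n) || n < 50L) abort("`n` must be at least 50.")
  if (is.na(replicates) || replicates < 1L) {
    abort("`replicates` must be at least 1.")
  }
  if (level <= 0 || level >= 1) abort("`level` must be in (0, 1).")
  structure(
    list(scenario = scenario, situation = situation, n = n,
         replicates = replicates, topology = topology, beta = beta,
         gamma = gamma, alpha = alpha, methods = methods, level = level,
         fixed_targets = fixed_targets, redraw_sigma = redraw_sigma,
         grid_mode = grid_mode),
    class = "sim_config"
  )
}

#' Draw a structured node covariance matrix
#'
#' Builds the p x p covariance used to generate node values: unit diagonal,
#' and for each topology edge an inter-node correlation drawn uniformly
#' from \{0.10, 0.15, ..., 0.55\}; non-edges are uncorrelated. The whole
#' matrix is redrawn until its smallest eigenvalue exceeds `1e-10`, so the
#' returned matrix is always positive definite.
#'
#' @param topology A [network_topology()].
#' @param rho_values Candidate edge correlations.
#' @param max_attempts Redraw limit before giving up.
#' @return A positive-definite covariance matrix with node-name dimnames.
#' @export
sample_covariance <- function(topology,
                              rho_values = seq(0.10, 0.55, by = 0.05),
                              max_attempts = 1000L) {
  stopifnot(inherits(topology, "network_topology"))
  p <- length(topology$nodes)
  idx <- cbind(topology$edges$i, topology$edges$j)
  for (attempt in seq_len(max_attempts)) {
    sigma <- diag(p)
    if (nrow(idx) > 0L) {
      rho <- sample(rho_values, nrow(idx), replace = TRUE)
      sigma[idx] <- rho
      sigma[idx[, 2:1, drop = FALSE]] <- rho
    }
    ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) > 1e-10) {
      dimnames(sigma) <- list(topology$nodes, topology$nodes)
      return(sigma)
    }
  }
  abort(sprintf(
    "No positive-definite covariance found in %d attempts; the topology may be too dense for the requested correlations.",
    max_attempts
  ))
}

#' Randomly select the effecting node and/or edge for a situation
#'
#' Implements the random-target designs: a single effecting node, a single
#' effecting edge, or a node-edge pair where the node either is
#' (`node_edge_on_edge`) or is not (`node_edge_off_edge`) an endpoint of
#' the edge. The null situation selects nothing.
#'
#' @param topology A [network_topology()].
#' @param situation See [sim_config()].
#' @return A list with `node` (node index or `NULL`) and `edge` (edge row
#'   index or `NULL`).
#' @export
pick_targets <- function(topology, situation) {
  situation <- match.arg(situation, SITUATIONS)
  p <- length(topology$nodes)
  ne <- nrow(topology$edges)
  need_edge <- situation %in% c("edge_only", "node_edge_on_edge",
                                "node_edge_off_edge")
  if (need_edge && ne == 0L) {
    abort(sprintf("Situation '%s' needs at least one edge.", situation))
  }
  switch(
    situation,
    null = list(node = NULL, edge = NULL),
    node_only = list(node = sample.int(p, 1L), edge = NULL),
    edge_only = list(node = NULL, edge = sample.int(ne, 1L)),
    node_edge_on_edge = {
      e <- sample.int(ne, 1L)
      ends <- c(topology$edges$i[e], topology$edges$j[e])
      list(node = sample(ends, 1L), edge = e)
    },
    node_edge_off_edge = {
      e <- sample.int(ne, 1L)
      ends <- c(topology$edges$i[e], topology$edges$j[e])
      off <- setdiff(seq_len(p), ends)
      if (length(off) == 0L) {
        abort("No node off the chosen edge exists in this topology.")
      }
      list(node = if (length(off) == 1L) off else sample(off, 1L), edge = e)
    }
  )
}

#' Generate node values from the structured multivariate normal
#'
#' Draws `n` observations from \eqn{N_p(0, \Sigma)}. Under a nonlinear
#' scenario the designated edge's higher-indexed node is overwritten with
#' \eqn{x_j = \alpha\, g(x_i) + \varepsilon}, \eqn{\varepsilon \sim N(0,1)},
#' with `g` the scenario's link (square, sine, or squared sine), so the
#' pair carries a purely nonlinear dependence.
#'
#' @param n Sample size.
#' @param sigma Covariance matrix from [sample_covariance()].
#' @param topology A [network_topology()].
#' @param scenario See [sim_config()].
#' @param nonlinear_edge Edge row index carrying the nonlinear dependence
#'   (ignored for the linear scenario).
#' @param alpha Nonlinear connection strength.
#' @return An `n x p` matrix with node-name columns.
#' @export
simulate_nodes <- function(n, sigma, topology, scenario = "linear",
                           nonlinear_edge = NULL, alpha = 1) {
  scenario <- match.arg(scenario, SCENARIOS)
  X <- MASS::mvrnorm(n, mu = rep(0, ncol(sigma)), Sigma = sigma)
  colnames(X) <- topology$nodes
  if (scenario != "linear" && !is.null(nonlinear_edge)) {
    i <- topology$edges$i[nonlinear_edge]
    j <- topology$edges$j[nonlinear_edge]
    g <- scenario_g(scenario)
    X[, j] <- alpha * g(X[, i]) + rnorm(n)
  }
  X
}

#' Build the effect map for a replicate
#'
#' Translates selected targets into named effect vectors: `beta` on the
#' effecting node, `gamma` on the effecting edge, zero elsewhere.
#'
#' @param topology A [network_topology()].
#' @param targets Result of [pick_targets()].
#' @param beta,gamma Effect sizes.
#' @return A list with named numeric vectors `node_effects` and
#'   `edge_effects`.
#' @export
effect_map <- function(topology, targets, beta = 0.3,
                       gamma = 0.2) {
  nodes <- numeric(0)
  edges <- numeric(0)
  if (!is.null(targets$node)) {
    nodes <- setNames(beta, topology$nodes[targets$node])
  }
  if (!is.null(targets$edge)) {
    edges <- setNames(gamma, edge_names(topology)[targets$edge])
  }
  list(node_effects = nodes, edge_effects = edges)
}

#' Generate the binary response from node values and network effects
#'
#' Computes the linear predictor
#' \eqn{\eta_l = \sum_i \beta_i x_{il} + \sum_{(i,j)} \gamma_{ij} e_{ij,l}}
#' with zero intercept (so groups are balanced under the null) and draws
#' \eqn{Y_l \sim \mathrm{Bernoulli}(\mathrm{logit}^{-1}(\eta_l))}. The
#' generator-side edge term is the node product \eqn{x_{il} x_{jl}} for the
#' linear scenario and \eqn{\alpha\, g(x_{il})\, x_{jl}} for the nonlinear
#' scenarios (e.g. \eqn{\alpha \sin(x_i)\, x_j} for the sine pattern).
#'
#' @param X Node matrix from [simulate_nodes()].
#' @param topology A [network_topology()].
#' @param effects Effect map from [effect_map()]; an edge effect on a pair
#'   that is not a topology edge is an error.
#' @param scenario See [sim_config()].
#' @param alpha Nonlinear connection strength.
#' @return Integer 0/1 vector of length `nrow(X)`.
#' @export
simulate_response <- function(X, topology, effects, scenario = "linear",
                              alpha = 1) {
  scenario <- match.arg(scenario, SCENARIOS)
  eta <- rep(0, nrow(X))
  ne <- effects$node_effects
  if (length(ne) > 0L) {
    bad <- setdiff(names(ne), topology$nodes)
    if (length(bad) > 0L) {
      abort(sprintf("Effect on unknown node(s): %s", paste(bad, collapse = ", ")))
    }
    for (nm in names(ne)) eta <- eta + ne[[nm]] * X[, nm]
  }
  ee <- effects$edge_effects
  if (length(ee) > 0L) {
    enames <- edge_names(topology)
    bad <- setdiff(names(ee), enames)
    if (length(bad) > 0L) {
      abort(sprintf(
        "Effect on pair(s) that are not topology edges: %s",
        paste(bad, collapse = ", ")
      ))
    }
    g <- scenario_g(scenario)
    for (nm in names(ee)) {
      e <- match(nm, enames)
      xi <- X[, topology$edges$i[e]]
      xj <- X[, topology$edges$j[e]]
      term <- if (scenario == "linear") xi * xj else alpha * g(xi) * xj
      eta <- eta + ee[[nm]] * term
    }
  }
  rbinom(nrow(X), 1L, plogis(eta))
}

#' Simulate one complete dataset under a configuration
#'
#' Draws the covariance, the targets, the node matrix and the response for
#' a single replicate, returning an analysis-ready tibble. Primarily a
#' convenience for examples and the command-line interface.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A tibble with the node columns, the response `y`, and attributes
#'   `targets` and `sigma`.
#' @export
simulate_network_data <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  topo <- config$topology
  sigma <- sample_covariance(topo)
  targets <- config$fixed_targets %||% pick_targets(topo, config$situation)
  nl_edge <- targets$edge %||%
    (if (config$scenario != "linear" && nrow(topo$edges) > 0L)
      sample.int(nrow(topo$edges), 1L) else NULL)
  X <- simulate_nodes(config$n, sigma, topo, config$scenario,
                      nonlinear_edge = nl_edge, alpha = config$alpha)
  eff <- effect_map(topo, targets, beta = config$beta, gamma = config$gamma)
  y <- simulate_response(X, topo, eff, config$scenario, alpha = config$alpha)
  out <- as_tibble(as.data.frame(X))
  out$y <- y
  attr(out, "targets") <- targets
  attr(out, "sigma") <- sigma
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
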