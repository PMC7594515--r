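test_that("covariance draws respect the edge structure and stay PD", {
  lonely <- network_topology(data.frame(from = "a", to = "b"),
                             nodes = c("a", "b", "c", "d"))
  lonely$edges <- lonely$edges[0, ]
  set.seed(501)
  expect_equal(unname(sample_covariance(lonely)), diag(4))

  net <- insulin_resistance_network()
  set.seed(502)
  sigma <- sample_covariance(net)
  off <- sigma[upper.tri(sigma)]
  I <- indicator_matrix(net)
  expect_true(all(off[I[upper.tri(I)] == 0] == 0))
  edge_rho <- off[I[upper.tri(I)] == 1]
  expect_true(all(edge_rho >= 0.10 - 1e-12 & edge_rho <= 0.55 + 1e-12))
  expect_true(all(abs(edge_rho / 0.05 - round(edge_rho / 0.05)) < 1e-9))
  expect_gt(min(eigen(sigma, symmetric = TRUE)$values), 0)

  # a star with a high fixed correlation is never positive definite
  star <- network_topology(data.frame(from = "hub", to = paste0("s", 1:20)))
  set.seed(503)
  expect_error(sample_covariance(star, rho_values = 0.55, max_attempts = 5),
               "positive-definite")
})

test_that("node generator matches its covariance and nonlinear links", {
  iso <- network_topology(data.frame(from = "n1", to = "n2"),
                          nodes = paste0("n", 1:5))
  iso$edges <- iso$edges[0, ]
  set.seed(504)
  X <- simulate_nodes(5000, diag(5), iso)
  expect_lt(max(abs(cov(X) - diag(5))), 0.06)

  net <- chain_topology(3)
  set.seed(505)
  sigma <- sample_covariance(net)
  Xs <- simulate_nodes(5000, sigma, net, scenario = "sine",
                       nonlinear_edge = 1L, alpha = 1)
  slope <- coef(lm(Xs[, 2] ~ sin(Xs[, 1])))[2]
  expect_equal(unname(slope), 1, tolerance = 0.1)

  set.seed(506)
  A <- simulate_nodes(200, sigma, net)
  set.seed(506)
  B <- simulate_nodes(200, sigma, net)
  expect_identical(A, B)
})

test_that("response generator is calibrated on the logit scale", {
  net <- chain_topology(3)
  sigma <- diag(3)
  set.seed(507)
  X <- simulate_nodes(10000, sigma, net)
  y0 <- simulate_response(X, net, effect_map(net, list(node = NULL, edge = NULL)))
  expect_gte(mean(y0), 0.47); expect_lte(mean(y0), 0.53)

  set.seed(508)
  X2 <- simulate_nodes(20000, sigma, net)
  y1 <- simulate_response(
    X2, net, effect_map(net, list(node = 1L, edge = NULL), beta = 0.3)
  )
  slope <- coef(glm(y1 ~ X2[, 1], family = binomial()))[2]
  expect_lt(abs(unname(slope) - 0.3), 0.05)

  # doubling the edge effect widens the case/control gap in the edge term
  set.seed(509)
  X3 <- simulate_nodes(5000, sample_covariance(net), net)
  gap <- sapply(c(0.3, 0.6), function(g) {
    set.seed(510)
    y <- simulate_response(X3, net, effect_map(net, list(node = NULL, edge = 1L),
                                               gamma = g))
    e <- X3[, net$edges$i[1]] * X3[, net$edges$j[1]]
    mean(e[y == 1]) - mean(e[y == 0])
  })
  expect_gt(gap[2], gap[1])

  bad <- list(node_effects = numeric(0),
              edge_effects = c("N1~N3" = 0.2))
  expect_error(simulate_response(X, net, bad), "not topology edges")
})

test_that("target selection respects each situation", {
  net <- insulin_resistance_network()
  set.seed(511)
  expect_equal(pick_targets(net, "null"), list(node = NULL, edge = NULL))
  t1 <- pick_targets(net, "node_only")
  expect_true(is.null(t1$edge) && t1$node %in% seq_len(26))
  t2 <- pick_targets(net, "edge_only")
  expect_true(is.null(t2$node) && t2$edge %in% seq_len(37))
  for (k in 1:200) {
    t3 <- pick_targets(net, "node_edge_on_edge")
    expect_true(t3$node %in% c(net$edges$i[t3$edge], net$edges$j[t3$edge]))
  }
  for (k in 1:1000) {
    t4 <- pick_targets(net, "node_edge_off_edge")
    expect_false(t4$node %in% c(net$edges$i[t4$edge], net$edges$j[t4$edge]))
  }
  pair <- network_topology(data.frame(from = "a", to = "b"))
  expect_error(pick_targets(pair, "node_edge_off_edge"), "off the chosen edge")
})

test_that("operating characteristics are deterministic and well-formed", {
  net <- chain_topology(4)
  cfg <- sim_config("linear", "null", n = 120, replicates = 6,
                    topology = net)
  oc1 <- run_operating_characteristics(cfg, seed = 9)
  oc2 <- run_operating_characteristics(cfg, seed = 9)
  expect_identical(as.data.frame(oc1), as.data.frame(oc2))
  expect_equal(nrow(oc1), 2 * 3) # methods x tests
  expect_true(all(oc1$proportion >= 0 & oc1$proportion <= 1, na.rm = TRUE))
  expect_equal(oc1$se, sqrt(oc1$proportion * (1 - oc1$proportion) /
                              oc1$replicates))
  expect_named(attr(oc1, "failures"), c("pmi", "product"))

  cfg1 <- sim_config("linear", "node_only", n = 120, replicates = 1,
                     topology = net, methods = "product")
  oc3 <- run_operating_characteristics(cfg1, seed = 10)
  expect_true(all(oc3$proportion %in% c(0, 1)))
  expect_true(all(oc3$se == 0))

  expect_error(sim_config("linear", "null", n = 10), "at least 50")
  expect_error(sim_config("linear", "null", replicates = 0), "at least 1")
  expect_error(sim_config("cubic", "null"), "arg")
})

test_that("sample-size grids stack cells deterministically", {
  net <- chain_topology(4)
  cfg <- sim_config("linear", "node_only", n = 60, replicates = 4,
                    topology = net, methods = "product")
  g1 <- run_oc_grid(cfg, n = c(60, 90), seed = 3)
  g2 <- run_oc_grid(cfg, n = c(60, 90), seed = 3)
  expect_identical(as.data.frame(g1), as.data.frame(g2))
  expect_setequal(unique(g1$n), c(60, 90))
  expect_s3_class(autoplot(g1), "ggplot")
})

test_that("simulated datasets carry their targets and are reproducible", {
  net <- chain_topology(4)
  cfg <- sim_config("quadratic", "node_edge_on_edge", n = 80, replicates = 1,
                    topology = net)
  d1 <- simulate_network_data(cfg, seed = 5)
  d2 <- simulate_network_data(cfg, seed = 5)
  expect_identical(d1, d2)
  expect_equal(dim(d1), c(80L, 5L))
  tg <- attr(d1, "targets")
  expect_true(tg$node %in% c(net$edges$i[tg$edge], net$edges$j[tg$edge]))
})
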