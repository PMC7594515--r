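test_that("product-moment features reduce to the Pearson correlation", {
  set.seed(201)
  topo <- network_topology(data.frame(from = "a", to = "b"))
  n <- 400
  z <- rbvn(n, 0.45)
  d <- data.frame(a = z[, 1], b = z[, 2])
  E <- pmnr_features(d, topo)
  expect_equal(mean(E[[1]]), cor(z[, 1], z[, 2]) * (n - 1) / n,
               tolerance = 1e-12)

  set.seed(202)
  d2 <- data.frame(a = rnorm(2000), b = rnorm(2000))
  expect_lt(abs(mean(pmnr_features(d2, topo)[[1]])), 0.05)

  # identical columns: every entry is the squared standardized value
  x <- c(1.2, -0.4, 2.2, 0.3, -1.8, 0.9)
  d3 <- data.frame(a = x, b = x)
  E3 <- pmnr_features(d3, topo)
  expect_equal(E3[[1]], ((x - mean(x)) / sd(x))^2)
  expect_equal(mean(E3[[1]]), (length(x) - 1) / length(x))
})

test_that("design matrix columns follow intercept-covariate-node-edge order", {
  net <- insulin_resistance_network()
  set.seed(203)
  n <- 60
  d <- as.data.frame(matrix(rnorm(n * 26), n, 26,
                            dimnames = list(NULL, net$nodes)))
  d$y <- rep(0:1, n / 2)
  E <- pmnr_features(d, net)
  des <- build_design(d, net, E, "y")
  expect_equal(ncol(des$x), 1 + 26 + 37)
  expect_equal(des$spec$role,
               c("intercept", rep("node", 26), rep("edge", 37)))

  empty <- network_topology(data.frame(from = "X1", to = "X2"))
  empty$edges <- empty$edges[0, ]
  d2 <- d[c("X1", "X2", "y")]
  d2$age <- rnorm(n)
  E2 <- pmnr_features(d2, empty)
  des2 <- build_design(d2, empty, E2, "y", covariates = "age")
  expect_equal(ncol(des2$x), 1 + 1 + 2)

  d3 <- d
  d3$y <- sample(0:2, n, replace = TRUE)
  expect_error(build_design(d3, net, E, "y"), "binary")
  expect_error(build_design(d[-1, ], net, E, "y"), "Row counts|lacks|disagree")
})

test_that("IRLS fit matches closed forms and the Newton/glm oracles", {
  # balanced intercept-only fit is exactly logit(0.5) = 0
  f0 <- fit_logistic(matrix(1, 40, 1), rep(0:1, 20))
  expect_identical(unname(f0$coefficients), 0)

  # fixed 20-row dataset against an independent Newton-Raphson oracle
  set.seed(204)
  x <- cbind(1, rnorm(20), runif(20))
  colnames(x) <- c("(Intercept)", "x1", "x2")
  y <- rbinom(20, 1, plogis(0.5 * x[, 2] - x[, 3]))
  f <- fit_logistic(x, y)
  expect_equal(unname(f$coefficients), newton_logistic(x, y),
               tolerance = 1e-6)

  # ten random small network problems against stats::glm
  net <- small_topology()
  for (k in 1:10) {
    set.seed(300 + k)
    z <- MASS::mvrnorm(200, rep(0, 5), diag(5))
    d <- as.data.frame(stats::setNames(as.data.frame(z), net$nodes))
    d$y <- rbinom(200, 1, plogis(0.4 * z[, 1]))
    E <- pmnr_features(d, net)
    des <- build_design(d, net, E, "y")
    f <- fit_logistic(des$x, des$y)
    g <- suppressWarnings(
      stats::glm.fit(des$x, des$y, family = stats::binomial())
    )
    expect_equal(unname(f$coefficients), unname(g$coefficients),
                 tolerance = 1e-5)
  }
})

test_that("separation is flagged and collinearity is a named error", {
  x <- cbind(1, c(rep(-1, 10), rep(1, 10)))
  colnames(x) <- c("(Intercept)", "sep")
  y <- c(rep(0, 10), rep(1, 10))
  expect_warning(f <- fit_logistic(x, y), "converge")
  expect_false(f$converged)

  set.seed(205)
  x2 <- cbind(`(Intercept)` = 1, a = rnorm(50), dup = 0)
  x2[, "dup"] <- x2[, "a"]
  expect_error(fit_logistic(x2, rbinom(50, 1, 0.5)), "dup|a")
})

test_that("Wald p-values follow the two-sided normal reference", {
  fake <- list(
    coefficients = c(zero = 0, crit = 1.959964, big = 3),
    vcov = diag(3),
    converged = TRUE
  )
  w <- wald_tests(fake)
  expect_equal(w$p.value[1], 1)
  expect_equal(w$p.value[2], 0.05, tolerance = 1e-6)
  expect_true(all(diff(w$p.value) < 0))

  fake$converged <- FALSE
  expect_warning(wald_tests(fake), "non-converged")
})

test_that("global LRT is zero on identical models and counts its df", {
  set.seed(206)
  x <- cbind(1, rnorm(80))
  y <- rbinom(80, 1, 0.5)
  f <- fit_logistic(x, y)
  same <- lrt_global(f, f, df = 0)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  f1 <- fit_logistic(x[, 1, drop = FALSE], y)
  nested <- lrt_global(f, f1, df = 1)
  expect_gte(nested$statistic, 0)
  expect_equal(nested$p.value,
               pchisq(nested$statistic, 1, lower.tail = FALSE))
})

test_that("fit_pminr composes features, fit and inference", {
  net <- small_topology()
  set.seed(207)
  z <- MASS::mvrnorm(250, rep(0, 5), diag(5) * 0.8 + 0.2)
  d <- as.data.frame(stats::setNames(as.data.frame(z), net$nodes))
  d$y <- rbinom(250, 1, plogis(0.5 * z[, 2]))
  fit <- fit_pminr(d, net, response = "y", method = "product",
                   bonferroni = TRUE)
  tt <- tidy(fit)
  expect_equal(nrow(tt), 1 + 5 + nrow(net$edges))
  expect_true(all(tt$p.value >= 0 & tt$p.value <= 1))
  expect_true(all(tt$p.bonferroni[tt$role != "intercept"] >=
                    tt$p.value[tt$role != "intercept"], na.rm = TRUE))
  g <- glance(fit)
  expect_equal(g$lrt_df, 5 + nrow(net$edges))
  expect_s3_class(autoplot(fit), "ggplot")
  expect_error(fit_pminr(d, net, "y", method = "mutual"), "arg")

  # permuting rows leaves every statistic unchanged
  perm <- sample(nrow(d))
  fit2 <- fit_pminr(d[perm, ], net, response = "y", method = "product")
  expect_equal(tidy(fit2)$estimate, tt$estimate, tolerance = 1e-9)
  expect_equal(fit2$lrt$statistic, fit$lrt$statistic, tolerance = 1e-9)
})

test_that("pmi and product node tests are concordant on Gaussian data", {
  net <- chain_topology(5)
  p_pmi <- p_prod <- numeric(0)
  for (k in 1:12) {
    set.seed(400 + k)
    z <- MASS::mvrnorm(300, rep(0, 5), diag(5) * 0.75 + 0.25)
    d <- as.data.frame(stats::setNames(as.data.frame(z), net$nodes))
    target <- sample(5, 1)
    d$y <- rbinom(300, 1, plogis(1 * z[, target]))
    f1 <- suppressWarnings(fit_pminr(d, net, "y", method = "pmi"))
    f2 <- suppressWarnings(fit_pminr(d, net, "y", method = "product"))
    p_pmi <- c(p_pmi, dplyr::filter(tidy(f1), role == "node")$p.value)
    p_prod <- c(p_prod, dplyr::filter(tidy(f2), role == "node")$p.value)
  }
  expect_gt(cor(p_pmi, p_prod, method = "spearman"), 0.8)
})
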