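test_that("CLR transform centres rows and matches the oracle", {
  expect_equal(unname(clr_transform(rbind(c(1, 1, 1)))[1, ]), c(0, 0, 0))
  m <- random_counts(8, 12, seed = 43)
  cl <- clr_transform(m)
  expect_equal(unname(rowSums(cl)), rep(0, 8), tolerance = 1e-9)
  expect_equal(unclass(cl), clr_brute(m), tolerance = 1e-10,
               ignore_attr = TRUE)

  # scaling counts and pseudocount together leaves the CLR unchanged
  expect_equal(unclass(clr_transform(10 * m, pseudocount = 10)),
               unclass(clr_transform(m, pseudocount = 1)),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(clr_transform(rbind(c(-1, 2))), "non-negative")
})

test_that("the lasso path shrinks from empty to dense", {
  set.seed(47)
  n <- 120; p <- 12
  z <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
  z[, 2] <- z[, 1] * 0.7 + rnorm(n, 0, 0.5)
  r <- cor(z); diag(r) <- 0
  lmax <- max(abs(r))

  path <- neighborhood_lasso_path(z, lambdas = c(lmax * 1.05, lmax * 0.9,
                                                 lmax * 0.05))
  expect_true(all(path$coefs[[1]] == 0))             # above lambda_max: empty
  expect_gt(sum(path$coefs[[3]] != 0), sum(path$coefs[[2]] != 0))

  # lambda -> 0 approaches the OLS partial fits
  tiny <- neighborhood_lasso_path(z, lambdas = c(lmax, 1e-5 * lmax))
  b_lasso <- tiny$coefs[[2]][1, -1]
  zs <- scale(z)
  b_ols <- coef(lm(zs[, 1] ~ zs[, -1] - 1))
  expect_equal(unname(b_lasso), unname(b_ols), tolerance = 1e-2)

  expect_error(neighborhood_lasso_path(z, lambdas = c(0.1, 0.2)),
               "decreasing")
})

test_that("planted chain support is recovered along the path", {
  prec <- make_precision(20, "chain", strength = 0.4, seed = 51)
  set.seed(51)
  z <- MASS::mvrnorm(300, rep(0, 20), prec$sigma)
  colnames(z) <- paste0("v", 1:20)
  path <- neighborhood_lasso_path(z)
  best_prec <- 0
  for (li in seq_along(path$lambdas)) {
    sel <- (path$coefs[[li]] != 0) | t(path$coefs[[li]] != 0)
    sel <- sel & upper.tri(sel)
    if (sum(sel) == 0) next
    tp <- sum(sel & prec$support)
    if (tp / sum(sel) >= 0.9 && tp / sum(prec$support) >= 0.9)
      best_prec <- max(best_prec, tp / sum(sel))
  }
  expect_gte(best_prec, 0.9)
})

test_that("StARS instability selection is sane at the extremes", {
  # duplicated deterministic pattern: identical subsamples, zero instability
  base <- matrix(rnorm(12 * 6), 12, 6)
  z <- base[rep(1:12, 10), ] + 0
  colnames(z) <- paste0("v", 1:6)
  st <- stars_select_lambda(z, n_subsamples = 10, seed = 1)
  expect_lt(max(st$instability), 0.31)   # duplicates only reduce instability

  # pure-noise data: selection stays near the sparse end with few edges
  set.seed(53)
  zn <- matrix(rnorm(150 * 15), 150, 15, dimnames = list(NULL, paste0("v", 1:15)))
  stn <- stars_select_lambda(zn, seed = 2)
  path <- neighborhood_lasso_path(zn)
  net <- assemble_network(path, stn$lambda_star)
  expect_lte(nrow(net$edges), 8)

  expect_error(stars_select_lambda(zn, lambdas = 0.5), "at least 2")

  # monotonised instability is non-decreasing toward denser graphs
  expect_true(all(diff(stn$instability) >= 0))
})

test_that("network assembly implements the edge and weight rules", {
  # fabricate a directed coefficient path for three nodes
  B <- matrix(0, 3, 3, dimnames = rep(list(c("x", "y", "z")), 2))
  B["x", "y"] <- 0.4          # x -> y selected
  B["y", "x"] <- 0.2          # y -> x selected
  B["x", "z"] <- -0.3         # x -> z only
  path <- structure(list(lambdas = 0.1, coefs = list(B),
                         nodes = c("x", "y", "z"), n = 100),
                    class = "lasso_path")
  net_or <- assemble_network(path, 0.1, rule = "or")
  expect_equal(nrow(net_or$edges), 2)
  exy <- net_or$edges[net_or$edges$from == "x" & net_or$edges$to == "y", ]
  expect_equal(exy$weight, 0.3)                     # mean of 0.4 and 0.2
  exz <- net_or$edges[net_or$edges$to == "z", ]
  expect_equal(exz$weight, -0.3)                    # single available coef

  net_and <- assemble_network(path, 0.1, rule = "and")
  expect_equal(nrow(net_and$edges), 1)              # only the reciprocal pair
  expect_equal(nrow(net_and$nodes), 3)              # isolated nodes retained
})

test_that("network summaries match graph-theoretic definitions", {
  empty <- structure(list(nodes = data.frame(asv_id = c("a", "b"),
                                             domain = NA_character_),
                          edges = data.frame(from = character(0),
                                             to = character(0),
                                             weight = numeric(0),
                                             weight_from_to = numeric(0),
                                             weight_to_from = numeric(0)),
                          directed = matrix(0, 2, 2), lambda = 1, rule = "or"),
                     class = "sparse_network")
  s0 <- network_summary(empty)
  expect_equal(s0$n_edges, 0)
  expect_equal(s0$density, 0)

  cmb <- t(combn(letters[1:5], 2))
  complete <- structure(list(
    nodes = data.frame(asv_id = letters[1:5], domain = "16S"),
    edges = data.frame(from = cmb[, 1], to = cmb[, 2], weight = 1,
                       weight_from_to = 1, weight_to_from = 1),
    directed = matrix(1, 5, 5), lambda = 1, rule = "or"),
    class = "sparse_network")
  s1 <- network_summary(complete)
  expect_equal(s1$clustering_coefficient, 1)
  expect_equal(s1$density, 1)
  expect_equal(s1$mean_degree, 2 * s1$n_edges / s1$n_nodes)
  expect_equal(s1$n_components, 1)
})

test_that("edge count is monotone along the path under the and rule", {
  set.seed(59)
  z <- matrix(rnorm(100 * 10), 100, 10, dimnames = list(NULL, paste0("v", 1:10)))
  z[, 2] <- z[, 1] + rnorm(100, 0, 0.4)
  z[, 3] <- z[, 2] + rnorm(100, 0, 0.4)
  path <- neighborhood_lasso_path(z)
  n_and <- vapply(path$coefs, function(B) {
    sel <- (B != 0) & t(B != 0)
    sum(sel[upper.tri(sel)])
  }, numeric(1))
  expect_true(all(diff(n_and) >= 0))                # lambdas decrease
})
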