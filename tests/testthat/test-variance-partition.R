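test_that("group kernels are PSD with trace n and respect block structure", {
  com <- shared_community()
  for (g in c("Archaeplastida", "Dinoflagellata")) {
    ids <- names(com$truth$group)[com$truth$group == g]
    k <- build_group_kernel(com$counts, ids, group = g, zero_total = "uniform")
    n <- length(k$samples)
    expect_equal(sum(diag(k$K)), n, tolerance = 1e-6)
    expect_gte(min(eigen(k$K, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
  expect_error(build_group_kernel(com$counts, "asv_001", group = "tiny"),
               "fewer than 2")

  # two clusters of identical samples: within-block similarity exceeds
  # between-block similarity
  m <- rbind(matrix(rep(c(10, 1, 1), 4), 4, byrow = TRUE),
             matrix(rep(c(1, 1, 10), 4), 4, byrow = TRUE))
  dimnames(m) <- list(paste0("s", 1:8), paste0("a", 1:3))
  k2 <- build_group_kernel(m, colnames(m))$K
  within <- c(k2[1, 2], k2[3, 4], k2[5, 6], k2[7, 8])
  between <- c(k2[1, 5], k2[2, 7], k2[3, 8])
  expect_gt(min(within), max(between))

  # identical samples everywhere: degenerate kernel, rank 0 reported
  ident <- matrix(rep(c(5, 3, 2), 5), 5, byrow = TRUE,
                  dimnames = list(paste0("s", 1:5), paste0("a", 1:3)))
  k3 <- build_group_kernel(ident, colnames(ident))
  expect_equal(k3$rank, 0)
})

test_that("multi-kernel REML matches closed-form one-way REML", {
  # balanced one-way layout: K = ZZ' for a grouping factor; REML estimates
  # have the classical ANOVA closed form sigma_e^2 = MSW,
  # sigma_a^2 = (MSB - MSW) / m
  set.seed(11)
  g <- 8; m <- 5; n <- g * m
  fac <- rep(seq_len(g), each = m)
  y <- 2 + rnorm(g, 0, sqrt(2))[fac] + rnorm(n, 0, 1)
  Z <- outer(fac, seq_len(g), "==") * 1
  K <- Z %*% t(Z)
  fit <- fit_multikernel_reml(y, NULL, list(group = K))
  msw <- sum((y - ave(y, fac))^2) / (n - g)
  gm <- tapply(y, fac, mean)
  msb <- m * sum((gm - mean(y))^2) / (g - 1)
  expect_equal(unname(fit$sigma2["group"]), (msb - msw) / m, tolerance = 1e-4)
  expect_equal(fit$sigma2_e, msw, tolerance = 1e-4)
})

test_that("REML estimates are permutation-invariant and fractions sum to one", {
  com <- shared_community()
  tr <- generate_traits(com, fractions = c(Archaeplastida = 0.5,
                                           Dinoflagellata = 0.3), seed = 21)
  y <- tr$traits$NCP
  X <- build_fixed_design(com$metadata)
  Ks <- lapply(tr$kernels, function(k) k$K)
  fit <- fit_multikernel_reml(y, X, tr$kernels)
  expect_equal(sum(fit$fractions), 1, tolerance = 1e-8)
  expect_true(all(fit$fractions >= 0 & fit$fractions <= 1))

  perm <- sample(length(y))
  Ks_p <- lapply(Ks, function(K) K[perm, perm])
  fit_p <- fit_multikernel_reml(y[perm], X[perm, , drop = FALSE], Ks_p)
  expect_equal(unname(fit_p$fractions), unname(fit$fractions),
               tolerance = 1e-4)
})

test_that("an identity kernel is flagged as aliased with the residual", {
  set.seed(13)
  y <- rnorm(40)
  expect_warning(fit <- fit_multikernel_reml(y, NULL, list(I = diag(40))),
                 "aliased")
  expect_identical(fit$non_identifiable, "I")
})

test_that("information criteria follow their definitions", {
  com <- shared_community()
  tr <- generate_traits(com, fractions = c(Archaeplastida = 0.5), seed = 31)
  y <- tr$traits$NCP
  X <- build_fixed_design(com$metadata)
  fit <- fit_multikernel_reml(y, X, tr$kernels)
  expect_equal(fit$aic, -2 * fit$loglik_reml + 2 * fit$k_params,
               tolerance = 1e-10)
  expect_equal(fit$bic - fit$aic, fit$k_params * (log(fit$n) - 2),
               tolerance = 1e-10)
  ic <- information_criteria(fit, y = y, X = X)
  expect_equal(ic$aic_delta - ic$bic_delta,
               (ic$aic - ic$bic) - (ic$aic_null - ic$bic_null),
               tolerance = 1e-10)
})

test_that("smaller models are preferred when the extra component is null", {
  # nested-model comparison: with one truly contributing kernel, adding a
  # null kernel should usually not improve AIC
  wins <- 0L
  for (r in 1:10) {
    com <- generate_community(n_lat = 12, seed = 500 + r)
    tr <- generate_traits(com, fractions = c(Archaeplastida = 0.5),
                          seed = 600 + r)
    y <- tr$traits$NCP
    X <- build_fixed_design(com$metadata)
    k_null <- build_group_kernel(
      com$counts, names(com$truth$group)[com$truth$group == "Haptophyta"],
      group = "Haptophyta", zero_total = "uniform")
    f1 <- fit_multikernel_reml(y, X, tr$kernels)
    f2 <- fit_multikernel_reml(y, X, c(tr$kernels, list(Haptophyta = k_null)))
    if (f1$aic <= f2$aic) wins <- wins + 1L
  }
  expect_gte(wins, 7L)
})

test_that("covariation direction tracks constructed trait-abundance links", {
  com <- shared_community()
  ra <- relative_abundance(com$counts)
  ids <- names(com$truth$group)[com$truth$group == "Archaeplastida"]
  idx <- rowSums(ra[, ids])
  X <- build_fixed_design(com$metadata)
  kern <- build_group_kernel(com$counts, ids, group = "Archaeplastida",
                             zero_total = "uniform")
  set.seed(41)
  y_up <- scale(idx)[, 1] + rnorm(nrow(ra), 0, 0.4)
  fit_up <- fit_multikernel_reml(y_up, X, list(Archaeplastida = kern))
  expect_equal(covariation_direction(fit_up, "Archaeplastida", idx)$sign, 1)

  y_dn <- -scale(idx)[, 1] + rnorm(nrow(ra), 0, 0.4)
  fit_dn <- fit_multikernel_reml(y_dn, X, list(Archaeplastida = kern))
  expect_equal(covariation_direction(fit_dn, "Archaeplastida", idx)$sign, -1)

  # a group with zero planted effect is mostly reported as directionless
  # (benchmark-scale samples; a <5% fraction is treated as no signal)
  nulls <- 0L
  for (r in 1:10) {
    com_r <- generate_community(n_lat = 34, seed = 700 + r)
    tr <- generate_traits(com_r, fractions = c(Archaeplastida = 0.5,
                                               Haptophyta = 0),
                          seed = 800 + r)
    X_r <- build_fixed_design(com_r$metadata)
    fit <- fit_multikernel_reml(tr$traits$NCP, X_r, tr$kernels)
    hap_ids <- names(com_r$truth$group)[com_r$truth$group == "Haptophyta"]
    hap_idx <- rowSums(relative_abundance(com_r$counts)[, hap_ids])
    d <- covariation_direction(fit, "Haptophyta", hap_idx,
                               min_fraction = 0.05)
    if (is.na(d$sign)) nulls <- nulls + 1L
  }
  expect_gte(nulls, 8L)
})

test_that("fraction recovery improves with sample size", {
  planted <- c(Archaeplastida = 0.45, Dinoflagellata = 0.20)
  target <- c(planted, residual = 0.35)
  err_at <- function(n_lat, seeds) {
    mean(vapply(seeds, function(s) {
      com <- generate_community(n_lat = n_lat, seed = 900 + s)
      tr <- generate_traits(com, fractions = planted, seed = 950 + s)
      fit <- fit_multikernel_reml(tr$traits$NCP,
                                  build_fixed_design(com$metadata),
                                  tr$kernels)
      mean(abs(fit$fractions[names(target)] - target))
    }, numeric(1)))
  }
  expect_lt(err_at(34, 1:4), err_at(9, 1:4) + 0.02)
})
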