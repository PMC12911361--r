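test_that("Box-Cox transform maximises the profile likelihood sensibly", {
  y <- c(2, 5, 3, 8, 1.5, 4)
  bc1 <- boxcox_transform(y, lambda_grid = 1)
  expect_equal(bc1$y, y - 1)                       # lambda = 1 is y - 1

  set.seed(17)
  ln <- exp(rnorm(200, 1, 0.7))
  expect_lt(abs(boxcox_transform(ln)$lambda), 0.25)    # lognormal -> log

  # already-normal data: transform is identity up to affine change
  nm <- rnorm(300, 50, 2)
  expect_gt(cor(boxcox_transform(nm)$y, nm), 0.999)

  expect_error(boxcox_transform(rep(2, 10)), "constant")

  # transformation improves normality of skewed data more often than not
  set.seed(18)
  better <- mean(replicate(60, {
    z <- exp(rnorm(80, 0, 0.8))
    shapiro.test(boxcox_transform(z)$y)$p.value > shapiro.test(z)$p.value
  }))
  expect_gt(better, 0.8)
})

test_that("soft-threshold adjacency and its report behave", {
  x <- random_counts(30, 25, seed = 19) + 1
  a1 <- adjacency_matrix(x, power = 1)
  expect_equal(a1, abs(cor(x)) * (1 - diag(25)) + diag(25), tolerance = 1e-12,
               ignore_attr = TRUE)

  rep_ <- pick_soft_threshold(x, powers = 1:10)
  expect_true(all(diff(rep_$report$mean_connectivity) < 0))  # decreasing in beta
  expect_true(all(rep_$report$r2 >= 0 & rep_$report$r2 <= 1))

  com <- shared_community()
  pers <- names(com$truth$persistence)[com$truth$persistence == "persistent"]
  xx <- relative_abundance(com$counts)[, pers]
  chosen <- vapply(1:3, function(s) {
    co <- generate_community(seed = 420 + s)
    pp <- names(co$truth$persistence)[co$truth$persistence == "persistent"]
    pick_soft_threshold(relative_abundance(co$counts)[, pp])$power
  }, numeric(1))
  expect_true(all(chosen >= 2 & chosen <= 14))      # structured, not degenerate
})

test_that("topological overlap matches the brute-force oracle", {
  expect_equal(topological_overlap(diag(5)), diag(5), ignore_attr = TRUE)

  # two nodes with identical neighbour profiles have TOM 1
  a <- matrix(0.2, 4, 4); diag(a) <- 1
  a[1, 2] <- a[2, 1] <- 0.9
  a[3, 4] <- a[4, 3] <- 0.9
  a[1, 3] <- a[3, 1] <- a[2, 3] <- a[3, 2] <- 0.5
  a[1, 4] <- a[4, 1] <- a[2, 4] <- a[4, 2] <- 0.5
  tom <- topological_overlap(a)
  expect_true(all(tom >= 0 & tom <= 1))

  # identical (binary) neighbour profiles give maximal overlap
  ident <- matrix(c(1, 1, 1, 0,
                    1, 1, 1, 0,
                    1, 1, 1, 0,
                    0, 0, 0, 1), 4, byrow = TRUE)
  expect_equal(topological_overlap(ident)[1, 2], 1)

  for (seed in 1:3) {
    set.seed(seed)
    r <- matrix(runif(15 * 15), 15)
    a <- (r + t(r)) / 2
    diag(a) <- 1
    expect_equal(topological_overlap(a), tom_brute(a), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  bad <- diag(3); bad[1, 2] <- bad[2, 1] <- 1.4
  expect_error(topological_overlap(bad), "\\[0, 1\\]")
})

test_that("module eigengenes summarise members with positive orientation", {
  set.seed(23)
  prof <- rnorm(40)
  x <- sapply(1:5, function(i) prof * runif(1, 2, 5) + rnorm(40, 0, 1e-8))
  rownames(x) <- paste0("s", 1:40)
  e <- module_eigengene(x)
  expect_gt(abs(cor(e, prof)), 0.999)
  expect_gt(mean(cor(e, scale(x))), 0)

  noisy <- matrix(rnorm(40 * 6), 40)
  expect_gt(mean(cor(module_eigengene(noisy), scale(noisy))), 0)
  expect_error(module_eigengene(cbind(rep(1, 10), rnorm(10))), "constant")
})

test_that("planted modules are recovered and identical modules merge", {
  com <- shared_community()
  pers <- names(com$truth$persistence)[com$truth$persistence == "persistent"]
  x <- relative_abundance(com$counts)[, pers]
  mod <- com$truth$module[pers]
  planted <- mod != "none"
  part <- coabundance_modules(x, power = 6)
  expect_gte(adjusted_rand_index(part$labels[planted], mod[planted]), 0.8)

  # partition is invariant to ASV input order
  perm <- sample(ncol(x))
  a_p <- adjacency_matrix(x[, perm], power = 6)
  part_p <- detect_modules(x[, perm], topological_overlap(a_p))
  agree <- table(part$labels[colnames(x)[perm]], part_p$labels)
  expect_gte(adjusted_rand_index(part$labels[colnames(x)[perm]],
                                 part_p$labels), 0.99)

  # two planted modules with the same factor collapse into one
  set.seed(29)
  f <- rnorm(60)
  dup <- sapply(1:14, function(i) f * runif(1, 0.8, 1.2) + rnorm(60, 0, 0.4))
  other <- sapply(1:10, function(i) rnorm(60) * 2)
  xx <- cbind(dup, other)
  colnames(xx) <- paste0("a", seq_len(ncol(xx)))
  rownames(xx) <- paste0("s", 1:60)
  a <- adjacency_matrix(xx, power = 6)
  p2 <- detect_modules(xx, topological_overlap(a))
  expect_equal(length(unique(p2$labels[1:14])), 1L)

  # pure noise: nothing coherent survives (majority unassigned, or the
  # all-unassigned error)
  set.seed(31)
  xn <- matrix(rnorm(60 * 80), 60, dimnames = list(NULL, paste0("n", 1:80)))
  res <- try(coabundance_modules(xn, power = 6), silent = TRUE)
  if (inherits(res, "try-error")) {
    expect_match(attr(res, "condition")$message, "unassigned")
  } else {
    expect_gt(mean(res$labels == "grey"), 0.5)
  }
})

test_that("module-trait correlations behave under construction and rescaling", {
  com <- shared_community()
  pers <- names(com$truth$persistence)[com$truth$persistence == "persistent"]
  x <- relative_abundance(com$counts)[, pers]
  part <- coabundance_modules(x, power = 6)
  m1 <- colnames(part$eigengenes)[1]
  set.seed(37)
  trait <- part$eigengenes[, m1] + rnorm(nrow(x), 0, 0.2)
  mt <- module_trait_correlation(part, data.frame(T1 = trait),
                                 transform = FALSE)
  rec <- mt[mt$module == m1, ]
  expect_gt(rec$r, 0.9)
  expect_lt(rec$p, 1e-3)

  # correlation invariant to affine rescaling of the trait
  mt2 <- module_trait_correlation(part, data.frame(T1 = 3 * trait + 40),
                                  transform = FALSE)
  expect_equal(mt$r, mt2$r, tolerance = 1e-12)

  # missing traits: too few pairs gives NA cells
  short <- rep(NA_real_, nrow(x)); short[1:2] <- trait[1:2]
  mt3 <- module_trait_correlation(part, data.frame(T1 = short),
                                  transform = FALSE)
  expect_true(all(is.na(mt3$r)))
})

test_that("module membership is stable across soft-threshold powers", {
  com <- shared_community()
  pers <- names(com$truth$persistence)[com$truth$persistence == "persistent"]
  x <- relative_abundance(com$counts)[, pers]
  mod <- com$truth$module[pers]
  stab <- module_power_stability(x, powers = c(2, 4, 6, 8),
                                 reference_power = 6)
  expect_true(all(stab$jaccard[stab$power == 6] == 1))  # self-comparison
  part <- coabundance_modules(x, power = 6)
  for (mm in paste0("M", 1:4)) {
    lab <- names(which.max(table(part$labels[mod == mm])))
    expect_gte(min(stab$jaccard[stab$module == lab]), 0.8)
  }
  expect_error(module_power_stability(x, powers = 6), "at least 2")
})
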