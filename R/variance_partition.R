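#' Build a dissimilarity-derived group kernel (G matrix)
#'
#' Converts the Bray-Curtis dissimilarities among samples, computed on the
#' relative abundances of one phytoplankton group's ASVs, into a positive
#' semi-definite sample-by-sample similarity kernel suitable as a
#' random-effect covariance: S = -1/2 * C (D o D) C with C the centering
#' projector (Gower's construction), negative eigenvalues clipped to zero,
#' and the result rescaled so that trace(K) = n.
#'
#' @param x an [asv_table] or abundance matrix over all ASVs.
#' @param asv_ids the group's ASV identifiers (>= 2 required).
#' @param group group name recorded in the result.
#' @param zero_total `"drop"` (default) removes samples with no reads in the
#'   group; `"uniform"` imputes an even composition for them.
#' @return Object of class `group_kernel`: list with `K` (n x n, trace n),
#'   `group`, `samples`, `n_asvs`, `dropped_samples`, `rank`.
#' @export
build_group_kernel <- function(x, asv_ids, group = "group",
                               zero_total = c("drop", "uniform")) {
  zero_total <- match.arg(zero_total)
  m <- unclass(x)
  asv_ids <- intersect(asv_ids, colnames(m))
  if (length(asv_ids) < 2)
    stop("group '", group, "' has fewer than 2 ASVs in the table")
  sub <- m[, asv_ids, drop = FALSE]
  totals <- rowSums(sub)
  dropped <- character(0)
  if (any(totals <= 0)) {
    if (zero_total == "drop") {
      dropped <- rownames(sub)[totals <= 0]
      sub <- sub[totals > 0, , drop = FALSE]
    } else {
      sub[totals <= 0, ] <- 1
    }
  }
  if (nrow(sub) < 3) stop("fewer than 3 samples with abundance in group '", group, "'")
  rel <- sub / rowSums(sub)
  D <- as.matrix(bray_curtis(rel))
  K <- kernel_from_dissimilarity(D)
  structure(list(K = K, group = group, samples = rownames(sub),
                 n_asvs = length(asv_ids), dropped_samples = dropped,
                 rank = attr(K, "rank")),
            class = "group_kernel")
}

#' Gower-center a squared dissimilarity matrix into a PSD kernel
#'
#' @param D symmetric dissimilarity matrix (zero diagonal).
#' @return PSD matrix with trace n (attribute `rank` = number of retained
#'   positive eigenvalues). Degenerate inputs (all samples identical) yield
#'   the zero-centred constant kernel with a reported rank of 0.
#' @export
kernel_from_dissimilarity <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  S <- -0.5 * J %*% (D * D) %*% J
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  K <- e$vectors %*% (vals * t(e$vectors))
  K <- (K + t(K)) / 2
  tr <- sum(diag(K))
  if (tr > 1e-12) K <- K * (n / tr)
  dimnames(K) <- dimnames(D)
  attr(K, "rank") <- sum(vals > 1e-10 * max(vals, 1e-300))
  K
}

#' Fixed-effects design matrix for the mixed model
#'
#' Builds the model matrix for the survey design: year-by-month interaction,
#' size fraction, and depth bin, dropping aliased columns so the returned
#' matrix has full column rank.
#'
#' @param meta data.frame with `year`, `month`, `size_fraction`, `depth_bin`
#'   (any subset; missing ones are skipped).
#' @param formula optional formula overriding the default
#'   `~ year:month + size_fraction + depth_bin`.
#' @return numeric design matrix with full column rank.
#' @export
build_fixed_design <- function(meta, formula = NULL) {
  if (is.null(formula)) {
    nlev <- function(v) length(unique(meta[[v]]))
    has <- function(v) v %in% names(meta) && nlev(v) >= 2
    terms <- c(
      if (has("year") && has("month")) "factor(year):factor(month)"
      else if (has("year")) "factor(year)"
      else if (has("month")) "factor(month)",
      if (has("size_fraction")) "factor(size_fraction)",
      if (has("depth_bin")) "factor(depth_bin)")
    formula <- stats::as.formula(paste("~", paste(c("1", terms), collapse = " + ")))
  }
  X <- stats::model.matrix(formula, data = meta)
  qrX <- qr(X)
  X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
}

# Restricted log-likelihood of the multi-kernel model at variances `theta`
# (length G+1; last element is the residual). Includes the Gaussian constant
# so that AIC/BIC are on the usual scale.
.reml_loglik <- function(theta, y, X, Ks) {
  n <- length(y)
  p <- ncol(X)
  V <- diag(theta[length(theta)], n)
  for (g in seq_along(Ks)) V <- V + theta[g] * Ks[[g]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    ch <- tryCatch(chol(V + diag(1e-8 * mean(diag(V)), n)),
                   error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
  }
  logdetV <- 2 * sum(log(diag(ch)))
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  XtViX <- crossprod(X, Vi_X)
  chM <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(chM)) return(-Inf)
  logdetM <- 2 * sum(log(diag(chM)))
  beta <- backsolve(chM, forwardsolve(t(chM), crossprod(X, Vi_y)))
  yPy <- sum(y * Vi_y) - sum(crossprod(Vi_X, y) * beta)
  -0.5 * (logdetV + logdetM + yPy + (n - p) * log(2 * pi))
}

#' Multi-kernel REML variance partitioning
#'
#' Fits the mixed model y = X beta + sum_g u_g + e with u_g ~ N(0, sigma^2_g
#' K_g) and e ~ N(0, sigma^2_e I) by maximising the restricted log-likelihood
#' l_R = -1/2 [ log|V| + log|X' V^-1 X| + y' P y ] (plus the Gaussian
#' constant) over the non-negative variance components, where V = sum_g
#' sigma^2_g K_g + sigma^2_e I. Optimisation is bound-constrained
#' quasi-Newton from several starting points; non-negativity is enforced by
#' the box constraint. The fitted components are reported both raw and as
#' fractions of total variance — the per-group "donut" shares.
#'
#' @param y numeric response (one biogeochemical trait), no missing values.
#' @param X fixed-effects design matrix (see [build_fixed_design()]); a
#'   column of ones if `NULL`.
#' @param kernels named list of `group_kernel` objects or plain PSD matrices
#'   aligned with `y`.
#' @param max_iter,tol optimiser control.
#' @param n_starts number of starting points.
#' @return Object of class `variance_decomposition`: list with `sigma2`
#'   (named per-group variances), `sigma2_e`, `fractions` (per group plus
#'   `residual`, summing to 1), `loglik_reml`, `aic`, `bic`, `k_params`,
#'   `beta`, `converged`, `non_identifiable` (groups whose kernel is
#'   numerically the identity, aliased with the residual), `n`, `rank_X`,
#'   and `Py` (residual projection, reused for BLUPs).
#' @export
fit_multikernel_reml <- function(y, X = NULL, kernels, max_iter = 200,
                                 tol = 1e-8, n_starts = 4) {
  y <- as.numeric(y)
  n <- length(y)
  if (anyNA(y)) stop("missing values in y; apply listwise deletion first")
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  if (n <= ncol(X) + 1) stop("too few samples for the fixed-effects design")
  Ks <- lapply(kernels, function(k) if (inherits(k, "group_kernel")) k$K else as.matrix(k))
  if (is.null(names(Ks)) || any(names(Ks) == ""))
    names(Ks) <- vapply(seq_along(kernels), function(i) {
      k <- kernels[[i]]
      if (inherits(k, "group_kernel")) k$group else paste0("K", i)
    }, character(1))
  for (K in Ks) if (nrow(K) != n) stop("kernel dimension does not match y")
  non_ident <- vapply(Ks, function(K) max(abs(K - diag(n))) < 1e-8, logical(1))
  if (any(non_ident))
    warning("kernel(s) numerically equal to the identity: ",
            paste(names(Ks)[non_ident], collapse = ", "),
            "; their variance is aliased with the residual")

  sy <- stats::sd(y)
  if (sy == 0) stop("constant response")
  ys <- y / sy
  vy <- 1                                     # var of scaled response
  G <- length(Ks)
  lower <- c(rep(0, G), 1e-10)
  obj <- function(th) -.reml_loglik(th, ys, X, Ks)

  set.seed(20160419)                          # deterministic multistart
  starts <- list(rep(vy / (G + 1), G + 1),
                 c(rep(0.05 * vy / G, G), 0.95 * vy))
  while (length(starts) < n_starts)
    starts[[length(starts) + 1]] <- stats::runif(G + 1, 0.01, 1) * vy
  best <- NULL
  for (st in starts) {
    fit <- try(stats::optim(st, obj, method = "L-BFGS-B", lower = lower,
                            control = list(maxit = max_iter, factr = tol / 1e-15)),
               silent = TRUE)
    if (inherits(fit, "try-error") || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("REML optimisation failed from every start")
  theta <- best$par * sy^2                    # back to original scale
  ll <- .reml_loglik(theta / sy^2, ys, X, Ks) - (n - ncol(X)) * log(sy)

  sigma2 <- stats::setNames(theta[seq_len(G)], names(Ks))
  sigma2_e <- theta[G + 1]
  total <- sum(sigma2) + sigma2_e
  fractions <- c(sigma2, residual = sigma2_e) / total

  k_params <- (G + 1) + ncol(X)
  aic <- -2 * ll + 2 * k_params
  bic <- -2 * ll + k_params * log(n)

  # beta and Py at the optimum, for BLUPs and covariation signs
  V <- diag(sigma2_e, n)
  for (g in seq_len(G)) V <- V + sigma2[g] * Ks[[g]]
  ch <- chol(V + diag(1e-10 * mean(diag(V)), n))
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  beta <- solve(crossprod(X, Vi_X), crossprod(X, Vi_y))
  Py <- backsolve(ch, forwardsolve(t(ch), y - X %*% beta))

  structure(list(sigma2 = sigma2, sigma2_e = sigma2_e, fractions = fractions,
                 loglik_reml = ll, aic = aic, bic = bic, k_params = k_params,
                 beta = drop(beta), converged = best$convergence == 0,
                 non_identifiable = names(Ks)[non_ident],
                 n = n, rank_X = ncol(X), Py = drop(Py), kernels = Ks),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat("Multi-kernel REML variance decomposition\n")
  cat(sprintf("  n = %d, logLik(REML) = %.3f, AIC = %.2f, BIC = %.2f\n",
              x$n, x$loglik_reml, x$aic, x$bic))
  fr <- x$fractions
  for (nm in names(fr)) cat(sprintf("  %-30s %6.1f%%\n", nm, 100 * fr[nm]))
  invisible(x)
}

#' Information criteria of a fitted decomposition
#'
#' AIC = -2 l + 2 k and BIC = -2 l + k log(n) with k the number of variance
#' components plus the fixed-effect rank, on the restricted-likelihood basis
#' (recorded in the output). Deltas against a residual-only null fit are also
#' reported, since published scores are sometimes differences against a null.
#'
#' @param decomp a `variance_decomposition`.
#' @param y,X optionally refit the null (residual-only) model for deltas.
#' @return list with `aic`, `bic`, `basis = "REML"`, and when `y` is given,
#'   `aic_delta`, `bic_delta` against the kernel-free null model.
#' @export
information_criteria <- function(decomp, y = NULL, X = NULL) {
  out <- list(aic = decomp$aic, bic = decomp$bic, basis = "REML",
              k = decomp$k_params, n = decomp$n)
  if (!is.null(y)) {
    if (is.null(X)) X <- matrix(1, length(y), 1)
    n <- length(y)
    fit0 <- stats::lm.fit(as.matrix(X), y)
    p <- fit0$rank
    s2 <- sum(fit0$residuals^2) / (n - p)
    # restricted likelihood of the iid null model, on .reml_loglik's scale
    ll0 <- .reml_loglik(s2, y, as.matrix(X), list())
    k0 <- 1 + p
    out$aic_null <- -2 * ll0 + 2 * k0
    out$bic_null <- -2 * ll0 + k0 * log(n)
    out$aic_delta <- out$aic - out$aic_null
    out$bic_delta <- out$bic - out$bic_null
  }
  out
}

#' Direction of covariation between a group and the trait
#'
#' Computes the group's predicted random effects (BLUPs)
#' u_hat_g = sigma^2_g K_g V^-1 (y - X beta_hat) and reports the sign of
#' their correlation with a per-sample group-abundance index (total relative
#' abundance of the group). Groups whose variance fraction is numerically
#' zero, or whose BLUP-index correlation is not distinguishable from zero,
#' are reported as `NA` (no defensible direction).
#'
#' @param decomp fitted `variance_decomposition`.
#' @param group group name (must match a kernel name).
#' @param abundance_index numeric per-sample index (e.g. rowSums of the
#'   group's relative abundances).
#' @param min_fraction fractions below this are treated as zero.
#' @param alpha significance level for calling a direction.
#' @return list with `sign` (+1, -1 or NA), `correlation`, `p_value`, `blup`.
#' @export
covariation_direction <- function(decomp, group, abundance_index,
                                  min_fraction = 0.01, alpha = 0.05) {
  if (!group %in% names(decomp$sigma2)) stop("unknown group: ", group)
  if (decomp$fractions[group] < min_fraction)
    return(list(sign = NA, correlation = NA_real_, p_value = NA_real_,
                blup = rep(0, decomp$n)))
  blup <- decomp$sigma2[group] * (decomp$kernels[[group]] %*% decomp$Py)
  ct <- stats::cor.test(drop(blup), abundance_index)
  sgn <- if (ct$p.value < alpha) unname(sign(ct$estimate)) else NA
  list(sign = sgn, correlation = unname(ct$estimate),
       p_value = ct$p.value, blup = drop(blup))
}
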