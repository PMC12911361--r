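#' Centered log-ratio transform
#'
#' x -> log(x + pseudocount) - mean(log(row + pseudocount)), mapping each
#' compositional sample into unconstrained space where conditional-dependence
#' estimation is meaningful. Every output row sums to zero.
#'
#' @param counts samples-by-ASVs non-negative matrix with positive row totals.
#' @param pseudocount added before the log (default 1).
#' @return matrix of the same shape with attribute `pseudocount`.
#' @export
clr_transform <- function(counts, pseudocount = 1) {
  m <- unclass(as.matrix(counts))
  if (any(m < 0)) stop("counts must be non-negative")
  if (any(rowSums(m) <= 0)) stop("row totals must be positive")
  lg <- log(m + pseudocount)
  out <- lg - rowMeans(lg)
  attr(out, "pseudocount") <- pseudocount
  out
}

# shared lambda path: geometric from lambda_max (max |cor|) down
.lambda_path <- function(z, n_lambda = 20, min_ratio = 0.01) {
  r <- stats::cor(z)
  diag(r) <- 0
  lmax <- max(abs(r))
  if (lmax <= 0) lmax <- 1e-3
  exp(seq(log(lmax), log(min_ratio * lmax), length.out = n_lambda))
}

#' Neighbourhood lasso path over all nodes
#'
#' Meinshausen-Buhlmann neighbourhood selection: for every node j, an
#' L1-penalised regression of its (standardised) CLR column on all other
#' columns, over a shared decreasing lambda path. Nonzero coefficients define
#' directed edges j -> i with signed weights.
#'
#' @param clr CLR-transformed matrix (samples x ASVs).
#' @param lambdas decreasing positive penalty path; default 20 geometric
#'   values from lambda_max = max absolute pairwise correlation down to
#'   0.01 lambda_max.
#' @param n_lambda,lambda_min_ratio used when `lambdas` is NULL.
#' @return Object of class `lasso_path`: list with `lambdas` and `coefs`
#'   (list over lambda of p x p matrices; row j holds the coefficients of
#'   node j's regression, so `coefs[[l]][j, i]` is the weight of edge
#'   j -> i), plus `nodes`.
#' @export
neighborhood_lasso_path <- function(clr, lambdas = NULL, n_lambda = 20,
                                    lambda_min_ratio = 0.01) {
  z <- scale(as.matrix(clr))
  z[is.nan(z)] <- 0                            # constant columns
  n <- nrow(z); p <- ncol(z)
  if (n < 10) warning("fewer than 10 samples; neighbourhood estimates unstable")
  if (is.null(lambdas)) lambdas <- .lambda_path(z, n_lambda, lambda_min_ratio)
  if (any(diff(lambdas) >= 0) || any(lambdas <= 0))
    stop("lambdas must be strictly decreasing and positive")
  nodes <- colnames(z)
  if (is.null(nodes)) nodes <- paste0("V", seq_len(p))
  coefs <- lapply(seq_along(lambdas), function(i)
    matrix(0, p, p, dimnames = list(nodes, nodes)))
  for (j in seq_len(p)) {
    yj <- z[, j]
    Xj <- z[, -j, drop = FALSE]
    if (stats::sd(yj) == 0) next
    fit <- try(glmnet::glmnet(Xj, yj, lambda = lambdas, standardize = FALSE,
                              intercept = FALSE), silent = TRUE)
    if (inherits(fit, "try-error")) next
    B <- as.matrix(fit$beta)                   # (p-1) x n_fitted
    fitted_l <- fit$lambda
    for (li in seq_along(lambdas)) {
      # glmnet may stop early on a degenerate path; reuse nearest fitted λ
      ci <- which.min(abs(fitted_l - lambdas[li]))
      coefs[[li]][j, -j] <- B[, ci]
    }
  }
  structure(list(lambdas = lambdas, coefs = coefs, nodes = nodes,
                 n = n), class = "lasso_path")
}

# upper-triangle edge indicator from a directed coefficient matrix
.edge_indicator <- function(B, rule = c("or", "and")) {
  rule <- match.arg(rule)
  sel <- B != 0
  if (rule == "or") (sel | t(sel)) else (sel & t(sel))
}

#' StARS: stability-based selection of the sparsity penalty
#'
#' Repeatedly re-estimates the neighbourhood-selection graph on random
#' subsamples; for each lambda the edge-selection frequencies theta_e give a
#' graph instability D(lambda) = mean over possible edges of
#' 2 theta_e (1 - theta_e). D is monotonised from the sparse end and the
#' selected lambda* is the smallest (densest graph) whose monotonised
#' instability stays within the bound `beta` — the least-regularised graph
#' that is still reproducible under subsampling.
#'
#' @param clr CLR matrix.
#' @param lambdas decreasing path (default as in
#'   [neighborhood_lasso_path()]).
#' @param n_subsamples number of subsamples.
#' @param subsample_size rows per subsample; default floor(10 sqrt(n))
#'   capped at n - 1, and floor(0.8 n) when n < 144.
#' @param beta instability bound (default 0.05).
#' @param rule edge combination rule used for the instability ("or"/"and").
#' @param seed integer seed.
#' @return list with `lambda_star`, `index` (position in the path),
#'   `instability` (monotonised), `instability_raw`, `lambdas`,
#'   `edge_frequency` (p x p at lambda*), `satisfied` (FALSE when no lambda
#'   meets the bound and the sparsest is returned).
#' @export
stars_select_lambda <- function(clr, lambdas = NULL, n_subsamples = 50,
                                subsample_size = NULL, beta = 0.05,
                                rule = "or", seed = 1) {
  z <- as.matrix(clr)
  n <- nrow(z); p <- ncol(z)
  if (is.null(lambdas)) lambdas <- .lambda_path(scale(z))
  if (length(lambdas) < 2) stop("need at least 2 lambda values")
  if (is.null(subsample_size))
    subsample_size <- if (n < 144) floor(0.8 * n) else min(floor(10 * sqrt(n)), n - 1)
  if (subsample_size < 10) stop("subsample size below 10; too few samples")
  set.seed(seed)
  nl <- length(lambdas)
  freq <- lapply(seq_len(nl), function(i) matrix(0, p, p))
  for (b in seq_len(n_subsamples)) {
    idx <- sample.int(n, subsample_size)
    path <- neighborhood_lasso_path(z[idx, , drop = FALSE], lambdas = lambdas)
    for (li in seq_len(nl))
      freq[[li]] <- freq[[li]] + .edge_indicator(path$coefs[[li]], rule)
  }
  ut <- upper.tri(freq[[1]])
  D <- vapply(freq, function(f) {
    th <- f[ut] / n_subsamples
    mean(2 * th * (1 - th))
  }, numeric(1))
  Dbar <- cummax(D)                 # lambdas decreasing: sparse end first
  ok <- which(Dbar <= beta)
  satisfied <- length(ok) > 0
  index <- if (satisfied) max(ok) else 1L
  theta_star <- freq[[index]] / n_subsamples
  dimnames(theta_star) <- list(colnames(z), colnames(z))
  list(lambda_star = lambdas[index], index = index,
       instability = Dbar, instability_raw = D, lambdas = lambdas,
       edge_frequency = theta_star, satisfied = satisfied,
       n_subsamples = n_subsamples, subsample_size = subsample_size,
       beta = beta, seed = seed)
}

#' Assemble the sparse co-occurrence network at the selected penalty
#'
#' Combines the directed neighbourhood selections at lambda* into an
#' undirected weighted network: an edge (i, j) exists when i -> j or j -> i
#' was selected ("or" rule; "and" requires both), and its symmetrised weight
#' is the mean of the available directed coefficients.
#'
#' @param path `lasso_path` fit on the full data.
#' @param lambda_star selected penalty (matched to the nearest path value).
#' @param rule `"or"` or `"and"`.
#' @param weight_rule only `"mean"` is implemented.
#' @param domains optional named vector `asv_id -> "16S"/"18S"`.
#' @return Object of class `sparse_network`: list with `nodes` (data.frame:
#'   asv_id, domain), `edges` (data.frame: from, to, weight, weight_from_to,
#'   weight_to_from; from < to lexicographically), `directed` (p x p
#'   coefficient matrix), `lambda`, `rule`.
#' @export
assemble_network <- function(path, lambda_star, rule = c("or", "and"),
                             weight_rule = "mean", domains = NULL) {
  rule <- match.arg(rule)
  stopifnot(inherits(path, "lasso_path"))
  li <- which.min(abs(path$lambdas - lambda_star))
  B <- path$coefs[[li]]
  sel <- .edge_indicator(B, rule)
  sel[lower.tri(sel, diag = TRUE)] <- FALSE
  idx <- which(sel, arr.ind = TRUE)
  nodes <- path$nodes
  dom <- if (is.null(domains)) rep(NA_character_, length(nodes)) else
    unname(domains[nodes])
  edges <- data.frame(
    from = nodes[idx[, 1]], to = nodes[idx[, 2]],
    weight_from_to = B[idx], weight_to_from = B[idx[, c(2, 1), drop = FALSE]],
    stringsAsFactors = FALSE)
  if (nrow(edges) > 0) {
    w <- mapply(function(a, b) {
      avail <- c(a, b)[c(a, b) != 0]
      if (length(avail) == 0) 0 else mean(avail)
    }, edges$weight_from_to, edges$weight_to_from)
    edges$weight <- unname(w)
  } else {
    edges$weight <- numeric(0)
  }
  structure(list(nodes = data.frame(asv_id = nodes, domain = dom,
                                    stringsAsFactors = FALSE),
                 edges = edges[, c("from", "to", "weight",
                                   "weight_from_to", "weight_to_from")],
                 directed = B, lambda = path$lambdas[li], rule = rule),
            class = "sparse_network")
}

#' @export
print.sparse_network <- function(x, ...) {
  cat(sprintf("Sparse co-occurrence network: %d nodes, %d edges (rule '%s', lambda %.4g)\n",
              nrow(x$nodes), nrow(x$edges), x$rule, x$lambda))
  invisible(x)
}

#' Summary statistics of a sparse network
#'
#' @param net `sparse_network`.
#' @return list with `n_nodes`, `n_edges`, `mean_degree` (2E/N), `density`,
#'   `clustering_coefficient` (global transitivity), `n_components`,
#'   `nodes_per_domain`.
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "sparse_network"))
  g <- igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = net$nodes$asv_id)
  n <- igraph::vcount(g); e <- igraph::ecount(g)
  list(n_nodes = n,
       n_edges = e,
       mean_degree = if (n > 0) 2 * e / n else 0,
       density = if (n > 1) igraph::edge_density(g) else 0,
       clustering_coefficient = {
         tr <- igraph::transitivity(g, type = "global")
         if (is.nan(tr)) 0 else tr
       },
       n_components = igraph::components(g)$no,
       nodes_per_domain = table(net$nodes$domain, useNA = "ifany"))
}

#' Full sparse co-occurrence pipeline
#'
#' CLR transform -> StARS penalty selection -> full-data neighbourhood fit ->
#' network assembly. 16S and 18S tables are concatenated over shared samples;
#' samples missing either marker are dropped.
#'
#' @param counts16s,counts18s [asv_table] objects (either may be NULL for a
#'   single-marker network).
#' @param n_lambda,lambda_min_ratio penalty path.
#' @param n_subsamples,beta,rule StARS parameters.
#' @param pseudocount CLR pseudocount.
#' @param seed integer seed.
#' @return list with `network` (`sparse_network`), `stars` (selection
#'   report), `path`, `summary`.
#' @export
cooccurrence_network <- function(counts16s = NULL, counts18s = NULL,
                                 n_lambda = 20, lambda_min_ratio = 0.01,
                                 n_subsamples = 50, beta = 0.05, rule = "or",
                                 pseudocount = 1, seed = 1) {
  tabs <- Filter(Negate(is.null), list(`16S` = counts16s, `18S` = counts18s))
  if (length(tabs) == 0) stop("at least one count table is required")
  shared <- Reduce(intersect, lapply(tabs, rownames))
  if (length(shared) < 10) stop("fewer than 10 samples shared across markers")
  dropped <- setdiff(unique(unlist(lapply(tabs, rownames))), shared)
  if (length(dropped) > 0)
    message("cooccurrence_network: dropping ", length(dropped),
            " sample(s) missing a marker")
  mats <- lapply(tabs, function(t) unclass(t)[shared, , drop = FALSE])
  counts <- do.call(cbind, unname(mats))
  domains <- unlist(mapply(function(t, nm) stats::setNames(
    rep(nm, ncol(t)), colnames(t)), tabs, names(tabs), SIMPLIFY = FALSE))
  names(domains) <- unlist(lapply(tabs, colnames))
  clr <- clr_transform(counts, pseudocount)
  lambdas <- .lambda_path(scale(clr), n_lambda, lambda_min_ratio)
  stars <- stars_select_lambda(clr, lambdas = lambdas,
                               n_subsamples = n_subsamples, beta = beta,
                               rule = rule, seed = seed)
  path <- neighborhood_lasso_path(clr, lambdas = lambdas)
  net <- assemble_network(path, stars$lambda_star, rule = rule,
                          domains = domains)
  list(network = net, stars = stars, path = path,
       summary = network_summary(net))
}
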