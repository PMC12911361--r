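#' Bray-Curtis dissimilarity matrix
#'
#' d(x, y) = sum |x_i - y_i| / sum (x_i + y_i), the standard abundance-based
#' community dissimilarity, computed between all sample pairs.
#'
#' @param x samples-by-taxa abundance matrix (counts or proportions); every
#'   row must have at least one positive entry.
#' @return A `dist` object with sample labels; values in `[0, 1]`.
#' @export
bray_curtis <- function(x) {
  m <- unclass(x)
  if (any(rowSums(m) <= 0))
    stop("all-zero row(s): ",
         paste(rownames(m)[rowSums(m) <= 0], collapse = ", "))
  vegan::vegdist(m, method = "bray")
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Minimises Kruskal stress-1 over `k`-dimensional configurations by
#' monotone-regression NMDS. One restart is initialised from classical
#' scaling of the dissimilarities (so the returned stress can never exceed
#' that of the metric solution); the remaining restarts are random. The best
#' (lowest-stress) converged solution is returned.
#'
#' @param d `dist` or symmetric matrix of dissimilarities.
#' @param k embedding dimension.
#' @param n_restarts number of starts (first is classical scaling).
#' @param seed integer seed for the random restarts.
#' @return list with `coordinates` (n x k), `stress` (in `[0,1]`),
#'   `converged`, `n_restarts`, and `stress_cmdscale_init` (stress of the
#'   solution started from classical scaling).
#' @export
nmds_embed <- function(d, k = 2, n_restarts = 10, seed = 1) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (k >= n) stop("k must be smaller than the number of samples")
  set.seed(seed)
  init <- stats::cmdscale(d, k = k, add = TRUE)$points
  best <- NULL
  stress_init_solution <- NA_real_
  for (r in seq_len(n_restarts)) {
    start <- if (r == 1L) init else matrix(stats::rnorm(n * k), n, k)
    fit <- try(vegan::monoMDS(d, y = start, k = k, model = "global",
                              maxit = 500, smin = 1e-6, sratmax = 0.999999),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (r == 1L) stress_init_solution <- fit$stress
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  if (is.null(best)) stop("NMDS failed in every restart")
  coords <- best$points
  rownames(coords) <- attr(d, "Labels")
  list(coordinates = coords,
       stress = best$stress,
       converged = best$iters < 500,
       n_restarts = n_restarts,
       stress_cmdscale_init = stress_init_solution)
}

#' Analysis of similarities (ANOSIM)
#'
#' Tests whether between-group rank dissimilarities exceed within-group rank
#' dissimilarities: R = (mean between-group rank - mean within-group rank) /
#' (M/2) with M = n(n-1)/2, and a permutation p-value
#' p = (1 + #\{permuted R >= observed\}) / (n_permutations + 1).
#'
#' @param d `dist` or symmetric dissimilarity matrix.
#' @param grouping factor/character of group memberships, one per sample;
#'   every group must contain at least two samples.
#' @param n_permutations number of permutations.
#' @param seed integer seed.
#' @return list with `statistic` (R), `p_value`, `n_permutations`, `seed`.
#' @export
anosim_test <- function(d, grouping, n_permutations = 999, seed = 1) {
  d <- stats::as.dist(d)
  grouping <- as.factor(grouping)
  sizes <- table(grouping)
  if (length(sizes) < 2) stop("need at least two groups")
  if (any(sizes < 2))
    stop("group(s) of size 1: ", paste(names(sizes)[sizes < 2], collapse = ", "))
  set.seed(seed)
  fit <- vegan::anosim(d, grouping, permutations = n_permutations)
  list(statistic = unname(fit$statistic),
       p_value = fit$signif,
       n_permutations = n_permutations,
       seed = seed)
}

#' Fit an environmental vector onto ordination coordinates
#'
#' Least-squares fit of a numeric variable onto the ordination axes; reports
#' the squared correlation r^2 = 1 - SS_res/SS_tot, the unit direction vector
#' (arrow) of steepest increase, and a permutation p-value obtained by
#' shuffling the variable across samples.
#'
#' @param coordinates n x k ordination coordinates.
#' @param variable numeric, finite, non-constant, one value per sample.
#' @param n_permutations permutations for the p-value.
#' @param seed integer seed.
#' @return list with `r2`, `p_value`, `arrow` (unit length k-vector),
#'   `n_permutations`, `seed`.
#' @export
envfit_vector <- function(coordinates, variable, n_permutations = 999, seed = 1) {
  coordinates <- as.matrix(coordinates)
  if (!is.numeric(variable) || any(!is.finite(variable)))
    stop("variable must be numeric and finite")
  if (stats::sd(variable) == 0) stop("variable is constant")
  if (length(variable) != nrow(coordinates))
    stop("variable length does not match coordinates")
  set.seed(seed)
  fit <- vegan::envfit(coordinates, data.frame(v = variable),
                       permutations = n_permutations)
  arrow <- drop(fit$vectors$arrows)          # direction cosines, unit length
  list(r2 = unname(fit$vectors$r),
       p_value = unname(fit$vectors$pvals),
       arrow = arrow,
       n_permutations = n_permutations,
       seed = seed)
}

#' Bray-Curtis distance between a persistence class and the whole community
#'
#' For each aggregation unit, compares the composition restricted to one
#' persistence class (ephemeral or persistent; renormalised over the unit's
#' ASV set with zeros outside the class) against the composition of all ASVs
#' of that unit. Distances near 0 mean the class mirrors the whole community;
#' distances near 1 mean it is compositionally distinct.
#'
#' @param x an [asv_table] (or abundance matrix).
#' @param labels data.frame from [classify_persistence()] covering the
#'   table's ASVs.
#' @param groups optional named vector `asv_id -> group` from
#'   [assign_groups()]; required for the default per-sample-per-group unit.
#' @param unit `"per_sample_group"` (default), `"per_sample"`, or `"pooled"`
#'   (compositions summed over samples first).
#' @return list with `distances` (data.frame: class, group, sample, distance)
#'   and `summary` (mean/median/n per class); skipped empty cells are counted
#'   in `n_skipped`.
#' @export
subset_vs_whole_dissimilarity <- function(x, labels, groups = NULL,
                                          unit = c("per_sample_group",
                                                   "per_sample", "pooled")) {
  unit <- match.arg(unit)
  m <- unclass(x)
  lab <- stats::setNames(labels$label, labels$asv_id)
  if (!all(colnames(m) %in% names(lab)))
    stop("persistence labels do not cover all ASVs in the table")
  lab <- lab[colnames(m)]
  if (unit == "per_sample_group") {
    if (is.null(groups)) stop("groups required for per_sample_group unit")
    grp <- groups[colnames(m)]
  } else {
    grp <- rep("all", ncol(m))
  }
  if (unit == "pooled") {
    m <- matrix(colSums(m), 1, dimnames = list("pooled", colnames(m)))
  }
  rows <- list()
  n_skipped <- 0L
  for (g in unique(grp)) {
    cols <- which(grp == g)
    sub <- m[, cols, drop = FALSE]
    class_of <- lab[cols]
    for (s in seq_len(nrow(sub))) {
      whole <- sub[s, ]
      if (sum(whole) <= 0) { n_skipped <- n_skipped + 1L; next }
      whole_p <- whole / sum(whole)
      for (cl in c("ephemeral", "persistent")) {
        part <- whole
        part[class_of != cl] <- 0
        if (sum(part) <= 0) { n_skipped <- n_skipped + 1L; next }
        part_p <- part / sum(part)
        dist_bc <- sum(abs(part_p - whole_p)) / sum(part_p + whole_p)
        rows[[length(rows) + 1L]] <- data.frame(
          class = cl, group = g, sample = rownames(sub)[s],
          distance = dist_bc, stringsAsFactors = FALSE)
      }
    }
  }
  distances <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(distances, distances$class), function(d)
    data.frame(class = d$class[1], mean = mean(d$distance),
               median = stats::median(d$distance), n = nrow(d))))
  rownames(summary) <- NULL
  list(distances = distances, summary = summary, n_skipped = n_skipped)
}
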