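#' Box-Cox transformation by profile likelihood
#'
#' y(lambda) = (y^lambda - 1) / lambda for lambda != 0 and log(y) at
#' lambda = 0; lambda maximises the profile log-likelihood of the normal
#' model over a grid on [-5, 5] (step 0.01). Non-positive inputs are made
#' strictly positive by a documented shift.
#'
#' @param y numeric with at least 3 finite values, non-constant.
#' @param lambda_grid grid of candidate exponents.
#' @return list with `y` (transformed, NA kept in place), `lambda`, `shift`
#'   (amount added before transforming; 0 when unneeded).
#' @export
boxcox_transform <- function(y, lambda_grid = seq(-5, 5, by = 0.01)) {
  ok <- is.finite(y)
  if (sum(ok) < 3) stop("need at least 3 finite values")
  v <- y[ok]
  if (stats::sd(v) == 0) stop("constant y cannot be transformed")
  shift <- 0
  if (min(v) <= 0) {
    shift <- -min(v) + 1e-3 * diff(range(v))
    if (shift <= -min(v)) shift <- -min(v) + 1   # degenerate range guard
    v <- v + shift
  }
  n <- length(v)
  slog <- sum(log(v))
  ll <- vapply(lambda_grid, function(l) {
    z <- if (abs(l) < 1e-12) log(v) else (v^l - 1) / l
    if (any(!is.finite(z))) return(-Inf)
    s2 <- stats::var(z) * (n - 1) / n
    if (s2 <= 0) return(-Inf)
    -n / 2 * log(s2) + (l - 1) * slog
  }, numeric(1))
  lambda <- lambda_grid[which.max(ll)]
  z <- if (abs(lambda) < 1e-12) log(v) else (v^lambda - 1) / lambda
  out <- rep(NA_real_, length(y))
  out[ok] <- z
  list(y = out, lambda = lambda, shift = shift)
}

#' Unsigned (or signed) soft-threshold adjacency
#'
#' @param x samples-by-ASVs abundance matrix (standardised internally).
#' @param power soft-threshold exponent beta.
#' @param type `"unsigned"` gives |cor|^beta; `"signed"` gives
#'   ((1 + cor)/2)^beta.
#' @return symmetric adjacency with unit diagonal, entries in `[0, 1]`.
#' @export
adjacency_matrix <- function(x, power = 6, type = c("unsigned", "signed")) {
  type <- match.arg(type)
  r <- stats::cor(as.matrix(x))
  a <- if (type == "unsigned") abs(r)^power else ((1 + r) / 2)^power
  diag(a) <- 1
  a
}

#' Scale-free topology fit across candidate soft-threshold powers
#'
#' For each power beta, forms the adjacency |cor|^beta, computes each node's
#' connectivity k_i = sum_j a_ij (j != i), bins k, and regresses
#' log10 p(k) on log10 mean(k) per bin. The fit R^2 (taken as 0 when the
#' slope is positive, since scale-free topology requires a decreasing
#' frequency) and the mean connectivity are reported; the chosen power is the
#' smallest with R^2 >= `target_r2`, falling back to the argmax of R^2.
#'
#' @param x samples-by-ASVs abundance matrix.
#' @param powers candidate integer powers.
#' @param target_r2 scale-free fit target.
#' @param n_bins histogram bins for the connectivity distribution.
#' @param type adjacency type, see [adjacency_matrix()].
#' @return list with `report` (data.frame: power, r2, slope,
#'   mean_connectivity), `power` (the chosen one), `degenerate` flag.
#' @export
pick_soft_threshold <- function(x, powers = 1:20, target_r2 = 0.8,
                                n_bins = 10, type = "unsigned") {
  x <- as.matrix(x)
  if (nrow(x) < 20)
    warning("fewer than 20 samples; scale-free fit estimates will be noisy")
  r <- stats::cor(x)
  degenerate <- FALSE
  rows <- lapply(powers, function(beta) {
    a <- if (type == "unsigned") abs(r)^beta else ((1 + r) / 2)^beta
    diag(a) <- 0
    k <- colSums(a)
    if (max(k) - min(k) < 1e-12) {
      degenerate <<- TRUE
      return(data.frame(power = beta, r2 = 0, slope = NA_real_,
                        mean_connectivity = mean(k)))
    }
    bins <- cut(k, breaks = n_bins)
    pk <- tapply(k, bins, length) / length(k)
    mk <- tapply(k, bins, mean)
    keep <- !is.na(pk) & pk > 0 & mk > 0
    if (sum(keep) < 3)
      return(data.frame(power = beta, r2 = 0, slope = NA_real_,
                        mean_connectivity = mean(k)))
    fit <- stats::lm(log10(pk[keep]) ~ log10(mk[keep]))
    r2 <- summary(fit)$r.squared
    slope <- stats::coef(fit)[2]
    if (is.finite(slope) && slope > 0) r2 <- 0
    data.frame(power = beta, r2 = r2, slope = slope, mean_connectivity = mean(k))
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  hit <- report$power[report$r2 >= target_r2]
  chosen <- if (length(hit) > 0) min(hit) else report$power[which.max(report$r2)]
  list(report = report, power = chosen, degenerate = degenerate)
}

#' Topological overlap matrix
#'
#' TOM_ij = (sum_{u != i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)
#' with k_i = sum_{u != i} a_iu, and TOM_ii = 1. Nodes with topological
#' overlap share network neighbourhoods even when their direct adjacency is
#' modest, which stabilises module detection.
#'
#' @param a symmetric adjacency, entries in `[0, 1]`, unit diagonal.
#' @return TOM matrix, entries in `[0, 1]`, unit diagonal.
#' @export
topological_overlap <- function(a) {
  a <- as.matrix(a)
  if (any(a < 0 | a > 1)) stop("adjacency entries must lie in [0, 1]")
  if (max(abs(a - t(a))) > 1e-10) stop("adjacency must be symmetric")
  a0 <- a
  diag(a0) <- 0
  L <- a0 %*% a0                     # u = i, j contribute 0 since diag(a0) = 0
  k <- colSums(a0)
  kmin <- outer(k, k, pmin)
  tom <- (L + a0) / (kmin + 1 - a0)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

# fixed module palette (size order); "grey" is reserved for unassigned
MODULE_COLORS <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                   "black", "pink", "magenta", "purple", "greenyellow", "tan",
                   "salmon", "cyan", "midnightblue", "lightcyan", "grey60",
                   "lightgreen", "lightyellow", "royalblue", "darkred",
                   "darkgreen", "darkturquoise", "darkgrey", "orange",
                   "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
                   "paleturquoise", "violet", "darkolivegreen", "darkmagenta")

#' Module eigengene
#'
#' First principal-component score of the standardised member profiles,
#' sign-oriented so that the mean correlation with the members is positive.
#'
#' @param x samples-by-members abundance matrix (>= 2 members).
#' @return numeric score per sample (unit variance).
#' @export
module_eigengene <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("module must have at least 2 members")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) stop("constant member profile(s)")
  z <- scale(x)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  e <- pc$x[, 1]
  if (mean(stats::cor(e, z)) < 0) e <- -e
  sde <- stats::sd(e)
  if (sde > 0) e <- e / sde
  stats::setNames(e, rownames(x))
}

#' Detect co-abundance modules from a topological overlap matrix
#'
#' Average-linkage hierarchical clustering of 1 - TOM; the tree is cut at
#' `cut_height`, branches smaller than `min_module_size` are left unassigned
#' ("grey"), modules whose eigengenes correlate above `1 - merge_threshold`
#' are merged iteratively, and unassigned ASVs whose profile correlates with
#' a module eigengene at `kme_rescue` or better are assigned to their
#' best-matching module (the membership-based assignment stage of the hybrid
#' tree cut). Surviving modules are labelled with a fixed colour palette in
#' decreasing size order.
#'
#' @param x samples-by-ASVs abundance matrix (for eigengenes).
#' @param tom TOM from [topological_overlap()] over the same ASVs.
#' @param min_module_size smallest retained module.
#' @param cut_height static tree-cut height on the 1 - TOM scale; `NULL`
#'   (default) scans the merge heights of the tree and keeps the cut whose
#'   partition maximises Newman modularity of the TOM-weighted graph, which
#'   makes the cut invariant to the overall TOM scale (and hence to the
#'   soft-threshold power).
#' @param merge_threshold eigengene dissimilarity below which modules merge.
#' @param kme_rescue minimum eigengene correlation for assigning a leftover
#'   ASV to a module (set to `NULL` to disable the rescue stage).
#' @return Object of class `module_partition`: list with `labels` (named by
#'   ASV; "grey" = unassigned), `eigengenes` (samples x modules),
#'   `sizes`, `cut_height`, `merged` (number of merges performed).
#' @export
detect_modules <- function(x, tom, min_module_size = 5, cut_height = NULL,
                           merge_threshold = 0.25, kme_rescue = 0.5) {
  x <- as.matrix(x)
  stopifnot(ncol(x) == ncol(tom))
  ids <- colnames(tom)
  if (is.null(ids)) ids <- colnames(x)
  if (is.null(ids)) ids <- paste0("ASV", seq_len(ncol(tom)))
  tree <- stats::hclust(stats::as.dist(1 - tom), method = "average")

  cut_at <- function(h) {
    cl <- stats::cutree(tree, h = h)
    tab <- table(cl)
    cl[cl %in% as.integer(names(tab)[tab < min_module_size])] <- 0L
    cl
  }
  if (is.null(cut_height)) {
    # choose the height carving out the largest number of viable branches
    # (>= min_module_size); over-splitting is harmless because the
    # refinement and eigengene-merge stages reassemble fragments, whereas an
    # under-split cut buries distinct modules inside one branch. Ties are
    # broken by weighted-graph modularity of the branch partition.
    w <- tom
    diag(w) <- 0
    tot <- sum(w)
    modularity_of <- function(cl) {
      mods <- setdiff(unique(cl), 0L)
      if (length(mods) < 1 || tot <= 0) return(-Inf)
      deg <- colSums(w)
      sum(vapply(mods, function(m) {
        i <- cl == m
        sum(w[i, i]) / tot - (sum(deg[i]) / tot)^2
      }, numeric(1)))
    }
    cand <- unique(stats::quantile(tree$height, seq(0.3, 0.995, by = 0.015)))
    n_viable <- vapply(cand, function(h) {
      cl <- cut_at(h)
      length(setdiff(unique(cl), 0L))
    }, numeric(1))
    top <- cand[n_viable == max(n_viable)]
    scores <- vapply(top, function(h) modularity_of(cut_at(h)), numeric(1))
    cut_height <- if (all(!is.finite(scores))) max(tree$height) * 0.99 else
      top[which.max(scores)]
  }
  cl <- cut_at(cut_height)
  if (all(cl == 0L))
    stop("all ASVs unassigned; raise cut_height or lower min_module_size")

  # membership refinement on the pre-merge modules: each ASV joins the
  # module whose eigengene it correlates with best (when that correlation
  # reaches kme_rescue), or is left unassigned. Final membership therefore
  # rests on profile-eigengene correlation, which does not depend on the
  # soft-threshold power; the power only shapes the initial tree.
  if (!is.null(kme_rescue)) {
    for (round in 1:2) {
      mods <- setdiff(unique(cl), 0L)
      if (length(mods) == 0) break
      eg <- sapply(mods, function(m) module_eigengene(x[, cl == m, drop = FALSE]))
      kme <- stats::cor(x, eg)
      kme[!is.finite(kme)] <- 0
      best <- apply(kme, 1, which.max)
      new_cl <- ifelse(kme[cbind(seq_len(ncol(x)), best)] >= kme_rescue,
                       mods[best], 0L)
      tab <- table(new_cl[new_cl != 0L])
      new_cl[new_cl %in% as.integer(names(tab)[tab < min_module_size])] <- 0L
      if (all(new_cl == cl) || all(new_cl == 0L)) break
      cl <- new_cl
    }
  }

  # iterative eigengene merging
  merged <- 0L
  repeat {
    mods <- setdiff(unique(cl), 0L)
    if (length(mods) < 2) break
    eg <- sapply(mods, function(m) module_eigengene(x[, cl == m, drop = FALSE]))
    cc <- stats::cor(eg)
    diag(cc) <- -Inf
    top <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (max(cc) <= 1 - merge_threshold) break
    cl[cl == mods[top[2]]] <- mods[top[1]]
    merged <- merged + 1L
  }

  # cohesion screen: a module must hang together beyond what chance
  # correlation among unrelated profiles produces (mean within-module
  # correlation above ~2 standard errors of a null correlation)
  cohesion_floor <- 2 / sqrt(nrow(x))
  for (m in setdiff(unique(cl), 0L)) {
    rm_ <- stats::cor(x[, cl == m, drop = FALSE])
    if (mean(rm_[upper.tri(rm_)]) < cohesion_floor) cl[cl == m] <- 0L
  }
  if (all(cl == 0L))
    stop("all ASVs unassigned; raise cut_height or lower min_module_size")

  mods <- setdiff(unique(cl), 0L)
  sizes <- vapply(mods, function(m) sum(cl == m), integer(1))
  ord <- order(sizes, decreasing = TRUE)
  labels <- rep("grey", length(cl))
  for (i in seq_along(ord))
    labels[cl == mods[ord[i]]] <- MODULE_COLORS[min(i, length(MODULE_COLORS))]
  names(labels) <- ids

  keep <- setdiff(unique(labels), "grey")
  eigengenes <- sapply(keep, function(m)
    module_eigengene(x[, labels == m, drop = FALSE]))
  if (is.null(dim(eigengenes)))
    eigengenes <- matrix(eigengenes, ncol = length(keep),
                         dimnames = list(rownames(x), keep))
  structure(list(labels = labels, eigengenes = eigengenes,
                 sizes = sort(table(labels[labels != "grey"]), decreasing = TRUE),
                 cut_height = cut_height, merged = merged),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("Module partition: %d modules over %d ASVs (%d unassigned)\n",
              length(x$sizes), length(x$labels), sum(x$labels == "grey")))
  print(x$sizes)
  invisible(x)
}

#' Full co-abundance module pipeline
#'
#' Standardised abundances -> soft-threshold adjacency -> TOM -> module
#' detection, in one call.
#'
#' @param x samples-by-ASVs abundance matrix.
#' @param power soft threshold; `"auto"` runs [pick_soft_threshold()].
#' @param type adjacency type.
#' @param ... passed to [detect_modules()].
#' @return `module_partition` with attribute `"power"`.
#' @export
coabundance_modules <- function(x, power = "auto", type = "unsigned", ...) {
  if (identical(power, "auto")) power <- pick_soft_threshold(x, type = type)$power
  a <- adjacency_matrix(x, power = power, type = type)
  tom <- topological_overlap(a)
  part <- detect_modules(x, tom, ...)
  attr(part, "power") <- power
  part
}

#' Module-trait correlation table
#'
#' Pearson correlation between each module eigengene and each (Box-Cox
#' transformed) trait, with the exact two-sided t-test p-value on n - 2
#' degrees of freedom; missing trait values are dropped pairwise.
#'
#' @param partition `module_partition`.
#' @param traits data.frame/matrix of traits (rows aligned with the
#'   eigengene samples), e.g. NCP, POC, PON.
#' @param transform Box-Cox transform each trait first (default TRUE).
#' @return data.frame with columns `module`, `trait`, `r`, `p`, `n`; cells
#'   with fewer than 3 paired observations are NA.
#' @export
module_trait_correlation <- function(partition, traits, transform = TRUE) {
  eg <- partition$eigengenes
  traits <- as.data.frame(traits)
  rows <- list()
  for (tr in names(traits)) {
    v <- traits[[tr]]
    if (transform && sum(is.finite(v)) >= 3) v <- boxcox_transform(v)$y
    for (m in colnames(eg)) {
      ok <- is.finite(v) & is.finite(eg[, m])
      if (sum(ok) < 3) {
        rows[[length(rows) + 1]] <- data.frame(module = m, trait = tr,
                                               r = NA_real_, p = NA_real_,
                                               n = sum(ok))
        next
      }
      ct <- stats::cor.test(eg[ok, m], v[ok])
      rows[[length(rows) + 1]] <- data.frame(module = m, trait = tr,
                                             r = unname(ct$estimate),
                                             p = ct$p.value, n = sum(ok))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Module membership stability across soft-threshold powers
#'
#' Rebuilds the partition at each power and reports, per reference module,
#' the best Jaccard overlap with any module of the rebuilt partition — the
#' robustness check that trait-linked modules are not artefacts of one
#' particular soft threshold.
#'
#' @param x samples-by-ASVs abundance matrix.
#' @param powers powers to scan.
#' @param reference_power power defining the reference partition.
#' @param ... passed to [detect_modules()] via [coabundance_modules()].
#' @return data.frame with `power`, `module` (reference label), `jaccard`.
#' @export
module_power_stability <- function(x, powers = 1:8, reference_power = 6, ...) {
  if (length(powers) < 2) stop("need at least 2 powers")
  ref <- coabundance_modules(x, power = reference_power, ...)
  ref_sets <- split(names(ref$labels), ref$labels)
  ref_sets <- ref_sets[names(ref_sets) != "grey"]
  rows <- list()
  for (b in powers) {
    part <- if (b == reference_power) ref else coabundance_modules(x, power = b, ...)
    sets <- split(names(part$labels), part$labels)
    sets <- sets[names(sets) != "grey"]
    for (m in names(ref_sets)) {
      jac <- if (length(sets) == 0) 0 else max(vapply(sets, function(s) {
        length(intersect(s, ref_sets[[m]])) / length(union(s, ref_sets[[m]]))
      }, numeric(1)))
      rows[[length(rows) + 1]] <- data.frame(power = b, module = m, jaccard = jac)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
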