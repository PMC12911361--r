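#' Adjusted Rand index between two partitions
#'
#' @param a,b partition label vectors of equal length.
#' @return ARI in `[-1, 1]`; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / denom
}

# group sizes giving p = 40 ASVs for the network benchmarks
.network_groups <- c(Prochlorococcus = 7, Synechococcus = 6,
                     Archaeplastida = 7, Dinoflagellata = 7,
                     Haptophyta = 6, Stramenopiles_photosynthetic = 7)

# gradient switched off: conditional-dependence recovery is evaluated on
# compositions whose only structured covariance is the planted graph
.flat_gradient <- list(lat_range = c(24, 42), salinity_front_lat = 32.3,
                       chl_front_lat = 34.5, strength = 0)

# undirected upper-triangle selection matrix from an assembled network
.selection_matrix <- function(net, ids) {
  sel <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(net$edges) > 0)
    sel[cbind(net$edges$from, net$edges$to)] <- TRUE
  (sel | t(sel)) & upper.tri(sel)
}

#' Variance-partition recovery benchmark
#'
#' Simulates traits with planted variance fractions 0.45 (Archaeplastida),
#' 0.20 (Dinoflagellata) and 0 (Haptophyta, the null group) over ~200
#' samples, refits by multi-kernel REML, and scores the mean absolute error
#' of the recovered fractions and how often the null group stays below 0.05.
#' A fresh community (hence fresh kernels) is generated per replicate.
#'
#' @param n_reps replicates.
#' @param n_lat latitude stations per year (34 gives 204 samples).
#' @param seed integer seed.
#' @return list with `mae` (per replicate), `mean_mae`, `null_fractions`,
#'   `null_below_05` (count), `n`, `fractions_planted`.
#' @export
benchmark_variance_partition <- function(n_reps = 20, n_lat = 34, seed = 1) {
  planted <- c(Archaeplastida = 0.45, Dinoflagellata = 0.20, Haptophyta = 0)
  target <- c(planted, residual = 0.35)
  mae <- nulls <- numeric(n_reps)
  n_used <- NA_integer_
  for (r in seq_len(n_reps)) {
    com <- generate_community(n_lat = n_lat, seed = seed + 7919L * r)
    tr <- generate_traits(com, fractions = planted,
                          seed = seed + 7919L * r + 1L)
    X <- build_fixed_design(com$metadata)
    fit <- fit_multikernel_reml(tr$traits$NCP, X, tr$kernels)
    mae[r] <- mean(abs(fit$fractions[names(target)] - target))
    nulls[r] <- fit$fractions["Haptophyta"]
    n_used <- fit$n
  }
  list(mae = mae, mean_mae = mean(mae), null_fractions = nulls,
       null_below_05 = sum(nulls < 0.05), n = n_used,
       fractions_planted = target)
}

#' REML optimiser versus exhaustive grid
#'
#' On a 30-sample toy problem with two kernels, compares the optimiser's
#' restricted log-likelihood against the best value on a dense grid over the
#' three variance components (`grid_size`^3 points, log-spaced).
#'
#' @param seed integer seed.
#' @param grid_size grid points per component.
#' @return list with `loglik_opt`, `loglik_grid`, `gap` (opt minus grid; the
#'   optimiser should not lose more than ~1e-4).
#' @export
benchmark_reml_grid <- function(seed = 1, grid_size = 20) {
  com <- generate_community(n_lat = 5, seed = seed)     # 30 samples
  tr <- generate_traits(com, fractions = c(Archaeplastida = 0.5,
                                           Dinoflagellata = 0.2),
                        seed = seed + 1L)
  y <- tr$traits$NCP
  X <- build_fixed_design(com$metadata)
  Ks <- lapply(tr$kernels, function(k) k$K)
  fit <- fit_multikernel_reml(y, X, tr$kernels)
  grid <- exp(seq(log(1e-3), log(3), length.out = grid_size)) * stats::var(y)
  best <- -Inf
  for (a in grid) for (b in grid) for (e in grid) {
    v <- .reml_loglik(c(a, b, e), y, X, Ks)
    if (v > best) best <- v
  }
  list(loglik_opt = fit$loglik_reml, loglik_grid = best,
       gap = fit$loglik_reml - best, n = length(y))
}

#' Co-abundance module recovery benchmark
#'
#' Generates the default community (150 ASVs, 60 samples, four planted
#' modules), runs the module pipeline at power 6, and scores: adjusted Rand
#' index over the planted members; correlation and p-value between the
#' planted trait-linked module's eigengene and a trait built from that
#' module's factor; and the minimum membership Jaccard of the trait-linked
#' module across powers 1-8.
#'
#' @param seed integer seed.
#' @return list with `ari`, `trait_r`, `trait_p`, `trait_module`,
#'   `stability_min_jaccard`, `n_modules`, `n_asvs`, `n_samples`.
#' @export
benchmark_module_recovery <- function(seed = 1) {
  com <- generate_community(seed = seed)
  pers <- names(com$truth$persistence)[com$truth$persistence == "persistent"]
  x <- relative_abundance(com$counts)[, pers]
  mod <- com$truth$module[pers]
  planted <- mod != "none"
  part <- coabundance_modules(x, power = 6)
  ari <- adjusted_rand_index(part$labels[planted], mod[planted])

  trait <- generate_trait_from_module(com, "M1", seed = seed + 1L)
  mt <- module_trait_correlation(part, data.frame(NCP = trait$NCP))
  m1_label <- names(which.max(table(part$labels[mod == "M1"])))
  rec <- mt[mt$module == m1_label, ]

  stab <- module_power_stability(x, powers = 1:8, reference_power = 6)
  min_j <- min(stab$jaccard[stab$module == m1_label])

  list(ari = ari, trait_r = rec$r, trait_p = rec$p, trait_module = m1_label,
       stability_min_jaccard = min_j, n_modules = length(part$sizes),
       n_asvs = ncol(x), n_samples = nrow(x))
}

#' Sparse-network support recovery benchmark
#'
#' Plants a modular sparse precision matrix over 40 ASVs (four blocks,
#' partial correlations ~0.3), generates 300 gradient-free compositional
#' samples, runs the StARS-selected neighbourhood network, and scores edge
#' precision/recall against the planted support, together with an
#' edge-count-matched baseline that thresholds marginal CLR correlations.
#'
#' @param n_seeds generator seeds.
#' @param seed base seed.
#' @return list with per-seed `precision`, `recall`, `baseline_precision`,
#'   `baseline_recall`, `beats_baseline` (strictly larger precision+recall),
#'   and medians.
#' @export
benchmark_network_recovery <- function(n_seeds = 10, seed = 1) {
  prc <- rcl <- bprc <- brcl <- numeric(n_seeds)
  beats <- logical(n_seeds)
  for (i in seq_len(n_seeds)) {
    s <- seed + 104729L * i
    com <- generate_community(n_lat = 100, size_fractions = 0.2,
      gradient = .flat_gradient, asvs_per_group = .network_groups,
      graph_spec = list(type = "modular", strength = 0.3,
                        within_prob = 0.35, between_prob = 0.01),
      module_spec = list(n_modules = 4, size = 10, strength = 0),
      persistence_spec = list(ephemeral_fraction = 0), seed = s)
    truth <- com$truth$precision_support
    clr <- clr_transform(com$counts)
    st <- stars_select_lambda(clr, seed = s)
    path <- neighborhood_lasso_path(clr)
    net <- assemble_network(path, st$lambda_star)
    sel <- .selection_matrix(net, colnames(com$counts))
    tp <- sum(sel & truth)
    prc[i] <- tp / max(sum(sel), 1)
    rcl[i] <- tp / max(sum(truth), 1)
    r <- abs(stats::cor(clr))
    r[lower.tri(r, diag = TRUE)] <- 0
    ne <- sum(sel)
    thr <- if (ne > 0) sort(r[upper.tri(r)], decreasing = TRUE)[ne] else Inf
    base <- (r >= thr) & upper.tri(r)
    tpb <- sum(base & truth)
    bprc[i] <- tpb / max(sum(base), 1)
    brcl[i] <- tpb / max(sum(truth), 1)
    beats[i] <- (prc[i] + rcl[i]) > (bprc[i] + brcl[i])
  }
  list(precision = prc, recall = rcl,
       baseline_precision = bprc, baseline_recall = brcl,
       beats_baseline = beats,
       median_precision = stats::median(prc),
       median_recall = stats::median(rcl),
       n_beats = sum(beats), n_seeds = n_seeds)
}

#' Known-pair positive and negative control benchmark
#'
#' Plants one strongly positively partially-correlated taxon pair (a
#' cyanobacterial and a haptophyte ASV, emulating a host-symbiont signal)
#' into the modular graph and checks how often the assembled network contains
#' that edge, against how often it links an arbitrary planted-independent
#' pair (no edge, different blocks).
#'
#' @param n_seeds generator seeds.
#' @param seed base seed.
#' @return list with `positive_detections`, `negative_detections`,
#'   `n_seeds`.
#' @export
benchmark_known_pair <- function(n_seeds = 10, seed = 1) {
  pos <- neg <- 0L
  pair <- c(8L, 28L)                    # a Synechococcus and a Haptophyta ASV
  for (i in seq_len(n_seeds)) {
    s <- seed + 15485863L %% 9973L * i + i
    com <- generate_community(n_lat = 100, size_fractions = 0.2,
      gradient = .flat_gradient, asvs_per_group = .network_groups,
      graph_spec = list(type = "modular", strength = 0.3,
                        within_prob = 0.35, between_prob = 0.01,
                        planted_pairs = rbind(pair), planted_strength = 0.6),
      module_spec = list(n_modules = 4, size = 10, strength = 0),
      persistence_spec = list(ephemeral_fraction = 0), seed = s)
    clr <- clr_transform(com$counts)
    st <- stars_select_lambda(clr, seed = s)
    path <- neighborhood_lasso_path(clr)
    net <- assemble_network(path, st$lambda_star)
    ids <- colnames(com$counts)
    sel <- .selection_matrix(net, ids)
    sel <- sel | t(sel)
    pos <- pos + sel[pair[1], pair[2]]
    # planted-independent pair: no edge, different blocks, not the pair
    sup <- com$truth$precision_support
    found <- FALSE
    for (a in seq_along(ids)) {
      if (found) break
      for (b in seq_along(ids)) {
        if (b <= a) next
        if (!sup[a, b] && !sup[b, a] &&
            com$truth$module[a] != com$truth$module[b] &&
            !(a == pair[1] && b == pair[2])) {
          neg <- neg + sel[a, b]
          found <- TRUE
          break
        }
      }
    }
  }
  list(positive_detections = pos, negative_detections = neg,
       n_seeds = n_seeds)
}

#' Permutation-test calibration benchmark
#'
#' Checks that p-values are uniform under the null: ANOSIM on random
#' groupings of unstructured communities, and module-trait correlations
#' against permuted traits. Uniformity is scored by a Kolmogorov-Smirnov
#' test and by the rejection rate at 0.05.
#'
#' @param n_reps null replicates per statistic.
#' @param seed integer seed.
#' @return list with `anosim_p`, `anosim_ks_p`, `anosim_rejection_rate`,
#'   `mt_p`, `mt_ks_p`, `mt_rejection_rate`.
#' @export
benchmark_permutation_calibration <- function(n_reps = 200, seed = 1) {
  # one independent RNG substream per replicate: the data seed and the
  # permutation seed are fixed up front, so replicates stay independent
  # even though anosim_test reseeds the generator internally
  anosim_p <- vapply(seq_len(n_reps), function(i) {
    set.seed(seed + 2L * i)
    m <- matrix(stats::rexp(20 * 30), 20, 30)
    anosim_test(bray_curtis(m), rep(1:2, each = 10),
                n_permutations = 199, seed = seed + 2L * i + 1L)$p_value
  }, numeric(1))
  com <- generate_community(seed = seed)
  pers <- names(com$truth$persistence)[com$truth$persistence == "persistent"]
  x <- relative_abundance(com$counts)[, pers]
  part <- coabundance_modules(x, power = 6)
  trait <- generate_trait_from_module(com, "M1", seed = seed + 1L)$NCP
  set.seed(seed + 2L)
  mt_p <- replicate(n_reps, {
    shuffled <- sample(trait)
    mt <- module_trait_correlation(part, data.frame(t = shuffled),
                                   transform = FALSE)
    mt$p[sample.int(nrow(mt), 1)]
  })
  # permutation p-values are discrete (multiples of 1/200), so ties are
  # expected; the KS comparison against the uniform is still informative
  list(anosim_p = anosim_p,
       anosim_ks_p = suppressWarnings(
         stats::ks.test(anosim_p, "punif")$p.value),
       anosim_rejection_rate = mean(anosim_p <= 0.05),
       mt_p = mt_p,
       mt_ks_p = stats::ks.test(mt_p, "punif")$p.value,
       mt_rejection_rate = mean(mt_p <= 0.05),
       n_reps = n_reps)
}

#' End-to-end microbial-neighbourhood benchmark
#'
#' Full pipeline on communities carrying both planted modules and a planted
#' modular co-occurrence graph: detect modules, correlate with a trait tied
#' to one module, select candidates, infer the network, and score (i) how
#' much of each candidate's planted positive neighbourhood appears among its
#' top-10 positively weighted network neighbours and (ii) the same-module
#' enrichment of positive versus negative neighbours.
#'
#' @param n_seeds generator seeds.
#' @param seed base seed.
#' @return list with per-seed `neighbor_recovery` (median over candidates),
#'   `odds_ratio`, `or_p`, and the overall `median_recovery`.
#' @export
benchmark_neighborhood_integration <- function(n_seeds = 3, seed = 1) {
  recov <- ors <- orp <- numeric(n_seeds)
  for (i in seq_len(n_seeds)) {
    s <- seed + 31L * i
    com <- generate_community(n_lat = 50, size_fractions = 0.2,
      gradient = list(lat_range = c(24, 42), salinity_front_lat = 32.3,
                      chl_front_lat = 34.5, strength = 0.5),
      graph_spec = list(type = "modular", strength = 0.3,
                        within_prob = 0.3, between_prob = 0.02),
      seed = s)
    pers <- names(com$truth$persistence)[com$truth$persistence == "persistent"]
    x <- relative_abundance(com$counts)[, pers]
    part <- coabundance_modules(x, power = 6)
    trait <- generate_trait_from_module(com, "M1", seed = s + 1L)
    mt <- module_trait_correlation(part, data.frame(NCP = trait$NCP))
    cand <- select_candidate_modules(mt, part)
    clr <- clr_transform(com$counts)
    st <- stars_select_lambda(clr, seed = s)
    path <- neighborhood_lasso_path(clr)
    net <- assemble_network(path, st$lambda_star, domains = com$truth$marker)
    possup <- com$truth$precision_support & com$truth$precision_sign > 0
    possup <- possup | t(possup)
    m1 <- intersect(cand$asv_ids,
                    names(com$truth$module)[com$truth$module == "M1"])
    fr <- vapply(m1, function(cd) {
      nb <- first_degree_neighbors(net, cd, part)
      top10 <- utils::head(nb$neighbor[nb$weight > 0], 10)
      truenb <- names(which(possup[cd, ]))
      if (length(truenb) == 0) return(NA_real_)
      mean(truenb %in% top10)
    }, numeric(1))
    nbs <- do.call(rbind, lapply(cand$asv_ids, function(cd)
      first_degree_neighbors(net, cd, part)))
    ct <- neighbor_module_crosstab(nbs, part, seed = s)
    recov[i] <- stats::median(fr, na.rm = TRUE)
    ors[i] <- ct$odds_ratio
    orp[i] <- ct$p_value
  }
  list(neighbor_recovery = recov, odds_ratio = ors, or_p = orp,
       median_recovery = stats::median(recov), n_seeds = n_seeds)
}
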