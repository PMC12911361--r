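#' Construct a sparse positive-definite precision matrix
#'
#' Builds the planted conditional-dependence graph for the community
#' generator: a sparse symmetric precision matrix Omega whose nonzero
#' off-diagonal support is the ground-truth edge set for co-occurrence
#' recovery. The matrix is made diagonally dominant, inverted, rescaled to a
#' correlation-scale covariance, and re-inverted, so both Omega and
#' Sigma = Omega^-1 are well conditioned.
#'
#' @param p number of nodes.
#' @param type `"chain"` (tridiagonal), `"random"` (Erdos-Renyi support), or
#'   `"modular"` (dense within blocks, sparse between).
#' @param strength absolute partial-correlation scale of planted edges.
#' @param prob edge probability for `"random"`.
#' @param blocks integer block labels (length p) for `"modular"`; nodes with
#'   block 0 receive only background edges.
#' @param within_prob,between_prob edge probabilities for `"modular"`.
#' @param planted_pairs optional 2-column index matrix of extra edges planted
#'   with strong weight (e.g. a known symbiont pair).
#' @param planted_strength partial-correlation scale for `planted_pairs`.
#' @param seed integer seed.
#' @return list with `omega`, `sigma`, `support` (logical p x p, upper
#'   triangle), `edges` (2-column index matrix).
#' @export
make_precision <- function(p, type = c("chain", "random", "modular"),
                           strength = 0.35, prob = 2 / p, blocks = NULL,
                           within_prob = 0.3, between_prob = 0.01,
                           planted_pairs = NULL, planted_strength = 0.6,
                           seed = 1) {
  type <- match.arg(type)
  set.seed(seed)
  # A positive association (positive partial correlation, positive lasso
  # coefficient) corresponds to a NEGATIVE off-diagonal precision entry, so
  # `strength` is entered with the opposite sign: most planted edges are
  # positive associations, a minority negative, as in observed networks.
  B <- matrix(0, p, p)
  assoc_sign <- function(k) sample(c(1, -1), k, replace = TRUE, prob = c(0.75, 0.25))
  if (type == "chain") {
    for (i in seq_len(p - 1)) B[i, i + 1] <- -strength * assoc_sign(1)
  } else if (type == "random") {
    ut <- which(upper.tri(B))
    on <- ut[stats::runif(length(ut)) < prob]
    B[on] <- -strength * assoc_sign(length(on))
  } else {
    # within-module edges are predominantly positive associations; the rarer
    # between-module edges are predominantly negative, mirroring networks
    # where negative partners sit in opposing community regimes
    if (is.null(blocks)) stop("modular precision needs block labels")
    for (i in seq_len(p - 1)) for (j in (i + 1):p) {
      same <- blocks[i] != 0 && blocks[i] == blocks[j]
      pr <- if (same) within_prob else between_prob
      if (stats::runif(1) < pr) {
        sgn <- if (same) sample(c(1, -1), 1, prob = c(0.9, 0.1))
               else sample(c(1, -1), 1, prob = c(0.25, 0.75))
        B[i, j] <- -strength * sgn
      }
    }
  }
  if (!is.null(planted_pairs)) {
    planted_pairs <- matrix(planted_pairs, ncol = 2)
    for (r in seq_len(nrow(planted_pairs))) {
      i <- min(planted_pairs[r, ]); j <- max(planted_pairs[r, ])
      B[i, j] <- -planted_strength
    }
  }
  B <- B + t(B)
  # With unit precision diagonal, pcor_ij = -omega_ij, so Omega = I + B plants
  # partial correlations of magnitude `strength` directly; B is shrunk only
  # as far as positive definiteness requires.
  omega <- diag(p) + B
  while (min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values) < 0.05) {
    B <- 0.9 * B
    omega <- diag(p) + B
  }
  sigma <- solve(omega)
  d <- sqrt(diag(sigma))
  sigma <- sigma / tcrossprod(d)               # unit-variance covariance
  sigma <- (sigma + t(sigma)) / 2
  omega <- solve(sigma)
  support <- (B != 0) & upper.tri(B)
  list(omega = omega, sigma = sigma, support = support,
       sign = sign(-B) * support,              # +1 positive association
       edges = which(support, arr.ind = TRUE))
}

# group-level defaults emulating the survey's biogeography
.group_defaults <- function() {
  data.frame(
    group = PHYTO_GROUPS,
    marker = c("16S", "16S", "18S", "18S", "18S", "18S"),
    niche_lat = c(26, 37, 38, 27, 30, 38),     # southern gyre vs northern TZ
    niche_width = c(5, 5, 5, 6, 8, 5),
    base = c(1.5, 0.5, 0.8, 1.0, 0.6, 0.6),    # log-scale mean abundance
    # log-offset applied in the large (3 um) size fraction: negative values
    # mean the group is enriched in the small fraction
    large_offset = c(-1.4, 0, -1.1, 0, -0.9, -1.1),
    stringsAsFactors = FALSE
  )
}

.lineage_for <- function(group, i, strameno_class = NULL) {
  switch(group,
    Prochlorococcus = sprintf("Bacteria;Cyanobacteria;Cyanobacteriia;Synechococcales;Cyanobiaceae;Prochlorococcus;Prochlorococcus_sp_%03d", i),
    Synechococcus = sprintf("Bacteria;Cyanobacteria;Cyanobacteriia;Synechococcales;Cyanobiaceae;Synechococcus;Synechococcus_sp_CC9902_%03d", i),
    Archaeplastida = sprintf("Eukaryota;Archaeplastida;Chlorophyta;Mamiellophyceae;Mamiellales;Bathycoccaceae;Chlorophyte_sp_%03d", i),
    Dinoflagellata = sprintf("Eukaryota;Alveolata;Dinoflagellata;Dinophyceae;Gymnodiniales;Gymnodiniaceae;Dinophyceae_sp_%03d", i),
    Haptophyta = sprintf("Eukaryota;Haptophyta;Prymnesiophyceae;Prymnesiales;Chrysochromulinaceae;Chrysochromulina;Haptophyte_sp_%03d", i),
    Stramenopiles_photosynthetic = sprintf("Eukaryota;Stramenopiles;Ochrophyta;%s;Ochrophyta_sp_%03d", strameno_class, i),
    Other = sprintf("Eukaryota;Opisthokonta;Metazoa;Copepoda;Calanoida;Copepod_sp_%03d", i)
  )
}

#' Generate a gradient-structured synthetic plankton community
#'
#' Emulates the study design that the package's analyses target: three yearly
#' surveys along a latitudinal gradient, two size fractions, six
#' phytoplankton-containing groups with latitude-structured relative
#' abundances (gyre-adapted groups peaking south of the salinity front,
#' transition-zone groups north of it), persistent and ephemeral ASVs, a
#' planted sparse conditional-dependence graph, and planted co-abundance
#' modules. Latent log-abundances are a Gaussian niche curve over latitude
#' plus module factors plus multivariate Gaussian noise with the planted
#' precision matrix; counts are drawn per sample by softmax-to-multinomial
#' with lognormal sequencing depth (a logistic-normal-multinomial, so the
#' planted precision matrix is the literal conditional-dependence truth).
#'
#' @param n_lat latitude stations per year (samples per year =
#'   `n_lat * length(size_fractions)`).
#' @param years survey years.
#' @param asvs_per_group named integer vector over
#'   `r paste(PHYTO_GROUPS, collapse = ", ")`; an `Other` entry is allowed.
#' @param gradient list: `lat_range`, `salinity_front_lat`, `chl_front_lat`,
#'   `strength` (0 flattens all niche structure).
#' @param graph_spec passed to [make_precision()] (list of arguments;
#'   `type = "modular"` uses the planted module labels as blocks). `NULL`
#'   plants no graph (iid noise).
#' @param module_spec list: `n_modules`, `size` (ASVs per module),
#'   `strength` (factor loading scale; 0 disables modules).
#' @param persistence_spec list: `ephemeral_fraction`.
#' @param depth_spec list: `meanlog`, `sdlog` of sequencing depth.
#' @param noise_sd standard deviation scale of the latent Gaussian noise.
#' @param size_fractions filter sizes in micrometres.
#' @param seed integer seed.
#' @return list with `counts` (all samples x all ASVs), `tables_16s` /
#'   `tables_18s` (per-year [asv_table] lists), `taxonomy`, `metadata`, and
#'   `truth` (groups, markers, persistence labels and active years, module
#'   labels and factors, precision support, niche parameters, seed).
#' @export
generate_community <- function(n_lat = 10,
                               years = c(2016, 2017, 2019),
                               asvs_per_group = c(Prochlorococcus = 20,
                                                  Synechococcus = 15,
                                                  Archaeplastida = 30,
                                                  Dinoflagellata = 30,
                                                  Haptophyta = 25,
                                                  Stramenopiles_photosynthetic = 30),
                               gradient = list(lat_range = c(24, 42),
                                               salinity_front_lat = 32.3,
                                               chl_front_lat = 34.5,
                                               strength = 1),
                               graph_spec = list(type = "modular",
                                                 strength = 0.35),
                               module_spec = list(n_modules = 4, size = 12,
                                                  strength = 2),
                               persistence_spec = list(ephemeral_fraction = 0.3),
                               depth_spec = list(meanlog = log(2e4), sdlog = 0.3),
                               noise_sd = 0.6,
                               size_fractions = c(0.2, 3.0),
                               seed = 1) {
  set.seed(seed)
  gdef <- .group_defaults()
  groups <- rep(names(asvs_per_group), asvs_per_group)
  p <- length(groups)
  asv_ids <- sprintf("asv_%03d", seq_len(p))
  gidx <- match(groups, gdef$group)
  marker <- ifelse(is.na(gidx), "16S", gdef$marker[gidx])
  gstrength <- if (is.null(gradient$strength)) 1 else gradient$strength

  # per-ASV niche parameters: group optimum + jitter
  niche_lat <- ifelse(is.na(gidx), mean(gradient$lat_range), gdef$niche_lat[gidx]) +
    stats::rnorm(p, 0, 1.5)
  niche_width <- pmax(ifelse(is.na(gidx), 8, gdef$niche_width[gidx]) *
                        stats::runif(p, 0.8, 1.2), 2)
  base <- ifelse(is.na(gidx), 0.5, gdef$base[gidx]) + stats::rnorm(p, 0, 0.4)
  large_offset <- ifelse(is.na(gidx), 0, gdef$large_offset[gidx])

  # taxonomy with realistic ranked lineages
  strameno_classes <- sample(PHOTOSYNTHETIC_STRAMENOPILE_CLASSES, p, replace = TRUE)
  lineage <- vapply(seq_len(p), function(i)
    .lineage_for(groups[i], i, strameno_classes[i]), character(1))
  taxonomy <- data.frame(asv_id = asv_ids, lineage = lineage,
                         stringsAsFactors = FALSE)

  # persistence classes
  eph_frac <- persistence_spec$ephemeral_fraction
  n_eph <- round(eph_frac * p)
  eph <- sample.int(p, n_eph)
  active_years <- lapply(seq_len(p), function(i) years)
  for (i in eph)
    active_years[[i]] <- sort(sample(years, sample(1:2, 1)))
  persistence <- ifelse(seq_len(p) %in% eph, "ephemeral", "persistent")

  # planted modules among persistent ASVs (labels double as graph blocks;
  # strength = 0 plants labels without co-abundance factors)
  module <- rep("none", p)
  n_modules <- if (is.null(module_spec)) 0 else module_spec$n_modules
  if (n_modules > 0) {
    pool <- sample(which(persistence == "persistent"))
    need <- n_modules * module_spec$size
    if (need > length(pool)) stop("not enough persistent ASVs for the module plan")
    for (m in seq_len(n_modules))
      module[pool[seq_len(module_spec$size) + (m - 1) * module_spec$size]] <-
        paste0("M", m)
  }

  # sample metadata
  lat <- seq(gradient$lat_range[1], gradient$lat_range[2], length.out = n_lat)
  months <- stats::setNames(c("April", "May", "June")[seq_along(years)], years)
  meta <- do.call(rbind, lapply(years, function(yr) {
    do.call(rbind, lapply(size_fractions, function(sf) {
      data.frame(year = yr, month = unname(months[as.character(yr)]),
                 latitude = lat + stats::rnorm(n_lat, 0, 0.1),
                 depth = 15, size_fraction = sf, stringsAsFactors = FALSE,
                 row.names = NULL)
    }))
  }))
  meta$sample_id <- sprintf("S%03d_%d_%sum", seq_len(nrow(meta)), meta$year,
                            sub("\\.", "p", format(meta$size_fraction)))
  meta$depth_bin <- as.character(depth_bin(meta$depth))
  sal_front <- gradient$salinity_front_lat
  chl_front <- gradient$chl_front_lat
  meta$salinity <- 34.82 + 0.15 * (sal_front - meta$latitude) +
    stats::rnorm(nrow(meta), 0, 0.02)
  meta$chlorophyll <- 0.15 * exp(0.25 * (meta$latitude - chl_front)) *
    exp(stats::rnorm(nrow(meta), 0, 0.1))
  meta$region <- assign_region(meta)
  n <- nrow(meta)

  # planted precision graph over all ASVs
  if (!is.null(graph_spec)) {
    gargs <- graph_spec
    gtype <- gargs$type %||% "random"
    gargs$type <- NULL
    block_lab <- as.integer(factor(module, levels = c("none", paste0("M", seq_len(max(1, n_modules))))) ) - 1L
    prec <- do.call(make_precision, c(list(p = p, type = gtype,
                                           seed = seed + 1),
                                      if (gtype == "modular") list(blocks = block_lab),
                                      gargs))
    noise <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = prec$sigma) * noise_sd
  } else {
    prec <- NULL
    noise <- matrix(stats::rnorm(n * p, 0, noise_sd), n, p)
  }

  # module factors: smooth latitude bumps plus sample noise. Members express
  # the module's shared spatial pattern instead of their own niche curve
  # (their individual niche contribution is damped), which is what a
  # co-abundance module is: a set of taxa with one coinciding spatial
  # profile.
  module_factors <- NULL
  eta_mod <- matrix(0, n, p)
  niche_damp <- rep(1, p)
  if (n_modules > 0 && module_spec$strength > 0) {
    centers <- seq(gradient$lat_range[1] + 2, gradient$lat_range[2] - 2,
                   length.out = n_modules)
    module_factors <- sapply(seq_len(n_modules), function(m) {
      # latitude bump with survey-to-survey amplitude variation: module
      # expression recurs spatially but waxes and wanes between years,
      # which separates module factors from the static group niche trends
      amp <- stats::setNames(stats::runif(length(years), 0.3, 1.7), years)
      f <- amp[as.character(meta$year)] *
        exp(-(meta$latitude - centers[m])^2 / (2 * 3^2)) +
        0.3 * stats::rnorm(n)
      as.numeric(scale(f))
    })
    colnames(module_factors) <- paste0("M", seq_len(n_modules))
    rownames(module_factors) <- meta$sample_id
    loading <- stats::runif(p, 0.8, 1.2) * module_spec$strength
    for (m in seq_len(n_modules)) {
      mem <- module == paste0("M", m)
      eta_mod[, mem] <- outer(module_factors[, m], loading[mem])
      niche_damp[mem] <- 0.25
    }
  }

  # latent log-abundance and counts
  eta_niche <- t(vapply(seq_len(n), function(s)
    base + gstrength * niche_damp * 3 *
      exp(-(meta$latitude[s] - niche_lat)^2 / (2 * niche_width^2)),
    numeric(p)))
  eta_sf <- outer(meta$size_fraction == max(size_fractions), large_offset)
  eta <- eta_niche + eta_sf + eta_mod + noise

  depth_reads <- pmax(round(stats::rlnorm(n, depth_spec$meanlog,
                                          depth_spec$sdlog)), 1000)
  counts <- matrix(0, n, p, dimnames = list(meta$sample_id, asv_ids))
  for (s in seq_len(n)) {
    active <- vapply(active_years, function(ay) meta$year[s] %in% ay, logical(1))
    pr <- rep(0, p)
    pr[active] <- exp(eta[s, active] - max(eta[s, active]))
    pr <- pr / sum(pr)
    counts[s, ] <- stats::rmultinom(1, depth_reads[s], pr)
  }

  mk_tables <- function(mk) {
    cols <- which(marker == mk)
    if (length(cols) == 0) return(NULL)
    out <- lapply(years, function(yr) {
      rows <- meta$year == yr
      asv_table(counts[rows, cols, drop = FALSE], mk)
    })
    stats::setNames(out, years)
  }

  truth <- list(
    group = stats::setNames(groups, asv_ids),
    marker = stats::setNames(marker, asv_ids),
    persistence = stats::setNames(persistence, asv_ids),
    active_years = stats::setNames(active_years, asv_ids),
    module = stats::setNames(module, asv_ids),
    module_factors = module_factors,
    precision_support = if (!is.null(prec)) {
      s <- prec$support
      dimnames(s) <- list(asv_ids, asv_ids)
      s
    } else NULL,
    precision_sign = if (!is.null(prec)) {
      s <- prec$sign
      dimnames(s) <- list(asv_ids, asv_ids)
      s
    } else NULL,
    niche = data.frame(asv_id = asv_ids, niche_lat = niche_lat,
                       niche_width = niche_width, base = base),
    seed = seed
  )
  list(counts = counts, tables_16s = mk_tables("16S"),
       tables_18s = mk_tables("18S"), taxonomy = taxonomy,
       metadata = meta, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate traits with planted group-attributable variance
#'
#' Draws each trait as a sum of zero-mean Gaussian group effects
#' u_g ~ N(0, sigma^2_g K_g), with K_g the dissimilarity-derived kernel of
#' group g built from the generated community, plus optional fixed effects
#' and an iid residual. With `exact = TRUE` each component is rescaled so the
#' empirical variance shares equal the planted fractions exactly, making the
#' fractions a sharp recovery target for [fit_multikernel_reml()].
#'
#' @param community output of [generate_community()].
#' @param fractions named vector of variance fractions per group (groups not
#'   named get 0); `sum(fractions) + residual` must be 1.
#' @param residual residual variance fraction.
#' @param trait_name column name of the generated trait.
#' @param fixed_effects optional numeric per-sample fixed-effect contribution
#'   added after variance scaling (e.g. a year effect on the trait scale).
#' @param total_sd marginal standard deviation of the trait.
#' @param mean_level trait mean.
#' @param exact rescale components to hit the fractions exactly.
#' @param seed integer seed.
#' @return list with `traits` (data.frame: sample_id, <trait_name>),
#'   `kernels` (the group kernels used, for refitting), `truth` (planted
#'   fractions incl. residual).
#' @export
generate_traits <- function(community, fractions, residual = NULL,
                            trait_name = "NCP", fixed_effects = NULL,
                            total_sd = 1, mean_level = 0, exact = TRUE,
                            seed = 1) {
  if (is.null(residual)) residual <- 1 - sum(fractions)
  if (any(fractions < 0) || residual < -1e-12)
    stop("fractions must be non-negative")
  if (abs(sum(fractions) + residual - 1) > 1e-8)
    stop("fractions plus residual must sum to 1")
  set.seed(seed)
  meta <- community$metadata
  n <- nrow(meta)
  kernels <- lapply(names(fractions), function(g) {
    ids <- names(community$truth$group)[community$truth$group == g]
    build_group_kernel(community$counts, ids, group = g,
                       zero_total = "uniform")
  })
  names(kernels) <- names(fractions)
  comp <- matrix(0, n, length(fractions) + 1)
  for (gi in seq_along(fractions)) {
    if (fractions[gi] == 0) next
    K <- kernels[[gi]]$K
    u <- MASS::mvrnorm(1, mu = rep(0, n), Sigma = K + diag(1e-8, n))
    u <- u - mean(u)
    if (exact) u <- u / stats::sd(u)
    comp[, gi] <- u * sqrt(fractions[gi]) * total_sd
  }
  e <- stats::rnorm(n)
  e <- e - mean(e)
  if (exact) e <- e / stats::sd(e)
  comp[, length(fractions) + 1] <- e * sqrt(max(residual, 0)) * total_sd
  y <- mean_level + rowSums(comp)
  if (!is.null(fixed_effects)) y <- y + fixed_effects
  traits <- data.frame(sample_id = meta$sample_id, y)
  names(traits)[2] <- trait_name
  list(traits = traits, kernels = kernels,
       truth = list(fractions = c(fractions, residual = residual),
                    trait = trait_name, seed = seed, exact = exact))
}

#' Trait tracking a planted module's factor
#'
#' Convenience generator for module-trait benchmarks: the trait equals the
#' planted module factor plus Gaussian noise, so the module's eigengene
#' should recover it with correlation roughly
#' 1 / sqrt(1 + noise_sd^2).
#'
#' @param community output of [generate_community()] with planted modules.
#' @param module planted module label (e.g. `"M1"`).
#' @param noise_sd noise level relative to the unit-variance factor.
#' @param trait_name trait column name.
#' @param seed integer seed.
#' @return data.frame with `sample_id` and the trait.
#' @export
generate_trait_from_module <- function(community, module = "M1",
                                       noise_sd = 0.5, trait_name = "NCP",
                                       seed = 1) {
  mf <- community$truth$module_factors
  if (is.null(mf) || !module %in% colnames(mf))
    stop("community has no planted module '", module, "'")
  set.seed(seed)
  y <- mf[, module] + stats::rnorm(nrow(mf), 0, noise_sd)
  out <- data.frame(sample_id = rownames(mf), y)
  names(out)[2] <- trait_name
  out
}

#' Export a synthetic dataset as a plain-text fixture tree
#'
#' Writes per-year, per-marker count TSVs, the taxonomy, metadata and trait
#' tables, and the planted truth as JSON, in the canonical formats the
#' readers consume.
#'
#' @param community output of [generate_community()].
#' @param traits optional trait data.frame (`sample_id` + trait columns).
#' @param dir output directory.
#' @param force overwrite an existing non-empty directory.
#' @return `dir`, invisibly.
#' @export
export_fixture <- function(community, traits = NULL, dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force)
    stop("directory ", dir, " is not empty; use force = TRUE")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(m, file) {
    df <- data.frame(sample_id = rownames(m), as.data.frame(unclass(m)),
                     check.names = FALSE)
    utils::write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  for (yr in names(community$tables_16s))
    wr(community$tables_16s[[yr]], sprintf("counts_16S_%s.tsv", yr))
  for (yr in names(community$tables_18s))
    wr(community$tables_18s[[yr]], sprintf("counts_18S_%s.tsv", yr))
  utils::write.table(community$taxonomy, file.path(dir, "taxonomy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(community$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(traits))
    utils::write.table(traits, file.path(dir, "traits.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  truth <- community$truth
  if (!is.null(truth$precision_support)) {
    idx <- which(truth$precision_support, arr.ind = TRUE)
    truth$precision_edges <- data.frame(
      from = rownames(truth$precision_support)[idx[, 1]],
      to = colnames(truth$precision_support)[idx[, 2]],
      sign = truth$precision_sign[idx])
  }
  truth$precision_support <- NULL
  truth$precision_sign <- NULL
  truth$module_factors <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
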