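#' Select candidate ASVs from trait-positive modules
#'
#' Candidates are the member ASVs of modules showing a positive, significant
#' correlation with at least one biogeochemical trait — the modules whose
#' composition tracks productivity and organic-matter stocks.
#'
#' @param module_trait data.frame from [module_trait_correlation()].
#' @param partition `module_partition` supplying module membership.
#' @param alpha significance level (applied to raw p-values by default,
#'   matching the quoted-p reporting style; set `adjust = "BH"` for a
#'   Benjamini-Hochberg screen).
#' @param adjust p-value adjustment method (any [stats::p.adjust()] method).
#' @return Object of class `candidate_set`: list with `asv_ids`, `modules`,
#'   and `records` (the qualifying module/trait/r/p rows).
#' @export
select_candidate_modules <- function(module_trait, partition, alpha = 0.05,
                                     adjust = "none") {
  mt <- module_trait
  mt$p_adj <- stats::p.adjust(mt$p, method = adjust)
  qual <- mt[!is.na(mt$r) & mt$r > 0 & !is.na(mt$p_adj) & mt$p_adj < alpha, ,
             drop = FALSE]
  mods <- unique(qual$module)
  if (length(mods) == 0) {
    warning("no module passes the positive-correlation screen")
    return(structure(list(asv_ids = character(0), modules = character(0),
                          records = qual), class = "candidate_set"))
  }
  asvs <- names(partition$labels)[partition$labels %in% mods]
  structure(list(asv_ids = asvs, modules = mods, records = qual),
            class = "candidate_set")
}

#' First-degree neighbours of a candidate ASV
#'
#' All network edges incident to the candidate, annotated with the
#' neighbour's module label and marker domain, sorted by decreasing
#' symmetrised weight (ties broken lexicographically by neighbour id).
#'
#' @param net `sparse_network`.
#' @param candidate ASV id (must be a network node).
#' @param partition optional `module_partition`; neighbours without a module
#'   get label `"none"`.
#' @return data.frame with columns `candidate`, `neighbor`, `weight`,
#'   `weight_out` (candidate -> neighbour), `weight_in`, `module`, `domain`.
#' @export
first_degree_neighbors <- function(net, candidate, partition = NULL) {
  stopifnot(inherits(net, "sparse_network"))
  if (!candidate %in% net$nodes$asv_id)
    stop("candidate '", candidate, "' is not a network node")
  e <- net$edges
  hit <- e$from == candidate | e$to == candidate
  e <- e[hit, , drop = FALSE]
  if (nrow(e) == 0)
    return(data.frame(candidate = character(0), neighbor = character(0),
                      weight = numeric(0), weight_out = numeric(0),
                      weight_in = numeric(0), module = character(0),
                      domain = character(0), stringsAsFactors = FALSE))
  nb <- ifelse(e$from == candidate, e$to, e$from)
  w_out <- ifelse(e$from == candidate, e$weight_from_to, e$weight_to_from)
  w_in <- ifelse(e$from == candidate, e$weight_to_from, e$weight_from_to)
  mod <- rep("none", length(nb))
  if (!is.null(partition)) {
    known <- nb %in% names(partition$labels)
    mod[known] <- unname(partition$labels[nb[known]])
    mod[mod == "grey"] <- "none"
  }
  dom <- net$nodes$domain[match(nb, net$nodes$asv_id)]
  out <- data.frame(candidate = candidate, neighbor = nb, weight = e$weight,
                    weight_out = w_out, weight_in = w_in, module = mod,
                    domain = dom, stringsAsFactors = FALSE)
  out[order(-out$weight, out$neighbor), , drop = FALSE]
}

#' Cross-tabulate neighbour module membership by edge sign
#'
#' Counts, for the pooled neighbour tables of a candidate set, how often
#' positively and negatively weighted neighbours fall in the candidate's own
#' module, and reports a same-module enrichment odds ratio (positive vs
#' negative edges) with a permutation p-value obtained by shuffling the
#' neighbours' module labels.
#'
#' @param neighbors data.frame from [first_degree_neighbors()] (possibly
#'   row-bound over candidates).
#' @param partition `module_partition` giving each candidate's own module.
#' @param n_permutations label permutations.
#' @param seed integer seed.
#' @return list with `table` (counts: sign x same/other module), `odds_ratio`
#'   (NA when a margin is empty), `p_value`, `crosstab` (candidate module x
#'   neighbour module x sign counts).
#' @export
neighbor_module_crosstab <- function(neighbors, partition,
                                     n_permutations = 999, seed = 1) {
  if (nrow(neighbors) == 0)
    return(list(table = table(character(0)), odds_ratio = NA_real_,
                p_value = NA_real_, crosstab = NULL))
  cand_mod <- unname(partition$labels[neighbors$candidate])
  cand_mod[is.na(cand_mod)] <- "none"
  sign_lab <- ifelse(neighbors$weight > 0, "positive", "negative")
  same <- neighbors$module == cand_mod
  tab <- table(sign = factor(sign_lab, c("positive", "negative")),
               same_module = factor(same, c(TRUE, FALSE)))
  # Haldane-Anscombe continuity correction when a cell is empty; NA only
  # when one of the sign margins has no edges at all
  or_from <- function(same, sign_lab) {
    a <- sum(same & sign_lab == "positive")
    b <- sum(!same & sign_lab == "positive")
    c_ <- sum(same & sign_lab == "negative")
    d <- sum(!same & sign_lab == "negative")
    if ((a + b) == 0 || (c_ + d) == 0) return(NA_real_)
    if (min(a, b, c_, d) == 0) { a <- a + 0.5; b <- b + 0.5
                                 c_ <- c_ + 0.5; d <- d + 0.5 }
    (a / b) / (c_ / d)
  }
  or_obs <- or_from(same, sign_lab)
  p_val <- NA_real_
  if (is.finite(or_obs)) {
    set.seed(seed)
    perm <- vapply(seq_len(n_permutations), function(i) {
      or_from(sample(neighbors$module) == cand_mod, sign_lab)
    }, numeric(1))
    perm <- perm[is.finite(perm)]
    p_val <- (1 + sum(perm >= or_obs)) / (length(perm) + 1)
  }
  crosstab <- table(candidate_module = cand_mod,
                    neighbor_module = neighbors$module, sign = sign_lab)
  list(table = tab, odds_ratio = or_obs, p_value = p_val, crosstab = crosstab)
}

#' Check a known taxon-pair association in the network
#'
#' Resolves two taxon labels to ASV sets by case-insensitive substring match
#' against the taxonomy lineages, and reports whether any network edge links
#' the two sets — the pipeline's internal positive control (e.g. a
#' haptophyte host and its nitrogen-fixing cyanobacterial symbiont).
#'
#' @param net `sparse_network`.
#' @param taxonomy data.frame with `asv_id`, `lineage`.
#' @param label_a,label_b taxon labels (genus or any lineage substring).
#' @param partition optional `module_partition` for module annotation.
#' @return list with `edge_present`, `edges` (data.frame of linking edges
#'   with weights), `asvs_a`, `asvs_b`, `modules_a`, `modules_b`.
#' @export
check_known_association <- function(net, taxonomy, label_a, label_b,
                                    partition = NULL) {
  resolve <- function(lab) {
    hit <- grepl(lab, taxonomy$lineage, ignore.case = TRUE, fixed = FALSE)
    ids <- taxonomy$asv_id[hit]
    if (length(ids) == 0) stop("label '", lab, "' matches no ASV")
    ids
  }
  a <- resolve(label_a); b <- resolve(label_b)
  e <- net$edges
  link <- (e$from %in% a & e$to %in% b) | (e$from %in% b & e$to %in% a)
  mods <- function(ids) {
    if (is.null(partition)) return(character(0))
    unique(unname(partition$labels[intersect(ids, names(partition$labels))]))
  }
  list(edge_present = any(link),
       edges = e[link, , drop = FALSE],
       asvs_a = a, asvs_b = b,
       modules_a = mods(a), modules_b = mods(b))
}
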