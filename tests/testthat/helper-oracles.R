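# Independent brute-force oracles used to pin down the fast implementations.

bray_brute <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- sum(abs(m[i, ] - m[j, ])) / sum(m[i, ] + m[j, ])
  d
}

tom_brute <- function(a) {
  p <- nrow(a)
  k <- numeric(p)
  for (i in seq_len(p)) k[i] <- sum(a[i, -i])
  tom <- matrix(1, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(p)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

clr_brute <- function(m, pc = 1) {
  out <- m
  for (i in seq_len(nrow(m))) {
    lg <- log(m[i, ] + pc)
    out[i, ] <- lg - mean(lg)
  }
  out
}

# small community shared across test files (computed once)
.shared <- new.env(parent = emptyenv())
shared_community <- function() {
  if (is.null(.shared$com)) .shared$com <- generate_community(seed = 401)
  .shared$com
}

# per-year tables combining both markers (classify_persistence input)
combined_year_tables <- function(com) {
  tabs <- lapply(names(com$tables_16s), function(yr)
    asv_table(cbind(unclass(com$tables_16s[[yr]]),
                    unclass(com$tables_18s[[yr]])), "16S"))
  stats::setNames(tabs, names(com$tables_16s))
}

random_counts <- function(n, p, seed, max_count = 50) {
  set.seed(seed)
  m <- matrix(rpois(n * p, lambda = runif(p, 1, max_count)), n, p, byrow = TRUE)
  dimnames(m) <- list(paste0("s", seq_len(n)), paste0("a", seq_len(p)))
  m
}
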