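# shared fixtures, built in code

# default cohort, cached per seed so multiple tests can reuse it
cohort_cache <- new.env(parent = emptyenv())
get_cohort <- function(seed = 1, ...) {
  key <- paste0(seed, "_", paste(deparse(list(...)), collapse = ""))
  if (is.null(cohort_cache[[key]])) {
    cohort_cache[[key]] <- simulate_cohort(sim_config(...), seed = seed)
  }
  cohort_cache[[key]]
}

get_normalized <- function(seed = 1, ...) {
  key <- paste0("norm_", seed, "_", paste(deparse(list(...)), collapse = ""))
  if (is.null(cohort_cache[[key]])) {
    co <- get_cohort(seed, ...)
    cohort_cache[[key]] <- co$metabolites |> pq_normalize() |> log2_median_center()
  }
  cohort_cache[[key]]
}

# tiny deterministic log2-centered matrix
toy_matrix <- function(n = 8, p = 6, seed = 42) {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("m%02d", 1:p)))
  m <- sweep(m, 2L, apply(m, 2L, median))
  out <- as_metab_tbl(m, state = "raw")
  attr(out, "metab_state") <- "log2_centered"
  out
}

restate <- function(x, state) {
  attr(x, "metab_state") <- state
  x
}

# best-match Jaccard of each planted module against detected modules
module_jaccard <- function(truth_modules, detected) {
  mods <- sort(unique(truth_modules$module[!is.na(truth_modules$module)]))
  vapply(mods, function(mt) {
    mem <- truth_modules$metabolite[!is.na(truth_modules$module) &
                                      truth_modules$module == mt]
    best <- 0
    for (md in setdiff(unique(detected$module), "grey")) {
      dm <- detected$metabolite[detected$module == md]
      best <- max(best, length(intersect(mem, dm)) / length(union(mem, dm)))
    }
    best
  }, numeric(1))
}

adjusted_rand <- function(a, b) {
  # ARI from the pair-counting contingency table
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
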