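#' Partitioning around medoids
#'
#' Classic BUILD + SWAP k-medoids on distances between sample profiles.
#' BUILD seeds medoids greedily; SWAP repeatedly applies the single
#' medoid/non-medoid exchange with the largest cost decrease until no
#' exchange improves the total cost (sum of distances from each sample to
#' its medoid). The algorithm is deterministic; `seed` only randomises the
#' candidate order used to break exact cost ties.
#'
#' @param metabolites Intensity tibble in state `"log2_centered"`.
#' @param k Number of medoids, `2 <= k < n`.
#' @param seed Integer tie-break seed.
#' @param metric `"euclidean"` or `"correlation"` (1 - Pearson r).
#' @return List with `labels` (integer medoid assignment per sample),
#'   `medoid_ids` (sample ids), `cost`, and `cost_trace` (total cost after
#'   each SWAP pass, non-increasing).
#' @export
pam_fit <- function(metabolites, k, seed = 1,
                    metric = c("euclidean", "correlation")) {
  require_state(metabolites, "log2_centered", "pam_fit")
  d <- sample_distances(metab_values(metabolites), match.arg(metric))
  fit <- pam_core(d, k, seed)
  fit$medoid_ids <- rownames(d)[fit$medoids]
  fit
}

sample_distances <- function(m, metric = "euclidean") {
  d <- if (metric == "correlation") {
    1 - cor(t(m))
  } else {
    as.matrix(dist(m))
  }
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

pam_core <- function(d, k, seed = 1) {
  n <- nrow(d)
  if (k < 2 || k >= n) abort("k must satisfy 2 <= k < n_samples")
  set.seed(as.integer(seed))
  ord <- sample.int(n)                     # tie-break ordering only

  cost_of <- function(medoids) {
    sum(do.call(pmin, lapply(medoids, function(m) d[m, ])))
  }

  # BUILD: start from the 1-medoid minimiser, then greedy additions
  totals <- rowSums(d)
  medoids <- ord[which.min(totals[ord])]
  nearest <- d[medoids, ]
  while (length(medoids) < k) {
    best_gain <- -Inf
    best_h <- NA_integer_
    for (h in ord) {
      if (h %in% medoids) next
      gain <- sum(pmax(nearest - d[h, ], 0))
      if (gain > best_gain) {
        best_gain <- gain
        best_h <- h
      }
    }
    medoids <- c(medoids, best_h)
    nearest <- pmin(nearest, d[best_h, ])
  }

  # SWAP until no exchange lowers the cost
  cost <- cost_of(medoids)
  trace <- cost
  repeat {
    best_delta <- 0
    best_swap <- NULL
    for (m_i in seq_along(medoids)) {
      others <- medoids[-m_i]
      d_others <- if (length(others)) {
        do.call(pmin, lapply(others, function(m) d[m, ]))
      } else {
        rep(Inf, n)
      }
      for (h in ord) {
        if (h %in% medoids) next
        delta <- sum(pmin(d_others, d[h, ])) - cost
        if (delta < best_delta - 1e-12) {
          best_delta <- delta
          best_swap <- c(m_i, h)
        }
      }
    }
    if (is.null(best_swap)) break
    medoids[best_swap[1L]] <- best_swap[2L]
    new_cost <- cost_of(medoids)
    stopifnot(new_cost <= cost + 1e-9)     # SWAP never increases cost
    cost <- new_cost
    trace <- c(trace, cost)
  }

  labels <- apply(d[medoids, , drop = FALSE], 2L, which.min)
  list(labels = as.integer(labels), medoids = medoids,
       cost = cost, cost_trace = trace)
}

#' Per-sample silhouette widths
#'
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with `a(i)` the mean distance
#' to the sample's own cluster (excluding itself) and `b(i)` the smallest
#' mean distance to any other cluster. Samples in singleton clusters get
#' `s(i) = 0`.
#'
#' @param distances Symmetric distance matrix.
#' @param labels Cluster label per sample (>= 2 non-empty clusters).
#' @return Numeric vector of widths in [-1, 1].
#' @export
silhouette_widths <- function(distances, labels) {
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2L) abort("silhouette needs at least 2 clusters")
  n <- length(labels)
  sizes <- tabulate(labels)
  vapply(seq_len(n), function(i) {
    own <- labels[i]
    if (sizes[own] == 1L) return(0)
    a <- sum(distances[i, labels == own]) / (sizes[own] - 1L)
    b <- min(vapply(setdiff(unique(labels), own), function(g) {
      mean(distances[i, labels == g])
    }, numeric(1)))
    if (a == 0 && b == 0) return(0)
    (b - a) / max(a, b)
  }, numeric(1))
}

#' Silhouette-guided cluster number selection
#'
#' Runs PAM for every `k` in `k_range`, scores each partition by its mean
#' silhouette width, and keeps the `k` with the largest mean width
#' (smallest `k` on ties). Samples with negative silhouette width are
#' flagged as non-core; downstream signature extraction uses core samples
#' only.
#'
#' @inheritParams pam_fit
#' @param k_range Candidate cluster numbers (default 2:12).
#' @return Object of class `"metab_clust"`: `k_selected`, `samples`
#'   (tibble with `sample_id`, `cluster`, `silhouette`, `core`),
#'   `mean_silhouette_by_k`, `medoid_ids`, `cost`.
#' @examples
#' cohort <- simulate_cohort(sim_config(), seed = 1)
#' clust <- cohort$metabolites |>
#'   pq_normalize() |>
#'   log2_median_center() |>
#'   top_variable(100) |>
#'   select_k(seed = 1)
#' clust$k_selected
#' @export
select_k <- function(metabolites, k_range = 2:12, seed = 1,
                     metric = c("euclidean", "correlation")) {
  require_state(metabolites, "log2_centered", "select_k")
  m <- metab_values(metabolites)
  d <- sample_distances(m, match.arg(metric))
  if (max(d) == 0) {
    abort("degenerate input: all samples identical, clustering undefined")
  }
  k_range <- k_range[k_range >= 2 & k_range < nrow(m)]
  if (!length(k_range)) abort("k_range empty after restriction to 2 <= k < n")

  fits <- map(k_range, function(k) {
    fit <- pam_core(d, k, seed)
    fit$silhouette <- silhouette_widths(d, fit$labels)
    fit
  })
  mean_sil <- map_dbl(fits, function(f) mean(f$silhouette))
  best <- which(mean_sil == max(mean_sil))[1L]   # ties -> smallest k
  fit <- fits[[best]]

  structure(
    list(
      k_selected = k_range[best],
      samples = tibble(
        sample_id = rownames(m),
        cluster = fit$labels,
        silhouette = fit$silhouette,
        core = fit$silhouette >= 0
      ),
      mean_silhouette_by_k = tibble(k = k_range, mean_silhouette = mean_sil),
      medoid_ids = rownames(m)[fit$medoids],
      cost = fit$cost,
      seed = as.integer(seed)
    ),
    class = "metab_clust"
  )
}

#' Re-cluster the samples of one cluster
#'
#' Restricts the matrix to the samples assigned to `cluster_id` and runs
#' [select_k()] there — the step that splits the second metabolic cluster
#' into its two subclusters.
#'
#' @param metabolites Intensity tibble in state `"log2_centered"`.
#' @param clust A `"metab_clust"` result on the same samples.
#' @param cluster_id Which cluster to split.
#' @inheritParams select_k
#' @return A `"metab_clust"` object on the subset.
#' @export
subcluster <- function(metabolites, clust, cluster_id, k_range = 2:12,
                       seed = 1) {
  keep <- clust$samples$sample_id[clust$samples$cluster == cluster_id]
  if (length(keep) < 3L) abort("cluster too small to subcluster")
  sub <- metabolites[metabolites$sample_id %in% keep, , drop = FALSE]
  attr(sub, "metab_state") <- metab_state(metabolites)
  select_k(sub, k_range = k_range, seed = seed)
}

#' @export
print.metab_clust <- function(x, ...) {
  cat(sprintf("<metab_clust> k = %d, mean silhouette %.3f, %d/%d core samples\n",
              x$k_selected,
              x$mean_silhouette_by_k$mean_silhouette[
                x$mean_silhouette_by_k$k == x$k_selected],
              sum(x$samples$core), nrow(x$samples)))
  print(table(cluster = x$samples$cluster))
  invisible(x)
}
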