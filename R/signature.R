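#' Nearest-shrunken-centroid signature
#'
#' Fits the standard nearest-shrunken-centroid model: per-metabolite class
#' centroid contrasts `d_ik = (class mean - overall mean) / (m_k (s_i +
#' s0))` are soft-thresholded by `delta`, and the shrinkage threshold is
#' chosen by cross-validation as the largest `delta` whose CV
#' misclassification rate is within one standard error of the minimum.
#' `s_i` is the pooled within-class standard deviation, `m_k =
#' sqrt(1/n_k - 1/n)`, and `s0` is the median of the `s_i` (a standard
#' stabilising offset). The signature is the set of metabolites with any
#' nonzero shrunken contrast at the chosen `delta`.
#'
#' @param metabolites Intensity tibble in state `"log2_centered"`.
#' @param labels Class label per sample (>= 2 classes, each with >= 2
#'   samples); typically core-sample cluster labels.
#' @param delta_grid Shrinkage grid; default 30 values from 0 to the
#'   largest absolute contrast.
#' @param cv_folds Cross-validation folds (reduced with a warning when the
#'   smallest class has fewer members).
#' @param seed Integer seed for fold assignment.
#' @return Object of class `"nsc_signature"`: `delta` (chosen threshold),
#'   `s0`, `centroids` (tibble of shrunken class centroids), `contrasts`
#'   (tibble of `d_ik` and shrunken values), `selected` (tibble
#'   `metabolite`, `class`, `shrunken_d`), `cv` (tibble `delta`,
#'   `cv_error`, `se`).
#' @export
shrunken_centroid_signature <- function(metabolites, labels,
                                        delta_grid = NULL, cv_folds = 10,
                                        seed = 1) {
  require_state(metabolites, "log2_centered", "shrunken_centroid_signature")
  x <- metab_values(metabolites)
  labels <- factor(labels)
  if (nlevels(labels) < 2L) abort("need at least 2 classes")
  if (any(table(labels) < 2L)) abort("each class needs at least 2 samples")

  stats <- nsc_stats(x, labels)
  if (is.null(delta_grid)) {
    delta_grid <- seq(0, max(abs(stats$d)), length.out = 30)
  }

  min_class <- min(table(labels))
  folds <- cv_folds
  if (min_class < cv_folds) {
    folds <- max(2L, min_class)
    warn(sprintf("smallest class has %d members; using %d CV folds",
                 min_class, folds))
  }
  set.seed(as.integer(seed))
  fold_of <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    fold_of[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }

  cv_err <- vapply(delta_grid, function(delta) {
    wrong <- 0L
    for (f in seq_len(folds)) {
      train <- fold_of != f
      st <- nsc_stats(x[train, , drop = FALSE], droplevels(labels[train]))
      pred <- nsc_classify(x[!train, , drop = FALSE], st, delta)
      wrong <- wrong + sum(pred != as.character(labels[!train]))
    }
    wrong / length(labels)
  }, numeric(1))
  se <- sqrt(cv_err * (1 - cv_err) / length(labels))
  within <- cv_err <= min(cv_err) + se[which.min(cv_err)]
  delta <- max(delta_grid[within])

  shrunk <- soft_threshold_d(stats, delta)
  sel <- which(abs(shrunk$d_shrunk) > 0, arr.ind = TRUE)
  selected <- tibble(
    metabolite = rownames(shrunk$d_shrunk)[sel[, 1L]],
    class = colnames(shrunk$d_shrunk)[sel[, 2L]],
    shrunken_d = shrunk$d_shrunk[sel]
  ) |> arrange(.data$class, desc(abs(.data$shrunken_d)))

  structure(
    list(delta = delta, s0 = stats$s0,
         centroids = as_tibble(shrunk$centroids, rownames = "metabolite"),
         contrasts = as_tibble(stats$d, rownames = "metabolite"),
         selected = selected,
         cv = tibble(delta = delta_grid, cv_error = cv_err, se = se),
         stats = stats),
    class = "nsc_signature"
  )
}

nsc_stats <- function(x, labels) {
  labels <- factor(labels)
  n <- nrow(x)
  K <- nlevels(labels)
  n_k <- table(labels)
  overall <- colMeans(x)
  centroids <- t(vapply(levels(labels), function(cl) {
    colMeans(x[labels == cl, , drop = FALSE])
  }, numeric(ncol(x))))
  within_ss <- Reduce(`+`, lapply(levels(labels), function(cl) {
    xs <- x[labels == cl, , drop = FALSE]
    colSums(sweep(xs, 2L, colMeans(xs))^2)
  }))
  s <- sqrt(within_ss / (n - K))
  s0 <- median(s)
  m_k <- sqrt(1 / as.numeric(n_k) - 1 / n)
  d <- (t(centroids) - overall) / outer(s + s0, m_k)   # metabolite x class
  dimnames(d) <- list(colnames(x), levels(labels))
  list(overall = overall, centroids = centroids, s = s, s0 = s0,
       m_k = m_k, d = d, prior = as.numeric(n_k) / n,
       classes = levels(labels))
}

soft_threshold_d <- function(stats, delta) {
  d_shrunk <- sign(stats$d) * pmax(abs(stats$d) - delta, 0)
  # metabolite x class, xbar'_ik = xbar_i + m_k (s_i + s0) d'_ik
  centroids <- stats$overall + d_shrunk * outer(stats$s + stats$s0, stats$m_k)
  dimnames(centroids) <- dimnames(stats$d)
  list(d_shrunk = d_shrunk, centroids = centroids)
}

nsc_classify <- function(xnew, stats, delta) {
  shrunk <- soft_threshold_d(stats, delta)
  scale2 <- (stats$s + stats$s0)^2
  scores <- vapply(seq_along(stats$classes), function(k) {
    cent <- shrunk$centroids[, k]
    rowSums(sweep(xnew, 2L, cent)^2 / matrix(scale2, nrow(xnew),
                                             length(scale2), byrow = TRUE)) -
      2 * log(stats$prior[k])
  }, numeric(nrow(xnew)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  stats$classes[apply(scores, 1L, which.min)]
}

#' Per-metabolite linear-model signature
#'
#' The generalized-linear-model route to cluster signatures: for each
#' metabolite, an ordinary least-squares fit of the centred log2 intensity
#' on a two-class indicator; the two-sided p-value of the slope is
#' Benjamini-Hochberg adjusted across metabolites. With more than two
#' classes each class is contrasted one-vs-rest.
#'
#' @param metabolites Intensity tibble in state `"log2_centered"`.
#' @param labels Class label per sample.
#' @param alpha Adjusted-p significance cutoff (default 0.05).
#' @return Tibble with `metabolite`, `class`, `estimate` (class mean minus
#'   rest mean), `statistic`, `p_value`, `p_adj`, `significant`,
#'   `zero_variance`.
#' @export
glm_signature <- function(metabolites, labels, alpha = 0.05) {
  require_state(metabolites, "log2_centered", "glm_signature")
  x <- metab_values(metabolites)
  labels <- factor(labels)
  if (nlevels(labels) < 2L) abort("need at least 2 classes")
  classes <- if (nlevels(labels) == 2L) levels(labels)[2L] else levels(labels)

  out <- list_rbind(map(classes, function(cl) {
    g <- as.numeric(labels == cl)
    n <- length(g)
    n1 <- sum(g)
    n0 <- n - n1
    m1 <- colMeans(x[g == 1, , drop = FALSE])
    m0 <- colMeans(x[g == 0, , drop = FALSE])
    ss <- colSums(sweep(x[g == 1, , drop = FALSE], 2L, m1)^2) +
      colSums(sweep(x[g == 0, , drop = FALSE], 2L, m0)^2)
    zero_var <- ss == 0 & m1 == m0
    sigma2 <- ss / (n - 2)
    se <- sqrt(sigma2 * (1 / n1 + 1 / n0))
    tstat <- ifelse(se > 0, (m1 - m0) / se, 0)
    p <- ifelse(se > 0, 2 * pt(-abs(tstat), df = n - 2), 1)
    tibble(metabolite = colnames(x), class = cl,
           estimate = unname(m1 - m0), statistic = unname(tstat),
           p_value = unname(p), zero_variance = unname(zero_var))
  }))
  out |>
    group_by(.data$class) |>
    mutate(p_adj = p.adjust(.data$p_value, method = "BH")) |>
    ungroup() |>
    mutate(significant = .data$p_adj <= alpha) |>
    arrange(.data$class, .data$p_value)
}
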