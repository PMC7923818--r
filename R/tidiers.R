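#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a clustering result
#'
#' @param x A `"metab_clust"` object from [select_k()].
#' @param ... Unused.
#' @return Per-sample tibble `sample_id`, `cluster`, `silhouette`, `core`.
#' @method tidy metab_clust
#' @export
tidy.metab_clust <- function(x, ...) x$samples

#' @rdname tidy.metab_clust
#' @return `glance()` returns a one-row model summary.
#' @method glance metab_clust
#' @export
glance.metab_clust <- function(x, ...) {
  tibble(
    k_selected = x$k_selected,
    mean_silhouette = x$mean_silhouette_by_k$mean_silhouette[
      x$mean_silhouette_by_k$k == x$k_selected],
    n_samples = nrow(x$samples),
    n_core = sum(x$samples$core),
    cost = x$cost
  )
}

#' Tidy a WCNA result
#'
#' @param x A `"metab_wcna"` object from [run_wcna()].
#' @param what `"modules"` (default), `"trait_stats"`, `"kme"` or
#'   `"hubs"`.
#' @param ... Unused.
#' @return The requested component as a tibble.
#' @method tidy metab_wcna
#' @export
tidy.metab_wcna <- function(x, what = c("modules", "trait_stats", "kme",
                                        "hubs"), ...) {
  what <- match.arg(what)
  switch(what,
         modules = x$module_of,
         trait_stats = x$trait_stats %||%
           tibble(module = character(), trait = character(), r = numeric(),
                  p_value = numeric(), p_adj = numeric()),
         kme = x$kme,
         hubs = x$hubs)
}

#' @rdname tidy.metab_wcna
#' @method glance metab_wcna
#' @export
glance.metab_wcna <- function(x, ...) {
  mods <- setdiff(unique(x$module_of$module), "grey")
  tibble(beta = x$beta,
         n_modules = length(mods),
         n_grey = sum(x$module_of$module == "grey"),
         max_scale_free_r2 = max(x$fits$r_squared))
}

#' Tidy a log-rank comparison
#'
#' @param x A `"metab_logrank"` object from [log_rank()].
#' @param ... Unused.
#' @return The per-group Kaplan-Meier curves as a tibble.
#' @method tidy metab_logrank
#' @export
tidy.metab_logrank <- function(x, ...) x$curves

#' @rdname tidy.metab_logrank
#' @method glance metab_logrank
#' @export
glance.metab_logrank <- function(x, ...) {
  tibble(statistic = x$chisq, df = 1, p_value = x$p_value,
         observed_1 = x$observed[1L], expected_1 = x$expected[1L])
}

#' Tidy a shrunken-centroid signature
#'
#' @param x An `"nsc_signature"` object.
#' @param ... Unused.
#' @return The selected metabolites with their shrunken contrasts.
#' @method tidy nsc_signature
#' @export
tidy.nsc_signature <- function(x, ...) x$selected

#' @rdname tidy.nsc_signature
#' @method glance nsc_signature
#' @export
glance.nsc_signature <- function(x, ...) {
  tibble(delta = x$delta, s0 = x$s0,
         n_selected = length(unique(x$selected$metabolite)),
         cv_error = x$cv$cv_error[which.min(abs(x$cv$delta - x$delta))])
}

#' Silhouette plot of a clustering result
#'
#' Per-sample silhouette widths grouped by cluster, with non-core
#' (negative-width) samples visible below zero, plus the mean-silhouette
#' profile over the candidate k.
#'
#' @param object A `"metab_clust"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot metab_clust
#' @export
autoplot.metab_clust <- function(object, ...) {
  df <- object$samples |>
    arrange(.data$cluster, desc(.data$silhouette)) |>
    mutate(idx = dplyr::row_number(), cluster = factor(.data$cluster))
  ggplot(df, aes(x = .data$idx, y = .data$silhouette,
                 fill = .data$cluster)) +
    geom_col(width = 1) +
    geom_hline(yintercept = 0, linewidth = 0.3) +
    labs(x = "sample (ordered within cluster)", y = "silhouette width s(i)",
         fill = "cluster",
         title = sprintf("PAM, k = %d", object$k_selected)) +
    theme_minimal()
}

#' Module-trait heatmap
#'
#' Tile map of module-trait correlations, annotated with BH-adjusted
#' p-values.
#'
#' @param object A `"metab_wcna"` object with trait statistics.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot metab_wcna
#' @export
autoplot.metab_wcna <- function(object, ...) {
  ts <- object$trait_stats
  if (is.null(ts)) abort("no trait statistics; run run_wcna() with clinical data")
  ggplot(ts, aes(x = .data$trait, y = .data$module, fill = .data$r)) +
    geom_tile() +
    geom_text(aes(label = sprintf("%.2f\n(%.2g)", .data$r, .data$p_adj)),
              size = 2.4) +
    scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B",
                         limits = c(-1, 1)) +
    labs(x = NULL, y = NULL, fill = "R") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Kaplan-Meier curves for a log-rank comparison
#'
#' @param object A `"metab_logrank"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot metab_logrank
#' @export
autoplot.metab_logrank <- function(object, ...) {
  ggplot(object$curves, aes(x = .data$time, y = .data$estimate,
                            colour = .data$group)) +
    geom_step() +
    coord_cartesian(ylim = c(0, 1)) +
    labs(x = "time (months)", y = "progression-free survival S(t)",
         colour = "cluster",
         subtitle = sprintf("log-rank p = %.4g", object$p_value)) +
    theme_minimal()
}
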