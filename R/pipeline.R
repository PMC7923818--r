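#' Read and write metabolite intensity tables
#'
#' Tables are TSV or CSV (delimiter auto-detected) with the sample id in
#' the first column and one metabolite per remaining column. The
#' processing-state flag survives a round trip through a JSON sidecar
#' (`<path>.meta.json`); a table without a sidecar loads as `"raw"`.
#'
#' @param path File path.
#' @param x Intensity tibble ([as_metab_tbl()]).
#' @return `read_metabolite_table()` a validated intensity tibble;
#'   `write_metabolite_table()` the path, invisibly.
#' @export
read_metabolite_table <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  first <- readr::read_lines(path, n_max = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, name_repair = "minimal")
  probs <- readr::problems(tbl)
  if (nrow(probs)) {
    abort(sprintf("parse error at line %d: %s", probs$row[1L] + 1L,
                  probs$expected[1L]))
  }
  nm <- names(tbl)[-1L]
  if (anyDuplicated(nm)) {
    abort(paste0("duplicate metabolite column: ", nm[duplicated(nm)][1L]))
  }
  state <- "raw"
  sidecar <- paste0(path, ".meta.json")
  if (file.exists(sidecar)) {
    state <- jsonlite::read_json(sidecar)$state %||% "raw"
  }
  as_metab_tbl(tbl, state = state)
}

#' @rdname read_metabolite_table
#' @export
write_metabolite_table <- function(x, path) {
  validate_metab_tbl(x)
  readr::write_tsv(x, path)
  jsonlite::write_json(list(state = metab_state(x)),
                       paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

# subset samples, keeping the state flag
filter_samples <- function(metabolites, ids) {
  out <- metabolites[metabolites$sample_id %in% ids, , drop = FALSE]
  attr(out, "metab_state") <- metab_state(metabolites)
  out
}

# deterministic per-stage seed fork, kept below 2^31
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) * 7919L + h) %% .Machine$integer.max
}

#' Run the full subtyping pipeline
#'
#' Normalisation (pseudo-counted quantile + log2 median-centre), top-100
#' PAM clustering with silhouette-selected k and a subcluster pass on the
#' larger cluster, shrunken-centroid and linear-model signatures on the
#' core samples, weighted correlation network analysis with module-trait
#' statistics, metabolite-set enrichment (ORA on the signature, QEA on
#' the cluster labels), the clinical characteristics table, and the
#' progression-free-survival log-rank comparison. One seed drives every
#' stochastic stage through deterministic per-stage forks.
#'
#' @param metabolites Raw-state intensity tibble.
#' @param clinical Clinical tibble with `cluster`-comparable covariates
#'   and `pfs_time` / `pfs_event`.
#' @param top_n Metabolites kept for clustering (default 100).
#' @param k_range Candidate cluster numbers (default 2:12).
#' @param sets Metabolite set library for enrichment.
#' @param n_perm QEA permutations.
#' @param alpha Significance cutoff for the linear-model signature.
#' @param seed Integer master seed.
#' @param out_dir Optional directory; when given, stage artifacts
#'   (normalised matrix, cluster result, trait and enrichment tables, KM
#'   curves, manifest) are written there.
#' @inheritParams run_wcna
#' @return Object of class `"menmetab_run"`: `clustering`, `subclusters`,
#'   `signature_nsc`, `signature_glm`, `wcna`, `ora`, `qea`,
#'   `cohort_table`, `survival`, `normalized`, `manifest`.
#' @export
run_all <- function(metabolites, clinical, top_n = 100, k_range = 2:12,
                    beta_grid = 1:20, target_r2 = 0.8, beta_min = 5,
                    cut_height = 0.975, min_size = 5, merge_cor = 0.9,
                    sets = builtin_metabolite_sets(), n_perm = 1000,
                    alpha = 0.05, seed = 1, out_dir = NULL) {
  if (missing(clinical) || is.null(clinical)) {
    abort("clinical table is required before any computation starts")
  }
  if (!all(metabolites$sample_id %in% clinical$sample_id)) {
    abort("clinical table does not cover all samples")
  }
  clinical <- clinical[match(metabolites$sample_id, clinical$sample_id), ]
  seeds <- list(cluster = stage_seed(seed, "cluster"),
                subcluster = stage_seed(seed, "subcluster"),
                signature = stage_seed(seed, "signature"),
                qea = stage_seed(seed, "qea"))

  normalized <- metabolites |> pq_normalize() |> log2_median_center()
  top <- top_variable(normalized, n = min(top_n, ncol(normalized) - 1L))

  clustering <- select_k(top, k_range = k_range, seed = seeds$cluster)
  labels <- clustering$samples$cluster

  subclusters <- NULL
  big <- as.integer(names(which.max(table(labels))))
  subclusters <- tryCatch(
    subcluster(top, clustering, big, k_range = k_range,
               seed = seeds$subcluster),
    error = function(e) NULL
  )

  core <- clustering$samples$core
  core_ids <- clustering$samples$sample_id[core]
  core_top <- filter_samples(top, core_ids)
  core_labels <- labels[core]
  signature_nsc <- tryCatch(
    shrunken_centroid_signature(core_top, core_labels,
                                seed = seeds$signature),
    error = function(e) {
      warn(paste0("signature stage skipped: ", conditionMessage(e)))
      NULL
    })
  signature_glm <- tryCatch(
    glm_signature(core_top, core_labels, alpha = alpha),
    error = function(e) NULL)

  wcna <- run_wcna(normalized, clinical, beta_grid = beta_grid,
                   target_r2 = target_r2, beta_min = beta_min,
                   cut_height = cut_height, min_size = min_size,
                   merge_cor = merge_cor)

  universe <- names(normalized)[-1L]
  selected <- unique(signature_nsc$selected$metabolite)
  ora_res <- if (length(selected)) ora(selected, sets, universe)
  qea_res <- if (length(unique(labels)) == 2L) {
    qea(normalized, labels, sets, n_perm = n_perm, seed = seeds$qea)
  }

  clin_table <- tryCatch(cohort_table(clinical, labels),
                         error = function(e) NULL)
  surv <- tryCatch(
    log_rank(clinical$pfs_time, clinical$pfs_event, labels),
    error = function(e) NULL)

  manifest <- list(
    parameters = list(top_n = top_n, k_range = range(k_range),
                      beta_grid = range(beta_grid), target_r2 = target_r2,
                      cut_height = cut_height, min_size = min_size,
                      merge_cor = merge_cor, n_perm = n_perm, alpha = alpha),
    seed = as.integer(seed), stage_seeds = seeds,
    n_samples = nrow(metabolites), n_metabolites = ncol(metabolites) - 1L
  )

  run <- structure(
    list(clustering = clustering, subclusters = subclusters,
         signature_nsc = signature_nsc, signature_glm = signature_glm,
         wcna = wcna, ora = ora_res, qea = qea_res,
         cohort_table = clin_table, survival = surv,
         normalized = normalized, manifest = manifest),
    class = "menmetab_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_metabolite_table(run$normalized, file.path(out_dir, "normalized.tsv"))
  jsonlite::write_json(
    list(k_selected = run$clustering$k_selected,
         samples = run$clustering$samples,
         mean_silhouette_by_k = run$clustering$mean_silhouette_by_k,
         manifest = run$manifest),
    file.path(out_dir, "cluster.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "columns"
  )
  if (!is.null(run$wcna$trait_stats)) {
    readr::write_tsv(run$wcna$trait_stats,
                     file.path(out_dir, "module_trait.tsv"))
  }
  if (!is.null(run$ora)) {
    readr::write_tsv(run$ora, file.path(out_dir, "enrichment_ora.tsv"))
  }
  if (!is.null(run$qea)) {
    readr::write_tsv(run$qea, file.path(out_dir, "enrichment_qea.tsv"))
  }
  if (!is.null(run$cohort_table)) {
    readr::write_tsv(run$cohort_table, file.path(out_dir, "cohort_table.tsv"))
  }
  if (!is.null(run$survival)) {
    readr::write_csv(run$survival$curves, file.path(out_dir, "km_curves.csv"))
  }
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.menmetab_run <- function(x, ...) {
  cat("<menmetab_run>\n")
  cat(sprintf("  clustering: k = %d (%d/%d core)\n",
              x$clustering$k_selected, sum(x$clustering$samples$core),
              nrow(x$clustering$samples)))
  n_mod <- length(setdiff(unique(x$wcna$module_of$module), "grey"))
  cat(sprintf("  wcna: beta = %d, %d modules\n", x$wcna$beta, n_mod))
  if (!is.null(x$survival)) {
    cat(sprintf("  survival: log-rank chisq = %.2f, p = %.4g\n",
                x$survival$chisq, x$survival$p_value))
  }
  invisible(x)
}
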