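#' Built-in metabolite set library
#'
#' A small pathway library over the named compounds of the default panel:
#' glycine/serine/threonine metabolism, glutamate metabolism, tryptophan
#' metabolism, choline/glycerophospholipid metabolism, sphingolipid
#' metabolism and glycolysis. Sets can also be read from GMT-style text
#' with [read_gmt()].
#'
#' @return Named list of character vectors.
#' @export
builtin_metabolite_sets <- function() {
  list(
    glycine_serine_threonine_metabolism =
      c("glycine", "serine", "threonine", "sarcosine", "betaine",
        "creatine", "arginine"),
    glutamate_metabolism =
      c("glutamate", "glutamine", "gaba", "alpha_ketoglutarate", "proline"),
    tryptophan_metabolism =
      c("tryptophan", "kynurenine", "kynurenic_acid", "serotonin",
        "indole_3_acetate"),
    choline_glycerophospholipid_metabolism =
      c("choline", "phosphocholine", "glycerophosphocholine",
        "ethanolamine", "phosphoethanolamine"),
    sphingolipid_metabolism =
      c("sphingosine", "sphinganine", "ceramide",
        "sphingosine_1_phosphate"),
    glycolysis =
      c("glucose", "lactate", "pyruvate", "phosphoenolpyruvate",
        "fructose_1_6_bisphosphate", "alanine")
  )
}

#' Read / write GMT-style set libraries
#'
#' One set per line: name, description, then tab-separated members.
#'
#' @param path File path.
#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector of set descriptions.
#' @return `read_gmt()` a named list; `write_gmt()` the path, invisibly.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  out <- map(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) abort("GMT line needs name, description, members")
    parts[-(1:2)]
  })
  names(out) <- map_chr(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L]
  })
  out
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("", length(sets))
  lines <- map_chr(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  })
  readr::write_lines(lines, path)
  invisible(path)
}

#' Over-representation analysis (ORA)
#'
#' For each metabolite set, tests whether the selected metabolites (for
#' example a cluster signature) contain more set members than expected by
#' chance: upper-tail hypergeometric `P(X >= k)` given `k` hits among `n`
#' selected, set size `K` and universe size `N`, with enrichment score
#' `ES = (k/n) / (K/N)` (observed over expected hit rate) and
#' Benjamini-Hochberg adjustment across sets. Sets with no member in the
#' universe are dropped.
#'
#' @param selected Character vector of selected metabolites (subset of
#'   `universe`, non-empty).
#' @param sets Named list of metabolite sets (default
#'   [builtin_metabolite_sets()]).
#' @param universe All quantified metabolites.
#' @return Tibble `set`, `hits`, `set_size`, `selected_size`, `universe_size`,
#'   `es`, `p_value`, `p_adj`, ordered by p-value.
#' @export
ora <- function(selected, sets = builtin_metabolite_sets(), universe) {
  if (!length(selected)) abort("selected metabolite list is empty")
  extra <- setdiff(selected, universe)
  if (length(extra)) {
    abort(paste0("selected metabolites outside the universe: ",
                 paste(extra, collapse = ", ")))
  }
  n_sel <- length(unique(selected))
  n_univ <- length(unique(universe))
  out <- list_rbind(imap(sets, function(members, name) {
    members <- intersect(members, universe)
    if (!length(members)) return(NULL)
    k <- length(intersect(selected, members))
    K <- length(members)
    tibble(
      set = name, hits = k, set_size = K,
      selected_size = n_sel, universe_size = n_univ,
      es = (k / n_sel) / (K / n_univ),
      p_value = phyper(k - 1, K, n_univ - K, n_sel, lower.tail = FALSE)
    )
  }))
  out$p_adj <- p.adjust(out$p_value, method = "BH")
  arrange(out, .data$p_value)
}

#' Quantitative enrichment analysis (QEA)
#'
#' A signature-free counterpart of [ora()]: each set is scored by the mean
#' absolute Welch t statistic of its member metabolites between the two
#' clusters, and significance comes from label permutations (`p =
#' (1 + #{perm >= observed}) / (1 + n_perm)`), BH-adjusted across sets.
#'
#' @param metabolites Intensity tibble in state `"log2_centered"`.
#' @param labels Two-group label per sample.
#' @param sets Named list of metabolite sets.
#' @param n_perm Number of label permutations (default 1000; below 100
#'   triggers a warning).
#' @param seed Integer seed.
#' @return Tibble `set`, `set_size`, `statistic`, `p_value`, `p_adj`.
#' @export
qea <- function(metabolites, labels, sets = builtin_metabolite_sets(),
                n_perm = 1000, seed = 1) {
  require_state(metabolites, "log2_centered", "qea")
  if (n_perm < 100) warn("fewer than 100 permutations; p-values are coarse")
  m <- metab_values(metabolites)
  labels <- factor(labels)
  if (nlevels(labels) != 2L) abort("qea needs exactly 2 groups")
  g <- labels == levels(labels)[1L]
  sets <- map(sets, intersect, colnames(m))
  sets <- sets[map_int(sets, length) > 0L]

  set.seed(as.integer(seed))
  obs <- set_stats(m, g, sets)
  exceed <- integer(length(sets))
  for (b in seq_len(n_perm)) {
    perm <- sample(g)
    exceed <- exceed + (set_stats(m, perm, sets) >= obs)
  }
  out <- tibble(
    set = names(sets),
    set_size = map_int(sets, length),
    statistic = obs,
    p_value = (1 + exceed) / (1 + n_perm)
  )
  out$p_adj <- p.adjust(out$p_value, method = "BH")
  arrange(out, .data$p_value)
}

# mean |Welch t| of member metabolites, vectorized over the matrix
set_stats <- function(m, g, sets) {
  t_all <- welch_t_columns(m, g)
  map_dbl(sets, function(members) mean(abs(t_all[members])))
}

welch_t_columns <- function(m, g) {
  x1 <- m[g, , drop = FALSE]
  x2 <- m[!g, , drop = FALSE]
  n1 <- nrow(x1)
  n2 <- nrow(x2)
  v1 <- apply(x1, 2L, var) / n1
  v2 <- apply(x2, 2L, var) / n2
  t_val <- (colMeans(x1) - colMeans(x2)) / sqrt(v1 + v2)
  t_val[!is.finite(t_val)] <- 0
  setNames(t_val, colnames(m))
}
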