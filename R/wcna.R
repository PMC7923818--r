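#' Soft-threshold power selection
#'
#' Builds the unsigned weighted adjacency `a_ij = |cor(x_i, x_j)|^beta`
#' for each candidate power and scores approximate scale-free topology by
#' the R^2 of the linear fit of `log10 p(k)` on `log10 k` over binned
#' connectivities `k_i = sum_j a_ij`. The selected power is the smallest
#' one reaching `target_r2`; if none does, the best-fitting power is
#' returned with a warning.
#'
#' @param metabolites Intensity tibble in state `"log2_centered"` with at
#'   least 10 metabolites. Constant metabolites are excluded with a
#'   warning.
#' @param beta_grid Candidate powers (default 1:20).
#' @param target_r2 Scale-free fit threshold (default 0.8).
#' @param beta_min Lower bound on the returned power (default 5). On
#'   cohorts of a few dozen samples the scale-free criterion is often met
#'   already at powers of 1-2, where the adjacency retains too little
#'   contrast between correlated modules and sampling noise for stable
#'   module separation; the floor keeps the network in the contrast
#'   regime the topological overlap step needs.
#' @param n_bins Connectivity histogram bins (default 10).
#' @return List with `beta` and `fits` (tibble `beta`, `r_squared`,
#'   `mean_connectivity`).
#' @export
soft_threshold <- function(metabolites, beta_grid = 1:20, target_r2 = 0.8,
                           beta_min = 5, n_bins = 10) {
  m <- wcna_matrix(metabolites)
  if (ncol(m) < 10L) abort("soft thresholding needs at least 10 metabolites")
  r <- abs(cor(m))
  diag(r) <- 0
  fits <- list_rbind(map(beta_grid, function(beta) {
    k <- rowSums(r^beta)
    tibble(beta = beta, r_squared = scale_free_r2(k, n_bins),
           mean_connectivity = mean(k))
  }))
  hit <- fits$beta[fits$r_squared >= target_r2]
  if (length(hit)) {
    beta <- hit[1L]
  } else {
    beta <- fits$beta[which.max(fits$r_squared)]
    warn(sprintf(
      "no power reached scale-free R^2 >= %.2f; using beta = %d (R^2 = %.2f)",
      target_r2, beta, max(fits$r_squared)))
  }
  beta <- max(beta, beta_min)
  list(beta = beta, fits = fits)
}

# signed scale-free fit index: R^2 of log10 p(k) ~ log10 k, negated when
# the slope is positive (a scale-free degree law must decay)
scale_free_r2 <- function(k, n_bins = 10) {
  cuts <- cut(k, breaks = n_bins)
  p_k <- tapply(k, cuts, length) / length(k)
  k_mean <- tapply(k, cuts, mean)
  keep <- !is.na(p_k) & p_k > 0 & k_mean > 0
  if (sum(keep) < 3L) return(0)
  fit <- lm(log10(p_k[keep]) ~ log10(k_mean[keep]))
  -sign(coef(fit)[2L]) * summary(fit)$r.squared
}

wcna_matrix <- function(metabolites) {
  require_state(metabolites, "log2_centered", "wcna")
  m <- metab_values(metabolites)
  const <- apply(m, 2L, function(v) var(v) == 0)
  if (any(const)) {
    warn(paste0("excluding constant metabolite(s): ",
                paste(colnames(m)[const], collapse = ", ")))
    m <- m[, !const, drop = FALSE]
  }
  m
}

#' Unsigned weighted adjacency
#'
#' @param metabolites Intensity tibble in state `"log2_centered"`.
#' @param beta Soft-threshold power.
#' @return Symmetric matrix `|cor|^beta` with zero diagonal.
#' @export
wcna_adjacency <- function(metabolites, beta) {
  m <- wcna_matrix(metabolites)
  a <- abs(cor(m))^beta
  diag(a) <- 0
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' `i != j`, with `TOM_ii = 1` — the shared-neighbour similarity used for
#' module detection.
#'
#' @param adjacency Symmetric adjacency with entries in [0, 1] and zero
#'   diagonal.
#' @return Symmetric TOM matrix with unit diagonal.
#' @export
topological_overlap <- function(adjacency) {
  if (!isSymmetric(unname(adjacency), tol = 1e-10)) {
    abort("adjacency must be symmetric")
  }
  if (any(adjacency < 0 | adjacency > 1)) abort("adjacency entries must lie in [0, 1]")
  a <- adjacency
  diag(a) <- 0
  l <- a %*% a
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Detect co-abundance modules
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity
#' `1 - TOM`, cut at a fixed height; clusters below `min_size` fall into
#' the unassigned "grey" pool, and modules whose eigengenes correlate
#' above `merge_cor` are merged iteratively until stable. Modules are
#' labelled `M1`, `M2`, ... in decreasing size order.
#'
#' @param tom TOM matrix from [topological_overlap()].
#' @param metabolites Intensity tibble (state `"log2_centered"`) used to
#'   compute eigengenes for the merge step.
#' @param cut_height Static tree-cut height on `1 - TOM` (default 0.975;
#'   with a few dozen samples topological overlap between even strongly
#'   correlated metabolites stays small, so branches sit high in the tree).
#' @param min_size Minimum module size (default 5).
#' @param merge_cor Eigengene correlation above which modules merge
#'   (default 0.9).
#' @return Tibble `metabolite`, `module` (`"grey"` = unassigned).
#' @export
detect_modules <- function(tom, metabolites, cut_height = 0.975,
                           min_size = 5, merge_cor = 0.9) {
  diss <- 1 - tom
  hc <- hclust(as.dist(diss), method = "average")
  raw <- cutree(hc, h = cut_height)
  sizes <- table(raw)
  raw[raw %in% as.integer(names(sizes[sizes < min_size]))] <- 0L

  m <- wcna_matrix(metabolites)[, colnames(tom), drop = FALSE]
  labels <- raw
  repeat {
    mods <- setdiff(unique(labels), 0L)
    if (length(mods) < 2L) break
    assign_tbl <- tibble(metabolite = colnames(tom),
                         module = ifelse(labels == 0L, NA, paste0("m", labels)))
    eg <- eigengene_matrix(m, assign_tbl)
    ec <- cor(eg)
    diag(ec) <- 0
    if (max(ec) <= merge_cor) break
    pair <- which(ec == max(ec), arr.ind = TRUE)[1L, ]
    from <- as.integer(sub("^m", "", colnames(ec)[pair[2L]]))
    to <- as.integer(sub("^m", "", colnames(ec)[pair[1L]]))
    labels[labels == from] <- to
  }

  mods <- setdiff(unique(labels), 0L)
  if (!length(mods)) {
    warn("no module passed the size threshold; all metabolites grey")
    return(tibble(metabolite = colnames(tom), module = "grey"))
  }
  by_size <- mods[order(-tabulate(match(labels, mods)), mods)]
  relabel <- setNames(paste0("M", seq_along(by_size)), by_size)
  tibble(
    metabolite = colnames(tom),
    module = ifelse(labels == 0L, "grey", unname(relabel[as.character(labels)]))
  )
}

# samples x modules eigengene matrix (internal; unit variance, oriented)
eigengene_matrix <- function(m, module_of) {
  mods <- sort(setdiff(unique(module_of$module), c(NA, "grey")))
  eg <- vapply(mods, function(mod) {
    members <- module_of$metabolite[!is.na(module_of$module) &
                                      module_of$module == mod]
    sub <- scale(m[, members, drop = FALSE])
    if (length(members) == 1L) {
      e <- sub[, 1L]
    } else {
      e <- svd(sub, nu = 1L, nv = 0L)$u[, 1L]
    }
    e <- e / sd(e)
    if (mean(cor(e, sub)) < 0) e <- -e
    e
  }, numeric(nrow(m)))
  rownames(eg) <- rownames(m)
  eg
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' standardized member submatrix (samples as observations), scaled to unit
#' variance and sign-oriented so that its mean correlation with the
#' members is positive. Singleton modules return the member's standardized
#' profile (flagged).
#'
#' @param metabolites Intensity tibble in state `"log2_centered"`.
#' @param module_of Tibble `metabolite`, `module` from [detect_modules()].
#' @return Tibble with `sample_id` and one column per module; attribute
#'   `"singleton_modules"` lists modules of size 1.
#' @export
module_eigengene <- function(metabolites, module_of) {
  m <- wcna_matrix(metabolites)
  mods <- setdiff(unique(module_of$module), c(NA, "grey"))
  sizes <- table(module_of$module[module_of$module %in% mods])
  singles <- names(sizes[sizes == 1L])
  if (length(singles)) {
    warn(paste0("singleton module(s), eigengene = standardized profile: ",
                paste(singles, collapse = ", ")))
  }
  eg <- eigengene_matrix(m, module_of)
  out <- bind_cols(tibble(sample_id = rownames(m)), as_tibble(eg))
  attr(out, "singleton_modules") <- singles
  out
}

#' Module membership (kME)
#'
#' Pearson correlation of every metabolite's profile with every module
#' eigengene. Zero-variance profiles get kME 0 and are flagged.
#'
#' @param metabolites Intensity tibble in state `"log2_centered"`.
#' @param eigengenes Tibble from [module_eigengene()].
#' @return Tibble `metabolite` plus one kME column per module; attribute
#'   `"zero_variance"` lists flagged metabolites.
#' @export
compute_kme <- function(metabolites, eigengenes) {
  require_state(metabolites, "log2_centered", "compute_kme")
  m <- metab_values(metabolites)
  eg <- as.matrix(eigengenes[-1L])
  zero_var <- apply(m, 2L, function(v) var(v) == 0)
  kme <- matrix(0, ncol(m), ncol(eg),
                dimnames = list(colnames(m), colnames(eg)))
  if (any(!zero_var)) {
    kme[!zero_var, ] <- cor(m[, !zero_var, drop = FALSE], eg)
  }
  if (any(zero_var)) {
    warn(paste0("zero-variance metabolite(s) get kME 0: ",
                paste(colnames(m)[zero_var], collapse = ", ")))
  }
  out <- bind_cols(tibble(metabolite = colnames(m)), as_tibble(kme))
  attr(out, "zero_variance") <- colnames(m)[zero_var]
  out
}

#' Module-trait statistics
#'
#' Correlates each module eigengene with each clinical trait: Pearson
#' (point-biserial for 0/1 indicators) correlation R, p-value from the t
#' transform at n - 2 df, and Benjamini-Hochberg adjustment across the
#' full module x trait grid. For binary traits a single-predictor
#' logistic regression of the trait on the eigengene is reported
#' alongside (coefficient and Wald p).
#'
#' @param eigengenes Tibble from [module_eigengene()].
#' @param clinical Clinical tibble (see [simulate_cohort()]); traits are
#'   derived as indicators for WHO grade I/II/III, high edema, male sex
#'   and each location, plus continuous age, size, MIB-1 and KPS.
#'   Constant traits are skipped with a warning.
#' @return Tibble `module`, `trait`, `r`, `p_value`, `p_adj`,
#'   `logistic_beta`, `logistic_p`.
#' @export
module_trait_stats <- function(eigengenes, clinical) {
  traits <- encode_traits(clinical[match(eigengenes$sample_id,
                                         clinical$sample_id), ])
  const <- vapply(traits, function(v) var(v, na.rm = TRUE) == 0, logical(1))
  if (any(const)) {
    warn(paste0("skipping constant trait(s): ",
                paste(names(traits)[const], collapse = ", ")))
    traits <- traits[!const]
  }
  eg <- as.matrix(eigengenes[-1L])
  n <- nrow(eg)
  out <- list_rbind(imap(traits, function(tv, tname) {
    binary <- all(tv %in% c(0, 1))
    list_rbind(map(colnames(eg), function(mod) {
      e <- eg[, mod]
      r <- cor(e, tv)
      tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
      lbeta <- lp <- NA_real_
      if (binary) {
        fit <- suppressWarnings(glm(tv ~ e, family = binomial()))
        cf <- summary(fit)$coefficients
        if (nrow(cf) >= 2L) {
          lbeta <- cf[2L, 1L]
          lp <- cf[2L, 4L]
        }
      }
      tibble(module = mod, trait = tname, r = r,
             p_value = 2 * pt(-abs(tstat), df = n - 2),
             logistic_beta = lbeta, logistic_p = lp)
    }))
  }))
  out$p_adj <- p.adjust(out$p_value, method = "BH")
  out[, c("module", "trait", "r", "p_value", "p_adj",
          "logistic_beta", "logistic_p")]
}

encode_traits <- function(clinical) {
  tr <- list()
  if ("who_grade" %in% names(clinical)) {
    for (g in c("I", "II", "III")) {
      tr[[paste0("grade_", g)]] <- as.numeric(clinical$who_grade == g)
    }
  }
  if ("edema" %in% names(clinical)) {
    tr$edema_high <- as.numeric(clinical$edema == "high")
  }
  if ("sex" %in% names(clinical)) {
    tr$sex_male <- as.numeric(clinical$sex == "male")
  }
  if ("location" %in% names(clinical)) {
    for (l in unique(clinical$location)) {
      tr[[paste0("location_", l)]] <- as.numeric(clinical$location == l)
    }
  }
  for (v in intersect(c("age", "size", "mib1", "kps_pre", "kps_post"),
                      names(clinical))) {
    tr[[v]] <- as.numeric(clinical[[v]])
  }
  tr
}

#' Hub metabolites per module
#'
#' Ranks each module's members by their kME to their own module and
#' returns the top `top_n` (ties broken by metabolite name).
#'
#' @param kme Tibble from [compute_kme()].
#' @param module_of Tibble from [detect_modules()].
#' @param top_n Hubs per module (default 3).
#' @return Tibble `module`, `metabolite`, `kme`, `rank`.
#' @export
hub_metabolites <- function(kme, module_of, top_n = 3) {
  mods <- setdiff(unique(module_of$module), c(NA, "grey"))
  list_rbind(map(sort(mods), function(mod) {
    members <- module_of$metabolite[module_of$module == mod]
    vals <- kme[[mod]][match(members, kme$metabolite)]
    ord <- order(-vals, members)
    keep <- head(ord, top_n)
    tibble(module = mod, metabolite = members[keep], kme = vals[keep],
           rank = seq_along(keep))
  }))
}

#' Cluster-of-clusters analysis
#'
#' Joint average-linkage hierarchical clustering, under correlation
#' distance `1 - r`, of the module eigengenes together with the
#' standardized metabolite profiles — so modules and metabolites with
#' matching sample patterns (equivalently, matching kME) fall into the
#' same branch. Flat groups are read off at `cut_height`.
#'
#' @param metabolites Intensity tibble in state `"log2_centered"`.
#' @param eigengenes Tibble from [module_eigengene()].
#' @param cut_height Flat-cut height on `1 - r` (default 0.5).
#' @return List with `order` (object names in dendrogram order), `groups`
#'   (tibble `object`, `type`, `group`) and the `hclust` tree.
#' @export
cluster_of_clusters <- function(metabolites, eigengenes, cut_height = 0.5) {
  m <- scale(wcna_matrix(metabolites))
  eg <- as.matrix(eigengenes[-1L])
  joint <- cbind(eg, m)
  colnames(joint) <- c(colnames(eg), colnames(m))
  d <- as.dist(1 - cor(joint))
  hc <- hclust(d, method = "average")
  groups <- cutree(hc, h = cut_height)
  list(
    order = colnames(joint)[hc$order],
    groups = tibble(
      object = names(groups),
      type = ifelse(names(groups) %in% colnames(eg), "module", "metabolite"),
      group = as.integer(groups)
    ),
    tree = hc
  )
}

#' Export the intramodular network
#'
#' Writes the intramodular edges (pairs of metabolites in the same module
#' with adjacency weight at or above `threshold`) as an edge-list tibble
#' and, optionally, GraphML and CSV files. Node attributes carry the
#' module and, when `kme` is given, the own-module kME.
#'
#' @param adjacency Adjacency matrix ([wcna_adjacency()]).
#' @param module_of Tibble from [detect_modules()].
#' @param threshold Minimum edge weight in [0, 1].
#' @param kme Optional kME tibble for node attributes.
#' @param graphml,edgelist Optional output file paths.
#' @return Tibble `source`, `target`, `weight`, `module` (invisibly also
#'   written to the requested files).
#' @export
export_network <- function(adjacency, module_of, threshold = 0.5,
                           kme = NULL, graphml = NULL, edgelist = NULL) {
  if (threshold < 0 || threshold > 1) abort("threshold must lie in [0, 1]")
  mods <- setdiff(unique(module_of$module), c(NA, "grey"))
  edges <- list_rbind(map(sort(mods), function(mod) {
    members <- intersect(module_of$metabolite[module_of$module == mod],
                         rownames(adjacency))
    if (length(members) < 2L) return(NULL)
    pairs <- combn(sort(members), 2L)
    w <- adjacency[cbind(pairs[1L, ], pairs[2L, ])]
    keep <- w >= threshold
    tibble(source = pairs[1L, keep], target = pairs[2L, keep],
           weight = w[keep], module = mod)
  }))
  if (is.null(edges) || ncol(edges) == 0L) {
    edges <- tibble(source = character(), target = character(),
                    weight = numeric(), module = character())
  }
  if (!is.null(edgelist)) readr::write_csv(edges, edgelist)
  if (!is.null(graphml)) {
    nodes <- module_of[module_of$module %in% mods, , drop = FALSE]
    nodes <- tibble(name = nodes$metabolite, module = nodes$module)
    if (!is.null(kme)) {
      nodes$kme <- map_dbl(seq_len(nrow(nodes)), function(i) {
        kme[[nodes$module[i]]][match(nodes$name[i], kme$metabolite)]
      })
    }
    g <- igraph::graph_from_data_frame(edges[1:3], directed = FALSE,
                                       vertices = nodes)
    igraph::write_graph(g, graphml, format = "graphml")
  }
  edges
}

#' Weighted correlation network analysis of a metabolite matrix
#'
#' End-to-end WCNA: soft-threshold power selection, adjacency and
#' topological overlap, module detection, eigengenes, kME, hubs, and —
#' when a clinical table is supplied — module-trait statistics.
#'
#' @inheritParams soft_threshold
#' @inheritParams detect_modules
#' @param clinical Optional clinical tibble for [module_trait_stats()].
#' @return Object of class `"metab_wcna"` with elements `beta`, `fits`,
#'   `module_of`, `eigengenes`, `kme`, `hubs`, `trait_stats` (NULL
#'   without clinical data) and `adjacency`.
#' @export
run_wcna <- function(metabolites, clinical = NULL, beta_grid = 1:20,
                     target_r2 = 0.8, beta_min = 5, cut_height = 0.975,
                     min_size = 5, merge_cor = 0.9) {
  st <- soft_threshold(metabolites, beta_grid, target_r2, beta_min)
  adj <- wcna_adjacency(metabolites, st$beta)
  tom <- topological_overlap(adj)
  module_of <- detect_modules(tom, metabolites, cut_height, min_size,
                              merge_cor)
  if (all(module_of$module == "grey")) {
    return(structure(list(beta = st$beta, fits = st$fits,
                          module_of = module_of, eigengenes = NULL,
                          kme = NULL, hubs = NULL, trait_stats = NULL,
                          adjacency = adj),
                     class = "metab_wcna"))
  }
  eigengenes <- module_eigengene(metabolites, module_of)
  kme <- compute_kme(metabolites, eigengenes)
  hubs <- hub_metabolites(kme, module_of)
  trait_stats <- if (!is.null(clinical)) {
    module_trait_stats(eigengenes, clinical)
  }
  structure(
    list(beta = st$beta, fits = st$fits, module_of = module_of,
         eigengenes = eigengenes, kme = kme, hubs = hubs,
         trait_stats = trait_stats, adjacency = adj),
    class = "metab_wcna"
  )
}

#' @export
print.metab_wcna <- function(x, ...) {
  n_mod <- length(setdiff(unique(x$module_of$module), "grey"))
  cat(sprintf("<metab_wcna> beta = %d, %d modules (%d metabolites grey)\n",
              x$beta, n_mod, sum(x$module_of$module == "grey")))
  invisible(x)
}
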