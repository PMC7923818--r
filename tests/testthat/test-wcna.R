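test_that("adjacency at power one equals absolute correlations", {
  set.seed(1)
  m <- matrix(rnorm(20 * 3), 20, 3,
              dimnames = list(sprintf("s%02d", 1:20), c("a", "b", "c")))
  tbl <- restate(as_metab_tbl(m), "log2_centered")
  a <- wcna_adjacency(tbl, beta = 1)
  r <- abs(cor(m))
  diag(r) <- 0
  expect_equal(a, r, tolerance = 1e-12)
  expect_true(all(a >= 0 & a <= 1))
})

test_that("soft threshold is reproducible and excludes constant metabolites", {
  norm <- get_normalized(1)
  a <- suppressWarnings(soft_threshold(norm))
  b <- suppressWarnings(soft_threshold(norm))
  expect_identical(a$fits, b$fits)
  expect_gte(a$beta, 5)   # floor for desk-scale cohorts
  v <- metab_values(norm)
  v[, 1] <- 0
  tbl <- restate(as_metab_tbl(v), "log2_centered")
  expect_warning(soft_threshold(tbl), "constant")
})

test_that("topological overlap matches hand and brute-force oracles", {
  # 3-node toy: all adjacencies 0.5
  a3 <- matrix(0.5, 3, 3)
  diag(a3) <- 0
  tom3 <- topological_overlap(a3)
  expect_equal(tom3[1, 2], (0.25 + 0.5) / (1 + 1 - 0.5), tolerance = 1e-12)
  # empty adjacency gives the identity
  expect_equal(topological_overlap(matrix(0, 4, 4)), diag(4))
  # random 8x8 matrices against a triple loop
  for (seed in 1:5) {
    set.seed(seed)
    a <- matrix(runif(64, 0, 0.9), 8, 8)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    tom <- topological_overlap(a)
    k <- rowSums(a)
    brute <- diag(8)
    for (i in 1:8) for (j in 1:8) {
      if (i == j) next
      l_ij <- sum(vapply(1:8, function(u) a[i, u] * a[u, j], numeric(1)))
      brute[i, j] <- (l_ij + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
    expect_equal(tom, brute, tolerance = 1e-12)
    expect_true(isSymmetric(tom))
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  }
  expect_error(topological_overlap(matrix(runif(9), 3, 3)), "symmetric")
})

test_that("block-diagonal TOM yields exactly the planted blocks", {
  a <- matrix(0, 10, 10,
              dimnames = list(paste0("m", 1:10), paste0("m", 1:10)))
  a[1:5, 1:5] <- 0.9
  a[6:10, 6:10] <- 0.9
  diag(a) <- 0
  tom <- topological_overlap(a)
  set.seed(1)
  m <- matrix(rnorm(12 * 10), 12, 10,
              dimnames = list(paste0("s", 1:12), paste0("m", 1:10)))
  tbl <- restate(as_metab_tbl(m), "log2_centered")
  det <- detect_modules(tom, tbl, cut_height = 0.5, min_size = 2)
  expect_equal(length(setdiff(unique(det$module), "grey")), 2L)
  expect_equal(sum(det$module == "grey"), 0L)
  expect_equal(length(unique(det$module[1:5])), 1L)
  expect_equal(length(unique(det$module[6:10])), 1L)
  # oversized min_size sends everything to grey
  expect_warning(all_grey <- detect_modules(tom, tbl, min_size = 11),
                 "grey")
  expect_true(all(all_grey$module == "grey"))
})

test_that("module eigengenes have unit variance, orientation and optimality", {
  norm <- get_normalized(1)
  w <- suppressWarnings(run_wcna(norm))
  eg <- w$eigengenes
  expect_false(is.null(eg))
  for (mod in names(eg)[-1L]) {
    e <- eg[[mod]]
    expect_equal(sd(e), 1, tolerance = 1e-9)
    members <- w$module_of$metabolite[w$module_of$module == mod]
    sub <- scale(metab_values(norm)[, members, drop = FALSE])
    expect_gt(mean(cor(e, sub)), 0)
    # first-PC optimality: explains at least as much as any single member
    var_along <- function(v) var(sub %*% v / sqrt(sum(v^2)))
    e_dir <- svd(sub, nu = 0, nv = 1)$v[, 1]
    best_single <- max(vapply(seq_along(members), function(i) {
      var_along(as.numeric(seq_along(members) == i))
    }, numeric(1)))
    expect_gte(var_along(e_dir) + 1e-9, best_single)
  }
})

test_that("eigengene closed form and sign symmetry on tiny modules", {
  m <- matrix(c(1, 2, 4, 2.1, 3.9, 8.2), 3, 2,
              dimnames = list(paste0("s", 1:3), c("a", "b")))
  tbl <- restate(as_metab_tbl(m), "log2_centered")
  mod <- tibble::tibble(metabolite = c("a", "b"), module = "M1")
  eg <- module_eigengene(tbl, mod)
  sub <- scale(m)
  sv <- svd(sub)
  ref <- sv$u[, 1] / sd(sv$u[, 1])
  if (mean(cor(ref, sub)) < 0) ref <- -ref
  expect_equal(eg$M1, ref, tolerance = 1e-9)
  # identical profiles: eigengene equals the standardized profile
  m2 <- cbind(a = c(1, 5, 3), b = c(1, 5, 3))
  rownames(m2) <- paste0("s", 1:3)
  eg2 <- module_eigengene(restate(as_metab_tbl(m2), "log2_centered"), mod)
  expect_equal(abs(cor(eg2$M1, scale(m2[, 1])[, 1])), 1, tolerance = 1e-9)
  # negating all member profiles leaves the oriented eigengene unchanged
  eg3 <- module_eigengene(restate(as_metab_tbl(-m), "log2_centered"), mod)
  expect_equal(abs(cor(eg$M1, eg3$M1)), 1, tolerance = 1e-9)
  expect_gt(cor(eg3$M1, scale(-m[, 1])[, 1]), 0)
})

test_that("kME is a bounded correlation with flagged degenerate profiles", {
  norm <- get_normalized(1)
  w <- suppressWarnings(run_wcna(norm))
  kme_mat <- as.matrix(w$kme[-1L])
  expect_true(all(kme_mat >= -1 - 1e-12 & kme_mat <= 1 + 1e-12))
  # rank-1 module member has |kME| = 1
  m2 <- cbind(a = c(1, 5, 3, 2), b = c(2, 10, 6, 4), c = rnorm(4))
  rownames(m2) <- paste0("s", 1:4)
  tbl <- restate(as_metab_tbl(m2), "log2_centered")
  mod <- tibble::tibble(metabolite = c("a", "b", "c"),
                        module = c("M1", "M1", "grey"))
  eg <- module_eigengene(tbl, mod)
  kme <- compute_kme(tbl, eg)
  expect_equal(abs(kme$M1[kme$metabolite == "a"]), 1, tolerance = 1e-9)
  # zero-variance profile flagged with kME 0
  m3 <- cbind(m2, d = rep(1, 4))
  tbl3 <- restate(as_metab_tbl(m3), "log2_centered")
  expect_warning(kme3 <- compute_kme(tbl3, eg), "zero-variance")
  expect_equal(kme3$M1[kme3$metabolite == "d"], 0)
})

test_that("module-trait statistics recover identity, null and planted signs", {
  co <- get_cohort(1)
  norm <- get_normalized(1)
  w <- suppressWarnings(run_wcna(norm, co$clinical))
  ts <- w$trait_stats
  expect_true(all(c("module", "trait", "r", "p_value", "p_adj",
                    "logistic_beta", "logistic_p") %in% names(ts)))
  expect_true(all(ts$p_adj >= ts$p_value - 1e-12))
  # identity: correlating an eigengene with itself as a trait
  eg <- w$eigengenes
  fake <- co$clinical
  fake$age <- eg[[2L]]
  ts2 <- suppressWarnings(module_trait_stats(eg, fake))
  row <- ts2[ts2$module == names(eg)[2L] & ts2$trait == "age", ]
  expect_equal(row$r, 1, tolerance = 1e-9)
  expect_lt(row$p_value, 1e-20)
  # constant trait skipped with warning
  fake$size <- 1
  expect_warning(module_trait_stats(eg, fake), "constant")
})

test_that("permuted traits are BH-significant at no more than the nominal rate", {
  co <- get_cohort(1)
  norm <- get_normalized(1)
  w <- suppressWarnings(run_wcna(norm))
  eg <- w$eigengenes
  set.seed(11)
  n_perm <- 200
  sig_frac <- vapply(seq_len(n_perm), function(i) {
    fake <- co$clinical
    perm <- sample(nrow(fake))
    for (v in c("edema", "who_grade", "age", "mib1")) {
      fake[[v]] <- fake[[v]][perm]
    }
    fake <- fake[, c("sample_id", "edema", "who_grade", "age", "mib1")]
    ts <- suppressWarnings(module_trait_stats(eg, fake))
    mean(ts$p_adj <= 0.05)
  }, numeric(1))
  # FDR control: mean significant fraction below alpha plus 3 SE
  se <- sd(sig_frac) / sqrt(n_perm)
  expect_lt(mean(sig_frac), 0.05 + 3 * se + 1e-9)
})

test_that("the benign-cluster module correlates negatively with edema", {
  neg <- 0
  checked <- 0
  for (seed in 1:10) {
    co <- get_cohort(seed)
    norm <- get_normalized(seed)
    w <- suppressWarnings(run_wcna(norm, co$clinical))
    mod1 <- w$module_of$module[w$module_of$metabolite == "glycine"]
    if (mod1 == "grey" || is.null(w$trait_stats)) next
    checked <- checked + 1
    r <- w$trait_stats$r[w$trait_stats$module == mod1 &
                           w$trait_stats$trait == "edema_high"]
    neg <- neg + (r < 0)
  }
  expect_gte(checked, 8)
  expect_gte(neg / checked, 0.8)
})

test_that("hub ranking follows own-module kME with name tie-breaks", {
  norm <- get_normalized(1)
  w <- suppressWarnings(run_wcna(norm))
  hubs <- hub_metabolites(w$kme, w$module_of, top_n = 3)
  for (mod in unique(hubs$module)) {
    h <- hubs[hubs$module == mod, ]
    members <- w$module_of$metabolite[w$module_of$module == mod]
    vals <- w$kme[[mod]][match(members, w$kme$metabolite)]
    expect_equal(h$kme, sort(vals, decreasing = TRUE)[1:3], tolerance = 1e-12)
  }
  # top_n beyond the module size returns the whole module in kME order
  all_h <- hub_metabolites(w$kme, w$module_of, top_n = 10000)
  mod1 <- unique(hubs$module)[1]
  expect_equal(sum(all_h$module == mod1),
               sum(w$module_of$module == mod1))
  # planted high-loading member ranks first in most seeds
  firsts <- 0
  for (seed in 1:10) {
    set.seed(seed)
    f <- rnorm(30)
    prof <- vapply(c(0.9, rep(0.5, 5)), function(l) {
      l * f + sqrt(1 - l^2) * rnorm(30)
    }, numeric(30))
    colnames(prof) <- paste0("m", 1:6)
    rownames(prof) <- sprintf("s%02d", 1:30)
    tbl <- restate(as_metab_tbl(prof), "log2_centered")
    mo <- tibble::tibble(metabolite = colnames(prof), module = "M1")
    kme <- compute_kme(tbl, module_eigengene(tbl, mo))
    firsts <- firsts +
      (hub_metabolites(kme, mo, top_n = 1)$metabolite == "m1")
  }
  expect_gte(firsts, 9)
})

test_that("cluster-of-clusters groups eigengenes with their members", {
  # rank-1 module: eigengene and members at correlation distance ~ 0
  set.seed(3)
  f1 <- rnorm(25)
  f2 <- rnorm(25)
  m <- cbind(a1 = f1, a2 = f1 * 2 + 1e-6 * rnorm(25),
             b1 = f2, b2 = f2 * 1.5 + 1e-6 * rnorm(25))
  rownames(m) <- sprintf("s%02d", 1:25)
  tbl <- restate(as_metab_tbl(m), "log2_centered")
  mo <- tibble::tibble(metabolite = colnames(m),
                       module = c("M1", "M1", "M2", "M2"))
  eg <- module_eigengene(tbl, mo)
  coc <- cluster_of_clusters(tbl, eg, cut_height = 0.5)
  g <- setNames(coc$groups$group, coc$groups$object)
  expect_equal(g[["M1"]], g[["a1"]])
  expect_equal(g[["M1"]], g[["a2"]])
  expect_equal(g[["M2"]], g[["b1"]])
  expect_false(g[["M1"]] == g[["M2"]])
  # deterministic ordering
  coc2 <- cluster_of_clusters(tbl, eg, cut_height = 0.5)
  expect_identical(coc$order, coc2$order)
})

test_that("network export counts edges correctly and round-trips GraphML", {
  norm <- get_normalized(1)
  w <- suppressWarnings(run_wcna(norm))
  # threshold 0 keeps every intramodular pair
  all_edges <- export_network(w$adjacency, w$module_of, threshold = 0)
  sizes <- table(w$module_of$module[w$module_of$module != "grey"])
  expect_equal(nrow(all_edges), sum(choose(sizes, 2)))
  # threshold 1 keeps only perfect edges
  none <- export_network(w$adjacency, w$module_of, threshold = 1)
  expect_true(all(none$weight >= 1))
  expect_error(export_network(w$adjacency, w$module_of, threshold = 2),
               "threshold")
  # GraphML round trip preserves the weighted edge set
  gml <- tempfile(fileext = ".graphml")
  csv <- tempfile(fileext = ".csv")
  edges <- export_network(w$adjacency, w$module_of, threshold = 0.3,
                          kme = w$kme, graphml = gml, edgelist = csv)
  g <- igraph::read_graph(gml, format = "graphml")
  back <- igraph::as_data_frame(g, what = "edges")
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  expect_setequal(key(back$from, back$to), key(edges$source, edges$target))
  expect_equal(sort(back$weight), sort(edges$weight), tolerance = 1e-9)
  expect_equal(nrow(readr::read_csv(csv, show_col_types = FALSE)),
               nrow(edges))
  unlink(c(gml, csv))
})
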