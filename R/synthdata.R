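#' Default metabolite name panel
#'
#' 270 metabolite names: 33 named compounds covering the built-in pathway
#' sets (amino acids, choline derivatives, sphingolipids, glycolytic
#' intermediates) followed by generic placeholders for the remainder of the
#' quantified panel.
#'
#' @param n_metabolites Total panel size (default 270).
#' @return Character vector of unique metabolite names.
#' @export
default_metabolite_names <- function(n_metabolites = 270) {
  named <- c(
    "glycine", "serine", "threonine", "sarcosine", "betaine", "creatine",
    "glutamate", "glutamine", "gaba", "alpha_ketoglutarate", "proline",
    "tryptophan", "kynurenine", "kynurenic_acid", "serotonin",
    "indole_3_acetate",
    "choline", "phosphocholine", "glycerophosphocholine", "ethanolamine",
    "phosphoethanolamine",
    "sphingosine", "sphinganine", "ceramide", "sphingosine_1_phosphate",
    "glucose", "lactate", "pyruvate", "phosphoenolpyruvate",
    "fructose_1_6_bisphosphate", "alanine",
    "arginine", "isoleucine"
  )
  if (n_metabolites < length(named)) return(named[seq_len(n_metabolites)])
  extra <- sprintf("met_%03d", seq_len(n_metabolites - length(named)) + length(named))
  c(named, extra)
}

#' Simulation configuration
#'
#' Parameters of the synthetic cohort generator. Defaults emulate a
#' 43-sample meningioma cohort with 270 quantified metabolites: one benign
#' subtype (cluster 1, n = 15) and a second cluster of 28 that splits into
#' two subclusters (13 + 15), each subtype marked by an upregulated
#' signature pathway, five correlated metabolite modules, and
#' cluster-linked clinical covariates and progression-free survival.
#'
#' @param n_samples,n_metabolites Cohort dimensions.
#' @param cluster_sizes Integer vector of subtype sizes (I, II-a, II-b);
#'   must sum to `n_samples`. Subtype I is cluster 1, II-a and II-b make up
#'   cluster 2.
#' @param signature_sets Named list mapping subtype to the metabolites it
#'   upregulates.
#' @param effect_size Log2 fold change added to a subtype's signature
#'   metabolites in samples of that subtype.
#' @param n_modules,module_size Number and size of planted co-abundance
#'   modules. The three signature pathways seed modules 1-3; remaining
#'   members are generic metabolites.
#' @param module_loading Loading of each module metabolite on its latent
#'   factor, in [0, 1).
#' @param noise_sd Residual standard deviation on the log2 scale.
#' @param mib1_means Mean MIB-1 proliferation index (%) per subtype.
#' @param edema_probs Probability of high peritumoral edema per cluster.
#' @param pfs_hazards Monthly progression hazard per cluster.
#' @param censor_horizon Administrative censoring time in months.
#' @param exact_margins If `TRUE`, categorical covariates reproduce the
#'   reference contingency-table counts deterministically instead of being
#'   sampled from the corresponding margins.
#' @param link_modules If `TRUE` (default) the first three module latent
#'   factors are partially loaded on the subtype contrasts (module 1 on
#'   the benign cluster-1 indicator, modules 2 and 3 on the two cluster-2
#'   subtypes with a shared cluster-2 component) and modules 4-5 carry
#'   only a faint cluster trace — mirroring a cohort in which three of
#'   five modules are grade-associated. `FALSE` makes all factors
#'   independent standard normals (a null cohort).
#' @param metabolite_names Metabolite name panel.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_samples = 43,
                       n_metabolites = 270,
                       cluster_sizes = c(15L, 13L, 15L),
                       signature_sets = list(
                         "I"    = c("glycine", "serine", "arginine",
                                    "creatine", "glutamate"),
                         "II-a" = c("choline", "phosphocholine",
                                    "sphingosine", "isoleucine"),
                         "II-b" = c("tryptophan", "kynurenine",
                                    "kynurenic_acid", "choline")
                       ),
                       effect_size = 1.0,
                       n_modules = 5,
                       module_size = 12,
                       module_loading = 0.6,
                       noise_sd = 0.5,
                       mib1_means = c(1.2, 2.1, 11.7),
                       edema_probs = c(4 / 15, 18 / 28),
                       pfs_hazards = c(0.01, 0.05),
                       censor_horizon = 60,
                       exact_margins = FALSE,
                       link_modules = TRUE,
                       metabolite_names = default_metabolite_names(n_metabolites)) {
  cfg <- list(
    n_samples = as.integer(n_samples),
    n_metabolites = as.integer(n_metabolites),
    cluster_sizes = as.integer(cluster_sizes),
    signature_sets = signature_sets,
    effect_size = effect_size,
    n_modules = as.integer(n_modules),
    module_size = as.integer(module_size),
    module_loading = module_loading,
    noise_sd = noise_sd,
    mib1_means = mib1_means,
    edema_probs = edema_probs,
    pfs_hazards = pfs_hazards,
    censor_horizon = censor_horizon,
    exact_margins = isTRUE(exact_margins),
    link_modules = isTRUE(link_modules),
    metabolite_names = metabolite_names
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (length(cfg$cluster_sizes) != 3L) {
    abort("cluster_sizes must have three entries (subtypes I, II-a, II-b)")
  }
  if (sum(cfg$cluster_sizes) != cfg$n_samples) {
    abort("invariant violated: sum(cluster_sizes) must equal n_samples")
  }
  if (length(cfg$metabolite_names) != cfg$n_metabolites ||
      anyDuplicated(cfg$metabolite_names)) {
    abort("metabolite_names must be n_metabolites unique names")
  }
  sig <- unique(unlist(cfg$signature_sets))
  missing <- setdiff(sig, cfg$metabolite_names)
  if (length(missing)) {
    abort(paste0("invariant violated: signature metabolites not in panel: ",
                 paste(missing, collapse = ", ")))
  }
  if (cfg$module_loading < 0 || cfg$module_loading >= 1) {
    abort("invariant violated: module_loading must lie in [0, 1)")
  }
  if (cfg$noise_sd < 0 || any(cfg$pfs_hazards < 0) || cfg$censor_horizon < 0 ||
      any(cfg$edema_probs < 0) || any(cfg$edema_probs > 1)) {
    abort("invariant violated: rates and probabilities must be non-negative (probs <= 1)")
  }
  tryCatch(plant_modules(cfg), error = function(e) {
    abort("invariant violated: not enough metabolites for the requested modules")
  })
  cfg
}

subtype_levels <- c("I", "II-a", "II-b")

table1_margins <- function() {
  # reference per-cluster counts of the clinical characteristics table
  list(
    sex_male = c(2L, 8L),
    edema_high = c(4L, 18L),
    location = list(
      levels = c("falx", "convexity", "frontobasal", "sphenoid_wing",
                 "petroclival", "spinal", "others"),
      counts = rbind(c(3L, 2L, 4L, 2L, 1L, 2L, 1L),
                     c(3L, 10L, 5L, 4L, 1L, 1L, 4L))
    ),
    simpson = rbind(c(5L, 9L, 0L, 1L), c(7L, 16L, 3L, 2L)),
    mib1_low = c(15L, 9L),
    who_grade1_in_cluster2 = 13L,
    who_grade3_in_cluster2 = 3L
  )
}

#' Simulate a synthetic metabolomic cohort
#'
#' Draws a positive intensity matrix, a clinical table and the generating
#' ground truth. On the log2 scale each metabolite is baseline + subtype
#' signature effect + module latent factor + Gaussian noise; intensities
#' are `2^x`. Clinical covariates are drawn with per-cluster margins
#' matching the reference cohort, and progression-free survival is
#' exponential per cluster with administrative censoring.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; identical `(config, seed)` give bit-identical
#'   output.
#' @return A list of class `"metab_cohort"` with elements `metabolites`
#'   (raw-state intensity tibble, see [as_metab_tbl()]), `clinical`
#'   (per-sample covariates including `pfs_time` / `pfs_event`), and
#'   `truth` (subtype / cluster labels, module assignment, signature
#'   flags).
#' @examples
#' cohort <- simulate_cohort(sim_config(), seed = 1)
#' dim(metab_values(cohort$metabolites))
#' table(cohort$truth$samples$cluster)
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1) {
  config <- validate_sim_config(config)
  set.seed(as.integer(seed))
  n <- config$n_samples
  p <- config$n_metabolites
  mets <- config$metabolite_names

  subtype <- factor(rep(subtype_levels, config$cluster_sizes),
                    levels = subtype_levels)
  cluster <- ifelse(subtype == "I", 1L, 2L)
  ids <- sprintf("S%02d", seq_len(n))

  module_of <- plant_modules(config)

  baseline <- rnorm(p, 0, 1)
  factors <- matrix(rnorm(n * config$n_modules), n, config$n_modules)
  if (config$link_modules) {
    zs <- function(ind) (ind - mean(ind)) / sd(ind)
    z <- cbind(zs(subtype == "I"), zs(subtype == "II-a"),
               zs(subtype == "II-b"))
    mix <- module_subtype_mix(config$n_modules)
    factors <- z %*% t(mix[, 1:3, drop = FALSE]) +
      factors * matrix(mix[, 4L], n, config$n_modules, byrow = TRUE)
  }
  noise <- matrix(rnorm(n * p, 0, config$noise_sd), n, p)

  x <- matrix(baseline, n, p, byrow = TRUE) + noise
  for (s in subtype_levels) {
    cols <- match(config$signature_sets[[s]], mets)
    rows <- which(subtype == s)
    x[rows, cols] <- x[rows, cols] + config$effect_size
  }
  mod_cols <- which(!is.na(module_of))
  x[, mod_cols] <- x[, mod_cols] +
    config$module_loading * factors[, module_of[mod_cols], drop = FALSE]

  intensities <- 2^x
  dimnames(intensities) <- list(ids, mets)

  clinical <- simulate_clinical(config, ids, subtype, cluster)

  truth <- list(
    samples = tibble(sample_id = ids,
                     subtype = as.character(subtype),
                     cluster = cluster),
    modules = tibble(metabolite = mets, module = unname(module_of)),
    signatures = list_rbind(imap(
      config$signature_sets,
      function(m, s) tibble(metabolite = m, subtype = s)
    ))
  )

  structure(
    list(metabolites = as_metab_tbl(intensities, state = "raw"),
         clinical = clinical, truth = truth,
         config = config, seed = as.integer(seed)),
    class = "metab_cohort"
  )
}

# clinical covariates; margins follow the reference cohort unless
# exact_margins fixes the categorical counts outright
simulate_clinical <- function(config, ids, subtype, cluster) {
  n <- length(ids)
  t1 <- table1_margins()
  n_by_cluster <- tabulate(cluster, 2L)

  draw_cat <- function(levels, probs_by_cluster, exact_counts) {
    out <- character(n)
    for (g in 1:2) {
      idx <- which(cluster == g)
      if (config$exact_margins) {
        out[idx] <- rep(levels, exact_counts[g, ])
      } else {
        out[idx] <- sample(levels, length(idx), replace = TRUE,
                           prob = probs_by_cluster[g, ])
      }
    }
    out
  }

  sex_counts <- cbind(t1$sex_male, n_by_cluster - t1$sex_male)
  sex <- draw_cat(c("male", "female"),
                  sex_counts / n_by_cluster, sex_counts)

  edema_counts <- cbind(t1$edema_high, n_by_cluster - t1$edema_high)
  edema_probs <- cbind(config$edema_probs, 1 - config$edema_probs)
  edema <- draw_cat(c("high", "low"), edema_probs, edema_counts)

  loc <- draw_cat(t1$location$levels,
                  t1$location$counts / n_by_cluster, t1$location$counts)
  simpson_lab <- draw_cat(as.character(1:4),
                          t1$simpson / n_by_cluster, t1$simpson)

  age_mean <- c(62.3, 64.4)[cluster]
  age_sd <- c(13.1, 12.8)[cluster]
  age <- rnorm(n, age_mean, age_sd)

  # tumour volume: lognormal matched to the reference mean/SD per cluster
  sz_mean <- c(48.3, 88.6)[cluster]
  sz_sd <- c(51.8, 103.3)[cluster]
  sdlog <- sqrt(log(1 + (sz_sd / sz_mean)^2))
  size <- rlnorm(n, log(sz_mean) - sdlog^2 / 2, sdlog)

  kps_levels <- seq(60, 100, 10)
  kps_pre_probs <- rbind(c(.05, .20, .45, .20, .10),
                         c(.20, .35, .30, .10, .05))
  kps_post_probs <- rbind(c(.02, .08, .30, .40, .20),
                          c(.25, .30, .25, .15, .05))
  kps_pre <- kps_post <- numeric(n)
  for (g in 1:2) {
    idx <- which(cluster == g)
    kps_pre[idx] <- sample(kps_levels, length(idx), TRUE, kps_pre_probs[g, ])
    kps_post[idx] <- sample(kps_levels, length(idx), TRUE, kps_post_probs[g, ])
  }

  if (config$exact_margins) {
    mib1 <- numeric(n)
    mib1[cluster == 1L] <- config$mib1_means[1L]
    c2 <- which(cluster == 2L)
    low2 <- t1$mib1_low[2L]
    mib1[c2] <- rep(config$mib1_means[2:3],
                    c(low2, length(c2) - low2))
  } else {
    sdlog_m <- 0.25
    mu <- config$mib1_means[as.integer(subtype)]
    mib1 <- rlnorm(n, log(mu) - sdlog_m^2 / 2, sdlog_m)
  }

  who <- character(n)
  who[subtype == "I"] <- "I"
  who[subtype == "II-a"] <- "I"   # benign histology despite cluster-2 metabolism
  iib <- which(subtype == "II-b")
  g3 <- t1$who_grade3_in_cluster2
  if (config$exact_margins) {
    who[iib] <- rep(c("II", "III"), c(length(iib) - g3, g3))
  } else {
    who[iib] <- sample(c("II", "III"), length(iib), TRUE,
                       prob = c(length(iib) - g3, g3))
  }

  raw_t <- rexp(n, rate = config$pfs_hazards[cluster])
  pfs_time <- pmin(raw_t, config$censor_horizon)
  pfs_event <- as.integer(raw_t <= config$censor_horizon)

  tibble(
    sample_id = ids,
    cluster = cluster,
    subtype = as.character(subtype),
    sex = sex,
    age = age,
    size = size,
    edema = edema,
    location = loc,
    simpson = simpson_lab,
    kps_pre = kps_pre,
    kps_post = kps_post,
    mib1 = mib1,
    who_grade = who,
    pfs_time = pfs_time,
    pfs_event = pfs_event
  )
}

#' @export
print.metab_cohort <- function(x, ...) {
  cat(sprintf("<metab_cohort> %d samples x %d metabolites (seed %d)\n",
              nrow(x$metabolites), ncol(x$metabolites) - 1L, x$seed))
  print(table(subtype = x$truth$samples$subtype))
  invisible(x)
}

# Module membership: the three signature pathways seed modules 1-3 (the
# grade-associated modules of the emulated cohort), topped up with generic
# metabolites; remaining modules are generic. choline, shared by the two
# cluster-2 signatures, belongs to module 2.
plant_modules <- function(config) {
  mets <- config$metabolite_names
  sig_union <- unique(unlist(config$signature_sets))
  pool <- rev(setdiff(mets, sig_union))   # generic tail of the panel
  module_of <- setNames(rep(NA_integer_, length(mets)), mets)
  used <- character(0)
  for (m in seq_len(config$n_modules)) {
    seedset <- if (m <= length(config$signature_sets)) {
      setdiff(config$signature_sets[[m]], used)
    } else character(0)
    n_fill <- config$module_size - length(seedset)
    if (n_fill < 0) abort("module_size smaller than its signature set")
    fill <- setdiff(pool, used)[seq_len(n_fill)]
    if (anyNA(fill)) abort("not enough metabolites to fill the modules")
    members <- c(seedset, fill)
    module_of[members] <- m
    used <- c(used, members)
  }
  module_of
}

# Loadings of the module latent factors on the standardized subtype
# indicators (z_I, z_IIa, z_IIb) and on module-specific noise. Modules 1-3
# are the grade-associated modules; 4-5 are essentially free.
module_subtype_mix <- function(n_modules) {
  base <- rbind(
    c(1, 0, 0, 0),
    c(0, sqrt(.20), 0, sqrt(.80)),
    c(0, 0, sqrt(.20), sqrt(.80)),
    c(sqrt(.10), 0, 0, sqrt(.90)),
    c(-sqrt(.10), 0, 0, sqrt(.90))
  )
  extra <- n_modules - nrow(base)
  if (extra > 0) {
    base <- rbind(base, matrix(rep(c(0, 0, 0, 1), extra), extra, 4,
                               byrow = TRUE))
  }
  base[seq_len(n_modules), , drop = FALSE]
}
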