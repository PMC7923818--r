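#' Pseudo-counted quantile normalisation
#'
#' Adds a pseudocount to every raw intensity, then quantile-normalises
#' across samples: each sample's sorted intensity vector is replaced by the
#' across-sample mean of order statistics, values re-inserted in the
#' sample's original rank order. Ties within a sample receive the mean of
#' their reference quantiles. Afterwards every sample shares the same
#' sorted value multiset (exactly, absent ties).
#'
#' @param metabolites Raw-state intensity tibble ([as_metab_tbl()]).
#' @param pseudocount Value added to all entries before normalisation
#'   (default 1).
#' @return Intensity tibble in state `"normalized"`.
#' @examples
#' cohort <- simulate_cohort(sim_config(), seed = 1)
#' norm <- pq_normalize(cohort$metabolites)
#' metab_state(norm)
#' @export
pq_normalize <- function(metabolites, pseudocount = 1.0) {
  require_state(metabolites, "raw", "pq_normalize")
  m <- metab_values(metabolites)
  if (any(m < 0)) abort("raw intensities must be non-negative")
  m <- m + pseudocount
  out <- quantile_normalize_rows(m)
  set_metab_values(metabolites, out, state = "normalized")
}

# rows = samples; reference = mean of order statistics, ties averaged
quantile_normalize_rows <- function(m) {
  sorted <- apply(m, 1L, sort)              # p x n, column per sample
  ref <- rowMeans(sorted)
  cs <- cumsum(ref)
  out <- t(apply(m, 1L, function(row) {
    # a run of ties spans reference ranks [r_min, r_max]; assign their mean
    r_min <- rank(row, ties.method = "min")
    r_max <- rank(row, ties.method = "max")
    (cs[r_max] - c(0, cs)[r_min]) / (r_max - r_min + 1)
  }))
  dimnames(out) <- dimnames(m)
  out
}

#' Log2 transform and median-centre
#'
#' Takes log2 of every normalised intensity and subtracts each
#' metabolite's median across samples, leaving every metabolite with
#' median 0.
#'
#' @param metabolites Intensity tibble in state `"normalized"`, all
#'   entries strictly positive.
#' @return Intensity tibble in state `"log2_centered"`.
#' @export
log2_median_center <- function(metabolites) {
  require_state(metabolites, "normalized", "log2_median_center")
  m <- metab_values(metabolites)
  if (any(m <= 0)) {
    bad <- which(m <= 0, arr.ind = TRUE)[1L, ]
    abort(sprintf("non-positive entry at sample '%s', metabolite '%s'",
                  rownames(m)[bad[1L]], colnames(m)[bad[2L]]))
  }
  lg <- log2(m)
  centered <- sweep(lg, 2L, apply(lg, 2L, median))
  set_metab_values(metabolites, centered, state = "log2_centered")
}

#' Keep the most variable metabolites
#'
#' Retains the `n` metabolites of largest (unbiased) sample variance,
#' ordered by descending variance; ties are broken by metabolite name.
#'
#' @param metabolites Intensity tibble in state `"log2_centered"`.
#' @param n Number of metabolites to keep (default 100).
#' @return Intensity tibble (state unchanged) with `n` metabolite columns.
#' @export
top_variable <- function(metabolites, n = 100) {
  require_state(metabolites, "log2_centered", "top_variable")
  if (n <= 0) abort("n must be positive")
  m <- metab_values(metabolites)
  if (n > ncol(m)) abort("n exceeds the number of metabolites")
  v <- apply(m, 2L, var)
  keep <- order(-v, colnames(m))[seq_len(n)]
  set_metab_values(metabolites, m[, keep, drop = FALSE],
                   state = "log2_centered")
}
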