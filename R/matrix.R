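#' Metabolite intensity tables
#'
#' The central data object of the workflow is a tibble with one row per
#' sample: a `sample_id` character column followed by one numeric column per
#' metabolite. A processing-state flag (`"raw"`, `"normalized"` or
#' `"log2_centered"`) is carried in the `"metab_state"` attribute and is
#' checked by every stage so that, for example, log transformation cannot be
#' applied before quantile normalisation. State moves only forward:
#' raw -> normalized -> log2_centered.
#'
#' @param x A data frame (first column sample id) or a numeric matrix with
#'   rownames as sample ids and colnames as metabolite names.
#' @param state Processing state flag.
#' @return `as_metab_tbl()` returns a validated tibble with the state
#'   attribute set; `metab_values()` the numeric matrix (samples x
#'   metabolites, dimnames set); `metab_state()` the state string.
#' @examples
#' m <- matrix(rexp(12), 3, 4,
#'             dimnames = list(paste0("s", 1:3), paste0("met", 1:4)))
#' tbl <- as_metab_tbl(m)
#' metab_state(tbl)
#' @export
as_metab_tbl <- function(x, state = c("raw", "normalized", "log2_centered")) {
  state <- match.arg(state)
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      abort("matrix input needs rownames (sample ids) and colnames (metabolite names)")
    }
    x <- bind_cols(tibble(sample_id = rownames(x)), as_tibble(x))
  }
  x <- as_tibble(x)
  if (ncol(x) < 2L) abort("need a sample id column plus at least one metabolite")
  names(x)[1L] <- "sample_id"
  x$sample_id <- as.character(x$sample_id)
  validate_metab_tbl(x)
  attr(x, "metab_state") <- state
  x
}

validate_metab_tbl <- function(x) {
  ids <- x[[1L]]
  if (anyNA(ids) || any(ids == "")) abort("missing sample ids")
  if (anyDuplicated(ids)) abort(paste0("duplicate sample id: ", ids[duplicated(ids)][1L]))
  mets <- names(x)[-1L]
  if (anyDuplicated(mets)) {
    abort(paste0("duplicate metabolite column: ", mets[duplicated(mets)][1L]))
  }
  bad <- mets[!vapply(x[-1L], is.numeric, logical(1))]
  if (length(bad)) abort(paste0("non-numeric metabolite column: ", bad[1L]))
  invisible(x)
}

#' @rdname as_metab_tbl
#' @export
metab_values <- function(x) {
  validate_metab_tbl(x)
  m <- as.matrix(x[-1L])
  rownames(m) <- x[[1L]]
  storage.mode(m) <- "double"
  m
}

#' @rdname as_metab_tbl
#' @export
metab_state <- function(x) {
  attr(x, "metab_state") %||% "raw"
}

# rebuild a metab tibble from a matrix, stamping the new state
set_metab_values <- function(x, m, state) {
  out <- bind_cols(tibble(sample_id = rownames(m)), as_tibble(m))
  attr(out, "metab_state") <- state
  out
}

require_state <- function(x, expected, op) {
  got <- metab_state(x)
  if (!identical(got, expected)) {
    abort(sprintf("%s() expects a matrix in state '%s', got '%s'", op, expected, got))
  }
  invisible(x)
}
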