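#' @keywords internal
#' @useDynLib ipclversa, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

# Condition constructors: every package error carries a class so callers and
# tests can match on meaning rather than message text.
ipcl_error <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "ipclversa_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

config_error <- function(msg) ipcl_error(msg, "ipclversa_config_error")
input_error  <- function(msg) ipcl_error(msg, "ipclversa_input_error")
numeric_error <- function(msg) ipcl_error(msg, "ipclversa_numeric_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an expression under a local, restored RNG state
#'
#' Seeds are always explicit in this package; `with_seed(NULL, ...)` uses the
#' ambient RNG stream so callers can compose their own determinism.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# L2 norms of the rows of a matrix.
row_norms <- function(m) sqrt(rowSums(m * m))

# Project rows of a matrix onto the unit hypersphere.
l2_normalize_rows <- function(m, tol = 1e-12) {
  n <- row_norms(m)
  if (any(n < tol)) input_error("cannot L2-normalize a (near-)zero vector")
  m / n
}

assert_unit_rows <- function(m, tol = 1e-5, what = "embedding") {
  n <- row_norms(m)
  if (any(abs(n - 1) > tol)) {
    input_error(sprintf("%s vectors must be unit-norm (max |norm-1| = %.3g)",
                        what, max(abs(n - 1))))
  }
  invisible(TRUE)
}

#' Flatten a single image/feature map to the pinned unit order
#'
#' Channel-major, spatial row-major: all units of channel 1 scanned row by
#' row, then channel 2, and so on.  Any fixed order would do for the
#' permutation-invariant analyses downstream; this one is pinned so cached
#' activations are comparable across runs.
#' @keywords internal
#' @noRd
flatten_chw <- function(a) {
  if (length(dim(a)) != 3L) input_error("expected an H x W x C array")
  as.vector(aperm(a, c(2L, 1L, 3L)))
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}
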