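# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_hetdta <- function(...) stop(..., call. = FALSE)

# check a square symmetric matrix with entries in [lo, hi]
check_square_symmetric <- function(m, what, lo = 0, hi = 1, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop_hetdta(what, " must be a square matrix")
  if (max(abs(m - t(m))) > tol)
    stop_hetdta(what, " must be symmetric")
  if (min(m) < lo - tol || max(m) > hi + tol)
    stop_hetdta(what, " entries must lie in [", lo, ", ", hi, "]")
  invisible(TRUE)
}

relu <- function(x) x * (x > 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

# mean over rows, kept as a 1 x d matrix
row_mean <- function(x) matrix(colMeans(x), nrow = 1)

# add a bias row-vector to every row of M
add_bias <- function(M, b) M + rep(b, each = nrow(M))
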