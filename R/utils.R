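#' @importFrom stats rexp rnorm runif sd setNames var
#' @importFrom utils write.csv read.csv modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# gas constant, kcal/(mol K)
.R_KCAL <- 1.9872e-3
# Avogadro constant, 1/mol
.N_AVOGADRO <- 6.02214e23

stop_ligandmsm <- function(...) {
  stop(..., call. = FALSE)
}

check_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_ligandmsm(sprintf("`%s` must be a single positive finite number", name))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != as.integer(x)) {
    stop_ligandmsm(sprintf("`%s` must be an integer >= %d", name, min))
  }
  as.integer(x)
}

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_ligandmsm("`seed` must be a single finite number")
  }
  as.integer(seed)
}

# Row-wise nearest column of `centers` for a block of points; ties go to the
# lowest center index.  Chunked so that the n x k distance matrix never gets
# large.
nearest_center <- function(x, centers, chunk = 100000L) {
  x <- as.matrix(x)
  n <- nrow(x)
  k <- nrow(centers)
  out <- integer(n)
  cc <- rowSums(centers^2)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    # squared distances up to the per-point constant ||x||^2
    d <- matrix(cc, nrow = length(idx), ncol = k, byrow = TRUE) -
      2 * x[idx, , drop = FALSE] %*% t(centers)
    out[idx] <- max.col(-d, ties.method = "first")
  }
  out
}
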