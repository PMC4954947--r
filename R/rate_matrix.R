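#' Continuous-time rate matrix
#'
#' Constructs a validated rate matrix `K` for a continuous-time Markov jump
#' process over `n` states, using the ROW convention employed throughout this
#' package: `K[i, j]` (for `i != j`) is the transition rate from state `i` to
#' state `j` in 1/ns, and each diagonal entry equals minus the total exit rate
#' of its row, so every row sums to zero.  The master equation for the row
#' vector of state probabilities `p(t)` is `dp/dt = p K`, with solution
#' `p(t) = p(0) exp(K t)`.
#'
#' @param K Square numeric matrix of rates (1/ns).  Off-diagonal entries must
#'   be non-negative and row sums must vanish to within `1e-12` (relative to
#'   the largest rate magnitude).
#' @param state_names Optional character vector of state labels.
#' @return A `rate_matrix` object (a numeric matrix with class attribute).
#' @examples
#' K <- rate_matrix(matrix(c(-1, 1, 1, -1), 2, byrow = TRUE))
#' exact_stationary(K)
#' @export
rate_matrix <- function(K, state_names = NULL) {
  K <- as.matrix(K)
  if (!is.numeric(K) || nrow(K) != ncol(K) || nrow(K) < 2L) {
    stop_ligandmsm("`K` must be a square numeric matrix with n >= 2 states")
  }
  if (anyNA(K) || any(!is.finite(K))) {
    stop_ligandmsm("`K` must be finite")
  }
  off <- K
  diag(off) <- 0
  if (any(off < 0)) {
    stop_ligandmsm("off-diagonal rates must be non-negative")
  }
  scale <- max(abs(K), 1)
  if (any(abs(rowSums(K)) > 1e-12 * scale)) {
    stop_ligandmsm("each row of `K` must sum to zero (non-conservative rate matrix)")
  }
  if (!is.null(state_names)) {
    if (length(state_names) != nrow(K)) {
      stop_ligandmsm("`state_names` length must match the number of states")
    }
    dimnames(K) <- list(state_names, state_names)
  }
  structure(K, class = c("rate_matrix", "matrix"))
}

#' @export
print.rate_matrix <- function(x, ...) {
  cat(sprintf("Rate matrix: %d states (1/ns, row convention)\n", nrow(x)))
  print(unclass(x), ...)
  invisible(x)
}

as_rate_matrix <- function(K) {
  if (inherits(K, "rate_matrix")) K else rate_matrix(K)
}

# directed graph of positive rates/counts; TRUE iff strongly connected
is_irreducible <- function(A) {
  g <- igraph::graph_from_adjacency_matrix((A > 0) * 1, mode = "directed",
                                           diag = FALSE)
  igraph::is_connected(g, mode = "strong")
}

#' Exact stationary distribution of a rate matrix
#'
#' Solves `pi K = 0` with `sum(pi) = 1` by a direct linear solve.  This is the
#' continuous-time analogue of the unit left eigenvector of a transition
#' matrix, i.e. the equilibrium probability of each state.
#'
#' @param K A [rate_matrix()] (or coercible matrix); must be irreducible.
#' @return Numeric probability vector, strictly positive, summing to 1.
#' @export
exact_stationary <- function(K) {
  K <- as_rate_matrix(K)
  off <- unclass(K)
  diag(off) <- 0
  if (!is_irreducible(off)) {
    stop_ligandmsm("`K` is reducible; the stationary distribution is not unique")
  }
  n <- nrow(K)
  # pi K = 0  <=>  t(K) pi' = 0; replace the last equation by normalization
  A <- t(unclass(K))
  A[n, ] <- 1
  b <- c(rep(0, n - 1L), 1)
  pi <- solve(A, b)
  pi <- as.numeric(pi)
  if (any(pi <= 0)) {
    stop_ligandmsm("stationary solve produced non-positive entries")
  }
  pi / sum(pi)
}

#' Exact lag-time transition matrix of a rate matrix
#'
#' Computes `T(lag) = exp(K * lag)` (matrix exponential, row convention), the
#' conditional probability `T[i, j]` of finding the process in state `j` a
#' time `lag` after it was in state `i`.
#'
#' @param K A [rate_matrix()].
#' @param lag Lag time in ns, `>= 0`.
#' @return Row-stochastic numeric matrix.
#' @export
exact_transition_matrix <- function(K, lag) {
  K <- as_rate_matrix(K)
  if (!is.numeric(lag) || length(lag) != 1L || !is.finite(lag) || lag < 0) {
    stop_ligandmsm("`lag` must be a single non-negative number (ns)")
  }
  if (lag == 0) {
    return(diag(nrow(K)))
  }
  T_ <- as.matrix(Matrix::expm(Matrix::Matrix(unclass(K) * lag)))
  dimnames(T_) <- dimnames(K)
  T_
}

#' Exact mean first passage time of a rate matrix
#'
#' Solves the linear system `K[-target, -target] m = -1` for the expected
#' first-hitting time `m` of the target set, then averages the source values
#' with weights proportional to the stationary distribution restricted to the
#' source set.
#'
#' @param K A [rate_matrix()].
#' @param source Integer vector of source state indices (1-based).
#' @param target Integer vector of target state indices (1-based), nonempty.
#' @return Mean first passage time in ns (0 when `source` is inside `target`).
#' @export
exact_mfpt <- function(K, source, target) {
  K <- as_rate_matrix(K)
  n <- nrow(K)
  source <- unique(as.integer(source))
  target <- unique(as.integer(target))
  if (length(target) == 0L || any(target < 1L) || any(target > n)) {
    stop_ligandmsm("`target` must be a nonempty set of valid state indices")
  }
  if (length(source) == 0L || any(source < 1L) || any(source > n)) {
    stop_ligandmsm("`source` must be a nonempty set of valid state indices")
  }
  m <- numeric(n)
  rest <- setdiff(seq_len(n), target)
  if (length(rest) > 0L) {
    # reachability of the target from every non-target state
    off <- unclass(K)
    diag(off) <- 0
    g <- igraph::graph_from_adjacency_matrix((off > 0) * 1, mode = "directed")
    d <- igraph::distances(g, v = rest, to = target, mode = "out")
    if (any(!is.finite(apply(d, 1, min)))) {
      stop_ligandmsm("`target` is not reachable from every non-target state")
    }
    m[rest] <- solve(unclass(K)[rest, rest, drop = FALSE], rep(-1, length(rest)))
  }
  if (all(source %in% target)) {
    return(0)
  }
  if (length(source) == 1L) {
    return(m[source])
  }
  pi <- exact_stationary(K)
  w <- pi[source] / sum(pi[source])
  sum(w * m[source])
}
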