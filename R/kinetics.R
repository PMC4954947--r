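#' PCCA+ macrostate lumping
#'
#' Lumps microstates into `M` metastable macrostates from the top-`M` right
#' eigenvectors of the reversible transition matrix, using the PCCA+ inner
#' simplex construction: the eigenvector rows live (approximately) inside a
#' simplex whose vertices correspond to the metastable sets; memberships are
#' the barycentric coordinates, clipped to `[0, 1]` and renormalized.  The
#' crisp assignment takes the macrostate of maximal membership, with ties to
#' the lower macrostate index.
#'
#' @param model A `transition_model` from [estimate_reversible()].
#' @param n_macrostates Number of macrostates `M >= 2`; the `M`-th eigenvalue
#'   must be positive.
#' @return A `macro_model` with fields `memberships` (n x M, rows sum to 1),
#'   `crisp_assignment` (microstate -> macrostate), `macro_pi` (aggregated
#'   stationary probabilities) and `labels` (filled by
#'   [identify_bulk_bound()]).
#' @export
pcca_lump <- function(model, n_macrostates) {
  if (!inherits(model, "transition_model")) {
    stop_ligandmsm("`model` must be a transition_model")
  }
  M <- check_count(n_macrostates, "n_macrostates", min = 2L)
  n <- nrow(model$T)
  if (M > n) stop_ligandmsm("more macrostates than microstates")
  es <- reversible_eigen(model$T, model$pi)
  ord <- order(es$values, decreasing = TRUE)
  ev <- es$values[ord]
  if (ev[M] <= 0) {
    stop_ligandmsm("the requested number of macrostates exceeds the number of positive eigenvalues")
  }
  if (M < n && abs(ev[M] - ev[M + 1L]) < 1e-12) {
    stop_ligandmsm("eigenvalue degeneracy at the macrostate cut; choose a different M")
  }
  X <- es$vectors[, ord[seq_len(M)], drop = FALSE]
  # fix the stationary eigenvector to the constant 1
  X[, 1L] <- 1
  # inner simplex algorithm: greedily pick the M most extreme rows
  vertices <- integer(M)
  Xw <- X
  vertices[1L] <- which.max(rowSums(Xw^2))
  Xw <- sweep(Xw, 2, Xw[vertices[1L], ])
  if (M > 1L) {
    for (i in 2:M) {
      nrm <- sqrt(rowSums(Xw^2))
      vertices[i] <- which.max(nrm)
      v <- Xw[vertices[i], ] / nrm[vertices[i]]
      Xw <- Xw - (Xw %*% v) %*% t(v)
    }
  }
  A <- solve(X[vertices, , drop = FALSE])
  chi <- X %*% A
  chi[chi < 0] <- 0
  chi <- chi / rowSums(chi)
  crisp <- max.col(chi, ties.method = "first")
  macro_pi <- as.numeric(tapply(model$pi, factor(crisp, levels = seq_len(M)),
                                sum, default = 0))
  structure(
    list(memberships = chi, crisp_assignment = crisp,
         macro_pi = macro_pi, n_macrostates = M, labels = NULL,
         model = model),
    class = "macro_model"
  )
}

#' @export
print.macro_model <- function(x, ...) {
  cat(sprintf("PCCA+ macro model: %d macrostates over %d microstates\n",
              x$n_macrostates, nrow(x$memberships)))
  if (!is.null(x$labels)) {
    cat("  labels:", paste(x$labels, collapse = ", "), "\n")
  }
  cat("  populations:", signif(x$macro_pi, 4), "\n")
  invisible(x)
}

#' Label bulk and bound macrostates
#'
#' Uses a per-microstate contact score (for contact-map features, the mean
#' number of receptor atoms in contact) to name the macrostates: the
#' macrostate with the lowest stationary-weighted mean score is `bulk`
#' (ligand far from the receptor), the highest is `bound`, and the rest are
#' `intermediate`.
#'
#' @param macro A `macro_model` from [pcca_lump()].
#' @param microstate_scores Numeric vector over the active microstates, e.g.
#'   from [microstate_contact_scores()].
#' @return The `macro_model` with `labels`, `bulk` and `bound` fields set.
#' @export
identify_bulk_bound <- function(macro, microstate_scores) {
  if (!inherits(macro, "macro_model")) stop_ligandmsm("`macro` must be a macro_model")
  scores <- as.numeric(microstate_scores)
  if (length(scores) != nrow(macro$memberships)) {
    stop_ligandmsm("need one score per active microstate")
  }
  pi <- macro$model$pi
  M <- macro$n_macrostates
  macro_score <- vapply(seq_len(M), function(m) {
    idx <- macro$crisp_assignment == m
    if (!any(idx)) return(NA_real_)
    sum(pi[idx] * scores[idx]) / sum(pi[idx])
  }, 1)
  bulk <- which.min(macro_score)
  bound <- which.max(macro_score)
  if (bulk == bound || !is.finite(macro_score[bulk]) ||
      macro_score[bulk] == macro_score[bound]) {
    stop_ligandmsm("bulk and bound resolve to the same macrostate (degenerate contact scores)")
  }
  labels <- rep("intermediate", M)
  labels[bulk] <- "bulk"
  labels[bound] <- "bound"
  macro$labels <- labels
  macro$bulk <- bulk
  macro$bound <- bound
  macro
}

#' Mean contact score per microstate
#'
#' Stationary currency for [identify_bulk_bound()]: the mean total feature
#' value (for binary contact maps, the number of receptor atoms in contact)
#' over the frames assigned to each active microstate.
#'
#' @param features List of [feature_trajectory()] objects (pre-projection).
#' @param dtrajs Aligned list of [discrete_trajectory()] objects.
#' @param active_set Active microstate indices of the transition model.
#' @return Numeric vector, one score per active microstate.
#' @export
microstate_contact_scores <- function(features, dtrajs, active_set) {
  features <- as_ftraj_list(features)
  dtrajs <- as_dtraj_list(dtrajs)
  if (length(features) != length(dtrajs)) {
    stop_ligandmsm("`features` and `dtrajs` must be aligned lists")
  }
  tot <- unlist(lapply(features, function(f) rowSums(f$frames)))
  st <- unlist(lapply(dtrajs, function(d) d$states))
  if (length(tot) != length(st)) {
    stop_ligandmsm("feature and discrete trajectories have mismatched lengths")
  }
  vapply(active_set, function(s) {
    idx <- st == s
    if (!any(idx)) return(NA_real_)
    mean(tot[idx])
  }, 1)
}

#' Mean first passage time of a transition model
#'
#' Solves `m_i = lag + sum_(j not in target) T_ij m_j` with `m = 0` on the
#' target set; the reported value is the stationary-weighted mean over the
#' source set (weights restricted and renormalized to the source).
#'
#' @param model A `transition_model`.
#' @param source,target Nonempty disjoint sets of active-microstate indices
#'   (positions within the active set).
#' @param source_weights `"stationary"` (default) or `"uniform"`.
#' @return Mean first passage time in ns.
#' @export
mfpt <- function(model, source, target, source_weights = c("stationary", "uniform")) {
  if (!inherits(model, "transition_model")) {
    stop_ligandmsm("`model` must be a transition_model")
  }
  source_weights <- match.arg(source_weights)
  n <- nrow(model$T)
  source <- unique(as.integer(source))
  target <- unique(as.integer(target))
  if (!length(source) || !length(target) ||
      any(c(source, target) < 1L) || any(c(source, target) > n)) {
    stop_ligandmsm("`source` and `target` must be nonempty sets of active-state indices")
  }
  if (all(source %in% target)) return(0)
  if (any(source %in% target)) {
    stop_ligandmsm("`source` and `target` must be disjoint")
  }
  rest <- setdiff(seq_len(n), target)
  Tr <- model$T[rest, rest, drop = FALSE]
  m <- numeric(n)
  sol <- try(solve(diag(length(rest)) - Tr, rep(model$lag, length(rest))),
             silent = TRUE)
  if (inherits(sol, "try-error") || any(!is.finite(sol))) {
    stop_ligandmsm("`target` is not reachable from the source set")
  }
  m[rest] <- sol
  w <- if (source_weights == "stationary") {
    model$pi[source] / sum(model$pi[source])
  } else {
    rep(1 / length(source), length(source))
  }
  sum(w * m[source])
}

#' Forward committor probabilities
#'
#' The probability, per microstate, of reaching set `B` before set `A`:
#' `q = 0` on `A`, `q = 1` on `B`, and harmonic with respect to `T`
#' elsewhere (a sparse linear solve).
#'
#' @param model A `transition_model`.
#' @param A,B Disjoint nonempty sets of active-microstate indices.
#' @return Numeric vector of committor values in `[0, 1]`.
#' @export
committor <- function(model, A, B) {
  if (!inherits(model, "transition_model")) {
    stop_ligandmsm("`model` must be a transition_model")
  }
  n <- nrow(model$T)
  A <- unique(as.integer(A))
  B <- unique(as.integer(B))
  if (!length(A) || !length(B) || any(c(A, B) < 1L) || any(c(A, B) > n)) {
    stop_ligandmsm("`A` and `B` must be nonempty sets of active-state indices")
  }
  if (length(intersect(A, B))) stop_ligandmsm("`A` and `B` must be disjoint")
  q <- numeric(n)
  q[B] <- 1
  U <- setdiff(seq_len(n), c(A, B))
  if (length(U)) {
    TU <- model$T[U, U, drop = FALSE]
    rhs <- rowSums(model$T[U, B, drop = FALSE])
    q[U] <- solve(diag(length(U)) - TU, rhs)
  }
  pmin(pmax(q, 0), 1)
}

#' Binding kinetics from on/off mean first passage times
#'
#' Converts single-ligand mean first passage times into bimolecular rate
#' constants and a standard binding free energy:
#' `kon = 1 / (MFPT_on * C_sim)`, `koff = 1 / MFPT_off`, and
#' `dG0 = R T log(koff / (kon * C0))` with `R = 1.9872e-3` kcal/(mol K) and
#' standard concentration `C0 = 1` M.  `MFPT_on` is a single-copy quantity;
#' `C_sim` is the single-copy simulation concentration (see
#' [concentration_from_box()]).
#'
#' @param mfpt_on Mean first passage time bulk -> bound, ns.
#' @param mfpt_off Mean first passage time bound -> bulk, ns.
#' @param concentration Simulation concentration in M.
#' @param temperature Temperature in K (default 298).
#' @param mfpt_matrix Optional full macrostate MFPT matrix (ns) to carry in
#'   the result.
#' @param labels Optional macrostate labels to carry in the result.
#' @return A `binding_kinetics` object with `kon` (1/(M s)), `koff` (1/s),
#'   `dG0` (kcal/mol), `Kd` (M) and the inputs.
#' @export
rates_from_mfpt <- function(mfpt_on, mfpt_off, concentration,
                            temperature = 298, mfpt_matrix = NULL,
                            labels = NULL) {
  check_scalar_positive(concentration, "concentration")
  check_scalar_positive(temperature, "temperature")
  if (!is.finite(mfpt_on) || mfpt_on <= 0 || !is.finite(mfpt_off) ||
      mfpt_off <= 0) {
    stop_ligandmsm("MFPTs must be finite and positive")
  }
  mfpt_on_s <- mfpt_on * 1e-9
  mfpt_off_s <- mfpt_off * 1e-9
  kon <- 1 / (mfpt_on_s * concentration)
  koff <- 1 / mfpt_off_s
  structure(
    list(kon = kon, koff = koff, Kd = koff / kon,
         dG0 = free_energy_from_rates(kon, koff, temperature),
         mfpt_on_ns = mfpt_on, mfpt_off_ns = mfpt_off,
         mfpt_matrix_ns = mfpt_matrix, labels = labels,
         concentration = concentration, temperature = temperature,
         standard_conc = 1),
    class = "binding_kinetics"
  )
}

#' Standard binding free energy from rate constants
#'
#' `dG0 = R T log(koff / (kon * C0))`, the free energy of binding at the
#' 1 M standard state, negative for binders.
#'
#' @param kon Association rate constant, 1/(M s).
#' @param koff Dissociation rate constant, 1/s.
#' @param temperature Kelvin.
#' @return Free energy in kcal/mol.
#' @export
free_energy_from_rates <- function(kon, koff, temperature = 298) {
  check_scalar_positive(kon, "kon")
  check_scalar_positive(koff, "koff")
  check_scalar_positive(temperature, "temperature")
  .R_KCAL * temperature * log(koff / kon)
}

#' @export
print.binding_kinetics <- function(x, ...) {
  cat("Binding kinetics\n")
  cat(sprintf("  kon  = %.3g 1/(M s)\n", x$kon))
  cat(sprintf("  koff = %.3g 1/s\n", x$koff))
  cat(sprintf("  Kd   = %.3g M\n", x$Kd))
  cat(sprintf("  dG0  = %.2f kcal/mol (T = %g K, C0 = 1 M)\n",
              x$dG0, x$temperature))
  invisible(x)
}

#' On-rate from an observed binding frequency
#'
#' For rarely sampled binding events the on-rate follows from the observed
#' per-ligand binding frequency and the simulation concentration:
#' `kon = frequency / concentration` after converting the frequency to 1/s.
#'
#' @param binding_frequency Events per microsecond (1/us).
#' @param concentration Simulation concentration, M.
#' @return `kon` in 1/(M s).
#' @export
on_rate_from_frequency <- function(binding_frequency, concentration) {
  check_scalar_positive(binding_frequency, "binding_frequency")
  check_scalar_positive(concentration, "concentration")
  (binding_frequency * 1e6) / concentration
}

#' Standard binding free energy from a dissociation constant
#'
#' `dG = R T log(Kd / C0)` at the 1 M standard state.
#'
#' @param Kd Dissociation constant, M.
#' @param temperature Kelvin.
#' @return Free energy in kcal/mol.
#' @export
free_energy_from_kd <- function(Kd, temperature = 298) {
  check_scalar_positive(Kd, "Kd")
  check_scalar_positive(temperature, "temperature")
  .R_KCAL * temperature * log(Kd)
}

#' Characteristic time of a first-order rate
#'
#' The reciprocal of a rate constant, e.g. a catalytic turnover number maps
#' to the mean time to process one substrate molecule.
#'
#' @param rate Rate in 1/s.
#' @return Time in seconds.
#' @export
timescale_from_rate <- function(rate) {
  check_scalar_positive(rate, "rate")
  1 / rate
}

#' Molar concentration of ligand copies in a box
#'
#' `C = n / (N_A V)` with Avogadro's number `N_A = 6.02214e23`.
#'
#' @param n_copies Number of ligand copies.
#' @param box_volume Box volume in litres.
#' @return Concentration in M.
#' @export
concentration_from_box <- function(n_copies, box_volume) {
  n_copies <- check_count(n_copies, "n_copies")
  check_scalar_positive(box_volume, "box_volume")
  n_copies / (.N_AVOGADRO * box_volume)
}

#' Macrostate binding kinetics from a lumped model
#'
#' Ties the microstate transition model, the labelled macrostates and the
#' simulation concentration together: computes the macrostate mean first
#' passage time matrix, extracts the bulk -> bound and bound -> bulk times,
#' and converts them with [rates_from_mfpt()].
#'
#' Passage times are measured between macrostate cores: the microstates
#' whose PCCA+ membership in their macrostate is at least `core_membership`.
#' Transition-region microstates (an encounter complex sitting at the
#' boundary, say) have ambiguous memberships near 1/M; counting arrival
#' there as arrival in the bound state would systematically shorten the
#' binding time, so they are excluded from the source and target sets.  A
#' macrostate whose core would be empty falls back to its full crisp set.
#'
#' @param macro A labelled `macro_model` (after [identify_bulk_bound()]).
#' @param concentration Simulation concentration in M.
#' @param temperature Kelvin.
#' @param core_membership Minimum membership for a microstate to count as
#'   part of a macrostate's metastable core (default 0.9); set to 0 to use
#'   the plain crisp sets.
#' @return A `binding_kinetics` object carrying the macrostate MFPT matrix.
#' @export
macro_binding_kinetics <- function(macro, concentration, temperature = 298,
                                   core_membership = 0.9) {
  if (!inherits(macro, "macro_model") || is.null(macro$labels)) {
    stop_ligandmsm("`macro` must be a labelled macro_model (run identify_bulk_bound)")
  }
  model <- macro$model
  M <- macro$n_macrostates
  members <- lapply(seq_len(M), function(m) {
    crisp <- which(macro$crisp_assignment == m)
    core <- crisp[macro$memberships[crisp, m] >= core_membership]
    if (length(core)) core else crisp
  })
  mfpt_mat <- matrix(0, M, M, dimnames = list(macro$labels, macro$labels))
  for (a in seq_len(M)) {
    for (b in seq_len(M)) {
      if (a != b) mfpt_mat[a, b] <- mfpt(model, members[[a]], members[[b]])
    }
  }
  rates_from_mfpt(mfpt_on = mfpt_mat[macro$bulk, macro$bound],
                  mfpt_off = mfpt_mat[macro$bound, macro$bulk],
                  concentration = concentration, temperature = temperature,
                  mfpt_matrix = mfpt_mat, labels = macro$labels)
}
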