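# One pass of featurized data through TICA -> k-centers -> (flag split) ->
# reversible MSM -> PCCA -> kinetics.  Shared by the point estimate and by
# every bootstrap run so "the same parameters" is true by construction.
fit_msm_pipeline <- function(features, config, flags = NULL,
                             cluster_seed = NULL) {
  features <- as_ftraj_list(features)
  cluster_seed <- cluster_seed %||% config$seed
  dim <- config$tica_dim
  n_feat <- ncol(features[[1L]]$frames)
  if (dim > n_feat) {
    warning(sprintf("tica_dim reduced from %d to the %d available feature(s)",
                    dim, n_feat))
    dim <- n_feat
  }
  tica <- fit_tica(features, lag = config$tica_lag, dim = dim)
  projected <- lapply(features, function(f) transform_tica(tica, f))
  cl <- kcenters_fit(projected, k = config$n_clusters, seed = cluster_seed)
  dtrajs <- lapply(projected, function(p) assign_microstates(cl, p))
  if (!is.null(flags)) {
    sp <- split_by_flag(cl, dtrajs, flags)
    cl <- sp$model
    dtrajs <- sp$assignments
  }
  counts <- count_transitions(dtrajs, lag = config$msm_lag)
  model <- estimate_reversible(counts)
  its <- implied_timescales(model, n_timescales = config$n_macrostates)
  M <- config$n_macrostates
  n_pos <- sum(reversible_eigen(model$T, model$pi)$values > 1e-12)
  if (M > n_pos) {
    warning(sprintf(
      "n_macrostates reduced from %d to %d (positive transition-matrix eigenvalues)",
      M, n_pos))
    M <- n_pos
  }
  macro <- pcca_lump(model, M)
  scores <- microstate_contact_scores(features, dtrajs, model$active_set)
  macro <- identify_bulk_bound(macro, scores)
  kin <- macro_binding_kinetics(macro, concentration = config$concentration,
                                temperature = config$temperature)
  list(tica = tica, cluster = cl, dtrajs = dtrajs, counts = counts,
       model = model, timescales = its, macro = macro, kinetics = kin)
}

pipeline_observables <- function(fit) {
  c(kon_M_s = fit$kinetics$kon,
    koff_s = fit$kinetics$koff,
    dG0_kcal_mol = fit$kinetics$dG0,
    tau2_ns = fit$timescales$timescales[1L])
}
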