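# The desk-scale synthetic study used by the acceptance-level tests: a
# 30-region connectome, a smooth heterogeneity map, and a Stuart-Landau
# ground truth whose bias/scale modulation spreads the regional bifurcation
# parameters from strongly damped to weakly supercritical while leaving the
# group synchronisation level at the homogeneous model's value for the same
# coupling (so the ground truth sits on the iso-error curve by construction).
study_design <- function() {
  spec <- synthetic_spec(n_regions = 30, seed = 11, subjects = 10,
                         duration = 900, tr = 0.72)
  list(spec = spec,
       map_seed = 12,
       map_smoothness = 20,
       G_star = 0.25,
       bias_star = 32.5,
       scale_star = -24,
       G_grid = seq(0, 1.5, by = 0.25),
       bias_grid = seq(28, 37, by = 1.5),
       scale_grid = seq(-36, -12, by = 6))
}

study_inputs <- function(design = study_design()) {
  bundle <- make_connectome(design$spec)
  map <- make_heterogeneity_map(bundle$coords, design$map_smoothness,
                                seed = design$map_seed)
  emp <- make_ground_truth_bold(
    bundle, design$spec, "hopf",
    params = hopf_params(bundle$n_regions, G = design$G_star,
                         duration = design$spec$duration),
    map = map, bias = design$bias_star, scale = design$scale_star)
  list(design = design, bundle = bundle, map = map, emp = emp)
}
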