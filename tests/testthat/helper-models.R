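# Shared fixtures: reduced models with closed-form solutions, built in code.

# neutral, unbound, evenly partitioning probe drug; single plasma clearance
probe_drug <- function(name = "probe", cl_plasma_lph = 5, bw = 73,
                       papp = 1e-4, gfr_fraction = 0) {
  # log P 2 keeps membrane permeation fast while lipid/protein binding
  # terms stay negligible at fup = 1
  drug_parameters(
    name = name, molecular_weight = 400, pka_list = list(), log_p = 2,
    permeability_papp = papp, fup_healthy = 1, rbp_healthy = 1,
    gfr_fraction = gfr_fraction, kia_scale = 1, kir_scale = 1,
    weibull_t50 = 30, weibull_shape = 1,
    cl_additional = cl_plasma_lph / bw
  )
}

# physiology tuned for compartmental reductions: very fast flows (instant
# mixing), no blood-brain barrier tightness
mixing_physiology <- function(flow_scale = 1000) {
  phys <- default_human_physiology()
  phys$organs$flow_lph <- phys$organs$flow_lph * flow_scale
  phys$organs$barrier_factor[] <- 1
  phys
}

# strip lipid/phospholipid binding so tissue capacities reduce to water
lipid_free <- function(phys) {
  phys$organs$f_nl <- 0
  phys$organs$f_np <- 0
  phys$organs$ap_mg_g <- 0
  phys
}

# equilibrium distribution volume (unbound = plasma basis for fup = rbp = 1)
effective_volume <- function(model, species = 1) {
  sp <- model$species[[species]]
  model$v_art + model$v_ven + sum(model$v_vas) +
    sum(model$v_int * sp$kpu_int) + sum(model$v_cell * sp$kpu_cell)
}

fast_settings <- function(t_end_h = 48, dt = 0.25) {
  simulation_settings(t_end_h = t_end_h, dt_out_h = dt,
                      rtol = 1e-8, atol = 1e-10)
}

# patient model for a shipped inhibitor
patient_model <- function(drug_name, engine = engine_defaults()) {
  ds <- load_drug_set(drug_name)
  cp <- apply_cancer_physiology(default_human_physiology(), ds[[1]])
  ds[[1]] <- cp$drug
  list(drugs = ds, physiology = cp$physiology,
       model = build_model(ds, cp$physiology, engine))
}
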