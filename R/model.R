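#' Dosing regimen
#'
#' @param route `"oral"`, `"iv_bolus"` or `"iv_infusion"`.
#' @param dose_mg Dose per administration, mg (>= 0).
#' @param interval_h Dosing interval, h (> 0 when `n_doses > 1`). BID = 12 h,
#'   OD = 24 h; the first dose is at `start_h`.
#' @param n_doses Number of administrations (>= 1).
#' @param start_h Time of the first dose, h.
#' @param infusion_h Infusion duration for `"iv_infusion"`, h.
#' @return An object of class `regimen`.
#' @export
regimen <- function(route = c("oral", "iv_bolus", "iv_infusion"),
                    dose_mg, interval_h = 24, n_doses = 1, start_h = 0,
                    infusion_h = 1) {
  route <- match.arg(route)
  .check_scalar(dose_mg, "dose_mg", 0)
  .check_scalar(n_doses, "n_doses", 1)
  if (n_doses > 1) .check_scalar(interval_h, "interval_h", 0, open_lower = TRUE)
  .check_scalar(start_h, "start_h", 0)
  if (route == "iv_infusion") {
    .check_scalar(infusion_h, "infusion_h", 0, open_lower = TRUE)
  }
  structure(list(route = route, dose_mg = dose_mg, interval_h = interval_h,
                 n_doses = n_doses, start_h = start_h,
                 infusion_h = infusion_h),
            class = "regimen")
}

#' Solver and output settings
#'
#' @param t_end_h Simulation end time, h (> 0).
#' @param dt_out_h Output grid step, h (> 0).
#' @param rtol,atol Relative/absolute solver tolerances (> 0).
#' @param seed Optional random seed recorded for population use.
#' @return An object of class `simulation_settings`.
#' @export
simulation_settings <- function(t_end_h = 24, dt_out_h = 0.25,
                                rtol = 1e-8, atol = 1e-10, seed = NULL) {
  .check_scalar(t_end_h, "t_end_h", 0, open_lower = TRUE)
  .check_scalar(dt_out_h, "dt_out_h", 0, open_lower = TRUE)
  .check_scalar(rtol, "rtol", 0, open_lower = TRUE)
  .check_scalar(atol, "atol", 0, open_lower = TRUE)
  structure(list(t_end_h = t_end_h, dt_out_h = dt_out_h,
                 rtol = rtol, atol = atol, seed = seed),
            class = "simulation_settings")
}

#' Weibull dissolution profile
#'
#' Fraction of an oral dose dissolved at time `t`, anchored so that exactly
#' half the dose is dissolved at `t50` (the tabulated "Weibull time"):
#' \deqn{F(t) = 1 - \exp(-\ln 2 \, (t/t_{50})^{shape})}
#'
#' @param t Time since administration, min (>= 0, vectorised).
#' @param t50 Time to 50% dissolution, min (> 0).
#' @param shape Weibull shape parameter (> 0).
#' @return Fraction dissolved in \[0, 1).
#' @export
weibull_fraction_dissolved <- function(t, t50, shape) {
  stopifnot(is.numeric(t), all(t >= 0))
  .check_scalar(t50, "t50", 0, open_lower = TRUE)
  .check_scalar(shape, "shape", 0, open_lower = TRUE)
  1 - exp(-log(2) * (t / t50)^shape)
}

#' Engine constants
#'
#' Numerical and scaling constants of the PBPK engine that are not printed
#' drug or physiology parameters. All are overridable; defaults were fixed
#' during model development against the clinical training data and are
#' documented in the methods vignette.
#'
#' @param peff_slope,peff_intercept Coefficients of the log-log correlation
#'   from apparent (monolayer) permeability (1e-6 cm/s) to human jejunal
#'   effective permeability (1e-4 cm/s).
#' @param intestine_radius_cm Effective small-intestinal radius for
#'   `ka = 2 Peff / r`.
#' @param transit_h Mean small-intestinal transit time (first-order loss of
#'   lumen contents to non-absorbing segments).
#' @param cell_perm_slope,cell_perm_intercept log10 cellular permeability
#'   (cm/s) correlation from log P.
#' @param ps_cap_factor Permeability-surface products are capped at this
#'   multiple of the organ blood flow (numerical stiffness control; inactive
#'   when exchange is flow-limited).
#' @param pgp_capacity Transporter capacity at the blood-brain barrier,
#'   10^6 cells per uM of P-gp expression (converts the per-cell intrinsic
#'   transport velocity into a barrier efflux clearance).
#' @param mbi_scale In-vivo scaling of mechanism-based CYP3A4 inactivation
#'   applied on top of the in-vitro kinact/KI term (in-vitro inactivation
#'   kinetics over-predict in vivo; calibrated against clinical steady-state
#'   exposure).
#' @param interaction_site `"liver_intracellular"` or `"venous_plasma"`:
#'   which unbound concentration drives enzyme inhibition/induction.
#' @param weibull_rate_cap_h Upper bound on the instantaneous dissolution
#'   hazard, 1/h.
#' @return A named list of engine constants.
#' @export
engine_defaults <- function(peff_slope = 0.4926, peff_intercept = -0.1454,
                            intestine_radius_cm = 1.25, transit_h = 3.25,
                            cell_perm_slope = 0.55, cell_perm_intercept = -4.2,
                            ps_cap_factor = 500, pgp_capacity = 5.6e4,
                            mbi_scale = 0.35,
                            interaction_site = c("liver_intracellular",
                                                 "venous_plasma"),
                            weibull_rate_cap_h = 100) {
  list(peff_slope = peff_slope, peff_intercept = peff_intercept,
       intestine_radius_cm = intestine_radius_cm, transit_h = transit_h,
       cell_perm_slope = cell_perm_slope,
       cell_perm_intercept = cell_perm_intercept,
       ps_cap_factor = ps_cap_factor, pgp_capacity = pgp_capacity,
       mbi_scale = mbi_scale,
       interaction_site = match.arg(interaction_site),
       weibull_rate_cap_h = weibull_rate_cap_h)
}

# healthy-reference expression anchors: tabulated intrinsic clearances refer
# to these liver reference concentrations (uM per L liver)
.reference_expression <- c(
  CYP3A4 = 4.32, CYP3A5 = 0.04, CYP2C8 = 2.56, CYP2C19 = 0.76,
  UGT1A3 = 0.53, UGT1A4 = 0.25, `P-gp` = 0.68
)

# internal: expression (uM/L liver) of a molecule in a physiology set
.expression_of <- function(physiology, molecule) {
  et <- physiology$expression_table
  i <- match(molecule, et$molecule)
  if (is.na(i)) NA_real_ else et$reference_conc_uM[i]
}

#' Assemble a whole-body PBPK model
#'
#' Builds the compartmental structure for one or more chemical species
#' (drugs and their metabolites) over a shared physiology: permeability-
#' limited tissues with vascular, interstitial and intracellular
#' sub-compartments (plasma and blood cells equilibrate within the vascular
#' space through the blood-to-plasma ratio), Weibull-dissolution oral
#' absorption with first-order lumen transit, hepatic metabolism scaled by
#' enzyme expression, P-gp efflux at the blood-brain barrier, renal
#' filtration clearance `GFR * fup * gfr_fraction` and optional additional
#' plasma clearance. Species listed in a drug's pathway `product` fields are
#' resolved against `drugs` and receive the formed molar flux in the liver.
#'
#' @param drugs A [drug_parameters()] object or list of them (parents and
#'   metabolites).
#' @param physiology A [physiology_parameters()] object.
#' @param engine Engine constants from [engine_defaults()].
#' @return An object of class `pbpk_model`.
#' @export
build_model <- function(drugs, physiology, engine = engine_defaults()) {
  if (inherits(drugs, "drug_parameters")) drugs <- list(drugs)
  stopifnot(length(drugs) >= 1,
            all(vapply(drugs, inherits, TRUE, "drug_parameters")),
            inherits(physiology, "physiology_parameters"))
  sp_names <- vapply(drugs, `[[`, "", "name")
  if (anyDuplicated(sp_names)) stop("duplicate species names")
  org <- physiology$organs
  n_org <- nrow(org)
  i_liv <- match("liver", org$organ)
  i_gut <- match("gut", org$organ)
  i_spl <- match("spleen", org$organ)
  i_lun <- match("lung", org$organ)
  i_brn <- match("brain", org$organ)
  i_kid <- match("kidney", org$organ)
  if (anyNA(c(i_liv, i_gut, i_spl, i_lun, i_brn, i_kid))) {
    stop("physiology must contain lung, brain, kidney, liver, gut, spleen")
  }
  q_co <- org$flow_lph[i_lun]
  systemic <- setdiff(seq_len(n_org), c(i_lun, i_gut, i_spl))
  if (abs(sum(org$flow_lph[setdiff(seq_len(n_org), i_lun)]) - q_co) >
      1e-6 * q_co) {
    stop("blood-flow graph not conservative: organ flows must sum to the ",
         "cardiac output carried by the lung")
  }

  gfr_lph <- physiology$gfr * 60 / 1000
  species <- vector("list", length(drugs))
  for (s in seq_along(drugs)) {
    d <- drugs[[s]]
    part <- rodgers_rowland_partition(d, physiology)
    fup <- .fup_for(d, physiology)
    rbp <- .rbp_for(d, physiology)
    # vascular <-> interstitial permeability-surface products (L/h)
    ps1 <- d$permeability_papp * 3600 * org$sa_factor * org$barrier_factor *
      org$volume_l / 1000
    # interstitial <-> intracellular, from the log P permeability correlation
    p_cell <- 10^(engine$cell_perm_slope * d$log_p + engine$cell_perm_intercept)
    ps2 <- p_cell * 3600 * org$sa_factor * org$volume_l / 1000
    cap <- engine$ps_cap_factor * pmax(org$flow_lph, q_co / 50)
    ps1 <- pmin(ps1, cap)
    ps2 <- pmin(ps2, cap)
    # oral absorption rate constant from jejunal effective permeability
    peff <- 10^(engine$peff_slope * log10(d$permeability_papp * 1e6) +
                  engine$peff_intercept) * 1e-4           # cm/s
    ka <- 2 * peff * 3600 / engine$intestine_radius_cm    # 1/h
    # hepatic pathways at current (static) expression, unbound basis
    mppgl <- physiology$liver$microsomal_protein_mg_per_g
    lmass <- physiology$liver$mass_g
    lvol <- physiology$liver$volume_l
    paths <- lapply(d$pathways, function(p) {
      enz <- p$enzyme
      expr_now <- if (enz == "HLM") NA_real_ else .expression_of(physiology, enz)
      expr_ref <- if (enz == "HLM") NA_real_ else .reference_expression[[enz]]
      if (!is.null(p$cl_int)) {
        cl_u <- if (p$cl_int_basis == "per_pmol_enzyme") {
          isef <- if (is.na(p$isef)) 1 else p$isef
          p$cl_int * isef * 60 * (if (is.na(expr_now)) 0 else expr_now) * lvol
        } else {
          base <- p$cl_int * 6e-5 * mppgl * lmass
          if (enz == "HLM") base else base * expr_now / expr_ref
        }
        list(type = "fo", enzyme = enz, cl_u = cl_u,
             product = p$product)
      } else {
        scale <- if (enz == "HLM") 1 else expr_now / expr_ref
        list(type = "mm", enzyme = enz,
             vmax_umol_h = p$v_max * 1e-6 * 60 * mppgl * lmass * scale,
             km = p$k_m, product = p$product)
      }
    })
    # brain P-gp efflux clearance at current expression
    pgp <- NULL
    for (tr in d$transporters) {
      if (tr$transporter == "P-gp" && tr$site == "brain") {
        e_brain <- .expression_of(physiology, "P-gp") *
          physiology$expression_table$rel_brain[
            physiology$expression_table$molecule == "P-gp"]
        pgp <- list(cl = tr$cl_int * 6e-5 * engine$pgp_capacity * e_brain,
                    km = tr$k_m)
      }
    }
    species[[s]] <- list(
      name = d$name, mw = d$molecular_weight, fup = fup, rbp = rbp,
      kpu_cell = part$kpu_cell, kpu_int = part$kpu_int,
      trap = part$trap_cell[1], ps1 = ps1, ps2 = ps2, ka = ka,
      kt = 1 / engine$transit_h,
      weibull_t50_h = d$weibull_t50 / 60, weibull_shape = d$weibull_shape,
      renal_cl_u = gfr_lph * d$gfr_fraction,
      cl_add = if (is.null(d$cl_additional)) 0 else
        d$cl_additional * physiology$body_weight,
      paths = paths, pgp = pgp, interaction = d$interaction
    )
  }
  names(species) <- sp_names
  # resolve metabolite products to species indices
  for (s in seq_along(species)) {
    for (k in seq_along(species[[s]]$paths)) {
      prod <- species[[s]]$paths[[k]]$product
      species[[s]]$paths[[k]]$product_idx <-
        if (identical(prod, "sink") || !prod %in% sp_names) NA_integer_
        else match(prod, sp_names)
    }
  }
  # dynamic enzymes: turnover defined and referenced by interactions or
  # inducible/inhibitable pathways
  et <- physiology$expression_table
  dyn <- character()
  any_interaction <- any(!vapply(species, function(sp)
    is.null(sp$interaction), TRUE))
  if (any_interaction) {
    dyn <- et$molecule[!is.na(et$turnover_half_life_h)]
  }
  enzymes <- lapply(dyn, function(m) {
    list(name = m, kdeg = log(2) / et$turnover_half_life_h[et$molecule == m])
  })
  names(enzymes) <- dyn

  structure(
    list(species = species, enzymes = enzymes, physiology = physiology,
         engine = engine, n_org = n_org, organs = org$organ,
         q = org$flow_lph, v_vas = org$volume_l * org$f_vas,
         v_int = org$volume_l * org$f_int, v_cell = org$volume_l * org$f_cell,
         i_liv = i_liv, i_gut = i_gut, i_spl = i_spl, i_lun = i_lun,
         i_brn = i_brn, i_kid = i_kid, q_co = q_co, systemic = systemic,
         v_art = physiology$blood$v_arterial,
         v_ven = physiology$blood$v_venous),
    class = "pbpk_model"
  )
}

#' @export
print.pbpk_model <- function(x, ...) {
  cat("<pbpk_model> species:", paste(names(x$species), collapse = ", "), "\n")
  cat(sprintf("  %d organs, cardiac output %.0f L/h, population %s\n",
              x$n_org, x$q_co, x$physiology$population_tag))
  invisible(x)
}
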