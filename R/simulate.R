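#' Enzyme turnover under inhibition and induction
#'
#' Rate of change of an enzyme pool subject to first-order turnover,
#' concentration-dependent induction of synthesis and mechanism-based
#' inactivation:
#' \deqn{dE/dt = k_{deg} E_0 \left(1 + \frac{E_{max} I}{EC_{50}+I}\right)
#'   - k_{deg} E - \frac{k_{inact} I}{K_I + I} E}
#' Reversible (competitive) inhibition does not change the pool; it scales
#' metabolic flux as `CL/(1 + I/Ki)` inside the simulation.
#'
#' @param enzyme_state Current enzyme amount/activity `E` (>= 0).
#' @param inhibitor_unbound Unbound perpetrator concentration `I`, uM (>= 0).
#' @param params An [interaction_parameters()] object.
#' @param kdeg First-order degradation rate constant, 1/h (> 0).
#' @param e0 Baseline enzyme amount (same units as `enzyme_state`).
#' @return dE/dt in units of `enzyme_state` per hour.
#' @export
enzyme_interaction_rates <- function(enzyme_state, inhibitor_unbound, params,
                                     kdeg, e0 = 1) {
  .check_scalar(enzyme_state, "enzyme_state", 0)
  .check_scalar(inhibitor_unbound, "inhibitor_unbound", 0)
  .check_scalar(kdeg, "kdeg", 0, open_lower = TRUE)
  stopifnot(inherits(params, "interaction_parameters"))
  ind <- 0
  if (!is.null(params$emax_cyp3a4)) {
    ind <- params$emax_cyp3a4 * inhibitor_unbound /
      (params$ec50_cyp3a4 + inhibitor_unbound)
  }
  inact <- 0
  if (!is.null(params$kinact_cyp3a4)) {
    inact <- params$kinact_cyp3a4 * inhibitor_unbound /
      (params$ki_cyp3a4 + inhibitor_unbound)
  }
  kdeg * e0 * (1 + ind) - kdeg * enzyme_state - inact * enzyme_state
}

# ---- state indexing -------------------------------------------------------

.state_index <- function(model) {
  n <- model$n_org
  per <- 5 + 3 * n + 7
  idx <- vector("list", length(model$species))
  nm <- character(0)
  for (s in seq_along(model$species)) {
    o <- (s - 1) * per
    sp <- names(model$species)[s]
    idx[[s]] <- list(
      solid = o + 1, diss = o + 2, tdose = o + 3, inf = o + 4, cumdose = o + 5,
      vas = o + 5 + seq_len(n), int = o + 5 + n + seq_len(n),
      cell = o + 5 + 2 * n + seq_len(n),
      art = o + 5 + 3 * n + 1, ven = o + 5 + 3 * n + 2,
      met = o + 5 + 3 * n + 3, renal = o + 5 + 3 * n + 4,
      add = o + 5 + 3 * n + 5, fecal = o + 5 + 3 * n + 6,
      formed = o + 5 + 3 * n + 7
    )
    nm <- c(nm, paste0(c("gut_solid", "gut_diss", "t_dose", "inf_rate",
                         "cum_dose",
                         paste0("vas_", model$organs),
                         paste0("int_", model$organs),
                         paste0("cell_", model$organs),
                         "art", "ven", "cum_met", "cum_renal", "cum_add",
                         "cum_fecal", "cum_formed"), ".", sp))
  }
  n_enz <- length(model$enzymes)
  e_idx <- if (n_enz) length(model$species) * per + seq_len(n_enz) else integer()
  nm <- c(nm, if (n_enz) paste0("enz_", names(model$enzymes)))
  list(idx = idx, enz = e_idx, names = nm, n_state = length(nm))
}

# ---- right-hand side ------------------------------------------------------

.pbpk_rhs <- function(t, y, p) {
  m <- p$model
  ix <- p$ix
  n <- m$n_org
  i_liv <- m$i_liv; i_gut <- m$i_gut; i_spl <- m$i_spl
  i_lun <- m$i_lun; i_brn <- m$i_brn; i_kid <- m$i_kid
  q <- m$q; q_co <- m$q_co
  q_liv_out <- q[i_liv] + q[i_gut] + q[i_spl]
  dy <- numeric(length(y))
  ns <- length(m$species)

  # pass 1: concentrations and perpetrator levels
  conc <- vector("list", ns)
  i_perp <- numeric(ns)
  for (s in seq_len(ns)) {
    sp <- m$species[[s]]
    id <- ix$idx[[s]]
    c_vas <- y[id$vas] / m$v_vas
    u_vas <- c_vas * sp$fup / sp$rbp
    u_int <- y[id$int] / (m$v_int * sp$kpu_int)
    u_cell <- y[id$cell] / (m$v_cell * sp$kpu_cell)
    c_art <- y[id$art] / m$v_art
    c_ven <- y[id$ven] / m$v_ven
    conc[[s]] <- list(c_vas = c_vas, u_vas = u_vas, u_int = u_int,
                      u_cell = u_cell, c_art = c_art, c_ven = c_ven)
    i_perp[s] <- if (p$site_liver) {
      max(0, sp$trap * u_cell[i_liv])
    } else {
      max(0, c_ven * sp$fup / sp$rbp)
    }
  }

  # enzyme dynamics and interaction modifiers (CYP3A4 pool)
  e_mult <- rep(1, ns)            # placeholder; enzyme multiplier by name
  e_state <- setNames(rep(1, length(m$enzymes)), names(m$enzymes))
  if (length(ix$enz)) e_state[] <- y[ix$enz]
  if (length(ix$enz)) {
    for (k in seq_along(m$enzymes)) {
      enz <- m$enzymes[[k]]
      ind_sum <- 0; inact_sum <- 0
      for (s in seq_len(ns)) {
        ip <- m$species[[s]]$interaction
        if (is.null(ip)) next
        I <- i_perp[s]
        if (!is.null(ip$emax_cyp3a4)) {
          ind_sum <- ind_sum + ip$emax_cyp3a4 * I / (ip$ec50_cyp3a4 + I)
        }
        if (!is.null(ip$kinact_cyp3a4)) {
          inact_sum <- inact_sum + ip$kinact_cyp3a4 * I / (ip$ki_cyp3a4 + I)
        }
      }
      E <- e_state[k]
      dy[ix$enz[k]] <- enz$kdeg * (1 + ind_sum) - enz$kdeg * E -
        p$mbi_scale * inact_sum * E
    }
  }
  # competitive inhibition factor on CYP3A4 flux of species s (other species)
  inh_factor <- rep(1, ns)
  for (s in seq_len(ns)) {
    tot <- 0
    for (j in seq_len(ns)) {
      if (j == s) next
      ip <- m$species[[j]]$interaction
      if (!is.null(ip) && !is.null(ip$ki_cyp3a4)) {
        tot <- tot + i_perp[j] / ip$ki_cyp3a4
      }
    }
    inh_factor[s] <- 1 + tot
  }

  # pass 2: species mass balances
  formed <- matrix(0, ns, 1)
  form_flux <- numeric(ns)
  for (s in seq_len(ns)) {
    sp <- m$species[[s]]
    id <- ix$idx[[s]]
    cc <- conc[[s]]
    j1 <- sp$ps1 * (cc$u_vas - cc$u_int)
    j2 <- sp$ps2 * (cc$u_int - cc$u_cell)

    d_vas <- q * (cc$c_art - cc$c_vas) - j1
    d_vas[i_lun] <- q_co * (cc$c_ven - cc$c_vas[i_lun]) - j1[i_lun]
    d_vas[i_liv] <- q[i_liv] * cc$c_art + q[i_gut] * cc$c_vas[i_gut] +
      q[i_spl] * cc$c_vas[i_spl] - q_liv_out * cc$c_vas[i_liv] - j1[i_liv]
    d_int <- j1 - j2
    d_cell <- j2

    # oral absorption and dissolution
    a_solid <- y[id$solid]; a_diss <- y[id$diss]
    age <- t - y[id$tdose]
    rate <- 0
    if (a_solid > 0 && age > 0) {
      rate <- log(2) * sp$weibull_shape * age^(sp$weibull_shape - 1) /
        sp$weibull_t50_h^sp$weibull_shape
      rate <- min(rate, p$weibull_cap)
    }
    dy[id$solid] <- -rate * a_solid - sp$kt * a_solid
    abs_flux <- sp$ka * a_diss
    dy[id$diss] <- rate * a_solid - abs_flux - sp$kt * a_diss
    dy[id$fecal] <- sp$kt * (a_solid + a_diss)
    d_vas[i_gut] <- d_vas[i_gut] + abs_flux

    # renal filtration
    renal_flux <- sp$renal_cl_u * max(0, cc$u_vas[i_kid])
    d_vas[i_kid] <- d_vas[i_kid] - renal_flux
    dy[id$renal] <- renal_flux

    # P-gp efflux at the blood-brain barrier
    if (!is.null(sp$pgp)) {
      u <- max(0, cc$u_int[i_brn])
      pgp_flux <- sp$pgp$cl * u / (1 + u / sp$pgp$km)
      d_int[i_brn] <- d_int[i_brn] - pgp_flux
      d_vas[i_brn] <- d_vas[i_brn] + pgp_flux
    }

    # hepatic metabolism (intracellular unbound water concentration)
    cu_liv <- max(0, sp$trap * cc$u_cell[i_liv])
    met_total <- 0
    for (pw in sp$paths) {
      emul <- if (pw$enzyme %in% names(e_state)) e_state[[pw$enzyme]] else 1
      v <- if (pw$type == "fo") {
        scale_inh <- if (pw$enzyme == "CYP3A4") inh_factor[s] else 1
        pw$cl_u * emul / scale_inh * cu_liv
      } else {
        km_app <- pw$km * (if (pw$enzyme == "CYP3A4") inh_factor[s] else 1)
        pw$vmax_umol_h * emul * cu_liv / (km_app + cu_liv)
      }
      met_total <- met_total + v
      if (!is.na(pw$product_idx)) {
        form_flux[pw$product_idx] <- form_flux[pw$product_idx] + v
      }
    }
    d_cell[i_liv] <- d_cell[i_liv] - met_total
    dy[id$met] <- met_total

    # systemic blood pools
    dy[id$art] <- q_co * (cc$c_vas[i_lun] - cc$c_art)
    ven_in <- sum(q[setdiff(m$systemic, c(i_liv, i_lun))] *
                    cc$c_vas[setdiff(m$systemic, c(i_liv, i_lun))]) +
      q_liv_out * cc$c_vas[i_liv]
    add_flux <- sp$cl_add * max(0, cc$c_ven) / sp$rbp
    dy[id$ven] <- ven_in - q_co * cc$c_ven - add_flux + y[id$inf]
    dy[id$add] <- add_flux
    dy[id$cumdose] <- y[id$inf]

    dy[id$vas] <- d_vas
    dy[id$int] <- d_int
    dy[id$cell] <- d_cell
  }
  # metabolite formation arrives in the liver intracellular space
  for (s in seq_len(ns)) {
    if (form_flux[s] > 0) {
      id <- ix$idx[[s]]
      dy[id$cell[i_liv]] <- dy[id$cell[i_liv]] + form_flux[s]
      dy[id$formed] <- form_flux[s]
    }
  }
  list(dy)
}

# ---- event schedule -------------------------------------------------------

.build_events <- function(model, doses, ix, t_end) {
  ns <- length(model$species)
  if (inherits(doses, "regimen")) {
    doses <- setNames(c(list(doses), rep(list(NULL), ns - 1)),
                      names(model$species))
  }
  rows <- list()
  for (s in seq_len(ns)) {
    reg <- doses[[names(model$species)[s]]]
    if (is.null(reg)) next
    stopifnot(inherits(reg, "regimen"))
    sp <- model$species[[s]]
    id <- ix$idx[[s]]
    times <- reg$start_h + (seq_len(reg$n_doses) - 1) * reg$interval_h
    times <- times[times <= t_end]
    if (!length(times)) next
    amt <- reg$dose_mg / sp$mw * 1000  # mg -> umol
    nmv <- ix$names
    for (tt in times) {
      if (reg$route == "oral") {
        rows[[length(rows) + 1]] <- data.frame(
          var = c(nmv[id$solid], nmv[id$tdose], nmv[id$cumdose]),
          time = tt, value = c(amt, tt, amt),
          method = c("add", "rep", "add"))
      } else if (reg$route == "iv_bolus") {
        rows[[length(rows) + 1]] <- data.frame(
          var = c(nmv[id$ven], nmv[id$cumdose]),
          time = tt, value = c(amt, amt), method = "add")
      } else {
        rate <- amt / reg$infusion_h
        rows[[length(rows) + 1]] <- data.frame(
          var = nmv[id$inf], time = c(tt, tt + reg$infusion_h),
          value = c(rate, 0), method = "rep")
      }
    }
  }
  if (!length(rows)) return(NULL)
  ev <- do.call(rbind, rows)
  ev[order(ev$time), , drop = FALSE]
}

#' Run a PBPK simulation
#'
#' Integrates the whole-body model with a stiff solver (lsoda), applying the
#' dosing schedule as solver events. Deterministic for fixed settings.
#'
#' @param model A [build_model()] object.
#' @param doses A [regimen()] (applied to the first species) or a named list
#'   of regimens keyed by species name (species without a regimen receive
#'   none, e.g. metabolites).
#' @param settings A [simulation_settings()] object.
#' @return An object of class `simulation_result` with elements `time` (h),
#'   `profiles` (per-species data frames: venous plasma total/unbound,
#'   brain-interstitial unbound, liver-intracellular unbound), `enzymes`
#'   (relative activity series), `state` (full state matrix, umol), `model`,
#'   `doses`, `settings`.
#' @export
simulate_pbpk <- function(model, doses, settings = simulation_settings()) {
  stopifnot(inherits(model, "pbpk_model"),
            inherits(settings, "simulation_settings"))
  ix <- .state_index(model)
  t_end <- settings$t_end_h
  ev <- .build_events(model, doses, ix, t_end)
  times <- seq(0, t_end, by = settings$dt_out_h)
  if (!is.null(ev)) times <- sort(unique(c(times, ev$time)))
  y0 <- setNames(numeric(ix$n_state), ix$names)
  if (length(ix$enz)) y0[ix$enz] <- 1
  for (s in seq_along(model$species)) y0[ix$idx[[s]]$tdose] <- -1e6
  parms <- list(model = model, ix = ix,
                site_liver = model$engine$interaction_site ==
                  "liver_intracellular",
                mbi_scale = model$engine$mbi_scale,
                weibull_cap = model$engine$weibull_rate_cap_h)
  out <- try(deSolve::lsoda(
    y = y0, times = times, func = .pbpk_rhs, parms = parms,
    rtol = settings$rtol, atol = settings$atol,
    events = if (is.null(ev)) NULL else list(data = ev),
    maxsteps = 50000
  ), silent = TRUE)
  if (inherits(out, "try-error") || anyNA(out[, 1])) {
    stop("ODE solver failure: ", attr(out, "condition")$message %||% "NA state",
         "\nstate dump written to last row of partial output")
  }
  tt <- out[, 1]
  profiles <- vector("list", length(model$species))
  for (s in seq_along(model$species)) {
    sp <- model$species[[s]]
    id <- ix$idx[[s]]
    c_ven_blood <- out[, 1 + id$ven] / model$v_ven      # uM blood
    c_pl <- c_ven_blood / sp$rbp                        # uM total plasma
    u_int_brn <- out[, 1 + id$int[model$i_brn]] /
      (model$v_int[model$i_brn] * sp$kpu_int[model$i_brn])
    u_cell_liv <- sp$trap * out[, 1 + id$cell[model$i_liv]] /
      (model$v_cell[model$i_liv] * sp$kpu_cell[model$i_liv])
    profiles[[s]] <- data.frame(
      time = tt,
      plasma_total_uM = c_pl,
      plasma_total_ngml = c_pl * sp$mw,
      plasma_unbound_uM = c_pl * sp$fup,
      brain_interstitial_unbound_uM = u_int_brn,
      liver_intracellular_unbound_uM = u_cell_liv
    )
  }
  names(profiles) <- names(model$species)
  enz <- NULL
  if (length(ix$enz)) {
    enz <- as.data.frame(out[, 1 + ix$enz, drop = FALSE])
    names(enz) <- names(model$enzymes)
    enz <- cbind(time = tt, enz)
  }
  structure(
    list(time = tt, profiles = profiles, enzymes = enz,
         state = out, ix = ix, model = model, doses = doses,
         settings = settings),
    class = "simulation_result"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result> ", length(x$time), " time points, species: ",
      paste(names(x$profiles), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Tidy concentration series
#'
#' @param x A `simulation_result`.
#' @param row.names,optional Ignored (S3 signature).
#' @param ... Ignored.
#' @return Long data frame: `time`, `species`, `compartment`, `value`, `unit`.
#' @export
as.data.frame.simulation_result <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  do.call(rbind, lapply(names(x$profiles), function(sp) {
    pr <- x$profiles[[sp]]
    comps <- setdiff(names(pr), "time")
    do.call(rbind, lapply(comps, function(cc) {
      data.frame(time = pr$time, species = sp, compartment = cc,
                 value = pr[[cc]],
                 unit = if (grepl("ngml", cc)) "ng/mL" else "uM")
    }))
  }))
}

#' Mass-balance audit of a simulation
#'
#' Total drug present across all compartments plus cumulative elimination and
#' lumen losses must equal administered dose plus formed metabolite at all
#' output times.
#'
#' @param result A `simulation_result`.
#' @return Data frame per species: administered, formed, and the maximum
#'   absolute balance error relative to the total input.
#' @export
mass_balance <- function(result) {
  out <- result$state
  ix <- result$ix
  m <- result$model
  res <- lapply(seq_along(m$species), function(s) {
    id <- ix$idx[[s]]
    present <- out[, 1 + id$solid] + out[, 1 + id$diss] +
      rowSums(out[, 1 + c(id$vas, id$int, id$cell), drop = FALSE]) +
      out[, 1 + id$art] + out[, 1 + id$ven]
    elim <- out[, 1 + id$met] + out[, 1 + id$renal] + out[, 1 + id$add] +
      out[, 1 + id$fecal]
    input <- out[, 1 + id$cumdose] + out[, 1 + id$formed]
    denom <- max(input, 1e-12)
    data.frame(species = names(m$species)[s],
               administered_umol = max(out[, 1 + id$cumdose]),
               formed_umol = max(out[, 1 + id$formed]),
               max_rel_error = max(abs(present + elim - input)) / denom)
  })
  do.call(rbind, res)
}

#' PK metrics from a simulated profile
#'
#' AUC by the trapezoid rule on the output grid, Cmax as the grid maximum and
#' Ctrough as the concentration at the end of the final dosing interval
#' inside the window.
#'
#' @param result A `simulation_result`.
#' @param species Species name (default first).
#' @param compartment Profile column (default total venous plasma, ng/mL).
#' @param window `c(t_start, t_end)` in h; default the full simulated span.
#' @param interval_h Dosing interval used to locate troughs and assess time
#'   to steady state (optional).
#' @return An object of class `pk_metrics`: `auc` (conc*h), `cmax`, `ctrough`
#'   (same unit as the profile), `time_to_steady_state` (h or `NA`).
#' @export
pk_metrics <- function(result, species = NULL,
                       compartment = "plasma_total_ngml",
                       window = NULL, interval_h = NULL) {
  stopifnot(inherits(result, "simulation_result"))
  species <- species %||% names(result$profiles)[1]
  pr <- result$profiles[[species]]
  if (is.null(pr)) stop("unknown species: ", species)
  if (!compartment %in% names(pr)) stop("unknown compartment: ", compartment)
  window <- window %||% range(pr$time)
  sel <- pr$time >= window[1] - 1e-9 & pr$time <= window[2] + 1e-9
  tt <- pr$time[sel]; cv <- pr[[compartment]][sel]
  if (length(tt) < 2) stop("window contains fewer than two output points")
  auc <- sum(diff(tt) * (head(cv, -1) + cv[-1]) / 2)
  ctrough <- cv[length(cv)]
  tss <- NA_real_
  if (!is.null(interval_h)) {
    tr_times <- seq(window[1] + interval_h, window[2], by = interval_h)
    if (length(tr_times) >= 2) {
      troughs <- stats::approx(tt, cv, xout = tr_times)$y
      final <- troughs[length(troughs)]
      if (final > 0) {
        ok <- which(abs(troughs - final) / final < 0.05)
        if (length(ok)) tss <- tr_times[min(ok)]
      }
    }
  }
  structure(list(auc = auc, cmax = max(cv), ctrough = ctrough,
                 time_to_steady_state = tss,
                 species = species, compartment = compartment,
                 window = window),
            class = "pk_metrics")
}

#' @export
print.pk_metrics <- function(x, ...) {
  cat(sprintf("<pk_metrics> %s / %s\n  AUC %.4g conc*h, Cmax %.4g, Ctrough %.4g\n",
              x$species, x$compartment, x$auc, x$cmax, x$ctrough))
  invisible(x)
}

#' Simulate repeated dosing to steady state
#'
#' Runs the regimen for at least 14 days and extends the simulation until the
#' trough concentration of successive dosing intervals changes by less than
#' 1% (or a cap is reached); returns the final-interval metrics.
#'
#' @param model A [build_model()] object.
#' @param reg A [regimen()] template; `n_doses` is derived from the simulated
#'   span.
#' @param settings Base [simulation_settings()]; `t_end_h` is managed.
#' @param species Species whose plasma trough drives convergence.
#' @param min_days,max_days Simulated span bounds, days.
#' @return `list(result, metrics, converged, days)` where `metrics` are the
#'   final-interval [pk_metrics()] on total venous plasma (ng/mL).
#' @export
simulate_steady_state <- function(model, reg,
                                  settings = simulation_settings(),
                                  species = NULL,
                                  min_days = 14, max_days = 35) {
  species <- species %||% names(model$species)[1]
  days <- min_days
  repeat {
    t_end <- days * 24
    n_doses <- ceiling(t_end / reg$interval_h)
    reg_full <- regimen(reg$route, reg$dose_mg, reg$interval_h, n_doses,
                        reg$start_h, reg$infusion_h)
    st <- settings
    st$t_end_h <- t_end
    res <- simulate_pbpk(model, setNames(list(reg_full), species), st)
    pr <- res$profiles[[species]]
    tr_times <- c(t_end - 2 * reg$interval_h, t_end - reg$interval_h, t_end)
    troughs <- stats::approx(pr$time, pr$plasma_total_ngml, xout = tr_times)$y
    converged <- abs(troughs[3] - troughs[2]) <= 0.01 * max(troughs[3], 1e-12)
    if (converged || days >= max_days) {
      mets <- pk_metrics(res, species, "plasma_total_ngml",
                         window = c(t_end - reg$interval_h, t_end),
                         interval_h = reg$interval_h)
      return(list(result = res, metrics = mets, converged = converged,
                  days = days))
    }
    days <- min(max_days, days + 7)
  }
}
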