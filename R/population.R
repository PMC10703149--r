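#' Virtual-population demographics
#'
#' @param n_subjects Number of virtual subjects; study cohorts smaller than
#'   10 are padded to 10, mirroring the simulation protocol.
#' @param age_range Two-element numeric, years (default 30-70).
#' @param proportion_female Fraction in \[0, 1\] (default 0.5).
#' @param population_tag `"healthy"` or `"cancer"`.
#' @return An object of class `demographics`.
#' @export
demographics <- function(n_subjects = 10, age_range = c(30, 70),
                         proportion_female = 0.5,
                         population_tag = c("healthy", "cancer")) {
  population_tag <- match.arg(population_tag)
  .check_scalar(n_subjects, "n_subjects", 1)
  stopifnot(length(age_range) == 2, age_range[1] <= age_range[2])
  .check_scalar(proportion_female, "proportion_female", 0, 1)
  structure(list(n_subjects = max(10, ceiling(n_subjects)),
                 n_source = n_subjects,
                 age_range = age_range,
                 proportion_female = proportion_female,
                 population_tag = population_tag),
            class = "demographics")
}

#' Sample a virtual population
#'
#' Draws individual demographics and individualises the base physiology:
#' organ volumes scale linearly and flows/GFR with the 3/4 power of body
#' weight; log-normal inter-individual variability is applied to enzyme and
#' transporter expression (`cv_expression`) and organ blood flows
#' (`cv_flow`). Reproducible for a fixed seed.
#'
#' @param demo A [demographics()] object.
#' @param base_physiology A [physiology_parameters()] object for the
#'   reference individual.
#' @param seed Integer seed.
#' @param cv_expression,cv_flow Coefficients of variation (fractions) of the
#'   log-normal inter-individual variability.
#' @return A list of `virtual_individual` objects, each with `id`, `age`,
#'   `sex`, `weight`, `height` and an individualised `physiology`.
#' @export
sample_population <- function(demo, base_physiology, seed = 1,
                              cv_expression = 0.30, cv_flow = 0.20) {
  stopifnot(inherits(demo, "demographics"),
            inherits(base_physiology, "physiology_parameters"))
  if (demo$age_range[1] > demo$age_range[2]) stop("empty age range")
  n <- demo$n_subjects
  rng <- .lecuyer_stream(seed)
  on.exit(rng$restore(), add = TRUE)
  out <- vector("list", n)
  ref_w <- base_physiology$body_weight
  for (i in seq_len(n)) {
    sex <- if (stats::runif(1) < demo$proportion_female) "F" else "M"
    age <- stats::runif(1, demo$age_range[1], demo$age_range[2])
    mu_w <- if (sex == "M") 78 else 66
    weight <- stats::rlnorm(1, log(mu_w), 0.15)
    height <- stats::rnorm(1, if (sex == "M") 176 else 163, 7)
    phys <- base_physiology
    sw <- weight / ref_w
    phys$body_weight <- weight
    phys$organs$volume_l <- phys$organs$volume_l * sw
    flow_iiv <- if (cv_flow > 0) {
      stats::rlnorm(1, -0.5 * log(1 + cv_flow^2), sqrt(log(1 + cv_flow^2)))
    } else 1
    phys$organs$flow_lph <- phys$organs$flow_lph * sw^0.75 * flow_iiv
    phys$gfr <- phys$gfr * sw^0.75
    phys$liver$mass_g <- phys$liver$mass_g * sw
    phys$liver$volume_l <- phys$liver$volume_l * sw
    phys$blood$v_venous <- phys$blood$v_venous * sw
    phys$blood$v_arterial <- phys$blood$v_arterial * sw
    if (cv_expression > 0) {
      sdl <- sqrt(log(1 + cv_expression^2))
      mul <- stats::rlnorm(nrow(phys$expression_table), -0.5 * sdl^2, sdl)
      phys$expression_table$reference_conc_uM <-
        phys$expression_table$reference_conc_uM * mul
    }
    out[[i]] <- structure(
      list(id = i, age = age, sex = sex, weight = weight, height = height,
           physiology = phys, seed = seed),
      class = "virtual_individual")
  }
  out
}

# isolated RNG scope: saves and restores the caller's .Random.seed
.lecuyer_stream <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  list(restore = function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
}

#' Geometric-mean summary with log-normal confidence interval
#'
#' Geometric mean `exp(mean(log x))`, CV% derived from the log-scale
#' variance (`100 * sqrt(exp(s^2) - 1)`), and a confidence interval for the
#' geometric mean from log-scale normal quantiles.
#'
#' @param values Positive numeric vector.
#' @param ci_level Confidence level (default 0.90).
#' @return A list: `geo_mean`, `cv_pct`, `ci_lower`, `ci_upper`, `n`,
#'   `ci_level`.
#' @export
summarize_geomean <- function(values, ci_level = 0.90) {
  stopifnot(is.numeric(values), length(values) >= 1)
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("all values must be positive and finite")
  }
  .check_scalar(ci_level, "ci_level", 0, 1, open_lower = TRUE,
                open_upper = TRUE)
  lx <- log(values)
  m <- mean(lx)
  s <- stats::sd(lx)
  if (is.na(s)) s <- 0
  n <- length(values)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  half <- z * s / sqrt(n)
  list(geo_mean = exp(m), cv_pct = 100 * sqrt(exp(s^2) - 1),
       ci_lower = exp(m - half), ci_upper = exp(m + half),
       n = n, ci_level = ci_level)
}

#' Population PBPK simulation of steady-state troughs
#'
#' Simulates the regimen to steady state for every virtual individual and
#' collects the final-interval plasma trough, Cmax and AUC.
#'
#' @param drugs Drug parameter set (as for [build_model()]).
#' @param individuals Output of [sample_population()].
#' @param reg A [regimen()] template.
#' @param settings Base [simulation_settings()].
#' @param engine Engine constants.
#' @param species Species reported (default the first drug).
#' @param min_days,max_days Steady-state simulation bounds.
#' @return Data frame per subject: `id`, `weight`, `ctrough_ngml`,
#'   `cmax_ngml`, `auc_ngh_ml`.
#' @export
simulate_population <- function(drugs, individuals, reg,
                                settings = simulation_settings(),
                                engine = engine_defaults(), species = NULL,
                                min_days = 14, max_days = 28) {
  rows <- lapply(individuals, function(ind) {
    model <- build_model(drugs, ind$physiology, engine)
    ss <- simulate_steady_state(model, reg, settings, species = species,
                                min_days = min_days, max_days = max_days)
    data.frame(id = ind$id, weight = ind$weight,
               ctrough_ngml = ss$metrics$ctrough,
               cmax_ngml = ss$metrics$cmax,
               auc_ngh_ml = ss$metrics$auc)
  })
  do.call(rbind, rows)
}
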