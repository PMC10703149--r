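#' Run a pipeline command and write its artifacts
#'
#' Single entry point wiring configs to the simulation stages. Every run
#' writes tidy CSV/JSON artifacts plus a `manifest.json` (command, config
#' paths and MD5 hashes, seed, package version, timestamp) sufficient to
#' reproduce the outputs; deterministic commands reproduce bit-for-bit for an
#' identical manifest.
#'
#' @param command One of `"simulate"`, `"population"`, `"ddi"`,
#'   `"occupancy"`, `"sensitivity"`, `"make-fixtures"`.
#' @param out_dir Output directory (created if needed).
#' @param drug Drug name (shipped config) or path to a drug YAML.
#' @param population `"healthy"` or `"cancer"` study population.
#' @param dose_mg,interval_h,n_doses Regimen; defaults to the drug's standard
#'   patient regimen for shipped drugs.
#' @param seed Integer seed for stochastic commands.
#' @param n_subjects Population size for `"population"`.
#' @param perpetrator DDI design name (see [ddi_design_library()]) for
#'   `"ddi"`.
#' @param days Simulated days for `"simulate"`.
#' @param quick Reduce problem sizes (shorter spans, fewer subjects); used by
#'   examples and smoke tests.
#' @return Invisibly, a character vector of artifact paths.
#' @export
run_pipeline <- function(command = c("simulate", "population", "ddi",
                                     "occupancy", "sensitivity",
                                     "make-fixtures"),
                         out_dir, drug = "crizotinib",
                         population = c("cancer", "healthy"),
                         dose_mg = NULL, interval_h = NULL, n_doses = NULL,
                         seed = 1, n_subjects = 10,
                         perpetrator = "cri_ketoconazole", days = NULL,
                         quick = FALSE) {
  command <- match.arg(command)
  population <- match.arg(population)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  std <- list(crizotinib = c(250, 12), alectinib = c(600, 12),
              lorlatinib = c(100, 24))
  drug_path <- if (file.exists(drug)) drug else
    alk_config("drugs", paste0(drug, ".yaml"))
  drugs <- if (file.exists(drug)) list(read_drug_config(drug)) else
    load_drug_set(drug)
  dname <- drugs[[1]]$name
  if (is.null(dose_mg)) dose_mg <- (std[[dname]] %||% c(100, 24))[1]
  if (is.null(interval_h)) interval_h <- (std[[dname]] %||% c(100, 24))[2]
  phys <- default_human_physiology()
  if (population == "cancer") {
    cp <- apply_cancer_physiology(phys, drugs[[1]])
    phys <- cp$physiology
    drugs[[1]] <- cp$drug
  }
  days <- days %||% if (quick) 2 else 14
  settings <- simulation_settings(t_end_h = days * 24,
                                  rtol = if (quick) 1e-6 else 1e-8,
                                  atol = if (quick) 1e-8 else 1e-10)
  reg <- regimen("oral", dose_mg, interval_h,
                 n_doses = n_doses %||% ceiling(days * 24 / interval_h))
  artifacts <- character()
  emit_csv <- function(df, file) {
    p <- file.path(out_dir, file)
    utils::write.csv(df, p, row.names = FALSE)
    artifacts <<- c(artifacts, p)
    p
  }
  emit_json <- function(x, file) {
    p <- file.path(out_dir, file)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    artifacts <<- c(artifacts, p)
    p
  }

  if (command == "simulate") {
    model <- build_model(drugs, phys)
    res <- simulate_pbpk(model, setNames(list(reg), dname), settings)
    emit_csv(as.data.frame(res), "concentrations.csv")
    win <- c(settings$t_end_h - interval_h, settings$t_end_h)
    m <- pk_metrics(res, dname, window = win, interval_h = interval_h)
    emit_json(list(auc_ngh_ml = m$auc, cmax_ngml = m$cmax,
                   ctrough_ngml = m$ctrough,
                   time_to_steady_state_h = m$time_to_steady_state),
              "metrics.json")
  } else if (command == "population") {
    n <- if (quick) 3 else n_subjects
    demo <- demographics(n, population_tag = population)
    inds <- sample_population(demo, phys, seed = seed)[seq_len(n)]
    pop <- simulate_population(drugs, inds, reg, settings,
                               min_days = days, max_days = days)
    emit_csv(pop, "subjects.csv")
    s <- summarize_geomean(pop$ctrough_ngml)
    emit_json(list(metric = "ctrough_ngml", geo_mean = s$geo_mean,
                   cv_pct = s$cv_pct, ci_lower = s$ci_lower,
                   ci_upper = s$ci_upper, n = s$n), "summary.json")
  } else if (command == "ddi") {
    lib <- ddi_design_library(perpetrator)
    perp <- read_drug_config(alk_config("perpetrators",
                                        lib$perpetrator_config))
    dsg <- lib$design
    if (quick) settings$rtol <- 1e-6
    dr <- co_simulate(drugs, perp, phys, dsg, settings)
    emit_csv(data.frame(
      victim = dr$victim, perpetrator = dr$perpetrator,
      auc_alone = dr$alone$auc, auc_combined = dr$combined$auc,
      auc_ratio = dr$auc_ratio,
      cmax_alone = dr$alone$cmax, cmax_combined = dr$combined$cmax,
      cmax_ratio = dr$cmax_ratio), "ddi-ratios.csv")
  } else if (command == "occupancy") {
    n <- if (quick) 3 else n_subjects
    demo <- demographics(n, population_tag = population)
    inds <- sample_population(demo, phys, seed = seed)[seq_len(n)]
    pop <- simulate_population(drugs, inds, reg, settings,
                               min_days = days, max_days = days)
    variants <- read_alk_variants(dname)
    assess <- assess_regimen(pop$ctrough_ngml, drugs[[1]], variants)
    emit_csv(as.data.frame(assess), "occupancy-table.csv")
  } else if (command == "sensitivity") {
    panel <- c("log_p", "fup", "rbp")
    sc <- local_scan(drugs, phys, reg, panel, settings = settings)
    emit_csv(sc, "sensitivity.csv")
  } else if (command == "make-fixtures") {
    model <- build_model(drugs, phys)
    res <- simulate_pbpk(model, setNames(list(reg), dname), settings)
    obs <- synthesize_observed(res, sample_times = seq(2, days * 24, by = 12),
                               residual_cv_pct = 30,
                               n_subjects = if (quick) 5 else n_subjects,
                               seed = seed)
    emit_csv(as.data.frame(obs), "observed.csv")
    emit_csv(attr(obs, "summary"), "observed-summary.csv")
  }

  manifest <- list(
    command = command,
    configs = list(list(path = drug_path,
                        md5 = unname(tools::md5sum(drug_path)))),
    drug = dname, population = population,
    regimen = list(dose_mg = dose_mg, interval_h = interval_h),
    seed = seed,
    package_version = as.character(utils::packageVersion("alkpbpk")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  emit_json(manifest, "manifest.json")
  invisible(artifacts)
}
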