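#' Synthesize an observed clinical PK dataset
#'
#' Generates sparse per-subject "observed" concentration data from a
#' simulated true profile by applying multiplicative log-normal residual
#' error at a stated CV%, mirroring how clinical PK tables report geometric
#' means with CV%. Concentrations stay strictly positive; no
#' below-quantification handling is applied.
#'
#' @param true_profile A `simulation_result` or a data frame with `time` and
#'   a concentration column.
#' @param sample_times Nominal sampling times, h (must lie within the
#'   profile).
#' @param residual_cv_pct Residual coefficient of variation, percent (>= 0).
#' @param n_subjects Number of subjects (>= 1).
#' @param seed Integer seed (reproducible draws).
#' @param species,compartment Profile selection when `true_profile` is a
#'   `simulation_result` (defaults: first species, total plasma ng/mL).
#' @return An object of class `observed_dataset`: data frame `subject`,
#'   `time`, `conc_ngml`, with the per-time geometric-mean/CV% summary in
#'   `attr(, "summary")` and the true concentrations in `attr(, "truth")`.
#' @export
synthesize_observed <- function(true_profile, sample_times, residual_cv_pct,
                                n_subjects, seed = 1,
                                species = NULL,
                                compartment = "plasma_total_ngml") {
  .check_scalar(residual_cv_pct, "residual_cv_pct", 0)
  .check_scalar(n_subjects, "n_subjects", 1)
  if (inherits(true_profile, "simulation_result")) {
    species <- species %||% names(true_profile$profiles)[1]
    pr <- true_profile$profiles[[species]]
    tt <- pr$time
    cc <- pr[[compartment]]
  } else {
    tt <- true_profile$time
    cc <- true_profile[[setdiff(names(true_profile), "time")[1]]]
  }
  if (any(sample_times < min(tt) - 1e-9) ||
      any(sample_times > max(tt) + 1e-9)) {
    stop("sample times outside the simulated profile")
  }
  truth <- stats::approx(tt, cc, xout = sort(sample_times))$y
  sdl <- sqrt(log(1 + (residual_cv_pct / 100)^2))
  rng <- .lecuyer_stream(seed)
  on.exit(rng$restore(), add = TRUE)
  rows <- lapply(seq_len(n_subjects), function(i) {
    # median-one residuals keep the geometric mean unbiased
    eps <- if (sdl > 0) stats::rlnorm(length(truth), 0, sdl)
           else rep(1, length(truth))
    data.frame(subject = i, time = sort(sample_times),
               conc_ngml = truth * eps)
  })
  out <- do.call(rbind, rows)
  smry <- do.call(rbind, lapply(split(out, out$time), function(d) {
    s <- summarize_geomean(pmax(d$conc_ngml, .Machine$double.xmin))
    data.frame(time = d$time[1], geo_mean = s$geo_mean, cv_pct = s$cv_pct)
  }))
  structure(out, summary = smry,
            truth = data.frame(time = sort(sample_times), conc_ngml = truth),
            class = c("observed_dataset", class(out)))
}

#' Prediction/observation fold errors
#'
#' Fold error per PK metric (`predicted / observed`) with the accepted
#' accuracy window of 0.5 to 2.0.
#'
#' @param predicted A [pk_metrics()] object or named list (`auc`, `cmax`,
#'   `ctrough`; `NA`/missing entries are skipped).
#' @param observed Named list of observed summary values on the same scale
#'   (> 0 where present).
#' @return Data frame: `metric`, `predicted`, `observed`, `fold_error`,
#'   `within_twofold`.
#' @export
#' @examples
#' prediction_observation_ratio(list(auc = 1968), list(auc = 2321))
prediction_observation_ratio <- function(predicted, observed) {
  metrics <- intersect(c("auc", "cmax", "ctrough"),
                       intersect(names(predicted), names(observed)))
  rows <- list()
  for (m in metrics) {
    p <- predicted[[m]]; o <- observed[[m]]
    if (is.null(p) || is.null(o) || is.na(p) || is.na(o)) next
    if (o <= 0) stop("observed ", m, " must be positive")
    fe <- p / o
    rows[[length(rows) + 1]] <- data.frame(
      metric = m, predicted = p, observed = o, fold_error = fe,
      within_twofold = fe >= 0.5 & fe <= 2.0, stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no comparable metrics between inputs")
  do.call(rbind, rows)
}
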