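#' Generative specification for a synthetic actigraphy cohort
#'
#' Describes the stochastic world the simulator draws from: per subject,
#' counts are a baseline level plus a sum of cosines at day-harmonic
#' periods with subject-specific amplitudes and phases, plus noise,
#' clipped at zero (activity counts are nonnegative) and optionally
#' rounded to integers. All-zero nonwear days can be injected so the
#' cleaning path is exercised end to end.
#'
#' @param n_subjects Number of subjects.
#' @param days Recording days per subject (default 7, the usual protocol).
#' @param epoch_seconds Epoch length in seconds (default 60).
#' @param baseline Mean activity level (counts/epoch). Presets set it to at
#'   least three times the worst-case rhythm-plus-noise excursion so the
#'   nonnegativity clip essentially never binds and planted amplitudes
#'   survive unbiased into the spectrum.
#' @param components `data.frame` with columns `period_minutes`,
#'   `mean_amplitude`, `amplitude_sd`, `phase_mode` (`"fixed"` or
#'   `"uniform"`). Subject i's amplitude for a component is drawn from
#'   `Normal(mean_amplitude, amplitude_sd)` truncated at 0; a `"fixed"`
#'   phase is 0 (cohort-aligned, e.g. the night-day cycle), `"uniform"` is
#'   drawn from `U(0, 2*pi)` per subject (e.g. nap timing).
#' @param noise_sd Epoch-level noise scale (counts).
#' @param noise_model `"gaussian"` (additive `N(0, noise_sd^2)`) or
#'   `"nbinom"` (counts drawn as negative binomial with mean equal to the
#'   clipped signal and a dispersion chosen so the variance at baseline is
#'   `noise_sd^2`; requires `noise_sd^2 > baseline`).
#' @param nonwear_day_prob Probability that a day is replaced by all-zero
#'   counts (device not worn). Default 0.
#' @param integer_counts Round counts to integers? Default `TRUE`.
#' @param seed Root RNG seed; per-subject substreams are derived
#'   deterministically from `(seed, subject_index)`.
#' @return An object of class `"cohort_spec"`.
#' @seealso [cohort_preset()], [simulate_subject()], [simulate_cohort()]
#' @export
cohort_spec <- function(n_subjects, days = 7L, epoch_seconds = 60L,
                        baseline = 0, components = NULL, noise_sd = 0,
                        noise_model = c("gaussian", "nbinom"),
                        nonwear_day_prob = 0, integer_counts = TRUE,
                        seed = 1L) {
  noise_model <- match.arg(noise_model)
  n_subjects <- as.integer(n_subjects)
  days <- as.integer(days)
  epoch_seconds <- as.integer(epoch_seconds)
  if (is.na(n_subjects) || n_subjects < 1L)
    stop_validation("n_subjects must be a positive integer")
  if (is.na(days) || days < 1L) stop_validation("days must be a positive integer")
  if (is.na(epoch_seconds) || epoch_seconds <= 0L || 86400L %% epoch_seconds != 0L)
    stop_validation("epoch_seconds must divide 86400")
  if (baseline < 0) stop_validation("baseline must be nonnegative")
  if (noise_sd < 0) stop_validation("noise_sd must be nonnegative")
  if (nonwear_day_prob < 0 || nonwear_day_prob > 1)
    stop_validation("nonwear_day_prob must be in [0, 1]")
  if (is.null(components))
    components <- data.frame(period_minutes = numeric(0),
                             mean_amplitude = numeric(0),
                             amplitude_sd = numeric(0),
                             phase_mode = character(0))
  req <- c("period_minutes", "mean_amplitude", "amplitude_sd", "phase_mode")
  if (!all(req %in% names(components)))
    stop_validation(sprintf("components must have columns: %s",
                            paste(req, collapse = ", ")))
  if (nrow(components)) {
    if (any(components$period_minutes <= 0) ||
        any(components$mean_amplitude < 0) || any(components$amplitude_sd < 0))
      stop_validation("component periods must be positive and amplitudes nonnegative")
    if (!all(components$phase_mode %in% c("fixed", "uniform")))
      stop_validation("phase_mode must be \"fixed\" or \"uniform\"")
  }
  if (noise_model == "nbinom" && noise_sd^2 <= baseline)
    stop_validation("nbinom noise requires noise_sd^2 > baseline (overdispersion)")
  seed <- as.integer(seed)
  if (is.na(seed)) stop_validation("seed must be an integer")
  structure(
    list(n_subjects = n_subjects, days = days, epoch_seconds = epoch_seconds,
         baseline = baseline, components = components, noise_sd = noise_sd,
         noise_model = noise_model, nonwear_day_prob = nonwear_day_prob,
         integer_counts = integer_counts, seed = seed),
    class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> n = %d, %d day(s), baseline %g, %d component(s), %s noise sd %g\n",
    x$n_subjects, x$days, x$baseline, nrow(x$components), x$noise_model,
    x$noise_sd))
  invisible(x)
}

#' Built-in age-regime cohort presets
#'
#' Canned [cohort_spec()]s whose amplitude profiles mimic the qualitative
#' developmental regimes seen in infant actigraphy: at 6 months only the
#' one-day periodicity is strong; around 12 months either a one-nap
#' (one-third-day) or a two-nap (one-fourth/one-fifth-day) daytime
#' structure emerges; by 24 months the one-day, half-day and one-third-day
#' periodicities together describe a consolidated two-peak, one-nap day.
#' The numeric amplitudes are package defaults chosen to be realistic for
#' 1-minute Actiwatch-style counts; they are a stated simulation world,
#' not estimates from any particular cohort.
#'
#' @param name One of `"6m"`, `"12m-one-nap"`, `"12m-two-nap"`, `"24m"`.
#' @param n_subjects,days,seed Passed to [cohort_spec()].
#' @return A [cohort_spec()].
#' @export
cohort_preset <- function(name = c("6m", "12m-one-nap", "12m-two-nap", "24m"),
                          n_subjects = 100L, days = 7L, seed = 1L) {
  name <- match.arg(name)
  comp <- function(...) {
    m <- matrix(c(...), ncol = 4L, byrow = TRUE)
    data.frame(period_minutes = as.numeric(m[, 1L]),
               mean_amplitude = as.numeric(m[, 2L]),
               amplitude_sd = as.numeric(m[, 3L]),
               phase_mode = c("fixed", "uniform")[as.integer(m[, 4L])])
  }
  cfg <- switch(name,
    "6m" = list(comp(1440, 150, 20, 1,
                      720,  15,  5, 2,
                      480,  12,  4, 2,
                      360,  10,  4, 2), baseline = 1800),
    "12m-one-nap" = list(comp(1440, 150, 20, 1,
                               720,  45, 10, 2,
                               480,  70, 12, 2), baseline = 2100),
    "12m-two-nap" = list(comp(1440, 150, 20, 1,
                               720,  40, 10, 2,
                               360,  70, 12, 2,
                               288,  55, 10, 2), baseline = 2400),
    "24m" = list(comp(1440, 150, 20, 1,
                       720,  90, 15, 2,
                       480, 100, 15, 2), baseline = 2400))
  cohort_spec(n_subjects = n_subjects, days = days, baseline = cfg$baseline,
              components = cfg[[1L]], noise_sd = 100, seed = seed)
}

# Deterministic per-subject seed below 2^31, spread by a large odd multiplier.
subject_seed <- function(seed, subject_index) {
  as.integer((as.double(seed) * 48271 + as.double(subject_index) * 9973) %%
               2147483647)
}

# N(mean, sd) truncated at 0 via inverse-CDF; uses the current RNG stream.
rtrunc_norm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(max(mean, 0), n))
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (1 - lo), mean, sd)
}

#' Simulate one subject's activity series
#'
#' Draws `counts_t = max(0, baseline + sum_m a_m cos(2 pi t / T_m + phi_m)
#' + eps_t)` (see [cohort_spec()] for the distributions), rounds if
#' requested, then replaces each day independently by zeros with
#' probability `nonwear_day_prob`. Fully reproducible from
#' `(spec$seed, subject_index)`; the caller's RNG state is left untouched.
#'
#' @param spec A [cohort_spec()].
#' @param subject_index Positive integer.
#' @return An [epoch_series()] (day flags all `TRUE`; injected nonwear days
#'   are removed later by [clean_nonwear_days()]).
#' @export
simulate_subject <- function(spec, subject_index) {
  stopifnot(inherits(spec, "cohort_spec"))
  subject_index <- as.integer(subject_index)
  if (is.na(subject_index) || subject_index < 1L)
    stop_validation("subject_index must be a positive integer")
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(subject_seed(spec$seed, subject_index))

  epd <- 86400L %/% spec$epoch_seconds
  L <- spec$days * epd
  epoch_min <- spec$epoch_seconds / 60
  signal <- rep(spec$baseline, L)
  comps <- spec$components
  for (m in seq_len(nrow(comps))) {
    a <- rtrunc_norm0(1L, comps$mean_amplitude[m], comps$amplitude_sd[m])
    phi <- if (comps$phase_mode[m] == "uniform") stats::runif(1L, 0, 2 * pi) else 0
    per_epochs <- comps$period_minutes[m] / epoch_min
    if (abs(per_epochs - round(per_epochs)) < .grid_tol &&
        L %% round(per_epochs) == 0L) {
      # exact whole number of cycles: compute one period, tile the rest
      pe <- as.integer(round(per_epochs))
      one <- a * cos(2 * pi * (0:(pe - 1L)) / per_epochs + phi)
      signal <- signal + rep(one, L %/% pe)
    } else {
      t_epoch <- 0:(L - 1L)
      signal <- signal + a * cos(2 * pi * t_epoch / per_epochs + phi)
    }
  }
  counts <- switch(spec$noise_model,
    gaussian = pmax(0, signal + stats::rnorm(L, 0, spec$noise_sd)),
    nbinom = {
      size <- spec$baseline^2 / (spec$noise_sd^2 - spec$baseline)
      stats::rnbinom(L, mu = pmax(signal, 1e-8), size = size)
    })
  if (spec$integer_counts) counts <- round(counts)
  if (spec$nonwear_day_prob > 0) {
    nonwear <- stats::runif(spec$days) < spec$nonwear_day_prob
    if (any(nonwear)) {
      dm <- matrix(counts, nrow = epd)
      dm[, nonwear] <- 0
      counts <- as.numeric(dm)
    }
  }
  epoch_series(sprintf("sim%04d", subject_index), counts,
               epoch_seconds = spec$epoch_seconds)
}

#' Simulate a full cohort
#'
#' @param spec A [cohort_spec()].
#' @return A list of [epoch_series()], one per subject.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  lapply(seq_len(spec$n_subjects), function(i) simulate_subject(spec, i))
}

#' Serialize a cohort specification to JSON
#'
#' @param spec A [cohort_spec()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_cohort_spec_json <- function(spec, file) {
  stopifnot(inherits(spec, "cohort_spec"))
  jsonlite::write_json(unclass(spec), file, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(file)
}
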