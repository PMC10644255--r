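# Synthetic time-course generator: simulated datasets with the noise
# structure the fitting stage assumes, standing in for quantified
# fluorescence measurements.

#' Measurement-noise specification
#'
#' @param kind \code{"additive_gaussian"} (sd in fraction units) or
#'   \code{"proportional_gaussian"} (sd relative to the signal).
#' @param sigma noise scale, >= 0. The default 0.02 fraction units yields
#'   parameter-recovery coefficients of variation comparable to those of
#'   the published fits (0.1-0.4).
#' @param seed integer seed; generation with the same seed is
#'   bit-reproducible. \code{NULL} leaves the RNG state alone.
#' @param clip_at_zero clip noisy values at 0 (fractions are non-negative).
#' @return An object of class \code{"noise_spec"}.
#' @export
noise_spec <- function(kind = c("additive_gaussian", "proportional_gaussian"),
                       sigma = 0.02, seed = NULL, clip_at_zero = TRUE) {
  kind <- match.arg(kind)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
    stop("'sigma' must be a single non-negative number", call. = FALSE)
  if (!is.null(seed) && (!is.numeric(seed) || length(seed) != 1L))
    stop("'seed' must be a single integer or NULL", call. = FALSE)
  structure(list(kind = kind, sigma = sigma,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 clip_at_zero = isTRUE(clip_at_zero)),
            class = "noise_spec")
}

apply_noise <- function(values, noise) {
  if (noise$sigma == 0) return(values)
  if (!is.null(noise$seed)) set.seed(noise$seed)
  eps <- stats::rnorm(length(values), mean = 0, sd = noise$sigma)
  out <- switch(noise$kind,
                additive_gaussian = values + eps,
                proportional_gaussian = values * (1 + eps))
  if (noise$clip_at_zero) out <- pmax(out, 0)
  out
}

#' Generate a synthetic pulse-chase dataset
#'
#' Simulates a closed variant from the pulse-chase initial condition
#' (all tracer in the PM) and samples the PM, RE and LELY observables on
#' the given grid, adding measurement noise. The default grid (0-120 min,
#' 10 points) mimics the sampling density of the chase experiments.
#'
#' @param params a [rate_constants()] object.
#' @param variant a closed variant (default \code{"closed_four"}).
#' @param grid time grid in minutes, starting at 0.
#' @param noise a [noise_spec()].
#' @param cell_line dataset label.
#' @return A [timecourse_dataset()] with a provenance \code{truth} block.
#' @examples
#' ds <- generate_pulse_chase(dhe_params("disease"),
#'                            noise = noise_spec(sigma = 0, seed = 1))
#' @export
generate_pulse_chase <- function(params, variant = "closed_four",
                                 grid = seq(0, 120, length.out = 10),
                                 noise = noise_spec(),
                                 cell_line = "synthetic") {
  variant <- model_variant(variant)
  if (!is_closed_variant(variant$name))
    stop("pulse-chase generation requires a closed variant", call. = FALSE)
  if (!is.numeric(grid) || grid[1L] != 0 || is.unsorted(grid, strictly = TRUE))
    stop("'grid' must start at 0 and be strictly increasing", call. = FALSE)
  params <- as_rate_constants(params)
  tr <- simulate_model(variant, params, init = c(1, 0, 0, 0), times = grid)
  obs <- c("PM", "RE", "LELY")
  long <- do.call(rbind, lapply(obs, function(ob)
    data.frame(observable = ob, time_min = grid, value = tr[[ob]])))
  long$value <- apply_noise(long$value, noise)
  timecourse_dataset(long, cell_line = cell_line, experiment = "pulse_chase",
                     truth = list(params = params, variant = variant$name,
                                  noise = noise, seed = noise$seed,
                                  grid = grid))
}

#' Generate a synthetic continuous-uptake dataset
#'
#' Simulates the open system from an empty cell (all compartments 0) under
#' constant influx \code{v0} and PM efflux \code{k5}; all observables rise
#' toward the analytic steady state, and the terminal intracellular
#' fraction converges to [intracellular_fraction()] as the grid end grows.
#'
#' @param params a [rate_constants()] object with \code{v0, k5 > 0}.
#' @param grid time grid in minutes starting at 0.
#' @param noise a [noise_spec()].
#' @param cell_line dataset label.
#' @return A [timecourse_dataset()].
#' @export
generate_continuous_uptake <- function(params,
                                       grid = seq(0, 600, length.out = 13),
                                       noise = noise_spec(),
                                       cell_line = "synthetic") {
  params <- as_rate_constants(params)
  if (params$v0 <= 0)
    stop("'v0' must be > 0 for continuous uptake (all-zero truth otherwise)",
         call. = FALSE)
  if (params$k5 <= 0)
    stop("'k5' must be > 0 for the open system", call. = FALSE)
  if (!is.numeric(grid) || grid[1L] != 0 || is.unsorted(grid, strictly = TRUE))
    stop("'grid' must start at 0 and be strictly increasing", call. = FALSE)
  tr <- simulate_model("open_four", params, init = c(0, 0, 0, 0),
                       times = grid)
  obs <- c("PM", "RE", "LELY")
  long <- do.call(rbind, lapply(obs, function(ob)
    data.frame(observable = ob, time_min = grid, value = tr[[ob]])))
  long$value <- apply_noise(long$value, noise)
  timecourse_dataset(long, cell_line = cell_line,
                     experiment = "continuous_uptake",
                     truth = list(params = params, variant = "open_four",
                                  noise = noise, seed = noise$seed,
                                  grid = grid))
}

#' Generate a synthetic efflux dataset
#'
#' Two generation modes for the fractional intracellular intensity during
#' sterol efflux:
#' \describe{
#'   \item{Weibull mode}{supply \code{tau_h}, \code{mu}, \code{f0},
#'     \code{f_inf}: emits \eqn{F(t) = f_\infty + (f_0 - f_\infty) S(t)}
#'     with the Weibull survival \eqn{S(t) = \exp(-(t/\tau)^\mu)}, the
#'     phenomenological description fitted to efflux measurements.}
#'   \item{Mechanistic mode}{supply \code{params} (efflux_two_pathway
#'     rates): emits all observables of [run_efflux()].}
#' }
#' The default grid \{0, 24, 48, 72, 96\} h mirrors the duration of the
#' efflux measurements; times are stored internally in minutes.
#'
#' @param tau_h,mu,f0,f_inf Weibull-mode truth: residence time constant in
#'   hours, shape, initial fraction and steady-state offset
#'   (\code{f0 > f_inf >= 0}).
#' @param params mechanistic-mode [rate_constants()]; overrides the
#'   Weibull arguments when supplied.
#' @param grid_h time grid in hours, starting at 0, within ~[0, 200] h.
#' @param noise a [noise_spec()].
#' @param cell_line dataset label.
#' @return A [timecourse_dataset()] (experiment \code{"efflux"}); the
#'   Weibull mode holds a single \code{intracellular_fraction} series.
#' @examples
#' w <- dhe_efflux_weibull("disease")
#' ds <- generate_efflux(tau_h = w$tau_h, mu = w$mu, f0 = 0.4, f_inf = 0.05,
#'                       noise = noise_spec(sigma = 0))
#' @export
generate_efflux <- function(tau_h = NULL, mu = NULL, f0 = NULL, f_inf = NULL,
                            params = NULL,
                            grid_h = c(0, 24, 48, 72, 96),
                            noise = noise_spec(),
                            cell_line = "synthetic") {
  if (!is.numeric(grid_h) || grid_h[1L] != 0 ||
      is.unsorted(grid_h, strictly = TRUE) || max(grid_h) > 220)
    stop("'grid_h' must start at 0, be strictly increasing and lie within ",
         "about [0, 200] h", call. = FALSE)
  if (!is.null(params)) {
    params <- as_rate_constants(params)
    tr <- run_efflux(params, times = grid_h * 60)
    long <- rbind(
      data.frame(observable = "PM", time_min = grid_h * 60, value = tr$PM),
      data.frame(observable = "RE", time_min = grid_h * 60, value = tr$RE),
      data.frame(observable = "LELY", time_min = grid_h * 60,
                 value = tr$LELY),
      data.frame(observable = "intracellular_fraction",
                 time_min = grid_h * 60, value = tr$lely_fraction))
    truth <- list(params = params, variant = "efflux_two_pathway",
                  noise = noise, seed = noise$seed, grid_h = grid_h)
  } else {
    for (nm in c("tau_h", "mu", "f0", "f_inf")) {
      x <- get(nm)
      if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
        stop("Weibull mode needs scalar '", nm, "'", call. = FALSE)
    }
    if (tau_h <= 0 || mu <= 0)
      stop("'tau_h' and 'mu' must be > 0", call. = FALSE)
    if (f_inf < 0 || f0 <= f_inf)
      stop("need f0 > f_inf >= 0", call. = FALSE)
    f <- f_inf + (f0 - f_inf) * weibull_survival(grid_h, tau_h, mu)
    long <- data.frame(observable = "intracellular_fraction",
                       time_min = grid_h * 60, value = f)
    truth <- list(tau_h = tau_h, mu = mu, f0 = f0, f_inf = f_inf,
                  noise = noise, seed = noise$seed, grid_h = grid_h)
  }
  long$value <- apply_noise(long$value, noise)
  timecourse_dataset(long, cell_line = cell_line, experiment = "efflux",
                     truth = truth)
}
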