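# Global multi-curve nonlinear regression, offset-Weibull efflux fits,
# and AIC/BIC model comparison.

# Initial state and variant check per experiment type.
fit_initial_state <- function(experiment, variant, params) {
  switch(experiment,
    pulse_chase = {
      if (!is_closed_variant(variant))
        stop("pulse_chase data requires a closed variant, not '", variant,
             "'", call. = FALSE)
      c(1, 0, 0, 0)
    },
    continuous_uptake = {
      if (variant != "open_four")
        stop("continuous_uptake data requires the open_four variant",
             call. = FALSE)
      c(0, 0, 0, 0)
    },
    efflux = {
      if (variant != "efflux_two_pathway")
        stop("efflux data requires the efflux_two_pathway variant",
             call. = FALSE)
      steady_fractions(params)
    },
    stop("unknown experiment type: ", experiment, call. = FALSE))
}

# Weighted residuals of one parameter vector against all datasets.
fit_residuals <- function(theta, free_params, base_params, variant,
                          datasets, rel_tol, abs_tol) {
  p <- base_params
  p[free_params] <- as.list(pmax(theta, 0))
  p <- tryCatch(do.call(rate_constants, unclass(p)[names(formals(rate_constants))]),
                error = function(e) NULL)
  if (is.null(p)) return(rep(1e6, attr(datasets, "n_obs")))
  res <- lapply(datasets, function(ds) {
    init <- fit_initial_state(ds$experiment, variant, p)
    times <- sort(unique(c(0, ds$data$time_min)))
    tr <- tryCatch(
      simulate_model(variant, p, init = init, times = times,
                     rel_tol = rel_tol, abs_tol = abs_tol),
      error = function(e) NULL)
    if (is.null(tr)) return(rep(1e6, nrow(ds$data)))
    model_obs <- cbind(PM = tr$PM, RE = tr$RE, LELY = tr$LELY,
                       intracellular_fraction = tr$intracellular_fraction)
    idx <- match(ds$data$time_min, times)
    pred <- model_obs[cbind(idx, match(ds$data$observable,
                                       colnames(model_obs)))]
    w <- ifelse(is.na(ds$data$sd) | ds$data$sd <= 0, 1, 1 / ds$data$sd)
    (pred - ds$data$value) * w
  })
  unlist(res, use.names = FALSE)
}

#' Global fit of a compartment model to time-course datasets
#'
#' Fits the free rate constants of one model variant to all supplied
#' datasets simultaneously by pooled weighted least squares (weights
#' \eqn{1/sd^2} where per-point uncertainties are given, uniform
#' otherwise), using bounded Levenberg-Marquardt minimisation. Parameter
#' standard deviations come from the Jacobian-based covariance at the
#' optimum; an optional multi-start loop re-runs from log-uniformly
#' perturbed guesses and keeps the best optimum.
#'
#' The initial state is implied by each dataset's experiment type:
#' pulse-chase starts at (1, 0, 0, 0); continuous uptake at an empty cell;
#' efflux at the steady fractional distribution.
#'
#' @param datasets a [timecourse_dataset()] or list of them.
#' @param variant variant name or [model_variant()].
#' @param free_params names of parameters to optimise; default: the
#'   variant's active rate constants (excluding \code{mu}).
#' @param fixed named list/vector of parameters held fixed at non-zero
#'   values during the fit (e.g. a known influx \code{v0}, or the Weibull
#'   shape \code{mu}); must be disjoint from \code{free_params}.
#' @param initial_guess named numeric vector of starting values for the
#'   free parameters (within bounds).
#' @param lower,upper bounds (scalars or named vectors); default
#'   \code{[0, Inf)}.
#' @param n_starts number of optimisation starts (default 1); additional
#'   starts perturb the guess by log-uniform factors in [0.2, 5].
#' @param seed integer seed for the multi-start perturbations (recorded in
#'   the result).
#' @param rel_tol,abs_tol ODE solver tolerances used inside the objective.
#' @param max_iter maximum Levenberg-Marquardt iterations per start.
#' @return An object of class \code{"fit_result"}: list with
#'   \code{variant}, \code{estimates}, \code{sd}, \code{cv} (= sd/estimate),
#'   \code{rss}, \code{n_obs}, \code{n_params}, \code{aic}, \code{bic},
#'   \code{converged}, \code{seed}, \code{message}.
#' @examples
#' \donttest{
#' ds <- generate_pulse_chase(dhe_params("disease"),
#'                            grid = seq(0, 360, length.out = 13),
#'                            noise = noise_spec(sigma = 0))
#' fit <- global_fit(ds, "closed_four",
#'                   initial_guess = c(k1 = 0.05, k2 = 0.3, k3 = 0.1,
#'                                     k4 = 0.01, km4 = 0.005))
#' fit$estimates
#' }
#' @export
global_fit <- function(datasets, variant, free_params = NULL,
                       initial_guess = NULL, fixed = NULL,
                       lower = 0, upper = Inf,
                       n_starts = 1L, seed = NULL,
                       rel_tol = 1e-8, abs_tol = 1e-10, max_iter = 200L) {
  variant <- model_variant(variant)
  if (inherits(datasets, "timecourse_dataset")) datasets <- list(datasets)
  if (!length(datasets) ||
      !all(vapply(datasets, inherits, logical(1), "timecourse_dataset")))
    stop("'datasets' must be timecourse_dataset objects", call. = FALSE)
  if (is.null(free_params))
    free_params <- setdiff(variant$active_parameters, "mu")
  bad <- setdiff(free_params, variant$active_parameters)
  if (length(bad))
    stop("free parameter(s) not active in variant '", variant$name, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(initial_guess)) {
    initial_guess <- stats::setNames(rep(0.1, length(free_params)),
                                     free_params)
  }
  if (is.null(names(initial_guess)) ||
      !setequal(names(initial_guess), free_params))
    stop("'initial_guess' must be named for exactly the free parameters",
         call. = FALSE)
  initial_guess <- initial_guess[free_params]
  expand <- function(x, default)
    if (length(x) == 1L && is.null(names(x)))
      stats::setNames(rep(x, length(free_params)), free_params)
    else {
      out <- stats::setNames(rep(default, length(free_params)), free_params)
      out[names(x)] <- x
      out
    }
  lower <- expand(lower, 0)
  upper <- expand(upper, Inf)
  if (any(initial_guess < lower | initial_guess > upper))
    stop("initial guess outside bounds", call. = FALSE)

  # base parameter values: inactive params zero, mu = 1, plus any
  # explicitly fixed values
  base <- as.list(rate_constants())
  if (!is.null(fixed)) {
    fixed <- as.list(fixed)
    bad <- setdiff(names(fixed), names(base))
    if (length(bad))
      stop("unknown fixed parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    clash <- intersect(names(fixed), free_params)
    if (length(clash))
      stop("parameter(s) both free and fixed: ",
           paste(clash, collapse = ", "), call. = FALSE)
    base[names(fixed)] <- fixed
  }
  n_obs <- sum(vapply(datasets, function(d) nrow(d$data), integer(1)))
  attr(datasets, "n_obs") <- n_obs

  if (!is.null(seed)) set.seed(seed)
  starts <- list(initial_guess)
  if (n_starts > 1L)
    for (i in seq_len(n_starts - 1L)) {
      f <- exp(stats::runif(length(free_params), log(0.2), log(5)))
      starts[[i + 1L]] <- pmin(pmax(initial_guess * f, lower), upper)
    }

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = st,
        lower = lower, upper = upper,
        fn = fit_residuals,
        free_params = free_params, base_params = base,
        variant = variant$name, datasets = datasets,
        rel_tol = rel_tol, abs_tol = abs_tol,
        control = minpack.lm::nls.lm.control(maxiter = max_iter,
                                             ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    return(structure(list(variant = variant$name, estimates = initial_guess,
                          sd = NA, cv = NA, rss = NA, n_obs = n_obs,
                          n_params = length(free_params), aic = NA, bic = NA,
                          converged = FALSE, seed = seed,
                          message = "all optimisation starts failed"),
                     class = "fit_result"))

  est <- best$par
  rss <- best$deviance
  p <- length(free_params)
  sd_est <- rep(NA_real_, p)
  hess <- best$hessian
  cov_ok <- FALSE
  if (!is.null(hess) && n_obs > p) {
    cv_mat <- tryCatch(solve(hess) * rss / (n_obs - p),
                       error = function(e) NULL)
    if (!is.null(cv_mat) && all(diag(cv_mat) >= 0)) {
      sd_est <- sqrt(diag(cv_mat))
      cov_ok <- TRUE
    }
  }
  names(sd_est) <- free_params
  ic <- if (rss > 0 && n_obs > p) information_criteria(rss, n_obs, p)
        else list(aic = NA_real_, bic = NA_real_)
  msg <- best$message
  if (!cov_ok)
    msg <- paste(msg, "| covariance singular: parameters may be",
                 "structurally non-identifiable on these data")
  structure(list(variant = variant$name,
                 estimates = est,
                 sd = sd_est,
                 cv = ifelse(est != 0, sd_est / est, NA_real_),
                 rss = rss, n_obs = n_obs, n_params = p,
                 aic = ic$aic, bic = ic$bic,
                 converged = best$info %in% 1:4,
                 seed = seed, message = msg),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> variant:", x$variant,
      "| converged:", x$converged, "\n")
  tab <- data.frame(estimate = x$estimates, sd = x$sd, cv = x$cv)
  print(tab, digits = 4)
  cat(sprintf("  rss = %.4g on %d obs, %d params | AIC = %.2f, BIC = %.2f\n",
              x$rss, x$n_obs, x$n_params, x$aic, x$bic))
  invisible(x)
}

#' Fit report as a data frame
#'
#' @param fit a \code{fit_result}.
#' @return \code{data.frame} with columns parameter, estimate, sd, cv.
#' @export
fit_report <- function(fit) {
  stopifnot(inherits(fit, "fit_result"))
  data.frame(parameter = names(fit$estimates),
             estimate = unname(fit$estimates),
             sd = unname(fit$sd), cv = unname(fit$cv))
}

#' Fit the offset Weibull survival model to an efflux curve
#'
#' Fits \eqn{F(t) = f_\infty + (f_0 - f_\infty) \exp(-(t/\tau)^\mu)} to a
#' fractional-intensity decay by (weighted) least squares: the Weibull
#' survival weighted by the initial fraction, with an offset for the
#' remaining intensity at steady state.
#'
#' @param time,value numeric vectors (>= 5 points); \code{value} in [0, 1].
#'   \code{time} may be in any unit; the recovered \code{tau} is in the
#'   same unit.
#' @param sd optional per-point standard deviations (weights 1/sd^2).
#' @param initial_guess optional named vector with any of
#'   \code{tau, mu, f0, f_inf}; missing entries use data-driven defaults.
#' @param fixed optional named vector of parameters to hold fixed,
#'   e.g. \code{c(mu = 1)} for a plain exponential.
#' @param multistart also try a deterministic grid of shape-regime starting
#'   values (\code{mu} in 0.7-4) and keep the best optimum; the
#'   (tau, mu, f_inf) landscape has local optima when the data cover only
#'   part of the decay. Defaults to \code{TRUE} when no
#'   \code{initial_guess} is supplied.
#' @return An object of class \code{"weibull_fit"}: list with \code{tau},
#'   \code{mu}, \code{f0}, \code{f_inf}, \code{rss}, \code{sd} (per free
#'   parameter), \code{converged}, \code{fitted}.
#' @examples
#' tt <- c(0, 12, 24, 48, 72, 96)
#' y <- 0.05 + 0.35 * weibull_survival(tt, 135.14, 2.577)
#' fit_weibull_efflux(tt, y)
#' @export
fit_weibull_efflux <- function(time, value, sd = NULL,
                               initial_guess = NULL, fixed = NULL,
                               multistart = is.null(initial_guess)) {
  if (!is.numeric(time) || !is.numeric(value) ||
      length(time) != length(value) || length(time) < 5L)
    stop("need >= 5 (time, value) pairs", call. = FALSE)
  if (anyNA(time) || anyNA(value) || any(time < 0))
    stop("times must be >= 0 and values non-missing", call. = FALSE)
  if (any(value < 0 | value > 1))
    stop("values must lie in [0, 1] (fractional intensities)",
         call. = FALSE)
  if (diff(range(value)) < 1e-10)
    stop("flat series: Weibull parameters are non-identifiable",
         call. = FALSE)
  w <- if (is.null(sd)) rep(1, length(value)) else {
    if (length(sd) != length(value) || any(sd <= 0, na.rm = TRUE))
      stop("'sd' must be positive and match 'value'", call. = FALSE)
    ifelse(is.na(sd), 1, 1 / sd)
  }

  defaults <- c(tau = NA, mu = 1.5,
                f0 = value[which.min(time)], f_inf = max(min(value), 0))
  # tau guess: time at which the decay has lost half its span
  span <- defaults[["f0"]] - defaults[["f_inf"]]
  half <- defaults[["f_inf"]] + span / 2
  below <- which(value <= half)
  defaults[["tau"]] <- if (length(below)) max(time[below[1L]], 1e-3)
                       else max(time)
  guess <- defaults
  if (!is.null(initial_guess)) guess[names(initial_guess)] <- initial_guess
  fixed_names <- names(fixed)
  free_names <- setdiff(c("tau", "mu", "f0", "f_inf"), fixed_names)
  full <- function(theta) {
    p <- c(theta, fixed)
    p[c("tau", "mu", "f0", "f_inf")]
  }
  resid_fn <- function(theta) {
    p <- full(theta)
    if (p[["tau"]] <= 0 || p[["mu"]] <= 0) return(rep(1e6, length(value)))
    pred <- p[["f_inf"]] +
      (p[["f0"]] - p[["f_inf"]]) * exp(-(time / p[["tau"]])^p[["mu"]])
    (pred - value) * w
  }
  lower <- c(tau = 1e-8, mu = 1e-3, f0 = 0, f_inf = 0)[free_names]
  starts <- list(guess[free_names])
  if (multistart && "mu" %in% free_names)
    for (mu0 in c(0.7, 1, 1.5, 2.5, 4)) {
      s <- guess[free_names]
      s[["mu"]] <- mu0
      starts <- c(starts, list(s))
    }
  fit <- NULL
  for (st in starts) {
    cand <- minpack.lm::nls.lm(
      par = st, lower = lower,
      fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 500,
                                           ftol = 1e-15, ptol = 1e-15))
    if (is.null(fit) || cand$deviance < fit$deviance) fit <- cand
  }
  est <- full(fit$par)
  if (est[["f0"]] <= est[["f_inf"]])
    warning("fitted f0 <= f_inf: no decaying component identified")
  p <- length(free_names)
  n <- length(value)
  sd_est <- rep(NA_real_, p)
  if (n > p) {
    cv_mat <- tryCatch(solve(fit$hessian) * fit$deviance / (n - p),
                       error = function(e) NULL)
    if (!is.null(cv_mat) && all(diag(cv_mat) >= 0))
      sd_est <- sqrt(diag(cv_mat))
  }
  names(sd_est) <- free_names
  structure(list(tau = est[["tau"]], mu = est[["mu"]],
                 f0 = est[["f0"]], f_inf = est[["f_inf"]],
                 rss = fit$deviance, sd = sd_est,
                 converged = fit$info %in% 1:4,
                 fitted = est[["f_inf"]] + (est[["f0"]] - est[["f_inf"]]) *
                   exp(-(time / est[["tau"]])^est[["mu"]])),
            class = "weibull_fit")
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf(paste0("<weibull_fit> tau = %.4g, mu = %.4g, f0 = %.4g, ",
                     "f_inf = %.4g\n  rss = %.4g | converged: %s\n"),
              x$tau, x$mu, x$f0, x$f_inf, x$rss, x$converged))
  invisible(x)
}

#' Akaike and Bayesian information criteria for least-squares fits
#'
#' Gaussian-likelihood forms: \eqn{AIC = n \ln(rss/n) + 2p} and
#' \eqn{BIC = n \ln(rss/n) + p \ln n}.
#'
#' @param rss residual sum of squares, > 0.
#' @param n_obs number of observations, > \code{n_params}.
#' @param n_params number of free parameters.
#' @return List with \code{aic} and \code{bic}.
#' @examples
#' information_criteria(0.01, 30, 3)
#' @export
information_criteria <- function(rss, n_obs, n_params) {
  if (!is.numeric(rss) || length(rss) != 1L || rss <= 0)
    stop("'rss' must be > 0 (rss = 0 is degenerate: criteria undefined)",
         call. = FALSE)
  if (n_obs <= n_params)
    stop("'n_obs' must exceed 'n_params'", call. = FALSE)
  gof <- n_obs * log(rss / n_obs)
  list(aic = gof + 2 * n_params, bic = gof + n_params * log(n_obs))
}

#' Fit and rank competing model variants
#'
#' Fits each variant to the same datasets with [global_fit()] and ranks
#' the results by BIC (ties broken by AIC), reporting Delta-criteria
#' relative to the best model. Variants whose fit fails are excluded with
#' a reason.
#'
#' @param datasets a [timecourse_dataset()] or list of them.
#' @param variants character vector of variant names (>= 1).
#' @param initial_guesses optional named list (per variant) of initial
#'   guess vectors.
#' @param ... passed to [global_fit()] (\code{n_starts}, \code{seed},
#'   tolerances).
#' @return An object of class \code{"model_comparison"}: list with
#'   \code{table} (variant, n_params, rss, aic, bic, delta_aic, delta_bic,
#'   converged; ordered by BIC), \code{fits}, \code{failures}.
#' @export
compare_models <- function(datasets, variants, initial_guesses = NULL, ...) {
  if (!length(variants)) stop("need at least one variant", call. = FALSE)
  fits <- list()
  failures <- list()
  for (v in variants) {
    guess <- if (!is.null(initial_guesses)) initial_guesses[[v]] else NULL
    fit <- tryCatch(global_fit(datasets, v, initial_guess = guess, ...),
                    error = function(e) e)
    if (inherits(fit, "error") || !is.finite(fit$rss %||% NA)) {
      failures[[v]] <- if (inherits(fit, "error")) conditionMessage(fit)
                       else fit$message
    } else fits[[v]] <- fit
  }
  if (!length(fits))
    stop("all variant fits failed: ",
         paste(names(failures), unlist(failures), sep = ": ",
               collapse = "; "), call. = FALSE)
  tab <- do.call(rbind, lapply(fits, function(f)
    data.frame(variant = f$variant, n_params = f$n_params, rss = f$rss,
               aic = f$aic, bic = f$bic, converged = f$converged)))
  tab <- tab[order(tab$bic, tab$aic), ]
  tab$delta_aic <- tab$aic - min(tab$aic)
  tab$delta_bic <- tab$bic - min(tab$bic)
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits, failures = failures),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison> ranked by BIC\n")
  print(x$table, digits = 5)
  if (length(x$failures))
    cat("  excluded:", paste(names(x$failures), unlist(x$failures),
                             sep = " - ", collapse = "; "), "\n")
  invisible(x)
}
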