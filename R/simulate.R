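# Numerical integration of the model variants (deSolve, lsoda).

#' Integrate a sterol transport model
#'
#' Solves the chosen model variant on a uniform time grid (or a supplied
#' one) with a stiff-capable adaptive solver. The rate constants span about
#' 0.004-0.43 min^-1, so stiffness is mild, but the Weibull hazard of the
#' efflux variant grows without bound, which motivates adaptive stepping.
#'
#' @param variant a variant name or [model_variant()] object.
#' @param params a [rate_constants()] object; parameters inactive in the
#'   variant must be zero.
#' @param init numeric length-4 initial state \code{(n1, n2, n3, n4)},
#'   all components >= 0.
#' @param t_end end time in minutes (> 0). Ignored when \code{times} given.
#' @param n_points number of grid points (>= 2) for the uniform grid
#'   starting at 0. Ignored when \code{times} given.
#' @param times optional explicit, strictly increasing time grid (minutes).
#' @param rel_tol,abs_tol relative/absolute solver tolerances.
#' @return A \code{"sterol_trajectory"}: a \code{data.frame} with columns
#'   \code{time, n1..n4} and derived observables \code{PM} (= n1),
#'   \code{RE} (= n2), \code{LM} (= n3), \code{ILV} (= n4),
#'   \code{LELY} (= n3 + n4), \code{total} and
#'   \code{intracellular_fraction} = (n2+n3+n4)/total. Solver undershoot
#'   below zero (within \code{abs_tol}) is clamped to 0 in the observables.
#' @examples
#' tr <- simulate_model("closed_four", dhe_params("disease"),
#'                      init = c(1, 0, 0, 0), t_end = 360, n_points = 13)
#' head(tr[, c("time", "PM", "RE", "LELY")])
#' @export
simulate_model <- function(variant, params, init, t_end = NULL,
                           n_points = 101L, times = NULL,
                           rel_tol = 1e-8, abs_tol = 1e-10) {
  variant <- model_variant(variant)
  params <- check_params_for_variant(variant, params)
  if (!is.numeric(init) || length(init) != 4L || anyNA(init))
    stop("'init' must be a numeric vector of length 4", call. = FALSE)
  if (any(init < 0))
    stop("'init' has negative component(s): n",
         paste(which(init < 0), collapse = ", n"), call. = FALSE)
  if (rel_tol <= 0 || abs_tol <= 0)
    stop("tolerances must be > 0", call. = FALSE)
  if (is.null(times)) {
    if (is.null(t_end) || !is.numeric(t_end) || t_end <= 0)
      stop("'t_end' must be > 0", call. = FALSE)
    if (n_points < 2L)
      stop("'n_points' must be >= 2", call. = FALSE)
    times <- seq(0, t_end, length.out = n_points)
  } else {
    if (!is.numeric(times) || length(times) < 2L || any(times < 0) ||
        is.unsorted(times, strictly = TRUE))
      stop("'times' must be >= 0 and strictly increasing", call. = FALSE)
  }
  y0 <- as.numeric(init); names(y0) <- c("n1", "n2", "n3", "n4")
  vn <- variant$name
  sol <- deSolve::ode(
    y = y0, times = times,
    func = function(t, y, p) list(rhs_core(vn, p, y, t)),
    parms = params, method = "lsoda", rtol = rel_tol, atol = abs_tol)
  diagn <- attr(sol, "istate")
  if (!is.null(diagn) && diagn[1L] < 0)
    stop("ODE integration failed (istate = ", diagn[1L], ") for variant '",
         vn, "'", call. = FALSE)
  sol <- as.data.frame(sol)
  as_trajectory(sol, variant = vn, params = params, abs_tol = abs_tol)
}

# Attach observables to a data.frame with columns time, n1..n4.
as_trajectory <- function(df, variant, params, abs_tol = 1e-10) {
  clamp <- function(x) pmax(x, 0)
  df$PM <- clamp(df$n1)
  df$RE <- clamp(df$n2)
  df$LM <- clamp(df$n3)
  df$ILV <- clamp(df$n4)
  df$LELY <- df$LM + df$ILV
  df$total <- df$PM + df$RE + df$LELY
  df$intracellular_fraction <-
    ifelse(df$total > 0, (df$RE + df$LELY) / df$total, 0)
  structure(df, class = c("sterol_trajectory", "data.frame"),
            variant = variant, params = params)
}

#' @export
print.sterol_trajectory <- function(x, ...) {
  cat("<sterol_trajectory> variant:", attr(x, "variant"),
      "|", nrow(x), "time points over [",
      format(min(x$time)), ",", format(max(x$time)), "] min\n")
  print.data.frame(utils::head(as.data.frame(x)), digits = 5)
  if (nrow(x) > 6L) cat("  ... (", nrow(x) - 6L, " more rows)\n", sep = "")
  invisible(x)
}

#' Trajectory observables in tidy long format
#'
#' @param trajectory a \code{sterol_trajectory}.
#' @param observables observable names to keep; default all of
#'   \code{PM, RE, LM, ILV, LELY, total, intracellular_fraction}.
#' @param label optional scenario label column.
#' @return \code{data.frame} with columns (\code{scenario_label},)
#'   \code{time}, \code{observable}, \code{value}.
#' @export
trajectory_long <- function(trajectory, observables = NULL, label = NULL) {
  all_obs <- c("PM", "RE", "LM", "ILV", "LELY", "total",
               "intracellular_fraction")
  if (is.null(observables) || length(observables) == 0L)
    observables <- all_obs
  bad <- setdiff(observables, all_obs)
  if (length(bad))
    stop("unknown observable(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  out <- do.call(rbind, lapply(observables, function(ob) {
    data.frame(time = trajectory$time, observable = ob,
               value = trajectory[[ob]])
  }))
  if (!is.null(label)) out <- cbind(scenario_label = label, out)
  rownames(out) <- NULL
  out
}
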