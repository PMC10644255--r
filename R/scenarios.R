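# Scenario runners: pulse-chase, efflux, and batch grids.

#' Scenario specification
#'
#' Bundles a model variant, parameters, initial state and grid for use with
#' [scenario_batch()].
#'
#' @param variant variant name or [model_variant()].
#' @param params a [rate_constants()] object.
#' @param initial_state numeric length-4 state, or the token
#'   \code{"steady_fractions"} (efflux variant only): the open-system
#'   steady fractions normalised to total 1.
#' @param t_end end time (minutes, > 0).
#' @param n_points grid size (>= 2).
#' @param label scenario label used in batch output.
#' @return An object of class \code{"scenario_spec"}.
#' @export
scenario_spec <- function(variant, params, initial_state, t_end,
                          n_points = 101L, label = NULL) {
  variant <- model_variant(variant)
  params <- check_params_for_variant(variant, params)
  if (identical(initial_state, "steady_fractions")) {
    if (variant$name != "efflux_two_pathway")
      stop("'steady_fractions' initial state is only valid for the ",
           "efflux_two_pathway variant", call. = FALSE)
  } else if (!is.numeric(initial_state) || length(initial_state) != 4L ||
             any(initial_state < 0)) {
    stop("'initial_state' must be a non-negative length-4 vector or ",
         "\"steady_fractions\"", call. = FALSE)
  }
  if (!is.numeric(t_end) || length(t_end) != 1L || t_end <= 0)
    stop("'t_end' must be > 0", call. = FALSE)
  if (n_points < 2L) stop("'n_points' must be >= 2", call. = FALSE)
  if (is.null(label)) label <- variant$name
  structure(list(variant = variant, params = params,
                 initial_state = initial_state, t_end = t_end,
                 n_points = as.integer(n_points), label = label),
            class = "scenario_spec")
}

#' Simulate a pulse-chase experiment
#'
#' All tracer starts in the PM (\code{n1(0) = 1}, others 0), mimicking a
#' brief pulse-labelling of the cell surface followed by a chase. Only
#' closed (conservative) variants are admitted. With the NPC2-deficient
#' four-compartment parameters the LE/LYS signal (n3 + n4) is biphasic:
#' fast arrival in the limiting membrane followed by delayed accumulation
#' in ILVs.
#'
#' @param params a [rate_constants()] object.
#' @param variant \code{"closed_four"} (default), \code{"closed_three"} or
#'   \code{"reversible_two_branch"}.
#' @param t_end chase duration in minutes.
#' @param n_points grid size.
#' @param ... passed to [simulate_model()] (tolerances, explicit times).
#' @return A \code{sterol_trajectory}.
#' @examples
#' tr <- run_pulse_chase(dhe_params("disease"), t_end = 360, n_points = 25)
#' @export
run_pulse_chase <- function(params, variant = "closed_four",
                            t_end = 120, n_points = 61L, ...) {
  variant <- model_variant(variant)
  if (!is_closed_variant(variant$name))
    stop("pulse-chase requires a closed variant, not '", variant$name, "'",
         call. = FALSE)
  simulate_model(variant, params, init = c(1, 0, 0, 0),
                 t_end = t_end, n_points = n_points, ...)
}

#' Simulate sterol efflux via the two-pathway model
#'
#' Runs the efflux variant: PM efflux with rate \code{k5} (pathway I,
#' ectosomes / apoA1) and Weibull-delayed export of the ILV pool with
#' hazard \eqn{\mu k_6^\mu t^{\mu-1}} (pathway II, lysosomal exocytosis of
#' ILVs as exosomes). By default the initial state is the open-system
#' steady fractional distribution of the same intracellular rates,
#' normalised to total 1, corresponding to the end of a long loading
#' period. The experimentally accessible observable is the intracellular
#' LE/LYS fraction \code{(n3 + n4)/total}.
#'
#' @param params a [rate_constants()] object for the
#'   \code{efflux_two_pathway} variant.
#' @param t_end efflux duration in minutes.
#' @param n_points grid size.
#' @param init explicit non-negative length-4 initial state, or \code{NULL}
#'   (default) for the steady fractions.
#' @param ... passed to [simulate_model()].
#' @return A \code{sterol_trajectory} with an extra column
#'   \code{lely_fraction} = (n3 + n4)/total, the efflux readout.
#' @examples
#' p <- update_rates(dhe_params("disease"), k5 = 1e-4, k6 = 0.0015,
#'                   mu = 2.577)
#' tr <- run_efflux(p, t_end = 12000, n_points = 49)
#' @export
run_efflux <- function(params, t_end = 12000, n_points = 201L,
                       init = NULL, ...) {
  params <- as_rate_constants(params)
  if (is.null(init) || identical(init, "steady_fractions"))
    init <- steady_fractions(params)
  if (!is.numeric(init) || length(init) != 4L || any(init < 0))
    stop("'init' must be a non-negative length-4 state", call. = FALSE)
  tr <- simulate_model("efflux_two_pathway", params, init = init,
                       t_end = t_end, n_points = n_points, ...)
  tr$lely_fraction <- ifelse(tr$total > 0, tr$LELY / tr$total, 0)
  tr
}

#' Run a batch of simulation scenarios
#'
#' Integrates each [scenario_spec()] and stacks the observables into one
#' tidy long table, e.g. to reproduce multi-panel efflux parameter grids.
#'
#' @param specs a list of [scenario_spec()] objects (>= 1).
#' @param observables observable subset for the table (default: all).
#' @return List with elements \code{trajectories} (named by label) and
#'   \code{table} (columns \code{scenario_label, time, observable, value}).
#' @export
scenario_batch <- function(specs, observables = NULL) {
  if (inherits(specs, "scenario_spec")) specs <- list(specs)
  if (!length(specs)) stop("need at least one scenario", call. = FALSE)
  trajs <- list()
  tables <- list()
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    if (!inherits(sp, "scenario_spec"))
      stop("element ", i, " is not a scenario_spec", call. = FALSE)
    tr <- tryCatch({
      if (identical(sp$initial_state, "steady_fractions"))
        run_efflux(sp$params, t_end = sp$t_end, n_points = sp$n_points)
      else
        simulate_model(sp$variant, sp$params, init = sp$initial_state,
                       t_end = sp$t_end, n_points = sp$n_points)
    }, error = function(e) {
      stop("scenario '", sp$label, "': ", conditionMessage(e), call. = FALSE)
    })
    trajs[[i]] <- tr
    tables[[i]] <- trajectory_long(tr, observables, label = sp$label)
  }
  names(trajs) <- vapply(specs, `[[`, character(1), "label")
  list(trajectories = trajs, table = do.call(rbind, tables))
}
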