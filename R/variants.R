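# Model variant registry and right-hand sides.
#
# All variants are linear compartment models on the state
# (n1, n2, n3, n4) = (PM, REs, LE/LYS limiting membrane, ILVs); the
# efflux variant has a time-dependent export coefficient on n4.

.variant_registry <- list(
  closed_three = list(
    active = c("k1", "k2", "k3"),
    description = paste("Closed three-compartment cycle PM -> REs -> LE/LYS",
                        "-> PM (k4 = k-4 = 0); adequate for control cells.")),
  closed_four = list(
    active = c("k1", "k2", "k3", "k4", "km4"),
    description = paste("Closed four-compartment model with bidirectional",
                        "LM <-> ILV exchange; pulse-chase model for",
                        "NPC2-deficient cells.")),
  open_four = list(
    active = c("k1", "k2", "k3", "k4", "km4", "v0", "k5"),
    description = paste("Open system: constant sterol influx v0 into the PM",
                        "and first-order PM efflux k5; admits an analytic",
                        "steady state.")),
  efflux_two_pathway = list(
    active = c("k1", "k2", "k3", "k4", "km4", "k5", "k6", "mu"),
    description = paste("Efflux model with pathway I (PM efflux, k5) and",
                        "pathway II (Weibull-delayed lysosomal exocytosis of",
                        "ILVs, hazard mu*k6^mu*t^(mu-1)).")),
  reversible_two_branch = list(
    active = c("kab", "kba", "kac", "kca"),
    description = paste("Two independent reversible branches PM <-> REs and",
                        "PM <-> LE/LYS; comparison model only."))
)

#' Model variants of the sterol transport system
#'
#' Look up one of the five model variants by name. Each variant defines
#' which rate constants appear in its right-hand side
#' (\code{active_parameters}).
#'
#' @param name one of \code{"closed_three"}, \code{"closed_four"},
#'   \code{"open_four"}, \code{"efflux_two_pathway"},
#'   \code{"reversible_two_branch"}, or an existing \code{model_variant}.
#' @return An object of class \code{"model_variant"} with fields
#'   \code{name}, \code{active_parameters} and \code{description}.
#' @examples
#' model_variant("closed_four")$active_parameters
#' @export
model_variant <- function(name) {
  if (inherits(name, "model_variant")) return(name)
  if (!is.character(name) || length(name) != 1L ||
      !name %in% names(.variant_registry))
    stop("unknown model variant: ", deparse(name), "; must be one of ",
         paste(names(.variant_registry), collapse = ", "), call. = FALSE)
  v <- .variant_registry[[name]]
  structure(list(name = name, active_parameters = v$active,
                 description = v$description),
            class = "model_variant")
}

#' @export
print.model_variant <- function(x, ...) {
  cat("<model_variant> ", x$name, "\n  parameters: ",
      paste(x$active_parameters, collapse = ", "), "\n  ",
      x$description, "\n", sep = "")
  invisible(x)
}

#' List available model variant names
#' @return Character vector of variant names.
#' @export
variant_names <- function() names(.variant_registry)

is_closed_variant <- function(name)
  name %in% c("closed_three", "closed_four", "reversible_two_branch")

# Validate that parameters inactive in a variant's RHS are zero, so a
# parameter set cannot silently mean something else than the variant
# computes. mu is exempt (dimensionless shape, default 1).
check_params_for_variant <- function(variant, params) {
  variant <- model_variant(variant)
  params <- as_rate_constants(params)
  dynamic <- setdiff(names(params), "mu")
  inactive <- setdiff(dynamic, variant$active_parameters)
  nz <- inactive[vapply(params[inactive], function(x) x != 0, logical(1))]
  if (length(nz))
    stop("parameter(s) ", paste(nz, collapse = ", "),
         " must be 0 for variant '", variant$name, "'", call. = FALSE)
  invisible(params)
}

# Core RHS, shared by sterol_derivatives() and the integrator. No
# validation here; callers validate once.
rhs_core <- function(variant_name, p, n, t) {
  n1 <- n[[1L]]; n2 <- n[[2L]]; n3 <- n[[3L]]; n4 <- n[[4L]]
  switch(variant_name,
    closed_three = ,
    closed_four = c(
      -p$k1 * n1 + p$k3 * n3,
       p$k1 * n1 - p$k2 * n2,
       p$k2 * n2 - (p$k3 + p$k4) * n3 + p$km4 * n4,
       p$k4 * n3 - p$km4 * n4),
    open_four = c(
      p$v0 - (p$k1 + p$k5) * n1 + p$k3 * n3,
      p$k1 * n1 - p$k2 * n2,
      p$k2 * n2 - (p$k3 + p$k4) * n3 + p$km4 * n4,
      p$k4 * n3 - p$km4 * n4),
    efflux_two_pathway = c(
      -(p$k1 + p$k5) * n1 + p$k3 * n3,
       p$k1 * n1 - p$k2 * n2,
       p$k2 * n2 - (p$k3 + p$k4) * n3 + p$km4 * n4,
       p$k4 * n3 - p$km4 * n4 - weibull_hazard(t, p$k6, p$mu) * n4),
    reversible_two_branch = c(
      -(p$kab + p$kac) * n1 + p$kba * n2 + p$kca * n3,
       p$kab * n1 - p$kba * n2,
       p$kac * n1 - p$kca * n3,
       0),
    stop("unknown model variant: ", variant_name, call. = FALSE))
}

#' Instantaneous rates of change of the compartment amounts
#'
#' Evaluates the right-hand side of the chosen model variant at a given
#' state and time. Closed variants are conservative: the four rates sum to
#' zero exactly.
#'
#' @param variant a variant name or [model_variant()] object.
#' @param params a [rate_constants()] object (or coercible); parameters not
#'   used by the variant must be zero.
#' @param state numeric length-4 state \code{(n1, n2, n3, n4)}; all
#'   components must be non-negative.
#' @param t time in minutes (only the efflux variant's hazard depends on it).
#' @return Named numeric vector \code{c(n1, n2, n3, n4)} of derivatives.
#' @examples
#' sterol_derivatives("closed_four", dhe_params("disease"), c(1, 0, 0, 0))
#' @export
sterol_derivatives <- function(variant, params, state, t = 0) {
  variant <- model_variant(variant)
  params <- check_params_for_variant(variant, params)
  if (!is.numeric(state) || length(state) != 4L || anyNA(state))
    stop("'state' must be a numeric vector of length 4", call. = FALSE)
  if (any(state < 0)) {
    i <- which(state < 0)[1L]
    stop("state component n", i, " is negative (", state[i], ")",
         call. = FALSE)
  }
  if (!is.numeric(t) || length(t) != 1L || t < 0)
    stop("'t' must be a single non-negative time", call. = FALSE)
  d <- rhs_core(variant$name, params, state, t)
  names(d) <- c("n1", "n2", "n3", "n4")
  d
}
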