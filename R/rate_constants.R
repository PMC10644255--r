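#' Kinetic rate constants for the sterol transport models
#'
#' Container for all first-order rate constants of the compartment models of
#' sterol trafficking between the plasma membrane (PM, compartment 1),
#' recycling endosomes (REs, compartment 2), the limiting membrane of late
#' endosomes/lysosomes (LM, compartment 3) and intraluminal vesicles
#' (ILVs, compartment 4). All rates are in \eqn{min^{-1}} unless stated
#' otherwise; the canonical internal time unit throughout the package is
#' minutes.
#'
#' @param k1 rate PM -> REs (min^-1).
#' @param k2 rate REs -> LM (min^-1).
#' @param k3 rate LM -> PM (min^-1).
#' @param k4 rate LM -> ILVs (min^-1).
#' @param km4 rate ILVs -> LM (min^-1); written \eqn{k_{-4}} in the model.
#' @param v0 constant sterol influx into the PM (amount min^-1); the product
#'   of an uptake rate constant and the (constant, excess) extracellular
#'   sterol amount.
#' @param k5 PM efflux rate constant (min^-1), efflux pathway I
#'   (ectosome shedding / efflux to apoA1).
#' @param k6 inverse Weibull time constant of lysosomal exocytosis,
#'   \eqn{k_6 = 1/\tau} (min^-1), efflux pathway II.
#' @param mu Weibull shape parameter (dimensionless, > 0). \code{mu = 1}
#'   recovers a constant export rate; \code{mu > 1} a delayed, accelerating
#'   (compressed-exponential) export.
#' @param kab,kba,kac,kca rates of the reversible two-branch comparison
#'   model: PM <-> REs (\code{kab}, \code{kba}) and PM <-> LE/LYS
#'   (\code{kac}, \code{kca}). Used only by the
#'   \code{"reversible_two_branch"} variant.
#'
#' @return An object of class \code{"rate_constants"}: a named list of the
#'   validated parameter values.
#'
#' @examples
#' p <- rate_constants(k1 = 0.03216, k2 = 0.4331, k3 = 0.1744,
#'                     k4 = 0.0084, km4 = 0.0039)
#' p$k1
#' @export
rate_constants <- function(k1 = 0, k2 = 0, k3 = 0, k4 = 0, km4 = 0,
                           v0 = 0, k5 = 0, k6 = 0, mu = 1,
                           kab = 0, kba = 0, kac = 0, kca = 0) {
  p <- list(k1 = k1, k2 = k2, k3 = k3, k4 = k4, km4 = km4,
            v0 = v0, k5 = k5, k6 = k6, mu = mu,
            kab = kab, kba = kba, kac = kac, kca = kca)
  for (nm in names(p)) {
    x <- p[[nm]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
    if (x < 0)
      stop("parameter '", nm, "' must be non-negative (got ", x, ")",
           call. = FALSE)
  }
  if (p$mu <= 0)
    stop("parameter 'mu' must be > 0", call. = FALSE)
  structure(p, class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("<rate_constants>\n")
  act <- unlist(x)
  act <- act[act != 0 | names(act) == "mu"]
  cat(paste0("  ", names(act), " = ", format(act, digits = 6),
             collapse = "\n"), "\n")
  invisible(x)
}

#' Coerce to rate_constants
#'
#' @param x a \code{rate_constants} object, or a named list/vector of
#'   parameter values understood by [rate_constants()].
#' @return A \code{rate_constants} object.
#' @export
as_rate_constants <- function(x) {
  if (inherits(x, "rate_constants")) return(x)
  x <- as.list(x)
  bad <- setdiff(names(x), names(formals(rate_constants)))
  if (length(bad))
    stop("unknown rate constant(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(rate_constants, x)
}

#' Update selected rate constants
#'
#' Returns a copy of \code{params} with the named values replaced and the
#' result re-validated.
#'
#' @param params a [rate_constants()] object.
#' @param ... named scalar replacements, e.g. \code{k5 = 1e-4}.
#' @return A \code{rate_constants} object.
#' @export
update_rates <- function(params, ...) {
  params <- as_rate_constants(params)
  repl <- list(...)
  bad <- setdiff(names(repl), names(params))
  if (length(bad))
    stop("unknown rate constant(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  params[names(repl)] <- repl
  do.call(rate_constants, unclass(params))
}

#' Published DHE transport rate constants for human fibroblasts
#'
#' Fitted first-order rate constants for transport of the fluorescent
#' cholesterol analogue DHE between PM, REs and LE/LYSs in human skin
#' fibroblasts, obtained by global regression of pulse-chase time courses.
#' For NPC2-deficient ("disease") fibroblasts the LE/LYS pool is
#' sub-compartmentalised into limiting membrane and ILVs (four-compartment
#' model, all five rates); for control cells a three-compartment model was
#' used (\code{k4 = km4 = 0}). \code{"control_full"} additionally carries
#' the ILV exchange rates inferred for NPC2-competent cells
#' (\code{k4 = 0.01686}, \code{km4 = 0.0843} min^-1, i.e. an ILV/LM
#' equilibrium constant \eqn{q_2 = 0.2}).
#'
#' @param cell_line one of \code{"disease"}, \code{"control"},
#'   \code{"control_full"}.
#' @return A [rate_constants()] object.
#' @examples
#' dhe_params("disease")
#' transit_time(dhe_params("control"))
#' @export
dhe_params <- function(cell_line = c("disease", "control", "control_full")) {
  cell_line <- match.arg(cell_line)
  switch(cell_line,
    disease = rate_constants(k1 = 0.03216, k2 = 0.4331, k3 = 0.1744,
                             k4 = 0.0084, km4 = 0.0039),
    control = rate_constants(k1 = 0.01204, k2 = 0.2465, k3 = 0.09351),
    control_full = rate_constants(k1 = 0.01204, k2 = 0.2465, k3 = 0.09351,
                                  k4 = 0.01686, km4 = 0.0843))
}

#' Published Weibull efflux parameters for DHE release from fibroblasts
#'
#' Offset-Weibull parameters describing the decay of the fractional
#' intracellular DHE intensity during sterol efflux: the residence time
#' constant \eqn{\tau} (hours) and shape parameter \eqn{\mu}. The
#' \code{"disease"} set describes NPC2-deficient fibroblasts; the
#' \code{"npc2_treated"} set the same cells after add-back of purified NPC2
#' protein.
#'
#' @param cell_line one of \code{"disease"}, \code{"npc2_treated"}.
#' @return A list with elements \code{tau_h} (hours) and \code{mu}.
#' @examples
#' dhe_efflux_weibull("disease")
#' @export
dhe_efflux_weibull <- function(cell_line = c("disease", "npc2_treated")) {
  cell_line <- match.arg(cell_line)
  switch(cell_line,
    disease = list(tau_h = 135.14, mu = 2.577),
    npc2_treated = list(tau_h = 86.96, mu = 1.324))
}
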