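# Analytic steady state of the open four-compartment system.
#
# Setting the RHS of the open system to zero gives, in closed form,
#   n4* = q2 n3*,  n2* = (k3/k2) n3*,  n1* = (k3/k1) n3*,
#   n3* = v0 k1 / (k3 k5),
# with q2 = k4/k-4. The fractional distribution (k3/k1 : k3/k2 : 1 : q2)
# is independent of the influx v0 and the efflux rate k5.

#' Equilibrium constant for ILV / limiting-membrane sterol exchange
#'
#' \eqn{q_2 = k_4 / k_{-4}}, the equilibrium constant for sterol exchange
#' between intraluminal vesicles and the limiting membrane of
#' endo-lysosomes. NPC2 activity lowers \eqn{q_2} by accelerating the
#' back-transfer \eqn{k_{-4}}.
#'
#' @param k4 rate LM -> ILVs (min^-1), >= 0.
#' @param km4 rate ILVs -> LM (min^-1); must be > 0 unless \code{k4 = 0}
#'   (then \eqn{q_2 = 0} by convention).
#' @return Dimensionless ratio \code{k4 / km4}.
#' @examples
#' q2_ratio(0.01686, 0.0843)  # 0.2, inferred for control cells
#' q2_ratio(0.0084, 0.0039)   # NPC2-deficient cells
#' @export
q2_ratio <- function(k4, km4) {
  if (!is.numeric(k4) || length(k4) != 1L || k4 < 0)
    stop("'k4' must be a single non-negative number", call. = FALSE)
  if (!is.numeric(km4) || length(km4) != 1L || km4 < 0)
    stop("'km4' must be a single non-negative number", call. = FALSE)
  if (km4 == 0) {
    if (k4 == 0) return(0)
    stop("km4 = 0 with k4 > 0: q2 is undefined (division by zero)",
         call. = FALSE)
  }
  k4 / km4
}

check_positive_rates <- function(params, rates) {
  for (nm in rates)
    if (params[[nm]] <= 0)
      stop("steady state is singular: rate '", nm, "' must be > 0",
           call. = FALSE)
  invisible(params)
}

#' Analytic steady state of the open sterol transport system
#'
#' Closed-form steady-state amounts and fractions of the open
#' four-compartment model (constant influx \code{v0} into the PM, PM
#' efflux \code{k5}). Amounts scale linearly with \code{v0} and inversely
#' with \code{k5}; the fractional distribution depends only on the
#' intracellular rates \code{k1..km4}.
#'
#' @param params a [rate_constants()] object with \code{k1, k2, k3, v0, k5}
#'   all > 0 and \code{km4 > 0} whenever \code{k4 > 0}.
#' @return An object of class \code{"steady_state_result"}: list with
#'   \code{amounts} (named n1..n4), \code{fractions} (sum to 1),
#'   \code{intracellular_fraction} = (n2+n3+n4)/total, and \code{q2}.
#' @examples
#' ss <- steady_state_amounts(update_rates(dhe_params("disease"),
#'                                         v0 = 1, k5 = 0.001))
#' ss$intracellular_fraction
#' @export
steady_state_amounts <- function(params) {
  params <- as_rate_constants(params)
  check_positive_rates(params, c("k1", "k2", "k3", "v0", "k5"))
  q2 <- q2_ratio(params$k4, params$km4)
  n3 <- params$v0 * params$k1 / (params$k3 * params$k5)
  amounts <- c(n1 = (params$k3 / params$k1) * n3,
               n2 = (params$k3 / params$k2) * n3,
               n3 = n3,
               n4 = q2 * n3)
  total <- sum(amounts)
  structure(list(amounts = amounts,
                 fractions = amounts / total,
                 intracellular_fraction = sum(amounts[2:4]) / total,
                 q2 = q2),
            class = "steady_state_result")
}

#' @export
print.steady_state_result <- function(x, ...) {
  cat("<steady_state_result>\n  amounts:   ",
      paste(sprintf("%s = %.6g", names(x$amounts), x$amounts),
            collapse = ", "),
      "\n  fractions: ",
      paste(sprintf("%s = %.4f", names(x$fractions), x$fractions),
            collapse = ", "),
      "\n  intracellular fraction = ", sprintf("%.4f", x$intracellular_fraction),
      "   q2 = ", sprintf("%.4g", x$q2), "\n", sep = "")
  invisible(x)
}

#' Steady-state intracellular sterol fraction
#'
#' Fraction of cellular sterol residing in REs + LM + ILVs at the steady
#' state of the open system:
#' \deqn{\frac{k_3/k_2 + 1 + q_2}{k_3/k_1 + k_3/k_2 + 1 + q_2}}
#' Independent of the influx \code{v0} and efflux \code{k5}. With the
#' rate constants fitted for NPC2-deficient fibroblasts this evaluates to
#' 0.3961.
#'
#' @param params a [rate_constants()] object with \code{k1, k2, k3 > 0} and
#'   \code{km4 > 0} whenever \code{k4 > 0}.
#' @return Fraction in [0, 1).
#' @examples
#' intracellular_fraction(dhe_params("disease"))  # 0.3961
#' intracellular_fraction(dhe_params("control"))  # 0.1508
#' @export
intracellular_fraction <- function(params) {
  params <- as_rate_constants(params)
  check_positive_rates(params, c("k1", "k2", "k3"))
  q2 <- q2_ratio(params$k4, params$km4)
  intra <- params$k3 / params$k2 + 1 + q2
  intra / (params$k3 / params$k1 + intra)
}

#' Intracellular sterol fraction as a function of q2
#'
#' Sweeps the ILV/LM equilibrium constant \eqn{q_2} while holding the
#' circuit rates \code{k1..k3} (and \code{km4}) fixed, evaluating the
#' steady-state intracellular fraction at each value. The fraction
#' increases hyperbolically with \eqn{q_2} and saturates below 1 —
#' intraluminal sterol trapping drives endo-lysosomal accumulation.
#'
#' @param params a [rate_constants()] object supplying \code{k1, k2, k3}
#'   (all > 0).
#' @param q2_values non-negative numeric vector of equilibrium constants.
#' @return \code{data.frame} with columns \code{q2} and
#'   \code{intracellular_fraction}.
#' @examples
#' fraction_vs_q2(dhe_params("disease"), c(0, 0.2, 1, 2.1538))
#' @export
fraction_vs_q2 <- function(params, q2_values) {
  params <- as_rate_constants(params)
  check_positive_rates(params, c("k1", "k2", "k3"))
  if (!is.numeric(q2_values) || anyNA(q2_values) || any(q2_values < 0))
    stop("'q2_values' must be non-negative numbers", call. = FALSE)
  km4 <- if (params$km4 > 0) params$km4 else 1
  frac <- vapply(q2_values, function(q2) {
    intracellular_fraction(update_rates(params, k4 = q2 * km4, km4 = km4))
  }, numeric(1))
  data.frame(q2 = q2_values, intracellular_fraction = frac)
}

#' Transit time of the PM -> REs -> LE/LYS -> PM sterol circuit
#'
#' Sum of the reciprocal rate constants of the circulation circuit,
#' \eqn{1/k_1 + 1/k_2 + 1/k_3} (minutes): about 40 min with the rates of
#' NPC2-deficient cells and about 1.6 h for control cells.
#'
#' @param params a [rate_constants()] object with \code{k1, k2, k3 > 0}.
#' @return Transit time in minutes.
#' @examples
#' transit_time(dhe_params("disease"))
#' @export
transit_time <- function(params) {
  params <- as_rate_constants(params)
  check_positive_rates(params, c("k1", "k2", "k3"))
  1 / params$k1 + 1 / params$k2 + 1 / params$k3
}

#' Steady-state fractional distribution of a parameter set
#'
#' The normalised steady fractions (k3/k1 : k3/k2 : 1 : q2)/total, used as
#' the default initial condition of efflux simulations (total = 1).
#'
#' @param params a [rate_constants()] object with \code{k1, k2, k3 > 0}.
#' @return Named numeric vector (n1..n4) summing to 1.
#' @export
steady_fractions <- function(params) {
  params <- as_rate_constants(params)
  check_positive_rates(params, c("k1", "k2", "k3"))
  q2 <- q2_ratio(params$k4, params$km4)
  w <- c(n1 = params$k3 / params$k1, n2 = params$k3 / params$k2,
         n3 = 1, n4 = q2)
  w / sum(w)
}

#' One-row steady-state summary table
#'
#' Collects the parameter values, q2, steady fractions, intracellular
#' fraction and transit time into a single row suitable for CSV export
#' (fractions reported to 4 decimals in print).
#'
#' @param params a [rate_constants()] object.
#' @param variant variant name used for labelling (default
#'   \code{"open_four"}).
#' @return A one-row \code{data.frame}.
#' @export
steady_state_summary <- function(params, variant = "open_four") {
  params <- as_rate_constants(params)
  fr <- steady_fractions(params)
  data.frame(variant = model_variant(variant)$name,
             k1 = params$k1, k2 = params$k2, k3 = params$k3,
             k4 = params$k4, km4 = params$km4, v0 = params$v0,
             k5 = params$k5, k6 = params$k6, mu = params$mu,
             q2 = q2_ratio(params$k4, params$km4),
             frac_PM = fr[["n1"]], frac_RE = fr[["n2"]],
             frac_LM = fr[["n3"]], frac_ILV = fr[["n4"]],
             intracellular_fraction = intracellular_fraction(params),
             transit_time_min = transit_time(params))
}
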