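# Time-course dataset container (fractional fluorescence per compartment).

.valid_observables <- c("PM", "RE", "LELY", "intracellular_fraction")
.valid_experiments <- c("pulse_chase", "continuous_uptake", "efflux")

#' Time-course dataset of fractional fluorescence
#'
#' Long-format container for observed (or generated) fractional
#' fluorescence curves: one row per (observable, time) measurement, with
#' optional per-point standard deviation. Times are stored in minutes.
#'
#' @param data \code{data.frame} with columns \code{observable} (one of
#'   \code{PM, RE, LELY, intracellular_fraction}), \code{time_min}
#'   (>= 0, sorted within each observable), \code{value} (>= 0) and
#'   optionally \code{sd} (> 0 or NA).
#' @param cell_line label, e.g. \code{"control"} or \code{"disease"}.
#' @param experiment one of \code{"pulse_chase"}, \code{"continuous_uptake"},
#'   \code{"efflux"}.
#' @param truth optional named list recording generator provenance
#'   (true parameters, seed, noise) for synthetic datasets.
#' @return An object of class \code{"timecourse_dataset"}.
#' @export
timecourse_dataset <- function(data, cell_line, experiment, truth = NULL) {
  experiment <- match.arg(experiment, .valid_experiments)
  need <- c("observable", "time_min", "value")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (!nrow(data)) stop("dataset has no rows", call. = FALSE)
  bad <- setdiff(unique(data$observable), .valid_observables)
  if (length(bad))
    stop("invalid observable(s): ", paste(bad, collapse = ", "),
         "; must be one of ", paste(.valid_observables, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(data$time_min) || anyNA(data$time_min) ||
      any(data$time_min < 0))
    stop("'time_min' must be non-negative numbers", call. = FALSE)
  if (!is.numeric(data$value) || anyNA(data$value) || any(data$value < 0))
    stop("'value' must be non-negative numbers", call. = FALSE)
  if (!"sd" %in% names(data)) data$sd <- NA_real_
  data <- data[order(data$observable, data$time_min),
               c("observable", "time_min", "value", "sd")]
  for (ob in unique(data$observable)) {
    tt <- data$time_min[data$observable == ob]
    if (anyDuplicated(tt))
      stop("duplicate times in series '", ob, "'", call. = FALSE)
  }
  rownames(data) <- NULL
  structure(list(cell_line = as.character(cell_line),
                 experiment = experiment, data = data, truth = truth),
            class = "timecourse_dataset")
}

#' @export
print.timecourse_dataset <- function(x, ...) {
  cat("<timecourse_dataset> cell_line:", x$cell_line,
      "| experiment:", x$experiment, "\n  series:",
      paste(sprintf("%s (%d pts)", unique(x$data$observable),
                    table(x$data$observable)[unique(x$data$observable)]),
            collapse = ", "), "\n")
  if (!is.null(x$truth))
    cat("  synthetic; seed:", x$truth$seed %||% "none", "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract one series from a dataset
#'
#' @param dataset a [timecourse_dataset()].
#' @param observable series name.
#' @return \code{data.frame} with columns \code{time_min, value, sd}.
#' @export
dataset_series <- function(dataset, observable) {
  stopifnot(inherits(dataset, "timecourse_dataset"))
  d <- dataset$data[dataset$data$observable == observable,
                    c("time_min", "value", "sd")]
  rownames(d) <- NULL
  d
}
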