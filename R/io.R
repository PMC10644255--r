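# CSV reading/writing of time-course datasets.
#
# One canonical long-format dialect: columns cell_line, experiment,
# observable, time, time_unit (min|h), value, sd (optional/empty).
# '#'-prefixed header lines carry provenance comments. Times are converted
# to minutes on ingest and stored internally in minutes only.

.csv_columns <- c("cell_line", "experiment", "observable", "time",
                  "time_unit", "value", "sd")

#' Read time-course datasets from CSV
#'
#' Parses the package's long-format CSV dialect, ignoring \code{#} comment
#' lines, validating the observable vocabulary, converting hour-valued
#' times to minutes, and grouping rows into one [timecourse_dataset()] per
#' (cell_line, experiment) block.
#'
#' @param path file path.
#' @return A list of [timecourse_dataset()] objects, named
#'   \code{"<cell_line>.<experiment>"}.
#' @export
read_timecourse <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  if (!any(keep)) stop("no data rows in ", path, call. = FALSE)
  line_no <- which(keep)
  df <- tryCatch(
    utils::read.csv(text = paste(lines[keep], collapse = "\n"),
                    stringsAsFactors = FALSE,
                    colClasses = "character", check.names = TRUE),
    error = function(e)
      stop("cannot parse CSV ", path, ": ", conditionMessage(e),
           call. = FALSE))
  miss <- setdiff(setdiff(.csv_columns, "sd"), names(df))
  if (length(miss))
    stop("missing required column(s) in ", path, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!"sd" %in% names(df)) df$sd <- ""
  rows <- line_no[-1L]  # file line of each data row (first kept = header)

  fail <- function(i, why)
    stop("parse error at line ", rows[i], " of ", path, ": ", why,
         call. = FALSE)
  num <- function(col, allow_empty = FALSE) {
    x <- trimws(df[[col]])
    out <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(out) & !(allow_empty & x == ""))
    if (length(bad))
      fail(bad[1L], paste0("non-numeric ", col, " value '",
                           x[bad[1L]], "'"))
    out
  }
  bad_obs <- which(!df$observable %in% .valid_observables)
  if (length(bad_obs))
    fail(bad_obs[1L], paste0("invalid observable '",
                             df$observable[bad_obs[1L]], "'"))
  bad_unit <- which(!df$time_unit %in% c("min", "h"))
  if (length(bad_unit))
    fail(bad_unit[1L], paste0("time_unit must be 'min' or 'h', got '",
                              df$time_unit[bad_unit[1L]], "'"))
  tt <- num("time")
  neg <- which(tt < 0)
  if (length(neg)) fail(neg[1L], "negative time")
  vv <- num("value")
  negv <- which(vv < 0)
  if (length(negv)) fail(negv[1L], "negative value")
  ss <- num("sd", allow_empty = TRUE)

  df$time_min <- ifelse(df$time_unit == "h", tt * 60, tt)
  df$value_num <- vv
  df$sd_num <- ss
  key <- paste(df$cell_line, df$experiment, sep = ".")
  for (k in unique(key))
    if (length(unique(df$time_unit[key == k])) > 1L)
      stop("inconsistent time_unit within block '", k, "' of ", path,
           call. = FALSE)
  out <- lapply(split(df, factor(key, levels = unique(key))), function(d) {
    timecourse_dataset(
      data.frame(observable = d$observable, time_min = d$time_min,
                 value = d$value_num, sd = d$sd_num),
      cell_line = d$cell_line[1L], experiment = d$experiment[1L])
  })
  out
}

#' Write time-course datasets to CSV
#'
#' Writes one or more datasets in the canonical long format (times in
#' minutes), optionally preceded by \code{#} provenance comment lines.
#' Numeric values are written with 15 significant digits so a
#' write/read round trip is lossless to 12 significant digits.
#'
#' @param datasets a [timecourse_dataset()] or list of them.
#' @param path output file path.
#' @param comments character vector of comment lines (without the leading
#'   \code{#}). For synthetic datasets the generator provenance (truth
#'   parameters, seed, grid) is appended automatically.
#' @return Invisibly, \code{path}.
#' @export
write_timecourse <- function(datasets, path, comments = NULL) {
  if (inherits(datasets, "timecourse_dataset")) datasets <- list(datasets)
  fmt <- function(x) ifelse(is.na(x), "", format(x, digits = 15))
  rows <- lapply(datasets, function(ds)
    data.frame(cell_line = ds$cell_line, experiment = ds$experiment,
               observable = ds$data$observable,
               time = fmt(ds$data$time_min), time_unit = "min",
               value = fmt(ds$data$value), sd = fmt(ds$data$sd)))
  body <- do.call(rbind, rows)
  hdr <- character(0)
  if (!is.null(comments)) hdr <- paste0("# ", comments)
  for (ds in datasets)
    if (!is.null(ds$truth)) {
      tp <- ds$truth
      pline <- if (!is.null(tp$params)) {
        act <- unlist(unclass(tp$params))
        paste(sprintf("%s=%g", names(act)[act != 0 | names(act) == "mu"],
                      act[act != 0 | names(act) == "mu"]), collapse = " ")
      } else {
        paste(sprintf("%s=%g", c("tau_h", "mu", "f0", "f_inf"),
                      c(tp$tau_h, tp$mu, tp$f0, tp$f_inf)), collapse = " ")
      }
      hdr <- c(hdr, sprintf("# truth [%s/%s]: %s | noise %s sigma=%g seed=%s",
                            ds$cell_line, ds$experiment, pline,
                            tp$noise$kind %||% "none",
                            tp$noise$sigma %||% 0,
                            tp$seed %||% "none"))
    }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(body, con, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
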