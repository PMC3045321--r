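#' Read an event table
#'
#' Reads a comma-separated event table with mandatory header and columns
#' `time,intensity` (UTF-8, `.` decimal).  Row order is preserved;
#' malformed intensities are reported with their line number.
#'
#' @param path Path to the CSV file.
#' @return Data frame with character `time` and numeric `intensity`.
#' @export
read_event_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character",
                        strip.white = TRUE, check.names = TRUE)
  if (nrow(df) == 0L) stop("empty event table: ", path, call. = FALSE)
  if (!all(c("time", "intensity") %in% names(df))) {
    stop("event table must have header 'time,intensity', got: ",
         paste(names(df), collapse = ","), call. = FALSE)
  }
  x <- suppressWarnings(as.numeric(df$intensity))
  if (anyNA(x) || any(!is.finite(x))) {
    bad <- which(is.na(x) | !is.finite(x))[1]
    stop("non-numeric or non-finite intensity at line ", bad + 1L,
         " of ", path, call. = FALSE)
  }
  if (any(!nzchar(df$time))) {
    bad <- which(!nzchar(df$time))[1]
    stop("empty time label at line ", bad + 1L, " of ", path, call. = FALSE)
  }
  data.frame(time = df$time, intensity = x, stringsAsFactors = FALSE)
}

#' Write an event table
#'
#' @param dataset Data frame with columns `time`, `intensity`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(dataset, path) {
  stopifnot(all(c("time", "intensity") %in% names(dataset)))
  utils::write.csv(dataset[c("time", "intensity")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a growth curve
#'
#' CSV with header `time_h,od600`.
#'
#' @param path Path to the CSV file.
#' @return Data frame with numeric `time_h`, `od600`.
#' @export
read_growth_curve <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  if (!all(c("time_h", "od600") %in% names(df))) {
    stop("growth curve must have header 'time_h,od600'", call. = FALSE)
  }
  if (nrow(df) == 0L) stop("empty growth curve: ", path, call. = FALSE)
  data.frame(time_h = as.numeric(df$time_h), od600 = as.numeric(df$od600))
}

#' @rdname read_growth_curve
#' @param curve Data frame with `time_h`, `od600`.
#' @export
write_growth_curve <- function(curve, path) {
  utils::write.csv(curve[c("time_h", "od600")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a structured run configuration
#'
#' Configurations (component parameters, schedules, sweep ranges, seeds)
#' are stored as YAML key-value text.
#'
#' @param path Path to the YAML file.
#' @return For `read_run_config`, a named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  yaml::read_yaml(path)
}

#' @rdname read_run_config
#' @param config Named list to serialize.
#' @export
write_run_config <- function(config, path) {
  stopifnot(is.list(config))
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Serialize a fitted mixture model to a config list
#'
#' @param model A [mixture_model()].
#' @return Named list suitable for [write_run_config()].
#' @export
mixture_to_config <- function(model) {
  stopifnot(inherits(model, "mixture_model"))
  list(gaussian = list(center = model$gaussian$center,
                       width = model$gaussian$width),
       lognormal = list(log_mean = model$lognormal$log_mean,
                        log_sd = model$lognormal$log_sd),
       weights = lapply(seq_len(nrow(model$weights)), function(i) {
         list(time = model$weights$time[i],
              C1 = model$weights$C1[i],
              C2 = model$weights$C2[i])
       }))
}

#' @rdname mixture_to_config
#' @param config A list produced by `mixture_to_config` (or read back from
#'   YAML).
#' @export
mixture_from_config <- function(config) {
  w <- do.call(rbind, lapply(config$weights, function(e) {
    data.frame(time = as.character(e$time), C1 = as.numeric(e$C1),
               C2 = as.numeric(e$C2), stringsAsFactors = FALSE)
  }))
  mixture_model(
    gaussian_component(config$gaussian$center, config$gaussian$width),
    lognormal_component(config$lognormal$log_mean, config$lognormal$log_sd),
    w
  )
}
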