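#' Default assay and regulatory constants
#'
#' Constants used throughout the package: IDEXX defined-substrate assay
#' detection limits, the value substituted for left-censored (below lower
#' limit of detection, LOD) samples, California single-sample regulatory
#' thresholds per indicator, and the beach-normal angle used to decompose
#' wind into alongshore and offshore components.
#'
#' Thresholds are in MPN/100 mL: total coliforms (tc) 10,000; E. coli (ec)
#' 400 (the fecal-coliform single-sample limit, used as a proxy because no
#' E. coli-specific marine standard exists); Enterococcus (ent) 104.
#'
#' @return A list with elements `lod_lower` (10), `lod_upper` (24196),
#'   `substitute` (1), `thresholds` (named vector, MPN/100 mL),
#'   `beach_normal` (degrees from true north).
#' @export
#' @examples
#' fib_defaults()$thresholds
fib_defaults <- function() {
  list(
    lod_lower    = 10,
    lod_upper    = 24196,
    substitute   = 1,
    thresholds   = c(tc = 10000, ec = 400, ent = 104),
    beach_normal = 140
  )
}

fib_indicators <- function() c("tc", "ec", "ent")

#' Construct a single-indicator concentration series
#'
#' A `fib_series` holds one indicator's concentration time series on a
#' regular sampling grid, together with its censoring flags and assay /
#' regulatory metadata. Concentrations are MPN/100 mL; timestamps are
#' `POSIXct` on a strictly increasing, constant-interval grid.
#'
#' @param values Numeric concentrations (MPN/100 mL). Censored samples may
#'   be `NA` if `below_lod` marks them, or already hold the substitute value.
#' @param timestamps `POSIXct` vector, strictly increasing, constant spacing.
#' @param indicator One of `"tc"`, `"ec"`, `"ent"`.
#' @param below_lod Logical vector flagging left-censored samples. Defaults
#'   to all `FALSE`.
#' @param lod_lower,lod_upper,threshold,substitute_value Metadata overrides;
#'   defaults come from [fib_defaults()].
#' @return An object of class `fib_series`.
#' @export
fib_series <- function(values, timestamps, indicator = c("ent", "ec", "tc"),
                       below_lod = NULL,
                       lod_lower = NULL, lod_upper = NULL,
                       threshold = NULL, substitute_value = NULL) {
  indicator <- match.arg(indicator)
  def <- fib_defaults()
  if (is.null(lod_lower)) lod_lower <- def$lod_lower
  if (is.null(lod_upper)) lod_upper <- def$lod_upper
  if (is.null(threshold)) threshold <- unname(def$thresholds[indicator])
  if (is.null(substitute_value)) substitute_value <- def$substitute
  if (is.null(below_lod)) below_lod <- rep(FALSE, length(values))

  values <- as.numeric(values)
  if (length(values) != length(timestamps) ||
      length(values) != length(below_lod)) {
    stop("values, timestamps and below_lod must have equal length")
  }
  timestamps <- as.POSIXct(timestamps)
  dt <- diff(as.numeric(timestamps))
  if (length(dt)) {
    if (any(dt <= 0)) stop("timestamps must be strictly increasing")
    if (max(dt) - min(dt) > 1e-6) {
      stop("timestamps must lie on a constant-interval grid")
    }
  }

  structure(
    list(
      indicator = indicator,
      values = values,
      below_lod = as.logical(below_lod),
      timestamps = timestamps,
      interval = if (length(dt)) dt[1] / 60 else NA_real_,
      lod_lower = lod_lower,
      lod_upper = lod_upper,
      threshold = threshold,
      substitute_value = substitute_value
    ),
    class = "fib_series"
  )
}

#' @export
print.fib_series <- function(x, ...) {
  cat(sprintf(
    "<fib_series> %s: %d samples every %g min, %d below LOD (<%g MPN/100 mL)\n",
    toupper(x$indicator), length(x$values), x$interval,
    sum(x$below_lod), x$lod_lower
  ))
  invisible(x)
}

#' Replace left-censored concentrations with the substitute value
#'
#' Samples flagged below the lower LOD are set to the substitute
#' concentration (1 MPN/100 mL by default) so the series can be
#' log10-transformed and summarized; detected samples are unchanged. Values
#' above the upper LOD trigger a warning (right-censoring is not modelled).
#'
#' @param fib A [fib_series()].
#' @return The series with censored values substituted.
#' @export
substitute_censored <- function(fib) {
  stopifnot(inherits(fib, "fib_series"))
  over <- !is.na(fib$values) & fib$values > fib$lod_upper
  if (any(over)) {
    warning(sprintf("%d value(s) above the upper LOD (%g); left unchanged",
                    sum(over), fib$lod_upper))
  }
  fib$values[fib$below_lod] <- fib$substitute_value
  fib
}

#' Flag regulatory-threshold exceedances
#'
#' A sample exceeds when its concentration is strictly greater than the
#' indicator's single-sample threshold. The strict inequality follows the
#' regulatory single-sample convention (concentrations rising above the
#' standard), so a sample exactly at the threshold does not exceed.
#'
#' @param fib A substituted [fib_series()].
#' @return Logical vector, one flag per sample.
#' @export
flag_exceedance <- function(fib) {
  stopifnot(inherits(fib, "fib_series"))
  fib$values > fib$threshold
}

#' Fill missing values by linear interpolation in time
#'
#' Interior gaps are filled linearly between the neighbouring observed
#' values; leading or trailing missing values are extended from the nearest
#' observed value (interpolation needs a value on both sides, so the series
#' ends fall back to nearest-value extension). More than `max_missing` of
#' the series missing is treated as a data-quality failure.
#'
#' @param x Numeric vector with possible `NA`s.
#' @param times Optional numeric/POSIXct positions (defaults to an even grid).
#' @param max_missing Maximum tolerated missing fraction (default 0.2).
#' @return Numeric vector with no missing values.
#' @export
#' @examples
#' interpolate_missing(c(1, NA, 3))
interpolate_missing <- function(x, times = NULL, max_missing = 0.2) {
  x <- as.numeric(x)
  n <- length(x)
  if (is.null(times)) times <- seq_len(n)
  times <- as.numeric(times)
  miss <- is.na(x)
  if (!any(miss)) return(x)
  # the fraction guard is only meaningful once the series has some length
  if (n > 10 && mean(miss) > max_missing) {
    stop(sprintf("%.0f%% of values missing exceeds the %.0f%% quality guard",
                 100 * mean(miss), 100 * max_missing))
  }
  if (sum(!miss) < 2) stop("need at least two observed values to interpolate")
  # rule = 2 extends the first/last observed value to the series ends
  stats::approx(times[!miss], x[!miss], xout = times, rule = 2)$y
}

#' Align an external series onto the sampling grid
#'
#' Third-party observations (e.g. six-minute tide gauge records) are mapped
#' onto the event's sampling timestamps: where a source timestamp matches a
#' grid timestamp exactly the source value is taken as-is, otherwise the
#' value is linearly interpolated between the bracketing source samples.
#' The source record must cover the whole grid span.
#'
#' @param source_times,source_values The external record.
#' @param grid_times Target timestamps.
#' @return One value per grid timestamp.
#' @export
align_external <- function(source_times, source_values, grid_times) {
  st <- as.numeric(as.POSIXct(source_times))
  gt <- as.numeric(as.POSIXct(grid_times))
  if (min(gt) < min(st) || max(gt) > max(st)) {
    stop("source series does not cover the target grid span")
  }
  stats::approx(st, as.numeric(source_values), xout = gt, rule = 1)$y
}

#' Construct an event dataset
#'
#' An `fib_event` bundles the aligned table of FIB concentrations,
#' censoring flags and environmental covariates for one sampling event on a
#' regular grid. FIB columns are `tc`, `ec`, `ent` with logical companions
#' `tc_blod`, `ec_blod`, `ent_blod`; environmental columns follow the field
#' shorthand (`wtemp`, `sal`, `chl`, `turb`, `rad`, `tide`, `temp`, `dtemp`,
#' `pres`, `wspd`, `wdir`, `vis`, `cloud`).
#'
#' @param data A data.frame with a `timestamp` column (`POSIXct`, strictly
#'   increasing on a constant interval) plus measurement columns.
#' @param meta Optional metadata list; defaults from [fib_defaults()].
#' @return An object of class `fib_event`.
#' @export
fib_event <- function(data, meta = fib_defaults()) {
  stopifnot(is.data.frame(data), "timestamp" %in% names(data))
  data$timestamp <- as.POSIXct(data$timestamp)
  dt <- diff(as.numeric(data$timestamp))
  if (any(dt <= 0)) stop("timestamps must be strictly increasing (no duplicates)")
  if (length(dt) && max(dt) - min(dt) > 1e-6) {
    stop("timestamps must lie on a constant-interval grid")
  }
  structure(
    list(data = data,
         interval = if (length(dt)) dt[1] / 60 else NA_real_,
         meta = meta),
    class = "fib_event"
  )
}

#' @export
print.fib_event <- function(x, ...) {
  cat(sprintf("<fib_event> %d samples every %g min, %d columns\n",
              nrow(x$data), x$interval, ncol(x$data) - 1L))
  cat("  span:", format(min(x$data$timestamp)), "to",
      format(max(x$data$timestamp)), "\n")
  invisible(x)
}

#' Extract one indicator's series from an event
#'
#' @param event A [fib_event()].
#' @param indicator `"tc"`, `"ec"` or `"ent"`.
#' @return A [fib_series()].
#' @export
event_fib_series <- function(event, indicator = c("ent", "ec", "tc")) {
  indicator <- match.arg(indicator)
  stopifnot(inherits(event, "fib_event"))
  blod_col <- paste0(indicator, "_blod")
  blod <- if (blod_col %in% names(event$data)) event$data[[blod_col]] else NULL
  fib_series(event$data[[indicator]], event$data$timestamp,
             indicator = indicator, below_lod = blod,
             lod_lower = event$meta$lod_lower, lod_upper = event$meta$lod_upper,
             substitute_value = event$meta$substitute)
}

#' Read a raw sampling-event CSV
#'
#' Parses a long-format CSV (one row per timestamp) into an unprocessed
#' [fib_event()]. Left-censored FIB cells written as `"<10"` (or any
#' `"<value"`) are recorded as below-LOD with a missing concentration until
#' [substitute_censored()] assigns the substitute value. Unparseable numeric
#' cells become missing values; a missing or non-monotone timestamp column
#' is fatal.
#'
#' @param path CSV path.
#' @param schema Optional named character vector mapping canonical column
#'   names (e.g. `ent`, `tide`) to the file's column names; unmapped
#'   canonical names are looked up verbatim.
#' @param tz Timezone used for clock-time features; timestamps are treated
#'   as timezone-naive local standard time (default `"UTC"` as a stand-in).
#' @return An unprocessed `fib_event` (no substitution/interpolation yet).
#' @export
read_event_csv <- function(path, schema = NULL, tz = "UTC") {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  rename <- function(canon) {
    if (!is.null(schema) && canon %in% names(schema)) schema[[canon]] else canon
  }
  ts_col <- rename("timestamp")
  if (!ts_col %in% names(raw)) stop("missing timestamp column: ", ts_col)
  ts <- as.POSIXct(raw[[ts_col]], tz = tz,
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                  "%Y-%m-%d %H:%M", "%Y-%m-%dT%H:%M"))
  if (anyNA(ts)) stop("unparseable timestamps in column ", ts_col)
  if (any(duplicated(ts))) stop("duplicated timestamps")
  if (is.unsorted(as.numeric(ts), strictly = TRUE)) {
    stop("timestamps must be strictly increasing")
  }

  out <- data.frame(timestamp = ts)
  num_cols <- c("wtemp", "sal", "chl", "turb", "rad", "tide", "temp",
                "dtemp", "pres", "wspd", "wdir", "vis")
  for (ind in fib_indicators()) {
    col <- rename(ind)
    if (!col %in% names(raw)) next
    cells <- trimws(raw[[col]])
    cens <- grepl("^<", cells)
    vals <- suppressWarnings(as.numeric(sub("^<", "", cells)))
    vals[cens] <- NA_real_
    out[[ind]] <- vals
    out[[paste0(ind, "_blod")]] <- cens
  }
  for (v in num_cols) {
    col <- rename(v)
    if (col %in% names(raw)) {
      out[[v]] <- suppressWarnings(as.numeric(trimws(raw[[col]])))
    }
  }
  cl <- rename("cloud")
  if (cl %in% names(raw)) out$cloud <- trimws(raw[[cl]])
  if (rename("daytime") %in% names(raw)) {
    out$daytime <- as.logical(raw[[rename("daytime")]])
  }
  fib_event(out)
}

#' Write a processed event table to CSV
#'
#' @param event A [fib_event()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_csv <- function(event, path) {
  stopifnot(inherits(event, "fib_event"))
  d <- event$data
  d$timestamp <- format(d$timestamp, "%Y-%m-%dT%H:%M:%S")
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Derive model-ready features from an aligned event
#'
#' Adds the engineered columns used by every downstream analysis:
#' \itemize{
#'   \item `log_tc`, `log_ec`, `log_ent`: log10 of substituted concentration;
#'   \item `log_chl`, `log_turb`: log10(x + 1) (both covariates can be zero);
#'   \item `tide_high`: tide level above 1 m relative to mean lower low water;
#'   \item `owind`, `awind`: offshore/alongshore wind components from speed,
#'     meteorological direction and the beach-normal angle. With theta the
#'     direction the wind blows toward (direction-of-origin + 180 deg),
#'     `owind = wspd * cos(theta - normal)` (positive onshore along the
#'     normal) and `awind = wspd * sin(theta - normal)` (positive along the
#'     beach, 90 deg counter-clockwise of the normal);
#'   \item cloud dummies `cloud_clear`, `cloud_overcast`, `cloud_partly`;
#'   \item `daytime` (supplied, or `rad > 0` if absent) and `rad` forced to
#'     0 W/m2 at night;
#'   \item `hours_from_noon`: absolute clock hours from 12:00 local standard
#'     time (an approximation to solar noon).
#' }
#'
#' @param event A substituted, interpolated [fib_event()].
#' @param daytime Optional logical vector overriding the day/night flag.
#' @param beach_normal Beach-normal angle, degrees from true north.
#' @return The event with derived columns appended.
#' @export
derive_features <- function(event, daytime = NULL,
                            beach_normal = fib_defaults()$beach_normal) {
  stopifnot(inherits(event, "fib_event"))
  d <- event$data

  for (ind in fib_indicators()) {
    if (ind %in% names(d)) d[[paste0("log_", ind)]] <- log10(d[[ind]])
  }
  if ("chl" %in% names(d)) d$log_chl <- log10(d$chl + 1)
  if ("turb" %in% names(d)) d$log_turb <- log10(d$turb + 1)
  if ("tide" %in% names(d)) d$tide_high <- d$tide > 1

  if (all(c("wspd", "wdir") %in% names(d))) {
    if (any(d$wspd < 0, na.rm = TRUE)) stop("negative wind speed")
    theta <- (d$wdir + 180) %% 360          # direction wind blows toward
    ang <- (theta - beach_normal) * pi / 180
    d$owind <- d$wspd * cos(ang)
    d$awind <- d$wspd * sin(ang)
  }

  if ("cloud" %in% names(d)) {
    known <- c("clear", "overcast", "partly")
    bad <- setdiff(unique(d$cloud), known)
    if (length(bad)) stop("unknown cloud category: ", paste(bad, collapse = ", "))
    for (k in known) d[[paste0("cloud_", k)]] <- as.numeric(d$cloud == k)
  }

  if (!is.null(daytime)) {
    d$daytime <- as.logical(daytime)
  } else if (!"daytime" %in% names(d) && "rad" %in% names(d)) {
    d$daytime <- d$rad > 0
  }
  if (all(c("rad", "daytime") %in% names(d))) d$rad[!d$daytime] <- 0

  lt <- as.POSIXlt(d$timestamp)
  d$hours_from_noon <- abs(lt$hour + lt$min / 60 + lt$sec / 3600 - 12)

  event$data <- d
  event
}

#' Process a raw event into analysis-ready form
#'
#' Runs the standard preprocessing sequence: substitute left-censored FIB
#' values, linearly interpolate missing environmental values, and derive
#' features. Irradiance is zeroed at night after interpolation, so
#' interpolated night-time values cannot leak positive irradiance.
#'
#' @param event A raw [fib_event()] (e.g. from [read_event_csv()]).
#' @param daytime Optional day/night flag forwarded to [derive_features()].
#' @return A processed `fib_event`.
#' @export
process_event <- function(event, daytime = NULL) {
  stopifnot(inherits(event, "fib_event"))
  d <- event$data
  for (ind in intersect(fib_indicators(), names(d))) {
    s <- substitute_censored(event_fib_series(event, ind))
    d[[ind]] <- s$values
    event$data <- d
  }
  env_cols <- intersect(
    c("wtemp", "sal", "chl", "turb", "rad", "tide", "temp", "dtemp",
      "pres", "wspd", "wdir", "vis"), names(d))
  for (v in env_cols) {
    if (anyNA(d[[v]])) {
      d[[v]] <- interpolate_missing(d[[v]], times = d$timestamp)
    }
  }
  event$data <- d
  derive_features(event, daytime = daytime)
}
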