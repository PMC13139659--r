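# Thermal-time phenology and green canopy duration.
#
# Thermal time (growing degree days) accumulates the daily mean of Tmin
# and Tmax above a base temperature (0 degC for winter wheat here); days
# whose mean falls below the base contribute zero rather than negative
# degree days. Canopy senescence after anthesis is summarized by a
# three-parameter declining logistic of green canopy area (GCA) against
# thermal time; green canopy duration (GCD) is the thermal time from
# anthesis to the fitted 50% GCA point, a stay-green measure.

check_weather <- function(weather) {
  need <- c("date", "tmin_C", "tmax_C")
  missing_cols <- setdiff(need, names(weather))
  if (length(missing_cols) > 0) {
    stop("weather series missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  w <- as.data.frame(weather)
  w$date <- as.Date(w$date)
  if (is.unsorted(as.numeric(w$date), strictly = TRUE)) {
    stop("weather dates must be strictly increasing", call. = FALSE)
  }
  if (any(w$tmax_C < w$tmin_C)) {
    stop("weather series violates tmax >= tmin", call. = FALSE)
  }
  w
}

#' Read a daily weather series from CSV
#'
#' Columns: `date` (ISO-8601), `tmin_C`, `tmax_C`, optional `precip_mm`.
#'
#' @param path CSV path.
#' @return Validated weather data.frame.
#' @export
read_weather <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  check_weather(read.csv(path, stringsAsFactors = FALSE))
}

#' Accumulated thermal time over a date window
#'
#' Sums `max(0, (Tmin + Tmax)/2 - t_base)` over the days from `from_date`
#' to `to_date` inclusive. Non-negative and additive over adjacent
#' windows.
#'
#' @param weather Daily weather series (`date`, `tmin_C`, `tmax_C`).
#' @param from_date,to_date Window bounds (inside the series,
#'   `from_date <= to_date`).
#' @param t_base Base temperature, degC (default 0, the winter wheat
#'   convention).
#' @return Thermal time in degC days.
#' @export
#' @examples
#' w <- data.frame(date = as.Date("2020-05-01") + 0:1,
#'                 tmin_C = c(5, 10), tmax_C = c(15, 20))
#' thermal_time(w, "2020-05-01", "2020-05-02")  # 25
thermal_time <- function(weather, from_date, to_date, t_base = 0) {
  w <- check_weather(weather)
  from_date <- as.Date(from_date)
  to_date <- as.Date(to_date)
  if (from_date > to_date) stop("from_date must be <= to_date", call. = FALSE)
  if (from_date < min(w$date) || to_date > max(w$date)) {
    stop("date range [", from_date, ", ", to_date,
         "] outside weather series", call. = FALSE)
  }
  sel <- w$date >= from_date & w$date <= to_date
  sum(pmax(0, (w$tmin_C[sel] + w$tmax_C[sel]) / 2 - t_base))
}

daily_tt <- function(w, t_base = 0) {
  pmax(0, (w$tmin_C + w$tmax_C) / 2 - t_base)
}

#' Thermal time from sowing to a BBCH stage
#'
#' Stages are scouted on a coarse (weekly) grid; a stage that was not hit
#' exactly on a visit is dated by linear interpolation on the BBCH-versus-
#' date line between the bracketing visits, and the thermal sum is
#' interpolated within the fractional final day.
#'
#' @param stages Data.frame with columns `bbch` (numeric code) and `date`;
#'   dates must be non-decreasing with BBCH code.
#' @param weather Daily weather series covering sowing to the stage date.
#' @param bbch Target BBCH code; must be bracketed by observed codes.
#' @param sowing_date Start of accumulation; defaults to the first weather
#'   day.
#' @param t_base Base temperature, degC.
#' @return Thermal time in degC days at the (interpolated) stage date.
#' @export
stage_tt <- function(stages, weather, bbch,
                     sowing_date = NULL, t_base = 0) {
  w <- check_weather(weather)
  s <- as.data.frame(stages)
  stopifnot(all(c("bbch", "date") %in% names(s)))
  s$date <- as.Date(s$date)
  s <- s[order(s$bbch), , drop = FALSE]
  if (is.unsorted(as.numeric(s$date))) {
    stop("stage dates must be non-decreasing with BBCH code", call. = FALSE)
  }
  if (is.null(sowing_date)) sowing_date <- min(w$date)
  sowing_date <- as.Date(sowing_date)

  if (bbch < min(s$bbch) || bbch > max(s$bbch)) {
    stop("coverage error: BBCH ", bbch, " not bracketed by observations [",
         min(s$bbch), ", ", max(s$bbch), "]", call. = FALSE)
  }
  exact <- which(s$bbch == bbch)
  if (length(exact) > 0) {
    target <- as.numeric(s$date[exact[1]])  # whole day
  } else {
    lo <- max(which(s$bbch < bbch))
    hi <- min(which(s$bbch > bbch))
    f <- (bbch - s$bbch[lo]) / (s$bbch[hi] - s$bbch[lo])
    target <- as.numeric(s$date[lo]) +
      f * (as.numeric(s$date[hi]) - as.numeric(s$date[lo]))
  }
  day_whole <- floor(target)
  frac <- target - day_whole
  if (day_whole > as.numeric(max(w$date)) ||
      sowing_date < min(w$date)) {
    stop("stage date outside weather series", call. = FALSE)
  }
  tt <- thermal_time(w, sowing_date, as.Date(day_whole, origin = "1970-01-01"),
                     t_base = t_base)
  if (frac > 0) {
    nxt <- w$date == as.Date(day_whole + 1, origin = "1970-01-01")
    if (!any(nxt)) stop("stage date outside weather series", call. = FALSE)
    tt <- tt + frac * daily_tt(w[nxt, , drop = FALSE], t_base)
  }
  tt
}

#' Fit a declining logistic to post-anthesis canopy senescence
#'
#' Least-squares fit of
#' \deqn{GCA(TT) = GCA_{max} / (1 + \exp(k (TT - TT_{50})))}
#' to (thermal time, green canopy area) points observed after anthesis.
#' `TT50` is the thermal time at which the canopy has dropped to 50% of
#' the fitted asymptote `GCA_max`; `k > 0` is the senescence rate.
#' Initialization: `GCA_max` at the observed maximum, `TT50` at the point
#' closest to half-maximum, `k = 4 / range(TT)`; `k` is box-constrained to
#' (0, 1].
#'
#' @param series Data.frame with columns `tt` (degC days) and `gca`;
#'   at least 4 points spanning the decline.
#' @return An object of class `senescence_fit`: list with `gca_max`,
#'   `tt50`, `k`, `sse`, `n`.
#' @export
fit_senescence <- function(series) {
  s <- as.data.frame(series)
  stopifnot(all(c("tt", "gca") %in% names(s)))
  s <- s[order(s$tt), , drop = FALSE]
  if (nrow(s) < 4) {
    stop("need at least 4 points to fit senescence, got ", nrow(s),
         call. = FALSE)
  }
  if (cor(s$tt, s$gca, method = "spearman") > 0 &&
      s$gca[nrow(s)] >= s$gca[1]) {
    stop("fit error: GCA increases with thermal time; no senescence decline",
         call. = FALSE)
  }
  gmax0 <- max(s$gca)
  tt50_0 <- s$tt[which.min(abs(s$gca - gmax0 / 2))]
  k0 <- 4 / diff(range(s$tt))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      gca ~ gca_max / (1 + exp(k * (tt - tt50))),
      data = s,
      start = list(gca_max = gmax0, tt50 = tt50_0, k = min(k0, 1)),
      lower = c(gca_max = 1e-8, tt50 = min(s$tt) - diff(range(s$tt)),
                k = 1e-8),
      upper = c(gca_max = Inf, tt50 = max(s$tt) + diff(range(s$tt)), k = 1),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      stop("fit error: logistic senescence fit failed to converge (",
           conditionMessage(e), "); n = ", nrow(s),
           ", GCA range [", min(s$gca), ", ", max(s$gca), "]",
           call. = FALSE)
    }
  )
  cf <- coef(fit)
  out <- list(gca_max = unname(cf["gca_max"]), tt50 = unname(cf["tt50"]),
              k = unname(cf["k"]), sse = sum(resid(fit)^2), n = nrow(s))
  class(out) <- "senescence_fit"
  out
}

#' @export
print.senescence_fit <- function(x, ...) {
  cat(sprintf(
    "Logistic senescence fit (n = %d): GCA_max = %.4g, TT50 = %.1f degCd, k = %.4g /degCd, SSE = %.3g\n",
    x$n, x$gca_max, x$tt50, x$k, x$sse))
  invisible(x)
}

#' Green canopy duration
#'
#' Thermal time from anthesis (BBCH61) to the fitted 50% GCA point:
#' `GCD = TT50 - tt_anthesis`. Longer GCD means longer canopy stay-green.
#' Invariant to vertical scaling of the GCA series (TT50 is relative to
#' the fitted asymptote, not an absolute level).
#'
#' @param fit A `senescence_fit`.
#' @param tt_anthesis Thermal time at anthesis, degC days; must precede
#'   `TT50`.
#' @return GCD in degC days (positive).
#' @export
green_canopy_duration <- function(fit, tt_anthesis) {
  stopifnot(inherits(fit, "senescence_fit"))
  if (tt_anthesis >= fit$tt50) {
    stop("ordering error: tt_anthesis (", tt_anthesis,
         ") must be below TT50 (", round(fit$tt50, 1), ")", call. = FALSE)
  }
  fit$tt50 - tt_anthesis
}
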