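#' Population doubling time from the exponential rate
#'
#' `PD = 0.6931 / B * 60` minutes. The natural-log-2 constant is used at
#' the conventional 4-digit precision 0.6931 by default so results match
#' spreadsheet-style calculations digit for digit; `exact = TRUE`
#' switches to full-precision `log(2)`.
#'
#' @param B Exponential growth rate, per hour (must be > 0).
#' @param exact Use `log(2)` at machine precision instead of 0.6931.
#' @return Doubling time in minutes.
#' @examples
#' doubling_time(0.6931)  # 60 min
#' @export
doubling_time <- function(B, exact = FALSE) {
  if (any(B <= 0)) stop("doubling time is undefined for B <= 0")
  ln2 <- if (exact) log(2) else 0.6931
  ln2 / B * 60
}

#' Fit the exponential phase of a growth curve
#'
#' Ordinary least squares of `log(OD)` on time over an automatically
#' selected window, giving `OD = Y * exp(B * t)`. Window policy: among
#' all runs of >= `min_points` consecutive readings with OD inside
#' `od_band` (and > 0), take the longest window whose fit reaches
#' `r2_min`; ties go to the higher r-squared. If no window reaches
#' `r2_min` the best-r-squared window is used and flagged
#' (`window_ok = FALSE`).
#'
#' @param times Hours, strictly increasing (or a data frame with columns
#'   `time_h` and `od600`, in which case `od` is ignored).
#' @param od OD600 readings, non-negative, same length as `times`.
#' @param od_band Candidate exponential-phase OD range (default
#'   `c(0.05, 0.5)`).
#' @param r2_min Minimum r-squared for window acceptance (default 0.99).
#' @param min_points Minimum window length (default 4).
#' @param exact_ln2 Passed to [doubling_time()]; default `FALSE` (use the
#'   0.6931 constant).
#' @param sample_id Label carried into the fit object.
#' @return Object of class `growth_fit`: `Y` (OD intercept), `B` (per
#'   hour), `PD` (minutes; `NA` with a flag when `B <= 0`), `r_squared`,
#'   `window` (start/end indices), `window_ok`, `pd_defined`, plus the
#'   data and the underlying `lm` fit.
#' @examples
#' t <- 0:8
#' fit <- fit_exponential(t, 0.05 * exp(0.6931 * t))
#' coef(fit)
#' @export
fit_exponential <- function(times, od = NULL, od_band = c(0.05, 0.5),
                            r2_min = 0.99, min_points = 4L,
                            exact_ln2 = FALSE, sample_id = "sample") {
  if (is.data.frame(times)) {
    od <- times$od600
    times <- times$time_h
  }
  stopifnot(length(times) == length(od), length(times) >= 4)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(od < 0)) stop("OD readings must be non-negative")

  eligible <- od > 0 & od >= od_band[1] & od <= od_band[2]
  runs <- rle(eligible)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  windows <- list()
  for (ri in which(runs$values & runs$lengths >= min_points)) {
    a <- starts[ri]; b <- ends[ri]
    for (w in min_points:(b - a + 1)) {
      for (s in a:(b - w + 1)) {
        windows[[length(windows) + 1]] <- c(s, s + w - 1)
      }
    }
  }
  if (!length(windows)) {
    stop("no window of >= ", min_points, " consecutive positive readings inside the OD band [",
         od_band[1], ", ", od_band[2], "]")
  }
  # r2 computed directly (summary.lm warns on exact fits)
  r2_of <- function(fit, y) {
    sst <- sum((y - mean(y))^2)
    if (sst == 0) return(0)  # zero-variance response
    max(0, 1 - sum(stats::residuals(fit)^2) / sst)
  }
  score <- vapply(windows, function(win) {
    sel <- win[1]:win[2]
    y <- log(od[sel])
    fit <- stats::lm(y ~ times[sel])
    c(len = length(sel), r2 = r2_of(fit, y))
  }, numeric(2))
  meets <- score["r2", ] >= r2_min
  pool <- if (any(meets)) which(meets) else seq_along(windows)
  # longest first, then best r2 (fallback pool: best r2 wins outright)
  if (any(meets)) {
    best <- pool[order(-score["len", pool], -score["r2", pool])[1]]
  } else {
    best <- pool[order(-score["r2", pool], -score["len", pool])[1]]
  }
  win <- windows[[best]]
  sel <- win[1]:win[2]
  y <- log(od[sel])
  fit <- stats::lm(y ~ times[sel])
  B <- unname(stats::coef(fit)[2])
  Y <- exp(unname(stats::coef(fit)[1]))
  r2 <- r2_of(fit, y)
  pd_defined <- is.finite(B) && B > 0
  structure(
    list(sample_id = sample_id, Y = Y, B = B,
         PD = if (pd_defined) doubling_time(B, exact = exact_ln2) else NA_real_,
         pd_defined = pd_defined,
         r_squared = if (is.finite(r2)) r2 else 0,
         window = c(start = win[1], end = win[2]),
         window_ok = any(meets),
         times = times, od = od, lm_fit = fit,
         exact_ln2 = exact_ln2),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit '%s'> OD = %.4g * exp(%.4g * t), r^2 = %.4f, window points %d..%d\n",
              x$sample_id, x$Y, x$B, x$r_squared, x$window[1], x$window[2]))
  if (x$pd_defined) {
    cat(sprintf("  population doubling time: %.2f min\n", x$PD))
  } else {
    cat("  population doubling time undefined (B <= 0)\n")
  }
  if (!x$window_ok) cat("  note: no window met the r^2 criterion; best available window used\n")
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) {
  c(Y = object$Y, B = object$B, PD_min = object$PD)
}

#' @export
summary.growth_fit <- function(object, ...) {
  print(object)
  cat("\nLog-linear fit over the selected window:\n")
  print(summary(object$lm_fit))
  invisible(object)
}

#' @export
predict.growth_fit <- function(object, newtimes = NULL, ...) {
  if (is.null(newtimes)) newtimes <- object$times
  object$Y * exp(object$B * newtimes)
}

#' @export
residuals.growth_fit <- function(object, ...) {
  sel <- object$window[1]:object$window[2]
  log(object$od[sel]) - log(predict(object, object$times[sel]))
}

#' @export
plot.growth_fit <- function(x, ...) {
  graphics::plot(x$times, x$od, log = "y", pch = 16, cex = 0.7,
                 xlab = "time (h)", ylab = "OD600", main = x$sample_id, ...)
  sel <- x$window[1]:x$window[2]
  graphics::points(x$times[sel], x$od[sel], col = "red", pch = 1, cex = 1.2)
  tt <- seq(min(x$times[sel]), max(x$times[sel]), length.out = 50)
  graphics::lines(tt, predict(x, tt), col = "red")
  invisible(x)
}

#' Read growth curves from a TSV
#' @param path TSV with columns `sample`, `time_h`, `od600`.
#' @return Named list of data frames (one per sample, sorted by time).
#' @export
read_growth_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(sample = "character"))
  stopifnot(all(c("sample", "time_h", "od600") %in% names(tab)))
  lapply(split(tab, tab$sample), function(d) d[order(d$time_h), ])
}

#' Fit all curves in a growth table and write the result
#' @param curves Named list from [read_growth_table()].
#' @param path Optional output TSV (`sample`, `B_per_h`, `Y`, `r2`,
#'   `window_start`, `window_end`, `PD_min`).
#' @param ... Passed to [fit_exponential()].
#' @return Data frame of fits (invisibly when writing).
#' @export
fit_growth_table <- function(curves, path = NULL, ...) {
  rows <- lapply(names(curves), function(s) {
    f <- fit_exponential(curves[[s]]$time_h, curves[[s]]$od600,
                         sample_id = s, ...)
    data.frame(sample = s, B_per_h = f$B, Y = f$Y, r2 = f$r_squared,
               window_start = f$window[1], window_end = f$window[2],
               PD_min = f$PD, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    write_tsv(out, path)
    return(invisible(out))
  }
  out
}
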