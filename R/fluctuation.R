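#' Mutant cells per culture from plating bookkeeping
#'
#' Scales counted resistant colonies back to the number of mutant cells
#' in the whole culture:
#' `r = culture_vol * (conc_factor * colonies / plated_vol * dilution)`.
#'
#' @param culture List or one-row data frame with fields
#'   `culture_volume_ml`, `concentration_factor`, `mutant_colonies`,
#'   `plated_volume_ml`, `dilution_factor`.
#' @return Estimated mutant cells `r` (non-negative real).
#' @examples
#' mutants_per_culture(list(culture_volume_ml = 1, concentration_factor = 1,
#'   mutant_colonies = 50, plated_volume_ml = 0.1, dilution_factor = 1))
#' @export
mutants_per_culture <- function(culture) {
  v <- as.numeric(culture$culture_volume_ml)
  cf <- as.numeric(culture$concentration_factor)
  k <- as.numeric(culture$mutant_colonies)
  pv <- as.numeric(culture$plated_volume_ml)
  df <- as.numeric(culture$dilution_factor)
  if (any(pv <= 0)) stop("plated volume must be positive")
  if (any(v <= 0)) stop("culture volume must be positive")
  if (any(cf < 1) || any(df < 1)) stop("concentration and dilution factors must be >= 1")
  if (any(k < 0) || any(k != round(k))) stop("mutant colony counts must be non-negative integers")
  v * (cf * k / pv * df)
}

#' Lea-Coulson forward relation
#'
#' Expected observed mutant count from `M` mutation events under the
#' Luria-Delbrueck model, median-based correction:
#' `r = M * (1.24 + ln M)`, with `r = 0` at `M = 0` (limit convention).
#'
#' @param M Mutation events (non-negative).
#' @return Mutant count `r`.
#' @export
lea_coulson_forward <- function(M) {
  if (any(M < 0)) stop("M must be non-negative")
  ifelse(M == 0, 0, M * (1.24 + log(M)))
}

#' Invert the Lea-Coulson relation
#'
#' Solves `M * (1.24 + ln M) = r` for the unique root `M > e^(-1.24)`
#' (the relation is strictly increasing there), by bracketed root finding
#' refined with Newton steps until `|forward(M) - r| <= tolerance`.
#' `r = 0` maps to `M = 0`.
#'
#' @param r Observed mutant count (non-negative scalar or vector).
#' @param tolerance Absolute tolerance on the forward residual
#'   (default 1e-10; scaled by `max(1, r)` to stay meaningful for large r).
#' @return Mutation events `M`.
#' @export
solve_lea_coulson <- function(r, tolerance = 1e-10) {
  if (any(r < 0)) stop("r must be non-negative")
  vapply(r, function(ri) {
    if (ri == 0) return(0)
    lo <- exp(-1.24)
    hi <- max(ri, 10) * 10
    while (lea_coulson_forward(hi) < ri) hi <- hi * 10
    f <- function(M) M * (1.24 + log(M)) - ri
    M <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
    tol <- tolerance * max(1, ri)
    for (it in 1:50) {
      resid <- f(M)
      if (abs(resid) <= tol) break
      M <- M - resid / (2.24 + log(M))  # f'(M) = 2.24 + ln M
    }
    if (abs(f(M)) > tol) stop("Lea-Coulson inversion did not converge for r = ", ri)
    M
  }, numeric(1))
}

#' Mutation rate per cell
#'
#' @param M Mutation events in the culture.
#' @param total_cells Total cells in the culture at plating (viable count).
#' @return Rate = `M / total_cells`.
#' @export
mutation_rate <- function(M, total_cells) {
  if (any(total_cells <= 0)) stop("total_cells must be positive")
  if (any(M < 0)) stop("M must be non-negative")
  M / total_cells
}

#' Median and exact order-statistic confidence interval
#'
#' Cohort summary for per-culture mutation rates: the sample median with
#' a distribution-free CI from binomial order statistics — the tightest
#' pair of order statistics (x_(l), x_(u)) whose coverage
#' P(l <= B < u), B ~ Binomial(n, 1/2), reaches the requested confidence.
#' Ties in tightness are broken by the most central (then lowest-l) pair.
#'
#' @param rates Numeric vector (>= 2 values; the assay uses >= 14
#'   cultures).
#' @param confidence Coverage level (default 0.95).
#' @return List `median`, `ci_low`, `ci_high`, `n`, `ranks` (c(l, u)).
#' @export
summarize_rates <- function(rates, confidence = 0.95) {
  rates <- rates[!is.na(rates)]
  n <- length(rates)
  if (n < 2) stop("need at least 2 rate values")
  s <- sort(rates)
  best <- NULL
  for (width in 1:n) {
    cands <- list()
    for (l in 1:(n - width + 1)) {
      u <- l + width  # interval [x_(l), x_(u)] with u = l + width <= n + 1
      if (u > n + 1) next
      cov <- stats::pbinom(u - 1, n, 0.5) - stats::pbinom(l - 1, n, 0.5)
      if (cov >= confidence) cands[[length(cands) + 1]] <- c(l, min(u, n))
    }
    if (length(cands)) {
      center <- vapply(cands, function(lu) abs(mean(lu) - (n + 1) / 2), numeric(1))
      best <- cands[[order(center, vapply(cands, `[`, numeric(1), 1))[1]]]
      break
    }
  }
  if (is.null(best)) best <- c(1L, n)  # whole sample if coverage unreachable
  list(median = stats::median(rates), ci_low = s[best[1]], ci_high = s[best[2]],
       n = n, ranks = as.integer(best))
}

#' Read a fluctuation-assay culture table
#' @param path TSV with columns `culture`, `culture_volume_ml`,
#'   `concentration_factor`, `mutant_colonies`, `plated_volume_ml`,
#'   `dilution_factor`, `total_cells`.
#' @return Data frame of cultures.
#' @export
read_culture_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(culture = "character"))
  need <- c("culture", "culture_volume_ml", "concentration_factor",
            "mutant_colonies", "plated_volume_ml", "dilution_factor", "total_cells")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("culture table missing columns: ", paste(miss, collapse = ", "))
  if (any(tab$total_cells <= 0)) stop("total_cells must be positive")
  tab
}

#' Estimate mutation rates from a fluctuation assay
#'
#' Full Lea-Coulson analysis of a culture table: per culture, the mutant
#' count `r` from the plating bookkeeping, the mutation events `M` from
#' inverting `r = M(1.24 + ln M)`, and the rate `M / total_cells`; the
#' cohort is summarized by the median rate with an exact order-statistic
#' confidence interval. Cultures with zero colonies map to `M = 0` and
#' rate 0 and are flagged (the zero-count estimator is out of scope).
#'
#' The classical method-of-the-median variant — apply the Lea-Coulson
#' correction once to the cohort median `r` — is available with
#' `mode = "median-r"`; its cohort rate is `M(median r) / median total
#' cells` and no per-culture rates are produced.
#'
#' @param cultures Data frame as from [read_culture_table()].
#' @param mode `"per-culture"` (default) or `"median-r"`.
#' @param confidence CI level for the median (default 0.95).
#' @return Object of class `fluctuation_fit`: `cultures` (per-culture r,
#'   M, rate), `median_rate`, `ci_low`, `ci_high`, `n_cultures`, `mode`,
#'   `n_zero` (zero-count cultures).
#' @examples
#' sim <- generate_fluctuation(mu = 1e-7, n0 = 1e3, n_final = 1e8, seed = 1)
#' fit <- fluctuation_fit(sim$cultures)
#' coef(fit)
#' @export
fluctuation_fit <- function(cultures, mode = c("per-culture", "median-r"),
                            confidence = 0.95) {
  mode <- match.arg(mode)
  if (nrow(cultures) < 2) stop("need at least 2 cultures")
  r <- mutants_per_culture(cultures)
  n_zero <- sum(r == 0)
  if (n_zero) {
    warning(n_zero, " culture(s) with zero mutant colonies; their rate is 0 ",
            "(consider the zero-fraction method for such cohorts)")
  }
  per <- data.frame(culture = cultures$culture, r = r,
                    M = solve_lea_coulson(r),
                    total_cells = cultures$total_cells,
                    stringsAsFactors = FALSE)
  per$rate <- mutation_rate(per$M, per$total_cells)
  if (mode == "per-culture") {
    sm <- summarize_rates(per$rate, confidence)
    est <- list(median_rate = sm$median, ci_low = sm$ci_low,
                ci_high = sm$ci_high, ranks = sm$ranks)
  } else {
    med_r <- stats::median(per$r)
    M <- solve_lea_coulson(med_r)
    rate <- mutation_rate(M, stats::median(per$total_cells))
    est <- list(median_rate = rate, ci_low = NA_real_, ci_high = NA_real_,
                ranks = NULL)
  }
  structure(
    c(list(cultures = per, n_cultures = nrow(per), n_zero = n_zero,
           mode = mode, confidence = confidence), est),
    class = "fluctuation_fit"
  )
}

#' @export
print.fluctuation_fit <- function(x, ...) {
  cat(sprintf("<fluctuation_fit> %d cultures, mode=%s\n", x$n_cultures, x$mode))
  cat(sprintf("  median mutation rate: %.4g per cell per culture growth\n", x$median_rate))
  if (!is.na(x$ci_low)) {
    cat(sprintf("  %.0f%% CI (order statistics %d..%d): [%.4g, %.4g]\n",
                100 * x$confidence, x$ranks[1], x$ranks[2], x$ci_low, x$ci_high))
  }
  if (x$n_zero) cat(sprintf("  note: %d zero-count culture(s)\n", x$n_zero))
  invisible(x)
}

#' @export
summary.fluctuation_fit <- function(object, ...) {
  print(object)
  cat("\nPer-culture estimates:\n")
  print(object$cultures, digits = 4)
  invisible(object)
}

#' @export
coef.fluctuation_fit <- function(object, ...) {
  c(median_rate = object$median_rate, ci_low = object$ci_low,
    ci_high = object$ci_high)
}

#' Write per-culture and cohort fluctuation results
#' @param fit A `fluctuation_fit`.
#' @param path Per-culture TSV path.
#' @param summary_path Optional cohort summary TSV path.
#' @export
write_fluctuation_results <- function(fit, path, summary_path = NULL) {
  write_tsv(fit$cultures, path)
  if (!is.null(summary_path)) {
    write_tsv(data.frame(n_cultures = fit$n_cultures, mode = fit$mode,
                         median_rate = fit$median_rate, ci_low = fit$ci_low,
                         ci_high = fit$ci_high, confidence = fit$confidence),
              summary_path)
  }
  invisible(path)
}
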