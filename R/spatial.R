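#' Mask non-experimental plate positions
#'
#' Assigns `NA` to every position whose layout role is `border_dummy` or
#' `empty` (the four outer rows and columns carry dummy strains by design
#' and empty positions carry nothing), leaving experimental measurements
#' untouched.
#'
#' @param plate A raw [colony_plate].
#' @param layout Matching [plate_layout].
#' @return The plate with non-experimental positions set to `NA`.
#' @export
mask_non_experimental <- function(plate, layout) {
  pos <- layout$positions[layout$positions$plate == plate$plate_id, ]
  if (!nrow(pos)) stop("layout has no positions for plate ", plate$plate_id)
  if (layout$n_rows != plate$n_rows || layout$n_cols != plate$n_cols) {
    stop(sprintf("layout format %dx%d does not match plate %dx%d",
                 layout$n_rows, layout$n_cols, plate$n_rows, plate$n_cols))
  }
  drop <- pos[pos$role != "experiment", c("row", "col")]
  if (nrow(drop)) plate$sizes[cbind(drop$row, drop$col)] <- NA_real_
  plate
}

#' Correct per-plate spatial effects
#'
#' Fits a multiplicative row-by-column surface to a masked plate and
#' divides it out. The surface comes from median polish of log colony
#' sizes (iterated row- and column-median sweeps, robust to colony
#' outliers), gauge-fixed so row and column effects each have geometric
#' mean 1 over the plate; the overall plate level is therefore preserved.
#' An optional second pass divides out a moving-median residual surface
#' for non-separable gradients (off by default).
#'
#' @param plate Masked [colony_plate] (stage `"raw"`); at least half of
#'   the experimental positions must be present.
#' @param layout Matching [plate_layout].
#' @param config A [screen_config] (border width is taken from the layout
#'   mask, so only reserved for future policy; may be omitted).
#' @param residual_pass Also fit a moving-median residual surface
#'   (window `residual_window`)? Default `FALSE`.
#' @param residual_window Odd window size for the residual pass.
#' @return List with `plate` (stage `"corrected"`) and `surface`, a
#'   `correction_surface` holding `row_effects`, `col_effects` (positive,
#'   geometric mean 1) and optionally `residual_surface`.
#' @export
correct_spatial <- function(plate, layout = NULL, config = screen_config(),
                            residual_pass = FALSE, residual_window = 7L) {
  x <- plate$sizes
  present <- !is.na(x)
  if (!is.null(layout)) {
    pos <- layout$positions[layout$positions$plate == plate$plate_id, ]
    n_exp <- sum(pos$role == "experiment")
    if (n_exp > 0 && sum(present) < 0.5 * n_exp) {
      stop(sprintf("plate %s: only %d of %d experimental positions present (<50%%); skip this plate",
                   plate$plate_id, sum(present), n_exp))
    }
  } else if (sum(present) < 4) {
    stop("too few present values to fit a spatial surface; skip this plate")
  }
  if (any(x[present] <= 0)) {
    stop("spatial correction requires strictly positive sizes; zero-size colonies must be handled upstream")
  }

  lx <- log(x)
  # stopping at the iteration cap is an accepted outcome of the sweep
  # schedule, not an anomaly: remaining updates are ~1e-10 on the log scale
  mp <- suppressWarnings(stats::medpolish(lx, eps = 1e-10, maxiter = 50L,
                                          trace.iter = FALSE, na.rm = TRUE))
  re <- mp$row; ce <- mp$col
  # rows/cols that are entirely NA get neutral effect 1
  re[is.na(re)] <- 0; ce[is.na(ce)] <- 0
  # gauge: geometric mean 1 over rows/cols that carry data
  row_has <- rowSums(present) > 0
  col_has <- colSums(present) > 0
  re[row_has] <- re[row_has] - mean(re[row_has])
  ce[col_has] <- ce[col_has] - mean(ce[col_has])
  re[!row_has] <- 0; ce[!col_has] <- 0

  surface_log <- outer(re, ce, `+`)
  corrected <- exp(lx - surface_log)

  residual_surface <- NULL
  if (residual_pass) {
    resid <- log(corrected) - stats::median(log(corrected), na.rm = TRUE)
    rs <- moving_median_surface(resid, residual_window)
    rs[is.na(rs)] <- 0
    corrected <- exp(log(corrected) - rs)
    residual_surface <- exp(rs)
  }

  out <- plate
  out$sizes <- corrected
  out <- advance_stage(out, "corrected")
  surface <- structure(
    list(plate_id = plate$plate_id,
         row_effects = exp(re), col_effects = exp(ce),
         residual_surface = residual_surface),
    class = "correction_surface"
  )
  list(plate = out, surface = surface)
}

# moving median over a square window, NA-aware; used by the optional
# residual pass of correct_spatial
moving_median_surface <- function(m, window) {
  h <- (as.integer(window) - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    ri <- max(1, i - h):min(nr, i + h)
    for (j in seq_len(nc)) {
      cj <- max(1, j - h):min(nc, j + h)
      out[i, j] <- stats::median(m[ri, cj], na.rm = TRUE)
    }
  }
  out
}

#' Export a correction surface for diagnostics
#' @param surface A `correction_surface` from [correct_spatial()].
#' @param path Output TSV path (columns plate, row, col, effect).
#' @export
write_surface <- function(surface, path) {
  nr <- length(surface$row_effects); nc <- length(surface$col_effects)
  eff <- outer(surface$row_effects, surface$col_effects)
  if (!is.null(surface$residual_surface)) eff <- eff * surface$residual_surface
  idx <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  write_tsv(data.frame(plate = surface$plate_id, row = idx$row, col = idx$col,
                       effect = eff[cbind(idx$row, idx$col)]), path)
}

#' Normalize a plate to its median
#'
#' Divides every present value by the median of present values so the
#' plate median becomes 1, putting plates on a common scale.
#'
#' @param plate A corrected [colony_plate] with at least one present value.
#' @return The plate at stage `"normalized"`.
#' @export
normalize_to_plate_median <- function(plate) {
  med <- stats::median(plate$sizes, na.rm = TRUE)
  if (is.na(med)) stop("cannot normalize an all-missing plate")
  if (med <= 0) stop("plate median is not positive; cannot normalize")
  plate$sizes <- plate$sizes / med
  advance_stage(plate, "normalized")
}
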