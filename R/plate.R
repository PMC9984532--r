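#' Colony plate object
#'
#' A `colony_plate` holds one plate's grid of colony sizes as produced by
#' colony-grid quantification tools (e.g. gitter). Sizes are non-negative;
#' positions without a measurement are `NA`, which is distinct from a zero
#' colony size (a legal measurement). The object tracks its processing
#' `stage`, which may only advance `raw -> corrected -> normalized`.
#'
#' @param plate_id Plate identifier (coerced to character).
#' @param sizes Numeric matrix of colony sizes, `n_rows x n_cols`, `NA` for
#'   missing positions. Row 1 / column 1 is the top-left plate position
#'   (1-based coordinates throughout).
#' @param stage Processing stage, one of `"raw"`, `"corrected"`,
#'   `"normalized"`.
#' @return An object of class `colony_plate` with fields `plate_id`,
#'   `n_rows`, `n_cols`, `sizes`, `stage`.
#' @examples
#' p <- colony_plate("p1", matrix(100, 32, 48))
#' dim(p$sizes)
#' @export
colony_plate <- function(plate_id, sizes, stage = "raw") {
  stopifnot(is.matrix(sizes), is.numeric(sizes))
  stage <- match.arg(stage, c("raw", "corrected", "normalized"))
  if (any(sizes < 0, na.rm = TRUE)) {
    stop("colony sizes must be non-negative (missing values are NA, never negative)")
  }
  structure(
    list(
      plate_id = as.character(plate_id),
      n_rows = nrow(sizes),
      n_cols = ncol(sizes),
      sizes = sizes,
      stage = stage
    ),
    class = "colony_plate"
  )
}

#' @export
print.colony_plate <- function(x, ...) {
  n_present <- sum(!is.na(x$sizes))
  cat(sprintf(
    "<colony_plate '%s'> %d x %d (%d positions), stage=%s, %d present / %d missing\n",
    x$plate_id, x$n_rows, x$n_cols, x$n_rows * x$n_cols, x$stage,
    n_present, x$n_rows * x$n_cols - n_present
  ))
  invisible(x)
}

# advance the stage, enforcing raw -> corrected -> normalized
advance_stage <- function(plate, to) {
  order <- c(raw = 1L, corrected = 2L, normalized = 3L)
  if (order[[to]] != order[[plate$stage]] + 1L) {
    stop(sprintf("illegal stage transition %s -> %s", plate$stage, to))
  }
  plate$stage <- to
  plate
}

#' Screen configuration
#'
#' Thresholds governing hit calling and replicate handling in the
#' interaction screen.
#'
#' @param fitness_ratio_threshold Synthetic-sick fitness-ratio cutoff
#'   (strict `<`); default 0.8.
#' @param alpha Significance cutoff on the (by default BH-adjusted) p-value
#'   (strict `<`); default 0.05.
#' @param variance_exclusion_threshold Leave-one-out variance share above
#'   which a replicate is excluded; default 0.9.
#' @param min_replicates_for_test Minimum replicates per group for the
#'   t-test; default 3.
#' @param border_width Dummy border depth masked on each plate edge;
#'   default 4.
#' @param use_adjusted_p Apply `alpha` to the BH-adjusted p-value (`TRUE`,
#'   default) or to the raw p-value (sensitivity mode).
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(fitness_ratio_threshold = 0.8,
                          alpha = 0.05,
                          variance_exclusion_threshold = 0.9,
                          min_replicates_for_test = 3L,
                          border_width = 4L,
                          use_adjusted_p = TRUE) {
  stopifnot(
    fitness_ratio_threshold > 0, fitness_ratio_threshold <= 1,
    alpha > 0, alpha < 1,
    variance_exclusion_threshold > 0, variance_exclusion_threshold < 1,
    min_replicates_for_test >= 1, border_width >= 0
  )
  structure(
    list(
      fitness_ratio_threshold = fitness_ratio_threshold,
      alpha = alpha,
      variance_exclusion_threshold = variance_exclusion_threshold,
      min_replicates_for_test = as.integer(min_replicates_for_test),
      border_width = as.integer(border_width),
      use_adjusted_p = isTRUE(use_adjusted_p)
    ),
    class = "screen_config"
  )
}

#' Read a colony-size table into plates
#'
#' Parses the tab-separated dialect emitted by colony-grid quantification
#' tools: header columns `plate`, `row`, `col`, `size`, one row per scored
#' position. Positions absent from the file, and positions whose size field
#' is not numeric, become missing (`NA`).
#'
#' @param path Path to the TSV file.
#' @param n_rows,n_cols Declared plate format (default 32 x 48 = 1536).
#' @return Named list of [colony_plate] objects (stage `"raw"`), one per
#'   distinct plate identifier.
#' @export
read_plate_table <- function(path, n_rows = 32L, n_cols = 48L) {
  tab <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  need <- c("plate", "row", "col", "size")
  if (!all(need %in% names(tab))) {
    stop("plate table must have columns: ", paste(need, collapse = ", "))
  }
  row_i <- as.integer(tab$row)
  col_i <- as.integer(tab$col)
  bad <- which(is.na(row_i) | is.na(col_i) | row_i < 1 | row_i > n_rows |
                 col_i < 1 | col_i > n_cols)
  if (length(bad)) {
    stop(sprintf("position out of range for %dx%d format at file row %d (row=%s, col=%s)",
                 n_rows, n_cols, bad[1], tab$row[bad[1]], tab$col[bad[1]]))
  }
  key <- paste(tab$plate, row_i, col_i)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate position in plate table: (plate,row,col) = (", gsub(" ", ",", d), ")")
  }
  sizes <- suppressWarnings(as.numeric(tab$size))
  plates <- list()
  for (pid in unique(tab$plate)) {
    sel <- tab$plate == pid
    m <- matrix(NA_real_, n_rows, n_cols)
    m[cbind(row_i[sel], col_i[sel])] <- sizes[sel]
    plates[[pid]] <- colony_plate(pid, m)
  }
  plates
}

#' Write plates to a colony-size table
#'
#' Inverse of [read_plate_table()]: missing positions are written with size
#' `NA` so round trips preserve missingness.
#'
#' @param plates A [colony_plate] or list of them.
#' @param path Output TSV path.
#' @export
write_plate_table <- function(plates, path) {
  if (inherits(plates, "colony_plate")) plates <- list(plates)
  rows <- lapply(plates, function(p) {
    idx <- which(!is.na(p$sizes) | TRUE, arr.ind = TRUE)  # all positions
    data.frame(
      plate = p$plate_id,
      row = idx[, 1], col = idx[, 2],
      size = p$sizes[idx],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$plate, out$row, out$col), ]
  write_tsv(out, path)
}

#' Plate layout object
#'
#' Maps every plate position to its query allele, array gene, technical
#' replicate index and role. Validates the screen geometry: a dummy border
#' of the given width on every edge, and each (query, gene) cross present
#' exactly `replicates` times in one contiguous rectangular block.
#'
#' @param positions Data frame with columns `plate`, `row`, `col`, `query`,
#'   `gene`, `replicate`, `role` (role one of `experiment`, `border_dummy`,
#'   `empty`; query/gene are `NA` for non-experiment roles).
#' @param n_rows,n_cols Plate format.
#' @param border_width Expected dummy border depth (default 4).
#' @param replicates Expected technical replicates per cross (default 4).
#' @param validate Run invariant checks (default `TRUE`).
#' @return Object of class `plate_layout`.
#' @export
plate_layout <- function(positions, n_rows = 32L, n_cols = 48L,
                         border_width = 4L, replicates = 4L,
                         validate = TRUE) {
  need <- c("plate", "row", "col", "query", "gene", "replicate", "role")
  if (!all(need %in% names(positions))) {
    stop("layout needs columns: ", paste(need, collapse = ", "))
  }
  positions$plate <- as.character(positions$plate)
  positions$role <- as.character(positions$role)
  out <- structure(
    list(positions = positions, n_rows = as.integer(n_rows),
         n_cols = as.integer(n_cols), border_width = as.integer(border_width),
         replicates = as.integer(replicates)),
    class = "plate_layout"
  )
  if (validate) validate_layout(out)
  out
}

#' @export
print.plate_layout <- function(x, ...) {
  p <- x$positions
  cat(sprintf(
    "<plate_layout> %d plates, %d x %d, border %d, %d replicates; %d experiment / %d border_dummy / %d empty positions\n",
    length(unique(p$plate)), x$n_rows, x$n_cols, x$border_width, x$replicates,
    sum(p$role == "experiment"), sum(p$role == "border_dummy"), sum(p$role == "empty")
  ))
  invisible(x)
}

#' Validate a plate layout
#'
#' Checks the layout invariants: roles are known; border positions are
#' `border_dummy`; experiment positions carry query and gene; every
#' (query, gene) cross on a plate occurs exactly `replicates` times in one
#' contiguous rectangular block. Violations raise an error naming the
#' offending positions or cross.
#'
#' @param layout A [plate_layout].
#' @return `layout`, invisibly, if valid.
#' @export
validate_layout <- function(layout) {
  p <- layout$positions
  bw <- layout$border_width
  nr <- layout$n_rows; nc <- layout$n_cols
  ok_roles <- c("experiment", "border_dummy", "empty")
  if (!all(p$role %in% ok_roles)) {
    stop("unknown role(s): ", paste(setdiff(unique(p$role), ok_roles), collapse = ", "))
  }
  if (any(p$row < 1 | p$row > nr | p$col < 1 | p$col > nc)) {
    stop("layout positions outside the declared plate format")
  }
  in_border <- p$row <= bw | p$row > nr - bw | p$col <= bw | p$col > nc - bw
  bad <- which(in_border & p$role == "experiment")
  if (length(bad)) {
    stop(sprintf(
      "border violation: experiment role inside the %d-deep dummy border at (plate %s, row %d, col %d)",
      bw, p$plate[bad[1]], p$row[bad[1]], p$col[bad[1]]))
  }
  exp <- p[p$role == "experiment", ]
  if (any(is.na(exp$query) | is.na(exp$gene))) {
    stop("experiment positions must have non-missing query and gene")
  }
  if (nrow(exp)) {
    key <- paste(exp$plate, exp$query, exp$gene, sep = "\r")
    for (k in unique(key)) {
      blk <- exp[key == k, ]
      if (nrow(blk) != layout$replicates) {
        stop(sprintf("cross (query=%s, gene=%s) on plate %s has %d replicates, expected %d",
                     blk$query[1], blk$gene[1], blk$plate[1], nrow(blk), layout$replicates))
      }
      rr <- range(blk$row); cr <- range(blk$col)
      if ((rr[2] - rr[1] + 1) * (cr[2] - cr[1] + 1) != nrow(blk)) {
        stop(sprintf("cross (query=%s, gene=%s) on plate %s is not a contiguous rectangular block",
                     blk$query[1], blk$gene[1], blk$plate[1]))
      }
    }
  }
  invisible(layout)
}

#' Read a plate layout table
#'
#' @param path TSV with columns `plate`, `row`, `col`, `query`, `gene`,
#'   `replicate`, `role`; empty / `NA` query and gene fields for dummy and
#'   empty positions.
#' @inheritParams plate_layout
#' @return A validated [plate_layout].
#' @export
read_layout <- function(path, n_rows = 32L, n_cols = 48L, border_width = 4L,
                        replicates = 4L) {
  tab <- utils::read.delim(path, colClasses = "character", na.strings = c("NA", ""))
  tab$row <- as.integer(tab$row)
  tab$col <- as.integer(tab$col)
  tab$replicate <- as.integer(tab$replicate)
  plate_layout(tab, n_rows = n_rows, n_cols = n_cols,
               border_width = border_width, replicates = replicates)
}

#' Write a plate layout table
#' @param layout A [plate_layout].
#' @param path Output TSV path.
#' @export
write_layout <- function(layout, path) {
  write_tsv(layout$positions, path)
}

#' Write an interaction results table
#'
#' One row per (query, gene) cross: replicate usage, mean fitness of query
#' and wild-type crosses, their ratio, Welch t statistic, raw and
#' BH-adjusted p-values and the hit call. Numeric fields carry at least 10
#' significant digits; missing values are written as `NA` (untestable
#' crosses have `NA` p-values and hit call).
#'
#' @param table Interaction table (data frame from [score_screen()]).
#' @param path Output TSV path.
#' @export
write_results_table <- function(table, path) {
  cols <- c("query", "gene", "n_replicates_used", "mean_fitness",
            "wt_mean_fitness", "fitness_ratio", "t_stat", "p_raw", "p_adj", "hit")
  miss <- setdiff(cols, names(table))
  if (length(miss)) stop("results table is missing columns: ", paste(miss, collapse = ", "))
  out <- as.data.frame(table)[, cols]
  for (nm in c("mean_fitness", "wt_mean_fitness", "fitness_ratio", "t_stat", "p_raw", "p_adj")) {
    out[[nm]] <- ifelse(is.na(out[[nm]]), NA, sprintf("%.12g", out[[nm]]))
  }
  write_tsv(out, path)
}

#' Read back an interaction results table
#' @param path TSV written by [write_results_table()].
#' @return Data frame with typed columns.
#' @export
read_results_table <- function(path) {
  tab <- utils::read.delim(path, na.strings = "NA", stringsAsFactors = FALSE,
                           colClasses = c(query = "character", gene = "character",
                                          hit = "character"))
  tab
}

# shared TSV writer: tab-separated, header, NA for missing, no quoting
write_tsv <- function(df, path) {
  ok <- tryCatch({
    suppressWarnings(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                        row.names = FALSE, na = "NA"))
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write to '", path, "': ", conditionMessage(ok))
  invisible(path)
}
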