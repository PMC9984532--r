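# Small in-code fixtures shared across test files.

# a plate at a given stage without going through the pipeline
make_plate <- function(sizes, stage = "raw", id = "p1") {
  colony_plate(id, sizes, stage = stage)
}

# minimal single-plate layout: one query block grid on a small plate.
# genes laid out rep x 1 blocks so tiny formats are easy to reason about.
tiny_layout <- function(queries, genes, n_rows, n_cols, border = 0L,
                        replicates = 1L, plate = "p1") {
  pairs <- expand.grid(query = queries, gene = genes, stringsAsFactors = FALSE)
  rows <- list()
  k <- 1L
  for (i in seq_len(nrow(pairs))) {
    for (r in seq_len(replicates)) {
      row <- border + ((k - 1L) %/% (n_cols - 2L * border)) + 1L
      col <- border + ((k - 1L) %% (n_cols - 2L * border)) + 1L
      rows[[k]] <- data.frame(plate = plate, row = row, col = col,
                              query = pairs$query[i], gene = pairs$gene[i],
                              replicate = r, role = "experiment",
                              stringsAsFactors = FALSE)
      k <- k + 1L
    }
  }
  plate_layout(do.call(rbind, rows), n_rows = n_rows, n_cols = n_cols,
               border_width = border, replicates = replicates,
               validate = FALSE)
}

# Welch statistic and two-sided p computed from the textbook formula,
# independent of stats::t.test
welch_oracle <- function(x, y) {
  vx <- sum((x - mean(x))^2) / (length(x) - 1)
  vy <- sum((y - mean(y))^2) / (length(y) - 1)
  se2 <- vx / length(x) + vy / length(y)
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / length(x))^2 / (length(x) - 1) +
                   (vy / length(y))^2 / (length(y) - 1))
  list(t = t, p = 2 * stats::pt(-abs(t), df))
}
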