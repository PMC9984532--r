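#' Per-replicate double-mutant fitness
#'
#' Converts normalized colony sizes into double-mutant fitness under the
#' multiplicative model: each replicate's normalized size is divided by
#' the median normalized size of its query across all array genes and
#' plates, so within each query the fitness median is 1 and deviations
#' below 1 reflect sickness relative to the query's typical cross.
#'
#' @param plates List of [colony_plate] objects at stage `"normalized"`.
#' @param layout A [plate_layout] covering all plates.
#' @return Data frame (`query`, `gene`, `replicate`, `fitness`,
#'   `excluded`); missing sizes give missing fitness, `excluded` is
#'   `FALSE` (replicate exclusion happens at test time).
#' @export
compute_fitness <- function(plates, layout) {
  if (inherits(plates, "colony_plate")) plates <- list(plates)
  bad <- vapply(plates, function(p) p$stage != "normalized", logical(1))
  if (any(bad)) stop("all plates must be at stage 'normalized'")
  pos <- layout$positions[layout$positions$role == "experiment", ]
  ids <- vapply(plates, function(p) p$plate_id, character(1))
  if (!all(unique(pos$plate) %in% ids)) {
    stop("layout references plates not supplied: ",
         paste(setdiff(unique(pos$plate), ids), collapse = ", "))
  }
  size <- rep(NA_real_, nrow(pos))
  for (p in plates) {
    sel <- pos$plate == p$plate_id
    size[sel] <- p$sizes[cbind(pos$row[sel], pos$col[sel])]
  }
  fit <- rep(NA_real_, length(size))
  for (q in unique(pos$query)) {
    sel <- pos$query == q
    med <- stats::median(size[sel], na.rm = TRUE)
    if (is.na(med)) stop("query '", q, "' has no present measurements")
    fit[sel] <- size[sel] / med
  }
  data.frame(query = pos$query, gene = pos$gene,
             replicate = as.integer(pos$replicate),
             fitness = fit, excluded = FALSE, stringsAsFactors = FALSE)
}

#' Exclude a variance-dominating replicate
#'
#' A replicate is excluded when it contributes more than `threshold` of
#' the replicate variance, measured by its leave-one-out share
#' `1 - SS(without i) / SS(all)` where `SS` is the sum of squared
#' deviations from the mean. The rule is a single pass: at most one
#' replicate (the largest share, if several exceed) is removed, and a
#' zero-variance vector excludes nothing.
#'
#' @param values Numeric vector (NAs allowed; at least 2 present values).
#' @param threshold Share above which to exclude (strict `>`); default 0.9.
#' @return List with integer vectors `kept` and `excluded` (indices into
#'   `values`; NA positions are in neither).
#' @export
exclude_dominant_replicates <- function(values, threshold = 0.9) {
  idx <- which(!is.na(values))
  if (length(idx) < 2) stop("need at least 2 present values")
  v <- values[idx]
  ss <- sum((v - mean(v))^2)
  if (ss == 0) return(list(kept = idx, excluded = integer(0)))
  share <- vapply(seq_along(v), function(i) {
    vi <- v[-i]
    1 - sum((vi - mean(vi))^2) / ss
  }, numeric(1))
  worst <- which.max(share)
  if (share[worst] > threshold) {
    list(kept = idx[-worst], excluded = idx[worst])
  } else {
    list(kept = idx, excluded = integer(0))
  }
}

#' Welch t-test between query and wild-type fitness replicates
#'
#' Applies the replicate-exclusion rule independently to each group, then
#' performs a two-sided Welch (unequal-variance) t-test. Exclusion is only
#' attempted in groups with at least 3 present values: with 2 values the
#' leave-one-out share is identically 1 whenever they differ, so the rule
#' would always delete one of them. Groups smaller than
#' `min_replicates_for_test` after exclusion make the cross untestable. When both groups are constant the test degenerates: equal
#' means give `t = 0, p = 1`; unequal means give infinite `t`, `p = 0`.
#'
#' @param query_fitness,wt_fitness Numeric fitness replicates.
#' @param config A [screen_config].
#' @return List `t_stat`, `p_raw`, `n_used` (query group), `n_wt_used`,
#'   `excluded` / `wt_excluded` (indices dropped by the exclusion rule).
#'   Untestable crosses have `NA` statistics.
#' @export
test_interaction <- function(query_fitness, wt_fitness, config = screen_config()) {
  if (!length(query_fitness) || !length(wt_fitness)) stop("empty input")
  thr <- config$variance_exclusion_threshold
  excl_side <- function(v) {
    if (sum(!is.na(v)) >= 3) exclude_dominant_replicates(v, thr)
    else list(kept = which(!is.na(v)), excluded = integer(0))
  }
  eq <- excl_side(query_fitness)
  ew <- excl_side(wt_fitness)
  x <- query_fitness[eq$kept]
  y <- wt_fitness[ew$kept]
  res <- list(t_stat = NA_real_, p_raw = NA_real_,
              n_used = length(x), n_wt_used = length(y),
              excluded = eq$excluded, wt_excluded = ew$excluded)
  if (length(x) < config$min_replicates_for_test ||
      length(y) < config$min_replicates_for_test) {
    return(res)
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    d <- mean(x) - mean(y)
    res$t_stat <- if (d == 0) 0 else sign(d) * Inf
    res$p_raw <- if (d == 0) 1 else 0
    return(res)
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  res$t_stat <- unname(tt$statistic)
  res$p_raw <- tt$p.value
  res
}

#' Benjamini-Hochberg adjustment with missing-value passthrough
#'
#' Standard step-up FDR adjustment; `NA` entries are passed through and do
#' not count toward the family size.
#'
#' @param p_values Numeric vector of p-values in [0, 1] (NAs allowed).
#' @return Adjusted p-values, same length and order.
#' @export
adjust_bh <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  out <- p_values
  out[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  out
}

#' Mean fitness over non-excluded replicates
#'
#' @param fitness Numeric replicate fitness values (NAs allowed).
#' @param config A [screen_config] (supplies the exclusion threshold).
#' @return Arithmetic mean of kept values; `NA` if none remain.
#' @export
summarize_replicates <- function(fitness, config = screen_config()) {
  n_present <- sum(!is.na(fitness))
  if (n_present == 0) return(NA_real_)
  if (n_present >= 3) {
    keep <- exclude_dominant_replicates(fitness, config$variance_exclusion_threshold)$kept
  } else {
    keep <- which(!is.na(fitness))
  }
  mean(fitness[keep])
}

#' Call synthetic-sick hits
#'
#' A cross is a hit when its fitness ratio (query mean over wild-type
#' mean) is strictly below the threshold and its adjusted p-value is
#' strictly below alpha. Untestable rows keep `hit = "untestable"`.
#'
#' @param table Interaction data frame with `fitness_ratio`, `p_adj`
#'   (and `p_raw`) columns.
#' @param config A [screen_config]; `use_adjusted_p = FALSE` thresholds
#'   the raw p-value instead (sensitivity mode).
#' @return The table with its `hit` column set to yes/no/untestable.
#' @export
call_hits <- function(table, config = screen_config()) {
  p_use <- if (config$use_adjusted_p) table$p_adj else table$p_raw
  hit <- ifelse(is.na(p_use) | is.na(table$fitness_ratio), "untestable",
                ifelse(table$fitness_ratio < config$fitness_ratio_threshold &
                         p_use < config$alpha, "yes", "no"))
  table$hit <- hit
  table
}

#' Score a colony-array genetic interaction screen
#'
#' Runs the full evaluation on raw plates: masks dummy borders and empty
#' positions, corrects per-plate spatial effects (median polish of log
#' sizes), normalizes each plate to its median, computes per-replicate
#' double-mutant fitness (per-query median gauge), then for every array
#' gene tests each query against the wild-type control with a Welch
#' t-test after replicate exclusion, adjusts p-values per query with
#' Benjamini-Hochberg, and calls synthetic-sick hits
#' (ratio < 0.8 and adjusted p < 0.05 by default).
#'
#' @param plates List of raw [colony_plate] objects.
#' @param layout A [plate_layout] covering the plates.
#' @param config A [screen_config].
#' @param wt_query Identifier of the wild-type control query (default
#'   `"wt"`).
#' @return An object of class `sga_screen`: list with `interactions`
#'   (one row per query x gene with columns query, gene,
#'   n_replicates_used, mean_fitness, wt_mean_fitness, fitness_ratio,
#'   t_stat, p_raw, p_adj, hit), `fitness` (per-replicate table),
#'   `surfaces` (per-plate correction surfaces), `config`, `wt_query`.
#' @examples
#' sim <- generate_screen(n_genes = 20, queries = c("wt", "q1"), seed = 1)
#' scr <- score_screen(sim$plates, sim$layout)
#' summary(scr)
#' @export
score_screen <- function(plates, layout, config = screen_config(),
                         wt_query = "wt") {
  if (inherits(plates, "colony_plate")) plates <- list(plates)
  queries <- unique(layout$positions$query[layout$positions$role == "experiment"])
  if (!wt_query %in% queries) {
    stop("wild-type query '", wt_query, "' not found in layout (queries: ",
         paste(queries, collapse = ", "), ")")
  }
  surfaces <- list()
  norm_plates <- lapply(plates, function(p) {
    m <- mask_non_experimental(p, layout)
    cs <- correct_spatial(m, layout, config)
    surfaces[[p$plate_id]] <<- cs$surface
    normalize_to_plate_median(cs$plate)
  })
  fitness <- compute_fitness(norm_plates, layout)

  test_queries <- setdiff(queries, wt_query)
  genes <- unique(fitness$gene)
  wt_by_gene <- split(fitness$fitness[fitness$query == wt_query],
                      fitness$gene[fitness$query == wt_query])

  rows <- vector("list", length(test_queries))
  for (qi in seq_along(test_queries)) {
    q <- test_queries[qi]
    qf <- split(fitness$fitness[fitness$query == q],
                fitness$gene[fitness$query == q])
    n <- length(genes)
    df <- data.frame(query = q, gene = genes, n_replicates_used = NA_integer_,
                     mean_fitness = NA_real_, wt_mean_fitness = NA_real_,
                     fitness_ratio = NA_real_, t_stat = NA_real_,
                     p_raw = NA_real_, p_adj = NA_real_, hit = "untestable",
                     stringsAsFactors = FALSE)
    for (gi in seq_len(n)) {
      g <- genes[gi]
      x <- qf[[g]]; y <- wt_by_gene[[g]]
      if (is.null(x) || is.null(y) || !sum(!is.na(x)) || !sum(!is.na(y))) next
      tst <- test_interaction(x, y, config)
      mf <- summarize_replicates(x, config)
      wf <- summarize_replicates(y, config)
      df$n_replicates_used[gi] <- tst$n_used
      df$mean_fitness[gi] <- mf
      df$wt_mean_fitness[gi] <- wf
      df$fitness_ratio[gi] <- mf / wf
      df$t_stat[gi] <- tst$t_stat
      df$p_raw[gi] <- tst$p_raw
    }
    # BH family: this query across all array genes
    df$p_adj <- adjust_bh(df$p_raw)
    rows[[qi]] <- df
  }
  interactions <- do.call(rbind, rows)
  interactions <- call_hits(interactions, config)
  rownames(interactions) <- NULL
  structure(
    list(interactions = interactions, fitness = fitness, surfaces = surfaces,
         config = config, wt_query = wt_query),
    class = "sga_screen"
  )
}

#' @export
print.sga_screen <- function(x, ...) {
  it <- x$interactions
  cat(sprintf("<sga_screen> %d queries x %d genes vs '%s' control\n",
              length(unique(it$query)), length(unique(it$gene)), x$wt_query))
  cat(sprintf("  hit criterion: fitness ratio < %g and %s p < %g\n",
              x$config$fitness_ratio_threshold,
              if (x$config$use_adjusted_p) "BH-adjusted" else "raw",
              x$config$alpha))
  for (q in unique(it$query)) {
    sub <- it[it$query == q, ]
    cat(sprintf("  %s: %d hits, %d tested, %d untestable\n", q,
                sum(sub$hit == "yes"), sum(sub$hit != "untestable"),
                sum(sub$hit == "untestable")))
  }
  invisible(x)
}

#' @export
summary.sga_screen <- function(object, ...) {
  it <- object$interactions
  qs <- unique(it$query)
  out <- data.frame(
    query = qs,
    n_genes = vapply(qs, function(q) sum(it$query == q), integer(1)),
    n_tested = vapply(qs, function(q) sum(it$query == q & it$hit != "untestable"), integer(1)),
    n_hits = vapply(qs, function(q) sum(it$query == q & it$hit == "yes"), integer(1)),
    median_ratio = vapply(qs, function(q)
      stats::median(it$fitness_ratio[it$query == q], na.rm = TRUE), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("summary.sga_screen", "data.frame")
  out
}

#' Scatter of query vs wild-type mean fitness
#'
#' One panel per query: each point is an array gene, hits highlighted.
#'
#' @param x An `sga_screen`.
#' @param ... Passed to [plot()].
#' @export
plot.sga_screen <- function(x, ...) {
  it <- x$interactions
  qs <- unique(it$query)
  old <- graphics::par(mfrow = c(1, length(qs)))
  on.exit(graphics::par(old))
  for (q in qs) {
    sub <- it[it$query == q, ]
    col <- ifelse(sub$hit == "yes", "magenta", "grey40")
    graphics::plot(sub$wt_mean_fitness, sub$mean_fitness, col = col, pch = 16,
                   cex = 0.6, xlab = "wild-type fitness", ylab = "query fitness",
                   main = q, ...)
    graphics::abline(0, 1, lty = 2)
    graphics::abline(0, x$config$fitness_ratio_threshold, col = "magenta", lty = 3)
  }
  invisible(x)
}

#' Extract hit sets from a scored screen
#' @param screen An `sga_screen`.
#' @return Named list: query -> character vector of hit genes.
#' @export
hit_sets <- function(screen) {
  it <- screen$interactions
  qs <- unique(it$query)
  stats::setNames(
    lapply(qs, function(q) sort(it$gene[it$query == q & it$hit == "yes"])), qs)
}
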