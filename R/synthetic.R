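#' Simulate a colony-array genetic interaction screen
#'
#' Generates raw plates, a layout and full ground truth under the
#' multiplicative fitness model the screen analysis assumes: colony size
#' = base x query fitness x gene fitness x interaction x spatial surface
#' x lognormal noise. Plates follow the screen geometry — queries
#' combined on each plate, `replicates` adjacent technical replicates
#' per cross in rectangular blocks, and a dummy border of `border_width`
#' on every edge (dummy strains have fitness 1 and the same noise).
#' Inner blocks left over after all crosses are placed are `empty`.
#' Spatial effects are smooth sinusoidal row/column gradients on the log
#' scale with geometric mean 1 and a random phase per plate.
#'
#' @param n_genes Number of array genes.
#' @param queries Character vector of query identifiers (include the
#'   wild-type control, conventionally `"wt"`).
#' @param replicates Technical replicates per cross (default 4, in 2x2
#'   blocks; `block` sets the block shape).
#' @param base_size Mean colony size in arbitrary units (default 300).
#' @param query_fitness,gene_fitness Named numeric vectors of single-
#'   mutant fitness factors; unnamed entries default to 1.
#' @param interactions Data frame (`query`, `gene`, `ratio`) of injected
#'   interactions; ratio 1 means none, 0.5 a strong synthetic-sick
#'   interaction.
#' @param spatial_amplitude Log-scale amplitude of the row/column
#'   gradients (default 0.1; 0 for flat plates).
#' @param noise_sigma Lognormal noise scale (default 0.1).
#' @param n_rows,n_cols Plate format (default 32 x 48).
#' @param border_width Dummy border depth (default 4).
#' @param block Replicate block shape `c(rows, cols)`; must multiply to
#'   `replicates` and tile the inner grid.
#' @param n_plates Optional plate budget; error (stating the required
#'   count) if the crosses do not fit.
#' @param seed Integer seed; identical seeds give identical output.
#' @return List: `plates` (raw [colony_plate]s), `layout`
#'   ([plate_layout]), `truth` (query/gene fitness, interaction table,
#'   per-plate spatial effects, `noise_sigma`, `seed`).
#' @export
generate_screen <- function(n_genes, queries = c("wt", "q1"), replicates = 4L,
                            base_size = 300, query_fitness = NULL,
                            gene_fitness = NULL, interactions = NULL,
                            spatial_amplitude = 0.1, noise_sigma = 0.1,
                            n_rows = 32L, n_cols = 48L, border_width = 4L,
                            block = c(2L, 2L), n_plates = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_genes >= 1, length(queries) >= 1, prod(block) == replicates)
  genes <- sprintf("gene%04d", seq_len(n_genes))
  qf <- stats::setNames(rep(1, length(queries)), queries)
  if (!is.null(query_fitness)) qf[names(query_fitness)] <- query_fitness
  gf <- stats::setNames(rep(1, n_genes), genes)
  if (!is.null(gene_fitness)) gf[names(gene_fitness)] <- gene_fitness
  imap <- new.env(parent = emptyenv())
  if (!is.null(interactions)) {
    for (i in seq_len(nrow(interactions))) {
      assign(paste(interactions$query[i], interactions$gene[i], sep = "\r"),
             interactions$ratio[i], envir = imap)
    }
  }
  inter_of <- function(q, g) {
    key <- paste(q, g, sep = "\r")
    if (exists(key, envir = imap, inherits = FALSE)) get(key, envir = imap) else 1
  }

  inner_r <- n_rows - 2L * border_width
  inner_c <- n_cols - 2L * border_width
  if (inner_r %% block[1] || inner_c %% block[2]) {
    stop(sprintf("block %dx%d does not tile the inner %dx%d grid",
                 block[1], block[2], inner_r, inner_c))
  }
  blocks_per_plate <- (inner_r %/% block[1]) * (inner_c %/% block[2])
  pairs <- expand.grid(query = queries, gene = genes,
                       stringsAsFactors = FALSE)  # queries adjacent per gene
  need_plates <- ceiling(nrow(pairs) / blocks_per_plate)
  if (!is.null(n_plates) && n_plates < need_plates) {
    stop(sprintf("capacity exceeded: %d crosses need %d plates of %d blocks, %d given",
                 nrow(pairs), need_plates, blocks_per_plate, n_plates))
  }

  plates <- list()
  layout_rows <- list()
  truth_spatial <- list()
  pair_i <- 1L
  for (pl in seq_len(need_plates)) {
    pid <- sprintf("plate%02d", pl)
    # smooth multiplicative gradients, geometric mean 1
    rph <- stats::runif(1, 0, 2 * pi); cph <- stats::runif(1, 0, 2 * pi)
    re <- spatial_amplitude * sin(2 * pi * seq_len(n_rows) / n_rows + rph)
    ce <- spatial_amplitude * sin(2 * pi * seq_len(n_cols) / n_cols + cph)
    re <- re - mean(re); ce <- ce - mean(ce)
    row_eff <- exp(re); col_eff <- exp(ce)
    truth_spatial[[pid]] <- list(row_effects = row_eff, col_effects = col_eff)

    sizes <- matrix(NA_real_, n_rows, n_cols)
    # border dummies (vectorized)
    grid <- expand.grid(row = seq_len(n_rows), col = seq_len(n_cols))
    on_border <- grid$row <= border_width | grid$row > n_rows - border_width |
      grid$col <= border_width | grid$col > n_cols - border_width
    bidx <- cbind(grid$row[on_border], grid$col[on_border])
    sizes[bidx] <- base_size * row_eff[bidx[, 1]] * col_eff[bidx[, 2]] *
      exp(stats::rnorm(nrow(bidx), 0, noise_sigma))
    lay_row <- grid$row[on_border]; lay_col <- grid$col[on_border]
    lay_q <- rep(NA_character_, sum(on_border))
    lay_g <- rep(NA_character_, sum(on_border))
    lay_rep <- rep(NA_integer_, sum(on_border))
    lay_role <- rep("border_dummy", sum(on_border))
    # replicate blocks over the inner grid, row-major
    cells <- expand.grid(dr = seq_len(block[1]), dc = seq_len(block[2]))
    R <- nrow(cells)
    for (br in seq_len(inner_r %/% block[1])) {
      for (bc in seq_len(inner_c %/% block[2])) {
        i <- border_width + (br - 1L) * block[1] + cells$dr
        j <- border_width + (bc - 1L) * block[2] + cells$dc
        if (pair_i <= nrow(pairs)) {
          q <- pairs$query[pair_i]; g <- pairs$gene[pair_i]
          mu_size <- base_size * qf[[q]] * gf[[g]] * inter_of(q, g)
          sizes[cbind(i, j)] <- mu_size * row_eff[i] * col_eff[j] *
            exp(stats::rnorm(R, 0, noise_sigma))
          lay_q <- c(lay_q, rep(q, R)); lay_g <- c(lay_g, rep(g, R))
          lay_rep <- c(lay_rep, seq_len(R))
          lay_role <- c(lay_role, rep("experiment", R))
          pair_i <- pair_i + 1L
        } else {
          lay_q <- c(lay_q, rep(NA_character_, R))
          lay_g <- c(lay_g, rep(NA_character_, R))
          lay_rep <- c(lay_rep, rep(NA_integer_, R))
          lay_role <- c(lay_role, rep("empty", R))
        }
        lay_row <- c(lay_row, i); lay_col <- c(lay_col, j)
      }
    }
    plates[[pid]] <- colony_plate(pid, sizes)
    layout_rows[[pid]] <- data.frame(
      plate = pid, row = lay_row, col = lay_col, query = lay_q, gene = lay_g,
      replicate = lay_rep, role = lay_role, stringsAsFactors = FALSE)
  }
  layout <- plate_layout(do.call(rbind, layout_rows), n_rows = n_rows,
                         n_cols = n_cols, border_width = border_width,
                         replicates = replicates)
  truth <- list(
    query_fitness = qf, gene_fitness = gf,
    interactions = if (is.null(interactions))
      data.frame(query = character(0), gene = character(0), ratio = numeric(0))
    else interactions,
    spatial = truth_spatial, noise_sigma = noise_sigma, seed = seed)
  list(plates = plates, layout = layout, truth = truth)
}

#' Simulate a Luria-Delbrueck fluctuation assay
#'
#' Grows `n_cultures` parallel cultures from `n0` to `n_final` cells by
#' doubling. At each generation the newly created cells acquire mutations
#' as a Poisson draw with mean `mu` x (new cells); each mutant clone then
#' expands deterministically by doubling to the end of growth (no death,
#' no differential fitness — the assumptions of the Lea-Coulson
#' estimator). Mutant cells are sampled binomially into the plated
#' aliquot with the fraction implied by the plating bookkeeping,
#' `plated_vol / (culture_vol x conc x dilution)`, so the per-culture
#' mutant-count reconstruction inverts the sampling exactly in
#' expectation.
#'
#' @param mu Mutation probability per cell division, in [0, 1e-3].
#' @param n0 Initial cells per culture.
#' @param n_final Final cells per culture (> `n0`).
#' @param n_cultures Number of parallel cultures (default 14).
#' @param plating Named list: `culture_volume_ml`, `concentration_factor`,
#'   `plated_volume_ml`, `dilution_factor`. The default plates the full
#'   culture equivalent (sampling fraction 1).
#' @param seed Integer seed.
#' @return List: `cultures` (data frame in the culture-table dialect,
#'   `total_cells` = `n_final`) and `truth` (`mu` and per-culture true
#'   mutation-event and mutant-cell counts).
#' @export
generate_fluctuation <- function(mu, n0, n_final, n_cultures = 14L,
                                 plating = list(culture_volume_ml = 1,
                                                concentration_factor = 1,
                                                plated_volume_ml = 1,
                                                dilution_factor = 1),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(mu >= 0, mu <= 1e-3, n_final > n0, n0 >= 1, n_cultures >= 1)
  frac <- plating$plated_volume_ml /
    (plating$culture_volume_ml * plating$concentration_factor *
       plating$dilution_factor)
  if (frac <= 0 || frac > 1) {
    stop("plating spec implies a sampling fraction of ", signif(frac, 3),
         "; must be in (0, 1]")
  }
  events <- integer(n_cultures)
  r_true <- numeric(n_cultures)
  colonies <- integer(n_cultures)
  for (cu in seq_len(n_cultures)) {
    N <- n0
    r <- 0
    ev <- 0L
    while (N < n_final) {
      N_next <- min(2 * N, n_final)
      e <- stats::rpois(1, mu * (N_next - N))
      ev <- ev + e
      r <- r + e * (n_final / N_next)  # deterministic doubling to the end
      N <- N_next
    }
    events[cu] <- ev
    r_true[cu] <- r
    colonies[cu] <- stats::rbinom(1, round(r), frac)
  }
  cultures <- data.frame(
    culture = sprintf("c%02d", seq_len(n_cultures)),
    culture_volume_ml = plating$culture_volume_ml,
    concentration_factor = plating$concentration_factor,
    mutant_colonies = colonies,
    plated_volume_ml = plating$plated_volume_ml,
    dilution_factor = plating$dilution_factor,
    total_cells = n_final, stringsAsFactors = FALSE)
  list(cultures = cultures,
       truth = list(mu = mu, events = events, mutant_cells = r_true,
                    seed = seed))
}

#' Simulate an OD600 growth curve
#'
#' Logistic trajectory `K / (1 + ((K - y0)/y0) exp(-rate t))` sampled at
#' a fixed interval with additive Gaussian noise floored at 0. Early in
#' growth (OD far below capacity) this is exponential to first order,
#' which is the regime [fit_exponential()] targets.
#'
#' @param inoculum Starting OD600 (default 0.05, in (0, capacity)).
#' @param rate Exponential growth rate per hour (default 0.7; 0 gives a
#'   flat curve at the inoculum).
#' @param capacity Carrying capacity OD600 (default 1.0).
#' @param duration Total time in hours (default 20).
#' @param interval Sampling interval in hours (default 1, i.e. hourly
#'   readings).
#' @param noise_sigma Additive noise SD in OD units (default 0.01).
#' @param sample_id Sample label.
#' @param seed Integer seed.
#' @return Data frame (`sample`, `time_h`, `od600`) ready for
#'   [fit_exponential()] / [read_growth_table()] round trips.
#' @export
generate_growth <- function(inoculum = 0.05, rate = 0.7, capacity = 1.0,
                            duration = 20, interval = 1, noise_sigma = 0.01,
                            sample_id = "sim", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inoculum > 0, inoculum < capacity, rate >= 0, duration > 0,
            interval > 0, noise_sigma >= 0)
  t <- seq(0, duration, by = interval)
  od <- capacity / (1 + ((capacity - inoculum) / inoculum) * exp(-rate * t))
  od <- pmax(0, od + stats::rnorm(length(t), 0, noise_sigma))
  data.frame(sample = sample_id, time_h = t, od600 = od,
             stringsAsFactors = FALSE)
}
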