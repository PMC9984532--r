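test_that("per-replicate fitness is the normalized size over the per-query median", {
  # one query, four genes, one replicate each: sizes {90,100,110,120},
  # already at plate-median scale
  lay <- tiny_layout("q", paste0("g", 1:4), n_rows = 2, n_cols = 4,
                     border = 0, replicates = 1)
  m <- matrix(NA_real_, 2, 4)
  m[1, ] <- c(90, 100, 110, 120)
  p <- make_plate(m, stage = "normalized")
  ft <- compute_fitness(p, lay)
  # median 105: fitness of the 90-size gene is 90/105 = 6/7
  expect_equal(ft$fitness[ft$gene == "g1"], 6 / 7)
  expect_equal(ft$fitness[ft$gene == "g4"], 120 / 105)
  expect_equal(median(ft$fitness), 1)

  # all sizes equal -> all fitness 1
  m2 <- m; m2[1, ] <- 100
  ft2 <- compute_fitness(make_plate(m2, stage = "normalized"), lay)
  expect_true(all(ft2$fitness == 1))

  # a gene at 40 against genome-wide median 100 -> fitness 0.4
  lay3 <- tiny_layout("q", paste0("g", 1:5), n_rows = 2, n_cols = 5,
                      border = 0, replicates = 1)
  m3 <- matrix(NA_real_, 2, 5); m3[1, ] <- c(40, 100, 100, 100, 100)
  ft3 <- compute_fitness(make_plate(m3, stage = "normalized"), lay3)
  expect_equal(ft3$fitness[ft3$gene == "g1"], 0.4)
})

test_that("compute_fitness rejects raw plates and empty queries", {
  lay <- tiny_layout("q", "g1", n_rows = 2, n_cols = 2, border = 0)
  expect_error(compute_fitness(make_plate(matrix(1, 2, 2)), lay),
               "stage 'normalized'")
  p <- make_plate(matrix(NA_real_, 2, 2), stage = "normalized")
  expect_error(compute_fitness(p, lay), "no present measurements")
})

test_that("the leave-one-out variance share rule excludes a dominating replicate", {
  # [1,1,1,100]: removing the outlier leaves SS 0, share = 1 > 0.9
  r <- exclude_dominant_replicates(c(1, 1, 1, 100), 0.9)
  expect_equal(r$excluded, 4L)
  expect_equal(r$kept, 1:3)
  # [1,2,3,4]: max share is 1 - 2/5 = 0.6, nothing excluded
  r2 <- exclude_dominant_replicates(c(1, 2, 3, 4), 0.9)
  expect_length(r2$excluded, 0)
  # zero variance excludes nothing
  r3 <- exclude_dominant_replicates(c(5, 5, 5, 5), 0.9)
  expect_length(r3$excluded, 0)
  expect_error(exclude_dominant_replicates(c(1, NA, NA, NA)), "at least 2")
})

test_that("replicate exclusion removes at most one value and settles under screen-like noise", {
  # single pass, at most one removal, for arbitrary inputs
  set.seed(21)
  for (i in 1:50) {
    v <- rlnorm(4, 0, 0.5)
    if (i %% 5 == 0) v[1] <- v[1] * 50
    r <- exclude_dominant_replicates(v, 0.9)
    expect_lte(length(r$excluded), 1)
  }
  # a gross outlier over near-tied replicates is always the one removed,
  # and the zero-variance remainder is then a fixed point
  set.seed(22)
  for (i in 1:20) {
    v <- c(rep(round(rlnorm(1), 2), 3), 50 * rlnorm(1, 0, 0.1))
    r <- exclude_dominant_replicates(v, 0.9)
    expect_equal(r$excluded, 4L)
    again <- exclude_dominant_replicates(replace(v, r$excluded, NA), 0.9)
    expect_length(again$excluded, 0)
  }
})

test_that("the interaction test is Welch's, verified against the formula oracle", {
  q <- c(0.50, 0.55, 0.45, 0.50)
  w <- c(1.00, 1.05, 0.95, 1.00)
  res <- test_interaction(q, w)
  orc <- welch_oracle(q, w)
  expect_equal(res$t_stat, orc$t, tolerance = 1e-12)
  expect_equal(res$p_raw, orc$p, tolerance = 1e-12)
  expect_lt(res$p_raw, 0.001)
  expect_equal(res$n_used, 4)
})

test_that("identical groups give t = 0, p = 1; outlier exclusion can degenerate to p = 1", {
  v <- c(1, 1.05, 0.95, 1)
  res <- test_interaction(v, v)
  expect_equal(res$t_stat, 0)
  expect_equal(res$p_raw, 1)
  # [1,1,1,100] vs [1,1,1,1]: the outlier is excluded, then both groups are
  # constant with equal means
  res2 <- test_interaction(c(1, 1, 1, 100), c(1, 1, 1, 1))
  expect_equal(res2$excluded, 4L)
  expect_equal(res2$t_stat, 0)
  expect_equal(res2$p_raw, 1)
})

test_that("the interaction test is sign-symmetric and respects the replicate floor", {
  set.seed(5)
  for (i in 1:10) {
    x <- rlnorm(4, 0, 0.2); y <- rlnorm(4, -0.3, 0.2)
    a <- test_interaction(x, y)
    b <- test_interaction(y, x)
    expect_equal(a$t_stat, -b$t_stat, tolerance = 1e-12)
    expect_equal(a$p_raw, b$p_raw, tolerance = 1e-12)
  }
  res <- test_interaction(c(1, 1.1), c(1, 1, 1, 1))
  expect_true(is.na(res$p_raw))
  expect_equal(res$n_used, 2)
  expect_error(test_interaction(numeric(0), 1:4), "empty")
})

test_that("Benjamini-Hochberg step-up matches the hand-computed example", {
  expect_equal(adjust_bh(c(0.01, 0.04, 0.03, 0.05)),
               c(0.04, 0.05, 0.05, 0.05))
  expect_equal(adjust_bh(rep(0.02, 6)), rep(0.02, 6))  # uniform case
  expect_equal(adjust_bh(0.3), 0.3)                    # single value
  # NA passthrough: family size counts non-missing entries only
  expect_equal(adjust_bh(c(0.01, NA, 0.04, 0.03, 0.05)),
               c(0.04, NA, 0.05, 0.05, 0.05))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH adjustment is monotone and order invariant", {
  set.seed(9)
  for (i in 1:20) {
    p <- runif(15)
    q <- adjust_bh(p)
    expect_true(all(q >= p - 1e-15))
    # order invariance
    perm <- sample(15)
    expect_equal(adjust_bh(p[perm]), q[perm])
    # pointwise larger inputs give pointwise >= outputs
    p2 <- pmin(1, p + runif(15, 0, 0.2))
    expect_true(all(adjust_bh(p2) >= q - 1e-12))
  }
})

test_that("hit calling applies both thresholds strictly", {
  tab <- data.frame(
    query = "q", gene = c("a", "b", "c", "d"),
    fitness_ratio = c(0.79, 0.80, 0.50, NA),
    p_raw = c(0.001, 0.001, 0.02, NA),
    p_adj = c(0.04, 0.01, 0.06, NA), hit = "untestable",
    stringsAsFactors = FALSE)
  out <- call_hits(tab, screen_config())
  expect_equal(out$hit, c("yes",        # 0.79 / 0.04: both arms pass
                          "no",         # ratio exactly 0.8 fails the strict <
                          "no",         # p_adj 0.06 fails significance
                          "untestable"))
  # raw-p sensitivity mode
  out2 <- call_hits(tab, screen_config(use_adjusted_p = FALSE))
  expect_equal(out2$hit[3], "yes")
})

test_that("replicate summarization averages the kept values", {
  expect_equal(summarize_replicates(c(1, 1, 1, 100)), 1)
  expect_equal(summarize_replicates(c(0.4, 0.5, 0.6)), 0.5)
  expect_equal(summarize_replicates(0.5), 0.5)
  expect_true(is.na(summarize_replicates(c(NA_real_, NA_real_))))
})

test_that("scored screens expose hit sets and summaries", {
  inj <- data.frame(query = "q1", gene = sprintf("gene%04d", c(3, 7, 11)),
                    ratio = 0.3)
  sim <- generate_screen(n_genes = 30, queries = c("wt", "q1"), seed = 4,
                         interactions = inj)
  scr <- score_screen(sim$plates, sim$layout)
  expect_s3_class(scr, "sga_screen")
  expect_equal(nrow(scr$interactions), 30)
  # strong injected interactions: ratios near 0.3 and significant
  got <- scr$interactions[scr$interactions$gene %in% inj$gene, ]
  expect_true(all(got$fitness_ratio < 0.5))
  expect_true("gene0007" %in% hit_sets(scr)$q1)
  sm <- summary(scr)
  expect_equal(sm$n_genes, 30)
  expect_true(all(scr$interactions$p_adj >= scr$interactions$p_raw, na.rm = TRUE))
  expect_error(score_screen(sim$plates, sim$layout, wt_query = "nope"),
               "not found")
})
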