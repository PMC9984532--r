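test_that("a complete colony table yields one plate with no missing positions", {
  grid <- expand.grid(row = 1:32, col = 1:48)
  tab <- data.frame(plate = "p1", row = grid$row, col = grid$col,
                    size = 100 + grid$row + grid$col)
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  plates <- read_plate_table(f)
  expect_length(plates, 1)
  expect_equal(sum(is.na(plates$p1$sizes)), 0)
  expect_equal(plates$p1$stage, "raw")
  expect_equal(plates$p1$sizes[5, 7], 112)
})

test_that("absent and non-numeric positions become missing, zeros stay zero", {
  grid <- expand.grid(row = 1:8, col = 1:6)
  tab <- data.frame(plate = "p1", row = grid$row, col = grid$col, size = "50",
                    stringsAsFactors = FALSE)
  tab <- tab[!(tab$row == 5 & tab$col == 5), ]    # absent position
  tab$size[tab$row == 1 & tab$col == 1] <- "bad"  # unparseable size
  tab$size[tab$row == 2 & tab$col == 2] <- "0"    # legal zero measurement
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  p <- read_plate_table(f, n_rows = 8, n_cols = 6)$p1
  expect_true(is.na(p$sizes[5, 5]))
  expect_true(is.na(p$sizes[1, 1]))
  expect_identical(p$sizes[2, 2], 0)
  expect_equal(sum(is.na(p$sizes)), 2)
})

test_that("duplicate and out-of-range positions are rejected with the position named", {
  f <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(plate = "p1", row = c(1, 1), col = c(2, 2), size = c(5, 6))
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_plate_table(f, 8, 6), "duplicate.*p1,1,2")
  tab2 <- data.frame(plate = "p1", row = 9, col = 1, size = 5)
  write.table(tab2, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_plate_table(f, 8, 6), "out of range")
})

test_that("plate tables round-trip losslessly, preserving missingness", {
  set.seed(42)
  m <- matrix(rlnorm(48, log(300), 0.2), 8, 6)
  m[cbind(c(2, 7), c(3, 1))] <- NA
  p <- make_plate(m)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_plate_table(p, f)
  back <- read_plate_table(f, 8, 6)$p1
  expect_equal(back$sizes, p$sizes)
})

test_that("layout validation enforces border, replicate count and contiguity", {
  sim <- generate_screen(n_genes = 6, queries = c("wt", "q1"),
                         n_rows = 12, n_cols = 12, border_width = 2,
                         seed = 1)
  expect_silent(validate_layout(sim$layout))

  # drop one replicate of a cross -> replicate-count error naming the cross
  pos <- sim$layout$positions
  drop <- which(pos$role == "experiment" & pos$gene == "gene0002" &
                  pos$query == "q1")[1]
  expect_error(
    plate_layout(pos[-drop, ], 12, 12, border_width = 2, replicates = 4),
    "query=q1, gene=gene0002.*3 replicates")

  # experiment role inside the dummy border
  pos2 <- sim$layout$positions
  b <- which(pos2$row == 2)[1]
  pos2$role[b] <- "experiment"; pos2$query[b] <- "q1"
  pos2$gene[b] <- "geneX"; pos2$replicate[b] <- 1
  expect_error(
    plate_layout(pos2, 12, 12, border_width = 2, replicates = 4),
    "border violation.*row 2")

  # scattered (non-contiguous) replicates of one cross
  pos3 <- sim$layout$positions
  idx <- which(pos3$role == "experiment" & pos3$gene == "gene0001" &
                 pos3$query == "wt")
  emp <- which(pos3$role == "empty")[1]
  tmp <- pos3[idx[1], c("row", "col")]
  pos3[idx[1], c("row", "col")] <- pos3[emp, c("row", "col")]
  pos3[emp, c("row", "col")] <- tmp
  expect_error(
    plate_layout(pos3, 12, 12, border_width = 2, replicates = 4),
    "not a contiguous rectangular block")
})

test_that("layout tables round-trip through the TSV dialect", {
  sim <- generate_screen(n_genes = 4, queries = c("wt", "q1"),
                         n_rows = 12, n_cols = 12, border_width = 2, seed = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_layout(sim$layout, f)
  back <- read_layout(f, 12, 12, border_width = 2, replicates = 4)
  expect_equal(back$positions$role, sim$layout$positions$role)
  expect_equal(back$positions$gene, sim$layout$positions$gene)
})

test_that("results tables carry 10+ significant digits, NA propagation and round-trip", {
  tab <- data.frame(
    query = c("q1", "q1"), gene = c("g1", "g2"),
    n_replicates_used = c(4L, 1L),
    mean_fitness = c(0.123456789012345, 0.9),
    wt_mean_fitness = c(1.000000000111, 1.1),
    fitness_ratio = c(0.123456789, 0.9 / 1.1),
    t_stat = c(-12.3456789012, NA), p_raw = c(1.23456789e-5, NA),
    p_adj = c(2.4691357802e-5, NA),
    hit = c("yes", "untestable"), stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_results_table(tab, f)
  lines <- readLines(f)
  expect_length(lines, 3)  # header + 2 rows
  expect_match(lines[3], "\tNA\tNA\tNA\tuntestable$")
  back <- read_results_table(f)
  for (nm in c("mean_fitness", "wt_mean_fitness", "fitness_ratio",
               "t_stat", "p_raw", "p_adj")) {
    expect_equal(back[[nm]], tab[[nm]], tolerance = 1e-10)
  }
  expect_error(write_results_table(tab, file.path(tempdir(), "no/such/dir/x.tsv")),
               "cannot write")
})
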