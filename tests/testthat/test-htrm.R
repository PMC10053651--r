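test_that("tandem detection finds maximal runs and ignores aperiodic input", {
  dt <- detect_tandem(c(2, 3, 2, 3, 2, 3), 2)
  expect_identical(nrow(dt), 1L)
  expect_identical(dt$start, 0L)
  expect_identical(dt$end, 6L)
  expect_identical(dt$repeats, 3L)
  expect_identical(dt$unit[[1]], c(2, 3))

  expect_identical(nrow(detect_tandem(c(1, 2, 3), 1)), 0L)
  # overlapping phases that are not contained are both reported
  dt2 <- detect_tandem(c(7, 7, 7, 7, 7), 2)
  expect_identical(dt2$start, c(0L, 1L))
  expect_identical(dt2$repeats, c(2L, 2L))
})

test_that("tandem detection matches the brute-force enumerator", {
  set.seed(123)
  for (i in 1:200) {
    n <- sample(5:30, 1)
    x <- sample.int(sample(2:5, 1), n, replace = TRUE)
    u <- sample(1:5, 1)
    got <- detect_tandem(x, u)
    want <- brute_tandem(x, u)
    expect_identical(got$start, want$start)
    expect_identical(got$end, want$end)
    expect_identical(got$repeats, want$repeats)
  }
})

test_that("simple mixed sequence yields the expected two-repeat layer", {
  layer <- run_htrm(c(1, 1, 2, 3, 2, 3))
  tree <- as_tandem_tree(layer)
  expect_length(tree, 2)
  expect_identical(tree[[1]]$unit, 1)
  expect_identical(tree[[1]]$span, c(0L, 2L))
  expect_identical(tree[[2]]$unit, c(2, 3))
  expect_identical(tree[[2]]$repeats, 2L)
  expect_identical(tree[[2]]$span, c(2L, 6L))
  expect_identical(expand_layer(layer), c(1, 1, 2, 3, 2, 3))
})

test_that("nested amplification is compressed and the outer repeat spans it", {
  # three HOR units, each with an internal (6,7,8,9) doubling
  unit <- c(1:5, rep(6:9, 2), 10, 11)
  x <- rep(unit, 3)
  layer <- run_htrm(x)
  tree <- as_tandem_tree(layer)
  expect_length(tree, 1)
  expect_identical(tree[[1]]$unit, c(1:9, 10, 11))  # nested span counted once
  expect_identical(tree[[1]]$repeats, 3L)
  expect_identical(tree[[1]]$span, c(0L, 45L))  # full 45-symbol input
  expect_length(tree[[1]]$children, 3)
  for (child in tree[[1]]$children) {
    expect_identical(child$unit, c(6, 7, 8, 9))
    expect_identical(child$repeats, 2L)
  }
  expect_identical(expand_layer(layer), x)
})

test_that("all-distinct symbols give an empty top layer", {
  layer <- run_htrm(c(4, 8, 15, 16, 23, 42))
  expect_length(layer$trs, 0)
  expect_identical(expand_layer(layer), c(4, 8, 15, 16, 23, 42))
})

test_that("repeats inside a compressed copy are replaced, not re-mined", {
  # (2,2,3) x 4: the unit-1 runs (2)x2 are found first and compressed, then
  # the unit-2 run over the collapsed copies covers and replaces them
  x <- rep(c(2, 2, 3), 4)
  layer <- run_htrm(x)
  tree <- as_tandem_tree(layer)
  expect_length(tree, 1)
  expect_identical(tree[[1]]$unit, c(2, 3))
  expect_identical(tree[[1]]$repeats, 4L)
  expect_length(tree[[1]]$children, 4)
  expect_identical(expand_layer(layer), x)
})

test_that("a run cutting into an old repeat region is trimmed away", {
  # (2,3)x2 is saved first; the later (3,4)x2 candidate spanning its right
  # boundary partially overlaps the saved region and is discarded, while the
  # clean (3,4,5)x2 further right is saved
  x <- c(2, 3, 2, 3, 4, 3, 4, 5, 3, 4, 5)
  layer <- run_htrm(x)
  tree <- as_tandem_tree(layer)
  spans <- lapply(tree, `[[`, "span")
  expect_identical(spans, list(c(0L, 4L), c(5L, 11L)))
  expect_identical(tree[[1]]$unit, c(2, 3))
  expect_identical(tree[[2]]$unit, c(3, 4, 5))
  expect_identical(expand_layer(layer), x)
})

test_that("expansion is lossless on random sequences", {
  set.seed(99)
  for (i in 1:60) {
    n <- sample(10:60, 1)
    x <- sample.int(sample(2:6, 1), n, replace = TRUE)
    layer <- run_htrm(x, max_unit_len = 10)
    expect_identical(expand_layer(layer), x)
    # top layer disjointness
    if (length(layer$trs) > 1) {
      starts <- vapply(layer$trs, `[[`, integer(1), "start")
      ends <- vapply(layer$trs, `[[`, integer(1), "end")
      expect_true(all(starts[-1] >= ends[-length(ends)]))
    }
  }
})
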