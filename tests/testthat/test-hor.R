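test_that("unit normalization maps all rotations to one canonical form", {
  expect_identical(normalize_unit(c(4, 1, 2, 3)), c(1, 2, 3, 4))
  expect_identical(normalize_unit(c(3, 4, 1, 2)), c(1, 2, 3, 4))
  expect_identical(normalize_unit(c(2, 3, 4, 1)), c(1, 2, 3, 4))
  expect_identical(normalize_unit(c(1, 2, 3, 4)), c(1, 2, 3, 4))
  expect_identical(normalize_unit(c(2, 1, 2, 1)), c(1, 2, 1, 2))
  expect_error(normalize_unit(integer(0)), "non-empty")
})

test_that("rotated tandem repeats merge into a single HOR", {
  x <- c(rep(c(1, 2, 3, 4), 3), 9, rep(c(3, 4, 1, 2), 3))
  hors <- merge_to_hors(run_htrm(x))
  expect_length(hors, 1)
  expect_identical(hors[[1]]$pattern, c(1, 2, 3, 4))
  expect_identical(hors[[1]]$rn, 6L)
  expect_identical(hors[[1]]$len, 24L)
  expect_length(hors[[1]]$instances, 6)

  y <- c(rep(c(1, 2), 3), 9, rep(c(1, 3), 3))
  expect_length(merge_to_hors(run_htrm(y)), 2)
})

test_that("HOR coverage is the covered fraction of monomer symbols", {
  x <- rep(c(1, 2, 3, 4), 5)
  hors <- merge_to_hors(run_htrm(x))
  expect_identical(hor_coverage(hors, length(x)), 1)
  expect_identical(hor_coverage(list(), 100), 0)
  two <- c(rep(c(1, 2), 5), 101:110, rep(c(3, 4), 5), 111:120)
  hors2 <- merge_to_hors(run_htrm(two))
  expect_identical(hor_coverage(hors2, 40), 0.5)
})

test_that("scoring follows HORscore = cr * pr and names follow R<rank>L<len>", {
  # direct substitution: m.len 100, HOR.len 50, unit 5, rn 10
  h <- list(list(pattern = 1:5, unit_len = 5L, rn = 10L, len = 50L,
                 first_start = 0L, instances = list()))
  r <- score_and_rank(h, 100)
  expect_equal(r$summary$cr, 0.5)
  expect_equal(r$summary$pr, 1.0)
  expect_equal(r$summary$score, 0.5)
  expect_identical(r$summary$name, "R1L5")

  # a full-coverage tiling HOR scores exactly 1
  x <- rep(c(1, 2, 3), 8)
  ranked <- score_and_rank(merge_to_hors(run_htrm(x)), length(x))
  expect_equal(ranked$summary$score, 1)
  expect_equal(ranked$summary$pr, 1)

  # ranking is by descending score
  h2 <- list(
    list(pattern = 1:2, unit_len = 2L, rn = 5L, len = 10L,
         first_start = 30L, instances = list()),
    list(pattern = 3:6, unit_len = 4L, rn = 10L, len = 40L,
         first_start = 0L, instances = list()))
  r2 <- score_and_rank(h2, 50)
  expect_identical(r2$summary$name, c("R1L4", "R2L2"))
})

test_that("threshold selection maximizes coverage with ties to the lowest", {
  res <- list(list(threshold = 0.94, coverage = 0.6),
              list(threshold = 0.945, coverage = 0.9),
              list(threshold = 0.95, coverage = 0.7))
  expect_identical(select_threshold(res), 2L)
  ties <- list(list(threshold = 0.94, coverage = 0.8),
               list(threshold = 0.945, coverage = 0.8))
  expect_identical(select_threshold(ties), 1L)
  expect_identical(select_threshold(ties[1]), 1L)
})

test_that("nesting lowers pr below 1 but keeps instances in one HOR", {
  x <- c(rep(c(1, 2, 3, 4, 5), 2), c(1, 2, 3, 2, 3, 2, 3, 4, 5),
         rep(c(1, 2, 3, 4, 5), 2))
  ranked <- score_and_rank(merge_to_hors(run_htrm(x)), length(x))
  expect_identical(nrow(ranked$summary), 1L)
  h <- ranked$hors[[1]]
  expect_identical(h$rn, 5L)
  expect_true(h$pr < 1)
  expect_equal(h$cr, 1)
  nested <- vapply(h$instances, `[[`, logical(1), "nested")
  expect_identical(sum(nested), 1L)
  patt <- vapply(h$instances, `[[`, character(1), "pattern")
  expect_identical(sort(unique(patt)), c("1_(2_3)x3_4_5", "1_2_3_4_5"))
})

test_that("annotation is invariant to monomer relabeling and unit rotation", {
  x <- rep(c(1, 2, 3, 4, 5), 8)
  relabel <- c(3L, 5L, 1L, 4L, 2L)
  y <- relabel[x]
  rx <- score_and_rank(merge_to_hors(run_htrm(x)), length(x))
  ry <- score_and_rank(merge_to_hors(run_htrm(y)), length(y))
  expect_equal(rx$summary$score, ry$summary$score)
  expect_equal(rx$summary$unit_len, ry$summary$unit_len)
  expect_equal(rx$summary$rn, ry$summary$rn)

  rot <- c(x[6:length(x)], x[1:5])  # rotation by one full unit
  rrot <- score_and_rank(merge_to_hors(run_htrm(rot)), length(rot))
  expect_identical(rrot$summary$pattern, rx$summary$pattern)
})

test_that("instances project to genomic intervals through the blocks", {
  ds <- simulate_hor_array(100, 0.2, 0, mode = "canonical", seed = 2)
  ann <- annotate_array(ds$dna, ds$raw_template, seed = 2)
  bed <- project_annotation(ann)
  expect_identical(nrow(bed), 40L)
  expect_identical(bed$start[1], 0L)
  expect_identical(bed$end[nrow(bed)], nchar(ds$dna))
  expect_true(all(bed$end - bed$start == 500L))  # 5 monomers x 100 bp
  expect_true(all(bed$name == "R1L5"))
})
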