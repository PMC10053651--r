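test_that("canonical monomer sequences are exact five-periodic tilings", {
  ms <- simulate_monomer_sequence("canonical", seed = 3)
  expect_identical(ms$symbols, rep(1:5, 40))
  expect_identical(nrow(ms$truth_ln), 0L)
})

test_that("LN mode amplifies spans in exactly 20 of 40 units", {
  for (seed in 1:5) {
    ms <- simulate_monomer_sequence("ln", seed = seed)
    tl <- ms$truth_ln
    expect_identical(nrow(tl), 20L)
    expect_identical(anyDuplicated(tl$unit), 0L)
    expect_true(all(tl$span_len %in% 1:4))
    expect_true(all(tl$copies %in% 2:5))
    expect_true(all(tl$span_start >= 1 & tl$span_start + tl$span_len - 1 <= 5))
    # ground-truth consistency: expanding the canonical layout by the
    # recorded events reproduces the simulated symbols
    expect_identical(ms$symbols, expand_truth(tl))
  }
})

test_that("template divergence introduces the exact substitution count", {
  tp0 <- simulate_templates(100, 0, seed = 1)
  expect_true(all(tp0$templates == tp0$raw))

  tp <- simulate_templates(100, 0.10, seed = 1)
  raw <- strsplit(tp$raw, "")[[1]]
  for (t in tp$templates) {
    expect_identical(sum(strsplit(t, "")[[1]] != raw), 10L)
  }
  tp4 <- simulate_templates(400, 0.30, seed = 2)
  raw4 <- strsplit(tp4$raw, "")[[1]]
  for (t in tp4$templates) {
    expect_identical(sum(strsplit(t, "")[[1]] != raw4), 120L)
  }
})

test_that("rendered DNA concatenates per-instance mutated templates", {
  tp <- simulate_templates(100, 0.2, seed = 4)
  ms <- simulate_monomer_sequence("canonical", seed = 4)
  dna0 <- render_dna(ms$symbols, tp$templates, 0, seed = 4)
  expect_identical(nchar(dna0), 200L * 100L)
  expect_identical(dna0, paste(tp$templates[ms$symbols], collapse = ""))

  dna <- render_dna(ms$symbols, tp$templates, 0.025, seed = 4)
  inst1 <- substr(dna, 1, 100)
  t1 <- strsplit(tp$templates[1], "")[[1]]
  expect_identical(sum(strsplit(inst1, "")[[1]] != t1),
                   as.integer(round(0.025 * 100)))
  expect_error(render_dna(c(1, 9), tp$templates, 0), "index a template")
})

test_that("datasets are reproducible and evaluation flags perfection", {
  d1 <- simulate_hor_array(100, 0.2, 0.005, mode = "ln", seed = 17)
  d2 <- simulate_hor_array(100, 0.2, 0.005, mode = "ln", seed = 17)
  expect_identical(d1$dna, d2$dna)
  expect_identical(d1$truth_ln, d2$truth_ln)

  ann <- annotate_array(d1$dna, d1$raw_template, seed = 17)
  ev <- evaluate_annotation(ann, d1)
  expect_identical(ev$GT, 40L)
  expect_identical(ev$bias, abs(ev$AN - ev$GT))
  expect_identical(ev$canonical_units + ev$ln_units, ev$AN)
  expect_error(
    evaluate_annotation(ann, simulate_hor_array(100, 0.2, 0.005,
                                                mode = "ln", seed = 18)),
    "does not correspond")
})

test_that("arrays without repeat structure yield an empty annotation", {
  set.seed(31)
  dna <- random_dna(2500)
  tmpl <- random_dna(120)
  ann <- annotate_array(dna, tmpl, seed = 31)
  expect_identical(ann$coverage, 0)
  expect_identical(nrow(ann$summary), 0L)
  ev <- evaluate_annotation(ann, structure(
    list(dna = dna, truth_ln = data.frame()), class = "sim_dataset"))
  expect_identical(ev$AN, 0L)
  expect_identical(ev$bias, 40L)
  expect_false(ev$exact_match)
})

test_that("grid runner honours the grid shape and the master seed", {
  g <- run_simulation_grid("canonical", reps = 3, seed = 5,
                           monomer_sizes = 100L,
                           monomer_divergences = 0.2,
                           hor_divergences = 0.005)
  expect_identical(nrow(g$results), 3L)
  g2 <- run_simulation_grid("canonical", reps = 3, seed = 5,
                            monomer_sizes = 100L,
                            monomer_divergences = 0.2,
                            hor_divergences = 0.005)
  expect_identical(g$results, g2$results)
  expect_true(all(g$results$bias == 0))
})
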