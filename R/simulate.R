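# Satellite-array simulator with ground truth, and evaluation of annotations
# against it.

.BASES <- c("A", "C", "G", "T")

# substitute exactly n_mut distinct positions, each to a different base
.mutate_chars <- function(chars, n_mut) {
  if (n_mut <= 0L) return(chars)
  pos <- sample.int(length(chars), n_mut)
  for (p in pos) {
    chars[p] <- sample(setdiff(.BASES, chars[p]), 1L)
  }
  chars
}

#' Simulate diverged monomer templates
#'
#' Draws one raw monomer template uniformly over A/C/G/T, then derives five
#' diverged templates by substituting `round(divergence * size)` distinct
#' positions each (every substitution to a different base). Substitution-only
#' divergence keeps block boundaries exact in the ground truth.
#'
#' @param monomer_size Template length in bases.
#' @param monomer_divergence Fraction of bases mutated per diverged template.
#' @param seed Optional integer seed.
#' @return List with `raw` (character scalar) and `templates` (character
#'   vector of length 5).
#' @export
simulate_templates <- function(monomer_size, monomer_divergence, seed = NULL) {
  if (monomer_size < 1L) stop("'monomer_size' must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  raw <- sample(.BASES, monomer_size, replace = TRUE)
  n_mut <- round(monomer_divergence * monomer_size)
  templates <- vapply(1:5, function(i)
    paste(.mutate_chars(raw, n_mut), collapse = ""), character(1))
  list(raw = paste(raw, collapse = ""), templates = templates)
}

#' Simulate a ground-truth monomer sequence
#'
#' Canonical mode: `n_units` repeats of the unit `1..unit_len`. Local-nested
#' (LN) mode: additionally, `ln_units` of the units are chosen uniformly
#' without replacement and, in each, a uniformly random contiguous span of
#' `span_range` consecutive monomers is tandemly amplified to a uniformly
#' random total of `copy_range` copies.
#'
#' @param mode `"canonical"` or `"ln"`.
#' @param n_units Number of HOR units (default 40).
#' @param unit_len Monomers per unit (default 5).
#' @param ln_units Number of units carrying an amplification in LN mode
#'   (default 20).
#' @param span_range,copy_range Inclusive ranges for the amplified span
#'   length and the total copy number (defaults 1:4 and 2:5).
#' @param seed Optional integer seed.
#' @return List with `symbols` (integer ground-truth monomer sequence) and
#'   `truth_ln` (`data.frame`: `unit`, `span_start`, `span_len`, `copies`;
#'   empty in canonical mode).
#' @export
simulate_monomer_sequence <- function(mode = c("canonical", "ln"),
                                      n_units = 40L, unit_len = 5L,
                                      ln_units = 20L, span_range = 1:4,
                                      copy_range = 2:5, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  truth_ln <- data.frame(unit = integer(0), span_start = integer(0),
                         span_len = integer(0), copies = integer(0))
  if (mode == "ln") {
    chosen <- sort(sample.int(n_units, ln_units))
    span_len <- sample(span_range, ln_units, replace = TRUE)
    span_start <- vapply(span_len, function(l)
      sample.int(unit_len - l + 1L, 1L), integer(1))
    copies <- sample(copy_range, ln_units, replace = TRUE)
    truth_ln <- data.frame(unit = chosen, span_start = span_start,
                           span_len = span_len, copies = copies)
  }
  units <- rep(list(seq_len(unit_len)), n_units)
  if (nrow(truth_ln)) {
    for (i in seq_len(nrow(truth_ln))) {
      u <- truth_ln$unit[i]
      s <- truth_ln$span_start[i]
      l <- truth_ln$span_len[i]
      k <- truth_ln$copies[i]
      base <- seq_len(unit_len)
      pre <- if (s > 1L) base[1:(s - 1L)] else integer(0)
      post <- if (s + l - 1L < unit_len) base[(s + l):unit_len] else integer(0)
      units[[u]] <- c(pre, rep(base[s:(s + l - 1L)], k), post)
    }
  }
  list(symbols = unlist(units), truth_ln = truth_ln)
}

#' Render a monomer sequence into DNA
#'
#' Concatenates, per ground-truth symbol, a fresh copy of its diverged
#' template with `round(hor_divergence * monomer_size)` positions substituted
#' independently per instance.
#'
#' @param symbols Integer monomer symbols in `1..length(templates)`.
#' @param templates Character vector of diverged monomer templates.
#' @param hor_divergence Fraction of bases mutated per monomer instance.
#' @param seed Optional integer seed.
#' @return DNA character scalar.
#' @export
render_dna <- function(symbols, templates, hor_divergence, seed = NULL) {
  if (!all(symbols %in% seq_along(templates))) {
    stop("every symbol must index a template", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  tmpl_chars <- lapply(templates, function(t) strsplit(t, "")[[1]])
  n_mut <- round(hor_divergence * nchar(templates[1]))
  paste(vapply(symbols, function(s)
    paste(.mutate_chars(tmpl_chars[[s]], n_mut), collapse = ""),
    character(1)), collapse = "")
}

#' Simulate one satellite array dataset with ground truth
#'
#' @param monomer_size Monomer length in bases (the study grid uses 100, 200,
#'   300, 400).
#' @param monomer_divergence Fraction of bases separating each diverged
#'   template from the raw template (grid: 0.10, 0.20, 0.30).
#' @param hor_divergence Fraction of bases mutated per monomer instance
#'   (grid: 0.005, 0.015, 0.025).
#' @param mode `"canonical"` or `"ln"`.
#' @param seed Integer seed (one stream per dataset).
#' @param ... Passed to [simulate_monomer_sequence()].
#' @return List of class `sim_dataset`: `raw_template`, `templates`,
#'   `truth_monomers`, `truth_ln`, `dna`, `config`.
#' @export
simulate_hor_array <- function(monomer_size, monomer_divergence,
                               hor_divergence, mode = c("canonical", "ln"),
                               seed = 1L, ...) {
  mode <- match.arg(mode)
  set.seed(seed)
  tp <- simulate_templates(monomer_size, monomer_divergence)
  ms <- simulate_monomer_sequence(mode = mode, ...)
  dna <- render_dna(ms$symbols, tp$templates, hor_divergence)
  structure(list(raw_template = tp$raw,
                 templates = tp$templates,
                 truth_monomers = ms$symbols,
                 truth_ln = ms$truth_ln,
                 dna = dna,
                 config = list(monomer_size = monomer_size,
                               monomer_divergence = monomer_divergence,
                               hor_divergence = hor_divergence,
                               mode = mode, seed = seed)),
            class = "sim_dataset")
}

# ground-truth expanded length of each unit and the unit span boundaries
.truth_unit_spans <- function(dataset, n_units = 40L, unit_len = 5L) {
  lens <- rep(unit_len, n_units)
  tl <- dataset$truth_ln
  if (nrow(tl)) {
    lens[tl$unit] <- unit_len + tl$span_len * (tl$copies - 1L)
  }
  ends <- cumsum(lens)
  data.frame(unit = seq_len(n_units), start = ends - lens, end = ends,
             len = lens)
}

#' Evaluate an annotation against simulation ground truth
#'
#' The annotated unit count `AN` is the total instance count of the
#' top-ranked HOR whose unit length equals the simulated unit length; the
#' bias is `|AN - GT|` with `GT` the simulated number of HOR units (40).
#' Instances are split into canonical (plain unit) and local-nested
#' (expanded pattern holds a nested repeat). An annotation is an exact match
#' when its instances tile the ground-truth unit spans and, under a single
#' monomer-ID bijection, every unit's nesting span, position and copy number
#' agree with the ground truth.
#'
#' @param annotation A `hor_annotation` for `dataset$dna`.
#' @param dataset A `sim_dataset`.
#' @param n_units,unit_len Ground-truth design (defaults 40 and 5).
#' @return List: `AN`, `GT`, `bias`, `canonical_units`, `ln_units`,
#'   `exact_match`, `hor_name`.
#' @export
evaluate_annotation <- function(annotation, dataset, n_units = 40L,
                                unit_len = 5L) {
  blk <- annotation$blocks
  if (nrow(blk) == 0L || blk$end[nrow(blk)] > nchar(dataset$dna) ||
      blk$sequence[1] != substr(dataset$dna, blk$start[1] + 1L, blk$end[1])) {
    stop("annotation does not correspond to the dataset sequence", call. = FALSE)
  }
  GT <- n_units
  cand <- which(vapply(annotation$hors, function(h) h$unit_len, integer(1)) ==
                  unit_len)
  if (length(cand) == 0L) {
    return(list(AN = 0L, GT = GT, bias = GT, canonical_units = 0L,
                ln_units = 0L, exact_match = FALSE, hor_name = NA_character_))
  }
  h <- annotation$hors[[cand[1]]]  # hors are rank-ordered
  nested <- vapply(h$instances, function(i) i$nested, logical(1))
  AN <- h$rn
  res <- list(AN = AN, GT = GT, bias = abs(AN - GT),
              canonical_units = sum(!nested), ln_units = sum(nested),
              exact_match = FALSE, hor_name = h$name)

  # exact match: spans tile the truth units and nesting structure agrees
  if (length(h$instances) != n_units) return(res)
  inst <- h$instances[order(vapply(h$instances, function(i) i$start, integer(1)))]
  spans <- .truth_unit_spans(dataset, n_units, unit_len)
  if (!all(vapply(inst, function(i) i$start, integer(1)) == spans$start) ||
      !all(vapply(inst, function(i) i$end, integer(1)) == spans$end)) {
    return(res)
  }
  mono <- annotation$monomer_sequence
  tl <- dataset$truth_ln
  is_ln_unit <- logical(n_units)
  if (nrow(tl)) is_ln_unit[tl$unit] <- TRUE
  canon_units <- which(!is_ln_unit)
  if (length(canon_units) == 0L) return(res)
  # bijection from inferred monomer IDs to truth IDs, read off one canonical unit
  ref <- canon_units[1]
  ids <- mono[(spans$start[ref] + 1L):spans$end[ref]]
  if (anyDuplicated(ids)) return(res)
  sigma <- stats::setNames(seq_len(unit_len), ids)
  map_ids <- function(v) unname(sigma[as.character(v)])
  for (u in seq_len(n_units)) {
    slice <- map_ids(mono[(spans$start[u] + 1L):spans$end[u]])
    if (anyNA(slice)) return(res)
    ev <- inst[[u]]$events
    if (!is_ln_unit[u]) {
      if (nrow(ev) != 0L || !identical(slice, seq_len(unit_len))) return(res)
    } else {
      row <- tl[tl$unit == u, ]
      if (nrow(ev) != 1L) return(res)
      truth_sym <- {
        base <- seq_len(unit_len)
        pre <- if (row$span_start > 1L) base[1:(row$span_start - 1L)] else integer(0)
        post <- if (row$span_start + row$span_len - 1L < unit_len)
          base[(row$span_start + row$span_len):unit_len] else integer(0)
        c(pre, rep(base[row$span_start:(row$span_start + row$span_len - 1L)],
                   row$copies), post)
      }
      if (!identical(slice, truth_sym)) return(res)
      ev_ids <- map_ids(strsplit(ev$unit, "_", fixed = TRUE)[[1]])
      if (ev$offset != row$span_start - 1L ||
          ev$copies != row$copies ||
          ev$unit_len != row$span_len ||
          anyNA(ev_ids) ||
          !identical(as.integer(ev_ids),
                     as.integer(row$span_start:(row$span_start + row$span_len - 1L)))) {
        return(res)
      }
    }
  }
  res$exact_match <- TRUE
  res
}

#' Run the simulation grid
#'
#' Simulates `monomer_sizes x monomer_divergences x hor_divergences` datasets
#' with `reps` replicates each, annotates each array with its raw template as
#' input, and evaluates against ground truth. Per-dataset RNG streams are
#' derived from the master seed so cells are independent and individually
#' re-runnable.
#'
#' @param mode `"canonical"` or `"ln"`.
#' @param reps Replicates per grid cell (default 10).
#' @param seed Master integer seed.
#' @param monomer_sizes,monomer_divergences,hor_divergences Grid axes
#'   (defaults 100/200/300/400 bp, 10/20/30%, 0.5/1.5/2.5%).
#' @param min_similarity,step,max_unit_len Annotator parameters.
#' @param progress Print one line per dataset.
#' @return List with `results` (one row per dataset: grid cell, replicate,
#'   `AN`, `bias`, `canonical_units`, `ln_units`, `exact_match`) and
#'   `summary` (fractions and means over all datasets).
#' @export
run_simulation_grid <- function(mode = c("canonical", "ln"), reps = 10L,
                                seed = 1L,
                                monomer_sizes = c(100L, 200L, 300L, 400L),
                                monomer_divergences = c(0.10, 0.20, 0.30),
                                hor_divergences = c(0.005, 0.015, 0.025),
                                min_similarity = 0.94, step = 0.005,
                                max_unit_len = 40L, progress = FALSE) {
  mode <- match.arg(mode)
  grid <- expand.grid(replicate = seq_len(reps),
                      hor_divergence = hor_divergences,
                      monomer_divergence = monomer_divergences,
                      monomer_size = monomer_sizes)
  set.seed(seed)
  ds_seeds <- sample.int(.Machine$integer.max - 1L, nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    ds <- simulate_hor_array(g$monomer_size, g$monomer_divergence,
                             g$hor_divergence, mode = mode,
                             seed = ds_seeds[i])
    ann <- annotate_array(ds$dna, ds$raw_template,
                          min_similarity = min_similarity, step = step,
                          max_unit_len = max_unit_len, seed = ds_seeds[i])
    ev <- evaluate_annotation(ann, ds)
    rows[[i]] <- data.frame(
      monomer_size = g$monomer_size,
      monomer_divergence = g$monomer_divergence,
      hor_divergence = g$hor_divergence,
      replicate = g$replicate,
      AN = ev$AN, bias = ev$bias,
      canonical_units = ev$canonical_units, ln_units = ev$ln_units,
      exact_match = ev$exact_match)
    if (progress) {
      message(sprintf("[%d/%d] size=%d mdiv=%.2f hdiv=%.3f AN=%d exact=%s",
                      i, nrow(grid), g$monomer_size, g$monomer_divergence,
                      g$hor_divergence, ev$AN, ev$exact_match))
    }
  }
  results <- do.call(rbind, rows)
  list(results = results,
       summary = list(
         n_datasets = nrow(results),
         frac_bias0 = mean(results$bias == 0L),
         frac_exact = mean(results$exact_match),
         mean_AN = mean(results$AN),
         mean_canonical_units = mean(results$canonical_units),
         mean_ln_units = mean(results$ln_units)))
}
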