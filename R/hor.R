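# HOR assembly: unit normalization, rotation merging, threshold selection by
# coverage, scoring (coverage x nesting balance), ranking, naming, projection.

.min_rotation <- function(v) {
  k <- length(v)
  if (k <= 1L) return(v)
  best <- v
  for (r in 1L:(k - 1L)) {
    rot <- c(v[(r + 1L):k], v[1L:r])
    for (i in seq_len(k)) {
      if (rot[i] < best[i]) { best <- rot; break }
      if (rot[i] > best[i]) break
    }
  }
  best
}

#' Canonical rotation of a tandem repeat unit
#'
#' All rotations of a unit map to the same canonical form, chosen as the
#' lexicographically smallest rotation, so shifted units such as 4-1-2-3,
#' 3-4-1-2 and 2-3-4-1 normalize to 1-2-3-4 and merge into one HOR.
#'
#' @param unit Atomic vector of symbols.
#' @return The canonical rotation of `unit`.
#' @examples
#' normalize_unit(c(4, 1, 2, 3))
#' @export
normalize_unit <- function(unit) {
  if (length(unit) == 0L) stop("'unit' must be non-empty", call. = FALSE)
  .min_rotation(unit)
}

# interval union over 0-based half-open intervals
.interval_union <- function(starts, ends) {
  if (length(starts) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  us <- starts[1]; ue <- ends[1]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= ue) {
      ue <- max(ue, ends[i])
    } else {
      out_s <- c(out_s, us); out_e <- c(out_e, ue)
      us <- starts[i]; ue <- ends[i]
    }
  }
  data.frame(start = c(out_s, us), end = c(out_e, ue))
}

.render_unit_tokens <- function(tokvec, registry, labels) {
  parts <- character(0)
  for (i in seq_along(tokvec$class)) {
    if (tokvec$cont[i]) next
    if (tokvec$tr[i] > 0L) {
      rec <- registry[[tokvec$tr[i]]]
      parts <- c(parts, paste0("(", .render_unit_tokens(rec$inst[[1]], registry, labels),
                               ")x", rec$repeats))
    } else {
      parts <- c(parts, as.character(labels[tokvec$class[i]]))
    }
  }
  paste(parts, collapse = "_")
}

.instance_from_tokens <- function(tokvec, registry, labels) {
  inst_start <- tokvec$start[1]
  inst_end <- tokvec$end[length(tokvec$end)]
  ev_off <- integer(0); ev_len <- integer(0); ev_copies <- integer(0)
  ev_unit <- character(0); ev_unit_len <- integer(0)
  for (i in seq_along(tokvec$class)) {
    if (!tokvec$cont[i] && tokvec$tr[i] > 0L) {
      rec <- registry[[tokvec$tr[i]]]
      ev_off <- c(ev_off, tokvec$start[i] - inst_start)
      ev_len <- c(ev_len, rec$end - rec$start)
      ev_copies <- c(ev_copies, rec$repeats)
      ev_unit <- c(ev_unit, paste(labels[rec$unit], collapse = "_"))
      ev_unit_len <- c(ev_unit_len, rec$unit_len)
    }
  }
  list(start = inst_start,
       end = inst_end,
       pattern = .render_unit_tokens(tokvec, registry, labels),
       nested = length(ev_off) > 0L,
       events = data.frame(offset = ev_off, len = ev_len, copies = ev_copies,
                           unit = ev_unit, unit_len = ev_unit_len,
                           stringsAsFactors = FALSE))
}

#' Merge tandem repeats into HORs
#'
#' Top-layer tandem repeats whose units are rotations of one another are
#' merged into a single HOR; each repeat contributes its repeat count to the
#' HOR's total and its instances (with per-instance expanded monomer patterns
#' and nesting events) to the HOR's instance list.
#'
#' @param layer An `htrm_layer` from [run_htrm()].
#' @return List of HOR records, each with `pattern` (canonical unit, original
#'   symbols), `unit_len` (unit length in the monomer pattern, nested spans
#'   counted once), `rn` (total repeat count), `len` (covered length in
#'   original monomer symbols), `first_start`, and `instances`.
#' @export
merge_to_hors <- function(layer) {
  if (length(layer$trs) == 0L) return(list())
  reg <- layer$registry
  labels <- layer$labels
  keys <- vapply(layer$trs, function(rec)
    paste(.min_rotation(rec$unit), collapse = ","), character(1))
  hors <- list()
  for (key in unique(keys)) {
    recs <- layer$trs[keys == key]
    instances <- list()
    for (rec in recs) {
      for (inst in rec$inst) {
        instances[[length(instances) + 1L]] <-
          .instance_from_tokens(inst, reg, labels)
      }
    }
    canon <- .min_rotation(recs[[1]]$unit)
    hors[[length(hors) + 1L]] <- list(
      pattern = as.vector(labels[canon]),
      unit_len = length(canon),
      rn = sum(vapply(recs, function(r) r$repeats, integer(1))),
      len = sum(vapply(recs, function(r) r$end - r$start, integer(1))),
      first_start = min(vapply(recs, function(r) r$start, integer(1))),
      instances = instances
    )
  }
  hors
}

#' HOR coverage of the monomer sequence
#'
#' @param hors List of HOR records from [merge_to_hors()].
#' @param m_len Length of the original monomer sequence.
#' @return Fraction of monomer symbols inside any HOR instance.
#' @export
hor_coverage <- function(hors, m_len) {
  if (m_len <= 0) stop("'m_len' must be positive", call. = FALSE)
  if (length(hors) == 0L) return(0)
  starts <- unlist(lapply(hors, function(h)
    vapply(h$instances, function(i) i$start, integer(1))))
  ends <- unlist(lapply(hors, function(h)
    vapply(h$instances, function(i) i$end, integer(1))))
  u <- .interval_union(starts, ends)
  sum(u$end - u$start) / m_len
}

#' Score, rank and name HORs
#'
#' `HORscore = cr * pr` with `cr = HOR.len / m.len` (coverage of the monomer
#' sequence) and `pr = HOR.rn / (HOR.len / HORunit.len)` (degree of local
#' nesting; 1 when instances tile their span with no nesting, below 1 when
#' the HOR is locally nested or over-compressed). HORs are sorted by
#' descending score (ties: longer `len`, then smaller `unit_len`, then first
#' occurrence) and named `R<rank>L<unit_len>`.
#'
#' @param hors List of HOR records from [merge_to_hors()].
#' @param m_len Length of the original monomer sequence.
#' @return List with `hors` (ranked records, each gaining `cr`, `pr`, `score`,
#'   `rank`, `name`) and `summary` (one row per HOR).
#' @export
score_and_rank <- function(hors, m_len) {
  if (m_len <= 0) stop("'m_len' must be positive", call. = FALSE)
  if (length(hors) == 0L) {
    return(list(hors = list(), summary = data.frame(
      name = character(0), pattern = character(0), unit_len = integer(0),
      rn = integer(0), len = integer(0), cr = numeric(0), pr = numeric(0),
      score = numeric(0), n_instances = integer(0))))
  }
  cr <- vapply(hors, function(h) h$len / m_len, numeric(1))
  pr <- vapply(hors, function(h) h$rn / (h$len / h$unit_len), numeric(1))
  score <- cr * pr
  len <- vapply(hors, function(h) h$len, integer(1))
  ulen <- vapply(hors, function(h) h$unit_len, integer(1))
  fs <- vapply(hors, function(h) h$first_start, integer(1))
  ord <- order(-score, -len, ulen, fs)
  ranked <- vector("list", length(ord))
  for (r in seq_along(ord)) {
    h <- hors[[ord[r]]]
    h$cr <- cr[ord[r]]
    h$pr <- pr[ord[r]]
    h$score <- score[ord[r]]
    h$rank <- r
    h$name <- paste0("R", r, "L", h$unit_len)
    ranked[[r]] <- h
  }
  summary <- data.frame(
    name = vapply(ranked, `[[`, character(1), "name"),
    pattern = vapply(ranked, function(h) paste(h$pattern, collapse = "_"), character(1)),
    unit_len = vapply(ranked, `[[`, integer(1), "unit_len"),
    rn = vapply(ranked, `[[`, integer(1), "rn"),
    len = vapply(ranked, `[[`, integer(1), "len"),
    cr = vapply(ranked, `[[`, numeric(1), "cr"),
    pr = vapply(ranked, `[[`, numeric(1), "pr"),
    score = vapply(ranked, `[[`, numeric(1), "score"),
    n_instances = vapply(ranked, function(h) length(h$instances), integer(1)),
    stringsAsFactors = FALSE
  )
  list(hors = ranked, summary = summary)
}

#' Select the similarity threshold with the largest HOR coverage
#'
#' @param results List of per-threshold results, each with elements
#'   `threshold` and `coverage`.
#' @return 1-based index of the selected result (largest coverage; ties go to
#'   the lowest threshold).
#' @export
select_threshold <- function(results) {
  if (length(results) == 0L) stop("no sweep results", call. = FALSE)
  cov <- vapply(results, function(r) r$coverage, numeric(1))
  thr <- vapply(results, function(r) r$threshold, numeric(1))
  o <- order(thr)
  o[which.max(cov[o])]
}

#' Annotate a satellite array
#'
#' End-to-end annotation: block decomposition against the monomer template,
#' identical-block merging, monomer inference by Louvain community detection
#' at every threshold of the schedule, hierarchical tandem repeat mining per
#' threshold, HOR assembly, coverage-based threshold selection and HOR
#' scoring/naming.
#'
#' @param sequence Array DNA sequence (character scalar) or path handled by
#'   the caller via [read_fasta_first()].
#' @param template Monomer template DNA sequence (character scalar).
#' @param min_similarity,step Threshold schedule (defaults 0.94, 0.005).
#' @param max_unit_len HTRM unit length bound (default 40).
#' @param seed Integer seed for community detection.
#' @return Object of class `hor_annotation`: selected `threshold`,
#'   `monomer_count`, `monomer_sequence`, ranked `hors`, `summary` table,
#'   `coverage`, `breakpoints` (count of maximal annotated runs), per-
#'   threshold `sweep` table, the `blocks` decomposition and run `params`.
#' @export
annotate_array <- function(sequence, template, min_similarity = 0.94,
                           step = 0.005, max_unit_len = 40L, seed = 1L) {
  blocks <- decompose_monomers(sequence, template)
  merged <- merge_identical(blocks)
  m_len <- merged$n
  sweep <- sweep_thresholds(merged, min_similarity, step, seed = seed)
  results <- lapply(sweep, function(sw) {
    layer <- run_htrm(sw$monomer_sequence, max_unit_len = max_unit_len)
    hors <- merge_to_hors(layer)
    list(threshold = sw$threshold,
         monomer_count = sw$assignment$monomer_count,
         monomer_sequence = sw$monomer_sequence,
         layer = layer,
         hors = hors,
         coverage = hor_coverage(hors, m_len))
  })
  best <- results[[select_threshold(results)]]
  ranked <- score_and_rank(best$hors, m_len)
  starts <- unlist(lapply(ranked$hors, function(h)
    vapply(h$instances, function(i) i$start, integer(1))))
  ends <- unlist(lapply(ranked$hors, function(h)
    vapply(h$instances, function(i) i$end, integer(1))))
  runs <- .interval_union(starts, ends)
  structure(list(
    threshold = best$threshold,
    monomer_count = best$monomer_count,
    monomer_sequence = best$monomer_sequence,
    hors = ranked$hors,
    summary = ranked$summary,
    coverage = best$coverage,
    breakpoints = nrow(runs),
    sweep = data.frame(
      threshold = vapply(results, `[[`, numeric(1), "threshold"),
      monomer_count = vapply(results, `[[`, integer(1), "monomer_count"),
      coverage = vapply(results, `[[`, numeric(1), "coverage")),
    blocks = blocks,
    params = list(min_similarity = min_similarity, step = step,
                  max_unit_len = max_unit_len, seed = seed)
  ), class = "hor_annotation")
}

#' Project HOR instances to genomic coordinates
#'
#' Each HOR instance's monomer-coordinate span is mapped to base coordinates
#' through the block decomposition (start of its first block to end of its
#' last block, 0-based half-open), together with the instance's expanded
#' monomer pattern.
#'
#' @param annotation A `hor_annotation` from [annotate_array()].
#' @param chrom Name for the BED `chrom` column.
#' @return `data.frame`: `chrom`, `start`, `end`, `name`, `pattern`.
#' @export
project_annotation <- function(annotation, chrom = "array") {
  blocks <- annotation$blocks
  rows <- list()
  for (h in annotation$hors) {
    for (inst in h$instances) {
      if (inst$start < 0L || inst$end > nrow(blocks)) {
        stop("instance span outside the block list", call. = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom,
        start = blocks$start[inst$start + 1L],
        end = blocks$end[inst$end],
        name = h$name,
        pattern = inst$pattern,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      pattern = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$end), , drop = FALSE]
}

#' @export
print.hor_annotation <- function(x, ...) {
  cat("HOR annotation\n")
  cat("  selected threshold:", x$threshold, "\n")
  cat("  monomers:", x$monomer_count, " monomer sequence length:",
      length(x$monomer_sequence), "\n")
  cat("  coverage:", sprintf("%.4f", x$coverage),
      " breakpoints:", x$breakpoints, "\n")
  top <- x$summary[x$summary$rn > 10, , drop = FALSE]
  top <- utils::head(top, 5L)
  if (nrow(top) > 0L) {
    cat("  top HORs (repeat number > 10):\n")
    print(top[, c("name", "pattern", "unit_len", "rn", "cr", "pr", "score")],
          row.names = FALSE)
  } else if (nrow(x$summary) > 0L) {
    cat("  HORs:\n")
    print(utils::head(x$summary, 5L), row.names = FALSE)
  } else {
    cat("  no HORs detected\n")
  }
  invisible(x)
}

#' Write annotation outputs
#'
#' Writes the monomer decomposition BED (block coordinates + monomer ID), the
#' HOR-instance BED (with expanded per-instance patterns), the HOR summary
#' TSV and a JSON run-metadata file. All detected HORs are written; the
#' human-readable report (see `print`) highlights only the top five with
#' repeat numbers greater than 10.
#'
#' @param annotation A `hor_annotation`.
#' @param dir Output directory (created if missing).
#' @param chrom Record name used in BED files.
#' @param prefix File name prefix.
#' @return Invisibly, the vector of written paths.
#' @export
write_annotation <- function(annotation, dir, chrom = "array",
                             prefix = "centrohor") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  blocks <- annotation$blocks
  mono_path <- file.path(dir, paste0(prefix, ".monomers.bed"))
  utils::write.table(
    data.frame(chrom = chrom, start = blocks$start, end = blocks$end,
               name = annotation$monomer_sequence),
    mono_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  hor_path <- file.path(dir, paste0(prefix, ".hors.bed"))
  utils::write.table(project_annotation(annotation, chrom = chrom),
                     hor_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  sum_path <- file.path(dir, paste0(prefix, ".hor_summary.tsv"))
  utils::write.table(annotation$summary, sum_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta_path <- file.path(dir, paste0(prefix, ".run.json"))
  jsonlite::write_json(
    list(params = annotation$params,
         selected_threshold = annotation$threshold,
         monomer_count = annotation$monomer_count,
         coverage = annotation$coverage,
         breakpoints = annotation$breakpoints,
         sweep = annotation$sweep),
    meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(mono_path, hor_path, sum_path, meta_path))
}
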