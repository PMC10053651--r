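# Hierarchical tandem repeat mining (HTRM).
#
# The working sequence is a token table: parallel vectors `class` (monomer
# class), `start`/`end` (0-based half-open projection to the ORIGINAL monomer
# sequence), `tr` (registry id of a compressed tandem repeat carried by this
# token, 0 if none) and `cont` (TRUE for the continuation tokens of a
# collapsed region; only the first token of a collapsed region carries the
# repeat). Compressing an accepted tandem repeat replaces its region by a
# single copy of the unit, so a locally amplified higher-order-repeat unit
# becomes class-identical to a canonical unit and the two join the same
# tandem run at the next round; the amplification survives as a nested child
# on the collapsed tokens. Token spans always partition the original
# coordinates, so overlap checks against old repeats stay exact and any run
# that would cut a collapsed region in half is caught as a partial overlap.

.tok_new <- function(cls) {
  n <- length(cls)
  list(class = as.integer(cls), start = 0:(n - 1L), end = 1:n,
       tr = integer(n), cont = logical(n))
}

.tok_slice <- function(tok, idx) {
  list(class = tok$class[idx], start = tok$start[idx], end = tok$end[idx],
       tr = tok$tr[idx], cont = tok$cont[idx])
}

.tok_len <- function(tok) length(tok$class)

# maximal tandem runs of period u over an integer class vector;
# returns data.frame(s = 1-based start token, k = repeats)
.find_runs <- function(cls, u) {
  n <- length(cls)
  empty <- data.frame(s = integer(0), k = integer(0))
  if (n < 2L * u) return(empty)
  eq <- cls[1:(n - u)] == cls[(u + 1L):n]
  r <- rle(eq)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out_s <- integer(0); out_k <- integer(0)
  for (i in which(r$values & r$lengths >= u)) {
    a <- starts[i]; b <- ends[i]
    for (s in a:min(a + u - 1L, b)) {
      k <- (b - s + 1L) %/% u + 1L
      if (k >= 2L) { out_s <- c(out_s, s); out_k <- c(out_k, k) }
    }
  }
  ord <- order(out_s)
  out_s <- out_s[ord]; out_k <- out_k[ord]
  # drop runs whose region is contained in an earlier (longer) run's region:
  # a shifted phase of the same repeat tract carries no extra information
  keep <- logical(length(out_s))
  max_end <- 0L
  for (i in seq_along(out_s)) {
    e <- out_s[i] + out_k[i] * u
    if (e > max_end) { keep[i] <- TRUE; max_end <- e }
  }
  data.frame(s = out_s[keep], k = out_k[keep])
}

#' Detect maximal tandem repeats of a given unit length
#'
#' Finds every maximal run where the subsequence of length `unit_len`
#' repeats consecutively at least twice; a run is maximal when it cannot be
#' extended by a full unit on either side. Runs whose region is contained in
#' another run's region (shifted phases of the same repeat tract) are
#' suppressed; the surviving runs are reported left to right.
#'
#' @param x Symbol sequence (atomic vector, e.g. monomer IDs).
#' @param unit_len Tandem repeat unit length (>= 1).
#' @return `data.frame` with 0-based half-open `start`, `end`, `repeats`, and
#'   a list column `unit` holding each run's unit.
#' @examples
#' detect_tandem(c(2, 3, 2, 3, 2, 3), 2)
#' @export
detect_tandem <- function(x, unit_len) {
  if (length(x) == 0L) stop("'x' must be non-empty", call. = FALSE)
  if (unit_len < 1L) stop("'unit_len' must be >= 1", call. = FALSE)
  unit_len <- as.integer(unit_len)
  uniq <- unique(x)
  cls <- match(x, uniq)
  runs <- .find_runs(cls, unit_len)
  data.frame(
    start = runs$s - 1L,
    end = runs$s - 1L + runs$k * unit_len,
    repeats = runs$k,
    unit = I(lapply(runs$s, function(s) x[s:(s + unit_len - 1L)]))
  )
}

# resolve overlaps among same-round runs: leftmost kept, later ones trimmed
# by full units; a trimmed remainder needs >= 2 repeats
.resolve_new_overlaps <- function(runs, u) {
  if (nrow(runs) == 0L) return(runs)
  kept_s <- integer(0); kept_e <- integer(0)
  out_s <- integer(0); out_k <- integer(0)
  overlaps_kept <- function(a, b) any(kept_s <= b & kept_e >= a)
  for (i in seq_len(nrow(runs))) {
    s <- runs$s[i]; k <- runs$k[i]
    while (k >= 2L && overlaps_kept(s, s + u - 1L)) { s <- s + u; k <- k - 1L }
    while (k >= 2L && overlaps_kept(s + (k - 1L) * u, s + k * u - 1L)) k <- k - 1L
    if (k < 2L || overlaps_kept(s, s + k * u - 1L)) next
    kept_s <- c(kept_s, s); kept_e <- c(kept_e, s + k * u - 1L)
    out_s <- c(out_s, s); out_k <- c(out_k, k)
  }
  data.frame(s = out_s, k = out_k)
}

# Region checking: each new run is compared against the old top-layer repeats
# it touches (original coordinates). No overlap -> saved; covered by an old
# repeat -> discarded; covering old repeats -> replaces them (they become
# children); partial overlap -> the conflicting flank units are removed and
# the remainder is kept when >= 2 full units survive.
.region_check <- function(runs, u, tok, layer, registry) {
  accepted <- list()
  removed <- integer(0)
  lay_start <- vapply(layer, function(id) registry[[id]]$start, integer(1))
  lay_end <- vapply(layer, function(id) registry[[id]]$end, integer(1))
  lay_ids <- as.integer(layer)
  alive <- rep(TRUE, length(lay_ids))
  for (i in seq_len(nrow(runs))) {
    s <- runs$s[i]; k <- runs$k[i]
    S <- tok$start[s]; E <- tok$end[s + k * u - 1L]
    touch <- which(alive & lay_start < E & lay_end > S)
    if (length(touch) == 0L) {
      accepted[[length(accepted) + 1L]] <- list(s = s, k = k, replaced = integer(0))
      next
    }
    if (any(lay_start[touch] <= S & lay_end[touch] >= E)) next  # covered by old
    partial <- touch[lay_start[touch] < S | lay_end[touch] > E]
    if (length(partial)) {
      repeat {
        if (k < 2L) break
        fs <- tok$start[s]; fe <- tok$end[s + u - 1L]
        if (any(lay_start[partial] < fe & lay_end[partial] > fs)) {
          s <- s + u; k <- k - 1L
        } else break
      }
      repeat {
        if (k < 2L) break
        ls <- tok$start[s + (k - 1L) * u]; le <- tok$end[s + k * u - 1L]
        if (any(lay_start[partial] < le & lay_end[partial] > ls)) {
          k <- k - 1L
        } else break
      }
      if (k < 2L) next
      S <- tok$start[s]; E <- tok$end[s + k * u - 1L]
      touch <- which(alive & lay_start < E & lay_end > S)
      if (any(lay_start[touch] < S | lay_end[touch] > E)) next
      if (any(lay_start[touch] <= S & lay_end[touch] >= E)) next
    }
    covered_old <- touch[lay_start[touch] >= S & lay_end[touch] <= E]
    alive[covered_old] <- FALSE
    removed <- c(removed, lay_ids[covered_old])
    accepted[[length(accepted) + 1L]] <-
      list(s = s, k = k, replaced = lay_ids[covered_old])
  }
  list(accepted = accepted, kept_layer = lay_ids[alive])
}

# compress accepted runs (disjoint in token coordinates): each region is
# replaced by one copy of its unit; per-repeat token slices are recorded on
# the registry record for later expansion and per-instance reporting
.compress_runs <- function(tok, accepted, u, registry, next_id) {
  new_ids <- integer(0)
  ord <- order(vapply(accepted, function(a) a$s, integer(1)), decreasing = TRUE)
  for (a in accepted[ord]) {
    s <- a$s; k <- a$k
    rows <- s:(s + k * u - 1L)
    inst <- lapply(0:(k - 1L), function(j)
      .tok_slice(tok, (s + j * u):(s + (j + 1L) * u - 1L)))
    rec <- list(id = next_id,
                unit = tok$class[s:(s + u - 1L)],
                unit_len = u,
                repeats = k,
                start = tok$start[s],
                end = tok$end[s + k * u - 1L],
                inst = inst,
                children = a$replaced)
    registry[[next_id]] <- rec
    fresh <- .tok_slice(tok, s:(s + u - 1L))
    fresh$end[u] <- rec$end
    fresh$tr <- c(next_id, integer(u - 1L))
    fresh$cont <- c(FALSE, rep(TRUE, u - 1L))
    keep_before <- if (s > 1L) 1:(s - 1L) else integer(0)
    keep_after <- if (s + k * u <= .tok_len(tok)) (s + k * u):.tok_len(tok) else integer(0)
    tok <- list(class = c(tok$class[keep_before], fresh$class, tok$class[keep_after]),
                start = c(tok$start[keep_before], fresh$start, tok$start[keep_after]),
                end = c(tok$end[keep_before], fresh$end, tok$end[keep_after]),
                tr = c(tok$tr[keep_before], fresh$tr, tok$tr[keep_after]),
                cont = c(tok$cont[keep_before], fresh$cont, tok$cont[keep_after]))
    new_ids <- c(new_ids, next_id)
    next_id <- next_id + 1L
  }
  list(tok = tok, registry = registry, new_ids = new_ids, next_id = next_id)
}

#' Hierarchical tandem repeat mining over a symbol sequence
#'
#' Iterates tandem repeat detection with unit length growing from 1 to
#' `max_unit_len`. Newly detected repeats are checked against the top layer
#' (non-overlapping repeats of maximal coverage); accepted repeats are
#' compressed to a single copy of their unit and the unit length resets to 1,
#' so nested repeats surface bottom-up. The loop ends when no unit length up
#' to the bound updates the top layer.
#'
#' @param x Symbol sequence (atomic vector of monomer IDs).
#' @param max_unit_len Upper bound for the tandem repeat unit length
#'   (default 40).
#' @return Object of class `htrm_layer`: list with `trs` (top-level repeat
#'   records, sorted by original start), `registry` (all repeat records),
#'   `tokens` (final working tokens), `m_len` (original sequence length) and
#'   `labels` (original symbol per internal class).
#' @export
run_htrm <- function(x, max_unit_len = 40L) {
  if (length(x) == 0L) stop("'x' must be non-empty", call. = FALSE)
  labels <- unique(x)
  tok <- .tok_new(match(x, labels))
  registry <- list()
  layer <- integer(0)
  next_id <- 1L
  u <- 1L
  while (u <= max_unit_len) {
    runs <- .find_runs(tok$class, u)
    runs <- .resolve_new_overlaps(runs, u)
    updated <- FALSE
    if (nrow(runs) > 0L) {
      chk <- .region_check(runs, u, tok, layer, registry)
      if (length(chk$accepted) > 0L) {
        cmp <- .compress_runs(tok, chk$accepted, u, registry, next_id)
        tok <- cmp$tok
        registry <- cmp$registry
        next_id <- cmp$next_id
        layer <- c(chk$kept_layer, cmp$new_ids)
        updated <- TRUE
      }
    }
    u <- if (updated) 1L else u + 1L
  }
  starts <- vapply(layer, function(id) registry[[id]]$start, integer(1))
  layer <- layer[order(starts)]
  structure(list(trs = lapply(layer, function(id) registry[[id]]),
                 registry = registry,
                 tokens = tok,
                 m_len = length(x),
                 labels = labels),
            class = "htrm_layer")
}

# recursive expansion back to original symbol classes
.expand_tokens <- function(tokvec, registry) {
  out <- vector("list", length(tokvec$class))
  for (i in seq_along(tokvec$class)) {
    if (tokvec$cont[i]) next
    out[[i]] <- if (tokvec$tr[i] > 0L) {
      .expand_record(registry[[tokvec$tr[i]]], registry)
    } else {
      tokvec$class[i]
    }
  }
  unlist(out, use.names = FALSE)
}

.expand_record <- function(rec, registry) {
  unlist(lapply(rec$inst, .expand_tokens, registry = registry),
         use.names = FALSE)
}

#' Expand an HTRM result back to the original symbol sequence
#'
#' Full expansion of the final working tokens (compressed repeats included)
#' reproduces the input sequence exactly; this is the losslessness invariant
#' of the compression scheme.
#'
#' @param layer An `htrm_layer` from [run_htrm()].
#' @return Vector of original symbols.
#' @export
expand_layer <- function(layer) {
  layer$labels[.expand_tokens(layer$tokens, layer$registry)]
}

#' Serialize an HTRM top layer as a nested tree
#'
#' @param layer An `htrm_layer` from [run_htrm()].
#' @return A list (one element per top-level repeat) of nested records with
#'   `unit`, `repeats`, `span` and `children`; convertible to JSON.
#' @export
as_tandem_tree <- function(layer) {
  reg <- layer$registry
  labels <- layer$labels
  rec_tree <- function(rec) {
    kids <- list()
    for (inst in rec$inst) {
      for (i in seq_along(inst$class)) {
        if (!inst$cont[i] && inst$tr[i] > 0L) {
          kids[[length(kids) + 1L]] <- rec_tree(reg[[inst$tr[i]]])
        }
      }
    }
    list(unit = as.vector(labels[rec$unit]),
         repeats = rec$repeats,
         span = c(rec$start, rec$end),
         children = kids)
  }
  lapply(layer$trs, rec_tree)
}
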