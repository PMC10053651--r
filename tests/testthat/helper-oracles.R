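# Independent oracles and small generators used across the suite.

# brute-force tandem repeat enumerator: tests every (start, repeats) pair for
# periodicity and maximality, then drops runs contained in another run's
# region (shifted phases of the same tract)
brute_tandem <- function(x, u) {
  n <- length(x)
  runs <- data.frame(start = integer(0), end = integer(0), repeats = integer(0))
  if (n >= 2 * u) {
    for (s in 1:(n - 2 * u + 1)) {
      for (k in 2:((n - s + 1) %/% u)) {
        e <- s + k * u - 1L
        if (!all(x[s:(e - u)] == x[(s + u):e])) next
        left_ext <- s - u >= 1 && all(x[(s - u):(s - 1)] == x[s:(s + u - 1)])
        right_ext <- e + u <= n && all(x[(e - u + 1):e] == x[(e + 1):(e + u)])
        if (left_ext || right_ext) next
        runs <- rbind(runs, data.frame(start = s - 1L, end = e, repeats = k))
      }
    }
  }
  if (nrow(runs) > 1) {
    contained <- vapply(seq_len(nrow(runs)), function(i) {
      any(runs$start <= runs$start[i] & runs$end >= runs$end[i] &
            (runs$start != runs$start[i] | runs$end != runs$end[i]))
    }, logical(1))
    runs <- runs[!contained, , drop = FALSE]
  }
  runs <- runs[order(runs$start), , drop = FALSE]
  rownames(runs) <- NULL
  runs
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# tiny helper: expand a canonical unit layout by local-nesting events
expand_truth <- function(truth_ln, n_units = 40L, unit_len = 5L) {
  units <- rep(list(seq_len(unit_len)), n_units)
  if (nrow(truth_ln)) {
    for (i in seq_len(nrow(truth_ln))) {
      u <- truth_ln$unit[i]; s <- truth_ln$span_start[i]
      l <- truth_ln$span_len[i]; k <- truth_ln$copies[i]
      base <- seq_len(unit_len)
      pre <- if (s > 1) base[1:(s - 1)] else integer(0)
      post <- if (s + l - 1 < unit_len) base[(s + l):unit_len] else integer(0)
      units[[u]] <- c(pre, rep(base[s:(s + l - 1)], k), post)
    }
  }
  unlist(units)
}
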