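# Bin-based positional enrichment of HOR pattern classes along an array.

#' Assign labelled instances to equal-width bins
#'
#' The region is split into `n_bins` equal-width bins and each instance is
#' assigned to the bin containing its midpoint.
#'
#' @param instances `data.frame` with `start`, `end` (0-based half-open) and
#'   `class` (pattern class label).
#' @param region Length-2 numeric, the `c(start, end)` of the region.
#' @param n_bins Number of bins (default 25).
#' @return Integer matrix of counts, `n_bins` rows x one column per class.
#' @export
bin_instances <- function(instances, region, n_bins = 25L) {
  if (length(region) != 2L || region[2] <= region[1]) {
    stop("'region' must be a non-empty c(start, end)", call. = FALSE)
  }
  if (n_bins < 1L) stop("'n_bins' must be >= 1", call. = FALSE)
  classes <- unique(as.character(instances$class))
  counts <- matrix(0L, nrow = n_bins, ncol = length(classes),
                   dimnames = list(NULL, classes))
  if (nrow(instances) == 0L) return(counts)
  mid <- (instances$start + instances$end) / 2
  if (any(mid < region[1] | mid > region[2])) {
    stop("instance midpoint outside the region", call. = FALSE)
  }
  width <- (region[2] - region[1]) / n_bins
  bin <- pmin(floor((mid - region[1]) / width) + 1L, n_bins)
  for (i in seq_len(nrow(instances))) {
    cl <- as.character(instances$class[i])
    counts[bin[i], cl] <- counts[bin[i], cl] + 1L
  }
  counts
}

#' Positional enrichment test for HOR pattern classes
#'
#' For each pattern class, the observed per-bin counts are compared with a
#' background built by re-placing the same number of instances uniformly at
#' random across the region `n_random` times. Per bin and class,
#' `z = (N_obv - mu) / sigma` with `mu`/`sigma` the background mean and
#' standard deviation, and a one-sided upper-tail p-value from the standard
#' normal (enrichment). Bins whose background never varies (`sigma = 0`) are
#' reported as `NA` (untestable). No multiple-testing correction is applied;
#' the `enriched` flag marks raw `p < 0.05`.
#'
#' @param instances `data.frame` with `start`, `end`, `class`.
#' @param region Length-2 numeric `c(start, end)`.
#' @param n_bins Number of bins (default 25).
#' @param n_random Background replicates (default 100).
#' @param seed Integer seed for the background placement.
#' @return `data.frame` of class `enrichment_result`: `bin`, `bin_start`,
#'   `bin_end`, `class`, `N_obv`, `mu`, `sigma`, `z`, `p`, `enriched`.
#' @export
enrichment_test <- function(instances, region, n_bins = 25L, n_random = 100L,
                            seed = 1L) {
  counts <- bin_instances(instances, region, n_bins)
  classes <- colnames(counts)
  if (any(colSums(counts) < 1L)) {
    stop("every class needs at least one instance", call. = FALSE)
  }
  set.seed(seed)
  width <- (region[2] - region[1]) / n_bins
  out <- list()
  for (cl in classes) {
    total <- sum(counts[, cl])
    # uniform midpoints binned over equal-width bins == equiprobable multinomial
    bg <- stats::rmultinom(n_random, total, rep(1 / n_bins, n_bins))
    mu <- rowMeans(bg)
    sigma <- apply(bg, 1, stats::sd)
    z <- ifelse(sigma > 0, (counts[, cl] - mu) / sigma, NA_real_)
    p <- stats::pnorm(z, lower.tail = FALSE)
    out[[cl]] <- data.frame(
      bin = seq_len(n_bins),
      bin_start = region[1] + (seq_len(n_bins) - 1L) * width,
      bin_end = region[1] + seq_len(n_bins) * width,
      class = cl,
      N_obv = counts[, cl],
      mu = mu, sigma = sigma, z = z, p = p,
      enriched = !is.na(p) & p < 0.05,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}
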