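#' Decompose a satellite array into monomer-sized blocks
#'
#' Segments a satellite DNA sequence into consecutive, non-overlapping blocks,
#' each aligned to a monomer template, by a dynamic program that scans the
#' array and at every position chooses the best-scoring preceding block
#' boundary (semi-global alignment of the template to each candidate block).
#' Block lengths track the template length but may deviate by indels.
#'
#' Soft-masked (lower-case) bases are treated as their upper-case equivalents;
#' `N` mismatches every base. Only the forward strand is aligned. Terminal
#' partial blocks shorter than `min_terminal_frac` of the template length are
#' trimmed, since they are alignment fragments and downstream similarity is
#' length-sensitive.
#'
#' @param sequence Array DNA sequence (character scalar over A/C/G/T/N).
#' @param template Monomer template DNA sequence (character scalar).
#' @param match,mismatch,indel Alignment scores (defaults +1/-1/-1).
#' @param min_terminal_frac Minimum length of a terminal block, as a fraction
#'   of the template length (default 0.6).
#' @return A `data.frame` of class `monomer_blocks` with columns `index`
#'   (0-based ordinal), `start`, `end` (0-based half-open base coordinates),
#'   `len`, and `sequence`. The template is attached as attribute `template`.
#' @examples
#' tmpl <- "ACGTACGTAC"
#' decompose_monomers(strrep(tmpl, 5), tmpl)
#' @export
decompose_monomers <- function(sequence, template,
                               match = 1L, mismatch = -1L, indel = -1L,
                               min_terminal_frac = 0.6) {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence)) {
    stop("'sequence' must be a non-empty DNA string", call. = FALSE)
  }
  if (length(template) != 1L || is.na(template) || !nzchar(template)) {
    stop("'template' must be a non-empty DNA string", call. = FALSE)
  }
  sequence <- toupper(sequence)
  template <- toupper(template)
  if (grepl("[^ACGTN]", template)) {
    stop("template alphabet restricted to A/C/G/T (N allowed in arrays only)",
         call. = FALSE)
  }
  n <- nchar(sequence)
  L <- nchar(template)
  if (n < L / 2) {
    stop("array too short: sequence (", n, " bp) is shorter than half the ",
         "template (", L, " bp)", call. = FALSE)
  }

  cuts <- .decompose_cuts_cpp(sequence, template,
                              as.integer(match), as.integer(mismatch),
                              as.integer(indel))
  starts <- c(0L, cuts)
  ends <- c(cuts, n)

  # trim terminal fragments
  min_len <- min_terminal_frac * L
  while (length(starts) > 1L && (ends[1] - starts[1]) < min_len) {
    starts <- starts[-1]; ends <- ends[-1]
  }
  k <- length(starts)
  while (k > 1L && (ends[k] - starts[k]) < min_len) {
    starts <- starts[-k]; ends <- ends[-k]; k <- k - 1L
  }

  blocks <- data.frame(
    index = seq_along(starts) - 1L,
    start = starts,
    end = ends,
    len = ends - starts,
    sequence = substring(sequence, starts + 1L, ends),
    stringsAsFactors = FALSE
  )
  attr(blocks, "template") <- template
  class(blocks) <- c("monomer_blocks", "data.frame")
  blocks
}

#' Write a block decomposition as BED4
#'
#' @param blocks A `monomer_blocks` data frame from [decompose_monomers()].
#' @param path Output path.
#' @param chrom Chromosome / record name for the first BED column.
#' @return Invisibly, `path`.
#' @export
write_blocks_bed <- function(blocks, path, chrom = "array") {
  bed <- data.frame(chrom = chrom, start = blocks$start, end = blocks$end,
                    name = blocks$index)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
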