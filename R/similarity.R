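#' Unit-cost edit distance between two sequences
#'
#' Levenshtein distance (substitution, insertion and deletion each cost 1),
#' computed with Myers' bit-parallel algorithm.
#'
#' @param a,b Character scalars.
#' @return Integer edit distance.
#' @export
edit_distance <- function(a, b) {
  .edit_distance_cpp(as.character(a), as.character(b))
}

#' Similarity between two blocks
#'
#' `1 - ed(b1, b2) / max(b1.len, b2.len)` where `ed` is the unit-cost
#' Levenshtein distance; the value lies in `[0, 1]` with 1 for identical
#' sequences.
#'
#' @param b1,b2 Block sequences (character scalars), or single rows of a
#'   `monomer_blocks` data frame.
#' @return Numeric similarity in `[0, 1]`.
#' @examples
#' block_similarity("ACGT", "ACGA")  # 0.75
#' @export
block_similarity <- function(b1, b2) {
  s1 <- if (is.data.frame(b1)) b1$sequence[1] else as.character(b1)
  s2 <- if (is.data.frame(b2)) b2$sequence[1] else as.character(b2)
  if (is.na(s1) || is.na(s2) || !nzchar(s1) || !nzchar(s2)) {
    stop("block sequences must be non-empty", call. = FALSE)
  }
  1 - .edit_distance_cpp(s1, s2) / max(nchar(s1), nchar(s2))
}

#' Pairwise block similarity matrix
#'
#' Symmetric matrix of [block_similarity()] over all block pairs.
#'
#' @param blocks A `monomer_blocks` data frame, or a character vector of
#'   block sequences.
#' @return Numeric `n x n` matrix with unit diagonal.
#' @export
similarity_matrix <- function(blocks) {
  seqs <- if (is.data.frame(blocks)) blocks$sequence else as.character(blocks)
  if (length(seqs) < 1L) stop("need at least one block", call. = FALSE)
  if (any(!nzchar(seqs))) stop("block sequences must be non-empty", call. = FALSE)
  D <- .edist_matrix_cpp(seqs)
  lens <- nchar(seqs)
  maxlen <- outer(lens, lens, pmax)
  S <- 1 - D / maxlen
  diag(S) <- 1
  S
}

#' Collapse identical blocks
#'
#' Blocks with identical sequences (similarity 100%) are merged; one
#' representative per distinct sequence is kept, in order of first occurrence
#' along the array, and the similarity matrix is computed over the
#' representatives only. This is a pure efficiency step: the full matrix is
#' recoverable exactly through `member_map`.
#'
#' @param blocks A `monomer_blocks` data frame (or character vector of block
#'   sequences).
#' @return An object of class `merged_blocks`: a list with `representatives`
#'   (block data frame rows of first occurrences), `multiplicity` (integer
#'   count per representative), `member_map` (for each original block, the
#'   1-based representative index), `similarity` (matrix over
#'   representatives), and `n` (number of original blocks).
#' @export
merge_identical <- function(blocks) {
  df <- if (is.data.frame(blocks)) {
    blocks
  } else {
    data.frame(index = seq_along(blocks) - 1L, start = NA_integer_,
               end = NA_integer_, len = nchar(blocks),
               sequence = as.character(blocks), stringsAsFactors = FALSE)
  }
  if (nrow(df) < 1L) stop("need at least one block", call. = FALSE)
  first <- !duplicated(df$sequence)
  reps <- df[first, , drop = FALSE]
  member_map <- match(df$sequence, reps$sequence)
  out <- list(
    representatives = reps,
    multiplicity = as.integer(tabulate(member_map, nbins = nrow(reps))),
    member_map = member_map,
    similarity = similarity_matrix(reps$sequence),
    n = nrow(df)
  )
  class(out) <- "merged_blocks"
  out
}

#' @export
print.merged_blocks <- function(x, ...) {
  cat("merged block set:", x$n, "blocks,", nrow(x$representatives),
      "distinct representatives\n")
  invisible(x)
}

#' Dump a merged similarity matrix as TSV (debugging aid)
#'
#' @param merged A `merged_blocks` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_merged_tsv <- function(merged, path) {
  df <- data.frame(representative = seq_len(nrow(merged$representatives)) - 1L,
                   multiplicity = merged$multiplicity)
  df <- cbind(df, as.data.frame(merged$similarity))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
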