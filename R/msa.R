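#' Remove gappy alignment columns
#'
#' Columns whose gap fraction is greater than or equal to `gap_threshold`
#' are removed (so at the default 0.9, a column that is exactly 90% gaps
#' is removed, matching ClipKIT gappy-mode semantics).
#'
#' @param alignment Character matrix from [as_alignment()].
#' @param gap_threshold Gap-fraction threshold in (0, 1].
#' @return List with `alignment` (trimmed matrix) and `column_map`
#'   (integer vector mapping retained column index to original index).
#' @export
trim_gappy_columns <- function(alignment, gap_threshold = 0.9) {
  stopifnot(is.matrix(alignment), nrow(alignment) > 0L)
  gap_frac <- colMeans(alignment == "-")
  keep <- which(gap_frac < gap_threshold)
  if (length(keep) == 0L)
    stop("all columns removed at gap threshold ", gap_threshold)
  list(alignment = alignment[, keep, drop = FALSE],
       column_map = keep)
}

#' Map reference-numbered residue ranges to alignment columns
#'
#' Walks the reference row of `alignment`, skipping its gaps, so that the
#' i-th non-gap character is reference residue i. Each named range
#' (1-based, inclusive) is translated to the alignment columns its residues
#' occupy. When `column_map` (from [trim_gappy_columns()]) is supplied,
#' `alignment` must be the untrimmed alignment and the returned `columns`
#' index the trimmed alignment; a reference residue whose column was
#' removed by trimming is an error reporting the original column index.
#'
#' @param alignment Character matrix (untrimmed when `column_map` given).
#' @param reference_id Row name of the reference sequence.
#' @param ranges Data frame with columns `name`, `start`, `end`.
#' @param column_map Optional integer vector of retained original columns.
#' @return List of stretch annotations, each a list with `name`, `start`,
#'   `end`, `columns` and `original_columns`.
#' @export
map_reference_ranges <- function(alignment, reference_id, ranges,
                                 column_map = NULL) {
  stopifnot(is.matrix(alignment))
  if (!reference_id %in% rownames(alignment))
    stop("reference '", reference_id, "' not in alignment")
  stopifnot(all(c("name", "start", "end") %in% names(ranges)))
  ref <- alignment[reference_id, ]
  pos <- which(ref != "-")  # residue i sits in original column pos[i]
  out <- vector("list", nrow(ranges))
  for (k in seq_len(nrow(ranges))) {
    s <- ranges$start[k]; e <- ranges$end[k]
    if (s < 1L || e < s) stop("invalid range ", ranges$name[k])
    if (e > length(pos))
      stop("range ", ranges$name[k], " (", s, "-", e,
           ") exceeds reference length ", length(pos))
    orig <- pos[s:e]
    if (is.null(column_map)) {
      cols <- orig
    } else {
      cols <- match(orig, column_map)
      if (anyNA(cols))
        stop("range ", ranges$name[k], ": reference residue(s) ",
             paste((s:e)[is.na(cols)], collapse = ","),
             " fall in trimmed column(s) ",
             paste(orig[is.na(cols)], collapse = ","))
    }
    out[[k]] <- list(name = as.character(ranges$name[k]),
                     start = s, end = e,
                     columns = cols, original_columns = orig)
  }
  names(out) <- as.character(ranges$name)
  out
}

#' All alignment columns covered by a set of stretch annotations
#'
#' @param annotations Output of [map_reference_ranges()].
#' @return Sorted integer vector of unique column indices.
#' @export
stretch_columns <- function(annotations) {
  sort(unique(unlist(lapply(annotations, `[[`, "columns"))))
}

#' Per-column amino-acid frequencies within a sequence subset
#'
#' Frequencies are over the 20 amino acids among the subset rows; gaps and
#' `X` are excluded from both numerator and denominator. A column that is
#' all-gap within the subset has `n_effective` 0 and `NA` frequencies.
#'
#' @param alignment Character matrix.
#' @param subset Character vector of row ids (default: all rows).
#' @return A `freq_table`: list with `freq` (20 x n_columns matrix, rows
#'   named by amino acid), `n_effective` (integer per column) and
#'   `n_subset`.
#' @export
column_frequencies <- function(alignment, subset = rownames(alignment)) {
  stopifnot(is.matrix(alignment))
  if (length(subset) == 0L) stop("empty subset")
  missing <- setdiff(subset, rownames(alignment))
  if (length(missing))
    stop("subset ids not in alignment: ",
         paste(utils::head(missing, 5), collapse = ", "))
  sub <- alignment[subset, , drop = FALSE]
  counts <- matrix(0, nrow = 20L, ncol = ncol(sub),
                   dimnames = list(AA20, NULL))
  for (a in AA20) counts[a, ] <- colSums(sub == a)
  n_eff <- colSums(counts)
  freq <- sweep(counts, 2L, pmax(n_eff, 1), "/")
  freq[, n_eff == 0] <- NA_real_
  structure(list(freq = freq, n_effective = as.integer(n_eff),
                 n_subset = length(subset)),
            class = "freq_table")
}

#' Consensus pattern and logo matrix from a frequency table
#'
#' Per column, the most frequent amino acid; exact ties are broken
#' alphabetically (and flagged); all-gap columns emit `-`.
#'
#' @param freqs A `freq_table` from [column_frequencies()].
#' @return List with `pattern` (single string), `logo` (the 20 x n
#'   frequency matrix) and `ties` (columns where the maximum was tied).
#' @export
consensus_pattern <- function(freqs) {
  stopifnot(inherits(freqs, "freq_table"))
  f <- freqs$freq
  cons <- character(ncol(f))
  ties <- integer(0)
  for (j in seq_len(ncol(f))) {
    if (freqs$n_effective[j] == 0L) { cons[j] <- "-"; next }
    mx <- max(f[, j])
    hits <- which(f[, j] == mx)
    if (length(hits) > 1L) ties <- c(ties, j)
    cons[j] <- AA20[hits[1L]]  # AA20 is alphabetical: first hit wins ties
  }
  list(pattern = paste(cons, collapse = ""), logo = f, ties = ties)
}
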