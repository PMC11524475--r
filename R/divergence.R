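#' Parameters for the clade-unique-residue statistic
#'
#' @param freq_cutoff Minimum within-query frequency of the majority amino
#'   acid for a position to be callable; the comparison is strict
#'   (frequency must exceed the cutoff).
#' @param ratio_cutoff Fold-change above which (strictly) a callable
#'   position is a unique residue.
#' @param clade_set Ordered character vector of clade names entering the
#'   comparison (query plus pooled subjects).
#' @return A `divergence_params` list.
#' @export
divergence_params <- function(freq_cutoff = 0.8, ratio_cutoff = 50,
                              clade_set = NULL) {
  stopifnot(freq_cutoff > 0, freq_cutoff <= 1, ratio_cutoff > 0)
  if (!is.null(clade_set) && length(clade_set) < 2L)
    stop("clade_set needs at least 2 clades")
  structure(list(freq_cutoff = freq_cutoff, ratio_cutoff = ratio_cutoff,
                 clade_set = clade_set),
            class = "divergence_params")
}

#' Relative amino-acid ratio at a single column
#'
#' Divides the query-clade frequency of the query's majority amino acid by
#' that amino acid's frequency in the pooled subject group. No call is
#' made unless the majority amino acid's query frequency strictly exceeds
#' `freq_cutoff` (at any cutoff > 0.5 at most one amino acid can qualify).
#' A qualifying amino acid absent from the subject group yields an
#' infinite ratio; a query column that is all gaps yields `NA`.
#'
#' @param query_freqs Length-20 frequency vector from
#'   [column_frequencies()] for the query clade (all-`NA` when the query
#'   column is all-gap).
#' @param subject_freqs Length-20 frequency vector for the pooled
#'   subjects.
#' @param freq_cutoff Strict query-frequency cutoff.
#' @return One-row data frame: `status` (`all_gap`, `below_cutoff`,
#'   `finite` or `infinite`), `major_aa`, `query_freq`, `subject_freq`,
#'   `ratio` (`NA` only when the query column is all-gap).
#' @export
relative_aa_ratio <- function(query_freqs, subject_freqs,
                              freq_cutoff = 0.8) {
  check_freq_vec <- function(v, who) {
    if (length(v) != 20L) stop(who, " frequency vector must have length 20")
    if (all(is.na(v))) return(invisible())
    if (anyNA(v) || any(v < 0) || abs(sum(v) - 1) > 1e-9)
      stop("invalid ", who, " frequency vector")
  }
  check_freq_vec(query_freqs, "query")
  check_freq_vec(subject_freqs, "subject")
  row <- function(status, major = NA_character_, qf = NA_real_,
                  sf = NA_real_, ratio = NA_real_)
    data.frame(status = status, major_aa = major, query_freq = qf,
               subject_freq = sf, ratio = ratio, stringsAsFactors = FALSE)
  if (all(is.na(query_freqs))) return(row("all_gap"))
  i <- which.max(query_freqs)
  qf <- query_freqs[[i]]
  if (qf <= freq_cutoff) return(row("below_cutoff"))
  aa <- AA20[i]
  # a subject column that is all-gap contributes no residues: the query
  # amino acid does not exist in the subject group
  sf <- if (all(is.na(subject_freqs))) 0 else subject_freqs[[i]]
  if (sf == 0) return(row("infinite", aa, qf, 0, Inf))
  row("finite", aa, qf, sf, qf / sf)
}

#' Call clade-unique residues for one query clade
#'
#' Applies [relative_aa_ratio()] at every alignment column, with the query
#' clade against the pooled remaining clades of `params$clade_set` (all
#' other clades of `partition` when `clade_set` is `NULL`). A position is
#' unique when it is callable and its ratio strictly exceeds
#' `params$ratio_cutoff` or is infinite. Gaps and `X` are ignored
#' throughout.
#'
#' @param alignment Character matrix.
#' @param partition A `clade_partition`.
#' @param query_clade Clade name to use as query.
#' @param params A [divergence_params()] object.
#' @param column_map Optional retained-to-original column map.
#' @return Data frame with one row per column: `clade`, `column`,
#'   `original_column`, `status`, `major_aa`, `query_freq`,
#'   `subject_freq`, `ratio`, `unique`.
#' @export
call_unique_residues <- function(alignment, partition, query_clade,
                                 params = divergence_params(),
                                 column_map = NULL) {
  stopifnot(inherits(partition, "clade_partition"))
  clade_set <- params$clade_set
  if (is.null(clade_set)) clade_set <- names(partition$clades)
  if (!query_clade %in% clade_set)
    stop("query clade '", query_clade, "' not in clade_set")
  missing <- setdiff(clade_set, names(partition$clades))
  if (length(missing))
    stop("clade_set members not in partition: ",
         paste(missing, collapse = ", "))
  query_ids <- partition$clades[[query_clade]]
  subject_ids <- unlist(partition$clades[setdiff(clade_set, query_clade)],
                        use.names = FALSE)
  if (length(query_ids) == 0L) stop("empty query clade")
  if (length(subject_ids) == 0L) stop("empty subject set")
  qf <- column_frequencies(alignment, query_ids)
  sf <- column_frequencies(alignment, subject_ids)
  nc <- ncol(qf$freq)
  calls <- vector("list", nc)
  for (j in seq_len(nc))
    calls[[j]] <- relative_aa_ratio(qf$freq[, j], sf$freq[, j],
                                    params$freq_cutoff)
  out <- do.call(rbind, calls)
  out <- cbind(data.frame(clade = query_clade, column = seq_len(nc),
                          original_column = if (is.null(column_map))
                            seq_len(nc) else column_map,
                          stringsAsFactors = FALSE),
               out)
  out$unique <- !is.na(out$ratio) &
    (is.infinite(out$ratio) | out$ratio > params$ratio_cutoff)
  out
}

#' Iterate unique-residue calls over every clade
#'
#' Runs [call_unique_residues()] once per clade of `params$clade_set` as
#' query, with the pooled remainder of the set as subjects.
#'
#' @inheritParams call_unique_residues
#' @return Named list of per-clade call tables (see
#'   [call_unique_residues()]).
#' @export
iterate_unique_calls <- function(alignment, partition,
                                 params = divergence_params(),
                                 column_map = NULL) {
  clade_set <- params$clade_set
  if (is.null(clade_set)) clade_set <- names(partition$clades)
  if (length(clade_set) < 2L) stop("need at least 2 clades")
  out <- lapply(clade_set, function(cl)
    call_unique_residues(alignment, partition, cl, params, column_map))
  names(out) <- clade_set
  out
}

#' Count unique calls falling within mapped stretch columns
#'
#' @param calls Output of [iterate_unique_calls()].
#' @param columns Integer vector of (trimmed-alignment) stretch columns,
#'   e.g. from [stretch_columns()].
#' @return Named integer vector: unique-call count per clade within the
#'   given columns.
#' @export
count_unique_in_columns <- function(calls, columns) {
  vapply(calls, function(tab)
    sum(tab$unique & tab$column %in% columns), integer(1))
}
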