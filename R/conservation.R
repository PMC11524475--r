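#' Shannon entropy of an amino-acid frequency vector
#'
#' Plug-in estimator `H = -sum(p * log2(p))` over the positive entries of
#' a frequency vector that sums to 1. Ranges from 0 bits for an invariant
#' position to `log2(20) ~ 4.32` bits when all 20 amino acids are equally
#' frequent.
#'
#' @param freqs Numeric vector of non-negative frequencies summing to 1
#'   (within 1e-9).
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(freqs) {
  if (anyNA(freqs)) stop("frequency vector contains NA")
  if (any(freqs < 0)) stop("negative frequency")
  if (abs(sum(freqs) - 1) > 1e-9)
    stop("frequencies must sum to 1 (got ", format(sum(freqs)), ")")
  p <- freqs[freqs > 0]
  -sum(p * log2(p))
}

#' Per-column Shannon entropy profile of a sequence subset
#'
#' Entropies use gap/`X`-excluded frequencies from [column_frequencies()].
#' Columns that are all-gap within the subset are `undefined`. A column is
#' classed `variable` only when its entropy strictly exceeds `threshold`
#' (so H exactly at the threshold is `conserved`).
#'
#' @param alignment Character matrix.
#' @param subset Row ids to profile (default: all rows).
#' @param threshold Variability threshold in bits.
#' @param column_map Optional retained-to-original column map from
#'   [trim_gappy_columns()], used to report original column indices.
#' @return Data frame (class `entropy_profile`) with columns `column`,
#'   `original_column`, `n_effective`, `H_bits`, `class`; `threshold` and
#'   `subset_size` attributes.
#' @export
entropy_profile <- function(alignment, subset = rownames(alignment),
                            threshold = 1.5, column_map = NULL) {
  ft <- column_frequencies(alignment, subset)
  nc <- ncol(ft$freq)
  H <- rep(NA_real_, nc)
  for (j in seq_len(nc))
    if (ft$n_effective[j] > 0L) H[j] <- shannon_entropy(ft$freq[, j])
  cls <- ifelse(is.na(H), "undefined",
                ifelse(H > threshold, "variable", "conserved"))
  out <- data.frame(
    column = seq_len(nc),
    original_column = if (is.null(column_map)) seq_len(nc) else column_map,
    n_effective = ft$n_effective,
    H_bits = H,
    class = cls,
    stringsAsFactors = FALSE
  )
  attr(out, "threshold") <- threshold
  attr(out, "subset_size") <- ft$n_subset
  class(out) <- c("entropy_profile", "data.frame")
  out
}
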