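# Independent brute-force oracles. These deliberately share no code with
# the package: explicit character counting and closed forms only.

ORACLE_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# plug-in Shannon entropy of a character column, gaps/X ignored
oracle_entropy <- function(chars) {
  ch <- chars[chars %in% ORACLE_AA]
  if (length(ch) == 0L) return(NA_real_)
  h <- 0
  for (a in unique(ch)) {
    p <- sum(ch == a) / length(ch)
    h <- h - p * log2(p)
  }
  h
}

# relative amino-acid ratio call on two character columns
oracle_ratio_call <- function(query_chars, subject_chars,
                              freq_cutoff = 0.8, ratio_cutoff = 50) {
  q <- query_chars[query_chars %in% ORACLE_AA]
  if (length(q) == 0L)
    return(list(status = "all_gap", unique = FALSE, ratio = NA_real_))
  best_aa <- NA_character_; best_f <- -1
  for (a in ORACLE_AA) {
    f <- sum(q == a) / length(q)
    if (f > best_f) { best_f <- f; best_aa <- a }
  }
  if (best_f <= freq_cutoff)
    return(list(status = "below_cutoff", unique = FALSE,
                ratio = NA_real_))
  s <- subject_chars[subject_chars %in% ORACLE_AA]
  sf <- if (length(s) == 0L) 0 else sum(s == best_aa) / length(s)
  if (sf == 0)
    return(list(status = "infinite", unique = TRUE, ratio = Inf,
                major = best_aa, qf = best_f))
  r <- best_f / sf
  list(status = "finite", unique = r > ratio_cutoff, ratio = r,
       major = best_aa, qf = best_f, sf = sf)
}

# random alignment column sampler used by the oracle-equivalence tests
random_column <- function(n, gap_prob = 0.15) {
  sample(c(ORACLE_AA, "-", "X"), n, replace = TRUE,
         prob = c(rep((1 - gap_prob) / 21, 20), gap_prob,
                  (1 - gap_prob) / 21))
}

# small aligned family as named character vector -> matrix
aln_from_strings <- function(...) {
  x <- c(...)
  do.call(rbind, strsplit(x, ""))
}

# the eight interface stretch ranges in reference residue numbering
dimer_stretch_ranges <- function() {
  data.frame(
    name = c("1a", "1b", "1c", "1d", "2a", "1e", "2b", "1f"),
    start = c(217L, 238L, 270L, 506L, 528L, 533L, 549L, 559L),
    end = c(220L, 244L, 274L, 513L, 532L, 536L, 554L, 563L))
}
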