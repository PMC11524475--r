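freqs_of <- function(chars) {
  m <- matrix(chars, ncol = 1)
  rownames(m) <- paste0("s", seq_along(chars))
  column_frequencies(m)$freq[, 1]
}

test_that("single-column ratio rules: infinite, finite, NA, below-cutoff", {
  # query fixed R, subject lacking R -> infinite and callable
  r <- relative_aa_ratio(freqs_of(rep("R", 10)),
                         freqs_of(rep(c("A", "K"), 10)))
  expect_equal(r$status, "infinite")
  expect_true(is.infinite(r$ratio))
  expect_equal(r$major_aa, "R")

  # query 0.9 R / subject 0.1 R -> ratio 9
  r <- relative_aa_ratio(freqs_of(c(rep("R", 9), "A")),
                         freqs_of(c("R", rep("A", 9))))
  expect_equal(r$ratio, 9)
  expect_equal(r$status, "finite")

  # all-gap query -> NA
  r <- relative_aa_ratio(freqs_of(rep("-", 6)), freqs_of(rep("A", 6)))
  expect_equal(r$status, "all_gap")
  expect_true(is.na(r$ratio))

  # majority at exactly the frequency cutoff is not callable (strict >)
  r <- relative_aa_ratio(freqs_of(c(rep("R", 8), "A", "K")),
                         freqs_of(rep("A", 10)), freq_cutoff = 0.8)
  expect_equal(r$status, "below_cutoff")

  # subject all-gap counts as absence -> infinite
  r <- relative_aa_ratio(freqs_of(rep("R", 5)), freqs_of(rep("-", 5)))
  expect_equal(r$status, "infinite")

  expect_error(relative_aa_ratio(rep(0.1, 20), rep(0.05, 20)), "invalid")
})

mk_partition_aln <- function(q, s) {
  # q, s: character vectors of equal-length sequences
  seqs <- c(setNames(q, paste0("q", seq_along(q))),
            setNames(s, paste0("s", seq_along(s))))
  list(aln = as_alignment(seqs),
       part = clade_partition(list(Q = names(seqs)[seq_along(q)],
                                   S = names(seqs)[-seq_along(q)])))
}

test_that("unique calls honour strict ratio cutoff and family-wide invariance", {
  # ratio exactly at the cutoff is not unique: qf 1, sf 1/64, cutoff 64
  x <- mk_partition_aln(rep("R", 4), c("R", rep(strrep("A", 1), 63)))
  calls <- call_unique_residues(x$aln, x$part, "Q",
                                divergence_params(ratio_cutoff = 64))
  expect_equal(calls$ratio[1], 64)
  expect_false(calls$unique[1])
  # strictly above passes
  calls <- call_unique_residues(x$aln, x$part, "Q",
                                divergence_params(ratio_cutoff = 63.9))
  expect_true(calls$unique[1])
  # family-wide invariant column: ratio 1, never unique
  y <- mk_partition_aln(rep("W", 5), rep("W", 7))
  calls <- call_unique_residues(y$aln, y$part, "Q")
  expect_equal(calls$ratio[1], 1)
  expect_false(calls$unique[1])
})

test_that("planted sites are called for their own clade only", {
  ps <- data.frame(clade = c(1, 1, 2, 2, 3), column = c(3, 11, 7, 19, 23),
                   clade_residue = c("W", "H", "Q", "M", "F"),
                   background_residue = c("A", "C", "D", "E", "G"))
  fam <- generate_clade_family(
    family_params(n_clades = 3, seqs_per_clade = 15, n_columns = 30,
                  planted_sites = ps, gap_rate = 0.05, seed = 12))
  calls <- iterate_unique_calls(fam$alignment, fam$partition)
  truth <- fam$truth$planted
  for (cl in names(calls))
    expect_setequal(calls[[cl]]$column[calls[[cl]]$unique],
                    truth$column[truth$clade == cl])
  # no call is shared between clades
  all_unique <- unlist(lapply(calls, function(x) x$column[x$unique]))
  expect_equal(anyDuplicated(all_unique), 0)
})

test_that("two-clade iteration computes both directions independently", {
  x <- mk_partition_aln(c("RA", "RA", "RA"), c("KA", "KA", "KA"))
  calls <- iterate_unique_calls(x$aln, x$part)
  expect_named(calls, c("Q", "S"))
  expect_true(calls$Q$unique[1])   # R absent from S
  expect_true(calls$S$unique[1])   # K absent from Q
  expect_false(calls$Q$unique[2])  # shared A
  expect_false(calls$S$unique[2])
})

test_that("raising cutoffs never enlarges the call sets", {
  fam <- generate_clade_family(
    family_params(n_clades = 3, seqs_per_clade = 8, n_columns = 60,
                  background_conservation = 0.3, gap_rate = 0.1,
                  seed = 44))
  uniq_at <- function(rc, fc) {
    calls <- iterate_unique_calls(
      fam$alignment, fam$partition,
      divergence_params(freq_cutoff = fc, ratio_cutoff = rc))
    lapply(calls, function(x) x$column[x$unique])
  }
  callable_at <- function(fc) {
    calls <- iterate_unique_calls(
      fam$alignment, fam$partition,
      divergence_params(freq_cutoff = fc))
    lapply(calls, function(x) x$column[!x$status %in%
                                         c("below_cutoff", "all_gap")])
  }
  u1 <- uniq_at(2, 0.6); u2 <- uniq_at(10, 0.6); u3 <- uniq_at(50, 0.6)
  for (cl in names(u1)) {
    expect_true(all(u2[[cl]] %in% u1[[cl]]))
    expect_true(all(u3[[cl]] %in% u2[[cl]]))
  }
  c1 <- callable_at(0.6); c2 <- callable_at(0.9)
  for (cl in names(c1)) expect_true(all(c2[[cl]] %in% c1[[cl]]))
})

test_that("calls are deterministic and match the brute-force oracle", {
  set.seed(55)
  for (rep in 1:25) {
    nq <- sample(3:12, 1); ns <- sample(3:12, 1); nc <- sample(1:10, 1)
    q <- replicate(nq, paste(random_column(nc), collapse = ""))
    s <- replicate(ns, paste(random_column(nc), collapse = ""))
    x <- mk_partition_aln(q, s)
    calls <- call_unique_residues(x$aln, x$part, "Q")
    calls2 <- call_unique_residues(x$aln, x$part, "Q")
    expect_identical(calls, calls2)
    for (j in seq_len(nc)) {
      o <- oracle_ratio_call(x$aln[x$part$clades$Q, j],
                             x$aln[x$part$clades$S, j])
      expect_identical(calls$unique[j], o$unique)
      expect_identical(calls$status[j], o$status)
      if (o$status %in% c("finite", "infinite")) {
        expect_equal(calls$ratio[j], o$ratio)
        expect_identical(calls$major_aa[j], o$major)
      }
    }
  }
})

test_that("planted-site recovery is perfect at full fixation across seeds", {
  for (seed in 1:5) {
    ps <- data.frame(clade = rep(1:3, each = 2),
                     column = c(4, 40, 12, 33, 21, 48),
                     clade_residue = rep(c("W", "H", "Q"), each = 2),
                     background_residue = rep(c("A", "C", "D"), each = 2),
                     query_fixation = 1, subject_leak = 0)
    fam <- generate_clade_family(
      family_params(n_clades = 3, seqs_per_clade = 12, n_columns = 50,
                    planted_sites = ps, gap_rate = 0.05, seed = seed))
    calls <- iterate_unique_calls(fam$alignment, fam$partition)
    hits <- unlist(lapply(names(calls), function(cl)
      calls[[cl]]$column[calls[[cl]]$unique]))
    expect_setequal(hits, ps$column)
  }
})

test_that("stretch-column intersection counts unique calls per clade", {
  ps <- data.frame(clade = c(1, 1, 2), column = c(3, 8, 5),
                   clade_residue = c("W", "H", "Q"),
                   background_residue = c("A", "C", "D"))
  fam <- generate_clade_family(
    family_params(n_clades = 3, seqs_per_clade = 10, n_columns = 10,
                  planted_sites = ps, gap_rate = 0, seed = 9))
  calls <- iterate_unique_calls(fam$alignment, fam$partition)
  counts <- count_unique_in_columns(calls, columns = c(3, 4, 5))
  expect_equal(unname(counts), c(1L, 1L, 0L))  # col 8 falls outside
})
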