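#' Parameters for the synthetic clade-structured protein family
#'
#' The generator emulates the statistical structure the divergence
#' analysis assumes: a family split into clades, background columns that
#' are either family-wide invariant or uniformly variable, and planted
#' clade-diagnostic polymorphisms at known columns with configurable
#' within-clade fixation and leakage into the other clades.
#'
#' @param n_clades Number of clades (>= 2).
#' @param seqs_per_clade Sequences per clade (>= 2).
#' @param n_columns Alignment width.
#' @param background_conservation Probability that a non-planted column is
#'   invariant family-wide.
#' @param planted_sites `NULL`, or a data frame with columns `clade`
#'   (clade name or 1-based clade index), `column`, `clade_residue`,
#'   `background_residue`, and optionally `query_fixation` (in (0.8, 1],
#'   default 1) and `subject_leak` (in \[0, 0.02), default 0). Planted
#'   columns must be distinct and the two residues different.
#' @param gap_rate Per-character gap probability in \[0, 0.5).
#' @param length_jitter Maximum residues gapped off each sequence end.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A `family_params` list.
#' @export
family_params <- function(n_clades = 3L, seqs_per_clade = 40L,
                          n_columns = 300L, background_conservation = 0.5,
                          planted_sites = NULL, gap_rate = 0.05,
                          length_jitter = 0L, seed = 1L) {
  stopifnot(n_clades >= 2L, seqs_per_clade >= 2L, n_columns >= 1L,
            background_conservation >= 0, background_conservation <= 1,
            gap_rate >= 0, gap_rate < 0.5, length_jitter >= 0L)
  clade_names <- sprintf("clade%02d", seq_len(n_clades))
  if (!is.null(planted_sites)) {
    ps <- as.data.frame(planted_sites, stringsAsFactors = FALSE)
    stopifnot(all(c("clade", "column", "clade_residue",
                    "background_residue") %in% names(ps)))
    if (is.numeric(ps$clade)) ps$clade <- clade_names[ps$clade]
    if (!all(ps$clade %in% clade_names)) stop("unknown clade in planted_sites")
    if (is.null(ps$query_fixation)) ps$query_fixation <- 1
    if (is.null(ps$subject_leak)) ps$subject_leak <- 0
    if (anyDuplicated(ps$column)) stop("planted columns must be distinct")
    if (any(ps$column < 1L | ps$column > n_columns))
      stop("planted column outside alignment")
    if (any(ps$clade_residue == ps$background_residue))
      stop("clade_residue must differ from background_residue")
    if (any(ps$query_fixation <= 0.8 | ps$query_fixation > 1))
      stop("query_fixation must lie in (0.8, 1]")
    if (any(ps$subject_leak < 0 | ps$subject_leak >= 0.02))
      stop("subject_leak must lie in [0, 0.02)")
    stopifnot(all(ps$clade_residue %in% AA20),
              all(ps$background_residue %in% AA20))
    planted_sites <- ps
  }
  structure(list(n_clades = as.integer(n_clades),
                 seqs_per_clade = as.integer(seqs_per_clade),
                 n_columns = as.integer(n_columns),
                 background_conservation = background_conservation,
                 planted_sites = planted_sites,
                 gap_rate = gap_rate,
                 length_jitter = as.integer(length_jitter),
                 seed = as.integer(seed),
                 clade_names = clade_names),
            class = "family_params")
}

## within-clade branches carry low support (poorly resolved, as is typical
## inside shallow clades); only the clade stems are "well-supported", so
## tree-guided clade extraction recovers exactly the generating partition
caterpillar_newick <- function(ids, stem_support = "1.0",
                               inner_support = "0.5") {
  k <- length(ids)
  if (k == 1L) return(ids)
  s <- ids[1L]
  if (k > 2L)
    for (i in 2L:(k - 1L))
      s <- sprintf("(%s,%s)%s", s, ids[i], inner_support)
  sprintf("(%s,%s)%s", s, ids[k], stem_support)
}

#' Generate a clade-structured protein family with planted polymorphisms
#'
#' Background columns are family-wide invariant (a single random residue)
#' with probability `background_conservation`, otherwise drawn uniformly
#' over the 20 amino acids per sequence. At each planted site, sequences
#' of the planted clade carry `clade_residue` with probability
#' `query_fixation` (else `background_residue`); all other sequences carry
#' `clade_residue` with probability `subject_leak` (else
#' `background_residue`). Gaps are then inserted independently per
#' character, and up to `length_jitter` residues are gapped off each end.
#' The companion tree is a star of clades, each clade a caterpillar with
#' support 1.0 on its stem.
#'
#' @param params A [family_params()] object.
#' @return List with `alignment` (character matrix), `partition`
#'   ([clade_partition()]), `tree` (`phylo`), and `truth` (planted sites
#'   as realized, per-column generating model, seed).
#' @export
generate_clade_family <- function(params) {
  stopifnot(inherits(params, "family_params"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(params$seed)
  ncl <- params$n_clades; nps <- params$seqs_per_clade
  nrow_ <- ncl * nps; nc <- params$n_columns
  clade_of_row <- rep(params$clade_names, each = nps)
  ids <- sprintf("%s_seq%03d", clade_of_row,
                 rep(seq_len(nps), times = ncl))
  column_type <- ifelse(stats::runif(nc) < params$background_conservation,
                        "invariant", "uniform")
  invariant_residue <- rep(NA_character_, nc)
  invariant_residue[column_type == "invariant"] <-
    sample(AA20, sum(column_type == "invariant"), replace = TRUE)
  m <- matrix(sample(AA20, nrow_ * nc, replace = TRUE),
              nrow = nrow_, ncol = nc, dimnames = list(ids, NULL))
  inv <- which(column_type == "invariant")
  for (j in inv) m[, j] <- invariant_residue[j]
  ps <- params$planted_sites
  if (!is.null(ps)) {
    column_type[ps$column] <- "planted"
    invariant_residue[ps$column] <- NA_character_
    for (k in seq_len(nrow(ps))) {
      j <- ps$column[k]
      in_clade <- clade_of_row == ps$clade[k]
      m[in_clade, j] <- ifelse(
        stats::runif(sum(in_clade)) < ps$query_fixation[k],
        ps$clade_residue[k], ps$background_residue[k])
      m[!in_clade, j] <- ifelse(
        stats::runif(sum(!in_clade)) < ps$subject_leak[k],
        ps$clade_residue[k], ps$background_residue[k])
    }
  }
  if (params$gap_rate > 0) {
    gaps <- matrix(stats::runif(nrow_ * nc) < params$gap_rate,
                   nrow = nrow_)
    m[gaps] <- "-"
  }
  if (params$length_jitter > 0L) {
    for (i in seq_len(nrow_)) {
      k1 <- sample(0:params$length_jitter, 1L)
      k2 <- sample(0:params$length_jitter, 1L)
      if (k1 > 0L) m[i, seq_len(k1)] <- "-"
      if (k2 > 0L) m[i, (nc - k2 + 1L):nc] <- "-"
    }
  }
  partition <- clade_partition(split(ids, clade_of_row))
  sub <- vapply(params$clade_names,
                function(cl) caterpillar_newick(ids[clade_of_row == cl]),
                character(1))
  tree <- ape::read.tree(text = paste0("(", paste(sub, collapse = ","),
                                       ");"))
  truth <- list(planted = ps, column_type = column_type,
                invariant_residue = invariant_residue, seed = params$seed)
  list(alignment = m, partition = partition, tree = tree, truth = truth)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Write a synthetic family to disk as inspectable standard formats
#'
#' @param family Output of [generate_clade_family()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly. Writes `alignment.fasta`, `tree.nwk`,
#'   `clades.tsv` and `truth.tsv`.
#' @export
write_family <- function(family, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(alignment_to_seqs(family$alignment),
              file.path(dir, "alignment.fasta"))
  ape::write.tree(family$tree, file.path(dir, "tree.nwk"))
  part <- family$partition
  ctab <- data.frame(
    clade = rep(names(part$clades), lengths(part$clades)),
    id = unlist(part$clades, use.names = FALSE))
  utils::write.table(ctab, file.path(dir, "clades.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tr <- family$truth$planted
  if (is.null(tr)) tr <- data.frame(clade = character(0),
                                    column = integer(0),
                                    clade_residue = character(0))
  utils::write.table(tr, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Parameters for a toy two-chain structure with known contacts
#'
#' @param n_residues_per_chain Residues per chain (one CA atom each).
#' @param contact_residue_pairs Two-column matrix or data frame of
#'   (chain A residue, chain B residue) to place in contact.
#' @param cutoff Contact distance cutoff in Angstrom; configured pairs
#'   are placed at `cutoff - 0.5`, all other inter-chain distances exceed
#'   `cutoff + 2`.
#' @param seed Integer seed (kept for interface symmetry; the geometry is
#'   deterministic).
#' @return A `dimer_params` list.
#' @export
dimer_params <- function(n_residues_per_chain = 10L,
                         contact_residue_pairs = NULL,
                         cutoff = 6.0, seed = 1L) {
  stopifnot(n_residues_per_chain >= 1L, cutoff > 0)
  if (!is.null(contact_residue_pairs)) {
    cp <- as.matrix(as.data.frame(contact_residue_pairs))
    storage.mode(cp) <- "integer"
    if (ncol(cp) != 2L) stop("contact_residue_pairs needs 2 columns")
    if (any(cp < 1L | cp > n_residues_per_chain))
      stop("contact pair references an invalid residue number")
    contact_residue_pairs <- cp
  }
  structure(list(n_residues_per_chain = as.integer(n_residues_per_chain),
                 contact_residue_pairs = contact_residue_pairs,
                 cutoff = cutoff, seed = as.integer(seed)),
            class = "dimer_params")
}

#' Generate a toy two-chain structure with known inter-chain contacts
#'
#' Single-CA "residues" are laid out on two widely separated lines; each
#' configured contact pair is realized by moving the chain B atom to
#' exactly `cutoff - 0.5` Angstrom from its chain A partner. The
#' construction is verified by brute force: exactly the configured pairs
#' lie within the cutoff and all other inter-chain distances exceed
#' `cutoff + 2`; geometric infeasibility (e.g. one chain B residue asked
#' to contact two distant chain A residues) is an error.
#'
#' @param params A [dimer_params()] object.
#' @return A `structure3d` with chains `A` and `B`.
#' @export
generate_toy_dimer <- function(params) {
  stopifnot(inherits(params, "dimer_params"))
  n <- params$n_residues_per_chain
  d_contact <- params$cutoff - 0.5
  spacing <- max(12, 2 * (params$cutoff + 2.5))
  xa <- cbind((seq_len(n) - 1L) * spacing, 0, 0)
  xb <- cbind((seq_len(n) - 1L) * spacing, 5 * (params$cutoff + 2), 0)
  cp <- params$contact_residue_pairs
  if (!is.null(cp)) {
    for (k in seq_len(nrow(cp))) {
      a <- cp[k, 1L]; b <- cp[k, 2L]
      prev <- sum(cp[seq_len(k), 1L] == a) - 1L  # earlier pairs on same A
      theta <- prev * (40 * pi / 180)
      xb[b, ] <- xa[a, ] + d_contact * c(0, cos(theta), sin(theta))
    }
  }
  atoms <- data.frame(
    chain = rep(c("A", "B"), each = n),
    resno = rep(seq_len(n), 2L),
    resid = "ALA",
    atom = "CA",
    element = "C",
    x = c(xa[, 1], xb[, 1]), y = c(xa[, 2], xb[, 2]),
    z = c(xa[, 3], xb[, 3]),
    radius = VDW_RADII[["C"]],
    is_protein = TRUE,
    stringsAsFactors = FALSE
  )
  # verify the contact contract by brute force over all inter-chain pairs
  d <- sqrt(outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb))
  want <- matrix(FALSE, n, n)
  if (!is.null(cp)) want[cp] <- TRUE
  ok_contacts <- all(abs(d[want] - d_contact) < 1e-6)
  ok_rest <- all(d[!want] > params$cutoff + 2)
  if (!ok_contacts || !ok_rest)
    stop("requested contact configuration is geometrically infeasible")
  structure3d(atoms)
}
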