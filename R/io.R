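#' @keywords internal
"_PACKAGE"

## Canonical 20-letter amino-acid alphabet, alphabetical. All column
## statistics are computed over this alphabet; '-' (gap) and 'X'
## (ambiguity) are excluded from numerators and denominators alike.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

ALLOWED_CHARS <- c(AA20, "-", "X")

## Van der Waals radii (Angstrom) used for contacts and SASA. Fixed,
## published set so that surface areas are reproducible across runs.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
VDW_DEFAULT <- 1.70

validate_sequences <- function(seqs) {
  if (length(seqs) == 0L) return(invisible(seqs))
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("every sequence must carry a non-empty id")
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  bad <- grepl(paste0("[^", paste(AA20, collapse = ""), "X-]"), seqs)
  if (any(bad))
    stop("illegal characters in sequence(s): ",
         paste(utils::head(ids[bad], 5), collapse = ", "),
         " (allowed: 20 amino acids, '-', 'X')")
  invisible(seqs)
}

#' Read protein sequences from a FASTA file
#'
#' Sequences are upper-cased and the alternative gap character `.` is
#' normalized to `-`. Ids are the first whitespace-delimited token of each
#' header and must be unique. Only the 20 amino-acid letters plus `-` and
#' `X` are accepted.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped).
#' @param require_aligned If `TRUE`, all entries must have equal character
#'   length (an alignment); unequal lengths are an error.
#' @return A named character vector of residue strings, in file order.
#' @export
read_fasta <- function(path, require_aligned = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  seqs <- toupper(as.character(set))
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  names(seqs) <- sub("\\s.*$", "", names(set))
  validate_sequences(seqs)
  if (require_aligned && length(unique(nchar(seqs))) > 1L)
    stop("require_aligned: records have unequal lengths (",
         paste(range(nchar(seqs)), collapse = "-"), ")")
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of residue strings.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  validate_sequences(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq.int(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Ungapped length of each sequence
#'
#' @param seqs Named character vector of residue strings.
#' @return Integer vector of residue counts excluding gaps.
#' @export
ungapped_length <- function(seqs) {
  nchar(gsub("-", "", seqs, fixed = TRUE))
}

#' Convert sequences to an alignment matrix
#'
#' @param seqs Named character vector of equal-length residue strings.
#' @return A character matrix, one row per sequence, rownames = ids.
#' @export
as_alignment <- function(seqs) {
  validate_sequences(seqs)
  if (length(seqs) == 0L) stop("empty alignment")
  if (length(unique(nchar(seqs))) > 1L)
    stop("sequences have unequal lengths; not an alignment")
  if (nchar(seqs[[1]]) == 0L) stop("alignment has zero columns")
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(m) <- names(seqs)
  m
}

#' Collapse an alignment matrix back to sequence strings
#'
#' @param alignment Character matrix as produced by [as_alignment()].
#' @return Named character vector.
#' @export
alignment_to_seqs <- function(alignment) {
  stats::setNames(apply(alignment, 1L, paste, collapse = ""),
                  rownames(alignment))
}

#' Read a phylogenetic tree from a newick file
#'
#' Branch support values, when present as internal node labels, are parsed
#' to numbers in \[0, 1\]; absent supports are recorded as `NA`, never as
#' zero.
#'
#' @param path Path to a newick file.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("malformed newick: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("malformed newick in ", path)
  validate_tree(tree)
  tree
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo tree")
  if (any(!nzchar(tree$tip.label))) stop("empty leaf name in tree")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf names: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  sup <- tree_supports(tree)
  if (any(!is.na(sup) & (sup < 0 | sup > 1)))
    stop("branch supports must lie in [0, 1]")
  invisible(tree)
}

#' Per-internal-node branch supports of a tree
#'
#' @param tree A `phylo` object.
#' @return Numeric vector of length `tree$Nnode`; `NA` where no support is
#'   recorded (including trees without node labels).
#' @export
tree_supports <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  sup <- suppressWarnings(as.numeric(tree$node.label))
  sup[!nzchar(tree$node.label)] <- NA_real_
  sup
}

#' Read a multimeric structure from PDB or mmCIF coordinates
#'
#' Loads the first model only; alternate locations other than blank or 'A'
#' and all hydrogens/deuteriums are discarded. Each heavy atom is assigned
#' a van der Waals radius from a fixed per-element table (C 1.70, N 1.55,
#' O 1.52, S 1.80, P 1.80, default 1.70 Angstrom). Residue numbering is
#' taken verbatim from the file.
#'
#' @param path Path to a coordinate file.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @return A `structure3d` object: a list with an `atoms` data frame
#'   (chain, resno, resid, atom, element, x, y, z, radius, is_protein).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  pdb <- if (format == "cif") bio3d::read.cif(path, verbose = FALSE)
         else bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$alt %in% c("", "A") | is.na(at$alt), , drop = FALSE]
  elem <- toupper(trimws(at$elesy))
  blank <- is.na(elem) | !nzchar(elem)
  if (any(blank))  # fall back on the first letter of the atom name
    elem[blank] <- substr(gsub("[^A-Za-z].*$", "",
                               trimws(at$elety[blank])), 1, 1)
  keep <- !(elem %in% c("H", "D"))
  at <- at[keep, , drop = FALSE]
  elem <- elem[keep]
  if (nrow(at) == 0L) stop("empty structure (no heavy atoms): ", path)
  radius <- unname(VDW_RADII[elem])
  radius[is.na(radius)] <- VDW_DEFAULT
  atoms <- data.frame(
    chain = as.character(at$chain),
    resno = as.integer(at$resno),
    resid = as.character(at$resid),
    atom = trimws(as.character(at$elety)),
    element = elem,
    x = at$x, y = at$y, z = at$z,
    radius = radius,
    is_protein = at$type == "ATOM",
    stringsAsFactors = FALSE
  )
  structure3d(atoms)
}

#' Construct a structure3d object from an atom table
#'
#' @param atoms Data frame with columns chain, resno, resid, atom, element,
#'   x, y, z, radius, is_protein.
#' @return A `structure3d` object.
#' @export
structure3d <- function(atoms) {
  needed <- c("chain", "resno", "resid", "atom", "element",
              "x", "y", "z", "radius", "is_protein")
  if (!all(needed %in% names(atoms)))
    stop("atoms table missing columns: ",
         paste(setdiff(needed, names(atoms)), collapse = ", "))
  if (nrow(atoms) == 0L) stop("empty structure")
  if (any(atoms$radius <= 0)) stop("every atom needs a positive radius")
  obj <- list(atoms = atoms)
  class(obj) <- "structure3d"
  obj
}

#' @export
print.structure3d <- function(x, ...) {
  ch <- table(x$atoms$chain)
  cat("structure3d:", nrow(x$atoms), "heavy atoms in",
      length(ch), "chain(s)\n")
  for (nm in names(ch))
    cat(sprintf("  chain %s: %d atoms, %d residues\n", nm, ch[[nm]],
                length(unique(x$atoms$resno[x$atoms$chain == nm]))))
  invisible(x)
}

#' Write a structure3d object as a minimal PDB file
#'
#' @param struct A `structure3d` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(struct, path) {
  at <- struct$atoms
  rec <- ifelse(at$is_protein, "ATOM  ", "HETATM")
  name4 <- ifelse(nchar(at$atom) >= 4, substr(at$atom, 1, 4),
                  sprintf(" %-3s", at$atom))
  lines <- sprintf("%s%5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec, seq_len(nrow(at)), name4, at$resid, at$chain,
                   at$resno, at$x, at$y, at$z, 1, 0, at$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
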