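#' Construct a clade partition
#'
#' @param clades Named list of character vectors of sequence ids; sets
#'   must be pairwise disjoint.
#' @param unassigned Character vector of ids in no clade.
#' @param failed Optional character vector of clade names for which no
#'   valid branch was found.
#' @return A `clade_partition` object.
#' @export
clade_partition <- function(clades, unassigned = character(0),
                            failed = character(0)) {
  if (length(clades) > 0L &&
      (is.null(names(clades)) || any(!nzchar(names(clades)))))
    stop("clades must be a named list")
  all_ids <- unlist(clades, use.names = FALSE)
  if (anyDuplicated(all_ids))
    stop("clade sets are not pairwise disjoint: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  if (length(intersect(all_ids, unassigned)))
    stop("ids both assigned and unassigned")
  structure(list(clades = clades, unassigned = unassigned, failed = failed),
            class = "clade_partition")
}

#' @export
print.clade_partition <- function(x, ...) {
  cat("clade_partition:", length(x$clades), "clades,",
      length(x$unassigned), "unassigned\n")
  for (nm in names(x$clades))
    cat(sprintf("  %s: %d sequences\n", nm, length(x$clades[[nm]])))
  if (length(x$failed))
    cat("  failed (inseparable/unsupported):",
        paste(x$failed, collapse = ", "), "\n")
  invisible(x)
}

#' Keep sequences whose ungapped length lies within a range
#'
#' Bounds are inclusive on both ends; order is preserved.
#'
#' @param records Named character vector of (ungapped) sequences.
#' @param min,max Length bounds in residues.
#' @return The filtered named character vector.
#' @export
filter_full_length <- function(records, min = 750L, max = 950L) {
  stopifnot(min < max)
  len <- ungapped_length(records)
  records[len >= min & len <= max]
}

#' Keep sequences whose annotated domain span lies within a length range
#'
#' The domain span of a record is `end - start + 1` from its entry in
#' `domain_ranges` (1-based, inclusive, in ungapped sequence coordinates).
#' Records without an annotated range are dropped and reported.
#'
#' @param records Named character vector of (ungapped) sequences.
#' @param domain_ranges Data frame with columns `id`, `start`, `end`.
#' @param min,max Span bounds in residues (inclusive).
#' @return List with `records` (kept, order preserved) and `dropped`
#'   (data frame of id and reason).
#' @export
filter_domain_length <- function(records, domain_ranges,
                                 min = 300L, max = 400L) {
  stopifnot(min < max,
            all(c("id", "start", "end") %in% names(domain_ranges)))
  idx <- match(names(records), domain_ranges$id)
  span <- domain_ranges$end[idx] - domain_ranges$start[idx] + 1L
  len <- ungapped_length(records)
  oob <- !is.na(idx) & (domain_ranges$start[idx] < 1L |
                          domain_ranges$end[idx] > len)
  if (any(oob))
    stop("domain range outside sequence bounds for: ",
         paste(names(records)[oob], collapse = ", "))
  keep <- !is.na(idx) & span >= min & span <= max
  reason <- ifelse(is.na(idx), "no_domain_range",
                   ifelse(span < min, "span_too_short", "span_too_long"))
  dropped <- data.frame(id = names(records)[!keep],
                        reason = reason[!keep],
                        stringsAsFactors = FALSE)
  list(records = records[keep], dropped = dropped)
}

#' Collapse exact duplicate sequences
#'
#' Only full-length exact identity is collapsed; the representative is the
#' first occurrence in input order. Idempotent. (Unlike CD-HIT at
#' `-c 1.00`, a sequence identical to a proper substring of another is
#' kept.)
#'
#' @param records Named character vector of (ungapped) sequences.
#' @return List with `records` (survivors, order preserved) and
#'   `duplicate_map` (named list: representative id -> dropped member
#'   ids; only groups with duplicates appear).
#' @export
deduplicate <- function(records) {
  first <- !duplicated(unname(records))
  reps <- records[first]
  dup_map <- list()
  if (any(!first)) {
    rep_of <- names(reps)[match(records[!first], reps)]
    dup_map <- split(names(records)[!first], rep_of)
    dup_map <- dup_map[unique(rep_of)]
  }
  list(records = reps, duplicate_map = dup_map)
}

node_tip_sets <- function(tree) {
  n <- length(tree$tip.label)
  sets <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) sets[[i]] <- i
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1L]; ch <- edge[k, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

#' Extract named clades from a tree using reference members
#'
#' For each clade name, finds the smallest internal branch that (a)
#' contains all of that clade's reference leaves, (b) contains no
#' reference of any other clade, and (c) is well supported (support >=
#' `support_threshold`). The leaf set of that branch becomes the clade;
#' leaves in no selected branch are unassigned. When the tree carries no
#' support values at all, condition (c) is waived; when supports are
#' present, a branch lacking one (e.g. the root) fails it. Clades whose
#' references cannot be separated from other clades' references by any
#' qualifying branch are reported in `failed` and their leaves left
#' unassigned.
#'
#' @param tree A `phylo` object.
#' @param reference_map Named list: clade name -> character vector of
#'   reference leaf ids.
#' @param support_threshold Minimum branch support for "well-supported".
#' @return A [clade_partition()].
#' @export
extract_clades <- function(tree, reference_map, support_threshold = 0.8) {
  validate_tree(tree)
  tips <- tree$tip.label
  refs <- unlist(reference_map, use.names = FALSE)
  if (!all(refs %in% tips))
    stop("reference ids not in tree: ",
         paste(setdiff(refs, tips), collapse = ", "))
  n <- length(tips)
  sets <- node_tip_sets(tree)
  internal <- (n + 1L):(n + tree$Nnode)
  sup <- tree_supports(tree)
  have_supports <- any(!is.na(sup))
  ref_idx <- lapply(reference_map, function(ids) match(ids, tips))
  clades <- list()
  failed <- character(0)
  for (cl in names(reference_map)) {
    own <- ref_idx[[cl]]
    other <- unlist(ref_idx[setdiff(names(reference_map), cl)])
    best <- NULL
    for (nd in internal) {
      leaves <- sets[[nd]]
      if (!all(own %in% leaves)) next
      if (any(other %in% leaves)) next
      if (have_supports) {
        s <- sup[nd - n]
        if (is.na(s) || s < support_threshold) next
      }
      if (is.null(best) || length(leaves) < length(best)) best <- leaves
    }
    if (is.null(best)) failed <- c(failed, cl)
    else clades[[cl]] <- tips[sort(best)]
  }
  if (length(failed))
    warning("no qualifying branch for clade(s): ",
            paste(failed, collapse = ", "),
            "; their leaves are unassigned")
  assigned <- unlist(clades, use.names = FALSE)
  if (anyDuplicated(assigned))
    stop("selected clade branches overlap; check reference_map")
  clade_partition(clades,
                  unassigned = setdiff(tips, assigned),
                  failed = failed)
}

#' Read a clade partition from a two-column TSV (clade, id)
#'
#' @param path TSV file with a header row and columns `clade`, `id`.
#' @param all_ids Optional universe of ids; ids absent from the table
#'   become `unassigned`.
#' @return A [clade_partition()].
#' @export
read_clades_tsv <- function(path, all_ids = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  stopifnot(all(c("clade", "id") %in% names(tab)))
  clades <- split(tab$id, tab$clade)
  unassigned <- if (is.null(all_ids)) character(0)
                else setdiff(all_ids, tab$id)
  clade_partition(clades, unassigned)
}
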