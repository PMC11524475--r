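config_digest <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(config[order(names(config))]), tf)
  unname(tools::md5sum(tf))
}

file_digests <- function(paths) {
  paths <- paths[!vapply(paths, is.null, logical(1))]
  paths <- unlist(paths)
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

write_tsv_stamped <- function(tab, path, digest) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_digest: ", digest), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

format_ratio <- function(r, status) {
  ifelse(status == "all_gap", "NA",
         ifelse(status == "below_cutoff", ".",
                ifelse(is.infinite(r), "INF", sprintf("%.6g", r))))
}

#' Read a flat key = value pipeline configuration file
#'
#' Lines are `key = value`; `#` starts a comment; keys with comma-separated
#' values become character vectors; numeric-looking values are converted.
#'
#' @param path Configuration file.
#' @return Named list.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) stop("malformed config line(s): ",
                     paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[`, character(1), 2L))
  vals <- trimws(vapply(kv, `[`, character(1), 3L))
  out <- lapply(vals, function(v) {
    if (grepl(",", v)) v <- trimws(strsplit(v, ",")[[1]])
    num <- suppressWarnings(as.numeric(v))
    if (!anyNA(num)) num else v
  })
  stats::setNames(out, keys)
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("[stage ", stage, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the sequence-divergence pipeline end to end
#'
#' Stages, in order: read aligned FASTA; optional full-length filter and
#' exact deduplication on the ungapped rows; clade assignment (from a
#' clades TSV, or a newick tree plus reference-map TSV); gappy-column
#' trimming; stretch/motif mapping onto the trimmed alignment; per-subset
#' entropy profiles (all sequences and each clade); per-clade
#' unique-residue calls. Writes TSV reports plus a JSON provenance
#' manifest; reruns with identical config and inputs are byte-identical.
#'
#' @param config Named list (or path via [read_pipeline_config()]) with
#'   entries: `alignment` (aligned FASTA path); one of `clades_tsv` or
#'   both `tree` and `reference_map_tsv`; optional `reference_id` +
#'   `stretch_ranges_tsv` (columns name/start/end in reference residue
#'   numbering); optional `full_length_min`/`full_length_max`,
#'   `deduplicate` (logical); `gap_threshold` (default 0.9);
#'   `entropy_threshold` (default 1.5); `freq_cutoff` (default 0.8);
#'   `ratio_cutoff` (default 50); optional `clade_set`;
#'   `support_threshold` (default 0.8); `out_dir`.
#' @return Invisibly, a list with the in-memory results (`alignment`,
#'   `partition`, `stretches`, `entropy`, `calls`, `unique_in_stretches`,
#'   `out_dir`).
#' @export
run_divergence_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- read_pipeline_config(config)
  if (is.null(config$alignment))
    stop("[stage config] config$alignment (aligned FASTA) is required")
  if (is.null(config$out_dir))
    stop("[stage config] config$out_dir is required")
  digest <- config_digest(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  seqs <- pipeline_stage("read_alignment",
                         read_fasta(config$alignment, require_aligned = TRUE))
  curation <- data.frame(id = character(0), action = character(0))
  if (!is.null(config$full_length_min)) {
    kept <- pipeline_stage("full_length_filter", {
      ungapped <- stats::setNames(gsub("-", "", seqs, fixed = TRUE),
                                  names(seqs))
      names(filter_full_length(ungapped, config$full_length_min,
                               config$full_length_max))
    })
    curation <- rbind(curation,
                      data.frame(id = setdiff(names(seqs), kept),
                                 action = "dropped_length"))
    seqs <- seqs[kept]
  }
  if (isTRUE(config$deduplicate) ||
      identical(config$deduplicate, "true")) {
    dd <- pipeline_stage("deduplicate", {
      ungapped <- stats::setNames(gsub("-", "", seqs, fixed = TRUE),
                                  names(seqs))
      deduplicate(ungapped)
    })
    dropped <- setdiff(names(seqs), names(dd$records))
    curation <- rbind(curation,
                      data.frame(id = dropped,
                                 action = "dropped_duplicate"))
    seqs <- seqs[names(dd$records)]
  }
  aln <- pipeline_stage("alignment_matrix", as_alignment(seqs))

  partition <- pipeline_stage("clade_assignment", {
    if (!is.null(config$clades_tsv)) {
      read_clades_tsv(config$clades_tsv, all_ids = rownames(aln))
    } else if (!is.null(config$tree) &&
               !is.null(config$reference_map_tsv)) {
      tree <- read_newick(config$tree)
      rm_tab <- utils::read.delim(config$reference_map_tsv,
                                  stringsAsFactors = FALSE,
                                  comment.char = "#")
      extract_clades(tree, split(rm_tab$id, rm_tab$clade),
                     support_threshold =
                       if (is.null(config$support_threshold)) 0.8
                       else config$support_threshold)
    } else {
      stop("need clades_tsv, or tree plus reference_map_tsv")
    }
  })
  # keep only clade members present in the (possibly curated) alignment
  partition <- clade_partition(
    lapply(partition$clades, intersect, rownames(aln)),
    unassigned = intersect(partition$unassigned, rownames(aln)),
    failed = partition$failed)

  gap_threshold <- if (is.null(config$gap_threshold)) 0.9
                   else config$gap_threshold
  trimmed <- pipeline_stage("trim",
                            trim_gappy_columns(aln, gap_threshold))

  stretches <- NULL
  scols <- integer(0)
  if (!is.null(config$stretch_ranges_tsv)) {
    if (is.null(config$reference_id))
      stop("[stage stretch_map] reference_id required with stretch_ranges_tsv")
    stretches <- pipeline_stage("stretch_map", {
      ranges <- utils::read.delim(config$stretch_ranges_tsv,
                                  stringsAsFactors = FALSE,
                                  comment.char = "#")
      map_reference_ranges(aln, config$reference_id, ranges,
                           column_map = trimmed$column_map)
    })
    scols <- stretch_columns(stretches)
  }

  ethr <- if (is.null(config$entropy_threshold)) 1.5
          else config$entropy_threshold
  subsets <- c(list(all = rownames(trimmed$alignment)),
               partition$clades)
  entropy <- pipeline_stage("entropy", lapply(subsets, function(ids)
    entropy_profile(trimmed$alignment, ids, threshold = ethr,
                    column_map = trimmed$column_map)))

  params <- divergence_params(
    freq_cutoff = if (is.null(config$freq_cutoff)) 0.8
                  else config$freq_cutoff,
    ratio_cutoff = if (is.null(config$ratio_cutoff)) 50
                   else config$ratio_cutoff,
    clade_set = config$clade_set)
  calls <- pipeline_stage("unique_residues",
                          iterate_unique_calls(trimmed$alignment,
                                               partition, params,
                                               trimmed$column_map))
  unique_in_stretches <- if (length(scols))
    count_unique_in_columns(calls, scols) else NULL

  ## reports
  write_tsv_stamped(curation, file.path(out_dir, "curation_report.tsv"),
                    digest)
  write_fasta(alignment_to_seqs(trimmed$alignment),
              file.path(out_dir, "trimmed_alignment.fasta"))
  if (!is.null(stretches)) {
    smap <- do.call(rbind, lapply(stretches, function(s)
      data.frame(name = s$name, reference_start = s$start,
                 reference_end = s$end, column = s$columns,
                 original_column = s$original_columns)))
    write_tsv_stamped(smap, file.path(out_dir, "stretch_map.tsv"), digest)
  }
  for (nm in names(entropy)) {
    tab <- entropy[[nm]]
    tab$H_bits <- ifelse(is.na(tab$H_bits), "NA",
                         sprintf("%.6f", tab$H_bits))
    write_tsv_stamped(tab,
                      file.path(out_dir,
                                sprintf("entropy_%s.tsv", nm)), digest)
  }
  for (nm in names(calls)) {
    tab <- calls[[nm]]
    in_stretch <- tab$column %in% scols
    smatch <- rep(NA_character_, nrow(tab))
    if (!is.null(stretches))
      for (s in stretches) smatch[tab$column %in% s$columns] <- s$name
    out_tab <- data.frame(
      clade = tab$clade, column = tab$column,
      original_column = tab$original_column,
      stretch_name = smatch,
      major_aa = ifelse(is.na(tab$major_aa), ".", tab$major_aa),
      query_freq = ifelse(is.na(tab$query_freq), ".",
                          sprintf("%.4f", tab$query_freq)),
      subject_freq = ifelse(is.na(tab$subject_freq), ".",
                            sprintf("%.4f", tab$subject_freq)),
      ratio = format_ratio(tab$ratio, tab$status),
      unique = tab$unique)
    write_tsv_stamped(out_tab,
                      file.path(out_dir,
                                sprintf("unique_residues_%s.tsv", nm)),
                      digest)
  }
  manifest <- list(
    tool = "nrcdiverge",
    version = as.character(utils::packageVersion("nrcdiverge")),
    config_digest = digest,
    config = config[order(names(config))],
    inputs = file_digests(config[c("alignment", "clades_tsv", "tree",
                                   "reference_map_tsv",
                                   "stretch_ranges_tsv")]),
    unique_in_stretches = as.list(unique_in_stretches))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(alignment = trimmed$alignment,
                 column_map = trimmed$column_map,
                 partition = partition, stretches = stretches,
                 entropy = entropy, calls = calls,
                 unique_in_stretches = unique_in_stretches,
                 out_dir = out_dir))
}

#' Run the structure-interface pipeline
#'
#' Reads a two-protomer structure, extracts inter-chain contacts at the
#' distance cutoff, groups them into stretches when domain boundaries are
#' supplied (skipped with a warning otherwise), and computes per-protomer
#' and total buried surface area. Writes TSV reports and a JSON manifest.
#'
#' @param config Named list (or config-file path) with: `structure`
#'   (PDB/mmCIF path), `chain_a`, `chain_b`, optional `cutoff` (default
#'   6.0), `probe_radius` (1.4), `sphere_points` (960),
#'   `domain_boundaries_tsv` (columns chain/domain/start/end),
#'   `include_ligands` (default FALSE), `out_dir`.
#' @return Invisibly, list with `interface`, `stretches` (or `NULL`),
#'   `bsa`, `out_dir`.
#' @export
run_interface_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- read_pipeline_config(config)
  for (need in c("structure", "chain_a", "chain_b", "out_dir"))
    if (is.null(config[[need]]))
      stop("[stage config] config$", need, " is required")
  digest <- config_digest(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cutoff <- if (is.null(config$cutoff)) 6.0 else config$cutoff
  probe <- if (is.null(config$probe_radius)) 1.4 else config$probe_radius
  npts <- if (is.null(config$sphere_points)) 960L
          else as.integer(config$sphere_points)
  protein_only <- !isTRUE(config$include_ligands)

  struct <- pipeline_stage("read_structure",
                           read_structure(config$structure))
  iface <- pipeline_stage("contacts",
                          find_interface_residues(struct, config$chain_a,
                                                  config$chain_b, cutoff,
                                                  protein_only))
  write_tsv_stamped(iface$pairs, file.path(out_dir, "contacts.tsv"),
                    digest)

  stretches <- NULL
  if (!is.null(config$domain_boundaries_tsv)) {
    stretches <- pipeline_stage("stretches", {
      db <- utils::read.delim(config$domain_boundaries_tsv,
                              stringsAsFactors = FALSE,
                              comment.char = "#")
      derive_stretches(iface, split(db[c("domain", "start", "end")],
                                    db$chain))
    })
    write_tsv_stamped(stretches, file.path(out_dir, "stretches.tsv"),
                      digest)
  } else {
    warning("no domain boundaries supplied; stretch grouping skipped")
  }

  bsa <- pipeline_stage("bsa",
                        buried_surface_area(struct, config$chain_a,
                                            config$chain_b, probe, npts,
                                            protein_only))
  bsa_tab <- data.frame(chain = c(names(bsa$per_protomer), "total"),
                        bsa_A2 = sprintf("%.2f", c(bsa$per_protomer,
                                                   bsa$total)))
  write_tsv_stamped(bsa_tab, file.path(out_dir, "bsa.tsv"), digest)
  manifest <- list(
    tool = "nrcdiverge",
    version = as.character(utils::packageVersion("nrcdiverge")),
    config_digest = digest,
    config = config[order(names(config))],
    inputs = file_digests(config[c("structure",
                                   "domain_boundaries_tsv")]),
    n_contact_pairs = nrow(iface$pairs),
    bsa_total_A2 = bsa$total)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(interface = iface, stretches = stretches, bsa = bsa,
                 out_dir = out_dir))
}
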