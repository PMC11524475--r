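chain_atoms <- function(struct, chain, protein_only = TRUE) {
  at <- struct$atoms
  at <- at[at$chain == chain & (!protein_only | at$is_protein), ,
           drop = FALSE]
  if (nrow(at) == 0L) stop("chain '", chain, "' has no atoms")
  at
}

cross_dist2 <- function(xa, xb) {
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  d2[d2 < 0] <- 0
  d2
}

#' Inter-chain contact residues at a distance cutoff
#'
#' A residue pair (one residue per chain) is a contact when the minimum
#' distance over all of its heavy-atom pairs is less than or equal to
#' `cutoff`. The permissive any-heavy-atom reading accommodates both
#' short- and long-range interacting residues.
#'
#' @param struct A `structure3d`.
#' @param chain_a,chain_b Chain identifiers.
#' @param cutoff Distance cutoff in Angstrom.
#' @param protein_only Restrict to protein (ATOM) records.
#' @return List of class `interface`: `pairs` (data frame `res_a`,
#'   `res_b`, `min_dist`), `residues_a`, `residues_b` (sorted residue
#'   numbers), plus the chains and cutoff used.
#' @export
find_interface_residues <- function(struct, chain_a, chain_b,
                                    cutoff = 6.0, protein_only = TRUE) {
  stopifnot(inherits(struct, "structure3d"), cutoff > 0)
  A <- chain_atoms(struct, chain_a, protein_only)
  B <- chain_atoms(struct, chain_b, protein_only)
  xb <- as.matrix(B[, c("x", "y", "z")])
  pairs <- list()
  block <- 2000L
  for (s in seq.int(1L, nrow(A), by = block)) {
    idx <- s:min(s + block - 1L, nrow(A))
    d2 <- cross_dist2(as.matrix(A[idx, c("x", "y", "z")]), xb)
    hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
    if (nrow(hit))
      pairs[[length(pairs) + 1L]] <- data.frame(
        res_a = A$resno[idx[hit[, 1L]]],
        res_b = B$resno[hit[, 2L]],
        dist = sqrt(d2[hit]))
  }
  if (length(pairs)) {
    all_hits <- do.call(rbind, pairs)
    agg <- stats::aggregate(dist ~ res_a + res_b, data = all_hits,
                            FUN = min)
    agg <- agg[order(agg$res_a, agg$res_b), , drop = FALSE]
    names(agg)[3L] <- "min_dist"
    rownames(agg) <- NULL
  } else {
    agg <- data.frame(res_a = integer(0), res_b = integer(0),
                      min_dist = numeric(0))
  }
  structure(list(pairs = agg,
                 residues_a = sort(unique(agg$res_a)),
                 residues_b = sort(unique(agg$res_b)),
                 chain_a = chain_a, chain_b = chain_b, cutoff = cutoff),
            class = "interface")
}

#' @export
print.interface <- function(x, ...) {
  cat(sprintf("interface %s:%s at %.1f A: %d residue pairs (%d | %d residues)\n",
              x$chain_a, x$chain_b, x$cutoff, nrow(x$pairs),
              length(x$residues_a), length(x$residues_b)))
  invisible(x)
}

domain_of <- function(resno, boundaries) {
  # boundaries: data frame domain/start/end for one chain
  hits <- boundaries$domain[resno >= boundaries$start &
                              resno <= boundaries$end]
  hits
}

#' Group interface residues into named stretches
#'
#' Each interface residue is labeled by the domain(s) of the partner-chain
#' residues it contacts; a residue contacting several partner domains
#' joins every relevant class (flagged in `multi_domain`). Within each
#' (own-domain, partner-domain) class, maximal runs of consecutive
#' residue numbers form stretches. Stretch families are the unordered
#' domain pairs, numbered by ascending first residue; stretches are
#' lettered a, b, c... by ascending start within each family and chain
#' (so an NB-to-LRR family yields names like `1a`, and an LRR-to-LRR
#' stacking family `2a`).
#'
#' @param interface Output of [find_interface_residues()].
#' @param domain_boundaries Named list (one entry per chain) of data
#'   frames with columns `domain`, `start`, `end`; ranges must not
#'   overlap within a chain and must cover every interface residue.
#' @return Data frame: `chain`, `name`, `own_domain`, `partner_domain`,
#'   `start`, `end`, `n_residues`, `multi_domain`.
#' @export
derive_stretches <- function(interface, domain_boundaries) {
  stopifnot(inherits(interface, "interface"))
  chains <- c(interface$chain_a, interface$chain_b)
  if (!all(chains %in% names(domain_boundaries)))
    stop("domain_boundaries missing chain(s): ",
         paste(setdiff(chains, names(domain_boundaries)), collapse = ", "))
  pr <- interface$pairs
  classify <- function(own_chain, partner_chain, own_col, partner_col) {
    own_b <- domain_boundaries[[own_chain]]
    par_b <- domain_boundaries[[partner_chain]]
    res <- sort(unique(pr[[own_col]]))
    rows <- list()
    for (r in res) {
      own_dom <- domain_of(r, own_b)
      if (length(own_dom) == 0L)
        stop("interface residue ", own_chain, ":", r,
             " outside all domain ranges")
      partners <- unique(pr[[partner_col]][pr[[own_col]] == r])
      par_dom <- unique(unlist(lapply(partners, domain_of, par_b)))
      if (length(par_dom) == 0L)
        stop("partner residue of ", own_chain, ":", r,
             " outside all domain ranges")
      for (pd in par_dom)
        rows[[length(rows) + 1L]] <- data.frame(
          chain = own_chain, resno = r, own_domain = own_dom[1L],
          partner_domain = pd, multi_domain = length(par_dom) > 1L,
          stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }
  lab <- rbind(classify(chains[1L], chains[2L], "res_a", "res_b"),
               classify(chains[2L], chains[1L], "res_b", "res_a"))
  if (is.null(lab) || nrow(lab) == 0L)
    return(data.frame(chain = character(0), name = character(0),
                      own_domain = character(0),
                      partner_domain = character(0), start = integer(0),
                      end = integer(0), n_residues = integer(0),
                      multi_domain = logical(0)))
  # maximal runs of consecutive residues within chain x class
  lab$family_key <- apply(cbind(pmin(lab$own_domain, lab$partner_domain),
                                pmax(lab$own_domain, lab$partner_domain)),
                          1L, paste, collapse = "|")
  out <- list()
  for (key in split(seq_len(nrow(lab)),
                    paste(lab$chain, lab$own_domain, lab$partner_domain,
                          sep = "\r"))) {
    sub <- lab[key, , drop = FALSE]
    res <- sort(unique(sub$resno))
    run <- cumsum(c(1L, diff(res) != 1L))
    for (g in split(res, run)) {
      out[[length(out) + 1L]] <- data.frame(
        chain = sub$chain[1L],
        own_domain = sub$own_domain[1L],
        partner_domain = sub$partner_domain[1L],
        family_key = sub$family_key[1L],
        start = min(g), end = max(g), n_residues = length(g),
        multi_domain = any(sub$multi_domain[sub$resno %in% g]),
        stringsAsFactors = FALSE)
    }
  }
  st <- do.call(rbind, out)
  # family numbering by ascending first residue across chains
  fam_start <- tapply(st$start, st$family_key, min)
  fam_no <- stats::setNames(rank(fam_start, ties.method = "first"),
                            names(fam_start))
  st$family <- fam_no[st$family_key]
  st <- st[order(st$chain, st$family, st$start), , drop = FALSE]
  st$name <- NA_character_
  for (ch in unique(st$chain))
    for (f in unique(st$family)) {
      i <- which(st$chain == ch & st$family == f)
      st$name[i] <- paste0(f, letters[seq_along(i)])
    }
  rownames(st) <- NULL
  st[, c("chain", "name", "own_domain", "partner_domain", "start", "end",
         "n_residues", "multi_domain")]
}

fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

sasa_atoms <- function(xyz, radii, probe_radius = 1.4,
                       sphere_points = 960L) {
  stopifnot(sphere_points >= 100L, probe_radius >= 0, all(radii > 0))
  R <- radii + probe_radius
  pts <- fibonacci_sphere(sphere_points)
  n <- nrow(xyz)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    di2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(di2 < (R + R[i])^2)
    nb <- nb[nb != i]
    if (length(nb) == 0L) {
      areas[i] <- 4 * pi * R[i]^2
      next
    }
    sp <- pts * R[i]
    sp[, 1] <- sp[, 1] + xyz[i, 1]
    sp[, 2] <- sp[, 2] + xyz[i, 2]
    sp[, 3] <- sp[, 3] + xyz[i, 3]
    occluded <- rep(FALSE, sphere_points)
    for (j in nb) {
      free <- !occluded
      if (!any(free)) break
      dj2 <- (sp[free, 1] - xyz[j, 1])^2 + (sp[free, 2] - xyz[j, 2])^2 +
        (sp[free, 3] - xyz[j, 3])^2
      occluded[free] <- dj2 < R[j]^2
    }
    areas[i] <- mean(!occluded) * 4 * pi * R[i]^2
  }
  areas
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA with a deterministic Fibonacci spiral point lattice (no
#' randomness): per atom, the fraction of points on the solvent-expanded
#' sphere of radius `vdW + probe` not inside any neighbour's expanded
#' sphere, times the sphere area.
#'
#' @param struct A `structure3d` (or subset of its atoms).
#' @param probe_radius Solvent probe radius in Angstrom.
#' @param sphere_points Number of lattice points per atom (>= 100).
#' @param protein_only Restrict to protein (ATOM) records, excluding
#'   ligands/heteroatoms.
#' @return List with `atom_area` (per retained atom, Angstrom^2),
#'   `residue_area` (data frame chain/resno/area) and `total`.
#' @export
sasa <- function(struct, probe_radius = 1.4, sphere_points = 960L,
                 protein_only = TRUE) {
  stopifnot(inherits(struct, "structure3d"))
  at <- struct$atoms
  if (protein_only) at <- at[at$is_protein, , drop = FALSE]
  if (nrow(at) == 0L) stop("no atoms selected")
  areas <- sasa_atoms(as.matrix(at[, c("x", "y", "z")]), at$radius,
                      probe_radius, sphere_points)
  res <- stats::aggregate(areas,
                          by = list(chain = at$chain, resno = at$resno),
                          FUN = sum)
  names(res)[3L] <- "area"
  res <- res[order(res$chain, res$resno), , drop = FALSE]
  rownames(res) <- NULL
  list(atom_area = areas, residue_area = res, total = sum(areas))
}

#' Buried surface area of a two-chain complex
#'
#' Per protomer, BSA = SASA of the isolated chain minus SASA of the same
#' atoms within the complex; the total is the sum over both protomers.
#'
#' @param struct A `structure3d` containing both chains.
#' @param chain_a,chain_b Chain identifiers.
#' @param probe_radius,sphere_points,protein_only Passed to [sasa()].
#' @return List with `per_protomer` (named numeric, Angstrom^2) and
#'   `total`.
#' @export
buried_surface_area <- function(struct, chain_a, chain_b,
                                probe_radius = 1.4, sphere_points = 960L,
                                protein_only = TRUE) {
  A <- chain_atoms(struct, chain_a, protein_only)
  B <- chain_atoms(struct, chain_b, protein_only)
  both <- rbind(A, B)
  xyz <- as.matrix(both[, c("x", "y", "z")])
  cplx <- sasa_atoms(xyz, both$radius, probe_radius, sphere_points)
  alone_a <- sasa_atoms(as.matrix(A[, c("x", "y", "z")]), A$radius,
                        probe_radius, sphere_points)
  alone_b <- sasa_atoms(as.matrix(B[, c("x", "y", "z")]), B$radius,
                        probe_radius, sphere_points)
  ia <- seq_len(nrow(A)); ib <- nrow(A) + seq_len(nrow(B))
  per <- c(sum(alone_a) - sum(cplx[ia]), sum(alone_b) - sum(cplx[ib]))
  names(per) <- c(chain_a, chain_b)
  list(per_protomer = per, total = sum(per))
}
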