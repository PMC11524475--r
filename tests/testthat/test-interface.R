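two_atom_struct <- function(d) {
  structure3d(data.frame(
    chain = c("A", "B"), resno = 1L, resid = "ALA", atom = "CA",
    element = "C", x = c(0, d), y = 0, z = 0, radius = 1.7,
    is_protein = TRUE))
}

test_that("contact detection is inclusive at the cutoff boundary", {
  expect_equal(nrow(find_interface_residues(two_atom_struct(5.9),
                                            "A", "B", 6)$pairs), 1)
  expect_equal(nrow(find_interface_residues(two_atom_struct(6.0),
                                            "A", "B", 6)$pairs), 1)
  expect_equal(nrow(find_interface_residues(two_atom_struct(6.1),
                                            "A", "B", 6)$pairs), 0)
  expect_error(find_interface_residues(two_atom_struct(5), "A", "C", 6),
               "no atoms")
})

test_that("contacts use the minimum heavy-atom distance per residue pair", {
  # residue A1 has two atoms; only the closer one is within the cutoff
  st <- structure3d(data.frame(
    chain = c("A", "A", "B"), resno = c(1L, 1L, 1L), resid = "ALA",
    atom = c("CA", "CB", "CA"), element = "C",
    x = c(0, 3, 5.5), y = 0, z = 0, radius = 1.7, is_protein = TRUE))
  iface <- find_interface_residues(st, "A", "B", 6)
  expect_equal(iface$pairs$min_dist, 2.5)
  # symmetry: swapping the chains transposes the pair set
  rev_iface <- find_interface_residues(st, "B", "A", 6)
  expect_equal(rev_iface$pairs[, c("res_a", "res_b")],
               iface$pairs[, c("res_b", "res_a")],
               ignore_attr = TRUE)
})

test_that("interface residue sets grow monotonically with the cutoff", {
  cp <- cbind(c(1L, 2L, 4L), c(1L, 3L, 4L))
  td <- generate_toy_dimer(dimer_params(n_residues_per_chain = 6,
                                        contact_residue_pairs = cp,
                                        cutoff = 6))
  prev <- integer(0)
  for (cut in c(4, 5.5, 6, 9)) {
    res <- find_interface_residues(td, "A", "B", cut)$residues_a
    expect_true(all(prev %in% res))
    prev <- res
  }
})

test_that("stretches split by partner-domain class despite contiguity", {
  # one run all contacting the partner's NBD -> a single stretch
  pairs <- data.frame(res_a = 10:14, res_b = 3L, min_dist = 5)
  iface <- structure(list(pairs = pairs, residues_a = 10:14,
                          residues_b = 3L, chain_a = "A", chain_b = "B",
                          cutoff = 6), class = "interface")
  bounds <- list(
    A = data.frame(domain = c("NBD", "LRR"), start = c(1, 100),
                   end = c(99, 200)),
    B = data.frame(domain = c("NBD", "LRR"), start = c(1, 100),
                   end = c(99, 200)))
  st <- derive_stretches(iface, bounds)
  a_rows <- st[st$chain == "A", ]
  expect_equal(nrow(a_rows), 1)
  expect_equal(c(a_rows$start, a_rows$end), c(10, 14))

  # consecutive residues 528-536: 528-532 contact partner LRR,
  # 533-536 contact partner NBD -> 2 stretches despite contiguity
  pairs <- data.frame(res_a = 528:536,
                      res_b = c(rep(550L, 5), rep(50L, 4)),
                      min_dist = 5)
  iface <- structure(list(pairs = pairs, residues_a = 528:536,
                          residues_b = c(50L, 550L), chain_a = "A",
                          chain_b = "B", cutoff = 6),
                     class = "interface")
  bounds <- list(
    A = data.frame(domain = c("NBD", "LRR"), start = c(1, 500),
                   end = c(499, 600)),
    B = data.frame(domain = c("NBD", "LRR"), start = c(1, 500),
                   end = c(499, 600)))
  st <- derive_stretches(iface, bounds)
  a_rows <- st[st$chain == "A", ]
  expect_equal(nrow(a_rows), 2)
  expect_setequal(paste(a_rows$start, a_rows$end), c("528 532", "533 536"))
  # family numbering: NBD-LRR contacts (starting at 50) are family 1,
  # the LRR-LRR stack family 2
  expect_equal(a_rows$name[a_rows$partner_domain == "LRR"], "2a")
  expect_equal(a_rows$name[a_rows$partner_domain == "NBD"], "1a")

  # a residue outside every domain range is an error
  bad <- list(A = bounds$A[1, ], B = bounds$B)  # A loses its LRR range
  expect_error(derive_stretches(iface, bad), "outside")
})

test_that("SASA matches closed forms for isolated and paired spheres", {
  lone <- nrcdiverge:::sasa_atoms(matrix(0, 1, 3), 1.7,
                                  probe_radius = 1.4,
                                  sphere_points = 960)
  expect_equal(lone, 4 * pi * 3.1^2, tolerance = 0.01)

  # two atoms 100 A apart: no occlusion, sum of isolated areas
  far <- nrcdiverge:::sasa_atoms(rbind(c(0, 0, 0), c(100, 0, 0)),
                                 c(1.7, 1.7), 1.4, 960)
  expect_equal(sum(far), 2 * 4 * pi * 3.1^2, tolerance = 1e-9)

  # overlapping identical spheres: spherical-cap closed form,
  # area = 4 pi R^2 - 2 pi R (R - d/2) per sphere
  R <- 1.7 + 1.4
  for (d in c(2.0, 3.0, 4.5)) {
    num <- nrcdiverge:::sasa_atoms(rbind(c(0, 0, 0), c(d, 0, 0)),
                                   c(1.7, 1.7), 1.4, 960)
    analytic <- 4 * pi * R^2 - 2 * pi * R * (R - d / 2)
    expect_equal(num[1], analytic, tolerance = 0.01)
    expect_equal(num[2], analytic, tolerance = 0.01)
  }
})

test_that("SASA converges: doubling sphere points moves totals < 0.5%", {
  td <- generate_toy_dimer(dimer_params(
    n_residues_per_chain = 6,
    contact_residue_pairs = cbind(c(1L, 3L), c(2L, 4L)), cutoff = 6))
  s1 <- sasa(td, sphere_points = 960)$total
  s2 <- sasa(td, sphere_points = 1920)$total
  expect_lt(abs(s2 - s1) / s1, 0.005)
})

test_that("BSA: zero for separated chains, symmetric for C2 dimers, additive", {
  # non-touching chains bury nothing
  td <- generate_toy_dimer(dimer_params(n_residues_per_chain = 5,
                                        cutoff = 6))
  b <- buried_surface_area(td, "A", "B")
  expect_equal(unname(b$per_protomer), c(0, 0))

  # exact C2 dimer: chain B is chain A rotated 180 degrees about z
  a_xyz <- rbind(c(2, 0, 0), c(3.5, 1, 0.5), c(2.5, -1, 1))
  b_xyz <- cbind(-a_xyz[, 1], -a_xyz[, 2], a_xyz[, 3])
  st <- structure3d(data.frame(
    chain = rep(c("A", "B"), each = 3), resno = rep(1:3, 2),
    resid = "ALA", atom = "CA", element = "C",
    x = c(a_xyz[, 1], b_xyz[, 1]), y = c(a_xyz[, 2], b_xyz[, 2]),
    z = c(a_xyz[, 3], b_xyz[, 3]), radius = 1.7, is_protein = TRUE))
  b <- buried_surface_area(st, "A", "B")
  expect_gt(b$total, 0)
  expect_equal(b$per_protomer[["A"]], b$per_protomer[["B"]],
               tolerance = 0.01)
  # additivity holds exactly
  expect_identical(b$total, sum(b$per_protomer))
})
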