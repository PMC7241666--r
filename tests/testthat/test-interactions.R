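# Park a chosen atom pair in empty space at an exactly representable
# separation and return a single-frame trajectory.
place_pair_traj <- function(topo, res_a, atom_a, res_b, atom_b, dist) {
  tp <- topo$topology
  ia <- atom_index(tp, res_a, atom_a); ib <- atom_index(tp, res_b, atom_b)
  co <- topo$coords
  co[ia, ] <- c(0, -20, 0)
  co[ib, ] <- c(dist, -20, 0)
  trajectory(tp, array(co, dim = c(nrow(co), 3, 1)))
}

# Presence bit of one named atom pair in a salt-bridge scan.
sb_pair_present <- function(ps, tp, res_a, atom_a, res_b, atom_b) {
  row <- ps$pairs$o == atom_index(tp, res_a, atom_a) &
    ps$pairs$n == atom_index(tp, res_b, atom_b)
  any(ps$presence[row, ])
}

test_that("salt bridges use the acidic-O/basic-N atom sets with a strict 4 A bound", {
  topo <- build_toy_topology(c("ASP", "GLY", "ARG", "GLY", "LYS", "GLU"))
  present <- function(res_a, atom_a, res_b, atom_b, dist) {
    ps <- detect_salt_bridges(place_pair_traj(topo, res_a, atom_a,
                                              res_b, atom_b, dist))
    sb_pair_present(ps, topo$topology, res_a, atom_a, res_b, atom_b)
  }
  expect_true(present(1, "OD1", 3, "NH1", 3.5))
  expect_false(present(6, "OE2", 5, "NZ", 4.2))
  expect_false(present(1, "OD1", 3, "NH1", 4.0))  # exactly 4.0: strict
  expect_true(present(1, "OD1", 3, "NH1", 3.99))
  # Glu oxygens are matched as OE1/OE2
  expect_true(present(6, "OE1", 3, "NE", 3.0))
  expect_error(detect_salt_bridges(place_pair_traj(topo, 1, "OD1", 3, "NH1", 3),
                                   cutoff = 0))
  # only the designated atoms participate
  ps <- detect_salt_bridges(place_pair_traj(topo, 1, "OD1", 3, "NH1", 3))
  expect_true(all(ps$pairs$acidic_atom %in% c("OD1", "OD2", "OE1", "OE2")))
  expect_true(all(ps$pairs$basic_atom %in% c("NE", "NH1", "NH2", "NZ")))
})

test_that("unique salt bridges keep the best atom pair per residue pair", {
  topo <- build_toy_topology(c("ASP", "GLY", "ARG"))
  tp <- topo$topology
  od1 <- atom_index(tp, 1, "OD1"); od2 <- atom_index(tp, 1, "OD2")
  nh1 <- atom_index(tp, 3, "NH1"); ne <- atom_index(tp, 3, "NE")
  nf <- 100
  co <- array(rep(topo$coords, nf), dim = c(nrow(tp$atoms), 3, nf))
  # OD1-NH1 in range 99 frames; OD2-NE in range 70 frames, elsewhere far
  for (f in 1:99) co[nh1, , f] <- co[od1, , f] + c(0, 0, 3.0)
  co[nh1, , 100] <- co[od1, , 100] + c(0, 0, 8)
  for (f in 1:70) co[ne, , f] <- co[od2, , f] + c(0, 0, 3.4)
  for (f in 71:100) co[ne, , f] <- co[od2, , f] + c(0, 0, 8)
  rec <- unique_salt_bridges(detect_salt_bridges(trajectory(tp, co)))
  expect_equal(nrow(rec), 1)  # one record per residue pair
  expect_equal(rec$occupancy, 99)
  expect_equal(rec$acidic_atom, "OD1")
  expect_equal(rec$basic_atom, "NH1")
  expect_equal(rec$pair, "D1-R3")
  expect_equal(rec$occupancy_union, 99)
  # a constant-geometry pair: occupancy 100, sd of distance 0
  nf2 <- 20
  co2 <- array(rep(topo$coords, nf2), dim = c(nrow(tp$atoms), 3, nf2))
  for (f in seq_len(nf2)) co2[nh1, , f] <- co2[od1, , f] + c(0, 0, 2.85)
  rec2 <- unique_salt_bridges(detect_salt_bridges(trajectory(tp, co2)))
  expect_equal(rec2$occupancy, 100)
  expect_equal(rec2$mean_dist, 2.85, tolerance = 1e-9)
  expect_equal(rec2$sd_dist, 0, tolerance = 1e-12)
})

test_that("hydrophobic contacts honour the carbon whitelist and adjacency rule", {
  topo <- build_toy_topology(c("LEU", "GLY", "ALA", "GLY", "VAL"))
  # LEU CD1 - VAL CG1 within 3.8: contact
  ps <- detect_hydrophobic_contacts(place_pair_traj(topo, 1, "CD1", 5, "CG1", 3.8))
  rec <- contact_records(ps)
  expect_true(any(rec$res_a == 1 & rec$res_b == 5))
  # sequence-adjacent residues never register, however close
  topo2 <- build_toy_topology(c("LEU", "ILE", "GLY"))
  ps2 <- detect_hydrophobic_contacts(place_pair_traj(topo2, 1, "CD1", 2, "CD1", 2.4))
  expect_false(any(ps2$pairs$res_a == 1 & ps2$pairs$res_b == 2))
  # several carbon pairs in range still give one presence bit per residue pair
  topo3 <- build_toy_topology(c("LEU", "GLY", "LEU"))
  tp3 <- topo3$topology
  co <- topo3$coords
  base <- co[atom_index(tp3, 1, "CD1"), ]
  for (nm in c("CB", "CG", "CD1", "CD2")) {
    i <- atom_index(tp3, 3, nm)
    co[i, ] <- base + c(0, 0, 3.0) + runif(3, 0, 0.3)
  }
  ps3 <- detect_hydrophobic_contacts(trajectory(tp3, array(co, dim = c(nrow(co), 3, 1))))
  hit <- ps3$pairs$res_a == 1 & ps3$pairs$res_b == 3
  expect_equal(sum(hit), 1)
  expect_true(ps3$presence[hit, 1])
  # contact count grows monotonically with the cutoff
  gen <- synthetic_trajectory(build_toy_topology(c("LEU", "GLY", "VAL", "GLY", "ILE")),
                              n_frames = 15, sigma = 1.5, seed = 401)
  tight <- detect_hydrophobic_contacts(gen$trajectory, cutoff = 3.9)
  loose <- detect_hydrophobic_contacts(gen$trajectory, cutoff = 4.0)
  expect_lte(sum(tight$presence), sum(loose$presence))
})

test_that("cell-list and brute-force detectors agree for salt bridges and contacts", {
  for (seed in c(411, 412)) {
    topo <- build_toy_topology(c("ASP", "GLY", "ARG", "LEU", "GLU", "GLY",
                                 "LYS", "VAL"))
    gen <- synthetic_trajectory(topo, n_frames = 4, sigma = 1.5, seed = seed)
    sb_b <- detect_salt_bridges(gen$trajectory, method = "brute")
    sb_c <- detect_salt_bridges(gen$trajectory, method = "cell")
    expect_identical(sb_b$presence, sb_c$presence)
    ct_b <- detect_hydrophobic_contacts(gen$trajectory, method = "brute")
    ct_c <- detect_hydrophobic_contacts(gen$trajectory, method = "cell")
    expect_identical(ct_b$presence, ct_c$presence)
  }
})

test_that("distance monitoring reports the series and in-range fraction", {
  topo <- build_toy_topology(c("ASP", "GLY", "HIS"))
  tp <- topo$topology
  # static frames 3.0 A apart: fraction 1
  tr <- place_pair_traj(topo, 1, "OD1", 3, "ND1", 3.0)
  m <- monitor_distance(tr, 1, "OD1", 3, "ND1")
  expect_equal(m$series$distance, 3.0, tolerance = 1e-9)
  expect_equal(m$fraction_below, 1.0)
  expect_equal(monitor_distance(tr, 1, "OD1", 3, "ND1", threshold = 0)$fraction_below, 0)
  expect_error(monitor_distance(tr, 1, "OD9", 3, "ND1"), "OD9")
  # designed 70% toggle recovered exactly under exact-count scheduling
  gen <- synthetic_trajectory(
    build_toy_topology(c("ASP", "GLY", "HIS")), n_frames = 200, sigma = 0.05,
    schedules = list(contact_schedule(1, "OD1", 3, "CE1", 70,
                                      in_distance = 3.0)),
    seed = 421)
  mm <- monitor_distance(gen$trajectory, 1, "OD1", 3, "CE1", threshold = 3.5)
  expect_equal(mm$fraction_below, 0.70)
})
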