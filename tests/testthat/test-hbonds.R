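test_that("donor/acceptor enumeration follows bonded-hydrogen chemistry", {
  topo <- build_toy_topology(c("SER", "GLY", "LYS"), n_waters = 1)$topology
  da <- enumerate_donors_acceptors(topo)
  og <- atom_index(topo, 1, "OG")
  expect_true(og %in% da$donors$donor)   # serine hydroxyl donates via HG
  expect_true(og %in% da$acceptors)      # and accepts
  nz <- atom_index(topo, 3, "NZ")
  expect_equal(sum(da$donors$donor == nz), 3)  # one candidate per NZ hydrogen
  wo <- atom_index(topo, 4, "O")
  expect_equal(sum(da$donors$donor == wo), 2)  # water donates via H1 and H2
  expect_true(wo %in% da$acceptors)
  # a hydrogen-free topology cannot be analyzed for hydrogen bonds
  bare <- build_toy_topology(c("PRO", "PRO"))$topology
  expect_error(enumerate_donors_acceptors(bare), "protonated")
})

test_that("geometric criteria: distance inclusive at 3.5 A, angle strict at 120 deg", {
  present <- function(dist, ang) {
    ps <- detect_hbonds(hbond_geometry_traj(dist, ang))
    any(ps$presence)
  }
  expect_true(present(3.4, 150))    # inside both criteria
  expect_false(present(3.6, 150))   # beyond the maximum donor-acceptor distance
  expect_false(present(3.6, 179))
  expect_true(present(2.9, 179.9))  # near-collinear
  expect_false(present(2.9, 110))   # bent below the angle cutoff
  expect_true(present(3.5, 180))    # boundary: exactly 3.5 A is inclusive
  expect_true(present(3.4, 121))    # just past the angle cutoff passes
  expect_false(present(3.4, 119))
  expect_error(detect_hbonds(hbond_geometry_traj(3, 150), distance_cutoff = 0))
})

test_that("relaxing either cutoff never removes a presence bit", {
  topo <- build_toy_topology(c("SER", "GLY", "ASP", "LYS", "THR"), n_waters = 2)
  gen <- synthetic_trajectory(topo, n_frames = 30, sigma = 0.8, seed = 301)
  tight <- detect_hbonds(gen$trajectory, distance_cutoff = 3.0, angle_cutoff = 140)
  loose_d <- detect_hbonds(gen$trajectory, distance_cutoff = 3.5, angle_cutoff = 140)
  loose_a <- detect_hbonds(gen$trajectory, distance_cutoff = 3.0, angle_cutoff = 120)
  expect_true(all(loose_d$presence >= tight$presence))
  expect_true(all(loose_a$presence >= tight$presence))
})

test_that("cell-list and brute-force engines agree bit for bit", {
  for (seed in c(311, 312, 313)) {
    topo <- build_toy_topology(c("SER", "ASP", "ARG", "LYS", "THR", "ASN"),
                               n_waters = 3)
    gen <- synthetic_trajectory(topo, n_frames = 5, sigma = 1.2, seed = seed)
    hb_b <- detect_hbonds(gen$trajectory, method = "brute")
    hb_c <- detect_hbonds(gen$trajectory, method = "cell")
    expect_identical(hb_b$presence, hb_c$presence)
    expect_identical(hb_b$pairs, hb_c$pairs)
  }
})

test_that("redundant hydrogens collapse to the highest-occupancy candidate", {
  topo <- build_toy_topology(c("LYS", "GLY", "GLY", "ASP"))
  tp <- topo$topology
  nz <- atom_index(tp, 1, "NZ"); od1 <- atom_index(tp, 4, "OD1")
  hz1 <- atom_index(tp, 1, "HZ1"); hz2 <- atom_index(tp, 1, "HZ2")
  nf <- 10
  coords <- array(rep(topo$coords, nf), dim = c(nrow(tp$atoms), 3, nf))
  u1 <- coords[hz1, , 1] - coords[nz, , 1]; u1 <- u1 / sqrt(sum(u1^2))
  u2 <- coords[hz2, , 1] - coords[nz, , 1]; u2 <- u2 / sqrt(sum(u2^2))
  for (f in 1:6) coords[od1, , f] <- coords[nz, , f] + 2.9 * u1
  for (f in 7:10) coords[od1, , f] <- coords[nz, , f] + 2.9 * u2
  traj <- trajectory(tp, coords)
  ps <- detect_hbonds(traj)
  occ_all <- occupancy_pct(ps$presence)
  dd <- dedupe_hbonds(ps)
  expect_lte(nrow(dd$pairs), nrow(ps$pairs))
  rec <- dd$pairs[dd$pairs$donor == nz & dd$pairs$acceptor == od1, ]
  expect_equal(nrow(rec), 1)
  expect_equal(rec$occupancy, 60)
  expect_equal(rec$hydrogen, hz1)
  # record occupancy equals the max over its merged candidates
  merged <- ps$pairs$donor == nz & ps$pairs$acceptor == od1
  expect_equal(rec$occupancy, max(occ_all[merged]))
  # exact tie resolves to the lowest hydrogen index
  coords2 <- coords
  for (f in 1:5) coords2[od1, , f] <- coords2[nz, , f] + 2.9 * u1
  for (f in 6:10) coords2[od1, , f] <- coords2[nz, , f] + 2.9 * u2
  dd2 <- dedupe_hbonds(detect_hbonds(trajectory(tp, coords2)))
  rec2 <- dd2$pairs[dd2$pairs$donor == nz & dd2$pairs$acceptor == od1, ]
  expect_equal(rec2$occupancy, 50)
  expect_equal(rec2$hydrogen, min(hz1, hz2))
})

test_that("classification assigns backbone role, chemistry and water partner", {
  topo <- build_toy_topology(c("ARG", "GLY", "ASP"))
  tp <- topo$topology
  nh1 <- atom_index(tp, 1, "NH1"); hh11 <- atom_index(tp, 1, "HH11")
  od1 <- atom_index(tp, 3, "OD1")
  co <- topo$coords
  u <- co[hh11, ] - co[nh1, ]; u <- u / sqrt(sum(u^2))
  co[od1, ] <- co[nh1, ] + 2.9 * u
  ps <- classify_hbonds(dedupe_hbonds(detect_hbonds(
    trajectory(tp, array(co, dim = c(nrow(co), 3, 1))))))
  rec <- ps$pairs[ps$pairs$donor == nh1 & ps$pairs$acceptor == od1, ]
  expect_equal(rec$backbone_class, "SS")
  expect_equal(rec$chem_class, "chr-chr")
  expect_equal(rec$partner_kind, "protein")
})

test_that("category mean counts equal the designed schedule bookkeeping", {
  # zero jitter: the only hydrogen bonds are the scheduled ones, so mean
  # per-frame counts equal designed occupancy / 100, summed per category
  spec <- synthetic_spec()
  topo <- build_toy_topology(spec$sequence, n_waters = 6)
  scheds <- list(
    hbond_schedule(15, "NE2", 9, "OE1", 95),   # SS, charged-other -> other
    hbond_schedule(13, "ND2", 9, "OE2", 75),   # SS, polar-charged -> other
    hbond_schedule(6, "OG", 13, "OD1", 55),    # SS, polar-polar
    hbond_schedule(2, "N", 14, "O", 25),       # MM, hydrophobic-hydrophobic
    hbond_schedule(16, "NE1", 17, "O", 5),     # side chain -> water
    hbond_schedule(18, "O", 12, "OG1", 60)     # water -> side chain
  )
  gen <- synthetic_trajectory(topo, n_frames = 200, sigma = 0,
                              schedules = scheds, seed = 5)
  hb <- classify_hbonds(dedupe_hbonds(detect_hbonds(gen$trajectory)))
  counts <- mean_hbond_counts(hb)
  getp <- function(cat) counts$protein$mean_count[counts$protein$category == cat]
  getw <- function(cat) counts$water$mean_count[counts$water$category == cat]
  expect_equal(getp("total"), (95 + 75 + 55 + 25) / 100)
  expect_equal(getp("MM"), 0.25)
  expect_equal(getp("SS"), 2.25)
  expect_equal(getp("MS"), 0)
  expect_equal(getp("phi-phi"), 0.55)
  expect_equal(getp("pho-pho"), 0.25)
  expect_equal(getp("other"), 0.95 + 0.75)
  expect_equal(getw("total"), 0.65)
  expect_equal(getw("S-water"), 0.65)
  expect_equal(getw("pho-water"), 0.05)
  expect_equal(getw("phi-water"), 0.60)
})

test_that("category counts partition the totals frame by frame", {
  topo <- build_toy_topology(c("SER", "ASP", "ARG", "LYS", "THR", "ASN"),
                             n_waters = 3)
  gen <- synthetic_trajectory(topo, n_frames = 40, sigma = 1.0, seed = 321)
  hb <- classify_hbonds(dedupe_hbonds(detect_hbonds(gen$trajectory)))
  p <- hb$pairs
  prot <- p$partner_kind == "protein"
  total <- count_series(hb, prot)
  bb_sum <- count_series(hb, prot & p$backbone_class == "MM") +
    count_series(hb, prot & p$backbone_class == "MS") +
    count_series(hb, prot & p$backbone_class == "SS")
  expect_equal(bb_sum, total)
  chem_sum <- Reduce(`+`, lapply(
    c("chr-chr", "pho-pho", "phi-phi", "pho-phi", "other"),
    function(cc) count_series(hb, prot & p$chem_class == cc)))
  expect_equal(chem_sum, total)
  # simple mean-count arithmetic: 1 bond present in half the frames
  half <- matrix(c(rep(TRUE, 20), rep(FALSE, 20)), 1)
  expect_equal(sum(half) / 40, 0.5)
})
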