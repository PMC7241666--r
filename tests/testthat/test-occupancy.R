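test_that("occupancy is the percentage of frames present", {
  expect_equal(occupancy_pct(c(rep(TRUE, 50), rep(FALSE, 50))), 50)
  expect_equal(occupancy_pct(rep(TRUE, 10)), 100)
  m <- rbind(rep(c(TRUE, FALSE), 10), rep(TRUE, 20))
  expect_equal(occupancy_pct(m), c(50, 100))
  expect_error(occupancy_pct(logical(0), n_frames = 0))
})

test_that("lifetime bins are right-inclusive and partition (0, 100]", {
  expect_equal(lifetime_bin(c(5, 95)), c("short", "long"))
  expect_equal(lifetime_bin(10), "short")     # exactly 10 is short-lived
  expect_equal(lifetime_bin(90), "substantial")
  expect_equal(lifetime_bin(90.0001), "long")
  expect_error(lifetime_bin(0))
  expect_error(lifetime_bin(101))
  h <- lifetime_histogram(c(5, 95))
  expect_equal(h$bins$count, c(1, 0, 1))
  h0 <- lifetime_histogram(numeric(0))
  expect_equal(h0$bins$count, c(0, 0, 0))
  expect_equal(sum(h0$fine$count), 0)
  # fine bins are right-inclusive 10-point bins and counts sum to records
  hf <- lifetime_histogram(c(10, 10.5, 20, 55, 100))
  expect_equal(sum(hf$fine$count), 5)
  expect_equal(hf$fine$count[hf$fine$bin_low == 0], 1)
  expect_equal(hf$fine$count[hf$fine$bin_low == 10], 2)  # 10.5 and 20
  expect_equal(hf$fine$count[hf$fine$bin_low == 90], 1)
})

test_that("occupancy filtering is strictly greater-than", {
  rec <- data.frame(id = 1:3, occupancy = c(49, 50, 51))
  kept <- filter_by_occupancy(rec, 50)
  expect_equal(kept$occupancy, 51)
  expect_equal(nrow(filter_by_occupancy(rec[0, ], 50)), 0)
  expect_error(filter_by_occupancy(rec, 0))
  expect_error(filter_by_occupancy(rec, 100))
  # nesting: a lower threshold keeps a superset
  set.seed(501)
  rec2 <- data.frame(id = 1:50, occupancy = runif(50, 1, 100))
  k30 <- filter_by_occupancy(rec2, 30)$id
  k70 <- filter_by_occupancy(rec2, 70)$id
  expect_true(all(k70 %in% k30))
})

test_that("differential classification reproduces the qualitative patterns", {
  tab <- function(...) {
    occ <- list(...)
    lapply(occ, function(o) data.frame(id = names(o), occupancy = unname(o)))
  }
  # weakening pattern from the temperature series: strictly decreasing, big drop
  tables <- list(
    `298K` = data.frame(id = c("E568-R875", "D803-R884", "X-Y", "only298"),
                        occupancy = c(99.75, 94, 60, 70)),
    `318K` = data.frame(id = c("E568-R875", "D803-R884", "X-Y", "new318"),
                        occupancy = c(81.06, 93, 95, 60)),
    `343K` = data.frame(id = c("E568-R875", "D803-R884", "X-Y", "new318"),
                        occupancy = c(64.94, 92, 85, 65))
  )
  calls <- differential_classify(tables)
  get <- function(id) calls$call[calls$id == id]
  expect_equal(get("E568-R875"), "weakened")
  expect_equal(get("D803-R884"), "comparable")   # spread 2 within tolerance
  expect_equal(get("X-Y"), "variable")           # present everywhere, non-monotone
  expect_equal(get("only298"), "lost")
  expect_equal(get("new318"), "gained")
  # maintained: high floor with spread above the comparability tolerance
  tables2 <- list(a = data.frame(id = "p", occupancy = 98),
                  b = data.frame(id = "p", occupancy = 96),
                  c = data.frame(id = "p", occupancy = 85))
  expect_equal(differential_classify(tables2)$call, "maintained")
  # classification is invariant to record order within conditions
  shuf <- lapply(tables, function(tb) tb[sample(nrow(tb)), , drop = FALSE])
  expect_equal(differential_classify(shuf), calls)
  expect_error(differential_classify(tables[1]))
  dup <- tables
  dup[[1]] <- rbind(dup[[1]], dup[[1]][1, ])
  expect_error(differential_classify(dup), "duplicate")
})

test_that("designed occupancies are recovered exactly and bin as designed", {
  topo <- build_toy_topology(synthetic_spec()$sequence, n_waters = 6)
  scheds <- list(
    hbond_schedule(15, "NE2", 9, "OE1", 95),
    hbond_schedule(13, "ND2", 9, "OE2", 75),
    hbond_schedule(6, "OG", 13, "OD1", 55),
    hbond_schedule(2, "N", 14, "O", 25),
    hbond_schedule(16, "NE1", 17, "O", 5)
  )
  gen <- synthetic_trajectory(topo, n_frames = 400, sigma = 0.25,
                              schedules = scheds, seed = 77)
  hb <- dedupe_hbonds(detect_hbonds(gen$trajectory))
  p <- hb$pairs
  tp <- topo$topology
  find_occ <- function(dres, datom, ares, aatom) {
    p$occupancy[p$donor == atom_index(tp, dres, datom) &
                  p$acceptor == atom_index(tp, ares, aatom)]
  }
  expect_equal(find_occ(15, "NE2", 9, "OE1"), 95)
  expect_equal(find_occ(13, "ND2", 9, "OE2"), 75)
  expect_equal(find_occ(6, "OG", 13, "OD1"), 55)
  expect_equal(find_occ(2, "N", 14, "O"), 25)
  expect_equal(find_occ(16, "NE1", 17, "O"), 5)
  expect_equal(lifetime_bin(c(95, 75, 55, 25, 5)),
               c("long", "substantial", "substantial", "substantial", "short"))
})
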