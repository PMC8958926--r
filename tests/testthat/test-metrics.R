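test_that("distance from injection is Euclidean displacement in micrometres", {
  # one agent at (3, 4) px from the injection site, 1.444 um per pixel
  snaps <- array(0, c(2, 1, 2))
  snaps[2, 1, ] <- c(3, 4)
  rec <- fake_record(snaps, snapshot_steps = c(0L, 10L), n_sites = 0L,
                     pixel_size = 1.444, injection_center = c(0, 0))
  d <- distance_from_injection(rec)
  expect_equal(d$median, c(0, 5 * 1.444))

  # radius-0 injection: all zero at step 0; stationary record is constant
  snaps2 <- array(rep(c(7, 9), each = 6), c(3, 2, 2))
  rec2 <- fake_record(snaps2, snapshot_steps = c(0L, 5L, 10L), n_sites = 0L,
                      injection_center = c(7, 9))
  d2 <- distance_from_injection(rec2)
  expect_true(all(d2$median == 0) && all(d2$max == 0))
})

test_that("white-matter percentage counts nearest-voxel membership", {
  # hand-built record: 3 of 10 agents on the tract at the last snapshot
  snaps <- array(0, c(1, 10, 2))
  snaps[1, , 1] <- 5
  snaps[1, , 2] <- c(20, 20, 20, 5, 5, 5, 5, 5, 5, 5)  # strip at y = 18..22
  wm <- matrix(c(rep(TRUE, 3), rep(FALSE, 7)), 1, 10)
  rec <- fake_record(snaps, snapshot_steps = 0L, snap_wm = wm, n_sites = 0L)
  expect_equal(percent_on_white_matter(rec)$wm_pct, 30)
  # recomputation from a tissue field agrees with the stored flags
  tis <- strip_tissue(c(60, 40), y0 = 18, y1 = 22)
  expect_equal(percent_on_white_matter(rec, tis)$wm_pct, 30)
  # all-grey phantom: 0 throughout
  expect_equal(percent_on_white_matter(rec, grey_tissue(c(60, 40)))$wm_pct, 0)
})

test_that("arrival percentage is cumulative over first entries", {
  n <- 1000
  arrival_site <- integer(n); arrival_step <- rep(NA_integer_, n)
  arrival_site[1:140] <- 1L
  arrival_step[1:140] <- rep(c(2L, 5L), each = 70)
  snaps <- array(0, c(3, n, 2))
  rec <- fake_record(snaps, snapshot_steps = c(0L, 3L, 10L),
                     arrival_site = arrival_site, arrival_step = arrival_step)
  a <- arrival_percentage(rec)
  expect_equal(a$arrival_pct, c(0, 7, 14))
  expect_true(all(diff(a$arrival_pct) >= 0))
})

test_that("the shortest-path agent minimises path length with id tie-break", {
  snaps <- array(0, c(2, 3, 2))
  rec <- fake_record(snaps, snapshot_steps = c(0L, 10L),
                     arrival_site = c(1L, 1L, 0L),
                     arrival_step = c(10L, 10L, NA),
                     arrival_path_um = c(12, 10, NA))
  sp <- shortest_path_agent(rec, 1)
  expect_equal(sp$agent, 2)
  expect_equal(sp$path_um, 10)
  # tie: lower id wins
  rec$arrival_path_um <- c(10, 10, NA)
  expect_equal(shortest_path_agent(rec, 1)$agent, 1)
  # no arrivals
  rec$arrival_site <- integer(3)
  expect_warning(res <- shortest_path_agent(rec, 1), "no agent")
  expect_null(res)
})

test_that("cluster and cell counts convert to published arrival percentages", {
  expect_equal(
    arrival_percentage_from_clusters(1321, 20, 4e5, clusters_sd = 775.7),
    c(percent = 6.61, uncertainty = 3.88)
  )
  expect_equal(arrival_percentage_from_clusters(2076, 20, 4e5),
               c(percent = 10.38))
  expect_equal(arrival_percentage_from_clusters(0, 20, 4e5), c(percent = 0))
  expect_equal(arrival_percentage_from_cells(3300, 6e5, cells_sd = 934),
               c(percent = 0.55, uncertainty = 0.16))
  expect_equal(arrival_percentage_from_cells(0, 6e5), c(percent = 0))
  expect_equal(arrival_percentage_from_cells(6e5, 6e5), c(percent = 100))
  expect_error(arrival_percentage_from_clusters(10, 20, 0), "dose")
  expect_error(arrival_percentage_from_cells(10, 0), "dose")
})

test_that("metric tables are pure functions of the record", {
  tis <- strip_tissue(c(60, 40), y0 = 18, y1 = 22)
  cfg <- simulation_config(d_w = 2, d_g = 1, lambda_c = 0, n_steps = 100L,
                           n_agents = 40, injection_center = c(30, 20),
                           injection_radius = 3, seed = 21)
  rec <- run_simulation(cfg, tis, NULL)
  expect_identical(metric_table(rec), metric_table(rec))
})
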