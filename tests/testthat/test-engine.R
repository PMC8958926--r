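test_that("configuration constraints are enforced", {
  expect_error(simulation_config(beta_w = 0.5), "beta_w")
  expect_error(simulation_config(alpha_c = 0.9), "alpha_c")
  expect_error(simulation_config(dt = 0), "dt")
  expect_error(simulation_config(epsilon_c = 0), "epsilon_c")
  cfg <- simulation_config(dt = 1 / 1000)
  expect_equal(cfg$n_steps, 30000L)  # 30 simulated days by default
})

test_that("speed factors are rescaled beta draws with mean one half", {
  set.seed(101)
  n <- 1e5
  for (beta_w in c(1, 2, 4)) {
    psi <- sample_speed_factor(beta_w, n)
    se <- sqrt(beta_w / (4 * (2 + beta_w)) / n)
    expect_lt(abs(mean(psi) - 0.5), 3 * se)
    expect_true(all(psi >= 0 & psi <= (1 + beta_w) / 2))
  }
  # beta_w = 1: exactly uniform on [0, 1]
  psi1 <- sample_speed_factor(1, n)
  expect_gt(stats::ks.test(psi1, "punif")$p.value, 0.01)
  # heavier right tail and smaller median at beta_w = 4
  psi4 <- sample_speed_factor(4, n)
  expect_gt(max(psi4), 1)
  expect_lt(median(psi4), median(psi1))
  expect_error(sample_speed_factor(0.5, 10), "beta_w")
})

test_that("sensitivity factors follow B[alpha_c, 1]", {
  set.seed(102)
  n <- 1e5
  eta1 <- sample_sensitivity_factor(1, n)
  expect_gt(stats::ks.test(eta1, "punif")$p.value, 0.01)
  eta50 <- sample_sensitivity_factor(50, n)
  se <- sqrt(50 / (51^2 * 52) / n)
  expect_lt(abs(mean(eta50) - 50 / 51), 3 * se)
  expect_gt(quantile(eta50, 0.05), 0.9)  # concentrates near 1
  expect_error(sample_sensitivity_factor(0.2, 5), "alpha_c")
})

test_that("random unit vectors are unit length and isotropic", {
  set.seed(103)
  n <- 1e5
  v2 <- random_unit_vector(n, 2)
  expect_lt(max(abs(sqrt(rowSums(v2^2)) - 1)), 1e-12)
  ang <- atan2(v2[, 2], v2[, 1]) + pi
  expect_gt(stats::ks.test(ang, "punif", 0, 2 * pi)$p.value, 0.01)
  v3 <- random_unit_vector(n, 3)
  expect_lt(max(abs(sqrt(rowSums(v3^2)) - 1)), 1e-12)
  expect_true(all(abs(colMeans(v3)) < 3 / sqrt(n)))
  expect_error(random_unit_vector(5, 4), "dim")
})

test_that("population initialization respects the injection ball and traits", {
  tis <- grey_tissue(c(40, 40))
  cfg <- simulation_config(n_agents = 500, injection_center = c(20, 20),
                           injection_radius = 0, seed = 1)
  set.seed(1)
  pop <- initialize_population(cfg, tis)
  expect_true(all(pop$pos[, 1] == 20 & pop$pos[, 2] == 20))
  expect_identical(pop$pos, pop$prev_pos)

  cfg$injection_radius <- 6
  set.seed(1)
  pop <- initialize_population(cfg, tis)
  r <- sqrt(rowSums(sweep(pop$pos, 2, c(20, 20))^2))
  expect_true(all(r <= 6))
  expect_true(all(pop$speed_factor >= 0) && all(pop$sens_factor <= 1))

  # injection centre outside the brain mask is rejected
  mask <- array(TRUE, c(40, 40)); mask[1:10, ] <- FALSE
  blocked <- tissue_field(array(0, c(40, 40)),
                          array(rep(c(1, 0), each = 1600), c(40, 40, 2)),
                          brain_mask = mask)
  cfg$injection_center <- c(5, 20)
  expect_error(initialize_population(cfg, blocked), "outside the brain")
})

test_that("migration steps follow the tract with inertia and are d_g-scaled in grey", {
  tis <- strip_tissue(c(60, 40), y0 = 18, y1 = 22)
  cfg <- simulation_config(d_w = 2, d_g = 0.7, lambda_c = 0,
                           injection_center = c(30, 20))
  set.seed(4)
  # grey step: exactly d_g in norm
  st <- migration_step(c(30, 5), c(30, 5), psi = 1, eta = 1, tis, NULL, cfg)
  expect_equal(sqrt(sum(st^2)), 0.7, tolerance = 1e-12)
  # white with previous displacement (0.3, 0.1): sign +1
  st <- migration_step(c(30, 20), c(29.7, 19.9), psi = 0.8, eta = 1, tis, NULL, cfg)
  expect_equal(st[1, ], c(2 * 0.8, 0))
  # previous displacement (-0.3, 0.1): sign -1
  st <- migration_step(c(30, 20), c(30.3, 19.9), psi = 0.8, eta = 1, tis, NULL, cfg)
  expect_equal(st[1, ], c(-2 * 0.8, 0))
})

test_that("the chemotaxis term is gated by epsilon_c and vanishes at the centre", {
  tis <- grey_tissue(c(60, 60))
  cf <- chemo_field(list(tumor_site(c(30, 30), half_decay = c(5, 5))),
                    epsilon_c = 0.05)
  cfg <- simulation_config(d_w = 0, d_g = 1, lambda_c = 8,
                           injection_center = c(30, 30))
  set.seed(5)
  # at the tumor centre the gradient is zero: a pure random step of norm d_g
  st <- migration_step(c(30, 30), c(30, 30), 1, 1, tis, cf, cfg)
  expect_equal(sqrt(sum(st^2)), 1, tolerance = 1e-12)
  # far away C < epsilon_c: no chemotaxis contribution either
  p_far <- c(2, 2)  # C ~ (1 + 2*784/25)^-1 << 0.05
  expect_lt(concentration(cf, p_far), 0.05)
  st <- migration_step(p_far, p_far, 1, 1, tis, cf, cfg)
  expect_equal(sqrt(sum(st^2)), 1, tolerance = 1e-12)
  # inside the detection region the gradient term is added
  p_near <- c(33, 30)
  expect_gt(concentration(cf, p_near), 0.05)
  set.seed(6)
  st <- migration_step(p_near, p_near, 1, 0.5, tis, cf, cfg)
  g <- chemo_gradient(cf, p_near)
  # the term is additive: subtracting lambda_c * eta * grad C leaves a unit step
  base <- st[1, ] - 8 * 0.5 * g[1, ]
  expect_equal(sqrt(sum(base^2)), 1, tolerance = 1e-12)
})

test_that("runs are deterministic, conservative and bounded per step", {
  tis <- strip_tissue(c(60, 40), y0 = 18, y1 = 22)
  cf <- chemo_field(list(tumor_site(c(50, 20), half_decay = c(8, 8),
                                    extent_um = c(3, 3))), epsilon_c = 0.05)
  cfg <- simulation_config(d_w = 2, d_g = 1, lambda_c = 4, beta_w = 2,
                           alpha_c = 2, n_steps = 200L, n_agents = 80,
                           injection_center = c(15, 20), injection_radius = 3,
                           seed = 9, snapshot_stride = 1L)
  rec1 <- run_simulation(cfg, tis, cf)
  rec2 <- run_simulation(cfg, tis, cf)
  expect_identical(rec1, rec2)

  # stationary degenerate configuration
  cfg0 <- simulation_config(d_w = 0, d_g = 0, lambda_c = 0, n_steps = 50L,
                            n_agents = 20, injection_center = c(15, 20),
                            injection_radius = 0, seed = 2)
  rec0 <- run_simulation(cfg0, tis, NULL)
  expect_true(all(rec0$final_pos[, 1] == 15 & rec0$final_pos[, 2] == 20))
  expect_equal(rec0$series$dist_median_um, rep(0, 51))

  # agent count conserved and arrivals monotone under absorption
  arr <- rec1$series$arrival_pct_site1
  expect_true(all(diff(arr) >= 0))
  expect_true(all(rec1$arrival_site %in% 0:1))
  expect_equal(rec1$n_agents, 80)

  # per-step displacement norm bound: d_w * s_max + lambda_c (|grad C| < 1 here)
  s_max <- (1 + cfg$beta_w) / 2
  bound <- cfg$d_w * s_max + cfg$lambda_c + 1e-9
  for (i in 2:40) {
    d <- matrix(rec1$snapshots[i, , ], ncol = 2) -
      matrix(rec1$snapshots[i - 1, , ], ncol = 2)
    expect_true(all(sqrt(rowSums(d^2)) <= bound))
  }

  # absorbed agents stay put after arrival
  hit <- which(rec1$arrival_site == 1L)
  if (length(hit)) {
    a <- hit[1]
    after <- rec1$snapshot_steps >= rec1$arrival_step[a]
    traj <- matrix(rec1$snapshots[after, a, ], ncol = 2)
    expect_lt(max(abs(sweep(traj, 2, traj[1, ]))), 1e-12)
  }
})

test_that("agents never leave the brain mask", {
  mask <- ellipse <- array(FALSE, c(40, 40))
  xx <- rep(1:40, 40); yy <- rep(1:40, each = 40)
  mask[cbind(xx, yy)] <- ((xx - 20.5) / 14)^2 + ((yy - 20.5) / 10)^2 <= 1
  tis <- tissue_field(array(0, c(40, 40)),
                      array(rep(c(1, 0), each = 1600), c(40, 40, 2)),
                      brain_mask = mask)
  cfg <- simulation_config(d_w = 0, d_g = 3, lambda_c = 0, n_steps = 300L,
                           n_agents = 50, injection_center = c(20.5, 20.5),
                           injection_radius = 2, seed = 3, snapshot_stride = 10L)
  rec <- run_simulation(cfg, tis, NULL)
  for (i in seq_along(rec$snapshot_steps)) {
    p <- matrix(rec$snapshots[i, , ], ncol = 2)
    vox <- floor(p + 0.5)
    expect_true(all(mask[vox]))
  }
})

test_that("tumor-free runs on a grey phantom follow the random-walk law (small n)", {
  tis <- grey_tissue(c(120, 120))
  cfg <- simulation_config(d_w = 0, d_g = 1, lambda_c = 0, n_steps = 100L,
                           n_agents = 2000, injection_center = c(60, 60),
                           injection_radius = 0, seed = 12)
  rec <- run_simulation(cfg, tis, NULL)
  msd <- mean(rowSums(sweep(rec$final_pos, 2, c(60, 60))^2))
  expect_gt(msd / 100, 0.9)
  expect_lt(msd / 100, 1.1)
})
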