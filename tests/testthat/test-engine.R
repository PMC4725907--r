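test_that("pair-event prediction solves the boundary kinematics", {
  # head-on approach: |r| = 10, closing speed 1, boundary at 6 -> t = 4
  ev <- predict_pair_event(c(10, 0, 0), c(-1, 0, 0), boundaries = 6)
  expect_equal(ev$time, 4)
  expect_equal(ev$boundary, 6)
  # purely tangential motion, no boundary between |r| and cutoff -> none
  expect_null(predict_pair_event(c(10, 0, 0), c(0, 1e-12, 0),
                                 boundaries = 6))
  expect_error(predict_pair_event(c(NaN, 0, 0), c(1, 0, 0), 6), "NaN")
})

test_that("pair-event prediction agrees with a brute-force time scan", {
  set.seed(42)
  for (rep in 1:50) {
    r <- stats::runif(3, -8, 8)
    v <- stats::rnorm(3, sd = 0.5)
    boundaries <- sort(stats::runif(3, 2, 12))
    got <- predict_pair_event(r, v, boundaries)
    want <- scan_first_crossing(r, v, boundaries)
    if (is.null(want)) {
      # the scan saw no crossing within its window; any predicted event
      # must lie beyond it
      if (!is.null(got)) expect_gt(got$time, 50 - 1e-3)
    } else {
      expect_false(is.null(got))
      expect_equal(got$time, want$time, tolerance = 1e-3)
      expect_equal(got$boundary, want$boundary)
    }
  }
})

test_that("collision resolution conserves momentum and books energy", {
  # equal masses, head-on, energies unchanged (hard wall): velocities
  # exchange
  res <- resolve_collision(5, 5, r12 = c(2, 0, 0),
                           v1 = c(1, 0, 0), v2 = c(-1, 0, 0), dU = Inf)
  expect_equal(res$v1, c(-1, 0, 0))
  expect_equal(res$v2, c(1, 0, 0))
  expect_equal(res$dU_applied, 0)
  # a genuinely flat step (zero height) is crossed without any deflection
  res0 <- resolve_collision(5, 5, c(2, 0, 0), c(1, 0, 0), c(-1, 0, 0),
                            dU = 0)
  expect_true(res0$crossed)
  expect_equal(res0$v1, c(1, 0, 0))
  # insufficient radial energy at an outward step: elastic reflection
  res <- resolve_collision(10, 10, c(3, 0, 0), c(0, 0, 0), c(1, 0, 0),
                           dU = 100)
  expect_false(res$crossed)
  expect_equal(res$v1, c(1, 0, 0))
  expect_equal(res$v2, c(0, 0, 0))
  # capture into a well of depth eps: kinetic energy grows by exactly eps
  eps <- 1.3
  m1 <- 7; m2 <- 11
  v1 <- c(0.3, 0.1, 0); v2 <- c(-0.4, 0, 0.05)
  res <- resolve_collision(m1, m2, c(4, 0, 0), v1, v2, dU = -eps)
  expect_true(res$crossed)
  ke0 <- 0.5 * m1 * sum(v1^2) + 0.5 * m2 * sum(v2^2)
  ke1 <- 0.5 * m1 * sum(res$v1^2) + 0.5 * m2 * sum(res$v2^2)
  expect_equal(ke1 - ke0, eps, tolerance = 1e-12)
  # momentum conserved exactly in every case
  expect_equal(m1 * res$v1 + m2 * res$v2, m1 * v1 + m2 * v2,
               tolerance = 1e-14)
})

test_that("a two-body square-well system conserves energy over 1e5 events", {
  spec <- two_body_spec(sigma = 4, lambda = 1.5, epsilon = 2, box_edge = 20)
  sys <- make_two_body_system(spec, seed = 3)
  tr <- run_dmd(sys, pair_table = two_body_table(spec), hbond = NULL,
                event_budget = 1e5, thermostat_rate = 0, emit_every = 5000)
  e <- tr$frames$kinetic + tr$frames$potential
  expect_lt((max(e) - min(e)) / abs(mean(e)), 1e-9)
  expect_equal(tr$n_pair_events, 1e5)
})

test_that("NVE dynamics conserves momentum and energy on a mixed system", {
  tr <- small_nve
  b <- tr$beads
  p0 <- colSums(b$mass * cbind(small_system$beads$vx,
                               small_system$beads$vy,
                               small_system$beads$vz))
  pf <- colSums(b$mass * cbind(tr$final_state$beads$vx,
                               tr$final_state$beads$vy,
                               tr$final_state$beads$vz))
  expect_equal(pf, p0, tolerance = 1e-9)
  e <- tr$frames$kinetic + tr$frames$potential
  expect_lt((max(e) - min(e)) / abs(mean(e)), 1e-8)
})

test_that("identical seeds give bit-identical trajectories", {
  tr2 <- run_dmd(small_system, pair_table = the_table,
                 event_budget = 2e4, thermostat_rate = 0, emit_every = 2000)
  expect_identical(small_nve$coords, tr2$coords)
  expect_identical(small_nve$frames$potential, tr2$frames$potential)
})

test_that("incremental potential bookkeeping equals the direct reference", {
  te <- total_energy(small_nve$final_state, pair_table = the_table,
                     hb_registry = small_nve$hb_registry)
  pe_incr <- small_nve$frames$potential[nrow(small_nve$frames)]
  expect_equal(pe_incr, te$potential, tolerance = 1e-9)
  # trivial checks of the reference itself
  gas <- make_ideal_gas(20, 40, seed = 5)
  expect_equal(total_energy(gas, hbond = NULL)$potential, 0)
})

test_that("no hardcore overlap at emitted frames", {
  b <- small_nve$beads
  lim2 <- outer(b$hardcore_radius, b$hardcore_radius, "+")^2
  excl <- matrix(FALSE, nrow(b), nrow(b))
  bonds <- small_system$bonds
  excl[cbind(bonds$i, bonds$j)] <- TRUE
  excl[cbind(bonds$j, bonds$i)] <- TRUE
  for (k in seq(1, n_frames(small_nve), by = 2)) {
    fr <- traj_frame(small_nve, k)
    d2 <- oligodmd:::.min_image_cross_dist2(cbind(fr$x, fr$y, fr$z),
                                            cbind(fr$x, fr$y, fr$z),
                                            small_nve$box_edge)
    bad <- d2 < lim2 - 1e-9 & !excl & upper.tri(d2)
    expect_false(any(bad))
  }
})

test_that("pair events only change the radial velocity component", {
  # angular momentum of the pair about its centre of mass is conserved by
  # a single resolved collision
  m1 <- 3; m2 <- 9
  r1 <- c(0, 0, 0); r2 <- c(4.2, 0, 0)
  v1 <- c(0.2, 0.3, -0.1); v2 <- c(-0.5, 0.1, 0.2)
  res <- resolve_collision(m1, m2, r2 - r1, v1, v2, dU = -0.7)
  com <- (m1 * r1 + m2 * r2) / (m1 + m2)
  ang <- function(v1, v2) {
    l1 <- pracma::cross(r1 - com, m1 * v1)
    l2 <- pracma::cross(r2 - com, m2 * v2)
    l1 + l2
  }
  expect_equal(ang(res$v1, res$v2), ang(v1, v2), tolerance = 1e-12)
})

test_that("the Anderson thermostat drives an ideal gas to the target", {
  gas <- make_ideal_gas(250, box_edge = 60, temperature = 150, seed = 9)
  tr <- run_dmd(gas, hbond = NULL, thermostat_rate = 0.1,
                event_budget = Inf, max_time = 400, emit_every = 0,
                emit_dt = 10, temperature = 300)
  # kinetic temperature approaches 300 K within 2% (averaged after burn-in)
  late <- tr$frames$temperature[tr$frames$time > 100]
  expect_equal(mean(late), 300, tolerance = 0.02)
})

test_that("thermostatted speeds follow the Maxwell-Boltzmann law", {
  gas <- make_ideal_gas(250, box_edge = 60, temperature = 300, seed = 2)
  tr <- run_dmd(gas, hbond = NULL, thermostat_rate = 0.1,
                event_budget = Inf, max_time = 1200, emit_every = 0,
                emit_dt = 8)
  keep <- tr$frames$time > 50
  vs <- tr$velocities[keep, , , drop = FALSE]
  speeds <- sqrt(vs[, , 1]^2 + vs[, , 2]^2 + vs[, , 3]^2)
  speeds <- as.numeric(speeds)
  # velocities persist between thermostat kicks, so deduplicate before
  # the continuous-distribution test
  speeds <- unique(speeds)
  set.seed(1)
  speeds <- sample(speeds, 1e4)
  a <- sqrt(kT(300) / 20)  # scale parameter for mass-20 beads
  mb_cdf <- function(v) {
    x <- v / a
    stats::pchisq(x^2, df = 3)
  }
  ks <- stats::ks.test(speeds, mb_cdf)
  # below the 1% critical value for n = 1e4
  expect_lt(unname(ks$statistic), 1.63 / sqrt(1e4))
})

test_that("an NVE ideal gas moves in straight minimum-image lines", {
  gas <- make_ideal_gas(15, box_edge = 30, seed = 4)
  tr <- run_dmd(gas, hbond = NULL, thermostat_rate = 0,
                event_budget = Inf, max_time = 50, emit_every = 0,
                emit_dt = 5)
  b <- gas$beads
  for (k in seq_len(n_frames(tr))) {
    t <- tr$frames$time[k]
    expected <- (cbind(b$x, b$y, b$z) +
                   t * cbind(b$vx, b$vy, b$vz)) %% 30
    expect_equal(tr$coords[k, , ], expected, tolerance = 1e-9)
  }
  expect_equal(tr$frames$kinetic,
               rep(tr$frames$kinetic[1], n_frames(tr)), tolerance = 1e-12)
  expect_equal(tr$event_counts[["cross"]] + tr$event_counts[["reflect"]], 0)
})

test_that("two-body bound fraction matches the configurational integral", {
  spec <- two_body_spec(sigma = 4, lambda = 1.5, epsilon = 2,
                        box_edge = 40, temperature = 300)
  oracle <- bound_fraction_oracle(spec)
  sys <- make_two_body_system(spec, seed = 6)
  tr <- run_dmd(sys, pair_table = two_body_table(spec), hbond = NULL,
                thermostat_rate = 0.05, event_budget = Inf,
                max_time = 60000, emit_every = 0, emit_dt = 5)
  r <- sqrt(rowSums((oligodmd:::.min_image(
    tr$coords[, 1, ] - tr$coords[, 2, ], 40))^2))
  bound <- as.numeric(r < spec$lambda * spec$sigma)
  # standard error from block averages over the second half
  half <- bound[seq(floor(length(bound) / 2), length(bound))]
  blocks <- split(half, cut(seq_along(half), 20))
  bm <- vapply(blocks, mean, numeric(1))
  se <- stats::sd(bm) / sqrt(length(bm))
  expect_lt(abs(mean(half) - oracle), 3 * se + 0.01)
})

test_that("the annealed protocol quenches to the target temperature", {
  cfg <- system_config(1, "curcumin", seed = 21)
  sys <- assemble_system(cfg)
  tr <- run_dmd_annealed(sys, hot_events = 3e4, cold_events = 1e5)
  hot <- attr(tr, "hot_stage")
  expect_s3_class(hot, "dmd_trajectory")
  expect_gt(max(tr$frames$time), max(hot$frames$time))
  late <- tr$frames$temperature[steady_state_window(tr)]
  expect_lt(abs(mean(late) - 300), 40)
})
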