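test_that("mode assignments match the quadrant-pair control strategies", {
  expect_equal(sort(assign_mode("mode1", 30, 0)$freqs),
               sort(c(30, 30, 0, 0, 0, 0, 0, 0)))
  expect_equal(assign_mode("mode4", 20)$freqs, rep(20, 8))
  expect_equal(sort(assign_mode("mode3", 10, 4)$freqs),
               sort(c(rep(10, 6), 4, 4)))
  # mode 1: f_out pair and f_in pair sit in diagonally opposite quadrants
  p1 <- assign_mode("mode1", 30, 10)
  quad <- rep(1:4, each = 2)
  expect_setequal(unique(quad[p1$freqs == 30]), 1)
  expect_setequal(unique(quad[p1$freqs == 10]), 3)
  # mode 2 variants split across one symmetry plane
  lay <- row_layout(morphometry())
  p2s <- assign_mode("mode2_sagittal", 30, 10)
  expect_true(all((cos(lay$eps_deg * pi / 180) > 0) == (p2s$freqs == 30)))
  p2t <- assign_mode("mode2_tentacular", 30, 10)
  expect_true(all((sin(lay$eps_deg * pi / 180) > 0) == (p2t$freqs == 30)))
  # frequency ordering enforced for turning modes
  expect_error(assign_mode("mode1", 10, 10), "f_out > f_in")
  expect_error(assign_mode("mode3", 10, 20), "f_out > f_in")
})

test_that("sweep enumeration covers the full frequency grid", {
  runs <- enumerate_sweep()
  expect_equal(nrow(runs), 612)
  expect_equal(length(unique(runs$mode)), 4)
  expect_equal(sum(runs$mode == "mode1"), 153)
  expect_true(all(runs$f_out %in% seq(2, 34, 2)))
  expect_true(all(runs$f_in %in% seq(0, 32, 2)))
  expect_true(all(runs$f_out - runs$f_in >= 2))
  expect_equal(min(runs$f_out - runs$f_in), 2)
})

test_that("row subsets enumerate every non-empty combination once", {
  subs <- enumerate_subsets(30)
  expect_equal(length(subs), 255)
  masks <- vapply(subs, function(p) paste(p$freqs > 0, collapse = ""),
                  character(1))
  expect_equal(length(unique(masks)), 255)
  sizes <- vapply(subs, function(p) sum(p$freqs > 0), numeric(1))
  expect_equal(as.numeric(table(sizes)), choose(8, 1:8))
  # the full subset is straight swimming (mode 4)
  full <- subs[[which(sizes == 8)]]
  expect_equal(full$freqs, assign_mode("mode4", 30)$freqs)
})

test_that("all-inactive program leaves the body at rest", {
  tr <- simulate_swim(row_frequency_program(rep(0, 8)), duration = 0.5)
  expect_equal(nrow(tr), 2)
  expect_true(all(as.matrix(tr[, -1]) == 0))
})

test_that("mode 4 symmetry yields straight axial swimming", {
  tr <- short_run("mode4", 20, duration = 0.5)
  scale <- max(abs(tr$x))
  expect_gt(tr$x[nrow(tr)], 0)                      # forward displacement
  expect_lt(max(abs(tr$y)), 1e-9 * scale)           # no lateral drift
  expect_lt(max(abs(tr$z)), 1e-9 * scale)
  expect_lt(max(abs(tr$wx), abs(tr$wy), abs(tr$wz)) * attr(tr, "L"),
            1e-9 * max(abs(tr$vx)))                 # no net rotation
})

test_that("reversed power stroke mirrors mode-4 swimming through the y-z plane", {
  fwd <- short_run("mode4", 20, direction = 1, duration = 0.5)
  bwd <- short_run("mode4", 20, direction = -1, duration = 0.5)
  expect_lt(bwd$x[nrow(bwd)], 0)
  # axial speed magnitudes agree closely; exact mirroring is broken only by
  # the aboral placement bias of the ctenes
  expect_equal(abs(bwd$x[nrow(bwd)]), abs(fwd$x[nrow(fwd)]),
               tolerance = 0.2)
})

test_that("mirror-image control patterns give mirror-image trajectories", {
  # quadrant 1 active vs quadrant 4 active (reflection through the
  # tentacular plane, z -> -z)
  f <- c(30, 30, 0, 0, 0, 0, 0, 0)
  trQ1 <- simulate_swim(row_frequency_program(f), duration = 0.4)
  fz <- c(0, 0, 0, 0, 0, 0, 30, 30)
  trQ4 <- simulate_swim(row_frequency_program(fz), duration = 0.4)
  expect_equal(trQ4$x, trQ1$x, tolerance = 1e-9)
  expect_equal(trQ4$y, trQ1$y, tolerance = 1e-9)
  expect_equal(trQ4$z, -trQ1$z, tolerance = 1e-9)
  # reflection through the sagittal plane: quadrant 1 -> quadrant 2
  fy <- c(0, 0, 30, 30, 0, 0, 0, 0)
  trQ2 <- simulate_swim(row_frequency_program(fy), duration = 0.4)
  expect_equal(trQ2$x, trQ1$x, tolerance = 1e-9)
  expect_equal(trQ2$y, -trQ1$y, tolerance = 1e-9)
  expect_equal(trQ2$z, trQ1$z, tolerance = 1e-9)
})

test_that("halving the time step changes the final position by < 0.1%", {
  tr1 <- simulate_swim(assign_mode("mode1", 30, 0), duration = 0.5,
                       halting = "none", steps_per_cycle = 200L)
  tr2 <- simulate_swim(assign_mode("mode1", 30, 0), duration = 0.5,
                       halting = "none", steps_per_cycle = 400L)
  p1 <- as.numeric(tr1[nrow(tr1), c("x", "y", "z")])
  p2 <- as.numeric(tr2[nrow(tr2), c("x", "y", "z")])
  path <- sqrt(sum(p1^2))
  expect_lt(sqrt(sum((p1 - p2)^2)) / path, 1e-3)
})

test_that("terminal speed saturates and grows with beat frequency", {
  v_end <- vapply(c(10, 20, 30), function(f) {
    tr <- simulate_swim(assign_mode("mode4", f), duration = 2.5,
                        halting = "none", stride = 20L)
    v <- sqrt(tr$vx^2 + tr$vy^2 + tr$vz^2)
    # saturation: consecutive quarter-second means agree to 0.5%
    # (instantaneous speed still pulses within each beat)
    m1 <- mean(v[tr$t > 2.0 & tr$t <= 2.25])
    m2 <- mean(v[tr$t > 2.25])
    expect_lt(abs(m2 - m1) / m1, 5e-3)
    m2
  }, numeric(1))
  expect_true(all(diff(v_end) > 0))
})

test_that("compiled derivative matches the R force assembly", {
  prog <- assign_mode("mode1", 30, 0)
  pars <- ctenoswim:::build_core_params(tplac, prog, tbeat, tm, tbody,
                                        tfluid, tcoef)
  set.seed(61)
  for (rep in 1:4) {
    state <- c(rnorm(3, sd = 1e-3), rnorm(3, sd = 3e-3),
               runif(3, -0.5, 0.5), rnorm(3, sd = 1))
    t <- runif(1, 0, 0.3)
    dR <- state_derivative(t, state, tplac, prog, tbeat, tm, tbody,
                           tfluid, tcoef)
    dC <- ctenoswim:::.cteno_deriv_cpp(t, state, pars)
    expect_equal(dC, dR, tolerance = 1e-12)
  }
})

test_that("replay reproduces a constant-frequency simulation exactly", {
  prog <- assign_mode("mode4", 20)
  tr <- simulate_swim(prog, duration = 0.3, halting = "none")
  sched <- data.frame(t = c(0, 0.3))
  for (i in 1:8) sched[[paste0("f", i)]] <- rep(prog$freqs[i], 2)
  tr_r <- replay(sched, duration = 0.3)
  expect_equal(tr_r$x, tr$x, tolerance = 1e-12)
  expect_equal(tr_r$vx, tr$vx, tolerance = 1e-12)
  # zero schedule -> rest
  sched0 <- sched; sched0[paste0("f", 1:8)] <- 0
  tr0 <- replay(sched0, duration = 0.2)
  expect_true(all(as.matrix(tr0[, -1]) == 0))
  expect_error(replay(transform(sched, f1 = -1)), ">= 0")
})

test_that("a mode switch in the schedule straightens the trajectory", {
  # turn (mode 1) for 0.8 s, then straight (mode 4): turning radius over the
  # second phase far exceeds the first
  m1 <- assign_mode("mode1", 30, 0)$freqs
  m4 <- assign_mode("mode4", 30)$freqs
  sched <- data.frame(t = c(0, 0.8))
  for (i in 1:8) sched[[paste0("f", i)]] <- c(m1[i], m4[i])
  tr <- replay(sched, duration = 1.6)
  ph1 <- tr[tr$t <= 0.8, ]; ph2 <- tr[tr$t > 0.9, ]   # skip the switch
  rl1 <- turning_radius_state(ph1, L = attr(tr, "L"), startup_cycles = 0)
  rl2 <- turning_radius_state(ph2, L = attr(tr, "L"), startup_cycles = 0)
  expect_gt(rl2$RL_bar, 3 * rl1$RL_bar)
})
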