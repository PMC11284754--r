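# Analysis observables on constructed states and toy traces.

test_that("wrapping fraction: bounds, linearity, errors", {
  ff <- forcefield()
  # 10 ligands in a row; receptors 1 sigma above
  n <- 10
  lig <- cbind(seq(2, 20, 2), 5, 10)
  rec <- cbind(seq(2, 20, 2), 5, 11)
  st <- toy_state(rbind(lig, rec),
                  kinds = c(rep("ligand", n), rep("receptor_head", n)),
                  box = c(24, 24, 30))
  expect_identical(wrapping_fraction(st, ff), 0)       # no bonds
  # all bonded at exactly r0: fraction 1
  lr <- integer(2 * n)
  lr[1:n] <- n + 1:n
  lr[n + 1:n] <- 1:n
  st$lr_bonds <- lr
  expect_equal(wrapping_fraction(st, ff), 1)
  # half bonded: 0.5 by linearity of the sum
  lr2 <- integer(2 * n)
  lr2[1:5] <- n + 1:5
  lr2[n + 1:5] <- 1:5
  st$lr_bonds <- lr2
  expect_equal(wrapping_fraction(st, ff), 0.5)
  # bonds at r > r0 bind less than fully
  st$positions[n + 1:n, 3] <- 12
  st$lr_bonds <- lr
  f2 <- wrapping_fraction(st, ff)
  expect_lt(f2, 1)
  expect_gt(f2, 0)
  st$kinds[st$kinds == 5L] <- 4L
  expect_error(wrapping_fraction(st, ff), "no ligands")
})

test_that("wrapping time: crossing, N/A, spike rejection", {
  times <- seq(0, 2000, by = 10)
  # monotone trace crossing 0.9 at t = 1000 and staying up
  wf <- pmin(1, times / 1111.11)
  tr <- list(times = times, wrap_fraction = wf)
  tw <- wrapping_time(tr, threshold = 0.9, hold = 100, smooth = 0)
  expect_equal(tw, 1000, tolerance = 15)
  # flat trace never completes
  expect_true(is.na(wrapping_time(list(times = times,
                                       wrap_fraction = rep(0.3, length(times))),
                                  0.9, 100)))
  # a single-frame spike above threshold is rejected by the hold filter
  wf_spike <- rep(0.3, length(times))
  wf_spike[100] <- 0.95
  expect_true(is.na(wrapping_time(list(times = times, wrap_fraction = wf_spike),
                                  0.9, 100, smooth = 0)))
  # but a sustained plateau counts
  wf_plateau <- ifelse(times >= 500, 0.95, 0.2)
  expect_equal(wrapping_time(list(times = times, wrap_fraction = wf_plateau),
                             0.9, 100, smooth = 0), 500)
})

test_that("thickness of constructed flat sheets is exact", {
  st <- flat_sheets_state(nx = 12, ny = 12, gap = 4.51)
  # bins matched to the 1-sigma lattice: every bin filled, thickness
  # exact with no interpolation active
  tm1 <- membrane_thickness(st, bin_width = 1.0)
  expect_equal(tm1$mean, 4.51, tolerance = 1e-9)
  expect_identical(sum(tm1$interpolated_mask), 0L)
  # production bin width (0.5 sigma): interpolation fills the empty
  # bins but the flat-sheet thickness stays exact
  tm <- membrane_thickness(st, bin_width = 0.5)
  expect_equal(tm$mean, 4.51, tolerance = 1e-9)
  expect_lt(tm$sd, 1e-9)
  expect_s3_class(tm, "thickness_map")
  # grid-origin independence: translating the whole system in XY
  # changes the mean by nothing (flat sheets)
  st2 <- st
  st2$positions[, 1] <- st2$positions[, 1] + 0.27
  st2$positions[, 2] <- st2$positions[, 2] - 1.13
  tm2 <- membrane_thickness(st2, bin_width = 0.5)
  expect_equal(tm2$mean, tm$mean, tolerance = 1e-9)
})

test_that("empty thickness bins are interpolated and flagged", {
  st <- flat_sheets_state(nx = 10, ny = 10, gap = 4.0, a = 1.0)
  # bins are 0.5 sigma; lipids sit on a 1-sigma lattice, so half the
  # bins are empty and must be interpolated between filled neighbors
  tm <- membrane_thickness(st, bin_width = 0.5)
  expect_gt(sum(tm$interpolated_mask), 0)
  expect_equal(tm$mean, 4.0, tolerance = 1e-9)  # flat: interp is exact
  expect_true(all(tm$grid >= 4 - 1e-9 & tm$grid <= 4 + 1e-9))
  # hand-checked interpolation: tilt the upper sheet linearly in x so
  # an emptied column must take the average of its neighbors
  st3 <- flat_sheets_state(nx = 10, ny = 10, gap = 4.0)
  up <- st3$head_idx[st3$positions[st3$head_idx, 3] > 0]
  st3$positions[up, 3] <- 2 + 0.1 * st3$positions[up, 1]
  tm3 <- membrane_thickness(st3, bin_width = 1.0)
  expect_equal(tm3$mean, 4 + 0.1 * unname(st3$box[1]) / 2, tolerance = 0.06)
  # leaflet-empty error
  st4 <- st
  st4$positions[, 3] <- abs(st4$positions[, 3])  # everything "upper"
  st4$positions[st4$tail2_idx, 3] <-
    st4$positions[st4$head_idx, 3] - 1.8         # tails below heads
  expect_error(membrane_thickness(st4), "leaflet")
})

test_that("vesicle membership: empty far away, closed under contact", {
  mem <- assign_receptors(build_bilayer(8, 8), 0.5, 31)
  part <- generate_sphere_surface(2, 1)
  sys <- assemble_system(mem, part, standoff = 8)   # particle far above
  expect_identical(vesicle_lipids(sys), integer(0))
  # particle touching the membrane: nearby lipids + contact closure
  sys2 <- assemble_system(mem, part, standoff = 0.05)
  ves <- vesicle_lipids(sys2)
  expect_gt(length(ves), 0)
  expect_true(all(ves >= 1 & ves <= sys2$n_lipids))
})

test_that("lipid displacement: statics, drift, and the frame oracle", {
  # toy trace: 10 heads
  nh <- 10
  mk_frame <- function(t, pos) list(time = t, x = pos, xu = pos,
                                    box = c(30, 30), lr_bonds = integer(3 * nh))
  base <- cbind(seq(1, 28, 3), 5, 2.25)
  pos0 <- matrix(0, 3 * nh, 3)
  head_idx <- (seq_len(nh) - 1L) * 3L + 1L
  pos0[head_idx, ] <- base
  # static lipids: zero displacement
  frames <- lapply(seq(0, 400, 50), function(t) mk_frame(t, pos0))
  d <- lipid_displacement(frames, window = 100, head_idx = head_idx)
  expect_true(all(d$mean_displacement == 0))
  # uniform drift v: displacement v * window each window
  v <- 0.03
  frames2 <- lapply(seq(0, 400, 50), function(t) {
    p <- pos0; p[, 1] <- p[, 1] + v * t; mk_frame(t, p)
  })
  d2 <- lipid_displacement(frames2, window = 100, head_idx = head_idx)
  expect_equal(d2$mean_displacement, rep(v * 100, nrow(d2)), tolerance = 1e-9)
  # oracle equality: random-walk toy trace vs direct recomputation
  set.seed(33)
  traj <- list()
  p <- pos0
  for (k in 0:8) {
    traj[[k + 1]] <- mk_frame(k * 50, p)
    p <- p + matrix(rnorm(3 * nh * 3, 0, 0.3), 3 * nh, 3)
  }
  d3 <- lipid_displacement(traj, window = 100, head_idx = head_idx)
  # independent brute-force recomputation
  for (w in seq_len(nrow(d3))) {
    t0 <- d3$window_start[w]
    i0 <- which(vapply(traj, `[[`, 0, "time") == t0)
    i1 <- which(vapply(traj, `[[`, 0, "time") == t0 + 100)
    ref <- mean(sqrt(rowSums((traj[[i1]]$xu[head_idx, ] -
                                traj[[i0]]$xu[head_idx, ])^2)))
    expect_equal(d3$mean_displacement[w], ref, tolerance = 1e-12)
  }
  # periodic-jump artifact detection
  bad <- traj
  bad[[3]]$xu[head_idx[2], 1] <- bad[[2]]$xu[head_idx[2], 1] + 20
  expect_error(lipid_displacement(bad, window = 100, head_idx = head_idx),
               "periodic")
})

test_that("relative wrapping time: identity, ratios, N/A handling", {
  expect_equal(relative_wrapping_time(c(150, 160), c(150, 160)), 1.0)
  expect_equal(relative_wrapping_time(rep(200, 5), rep(100, 5)), 2.0)
  expect_true(is.na(relative_wrapping_time(rep(NA_real_, 5), c(100, 120))))
  # incomplete sphere replicas are dropped from the mean
  expect_equal(relative_wrapping_time(c(200, NA, 300), c(100, 100)), 2.5)
  expect_error(relative_wrapping_time(c(200, 300), rep(NA_real_, 3)),
               "baseline")
  # trace-object interface
  mk <- function(t_half) {
    structure(list(times = seq(0, 1000, 10),
                   wrap_fraction = pmin(1, seq(0, 1000, 10) / t_half)),
              class = "wrapping_trace")
  }
  r <- relative_wrapping_time(list(mk(400)), list(mk(200)),
                              threshold = 0.9, hold = 50)
  expect_equal(r, 2, tolerance = 0.1)
})

test_that("transwell permeability: units, linearity, errors", {
  # frozen hand unit conversion: V = 750 uL, A = 0.3 cm^2,
  # C0 = 0.5 mg/mL, dt = 4 h, dC = 0.01 mg/mL -> 3.4722e-6 cm/s
  expect_equal(transwell_papp(0.01), 3.4722222222e-06, tolerance = 1e-9)
  expect_identical(transwell_papp(0), 0)
  expect_equal(transwell_papp(0.02) / transwell_papp(0.01), 2)
  expect_error(transwell_papp(0.01, A = 0), "positive")
  expect_error(transwell_papp(-0.01), "dC")
})

test_that("observable CSV writer round-trips", {
  obs <- data.frame(time = 1:3, wrap_fraction = c(0, 0.5, 1),
                    bond_count = c(0L, 5L, 10L))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_observables_csv(obs, path)
  back <- utils::read.csv(path)
  expect_equal(back, obs)
})
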