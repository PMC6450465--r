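# Small, fast cables for the structural properties; the standard 240-cell
# configuration is exercised by the vulnerability and acceptance tests.

small_nz <- function(n_prepace = 8, bcl = 400, ...) {
  fiber_config(n_cells = 80, composition = "NZ only", bcl = bcl,
               n_prepace = n_prepace, s1_segment = 1:8, ...)
}

test_that("fiber configuration enforces geometry and positivity", {
  expect_error(fiber_config(n_cells = 10), "too small")
  expect_error(fiber_config(bz_range = c(1, 100)), "strictly inside")
  expect_error(fiber_config(bz_range = c(150, 100)), "strictly inside")
  expect_error(fiber_config(diffusion = 0), "positive")
  expect_error(fiber_config(s1_segment = 300:305), "bounds")
  cfg <- fiber_config()
  expect_equal(sum(cfg$zones == "BZ"),
               cfg$bz_range[2] - cfg$bz_range[1] + 1)
  expect_true(all(cfg$zones[1:(cfg$bz_range[1] - 1)] == "NZ"))
})

test_that("activation moves monotonically away from the stimulus site", {
  pp <- run_prepace(small_nz())
  act <- pp$activation[, ncol(pp$activation)]
  expect_true(all(is.finite(act)))
  expect_true(all(diff(act[10:75]) > 0))
})

test_that("every cell activates on every recorded beat during 1:1 conduction", {
  pp <- run_prepace(small_nz(n_prepace = 10), record_beats = 3)
  expect_true(all(is.finite(pp$activation)))
  expect_equal(ncol(pp$activation), 3)
})

test_that("with negligible coupling the stimulated segment fires alone", {
  cfg <- small_nz(n_prepace = 3, diffusion = 1e-9)
  pp <- run_prepace(cfg, record_beats = 1)
  act <- pp$activation[, 1]
  expect_true(all(is.finite(act[cfg$s1_segment])))
  expect_true(all(is.na(act[20:80])))
})

test_that("conduction velocity scales as the square root of the diffusion", {
  cv1 <- conduction_velocity(run_prepace(small_nz()), 20:70)
  # halve the diffusion (doubling it would break the explicit-step
  # stability bound at the default dt/dx)
  cvh <- conduction_velocity(run_prepace(small_nz(diffusion = 3.3e-3 / 2)),
                             20:70)
  expect_equal(cv1 / cvh, sqrt(2), tolerance = 0.05)
  # homogeneous fiber: velocity uniform across sub-ranges
  pp <- run_prepace(small_nz())
  expect_equal(conduction_velocity(pp, 15:40),
               conduction_velocity(pp, 45:70), tolerance = 0.05)
  # uncoupled/blocked recording: undefined
  ppb <- run_prepace(small_nz(n_prepace = 3, diffusion = 1e-9),
                     record_beats = 1)
  expect_error(conduction_velocity(ppb, 20:70, beat = 1), "undefined")
})

test_that("mirrored composition and stimulus reflect the voltage record", {
  cfg <- fiber_config(n_cells = 80, composition = "NZ-BZ-NZ",
                      bz_range = c(21, 40), bcl = 400, n_prepace = 6,
                      s1_segment = 1:6)
  cfgm <- fiber_config(n_cells = 80, composition = "NZ-BZ-NZ",
                       bz_range = c(41, 60), bcl = 400, n_prepace = 6,
                       s1_segment = 75:80)
  vm <- run_prepace(cfg, record_beats = 1)$vm
  vmm <- run_prepace(cfgm, record_beats = 1)$vm
  expect_equal(vm, vmm[nrow(vmm):1, ], tolerance = 1e-6)
})

test_that("space-time refinement leaves activation and APD90 nearly unchanged", {
  base <- run_prepace(small_nz(), record_beats = 1)
  fine_t <- run_prepace(small_nz(dt = 0.01), record_beats = 1)
  expect_lt(max(abs(base$activation - fine_t$activation)), 1)
  expect_lt(max(abs(base$apd90 - fine_t$apd90)), 0.5)
  # halve dx (double the cells over the same physical length)
  cfgx <- fiber_config(n_cells = 160, composition = "NZ only", bcl = 400,
                       n_prepace = 8, s1_segment = 1:16, dx = 0.0125 / 2,
                       dt = 0.005)  # halved dx tightens the stability bound
  fine_x <- run_prepace(cfgx, record_beats = 1)
  probe <- c(20, 40, 60)  # physical positions via matching indices
  expect_lt(max(abs(base$activation[probe, 1] -
                      fine_x$activation[2 * probe - 1, 1])), 1)
  expect_lt(max(abs(base$apd90[probe, 1] -
                      fine_x$apd90[2 * probe - 1, 1])), 0.5)
})

test_that("premature stimulation validates its inputs", {
  pp <- run_prepace(small_nz(n_prepace = 4), record_beats = 2)
  expect_error(apply_s2(pp, 300:310, 200), "bounds")
  expect_error(apply_s2(pp, 40:47, -5), "positive")
  rec <- apply_s2(pp, 40:47, 250)
  expect_s3_class(rec, "fiber_recording")
  expect_equal(rec$s2$ci, 250)
})

test_that("integration failure is reported with its location", {
  cfg <- small_nz(n_prepace = 2, dt = 1)  # grossly unstable step
  expect_error(run_prepace(cfg), "integration failure")
})
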