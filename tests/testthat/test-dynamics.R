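test_that("identical seed and configuration give bitwise-identical output", {
  sv <- small_vesicle()
  ves <- add_solutes(sv$ves, 40, 80, seed = 3)
  db <- place_dumbbell(ves, a = 2.0, "perpendicular", seed = 3)
  sp <- sim_params(dt = 0.008, n_steps = 1500, kBT = 0.23, seed = 9,
                   stride = 500)
  t1 <- run_dynamics(ves, db, sp)
  t2 <- run_dynamics(ves, db, sp)
  expect_identical(t1$final, t2$final)
  expect_identical(t1$diag, t2$diag)
  t3 <- run_dynamics(ves, db, sim_params(dt = 0.008, n_steps = 1500,
                                         kBT = 0.23, seed = 10, stride = 500))
  expect_false(identical(t1$final$beads, t3$final$beads))
})

test_that("free streaming at zero temperature leaves the state frozen", {
  sv <- small_vesicle()
  sp <- sim_params(dt = 0.01, n_steps = 500, kBT = 0, interactions = FALSE,
                   thermal_init = FALSE, rupture_check = FALSE)
  tr <- run_dynamics(sv$ves, sim = sp)
  expect_identical(tr$final$beads, sv$ves$beads)
  expect_identical(tr$final$normals, sv$ves$normals)
})

test_that("particle counts are conserved and normals stay unit length", {
  sv <- small_vesicle()
  ves <- add_solutes(sv$ves, 30, 60, seed = 2)
  tr <- run_dynamics(ves, sim = sim_params(dt = 0.008, n_steps = 2000,
                                           kBT = 0.23, seed = 4))
  expect_equal(nrow(tr$final$beads), nrow(ves$beads))
  expect_equal(nrow(tr$final$solutes_in), 30)
  expect_equal(nrow(tr$final$solutes_out), 60)
  expect_equal(rowSums(tr$final$normals^2), rep(1, nrow(ves$beads)),
               tolerance = 1e-9)
})

test_that("the dumbbell stays rigid: lobe separation exactly 2a", {
  sv <- small_vesicle()
  db <- place_dumbbell(sv$ves, a = 2.0, "parallel", seed = 5)
  tr <- run_dynamics(sv$ves, db,
                     sim_params(dt = 0.008, n_steps = 3000, kBT = 0.23,
                                epsilon_ad = 1.5, r_cut_ad = 2.2, seed = 5,
                                stride = 300))
  for (i in seq_along(tr$times)) {
    ax <- tr$dumbbell_axis[i, ]
    expect_equal(sqrt(sum(ax^2)), 1, tolerance = 1e-9)
    lc <- rbind(tr$dumbbell_center[i, ] + 2.0 * ax,
                tr$dumbbell_center[i, ] - 2.0 * ax)
    expect_equal(sqrt(sum((lc[1, ] - lc[2, ])^2)), 4.0, tolerance = 1e-9)
  }
})

test_that("the thermostat equipartitions energy over the degrees of freedom", {
  sv <- small_vesicle()
  kBT <- 0.23
  tr <- run_dynamics(sv$ves, sim = sim_params(dt = 0.008, n_steps = 8000,
                                              kBT = kBT, seed = 6,
                                              diag_stride = 10))
  n <- nrow(sv$ves$beads)
  late <- tr$diag$time > 20
  # 3 translational DOF -> 3/2 kBT, 2 rotational DOF -> kBT per bead
  expect_equal(mean(tr$diag$ke_trans[late]) / n, 1.5 * kBT, tolerance = 0.05)
  expect_equal(mean(tr$diag$ke_rot[late]) / n, kBT, tolerance = 0.05)
})

test_that("microcanonical dynamics conserve energy at small timestep", {
  sv <- small_vesicle()
  # thermalise briefly, then switch the thermostat off
  t1 <- run_dynamics(sv$ves, sim = sim_params(dt = 0.005, n_steps = 2000,
                                              kBT = 0.2, seed = 7))
  st <- sv$ves
  st$beads <- t1$final$beads
  st$normals <- t1$final$normals
  t2 <- run_dynamics(st, sim = sim_params(dt = 0.002, n_steps = 10000,
                                          kBT = 0.2, gamma_t = 0, gamma_r = 0,
                                          seed = 8, diag_stride = 100,
                                          rupture_check = FALSE))
  E <- t2$diag$pe + t2$diag$ke_trans + t2$diag$ke_rot
  drift_per_bead <- abs(E[length(E)] - E[1]) / nrow(st$beads)
  expect_lt(drift_per_bead, 1e-3)
})

test_that("solute pressure on the membrane follows the ideal-gas estimate", {
  sv <- small_vesicle()
  kBT <- 0.23
  ctr <- colMeans(sv$ves$beads)
  Rrel <- mean(sqrt(rowSums(sweep(sv$ves$beads, 2, ctr, `-`)^2)))
  cnt <- set_tension_by_solutes(0.06, Rrel + 0.2, kBT,
                                geometry = list(R_wall = 1.6 * sv$R0,
                                                c_out = 0.02))
  ves <- add_solutes(sv$ves, cnt$n_in, cnt$n_out, R_wall = 1.6 * sv$R0,
                     seed = 7)
  tr <- run_dynamics(ves, sim = sim_params(dt = 0.005, n_steps = 22000,
                                           kBT = kBT, seed = 8,
                                           diag_stride = 5))
  late <- tr$diag$time > 35
  dp <- mean(tr$diag$p_in[late] - tr$diag$p_out[late])
  expect_equal(dp, cnt$dP, tolerance = 0.15)
})

test_that("overwhelming adhesion tears the membrane and flags rupture", {
  sv <- small_vesicle()
  db <- place_dumbbell(sv$ves, a = 2.2, "perpendicular", seed = 9)
  tr <- run_dynamics(sv$ves, db,
                     sim_params(dt = 0.008, n_steps = 30000, kBT = 0.23,
                                epsilon_ad = 6, r_cut_ad = 1.5, seed = 9,
                                stride = 2000))
  expect_true(tr$ruptured)
  expect_gt(tr$rupture_step, 0)
  expect_lt(max(tr$times), 30000 * 0.008 + 1e-9)  # run stopped early
})
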