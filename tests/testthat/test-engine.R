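# Integrator, pair-list maintenance and run-loop behaviour.

test_that("Euler relaxation of a tethered node matches the closed form", {
  # one free node tied by a zero-rest spring (k) to a fixed anchor: the
  # Euler-discretised distance follows x0 * (1 - k*dt/C)^n exactly
  k <- 4; dt <- 0.002; x0 <- 1.5; n <- 400
  pos <- rbind(c(0, 0), c(x0, 0))
  packed <- list(si = 1L, sj = 2L, sk = k, sr0 = 0, sbrk = Inf,
                 vi = integer(0), vj = integer(0),
                 vprm = c(1, 0.1, 1, 0.2, 0.3),
                 ni = integer(0), nj = integer(0),
                 nprm = c(1, 0.1, 1, 0.2, 0.3),
                 ring_idx = integer(0), ring_off = 0L,
                 area0 = numeric(0), kvol = 0)
  inv_damp <- c(0, 1)       # anchor has infinite drag
  out <- wingsce:::cpp_step_n(pos, inv_damp, packed, n, dt)
  expect_equal(out[2, 1], x0 * (1 - k * dt)^n, tolerance = 1e-12)
  expect_equal(out[1, ], c(0, 0))
})

test_that("zero forces leave positions unchanged; dt scales one-step motion", {
  ep <- energy_params()
  dp <- damping_params()
  st <- mini_tissue()
  st1 <- step_tissue(st, ep, dp, dt = 0.002)
  expect_lt(max(abs(st1$pos - st$pos)), 0.05 * 0.002 * 1.01)
  # linearity of a single Euler step in dt (engaged forces)
  ep2 <- energy_params()
  ep2$e_cont$k <- 9
  st <- refresh_pairs(st, ep2)
  a <- step_tissue(st, ep2, dp, dt = 0.002)$pos - st$pos
  b <- step_tissue(st, ep2, dp, dt = 0.001)$pos - st$pos
  expect_lt(max(abs(a - 2 * b)), 1e-12)
})

test_that("the engine refuses an unstable time step and names the term", {
  ep <- energy_params()
  ep$e_memb$k <- 2000
  st <- three_cell_rig()
  expect_error(run_simulation(st, ep, damping_params(), sim_config()),
               "E_memb")
})

test_that("blow-up is reported with the step and node", {
  st <- three_cell_rig()
  ep <- energy_params()
  ep$e_cont$k <- 9
  st <- refresh_pairs(st, ep)
  expect_error(step_tissue(st, ep, damping_params(), dt = 50, n_steps = 50),
               "blew up")
})

test_that("pair matching is symmetric and respects adjacency rules", {
  ep <- energy_params()
  st <- three_cell_rig(ep)
  st <- refresh_pairs(st, ep)
  # volume-exclusion pairs: no duplicated unordered pair
  key <- paste(pmin(st$excl_pairs[, 1], st$excl_pairs[, 2]),
               pmax(st$excl_pairs[, 1], st$excl_pairs[, 2]))
  expect_false(any(duplicated(key)))
  # no bonded ring neighbours in the exclusion list
  for (r in seq_len(nrow(st$excl_pairs))) {
    i <- st$excl_pairs[r, 1]; j <- st$excl_pairs[r, 2]
    if (!is.na(st$cell_id[i]) && !is.na(st$cell_id[j]) &&
        st$cell_id[i] == st$cell_id[j] &&
        st$node_class[i] == 2L && st$node_class[j] == 2L) {
      dpos <- abs(st$ring_pos[i] - st$ring_pos[j])
      expect_true(dpos > 1 && dpos < st$ring_len[i] - 1)
    }
  }
  # adhesion: one partner per node within each list
  expect_false(any(duplicated(st$bonds$adh_basal$i)))
  expect_false(any(duplicated(st$bonds$adh_basal$j)))
})

test_that("contractility pairs track the nucleus height", {
  ep <- energy_params()
  ep$e_cont$k <- 9
  st <- three_cell_rig(ep)
  st <- refresh_pairs(st, ep)
  cid <- st$columnar_cells[2]
  n0 <- sum(st$cell_id[st$bonds$cont$i] == cid)
  # brute-force recount from node heights
  cl <- st$cells[[cid]]
  thr <- min(st$pos[cl$nucleus, 2]) - st$config$membrane_node_spacing
  nL <- sum(st$region[cl$ring] == "lateral_left" &
              st$pos[cl$ring, 2] < thr)
  nR <- sum(st$region[cl$ring] == "lateral_right" &
              st$pos[cl$ring, 2] < thr)
  expect_equal(n0, min(nL, nR))
  # move the nucleus apically: freed levels join the contraction zone
  st2 <- st
  st2$pos[cl$nucleus, 2] <- st2$pos[cl$nucleus, 2] + 5
  st2 <- refresh_pairs(st2, ep)
  n2 <- sum(st2$cell_id[st2$bonds$cont$i] == cid)
  thr2 <- min(st2$pos[cl$nucleus, 2]) - st2$config$membrane_node_spacing
  nL2 <- sum(st2$region[cl$ring] == "lateral_left" &
               st2$pos[cl$ring, 2] < thr2)
  nR2 <- sum(st2$region[cl$ring] == "lateral_right" &
               st2$pos[cl$ring, 2] < thr2)
  expect_equal(n2, min(nL2, nR2))
  expect_gt(n2, n0)
})

test_that("trajectories are deterministic", {
  ep <- energy_params()
  ep$e_cont$k <- 6
  dp <- damping_params()
  sim <- sim_config(max_steps = 600L, output_interval = 200L)
  tr1 <- run_simulation(build_tissue(tissue_config(preset = "mini"), ep),
                        ep, dp, sim)
  tr2 <- run_simulation(build_tissue(tissue_config(preset = "mini"), ep),
                        ep, dp, sim)
  expect_identical(tr1$state$pos, tr2$state$pos)
  expect_identical(tr1$curvature, tr2$curvature)
})

test_that("a rigid motion of the initial state rigidly moves the outcome", {
  ep <- energy_params()
  ep$e_cont$k <- 9
  dp <- damping_params()
  sim <- sim_config(max_steps = 500L, output_interval = 250L)
  st <- build_tissue(tissue_config(preset = "mini"), ep)
  th <- 0.35
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  st2 <- st
  st2$pos <- sweep(st$pos %*% t(R), 2, c(5, 7), "+")
  out1 <- run_simulation(st, ep, dp, sim)
  out2 <- run_simulation(st2, ep, dp, sim)
  back <- sweep(out2$state$pos, 2, c(5, 7), "-") %*% R
  expect_equal(back, out1$state$pos, tolerance = 1e-8)
  expect_equal(out2$curvature, out1$curvature, tolerance = 1e-9)
})

test_that("the convergence detector fires on a constant series", {
  ep <- energy_params()        # baseline: nothing moves
  dp <- damping_params()
  sim <- sim_config(max_steps = 20000L, output_interval = 250L,
                    convergence_window = 2000L)
  st <- build_tissue(tissue_config(preset = "mini"), ep)
  out <- run_simulation(st, ep, dp, sim)
  expect_true(out$converged)
  expect_lt(out$steps, sim$max_steps)
})

test_that("halving dt changes the short-run outcome only slightly", {
  ep <- energy_params()
  ep$e_cont$k <- 9
  dp <- damping_params()
  st <- build_tissue(tissue_config(preset = "mini"), ep)
  sim1 <- sim_config(dt = 0.002, max_steps = 4000L,
                     convergence_window = 4000L)
  sim2 <- sim_config(dt = 0.001, max_steps = 8000L,
                     convergence_window = 8000L)
  k1 <- run_simulation(st, ep, dp, sim1)
  k2 <- run_simulation(st, ep, dp, sim2)
  c1 <- k1$curvature[length(k1$curvature)]
  c2 <- k2$curvature[length(k2$curvature)]
  expect_lt(abs(c1 - c2), 0.01 * max(abs(c2), 0.005))
})

test_that("scheduled events validate and apply", {
  ep <- energy_params()
  dp <- damping_params()
  st <- build_tissue(tissue_config(preset = "mini"), ep)
  expect_error(
    run_simulation(st, ep, dp, sim_config(max_steps = 100L),
                   events = list(list(time = 100, action = "set_k_cont",
                                      value = 0))),
    "beyond")
  out <- run_simulation(st, ep, dp,
                        sim_config(max_steps = 400L, output_interval = 200L),
                        events = list(list(time = 0.2, action = "set_k_cont",
                                           value = 5)))
  expect_equal(out$ep$e_cont$k, 5)
})
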