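# Tissue construction, prestrain, fixtures and snapshot IO.

test_that("the calibrated geometry is built with the configured counts", {
  cfg <- tissue_config(preset = "full")
  expect_equal(cfg$n_columnar, 65)
  expect_equal(cfg$columnar_width, 2.5)
  expect_equal(cfg$columnar_height, 25)
  expect_equal(cfg$n_squamous, 10)
  st <- build_tissue(cfg, relax = FALSE)   # geometry checks only
  expect_equal(length(st$columnar_cells), 65)
  expect_equal(length(st$squamous_cells), 10)
  expect_equal(length(st$boundary_cells), 4)
  cl <- st$cells[[st$columnar_cells[1]]]
  P <- st$pos[cl$ring, ]
  expect_equal(diff(range(P[, 2])), 25)
  expect_equal(diff(range(P[, 1])), 2.5 - 0.2, tolerance = 1e-9)
})

test_that("built tissue is flat with nuclei at the configured fraction", {
  st <- mini_tissue()
  expect_lt(abs(tissue_global_curvature(st)), 5e-3)
  np <- tissue_nuclear_positions(st)
  expect_equal(mean(np$fraction), 0.65, tolerance = 6e-3)
  # target areas match the constructed polygons
  for (cid in st$columnar_cells) {
    cl <- st$cells[[cid]]
    expect_gt(cl$target_area, 0)
  }
})

test_that("cells tile without overlap and rings are simple polygons", {
  st <- build_tissue(tissue_config(preset = "mini"), relax = FALSE)
  for (cl in st$cells) {
    expect_gt(polygon_area(st$pos[cl$ring, ]), 0)     # counter-clockwise
    # nuclei inside the bounding box of the ring
    P <- st$pos[cl$ring, ]
    N <- st$pos[cl$nucleus, , drop = FALSE]
    expect_true(all(N[, 1] > min(P[, 1]) & N[, 1] < max(P[, 1])))
    expect_true(all(N[, 2] > min(P[, 2]) & N[, 2] < max(P[, 2])))
  }
  # region tags partition each ring into contiguous arcs
  for (cl in st$cells) {
    tags <- st$region[cl$ring]
    runs <- rle(tags)$values
    expect_lte(length(runs), 4 + (tags[1] == tags[length(tags)]))
  }
})

test_that("ECM chain regions are contiguous in the order ECMs-ECMbc-ECMc-ECMbc", {
  st <- build_tissue(tissue_config(preset = "mini"), relax = FALSE)
  runs <- rle(st$region[st$ecm_chain])$values
  expect_equal(runs, c("ECMs", "ECMbc", "ECMc", "ECMbc"))
})

test_that("adjacent columnar cells share lateral adhesion at matching heights", {
  st <- build_tissue(tissue_config(preset = "mini"), relax = FALSE)
  b <- st$bonds$adh_lateral
  dy <- abs(st$pos[b$i, 2] - st$pos[b$j, 2])
  expect_lt(max(dy), 1e-9)
})

test_that("prestrain loads each ECM region with the requested tension", {
  ep <- energy_params()
  st <- build_tissue(tissue_config(preset = "mini"), ep, relax = FALSE)
  st0 <- apply_prestrain(st, prestrain_spec(0, 0, 0), ep)
  expect_equal(st0$bonds$ecm$r0, st$bonds$ecm$r0)

  spec <- prestrain_spec(F_ECMs = 1.5, F_ECMc = 6)
  st2 <- apply_prestrain(st, spec, ep)
  ten <- ecm_spring_tension(st2, ep)
  for (reg in c("ECMs", "ECMbc", "ECMc")) {
    want <- switch(reg, ECMs = 1.5, ECMbc = 1.5, ECMc = 6)
    expect_equal(ten$tension[ten$region == reg],
                 rep(want, sum(ten$region == reg)), tolerance = 1e-9)
  }
  # ratio of mean tensions is exactly the requested 4x
  st4 <- apply_prestrain(st, prestrain_spec(F_ECMs = 1, F_ECMc = 4), ep)
  t4 <- ecm_spring_tension(st4, ep)
  expect_equal(mean(t4$tension[t4$region == "ECMc"]) /
                 mean(t4$tension[t4$region == "ECMs"]), 4, tolerance = 1e-9)
  expect_error(apply_prestrain(st, prestrain_spec(F_ECMs = 1e5), ep),
               "rest length")
})

test_that("arc fixtures carry their analytic curvature", {
  a <- make_arc_fixture(10, 1, 50)
  expect_equal(a$curvature, 0.1)
  expect_equal(sqrt(sum(a$points[1, ]^2)), 10, tolerance = 1e-12)
  flat <- make_arc_fixture(Inf, 12, 5)
  expect_equal(flat$curvature, 0)
  # seeded noise is reproducible
  n1 <- make_arc_fixture(5, 1, 30, noise_sd = 0.1, seed = 4)
  n2 <- make_arc_fixture(5, 1, 30, noise_sd = 0.1, seed = 4)
  expect_identical(n1$points, n2$points)
})

test_that("node snapshots round-trip through CSV", {
  st <- build_tissue(tissue_config(preset = "mini"), relax = FALSE)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  tab <- write_tissue_csv(st, path)
  back <- read_tissue_csv(path)
  expect_equal(back$x, tab$x)
  expect_equal(back$y, tab$y)
  expect_equal(back$class, tab$class)
  expect_equal(back$region, tab$region)
})

test_that("trajectory containers round-trip", {
  ep <- energy_params()
  st <- build_tissue(tissue_config(preset = "mini"), ep)
  tr <- run_simulation(st, ep, damping_params(),
                       sim_config(max_steps = 300L, output_interval = 100L))
  path <- tempfile(fileext = ".rds")
  on.exit(unlink(path))
  write_trajectory(tr, path)
  back <- read_trajectory(path)
  expect_identical(back$curvature, tr$curvature)
  expect_identical(back$state$pos, tr$state$pos)
})

test_that("node removal drops all references and reindexes", {
  st <- build_tissue(tissue_config(preset = "mini"), relax = FALSE)
  ecm <- which(st$node_class == 3L)
  st2 <- remove_nodes(st, ecm)
  expect_equal(nrow(st2$pos), nrow(st$pos) - length(ecm))
  expect_false(any(st2$node_class == 3L))
  expect_length(st2$ecm_chain, 0)
  expect_length(st2$bonds$ecm$i, 0)
  expect_length(st2$bonds$adh_basal$i, 0)
  # cells intact
  expect_equal(length(st2$cells), length(st$cells))
  expect_error(remove_nodes(st, st$cells[[1]]$ring[1]), "belonging")
})

test_that("parameter config files round-trip with unknown keys rejected", {
  path <- tempfile(fileext = ".yaml")
  on.exit(unlink(path))
  writeLines(c("E_cont:", "  k: 9",
               "E_vol:", "  k_vol: 7",
               "damping:", "  C_nuc: 2"), path)
  cfg <- read_param_config(path)
  expect_equal(cfg$energy$e_cont$k, 9)
  expect_equal(cfg$energy$k_vol, 7)
  expect_equal(cfg$damping$C_nuc, 2)
  writeLines(c("E_bogus:", "  k: 1"), path)
  expect_error(read_param_config(path), "unknown configuration block")
  writeLines(c("E_memb:", "  stiffness: 1"), path)
  expect_error(read_param_config(path), "unknown key")
})
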