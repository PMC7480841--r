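# Shape metrics: circumcircle/Menger curvature, nuclear position, fits.

test_that("circumcircle curvature recovers 1/R and matches a geometric oracle", {
  th <- c(0.3, 1.1, 2.2)
  P <- 10 * cbind(cos(th), sin(th))
  expect_equal(abs(circumcircle_curvature(P[1, ], P[2, ], P[3, ])), 0.1,
               tolerance = 1e-12)
  expect_equal(circumcircle_curvature(c(0, 0), c(1, 0), c(2, 0)), 0)
  expect_error(circumcircle_curvature(c(0, 0), c(0, 0), c(1, 1)), "duplicate")

  # independent oracle: circumcentre from perpendicular-bisector intersection
  circum_r <- function(p1, p2, p3) {
    ax <- p1[1]; ay <- p1[2]; bx <- p2[1]; by <- p2[2]; cx <- p3[1]; cy <- p3[2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    sqrt((ax - ux)^2 + (ay - uy)^2)
  }
  set.seed(3)
  for (k in 1:200) {
    p <- matrix(rnorm(6, sd = 4), 3, 2)
    a <- sqrt(sum((p[1, ] - p[2, ])^2))
    if (abs(circumcircle_curvature(p[1, ], p[2, ], p[3, ])) < 1e-6) next
    expect_equal(abs(circumcircle_curvature(p[1, ], p[2, ], p[3, ])),
                 1 / circum_r(p[1, ], p[2, ], p[3, ]), tolerance = 1e-10)
  }
})

test_that("Menger and circumcircle curvature agree on random triples", {
  set.seed(17)
  for (k in 1:1000) {
    p <- matrix(runif(6, -5, 5), 3, 2)
    if (min(dist(p)) < 1e-3) next
    # Menger curvature: 4 * area / product of side lengths
    a <- sqrt(sum((p[1, ] - p[2, ])^2))
    b <- sqrt(sum((p[2, ] - p[3, ])^2))
    d <- sqrt(sum((p[3, ] - p[1, ])^2))
    area <- abs((p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
                  (p[3, 1] - p[1, 1]) * (p[2, 2] - p[1, 2])) / 2
    expect_equal(abs(circumcircle_curvature(p[1, ], p[2, ], p[3, ])),
                 4 * area / (a * b * d), tolerance = 1e-10)
  }
})

test_that("global curvature of arc fixtures is the analytic 1/R with sign", {
  arc <- make_arc_fixture(20, pi, 101)
  expect_equal(global_curvature(arc$points), 0.05, tolerance = 1e-9)
  flat <- make_arc_fixture(Inf, 30, 11)
  expect_equal(global_curvature(flat$points), 0)
  # reflection flips the sign, rigid motion preserves it
  refl <- arc$points %*% diag(c(1, -1))
  expect_equal(global_curvature(refl), -0.05, tolerance = 1e-9)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- sweep(arc$points %*% t(R), 2, c(3, -4), "+")
  expect_equal(global_curvature(rot), 0.05, tolerance = 1e-9)
})

test_that("Menger profile recovers constant and piecewise-constant curvature", {
  circ <- make_arc_fixture(5, 2.5, 401)
  # a window that is an exact multiple of the vertex spacing makes the
  # interpolated window endpoints coincide with true circle points
  w_exact <- polyline_arclength(circ$points)[33]
  prof <- menger_profile(circ$points, window_halfwidth = w_exact)
  expect_true(all(abs(prof$curvature - 0.2) < 1e-6))

  line <- make_arc_fixture(Inf, 40, 200)
  prof0 <- menger_profile(line$points, window_halfwidth = 5)
  expect_true(all(abs(prof0$curvature) < 1e-9))

  # two joined arcs of different radii: both plateaus recovered away from
  # the junction
  a1 <- make_arc_fixture(10, 1.2, 150)$points
  a2 <- make_arc_fixture(25, 0.6, 150)$points
  a2 <- sweep(a2, 2, a2[1, ] - a1[nrow(a1), ], "-")[-1, ]
  two <- rbind(a1, a2)
  prof2 <- menger_profile(two, window_halfwidth = 1)
  s_join <- polyline_arclength(two)[nrow(a1)]
  left <- prof2$curvature[prof2$arclength < s_join - 2]
  right <- prof2$curvature[prof2$arclength > s_join + 2]
  expect_lt(max(abs(left - 0.1) / 0.1), 0.05)
  expect_lt(max(abs(right - 0.04) / 0.04), 0.05)
})

test_that("noisy arc fixture is recovered by the Menger profile mean", {
  arc <- make_arc_fixture(5, 2, 200, noise_sd = 0.05, seed = 5)
  prof <- menger_profile(arc$points, window_halfwidth = 2.5)
  expect_lt(abs(mean(prof$curvature) - 0.2) / 0.2, 0.05)
})

test_that("fractional nuclear position spans basal 0 to apical 1", {
  ap <- cbind(seq(0, 2.5, by = 0.5), 25)
  ba <- cbind(seq(0, 2.5, by = 0.5), 0)
  at_basal <- nuclear_position(ap, ba, c(1.25, 0))
  expect_equal(at_basal$fraction, 0)
  at_apical <- nuclear_position(ap, ba, c(1.25, 25))
  expect_equal(at_apical$fraction, 1)
  mid <- nuclear_position(ap, ba, c(1.25, 12.5))
  expect_equal(mid$L_A, 12.5)
  expect_equal(mid$L_B, 12.5)
  expect_equal(mid$fraction, 0.5)
  expect_equal(mid$height, 25)
  expect_error(nuclear_position(ap, ap, ap[1, ]), "degenerate")
})

test_that("per-cell metrics and the summary table are consistent", {
  st <- mini_tissue()
  np <- tissue_nuclear_positions(st)
  expect_true(all(np$fraction >= 0 & np$fraction <= 1))
  expect_true(all(np$height > 0))
  expect_equal(mean(np$fraction), 0.65, tolerance = 6e-3)
  tab <- shape_metric_table(st)
  expect_equal(tab$fraction[nrow(tab)], mean(np$fraction))
  expect_equal(attr(tab, "fraction_sd"), sd(np$fraction))
})

test_that("asymptotic fit recovers plateaus", {
  t <- seq(0, 30000, length.out = 100)
  c_exact <- 0.04 * (1 - exp(-t / 5000))
  fit <- asymptotic_fit(t, c_exact)
  expect_equal(fit$c_inf, 0.04, tolerance = 1e-6)
  expect_lt(fit$residual, 1e-6)

  const <- asymptotic_fit(t[1:50], rep(0.02, 50))
  expect_equal(const$c_inf, 0.02)
  expect_equal(const$residual, 0)

  set.seed(21)
  noisy <- c_exact + rnorm(length(t), sd = 0.02 * 0.04)
  fitn <- asymptotic_fit(t, noisy)
  expect_lt(abs(fitn$c_inf - 0.04) / 0.04, 0.03)
})

test_that("tissue curvature metrics are invariant under rigid motion", {
  st <- mini_tissue()
  k0 <- tissue_global_curvature(st)
  np0 <- tissue_nuclear_positions(st)
  th <- 0.5
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  st2 <- st
  st2$pos <- sweep(st$pos %*% t(R), 2, c(10, -3), "+")
  expect_equal(tissue_global_curvature(st2), k0, tolerance = 1e-9)
  np2 <- tissue_nuclear_positions(st2)
  expect_equal(np2$fraction, np0$fraction, tolerance = 1e-9)
  expect_equal(np2$height, np0$height, tolerance = 1e-9)
})
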