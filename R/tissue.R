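# Construction of the flat initial tissue: columnar pouch, marginal boundary
# cells, squamous layer above a lumen gap, and a three-region ECM chain
# wrapping the basal perimeter. Geometry is arranged so that every spring sits
# at rest, every cell at its target area, every non-bonded gap at or beyond
# the volume-exclusion cutoff and every nucleus cluster at a relaxed Morse
# equilibrium: a freshly built tissue carries no force.

NODE_CLASSES <- c("nucleus", "membrane", "ecm")

#' Tissue geometry configuration
#'
#' Defaults reproduce the calibrated cross-section: 65 columnar cells of
#' 2.5 x 25 um, 10 squamous cells of nominally 16 x 4 um, 2 marginal boundary
#' cells per side, nuclei biased to fractional height 0.65. Presets:
#' `"full"` (the calibrated geometry), `"reduced"` (17 columnar cells at
#' 1.25 um node spacing, for desk-scale runs), and `"mini"` (9 columnar
#' cells, for parameter sweeps).
#'
#' @param n_columnar number of columnar pouch cells
#' @param columnar_width,columnar_height columnar cell size (um)
#' @param n_squamous number of squamous cells; the layer is stretched to span
#'   the full tissue width, so the realised cell width is span/n_squamous
#' @param squamous_width,squamous_height nominal squamous cell size (um);
#'   the height is used as given, the width only to sanity-check the span
#' @param n_boundary_per_side marginal boundary cells closing each margin
#' @param membrane_node_spacing target arc distance between membrane nodes (um)
#' @param nucleus_nodes_per_cell nodes in each nucleus cluster
#' @param initial_nuclear_fraction initial fractional apicobasal nuclear
#'   position of columnar cells (0 basal, 1 apical)
#' @param ecm_node_spacing target ECM node spacing (um); defaults to the
#'   membrane spacing
#' @param adhesion_zone_fraction central fraction of columnar cells forming
#'   the tight adhesion zone used for interlayer-gap detection
#' @param adhesion_span_fraction fraction of columnar cells (centred) whose
#'   apical nodes may form interlayer adhesion; the default couples the whole
#'   pouch to the squamous layer, standing in for force transmission through
#'   the enclosed lumen
#' @param lumen_gap apical separation between the two layers (um); defaults to
#'   the apical-adhesion rest length at build time
#' @param squamous_prestress fractional shortening of squamous membrane rest
#'   lengths, encoding the lateral actomyosin tension that keeps squamous
#'   cells flat and taut; this is the pulling force the squamous layer exerts
#'   on the columnar layer through the marginal cells
#' @param rng_seed seed used by stochastic fixtures derived from this config
#' @param preset one of `"full"`, `"reduced"`, `"mini"`
#' @return an object of class `tissue_config`
#' @export
tissue_config <- function(n_columnar = 65, columnar_width = 2.5,
                          columnar_height = 25, n_squamous = 10,
                          squamous_width = 16, squamous_height = 4,
                          n_boundary_per_side = 2,
                          membrane_node_spacing = 0.5,
                          nucleus_nodes_per_cell = 10,
                          initial_nuclear_fraction = 0.65,
                          ecm_node_spacing = membrane_node_spacing,
                          adhesion_zone_fraction = 0.2,
                          adhesion_span_fraction = 1,
                          lumen_gap = NULL,
                          squamous_prestress = 0.1,
                          rng_seed = 1L,
                          preset = c("custom", "full", "reduced", "mini")) {
  preset <- match.arg(preset)
  if (preset == "reduced") {
    n_columnar <- 17; membrane_node_spacing <- 1.25
    ecm_node_spacing <- 1.25; n_squamous <- 3
  } else if (preset == "mini") {
    n_columnar <- 9; membrane_node_spacing <- 1.25
    ecm_node_spacing <- 1.25; n_squamous <- 2; n_boundary_per_side <- 1
  }
  stopifnot(n_columnar >= 1, n_squamous >= 1, n_boundary_per_side >= 1,
            columnar_width > 0, columnar_height > 0, squamous_height > 0,
            membrane_node_spacing > 0, ecm_node_spacing > 0,
            nucleus_nodes_per_cell >= 1,
            initial_nuclear_fraction > 0, initial_nuclear_fraction < 1,
            adhesion_zone_fraction > 0, adhesion_zone_fraction <= 1,
            adhesion_span_fraction > 0, adhesion_span_fraction <= 1,
            squamous_prestress >= 0, squamous_prestress < 1)
  structure(list(n_columnar = n_columnar, columnar_width = columnar_width,
                 columnar_height = columnar_height, n_squamous = n_squamous,
                 squamous_width = squamous_width,
                 squamous_height = squamous_height,
                 n_boundary_per_side = n_boundary_per_side,
                 membrane_node_spacing = membrane_node_spacing,
                 nucleus_nodes_per_cell = nucleus_nodes_per_cell,
                 initial_nuclear_fraction = initial_nuclear_fraction,
                 ecm_node_spacing = ecm_node_spacing,
                 adhesion_zone_fraction = adhesion_zone_fraction,
                 adhesion_span_fraction = adhesion_span_fraction,
                 lumen_gap = lumen_gap, squamous_prestress = squamous_prestress,
                 rng_seed = as.integer(rng_seed)),
            class = "tissue_config")
}

# nodes of a rectangular membrane ring, counter-clockwise from the
# bottom-left corner; tags partition the ring into four contiguous arcs.
# For squamous cells the apical surface faces the lumen below, so tags flip.
ring_rect <- function(xl, xr, yb, yt, spacing, apical_on_top = TRUE) {
  nx <- max(1L, round((xr - xl) / spacing))
  ny <- max(1L, round((yt - yb) / spacing))
  xs <- seq(xl, xr, length.out = nx + 1)
  ys <- seq(yb, yt, length.out = ny + 1)
  pts <- rbind(cbind(xs, yb),                       # bottom, left -> right
               cbind(xr, ys[seq(2, ny)]),           # right, up (interior)
               cbind(rev(xs), yt),                  # top, right -> left
               cbind(xl, rev(ys[seq(2, ny)])))      # left, down (interior)
  bot <- if (apical_on_top) "basal" else "apical"
  top <- if (apical_on_top) "apical" else "basal"
  tag <- c(rep(bot, nx + 1), rep("lateral_right", ny - 1),
           rep(top, nx + 1), rep("lateral_left", ny - 1))
  dimnames(pts) <- NULL
  list(pts = pts, tag = tag)
}

# Seed arrangement for an M-node nucleus cluster: a narrow two-column
# lattice at the cohesion equilibrium spacing, centred at the origin. It fits
# inside the cell at build time; the build-time relaxation then lets it round
# up against the membrane into its true equilibrium shape.
nucleus_seed <- function(M, p) {
  rstar <- morse_equilibrium(p)
  if (M == 1) return(matrix(0, 1, 2))
  nrow_ <- ceiling(M / 2)
  ys <- rep(seq_len(nrow_), each = 2)[seq_len(M)]
  xs <- rep(c(-0.45, 0.45) * rstar, length.out = M)
  P <- cbind(xs, 0.95 * rstar * ys)
  P - rep(colMeans(P), each = M)
}

.wingsce_cache <- new.env(parent = emptyenv())

empty_bonds <- function() list(i = integer(0), j = integer(0), r0 = numeric(0))

#' Build the flat initial tissue
#'
#' Constructs the full cross-section: columnar cells side by side, boundary
#' cells closing both margins, the squamous layer above the lumen, nucleus
#' clusters at the configured fractional height, the ECM chain wrapping the
#' basal perimeter (regions ECMs over squamous, ECMbc at the margins, ECMc
#' under the pouch), all adhesion/contractility/exclusion pair lists, and
#' per-cell target areas equal to the constructed polygon areas. The result
#' is force-free: every bonded spring at rest, every non-bonded pair at or
#' beyond its interaction range.
#'
#' @param cfg a [tissue_config()]
#' @param ep an [energy_params()]; rest lengths of the adhesion terms set the
#'   inter-cell, cell-ECM and lumen gaps
#' @param relax relax the built tissue to mechanical equilibrium (recommended:
#'   the nucleus clusters must settle against their membranes)
#' @param relax_tol force tolerance (nN) declaring equilibrium
#' @param relax_max_steps cap on relaxation steps
#' @return an object of class `sce_tissue`
#' @export
build_tissue <- function(cfg, ep = energy_params(), relax = TRUE,
                         relax_tol = 0.02, relax_max_steps = 60000L) {
  stopifnot(inherits(cfg, "tissue_config"), inherits(ep, "energy_params"))
  g_lat <- ep$e_adhL$r0
  g_bas <- ep$e_adhB$r0
  g_lum <- if (is.null(cfg$lumen_gap)) ep$e_adhA$r0 else cfg$lumen_gap
  if (g_lat <= 0 || g_bas <= 0 || g_lum <= 0)
    stop("adhesion rest lengths must be positive: cells would overlap")
  w <- cfg$columnar_width
  h <- cfg$columnar_height
  nb <- cfg$n_boundary_per_side
  Wc <- cfg$n_columnar * w
  x_min <- -nb * w
  x_max <- Wc + nb * w
  sq_yb <- h + g_lum
  sq_yt <- sq_yb + cfg$squamous_height
  sq_w <- (x_max - x_min) / cfg$n_squamous
  if (sq_w <= g_lat) stop("squamous cells degenerate: span too narrow")

  pos <- matrix(numeric(0), 0, 2)
  node_class <- integer(0)
  cell_id <- integer(0)
  region <- character(0)
  cells <- list()
  ncl_template <- nucleus_seed(cfg$nucleus_nodes_per_cell, ep$e_nuc)

  add_cell <- function(kind, xl, xr, yb, yt, apical_on_top, nuc_frac) {
    ring <- ring_rect(xl + g_lat / 2, xr - g_lat / 2, yb, yt,
                      cfg$membrane_node_spacing, apical_on_top)
    cid <- length(cells) + 1L
    m0 <- nrow(pos)
    pos <<- rbind(pos, ring$pts)
    node_class <<- c(node_class, rep(2L, nrow(ring$pts)))
    cell_id <<- c(cell_id, rep(cid, nrow(ring$pts)))
    region <<- c(region, ring$tag)
    ring_ids <- m0 + seq_len(nrow(ring$pts))
    nuc_y <- if (apical_on_top) yb + nuc_frac * (yt - yb)
             else yt - nuc_frac * (yt - yb)
    tmpl <- ncl_template
    # lay the cluster along the cell's long axis so it fits flat cells too
    if ((yt - yb) < diff(range(tmpl[, 2])) + 1) tmpl <- tmpl[, 2:1]
    nuc <- sweep(tmpl, 2, c((xl + xr) / 2, nuc_y), "+")
    n0 <- nrow(pos)
    pos <<- rbind(pos, nuc)
    node_class <<- c(node_class, rep(1L, nrow(nuc)))
    cell_id <<- c(cell_id, rep(cid, nrow(nuc)))
    region <<- c(region, rep(NA_character_, nrow(nuc)))
    cells[[cid]] <<- list(kind = kind, ring = ring_ids,
                          nucleus = n0 + seq_len(nrow(nuc)),
                          target_area = polygon_area(ring$pts))
    cid
  }

  lb <- vapply(seq_len(nb), function(k)       # left margin, outer -> inner
    add_cell("boundary", x_min + (k - 1) * w, x_min + k * w, 0, h, TRUE, 0.5),
    integer(1))
  cc <- vapply(seq_len(cfg$n_columnar), function(k)
    add_cell("columnar", (k - 1) * w, k * w, 0, h, TRUE,
             cfg$initial_nuclear_fraction), integer(1))
  rb <- vapply(seq_len(nb), function(k)       # right margin, inner -> outer
    add_cell("boundary", Wc + (k - 1) * w, Wc + k * w, 0, h, TRUE, 0.5),
    integer(1))
  sq <- vapply(seq_len(cfg$n_squamous), function(k)
    add_cell("squamous", x_min + (k - 1) * sq_w, x_min + k * sq_w,
             sq_yb, sq_yt, FALSE, 0.5), integer(1))

  # --- ECM chain: aligned one basal-adhesion gap outside the membranes ------
  x_m_l <- x_min + g_lat / 2                  # outermost membrane faces
  x_m_r <- x_max - g_lat / 2
  node_x <- function(ids) pos[ids, 1]
  node_y <- function(ids) pos[ids, 2]
  sel <- function(cid_set, reg) {
    idx <- which(cell_id %in% cid_set & !is.na(region) & region == reg &
                   node_class == 2L)
    idx
  }
  fill_gap <- function(a, b, spacing) {
    d <- abs(b - a)
    n <- floor(d / spacing - 1e-9)
    if (n < 1) return(numeric(0))
    seq(a, b, length.out = n + 2)[-c(1, n + 2)]
  }
  # side-chain filler nodes must stay outside the exclusion range of the
  # lumen-level membrane corners (boundary-cell tops at y = h, squamous
  # bottoms at y = sq_yb)
  lumen_band <- sqrt(max(ep$e_v$cutoff^2 - g_bas^2, 0)) + 0.01
  # top row over the squamous layer, left -> right; inter-cell gaps get the
  # same single-node treatment as the bottom row (see below)
  top_x <- sort(unique(node_x(sel(sq, "basal"))))
  top_y <- rep(sq_yt + g_bas, length(top_x))
  tgap <- which(diff(top_x) < 2 * g_bas)
  if (length(tgap)) {
    tdip <- sqrt(pmax(g_bas^2 - (diff(top_x)[tgap] / 2)^2, (g_bas / 2)^2))
    top_x[tgap] <- (top_x[tgap] + top_x[tgap + 1]) / 2
    top_y[tgap] <- sq_yt + tdip
    top_x <- top_x[-(tgap + 1)]
    top_y <- top_y[-(tgap + 1)]
  }
  # side columns: aligned with squamous end faces and boundary outer faces,
  # with filler nodes across the lumen-level gap
  side_ys <- function(sq_end_cell, bnd_outer_cell, outer_tag) {
    ys_sq <- sort(node_y(sel(sq_end_cell, outer_tag)), decreasing = TRUE)
    ys_bd <- sort(node_y(sel(bnd_outer_cell, outer_tag)), decreasing = TRUE)
    lo_sq <- if (length(ys_sq)) min(ys_sq) else sq_yb
    hi_bd <- if (length(ys_bd)) max(ys_bd) else h
    fill <- fill_gap(lo_sq, hi_bd, cfg$ecm_node_spacing)
    fill <- fill[fill > sq_yb + lumen_band | fill < h - lumen_band]
    c(ys_sq, sort(fill, decreasing = TRUE), ys_bd)
  }
  right_ys <- side_ys(sq[length(sq)], rb[length(rb)], "lateral_right")
  left_ys <- side_ys(sq[1], lb[1], "lateral_left")
  # bottom row under boundary + columnar cells, right -> left; under each
  # inter-cell gap the two corner-aligned nodes merge into one node placed
  # exactly one adhesion gap from both bottom corners (a shallow dip), so the
  # built chain carries no exclusion force
  bot_x <- sort(unique(node_x(sel(c(lb, cc, rb), "basal"))))
  bot_y <- rep(-g_bas, length(bot_x))
  gap_at <- which(diff(bot_x) < 2 * g_bas)
  if (length(gap_at)) {
    dip <- sqrt(pmax(g_bas^2 - (diff(bot_x)[gap_at] / 2)^2, (g_bas / 2)^2))
    bot_x[gap_at] <- (bot_x[gap_at] + bot_x[gap_at + 1]) / 2
    bot_y[gap_at] <- -dip
    bot_x <- bot_x[-(gap_at + 1)]
    bot_y <- bot_y[-(gap_at + 1)]
  }
  ord <- order(bot_x, decreasing = TRUE)
  bot_x <- bot_x[ord]; bot_y <- bot_y[ord]
  bot_reg <- ifelse(bot_x > g_lat / 4 & bot_x < Wc - g_lat / 4, "ECMc", "ECMbc")
  corner <- ep$e_v$cutoff / sqrt(2) + 0.01   # outer corners sit beyond the
                                             # exclusion range of the membrane

  ecm_xy <- rbind(
    c(x_m_l - corner, sq_yt + corner),                  # top-left corner
    cbind(top_x, top_y),
    c(x_m_r + corner, sq_yt + corner),                  # top-right corner
    cbind(x_m_r + g_bas, right_ys),
    c(x_m_r + corner, -corner),                         # bottom-right corner
    cbind(bot_x, bot_y),
    c(x_m_l - corner, -corner),                         # bottom-left corner
    cbind(x_m_l - g_bas, sort(left_ys)))
  ecm_reg <- c("ECMs", rep("ECMs", length(top_x)), "ECMs",
               rep("ECMbc", length(right_ys)), "ECMbc", bot_reg, "ECMbc",
               rep("ECMbc", length(left_ys)))
  e0 <- nrow(pos)
  pos <- rbind(pos, ecm_xy)
  node_class <- c(node_class, rep(3L, nrow(ecm_xy)))
  cell_id <- c(cell_id, rep(NA_integer_, nrow(ecm_xy)))
  region <- c(region, ecm_reg)
  ecm_chain <- e0 + seq_len(nrow(ecm_xy))

  # --- bonded springs at rest ----------------------------------------------
  seg_rest <- function(i, j) sqrt(rowSums((pos[i, , drop = FALSE] -
                                             pos[j, , drop = FALSE])^2))
  memb_i <- integer(0); memb_j <- integer(0)
  for (cl in cells) {
    r <- cl$ring
    memb_i <- c(memb_i, r)
    memb_j <- c(memb_j, c(r[-1], r[1]))
  }
  ec_i <- ecm_chain[-length(ecm_chain)]
  ec_j <- ecm_chain[-1]

  state <- structure(list(
    pos = pos, node_class = node_class, cell_id = cell_id, region = region,
    cells = cells, ecm_chain = ecm_chain,
    columnar_cells = cc, boundary_cells = c(lb, rb), squamous_cells = sq,
    bonds = list(
      memb = list(i = memb_i, j = memb_j, r0 = seg_rest(memb_i, memb_j)),
      ecm = list(i = ec_i, j = ec_j, r0 = seg_rest(ec_i, ec_j),
                 region = region[ec_i]),
      adh_lateral = empty_bonds(), adh_basal = empty_bonds(),
      adh_apical = empty_bonds(), adh_margin = empty_bonds(),
      cont = empty_bonds()),
    ring_pos = NULL, ring_len = NULL,
    excl_pairs = matrix(integer(0), 0, 2),
    nuc_pairs = do.call(rbind, lapply(cells, function(cl) {
      if (length(cl$nucleus) < 2) return(NULL)
      t(utils::combn(cl$nucleus, 2))
    })),
    lateral_interfaces = NULL, basal_candidates = NULL,
    adh_zone_cells = NULL, adh_apical_enabled = TRUE,
    time = 0, config = cfg), class = "sce_tissue")

  rp <- rep(-1L, nrow(pos)); rl <- rep(0L, nrow(pos))
  for (cl in cells) {
    rp[cl$ring] <- seq_along(cl$ring) - 1L
    rl[cl$ring] <- length(cl$ring)
  }
  state$ring_pos <- rp
  state$ring_len <- rl

  # lateral interfaces in x order (bottom layer, then squamous row)
  bottom_row <- c(lb, cc, rb)        # already in left -> right order
  # adherens-belt nodes: lateral-wall nodes within belt_depth (ring distance)
  # of the cell's apical arc; their inter-cell bonds are persistent and
  # unbreakable, making the apical surface a mechanically connected band
  belt_n <- max(1L, ceiling(2.5 / cfg$membrane_node_spacing))
  belt_of <- function(cid, tag) {
    cl <- cells[[cid]]
    wall <- cl$ring[region[cl$ring] == tag]
    ap <- cl$ring[region[cl$ring] == "apical"]
    m <- length(cl$ring)
    posr <- match(wall, cl$ring)
    posa <- match(ap, cl$ring)
    keep <- vapply(posr, function(p) {
      d <- abs(posa - p)
      min(pmin(d, m - d)) <= belt_n
    }, logical(1))
    wall[keep]
  }
  row_ifaces <- function(row) {
    lapply(seq_len(length(row) - 1), function(k) {
      list(a = sel(row[k], "lateral_right"), b = sel(row[k + 1], "lateral_left"),
           a_belt = belt_of(row[k], "lateral_right"),
           b_belt = belt_of(row[k + 1], "lateral_left"))
    })
  }
  state$lateral_interfaces <- c(row_ifaces(bottom_row), row_ifaces(sq))
  state$basal_candidates <- c(
    which(node_class == 2L & !is.na(region) & region == "basal"),
    sel(lb[1], "lateral_left"), sel(rb[length(rb)], "lateral_right"))
  central <- function(frac) {
    nz <- max(1L, round(frac * cfg$n_columnar))
    mid <- (cfg$n_columnar + 1) / 2
    cc[sort(order(abs(seq_len(cfg$n_columnar) - mid))[seq_len(nz)])]
  }
  state$adh_zone_cells <- central(cfg$adhesion_zone_fraction)
  state$adh_span_cells <- central(cfg$adhesion_span_fraction)

  # static margin links: boundary-cell apical tops to the squamous layer
  bd_ap <- sel(c(lb, rb), "apical")
  sq_ap <- sel(sq, "apical")
  mm <- cpp_mutual_nn(pos, bd_ap, sq_ap, 2 * g_lum)
  state$bonds$adh_margin <- list(i = mm[, 1], j = mm[, 2],
                                 r0 = pmax(seg_rest(mm[, 1], mm[, 2]),
                                           ep$e_adhL$r0))
  # intrinsic lateral tension of the squamous layer: shortened membrane
  # rest lengths keep the peripodial lid taut
  if (cfg$squamous_prestress > 0) {
    sq_nodes <- unlist(lapply(state$cells[sq], `[[`, "ring"))
    in_sq <- state$bonds$memb$i %in% sq_nodes
    state$bonds$memb$r0[in_sq] <-
      (1 - cfg$squamous_prestress) * state$bonds$memb$r0[in_sq]
  }
  state <- refresh_pairs(state, ep)
  if (relax) state <- relax_to_equilibrium(state, ep, relax_tol,
                                           relax_max_steps)
  state$time <- 0
  state
}

# Relax the built tissue to a true energy minimum: a short overdamped
# descent settles the stiff contact modes, then L-BFGS polishes the soft
# (nucleus rearrangement) modes with frozen pair lists, re-matching pairs
# between cycles. Contractility is off during relaxation.
relax_to_equilibrium <- function(state, ep, tol = 0.02, max_steps = 60000L) {
  ep0 <- ep
  ep0$e_cont$k <- 0
  dp0 <- damping_params()
  done <- 0L
  f <- Inf
  while (done < min(10000L, max_steps)) {
    state <- step_tissue(state, ep0, dp0, dt = 0.002, n_steps = 250L)
    state <- refresh_pairs(state, ep0)
    done <- done + 250L
    f <- max(abs(compute_total_forces(state, ep0)))
    if (f < tol) return(state)
  }
  for (cycle in 1:6) {
    packed <- pack_interactions(state, ep0)
    n <- nrow(state$pos)
    opt <- stats::optim(as.vector(state$pos),
                        fn = function(v) cpp_energy(matrix(v, n, 2), packed),
                        gr = function(v) -as.vector(cpp_forces(matrix(v, n, 2),
                                                               packed)),
                        method = "L-BFGS-B",
                        control = list(maxit = 5000L, factr = 1, pgtol = 0))
    cand <- state
    cand$pos <- matrix(opt$par, n, 2)
    cand <- refresh_pairs(cand, ep0)
    fc <- max(abs(compute_total_forces(cand, ep0)))
    if (fc < f) {                  # polish only counts with live pair lists:
      state <- cand                # frozen-list descents can tunnel nodes
      f <- fc                      # through membranes, so verify and revert
    } else {
      state <- step_tissue(state, ep0, dp0, dt = 0.002, n_steps = 2000L)
      state <- refresh_pairs(state, ep0)
      f <- max(abs(compute_total_forces(state, ep0)))
    }
    if (f < tol) break
  }
  if (f >= tol)
    warning(sprintf("build relaxation stopped at max|F| = %.2e nN", f))
  state
}

#' ECM prestrain specification
#'
#' Passive tension carried by each ECM region's springs at the initial
#' geometry: `F_ECMs` over the squamous layer, `F_ECMc` under the columnar
#' pouch, `F_ECMbc` at the margins (defaults to `F_ECMs`).
#'
#' @param F_ECMs,F_ECMc,F_ECMbc per-spring tension (nN), all non-negative
#' @return an object of class `prestrain_spec`
#' @export
prestrain_spec <- function(F_ECMs = 0, F_ECMc = 0, F_ECMbc = F_ECMs) {
  stopifnot(F_ECMs >= 0, F_ECMc >= 0, F_ECMbc >= 0)
  structure(list(F_ECMs = F_ECMs, F_ECMc = F_ECMc, F_ECMbc = F_ECMbc),
            class = "prestrain_spec")
}

#' Apply ECM prestrain by rest-length reduction
#'
#' Encodes the configured tension into each ECM spring by shortening its rest
#' length to `r0 - F_R / k_ecm`, so the spring carries exactly `F_R` of
#' tension at the built geometry (a taut versus loose basement membrane).
#'
#' @param state a built `sce_tissue`
#' @param spec a [prestrain_spec()]
#' @param ep the [energy_params()] whose `ecm` stiffness converts tension to
#'   rest-length offset
#' @return the modified tissue
#' @export
apply_prestrain <- function(state, spec, ep) {
  stopifnot(inherits(spec, "prestrain_spec"), ep$e_ecm$k > 0)
  FR <- c(ECMs = spec$F_ECMs, ECMbc = spec$F_ECMbc, ECMc = spec$F_ECMc)
  off <- unname(FR[state$bonds$ecm$region]) / ep$e_ecm$k
  if (any(off >= state$bonds$ecm$r0))
    stop("prestrain too large: rest length would become non-positive")
  state$bonds$ecm$r0 <- state$bonds$ecm$r0 - off
  state
}

#' Current tension in each ECM spring
#'
#' @param state an `sce_tissue`
#' @param ep an [energy_params()]
#' @return data frame with one row per ECM bond: region and tension
#'   `k_ecm * (length - r0)` (nN, positive = taut)
#' @export
ecm_spring_tension <- function(state, ep) {
  b <- state$bonds$ecm
  len <- sqrt(rowSums((state$pos[b$i, , drop = FALSE] -
                         state$pos[b$j, , drop = FALSE])^2))
  data.frame(region = b$region, tension = ep$e_ecm$k * (len - b$r0))
}

#' Circular-arc fixture with known curvature
#'
#' Points on a circular arc (bowing toward +y, ordered left to right),
#' optionally perturbed by isotropic Gaussian noise, together with the
#' analytic curvature 1/radius. `radius = Inf` produces a straight segment of
#' length `span` with zero curvature. Used to validate the curvature metrics.
#'
#' @param radius arc radius (um), or `Inf`
#' @param span subtended angle (radians), or segment length when `radius = Inf`
#' @param n_points number of points (>= 3)
#' @param noise_sd isotropic noise standard deviation (um)
#' @param seed RNG seed for the noise
#' @return list with `points` (n x 2 matrix) and `curvature` (1/radius)
#' @export
make_arc_fixture <- function(radius, span, n_points, noise_sd = 0, seed = 1L) {
  stopifnot(radius > 0, n_points >= 3)
  if (is.infinite(radius)) {
    pts <- cbind(seq(0, span, length.out = n_points), 0)
    kappa <- 0
  } else {
    th <- seq(pi / 2 + span / 2, pi / 2 - span / 2, length.out = n_points)
    pts <- cbind(radius * cos(th), radius * sin(th))
    kappa <- 1 / radius
  }
  if (noise_sd > 0) {
    old <- .Random.seed_exists()
    set.seed(seed)
    pts <- pts + matrix(stats::rnorm(2 * n_points, sd = noise_sd), ncol = 2)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  list(points = pts, curvature = kappa)
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  else NULL
}

#' Remove nodes from a tissue
#'
#' Deletes the given nodes and every bond, pair and chain entry touching
#' them, reindexing everything else. Used by the collagenase scenario to
#' remove the ECM. Nodes referenced by a cell ring or nucleus cannot be
#' removed.
#'
#' @param state an `sce_tissue`
#' @param ids node indices to drop
#' @return the reduced tissue
#' @export
remove_nodes <- function(state, ids) {
  ids <- unique(as.integer(ids))
  in_cells <- unlist(lapply(state$cells, function(cl) c(cl$ring, cl$nucleus)))
  if (any(ids %in% in_cells)) stop("cannot remove nodes belonging to a cell")
  n <- nrow(state$pos)
  keep <- setdiff(seq_len(n), ids)
  map <- integer(n)
  map[keep] <- seq_along(keep)
  remap <- function(v) {
    out <- map[v]
    out[v %in% ids] <- NA_integer_
    out
  }
  fix_bonds <- function(b) {
    i <- remap(b$i); j <- remap(b$j)
    ok <- !is.na(i) & !is.na(j)
    out <- list(i = i[ok], j = j[ok], r0 = b$r0[ok])
    if (!is.null(b$region)) out$region <- b$region[ok]
    out
  }
  state$pos <- state$pos[keep, , drop = FALSE]
  state$node_class <- state$node_class[keep]
  state$cell_id <- state$cell_id[keep]
  state$region <- state$region[keep]
  state$cells <- lapply(state$cells, function(cl) {
    cl$ring <- map[cl$ring]; cl$nucleus <- map[cl$nucleus]; cl
  })
  state$bonds <- lapply(state$bonds, fix_bonds)
  ec <- remap(state$ecm_chain)
  state$ecm_chain <- ec[!is.na(ec)]
  np <- cbind(remap(state$nuc_pairs[, 1]), remap(state$nuc_pairs[, 2]))
  state$nuc_pairs <- np[stats::complete.cases(np), , drop = FALSE]
  xp <- cbind(remap(state$excl_pairs[, 1]), remap(state$excl_pairs[, 2]))
  state$excl_pairs <- xp[stats::complete.cases(xp), , drop = FALSE]
  state$lateral_interfaces <- lapply(state$lateral_interfaces, function(f) {
    list(a = map[setdiff(f$a, ids)], b = map[setdiff(f$b, ids)])
  })
  state$basal_candidates <- map[setdiff(state$basal_candidates, ids)]
  state$ring_pos <- state$ring_pos[keep]
  state$ring_len <- state$ring_len[keep]
  state
}

#' Write a tissue snapshot as flat CSV
#'
#' One row per node: id, class, cell id, region tag, x, y. Round-trips via
#' [read_tissue_csv()].
#'
#' @param state an `sce_tissue`
#' @param path output file
#' @return the node table, invisibly
#' @export
write_tissue_csv <- function(state, path) {
  df <- as_node_table(state)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Node table of a tissue
#'
#' @param state an `sce_tissue`
#' @return data frame with columns id, class, cell, region, x, y
#' @export
as_node_table <- function(state) {
  data.frame(id = seq_len(nrow(state$pos)),
             class = NODE_CLASSES[state$node_class],
             cell = state$cell_id, region = state$region,
             x = state$pos[, 1], y = state$pos[, 2])
}

#' Read a tissue snapshot CSV
#'
#' @param path file written by [write_tissue_csv()]
#' @return the node table data frame
#' @export
read_tissue_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "class", "cell", "region", "x", "y")
  if (!all(need %in% names(df))) stop("not a tissue snapshot CSV")
  df$region <- as.character(df$region)
  df
}

#' Save / load a trajectory container
#'
#' Trajectories (metric time series plus final state) are stored in R's
#' binary serialisation format.
#'
#' @param traj an `sce_trajectory`
#' @param path file path
#' @return `read_trajectory` returns the trajectory
#' @export
write_trajectory <- function(traj, path) {
  saveRDS(traj, path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) readRDS(path)
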