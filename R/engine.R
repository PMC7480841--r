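# Overdamped explicit-Euler dynamics over the tissue, dynamic pair-list
# maintenance and convergence detection of the global shape.

#' Simulation configuration
#'
#' @param dt time step (AU); the model's calibrated step is 0.002
#' @param max_steps horizon cap in steps
#' @param pair_refresh_interval steps between pair-list rebuilds
#' @param output_interval steps between metric samples
#' @param convergence_window trailing window (steps) over which the global
#'   curvature must be stable to declare convergence
#' @param convergence_tol relative curvature variation tolerated inside the
#'   window; compared against `max(|curvature|, curvature_floor)` so a flat
#'   tissue (curvature near zero) can also converge
#' @param curvature_floor curvature scale (1/um) below which variation is
#'   measured absolutely
#' @param store_snapshots record node positions at every output sample
#' @return an object of class `sim_config`
#' @export
sim_config <- function(dt = 0.002, max_steps = 50000L,
                       pair_refresh_interval = 50L, output_interval = 250L,
                       convergence_window = 5000L, convergence_tol = 0.01,
                       curvature_floor = 0.005, store_snapshots = FALSE) {
  stopifnot(dt > 0, max_steps >= 1, pair_refresh_interval >= 1,
            output_interval >= 1, convergence_window >= output_interval,
            convergence_tol > 0, curvature_floor > 0)
  structure(list(dt = dt, max_steps = as.integer(max_steps),
                 pair_refresh_interval = as.integer(pair_refresh_interval),
                 output_interval = as.integer(output_interval),
                 convergence_window = as.integer(convergence_window),
                 convergence_tol = convergence_tol,
                 curvature_floor = curvature_floor,
                 store_snapshots = store_snapshots),
            class = "sim_config")
}

# per-node reciprocal drag from the damping parameters, honouring ECM region
# multipliers
inv_damping <- function(state, dp) {
  C <- numeric(nrow(state$pos))
  C[state$node_class == 1L] <- dp$C_nuc
  C[state$node_class == 2L] <- dp$C_memb
  ecm <- which(state$node_class == 3L)
  C[ecm] <- dp$C_ecm * dp$ecm_region_multipliers[state$region[ecm]]
  1 / C
}

# The explicit Euler scheme is conditionally stable: a spring of stiffness k
# on a node with drag C requires k*dt/C < 2. Checked for every energy term
# before a run, naming the offender. For the area penalty the stiffest mode
# is uniform dilation of a ring, with effective stiffness
# k_vol * perimeter * edge length.
check_stability <- function(ep, dp, dt, state = NULL) {
  cmin <- min(dp$C_nuc, dp$C_memb, dp$C_ecm * min(dp$ecm_region_multipliers))
  kvol_eff <- 0
  if (!is.null(state) && length(state$cells)) {
    kvol_eff <- max(vapply(state$cells, function(cl) {
      P <- state$pos[cl$ring, , drop = FALSE]
      seg <- sqrt(rowSums((P - P[c(2:nrow(P), 1), , drop = FALSE])^2))
      ep$k_vol * sum(seg) * max(seg)
    }, numeric(1)))
  }
  ks <- c(E_memb = ep$e_memb$k, E_adhL = ep$e_adhL$k, E_adhB = ep$e_adhB$k,
          E_adhA = ep$e_adhA$k, E_cont = ep$e_cont$k, E_ecm = ep$e_ecm$k,
          E_v = ep$e_v$U0 / ep$e_v$xi0^2,
          E_nuc = ep$e_nuc$U0 / ep$e_nuc$xi0^2,
          E_vol = kvol_eff)
  bad <- which(ks * dt / cmin >= 2)
  if (length(bad))
    stop("dt = ", dt, " violates the stability bound k*dt/C < 2 for term(s): ",
         paste(names(ks)[bad], collapse = ", "))
  invisible(TRUE)
}

#' Advance the tissue by explicit-Euler overdamped steps
#'
#' Every node moves by `dt * F / C` with its class (and, for ECM nodes,
#' region) drag coefficient. Pair lists are held fixed; callers running many
#' steps interleave [refresh_pairs()] (as [run_simulation()] does).
#'
#' @param state an `sce_tissue`
#' @param ep an [energy_params()]
#' @param dp a [damping_params()]
#' @param dt time step (AU)
#' @param n_steps number of steps to take
#' @return the advanced tissue
#' @export
step_tissue <- function(state, ep, dp, dt, n_steps = 1L) {
  state$pos <- cpp_step_n(state$pos, inv_damping(state, dp),
                          pack_interactions(state, ep), as.integer(n_steps), dt)
  state$time <- state$time + n_steps * dt
  state
}

#' Rebuild the dynamic interaction pair lists
#'
#' Re-matches lateral and basal adhesion by mutual nearest neighbour within
#' the adhesion break distance (one partner per node), rebuilds the
#' volume-exclusion neighbour list on a uniform grid, re-matches the apical
#' interlayer adhesion over the central zone (persisting pairs keep their
#' rest length), and recomputes contractility pairs as the laterally opposed
#' membrane nodes of each columnar cell lying below its basal-most nucleus
#' node minus one node spacing.
#'
#' @inheritParams step_tissue
#' @return the tissue with updated pair lists
#' @export
refresh_pairs <- function(state, ep) {
  pos <- state$pos
  match_cut <- function(p) if (is.finite(p$break_distance)) p$break_distance
                           else 3 * max(p$r0, 1)

  # Adhesion bonds persist while within their break distance (adhesion
  # molecules do not hop); only unpaired nodes are offered new partners by
  # mutual nearest-neighbour matching. Persistence gives adhesion its
  # tangential friction: without it cells slide freely along the ECM.
  persist_match <- function(old, A, B, p) {
    keep_i <- integer(0); keep_j <- integer(0)
    if (length(old$i)) {
      d <- sqrt(rowSums((pos[old$i, , drop = FALSE] -
                           pos[old$j, , drop = FALSE])^2))
      ok <- d <= p$break_distance & old$i %in% A & old$j %in% B
      keep_i <- old$i[ok]; keep_j <- old$j[ok]
    }
    freeA <- setdiff(A, keep_i)
    freeB <- setdiff(B, keep_j)
    if (length(freeA) && length(freeB)) {
      mm <- cpp_mutual_nn(pos, freeA, freeB, match_cut(p))
      keep_i <- c(keep_i, mm[, 1]); keep_j <- c(keep_j, mm[, 2])
    }
    list(i = keep_i, j = keep_j, r0 = rep(p$r0, length(keep_i)))
  }

  lat_i <- integer(0); lat_j <- integer(0); lat_brk <- numeric(0)
  oldL <- state$bonds$adh_lateral
  pL <- ep$e_adhL
  for (f in state$lateral_interfaces) {
    if (!length(f$a) || !length(f$b)) next
    if (length(f$a_belt) && length(f$b_belt)) {
      pBelt <- pL
      pBelt$break_distance <- Inf       # adherens belt: junctions persist
      mm <- persist_match(oldL, f$a_belt, f$b_belt, pBelt)
      lat_i <- c(lat_i, mm$i); lat_j <- c(lat_j, mm$j)
      lat_brk <- c(lat_brk, rep(Inf, length(mm$i)))
      a_rest <- setdiff(f$a, f$a_belt); b_rest <- setdiff(f$b, f$b_belt)
    } else {
      a_rest <- f$a; b_rest <- f$b
    }
    if (length(a_rest) && length(b_rest)) {
      mm <- persist_match(oldL, a_rest, b_rest, pL)
      lat_i <- c(lat_i, mm$i); lat_j <- c(lat_j, mm$j)
      lat_brk <- c(lat_brk, rep(pL$break_distance, length(mm$i)))
    }
  }
  state$bonds$adh_lateral <- list(i = lat_i, j = lat_j,
                                  r0 = rep(pL$r0, length(lat_i)),
                                  brk = lat_brk)

  ecm_nodes <- which(state$node_class == 3L)
  if (length(ecm_nodes) && length(state$basal_candidates)) {
    state$bonds$adh_basal <- persist_match(state$bonds$adh_basal,
                                           state$basal_candidates, ecm_nodes,
                                           ep$e_adhB)
  } else state$bonds$adh_basal <- empty_bonds()

  if (isTRUE(state$adh_apical_enabled)) {
    zone_ap <- which(state$node_class == 2L &
                       state$cell_id %in% state$adh_span_cells &
                       !is.na(state$region) & state$region == "apical")
    sq_ap <- which(state$node_class == 2L &
                     state$cell_id %in% state$squamous_cells &
                     !is.na(state$region) & state$region == "apical")
    state$bonds$adh_apical <- persist_match(state$bonds$adh_apical,
                                            zone_ap, sq_ap, ep$e_adhA)
  } else state$bonds$adh_apical <- empty_bonds()

  # Contractility: laterally opposed membrane-node pairs below the basal-most
  # nucleus node minus one node spacing, measured along the cell's own
  # apicobasal axis (frame-invariant). k_cont is the cell's total contractile
  # stiffness, split evenly across its pairs, so the contraction force is
  # independent of the node resolution.
  con_i <- integer(0); con_j <- integer(0); con_k <- numeric(0)
  margin <- state$config$membrane_node_spacing
  for (cid in state$columnar_cells) {
    cl <- state$cells[[cid]]
    ap <- colMeans(pos[cl$ring[state$region[cl$ring] == "apical"], ,
                       drop = FALSE])
    ba <- colMeans(pos[cl$ring[state$region[cl$ring] == "basal"], ,
                       drop = FALSE])
    axis <- ap - ba
    axis <- axis / max(sqrt(sum(axis^2)), .Machine$double.eps)
    height_of <- function(ids) pos[ids, , drop = FALSE] %*% axis
    thr <- min(height_of(cl$nucleus)) - margin
    sub <- function(tag) {
      ids <- cl$ring[state$region[cl$ring] == tag]
      h <- height_of(ids)
      ids <- ids[h < thr]
      ids[order(height_of(ids))]
    }
    L <- sub("lateral_left"); R <- sub("lateral_right")
    m <- min(length(L), length(R))
    if (m) {
      con_i <- c(con_i, L[1:m]); con_j <- c(con_j, R[1:m])
      con_k <- c(con_k, rep(1 / m, m))
    }
  }
  state$bonds$cont <- list(i = con_i, j = con_j, r0 = rep(0, length(con_i)),
                           kmul = con_k)

  cid0 <- state$cell_id
  cid0[is.na(cid0)] <- 0L
  state$excl_pairs <- cpp_grid_pairs(pos, ep$e_v$cutoff, state$node_class,
                                     cid0, state$ring_pos, state$ring_len)
  state
}

#' Run the simulation to convergence or a step horizon
#'
#' Iterates Euler steps with periodic pair refresh, samples the shape metrics
#' (global curvature of the pouch basal surface, mean fractional nuclear
#' position and mean height of columnar cells), applies scheduled events at
#' their trigger times, and stops early once the global curvature is stable
#' over the trailing convergence window.
#'
#' @inheritParams step_tissue
#' @param sim a [sim_config()]
#' @param events optional list of events, each `list(time =, action =, ...)`
#'   with action one of `"set_k_cont"` (field `value`),
#'   `"multiply_ecm_damping"` (fields `region`, `factor`), `"delete_ecm"`,
#'   `"delete_apical_adhesion"`
#' @return an `sce_trajectory`: metric time series, final state, updated
#'   energy/damping parameters, convergence flag
#' @export
run_simulation <- function(state, ep, dp, sim = sim_config(), events = NULL) {
  check_stability(ep, dp, sim$dt, state)
  if (!is.null(events)) {
    tmax <- sim$max_steps * sim$dt
    tev <- vapply(events, `[[`, numeric(1), "time")
    if (is.unsorted(tev)) stop("event trigger times must be non-decreasing")
    if (any(tev > state$time + tmax + 1e-9))
      stop("scheduled event lies beyond the simulation horizon")
  }
  t0 <- state$time
  times <- numeric(0); curv <- numeric(0)
  nfrac <- numeric(0); hgt <- numeric(0)
  snaps <- list()
  record <- function(st) {
    times <<- c(times, st$time)
    curv <<- c(curv, tissue_global_curvature(st))
    np <- tissue_nuclear_positions(st)
    nfrac <<- c(nfrac, mean(np$fraction))
    hgt <<- c(hgt, mean(np$height))
    if (sim$store_snapshots) snaps[[length(snaps) + 1]] <<- st$pos
  }
  record(state)
  nwin <- max(2L, sim$convergence_window %/% sim$output_interval)
  converged <- FALSE
  steps_done <- 0L
  ev_queue <- events
  while (steps_done < sim$max_steps) {
    # next stop: refresh boundary, output boundary, or event trigger
    nxt <- min(sim$pair_refresh_interval -
                 steps_done %% sim$pair_refresh_interval,
               sim$output_interval - steps_done %% sim$output_interval,
               sim$max_steps - steps_done)
    if (length(ev_queue)) {
      steps_to_ev <- round((ev_queue[[1]]$time - state$time) / sim$dt)
      if (steps_to_ev <= 0) {
        res <- apply_scenario_event(state, ep, dp, ev_queue[[1]])
        state <- res$state; ep <- res$ep; dp <- res$dp
        state <- refresh_pairs(state, ep)
        ev_queue <- ev_queue[-1]
        next
      }
      nxt <- min(nxt, steps_to_ev)
    }
    state <- step_tissue(state, ep, dp, sim$dt, nxt)
    steps_done <- steps_done + nxt
    if (steps_done %% sim$pair_refresh_interval == 0)
      state <- refresh_pairs(state, ep)
    if (steps_done %% sim$output_interval == 0) {
      record(state)
      if (!length(ev_queue) && length(curv) > nwin) {
        w <- curv[seq(length(curv) - nwin, length(curv))]
        scale <- max(abs(mean(w)), sim$curvature_floor)
        if (max(abs(w - mean(w))) < sim$convergence_tol * scale) {
          converged <- TRUE
          break
        }
      }
    }
  }
  structure(list(time = times, curvature = curv, nuclear_fraction = nfrac,
                 height = hgt, snapshots = snaps, state = state, ep = ep,
                 dp = dp, converged = converged, steps = steps_done,
                 t_start = t0), class = "sce_trajectory")
}

#' @export
print.sce_trajectory <- function(x, ...) {
  cat("SCE trajectory:", x$steps, "steps, t =",
      format(x$time[length(x$time)], digits = 5), "AU\n")
  cat("  final global curvature :",
      format(x$curvature[length(x$curvature)], digits = 4), "1/um\n")
  cat("  mean nuclear fraction  :",
      format(x$nuclear_fraction[length(x$nuclear_fraction)], digits = 4), "\n")
  cat("  converged              :", x$converged, "\n")
  invisible(x)
}
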