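# The five in-silico experiments as declarative schedules over the engine:
# patterned ECM tension, basal contractility, shape maintenance after
# contractility switch-off, collagenase-like ECM removal, and the dual
# perturbation that additionally severs the interlayer adhesion.

#' Declarative perturbation scenario
#'
#' A scenario fixes the initial ECM prestrain and contractility level and
#' optionally schedules perturbation events once the generated shape has
#' converged: switching contractility off, multiplying the drag of an ECM
#' region, deleting the ECM outright, or deleting the apical interlayer
#' adhesion.
#'
#' @param name scenario label
#' @param prestrain a [prestrain_spec()]
#' @param k_cont basal actomyosin contractility (nN/um)
#' @param events_at_convergence list of event actions applied after the
#'   generation phase converges; each `list(action =, ...)`
#' @param post_phase `"none"` (single phase), `"equal"` (run the
#'   perturbation phase for as long as the generation phase took) or
#'   `"convergence"` (run it to its own convergence)
#' @return an object of class `scenario_spec`
#' @export
scenario_spec <- function(name, prestrain = prestrain_spec(), k_cont = 0,
                          events_at_convergence = list(),
                          post_phase = c("none", "equal", "convergence")) {
  stopifnot(inherits(prestrain, "prestrain_spec"), k_cont >= 0)
  post_phase <- match.arg(post_phase)
  ok <- c("set_k_cont", "multiply_ecm_damping", "delete_ecm",
          "delete_apical_adhesion")
  for (e in events_at_convergence) {
    if (!e$action %in% ok) stop("unknown scenario action: ", e$action)
    if (e$action == "multiply_ecm_damping" &&
        !e$region %in% c("ECMs", "ECMbc", "ECMc"))
      stop("unknown ECM region: ", e$region)
  }
  structure(list(name = name, prestrain = prestrain, k_cont = k_cont,
                 events = events_at_convergence, post_phase = post_phase),
            class = "scenario_spec")
}

#' Baseline scenario: no prestrain, no contractility
#' @return a `scenario_spec`
#' @export
scenario_baseline <- function() {
  scenario_spec("baseline")
}

#' Patterned ECM tension scenario
#'
#' Zero contractility; the ECM under the columnar pouch carries `ratio`-fold
#' the tension of the ECM over the squamous layer. The study varies the ratio
#' from 4 to 7.
#'
#' @param ratio tension ratio F_ECMc / F_ECMs
#' @param F_ECMs squamous-side tension per spring (nN)
#' @return a `scenario_spec`
#' @export
scenario_ecm_tension <- function(ratio, F_ECMs = 2) {
  stopifnot(ratio >= 0, F_ECMs >= 0)
  scenario_spec(sprintf("ecm_tension_%g", ratio),
                prestrain = prestrain_spec(F_ECMs = F_ECMs,
                                           F_ECMc = ratio * F_ECMs))
}

#' Basal actomyosin contractility scenario
#'
#' No ECM prestrain; contractility springs beneath the nuclei of columnar
#' cells at the low (3), medium (6) or high (9 nN/um) level, or an explicit
#' value.
#'
#' @param level `"low"`, `"medium"`, `"high"` or a contractility in nN/um
#' @return a `scenario_spec`
#' @export
scenario_contractility <- function(level = "high") {
  k <- if (is.character(level))
    c(low = 3, medium = 6, high = 9)[[match.arg(level, c("low", "medium", "high"))]]
  else as.numeric(level)
  stopifnot(k >= 0)
  scenario_spec(sprintf("contractility_%g", k), k_cont = k)
}

#' Shape-maintenance scenario
#'
#' Generate the bend with high contractility, then switch contractility off
#' while multiplying the damping of the columnar-associated ECM (ECMc) by
#' three orders of magnitude; the stiff, slow ECM preserves the generated
#' shape. `with_damping = FALSE` gives the relaxation control without the
#' damping multiplier.
#'
#' @param with_damping apply the ECMc damping multiplier
#' @param factor the damping multiplier (default 1e3)
#' @return a `scenario_spec`
#' @export
scenario_maintenance <- function(with_damping = TRUE, factor = 1e3) {
  ev <- list(list(action = "set_k_cont", value = 0))
  if (with_damping)
    ev <- c(ev, list(list(action = "multiply_ecm_damping", region = "ECMc",
                          factor = factor)))
  scenario_spec(if (with_damping) "maintenance" else "maintenance_control",
                k_cont = 9, events_at_convergence = ev, post_phase = "equal")
}

#' Collagenase scenario: acute ECM removal
#'
#' Generate the bend with high contractility, then delete the entire ECM
#' chain (with its basal adhesion) and switch contractility off. The pull of
#' the squamous layer transmitted through the marginal cells then inverts
#' the bend.
#'
#' @return a `scenario_spec`
#' @export
scenario_collagenase <- function() {
  scenario_spec("collagenase", k_cont = 9,
                events_at_convergence = list(
                  list(action = "delete_ecm"),
                  list(action = "set_k_cont", value = 0)),
                post_phase = "equal")
}

#' Dual-perturbation scenario: ECM, contractility and interlayer adhesion
#'
#' As [scenario_collagenase()] plus deletion of the apical adhesion between
#' the columnar and squamous layers, opening a gap between the two layers at
#' the centre.
#'
#' @return a `scenario_spec`
#' @export
scenario_dual_perturbation <- function() {
  scenario_spec("dual_perturbation", k_cont = 9,
                events_at_convergence = list(
                  list(action = "delete_ecm"),
                  list(action = "set_k_cont", value = 0),
                  list(action = "delete_apical_adhesion")),
                post_phase = "equal")
}

# apply one scenario event to (state, ep, dp); returns the updated triple
apply_scenario_event <- function(state, ep, dp, event) {
  switch(event$action,
    set_k_cont = {
      ep$e_cont$k <- event$value
    },
    multiply_ecm_damping = {
      dp$ecm_region_multipliers[event$region] <-
        dp$ecm_region_multipliers[event$region] * event$factor
    },
    delete_ecm = {
      state <- remove_nodes(state, which(state$node_class == 3L))
      state$bonds$ecm <- c(empty_bonds(), list(region = character(0)))
      state$bonds$adh_basal <- empty_bonds()
    },
    delete_apical_adhesion = {
      state$bonds$adh_apical <- empty_bonds()
      state$adh_apical_enabled <- FALSE
    },
    stop("unknown scenario action: ", event$action))
  list(state = state, ep = ep, dp = dp)
}

#' Run a perturbation scenario
#'
#' Builds the tissue, applies the scenario's prestrain and contractility,
#' runs the generation phase to convergence (or the step cap), applies the
#' scheduled events, and runs the perturbation phase per the scenario's
#' post-phase rule. Returns both phases' metric series and summary readouts.
#'
#' @param spec a `scenario_spec`
#' @param cfg a [tissue_config()]
#' @param ep,dp energy and damping parameters
#' @param sim a [sim_config()]
#' @return list of class `scenario_result`: `trajectory` (generation phase),
#'   `post_trajectory` (perturbation phase or NULL), `state` (final),
#'   `curvature_at_switch`, `final_curvature`, `gap` ([detect_layer_gap()]
#'   report on the final state), `spec`
#' @export
run_scenario <- function(spec, cfg = tissue_config(preset = "reduced"),
                         ep = energy_params(), dp = damping_params(),
                         sim = sim_config()) {
  stopifnot(inherits(spec, "scenario_spec"))
  ep$e_cont$k <- spec$k_cont
  state <- build_tissue(cfg, ep)
  state <- apply_prestrain(state, spec$prestrain, ep)
  traj <- run_simulation(state, ep, dp, sim)
  c_switch <- traj$curvature[length(traj$curvature)]
  post <- NULL
  if (length(spec$events)) {
    st <- traj$state; ep2 <- traj$ep; dp2 <- traj$dp
    for (e in spec$events) {
      res <- apply_scenario_event(st, ep2, dp2, e)
      st <- res$state; ep2 <- res$ep; dp2 <- res$dp
    }
    st <- refresh_pairs(st, ep2)
    sim2 <- sim
    if (spec$post_phase == "equal") {
      sim2$max_steps <- traj$steps
      sim2$convergence_window <- .Machine$integer.max  # run the full horizon
    }
    post <- run_simulation(st, ep2, dp2, sim2)
  }
  fin <- if (is.null(post)) traj else post
  final_state <- fin$state
  gap <- tryCatch(detect_layer_gap(final_state), error = function(e) NULL)
  structure(list(trajectory = traj, post_trajectory = post,
                 state = final_state, curvature_at_switch = c_switch,
                 final_curvature = fin$curvature[length(fin$curvature)],
                 gap = gap, spec = spec),
            class = "scenario_result")
}

#' Detect an interlayer gap over the central adhesion zone
#'
#' For each columnar cell of the central adhesion zone, measures the minimum
#' distance from its apical midpoint to the squamous layer's apical
#' polyline; a gap is reported when the largest such distance exceeds the
#' threshold (by default twice the apical-adhesion rest length).
#'
#' @param state an `sce_tissue` with both layers present
#' @param threshold gap threshold (um); the default (2 um, ten times the
#'   apposed-layer adhesion rest length) flags separations far beyond
#'   ordinary interlayer spacing
#' @return list of class `gap_report`: `gap_present`, `gap_width` (um),
#'   `location` (range of zone cell ids exceeding the threshold, or NULL)
#' @export
detect_layer_gap <- function(state, threshold = 2) {
  if (!length(state$adh_zone_cells)) stop("empty apical adhesion zone")
  if (!length(state$squamous_cells)) stop("squamous layer absent")
  sq <- surface_polyline(state, "squamous_apical")
  d <- vapply(state$adh_zone_cells, function(cid) {
    cl <- state$cells[[cid]]
    ap <- state$pos[cl$ring[state$region[cl$ring] == "apical"], , drop = FALSE]
    point_polyline_distance(colMeans(ap), sq)
  }, numeric(1))
  over <- which(d > threshold)
  structure(list(gap_present = length(over) > 0, gap_width = max(d),
                 location = if (length(over)) range(state$adh_zone_cells[over])
                            else NULL),
            class = "gap_report")
}
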