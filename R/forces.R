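#' Force of a Morse pair on the first node
#'
#' Evaluates \eqn{-\partial U/\partial x_1} for
#' \eqn{U(r) = U_0 e^{-r/\xi_0} - W_0 e^{-r/\gamma_0}} with a hard cutoff,
#' where `r` is the separation vector from node 2 to node 1. Positive radial
#' component pushes the nodes apart.
#'
#' @param r numeric length-2 separation vector `x1 - x2` (um)
#' @param p a [morse_params()] object
#' @return length-2 force vector on node 1 (nN)
#' @export
morse_force <- function(r, p) {
  stopifnot(inherits(p, "morse_params"), length(r) == 2)
  d <- sqrt(sum(r^2))
  if (d == 0) stop("degenerate Morse pair: zero separation")
  if (d >= p$cutoff - 1e-9) return(c(0, 0))
  fr <- p$U0 / p$xi0 * exp(-d / p$xi0) - p$W0 / p$ga0 * exp(-d / p$ga0)
  fr * r / d
}

#' Energy of a Morse pair
#'
#' @inheritParams morse_force
#' @return scalar energy (nN um); zero at or beyond the cutoff
#' @export
morse_energy <- function(r, p) {
  d <- sqrt(sum(r^2))
  if (d >= p$cutoff - 1e-9) return(0)
  p$U0 * exp(-d / p$xi0) - p$W0 * exp(-d / p$ga0)
}

#' Force of a linear spring on the first node
#'
#' Magnitude \eqn{k(|r| - r_0)} directed to restore the rest length. A
#' breakable spring exerts no force beyond its break distance. At exactly zero
#' separation the force is defined (zero) only for zero-rest-length springs.
#'
#' @inheritParams morse_force
#' @param p a [spring_params()] object
#' @return length-2 force vector on node 1 (nN)
#' @export
spring_force <- function(r, p) {
  stopifnot(inherits(p, "spring_params"), length(r) == 2)
  d <- sqrt(sum(r^2))
  if (d > p$break_distance) return(c(0, 0))
  if (d == 0) {
    if (p$r0 == 0) return(c(0, 0))
    stop("degenerate spring pair: zero separation with nonzero rest length")
  }
  -p$k * (d - p$r0) * r / d
}

#' Energy of a linear spring
#'
#' @inheritParams spring_force
#' @return scalar energy (nN um); zero beyond the break distance
#' @export
spring_energy <- function(r, p) {
  d <- sqrt(sum(r^2))
  if (d > p$break_distance) return(0)
  0.5 * p$k * (d - p$r0)^2
}

#' Area-conservation forces on one cell's membrane ring
#'
#' The 2D realisation of cytoplasmic volume conservation: a stiff quadratic
#' penalty \eqn{E = \frac12 k_{vol} (A - A_0)^2} on the signed shoelace area
#' of the membrane polygon. Returns the analytic gradient force on each ring
#' node; these sum to zero over the ring.
#'
#' @param cell a cell entry of a tissue (with `ring` and `target_area`)
#' @param state an `sce_tissue` object
#' @param k_vol penalty stiffness (nN/um^3)
#' @return matrix with one force row (nN) per ring node, in ring order
#' @export
area_constraint_force <- function(cell, state, k_vol) {
  ring <- cell$ring
  if (length(ring) < 3) stop("cell polygon needs at least 3 vertices")
  P <- state$pos[ring, , drop = FALSE]
  A <- polygon_area(P)
  if (abs(A) < 1e-12) stop("zero-area cell polygon")
  if (A < 0)
    warning("negative signed area: ring is clockwise or self-intersecting")
  m <- nrow(P)
  nxt <- c(2:m, 1)
  prv <- c(m, 1:(m - 1))
  dAdx <- 0.5 * (P[nxt, 2] - P[prv, 2])
  dAdy <- 0.5 * (P[prv, 1] - P[nxt, 1])
  -k_vol * (A - cell$target_area) * cbind(dAdx, dAdy, deparse.level = 0)
}

#' Signed polygon area (shoelace)
#'
#' @param P matrix of polygon vertices (rows), in order
#' @return signed area; positive for counter-clockwise rings
#' @export
polygon_area <- function(P) {
  x <- P[, 1]; y <- P[, 2]
  nxt <- c(2:nrow(P), 1)
  sum(x * y[nxt] - x[nxt] * y) / 2
}

# Flatten the tissue's interaction lists plus energy parameters into the
# packed table consumed by the C++ kernels. Bond family order: membrane, ECM,
# lateral adhesion, basal adhesion, apical interlayer adhesion, margin
# adhesion (built boundary-squamous links, using E_adhL stiffness), then
# contractility.
pack_interactions <- function(state, ep) {
  fam <- function(b, p) {
    n <- length(b$i)
    brk <- if (!is.null(b$brk)) b$brk else rep(p$break_distance, n)
    k <- if (!is.null(b$kmul)) p$k * b$kmul else rep(p$k, n)
    list(i = b$i, j = b$j, k = k, r0 = b$r0, brk = brk)
  }
  fams <- list(
    fam(state$bonds$memb, ep$e_memb),
    fam(state$bonds$ecm, ep$e_ecm),
    fam(state$bonds$adh_lateral, ep$e_adhL),
    fam(state$bonds$adh_basal, ep$e_adhB),
    fam(state$bonds$adh_apical, ep$e_adhA),
    fam(state$bonds$adh_margin, ep$e_adhL),
    fam(state$bonds$cont, ep$e_cont)
  )
  rings <- lapply(state$cells, `[[`, "ring")
  list(
    si = as.integer(unlist(lapply(fams, `[[`, "i"), use.names = FALSE)),
    sj = as.integer(unlist(lapply(fams, `[[`, "j"), use.names = FALSE)),
    sk = as.numeric(unlist(lapply(fams, `[[`, "k"), use.names = FALSE)),
    sr0 = as.numeric(unlist(lapply(fams, `[[`, "r0"), use.names = FALSE)),
    sbrk = as.numeric(unlist(lapply(fams, `[[`, "brk"), use.names = FALSE)),
    vi = as.integer(state$excl_pairs[, 1]),
    vj = as.integer(state$excl_pairs[, 2]),
    vprm = with(ep$e_v, c(U0, xi0, W0, ga0, cutoff)),
    ni = as.integer(state$nuc_pairs[, 1]),
    nj = as.integer(state$nuc_pairs[, 2]),
    nprm = with(ep$e_nuc, c(U0, xi0, W0, ga0, cutoff)),
    ring_idx = as.integer(unlist(rings, use.names = FALSE)),
    ring_off = as.integer(c(0, cumsum(lengths(rings)))),
    area0 = as.numeric(vapply(state$cells, `[[`, numeric(1), "target_area")),
    kvol = ep$k_vol
  )
}

#' Total force on every node of a tissue
#'
#' Assembles the negative gradient of the full model energy: nucleus nodes
#' feel nucleus cohesion and volume exclusion; membrane nodes feel membrane,
#' contractility, volume-exclusion, area-penalty and the three adhesion
#' terms; ECM nodes feel ECM, volume-exclusion and basal-adhesion terms.
#' All interactions are internal pairs, so forces sum to zero.
#'
#' @param state an `sce_tissue` object with current pair lists (see
#'   [refresh_pairs()])
#' @param ep an [energy_params()] object
#' @return matrix of per-node forces (nN), one row per node
#' @export
compute_total_forces <- function(state, ep) {
  cpp_forces(state$pos, pack_interactions(state, ep))
}

#' Total potential energy of a tissue
#'
#' Sum of all spring, Morse and area-penalty terms at the current positions,
#' consistent with [compute_total_forces()] (whose output is its negative
#' gradient).
#'
#' @inheritParams compute_total_forces
#' @return scalar energy (nN um)
#' @export
total_energy <- function(state, ep) {
  cpp_energy(state$pos, pack_interactions(state, ep))
}
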