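# Shape metrics on point sets from simulations or fixtures: circumcircle
# global curvature, Menger local curvature profile, fractional apicobasal
# nuclear position and cell height, and the asymptotic convergence fit.

#' Signed circumcircle (Menger) curvature of three points
#'
#' The reciprocal circumradius \eqn{4 A(p_1,p_2,p_3) / (|p_1p_2||p_2p_3||p_3p_1|)}
#' with the sign of the triangle's orientation (counter-clockwise positive).
#' Collinear points give 0; duplicated points are an error.
#'
#' @param p1,p2,p3 length-2 numeric points (um)
#' @return signed curvature (1/um)
#' @export
circumcircle_curvature <- function(p1, p2, p3) {
  a <- sqrt(sum((p1 - p2)^2))
  b <- sqrt(sum((p2 - p3)^2))
  d <- sqrt(sum((p3 - p1)^2))
  if (a == 0 || b == 0 || d == 0) stop("duplicate points have no circumcircle")
  A2 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) -
        (p3[1] - p1[1]) * (p2[2] - p1[2])   # twice the signed area
  2 * A2 / (a * b * d)
}

# interpolated point at a given arc length along a polyline
polyline_point_at <- function(P, s_target, s = NULL) {
  if (is.null(s)) s <- polyline_arclength(P)
  s_target <- min(max(s_target, 0), s[length(s)])
  k <- findInterval(s_target, s, rightmost.closed = TRUE)
  k <- min(max(k, 1L), nrow(P) - 1L)
  ds <- s[k + 1] - s[k]
  w <- if (ds > 0) (s_target - s[k]) / ds else 0
  (1 - w) * P[k, ] + w * P[k + 1, ]
}

polyline_arclength <- function(P) {
  seg <- sqrt(rowSums((P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2))
  if (any(seg == 0)) stop("polyline has coincident consecutive points")
  c(0, cumsum(seg))
}

#' Global curvature of a surface polyline
#'
#' Circumcircle curvature through the polyline's first point, its arc-length
#' midpoint and its last point. The sign convention is dome-positive: for a
#' pouch surface ordered along the tissue (squamous side to the local left of
#' travel), positive curvature means the margins deflect basally, away from
#' the squamous layer -- the wild-type dome. Reflection flips the sign,
#' rigid motions leave it unchanged.
#'
#' @param P n x 2 matrix of ordered polyline points (n >= 3)
#' @return signed global curvature (1/um)
#' @export
global_curvature <- function(P) {
  P <- as.matrix(P)
  if (nrow(P) < 3) stop("polyline needs at least 3 points")
  s <- polyline_arclength(P)
  mid <- polyline_point_at(P, s[length(s)] / 2, s)
  p1 <- P[1, ]; p3 <- P[nrow(P), ]
  if (sqrt(sum((mid - p1)^2)) == 0 || sqrt(sum((mid - p3)^2)) == 0)
    return(0)
  -circumcircle_curvature(p1, mid, p3)
}

#' Local Menger curvature profile along a polyline
#'
#' At each interior point, the signed Menger (circumcircle) curvature of the
#' triple formed with the polyline points one arc-length half-window behind
#' and ahead (linearly interpolated along the polyline). Points whose window
#' does not fit are omitted. Sign convention matches [global_curvature()].
#'
#' @param P n x 2 matrix of ordered polyline points
#' @param window_halfwidth arc-length half window `w` (um)
#' @return data frame with `arclength` and `curvature` per retained point
#' @export
menger_profile <- function(P, window_halfwidth) {
  P <- as.matrix(P)
  s <- polyline_arclength(P)
  total <- s[length(s)]
  if (2 * window_halfwidth >= total)
    stop("polyline shorter than the Menger window")
  keep <- which(s >= window_halfwidth & s <= total - window_halfwidth)
  kappa <- vapply(keep, function(k) {
    pm <- polyline_point_at(P, s[k] - window_halfwidth, s)
    pp <- polyline_point_at(P, s[k] + window_halfwidth, s)
    if (min(sqrt(sum((pm - P[k, ])^2)), sqrt(sum((pp - P[k, ])^2))) == 0)
      return(0)
    -circumcircle_curvature(pm, P[k, ], pp)
  }, numeric(1))
  data.frame(arclength = s[keep], curvature = kappa)
}

# minimum distance from point q to a polyline (over all segments)
point_polyline_distance <- function(q, P) {
  A <- P[-nrow(P), , drop = FALSE]
  B <- P[-1, , drop = FALSE]
  ab <- B - A
  len2 <- rowSums(ab^2)
  t <- ((q[1] - A[, 1]) * ab[, 1] + (q[2] - A[, 2]) * ab[, 2]) /
    pmax(len2, .Machine$double.eps)
  t <- pmin(pmax(t, 0), 1)
  px <- A[, 1] + t * ab[, 1]
  py <- A[, 2] + t * ab[, 2]
  sqrt(min((q[1] - px)^2 + (q[2] - py)^2))
}

#' Fractional apicobasal nuclear position and cell height
#'
#' `L_A` is the distance from the nucleus centre to the apical surface,
#' `L_B` to the basal surface; the fractional position `L_B / (L_A + L_B)`
#' is 0 at the basal and 1 at the apical surface, and the cell height is
#' `L_A + L_B`. A nucleus centre outside the band is clamped (fraction 0 or
#' 1) and flagged.
#'
#' @param apical,basal n x 2 matrices: the cell's apical and basal surface
#'   polylines (single points are allowed and treated as degenerate
#'   one-point surfaces)
#' @param center length-2 nucleus centre
#' @return list with `L_A`, `L_B`, `fraction`, `height`, `clamped`
#' @export
nuclear_position <- function(apical, basal, center) {
  apical <- matrix(as.numeric(apical), ncol = 2)
  basal <- matrix(as.numeric(basal), ncol = 2)
  dist_to <- function(P) {
    if (nrow(P) == 1) sqrt(sum((center - P[1, ])^2))
    else point_polyline_distance(center, P)
  }
  L_A <- dist_to(apical)
  L_B <- dist_to(basal)
  if (L_A + L_B == 0) stop("degenerate cell: apical and basal surfaces coincide")
  list(L_A = L_A, L_B = L_B, fraction = L_B / (L_A + L_B),
       height = L_A + L_B, clamped = FALSE)
}

#' Per-cell nuclear-position metrics of a tissue
#'
#' Applies [nuclear_position()] to every columnar cell, using the nucleus
#' cluster centroid as the nucleus centre and the cell's own apical and
#' basal membrane nodes as its surfaces.
#'
#' @param state an `sce_tissue`
#' @return data frame with one row per columnar cell: `cell`, `L_A`, `L_B`,
#'   `fraction`, `height`
#' @export
tissue_nuclear_positions <- function(state) {
  rows <- lapply(state$columnar_cells, function(cid) {
    cl <- state$cells[[cid]]
    ap <- state$pos[cl$ring[state$region[cl$ring] == "apical"], , drop = FALSE]
    ba <- state$pos[cl$ring[state$region[cl$ring] == "basal"], , drop = FALSE]
    ctr <- colMeans(state$pos[cl$nucleus, , drop = FALSE])
    m <- nuclear_position(ap, ba, ctr)
    data.frame(cell = cid, L_A = m$L_A, L_B = m$L_B, fraction = m$fraction,
               height = m$height)
  })
  do.call(rbind, rows)
}

#' Surface polyline of the tissue
#'
#' Concatenates the requested membrane surface's nodes cell by cell in
#' left-to-right tissue order (node order within each cell follows the ring,
#' reversed where the ring runs right-to-left), yielding the polylines the
#' curvature metrics operate on.
#'
#' @param state an `sce_tissue`
#' @param surface one of `"pouch_basal"`, `"pouch_apical"`,
#'   `"squamous_apical"`, `"squamous_basal"`
#' @return matrix of ordered points
#' @export
surface_polyline <- function(state,
                             surface = c("pouch_basal", "pouch_apical",
                                         "squamous_apical", "squamous_basal")) {
  surface <- match.arg(surface)
  cells <- if (startsWith(surface, "pouch")) state$columnar_cells
           else state$squamous_cells
  tag <- if (endsWith(surface, "basal")) "basal" else "apical"
  pts <- lapply(cells, function(cid) {
    cl <- state$cells[[cid]]
    ids <- cl$ring[state$region[cl$ring] == tag]
    P <- state$pos[ids, , drop = FALSE]
    # ring order runs left->right on the bottom edge and right->left on top;
    # normalise to left->right using the cell's own edge direction
    if (P[1, 1] > P[nrow(P), 1]) P <- P[rev(seq_len(nrow(P))), , drop = FALSE]
    P
  })
  do.call(rbind, pts)
}

#' Global curvature of the tissue
#'
#' The headline shape readout: dome-positive global curvature of the columnar
#' pouch's apical membrane polyline (the surface customarily quantified
#' together with the basal peripodial surface). The pouch apical surface is
#' used because the basal one convolves bending with columnar height growth.
#'
#' @param state an `sce_tissue`
#' @param surface which surface to quantify (default pouch apical)
#' @return signed curvature (1/um)
#' @export
tissue_global_curvature <- function(state, surface = "pouch_apical") {
  global_curvature(surface_polyline(state, surface))
}

#' Asymptotic plateau fit of a curvature time series
#'
#' Least-squares fit of \eqn{c(t) = c_\infty - a e^{-t/\tau}} to a
#' convergence trace; reports the plateau, the time constant and the RMS
#' residual normalised by the plateau magnitude. A constant series returns
#' its value with zero residual; a non-convergent fit is flagged with
#' infinite residual.
#'
#' @param times increasing sample times (AU)
#' @param curvatures curvature samples (1/um)
#' @return list with `c_inf`, `tau`, `residual`, `converged`
#' @export
asymptotic_fit <- function(times, curvatures) {
  stopifnot(length(times) == length(curvatures), length(times) >= 5,
            !is.unsorted(times, strictly = TRUE))
  if (stats::sd(curvatures) < 1e-14)
    return(list(c_inf = mean(curvatures), tau = NA_real_, residual = 0,
                converged = TRUE))
  df <- data.frame(t = times - times[1], c = curvatures)
  n <- nrow(df)
  c_inf0 <- mean(df$c[max(1, n - 4):n])
  a0 <- c_inf0 - df$c[1]
  if (abs(a0) < 1e-14) a0 <- 1e-14
  tau0 <- max(diff(range(df$t)) / 3, .Machine$double.eps)
  fit <- tryCatch(
    minpack.lm::nlsLM(c ~ cinf - a * exp(-t / tau), data = df,
                      start = list(cinf = c_inf0, a = a0, tau = tau0),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    sse <- function(p) sum((df$c - (p[1] - p[2] * exp(-df$t / abs(p[3]))))^2)
    op <- tryCatch(stats::optim(c(c_inf0, a0, tau0), sse,
                                control = list(maxit = 5000)),
                   error = function(e) NULL)
    if (is.null(op))
      return(list(c_inf = NA_real_, tau = NA_real_, residual = Inf,
                  converged = FALSE))
    p <- op$par
    rmse <- sqrt(sse(p) / n)
    return(list(c_inf = p[1], tau = abs(p[3]),
                residual = rmse / max(abs(p[1]), 1e-12), converged = TRUE))
  }
  p <- stats::coef(fit)
  rmse <- sqrt(mean(stats::residuals(fit)^2))
  list(c_inf = unname(p["cinf"]), tau = unname(p["tau"]),
       residual = rmse / max(abs(p["cinf"]), 1e-12), converged = TRUE)
}

#' Summary table of per-cell shape metrics
#'
#' One row per columnar cell plus a trailing summary row (mean and sd),
#' matching the boxplot statistics customarily reported for nuclear position
#' and cell height.
#'
#' @param state an `sce_tissue`
#' @return data frame with columns cell, fraction, height and a final
#'   `"summary"` row carrying means; attributes `fraction_sd`, `height_sd`
#' @export
shape_metric_table <- function(state) {
  np <- tissue_nuclear_positions(state)
  out <- data.frame(cell = as.character(np$cell), fraction = np$fraction,
                    height = np$height)
  out <- rbind(out, data.frame(cell = "summary",
                               fraction = mean(np$fraction),
                               height = mean(np$height)))
  attr(out, "fraction_sd") <- stats::sd(np$fraction)
  attr(out, "height_sd") <- stats::sd(np$height)
  out
}
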