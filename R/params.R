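#' Morse pair-potential parameters
#'
#' The Morse interaction used for volume exclusion (`E_v`) and nucleus
#' cohesion (`E_nuc`) has the two-exponential subcellular-element form
#' \deqn{U(r) = U_0 e^{-r/\xi_0} - W_0 e^{-r/\gamma_0},}
#' short-range repulsion plus longer-range attraction, truncated at a hard
#' cutoff. The force vanishes at the equilibrium separation
#' \eqn{r^* = \log(U_0\gamma_0 / (W_0\xi_0)) / (1/\xi_0 - 1/\gamma_0)}.
#'
#' @param U0 repulsion amplitude (nN)
#' @param xi0 repulsion decay length (um)
#' @param W0 attraction amplitude (nN)
#' @param ga0 attraction decay length (um); must exceed `xi0`
#' @param cutoff interaction cutoff (um); must be at least `ga0`
#' @return an object of class `morse_params`
#' @seealso [morse_equilibrium()], [spring_params()], [energy_params()]
#' @export
morse_params <- function(U0, xi0, W0, ga0, cutoff) {
  stopifnot(U0 > 0, xi0 > 0, W0 > 0, ga0 > 0, cutoff > 0)
  if (xi0 >= ga0) stop("Morse repulsion scale xi0 must be shorter than attraction scale ga0")
  if (cutoff < ga0) stop("Morse cutoff must be >= the attraction scale ga0")
  structure(list(U0 = U0, xi0 = xi0, W0 = W0, ga0 = ga0, cutoff = cutoff),
            class = "morse_params")
}

#' Equilibrium separation of a Morse pair
#'
#' Distance at which the pairwise Morse force vanishes (repulsion balances
#' attraction). The tissue builder places non-bonded neighbours at exactly this
#' separation so that freshly built tissues carry no force.
#'
#' @param p a [morse_params()] object
#' @return equilibrium separation (um)
#' @export
morse_equilibrium <- function(p) {
  log((p$U0 * p$ga0) / (p$W0 * p$xi0)) / (1 / p$xi0 - 1 / p$ga0)
}

#' Linear spring parameters
#'
#' Springs realise membrane stiffness (`E_memb`), the three adhesion classes
#' (`E_adhL`, `E_adhB`, `E_adhA`), basal actomyosin contractility (`E_cont`)
#' and ECM stiffness (`E_ecm`). Energy is \eqn{\frac12 k (|r| - r_0)^2}.
#' Breakable springs (adhesion) exert no force beyond `break_distance`,
#' allowing delamination under strong perturbations.
#'
#' @param k stiffness (nN/um)
#' @param r0 rest length (um)
#' @param breakable whether the spring detaches beyond `break_distance`
#' @param break_distance detachment distance (um); defaults to `3 * r0`
#' @return an object of class `spring_params`
#' @export
spring_params <- function(k, r0 = 0, breakable = FALSE,
                          break_distance = if (breakable) 3 * r0 else Inf) {
  stopifnot(k >= 0, r0 >= 0)
  if (breakable && !(break_distance > 0)) stop("break_distance must be positive")
  structure(list(k = k, r0 = r0, breakable = breakable,
                 break_distance = if (breakable) break_distance else Inf),
            class = "spring_params")
}

#' Full energy-parameter set of the tissue model
#'
#' Collects the nine potential-energy terms that drive the node dynamics:
#' volume exclusion and nucleus cohesion (Morse), membrane / adhesion /
#' contractility / ECM springs, and the quadratic area (2D volume) penalty per
#' cell. Defaults give a force-free flat tissue whose non-bonded gaps sit at
#' the `E_v` equilibrium separation; the supplementary table of the original
#' study is not public, so these are package calibrations (see the vignette).
#'
#' @param volume_exclusion,nucleus [morse_params()] for `E_v` and `E_nuc`
#' @param membrane,lateral_adhesion,basal_adhesion,apical_interlayer_adhesion
#'   [spring_params()] for `E_memb`, `E_adhL`, `E_adhB`, `E_adhA`
#' @param contractility [spring_params()] for `E_cont`; its stiffness is the
#'   basal actomyosin contractility level `k_cont` (nN/um) and its rest length
#'   is zero
#' @param ecm [spring_params()] for `E_ecm`
#' @param k_vol area-penalty stiffness (nN/um^3) for `E_vol`
#' @return an object of class `energy_params`
#' @export
energy_params <- function(
    volume_exclusion = morse_params(U0 = 0.4 * exp(2), xi0 = 0.06, W0 = 1,
                                    ga0 = 0.15, cutoff = 0.5),
    nucleus = morse_params(U0 = 4 / 3 * exp(100 / 42), xi0 = 0.308, W0 = 4,
                           ga0 = 0.924, cutoff = 2.5),
    membrane = spring_params(k = 25),
    lateral_adhesion = spring_params(k = 20, r0 = 0.2, breakable = TRUE),
    basal_adhesion = spring_params(k = 20, r0 = 0.2, breakable = TRUE),
    apical_interlayer_adhesion = spring_params(k = 10, r0 = 0.2, breakable = TRUE,
                                               break_distance = 1.5),
    contractility = spring_params(k = 0, r0 = 0),
    ecm = spring_params(k = 40),
    k_vol = 5) {
  stopifnot(inherits(volume_exclusion, "morse_params"),
            inherits(nucleus, "morse_params"),
            inherits(membrane, "spring_params"),
            inherits(lateral_adhesion, "spring_params"),
            inherits(basal_adhesion, "spring_params"),
            inherits(apical_interlayer_adhesion, "spring_params"),
            inherits(contractility, "spring_params"),
            inherits(ecm, "spring_params"),
            k_vol >= 0)
  if (contractility$r0 != 0)
    stop("contractility springs have zero rest length")
  structure(list(e_v = volume_exclusion, e_nuc = nucleus, e_memb = membrane,
                 e_adhL = lateral_adhesion, e_adhB = basal_adhesion,
                 e_adhA = apical_interlayer_adhesion, e_cont = contractility,
                 e_ecm = ecm, k_vol = k_vol),
            class = "energy_params")
}

#' Drag coefficients of the overdamped dynamics
#'
#' One coefficient per node class (nucleus, membrane, ECM), with per-region
#' multipliers for the ECM chain (used by the shape-maintenance scenario,
#' which raises the ECMc drag by three orders of magnitude).
#'
#' @param C_nuc,C_memb,C_ecm drag coefficients (nN AU/um), all positive
#' @param ecm_region_multipliers named numeric multipliers for `ECMs`,
#'   `ECMbc`, `ECMc`
#' @return an object of class `damping_params`
#' @export
damping_params <- function(C_nuc = 1, C_memb = 1, C_ecm = 1,
                           ecm_region_multipliers = c(ECMs = 1, ECMbc = 1, ECMc = 1)) {
  stopifnot(C_nuc > 0, C_memb > 0, C_ecm > 0,
            all(ecm_region_multipliers > 0),
            all(c("ECMs", "ECMbc", "ECMc") %in% names(ecm_region_multipliers)))
  structure(list(C_nuc = C_nuc, C_memb = C_memb, C_ecm = C_ecm,
                 ecm_region_multipliers = ecm_region_multipliers),
            class = "damping_params")
}

#' Read energy and damping parameters from a YAML configuration file
#'
#' The file holds one block per energy term, named exactly `E_v`, `E_nuc`,
#' `E_memb`, `E_adhL`, `E_adhB`, `E_adhA`, `E_cont`, `E_ecm`, `E_vol`, plus a
#' `damping` block with `C_nuc`, `C_memb`, `C_ECM` (and optional
#' `ecm_region_multipliers`). Unknown top-level or block-level keys are
#' rejected so typos fail loudly rather than silently using a default.
#'
#' @param path path to the YAML file
#' @return list with elements `energy` ([energy_params()]) and `damping`
#'   ([damping_params()])
#' @export
read_param_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("E_v", "E_nuc", "E_memb", "E_adhL", "E_adhB", "E_adhA",
             "E_cont", "E_ecm", "E_vol", "damping")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown configuration block(s): ", paste(extra, collapse = ", "))

  take <- function(block, allowed, where) {
    if (is.null(block)) return(list())
    bad <- setdiff(names(block), allowed)
    if (length(bad))
      stop("unknown key(s) in ", where, ": ", paste(bad, collapse = ", "))
    block
  }
  morse_from <- function(name) {
    b <- take(cfg[[name]], c("U0", "xi0", "W0", "ga0", "cutoff"), name)
    if (!length(b)) return(NULL)
    do.call(morse_params, b)
  }
  spring_from <- function(name) {
    b <- take(cfg[[name]], c("k", "r0", "breakable", "break_distance"), name)
    if (!length(b)) return(NULL)
    do.call(spring_params, b)
  }
  args <- list()
  if (!is.null(m <- morse_from("E_v"))) args$volume_exclusion <- m
  if (!is.null(m <- morse_from("E_nuc"))) args$nucleus <- m
  if (!is.null(s <- spring_from("E_memb"))) args$membrane <- s
  if (!is.null(s <- spring_from("E_adhL"))) args$lateral_adhesion <- s
  if (!is.null(s <- spring_from("E_adhB"))) args$basal_adhesion <- s
  if (!is.null(s <- spring_from("E_adhA"))) args$apical_interlayer_adhesion <- s
  if (!is.null(s <- spring_from("E_cont"))) args$contractility <- s
  if (!is.null(s <- spring_from("E_ecm"))) args$ecm <- s
  ev <- take(cfg$E_vol, "k_vol", "E_vol")
  if (length(ev)) args$k_vol <- ev$k_vol
  energy <- do.call(energy_params, args)

  db <- take(cfg$damping, c("C_nuc", "C_memb", "C_ECM", "ecm_region_multipliers"),
             "damping")
  dargs <- list()
  if (!is.null(db$C_nuc)) dargs$C_nuc <- db$C_nuc
  if (!is.null(db$C_memb)) dargs$C_memb <- db$C_memb
  if (!is.null(db$C_ECM)) dargs$C_ecm <- db$C_ECM
  if (!is.null(db$ecm_region_multipliers))
    dargs$ecm_region_multipliers <- unlist(db$ecm_region_multipliers)
  damping <- do.call(damping_params, dargs)

  list(energy = energy, damping = damping)
}
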