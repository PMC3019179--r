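#' Kinase forcing profile
#'
#' A normalized activity time course for one input kinase on the 0-60 min
#' window. Activities are dimensionless in [0, 1]; the nuclear concentration
#' at time t is `scale * activity(t)`.
#'
#' @param times time grid (min), strictly increasing
#' @param activity dimensionless activity values in [0, 1]
#' @param scale maximum nuclear concentration (nM); nominal 100
#' @param basal basal (unstimulated) activity level; defaults to the first
#'   activity value
#' @return object of class `kinase_profile`
#' @export
kinase_profile <- function(times, activity, scale = 100,
                           basal = activity[1]) {
  stopifnot(length(times) == length(activity), length(times) >= 2,
            all(diff(times) > 0), all(is.finite(activity)),
            scale >= 0, basal >= 0)
  if (any(activity < -1e-12) || any(activity > 1 + 1e-12))
    stop("kinase activity must lie in [0, 1]")
  structure(list(times = as.numeric(times),
                 activity = pmin(pmax(as.numeric(activity), 0), 1),
                 scale = scale, basal = basal),
            class = "kinase_profile")
}

#' Interpolate a kinase profile
#'
#' Piecewise-linear interpolation of the profile's activity, scaled to a
#' nuclear concentration in nM.
#'
#' @param profile a [kinase_profile()]
#' @param t time (min); must lie within the profile's support
#' @return concentration in nM
#' @export
interpolate_kinase <- function(profile, t) {
  rng <- range(profile$times)
  if (any(t < rng[1] - 1e-9) || any(t > rng[2] + 1e-9))
    stop("t outside kinase profile support [", rng[1], ", ", rng[2], "]")
  profile$scale * stats::approx(profile$times, profile$activity,
                                xout = t, rule = 2)$y
}

#' Clamp a kinase profile to its basal level
#'
#' Emulates a pathway inhibitor: the activity is held at the basal level for
#' all times, as in pre-treatment with a kinase inhibitor.
#'
#' @param profile a [kinase_profile()]
#' @return a clamped `kinase_profile`
#' @export
clamp_profile <- function(profile) {
  kinase_profile(profile$times, rep(profile$basal, length(profile$times)),
                 scale = profile$scale, basal = profile$basal)
}

.params_hash <- function(params) {
  # cheap, dependency-free content hash for provenance metadata
  v <- c(as.numeric(params), utf8ToInt(paste(names(params), collapse = "")))
  sprintf("%08x", as.integer(sum(v * seq_along(v)) %% 2^31))
}

#' Simulate the network over 0-60 min
#'
#' Integrates the 29 ODE states with a stiff-capable solver (lsoda) and
#' reports concentrations on a fixed 1-min grid. Two engines exist: the
#' compiled table-driven right-hand side (default, used for all large
#' screens) and the pure-R one built by [assemble_rhs()]; both evaluate the
#' identical flux plan.
#'
#' @param network an `ap1_network`
#' @param params named parameter vector (77 entries for the packaged model)
#' @param inputs named list of [kinase_profile()]s covering every input
#' @param times reporting grid (min), default `0:60`
#' @param engine `"compiled"` or `"r"`
#' @param rtol,atol solver tolerances (recorded in metadata)
#' @param scenario label stored in the trajectory metadata
#' @return object of class `ap1_trajectory`: list with `times`,
#'   `conc` (time x state matrix, nM) and `metadata`
#' @export
simulate_network <- function(network, params, inputs, times = 0:60,
                             engine = c("compiled", "r"),
                             rtol = 1e-6, atol = 1e-9,
                             scenario = "angII") {
  engine <- match.arg(engine)
  stopifnot(all(network$inputs %in% names(inputs)))
  y0 <- initial_state(network, params)
  if (length(network$inputs)) {
    support <- range(inputs[[network$inputs[1]]]$times)
    if (min(times) < support[1] - 1e-9 || max(times) > support[2] + 1e-9)
      stop("requested times outside kinase input support")
  } else if (engine == "compiled") {
    engine <- "r"   # the compiled path always expects three forcings
  }

  if (engine == "compiled") {
    enc <- .encode_network(network, params)
    forc <- lapply(network$inputs, function(nm)
      cbind(inputs[[nm]]$times, inputs[[nm]]$activity))
    out <- deSolve::ode(y = y0, times = times, func = "ap1grn_derivs",
                        parms = enc, dllname = "ap1grn",
                        initfunc = "ap1grn_initpar",
                        initforc = "ap1grn_initforc",
                        forcings = forc,
                        fcontrol = list(method = "linear", rule = 2),
                        method = "lsoda", rtol = rtol, atol = atol)
  } else {
    rhs <- assemble_rhs(network, params, inputs)
    out <- deSolve::ode(y = y0, times = times,
                        func = function(t, y, p) list(rhs(t, y)),
                        parms = NULL, method = "lsoda",
                        rtol = rtol, atol = atol)
  }
  if (attr(out, "istate")[1] < 0 || nrow(out) < length(times)) {
    last_t <- if (nrow(out)) out[nrow(out), 1] else NA_real_
    stop("integration failed at t = ", last_t,
         " (params ", .params_hash(params), ")")
  }
  conc <- out[, -1, drop = FALSE]
  if (min(conc) < -1e-6)
    stop("negative concentration beyond tolerance (min ", min(conc),
         " nM, params ", .params_hash(params), ")")
  structure(list(times = times, conc = conc,
                 metadata = list(scenario = scenario,
                                 params_hash = .params_hash(params),
                                 rtol = rtol, atol = atol,
                                 engine = engine)),
            class = "ap1_trajectory")
}

#' Simulate a kinase-inhibition scenario
#'
#' Clamps the named kinase's activity profile to its basal level for all
#' times (the other inputs are untouched) and simulates.
#'
#' @inheritParams simulate_network
#' @param kinase name of an input kinase (`"ERK"`, `"FRK"` or `"JNK"` for the
#'   packaged network); may be a vector to inhibit several at once
#' @param ... passed on to [simulate_network()]
#' @return an `ap1_trajectory`
#' @export
simulate_inhibition <- function(network, params, inputs, kinase, ...) {
  unknown <- setdiff(kinase, network$inputs)
  if (length(unknown))
    stop("unknown kinase: ", paste(unknown, collapse = ", "))
  for (k in kinase) inputs[[k]] <- clamp_profile(inputs[[k]])
  simulate_network(network, params, inputs,
                   scenario = paste0(paste(kinase, collapse = "+"),
                                     "-inhib"), ...)
}

#' Extract a species time series from a trajectory
#'
#' @param traj an `ap1_trajectory`
#' @param species state name
#' @return numeric vector over the trajectory's time grid
#' @export
species_series <- function(traj, species) {
  if (!species %in% colnames(traj$conc))
    stop("species '", species, "' not in trajectory")
  as.numeric(traj$conc[, species])
}

#' Total AP-1 activity
#'
#' The aggregate Total AP-1 output: the elementwise sum of the nuclear
#' ppc-Fos:ppc-Jun and ppc-Jun:ppc-Jun dimer concentrations, matching the
#' net DNA-binding signal measured by gel-shift assays that cannot
#' distinguish the two dimers.
#'
#' @param traj an `ap1_trajectory`
#' @param hetero,homo state names of the two dimers
#' @return numeric time series (nM)
#' @export
total_ap1 <- function(traj, hetero = "FosJun", homo = "JunJun") {
  species_series(traj, hetero) + species_series(traj, homo)
}

#' Normalize a time series to the 0-at-start, max-1 convention
#'
#' Subtracts the value at the first time point and divides by the maximum of
#' the shifted series, yielding a dimensionless series with initial value 0
#' and maximum 1. A constant series cannot be normalized; it is returned as
#' all zeros with `degenerate = TRUE`.
#'
#' @param values numeric series
#' @param times optional time grid carried through
#' @return object of class `normalized_series` with fields `times`,
#'   `values`, `degenerate`
#' @export
normalize_series <- function(values, times = NULL) {
  stopifnot(length(values) >= 1, all(is.finite(values)))
  shifted <- values - values[1]
  m <- max(shifted)
  if (m <= 0) {
    out <- rep(0, length(values))
    degen <- TRUE
  } else {
    out <- shifted / m
    degen <- FALSE
  }
  structure(list(times = times, values = out, degenerate = degen),
            class = "normalized_series")
}

#' Time of equal dimer contribution
#'
#' Locates the dimer crossover: the earliest time after the heterodimer peak
#' at which the heterodimer and homodimer concentrations cross, found by a
#' sign change on the reporting grid and refined by linear interpolation.
#'
#' @param traj an `ap1_trajectory`
#' @param hetero,homo dimer state names
#' @return crossover time in min, or `NA_real_` when the two series never
#'   cross after the heterodimer peak
#' @export
crossover_time <- function(traj, hetero = "FosJun", homo = "JunJun") {
  h <- species_series(traj, hetero)
  j <- species_series(traj, homo)
  tt <- traj$times
  ipk <- which.max(h)
  if (ipk >= length(tt)) return(NA_real_)
  d <- h - j
  for (i in seq(max(ipk, 1), length(tt) - 1)) {
    # a strict sign change; touching zero without reversal is not a crossover
    if (d[i] > 0 && d[i + 1] < 0) {
      frac <- d[i] / (d[i] - d[i + 1])
      return(tt[i] + frac * (tt[i + 1] - tt[i]))
    }
    if (d[i] == 0 && d[i + 1] < 0) return(tt[i])
  }
  NA_real_
}
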