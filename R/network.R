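#' @useDynLib ap1grn, .registration = FALSE
NULL

# Compartment volumes (uL) estimated for brainstem neurons assuming spherical
# geometry; promoter pools are two binding sites per nuclear volume.
.AVOGADRO <- 6.02214076e23

#' Default compartment volumes
#'
#' Nuclear and cytoplasmic volumes of a brainstem neuron in microlitres.
#'
#' @return Named numeric vector with elements `nucleus` and `cytosol` (uL).
#' @export
default_volumes <- function() {
  c(nucleus = 14.1e-9, cytosol = 65.3e-9)
}

#' Concentration of a promoter pool with two free binding sites
#'
#' Converts a molecule count per nuclear volume into nM.
#'
#' @param n_sites number of unoccupied binding sites (default 2)
#' @param v_nucleus nuclear volume in uL
#' @return concentration in nM
#' @export
promoter_concentration <- function(n_sites = 2,
                                   v_nucleus = default_volumes()[["nucleus"]]) {
  # nM = mol / L * 1e9 ; v_nucleus uL -> L via 1e-6
  n_sites / (.AVOGADRO * v_nucleus * 1e-6) * 1e9
}

#' Canonical reaction-kind inventory of the AT1R gene regulatory network
#'
#' Reaction ids grouped by mechanistic class. Phosphorylation and
#' dephosphorylation steps follow Michaelis-Menten kinetics, dimerization and
#' TF:promoter binding are mass-action, and all synthesis/processing/
#' degradation/transport steps are first-order.
#'
#' @return Named list of integer vectors of reaction ids.
#' @export
at1rgrn_inventory <- function() {
  list(
    phosphorylation   = c(1L, 4L, 8L, 10L, 13L, 17L, 19L),
    dephosphorylation = c(2L, 5L, 9L, 11L, 14L, 18L, 20L, 23L, 26L, 28L),
    degradation       = c(3L, 6L, 7L, 12L, 15L, 16L, 22L, 25L, 33L, 40L, 48L),
    dimerization      = c(21L, 24L, 27L),
    dna_binding       = c(29L, 36L, 43L, 45L),
    transcription     = c(30L, 37L, 44L, 46L),
    basal_transcription = c(31L, 38L),
    processing        = c(32L, 39L, 47L),
    translation       = c(34L, 41L),
    translocation     = c(35L, 42L)
  )
}

.parse_participants <- function(x) {
  # "2*ppcJun;cFos_n" -> named stoichiometry vector
  x <- trimws(x)
  if (is.na(x) || x == "") return(numeric(0))
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  if (!length(parts)) return(numeric(0))
  coefs <- rep(1, length(parts))
  has_mult <- grepl("*", parts, fixed = TRUE)
  coefs[has_mult] <- as.numeric(sub("\\*.*$", "", parts[has_mult]))
  nm <- ifelse(has_mult, sub("^.*\\*", "", parts), parts)
  out <- numeric(0)
  for (i in seq_along(nm)) {   # merge duplicates
    out[nm[i]] <- (if (nm[i] %in% names(out)) out[[nm[i]]] else 0) + coefs[i]
  }
  out
}

#' Build a validated reaction network
#'
#' Assembles species and reaction tables into a network object holding the
#' stoichiometry (with compartment-volume scaling for transport fluxes), the
#' kinetic-law kind of every reaction and the full rate-parameter name list.
#'
#' @param reaction_table data.frame with columns `id`, `kind`, `substrates`,
#'   `products`, `modifier`, `params`, `compartment`. Participants are
#'   `;`-separated species names with optional `n*` stoichiometry prefixes;
#'   `params` holds `;`-separated rate-parameter names (two for
#'   Michaelis-Menten and reversible mass-action laws, one for first-order).
#' @param species_table data.frame with columns `name`, `compartment`,
#'   `role` (`state` or `input`) and `init` (a number, a parameter name, or
#'   `promoter` for the two-site promoter pool).
#' @param volumes named compartment volumes in uL
#' @param inventory optional named list of reaction-id sets (as from
#'   [at1rgrn_inventory()]); when supplied, kinetic-law kinds are checked
#'   id-by-id against it and any mismatch is a validation error.
#' @return An object of class `ap1_network`.
#' @export
build_network <- function(reaction_table, species_table,
                          volumes = default_volumes(),
                          inventory = NULL) {
  if (is.null(reaction_table) || nrow(reaction_table) == 0)
    stop("no reactions")
  stopifnot(all(c("id", "kind", "substrates", "products", "params") %in%
                  names(reaction_table)))
  stopifnot(all(c("name", "compartment", "role", "init") %in%
                  names(species_table)))
  if (anyDuplicated(reaction_table$id))
    stop("duplicate reaction id: ",
         paste(unique(reaction_table$id[duplicated(reaction_table$id)]),
               collapse = ", "))
  if (anyDuplicated(species_table$name))
    stop("duplicate species name")
  if (!all(species_table$compartment %in% names(volumes)))
    stop("species declared in unknown compartment")
  if (any(volumes <= 0)) stop("compartment volumes must be positive")

  sp_names <- species_table$name
  sp_comp <- stats::setNames(species_table$compartment, sp_names)
  kinds_ok <- c("michaelis_menten", "mass_action", "first_order")

  reactions <- vector("list", nrow(reaction_table))
  for (i in seq_len(nrow(reaction_table))) {
    row <- reaction_table[i, ]
    id <- as.integer(row$id)
    kind <- as.character(row$kind)
    if (!kind %in% kinds_ok)
      stop("reaction ", id, ": unknown kind '", kind, "'")
    subs <- .parse_participants(as.character(row$substrates))
    prods <- .parse_participants(as.character(row$products))
    modifier <- trimws(as.character(row$modifier %||% ""))
    if (is.na(modifier)) modifier <- ""
    pnames <- trimws(strsplit(as.character(row$params), ";", fixed = TRUE)[[1]])
    pnames <- pnames[nzchar(pnames)]
    refs <- c(names(subs), names(prods), if (nzchar(modifier)) modifier)
    bad <- setdiff(refs, sp_names)
    if (length(bad))
      stop("reaction ", id, ": undeclared species ",
           paste(bad, collapse = ", "))
    n_expected <- switch(kind,
                         michaelis_menten = 2L,
                         mass_action = 2L,   # kon, koff (koff may be zero)
                         first_order = 1L)
    if (length(pnames) != n_expected)
      stop("reaction ", id, ": expected ", n_expected,
           " parameter name(s), got ", length(pnames))
    if (kind == "michaelis_menten" && length(subs) != 1)
      stop("reaction ", id,
           ": Michaelis-Menten law requires exactly one substrate")
    if (kind == "first_order" && length(subs) != 1)
      stop("reaction ", id, ": first-order law requires exactly one substrate")
    if (kind == "mass_action" && !sum(subs) %in% c(1, 2))
      stop("reaction ", id, ": mass-action law supports order 1 or 2")
    reactions[[i]] <- list(
      id = id, kind = kind, substrates = subs, products = prods,
      modifier = if (nzchar(modifier)) modifier else NULL,
      params = pnames,
      compartment = sp_comp[[names(subs)[1]]],
      note = as.character(row$note %||% "")
    )
  }

  if (!is.null(inventory)) .check_inventory(reactions, inventory)

  param_names <- unique(unlist(lapply(reactions, `[[`, "params")))
  states <- species_table$name[species_table$role == "state"]
  inputs <- species_table$name[species_table$role == "input"]

  net <- structure(list(
    species = species_table,
    reactions = reactions,
    compartments = volumes,
    states = states,
    inputs = inputs,
    rate_param_names = param_names
  ), class = "ap1_network")
  net
}

.check_inventory <- function(reactions, inventory) {
  kind_of <- stats::setNames(vapply(reactions, `[[`, "", "kind"),
                             vapply(reactions, `[[`, 0L, "id"))
  expect <- list(
    michaelis_menten = c(inventory$phosphorylation,
                         inventory$dephosphorylation),
    mass_action = c(inventory$dimerization, inventory$dna_binding),
    first_order = c(inventory$degradation, inventory$transcription,
                    inventory$basal_transcription, inventory$processing,
                    inventory$translation, inventory$translocation)
  )
  for (k in names(expect)) {
    for (id in expect[[k]]) {
      got <- kind_of[[as.character(id)]]
      if (is.null(got) || is.na(got))
        stop("inventory check: reaction ", id, " missing from table")
      if (got != k)
        stop("inventory check: reaction ", id, " declared '", got,
             "' but must be '", k, "'")
    }
  }
  # degradation = first-order consumption with no products
  deg <- sort(vapply(Filter(function(r)
    r$kind == "first_order" && length(r$products) == 0, reactions),
    `[[`, 0L, "id"))
  if (!identical(deg, sort(inventory$degradation)))
    stop("inventory check: degradation reactions are {",
         paste(deg, collapse = ","), "}, expected {",
         paste(sort(inventory$degradation), collapse = ","), "}")
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load the packaged AT1R gene regulatory network
#'
#' Reads the versioned reaction and species tables shipped with the package
#' (48 reactions, 32 species in nuclear and cytosolic compartments) and builds
#' the validated network. The id-by-id kinetic-law inventory is enforced.
#'
#' @param dimer_dephos_product phospho-state of the monomers returned by the
#'   single-step dimer dissociation/dephosphorylation reactions (23, 26, 28):
#'   `"unphosphorylated"` (default) or `"singly_phosphorylated"`.
#' @return An `ap1_network` object.
#' @export
at1rgrn_network <- function(dimer_dephos_product =
                              c("unphosphorylated", "singly_phosphorylated")) {
  dimer_dephos_product <- match.arg(dimer_dephos_product)
  rx <- utils::read.delim(system.file("extdata", "at1rgrn_reactions.tsv",
                                      package = "ap1grn"),
                          stringsAsFactors = FALSE)
  sp <- utils::read.delim(system.file("extdata", "at1rgrn_species.tsv",
                                      package = "ap1grn"),
                          stringsAsFactors = FALSE)
  if (dimer_dephos_product == "singly_phosphorylated") {
    rx$products[rx$id == 23] <- "pcFos;pcJun"
    rx$products[rx$id == 26] <- "2*pcJun"
    rx$products[rx$id == 28] <- "pcJun;pATF2"
  }
  net <- build_network(rx, sp, inventory = at1rgrn_inventory())
  stopifnot(nrow(net$species) == 32, length(net$states) == 29,
            length(net$inputs) == 3, length(net$rate_param_names) == 72)
  net
}

#' Nominal parameter set of the packaged network
#'
#' Returns the 77 model parameters: 72 reaction-rate parameters, the two
#' non-zero initial conditions (nuclear Elk-1 and ATF-2, nM) and the maximum
#' nuclear concentrations of the three input kinases (nM). Rate-parameter
#' values are a synthetic calibration of the model to its documented nominal
#' behaviour (early heterodimer peak, dimer crossover near 40 min, late
#' homodimer dominance); they are not literature measurements.
#'
#' @return Named numeric vector of length 77.
#' @export
nominal_parameters <- function() {
  p <- jsonlite::read_json(system.file("extdata",
                                       "at1rgrn_nominal_params.json",
                                       package = "ap1grn"),
                           simplifyVector = TRUE)
  unlist(p)
}

#' Parameter bookkeeping for a parameter set
#'
#' Partitions a full parameter vector into reaction-rate parameters,
#' non-zero initial conditions and kinase concentration scales, and checks
#' positivity and cardinality.
#'
#' @param params named numeric vector (typically length 77)
#' @param network an `ap1_network`
#' @return list with elements `rate`, `init`, `kinase` (character name sets)
#' @export
partition_parameters <- function(params, network) {
  stopifnot(is.numeric(params), !is.null(names(params)))
  if (any(!is.finite(params)) || any(params <= 0))
    stop("all parameters must be positive and finite")
  rate <- intersect(names(params), network$rate_param_names)
  kin <- intersect(names(params), paste0(network$inputs, "_max"))
  init <- setdiff(names(params), c(rate, kin))
  missing <- setdiff(network$rate_param_names, rate)
  if (length(missing))
    stop("missing rate parameters: ", paste(missing, collapse = ", "))
  list(rate = rate, init = init, kinase = kin)
}

#' Initial state of a network
#'
#' Resolves the `init` column of the species table: numbers are used as-is,
#' parameter names are looked up in `params`, and `promoter` expands to the
#' two-unoccupied-binding-sites-per-nuclear-volume concentration.
#'
#' @param network an `ap1_network`
#' @param params named parameter vector (for `ic_*` entries)
#' @return named state vector (nM) over the ODE states only
#' @export
initial_state <- function(network, params) {
  sp <- network$species[network$species$role == "state", ]
  prom <- promoter_concentration(
    2, network$compartments[["nucleus"]])
  vals <- vapply(sp$init, function(x) {
    if (identical(x, "promoter")) return(prom)
    v <- suppressWarnings(as.numeric(x))
    if (!is.na(v)) return(v)
    if (!x %in% names(params)) stop("initial condition parameter '", x,
                                    "' not in parameter set")
    params[[x]]
  }, numeric(1), USE.NAMES = FALSE)
  stats::setNames(vals, sp$name)
}

#' Rate law of a single reaction
#'
#' Evaluates the flux (nM/min, in the reaction's own compartment) of one
#' reaction at a given state. Michaelis-Menten reactions with a kinase
#' modifier use `v = kcat * [E] * [S] / (Km + [S])`; without a modifier the
#' constant-phosphatase assumption folds the enzyme level into
#' `v = Vmax * [S] / (Km + [S])`. Mass-action reactions return the forward
#' flux `kon * prod([S])`; their reverse flux is assembled separately by the
#' right-hand side. First-order reactions return `k * [S]`.
#'
#' @param reaction a reaction entry from an `ap1_network`
#' @param state named concentration vector (nM); must contain every substrate
#' @param params named parameter vector
#' @param modifiers named concentrations of input species (kinases), required
#'   when the reaction has a modifier that is not part of `state`
#' @return non-negative flux in nM/min
#' @export
reaction_rate <- function(reaction, state, params, modifiers = NULL) {
  getp <- function(nm) {
    if (!nm %in% names(params))
      stop("missing parameter '", nm, "' for reaction ", reaction$id)
    params[[nm]]
  }
  conc <- function(nm) {
    if (nm %in% names(state)) return(state[[nm]])
    if (!is.null(modifiers) && nm %in% names(modifiers))
      return(modifiers[[nm]])
    stop("no concentration for species '", nm, "' (reaction ",
         reaction$id, ")")
  }
  s <- names(reaction$substrates)
  switch(reaction$kind,
    michaelis_menten = {
      S <- conc(s[1])
      km <- getp(reaction$params[2])
      vmax <- getp(reaction$params[1])
      if (!is.null(reaction$modifier)) vmax <- vmax * conc(reaction$modifier)
      vmax * S / (km + S)
    },
    mass_action = {
      kon <- getp(reaction$params[1])
      kon * prod(vapply(s, conc, numeric(1))^reaction$substrates)
    },
    first_order = getp(reaction$params[1]) * conc(s[1])
  )
}

# Stoichiometry of one network as a dense states x fluxes matrix, where
# mass-action reactions contribute a forward and (if koff named) a reverse
# flux column. Transport across compartments is scaled by the volume ratio
# so that amounts, not concentrations, are conserved.
.flux_plan <- function(network) {
  vol <- network$compartments
  states <- network$states
  fluxes <- list()
  for (r in network$reactions) {
    add_flux <- function(subs, prods, kind, pidx, modifier, id) {
      coef <- stats::setNames(numeric(length(states)), states)
      rcomp <- network$species$compartment[
        match(names(subs)[1], network$species$name)]
      for (nm in names(subs)) coef[nm] <- coef[nm] - subs[[nm]]
      for (nm in names(prods)) {
        scomp <- network$species$compartment[
          match(nm, network$species$name)]
        scale <- vol[[rcomp]] / vol[[scomp]]
        coef[nm] <- coef[nm] + prods[[nm]] * scale
      }
      fluxes[[length(fluxes) + 1]] <<- list(
        id = id, kind = kind, substrates = subs, params = pidx,
        modifier = modifier, coef = coef)
    }
    if (r$kind == "mass_action") {
      add_flux(r$substrates, r$products, "mass_action",
               r$params[1], NULL, r$id)
      add_flux(r$products, r$substrates, "mass_action",
               r$params[2], NULL, r$id)   # reverse
    } else {
      add_flux(r$substrates, r$products, r$kind, r$params, r$modifier, r$id)
    }
  }
  fluxes
}

#' Assemble the ODE right-hand side
#'
#' Returns a derivative function `f(t, state)` over the 29 ODE states.
#' Kinase inputs are evaluated from the supplied forcing profiles by linear
#' interpolation, never integrated. Fluxes that cross compartments are
#' volume-scaled so that amount (concentration x volume) is conserved.
#'
#' @param network an `ap1_network`
#' @param params named parameter vector covering every rate parameter plus
#'   the `<kinase>_max` scales
#' @param kinase_inputs named list of [kinase_profile()] objects, one per
#'   input species
#' @return function of `(t, state)` returning the named derivative vector
#' @export
assemble_rhs <- function(network, params, kinase_inputs = list()) {
  stopifnot(all(network$inputs %in% names(kinase_inputs)))
  plan <- .flux_plan(network)
  interp <- lapply(network$inputs, function(nm) {
    pr <- kinase_inputs[[nm]]
    scale_name <- paste0(nm, "_max")
    sc <- if (scale_name %in% names(params)) params[[scale_name]] else pr$scale
    f <- stats::approxfun(pr$times, pr$activity, rule = 2)
    function(t) sc * f(t)
  })
  names(interp) <- network$inputs
  support <- if (length(network$inputs))
    range(kinase_inputs[[network$inputs[1]]]$times) else c(-Inf, Inf)
  # stiff solvers overshoot the final reporting time by up to one step;
  # forcing values are constant-extrapolated inside this margin only
  margin <- if (is.finite(diff(support))) 0.05 * diff(support) else 0

  function(t, state) {
    if (t < support[1] - margin || t > support[2] + margin)
      stop("time ", t, " outside kinase input support [",
           support[1], ", ", support[2], "]")
    mods <- vapply(interp, function(f) f(t), numeric(1))
    dx <- stats::setNames(numeric(length(network$states)), network$states)
    for (fl in plan) {
      v <- .eval_flux(fl, state, params, mods)
      if (v != 0) dx <- dx + v * fl$coef
    }
    dx
  }
}

.eval_flux <- function(fl, state, params, mods) {
  # solver-tolerance negative excursions are treated as zero concentration,
  # matching the compiled engine
  s <- names(fl$substrates)
  switch(fl$kind,
    michaelis_menten = {
      S <- max(state[[s[1]]], 0)
      vmax <- params[[fl$params[1]]]
      if (!is.null(fl$modifier)) {
        vmax <- vmax * (if (fl$modifier %in% names(mods))
          mods[[fl$modifier]] else state[[fl$modifier]])
      }
      vmax * S / (params[[fl$params[2]]] + S)
    },
    mass_action = {
      k <- params[[fl$params[1]]]
      if (k == 0) return(0)
      k * prod(vapply(s, function(nm) max(state[[nm]], 0),
                      numeric(1))^fl$substrates)
    },
    first_order = params[[fl$params[1]]] * max(state[[s[1]]], 0)
  )
}
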