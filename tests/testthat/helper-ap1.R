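# Shared fixtures, built once per test run.

.fx <- new.env(parent = emptyenv())

fx_network <- function() {
  if (is.null(.fx$net)) .fx$net <- at1rgrn_network()
  .fx$net
}
fx_params <- function() {
  if (is.null(.fx$par)) .fx$par <- nominal_parameters()
  .fx$par
}
fx_inputs <- function() {
  if (is.null(.fx$inp)) .fx$inp <- synth_kinase_profiles()
  .fx$inp
}
fx_nominal <- function() {
  if (is.null(.fx$nom))
    .fx$nom <- simulate_network(fx_network(), fx_params(), fx_inputs())
  .fx$nom
}

# A two-species, one-reaction toy: nuclear pre-mRNA exported to the cytosol.
# Used for amount-conservation checks across compartments.
toy_transport_network <- function() {
  rx <- data.frame(id = 1L, kind = "first_order", substrates = "pre",
                   products = "mat", modifier = "", params = "k_exp",
                   compartment = "nucleus")
  sp <- data.frame(name = c("pre", "mat"),
                   compartment = c("nucleus", "cytosol"),
                   role = "state", init = c("10", "0"))
  build_network(rx, sp)
}

# Pure first-order decay chain with an analytic solution.
toy_decay_network <- function() {
  rx <- data.frame(id = 1L, kind = "first_order", substrates = "A",
                   products = "", modifier = "", params = "kdeg",
                   compartment = "cytosol")
  sp <- data.frame(name = "A", compartment = "cytosol", role = "state",
                   init = "5")
  build_network(rx, sp)
}

# Fos-arm / Jun-arm attribution of a parameter, by the reaction it rates.
# Kinase scales attribute to their own pathway; initial conditions to the
# TF they seed.
arm_of <- function(nm) {
  if (nm %in% c("FRK_max", "ERK_max", "ic_Elk1")) return("fos")
  if (nm %in% c("JNK_max", "ic_ATF2")) return("jun")
  fos_rx <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 12, 29, 30, 31, 32, 33, 34, 35,
              43, 44)
  id <- suppressWarnings(as.integer(sub("^r([0-9]+)_.*$", "\\1", nm)))
  if (is.na(id)) return("other")
  if (id %in% fos_rx) "fos" else "jun"
}
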