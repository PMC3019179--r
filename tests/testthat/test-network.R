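test_that("the packaged network matches its structural contract", {
  net <- fx_network()
  expect_equal(nrow(net$species), 32)
  expect_equal(length(net$states), 29)
  expect_equal(sort(net$inputs), c("ERK", "FRK", "JNK"))
  expect_equal(length(net$rate_param_names), 72)

  p <- fx_params()
  expect_equal(length(p), 77)
  part <- partition_parameters(p, net)
  expect_equal(length(part$rate), 72)
  expect_equal(sort(part$init), c("ic_ATF2", "ic_Elk1"))
  expect_equal(length(part$kinase), 3)

  inv <- at1rgrn_inventory()
  expect_equal(sort(unlist(inv, use.names = FALSE)), 1:48)
  kinds <- vapply(net$reactions, `[[`, "", "kind")
  ids <- vapply(net$reactions, `[[`, 0L, "id")
  expect_setequal(ids[kinds == "michaelis_menten"],
                  c(inv$phosphorylation, inv$dephosphorylation))
  expect_setequal(ids[kinds == "mass_action"],
                  c(inv$dimerization, inv$dna_binding))
})

test_that("network validation rejects malformed tables", {
  rx <- utils::read.delim(system.file("extdata", "at1rgrn_reactions.tsv",
                                      package = "ap1grn"))
  sp <- utils::read.delim(system.file("extdata", "at1rgrn_species.tsv",
                                      package = "ap1grn"))
  expect_error(build_network(rx[0, ], sp), "no reactions")
  rx_dup <- rbind(rx, rx[1, ])
  expect_error(build_network(rx_dup, sp), "duplicate reaction id: 1")
  rx_bad <- rx
  rx_bad$substrates[3] <- "not_a_species"
  expect_error(build_network(rx_bad, sp), "undeclared species not_a_species")
  # dimerization declared first-order must fail the inventory check
  rx_kind <- rx
  rx_kind$kind[rx_kind$id == 21] <- "first_order"
  rx_kind$params[rx_kind$id == 21] <- "r21_kon"
  expect_error(build_network(rx_kind, sp, inventory = at1rgrn_inventory()),
               "reaction 21")
})

test_that("initial conditions resolve promoters and parameter references", {
  net <- fx_network()
  y0 <- initial_state(net, fx_params())
  expect_equal(length(y0), 29)
  expect_equal(unname(y0["Elk1"]), 56.312)
  expect_equal(unname(y0["ATF2"]), 56.312)
  prom <- promoter_concentration()
  expect_equal(unname(y0[c("FosProm", "JunProm", "THProm")]),
               rep(prom, 3))
  expect_equal(prom, 0.23554, tolerance = 1e-4)
  expect_true(all(y0 >= 0))
  expect_equal(sum(y0 > 0), 5)  # two TFs + three promoter pools
})

test_that("kinetic laws evaluate to their closed forms", {
  net <- fx_network()
  p <- fx_params()
  rx <- net$reactions
  byid <- function(i) rx[[which(vapply(rx, `[[`, 0L, "id") == i)]]

  # zero substrate gives zero flux for every kind
  zero <- stats::setNames(rep(0, 29), net$states)
  for (i in c(1, 21, 3)) {
    expect_equal(reaction_rate(byid(i), zero, p,
                               modifiers = c(ERK = 50, FRK = 50, JNK = 50)),
                 0)
  }
  # half-saturation identity for a kinase-driven reaction
  r1 <- byid(1)
  st <- zero; st["Elk1"] <- p[["r01_Km"]]
  expect_equal(reaction_rate(r1, st, p, modifiers = c(ERK = 80)),
               p[["r01_kcat"]] * 80 / 2)
  # mass-action heterodimerization at unit concentrations
  r21 <- byid(21)
  st2 <- zero; st2["ppcFos"] <- 1; st2["ppcJun"] <- 1
  p2 <- p; p2["r21_kon"] <- 0.5
  expect_equal(reaction_rate(r21, st2, p2), 0.5)
  # missing parameter is reported with the reaction id
  p3 <- p[setdiff(names(p), "r03_k")]
  expect_error(reaction_rate(byid(3), st, p3), "r03_k.*reaction 3")
})

test_that("the RHS conserves amounts across compartments and promoter pools", {
  # transport toy: amount leaving the nucleus equals amount entering cytosol
  toy <- toy_transport_network()
  rhs <- assemble_rhs(toy, c(k_exp = 0.4))
  d <- rhs(0, c(pre = 10, mat = 0))
  vol <- default_volumes()
  expect_equal(unname(vol["nucleus"] * d["pre"] + vol["cytosol"] * d["mat"]),
               0)
  expect_equal(unname(d["pre"]), -4)

  # promoter pools: free + bound sums have zero net derivative
  net <- fx_network()
  p <- fx_params()
  rhs2 <- assemble_rhs(net, p, fx_inputs())
  st <- initial_state(net, p)
  st[] <- abs(sin(seq_along(st))) * 5   # arbitrary positive state
  d2 <- rhs2(10, st)
  expect_equal(unname(d2["FosProm"] + d2["FosProm_pElk1"]), 0,
               tolerance = 1e-12)
  expect_equal(unname(d2["JunProm"] + d2["JunProm_JunATF"]), 0,
               tolerance = 1e-12)
  expect_equal(unname(d2["THProm"] + d2["THProm_FosJun"] +
                        d2["THProm_JunJun"]), 0, tolerance = 1e-12)

  # zero state with zero basal transcription: no negative derivative and
  # only basal terms could fire
  p0 <- p; p0["r31_k"] <- 1e-12; p0["r38_k"] <- 1e-12
  d0 <- rhs2(10, stats::setNames(rep(0, 29), net$states))
  expect_true(all(d0 >= 0))
  expect_true(all(abs(d0) < 1e-10))
})

test_that("compiled and interpreted right-hand sides agree", {
  net <- fx_network()
  p <- fx_params()
  inp <- fx_inputs()
  tr1 <- simulate_network(net, p, inp, engine = "compiled")
  tr2 <- simulate_network(net, p, inp, engine = "r")
  expect_lt(max(abs(tr1$conc - tr2$conc)) / max(tr1$conc), 1e-4)
})
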