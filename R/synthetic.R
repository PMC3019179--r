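#' Specification for the synthetic-data generator
#'
#' Collects the knobs of the generator that stands in for the wet-lab
#' inputs: unimodal kinase activation profiles and noisy normalized target
#' curves. Peak times and widths parameterize scaled gamma-density pulses;
#' FRK activates and decays earliest, JNK peaks at 30 min, ERK is
#' intermediate.
#'
#' @param seed RNG seed used by noisy generators
#' @param peak named peak times (min) for `ERK`, `FRK`, `JNK`
#' @param width named pulse widths (min; the gamma shape parameter is
#'   `(peak/width)^2`)
#' @param basal named basal activity levels (fraction of maximum)
#' @param scale named maximum nuclear concentrations (nM)
#' @param noise_sd standard deviation of additive Gaussian noise applied to
#'   normalized target series
#' @return object of class `ap1_synth_spec`
#' @export
synthetic_spec <- function(seed = 1L,
                           peak = c(ERK = 20, FRK = 8, JNK = 30),
                           width = c(ERK = 12, FRK = 6, JNK = 14),
                           basal = c(ERK = 0.05, FRK = 0.05, JNK = 0.05),
                           scale = c(ERK = 100, FRK = 100, JNK = 100),
                           noise_sd = 0.05) {
  stopifnot(noise_sd >= 0, all(peak > 0), all(peak < 60), all(width > 0),
            all(basal >= 0), all(basal < 1), all(scale >= 0))
  structure(list(seed = as.integer(seed), peak = peak, width = width,
                 basal = basal, scale = scale, noise_sd = noise_sd),
            class = "ap1_synth_spec")
}

#' Generate unimodal kinase forcing profiles
#'
#' Builds the three kinase inputs on the 1-min grid as basal-offset,
#' max-normalized gamma-density pulses. The pulse for each kinase peaks at
#' the specified time; with the default spec FRK peaks first and decays
#' before JNK, which peaks at 30 min.
#'
#' @param spec an [synthetic_spec()]
#' @param times time grid (min), default `0:60`
#' @return named list of three [kinase_profile()]s (`ERK`, `FRK`, `JNK`)
#' @export
synth_kinase_profiles <- function(spec = synthetic_spec(), times = 0:60) {
  out <- lapply(c("ERK", "FRK", "JNK"), function(nm) {
    pk <- spec$peak[[nm]]; w <- spec$width[[nm]]; b <- spec$basal[[nm]]
    shape <- (pk / w)^2 + 1
    rate <- (shape - 1) / pk          # mode of the gamma density at pk
    g <- stats::dgamma(times, shape = shape, rate = rate)
    g <- g / max(g)
    act <- b + (1 - b) * g
    act <- act / max(act)             # exact max 1 on the grid
    kinase_profile(times, act, scale = spec$scale[[nm]], basal = act[1])
  })
  names(out) <- c("ERK", "FRK", "JNK")
  out
}

#' Generate surrogate experimental fitting targets
#'
#' Simulates the network under `true_params`, extracts the four fitting
#' channels (nuclear pElk-1, cytoplasmic c-Fos mRNA, Total AP-1 and
#' cytoplasmic TH mRNA), normalizes each to the 0-at-start/max-1 convention,
#' adds Gaussian noise of `spec$noise_sd` on the normalized scale and
#' re-normalizes so that the published normalization contract still holds.
#'
#' @param network an `ap1_network`
#' @param true_params the generating parameter set
#' @param spec an [synthetic_spec()]; its seed drives the noise
#' @param times sampling grid for the targets (default every 5 min)
#' @param inputs optional kinase profiles (default from the same spec)
#' @return object of class `ap1_fit_targets`: named list of
#'   `normalized_series` (`pElk1`, `cFos_mRNA`, `AP1`, `TH_mRNA`)
#' @export
synth_fit_targets <- function(network, true_params,
                              spec = synthetic_spec(),
                              times = seq(0, 60, by = 5),
                              inputs = synth_kinase_profiles(spec)) {
  traj <- simulate_network(network, true_params, inputs)
  channels <- fit_channels(traj)
  set.seed(spec$seed)
  out <- lapply(channels, function(ch) {
    # normalize on the simulation's own 1-min window (the convention the
    # screening SSE uses for model output), then sample the target grid
    ns_full <- normalize_series(ch, traj$times)
    if (ns_full$degenerate)
      stop("degenerate normalization of a fitting channel")
    v <- stats::approx(traj$times, ns_full$values, xout = times)$y
    ns <- structure(list(times = times, values = v, degenerate = FALSE),
                    class = "normalized_series")
    if (spec$noise_sd > 0) {
      noisy <- v + stats::rnorm(length(times), 0, spec$noise_sd)
      noisy[1] <- 0
      ns <- normalize_series(noisy, times)
    }
    ns
  })
  structure(out, class = "ap1_fit_targets")
}

#' Extract the four fitting channels from a trajectory
#'
#' @param traj an `ap1_trajectory`
#' @return named list of numeric series: `pElk1`, `cFos_mRNA`, `AP1`
#'   (Total AP-1) and `TH_mRNA`
#' @export
fit_channels <- function(traj) {
  list(pElk1 = species_series(traj, "pElk1"),
       cFos_mRNA = species_series(traj, "cFos_mRNA"),
       AP1 = total_ap1(traj),
       TH_mRNA = species_series(traj, "TH_mRNA"))
}

#' Analytic oracles for the sensitivity estimators
#'
#' Test functions with closed-form variance decompositions used to validate
#' the first-order/total-effect estimators: the Ishigami function (a = 7,
#' b = 0.1, inputs uniform on \[-pi, pi\]^3) and an additive linear model
#' with independent uniform inputs (all interactions zero, alpha = 1).
#'
#' @return named list; each oracle has `fn` (vectorized over an n x k
#'   matrix on \[0, 1\]^k), `k`, `S1`, `ST`
#' @export
gsa_oracles <- function() {
  a <- 7; b <- 0.1
  ish_fn <- function(X) {
    Z <- (X * 2 - 1) * pi
    sin(Z[, 1]) + a * sin(Z[, 2])^2 + b * Z[, 3]^4 * sin(Z[, 1])
  }
  v1 <- 0.5 * (1 + b * pi^4 / 5)^2
  v2 <- a^2 / 8
  vt3 <- 8 * b^2 * pi^8 / 225
  vtot <- v1 + v2 + vt3
  ishigami <- list(fn = ish_fn, k = 3L,
                  S1 = c(v1, v2, 0) / vtot,
                  ST = c(v1 + vt3, v2, vt3) / vtot)
  additive <- function(coef = c(4, 2, 1)) {
    k <- length(coef)
    vi <- coef^2 / 12      # Var of Unif(0,1) is 1/12
    list(fn = function(X) as.numeric(X %*% coef), k = k,
         S1 = vi / sum(vi), ST = vi / sum(vi))
  }
  list(ishigami = ishigami, additive = additive)
}

#' Generate rule-labeled parameter samples for tree recovery
#'
#' Draws Latin-hypercube samples of the named parameters within their
#' two-fold boxes and labels each point by a finite list of axis-aligned
#' threshold clauses, optionally flipping a fraction of labels. Used as a
#' planted-truth fixture for decision-tree recovery checks.
#'
#' @param rule list of clauses; each clause is
#'   `list(label=, param=, op=">"` or `"<", threshold=)`, evaluated in
#'   order with a final `default` label
#' @param n number of samples
#' @param seed RNG seed
#' @param ranges named list of `c(lo, hi)` per parameter
#' @param default label when no clause fires
#' @param flip fraction of labels to flip uniformly at random
#' @return list with `params` (data.frame) and `labels` (factor)
#' @export
synth_labeled_responses <- function(rule, n, seed = 1L, ranges,
                                    default = "balance", flip = 0) {
  stopifnot(length(rule) >= 1, n >= 1, flip >= 0, flip < 1)
  set.seed(seed)
  k <- length(ranges)
  U <- lhs::randomLHS(n, k)
  P <- as.data.frame(sapply(seq_len(k), function(j)
    ranges[[j]][1] + U[, j] * (ranges[[j]][2] - ranges[[j]][1])))
  names(P) <- names(ranges)
  labels <- rep(default, n)
  assigned <- rep(FALSE, n)
  for (cl in rule) {
    if (!cl$param %in% names(P)) stop("rule names unknown parameter '",
                                      cl$param, "'")
    hit <- if (cl$op == ">") P[[cl$param]] > cl$threshold
           else P[[cl$param]] < cl$threshold
    sel <- hit & !assigned
    labels[sel] <- cl$label
    assigned <- assigned | sel
  }
  if (flip > 0) {
    idx <- sample.int(n, round(flip * n))
    lv <- unique(labels)
    if (length(lv) < 2) stop("label flipping requires at least two classes")
    labels[idx] <- vapply(labels[idx], function(l)
      sample(setdiff(lv, l), 1), character(1))
  }
  list(params = P, labels = factor(labels))
}
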