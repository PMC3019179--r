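#' Sample perturbed parameter sets
#'
#' Draws `n` random parameter vectors with every free parameter perturbed
#' independently within a `fold`-range of its base value
#' (`base/fold <= p <= fold*base`). Fixed model quantities (compartment
#' volumes, kinase maxima, promoter sites and the non-zero initial
#' conditions) are excluded by listing them in `fixed`.
#'
#' @param base named base parameter vector (all entries positive)
#' @param n number of sets
#' @param fold fold-range half-width (default 2); `fold = 1` returns the
#'   base values unchanged
#' @param seed RNG seed
#' @param fixed names of parameters to keep at their base value
#' @param scale `"linear"` (uniform on `[base/fold, fold*base]`) or
#'   `"log"` (log-uniform, symmetric in fold change)
#' @return n x length(base) matrix with column names
#' @export
sample_parameter_sets <- function(base, n, fold = 2, seed = 1L,
                                  fixed = character(),
                                  scale = c("linear", "log")) {
  scale <- match.arg(scale)
  stopifnot(n >= 1, fold >= 1)
  if (any(base <= 0)) stop("non-positive base parameter")
  set.seed(seed)
  k <- length(base)
  free <- setdiff(names(base), fixed)
  U <- matrix(0.5, nrow = n, ncol = k, dimnames = list(NULL, names(base)))
  if (length(free) && fold > 1)
    U[, free] <- lhs::randomLHS(n, length(free))
  P <- matrix(rep(base, each = n), nrow = n,
              dimnames = list(NULL, names(base)))
  if (fold > 1 && length(free)) {
    lo <- base[free] / fold
    hi <- base[free] * fold
    if (scale == "linear") {
      P[, free] <- sweep(sweep(U[, free, drop = FALSE], 2, hi - lo, "*"),
                         2, lo, "+")
    } else {
      P[, free] <- exp(sweep(sweep(U[, free, drop = FALSE], 2,
                                   log(hi) - log(lo), "*"), 2, log(lo), "+"))
    }
  }
  P
}

#' Sum-squared error between a model series and a target
#'
#' The model series is linearly interpolated onto the target's time points
#' before summation.
#'
#' @param model a `normalized_series` (or list with `times`, `values`)
#' @param target a `normalized_series` with its own time grid
#' @return scalar sum of squared deviations (dimensionless)
#' @export
sse <- function(model, target) {
  if (is.null(model$times) || is.null(target$times))
    stop("both series need time grids")
  if (max(model$times) < min(target$times) ||
      min(model$times) > max(target$times))
    stop("disjoint time supports")
  mv <- stats::approx(model$times, model$values, xout = target$times,
                      rule = 2)$y
  sum((mv - target$values)^2)
}

#' Sequential experimental-constraint screening
#'
#' The Monte-Carlo calibration funnel: each candidate parameter set is
#' simulated once and its four normalized output channels are scored against
#' the targets; candidates are then filtered stage by stage in the fixed
#' order pElk-1 DNA binding, c-Fos mRNA, Total AP-1 DNA binding, TH mRNA,
#' keeping the best `keep_fraction` by that stage's SSE at each stage.
#' Survivor sets are nested by construction.
#'
#' @param sets parameter matrix from [sample_parameter_sets()] (rows are
#'   candidates; columns may cover only the perturbed subset of parameters)
#' @param network an `ap1_network`
#' @param inputs kinase profiles
#' @param targets an `ap1_fit_targets` object
#' @param base_params full parameter vector supplying any parameter not in
#'   `sets`
#' @param keep_fraction fraction of candidates retained per stage (scalar or
#'   length-4 vector)
#' @param times reporting grid for the candidate simulations
#' @param engine simulation engine
#' @return object of class `ap1_screen`: list with `sse` (n x 4 matrix),
#'   `stages` (list of survivor index vectors), `survivors` (final indices),
#'   `failed` (indices of failed simulations), `keep_fraction`
#' @export
sequential_screen <- function(sets, network, inputs, targets, base_params,
                              keep_fraction = 0.10, times = 0:60,
                              engine = "compiled") {
  stages <- c("pElk1", "cFos_mRNA", "AP1", "TH_mRNA")
  stopifnot(all(stages %in% names(targets)))
  keep_fraction <- rep_len(keep_fraction, 4)
  n <- nrow(sets)
  err <- matrix(NA_real_, n, 4, dimnames = list(NULL, stages))
  for (i in seq_len(n)) {
    p <- base_params
    p[colnames(sets)] <- sets[i, ]
    traj <- tryCatch(simulate_network(network, p, inputs, times = times,
                                      engine = engine),
                     error = function(e) NULL)
    if (is.null(traj)) next
    ch <- fit_channels(traj)
    for (s in stages) {
      ns <- normalize_series(ch[[s]], traj$times)
      err[i, s] <- sse(ns, targets[[s]])
    }
  }
  failed <- which(is.na(err[, 1]))
  alive <- setdiff(seq_len(n), failed)
  stage_list <- list()
  for (j in seq_along(stages)) {
    if (!length(alive))
      stop("no survivors at stage '", stages[j], "'")
    keep <- max(1L, floor(keep_fraction[j] * length(alive)))
    ord <- alive[order(err[alive, stages[j]])]
    alive <- sort(ord[seq_len(keep)])
    stage_list[[stages[j]]] <- alive
  }
  structure(list(sse = err, stages = stage_list, survivors = alive,
                 failed = failed, keep_fraction = keep_fraction),
            class = "ap1_screen")
}
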