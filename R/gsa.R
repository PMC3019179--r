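#' Build a sampling design for variance-based sensitivity analysis
#'
#' Generates the two independent base matrices A and B of the
#' Saltelli/Jansen radial scheme as stratified Latin-hypercube points on
#' the unit cube, mapped linearly onto the two-fold perturbation box
#' `[base/fold, fold*base]` per parameter. The radial matrices `A_B^(i)`
#' (A with column i replaced from B) are formed during evaluation; the full
#' design costs `n * (k + 2)` model runs.
#'
#' @param base named base parameter vector (the k perturbed parameters)
#' @param n base sample size (a power of 2 is recommended)
#' @param seed RNG seed; the same seed reproduces the design exactly
#' @param fold fold-range of the perturbation box (default 2)
#' @return object of class `gsa_design` with unit-cube matrices `U_A`,
#'   `U_B`, parameter matrices `A`, `B`, `ranges`, `k`, `n`
#' @export
build_design <- function(base, n, seed = 1L, fold = 2) {
  if (n < 2) stop("n must be at least 2")
  if (any(base <= 0)) stop("base parameters must be positive")
  k <- length(base)
  set.seed(seed)
  U <- lhs::randomLHS(n, 2L * k)
  U_A <- U[, seq_len(k), drop = FALSE]
  U_B <- U[, k + seq_len(k), drop = FALSE]
  lo <- base / fold
  hi <- base * fold
  map <- function(M) {
    out <- sweep(sweep(M, 2, hi - lo, "*"), 2, lo, "+")
    colnames(out) <- names(base)
    out
  }
  structure(list(U_A = U_A, U_B = U_B, A = map(U_A), B = map(U_B),
                 ranges = rbind(lo = lo, hi = hi), k = k, n = n,
                 seed = seed, fold = fold),
            class = "gsa_design")
}

#' Evaluate a model over a sensitivity design
#'
#' Runs the model at every point of A, B and each radial matrix `A_B^(i)`.
#' `model_fn` must accept an m x k parameter matrix and return an m x T
#' output matrix (T = 1 for scalar outputs). Failed rows (NA) are tolerated
#' up to `max_fail_fraction`, beyond which evaluation aborts.
#'
#' @param design a [build_design()] object
#' @param model_fn vectorized model evaluator
#' @param max_fail_fraction abort threshold for failed simulations
#' @return object of class `gsa_evaluation` with `YA`, `YB` (n x T) and
#'   `YAB` (list of k n x T matrices), plus the failure count
#' @export
evaluate_design <- function(design, model_fn, max_fail_fraction = 0.01) {
  k <- design$k
  YA <- model_fn(design$A)
  if (is.null(dim(YA))) YA <- matrix(YA, ncol = 1)
  YB <- model_fn(design$B)
  if (is.null(dim(YB))) YB <- matrix(YB, ncol = 1)
  YAB <- vector("list", k)
  for (i in seq_len(k)) {
    Ai <- design$A
    Ai[, i] <- design$B[, i]
    Yi <- model_fn(Ai)
    if (is.null(dim(Yi))) Yi <- matrix(Yi, ncol = 1)
    YAB[[i]] <- Yi
  }
  n_fail <- sum(is.na(YA[, 1])) + sum(is.na(YB[, 1])) +
    sum(vapply(YAB, function(m) sum(is.na(m[, 1])), numeric(1)))
  n_total <- design$n * (k + 2)
  if (n_fail / n_total > max_fail_fraction)
    stop("more than ", 100 * max_fail_fraction,
         "% of simulations failed (", n_fail, "/", n_total, ")")
  structure(list(YA = YA, YB = YB, YAB = YAB, n_fail = n_fail,
                 param_names = colnames(design$A)),
            class = "gsa_evaluation")
}

#' First-order and total-effect sensitivity indices
#'
#' Estimates, per output time point, the first-order index
#' `S1_i = V_i / V(Y)` (Saltelli-2010 estimator) and the total-effect index
#' `ST_i = (V_i + sum of all interaction terms involving i) / V(Y)`
#' (Jansen estimator), together with the output variance `V[t]` and the
#' interaction ratio `alpha = S1/ST`.
#'
#' @param evaluation a [evaluate_design()] result
#' @param design the matching design
#' @param st_floor noise floor on ST below which alpha is masked
#' @return object of class `sensitivity_result`: matrices `S1`, `ST`,
#'   `alpha` (k x T), vectors `V`, `valid` (initially all TRUE where V > 0)
#' @export
sensitivity_indices <- function(evaluation, design, st_floor = 0.02) {
  YA <- evaluation$YA
  YB <- evaluation$YB
  k <- design$k
  Tn <- ncol(YA)
  cc <- stats::complete.cases(YA, YB) &
    Reduce(`&`, lapply(evaluation$YAB, stats::complete.cases))
  YA <- YA[cc, , drop = FALSE]
  YB <- YB[cc, , drop = FALSE]
  YAB <- lapply(evaluation$YAB, function(m) m[cc, , drop = FALSE])
  n <- nrow(YA)
  Yall <- rbind(YA, YB)
  V <- apply(Yall, 2, function(col) mean((col - mean(col))^2))
  S1 <- ST <- matrix(NA_real_, k, Tn,
                     dimnames = list(evaluation$param_names, NULL))
  for (i in seq_len(k)) {
    D <- YAB[[i]] - YA
    S1[i, ] <- colMeans(YB * D) / V
    ST[i, ] <- colMeans(D^2) / (2 * V)
  }
  alpha <- pmin(pmax(S1 / ST, 0), 1)
  alpha[ST <= st_floor] <- NA_real_
  valid <- V > 0
  S1[, !valid] <- NA_real_
  ST[, !valid] <- NA_real_
  structure(list(S1 = S1, ST = ST, alpha = alpha, V = as.numeric(V),
                 valid = valid, n = n, st_floor = st_floor),
            class = "sensitivity_result")
}

#' Interaction ratio alpha = S1 / ST
#'
#' A ratio near 1 means the parameter acts directly (its influence is not
#' conditional on other parameters); near 0 means it acts only through
#' interactions. Values are clipped to \[0, 1\] and masked where ST is at or
#' below the estimator noise floor.
#'
#' @param result a [sensitivity_indices()] result
#' @return k x T matrix of alpha values (NA where masked)
#' @export
alpha_ratio <- function(result) {
  result$alpha
}

#' Mask time points with unreliable variance
#'
#' Sensitivity indices computed where the output variance is small are
#' numerically unreliable; times with `V[t] < fraction * max(V)` are marked
#' invalid and their indices set to NA.
#'
#' @param result a `sensitivity_result`
#' @param fraction variance threshold as a fraction of the maximum variance
#'   (default 0.10)
#' @return the masked `sensitivity_result`
#' @export
mask_low_variance <- function(result, fraction = 0.10) {
  valid <- result$V >= fraction * max(result$V)
  result$valid <- valid & result$valid
  result$S1[, !result$valid] <- NA_real_
  result$ST[, !result$valid] <- NA_real_
  result$alpha[, !result$valid] <- NA_real_
  result$mask_fraction <- fraction
  result
}

#' Rank parameters by total-effect sensitivity
#'
#' Orders parameters by the maximum of ST over the valid time points
#' (optionally restricted to `t_idx` columns).
#'
#' @param result a `sensitivity_result`
#' @param t_idx optional column indices to restrict the ranking to
#' @return data.frame with `parameter`, `max_ST`, ordered decreasing
#' @export
rank_parameters <- function(result, t_idx = NULL) {
  cols <- which(result$valid)
  if (!is.null(t_idx)) cols <- intersect(cols, t_idx)
  if (!length(cols)) stop("no valid time points to rank over")
  m <- apply(result$ST[, cols, drop = FALSE], 1,
             function(x) max(x, na.rm = TRUE))
  out <- data.frame(parameter = names(m), max_ST = as.numeric(m))
  out[order(-out$max_ST), , drop = FALSE]
}

#' Model evaluator for Total AP-1 over a parameter matrix
#'
#' Wraps the simulator into the row-wise evaluator consumed by
#' [evaluate_design()]: each row of the parameter matrix is spliced into
#' `base_params`, simulated, and the Total AP-1 series returned. Failed
#' simulations yield NA rows.
#'
#' @param network an `ap1_network`
#' @param base_params full named parameter vector
#' @param inputs kinase profiles
#' @param times reporting grid
#' @param engine simulation engine
#' @return function mapping an m x k matrix to an m x length(times) matrix
#' @export
make_ap1_evaluator <- function(network, base_params, inputs,
                               times = 0:60, engine = "compiled") {
  force(network); force(base_params); force(inputs)
  function(P) {
    out <- matrix(NA_real_, nrow(P), length(times))
    for (r in seq_len(nrow(P))) {
      p <- base_params
      p[colnames(P)] <- P[r, ]
      traj <- tryCatch(simulate_network(network, p, inputs, times = times,
                                        engine = engine),
                       error = function(e) NULL)
      if (!is.null(traj)) out[r, ] <- total_ap1(traj)
    }
    out
  }
}
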