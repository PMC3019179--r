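#' Response templates from the nominal trajectory
#'
#' Builds the three reference profiles used for template matching of
#' perturbed Total AP-1 responses: the nominal heterodimer
#' (ppc-Fos:ppc-Jun) dynamics (`FosJun`), the nominal homodimer
#' (ppc-Jun:ppc-Jun) dynamics (`JunJun`), and the nominal Total AP-1
#' dynamics (`balance`). Templates are normalized; construction asserts
#' that all pairwise Pearson correlations are below the classification
#' threshold, otherwise classification would be ill-posed.
#'
#' @param nominal_traj the nominal `ap1_trajectory`
#' @param r_threshold classification threshold (default 0.95)
#' @return object of class `ap1_templates`: named list of
#'   `normalized_series`
#' @export
make_templates <- function(nominal_traj, r_threshold = 0.95) {
  profs <- list(FosJun = species_series(nominal_traj, "FosJun"),
                JunJun = species_series(nominal_traj, "JunJun"),
                balance = total_ap1(nominal_traj))
  out <- lapply(profs, function(v) {
    ns <- normalize_series(v, nominal_traj$times)
    if (ns$degenerate) stop("degenerate (constant) nominal profile")
    ns
  })
  cmb <- utils::combn(names(out), 2)
  for (j in seq_len(ncol(cmb))) {
    r <- stats::cor(out[[cmb[1, j]]]$values, out[[cmb[2, j]]]$values)
    if (r >= r_threshold)
      stop("templates '", cmb[1, j], "' and '", cmb[2, j],
           "' correlate at r = ", round(r, 3),
           " >= ", r_threshold, "; classification ill-posed")
  }
  structure(out, class = "ap1_templates", r_threshold = r_threshold)
}

#' Classify a response profile by template matching
#'
#' Computes the Pearson correlation of the profile against each template
#' and assigns the label of the best-matching template provided its
#' correlation exceeds the threshold; profiles matching no template are
#' `unclassified` and excluded from downstream analysis. Pearson r is
#' invariant to positive affine transforms, so scaled or shifted copies of
#' a template classify identically.
#'
#' @param profile numeric series on the template time grid
#' @param templates an [make_templates()] object
#' @param r_threshold threshold (default the templates' own)
#' @return list with `label` (factor level among template names +
#'   `unclassified`) and `r` (named correlations)
#' @export
classify_response <- function(profile, templates,
                              r_threshold = attr(templates, "r_threshold")) {
  lv <- c(names(templates), "unclassified")
  if (stats::sd(profile) == 0)
    return(list(label = factor("unclassified", levels = lv),
                r = stats::setNames(rep(NA_real_, length(templates)),
                                    names(templates)),
                flag = "zero-variance profile"))
  r <- vapply(templates, function(tp) stats::cor(profile, tp$values),
              numeric(1))
  lab <- if (max(r) > r_threshold) names(templates)[which.max(r)]
         else "unclassified"
  list(label = factor(lab, levels = lv), r = r)
}

#' Perturb key parameters and label the AP-1 responses
#'
#' Samples `n` parameter sets with the named key parameters perturbed
#' independently within their two-fold boxes (all other parameters at
#' nominal), simulates each, and classifies the Total AP-1 profile against
#' the nominal templates.
#'
#' @param base full nominal parameter vector
#' @param key_params names of the perturbed parameters (the seven most
#'   sensitive, from [rank_parameters()])
#' @param n number of perturbations
#' @param seed RNG seed
#' @param network an `ap1_network`
#' @param inputs kinase profiles
#' @param templates templates from [make_templates()]; built from the
#'   nominal simulation when NULL
#' @param fold perturbation fold-range (default 2)
#' @param engine simulation engine
#' @return list with `params` (n x length(key_params) data.frame),
#'   `labels` (factor), `r` (n x 3 matrix), `n_failed`
#' @export
perturb_and_label <- function(base, key_params, n, seed, network, inputs,
                              templates = NULL, fold = 2,
                              engine = "compiled") {
  stopifnot(all(key_params %in% names(base)))
  if (is.null(templates)) {
    nominal <- simulate_network(network, base, inputs, engine = engine)
    templates <- make_templates(nominal)
  }
  P <- sample_parameter_sets(base[key_params], n, fold = fold, seed = seed)
  lv <- c(names(templates), "unclassified")
  labels <- factor(rep("unclassified", n), levels = lv)
  rmat <- matrix(NA_real_, n, length(templates),
                 dimnames = list(NULL, names(templates)))
  n_failed <- 0L
  for (i in seq_len(n)) {
    p <- base
    p[key_params] <- P[i, ]
    traj <- tryCatch(simulate_network(network, p, inputs, engine = engine),
                     error = function(e) NULL)
    if (is.null(traj)) { n_failed <- n_failed + 1L; next }
    cl <- classify_response(total_ap1(traj), templates)
    labels[i] <- cl$label
    rmat[i, ] <- cl$r
  }
  list(params = as.data.frame(P), labels = labels, r = rmat,
       n_failed = n_failed)
}

#' Build the constrained decision tree over perturbed parameters
#'
#' Recursive binary partitioning (Gini impurity, via rpart) of the
#' perturbed-parameter space into AP-1 response classes, under the
#' eligibility constraint that a node may only be split if it holds at
#' least `min_fraction` of the size of the smallest response class.
#' Unclassified responses are dropped before training.
#'
#' Two readings of the constraint are supported: `"node_size"` (default)
#' requires the node's total count to reach `min_fraction` times the global
#' count of the rarest class (mapped to rpart's `minsplit`);
#' `"class_share"` requires the node to contain at least that share of the
#' rarest class's own members (enforced by post-hoc snipping).
#'
#' @param param_table data.frame of perturbed parameter values
#' @param labels factor of response labels (may include `unclassified`)
#' @param min_fraction the 15 percent rule (default 0.15)
#' @param rule constraint reading, `"node_size"` or `"class_share"`
#' @param cp rpart complexity parameter (no additional pruning by default)
#' @return object of class `ap1_tree` wrapping the rpart fit
#' @export
build_tree <- function(param_table, labels, min_fraction = 0.15,
                       rule = c("node_size", "class_share"), cp = 0.01) {
  rule <- match.arg(rule)
  keep <- labels != "unclassified"
  dat <- param_table[keep, , drop = FALSE]
  y <- droplevels(labels[keep])
  if (!nrow(dat)) stop("no classified responses to train on")
  if (nlevels(y) < 2) {
    # single-class input: depth-0 tree
    fit <- NULL
    return(structure(list(rpart = NULL, single_class = levels(y),
                          classes = levels(y), n = nrow(dat)),
                     class = "ap1_tree"))
  }
  min_class <- min(table(y))
  minsplit <- max(2L, ceiling(min_fraction * min_class))
  fit <- rpart::rpart(y ~ ., data = cbind(dat, y = y), method = "class",
                      parms = list(split = "gini"),
                      control = rpart::rpart.control(
                        minsplit = if (rule == "node_size") minsplit else 2L,
                        minbucket = 1L, cp = cp, xval = 0))
  if (rule == "class_share" && nrow(fit$frame) > 1) {
    rare <- names(which.min(table(y)))
    counts <- fit$frame$yval2[, 1 + match(rare, levels(y)), drop = TRUE]
    need <- min_fraction * min_class
    bad <- as.numeric(rownames(fit$frame))[
      fit$frame$var != "<leaf>" & counts < need]
    if (length(bad)) fit <- rpart::snip.rpart(fit, toss = bad)
  }
  structure(list(rpart = fit, single_class = NULL, classes = levels(y),
                 n = nrow(dat), minsplit = minsplit, rule = rule),
            class = "ap1_tree")
}

#' Predict response classes from a fitted tree
#'
#' Deterministic root-to-leaf descent for new parameter values.
#'
#' @param object an `ap1_tree`
#' @param newdata data.frame containing every split variable
#' @param ... unused
#' @return factor of predicted labels
#' @export
predict.ap1_tree <- function(object, newdata, ...) {
  if (!is.null(object$single_class))
    return(factor(rep(object$single_class, nrow(newdata)),
                  levels = object$classes))
  vars <- setdiff(unique(as.character(object$rpart$frame$var)), "<leaf>")
  missing <- setdiff(vars, names(newdata))
  if (length(missing))
    stop("missing split variable(s): ", paste(missing, collapse = ", "))
  predict(object$rpart, newdata = newdata, type = "class")
}

#' Root split variable of a tree
#'
#' @param tree an `ap1_tree`
#' @return character split-variable name, or NA for a depth-0 tree
#' @export
root_variable <- function(tree) {
  if (is.null(tree$rpart) || nrow(tree$rpart$frame) == 1) return(NA_character_)
  as.character(tree$rpart$frame$var[1])
}

#' Serialize a tree to a node list
#'
#' @param tree an `ap1_tree`
#' @return data.frame with node id, split variable, threshold, class and
#'   class counts, suitable for JSON export
#' @export
tree_nodes <- function(tree) {
  if (is.null(tree$rpart))
    return(data.frame(node = 1L, var = "<leaf>", n = tree$n,
                      class = tree$single_class))
  fr <- tree$rpart$frame
  sp <- tree$rpart$splits
  idx <- as.integer(rownames(fr))
  thr <- rep(NA_real_, nrow(fr))
  j <- 1L
  for (i in seq_len(nrow(fr))) {
    if (fr$var[i] != "<leaf>") {
      thr[i] <- sp[j, "index"]
      j <- j + fr$ncompete[i] + fr$nsurrogate[i] + 1L
    }
  }
  data.frame(node = idx, var = as.character(fr$var), n = fr$n,
             threshold = thr,
             class = tree$classes[fr$yval])
}

#' Graphviz DOT rendering of a tree
#'
#' @param tree an `ap1_tree`
#' @return character scalar with DOT source
#' @export
tree_to_dot <- function(tree) {
  nd <- tree_nodes(tree)
  lines <- c("digraph ap1_tree {", "  node [shape=box];")
  for (i in seq_len(nrow(nd))) {
    lab <- if (nd$var[i] == "<leaf>") {
      sprintf("%s\\n(n=%d)", nd$class[i], nd$n[i])
    } else sprintf("%s < %.3g", nd$var[i], nd$threshold[i])
    lines <- c(lines, sprintf("  n%d [label=\"%s\"];", nd$node[i], lab))
  }
  for (i in nd$node) {
    for (child in c(2L * i, 2L * i + 1L)) {
      if (child %in% nd$node)
        lines <- c(lines, sprintf("  n%d -> n%d;", i, child))
    }
  }
  paste(c(lines, "}"), collapse = "\n")
}
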