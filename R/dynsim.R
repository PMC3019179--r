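#' DyNSIM snapshot: network state joined with reaction sensitivities
#'
#' Builds a Dynamic Network Sensitivity and Interaction Map record for one
#' reporting time: per-species concentrations and normalized levels, and
#' per-reaction total-effect sensitivity of Total AP-1 (the maximum ST over
#' the reaction's rate parameters at that time). At times masked by the
#' low-variance rule the snapshot is flagged and sensitivities are NA.
#'
#' @param traj an `ap1_trajectory`
#' @param sensitivity a `sensitivity_result` over the same time grid
#' @param t requested time (min), must be on the reporting grid
#' @param network the `ap1_network`
#' @return object of class `dynsim_snapshot`: list with `time`, `masked`,
#'   `nodes` (data.frame) and `edges` (data.frame)
#' @export
dynsim_export <- function(traj, sensitivity, t, network) {
  ti <- match(t, traj$times)
  if (is.na(ti)) stop("t = ", t, " not on the reporting grid")
  masked <- !isTRUE(sensitivity$valid[ti])
  states <- network$states
  conc <- traj$conc[ti, states]
  norm_level <- vapply(states, function(s) {
    ns <- normalize_series(species_series(traj, s))
    ns$values[ti]
  }, numeric(1))
  nodes <- data.frame(
    species = states,
    compartment = network$species$compartment[
      match(states, network$species$name)],
    concentration = as.numeric(conc),
    normalized = as.numeric(norm_level))
  rx_id <- vapply(network$reactions, `[[`, 0L, "id")
  st_of <- function(pnames) {
    present <- intersect(pnames, rownames(sensitivity$ST))
    if (!length(present) || masked) return(NA_real_)
    max(sensitivity$ST[present, ti], na.rm = TRUE)
  }
  edges <- data.frame(
    reaction = rx_id,
    kind = vapply(network$reactions, `[[`, "", "kind"),
    ST = vapply(network$reactions, function(r) st_of(r$params), numeric(1)),
    masked = masked)
  structure(list(time = t, masked = masked, nodes = nodes, edges = edges),
            class = "dynsim_snapshot")
}

#' Write a DyNSIM snapshot as TSV tables
#'
#' @param snapshot a [dynsim_export()] result
#' @param dir output directory
#' @return invisibly, the written file paths
#' @export
write_dynsim <- function(snapshot, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fn <- file.path(dir, sprintf("dynsim_t%02d_%s.tsv", snapshot$time,
                               c("nodes", "edges")))
  utils::write.table(snapshot$nodes, fn[1], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(snapshot$edges, fn[2], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(fn)
}
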