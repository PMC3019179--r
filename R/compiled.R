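# Encoding of a network + parameter vector into the flat double vector read
# by the compiled right-hand side (src/ap1grn_rhs.c). The layout is
# documented at the top of that file. The encoding is cached per network in
# the object's environment-free list form, so per-simulation work is only
# the parameter-value splice.

.MAXPAR <- 4096L

.encode_plan <- function(network) {
  states <- network$states
  inputs <- network$inputs
  plan <- .flux_plan(network)
  if (length(plan) > 256)
    stop("compiled engine supports at most 256 fluxes")
  recs <- matrix(0, nrow = length(plan), ncol = 6)
  trips <- list()
  pnames <- NULL  # resolved later against the full parameter vector
  getrec <- function(fl) {
    s <- names(fl$substrates)
    i1 <- match(s[1], states) - 1L
    kind <- i2 <- ifor <- ip2 <- -1L
    if (fl$kind == "michaelis_menten") {
      if (!is.null(fl$modifier)) {
        if (!fl$modifier %in% inputs)
          stop("compiled engine: MM modifier must be an input kinase")
        kind <- 1L
        ifor <- match(fl$modifier, inputs) - 1L
        i2 <- NA  # parameter index of the kinase scale, resolved below
      } else kind <- 2L
    } else if (fl$kind == "first_order") {
      kind <- 3L
    } else if (fl$kind == "mass_action") {
      if (length(fl$substrates) == 2) {
        kind <- 4L
        i2 <- match(s[2], states) - 1L
      } else if (fl$substrates[[1]] == 2) {
        kind <- 5L
      } else kind <- 3L
    }
    list(kind = kind, i1 = i1, i2 = i2, ifor = ifor,
         p1 = fl$params[1], p2 = if (length(fl$params) > 1) fl$params[2]
         else NA_character_,
         scale = if (kind == 1L) paste0(fl$modifier, "_max")
         else NA_character_)
  }
  flux_meta <- lapply(plan, getrec)
  for (f in seq_along(plan)) {
    coef <- plan[[f]]$coef
    nz <- which(coef != 0)
    for (j in nz)
      trips[[length(trips) + 1]] <- c(f - 1L, j - 1L, coef[[j]])
  }
  list(flux_meta = flux_meta, trips = do.call(rbind, trips),
       n_state = length(states))
}

.plan_cache <- new.env(parent = emptyenv())

.network_plan <- function(network) {
  key <- paste0("p", length(network$reactions), "_",
                paste(network$states, collapse = ""))
  key <- sprintf("k%08x",
                 as.integer(sum(utf8ToInt(key) * seq_len(nchar(key))) %% 2^31))
  if (!is.null(.plan_cache[[key]])) return(.plan_cache[[key]])
  pl <- .encode_plan(network)
  .plan_cache[[key]] <- pl
  pl
}

.encode_network <- function(network, params) {
  pl <- .network_plan(network)
  pn <- names(params)
  n_flux <- length(pl$flux_meta)
  recs <- matrix(-1, nrow = n_flux, ncol = 6)
  for (f in seq_len(n_flux)) {
    m <- pl$flux_meta[[f]]
    ip1 <- match(m$p1, pn) - 1L
    if (is.na(ip1)) stop("missing parameter '", m$p1, "'")
    ip2 <- if (!is.na(m$p2)) {
      v <- match(m$p2, pn) - 1L
      if (is.na(v)) stop("missing parameter '", m$p2, "'")
      v
    } else -1L
    i2 <- if (m$kind == 1L) {
      v <- match(m$scale, pn) - 1L
      if (is.na(v)) stop("missing kinase scale parameter '", m$scale, "'")
      v
    } else m$i2
    recs[f, ] <- c(m$kind, m$i1, i2, m$ifor, ip1, ip2)
  }
  trips <- pl$trips
  header <- numeric(8)
  off_flux <- 8
  off_sto <- off_flux + 6 * n_flux
  off_par <- off_sto + 3 * nrow(trips)
  header[1] <- length(params)
  header[2] <- pl$n_state
  header[3] <- n_flux
  header[4] <- nrow(trips)
  header[5] <- off_flux
  header[6] <- off_sto
  header[7] <- off_par
  enc <- c(header, as.numeric(t(recs)), as.numeric(t(trips)),
           as.numeric(params))
  if (length(enc) > .MAXPAR)
    stop("encoded network exceeds compiled buffer")
  c(enc, numeric(.MAXPAR - length(enc)))
}
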