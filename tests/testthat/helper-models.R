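# Shared fixtures: memoised model runs (the deterministic mid-NC14 solves are
# reused across files) and a minimal network constructor for engine-level
# tests on analytically tractable systems.

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache))
    assign(key, force(expr), envir = .run_cache)
  get(key, envir = .run_cache)
}

det_run <- function(variant, rates = rate_table(),
                    record = c(0, 1200, 1800, 2400), key = variant) {
  cached(paste0("det_", key), {
    run_deterministic(hb_kr_model(variant, rates = rates), record = record)
  })
}

# hand-built network over arbitrary species/reactions, on the package lattice
# (reactions: list of list(re1 =, re2 =, stoich = c(name = delta), rate =
# scalar or per-subvolume vector))
toy_network <- function(species, reactions, n_ap = 2,
                        dif_species = character(0), dif_rate = numeric(0)) {
  lat <- lattice_config(n_ap = n_ap)
  R <- length(reactions)
  idx <- function(nm) if (is.na(nm)) -1L else match(nm, species) - 1L
  re1 <- vapply(reactions, function(r) idx(r$re1), integer(1))
  re2 <- vapply(reactions, function(r) idx(r$re2), integer(1))
  st <- lapply(reactions, function(r) r$stoich)
  st_ptr <- c(0L, cumsum(vapply(st, length, integer(1))))
  st_sp <- unlist(lapply(st, function(s) match(names(s), species) - 1L),
                  use.names = FALSE)
  st_delta <- as.integer(unlist(st, use.names = FALSE))
  rate_mat <- matrix(0, nrow = R, ncol = lat$n)
  for (r in seq_len(R)) {
    v <- reactions[[r]]$rate
    rate_mat[r, ] <- if (length(v) == 1L) rep(v, lat$n) else v
  }
  rx_df <- if (R == 0L) {
    data.frame(name = character(0), rate_name = character(0),
               rate = numeric(0), stringsAsFactors = FALSE)
  } else {
    data.frame(name = paste0("rx", seq_len(R)),
               rate_name = paste0("rx", seq_len(R)),
               rate = vapply(reactions, function(r) r$rate[1], numeric(1)),
               stringsAsFactors = FALSE)
  }
  structure(list(
    variant = "toy", loci = 1L, species = species,
    reactions = rx_df,
    stoich = st, re1 = re1, re2 = re2,
    st_ptr = as.integer(st_ptr), st_sp = as.integer(st_sp),
    st_delta = st_delta, rate_matrix = rate_mat,
    dif_sp = as.integer(match(dif_species, species) - 1L),
    dif_rate = dif_rate, lattice = lat,
    rates = NULL, bcd = NULL, bcd_field = NULL, basal_field = NULL
  ), class = "hbkr_network")
}

# birth-death toy: 0 -> X at rate a (per subvolume), X -> 0 at rate g
birth_death_net <- function(a = 5, g = 0.1, n_ap = 2) {
  toy_network(
    species = "X",
    reactions = list(list(re1 = NA, re2 = NA, stoich = c(X = 1L), rate = a),
                     list(re1 = "X", re2 = NA, stoich = c(X = -1L), rate = g)),
    n_ap = n_ap)
}

empty_state <- function(net, fill = list()) {
  st <- matrix(0L, nrow = length(net$species), ncol = net$lattice$n,
               dimnames = list(net$species, NULL))
  for (nm in names(fill)) st[nm, ] <- fill[[nm]]
  st
}
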