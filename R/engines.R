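new_trajectory <- function(times, states, network, engine, seed = NULL,
                           n_events = NA_real_, dt = NA_real_) {
  states <- lapply(states, function(s) {
    rownames(s) <- network$species
    s
  })
  structure(list(times = times, states = states, species = network$species,
                 lattice = network$lattice, variant = network$variant,
                 loci = network$loci, engine = engine, seed = seed,
                 n_events = n_events, dt = dt),
            class = "hbkr_trajectory")
}

#' @export
print.hbkr_trajectory <- function(x, ...) {
  cat(sprintf("hbkr %s trajectory: variant '%s', %d loci, %d snapshots (t = %g..%g s)\n",
              x$engine, x$variant, x$loci, length(x$times),
              min(x$times), max(x$times)))
  if (!is.null(x$seed)) cat(sprintf("  seed %s, %.3g events\n", format(x$seed), x$n_events))
  invisible(x)
}

#' Mean-field mass-action derivative of a lattice state
#'
#' Reference (pure R) evaluation of the deterministic right-hand side:
#' stoichiometry times mass-action propensities with continuous counts, plus
#' the discrete protein-diffusion Laplacian with zero-flux ends. The RK4
#' integrator uses a compiled evaluation of the same expression.
#'
#' @param state species-by-subvolume matrix (continuous counts).
#' @param network an `hbkr_network`.
#' @return derivative matrix, same shape as `state`.
#' @export
mass_action_rhs <- function(state, network) {
  stopifnot(inherits(network, "hbkr_network"))
  S <- length(network$species); N <- network$lattice$n
  if (nrow(state) != S || ncol(state) != N)
    stop("state dimensions do not match network")
  R <- nrow(network$reactions)
  f1 <- ifelse(network$re1 >= 0, network$re1 + 1L, NA)
  f2 <- ifelse(network$re2 >= 0, network$re2 + 1L, NA)
  P <- network$rate_matrix
  if (any(!is.na(f1))) {
    m1 <- matrix(1, R, N); m1[!is.na(f1), ] <- state[f1[!is.na(f1)], , drop = FALSE]
    P <- P * m1
  }
  if (any(!is.na(f2))) {
    m2 <- matrix(1, R, N); m2[!is.na(f2), ] <- state[f2[!is.na(f2)], , drop = FALSE]
    P <- P * m2
  }
  if (any(!is.finite(P))) {
    bad <- which(rowSums(!is.finite(P)) > 0)[1]
    stop("non-finite propensity in reaction '", network$reactions$name[bad], "'")
  }
  Smat <- matrix(0, S, R)
  for (r in seq_len(R)) {
    idx <- network$st_sp[(network$st_ptr[r] + 1L):network$st_ptr[r + 1L]] + 1L
    del <- network$st_delta[(network$st_ptr[r] + 1L):network$st_ptr[r + 1L]]
    Smat[idx, r] <- Smat[idx, r] + del
  }
  d <- Smat %*% P
  # protein diffusion: reflecting graph Laplacian
  lat <- network$lattice
  for (k in seq_along(network$dif_sp)) {
    s <- network$dif_sp[k] + 1L
    rate <- network$dif_rate[k]
    lap <- numeric(N)
    for (i in seq_len(N)) {
      nb <- lat$nb_idx[(lat$nb_ptr[i] + 1L):lat$nb_ptr[i + 1L]] + 1L
      lap[i] <- sum(state[s, nb] - state[s, i])
    }
    d[s, ] <- d[s, ] + rate * lap
  }
  dimnames(d) <- dimnames(state)
  d
}

#' Deterministic integration (fixed-step RK4)
#'
#' Integrates the mean-field equations with the classical fourth-order
#' Runge-Kutta scheme at fixed step `dt`. Gene-state variables are treated as
#' continuous occupancy fractions. Small negative excursions (below
#' `neg_tol` copies) are clipped to zero; larger ones indicate the step is
#' too long for the fastest binding channels, and the integrator halves `dt`
#' and restarts (up to `max_halvings` times) before giving up.
#'
#' @param network an `hbkr_network` (or an `hbkr_model`).
#' @param state0 initial state; defaults to [initial_state()] of the model.
#' @param t_end end time, s (mid-NC14 is 2400 s).
#' @param dt time step, s. The default sits below the stability limit of the
#'   stiffest channel (second Hb binding on the *Kr* gene at anterior Hb
#'   levels, ~750 1/s).
#' @param record snapshot times, s (subset of `[0, t_end]`).
#' @param neg_tol clipping tolerance, copies.
#' @param max_halvings retries with halved `dt` on instability.
#' @return an `hbkr_trajectory`.
#' @export
run_deterministic <- function(network, state0 = NULL, t_end = 2400,
                              dt = 0.003, record = seq(0, 2400, by = 600),
                              neg_tol = 1e-4, max_halvings = 8L,
                              init = initial_profile_params()) {
  if (inherits(network, "hbkr_model")) {
    if (is.null(state0)) state0 <- initial_state(network$network, network$init)
    network <- network$network
  }
  stopifnot(inherits(network, "hbkr_network"), dt > 0, t_end > 0)
  record <- sort(unique(record))
  if (any(record < 0 | record > t_end + 1e-9))
    stop("record times must lie in [0, t_end]")
  if (is.null(state0)) state0 <- initial_state(network, init)
  storage.mode(state0) <- "double"

  S <- length(network$species); N <- network$lattice$n
  for (h in 0:max_halvings) {
    res <- .rk4_cpp(state0, network$rate_matrix, network$re1, network$re2,
                    network$st_ptr, network$st_sp, network$st_delta,
                    network$dif_sp, network$dif_rate,
                    network$lattice$nb_ptr, network$lattice$nb_idx,
                    t_end, dt, record, neg_tol)
    if (res$status == 0L && res$recorded == length(record)) {
      arr <- array(res$snapshots, dim = c(S, N, length(record)))
      states <- lapply(seq_along(record), function(ti) arr[, , ti, drop = TRUE])
      states <- lapply(states, function(s) matrix(s, nrow = S, ncol = N))
      return(new_trajectory(record, states, network, "deterministic", dt = dt))
    }
    dt <- dt / 2
  }
  stop("RK4 integration unstable; smaller dt than ", dt, " required")
}

#' Exact stochastic simulation (next-subvolume method)
#'
#' Samples the reaction-diffusion master equation exactly: every reaction and
#' diffusion event is drawn from its propensity, with each subvolume holding
#' its next-event time in an indexed priority queue. Snapshots are the state
#' at the last event at or before each record time. Identical inputs and
#' seed give identical trajectories.
#'
#' @param network an `hbkr_network` (or an `hbkr_model`).
#' @param state0 integer initial state; defaults to the rounded
#'   [initial_state()].
#' @param t_end end time, s.
#' @param seed integer seed for the replicate's own RNG stream.
#' @param record snapshot times, s.
#' @param log_events if positive, also return up to this many event times
#'   (used for event-statistics checks).
#' @return an `hbkr_trajectory` with `n_events` and, if requested, an
#'   `event_times` attribute.
#' @export
nsm_run <- function(network, state0 = NULL, t_end = 2400, seed = 1,
                    record = seq(0, 2400, by = 600), log_events = 0L,
                    init = initial_profile_params()) {
  if (inherits(network, "hbkr_model")) {
    if (is.null(state0))
      state0 <- initial_state(network$network, network$init, integer = TRUE)
    network <- network$network
  }
  stopifnot(inherits(network, "hbkr_network"))
  record <- sort(unique(record))
  if (any(record < 0 | record > t_end + 1e-9))
    stop("record times must lie in [0, t_end]")
  if (is.null(state0)) state0 <- initial_state(network, init, integer = TRUE)
  if (!is.integer(state0)) {
    if (max(abs(state0 - round(state0))) > 1e-9)
      stop("stochastic engine requires an integer initial state")
    storage.mode(state0) <- "integer"
  }
  # snapshot convention: state at last event <= record time; pass record
  # times nudged so an event exactly at a record time is included
  res <- .nsm_cpp(state0, network$rate_matrix, network$re1, network$re2,
                  network$st_ptr, network$st_sp, network$st_delta,
                  network$dif_sp, network$dif_rate,
                  network$lattice$nb_ptr, network$lattice$nb_idx,
                  record + 1e-9, as.double(seed), as.integer(log_events))
  S <- length(network$species); N <- network$lattice$n
  arr <- array(res$snapshots, dim = c(S, N, length(record)))
  states <- lapply(seq_along(record), function(ti)
    matrix(arr[, , ti, drop = TRUE], nrow = S, ncol = N))
  tr <- new_trajectory(record, states, network, "stochastic", seed = seed,
                       n_events = res$n_events)
  if (log_events > 0)
    attr(tr, "event_times") <- res$event_times[seq_len(res$n_logged)]
  tr
}

#' Seeded stochastic ensembles
#'
#' Runs `n` independent replicates; replicate `i` uses seed
#' `base_seed + i`, so each trajectory is fully determined by the base seed
#' and its index, and the ensemble is order-independent. Per-replicate
#' failures are collected, not fatal.
#'
#' @param network an `hbkr_network` or `hbkr_model`.
#' @param n number of replicates.
#' @param base_seed integer base seed.
#' @inheritParams nsm_run
#' @return list of class `hbkr_ensemble` (trajectories; failed replicates
#'   carry the error condition).
#' @export
run_ensemble <- function(network, n = 25, base_seed = 1, state0 = NULL,
                         t_end = 2400, record = seq(0, 2400, by = 600),
                         init = initial_profile_params()) {
  stopifnot(n >= 1)
  if (inherits(network, "hbkr_model")) {
    if (is.null(state0))
      state0 <- initial_state(network$network, network$init, integer = TRUE)
    network <- network$network
  }
  if (is.null(state0)) state0 <- initial_state(network, init, integer = TRUE)
  out <- lapply(seq_len(n), function(i) {
    tryCatch(nsm_run(network, state0, t_end = t_end, seed = base_seed + i,
                     record = record),
             error = function(e) e)
  })
  failed <- vapply(out, inherits, logical(1), "error")
  if (any(failed))
    warning(sum(failed), " replicate(s) failed; first error: ",
            conditionMessage(out[[which(failed)[1]]]))
  structure(out, class = "hbkr_ensemble", base_seed = base_seed)
}

#' Extract one species' AP profile from a trajectory
#'
#' For 2D lattices the DV direction is averaged (`dv = "mean"`), summed, or
#' a single row selected by index. In two-locus networks the pooled names
#' `"MH"` and `"MKr"` resolve to the sum of the per-locus pools.
#'
#' @param traj an `hbkr_trajectory`.
#' @param species species name (or pooled name in two-locus mode).
#' @param time snapshot time, s (must be one of `traj$times`).
#' @param dv `"mean"`, `"sum"`, or a 1-based DV row index.
#' @return data.frame with `ap` (%EL) and `count`.
#' @export
species_profile <- function(traj, species, time, dv = "mean") {
  stopifnot(inherits(traj, "hbkr_trajectory"))
  ti <- match(TRUE, abs(traj$times - time) < 1e-6)
  if (is.na(ti)) stop("time ", time, " not among recorded snapshots")
  st <- traj$states[[ti]]
  if (!species %in% rownames(st) && species %in% c("MH", "MKr") && traj$loci == 2L) {
    v <- st[paste0(species, "_A"), ] + st[paste0(species, "_B"), ]
  } else {
    if (!species %in% rownames(st)) stop("unknown species '", species, "'")
    v <- st[species, ]
  }
  lat <- traj$lattice
  m <- matrix(v, nrow = lat$n_ap, ncol = lat$n_dv)
  count <- if (identical(dv, "mean")) rowMeans(m)
           else if (identical(dv, "sum")) rowSums(m)
           else m[, as.integer(dv)]
  data.frame(ap = lat$ap_pos[seq_len(lat$n_ap)], count = count)
}

#' @export
plot.hbkr_trajectory <- function(x, species = c("H", "Kr"), ...) {
  cols <- c(H = "red3", Kr = "green4", MH = "salmon", MKr = "palegreen3")
  prof <- lapply(species, function(s)
    vapply(x$times, function(tt) species_profile(x, s, tt)$count,
           numeric(x$lattice$n_ap)))
  ymax <- max(unlist(prof))
  ap <- x$lattice$ap_pos[seq_len(x$lattice$n_ap)]
  graphics::plot(NA, xlim = range(ap), ylim = c(0, ymax * 1.05),
                 xlab = "AP position (%EL)", ylab = "copies per nucleus",
                 main = sprintf("%s (%s)", x$variant, x$engine), ...)
  for (si in seq_along(species)) {
    col <- if (species[si] %in% names(cols)) cols[[species[si]]] else si
    for (ti in seq_along(x$times))
      graphics::lines(ap, prof[[si]][, ti], col = col,
                      lwd = 1 + 1.5 * (ti == length(x$times)))
  }
  graphics::legend("topright", legend = species, lwd = 2, bty = "n",
                   col = vapply(species, function(s)
                     if (s %in% names(cols)) cols[[s]] else "black",
                     character(1)))
  invisible(x)
}
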