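#' Deterministic WT and Kr-null pattern comparison
#'
#' Runs the `kr_dual` (wild type) and `kr_null` (*Kr-*) models
#' deterministically to mid-NC14 with snapshots at 10-minute intervals, and
#' extracts boundary, PS4-peak, Kr-peak and trough metrics at each snapshot.
#'
#' @param t_end end time, s.
#' @param record snapshot times, s.
#' @param ... passed to [hb_kr_model()] (e.g. custom `rates`).
#' @return list with both trajectories and a data.frame of metrics per
#'   variant and time.
#' @export
experiment_patterns <- function(t_end = 2400, record = seq(0, 2400, by = 600),
                                ...) {
  out <- list()
  mets <- list()
  for (v in c("kr_dual", "kr_null")) {
    m <- hb_kr_model(v, ...)
    tr <- run_deterministic(m, t_end = t_end, record = record)
    out[[v]] <- tr
    for (tt in record[record > 0]) {
      s <- summary(tr, time = tt)
      mets[[length(mets) + 1L]] <- data.frame(
        variant = v, time_s = tt, boundary = s$boundary,
        ps4_peak = s$ps4_peak, kr_peak = s$kr_peak,
        trough_ratio = s$trough_ratio, anterior_H = s$anterior_H,
        anterior_MH = s$anterior_MH)
    }
  }
  out$metrics <- do.call(rbind, mets)
  out
}

#' Between-replicate boundary variability, WT vs Kr-null
#'
#' Runs seeded 1D stochastic ensembles of the wild-type (`kr_dual`) and
#' *Kr-* (`kr_null`) models, extracts the half-height Hb boundary position
#' of every replicate at each requested time, and summarises positional SDs,
#' Kr-null/WT SD ratios, F-tests and jaggedness.
#'
#' @param n replicates per condition.
#' @param base_seed integer; WT replicates use `base_seed + 1..n`, Kr-null
#'   `base_seed + 1000 + 1..n` (unpaired streams).
#' @param times analysis times, s (7, 20, 40 min).
#' @param ... passed to [hb_kr_model()].
#' @return list with per-time summary data.frame, per-replicate boundary
#'   positions, jaggedness counts, and the two ensembles.
#' @export
experiment_boundary_sd <- function(n = 25, base_seed = 1,
                                   times = c(420, 1200, 2400), ...) {
  record <- sort(unique(c(0, times)))
  wt_model <- hb_kr_model("kr_dual", ...)
  mu_model <- hb_kr_model("kr_null", ...)
  wt <- run_ensemble(wt_model, n = n, base_seed = base_seed,
                     t_end = max(times), record = record)
  mu <- run_ensemble(mu_model, n = n, base_seed = base_seed + 1000,
                     t_end = max(times), record = record)
  prof <- function(ens, tt)
    do.call(rbind, lapply(ens, function(tr) species_profile(tr, "H", tt)$count))
  ap <- wt_model$network$lattice$ap_pos
  rows <- list(); positions <- list()
  for (tt in times) {
    pw <- positional_sd(prof(wt, tt), ap)
    pm <- positional_sd(prof(mu, tt), ap)
    ft <- variance_f_test(pm$sd, length(pm$positions), pw$sd, length(pw$positions))
    rows[[length(rows) + 1L]] <- data.frame(
      time_s = tt, sd_wt = pw$sd, sd_krnull = pm$sd,
      ratio = pm$sd / pw$sd, F = ft$F, p = ft$p)
    positions[[paste0("wt_", tt)]] <- pw$positions
    positions[[paste0("krnull_", tt)]] <- pm$positions
  }
  tmax <- max(times)
  jag <- function(ens) vapply(ens, function(tr) {
    p <- species_profile(tr, "H", tmax)
    b <- tryCatch(boundary_position(p$ap, p$count), error = function(e) NA_real_)
    if (is.na(b)) return(NA_integer_)
    jaggedness(p$ap, p$count, window = c(b - 5, b + 5))
  }, integer(1))
  list(summary = do.call(rbind, rows), positions = positions,
       jaggedness = list(wt = jag(wt), krnull = jag(mu)),
       ensembles = list(wt = wt, krnull = mu))
}

#' Within-nucleus two-locus transcript noise, WT vs Kr-null
#'
#' Runs 2D two-locus stochastic simulations of the wild-type and Kr-null
#' models, computes the within-nucleus noise (see [noise_in_nuc()]) of *hb*
#' transcripts per replicate over nuclei within 5 %EL of the Hb boundary,
#' and compares the conditions with a pooled t-test.
#'
#' @param n replicates per condition.
#' @param base_seed integer base seed (unpaired streams per condition).
#' @param n_dv DV extent of the lattice (10 subvolumes = 10% DV strip).
#' @param t_end analysis time, s.
#' @param ... passed to [hb_kr_model()].
#' @return list with per-replicate noise values, group means, the t-test,
#'   and per-nucleus A/B counts of the final replicates.
#' @export
experiment_locus_noise <- function(n = 12, base_seed = 1, n_dv = 10,
                                   t_end = 2400, ...) {
  lat <- lattice_config(n_dv = n_dv)
  res <- list()
  for (v in c("kr_dual", "kr_null")) {
    model <- hb_kr_model(v, lattice = lat, loci = 2, ...)
    offs <- if (v == "kr_dual") 0 else 1000
    ens <- run_ensemble(model, n = n, base_seed = base_seed + offs,
                        t_end = t_end, record = c(0, t_end))
    vals <- numeric(0); ms <- integer(0); ab <- NULL
    for (tr in ens) {
      if (inherits(tr, "error")) next
      nn <- locus_noise_of(tr, time = t_end)
      vals <- c(vals, nn$value); ms <- c(ms, nn$m)
      ab <- nn$nuclei
    }
    res[[v]] <- list(noise = vals, m = ms, nuclei = ab)
  }
  tt <- two_sample_t(res$kr_dual$noise, res$kr_null$noise)
  list(wt = res$kr_dual, krnull = res$kr_null,
       mean_wt = mean(res$kr_dual$noise), mean_krnull = mean(res$kr_null$noise),
       t_test = tt)
}

#' Within-nucleus noise of one two-locus trajectory
#'
#' Helper extracting per-nucleus `MH_A`/`MH_B` counts at `time`, locating
#' the Hb boundary from the DV-averaged protein profile, and evaluating
#' [noise_in_nuc()].
#'
#' @param tr a two-locus `hbkr_trajectory`.
#' @param time snapshot time, s.
#' @param window half-width around the boundary, %EL.
#' @return list with `value`, `m`, `boundary`, and the per-nucleus data.
#' @export
locus_noise_of <- function(tr, time = max(tr$times), window = 5) {
  stopifnot(inherits(tr, "hbkr_trajectory"))
  if (tr$loci != 2L) stop("trajectory is not from a two-locus network")
  h <- species_profile(tr, "H", time)
  b <- boundary_position(h$ap, h$count)
  ti <- match(TRUE, abs(tr$times - time) < 1e-6)
  st <- tr$states[[ti]]
  A <- st["MH_A", ]; B <- st["MH_B", ]
  ap <- tr$lattice$ap_pos
  nn <- noise_in_nuc(A, B, ap, b, window = window)
  nn$boundary <- b
  nn$nuclei <- data.frame(ap = ap, dv = tr$lattice$dv_index, A = A, B = B)
  nn
}

#' Qualitative survey of the mechanism variants
#'
#' Deterministic runs of the alternative wirings (`mut_inh`, `hb_dual`,
#' `dual_dual`, `static_kr`) reporting PS4 presence and boundary drift, and
#' short stochastic runs comparing boundary-region temporal variability of
#' `kr_dual`, `static_kr`, `mut_inh` against the no-Kr baseline.
#'
#' @param base_seed seed for the stochastic comparisons.
#' @param stochastic also run the interface-variability comparison.
#' @param ... passed to [hb_kr_model()].
#' @return list with `deterministic` (data.frame) and optionally
#'   `interface_sd` (named numeric).
#' @export
experiment_variants <- function(base_seed = 1, stochastic = TRUE, ...) {
  rows <- list()
  for (v in c("kr_dual", "kr_null", "mut_inh", "hb_dual", "dual_dual",
              "static_kr")) {
    m <- hb_kr_model(v, ...)
    tr <- run_deterministic(m, t_end = 2400, record = c(0, 1800, 2400))
    s40 <- summary(tr, time = 2400)
    s30 <- summary(tr, time = 1800)
    rows[[v]] <- data.frame(
      variant = v, ps4 = !is.na(s40$ps4_peak), ps4_pos = s40$ps4_peak,
      boundary_30 = s30$boundary, boundary_40 = s40$boundary,
      drift_30_40 = s40$boundary - s30$boundary)
  }
  out <- list(deterministic = do.call(rbind, rows))
  if (stochastic) {
    out$interface_sd <- vapply(
      c(kr_dual = "kr_dual", mut_inh = "mut_inh", static_kr = "static_kr",
        no_kr = "no_kr"),
      function(v) interface_variability(hb_kr_model(v, ...), seed = base_seed),
      numeric(1))
  }
  out
}

#' Temporal variability of the Hb interface in one stochastic run
#'
#' Follows the overlay protocol: snapshots at 1-minute intervals over
#' 30-40 minutes; the half-height Hb boundary position is extracted from
#' each snapshot (3-point smoothed, as in [positional_sd()]) and its
#' standard deviation across the snapshots is returned. A steady, monotone
#' interface gives a small value; a jagged, wandering one a large value.
#'
#' @param model an `hbkr_model` (1D).
#' @param seed replicate seed.
#' @return temporal SD of the boundary position, %EL.
#' @export
interface_variability <- function(model, seed = 1) {
  record <- c(0, seq(1800, 2400, by = 60))
  tr <- nsm_run(model, t_end = 2400, seed = seed, record = record)
  ap <- tr$lattice$ap_pos[seq_len(tr$lattice$n_ap)]
  prof <- vapply(record[record >= 1800],
                 function(tt) species_profile(tr, "H", tt)$count,
                 numeric(tr$lattice$n_ap))
  positional_sd(t(prof), ap)$sd
}
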