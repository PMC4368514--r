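#' Construct a Hb-Kr patterning model
#'
#' Bundles a mechanism variant, rate table, lattice, Bcd gradient and
#' initial-profile parameters into a single model object; compiles the
#' reaction network on construction. Solve it with [run_deterministic()] for
#' the mean-field pattern, or draw stochastic replicates with
#' [simulate()][simulate.hbkr_model].
#'
#' @param variant one of [mechanism-variants].
#' @param lattice a [lattice_config()].
#' @param rates a [rate_table()].
#' @param init an [initial_profile_params()].
#' @param bcd a [bcd_params()].
#' @param loci 1 or 2 transcription loci per nucleus.
#' @param krh1_scale see [compile_reactions()].
#' @return object of class `hbkr_model` with elements `network` and `init`.
#' @examples
#' m <- hb_kr_model("kr_dual")
#' tr <- run_deterministic(m, t_end = 60, record = c(0, 60))
#' summary(tr)
#' @export
hb_kr_model <- function(variant = "kr_dual", lattice = lattice_config(),
                        rates = rate_table(), init = initial_profile_params(),
                        bcd = bcd_params(), loci = 1, krh1_scale = 25) {
  network <- compile_reactions(variant, rates, lattice, bcd, loci, krh1_scale)
  structure(list(variant = network$variant, loci = network$loci,
                 network = network, init = init),
            class = "hbkr_model")
}

#' @export
print.hbkr_model <- function(x, ...) {
  cat(sprintf("Hb-Kr patterning model: variant '%s', %d loci\n",
              x$variant, x$loci))
  print(x$network$lattice)
  cat(sprintf("  %d reactions; anterior Bcd %g copies, length scale %g %%EL\n",
              nrow(x$network$reactions), x$network$bcd$B0, x$network$bcd$lambda))
  invisible(x)
}

#' @export
summary.hbkr_model <- function(object, ...) {
  cat(sprintf("Variant '%s' (%d loci) on %dx%d lattice\n", object$variant,
              object$loci, object$network$lattice$n_ap,
              object$network$lattice$n_dv))
  print(reaction_list(object$network))
  invisible(object)
}

#' Stochastic replicates of a model
#'
#' Method for [stats::simulate()]: draws `nsim` independent exact-SSA
#' trajectories with seeds `seed + 1 .. seed + nsim`.
#'
#' @param object an `hbkr_model`.
#' @param nsim number of replicates.
#' @param seed integer base seed.
#' @param t_end,record passed to [nsm_run()].
#' @param ... unused.
#' @return an `hbkr_ensemble` (list of trajectories).
#' @export
simulate.hbkr_model <- function(object, nsim = 1, seed = 1, t_end = 2400,
                                record = seq(0, 2400, by = 600), ...) {
  run_ensemble(object, n = nsim, base_seed = seed, t_end = t_end,
               record = record)
}

#' Pattern metrics of a trajectory snapshot
#'
#' Computes the standard positional summary of the final (or requested)
#' snapshot: Hb half-height boundary, PS4 peak position, Kr peak position,
#' and trough/peak ratio.
#'
#' @param object an `hbkr_trajectory`.
#' @param time snapshot time (default: last).
#' @param ... unused.
#' @return list of class `hbkr_pattern_summary`.
#' @export
summary.hbkr_trajectory <- function(object, time = max(object$times), ...) {
  h <- species_profile(object, "H", time)
  out <- list(time = time, variant = object$variant, engine = object$engine)
  out$boundary <- tryCatch(boundary_position(h$ap, h$count),
                           error = function(e) NA_real_)
  out$ps4_peak <- peak_position(h$ap, h$count, window = c(40, 55))
  out$trough_ratio <- trough_ratio(h$ap, h$count)
  out$kr_peak <- if ("Kr" %in% object$species) {
    k <- species_profile(object, "Kr", time)
    if (max(k$count) > 0) peak_position(k$ap, k$count, local = FALSE) else NA_real_
  } else NA_real_
  out$anterior_H <- max(h$count)
  mh <- species_profile(object, "MH", time)
  out$anterior_MH <- max(mh$count)
  structure(out, class = "hbkr_pattern_summary")
}

#' @export
print.hbkr_pattern_summary <- function(x, ...) {
  cat(sprintf("Pattern summary ('%s', %s engine, t = %g s)\n",
              x$variant, x$engine, x$time))
  cat(sprintf("  Hb half-height boundary : %s %%EL\n", format(round(x$boundary, 2))))
  cat(sprintf("  Hb PS4 peak             : %s\n",
              if (is.na(x$ps4_peak)) "absent" else paste(round(x$ps4_peak, 2), "%EL")))
  cat(sprintf("  Kr peak                 : %s\n",
              if (is.na(x$kr_peak)) "absent" else paste(round(x$kr_peak, 2), "%EL")))
  if (!is.na(x$trough_ratio))
    cat(sprintf("  trough / PS4 peak       : %.3f\n", x$trough_ratio))
  cat(sprintf("  anterior Hb protein     : %.0f copies/nucleus\n", x$anterior_H))
  cat(sprintf("  anterior hb mRNA        : %.1f copies/nucleus\n", x$anterior_MH))
  invisible(x)
}
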