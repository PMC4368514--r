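#' @useDynLib hbkr, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats pf pt sd setNames simulate
#' @importFrom utils read.csv write.csv
NULL

.AVOGADRO <- 6.02214076e23

#' Subvolume volume in litres
#'
#' A cubic subvolume of edge `h_um` micrometres represents one nucleus plus
#' its neighbouring cytoplasm. For the default 5 um edge the volume is
#' 125 um^3 = 1.25e-13 L.
#'
#' @param h_um subvolume edge length, micrometres.
#' @return volume in litres.
#' @export
subvolume_volume <- function(h_um = 5) {
  stopifnot(is.numeric(h_um), h_um > 0)
  h_um^3 * 1e-15
}

#' Convert a macroscopic rate constant to a per-event stochastic rate
#'
#' First-order constants (s^-1) are returned unchanged. Second-order
#' constants (M^-1 s^-1) are divided by Avogadro's number times the subvolume
#' volume, so that `propensity = k' * count1 * count2` reproduces the
#' macroscopic mass-action rate at that volume.
#'
#' @param k rate constant, M^-1 s^-1 (order 2) or s^-1 (order 1).
#' @param order reaction order, 1 or 2.
#' @param volume subvolume volume in litres.
#' @param name constant name used in error messages.
#' @return per-event rate in s^-1 (order 2: s^-1 per molecule pair).
#' @examples
#' molar_to_stochastic(6.8e-3, 1, subvolume_volume())   # unchanged
#' molar_to_stochastic(2.2e6, 2, subvolume_volume())    # per-pair rate
#' @export
molar_to_stochastic <- function(k, order, volume, name = deparse(substitute(k))) {
  if (!is.numeric(volume) || length(volume) != 1L || volume <= 0)
    stop("non-positive subvolume volume for constant '", name, "'")
  if (!order %in% c(1L, 2L))
    stop("unknown reaction order ", order, " for constant '", name, "'")
  if (any(k < 0)) stop("negative rate constant '", name, "'")
  if (order == 1L) k else k / (.AVOGADRO * volume)
}

#' Diffusion jump rate on the subvolume lattice
#'
#' Standard RDME discretisation: the per-molecule, per-neighbour jump rate is
#' `D / h^2`.
#'
#' @param D_cm2_s diffusivity in cm^2/s.
#' @param h_um subvolume edge length in micrometres.
#' @return jump rate in s^-1.
#' @examples
#' diffusion_jump_rate(3e-10, 5)  # Hb: 1.2e-3 s^-1
#' @export
diffusion_jump_rate <- function(D_cm2_s, h_um = 5) {
  if (any(D_cm2_s < 0)) stop("negative diffusivity")
  stopifnot(h_um > 0)
  (D_cm2_s * 1e8) / h_um^2     # cm^2/s -> um^2/s, divided by h^2 um^2
}

#' Rate constants of the Hb-Kr regulation model
#'
#' Returns the named rate constants `k1`..`k27` (binding, unbinding,
#' transcription, translation, decay), the protein diffusivities and the
#' subvolume edge, with any value overridable by name. Second-order constants
#' are in M^-1 s^-1 and are converted per subvolume at network compile time;
#' first-order constants are in s^-1. All unbinding constants are unity, so
#' binding constants are relative affinities.
#'
#' @param ... named overrides, e.g. `rate_table(k10 = 0, k12 = 0)`.
#' @return an object of class `hbkr_rates`: a named list of constants plus an
#'   `order` attribute tagging each `k` as first- or second-order.
#' @examples
#' r <- rate_table()
#' r$k16
#' rate_table(k14 = r$k16)  # h1-kr1 state transcribes like h2-kr1
#' @export
rate_table <- function(...) {
  r <- list(
    # hb gene: Hb self-binding and Hb-dependent transcription
    k1 = 2.2e6,  k2 = 1,  k3 = 3.4e8,  k4 = 1,
    k5 = 5e9,    k6 = 4.5e10,
    # hb mRNA decay, translation, Hb protein decay
    k7 = 6.8e-3, k8 = 3.125e-1, k9 = 6e-3,
    # Kr binding on hb and Kr-gated transcription
    k10 = 8e7,  k11 = 1, k12 = 1e7, k13 = 1,
    k14 = 0, k15 = 0, k16 = 1.25e11, k17 = 0,
    # Kr gene: Bcd binding, Hb binding, transcription
    k18 = 1.8e7, k19 = 1, k20 = 5e5, k21 = 1, k22 = 8e9, k23 = 1,
    k24 = 4.5e11,
    # Kr mRNA decay, translation, Kr protein decay
    k25 = 6.8e-3, k26 = 3.57e-1, k27 = 6e-3,
    # transport and geometry
    D_Hb = 3e-10, D_Kr = 3e-9, h_um = 5
  )
  ord <- c(
    k1 = 2, k2 = 1, k3 = 2, k4 = 1, k5 = 2, k6 = 2,
    k7 = 1, k8 = 1, k9 = 1,
    k10 = 2, k11 = 1, k12 = 2, k13 = 1,
    k14 = 2, k15 = 2, k16 = 2, k17 = 2,
    k18 = 2, k19 = 1, k20 = 2, k21 = 1, k22 = 2, k23 = 1,
    k24 = 2, k25 = 1, k26 = 1, k27 = 1
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(r))
    if (length(bad)) stop("unknown rate constant(s): ", paste(bad, collapse = ", "))
    r[names(ov)] <- ov
  }
  neg <- names(r)[vapply(r, function(v) any(v < 0), logical(1))]
  if (length(neg)) stop("negative value for constant '", neg[1], "'")
  structure(r, order = ord, class = "hbkr_rates")
}

#' @export
print.hbkr_rates <- function(x, ...) {
  ord <- attr(x, "order")
  ks <- names(ord)
  cat("Hb-Kr model rate constants\n")
  cat("  2nd order (M^-1 s^-1):",
      paste0(ks[ord == 2], "=", unlist(x[ks[ord == 2]])), "\n")
  cat("  1st order (s^-1):    ",
      paste0(ks[ord == 1], "=", unlist(x[ks[ord == 1]])), "\n")
  cat(sprintf("  D_Hb=%g cm^2/s, D_Kr=%g cm^2/s, subvolume edge %g um\n",
              x$D_Hb, x$D_Kr, x$h_um))
  invisible(x)
}
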