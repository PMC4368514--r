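#' Lattice of nuclear subvolumes over the mid-embryo window
#'
#' The simulated region is a strip of the blastoderm between `ap_min` and
#' `ap_max` percent egg length (%EL), discretised into `n_ap` subvolumes of
#' edge `h_um` along the AP axis and `n_dv` subvolumes along DV (1 for 1D
#' runs, 10 for the 2D within-nucleus noise experiments). Subvolume `i`
#' (0-based AP index) is centred at `ap_min + (i + 0.5) * (ap_max - ap_min) /
#' n_ap` %EL. Boundaries are reflecting in both directions.
#'
#' @param n_ap number of AP subvolumes.
#' @param n_dv number of DV subvolumes.
#' @param h_um subvolume edge, micrometres.
#' @param ap_min,ap_max AP window in %EL.
#' @return object of class `hbkr_lattice` with fields `n`, `ap_pos` (per
#'   subvolume AP centre, %EL), `dv_index`, and flattened neighbour lists
#'   (`nb_ptr`, `nb_idx`, 0-based) consumed by the engines.
#' @examples
#' lattice_config()            # 60 x 1, 20-80 %EL
#' lattice_config(n_dv = 10)   # 2D grid for two-locus runs
#' @export
lattice_config <- function(n_ap = 60, n_dv = 1, h_um = 5,
                           ap_min = 20, ap_max = 80) {
  stopifnot(n_ap >= 2, n_dv >= 1, h_um > 0, ap_max > ap_min)
  n <- n_ap * n_dv
  step <- (ap_max - ap_min) / n_ap
  ap_i <- rep(seq_len(n_ap) - 1L, times = n_dv)
  dv_i <- rep(seq_len(n_dv) - 1L, each = n_ap)
  ap_pos <- ap_min + (ap_i + 0.5) * step
  # 4-neighbour grid, reflecting (missing neighbours simply absent)
  nbs <- vector("list", n)
  idx <- function(a, d) a + n_ap * d + 1L
  for (d in 0:(n_dv - 1L)) {
    for (a in 0:(n_ap - 1L)) {
      k <- idx(a, d)
      nb <- integer(0)
      if (a > 0L)          nb <- c(nb, idx(a - 1L, d))
      if (a < n_ap - 1L)   nb <- c(nb, idx(a + 1L, d))
      if (d > 0L)          nb <- c(nb, idx(a, d - 1L))
      if (d < n_dv - 1L)   nb <- c(nb, idx(a, d + 1L))
      nbs[[k]] <- nb - 1L   # 0-based for the kernels
    }
  }
  structure(list(
    n_ap = n_ap, n_dv = n_dv, n = n, h_um = h_um,
    ap_min = ap_min, ap_max = ap_max, step = step,
    ap_index = ap_i, dv_index = dv_i, ap_pos = ap_pos,
    nb_ptr = c(0L, cumsum(lengths(nbs))),
    nb_idx = unlist(nbs)
  ), class = "hbkr_lattice")
}

#' @export
print.hbkr_lattice <- function(x, ...) {
  cat(sprintf("hbkr lattice: %d x %d subvolumes (%g um edge), %g-%g %%EL\n",
              x$n_ap, x$n_dv, x$h_um, x$ap_min, x$ap_max))
  invisible(x)
}
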