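#' Bcd gradient and lumped activation parameters
#'
#' The static anterior-high Bcd field is exponential in AP position,
#' `B(x) = B0 * exp(-(x - ap_min) / lambda)`, and never changes during a
#' run. Two roles: (i) it multiplies the k18 Bcd-binding channel of the *Kr*
#' gene; (ii) it drives a lumped basal *hb* transcription channel
#' `alpha_B(x) = basal_rate * B^n / (B^n + K^n)` (copies/s), standing in for
#' the multi-Bcd-binding-site sub-model that the full enhancer treatment
#' would carry. The defaults are calibrated so that the Kr-null deterministic
#' boundary sits at 44 %EL and anterior *hb* mRNA reaches ~140 copies by
#' mid-NC14.
#'
#' @param B0 Bcd copies per subvolume at the anterior edge of the window.
#' @param lambda exponential length scale, %EL.
#' @param basal_rate maximal basal transcription rate, copies/s.
#' @param basal_K Hill half-saturation in Bcd copies.
#' @param basal_n Hill coefficient.
#' @return list of class `hbkr_bcd`.
#' @export
bcd_params <- function(B0 = 3000, lambda = 30, basal_rate = 0.16,
                       basal_K = 1500, basal_n = 8) {
  stopifnot(B0 > 0, lambda > 0, basal_rate >= 0, basal_K > 0, basal_n > 0)
  structure(list(B0 = B0, lambda = lambda, basal_rate = basal_rate,
                 basal_K = basal_K, basal_n = basal_n), class = "hbkr_bcd")
}

#' Static Bcd field on the lattice
#'
#' @param lattice a [lattice_config()].
#' @param B0 anterior amplitude (copies per subvolume).
#' @param lambda exponential length scale in %EL; `Inf` gives a flat field.
#' @return integer vector of Bcd counts per subvolume, monotone
#'   non-increasing in AP and constant across DV.
#' @export
bcd_field <- function(lattice, B0 = 3000, lambda = 30) {
  stopifnot(inherits(lattice, "hbkr_lattice"), B0 > 0)
  if (!is.numeric(lambda) || lambda <= 0) stop("non-positive Bcd length scale")
  round(B0 * exp(-(lattice$ap_pos - lattice$ap_min) / lambda))
}

#' Initial-profile parameters (t = 0, NC14 onset)
#'
#' The t = 0 profiles emulate end-of-NC13 expression: all amplitudes are a
#' fixed fraction (default 0.6) of the calibrated mid-NC14 values. *hb* mRNA
#' and Hb protein are anterior-high descending sigmoids; *Kr* mRNA and
#' protein are a Gaussian bump over the central domain. Amplitude units are
#' copies per subvolume (nucleus plus neighbouring cytoplasm).
#'
#' @param mh_max t = 0 anterior maximum of *hb* mRNA (copies).
#' @param h_max t = 0 anterior maximum of Hb protein (copies); default
#'   0.6 x 7000.
#' @param hb_half AP position of the initial Hb sigmoid half-height, %EL.
#' @param hb_width logistic scale of the sigmoid, %EL.
#' @param kr_centre,kr_sigma centre and width of the Kr Gaussian, %EL.
#' @param kr_final,mkr_final calibrated mid-NC14 Kr protein / mRNA peak
#'   amplitudes (copies); t = 0 uses `fraction` times these.
#' @param fraction fraction-of-final scaling applied to all t = 0 amplitudes
#'   relative to their mid-NC14 reference (in (0, 1]).
#' @return list of class `hbkr_init`.
#' @export
initial_profile_params <- function(mh_max = 100, h_max = 4200,
                                   hb_half = 48, hb_width = 2,
                                   kr_centre = 55, kr_sigma = 6,
                                   kr_final = 9000, mkr_final = 150,
                                   fraction = 0.6) {
  stopifnot(mh_max >= 0, h_max >= 0, hb_width > 0, kr_sigma > 0,
            kr_final >= 0, mkr_final >= 0, fraction > 0, fraction <= 1)
  structure(list(mh_max = mh_max, h_max = h_max, hb_half = hb_half,
                 hb_width = hb_width, kr_centre = kr_centre,
                 kr_sigma = kr_sigma, kr_final = kr_final,
                 mkr_final = mkr_final, fraction = fraction),
            class = "hbkr_init")
}

#' Initial lattice state
#'
#' Builds the t = 0 species-by-subvolume state matrix: anterior-high sigmoids
#' for *hb* mRNA/protein, a central Gaussian bump for *Kr* mRNA/protein
#' (zero outside the central domain tails), all gene-state species unbound
#' (`h0 = kr0 = KrB0 = KrH0 = 1` per locus), DV-uniform. For the stochastic
#' engine counts are deterministic rounds of the same profiles, so replicate
#' variation enters only through trajectory noise. In the `static_kr` variant
#' the Kr pool is set to the full mid-NC14 bump and acts as the frozen field.
#'
#' @param network an `hbkr_network`.
#' @param params an [initial_profile_params()].
#' @param integer round counts to integers (stochastic engine).
#' @return species-by-subvolume matrix with species rownames.
#' @export
initial_state <- function(network, params = initial_profile_params(),
                          integer = FALSE) {
  stopifnot(inherits(network, "hbkr_network"), inherits(params, "hbkr_init"))
  lat <- network$lattice
  sp <- network$species
  x <- lat$ap_pos
  sig <- 1 / (1 + exp((x - params$hb_half) / params$hb_width))
  bump <- exp(-(x - params$kr_centre)^2 / (2 * params$kr_sigma^2))

  mh <- params$mh_max * sig
  h <- params$h_max * sig
  kr_amp <- if (network$variant == "static_kr") params$kr_final
            else params$fraction * params$kr_final
  kr <- kr_amp * bump
  mkr <- params$fraction * params$mkr_final * bump
  if (network$variant %in% c("no_kr")) { kr[] <- 0; mkr[] <- 0 }

  state <- matrix(0, nrow = length(sp), ncol = lat$n, dimnames = list(sp, NULL))
  put <- function(nm, v) if (nm %in% sp) state[nm, ] <<- v
  if (network$loci == 1L) {
    put("MH", mh); put("MKr", mkr)
    for (nm in c("h0", "kr0", "KrB0", "KrH0")) put(nm, 1)
  } else {
    for (s in c("_A", "_B")) {
      put(paste0("MH", s), mh / 2); put(paste0("MKr", s), mkr / 2)
      for (nm in c("h0", "kr0", "KrB0", "KrH0")) put(paste0(nm, s), 1)
    }
  }
  put("H", h); put("Kr", kr)
  if (integer) state <- round(state)
  storage.mode(state) <- if (integer) "integer" else "double"
  state
}

#' Write a state or trajectory as a long-format profile CSV
#'
#' Columns: `time_s, ap_percent_el, dv_index, species, count, replicate,
#' seed`. The matching [read_profiles()] round-trips losslessly.
#'
#' @param x an `hbkr_trajectory`, or a species-by-subvolume state matrix.
#' @param path output file path.
#' @param network needed when `x` is a bare state matrix.
#' @param replicate replicate label stored in the file.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(x, path, network = NULL, replicate = 1L) {
  if (inherits(x, "hbkr_trajectory")) {
    lat <- x$lattice
    rows <- lapply(seq_along(x$times), function(ti) {
      st <- x$states[[ti]]
      data.frame(time_s = x$times[ti],
                 ap_percent_el = rep(lat$ap_pos, each = nrow(st)),
                 dv_index = rep(lat$dv_index, each = nrow(st)),
                 species = rep(rownames(st), times = ncol(st)),
                 count = as.vector(st),
                 replicate = replicate,
                 seed = if (is.null(x$seed)) NA else x$seed)
    })
    df <- do.call(rbind, rows)
  } else {
    if (is.null(network)) stop("network required to write a bare state matrix")
    lat <- network$lattice
    df <- data.frame(time_s = 0,
                     ap_percent_el = rep(lat$ap_pos, each = nrow(x)),
                     dv_index = rep(lat$dv_index, each = nrow(x)),
                     species = rep(rownames(x), times = ncol(x)),
                     count = as.vector(x),
                     replicate = replicate, seed = NA)
  }
  tryCatch(suppressWarnings(write.csv(df, path, row.names = FALSE)),
           error = function(e) stop("failed writing '", path, "': ",
                                    conditionMessage(e)))
  invisible(path)
}

#' Read a long-format profile CSV back into per-time state matrices
#'
#' @param path CSV written by [write_profiles()].
#' @return list with `times` and `states` (list of species x subvolume
#'   matrices, subvolumes ordered as on the originating lattice).
#' @export
read_profiles <- function(path) {
  df <- tryCatch(suppressWarnings(read.csv(path, stringsAsFactors = FALSE)),
                 error = function(e) stop("failed reading '", path, "': ",
                                          conditionMessage(e)))
  need <- c("time_s", "ap_percent_el", "dv_index", "species", "count")
  if (!all(need %in% names(df))) stop("'", path, "' is not a profile CSV")
  times <- sort(unique(df$time_s))
  species <- unique(df$species)
  states <- lapply(times, function(tt) {
    d <- df[df$time_s == tt, ]
    pos <- unique(d[, c("ap_percent_el", "dv_index")])
    pos <- pos[order(pos$dv_index, pos$ap_percent_el), ]
    m <- matrix(0, nrow = length(species), ncol = nrow(pos),
                dimnames = list(species, NULL))
    key <- paste(d$ap_percent_el, d$dv_index)
    poskey <- paste(pos$ap_percent_el, pos$dv_index)
    m[cbind(match(d$species, species), match(key, poskey))] <- d$count
    m
  })
  list(times = times, states = states, species = species)
}
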