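#' Half-height boundary position of an AP profile
#'
#' The boundary is the anterior-most AP position where the profile crosses
#' from at or above half of its maximum to below it, linearly interpolated
#' between subvolume centres. For non-monotonic (e.g. jagged stochastic)
#' profiles this is the anterior-most such crossing.
#'
#' @param ap AP positions, %EL, ascending.
#' @param counts species counts at those positions (same length).
#' @return boundary position in %EL.
#' @examples
#' boundary_position(c(49.5, 50.5), c(100, 0))  # 50
#' @export
boundary_position <- function(ap, counts) {
  stopifnot(length(ap) == length(counts), !is.unsorted(ap))
  if (length(ap) < 2 || max(counts) <= 0)
    stop("profile empty or without positive maximum")
  half <- max(counts) / 2
  for (j in seq_len(length(ap) - 1L)) {
    if (counts[j] >= half && counts[j + 1L] < half) {
      return(ap[j] + (counts[j] - half) / (counts[j] - counts[j + 1L]) *
               (ap[j + 1L] - ap[j]))
    }
  }
  stop("profile never crosses half-height from above; boundary undefined")
}

.smooth3 <- function(v) {
  n <- length(v)
  if (n < 3) return(v)
  out <- v
  out[2:(n - 1)] <- (v[1:(n - 2)] + v[2:(n - 1)] + v[3:n]) / 3
  out[1] <- (v[1] + v[2]) / 2
  out[n] <- (v[n - 1] + v[n]) / 2
  out
}

#' Peak position within an AP window
#'
#' Position of the maximum within `window`. With `local = TRUE` (the PS4
#' test) the maximum must be a genuine local maximum: strictly above both
#' neighbours after 3-point smoothing, and interior to the window; otherwise
#' `NA` is returned (a "no peak" result, not an error), which is how the
#' Kr-null loss of PS4 is detected. With `local = FALSE` the plain argmax is
#' returned (used for the Kr peak).
#'
#' @param ap,counts profile as in [boundary_position()].
#' @param window AP range searched, %EL.
#' @param local require a local maximum (3-point smoothed).
#' @param smooth apply the 3-point smoothing before locating the maximum.
#' @return peak position in %EL, or `NA` if no qualifying peak.
#' @export
peak_position <- function(ap, counts, window = range(ap), local = TRUE,
                          smooth = local) {
  stopifnot(length(ap) == length(counts), !is.unsorted(ap))
  if (window[1] < min(ap) - 1e-9 || window[2] > max(ap) + 1e-9)
    stop("window outside profile span")
  v <- if (smooth) .smooth3(counts) else counts
  inw <- which(ap >= window[1] & ap <= window[2])
  if (!length(inw)) return(NA_real_)
  j <- inw[which.max(v[inw])]
  if (!local) return(ap[j])
  if (j <= 1L || j >= length(ap)) return(NA_real_)
  if (j == inw[1] || j == inw[length(inw)]) return(NA_real_)
  if (v[j] > v[j - 1L] && v[j] > v[j + 1L]) ap[j] else NA_real_
}

#' Trough-to-peak ratio anterior of the PS4 peak
#'
#' Minimum of the profile between the anterior plateau and the PS4 peak,
#' divided by the PS4 peak height. Returns `NA` when there is no PS4 peak.
#'
#' @param ap,counts profile.
#' @param peak_window window used to locate the PS4 peak, %EL.
#' @param search_from anterior limit of the trough search, %EL.
#' @return ratio in [0, 1], or `NA` if no peak.
#' @export
trough_ratio <- function(ap, counts, peak_window = c(40, 55), search_from = 40) {
  p <- peak_position(ap, counts, window = peak_window)
  if (is.na(p)) return(NA_real_)
  peak_h <- counts[which.min(abs(ap - p))]
  sel <- ap >= search_from & ap <= p
  if (!any(sel) || peak_h <= 0) return(NA_real_)
  min(counts[sel]) / peak_h
}

#' Between-replicate positional standard deviation
#'
#' Sample SD (n - 1 denominator) of the half-height boundary position across
#' an ensemble of profiles. Replicates whose boundary is undefined are
#' excluded and reported. By default each stochastic profile is passed
#' through the same 3-point smoothing used for peak detection before the
#' half-height crossing is located, so that single-event spikes in one
#' subvolume do not masquerade as anterior boundary crossings; set
#' `smooth = FALSE` for raw profiles.
#'
#' @param profiles replicate-by-position matrix of counts, or a list of
#'   count vectors.
#' @param ap AP positions, %EL.
#' @param smooth apply 3-point smoothing to each profile first.
#' @return list with `sd`, `positions` (per usable replicate), and
#'   `excluded` (indices of replicates without a defined boundary).
#' @export
positional_sd <- function(profiles, ap, smooth = TRUE) {
  if (is.list(profiles)) profiles <- do.call(rbind, profiles)
  pos <- rep(NA_real_, nrow(profiles))
  for (i in seq_len(nrow(profiles))) {
    v <- if (smooth) .smooth3(profiles[i, ]) else profiles[i, ]
    pos[i] <- tryCatch(boundary_position(ap, v),
                       error = function(e) NA_real_)
  }
  excluded <- which(is.na(pos))
  usable <- pos[!is.na(pos)]
  if (length(usable) < 2)
    stop("fewer than 2 replicates with a defined boundary")
  list(sd = sd(usable), positions = usable, excluded = excluded)
}

#' Two-sided F-test for equality of positional variances
#'
#' `F` is the larger variance over the smaller; the two-sided p-value comes
#' from the F distribution with (n - 1, n - 1) degrees of freedom. A
#' one-sided p-value is also reported.
#'
#' @param sd1,n1 SD and replicate count of group 1.
#' @param sd2,n2 SD and replicate count of group 2.
#' @return list with `F`, `df`, `p` (two-sided), `p_one_sided`, and
#'   `degenerate` flag (TRUE when either variance is zero).
#' @export
variance_f_test <- function(sd1, n1, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2)
  if (sd1 <= 0 || sd2 <= 0)
    return(list(F = NA_real_, df = c(n1 - 1, n2 - 1), p = NA_real_,
                p_one_sided = NA_real_, degenerate = TRUE))
  v1 <- sd1^2; v2 <- sd2^2
  if (v1 >= v2) { Fv <- v1 / v2; df <- c(n1 - 1, n2 - 1) }
  else { Fv <- v2 / v1; df <- c(n2 - 1, n1 - 1) }
  p1 <- pf(Fv, df[1], df[2], lower.tail = FALSE)
  list(F = Fv, df = df, p = min(1, 2 * p1), p_one_sided = p1,
       degenerate = FALSE)
}

#' Within-nucleus two-locus transcript noise
#'
#' Standard deviation of the relative difference in transcript counts
#' between the two gene copies of a nucleus,
#' `sqrt( sum( ((A - B) / ((A + B) / 2))^2 ) / (m - 1) )`,
#' over the `m` nuclei with non-zero A and B (two measurable transcription
#' dots) lying within `window` %EL of the half-height Hb boundary.
#'
#' @param A,B per-nucleus transcript counts at loci A and B.
#' @param ap per-nucleus AP positions, %EL.
#' @param boundary Hb boundary position, %EL.
#' @param window half-width of the analysed band, %EL.
#' @return list with `value` (the noise, unitless) and `m` (nuclei used).
#' @export
noise_in_nuc <- function(A, B, ap, boundary, window = 5) {
  stopifnot(length(A) == length(B), length(A) == length(ap))
  sel <- ap >= boundary - window & ap <= boundary + window & A > 0 & B > 0
  m <- sum(sel)
  if (m < 2) stop("fewer than 2 nuclei with both loci active in the window")
  d <- (A[sel] - B[sel]) / ((A[sel] + B[sel]) / 2)
  list(value = sqrt(sum(d^2) / (m - 1)), m = m)
}

#' Pooled-variance two-sample t-test
#'
#' Two-sided t-test assuming equal variances, applied to per-simulation
#' noise values of two conditions.
#'
#' @param values1,values2 numeric vectors, each of length >= 2.
#' @return list with `t`, `df`, `p`, and `degenerate` flag.
#' @export
two_sample_t <- function(values1, values2) {
  stopifnot(length(values1) >= 2, length(values2) >= 2)
  n1 <- length(values1); n2 <- length(values2)
  sp2 <- ((n1 - 1) * stats::var(values1) + (n2 - 1) * stats::var(values2)) /
    (n1 + n2 - 2)
  if (sp2 <= 0) {
    if (mean(values1) == mean(values2))
      return(list(t = 0, df = n1 + n2 - 2, p = 1, degenerate = TRUE))
    return(list(t = Inf, df = n1 + n2 - 2, p = 0, degenerate = TRUE))
  }
  tval <- (mean(values1) - mean(values2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = tval, df = df, p = 2 * pt(abs(tval), df, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Jaggedness of a profile segment
#'
#' Number of strict sign changes of the first difference within the window:
#' zero for a monotone boundary, positive for jagged, non-monotonic ones.
#'
#' @param ap,counts profile.
#' @param window AP range examined, %EL.
#' @return integer count of sign changes.
#' @examples
#' jaggedness(1:4, c(10, 5, 8, 3))  # 2
#' @export
jaggedness <- function(ap, counts, window = range(ap)) {
  sel <- ap >= window[1] & ap <= window[2]
  s <- sign(diff(counts[sel]))
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(s[-1] * s[-length(s)] < 0)
}
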