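#' Mechanism variants
#'
#' @description
#' The wiring of Hb-Kr cross-regulation can be varied while keeping the same
#' species and rate table:
#'
#' * `kr_dual` - wild type. Kr acts dually on *hb*: one bound Kr site
#'   (`kr1`), with two Hb sites bound (`h2`), activates transcription (k16);
#'   two bound Kr sites (`kr2`) silence the gap-dependent channels. Hb simply
#'   inhibits *Kr*; Bcd activates *Kr* (k24 fires only in `KrB1, KrH0`).
#' * `kr_null` - the *Kr-* mutant: Kr binding on *hb* removed
#'   (k10 = k12 = 0).
#' * `mut_inh` - simple mutual inhibition: both `kr1` and `kr2` silence
#'   gap-dependent *hb* transcription (k16 = 0); Hb inhibition of *Kr* kept.
#' * `static_kr` - a frozen Kr spatial profile inhibits *hb* (binding reads,
#'   but never consumes, the static Kr pool); the *Kr* gene is removed.
#' * `hb_dual` - the reversed mechanism: *Kr* is activated by the first Hb
#'   binding (`KrH1`) and silenced by the second (`KrH2`), with no Bcd role;
#'   Kr is purely inhibitory on *hb*.
#' * `dual_dual` - `hb_dual`'s *Kr* wiring combined with `kr_dual`'s *hb*
#'   wiring.
#' * `no_kr` - Bcd-Hb baseline: no Kr species dynamics at all.
#'
#' @name mechanism-variants
NULL

.VARIANTS <- c("kr_dual", "kr_null", "mut_inh", "static_kr",
               "hb_dual", "dual_dual", "no_kr")

#' Species catalogue
#'
#' Per-locus gene-state species for the *hb* enhancer (`h0 h1 h2` Hb-site
#' state, `kr0 kr1 kr2` Kr-site state) and the *Kr* regulatory region
#' (`KrB0 KrB1` Bcd-site state, `KrH0 KrH1 KrH2` Hb-site state), plus the
#' pools `MH` (*hb* mRNA), `MKr` (*Kr* mRNA), `H` (Hb protein) and `Kr`
#' (Kr protein). With `loci = 2` the gene-state species and mRNA pools are
#' duplicated with `_A`/`_B` suffixes; proteins remain pooled.
#'
#' @param loci 1 or 2 transcription loci per nucleus.
#' @return character vector of species names.
#' @export
species_catalog <- function(loci = 1) {
  stopifnot(loci %in% c(1L, 2L))
  gene <- c("h0", "h1", "h2", "kr0", "kr1", "kr2",
            "KrB0", "KrB1", "KrH0", "KrH1", "KrH2", "MH", "MKr")
  if (loci == 1L) c(gene, "H", "Kr")
  else c(paste0(gene, "_A"), paste0(gene, "_B"), "H", "Kr")
}

# gene-state groups whose per-locus sum must equal one
.state_groups <- function(loci = 1) {
  base <- list(hb_hbsites = c("h0", "h1", "h2"),
               hb_krsites = c("kr0", "kr1", "kr2"),
               kr_bcdsites = c("KrB0", "KrB1"),
               kr_hbsites = c("KrH0", "KrH1", "KrH2"))
  if (loci == 1L) return(base)
  out <- list()
  for (sfx in c("_A", "_B"))
    for (nm in names(base))
      out[[paste0(nm, sfx)]] <- paste0(base[[nm]], sfx)
  out
}

#' Compile a mechanism variant into an executable reaction set
#'
#' Builds the full elementary reaction list (binding/unbinding, gated
#' transcription, translation, decay, protein diffusion) for one mechanism
#' variant, converts second-order constants to per-molecule-pair rates at the
#' subvolume volume, and bakes the static Bcd field into the position
#' dependent rate matrix. Bcd enters as a multiplier (k18 * B(i) on the *Kr*
#' Bcd site; a lumped Hill-activation zeroth-order channel on *hb*) and is
#' never consumed. Channels whose rate is exactly zero are pruned, so the
#' compiled set lists only live reactions.
#'
#' @param variant one of [mechanism-variants].
#' @param rates a [rate_table()].
#' @param lattice a [lattice_config()].
#' @param bcd a [bcd_params()] list (gradient + lumped activation).
#' @param loci 1 or 2 transcription loci per nucleus. With two loci every
#'   per-locus transcription channel runs at half rate so that pooled levels
#'   match the one-locus calibration.
#' @param krh1_scale calibration multiplier on the `KrH1 -> MKr` channel of
#'   the reversed (`hb_dual`, `dual_dual`) wirings. The tabulated Hb-binding
#'   constants on *Kr* were calibrated for the repressive role, leaving the
#'   singly-bound state rare; the default rescales the channel so the
#'   Hb-activated Kr domain reaches a mid-embryo amplitude at which its
#'   feedback on *hb* is expressed.
#' @return object of class `hbkr_network`.
#' @export
compile_reactions <- function(variant = "kr_dual", rates = rate_table(),
                              lattice = lattice_config(), bcd = bcd_params(),
                              loci = 1, krh1_scale = 25) {
  variant <- match.arg(variant, .VARIANTS)
  stopifnot(inherits(rates, "hbkr_rates"), loci %in% c(1L, 2L))
  ord <- attr(rates, "order")
  miss <- setdiff(names(ord), names(rates))
  if (length(miss)) stop("missing rate constant(s): ", paste(miss, collapse = ", "))

  V <- subvolume_volume(rates$h_um)
  conv <- function(kn) molar_to_stochastic(rates[[kn]], ord[[kn]], V, name = kn)
  B <- bcd_field(lattice, bcd$B0, bcd$lambda)
  basal <- bcd$basal_rate * B^bcd$basal_n / (B^bcd$basal_n + bcd$basal_K^bcd$basal_n)

  # variant wiring: effective constants and structural switches
  k <- vapply(names(ord), conv, numeric(1))
  kr_on_hb <- TRUE; kr_gene <- TRUE; kr_static <- FALSE
  kr_consumed <- TRUE; bcd_on_kr <- TRUE; krh1_activates <- FALSE
  if (variant == "kr_null") { k[["k10"]] <- 0; k[["k12"]] <- 0; kr_on_hb <- FALSE }
  if (variant == "mut_inh") k[["k16"]] <- 0
  if (variant == "static_kr") {
    k[["k16"]] <- 0; kr_gene <- FALSE; kr_static <- TRUE; kr_consumed <- FALSE
  }
  if (variant %in% c("hb_dual", "dual_dual")) {
    bcd_on_kr <- FALSE; krh1_activates <- TRUE
    if (variant == "hb_dual") k[["k16"]] <- 0
  }
  if (variant == "no_kr") {
    k[["k10"]] <- 0; k[["k12"]] <- 0; kr_on_hb <- FALSE; kr_gene <- FALSE
  }

  species <- species_catalog(loci)
  txn_scale <- if (loci == 2L) 0.5 else 1   # per-locus channels, pooled output
  sfx <- if (loci == 2L) c("_A", "_B") else ""

  rx <- list()
  add <- function(name, rate_name, rate, re1 = NA, re2 = NA, stoich,
                  mult = "unit") {
    rx[[length(rx) + 1L]] <<- list(name = name, rate_name = rate_name,
                                   rate = rate, re1 = re1, re2 = re2,
                                   stoich = stoich, mult = mult)
  }
  st <- function(...) {
    v <- c(...)
    stats::setNames(as.integer(v), names(v))
  }

  for (s in sfx) {
    p <- function(x) paste0(x, s)
    # Hb self-binding on hb (protein sequestered while bound)
    add(paste0("h0", s, "+H->h1", s), "k1", k[["k1"]], p("h0"), "H",
        st(setNames(c(-1, 1, -1), c(p("h0"), p("h1"), "H"))))
    add(paste0("h1", s, "->h0", s, "+H"), "k2", k[["k2"]], p("h1"), NA,
        st(setNames(c(-1, 1, 1), c(p("h1"), p("h0"), "H"))))
    add(paste0("h1", s, "+H->h2", s), "k3", k[["k3"]], p("h1"), "H",
        st(setNames(c(-1, 1, -1), c(p("h1"), p("h2"), "H"))))
    add(paste0("h2", s, "->h1", s, "+H"), "k4", k[["k4"]], p("h2"), NA,
        st(setNames(c(-1, 1, 1), c(p("h2"), p("h1"), "H"))))
    # Kr binding on hb
    if (kr_on_hb) {
      krgain <- if (kr_consumed) st(setNames(c(-1, 1, -1), c(p("kr0"), p("kr1"), "Kr")))
                else st(setNames(c(-1, 1), c(p("kr0"), p("kr1"))))
      krgain2 <- if (kr_consumed) st(setNames(c(-1, 1, -1), c(p("kr1"), p("kr2"), "Kr")))
                 else st(setNames(c(-1, 1), c(p("kr1"), p("kr2"))))
      krloss <- if (kr_consumed) st(setNames(c(-1, 1, 1), c(p("kr1"), p("kr0"), "Kr")))
                else st(setNames(c(-1, 1), c(p("kr1"), p("kr0"))))
      krloss2 <- if (kr_consumed) st(setNames(c(-1, 1, 1), c(p("kr2"), p("kr1"), "Kr")))
                 else st(setNames(c(-1, 1), c(p("kr2"), p("kr1"))))
      add(paste0("kr0", s, "+Kr->kr1", s), "k10", k[["k10"]], p("kr0"), "Kr", krgain)
      add(paste0("kr1", s, "->kr0", s, "+Kr"), "k11", k[["k11"]], p("kr1"), NA, krloss)
      add(paste0("kr1", s, "+Kr->kr2", s), "k12", k[["k12"]], p("kr1"), "Kr", krgain2)
      add(paste0("kr2", s, "->kr1", s, "+Kr"), "k13", k[["k13"]], p("kr2"), NA, krloss2)
    }
    # gap-gated hb transcription (enhancer state catalytic)
    mh <- st(setNames(1, p("MH")))
    add(paste0("h1", s, ".kr0", s, "->MH", s), "k5", txn_scale * k[["k5"]],
        p("h1"), p("kr0"), mh)
    add(paste0("h2", s, ".kr0", s, "->MH", s), "k6", txn_scale * k[["k6"]],
        p("h2"), p("kr0"), mh)
    if (kr_on_hb || kr_static) {
      add(paste0("h1", s, ".kr1", s, "->MH", s), "k14", txn_scale * k[["k14"]],
          p("h1"), p("kr1"), mh)
      add(paste0("h2", s, ".kr1", s, "->MH", s), "k16", txn_scale * k[["k16"]],
          p("h2"), p("kr1"), mh)
      add(paste0("h1", s, ".kr2", s, "->MH", s), "k15", txn_scale * k[["k15"]],
          p("h1"), p("kr2"), mh)
      add(paste0("h2", s, ".kr2", s, "->MH", s), "k17", txn_scale * k[["k17"]],
          p("h2"), p("kr2"), mh)
    }
    # lumped Bcd-dependent basal hb transcription (position-dependent rate)
    add(paste0("basal->MH", s), "basal", txn_scale, NA, NA, mh, mult = "basal")
    # hb mRNA decay, translation, (pooled) protein decay handled below
    add(paste0("MH", s, "->0"), "k7", k[["k7"]], p("MH"), NA,
        st(setNames(-1, p("MH"))))
    add(paste0("MH", s, "->MH", s, "+H"), "k8", k[["k8"]], p("MH"), NA,
        st(H = 1))
    # Kr gene
    if (kr_gene) {
      if (bcd_on_kr) {
        add(paste0("KrB0", s, "+B->KrB1", s), "k18", k[["k18"]], p("KrB0"), NA,
            st(setNames(c(-1, 1), c(p("KrB0"), p("KrB1")))), mult = "bcd")
        add(paste0("KrB1", s, "->KrB0", s, "+B"), "k19", k[["k19"]], p("KrB1"), NA,
            st(setNames(c(-1, 1), c(p("KrB1"), p("KrB0")))))
      }
      add(paste0("KrH0", s, "+H->KrH1", s), "k20", k[["k20"]], p("KrH0"), "H",
          st(setNames(c(-1, 1, -1), c(p("KrH0"), p("KrH1"), "H"))))
      add(paste0("KrH1", s, "->KrH0", s, "+H"), "k21", k[["k21"]], p("KrH1"), NA,
          st(setNames(c(-1, 1, 1), c(p("KrH1"), p("KrH0"), "H"))))
      add(paste0("KrH1", s, "+H->KrH2", s), "k22", k[["k22"]], p("KrH1"), "H",
          st(setNames(c(-1, 1, -1), c(p("KrH1"), p("KrH2"), "H"))))
      add(paste0("KrH2", s, "->KrH1", s, "+H"), "k23", k[["k23"]], p("KrH2"), NA,
          st(setNames(c(-1, 1, 1), c(p("KrH2"), p("KrH1"), "H"))))
      mkr <- st(setNames(1, p("MKr")))
      if (krh1_activates)
        add(paste0("KrH1", s, "->MKr", s), "k24", txn_scale * krh1_scale * k[["k24"]],
            p("KrH1"), NA, mkr)
      else
        add(paste0("KrB1", s, ".KrH0", s, "->MKr", s), "k24",
            txn_scale * k[["k24"]], p("KrB1"), p("KrH0"), mkr)
      add(paste0("MKr", s, "->0"), "k25", k[["k25"]], p("MKr"), NA,
          st(setNames(-1, p("MKr"))))
      add(paste0("MKr", s, "->MKr", s, "+Kr"), "k26", k[["k26"]], p("MKr"), NA,
          st(Kr = 1))
    }
  }
  # pooled protein decay
  add("H->0", "k9", k[["k9"]], "H", NA, st(H = -1))
  if (kr_gene) add("Kr->0", "k27", k[["k27"]], "Kr", NA, st(Kr = -1))

  # prune dead channels
  rx <- Filter(function(r) r$rate > 0 || r$mult != "unit", rx)

  # order channels by expected event frequency (pool turnover first, gated
  # transcription last) so the samplers' linear channel scan stays short
  freq_class <- c(k8 = 1, k26 = 1, k9 = 1, k27 = 1, k7 = 2, k25 = 2,
                  k1 = 3, k2 = 3, k3 = 3, k4 = 3, k10 = 3, k11 = 3,
                  k12 = 3, k13 = 3, k18 = 3, k19 = 3, k20 = 3, k21 = 3,
                  k22 = 3, k23 = 3,
                  k5 = 4, k6 = 4, k14 = 4, k15 = 4, k16 = 4, k17 = 4,
                  k24 = 4, basal = 4)
  pr <- vapply(rx, function(r) freq_class[[r$rate_name]], numeric(1))
  rx <- rx[order(pr)]

  R <- length(rx)
  N <- lattice$n
  sp_idx <- function(nm) {
    i <- match(nm, species)
    if (any(is.na(i))) stop("unknown species: ", paste(nm[is.na(i)], collapse = ", "))
    i
  }
  re1 <- vapply(rx, function(r) if (is.na(r$re1)) -1L else sp_idx(r$re1) - 1L, integer(1))
  re2 <- vapply(rx, function(r) if (is.na(r$re2)) -1L else sp_idx(r$re2) - 1L, integer(1))
  st_list <- lapply(rx, function(r) r$stoich)
  st_ptr <- c(0L, cumsum(vapply(st_list, length, integer(1))))
  st_sp <- unlist(lapply(st_list, function(s) sp_idx(names(s)) - 1L), use.names = FALSE)
  st_delta <- unlist(st_list, use.names = FALSE)

  rate_mat <- matrix(0, nrow = R, ncol = N)
  for (r in seq_len(R)) {
    rate_mat[r, ] <- switch(rx[[r]]$mult,
      unit = rx[[r]]$rate,
      bcd = rx[[r]]$rate * B,
      basal = rx[[r]]$rate * basal)
  }

  dif_sp <- integer(0); dif_rate <- numeric(0)
  dif_sp <- c(dif_sp, sp_idx("H") - 1L)
  dif_rate <- c(dif_rate, diffusion_jump_rate(rates$D_Hb, rates$h_um))
  if (kr_gene) {   # only dynamic Kr protein diffuses; mRNA never does
    dif_sp <- c(dif_sp, sp_idx("Kr") - 1L)
    dif_rate <- c(dif_rate, diffusion_jump_rate(rates$D_Kr, rates$h_um))
  }

  reactions <- data.frame(
    name = vapply(rx, `[[`, character(1), "name"),
    rate_name = vapply(rx, `[[`, character(1), "rate_name"),
    rate = vapply(rx, `[[`, numeric(1), "rate"),
    stringsAsFactors = FALSE
  )

  structure(list(
    variant = variant, loci = as.integer(loci), species = species,
    reactions = reactions, stoich = st_list,
    re1 = as.integer(re1), re2 = as.integer(re2),
    st_ptr = as.integer(st_ptr), st_sp = as.integer(st_sp),
    st_delta = as.integer(st_delta),
    rate_matrix = rate_mat, dif_sp = as.integer(dif_sp), dif_rate = dif_rate,
    lattice = lattice, rates = rates, bcd = bcd,
    bcd_field = B, basal_field = basal
  ), class = "hbkr_network")
}

#' Duplicate a one-locus reaction set into two-locus form
#'
#' Recompiles the network with per-locus gene-state species and transcription
#' channels (`_A`/`_B`), per-locus mRNA pools, and pooled proteins; per-locus
#' transcription rates are halved so pooled output matches the one-locus
#' calibration.
#'
#' @param network a one-locus `hbkr_network`.
#' @return a two-locus `hbkr_network`.
#' @export
two_locus_mode <- function(network) {
  stopifnot(inherits(network, "hbkr_network"))
  if (network$loci == 2L) stop("network is already in two-locus mode")
  compile_reactions(network$variant, network$rates, network$lattice,
                    network$bcd, loci = 2L)
}

#' @export
print.hbkr_network <- function(x, ...) {
  cat(sprintf("hbkr reaction network: variant '%s', %d loci\n", x$variant, x$loci))
  cat(sprintf("  %d species, %d reactions, %d subvolumes (%dx%d)\n",
              length(x$species), nrow(x$reactions), x$lattice$n,
              x$lattice$n_ap, x$lattice$n_dv))
  cat(sprintf("  diffusing species: %s\n",
              paste(x$species[x$dif_sp + 1L], collapse = ", ")))
  invisible(x)
}

#' Human-readable reaction tabulation
#'
#' @param network an `hbkr_network`.
#' @return data.frame with reaction name, rate-constant name and converted
#'   per-event rate, suitable for auditing against the model's rate tables.
#' @export
reaction_list <- function(network) {
  stopifnot(inherits(network, "hbkr_network"))
  network$reactions
}

#' Check lattice-state invariants
#'
#' Verifies, in every subvolume, that all counts are non-negative and that
#' each locus's gene-state species sum to one (states are mutually
#' exclusive: one enhancer per locus).
#'
#' @param state species-by-subvolume matrix (rownames = species).
#' @param network the `hbkr_network` the state belongs to.
#' @return list with `ok` (logical) and `violations` (data.frame naming the
#'   subvolume and invariant of each failure).
#' @export
validate_state <- function(state, network) {
  stopifnot(inherits(network, "hbkr_network"))
  sp <- network$species
  if (nrow(state) != length(sp) || ncol(state) != network$lattice$n)
    stop("state dimensions do not match network/lattice")
  viol <- list()
  neg <- which(state < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    viol[[length(viol) + 1L]] <- data.frame(
      subvolume = neg[, 2], invariant = "non-negativity",
      detail = paste0(sp[neg[, 1]], " = ", state[neg]))
  }
  for (gn in names(.state_groups(network$loci))) {
    g <- .state_groups(network$loci)[[gn]]
    sums <- colSums(state[match(g, sp), , drop = FALSE])
    bad <- which(abs(sums - 1) > 1e-9)
    if (length(bad)) {
      viol[[length(viol) + 1L]] <- data.frame(
        subvolume = bad, invariant = paste0("state-sum ", gn),
        detail = paste0("sum = ", sums[bad]))
    }
  }
  violations <- if (length(viol)) do.call(rbind, viol)
    else data.frame(subvolume = integer(0), invariant = character(0),
                    detail = character(0))
  list(ok = nrow(violations) == 0L, violations = violations)
}
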