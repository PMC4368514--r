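test_that("birth-death sampling reproduces the Poisson stationary law (mean and Fano within 3 SE)", {
  a <- 5; g <- 0.1                      # stationary mean 50, Fano 1
  net <- birth_death_net(a, g)
  st <- empty_state(net, list(X = 50))  # start at the mean, sample at 5 lifetimes
  n <- 200
  x <- unlist(lapply(seq_len(n), function(i) {
    tr <- nsm_run(net, state0 = st, t_end = 50, seed = 100 + i, record = 50)
    as.numeric(tr$states[[1]]["X", ])
  }))
  mu <- a / g
  se_mean <- sqrt(mu / length(x))
  expect_lt(abs(mean(x) - mu), 3 * se_mean)
  fano <- var(x) / mean(x)
  se_fano <- sqrt(2 / (length(x) - 1))  # var of sample variance, Poisson approx
  expect_lt(abs(fano - 1), 3 * se_fano)
})

test_that("diffusion events conserve the total count exactly", {
  net <- toy_network("H", list(), n_ap = 60,
                     dif_species = "H", dif_rate = 1.2e-2)
  st <- empty_state(net, list(H = 0))
  st["H", 30] <- 5000
  tr <- nsm_run(net, state0 = st, t_end = 2000, seed = 11,
                record = c(0, 10, 100, 500, 2000))
  tot <- vapply(tr$states, function(s) sum(s["H", ]), numeric(1))
  expect_true(all(tot == 5000))
  # and the profile spreads
  expect_gt(sum(tr$states[[5]]["H", ] > 0), 10)
})

test_that("identical seeds give identical trajectories; different seeds differ", {
  m <- hb_kr_model("kr_dual")
  a <- nsm_run(m, t_end = 120, seed = 42, record = c(0, 120))
  b <- nsm_run(m, t_end = 120, seed = 42, record = c(0, 120))
  d <- nsm_run(m, t_end = 120, seed = 43, record = c(0, 120))
  expect_identical(a$states, b$states)
  expect_false(identical(a$states[[2]], d$states[[2]]))
})

test_that("ensembles are reproducible and their replicates match individually seeded runs", {
  m <- hb_kr_model("kr_dual")
  e1 <- run_ensemble(m, n = 2, base_seed = 7, t_end = 60, record = c(0, 60))
  e2 <- run_ensemble(m, n = 2, base_seed = 7, t_end = 60, record = c(0, 60))
  expect_identical(lapply(e1, `[[`, "states"), lapply(e2, `[[`, "states"))
  single <- nsm_run(m, t_end = 60, seed = 8, record = c(0, 60))
  expect_identical(e1[[1]]$states, single$states)
})

test_that("single-channel inter-event times are exponential (KS test)", {
  a <- 100
  net <- toy_network("X",
    list(list(re1 = NA, re2 = NA, stoich = c(X = 1L), rate = c(a, 0))),
    n_ap = 2)
  st <- empty_state(net)
  tr <- nsm_run(net, state0 = st, t_end = 150, seed = 99, record = 150,
                log_events = 10000)
  times <- attr(tr, "event_times")
  expect_gte(length(times), 10000)
  gaps <- diff(c(0, times[1:10000]))
  ks <- suppressWarnings(stats::ks.test(gaps, "pexp", rate = a))
  expect_gt(ks$p.value, 0.01)
})

test_that("the ensemble mean approaches the deterministic solution as counts scale up", {
  g <- 0.1; t_end <- 30
  gap_at_scale <- function(scale, seed0) {
    net <- birth_death_net(5 * scale, g)
    st <- empty_state(net)
    ode <- unname(run_deterministic(net, state0 = st, t_end = t_end,
                                    dt = 0.05, record = t_end)$states[[1]]["X", 1])
    x <- unlist(lapply(1:60, function(i) {
      as.numeric(nsm_run(net, state0 = st, t_end = t_end, seed = seed0 + i,
                         record = t_end)$states[[1]]["X", ])
    }))
    abs(mean(x) - ode) / ode
  }
  expect_lt(gap_at_scale(10, 3000), gap_at_scale(1, 2000) + 0.01)
  expect_lt(gap_at_scale(10, 3000), 0.03)
})

test_that("two-locus networks keep a silenced locus silent", {
  net2 <- compile_reactions("kr_dual", loci = 2)
  # silence every channel that produces MH_B
  mhb <- match("MH_B", net2$species) - 1L
  for (r in seq_len(nrow(net2$reactions))) {
    sp <- net2$st_sp[(net2$st_ptr[r] + 1L):net2$st_ptr[r + 1L]]
    de <- net2$st_delta[(net2$st_ptr[r] + 1L):net2$st_ptr[r + 1L]]
    if (any(sp == mhb & de > 0)) net2$rate_matrix[r, ] <- 0
  }
  st <- initial_state(net2, integer = TRUE)
  st["MH_B", ] <- 0L
  tr <- nsm_run(net2, state0 = st, t_end = 300, seed = 5, record = c(0, 300))
  expect_true(all(tr$states[[2]]["MH_B", ] == 0))
  expect_gt(sum(tr$states[[2]]["MH_A", ]), 0)
})

test_that("gene-state sums hold at every snapshot of a stochastic run", {
  m <- hb_kr_model("kr_dual")
  tr <- nsm_run(m, t_end = 300, seed = 21, record = c(0, 100, 200, 300))
  net <- m$network
  for (s in tr$states) expect_true(validate_state(s, net)$ok)
})

test_that("the interface position is temporally steadier with Kr dual regulation than without Kr", {
  sds <- vapply(c("kr_dual", "no_kr"), function(v) {
    median(vapply(1:3, function(i)
      interface_variability(hb_kr_model(v), seed = 400 + i), numeric(1)))
  }, numeric(1))
  expect_lt(sds[["kr_dual"]], sds[["no_kr"]])
})
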