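test_that("the mass-action derivative reproduces hand-computed decay and conservation", {
  # decay-only: dMH/dt = -k7 * MH = -0.68 at MH = 100
  net <- toy_network("MH",
    list(list(re1 = "MH", re2 = NA, stoich = c(MH = -1L), rate = 6.8e-3)))
  st <- empty_state(net, list(MH = 100))
  d <- mass_action_rhs(st, net)
  expect_equal(d["MH", ], rep(-0.68, 2))

  # full network: gene-state sums have zero derivative everywhere
  full <- compile_reactions("kr_dual")
  s0 <- initial_state(full)
  s0["H", ] <- 3000; s0["Kr", ] <- 2000   # make binding channels active
  s0["h0", ] <- 0.5; s0["h1", ] <- 0.3; s0["h2", ] <- 0.2
  s0["kr0", ] <- 0.6; s0["kr1", ] <- 0.3; s0["kr2", ] <- 0.1
  d <- mass_action_rhs(s0, full)
  expect_equal(colSums(d[c("h0", "h1", "h2"), ]), rep(0, 60), tolerance = 1e-12)
  expect_equal(colSums(d[c("kr0", "kr1", "kr2"), ]), rep(0, 60), tolerance = 1e-12)
  expect_equal(colSums(d[c("KrB0", "KrB1"), ]), rep(0, 60), tolerance = 1e-12)
})

test_that("a uniform diffusing field has zero derivative under diffusion alone", {
  net <- toy_network("H", list(), n_ap = 10,
                     dif_species = "H", dif_rate = 1.2e-3)
  st <- empty_state(net, list(H = 500))
  d <- mass_action_rhs(st, net)
  expect_equal(d["H", ], rep(0, 10))
})

test_that("RK4 matches the closed-form exponential decay to 1e-6 relative", {
  net <- toy_network("MH",
    list(list(re1 = "MH", re2 = NA, stoich = c(MH = -1L), rate = 6.8e-3)))
  st <- empty_state(net, list(MH = 100))
  tr <- run_deterministic(net, state0 = st, t_end = 2400, dt = 0.5,
                          record = c(0, 600, 2400))
  for (tt in c(600, 2400)) {
    got <- unname(tr$states[[match(tt, tr$times)]]["MH", 1])
    expect_equal(got, 100 * exp(-6.8e-3 * tt), tolerance = 1e-6)
  }
})

test_that("halving the step changes recorded values by less than 1e-4 relative", {
  m <- hb_kr_model("kr_dual")
  a <- run_deterministic(m, t_end = 60, dt = 0.003, record = c(0, 60))
  b <- run_deterministic(m, t_end = 60, dt = 0.0015, record = c(0, 60))
  sa <- a$states[[2]]; sb <- b$states[[2]]
  scale <- pmax(abs(sb), 1)
  expect_lt(max(abs(sa - sb) / scale), 1e-4)
})

test_that("deterministic runs are bit-identical on repeat", {
  m <- hb_kr_model("kr_dual")
  a <- run_deterministic(m, t_end = 30, record = c(0, 30))
  b <- run_deterministic(m, t_end = 30, record = c(0, 30))
  expect_identical(a$states, b$states)
})

test_that("with diffusion only, total protein is conserved and the profile flattens", {
  net <- toy_network("H", list(), n_ap = 20,
                     dif_species = "H", dif_rate = 5e-3)
  st <- empty_state(net, list(H = 0))
  st["H", 10] <- 2000
  tr <- run_deterministic(net, state0 = st, t_end = 5000, dt = 0.5,
                          record = c(0, 500, 5000))
  tot <- vapply(tr$states, function(s) sum(s["H", ]), numeric(1))
  expect_equal(tot, rep(2000, 3), tolerance = 1e-8)
  v <- vapply(tr$states, function(s) var(s["H", ]), numeric(1))
  expect_true(all(diff(v) < 0))
  expect_lt(v[3], v[1] / 50)   # approaching uniform
})

test_that("gene-state sums stay exactly one through a full integration", {
  tr <- det_run("kr_dual")
  net <- compile_reactions("kr_dual")
  for (s in tr$states) {
    expect_equal(colSums(s[c("h0", "h1", "h2"), ]), rep(1, 60), tolerance = 1e-9)
    expect_equal(colSums(s[c("kr0", "kr1", "kr2"), ]), rep(1, 60), tolerance = 1e-9)
    expect_equal(colSums(s[c("KrH0", "KrH1", "KrH2"), ]), rep(1, 60),
                 tolerance = 1e-9)
  }
})

test_that("the deterministic solution equals the stochastic ensemble mean on a birth-death system", {
  a <- 5; g <- 0.1; t_end <- 60
  net <- birth_death_net(a, g)
  st <- empty_state(net)
  ode <- run_deterministic(net, state0 = st, t_end = t_end, dt = 0.05,
                           record = c(0, t_end))
  mean_ode <- unname(ode$states[[2]]["X", 1])
  expect_equal(mean_ode, a / g * (1 - exp(-g * t_end)), tolerance = 1e-6)

  n <- 200
  finals <- vapply(seq_len(n), function(i) {
    tr <- nsm_run(net, state0 = st, t_end = t_end, seed = 5000 + i,
                  record = t_end)
    as.numeric(tr$states[[1]]["X", ])  # two independent subvolumes
  }, numeric(2))
  x <- as.vector(finals)
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - mean_ode), 3 * se + 1e-9)
})
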