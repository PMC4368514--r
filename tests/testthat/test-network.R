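V_SUB <- subvolume_volume(5)
conv2 <- function(k) k / (6.02214076e23 * V_SUB)

test_that("the wild-type compile carries the gated transcription channels at converted rates", {
  net <- compile_reactions("kr_dual")
  rx <- reaction_list(net)
  # Kr-gated hb transcription only from the h2-kr1 state, at converted k16
  k16row <- rx[rx$rate_name == "k16", ]
  expect_equal(nrow(k16row), 1L)
  expect_equal(k16row$rate, conv2(1.25e11), tolerance = 1e-12)
  expect_false(any(rx$rate_name %in% c("k14", "k15", "k17")))  # silent states pruned
  # Kr gene transcribes only in the KrB1.KrH0 state
  k24row <- rx[rx$rate_name == "k24", ]
  expect_match(k24row$name, "KrB1.KrH0")
  expect_equal(k24row$rate, conv2(4.5e11), tolerance = 1e-12)
  # only the proteins diffuse
  expect_setequal(net$species[net$dif_sp + 1L], c("H", "Kr"))
})

test_that("the Kr-null compile has no reaction touching Kr on the hb enhancer", {
  net <- compile_reactions("kr_null")
  rx <- reaction_list(net)
  expect_false(any(grepl("kr1|kr2", rx$name)))
  expect_false(any(rx$rate_name %in% c("k10", "k11", "k12", "k13", "k16")))
  # the Kr gene itself still runs
  expect_true(any(rx$rate_name == "k24"))
  # with the kr-sites frozen at kr0, the k5/k6 channels remain gated on kr0
  expect_true(any(grepl("h2.*kr0", rx$name)))
})

test_that("compilation is deterministic with stable ordering", {
  a <- compile_reactions("kr_dual")
  b <- compile_reactions("kr_dual")
  expect_identical(reaction_list(a), reaction_list(b))
  expect_identical(a$rate_matrix, b$rate_matrix)
  expect_identical(a$st_sp, b$st_sp)
})

test_that("mutual inhibition differs from the wild type by exactly the k16 channel", {
  wt <- reaction_list(compile_reactions("kr_dual"))
  mi <- reaction_list(compile_reactions("mut_inh"))
  expect_setequal(setdiff(wt$name, mi$name),
                  wt$name[wt$rate_name == "k16"])
  expect_length(setdiff(mi$name, wt$name), 0)
})

test_that("setting k14 = k16 adds the h1-kr1 channel and leaves the rest unchanged", {
  r <- rate_table()
  wt <- reaction_list(compile_reactions("kr_dual"))
  alt <- reaction_list(compile_reactions("kr_dual", rate_table(k14 = r$k16)))
  added <- setdiff(alt$name, wt$name)
  expect_length(added, 1L)
  expect_match(added, "h1.kr1")
  expect_equal(alt$rate[alt$name == added], conv2(r$k16), tolerance = 1e-12)
  expect_length(setdiff(wt$name, alt$name), 0)
})

test_that("the Bcd field enters the k18 channel as a static per-position multiplier", {
  net <- compile_reactions("kr_dual")
  r18 <- which(net$reactions$rate_name == "k18")
  expect_equal(net$rate_matrix[r18, ], conv2(1.8e7) * net$bcd_field,
               tolerance = 1e-12)
  # Bcd is never consumed: no stoichiometry entry outside the KrB states
  sp <- net$stoich[[r18]]
  expect_setequal(names(sp), c("KrB0", "KrB1"))
})

test_that("two-locus mode duplicates gene states symmetrically with halved per-locus transcription", {
  net1 <- compile_reactions("kr_dual", loci = 1)
  net2 <- two_locus_mode(net1)
  expect_true(all(c("MH_A", "MH_B", "h0_A", "h0_B", "KrH2_A", "KrH2_B") %in%
                    net2$species))
  expect_false(any(c("MH", "h0") %in% net2$species))
  rx2 <- reaction_list(net2)
  a16 <- rx2$rate[rx2$rate_name == "k16" & grepl("_A", rx2$name)]
  b16 <- rx2$rate[rx2$rate_name == "k16" & grepl("_B", rx2$name)]
  expect_equal(a16, b16)
  expect_equal(a16, conv2(1.25e11) / 2, tolerance = 1e-12)
  # proteins pooled: translation of either mRNA makes the same H
  expect_true(all(c("H", "Kr") %in% net2$species))
  expect_error(two_locus_mode(net2), "already")
})

test_that("state validation enforces mutually exclusive gene states and non-negativity", {
  net <- compile_reactions("kr_dual")
  st <- initial_state(net, integer = TRUE)
  expect_true(validate_state(st, net)$ok)

  bad <- st; bad["h1", 3] <- 1L          # h0 + h1 = 2 in subvolume 3
  v <- validate_state(bad, net)
  expect_false(v$ok)
  expect_true(any(v$violations$subvolume == 3 &
                    grepl("hb_hbsites", v$violations$invariant)))

  neg <- st; neg["MH", 1] <- -1L
  v2 <- validate_state(neg, net)
  expect_false(v2$ok)
  expect_true(any(v2$violations$invariant == "non-negativity"))
})

test_that("unknown variants and incomplete rate tables are rejected", {
  expect_error(compile_reactions("not_a_variant"))
  broken <- rate_table()
  broken$k16 <- NULL
  expect_error(compile_reactions("kr_dual", broken), "k16")
})
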