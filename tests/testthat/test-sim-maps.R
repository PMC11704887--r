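test_that("zero noise and saturated shrink reproduce the topography exactly", {
  cfg <- small_config(noise_sd_map = 0, shrink_c0 = 50)  # shrink == 1
  topo <- make_topography(cfg)
  pts <- simulate_participants(cfg, 11)
  maps <- simulate_tmaps(cfg, pts, topo, 12)
  expect_equal(maps$tmaps$novelty[1, ], as.vector(topo$novelty), tolerance = 1e-12)
  expect_equal(maps$tmaps$memory[5, ], as.vector(topo$memory), tolerance = 1e-12)
})

test_that("map generation is reproducible and checks the grid", {
  cfg <- small_config()
  topo <- make_topography(cfg)
  a <- simulate_tmaps(cfg, NULL, topo, 13)
  b <- simulate_tmaps(cfg, NULL, topo, 13)
  expect_identical(a, b)
  topo_big <- make_topography(sim_config(grid_dims = c(10L, 10L, 10L)))
  expect_error(simulate_tmaps(cfg, NULL, topo_big, 13), "grid")
})

test_that("null enrichment coupling leaves EE uncorrelated with preservation", {
  rs <- replicate(50, {
    s <- sample.int(1e7, 1)
    cfg <- sim_config(n_old = 400L, effect_beta = 0)
    p <- simulate_participants(cfg, s)
    r <- score_leq(generate_leq_responses(p, s + 1L))
    cor(r$ee_score, r$preservation_z)
  })
  expect_lt(mean(abs(rs)), 0.1)
  expect_lt(abs(mean(rs)), 0.03)
})

test_that("latent coupling reaches the target correlation at large n", {
  cfg <- sim_config(n_old = 2000L, effect_beta = 0.5, wire = "preservation",
                    scd_shift = 0)
  p <- simulate_participants(cfg, 21)
  expect_equal(cor(p$ee_propensity_z, p$preservation_z), 0.5, tolerance = 0.05)
  r <- score_leq(generate_leq_responses(p, 22))
  expect_equal(cor(r$ee_score, r$preservation_z), 0.5, tolerance = 0.05)
})

test_that("selective wiring direction is invisible to the FADE score", {
  cfg <- sim_config(wire = "same_novelty")
  topo <- make_topography(cfg)
  d <- fadesame:::wiring_direction(topo)
  vpos <- as.vector(topo$novelty_pos)
  outside <- as.vector(topo$mask) & !vpos
  expect_equal(sum(d[outside]), 0, tolerance = 1e-12)
  expect_true(all(d[vpos] == 0))
  expect_true(all(d[!as.vector(topo$mask)] == 0))
})

test_that("MCAR injection hits the expected number of participants blindly", {
  prof <- random_profiles(372, seed = 31)
  out0 <- inject_mcar(prof, 0, seed = 32)
  expect_false(anyNA(out0))

  out <- inject_mcar(prof, 30 / 372, seed = 33)
  mask <- attr(out, "mcar_mask")
  n_inc <- sum(rowSums(mask) > 0)
  expect_gt(n_inc, 15)
  expect_lt(n_inc, 50)
  expect_true(all(rowSums(mask)[rowSums(mask) > 0] %in% 1:12))
  expect_error(inject_mcar(prof, 1.2, 1), "0, 1")
})
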