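test_that("FADE score matches hand-computed toy values", {
  ref <- toy_reference(vpos = c(TRUE, TRUE, FALSE),
                       vneg = rep(FALSE, 3),
                       m = c(0, 0, 0), s = c(1, 1, 1))
  expect_equal(fade_score(c(2, 4, 1), ref), 1 - 3)  # = -2
  expect_equal(fade_score(c(7, 7, 7), ref), 0)      # constant map
  # amplifying activation confined to V+ strictly decreases FADE
  k <- c(1, 2, 5)
  fades <- sapply(k, function(kk) fade_score(c(2 * kk, 4 * kk, 1), ref))
  expect_true(all(diff(fades) < 0))
})

test_that("SAME score matches hand-computed toy values and sign convention", {
  ref <- toy_reference(vpos = c(TRUE, FALSE), vneg = c(FALSE, TRUE),
                       m = c(3, -2), s = c(1, 2))
  expect_equal(same_score(c(2, -1), ref), (2 - 3) / 1 + (-2 - (-1)) / 2)  # -1.5
  expect_equal(same_score(c(4, -3), ref), 1 + 0.5)                       # +1.5
  expect_equal(same_score(c(3, -2), ref), 0)  # young mean map
  expect_error(
    same_score(c(1, 1), toy_reference(c(TRUE, FALSE), c(FALSE, TRUE),
                                      m = c(3, -2), s = c(0, 2))),
    "voxel"
  )
})

test_that("degenerate reference voxel sets are rejected", {
  ref <- toy_reference(vpos = c(FALSE, FALSE), vneg = c(FALSE, TRUE),
                       m = c(0, 0), s = c(1, 1))
  expect_error(fade_score(c(1, 2), ref), "positive")
  expect_error(same_score(c(1, 2), ref), "voxel set")
  full <- toy_reference(vpos = c(TRUE, TRUE), vneg = c(FALSE, FALSE),
                        m = c(0, 0), s = c(1, 1))
  expect_error(fade_score(c(1, 2), full), "outside")
})

test_that("reference derivation recovers a planted topography", {
  cfg <- small_config(noise_sd_map = 0.05)
  topo <- make_topography(cfg)
  young <- simulate_tmaps(cfg, NULL, topo, 61)
  ref <- derive_reference(young)
  # every planted voxel is recovered; the uncorrected threshold admits at
  # most a few false-positive voxels among the ~200 null tests
  for (pair in list(list(ref$contrasts$novelty$vpos, topo$novelty_pos),
                    list(ref$contrasts$novelty$vneg, topo$novelty_neg),
                    list(ref$contrasts$memory$vpos, topo$memory_pos))) {
    got <- pair[[1]]
    planted <- as.vector(pair[[2]])
    expect_true(all(got[planted]))
    expect_lte(sum(got & !planted), 3L)
  }

  # loosening the threshold can only grow the voxel sets
  loose <- derive_reference(simulate_tmaps(sim_config(), NULL,
                                           make_topography(sim_config()), 62),
                            threshold = 0.05)
  strict <- derive_reference(simulate_tmaps(sim_config(), NULL,
                                            make_topography(sim_config()), 62),
                             threshold = 0.001)
  expect_true(all(strict$contrasts$novelty$vpos <= loose$contrasts$novelty$vpos))
  expect_true(all(strict$contrasts$novelty$vneg <= loose$contrasts$novelty$vneg))

  # pure function: identical inputs give identical models
  expect_identical(derive_reference(young), ref)
})

test_that("null young maps select roughly the nominal tail fraction", {
  cfg <- sim_config(amp_novelty = c(0, 0), amp_memory = c(0, 0))
  young <- simulate_tmaps(cfg, NULL, make_topography(cfg), 63)
  ref <- suppressWarnings(derive_reference(young, threshold = 0.01))
  frac <- (sum(ref$contrasts$novelty$vpos) + sum(ref$contrasts$novelty$vneg)) /
    sum(ref$mask)
  expect_equal(frac, 0.02, tolerance = 0.5)  # two one-sided 1% tails
})

test_that("cohort scoring is vectorised, joins records and tracks preservation", {
  cfg <- sim_config(n_old = 200L, noise_sd_map = 0.3)
  topo <- make_topography(cfg)
  pts <- simulate_participants(cfg, 64)
  ref <- derive_reference(simulate_tmaps(cfg, NULL, topo, 65))
  maps <- simulate_tmaps(cfg, pts, topo, 66)
  sc <- score_cohort(maps, ref, pts)
  expect_identical(nrow(sc), 200L)
  expect_true(all(is.finite(sc$same_novelty)))

  # matches the single-map scorers
  i <- 17
  expect_equal(sc$fade_novelty[i],
               fade_score(as_contrast_map(maps, sc$id[i], "novelty"),
                          ref, "novelty"))
  expect_equal(sc$same_memory[i],
               same_score(as_contrast_map(maps, sc$id[i], "memory"),
                          ref, "memory"))

  expect_gt(cor(sc$preservation_z, sc$same_novelty, method = "spearman"), 0.5)

  # a participant whose map equals the young mean scores SAME = 0
  maps$tmaps$novelty[1, ] <- ref$contrasts$novelty$m
  expect_equal(score_cohort(maps, ref)$same_novelty[1], 0, tolerance = 1e-12)
})

test_that("constant shifts leave FADE unchanged but move SAME", {
  ref <- toy_reference(vpos = c(TRUE, FALSE, FALSE), vneg = c(FALSE, TRUE, FALSE),
                       m = c(2, -1, 0), s = c(1, 2, 1))
  t0 <- c(1.5, -0.5, 0.2)
  expect_equal(fade_score(t0 + 3, ref), fade_score(t0, ref), tolerance = 1e-12)
  shift <- same_score(t0 + 3, ref) - same_score(t0, ref)
  expect_equal(shift, 3 / 1 - 3 / 2, tolerance = 1e-12)
})
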