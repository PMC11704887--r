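test_that("design matrix handles degenerate sessions as specified", {
  cfg <- sim_config()
  spec <- design_spec(cfg)
  ses <- simulate_session(cfg, list(id = "p", memory_ability = 0), seed = 41)

  expect_identical(build_design_matrix(ses, spec),
                   build_design_matrix(ses, spec))

  flat <- ses
  flat$trials$confidence[flat$trials$trial_type == "novel"] <- 3L
  expect_warning(x <- build_design_matrix(flat, spec), "modulator")
  expect_false("modulator" %in% colnames(x))

  no_master <- ses
  no_master$trials <- no_master$trials[no_master$trials$trial_type == "novel", ]
  expect_error(build_design_matrix(no_master, spec), "master")
})

test_that("noiseless BOLD recovers the embedded betas and scales linearly", {
  cfg <- small_config(noise_sd_bold = 0)
  topo <- make_topography(cfg)
  ses <- simulate_session(cfg, list(id = "p", memory_ability = 0.5), seed = 42)
  sim <- simulate_bold(ses, topo, cfg, seed = 43)
  fit <- fit_first_level(sim)
  expect_lt(max(abs(fit$betas - sim$true_betas)), 1e-8)

  cfg2 <- small_config(noise_sd_bold = 0,
                       amp_novelty = 2 * cfg$amp_novelty,
                       amp_memory = cfg$amp_memory)
  sim2 <- simulate_bold(ses, make_topography(cfg2), cfg2, seed = 43)
  fit2 <- fit_first_level(sim2)
  expect_equal(fit2$betas["novel", ], 2 * fit$betas["novel", ],
               tolerance = 1e-8)
})

test_that("memory t-map is invariant to adding a constant to confidences", {
  cfg <- small_config(noise_sd_bold = 1)
  topo <- make_topography(cfg)
  ses <- simulate_session(cfg, list(id = "p", memory_ability = 0.2), seed = 44)
  sim <- simulate_bold(ses, topo, cfg, seed = 45)
  fit <- fit_first_level(sim)

  shifted <- ses
  i <- shifted$trials$trial_type == "novel"
  # constant offset is removed by mean-centering of the modulator
  shifted$trials$confidence[i] <- shifted$trials$confidence[i] - 1L
  x2 <- build_design_matrix(shifted, design_spec(cfg))
  fit2 <- fit_first_level(sim$bold, x2, cfg$grid_dims)
  expect_equal(fit2$tmaps$memory, fit$tmaps$memory, tolerance = 1e-10)
})

test_that("fast and slow paths agree on the topography sign pattern", {
  cfg <- small_config(noise_sd_bold = 0.2, noise_sd_map = 0.2, shrink_c0 = 50)
  topo <- make_topography(cfg)
  pts <- simulate_participants(cfg, 46)[1, ]
  fast <- simulate_tmaps(cfg, pts, topo, 47)
  ses <- simulate_session(cfg, list(id = pts$id, memory_ability = 0), seed = 48)
  slow <- fit_first_level(simulate_bold(ses, topo, cfg, seed = 49))
  for (con in c("novelty", "memory")) {
    designated <- as.vector(topo[[con]]) != 0
    truth_sign <- sign(as.vector(topo[[con]])[designated])
    agree_fast <- mean(sign(fast$tmaps[[con]][1, designated]) == truth_sign)
    agree_slow <- mean(sign(as.vector(slow$tmaps[[con]])[designated]) == truth_sign)
    expect_gte(agree_fast, 0.95)
    expect_gte(agree_slow, 0.95)
  }
})

test_that("non-finite data and length mismatches are rejected", {
  cfg <- small_config()
  ses <- simulate_session(cfg, list(id = "p", memory_ability = 0), seed = 50)
  x <- build_design_matrix(ses, design_spec(cfg))
  y <- matrix(rnorm(nrow(x) * 4), nrow(x))
  y[3, 2] <- NA
  expect_error(fit_first_level(y, x), "finite")
  expect_error(fit_first_level(matrix(0, nrow(x) - 1, 4), x), "length")
})
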