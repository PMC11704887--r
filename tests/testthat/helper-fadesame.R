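# Shared fixtures built in code.

leq_cols <- paste0("leq_", rep(leq_activities, 2), "_",
                   rep(c("early", "mid"), each = 6))

# A small, fast configuration for unit tests (8^3 grid, small cohorts).
small_config <- function(...) {
  args <- modifyList(list(grid_dims = c(8L, 8L, 8L), n_young = 30L,
                          n_old = 60L), list(...))
  do.call(sim_config, args)
}

# Random LEQ profile matrix (integer codes 0-5), n rows x 12 items.
random_profiles <- function(n, seed) {
  set.seed(seed)
  m <- matrix(sample(0:5, n * 12L, replace = TRUE), n, 12L,
              dimnames = list(NULL, leq_cols))
  tibble::as_tibble(m)
}

# Missing-at-random injector for power checks: the probability that the
# first six items go missing increases steeply with the (observed)
# twelfth item's value.
inject_mar <- function(data, seed) {
  set.seed(seed)
  driver <- data[[leq_cols[12]]]
  p_miss <- plogis(-2.5 + 1.6 * as.numeric(scale(driver)))
  hit <- runif(nrow(data)) < p_miss
  for (cl in leq_cols[1:6]) {
    v <- data[[cl]]
    v[hit] <- NA
    data[[cl]] <- v
  }
  data
}

# Tiny single-contrast reference on an n-voxel "grid" (vectors, no 3-D
# structure needed) for hand-computed score checks.
toy_reference <- function(vpos, vneg, m, s, mask = rep(TRUE, length(m))) {
  reference_model(
    list(novelty = list(vpos = vpos, vneg = vneg, m = m, s = s)),
    mask = mask
  )
}
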