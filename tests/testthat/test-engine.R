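test_that("initialization places identical founders in a single patch", {
  st <- initialize_state(sim_config(n_steps = 1))
  expect_equal(nrow(st$patches[[1]]$residents), 100)
  expect_true(all(st$patches[[1]]$residents$age == 1L))
  expect_true(all(st$patches[[1]]$residents$D == 0))
  expect_true(all(st$patches[[1]]$residents$I == 0))
  for (p in 2:10) expect_equal(nrow(st$patches[[p]]$residents), 0)
  # founders sit exactly at the ~12% informed floor
  cfg <- sim_config(n_steps = 1)
  juv <- new_individuals(1, age = 0L)
  patch <- new_patch(1, 100, juv, M = 0L)
  pr <- dispersal_probabilities(juv[1, ], patch, cfg)
  expect_equal(pr$d_D, logistic(-2))
  # capacity below 100 caps the founding cohort
  st2 <- initialize_state(sim_config(K = 50, n_steps = 1))
  expect_equal(nrow(st2$patches[[1]]$residents), 50)
})

test_that("environmental catastrophes hit patches at the configured rate", {
  st <- initialize_state(sim_config(n_steps = 1))
  expect_identical(apply_env_stochasticity(st, sim_config(n_steps = 1)),
                   st)  # probability 0: untouched
  cfg1 <- sim_config(env_stoch_prob = 1, n_steps = 1)
  st1 <- apply_env_stochasticity(initialize_state(cfg1), cfg1)
  expect_equal(metapop_size(st1$patches), 0)

  set.seed(11)
  cfg <- sim_config(env_stoch_prob = 0.05, n_patches = 100L, K = 2L,
                    n_steps = 1)
  hits <- 0
  trials <- 100
  for (i in seq_len(trials)) {
    st <- initialize_state(cfg)
    for (p in seq_along(st$patches))
      st$patches[[p]]$residents <- new_individuals(1, age = 1L)
    out <- apply_env_stochasticity(st, cfg)
    hits <- hits + sum(vapply(out$patches,
                              function(p) nrow(p$residents) == 0,
                              logical(1)))
  }
  expect_true(within_3se(hits / (trials * 100), 0.05, trials * 100))
})

test_that("frozen dynamics: immortal, sterile, sedentary populations persist", {
  cfg <- sim_config(variant = "U_only", d_U = 0, n_patches = 4L, K = 120L,
                    life_history = life_history(s0 = 1, s1 = 1, s2 = 1,
                                                f1 = 0, f2 = 0),
                    n_steps = 5)
  r <- run(cfg, seed = 3, record_every = 1)
  expect_true(all(r$trajectory$total_N == 100))
  expect_false(r$summary$extinct)
  expect_true(all(r$final_state$individuals$age == 2L))
})

test_that("an empty metapopulation is terminal", {
  cfg <- sim_config(env_stoch_prob = 1, n_patches = 3L, K = 20L,
                    n_steps = 50)
  r <- run(cfg, seed = 5)
  expect_true(r$summary$extinct)
  expect_equal(r$summary$persistence_time, 1)
  expect_true(is.na(r$summary$final_mean_D))
})

test_that("expected survivor counts match a Leslie-type projection", {
  # matrix-projection oracle on expectations: E[survivors] = s . n
  set.seed(21)
  lh <- life_history()
  comp <- c(juv = 40L, sub = 30L, ad = 30L)
  expected <- 40 * lh$s0 + 30 * lh$s1 + 30 * lh$s2    # 33.5
  vr <- 40 * lh$s0 * (1 - lh$s0) + 30 * lh$s1 * (1 - lh$s1) +
    30 * lh$s2 * (1 - lh$s2)
  reps <- 2000
  counts <- replicate(reps, {
    p <- new_patch(1, 200, new_individuals(100, age = rep(c(0L, 1L, 2L),
                                                          comp)))
    nrow(survive(p, lh)$residents)
  })
  expect_lt(abs(mean(counts) - expected), 3 * sqrt(vr / reps))
})

test_that("n_steps = 0 yields only the initial census", {
  r <- run(sim_config(n_steps = 0), seed = 1)
  expect_equal(nrow(r$trajectory), 1)
  expect_equal(r$trajectory$t, 0)
  expect_false(r$summary$extinct)
})

test_that("identical config and seed give identical trajectories", {
  cfg <- tiny_cfg(n_steps = 300, env_stoch_prob = 0.02)
  a <- run(cfg, seed = 99)
  b <- run(cfg, seed = 99)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$final_state, b$final_state)
  c2 <- run(cfg, seed = 100)
  expect_false(identical(a$trajectory, c2$trajectory))
})

test_that("compiled engine reproduces the reference step semantics exactly", {
  configs <- list(
    tiny_cfg(variant = "D_and_I", n_steps = 60, dispersal_cost = 0.05,
             env_stoch_prob = 0.05),
    tiny_cfg(variant = "I_only", n_steps = 60,
             immigrant_signal = "presence"),
    tiny_cfg(variant = "U_only", n_steps = 40, evolvable_U = TRUE,
             env_stoch_prob = 0.1, env_stoch_severity = 0.5),
    tiny_cfg(variant = "D_only", n_steps = 40, K = 15L))
  for (cfg in configs) {
    a <- run(cfg, seed = 17, record_every = 1, collect_events = TRUE,
             engine = "compiled")
    b <- run(cfg, seed = 17, record_every = 1, collect_events = TRUE,
             engine = "reference")
    expect_equal(a$trajectory, b$trajectory, tolerance = 1e-12,
                 info = cfg$variant)
    expect_equal(a$final_state$individuals, b$final_state$individuals,
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(as.integer(a$final_state$M),
                 as.integer(b$final_state$M))
    expect_equal(a$events, b$events, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("population never exceeds n_patches * K at any census", {
  cfg <- tiny_cfg(n_steps = 400, env_stoch_prob = 0.05)
  r <- run(cfg, seed = 1, record_every = 1)
  expect_true(all(r$trajectory$total_N <= cfg$n_patches * cfg$K))
})

test_that("with only baseline dispersal the juvenile emigration rate is d_U", {
  cfg <- sim_config(variant = "U_only", n_patches = 6L, K = 80L,
                    n_steps = 400)
  r <- run(cfg, seed = 8, record_every = 1)
  tr <- r$trajectory[r$trajectory$t > 20, ]  # past colonization burn-in
  n_juv <- sum(tr$n_juveniles)
  expect_true(within_3se(sum(tr$n_dispersed) / n_juv, 0.1, n_juv))
  # and all of it is attributed to the uninformed strategy
  expect_true(all(tr$rate_density == 0 & tr$rate_immigrant == 0))
})

test_that("trajectory thinning records step 0, multiples, and the end", {
  r <- run(tiny_cfg(n_steps = 250), seed = 2, record_every = 100)
  expect_true(all(c(0, 100, 200, 250) %in% r$trajectory$t))
  expect_lte(nrow(r$trajectory), 5)
})
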