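test_that("behaviour functions are the stated linear forms", {
  expect_equal(behavior_density(D = 2, n = 100, K = 100), 0)
  expect_equal(behavior_density(D = 0, n = 50, K = 100), -2)
  expect_equal(behavior_density(D = 4, n = 75, K = 100), 1)
  expect_error(behavior_density(D = 1, n = 10, K = 0), "K")
  expect_equal(behavior_immigrant(I = 1, M = 2), 0)
  expect_equal(behavior_immigrant(I = 3, M = 1, signal = "presence"), 1)
  # presence mode saturates: any M > 0 is the same cue
  expect_equal(behavior_immigrant(I = 3, M = 7, signal = "presence"),
               behavior_immigrant(I = 3, M = 1, signal = "presence"))
})

test_that("the logistic transform is exact, symmetric and overflow-safe", {
  expect_equal(logistic(0), 0.5)
  expect_equal(logistic(-2), 1 / (1 + exp(2)))
  expect_equal(round(logistic(-2), 2), 0.12)  # the 12% floor
  x <- seq(-5, 5, by = 0.25)
  expect_equal(logistic(x) + logistic(-x), rep(1, length(x)))
  expect_equal(logistic(1000), 1)
  expect_equal(logistic(-1000), 0)
  expect_false(any(is.nan(logistic(c(-1e308, 1e308)))))
})

test_that("per-channel probabilities honour the variant and the M > 0 gate", {
  mk <- function(variant, D = 2, I = 1, n = 100, M = 2, ...) {
    cfg <- sim_config(variant = variant, n_steps = 1, ...)
    p <- new_patch(1, 100, new_individuals(n, age = 0L, D = D, I = I),
                   M = M)
    dispersal_probabilities(p$residents[1, ], p, cfg)
  }
  expect_equal(mk("U_only"), list(d_U = 0.1, d_D = 0, d_I = 0))
  expect_equal(mk("D_and_I"), list(d_U = 0.1, d_D = 0.5, d_I = 0.5))
  # no immigrants: the immigrant channel is off no matter how large I is
  expect_equal(mk("D_and_I", I = 50, M = 0)$d_I, 0)
  expect_equal(mk("I_only", I = 50, M = 0)$d_I, 0)
  # evolvable U reads the heritable logit-scale trait
  cfg <- sim_config(variant = "U_only", evolvable_U = TRUE, n_steps = 1)
  p <- new_patch(1, 100, new_individuals(1, age = 0L, U = 0))
  expect_equal(dispersal_probabilities(p$residents[1, ], p, cfg)$d_U, 0.5)
  # non-juveniles never disperse
  p2 <- new_patch(1, 100, new_individuals(1, age = 1L))
  expect_error(dispersal_probabilities(p2$residents[1, ], p2,
                                       sim_config(n_steps = 1)),
               "juvenile")
})

test_that("informed channels are monotone in their cue", {
  dD <- logistic(behavior_density(2, 0:100, 100))
  expect_true(all(diff(dD) > 0))
  dI <- logistic(behavior_immigrant(1.5, 0:20))
  expect_true(all(diff(dI) > 0))
  # floor: at zero cue the density channel sits exactly at logistic(-2)
  expect_equal(dD[1], logistic(-2))
})

test_that("decide() follows the two-stage rule with capped informed sum", {
  for (i in 1:50) {
    expect_false(decide(list(d_U = 0, d_D = 0, d_I = 0))$disperse)
    d <- decide(list(d_U = 0, d_D = 0.7, d_I = 0.6))  # sum 1.3 -> certain
    expect_true(d$disperse)
    expect_true(d$strategy %in% c("density", "immigrant"))
    expect_identical(decide(list(d_U = 1, d_D = 0, d_I = 0))$strategy,
                     "uninformed")
  }
})

test_that("decide() outcome frequencies match the exact two-stage law", {
  set.seed(55)
  n <- 100000
  probs <- list(d_U = 0.1, d_D = 0.6, d_I = 0.2)
  out <- vapply(seq_len(n), function(i) decide(probs)$strategy,
                character(1))
  # closed-form enumeration of the two-stage Bernoulli process
  s <- probs$d_D + probs$d_I
  p_uninf <- probs$d_U
  p_inf <- (1 - probs$d_U) * min(1, s)
  expected <- c(uninformed = p_uninf,
                density = p_inf * probs$d_D / s,
                immigrant = p_inf * probs$d_I / s,
                none = 1 - p_uninf - p_inf)
  for (k in names(expected))
    expect_true(within_3se(mean(out == k), expected[[k]], n),
                info = paste("strategy", k))
  # conditional attribution ratio: P(density | informed) = 0.6 / 0.8
  informed <- out[out %in% c("density", "immigrant")]
  expect_true(within_3se(mean(informed == "density"), 0.75,
                         length(informed)))
})

test_that("dispersal phase conserves individuals and counts immigrants", {
  set.seed(77)
  cfg <- tiny_cfg(variant = "D_and_I")
  patches <- list(
    new_patch(1, 30, new_individuals(25, age = 0L, D = 3, I = 1)),
    new_patch(2, 30, new_individuals(28, age = rep(0:2, len = 28))),
    new_patch(3, 30, new_individuals(5, age = 1L)),
    new_patch(4, 30))
  before <- metapop_size(patches)
  out <- dispersal_phase(patches, cfg)
  expect_equal(metapop_size(out$patches), before)
  # each destination's M equals the number of events that targeted it
  for (p in 1:4)
    expect_equal(out$patches[[p]]$M, sum(out$events$dest == p))
  expect_true(all(out$events$origin != out$events$dest))
  # only juveniles moved, and movers carry their strategy
  moved <- all_individuals(out$patches)
  moved <- moved[moved$dispersed, ]
  expect_true(all(moved$age == 0L))
  expect_true(all(moved$strategy != "none"))
  # non-movers carry none
  stay <- all_individuals(out$patches)
  stay <- stay[!stay$dispersed, ]
  expect_true(all(stay$strategy == "none"))
})

test_that("a lone certain disperser always leaves and is counted on arrival", {
  cfg <- tiny_cfg(variant = "U_only", d_U = 1, n_patches = 3L)
  for (i in 1:25) {
    patches <- list(new_patch(1, 30, new_individuals(1, age = 0L)),
                    new_patch(2, 30), new_patch(3, 30))
    out <- dispersal_phase(patches, cfg)
    expect_equal(nrow(out$events), 1)
    expect_equal(out$events$origin, 1)
    expect_true(out$events$dest %in% c(2, 3))
    expect_equal(out$patches[[out$events$dest]]$M, 1L)
    expect_equal(nrow(out$patches[[1]]$residents), 0)
  }
})

test_that("immigrant-only dispersal cannot start without baseline dispersal", {
  # nobody has dispersed yet, so M = 0 everywhere; with d_U = 0 the
  # immigrant channel can never fire
  cfg <- suppressWarnings(tiny_cfg(variant = "I_only", d_U = 0))
  patches <- list(new_patch(1, 30, new_individuals(25, age = 0L, I = 10)),
                  new_patch(2, 30, new_individuals(25, age = 0L, I = 10)),
                  new_patch(3, 30), new_patch(4, 30))
  out <- dispersal_phase(patches, cfg)
  expect_equal(nrow(out$events), 0)
})

test_that("degenerate landscapes are handled", {
  cfg <- tiny_cfg()
  out <- dispersal_phase(list(new_patch(1, 30), new_patch(2, 30)), cfg)
  expect_equal(nrow(out$events), 0)  # no juveniles: empty log
  cfg1 <- sim_config(n_steps = 1)
  cfg1$n_patches <- 1L  # cannot be built via the validator
  expect_warning(
    dispersal_phase(list(new_patch(1, 30, new_individuals(3))), cfg1),
    "single patch")
})
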