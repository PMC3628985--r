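#' Initialize the metapopulation
#'
#' The simulation starts from 100 subadults (or `K` if `K < 100`) carrying
#' an identical genotype, all in patch 1; every other patch is empty. The
#' initial coefficients are `D = I = 0`, which puts both informed channels
#' exactly at the `plogis(intercept)` floor (about 12% with the default
#' intercept of -2), and `U = qlogis(d_U)` so the evolvable-U variant starts
#' at the same realized uninformed rate as the fixed one.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `sim_state`: a list with `t` (time step),
#'   `patches` (list of [new_patch()]), `pending` (origin/destination
#'   patches of last step's dispersers, awaiting the benefit census) and
#'   `extinct`.
#' @examples
#' st <- initialize_state(sim_config(n_steps = 10))
#' nrow(st$patches[[1]]$residents)  # 100
#' @export
initialize_state <- function(cfg) {
  n0 <- min(cfg$K, 100L)
  founders <- new_individuals(n0, age = 1L, D = 0, I = 0,
                              U = stats::qlogis(cfg$d_U))
  patches <- lapply(seq_len(cfg$n_patches), function(p)
    new_patch(p, cfg$K,
              if (p == 1L) founders else new_individuals(0)))
  structure(list(t = 0, patches = patches,
                 pending = data.frame(origin = integer(),
                                      dest = integer()),
                 extinct = FALSE),
            class = "sim_state")
}

#' Environmental stochasticity
#'
#' Each patch is independently hit by a catastrophe with probability
#' `env_stoch_prob` per time step. A hit kills all residents when
#' `env_stoch_severity = 1` (the default), otherwise each resident dies
#' independently with probability `env_stoch_severity`.
#'
#' @param state A `sim_state`.
#' @param cfg A [sim_config()].
#' @return The state after catastrophes.
#' @examples
#' cfg <- sim_config(env_stoch_prob = 1, n_steps = 1)
#' st <- apply_env_stochasticity(initialize_state(cfg), cfg)
#' sum(sapply(st$patches, function(p) nrow(p$residents)))  # 0
#' @export
apply_env_stochasticity <- function(state, cfg) {
  if (cfg$env_stoch_prob <= 0) return(state)
  for (p in seq_along(state$patches)) {
    if (stats::runif(1L) < cfg$env_stoch_prob) {
      res <- state$patches[[p]]$residents
      if (cfg$env_stoch_severity >= 1) {
        state$patches[[p]]$residents <- res[integer(0), , drop = FALSE]
      } else if (nrow(res)) {
        u <- stats::runif(nrow(res))
        state$patches[[p]]$residents <-
          res[u >= cfg$env_stoch_severity, , drop = FALSE]
      }
      rownames(state$patches[[p]]$residents) <- NULL
    }
  }
  state
}

# Whole-metapopulation census used for trajectory records.
census <- function(state) {
  all_res <- do.call(rbind, lapply(state$patches, `[[`, "residents"))
  N <- nrow(all_res)
  list(total_N = N,
       occupied_patches = sum(vapply(state$patches,
                                     function(p) nrow(p$residents) > 0L,
                                     logical(1))),
       mean_D = if (N) mean(all_res$D) else NA_real_,
       mean_I = if (N) mean(all_res$I) else NA_real_,
       mean_U = if (N) mean(all_res$U) else NA_real_)
}

#' Advance the simulation by one time step
#'
#' Applies, in order: environmental stochasticity (if configured), survival
#' in every patch, the dispersal-benefit census for the previous step's
#' dispersers (patch densities right before reproduction), reproduction
#' with mutation in every patch, and the metapopulation-wide dispersal
#' phase; then increments time. This pure-R composition of the module
#' operations defines the step semantics; [run()]'s compiled engine
#' reproduces it draw for draw on the same RNG stream.
#'
#' @param state A `sim_state`.
#' @param cfg A [sim_config()].
#' @return The advanced state, with step bookkeeping in fields
#'   `last_events` (dispersal events of this step), `last_counts` (events
#'   by strategy), `last_n_juveniles`, `last_benefit` (mean
#'   origin/destination density ratio of the previous step's dispersers)
#'   and `last_benefit_excluded` (dispersers whose destination was empty at
#'   the census).
#' @examples
#' cfg <- sim_config(variant = "D_only", n_patches = 3, K = 30, n_steps = 5)
#' set.seed(1)
#' st <- sim_step(initialize_state(cfg), cfg)
#' st$t
#' @export
sim_step <- function(state, cfg) {
  lh <- cfg$life_history
  state <- apply_env_stochasticity(state, cfg)
  for (p in seq_along(state$patches))
    state$patches[[p]] <- survive(state$patches[[p]], lh,
                                  cfg$dispersal_cost)

  # benefit of last step's dispersers, at the pre-reproduction census
  n_now <- vapply(state$patches, function(p) nrow(p$residents), integer(1))
  benefit <- NA_real_
  excluded <- 0L
  if (nrow(state$pending)) {
    dn <- n_now[state$pending$dest]
    ok <- dn > 0L
    excluded <- sum(!ok)
    if (any(ok)) benefit <- mean(n_now[state$pending$origin[ok]] / dn[ok])
  }
  state$pending <- data.frame(origin = integer(), dest = integer())

  loci <- c("D", "I", if (cfg$evolvable_U) "U")
  for (p in seq_along(state$patches)) {
    patch <- reproduce(state$patches[[p]], lh)
    n_off <- attr(patch, "n_offspring")
    if (n_off > 0L && cfg$mutation_prob > 0) {
      idx <- seq.int(nrow(patch$residents) - n_off + 1L,
                     nrow(patch$residents))
      patch$residents[idx, ] <- mutate(patch$residents[idx, , drop = FALSE],
                                       cfg$mutation_prob, cfg$mutation_sd,
                                       loci)
    }
    state$patches[[p]] <- patch
  }

  n_juv <- sum(vapply(state$patches,
                      function(p) sum(p$residents$age == 0L), integer(1)))
  ph <- dispersal_phase(state$patches, cfg)
  state$patches <- ph$patches
  events <- ph$events

  state$t <- state$t + 1
  state$pending <- events[, c("origin", "dest"), drop = FALSE]
  state$last_events <- events
  state$last_counts <- c(
    uninformed = sum(events$strategy == "uninformed"),
    density = sum(events$strategy == "density"),
    immigrant = sum(events$strategy == "immigrant"))
  state$last_n_juveniles <- n_juv
  state$last_benefit <- benefit
  state$last_benefit_excluded <- excluded
  state$extinct <- sum(vapply(state$patches,
                              function(p) nrow(p$residents),
                              integer(1))) == 0L
  state
}

.traj_cols <- c("t", "total_N", "occupied_patches", "mean_D", "mean_I",
                "mean_U", "rate_uninformed", "rate_density",
                "rate_immigrant", "n_juveniles", "n_dispersed",
                "mean_benefit", "n_benefit_excluded")

.record_row <- function(state, counts = c(uninformed = 0L, density = 0L,
                                          immigrant = 0L),
                        n_juv = 0L, benefit = NA_real_, excluded = 0L) {
  cs <- census(state)
  N <- cs$total_N
  rate <- function(k) if (N > 0L) k / N else NA_real_
  c(t = state$t, total_N = N, occupied_patches = cs$occupied_patches,
    mean_D = cs$mean_D, mean_I = cs$mean_I, mean_U = cs$mean_U,
    rate_uninformed = rate(counts[["uninformed"]]),
    rate_density = rate(counts[["density"]]),
    rate_immigrant = rate(counts[["immigrant"]]),
    n_juveniles = n_juv, n_dispersed = sum(counts),
    mean_benefit = benefit, n_benefit_excluded = excluded)
}

run_reference <- function(cfg, record_every = 100L, collect_events = FALSE) {
  state <- initialize_state(cfg)
  rows <- list(.record_row(state))
  events <- if (collect_events) list() else NULL
  while (state$t < cfg$n_steps && !state$extinct) {
    state <- sim_step(state, cfg)
    if (collect_events && nrow(state$last_events)) {
      ev <- state$last_events
      ev <- cbind(t = state$t, ev)
      events[[length(events) + 1L]] <- ev
    }
    if (state$t %% record_every == 0 || state$t == cfg$n_steps ||
        state$extinct)
      rows[[length(rows) + 1L]] <- .record_row(
        state, state$last_counts, state$last_n_juveniles,
        state$last_benefit, state$last_benefit_excluded)
  }
  trajectory <- as.data.frame(do.call(rbind, rows))
  names(trajectory) <- .traj_cols
  all_res <- do.call(rbind, lapply(state$patches, `[[`, "residents"))
  final_state <- list(
    individuals = cbind(all_res,
                        patch = rep.int(seq_along(state$patches),
                                        vapply(state$patches,
                                               function(p) nrow(p$residents),
                                               integer(1)))),
    M = vapply(state$patches, `[[`, integer(1), "M"),
    t = state$t, extinct = state$extinct)
  list(trajectory = trajectory,
       events = if (collect_events) {
         if (length(events)) do.call(rbind, events) else
           data.frame(t = numeric(), origin = integer(), dest = integer(),
                      strategy = character(), origin_n = integer(),
                      dest_n = integer(), stringsAsFactors = FALSE)
       } else NULL,
       final_state = final_state)
}

run_compiled <- function(cfg, record_every = 100L, collect_events = FALSE) {
  lh <- cfg$life_history
  packed <- list(
    variant = match(cfg$variant, .variants) - 1L,
    n_patches = cfg$n_patches, K = cfg$K,
    s0 = lh$s0, s1 = lh$s1, s2 = lh$s2, f1 = lh$f1, f2 = lh$f2,
    d_U = cfg$d_U, evolvable_U = cfg$evolvable_U,
    dispersal_cost = cfg$dispersal_cost,
    mutation_prob = cfg$mutation_prob, mutation_sd = cfg$mutation_sd,
    intercept = cfg$intercept,
    signal_count = cfg$immigrant_signal == "count",
    env_stoch_prob = cfg$env_stoch_prob,
    env_stoch_severity = cfg$env_stoch_severity,
    n_steps = as.numeric(cfg$n_steps),
    init_U = stats::qlogis(cfg$d_U))
  res <- cpp_run(packed, as.integer(record_every), collect_events)
  trajectory <- as.data.frame(res$trajectory)
  names(trajectory) <- .traj_cols
  fs <- res$final_state
  individuals <- data.frame(age = fs$age, D = fs$D, I = fs$I, U = fs$U,
                            dispersed = fs$dispersed,
                            strategy = c("none", "uninformed", "density",
                                         "immigrant")[fs$strategy + 1L],
                            patch = fs$patch,
                            stringsAsFactors = FALSE)
  events <- NULL
  if (collect_events) {
    ev <- res$events
    events <- data.frame(t = ev$t, origin = ev$origin, dest = ev$dest,
                         strategy = c("uninformed", "density",
                                      "immigrant")[ev$strategy],
                         origin_n = ev$origin_n, dest_n = ev$dest_n,
                         stringsAsFactors = FALSE)
  }
  list(trajectory = trajectory, events = events,
       final_state = list(individuals = individuals, M = fs$M,
                          t = fs$t, extinct = fs$extinct))
}

#' Run one replicate
#'
#' Executes a full simulation: initialization, then `n_steps` time steps
#' (or fewer if the metapopulation goes extinct), recording a thinned
#' trajectory of censuses, realized per-strategy dispersal rates and the
#' dispersal-benefit series, and summarising the replicate (final mean
#' coefficients, extinction, persistence time, final-window realized
#' rates).
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed (default `cfg$seed`); `NULL` leaves the RNG
#'   state untouched.
#' @param record_every Record every this-many steps (plus step 0, the final
#'   step, and the extinction step).
#' @param collect_events If `TRUE`, also return the full dispersal event
#'   log (one row per event; intended for short runs).
#' @param engine `"compiled"` (default, the fast C++ core) or
#'   `"reference"` (the pure-R composition of [sim_step()]; identical
#'   output, for verification and instrumentation).
#' @return An object of class `replicate_result`: a list with `trajectory`
#'   (data frame, one row per recorded step), `summary` (list with
#'   `final_mean_D`, `final_mean_I`, `final_mean_U`, `extinct`,
#'   `persistence_time`, final-window `rate_uninformed`, `rate_density`,
#'   `rate_immigrant`, and `mean_benefit`), `events` (or `NULL`),
#'   `final_state`, `config` and `seed`.
#' @examples
#' cfg <- sim_config(variant = "D_only", n_patches = 4, K = 50,
#'                   n_steps = 200, seed = 7)
#' r <- run(cfg)
#' r$summary$final_mean_D
#' @export
run <- function(cfg, seed = cfg$seed, record_every = 100L,
                collect_events = FALSE,
                engine = c("compiled", "reference")) {
  cfg <- validate_config(cfg)
  engine <- match.arg(engine)
  if (!is.null(seed)) set.seed(seed)
  res <- if (engine == "compiled")
    run_compiled(cfg, record_every, collect_events)
  else run_reference(cfg, record_every, collect_events)

  traj <- res$trajectory
  last <- traj[nrow(traj), ]
  extinct <- res$final_state$extinct
  persistence <- if (extinct) res$final_state$t else cfg$n_steps
  window <- traj[traj$t > 0.9 * persistence, , drop = FALSE]
  if (!nrow(window)) window <- last
  wmean <- function(col) {
    v <- window[[col]]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  summary <- list(
    final_mean_D = if (extinct) NA_real_ else last$mean_D,
    final_mean_I = if (extinct) NA_real_ else last$mean_I,
    final_mean_U = if (extinct) NA_real_ else last$mean_U,
    extinct = extinct,
    persistence_time = persistence,
    rate_uninformed = wmean("rate_uninformed"),
    rate_density = wmean("rate_density"),
    rate_immigrant = wmean("rate_immigrant"),
    mean_benefit = {
      v <- traj$mean_benefit
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    })
  structure(list(trajectory = traj, summary = summary,
                 events = res$events, final_state = res$final_state,
                 config = cfg, seed = seed),
            class = "replicate_result")
}

#' @export
print.replicate_result <- function(x, ...) {
  s <- x$summary
  cat("<replicate_result> variant =", x$config$variant,
      " seed =", if (is.null(x$seed)) "none" else x$seed, "\n")
  cat("  steps:", format(x$final_state$t, scientific = FALSE),
      if (s$extinct) " (extinct)" else "", "\n")
  cat(sprintf("  final means: D = %.4f  I = %.4f  U = %.4f\n",
              s$final_mean_D, s$final_mean_I, s$final_mean_U))
  cat(sprintf("  final-window realized rates: U %.4f  D %.4f  I %.4f\n",
              s$rate_uninformed, s$rate_density, s$rate_immigrant))
  invisible(x)
}
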