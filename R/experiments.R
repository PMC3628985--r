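#' Exact binomial sign test
#'
#' Tests whether final coefficients are positive more often than the 50%
#' expected under pure drift: an exact two-sided binomial test of
#' `n_positive` successes in `n_total` trials against probability 0.5
#' (two-sided p-value as the sum of outcome probabilities no larger than
#' the observed one).
#'
#' @param n_positive Number of replicates with a positive final coefficient.
#' @param n_total Number of replicates tested.
#' @return The two-sided p-value.
#' @examples
#' sign_test(50, 100)   # 1
#' sign_test(97, 100)   # << 0.0001
#' @export
sign_test <- function(n_positive, n_total) {
  if (length(n_total) != 1L || is.na(n_total) || n_total < 1)
    stop("sign_test: n_total must be a positive count", call. = FALSE)
  if (n_positive < 0 || n_positive > n_total)
    stop("sign_test: n_positive must be between 0 and n_total",
         call. = FALSE)
  stats::binom.test(n_positive, n_total, p = 0.5)$p.value
}

#' Classify the evolutionary outcome of one replicate
#'
#' A heritable informed-dispersal strategy is considered to have evolved in
#' a replicate if its population-mean coefficient at the final recorded
#' step is greater than 0 (under drift alone, positive and negative values
#' are equally likely). Only channels expressed by the configured variant
#' are eligible; extinct replicates are classified `"none"`.
#'
#' @param summary A replicate summary (the `summary` element of a [run()]
#'   result, or any list with `final_mean_D`, `final_mean_I`, `extinct`).
#' @param cfg The [sim_config()] the replicate was run under.
#' @return One of `"D_only"`, `"I_only"`, `"both"`, `"none"`.
#' @examples
#' cfg <- sim_config(variant = "D_and_I", n_steps = 1)
#' classify_outcome(list(final_mean_D = 0.5, final_mean_I = -0.1,
#'                       extinct = FALSE), cfg)  # "D_only"
#' @export
classify_outcome <- function(summary, cfg) {
  if (isTRUE(summary$extinct)) return("none")
  d <- has_density_channel(cfg) && !is.na(summary$final_mean_D) &&
    summary$final_mean_D > 0
  i <- has_immigrant_channel(cfg) && !is.na(summary$final_mean_I) &&
    summary$final_mean_I > 0
  if (d && i) "both" else if (d) "D_only" else if (i) "I_only" else "none"
}

#' Monte Carlo batch of replicates
#'
#' Runs `n_replicates` independent replicates of the same configuration,
#' replicate `i` seeded with `base_seed + i - 1`, and collects their
#' summaries, outcome classification and extinction fraction. Replicates
#' are mutually independent, so results do not depend on execution order.
#'
#' @param cfg A [sim_config()].
#' @param n_replicates Number of replicates (default 100).
#' @param base_seed Seed of the first replicate (default `cfg$seed`).
#' @param record_every Trajectory thinning passed to [run()].
#' @return An object of class `batch_result`: a list with `config`,
#'   `n_replicates`, `summaries` (data frame, one row per replicate),
#'   `outcome_counts` (named counts of `D_only`, `I_only`, `both`,
#'   `none`), `extinction_fraction` and `base_seed`.
#' @examples
#' cfg <- sim_config(variant = "D_only", n_patches = 4, K = 40,
#'                   n_steps = 200)
#' b <- monte_carlo(cfg, n_replicates = 3, base_seed = 1)
#' b$outcome_counts
#' @export
monte_carlo <- function(cfg, n_replicates = 100L, base_seed = cfg$seed,
                        record_every = 100L) {
  cfg <- validate_config(cfg)
  if (!is.numeric(n_replicates) || length(n_replicates) != 1L ||
      is.na(n_replicates) || n_replicates < 1)
    stop("monte_carlo: n_replicates must be >= 1", call. = FALSE)
  n_replicates <- as.integer(n_replicates)
  rows <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    seed_i <- as.integer(base_seed + i - 1L)
    r <- run(cfg, seed = seed_i, record_every = record_every)
    s <- r$summary
    rows[[i]] <- data.frame(
      replicate = i, seed = seed_i,
      final_mean_D = s$final_mean_D, final_mean_I = s$final_mean_I,
      final_mean_U = s$final_mean_U, extinct = s$extinct,
      persistence_time = s$persistence_time,
      rate_uninformed = s$rate_uninformed,
      rate_density = s$rate_density,
      rate_immigrant = s$rate_immigrant,
      mean_benefit = s$mean_benefit,
      outcome = classify_outcome(s, cfg),
      stringsAsFactors = FALSE)
  }
  summaries <- do.call(rbind, rows)
  counts <- vapply(c("D_only", "I_only", "both", "none"),
                   function(k) sum(summaries$outcome == k), integer(1))
  structure(list(config = cfg, n_replicates = n_replicates,
                 summaries = summaries, outcome_counts = counts,
                 extinction_fraction = mean(summaries$extinct),
                 base_seed = as.integer(base_seed)),
            class = "batch_result")
}

#' @export
print.batch_result <- function(x, ...) {
  cat("<batch_result>", x$n_replicates, "replicates, variant =",
      x$config$variant, "\n")
  cat("  outcomes:",
      paste(names(x$outcome_counts), x$outcome_counts, sep = " = ",
            collapse = ", "), "\n")
  cat("  extinction fraction:", x$extinction_fraction, "\n")
  invisible(x)
}

#' Per-strategy realized dispersal rates from an event log
#'
#' The realized dispersal rate of a strategy at a time step is the number
#' of individuals that dispersed playing that strategy divided by the total
#' metapopulation size at that step. Steps with zero total size yield
#' missing rates.
#'
#' @param events Event log data frame with columns `t` and `strategy`
#'   (e.g. from `run(..., collect_events = TRUE)$events`).
#' @param totals Data frame with columns `t` and `total_N` (e.g. the
#'   trajectory).
#' @return A data frame with columns `t`, `rate_uninformed`,
#'   `rate_density`, `rate_immigrant`.
#' @examples
#' ev <- data.frame(t = c(1, 1), strategy = c("uninformed", "density"))
#' realized_rates(ev, data.frame(t = 1, total_N = 100))
#' @export
realized_rates <- function(events, totals) {
  out <- totals[, c("t", "total_N")]
  for (s in c("uninformed", "density", "immigrant")) {
    k <- vapply(out$t, function(tt)
      sum(events$strategy == s & events$t == tt), numeric(1))
    out[[paste0("rate_", s)]] <- ifelse(out$total_N > 0, k / out$total_N,
                                        NA_real_)
  }
  out$total_N <- NULL
  out
}

#' Dispersal benefit ratios
#'
#' For each disperser, the benefit of having moved is the ratio of its
#' origin patch density to its destination patch density, both measured at
#' the reproduction census following dispersal. A ratio above 1 means the
#' disperser found a less crowded patch. Dispersers whose destination was
#' empty at the census are excluded (the ratio is undefined) and counted.
#'
#' @param events Event log with columns `t`, `origin`, `dest`.
#' @param densities Data frame of patch censuses at the pre-reproduction
#'   census of the step after dispersal, with columns `t` (the *dispersal*
#'   step the census refers to), `patch`, `n`.
#' @return A list with `per_step` (data frame `t`, `mean_benefit`,
#'   `n_dispersers`, `n_excluded`) and `ratios` (one per usable disperser).
#' @examples
#' ev <- data.frame(t = 1, origin = 1, dest = 2)
#' dens <- data.frame(t = c(1, 1), patch = c(1, 2), n = c(100, 80))
#' dispersal_benefit(ev, dens)$per_step$mean_benefit  # 1.25
#' @export
dispersal_benefit <- function(events, densities) {
  key <- function(t, p) paste(t, p, sep = ":")
  lut <- stats::setNames(densities$n, key(densities$t, densities$patch))
  no <- lut[key(events$t, events$origin)]
  nd <- lut[key(events$t, events$dest)]
  ok <- !is.na(nd) & nd > 0 & !is.na(no)
  ratios <- no[ok] / nd[ok]
  steps <- sort(unique(events$t))
  per_step <- do.call(rbind, lapply(steps, function(tt) {
    sel <- events$t == tt
    data.frame(t = tt,
               mean_benefit = if (any(sel & ok))
                 mean(no[sel & ok] / nd[sel & ok]) else NA_real_,
               n_dispersers = sum(sel),
               n_excluded = sum(sel & !ok))
  }))
  list(per_step = per_step, ratios = unname(ratios))
}

#' Behavioural reaction norm of an informed channel
#'
#' Evaluates the evolved dispersal reaction norm — the logistic of the
#' behaviour function at the mean evolved coefficient — over a grid of the
#' cue, with a 95% band obtained from the among-replicate spread of the
#' coefficient (`coeff_mean +/- 1.96 * coeff_sd`, a normal approximation).
#' For the immigrant channel the probability is 0 at `M = 0` (the channel
#' is inactive without immigrants).
#'
#' @param coeff_mean Mean evolved coefficient across replicates.
#' @param coeff_sd Among-replicate standard deviation of the coefficient.
#' @param channel `"density"` or `"immigrant"`.
#' @param cfg A [sim_config()] (provides `K`, `intercept`,
#'   `immigrant_signal`).
#' @param x Cue grid: density `n` in `[0, K]` (default 101 points) or
#'   immigrant count `M` (default `0:20`).
#' @return Data frame with columns `x`, `p`, `lower`, `upper`.
#' @examples
#' cfg <- sim_config(n_steps = 1)
#' rn <- reaction_norm(0, 0, "density", cfg)
#' all(abs(rn$p - plogis(-2)) < 1e-12)  # flat at the floor
#' @export
reaction_norm <- function(coeff_mean, coeff_sd, channel = c("density",
                                                            "immigrant"),
                          cfg, x = NULL) {
  channel <- match.arg(channel)
  if (channel == "density") {
    if (is.null(x)) x <- seq(0, cfg$K, length.out = 101L)
    f <- function(cf) logistic(behavior_density(cf, x, cfg$K,
                                                cfg$intercept))
  } else {
    if (is.null(x)) x <- 0:20
    f <- function(cf) ifelse(x > 0,
                             logistic(behavior_immigrant(
                               cf, x, cfg$intercept,
                               cfg$immigrant_signal)), 0)
  }
  lo <- coeff_mean - 1.96 * coeff_sd
  hi <- coeff_mean + 1.96 * coeff_sd
  band <- cbind(f(lo), f(hi))
  data.frame(x = x, p = f(coeff_mean),
             lower = pmin(band[, 1], band[, 2]),
             upper = pmax(band[, 1], band[, 2]))
}

#' Reaction norm of a batch
#'
#' Convenience wrapper: estimates the mean and among-replicate SD of the
#' evolved coefficient from the non-extinct replicates of a batch and
#' evaluates [reaction_norm()].
#'
#' @param batch A [monte_carlo()] result.
#' @param channel `"density"` or `"immigrant"`.
#' @param x Optional cue grid.
#' @return As [reaction_norm()].
#' @export
batch_reaction_norm <- function(batch, channel = c("density", "immigrant"),
                                x = NULL) {
  channel <- match.arg(channel)
  s <- batch$summaries[!batch$summaries$extinct, , drop = FALSE]
  if (!nrow(s))
    stop("batch_reaction_norm: no surviving replicates", call. = FALSE)
  col <- if (channel == "density") "final_mean_D" else "final_mean_I"
  cf <- s[[col]]
  reaction_norm(mean(cf), if (length(cf) > 1L) stats::sd(cf) else 0,
                channel, batch$config, x)
}

#' Extinction and persistence metrics of a batch
#'
#' @param batch A [monte_carlo()] result.
#' @return A list with `extinction_fraction` (proportion of replicates in
#'   which the metapopulation went extinct before `n_steps`) and
#'   `persistence_times` (time steps until extinction, extinct replicates
#'   only).
#' @examples
#' cfg <- sim_config(variant = "U_only", n_patches = 4, K = 40,
#'                   n_steps = 100)
#' extinction_metrics(monte_carlo(cfg, 2, base_seed = 1))
#' @export
extinction_metrics <- function(batch) {
  s <- batch$summaries
  list(extinction_fraction = mean(s$extinct),
       persistence_times = s$persistence_time[s$extinct])
}

#' Batch-level evolution report
#'
#' Aggregates a batch into the quantities used to decide whether each form
#' of information use evolved: per-channel positive-coefficient counts
#' among surviving replicates, exact sign-test p-values, outcome-class
#' counts, the coexistence fraction (the `both` class over all
#' replicates), and extinction metrics.
#'
#' @param batch A [monte_carlo()] result.
#' @return A list; see Details.
#' @export
batch_report <- function(batch) {
  cfg <- batch$config
  s <- batch$summaries
  alive <- s[!s$extinct, , drop = FALSE]
  rep_channel <- function(col) {
    n <- nrow(alive)
    pos <- sum(alive[[col]] > 0)
    list(n_positive = pos, n_tested = n,
         p_value = if (n > 0) sign_test(pos, n) else NA_real_)
  }
  out <- list(variant = cfg$variant,
              n_replicates = batch$n_replicates,
              n_extinct = sum(s$extinct),
              outcome_counts = as.list(batch$outcome_counts),
              coexistence_fraction =
                unname(batch$outcome_counts["both"]) / batch$n_replicates,
              extinction_fraction = batch$extinction_fraction)
  if (has_density_channel(cfg)) out$density <- rep_channel("final_mean_D")
  if (has_immigrant_channel(cfg))
    out$immigrant <- rep_channel("final_mean_I")
  out
}
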