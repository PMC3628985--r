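#' Behaviour functions of informed dispersal
#'
#' The propensity of a juvenile to disperse in response to each information
#' source is a linear behaviour function of the cue, later transformed to a
#' probability by [logistic()].
#'
#' * density channel: `B_D = D * n / K + intercept` — the cue is relative
#'   local density `n / K`;
#' * immigrant channel: `B_I = I * M + intercept` in `"count"` mode, or
#'   `B_I = I * 1(M > 0) + intercept` in `"presence"` mode — the cue is the
#'   number (or presence) of immigrants that have already arrived in the
#'   patch during the current dispersal phase.
#'
#' The fixed intercept (default -2) sets the floor of each channel at
#' `plogis(-2)`, about 12% dispersal, which lets selection act on the slope
#' from the start. The immigrant channel is only expressed when `M > 0`;
#' callers must zero its probability otherwise (see
#' [dispersal_probabilities()]).
#'
#' @param D,I Heritable coefficients.
#' @param n Local density (resident count).
#' @param K Carrying capacity (> 0).
#' @param M Immigrant count (>= 0).
#' @param intercept Fixed intercept.
#' @param signal `"count"` or `"presence"`.
#' @return The behaviour value (real), vectorized over the inputs.
#' @examples
#' behavior_density(D = 2, n = 100, K = 100)      # 0
#' behavior_immigrant(I = 1, M = 2)               # 0
#' plogis(behavior_density(D = 0, n = 50, K = 100))  # the 12% floor
#' @export
behavior_density <- function(D, n, K, intercept = -2) {
  if (any(K <= 0)) stop("behavior_density: K must be > 0", call. = FALSE)
  D * n / K + intercept
}

#' @rdname behavior_density
#' @export
behavior_immigrant <- function(I, M, intercept = -2, signal = "count") {
  signal <- match.arg(signal, .signals)
  cue <- if (signal == "count") M else as.numeric(M > 0)
  I * cue + intercept
}

#' Logistic transform
#'
#' Maps a behaviour value to a dispersal probability,
#' `d(x) = 1 / (1 + exp(-x))`, evaluated overflow-safely.
#'
#' @param x Real number(s).
#' @return Probabilities in `(0, 1)`.
#' @examples
#' logistic(0)    # 0.5
#' logistic(-2)   # ~0.119, the informed-dispersal floor
#' @export
logistic <- function(x) stats::plogis(x)

#' Per-channel dispersal probabilities of a juvenile
#'
#' Evaluates the three dispersal channels for one juvenile given the current
#' state of its patch: the uninformed baseline `d_U` (or the logistic of the
#' individual's heritable `U` trait in the evolvable-U variant), the
#' density-informed probability `d_D`, and the immigrant-informed
#' probability `d_I`. Channels not expressed by the configured variant are
#' exactly 0, and `d_I = 0` whenever the patch has received no immigrants
#' this phase (`M = 0`).
#'
#' @param ind A single individual (one-row data frame or list with fields
#'   `age`, `D`, `I`, `U`). Must be a juvenile.
#' @param patch A [new_patch()] object; its current resident count is the
#'   density cue and its `M` the immigrant cue.
#' @param cfg A [sim_config()].
#' @return A list with elements `d_U`, `d_D`, `d_I`.
#' @examples
#' cfg <- sim_config(variant = "D_and_I", n_steps = 1)
#' p <- new_patch(1, 100, new_individuals(100, age = 0, D = 2, I = 1), M = 2)
#' dispersal_probabilities(p$residents[1, ], p, cfg)  # d_U 0.1, d_D 0.5, d_I 0.5
#' @export
dispersal_probabilities <- function(ind, patch, cfg) {
  if (ind$age != 0L)
    stop("dispersal_probabilities: only juveniles disperse", call. = FALSE)
  n <- nrow(patch$residents)
  M <- patch$M
  d_U <- if (cfg$evolvable_U) logistic(ind$U) else cfg$d_U
  d_D <- if (has_density_channel(cfg))
    logistic(behavior_density(ind$D, n, patch$K, cfg$intercept)) else 0
  d_I <- if (has_immigrant_channel(cfg) && M > 0L)
    logistic(behavior_immigrant(ind$I, M, cfg$intercept,
                                cfg$immigrant_signal)) else 0
  list(d_U = d_U, d_D = d_D, d_I = d_I)
}

#' One juvenile's dispersal decision
#'
#' The two-stage decision rule. Uninformed dispersal is always drawn first:
#' with probability `d_U` the juvenile disperses and the event is attributed
#' to the uninformed strategy. Otherwise informed dispersal is drawn with
#' probability `min(1, d_D + d_I)` (the two channels combine additively and
#' the sum is capped; if the sum exceeds 1 the juvenile always disperses).
#' A realized informed event is attributed to the density or the immigrant
#' strategy by a random draw proportional to `d_D` and `d_I`.
#'
#' @param probs A list with `d_U`, `d_D`, `d_I` (see
#'   [dispersal_probabilities()]).
#' @return A list with `disperse` (logical) and `strategy` (`"none"`,
#'   `"uninformed"`, `"density"` or `"immigrant"`).
#' @examples
#' set.seed(1)
#' decide(list(d_U = 0.1, d_D = 0.6, d_I = 0.2))
#' @export
decide <- function(probs) {
  if (stats::runif(1L) < probs$d_U)
    return(list(disperse = TRUE, strategy = "uninformed"))
  s <- probs$d_D + probs$d_I
  if (s > 0 && stats::runif(1L) < min(1, s)) {
    strategy <- if (probs$d_D > 0 && probs$d_I > 0) {
      if (stats::runif(1L) < probs$d_D / s) "density" else "immigrant"
    } else if (probs$d_D > 0) "density" else "immigrant"
    return(list(disperse = TRUE, strategy = strategy))
  }
  list(disperse = FALSE, strategy = "none")
}

#' The dispersal phase
#'
#' Visits every juvenile in the metapopulation in a single uniformly random
#' order (re-randomized each time step, so early deciders see patches before
#' any immigrants have arrived). Each juvenile decides via [decide()] using
#' its patch's *current* resident count and *current* within-phase immigrant
#' count: emigrants that already left reduce the density seen by later
#' deciders, and immigrants that already arrived are visible both in the
#' density and in the immigrant cue. A disperser is assigned a destination
#' uniformly among the other patches, increments the destination's `M`, is
#' flagged `dispersed` and records the strategy it played. Dispersal is
#' cost-free at this point; the cost is charged against the disperser's
#' juvenile survival at the next survival step.
#'
#' @param patches List of [new_patch()] objects (all `M` counters are reset
#'   to 0 at the start of the phase).
#' @param cfg A [sim_config()].
#' @return A list with `patches` (updated) and `events`, a data frame with
#'   one row per dispersal event (columns `origin`, `dest`, `strategy`,
#'   `origin_n` — origin density at the decision, including the mover —
#'   and `dest_n` — destination density just after arrival).
#' @examples
#' set.seed(1)
#' cfg <- sim_config(variant = "D_only", n_patches = 3, K = 50, n_steps = 1)
#' ps <- list(new_patch(1, 50, new_individuals(40)), new_patch(2, 50),
#'            new_patch(3, 50))
#' out <- dispersal_phase(ps, cfg)
#' nrow(out$events)
#' @export
dispersal_phase <- function(patches, cfg) {
  P <- length(patches)
  empty_events <- data.frame(origin = integer(), dest = integer(),
                             strategy = character(), origin_n = integer(),
                             dest_n = integer(), stringsAsFactors = FALSE)
  for (p in seq_len(P)) patches[[p]]$M <- 0L
  if (P == 1L) {
    warning("dispersal_phase: single patch, no dispersal possible",
            call. = FALSE)
    return(list(patches = patches, events = empty_events))
  }
  juv_patch <- integer(0)
  juv_row <- integer(0)
  for (p in seq_len(P)) {
    jr <- which(patches[[p]]$residents$age == 0L)
    juv_patch <- c(juv_patch, rep.int(p, length(jr)))
    juv_row <- c(juv_row, jr)
  }
  nJ <- length(juv_patch)
  if (nJ == 0L) return(list(patches = patches, events = empty_events))

  n <- vapply(patches, function(p) nrow(p$residents), integer(1))
  M <- integer(P)
  ord <- order(stats::runif(nJ))
  mv_origin <- integer(0); mv_row <- integer(0); mv_dest <- integer(0)
  mv_strategy <- character(0); mv_origin_n <- integer(0)
  mv_dest_n <- integer(0)

  for (jj in ord) {
    p0 <- juv_patch[jj]
    i0 <- juv_row[jj]
    ind <- patches[[p0]]$residents[i0, ]
    d_U <- if (cfg$evolvable_U) logistic(ind$U) else cfg$d_U
    d_D <- if (has_density_channel(cfg))
      logistic(behavior_density(ind$D, n[p0], cfg$K, cfg$intercept)) else 0
    d_I <- if (has_immigrant_channel(cfg) && M[p0] > 0L)
      logistic(behavior_immigrant(ind$I, M[p0], cfg$intercept,
                                  cfg$immigrant_signal)) else 0
    dec <- decide(list(d_U = d_U, d_D = d_D, d_I = d_I))
    if (dec$disperse) {
      dest <- floor(stats::runif(1L) * (P - 1L)) + 1L
      if (dest >= p0) dest <- dest + 1L
      mv_origin <- c(mv_origin, p0)
      mv_row <- c(mv_row, i0)
      mv_dest <- c(mv_dest, dest)
      mv_strategy <- c(mv_strategy, dec$strategy)
      mv_origin_n <- c(mv_origin_n, n[p0])
      mv_dest_n <- c(mv_dest_n, n[dest] + 1L)
      n[p0] <- n[p0] - 1L
      n[dest] <- n[dest] + 1L
      M[dest] <- M[dest] + 1L
    }
  }

  # apply the moves: remove emigrants (order preserved), append arrivals in
  # chronological order
  movers <- vector("list", length(mv_origin))
  for (k in seq_along(mv_origin)) {
    ind <- patches[[mv_origin[k]]]$residents[mv_row[k], ]
    ind$dispersed <- TRUE
    ind$strategy <- mv_strategy[k]
    movers[[k]] <- ind
  }
  for (p in unique(mv_origin)) {
    drop <- mv_row[mv_origin == p]
    patches[[p]]$residents <-
      patches[[p]]$residents[-drop, , drop = FALSE]
  }
  for (k in seq_along(movers)) {
    d <- mv_dest[k]
    patches[[d]]$residents <- rbind(patches[[d]]$residents, movers[[k]])
  }
  for (p in seq_len(P)) {
    rownames(patches[[p]]$residents) <- NULL
    patches[[p]]$M <- M[p]
  }
  events <- data.frame(origin = mv_origin, dest = mv_dest,
                       strategy = mv_strategy, origin_n = mv_origin_n,
                       dest_n = mv_dest_n, stringsAsFactors = FALSE)
  list(patches = patches, events = events)
}
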