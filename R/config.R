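#' @keywords internal
.variants <- c("U_only", "D_only", "I_only", "D_and_I")
.signals <- c("count", "presence")

#' Age-structured life history rates
#'
#' Bundle the age-specific survival and fecundity rates of the two-age-class
#' life cycle: juveniles (age 0) survive their first year with probability
#' `s0` and become subadults, subadults (age 1) survive with `s1` and become
#' adults, adults (age 2+) survive each year with `s2`. Subadults and adults
#' breed with mean fecundities `f1` and `f2` (Poisson-distributed offspring).
#' Defaults are the "fast" life history of a small lizard or passerine.
#'
#' @param s0,s1,s2 Survival probabilities in `[0, 1]` for juveniles,
#'   subadults and adults.
#' @param f1,f2 Non-negative mean fecundities of subadults and adults.
#' @return An object of class `life_history` (a named list).
#' @examples
#' life_history()            # fast life history
#' life_history(s2 = 0.8, f2 = 2)  # slower, adult-biased variant
#' @export
life_history <- function(s0 = 0.2, s1 = 0.35, s2 = 0.5, f1 = 7, f2 = 7) {
  for (nm in c("s0", "s1", "s2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("life_history: `", nm, "` must be a probability in [0, 1]",
           call. = FALSE)
  }
  for (nm in c("f1", "f2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("life_history: `", nm, "` must be a non-negative number",
           call. = FALSE)
  }
  structure(list(s0 = as.numeric(s0), s1 = as.numeric(s1),
                 s2 = as.numeric(s2), f1 = as.numeric(f1),
                 f2 = as.numeric(f2)),
            class = "life_history")
}

#' Simulation configuration
#'
#' Build the full, validated parameterization of one simulation run. All
#' defaults are the baseline conditions of the model: patches of carrying
#' capacity `K = 100`, fixed uninformed natal dispersal `d_U = 0.1`,
#' per-locus mutation probability 0.02 with Gaussian step SD 0.02, and the
#' fixed intercept -2 that puts the floor of each informed dispersal channel
#' at `plogis(-2)` (about 12%).
#'
#' @param variant Which dispersal-information channels are heritable and
#'   active: `"U_only"` (uninformed baseline only; the informed coefficients
#'   still mutate but are never expressed, which makes this variant the
#'   neutral-drift control), `"D_only"` (density information), `"I_only"`
#'   (immigrant information), or `"D_and_I"` (both, combined additively).
#' @param n_patches Number of equally connected patches (>= 2).
#' @param K Patch carrying capacity enforced at reproduction.
#' @param life_history A [life_history()] object.
#' @param d_U Baseline uninformed dispersal probability of juveniles.
#' @param evolvable_U If `TRUE`, the uninformed rate is itself a heritable
#'   logit-scale trait initialised at `qlogis(d_U)`.
#' @param dispersal_cost Probability cost of dispersal, charged by
#'   multiplying the disperser's subsequent juvenile survival by
#'   `(1 - dispersal_cost)`.
#' @param mutation_prob Per-locus mutation probability applied to each
#'   offspring.
#' @param mutation_sd Standard deviation of the Gaussian mutation step.
#' @param intercept Fixed intercept of the behaviour functions (default -2).
#' @param immigrant_signal `"count"` (behaviour input is the number of
#'   immigrants `M`) or `"presence"` (input is `1` whenever `M > 0`).
#' @param env_stoch_prob Per-patch, per-step probability of an environmental
#'   catastrophe.
#' @param env_stoch_severity Fraction of residents killed when a patch is
#'   hit (default 1, whole-patch catastrophe).
#' @param n_steps Run length in time steps (about 2 steps per generation).
#' @param seed Default integer seed used by [run()] when none is given.
#' @return An object of class `sim_config` (a named list with defaults
#'   filled in and all fields validated).
#' @seealso [validate_config()], [read_config()], [run()]
#' @examples
#' cfg <- sim_config(variant = "D_only", n_steps = 1000)
#' cfg$K
#' @export
sim_config <- function(variant = "D_and_I",
                       n_patches = 10L,
                       K = 100L,
                       life_history = dispersim::life_history(),
                       d_U = 0.1,
                       evolvable_U = FALSE,
                       dispersal_cost = 0,
                       mutation_prob = 0.02,
                       mutation_sd = 0.02,
                       intercept = -2,
                       immigrant_signal = "count",
                       env_stoch_prob = 0,
                       env_stoch_severity = 1,
                       n_steps = 1.5e6,
                       seed = 1L) {
  if (!is.character(variant) || length(variant) != 1L ||
      !variant %in% .variants)
    stop("sim_config: `variant` must be one of ",
         paste(.variants, collapse = ", "), call. = FALSE)
  if (!is.character(immigrant_signal) || length(immigrant_signal) != 1L ||
      !immigrant_signal %in% .signals)
    stop("sim_config: `immigrant_signal` must be \"count\" or \"presence\"",
         call. = FALSE)
  if (is.list(life_history) && !inherits(life_history, "life_history"))
    life_history <- do.call(dispersim::life_history, life_history)
  if (!inherits(life_history, "life_history"))
    stop("sim_config: `life_history` must be a life_history object",
         call. = FALSE)

  chk_num <- function(nm, v, lo = -Inf, hi = Inf, int = FALSE) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < lo || v > hi)
      stop("sim_config: `", nm, "` must be a number in [", lo, ", ", hi, "]",
           call. = FALSE)
    if (int) as.integer(v) else as.numeric(v)
  }
  n_patches <- chk_num("n_patches", n_patches, 2, Inf, int = TRUE)
  K <- chk_num("K", K, 1, Inf, int = TRUE)
  d_U <- chk_num("d_U", d_U, 0, 1)
  dispersal_cost <- chk_num("dispersal_cost", dispersal_cost, 0, 1)
  mutation_prob <- chk_num("mutation_prob", mutation_prob, 0, 1)
  mutation_sd <- chk_num("mutation_sd", mutation_sd, 0, Inf)
  intercept <- chk_num("intercept", intercept)
  env_stoch_prob <- chk_num("env_stoch_prob", env_stoch_prob, 0, 1)
  env_stoch_severity <- chk_num("env_stoch_severity", env_stoch_severity, 0, 1)
  n_steps <- chk_num("n_steps", n_steps, 0, Inf)
  if (n_steps != floor(n_steps))
    stop("sim_config: `n_steps` must be a whole number", call. = FALSE)
  seed <- chk_num("seed", seed, -.Machine$integer.max, .Machine$integer.max,
                  int = TRUE)
  if (!is.logical(evolvable_U) || length(evolvable_U) != 1L ||
      is.na(evolvable_U))
    stop("sim_config: `evolvable_U` must be TRUE or FALSE", call. = FALSE)
  if (evolvable_U && (d_U <= 0 || d_U >= 1))
    stop("sim_config: evolvable_U requires d_U strictly inside (0, 1) ",
         "(the heritable trait lives on the logit scale)", call. = FALSE)
  if (variant == "I_only" && d_U == 0)
    warning("I_only with d_U = 0: immigrant-dependent dispersal cannot ",
            "bootstrap because no uninformed dispersal ever generates ",
            "immigrants", call. = FALSE)

  structure(list(variant = variant,
                 n_patches = n_patches,
                 K = K,
                 life_history = life_history,
                 d_U = d_U,
                 evolvable_U = evolvable_U,
                 dispersal_cost = dispersal_cost,
                 mutation_prob = mutation_prob,
                 mutation_sd = mutation_sd,
                 intercept = intercept,
                 immigrant_signal = immigrant_signal,
                 env_stoch_prob = env_stoch_prob,
                 env_stoch_severity = env_stoch_severity,
                 n_steps = n_steps,
                 seed = seed),
            class = "sim_config")
}

#' Validate a raw configuration mapping
#'
#' Turn a plain named list (parsed from a YAML/JSON file or assembled from
#' command-line flags) into a validated [sim_config()], filling every
#' unspecified field with its default. Unknown fields and out-of-range
#' values raise a descriptive error naming the offending field.
#'
#' @param raw A named list of configuration fields (possibly empty).
#' @return A `sim_config` object.
#' @examples
#' validate_config(list())$K            # 100
#' validate_config(list(variant = "D_only", n_steps = 500))
#' @export
validate_config <- function(raw) {
  if (inherits(raw, "sim_config")) return(raw)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw))
    stop("validate_config: expected a named list", call. = FALSE)
  if (length(raw) && (is.null(names(raw)) || any(names(raw) == "")))
    stop("validate_config: all fields must be named", call. = FALSE)
  known <- names(formals(sim_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("validate_config: unknown field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(sim_config, raw)
}

#' @export
as.list.sim_config <- function(x, ...) {
  out <- unclass(x)
  out$life_history <- unclass(out$life_history)
  out
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  variant:", x$variant,
      if (x$evolvable_U) "(evolvable U)" else "", "\n")
  cat("  landscape:", x$n_patches, "patches, K =", x$K, "\n")
  lh <- x$life_history
  cat("  life history: s0 =", lh$s0, " s1 =", lh$s1, " s2 =", lh$s2,
      " f1 =", lh$f1, " f2 =", lh$f2, "\n")
  cat("  dispersal: d_U =", x$d_U, " cost =", x$dispersal_cost,
      " intercept =", x$intercept, " signal =", x$immigrant_signal, "\n")
  cat("  mutation: prob =", x$mutation_prob, " sd =", x$mutation_sd, "\n")
  if (x$env_stoch_prob > 0)
    cat("  env stochasticity: prob =", x$env_stoch_prob,
        " severity =", x$env_stoch_severity, "\n")
  cat("  run: n_steps =", format(x$n_steps, scientific = FALSE),
      " seed =", x$seed, "\n")
  invisible(x)
}

#' Read and write configuration files
#'
#' Configurations are stored as flat YAML (JSON is a YAML subset and is
#' accepted too). `read_config()` validates on load, so a round trip through
#' `write_config()` reproduces an identical `sim_config`.
#'
#' @param path File path.
#' @param cfg A `sim_config` object (or raw list accepted by
#'   [validate_config()]).
#' @return `read_config()` returns a `sim_config`; `write_config()` returns
#'   `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_config(sim_config(variant = "I_only", n_steps = 100), f)
#' identical(read_config(f), sim_config(variant = "I_only", n_steps = 100))
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop("read_config: no such file: ", path, call. = FALSE)
  validate_config(yaml::read_yaml(path))
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  cfg <- validate_config(cfg)
  yaml::write_yaml(as.list(cfg), path, precision = 15L)
  invisible(path)
}

# Which informed channels the variant expresses.
has_density_channel <- function(cfg) cfg$variant %in% c("D_only", "D_and_I")
has_immigrant_channel <- function(cfg) cfg$variant %in% c("I_only", "D_and_I")

#' Convert time steps to generations
#'
#' Reporting helper: with the two-age-class fast life history one generation
#' corresponds to roughly two time steps.
#'
#' @param t Time steps (numeric vector).
#' @return `t / 2`, in generations.
#' @examples
#' steps_to_generations(200)  # 100 generations
#' @export
steps_to_generations <- function(t) t / 2
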