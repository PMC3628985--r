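#' Tabular writers and readers
#'
#' All tables are tab-separated text with `#`-prefixed metadata lines
#' embedding the fully resolved configuration and seed, so any output file
#' is self-describing and re-runnable. `write_trajectory()` /
#' `write_batch_summary()` store a replicate trajectory or a batch summary
#' table; the matching readers recover both the data and the
#' configuration.
#'
#' @param result A [run()] result (`write_trajectory`) or a
#'   [monte_carlo()] result (`write_batch_summary`).
#' @param path Output file path.
#' @return The path, invisibly. Readers return a list with `data` (data
#'   frame), `config` (a [sim_config()]) and `seed` (trajectories) or
#'   `base_seed` (batch summaries).
#' @examples
#' cfg <- sim_config(variant = "D_only", n_patches = 3, K = 30, n_steps = 50)
#' f <- tempfile(fileext = ".tsv")
#' write_trajectory(run(cfg, seed = 1), f)
#' nrow(read_trajectory(f)$data)
#' @export
write_trajectory <- function(result, path) {
  stopifnot(inherits(result, "replicate_result"))
  .write_table(result$trajectory, path,
               c("# dispersim trajectory",
                 .config_header(result$config),
                 paste0("# seed: ", if (is.null(result$seed)) "NA"
                        else result$seed)))
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  meta <- .read_header(path)
  list(data = utils::read.delim(path, comment.char = "#"),
       config = meta$config, seed = meta$seed)
}

#' @rdname write_trajectory
#' @export
write_batch_summary <- function(result, path) {
  stopifnot(inherits(result, "batch_result"))
  .write_table(result$summaries, path,
               c("# dispersim batch summary",
                 .config_header(result$config),
                 paste0("# base_seed: ", result$base_seed)))
}

#' @rdname write_trajectory
#' @export
read_batch_summary <- function(path) {
  meta <- .read_header(path)
  list(data = utils::read.delim(path, comment.char = "#"),
       config = meta$config, base_seed = meta$base_seed)
}

#' Write the dispersal event log
#'
#' @param result A [run()] result obtained with `collect_events = TRUE`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_events <- function(result, path) {
  stopifnot(inherits(result, "replicate_result"))
  if (is.null(result$events))
    stop("write_events: run() was called without collect_events = TRUE",
         call. = FALSE)
  .write_table(result$events, path,
               c("# dispersim dispersal events",
                 .config_header(result$config),
                 paste0("# seed: ", if (is.null(result$seed)) "NA"
                        else result$seed)))
}

#' Write a batch report as JSON
#'
#' Serialises [batch_report()] output (outcome counts, sign-test p-values,
#' coexistence and extinction fractions) together with the resolved
#' configuration.
#'
#' @param batch A [monte_carlo()] result.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_batch_report <- function(batch, path) {
  stopifnot(inherits(batch, "batch_result"))
  rep <- batch_report(batch)
  rep$config <- as.list(batch$config)
  rep$base_seed <- batch$base_seed
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

.config_header <- function(cfg) {
  lst <- as.list(cfg)
  lst$life_history <- NULL
  lh <- cfg$life_history
  vals <- c(vapply(lst, function(v) paste(format(v, scientific = FALSE),
                                          collapse = ","), character(1)),
            s0 = lh$s0, s1 = lh$s1, s2 = lh$s2, f1 = lh$f1, f2 = lh$f2)
  paste0("# config ", names(vals), ": ", vals)
}

.read_header <- function(path) {
  if (!file.exists(path))
    stop("no such file: ", path, call. = FALSE)
  lines <- character(0)
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    l <- readLines(con, n = 1L)
    if (!length(l) || !startsWith(l, "#")) break
    lines <- c(lines, l)
  }
  cfg_lines <- grep("^# config ", lines, value = TRUE)
  kv <- sub("^# config ", "", cfg_lines)
  keys <- sub(":.*$", "", kv)
  vals <- sub("^[^:]+: ", "", kv)
  raw <- stats::setNames(as.list(vals), keys)
  lh_keys <- c("s0", "s1", "s2", "f1", "f2")
  lh <- lapply(raw[intersect(lh_keys, names(raw))], as.numeric)
  raw <- raw[setdiff(names(raw), lh_keys)]
  for (k in names(raw)) {
    v <- raw[[k]]
    if (k %in% c("variant", "immigrant_signal")) next
    if (v %in% c("TRUE", "FALSE")) raw[[k]] <- as.logical(v)
    else raw[[k]] <- as.numeric(v)
  }
  if (length(lh)) raw$life_history <- do.call(life_history, lh)
  seed_line <- grep("^# (base_)?seed: ", lines, value = TRUE)
  seed <- if (length(seed_line))
    suppressWarnings(as.integer(sub("^# (base_)?seed: ", "",
                                    seed_line[1]))) else NA_integer_
  list(config = validate_config(raw), seed = seed, base_seed = seed)
}

.write_table <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
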