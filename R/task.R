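#' Configure the stable/volatile bandit task
#'
#' Defines the reward schedule of the two-option ("two pirates") probabilistic
#' task: one 60-trial stable phase in which a single option is rewarded on a
#' fixed 75% of trials, and a 60-trial volatile phase split into three
#' 20-trial blocks whose 80/20 contingency reverses at every block boundary.
#' Schedules are exact-ratio: the configured contingencies are realised
#' exactly by construction, with the positions of rewarded trials permuted
#' under the seed.
#'
#' @param n_stable_trials Number of stable-phase trials.
#' @param stable_p Probability that the stable-phase high-probability option
#'   is rewarded; `stable_p * n_stable_trials` must be an integer.
#' @param n_volatile_blocks Number of volatile blocks.
#' @param volatile_block_len Trials per volatile block;
#'   `volatile_p * volatile_block_len` must be an integer.
#' @param volatile_p Within-block reward probability of the currently
#'   high-probability option.
#' @param order `"stable_first"` or `"volatile_first"`; phase order is
#'   counterbalanced across participants in a cohort.
#' @param magnitude_rule `"none"` (probability-only task) or
#'   `"complementary_uniform"` (displayed coin counts drawn uniformly from
#'   10..90 with the two options summing to 100).
#' @param seed Integer seed controlling the within-block permutation of
#'   rewarded trials (and magnitudes, when assigned at generation time).
#' @return An object of class `task_config`.
#' @export
task_config <- function(n_stable_trials = 60L, stable_p = 0.75,
                        n_volatile_blocks = 3L, volatile_block_len = 20L,
                        volatile_p = 0.80,
                        order = c("stable_first", "volatile_first"),
                        magnitude_rule = c("complementary_uniform", "none"),
                        seed = 1L) {
  order <- match.arg(order)
  magnitude_rule <- match.arg(magnitude_rule)
  cfg <- list(n_stable_trials = as.integer(n_stable_trials),
              stable_p = stable_p,
              n_volatile_blocks = as.integer(n_volatile_blocks),
              volatile_block_len = as.integer(volatile_block_len),
              volatile_p = volatile_p,
              order = order, magnitude_rule = magnitude_rule,
              seed = as.integer(seed))
  validate_task_config(cfg)
  structure(cfg, class = "task_config")
}

validate_task_config <- function(cfg) {
  stopifnot(cfg$n_stable_trials >= 1L, cfg$n_volatile_blocks >= 1L,
            cfg$volatile_block_len >= 1L)
  if (!(cfg$stable_p > 0.5 && cfg$stable_p < 1))
    stop("stable_p must lie in (0.5, 1)", call. = FALSE)
  if (!(cfg$volatile_p > 0.5 && cfg$volatile_p < 1))
    stop("volatile_p must lie in (0.5, 1)", call. = FALSE)
  .check_exact_ratio(cfg$stable_p, cfg$n_stable_trials, "stable_p")
  .check_exact_ratio(cfg$volatile_p, cfg$volatile_block_len, "volatile_p")
  invisible(cfg)
}

.check_exact_ratio <- function(p, n, field) {
  k <- p * n
  if (abs(k - round(k)) > 1e-9)
    stop(sprintf(
      "%s: expected reward count %s * %d = %.3f is not an integer under the exact-ratio scheme",
      field, format(p), n, k), call. = FALSE)
  invisible(round(k))
}

# Evaluate expr with a local, restorable RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate an exact-ratio reward schedule
#'
#' @param config A [task_config()].
#' @return A `task_schedule`: a data frame with one row per trial and columns
#'   `trial_index`, `phase`, `block_id`, `high_prob_option`,
#'   `rewarded_option`, `magnitude_A`, `magnitude_B`, carrying the config as
#'   an attribute. Block 0 is the stable phase; volatile blocks are numbered
#'   1..`n_volatile_blocks` and the high-probability option alternates
#'   between consecutive volatile blocks (A-high in odd blocks).
#' @examples
#' sch <- generate_schedule(task_config(seed = 7))
#' nrow(sch)                    # 120
#' mean(sch$rewarded_option[sch$phase == "stable"] == "A")  # exactly 0.75
#' @export
generate_schedule <- function(config = task_config()) {
  validate_task_config(config)
  blk <- function(len, p, high, block_id, phase, seed_off) {
    k <- round(p * len)
    rewarded <- rep(if (high == "A") "B" else "A", len)
    pos <- with_seed(config$seed + seed_off, sample.int(len, k))
    rewarded[pos] <- high
    data.frame(phase = phase, block_id = block_id,
               high_prob_option = high, rewarded_option = rewarded,
               stringsAsFactors = FALSE)
  }
  stable <- blk(config$n_stable_trials, config$stable_p, "A", 0L, "stable", 0L)
  vol <- lapply(seq_len(config$n_volatile_blocks), function(j) {
    blk(config$volatile_block_len, config$volatile_p,
        if (j %% 2L == 1L) "A" else "B", j, "volatile", j)
  })
  vol <- do.call(rbind, vol)
  trials <- if (config$order == "stable_first") rbind(stable, vol)
            else rbind(vol, stable)
  trials$trial_index <- seq_len(nrow(trials))
  trials$magnitude_A <- NA_integer_
  trials$magnitude_B <- NA_integer_
  trials <- trials[, c("trial_index", "phase", "block_id", "high_prob_option",
                       "rewarded_option", "magnitude_A", "magnitude_B")]
  sch <- structure(trials, config = config,
                   class = c("task_schedule", "data.frame"))
  if (config$magnitude_rule == "complementary_uniform")
    sch <- assign_magnitudes(sch, seed = config$seed + 1000L)
  sch
}

#' Assign complementary coin magnitudes to a schedule
#'
#' Draws `magnitude_A` uniformly from 10..90 and sets
#' `magnitude_B = 100 - magnitude_A` on every trial. A no-op (with a warning)
#' when the schedule's `magnitude_rule` is `"none"`.
#'
#' @param schedule A `task_schedule`.
#' @param seed Integer seed for the draws.
#' @return The schedule with magnitudes filled in.
#' @export
assign_magnitudes <- function(schedule, seed = 1L) {
  cfg <- attr(schedule, "config")
  if (!is.null(cfg) && cfg$magnitude_rule == "none") {
    warning("magnitude_rule is 'none'; magnitudes left unassigned")
    return(schedule)
  }
  mA <- with_seed(seed, sample(10:90, nrow(schedule), replace = TRUE))
  schedule$magnitude_A <- as.integer(mA)
  schedule$magnitude_B <- 100L - as.integer(mA)
  schedule
}

#' @export
print.task_schedule <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Task schedule: %d trials (%d stable @ %.0f%%, %d x %d volatile @ %.0f%%), %s\n",
              nrow(x), cfg$n_stable_trials, 100 * cfg$stable_p,
              cfg$n_volatile_blocks, cfg$volatile_block_len,
              100 * cfg$volatile_p, cfg$order))
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat(sprintf("... %d more trials\n", nrow(x) - 6L))
  invisible(x)
}

.schedule_header <- c("trial_index", "phase", "block_id", "high_prob_option",
                      "rewarded_option", "magnitude_A", "magnitude_B")

#' Write / read a schedule as CSV
#'
#' The file dialect is fixed: header
#' `trial_index,phase,block_id,high_prob_option,rewarded_option,magnitude_A,magnitude_B`,
#' 1-based trial indices, lower-case phase labels, empty magnitude cells when
#' unassigned. Reading is strict; malformed files raise a parse error naming
#' the offending line.
#'
#' @param schedule A `task_schedule`.
#' @param path File path.
#' @return `read_schedule_csv` returns a `task_schedule` (without the
#'   generating config attribute).
#' @export
write_schedule_csv <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule)[, .schedule_header],
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L)
    stop(sprintf("parse error in '%s': no trial rows", path), call. = FALSE)
  if (!identical(strsplit(lines[1L], ",")[[1L]], .schedule_header))
    stop(sprintf("parse error in '%s' line 1: expected header '%s'",
                 path, paste(.schedule_header, collapse = ",")), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("integer", "character", "integer",
                                       "character", "character",
                                       "integer", "integer"))
  for (i in seq_len(nrow(df))) {
    ln <- i + 1L
    if (!df$phase[i] %in% c("stable", "volatile"))
      stop(sprintf("parse error in '%s' line %d: phase '%s' (expected 'stable' or 'volatile')",
                   path, ln, df$phase[i]), call. = FALSE)
    if (!df$high_prob_option[i] %in% c("A", "B") ||
        !df$rewarded_option[i] %in% c("A", "B"))
      stop(sprintf("parse error in '%s' line %d: options must be 'A' or 'B'",
                   path, ln), call. = FALSE)
    if (df$trial_index[i] != i)
      stop(sprintf("parse error in '%s' line %d: trial_index %d out of order",
                   path, ln, df$trial_index[i]), call. = FALSE)
    m <- c(df$magnitude_A[i], df$magnitude_B[i])
    if (any(!is.na(m) & m < 1L))
      stop(sprintf("parse error in '%s' line %d: magnitudes must be >= 1",
                   path, ln), call. = FALSE)
  }
  structure(df, class = c("task_schedule", "data.frame"))
}

#' Read a task configuration from JSON or YAML
#'
#' @param path A `.json`, `.yaml` or `.yml` file with exactly the
#'   [task_config()] field names.
#' @return A `task_config`.
#' @export
read_task_config <- function(path) {
  vals <- .read_config_file(path)
  do.call(task_config, vals)
}

.read_config_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs")
    yaml::read_yaml(path)
  } else stop("unsupported config format: ", ext)
}
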