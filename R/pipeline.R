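#' Configure a full analysis run
#'
#' Bundles the task, cohort, prior, sampler, selection and statistics
#' settings with a global seed. Stage seeds are derived deterministically
#' from the global seed and the stage name, so any stage can be re-run
#' independently yet reproducibly.
#'
#' @param task A [task_config()].
#' @param cohort A [cohort_config()].
#' @param priors A [prior_spec()].
#' @param sampler A [sampler_config()].
#' @param selection List: `K` (folds), `fit_family` (model ids to fit
#'   hierarchically at the group stage; defaults to the full family).
#' @param stats List: `alpha`, `correction` (Holm on the headline group
#'   tests; off by default).
#' @param seed Global integer seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(task = task_config(), cohort = cohort_config(),
                       priors = prior_spec(), sampler = sampler_config(),
                       selection = list(), stats = list(), seed = 1L) {
  sel_def <- list(K = 10L, fit_family = names(default_family()))
  st_def <- list(alpha = 0.05, correction = FALSE)
  structure(list(task = task, cohort = cohort, priors = priors,
                 sampler = sampler,
                 selection = utils::modifyList(sel_def, selection),
                 stats = utils::modifyList(st_def, stats),
                 seed = as.integer(seed)),
            class = "run_config")
}

# deterministic stage seed below 2^31, derived from the global seed and name
stage_seed <- function(config, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (config$seed * 1009L + h * 31L) %% 2147483563L
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass_deep(config), tmp, auto_unbox = TRUE,
                       digits = 12)
  unname(tools::md5sum(tmp))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else unclass(x)
}

.sidecar <- function(out, stage, config, seed, files, extra = list()) {
  meta <- c(list(stage = stage, seed = seed, config_hash = config_hash(config),
                 files = files,
                 elapsed_s = round(extra$elapsed %||% NA_real_, 2),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
            extra[setdiff(names(extra), "elapsed")])
  jsonlite::write_json(meta, file.path(out, paste0(stage, ".meta.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = 12)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_upstream <- function(out, file, stage_needed) {
  p <- file.path(out, file)
  if (!file.exists(p))
    stop(sprintf("missing artifact '%s'; run stage '%s' first", file,
                 stage_needed), call. = FALSE)
  p
}

#' Pipeline stages
#'
#' `stage_simulate` writes the schedule, cohort and trials CSVs;
#' `stage_fit` fits the configured models hierarchically and stores draws
#' (long CSV), pointwise log-likelihoods (RDS) and diagnostics (JSON);
#' `stage_select` runs the participant-level null comparison and group-level
#' WAIC comparison; `stage_stats` computes the group-difference, retention,
#' power and longitudinal moderation statistics; [reproduce_study()] chains
#' all stages and renders a markdown report. Each stage writes a sidecar
#' JSON with its seed, config hash, wall time and artifact paths.
#'
#' @param config A [run_config()].
#' @param out Output directory (created if needed).
#' @return Invisibly, the paths of written artifacts.
#' @export
stage_simulate <- function(config, out) {
  t0 <- proc.time()[["elapsed"]]
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- stage_seed(config, "simulate")
  sch <- generate_schedule(config$task)
  ccfg <- config$cohort
  ccfg$task <- config$task
  ccfg$seed <- seed
  dat <- generate_cohort(ccfg, followup = TRUE)
  files <- c(schedule = "schedule.csv", cohort = "cohort.csv",
             trials = "trials.csv")
  write_schedule_csv(sch, file.path(out, files["schedule"]))
  write_cohort_csv(dat$cohort, file.path(out, files["cohort"]))
  write_trials_csv(dat$trials, file.path(out, files["trials"]))
  .sidecar(out, "simulate", config, seed, files,
           list(elapsed = proc.time()[["elapsed"]] - t0))
  invisible(file.path(out, files))
}

#' @rdname stage_simulate
#' @param models Model ids to fit; defaults to `config$selection$fit_family`.
#' @export
stage_fit <- function(config, out, models = NULL) {
  t0 <- proc.time()[["elapsed"]]
  seed <- stage_seed(config, "fit")
  trials_path <- .check_upstream(out, "trials.csv", "simulate")
  trials <- tryCatch(read_trials_csv(trials_path), error = function(e)
    stop(sprintf("fit stage: cannot parse '%s': %s", trials_path,
                 conditionMessage(e)), call. = FALSE))
  need <- c("participant_id", "trial_index", "phase", "chosen", "outcome")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop(sprintf("fit stage: '%s' lacks column(s) %s", trials_path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  fam <- default_family()
  models <- models %||% config$selection$fit_family
  fitdir <- file.path(out, "fits")
  dir.create(fitdir, showWarnings = FALSE)
  sampler <- config$sampler
  sampler$seed <- seed
  files <- character(0)
  for (m in models) {
    fit <- fit_rl(fam[[m]], trials, config$priors, sampler)
    saveRDS(fit, file.path(fitdir, paste0(m, ".rds")))
    if (fit$k > 0) {
      long <- do.call(rbind, lapply(seq_len(fit$sampler$chains), function(ch) {
        do.call(rbind, lapply(seq_len(fit$k), function(j) {
          rbind(
            data.frame(draw = seq_len(fit$sampler$iter), chain = ch,
                       parameter = paste0("mu_", fit$param_names[j]),
                       participant_id = NA_character_,
                       value = fit$draws$mu[, ch, j]),
            data.frame(draw = seq_len(fit$sampler$iter), chain = ch,
                       parameter = paste0("sigma_", fit$param_names[j]),
                       participant_id = NA_character_,
                       value = fit$draws$sigma[, ch, j]))
        }))
      }))
      utils::write.csv(long, file.path(fitdir, paste0(m, "_draws.csv")),
                       row.names = FALSE, na = "")
    }
    jsonlite::write_json(
      list(model = m, rhat = as.list(fit$diagnostics$rhat),
           ess = as.list(fit$diagnostics$ess),
           divergences = fit$diagnostics$divergences),
      file.path(fitdir, paste0(m, "_diagnostics.json")),
      auto_unbox = TRUE, pretty = TRUE, digits = 12)
    files <- c(files, paste0("fits/", m, ".rds"))
  }
  .sidecar(out, "fit", config, seed, files,
           list(elapsed = proc.time()[["elapsed"]] - t0))
  invisible(file.path(out, files))
}

#' @rdname stage_simulate
#' @export
stage_select <- function(config, out) {
  t0 <- proc.time()[["elapsed"]]
  seed <- stage_seed(config, "select")
  trials <- read_trials_csv(.check_upstream(out, "trials.csv", "simulate"))
  cohort <- read_cohort_csv(.check_upstream(out, "cohort.csv", "simulate"))
  excl <- participant_null_comparison(trials, default_family(),
                                      config$priors, cohort, seed = seed)
  utils::write.csv(as.data.frame(excl), file.path(out, "exclusion.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(excluded_fraction = attr(excl, "excluded_fraction"),
         group_sizes = as.list(attr(excl, "group_sizes"))),
    file.path(out, "exclusion.json"), auto_unbox = TRUE, digits = 12)
  fitdir <- file.path(out, "fits")
  fitfiles <- list.files(fitdir, pattern = "^M\\d+\\.rds$",
                         full.names = TRUE)
  files <- c("exclusion.csv", "exclusion.json")
  if (length(fitfiles) >= 2L) {
    fits <- lapply(fitfiles, readRDS)
    keep <- excl$participant_id[!excl$excluded]
    cmp <- compare_models(fits, include = keep)
    utils::write.csv(as.data.frame(cmp), file.path(out, "comparison.csv"),
                     row.names = FALSE)
    files <- c(files, "comparison.csv")
  }
  .sidecar(out, "select", config, seed, files,
           list(elapsed = proc.time()[["elapsed"]] - t0))
  invisible(file.path(out, files))
}

#' @rdname stage_simulate
#' @export
stage_stats <- function(config, out) {
  t0 <- proc.time()[["elapsed"]]
  seed <- stage_seed(config, "stats")
  cohort <- read_cohort_csv(.check_upstream(out, "cohort.csv", "simulate"))
  excl_path <- file.path(out, "exclusion.csv")
  kept <- if (file.exists(excl_path)) {
    e <- utils::read.csv(excl_path, stringsAsFactors = FALSE)
    e$participant_id[!e$excluded]
  } else cohort$participant_id
  co <- cohort[cohort$participant_id %in% kept, ]
  tt <- two_sample_ttest(co$tau_true[co$group == "NMT"],
                         co$tau_true[co$group == "MT"])
  lr <- paired_ttest(co$alpha_stable_true, co$alpha_volatile_true)
  ret <- table(factor(cohort$group, c("MT", "NMT")),
               factor(cohort$retained, c(TRUE, FALSE)))
  # degenerate retention (e.g. everyone retained in a small cohort) yields
  # an NA test rather than a failed stage
  chi <- tryCatch(chi_square_2x2(ret), error = function(e)
    list(chi2 = NA_real_, df = 1L, p = NA_real_, observed = ret))
  pw <- power_two_sample_t(sum(cohort$group == "MT"),
                           sum(cohort$group == "NMT"),
                           d = 0.70, alpha = config$stats$alpha)
  sd_ <- sensitivity_d(sum(cohort$group == "MT"),
                       sum(cohort$group == "NMT"),
                       alpha = config$stats$alpha, power = 0.80)
  reg <- tryCatch(
    hierarchical_regression(co, "sdq_emotional_followup",
                            "sdq_emotional_baseline"),
    error = function(e) list(
      r_squared = NA_real_, F = NA_real_, df1 = NA_real_, df2 = NA_real_,
      terms = data.frame(term = "group:tau_true", beta = NA_real_,
                         t = NA_real_, df = NA_real_, p = NA_real_,
                         r_part = NA_real_)))
  res <- list(
    temperature_ttest = unclass(tt)[c("t", "df", "p", "mean_diff", "cohen_d")],
    learning_rate_paired = unclass(lr)[c("t", "df", "p", "mean_diff")],
    retention_chisq = list(chi2 = chi$chi2, df = chi$df, p = chi$p,
                           observed = as.vector(chi$observed)),
    followup_complete_fraction = mean(cohort$retained),
    power = list(power_at_d = pw$power, d = pw$d,
                 sensitivity_d = sd_$d),
    moderation = list(
      r_squared = reg$r_squared, F = reg$F, df1 = reg$df1, df2 = reg$df2,
      interaction = as.list(
        reg$terms[reg$terms$term == "group:tau_true",
                  c("beta", "t", "df", "p", "r_part")])),
    seed = seed)
  jsonlite::write_json(res, file.path(out, "stats.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = 12, na = "null")
  .sidecar(out, "stats", config, seed, "stats.json",
           list(elapsed = proc.time()[["elapsed"]] - t0))
  invisible(file.path(out, "stats.json"))
}

#' Run the whole pipeline and render a report
#'
#' Chains simulate, fit, select and stats, then writes `report.md`
#' summarising the schedule structure, model family, exclusion, model
#' comparison, and cohort statistics. `render_report` re-renders from
#' stored artifacts without recomputing.
#'
#' @param config A [run_config()].
#' @param out Output directory.
#' @param models Model ids for the fit stage (default: configured family).
#' @return Path to the report, invisibly.
#' @export
reproduce_study <- function(config = run_config(), out, models = NULL) {
  stage_simulate(config, out)
  stage_fit(config, out, models = models)
  stage_select(config, out)
  stage_stats(config, out)
  render_report(out)
}

#' @rdname reproduce_study
#' @export
render_report <- function(out) {
  st <- jsonlite::read_json(.check_upstream(out, "stats.json", "stats"),
                            simplifyVector = TRUE)
  ex <- jsonlite::read_json(.check_upstream(out, "exclusion.json", "select"),
                            simplifyVector = TRUE)
  sch <- read_schedule_csv(.check_upstream(out, "schedule.csv", "simulate"))
  fam <- default_family()
  nn <- function(x) {
    x <- suppressWarnings(as.numeric(x))
    if (length(x) == 0) NA_real_ else x
  }
  st$retention_chisq$chi2 <- nn(st$retention_chisq$chi2)
  st$retention_chisq$p <- nn(st$retention_chisq$p)
  for (f in c("beta", "df", "t", "p", "r_part"))
    st$moderation$interaction[[f]] <- nn(st$moderation$interaction[[f]])
  lines <- c(
    "# Volatility bandit pipeline report", "",
    sprintf("- Schedule: %d trials (%d stable, %d volatile); stable contingency %.0f%%; volatile contingency %.0f%%",
            nrow(sch), sum(sch$phase == "stable"),
            sum(sch$phase == "volatile"),
            100 * mean(sch$rewarded_option[sch$phase == "stable"] ==
                         sch$high_prob_option[sch$phase == "stable"]),
            100 * mean(sch$rewarded_option[sch$phase == "volatile"] ==
                         sch$high_prob_option[sch$phase == "volatile"])),
    sprintf("- Model family: %d candidates; winning model %s with %d free parameters",
            length(fam), winning_spec(fam)$model_id,
            winning_spec(fam)$n_free_params),
    sprintf("- Excluded by null-model comparison: %.0f%%",
            100 * ex$excluded_fraction),
    sprintf("- Temperature group difference: t(%g) = %.2f, p = %.3f",
            st$temperature_ttest$df, st$temperature_ttest$t,
            st$temperature_ttest$p),
    sprintf("- Stable vs volatile learning rates (paired): t(%g) = %.2f, p = %.3f",
            st$learning_rate_paired$df, st$learning_rate_paired$t,
            st$learning_rate_paired$p),
    sprintf("- Retention: X2(1) = %.2f, p = %.3f; complete follow-up %.0f%%",
            st$retention_chisq$chi2, st$retention_chisq$p,
            100 * st$followup_complete_fraction),
    sprintf("- Power at d = 0.70: %.3f; sensitivity d at 80%% power: %.3f",
            st$power$power_at_d, st$power$sensitivity_d),
    sprintf("- Group-by-temperature interaction: beta = %.2f, t(%g) = %.2f, p = %.3g, r_part = %.2f",
            st$moderation$interaction$beta, st$moderation$interaction$df,
            st$moderation$interaction$t, st$moderation$interaction$p,
            st$moderation$interaction$r_part))
  cmp_path <- file.path(out, "comparison.csv")
  if (file.exists(cmp_path)) {
    cmp <- utils::read.csv(cmp_path, stringsAsFactors = FALSE)
    lines <- c(lines, "",
               "## Group model comparison (WAIC, best first)", "",
               paste0("| model | params | WAIC | delta |"),
               paste0("|---|---|---|---|"),
               sprintf("| %s | %d | %.1f | %.1f |", cmp$model_id,
                       cmp$n_params, cmp$waic, cmp$delta_waic))
  }
  writeLines(lines, file.path(out, "report.md"))
  invisible(file.path(out, "report.md"))
}
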