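#' Default run configuration
#'
#' All seeds are explicit — nothing is ever seeded from the clock — and the
#' whole configuration is serialized into the output directory for
#' provenance. Any field can be overridden in a YAML file with the same
#' structure.
#'
#' @param output_dir where stage artifacts are written.
#' @return nested list understood by [run_all()].
#' @export
default_run_config <- function(output_dir = "icudce-out") {
  list(
    attributes_config = NULL,
    design = list(tasks = 24L, blocks = 2L, sweeps = 10L, seed = 1L,
                  quality_seed = 2L),
    simulation = list(n = 303L, careless_rate = 0.1, seed = 7L),
    quality = list(min_median_ms = 2000L, max_inconsistencies = 1L,
                   drop_failures = NULL),
    ri = list(draws = 2000L, seed = 3L),
    latent_class = list(classes = 1:4, starts = 5L, seed = 11L),
    output_dir = output_dir)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; missing fields fall back to
#'   [default_run_config()] values.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  for (k in names(user)) {
    if (is.list(cfg[[k]]) && is.list(user[[k]])) {
      for (j in names(user[[k]])) cfg[[k]][[j]] <- user[[k]][[j]]
    } else {
      cfg[[k]] <- user[[k]]
    }
  }
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' design -> simulate -> quality -> pooled fit -> odds ratios -> relative
#' importance -> latent classes -> membership effects -> type x severity
#' interactions, each stage writing its artifact file before the next
#' starts. Rerunning with an identical configuration reproduces identical
#' artifacts.
#'
#' @param config list from [default_run_config()] / [read_run_config()].
#' @return invisibly, a list with every stage result (the run report).
#' @export
run_all <- function(config = default_run_config()) {
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  note <- function(...) message(sprintf("[icudce %5.1fs] ",
    as.numeric(Sys.time() - t0, units = "secs")), ...)

  attrs <- stage("config", {
    if (is.null(config$attributes_config)) default_attributes()
    else read_attributes(config$attributes_config)
  })
  write_attributes(attrs, file.path(out, "attributes.yaml"))
  yaml::write_yaml(config, file.path(out, "run_config.yaml"))

  note("design: ", config$design$tasks, " tasks, ", config$design$blocks,
       " blocks, seed ", config$design$seed)
  design <- stage("design", {
    d <- generate_design(attrs, n_tasks = config$design$tasks,
                         n_blocks = config$design$blocks,
                         n_sweeps = config$design$sweeps,
                         seed = config$design$seed)
    inject_quality_tasks(d, seed = config$design$quality_seed)
  })
  write_design(design, file.path(out, "design.csv"))

  note("simulate: n = ", config$simulation$n)
  sim <- stage("simulate", {
    pop <- default_population(attrs)
    respondents <- simulate_respondents(config$simulation$n, pop,
                                        careless_rate = config$simulation$careless_rate,
                                        seed = config$simulation$seed)
    responses <- simulate_responses(respondents, design, pop,
                                    seed = config$simulation$seed + 1L)
    list(pop = pop, respondents = respondents, responses = responses)
  })
  write_choice_data(sim$responses, sim$respondents, file.path(out, "data"))

  note("quality screening")
  qrep <- stage("quality", assess_quality(sim$responses, design,
    min_median_ms = config$quality$min_median_ms,
    max_inconsistencies = config$quality$max_inconsistencies))
  write_quality(qrep, file.path(out, "quality.csv"))
  qsum <- quality_summary(qrep)
  jsonlite::write_json(qsum, file.path(out, "quality_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  responses <- sim$responses
  if (!is.null(config$quality$drop_failures)) {
    keep <- qrep$respondent_id[qrep$n_failed <= config$quality$drop_failures]
    responses <- responses[responses$respondent_id %in% keep, , drop = FALSE]
    note("kept ", length(keep), " respondents after quality filter")
  }

  note("pooled logit")
  fit <- stage("estimation", fit_logit(code_dataset(responses, attrs, "admit")))
  write_fit(fit, file.path(out, "fit.json"))
  or_tab <- odds_ratios(fit)
  utils::write.csv(or_tab, file.path(out, "odds_ratios.csv"), row.names = FALSE)

  note("relative importance")
  ri <- stage("relative_importance",
              ri_uncertainty(fit, n_draws = config$ri$draws,
                             seed = config$ri$seed))
  utils::write.csv(as.data.frame(ri), file.path(out, "relative_importance.csv"),
                   row.names = FALSE)

  note("latent classes: C in {",
       paste(config$latent_class$classes, collapse = ","), "}")
  lc <- stage("latent_class", {
    coded <- code_dataset(responses, attrs, "admit")
    seltab <- select_classes(coded, sim$respondents,
                             C_range = config$latent_class$classes,
                             n_starts = config$latent_class$starts,
                             seed = config$latent_class$seed)
    C_best <- seltab$C[seltab$best_bic][1]
    best <- fit_latent_class(coded, sim$respondents, C = C_best,
                             n_starts = config$latent_class$starts,
                             seed = config$latent_class$seed)
    list(selection = seltab, fit = best)
  })
  utils::write.csv(lc$selection, file.path(out, "lc_selection.csv"),
                   row.names = FALSE)
  class_ri <- class_ri_profiles(lc$fit)
  cri <- do.call(rbind, lapply(names(class_ri), function(k) {
    df <- as.data.frame(class_ri[[k]]); df$class <- k; df
  }))
  utils::write.csv(cri, file.path(out, "class_ri.csv"), row.names = FALSE)
  memb <- if (lc$fit$n_classes >= 2L) membership_effects(lc$fit) else NULL
  if (!is.null(memb)) {
    utils::write.csv(memb, file.path(out, "membership_effects.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(list(
    n_classes = lc$fit$n_classes, shares = lc$fit$shares,
    loglik = lc$fit$loglik, aic = lc$fit$aic, bic = lc$fit$bic,
    class_betas = lapply(lc$fit$class_betas, as.list),
    theta = lc$fit$theta), file.path(out, "lc_fit.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  note("type x severity interactions")
  ifit <- stage("interactions", fit_interaction_model(responses, attrs))
  grid <- interaction_or_grid(ifit)
  utils::write.csv(grid, file.path(out, "interaction_grid.csv"),
                   row.names = FALSE)

  report <- list(
    config = config,
    quality_summary = qsum,
    odds_ratios = or_tab,
    relative_importance = as.data.frame(ri),
    lc_selection = lc$selection,
    lc_shares = lc$fit$shares,
    class_ri = cri,
    membership_effects = memb,
    interaction_grid = grid,
    versions = list(icudce = as.character(utils::packageVersion("icudce")),
                    r = R.version.string))
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(render_report_md(report), file.path(out, "report.md"))
  note("done; artifacts in ", normalizePath(out))
  invisible(report)
}

fmt_or <- function(or) {
  if (or >= 1) sprintf("%.2f times more likely", or)
  else sprintf("%.2f times less likely", 1 / or)
}

render_report_md <- function(report) {
  ri <- report$relative_importance
  ri <- ri[order(-ri$ri_percent), ]
  c("# ICU admission choice-experiment run report",
    "",
    sprintf("Quality: %.1f%% of respondents pass all four criteria (max %d failures observed).",
            100 * report$quality_summary$proportion_all_pass,
            report$quality_summary$max_failures_observed),
    "",
    "## Relative importance (benchmark 12.5% = equal weighting)",
    "",
    sprintf("- %s: %.1f%% [%.1f, %.1f]", ri$attribute, ri$ri_percent,
            ri$ci_low, ri$ci_high),
    "",
    "## Odds ratios (vs reference level)",
    "",
    sprintf("- %s: OR %.2f (95%% CI %.2f-%.2f) — %s", report$odds_ratios$contrast,
            report$odds_ratios$or, report$odds_ratios$ci_low,
            report$odds_ratios$ci_high,
            vapply(report$odds_ratios$or, fmt_or, character(1))),
    "",
    "## Latent classes",
    "",
    sprintf("- selected C = %d; shares: %s", length(report$lc_shares),
            paste(sprintf("%.3f", report$lc_shares), collapse = ", ")),
    "",
    "## Type x severity interaction (OR vs severe prostate cancer)",
    "",
    sprintf("- %s, %s: OR %.2f%s", report$interaction_grid$type,
            report$interaction_grid$severity, report$interaction_grid$or,
            ifelse(report$interaction_grid$crosses_null, " (CI crosses 1)", "")))
}
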