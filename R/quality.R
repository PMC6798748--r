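#' Response-quality screening
#'
#' Four standard stated-preference quality criteria, reconstructed from
#' common practice (the exact operationalizations of the original study are
#' in an unavailable supplement):
#' \describe{
#'   \item{desirability}{the respondent prioritized the dominating profile
#'     in the dominance task of their block;}
#'   \item{stability}{the priority answer on the repeat task equals the
#'     priority answer on the standard task it repeats;}
#'   \item{consistency}{whenever exactly one of the two profiles received
#'     admit = yes, the priority answer names that profile; at most
#'     `max_inconsistencies` violations are tolerated;}
#'   \item{response time}{the respondent's median per-task response time is
#'     at least `min_median_ms` milliseconds.}
#' }
#'
#' @param responses long-format response data (see [simulate_responses()]).
#' @param design the `dce_design` the responses were collected on.
#' @param min_median_ms minimum acceptable median per-task response time.
#' @param max_inconsistencies tolerated admit/priority contradictions.
#' @return data.frame, one row per respondent: `respondent_id,
#'   desirability_pass, stability_pass, consistency_pass,
#'   response_time_pass, n_failed`.
#' @export
assess_quality <- function(responses, design, min_median_ms = 2000L,
                           max_inconsistencies = 1L) {
  attrs <- design_attrs(design)
  ddf <- as.data.frame(design)
  # dominant alternative of each dominance task
  dom_alt <- list()
  for (tid in unique(ddf$task_id[ddf$task_type == "dominance"])) {
    rows <- ddf[ddf$task_id == tid, , drop = FALSE]
    a <- rows[rows$alternative == "A", names(attrs), drop = FALSE]
    b <- rows[rows$alternative == "B", names(attrs), drop = FALSE]
    dom_alt[[as.character(tid)]] <-
      if (dominates(a, b, attrs)) "A" else if (dominates(b, a, attrs)) "B" else NA_character_
  }
  out <- lapply(split(responses, responses$respondent_id), function(r) {
    rid <- r$respondent_id[1]
    dom <- r[r$task_type == "dominance", , drop = FALSE]
    rep_t <- r[r$task_type == "repeat", , drop = FALSE]
    if (nrow(dom) == 0L) {
      stop("respondent ", rid, " has no dominance task", call. = FALSE)
    }
    if (nrow(rep_t) == 0L) {
      stop("respondent ", rid, " has no repeat task", call. = FALSE)
    }
    prio_of <- function(rows) rows$alternative[rows$priority_chosen == 1][1]
    # desirability
    want <- dom_alt[[as.character(dom$task_id[1])]]
    desirability <- !is.na(want) && identical(prio_of(dom), want)
    # stability
    orig <- r[r$task_id == rep_t$repeat_of[1], , drop = FALSE]
    stability <- nrow(orig) > 0 && identical(prio_of(rep_t), prio_of(orig))
    # logical consistency across all presented tasks
    viol <- 0L
    for (tid in unique(r$task_id)) {
      rows <- r[r$task_id == tid, , drop = FALSE]
      adm <- stats::setNames(rows$admit, rows$alternative)
      if (sum(adm) == 1L) {
        admitted <- names(adm)[adm == 1]
        if (!identical(prio_of(rows), admitted)) viol <- viol + 1L
      }
    }
    consistency <- viol <= max_inconsistencies
    # response time
    rt <- r$response_time_ms[r$alternative == "A"]
    response_time <- stats::median(rt) >= min_median_ms
    data.frame(respondent_id = rid,
               desirability_pass = desirability, stability_pass = stability,
               consistency_pass = consistency, response_time_pass = response_time,
               n_failed = sum(!c(desirability, stability, consistency,
                                 response_time)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize quality reports over a sample
#'
#' @param reports output of [assess_quality()].
#' @return list with `proportion_all_pass`, `max_failures_observed`, and
#'   `pass_rates` (named per-criterion pass proportions).
#' @export
quality_summary <- function(reports) {
  if (is.null(reports) || nrow(reports) == 0L) {
    stop("no quality reports supplied", call. = FALSE)
  }
  crit <- c("desirability_pass", "stability_pass", "consistency_pass",
            "response_time_pass")
  list(proportion_all_pass = mean(reports$n_failed == 0),
       max_failures_observed = max(reports$n_failed),
       pass_rates = vapply(crit, function(k) mean(reports[[k]]), numeric(1)))
}

#' @rdname assess_quality
#' @param reports quality report data.frame.
#' @param path output CSV path.
#' @export
write_quality <- function(reports, path) {
  out <- data.frame(respondent_id = reports$respondent_id,
                    desirability = as.integer(reports$desirability_pass),
                    stability = as.integer(reports$stability_pass),
                    consistency = as.integer(reports$consistency_pass),
                    response_time = as.integer(reports$response_time_pass),
                    n_failed = reports$n_failed)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
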