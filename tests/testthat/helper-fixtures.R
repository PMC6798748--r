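# Shared fixtures: tiny attribute spaces, hand-built designs and responses,
# and fake fit objects. Everything is generated in code; no stored data.

toy_attrs2 <- function() {
  dce_attributes(list(
    list(name = "a", label = "A", levels = c("lo", "hi"), reference = "lo",
         ordinal = FALSE),
    list(name = "b", label = "B", levels = c("x", "y"), reference = "x",
         ordinal = FALSE)))
}

# three binary non-ordinal attributes: the smallest space where a 4-task
# design can carry a nonsingular 3-parameter information matrix
toy_attrs_bin3 <- function() {
  dce_attributes(lapply(c("u", "v", "w"), function(nm) {
    list(name = nm, label = nm, levels = c("0", "1"), reference = "0",
         ordinal = FALSE)
  }))
}

toy_attrs3 <- function() {
  dce_attributes(list(
    list(name = "age", label = "age", levels = c("39", "66", "89"),
         reference = "89", ordinal = TRUE),
    list(name = "sev", label = "severity", levels = c("mild", "mod", "sev"),
         reference = "sev", ordinal = TRUE),
    list(name = "fam", label = "family", levels = c("pro", "unk", "anti"),
         reference = "unk", ordinal = TRUE)))
}

# wrap a task table (profile label columns) into a dce_design
make_design <- function(df, attrs, n_blocks = 1L) {
  icudce:::new_dce_design(df, attrs, n_blocks)
}

# a one-block design on toy_attrs3 with 2 standard tasks, 1 dominance,
# 1 repeat (of task 1) and 1 warmup, built by hand
fixture_design <- function() {
  attrs <- toy_attrs3()
  row <- function(task, type, rep_of, alt, age, sev, fam) {
    data.frame(task_id = task, block_id = 1L, alternative = alt,
               task_type = type, repeat_of = rep_of, age = age, sev = sev,
               fam = fam, stringsAsFactors = FALSE)
  }
  df <- rbind(
    row(1L, "standard", NA_integer_, "A", "39", "sev", "unk"),
    row(1L, "standard", NA_integer_, "B", "89", "mild", "unk"),
    row(2L, "standard", NA_integer_, "A", "66", "mild", "anti"),
    row(2L, "standard", NA_integer_, "B", "39", "mod", "pro"),
    row(3L, "dominance", NA_integer_, "A", "39", "mild", "pro"),
    row(3L, "dominance", NA_integer_, "B", "89", "sev", "anti"),
    row(4L, "repeat", 1L, "A", "39", "sev", "unk"),
    row(4L, "repeat", 1L, "B", "89", "mild", "unk"),
    row(5L, "warmup", NA_integer_, "A", "66", "mod", "unk"),
    row(5L, "warmup", NA_integer_, "B", "39", "sev", "anti"))
  make_design(df, attrs)
}

# deterministic responses for one respondent on fixture_design(); answers
# follow the utility ordering implied by `beta` (named by coded columns),
# with overrides for planting single violations
fixture_responses <- function(rid = "R1",
                              beta = c("age.39" = 2, "age.66" = 1,
                                       "sev.mild" = 1.5, "sev.mod" = 0.7,
                                       "fam.pro" = 0.5, "fam.anti" = -1.5),
                              rt_ms = 5000L,
                              flip_priority_tasks = integer(0),
                              contradict_tasks = integer(0)) {
  design <- fixture_design()
  attrs <- icudce:::design_attrs(design)
  df <- as.data.frame(design)
  X <- icudce:::code_profiles(df[names(attrs)], attrs)
  v <- drop(X %*% beta[colnames(X)])
  df$respondent_id <- rid
  df$admit <- as.integer(v > 0)
  df$priority_chosen <- 0L
  for (tid in unique(df$task_id)) {
    i <- which(df$task_id == tid)
    best <- i[which.max(v[i])]
    df$priority_chosen[best] <- 1L
    if (tid %in% flip_priority_tasks) {
      df$priority_chosen[i] <- 1L - df$priority_chosen[i]
    }
    if (tid %in% contradict_tasks) {
      # admit only the preferred profile but prioritize the other one
      df$admit[i] <- df$priority_chosen[i]
      df$priority_chosen[i] <- 1L - df$priority_chosen[i]
    }
  }
  df$response_time_ms <- rt_ms
  df[c("respondent_id", "task_id", "block_id", "alternative", "task_type",
       "repeat_of", names(attrs), "admit", "priority_chosen",
       "response_time_ms")]
}

# fake logit fit with chosen coefficients and zero (or given) covariance
fake_fit <- function(beta, attrs, vcov = NULL, model = "admit") {
  meta <- coding_metadata(attrs)
  nm <- if (model == "admit") c("(Intercept)", meta$column) else meta$column
  b <- stats::setNames(rep(0, length(nm)), nm)
  b[names(beta)] <- beta
  V <- if (is.null(vcov)) matrix(0, length(b), length(b),
                                 dimnames = list(nm, nm)) else vcov
  structure(list(beta = b, vcov = V, loglik = NA_real_, null_loglik = NA_real_,
                 n_obs = 0L, n_clusters = 0L, converged = TRUE,
                 iterations = 0L, meta = meta, model = model, attrs = attrs),
            class = "dce_logit_fit")
}

# single-class population with the default pooled target coefficients
single_class_population <- function(attrs = default_attributes(),
                                    beta = icudce:::pooled_target_beta(),
                                    alpha = NULL) {
  if (is.null(alpha)) {
    X <- icudce:::code_profiles(enumerate_full_factorial(attrs), attrs)
    alpha <- icudce:::solve_alpha(drop(X %*% beta[colnames(X)]))
  }
  dce_population(list(list(label = "only", share = 1, alpha = alpha,
                           beta = beta)), attrs)
}

# canonical study design used by several heavier tests (built once per run)
study_design <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- generate_design(default_attributes(), 24L, 2L, seed = 1L)
      cache <<- inject_quality_tasks(d, seed = 2L)
    }
    cache
  }
})
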