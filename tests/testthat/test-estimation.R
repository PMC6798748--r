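make_responses <- function(n = 200, seed = 31L, attrs = default_attributes(),
                           pop = NULL, design = NULL, careless = 0) {
  if (is.null(pop)) pop <- single_class_population(attrs)
  if (is.null(design)) design <- study_design()
  rs <- simulate_respondents(n, pop, careless_rate = careless, seed = seed)
  simulate_responses(rs, design, pop, seed = seed + 1L)
}

test_that("dummy coding has the documented shape and rejects unknown levels", {
  attrs <- default_attributes()
  rr <- make_responses(20)
  coded <- code_dataset(rr, attrs, "admit")
  expect_equal(ncol(coded$X), 15L)  # 1 + sum(L_k - 1)
  expect_equal(colnames(coded$X)[1], "(Intercept)")
  expect_false(any(unique(rr$task_id[rr$task_type != "standard"]) %in%
                     coded$ids$task_id))
  # priority model: difference coding, no intercept
  pri <- code_dataset(rr, attrs, "priority")
  expect_equal(ncol(pri$X), 14L)
  # identical profiles -> an all-zero priority row
  one <- rr[rr$respondent_id == rr$respondent_id[1] & rr$task_id == rr$task_id[1], ]
  one[one$alternative == "B", names(attrs)] <- one[one$alternative == "A", names(attrs)]
  pri1 <- code_dataset(one, attrs, "priority")
  expect_true(all(pri1$X == 0))
  # reference-level-only profile codes to intercept only
  ref <- as.data.frame(lapply(attrs, `[[`, "reference"), optional = TRUE)
  names(ref) <- names(attrs)
  x <- icudce:::code_profiles(ref, attrs, intercept = TRUE)
  expect_equal(sum(x), 1)
  # unknown level errors name the attribute
  bad <- rr
  bad$age[3] <- "97"
  expect_error(code_dataset(bad, attrs, "admit"), "age")
})

test_that("coding round-trips back to level labels", {
  attrs <- default_attributes()
  rr <- make_responses(10)
  X <- icudce:::code_profiles(rr[names(attrs)], attrs)
  back <- icudce:::decode_profiles(X, attrs)
  expect_equal(back, rr[names(attrs)], ignore_attr = TRUE)
})

test_that("intercept-only fit on balanced data returns exactly zero", {
  coded <- structure(list(
    y = rep(c(0, 1), 25),
    X = matrix(1, 50, 1, dimnames = list(NULL, "(Intercept)")),
    cluster = as.character(rep(1:10, each = 5)),
    meta = data.frame(column = character(0), attribute = character(0),
                      level = character(0)),
    model = "admit", attrs = NULL), class = "dce_coded")
  fit <- fit_logit(coded)
  expect_identical(unname(fit$beta), 0)
  expect_true(fit$converged)
})

test_that("one-parameter MLE matches a grid-search oracle", {
  set.seed(41)
  x <- c(-2, -1.5, -1, -0.5, 0, 0.5, 1, 1.5, 2, 3)
  y <- c(0, 0, 1, 0, 1, 0, 1, 1, 1, 1)
  coded <- structure(list(
    y = y, X = matrix(x, ncol = 1, dimnames = list(NULL, "x")),
    cluster = as.character(1:10),
    meta = data.frame(column = "x", attribute = "x", level = "x"),
    model = "priority", attrs = NULL), class = "dce_coded")
  fit <- fit_logit(coded)
  grid <- seq(-10, 10, by = 1e-4)
  ll <- vapply(grid, function(b) sum(y * stats::plogis(x * b, log.p = TRUE) +
                                       (1 - y) * stats::plogis(-x * b, log.p = TRUE)),
               numeric(1))
  expect_lt(abs(unname(fit$beta) - grid[which.max(ll)]), 1e-3)
  expect_gte(fit$loglik, max(ll))
})

test_that("pooled logit recovers generating coefficients within 3 SE", {
  attrs <- default_attributes()
  pop <- single_class_population(attrs)
  rr <- make_responses(300, seed = 51L, pop = pop)
  fit <- fit_logit(code_dataset(rr, attrs, "admit"))
  truth <- c(`(Intercept)` = pop$classes[[1]]$alpha, pop$classes[[1]]$beta)
  se <- sqrt(diag(fit$vcov))
  expect_true(all(abs(fit$beta - truth[names(fit$beta)]) <= 3 * se))
  # the priority conditional logit recovers the same preferences up to noise
  pfit <- fit_logit(code_dataset(rr, attrs, "priority"))
  pse <- sqrt(diag(pfit$vcov))
  expect_true(all(abs(pfit$beta - pop$classes[[1]]$beta[names(pfit$beta)]) <=
                    3 * pse))
})

test_that("estimates are invariant to row order; A/B flip mirrors the priority model", {
  attrs <- default_attributes()
  rr <- make_responses(60, seed = 61L)
  fit <- fit_logit(code_dataset(rr, attrs, "admit"))
  perm <- rr[sample(nrow(rr)), ]
  fit_p <- fit_logit(code_dataset(perm, attrs, "admit"))
  expect_equal(fit$beta, fit_p$beta, tolerance = 1e-8)
  expect_equal(fit$loglik, fit_p$loglik, tolerance = 1e-8)
  # relabeling alternatives A <-> B flips both the difference coding and the
  # response, so estimates are unchanged in either model
  flip <- rr
  flip$alternative <- ifelse(rr$alternative == "A", "B", "A")
  fit_f <- fit_logit(code_dataset(flip, attrs, "admit"))
  expect_equal(fit$beta, fit_f$beta, tolerance = 1e-8)
  pri <- fit_logit(code_dataset(rr, attrs, "priority"))
  pri_f <- fit_logit(code_dataset(flip, attrs, "priority"))
  expect_equal(pri$beta, pri_f$beta, tolerance = 1e-8)
  # complementing only the response definition flips the sign of beta
  neg <- rr
  neg$priority_chosen <- 1L - rr$priority_chosen
  pri_n <- fit_logit(code_dataset(neg, attrs, "priority"))
  expect_equal(pri$beta, -pri_n$beta, tolerance = 1e-8)
  # fitted likelihood always beats the null
  expect_gte(fit$loglik, fit$null_loglik)
  expect_gte(pri$loglik, pri$null_loglik)
})

test_that("degenerate design matrices raise informative errors", {
  rr <- make_responses(20, seed = 71L)
  attrs <- default_attributes()
  coded <- code_dataset(rr, attrs, "admit")
  coded$X <- cbind(coded$X, dup = coded$X[, "age.39"])
  expect_error(fit_logit(coded), "collinear.*dup")
  # perfect separation
  sep <- structure(list(
    y = c(0, 0, 0, 1, 1, 1),
    X = matrix(c(-3, -2, -1, 1, 2, 3), ncol = 1,
               dimnames = list(NULL, "z")),
    cluster = as.character(1:6),
    meta = data.frame(column = "z", attribute = "z", level = "z"),
    model = "priority", attrs = NULL), class = "dce_coded")
  expect_error(fit_logit(sep), "separation")
})

test_that("odds ratios obey the contrast arithmetic", {
  attrs <- default_attributes()
  fit <- fake_fit(c("comorb_severity.mild" = log(6.4), "age.39" = log(12)),
                  attrs)
  tab <- odds_ratios(fit)
  expect_equal(tab$or[tab$level == "mild"], 6.4, tolerance = 1e-12)
  expect_equal(tab$ci_low[tab$level == "mild"], 6.4, tolerance = 1e-12)
  # zero contrast
  z <- stats::setNames(rep(0, length(fit$beta)), names(fit$beta))
  tab0 <- odds_ratios(fit, contrasts = list(null = z))
  expect_equal(tab0$or, 1)
  expect_equal(tab0$ci_low, 1)
  expect_equal(tab0$ci_high, 1)
  # reciprocal property OR(c) * OR(-c) = 1
  cv <- z; cv["age.39"] <- 1; cv["age.66"] <- -2
  both <- odds_ratios(fit, contrasts = list(up = cv, down = -cv))
  expect_equal(both$or[1] * both$or[2], 1, tolerance = 1e-12)
  # "times less likely" rendering
  fit2 <- fake_fit(c("comorb_type.dementia" = -log(1.48)), attrs)
  tab2 <- odds_ratios(fit2)
  expect_equal(tab2$reciprocal[tab2$level == "dementia"], 1.48,
               tolerance = 1e-12)
  expect_error(odds_ratios(fit, contrasts = list(short = c(1, 2))), "length")
})

test_that("predicted admission probabilities follow the logit", {
  attrs <- default_attributes()
  fit <- fake_fit(c("age.39" = log(12)), attrs)
  ref_profile <- lapply(attrs, `[[`, "reference")
  expect_equal(predict_admission(fit, ref_profile), 0.5)
  young <- ref_profile; young$age <- "39"
  p_young <- predict_admission(fit, young)
  p_old <- predict_admission(fit, ref_profile)
  expect_equal((p_young / (1 - p_young)) / (p_old / (1 - p_old)), 12,
               tolerance = 1e-12)
  # monotone in each coefficient
  fit_hi <- fake_fit(c("age.39" = log(12) + 0.5), attrs)
  expect_gt(predict_admission(fit_hi, young), p_young)
  bad <- ref_profile; bad$age <- "97"
  expect_error(predict_admission(fit, bad), "age")
})
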