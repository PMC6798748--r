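#' Code a choice dataset for estimation
#'
#' Dummy-codes long-format responses against the configured reference
#' levels. Two model layouts are supported:
#' \describe{
#'   \item{admit}{one row per respondent x task x alternative; response is
#'     the binary admit answer; design matrix has an intercept plus one
#'     dummy per non-reference level.}
#'   \item{priority}{one row per respondent x task; design matrix is the
#'     coded difference profile A minus profile B, no intercept; response is
#'     1 when A was prioritized (paired conditional logit).}
#' }
#' Warm-up tasks are always excluded; repeat and dominance quality tasks are
#' excluded by default so quality checks do not double-count information.
#'
#' @param responses long-format response data.frame (see
#'   [simulate_responses()] for the column contract).
#' @param attrs a `dce_attributes` object.
#' @param model `"admit"` or `"priority"`.
#' @param include_quality if TRUE, repeat and dominance tasks enter the
#'   likelihood as ordinary observations.
#' @return a `dce_coded` list: `y`, `X`, `cluster` (respondent ids),
#'   `meta` (column metadata), `model`, `attrs`, `ids`.
#' @export
code_dataset <- function(responses, attrs, model = c("admit", "priority"),
                         include_quality = FALSE) {
  model <- match.arg(model)
  attrs <- as_dce_attributes(attrs)
  keep_types <- if (include_quality) c("standard", "dominance", "repeat") else "standard"
  d <- responses[responses$task_type %in% keep_types, , drop = FALSE]
  if (nrow(d) == 0L) stop("no estimable rows after task-type filtering", call. = FALSE)
  if (model == "admit") {
    X <- code_profiles(d[names(attrs)], attrs, intercept = TRUE)
    coded <- list(y = as.numeric(d$admit), X = X,
                  cluster = as.character(d$respondent_id),
                  ids = d[c("respondent_id", "task_id", "alternative")])
  } else {
    a <- d[d$alternative == "A", , drop = FALSE]
    b <- d[d$alternative == "B", , drop = FALSE]
    key <- function(z) paste(z$respondent_id, z$task_id)
    b <- b[match(key(a), key(b)), , drop = FALSE]
    X <- code_profiles(a[names(attrs)], attrs) - code_profiles(b[names(attrs)], attrs)
    coded <- list(y = as.numeric(a$priority_chosen), X = X,
                  cluster = as.character(a$respondent_id),
                  ids = a[c("respondent_id", "task_id")])
  }
  coded$meta <- coding_metadata(attrs)
  coded$model <- model
  coded$attrs <- attrs
  structure(coded, class = "dce_coded")
}

bernoulli_loglik <- function(eta, y, w = NULL) {
  # numerically safe: -log(1+exp(-eta)) etc. via plogis on log scale
  ll <- y * stats::plogis(eta, log.p = TRUE) +
    (1 - y) * stats::plogis(-eta, log.p = TRUE)
  if (is.null(w)) sum(ll) else sum(w * ll)
}

# Newton-Raphson with step-halving for the Bernoulli logit.
# Accepts fractional y and observation weights (used by the latent-class
# M-step and by the population calibration). Returns last iterate on
# non-convergence together with converged = FALSE.
newton_logit <- function(X, y, weights = NULL, start = NULL,
                         tol = 1e-8, max_iter = 100L) {
  n <- nrow(X); K <- ncol(X)
  w <- if (is.null(weights)) rep(1, n) else weights
  beta <- if (is.null(start)) rep(0, K) else start
  ll <- bernoulli_loglik(drop(X %*% beta), y, w)
  converged <- FALSE
  iter <- 0L
  grad <- rep(NA_real_, K)
  while (iter < max_iter) {
    iter <- iter + 1L
    p <- stats::plogis(drop(X %*% beta))
    grad <- drop(crossprod(X, w * (y - p)))
    if (max(abs(grad)) <= tol) { converged <- TRUE; break }
    wt <- w * p * (1 - p)
    H <- crossprod(X * sqrt(wt))
    delta <- tryCatch(solve(H, grad), error = function(e)
      stop("Hessian is singular at iteration ", iter,
           "; check the design matrix for collinearity", call. = FALSE))
    step <- 1
    repeat {
      cand <- beta + step * delta
      ll_new <- bernoulli_loglik(drop(X %*% cand), y, w)
      if (ll_new >= ll - 1e-12 || step < 1e-10) break
      step <- step / 2
    }
    beta <- beta + step * delta
    ll <- bernoulli_loglik(drop(X %*% beta), y, w)
    if (max(abs(beta)) > 30) {
      j <- which.max(abs(beta))
      stop("apparent perfect separation: coefficient '", colnames(X)[j],
           "' diverged (|beta| > 30)", call. = FALSE)
    }
  }
  list(beta = stats::setNames(beta, colnames(X)), loglik = ll,
       converged = converged, iterations = iter, gradient = grad)
}

#' Fit a binary or paired-choice logit by maximum likelihood
#'
#' Newton-Raphson with step-halving on the Bernoulli log-likelihood
#' `sum(y log p + (1-y) log(1-p))`, `p = plogis(X beta)`; convergence when
#' the gradient max-norm falls below `tol`. The covariance is the sandwich
#' estimator clustered on respondent with a `G/(G-1)` small-sample factor.
#'
#' @param coded a `dce_coded` object from [code_dataset()].
#' @param tol gradient max-norm tolerance.
#' @param max_iter maximum Newton iterations.
#' @return a `dce_logit_fit`: `beta`, `vcov`, `loglik`, `null_loglik`,
#'   `n_obs`, `n_clusters`, `converged`, `iterations`, plus the coding
#'   metadata and model tag.
#' @export
fit_logit <- function(coded, tol = 1e-8, max_iter = 100L) {
  stopifnot(inherits(coded, "dce_coded"))
  X <- coded$X; y <- coded$y
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  res <- newton_logit(X, y, tol = tol, max_iter = max_iter)
  if (max(abs(res$beta)) > 15) {
    j <- which.max(abs(res$beta))
    stop("apparent perfect separation on column '", names(res$beta)[j],
         "' (|coefficient| > 15)", call. = FALSE)
  }
  if (!res$converged) {
    stop("logit did not converge in ", max_iter,
         " iterations (gradient max-norm ", format(max(abs(res$gradient))), ")",
         call. = FALSE)
  }
  p <- stats::plogis(drop(X %*% res$beta))
  A <- crossprod(X * sqrt(p * (1 - p)))      # observed = expected information
  sc <- X * (y - p)
  G <- rowsum(sc, coded$cluster)
  B <- crossprod(as.matrix(G))
  ng <- nrow(G)
  Ainv <- solve(A)
  V <- Ainv %*% B %*% Ainv * ng / max(ng - 1, 1)
  V <- (V + t(V)) / 2
  dimnames(V) <- list(colnames(X), colnames(X))
  null_ll <- if (coded$model == "admit") {
    bernoulli_loglik(rep(stats::qlogis(mean(y)), length(y)), y)
  } else {
    bernoulli_loglik(rep(0, length(y)), y)  # null conditional logit: p = 1/2
  }
  structure(list(beta = res$beta, vcov = V, loglik = res$loglik,
                 null_loglik = null_ll, n_obs = length(y), n_clusters = ng,
                 converged = res$converged, iterations = res$iterations,
                 meta = coded$meta, model = coded$model, attrs = coded$attrs),
            class = "dce_logit_fit")
}

#' @export
print.dce_logit_fit <- function(x, ...) {
  cat("Logit fit (", x$model, " model): ", length(x$beta), " coefficients, ",
      x$n_obs, " obs, ", x$n_clusters, " clusters\n", sep = "")
  cat(sprintf("log-likelihood %.3f (null %.3f), %d Newton iterations\n",
              x$loglik, x$null_loglik, x$iterations))
  se <- sqrt(diag(x$vcov))
  print(data.frame(estimate = round(x$beta, 4), se = round(se, 4),
                   or = round(exp(x$beta), 3)))
  invisible(x)
}

#' Odds ratios for level contrasts
#'
#' `OR = exp(c' beta)` with 95% Wald interval
#' `exp(c' beta +/- 1.96 sqrt(c' V c))`. By default one contrast per
#' non-reference level against its reference. ORs below 1 additionally carry
#' the reciprocal ("times less likely") in the `reciprocal` column.
#'
#' @param fit a `dce_logit_fit`.
#' @param contrasts optional named list of numeric contrast vectors
#'   conformable with `coef(fit)`.
#' @return data.frame `contrast, attribute, level, or, ci_low, ci_high,
#'   reciprocal`.
#' @export
odds_ratios <- function(fit, contrasts = NULL) {
  beta <- fit$beta; V <- fit$vcov
  if (is.null(contrasts)) {
    contrasts <- lapply(seq_len(nrow(fit$meta)), function(j) {
      v <- stats::setNames(rep(0, length(beta)), names(beta))
      v[fit$meta$column[j]] <- 1
      v
    })
    names(contrasts) <- paste0(fit$meta$attribute, ": ", fit$meta$level,
                               " vs ", vapply(fit$meta$attribute, function(a)
                                 fit$attrs[[a]]$reference, character(1)))
    attribute <- fit$meta$attribute
    level <- fit$meta$level
  } else {
    attribute <- rep(NA_character_, length(contrasts))
    level <- rep(NA_character_, length(contrasts))
  }
  rows <- lapply(seq_along(contrasts), function(i) {
    cv <- contrasts[[i]]
    if (length(cv) != length(beta)) {
      stop("contrast ", i, " has length ", length(cv), ", expected ",
           length(beta), call. = FALSE)
    }
    est <- sum(cv * beta)
    se <- sqrt(max(0, drop(t(cv) %*% V %*% cv)))
    or <- exp(est)
    data.frame(contrast = names(contrasts)[i] %||% paste0("c", i),
               attribute = attribute[i], level = level[i], or = or,
               ci_low = exp(est - 1.96 * se), ci_high = exp(est + 1.96 * se),
               reciprocal = if (or < 1) 1 / or else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predicted admission probability for a patient profile
#'
#' `plogis(alpha + V(profile))` under an admit-model fit; the backbone of a
#' decision-making simulator where a consultant can vary one factor of a
#' profile and watch the admission probability respond.
#'
#' @param fit an admit-model `dce_logit_fit`.
#' @param profile named character vector or list mapping every attribute to
#'   a level.
#' @return probability in (0, 1).
#' @export
predict_admission <- function(fit, profile) {
  if (fit$model != "admit") stop("prediction requires an admit-model fit", call. = FALSE)
  pf <- as.data.frame(lapply(profile, as.character), stringsAsFactors = FALSE,
                      optional = TRUE)
  x <- code_profiles(pf[names(fit$attrs)], fit$attrs, intercept = TRUE)
  stats::plogis(drop(x %*% fit$beta[colnames(x)]))
}

#' Likelihood-ratio test between nested logit fits
#'
#' @param full,reduced `dce_logit_fit` objects fitted to the same data.
#' @return list `stat`, `df`, `p_value`.
#' @export
lr_test <- function(full, reduced) {
  stat <- 2 * (full$loglik - reduced$loglik)
  df <- length(full$beta) - length(reduced$beta)
  if (df <= 0) stop("models are not nested in the expected direction", call. = FALSE)
  list(stat = stat, df = df, p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Serialize / restore a logit fit as JSON
#'
#' @param fit a `dce_logit_fit`.
#' @param path file path.
#' @export
write_fit <- function(fit, path) {
  obj <- list(model = fit$model,
              coefficients = as.list(fit$beta),
              vcov = fit$vcov, loglik = fit$loglik, null_loglik = fit$null_loglik,
              n_obs = fit$n_obs, n_clusters = fit$n_clusters,
              converged = fit$converged, iterations = fit$iterations,
              meta = fit$meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
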