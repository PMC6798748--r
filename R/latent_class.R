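#' Latent-class logit with covariate-driven class membership
#'
#' Finite mixture of admit logits: respondent `n` belongs to class `c` with
#' probability `pi_c(z_n; theta)` (multinomial logit on respondent
#' covariates, reference class fixed at zero) and answers each admit
#' question with probability `plogis(x' beta_c)`. The observed-data
#' log-likelihood `sum_n log sum_c pi_c(z_n) prod_t P(y_nt | beta_c)` is
#' maximized by EM from several random starts, followed by a quasi-Newton
#' (BFGS) polish of the full likelihood. The log-likelihood is asserted to
#' be non-decreasing at every EM iteration. Classes are relabelled in
#' descending share order (ties broken by the first coefficient), which
#' makes repeated fits with the same seed identical.
#'
#' @param coded a `dce_coded` admit-model dataset from [code_dataset()].
#' @param covariates respondent covariate data.frame (`respondent_id`,
#'   `age_band`, `years_in_icu`, `icu_size`, `hospital_type`, `gender`), or
#'   NULL for intercept-only (covariate-free) membership.
#' @param C number of latent classes (>= 1).
#' @param n_starts random EM initializations (best kept).
#' @param tol relative log-likelihood convergence tolerance for EM.
#' @param max_iter maximum EM iterations per start.
#' @param seed integer seed.
#' @param floor_frac a start is flagged degenerate and discarded when any
#'   class's posterior mass falls below `floor_frac` of respondents.
#' @return a `dce_lc_fit`: `n_classes`, `class_betas` (list), `theta`
#'   ((C-1) x p matrix, reference class last), `shares`, `posterior`,
#'   `loglik`, `aic`, `bic`, `n_params`, `converged`, `n_starts_used`,
#'   `best_start_seed`, `hessian`, plus metadata.
#' @export
fit_latent_class <- function(coded, covariates = NULL, C = 4L, n_starts = 20L,
                             tol = 1e-6, max_iter = 200L, seed = 1L,
                             floor_frac = 0.01) {
  stopifnot(inherits(coded, "dce_coded"), C >= 1L)
  X <- coded$X; y <- coded$y
  ids <- sort(unique(coded$cluster))
  N <- length(ids)
  gi <- match(coded$cluster, ids)
  K <- ncol(X)
  if (is.null(covariates)) {
    Z <- matrix(1, N, 1, dimnames = list(ids, "(Intercept)"))
  } else {
    miss <- setdiff(ids, covariates$respondent_id)
    if (length(miss)) stop("no covariate row for respondent(s): ",
                           paste(utils::head(miss, 3), collapse = ", "),
                           call. = FALSE)
    cv <- covariates[match(ids, covariates$respondent_id), , drop = FALSE]
    Z <- code_covariates(cv)
  }
  p <- ncol(Z)

  if (C == 1L) {
    fit <- fit_logit(coded)
    post <- matrix(1, N, 1, dimnames = list(ids, NULL))
    n_params <- K
    return(structure(list(
      n_classes = 1L, class_betas = list(fit$beta),
      theta = matrix(numeric(0), 0, p, dimnames = list(NULL, colnames(Z))),
      shares = 1, posterior = post, loglik = fit$loglik,
      n_params = n_params, aic = -2 * fit$loglik + 2 * n_params,
      bic = -2 * fit$loglik + log(N) * n_params,
      converged = TRUE, n_starts_used = 1L, best_start_seed = as.integer(seed),
      hessian = NULL, meta = coded$meta, attrs = coded$attrs, Z = Z, ids = ids,
      class_labels = "class 1"), class = "dce_lc_fit"))
  }

  log_f <- function(betas) {
    # N x C matrix of per-respondent class log-likelihoods
    out <- matrix(0, N, C)
    for (c in seq_len(C)) {
      eta <- drop(X %*% betas[[c]])
      ll <- y * stats::plogis(eta, log.p = TRUE) +
        (1 - y) * stats::plogis(-eta, log.p = TRUE)
      out[, c] <- rowsum(ll, gi)[, 1]
    }
    out
  }
  log_pi <- function(theta) {
    eta <- cbind(Z %*% t(theta), 0)
    eta - log(rowSums(exp(eta - apply(eta, 1, max)))) - apply(eta, 1, max)
  }
  obs_loglik <- function(betas, theta) {
    lw <- log_pi(theta) + log_f(betas)
    m <- apply(lw, 1, max)
    sum(m + log(rowSums(exp(lw - m))))
  }
  theta_mstep <- function(w, theta0) {
    pack <- as.vector(theta0)
    negll <- function(v) {
      th <- matrix(v, C - 1L, p)
      -sum(w * log_pi(th))
    }
    grad <- function(v) {
      th <- matrix(v, C - 1L, p)
      pi_n <- exp(log_pi(th))
      -as.vector(t(crossprod(Z, (w - pi_n)[, seq_len(C - 1L), drop = FALSE])))
    }
    res <- stats::optim(pack, negll, grad, method = "BFGS",
                        control = list(maxit = 100L))
    matrix(res$par, C - 1L, p, dimnames = dimnames(theta0))
  }

  best <- NULL
  n_used <- 0L
  for (s in seq_len(n_starts)) {
    start_seed <- as.integer(seed) + s - 1L
    w <- with_seed(start_seed, matrix(stats::rexp(N * C), N, C))
    w <- w / rowSums(w)
    betas <- replicate(C, stats::setNames(rep(0, K), colnames(X)),
                       simplify = FALSE)
    theta <- matrix(0, C - 1L, p, dimnames = list(NULL, colnames(Z)))
    ll_prev <- -Inf
    degenerate <- FALSE
    converged <- FALSE
    for (iter in seq_len(max_iter)) {
      # M-step (a diverging weighted logit marks the start degenerate)
      mstep_ok <- TRUE
      for (c in seq_len(C)) {
        wf <- w[gi, c]
        nb <- tryCatch(newton_logit(X, y, weights = wf, start = betas[[c]],
                                    tol = 1e-7, max_iter = 50L)$beta,
                       error = function(e) NULL)
        if (is.null(nb)) { mstep_ok <- FALSE; break }
        betas[[c]] <- nb
      }
      if (!mstep_ok) { degenerate <- TRUE; break }
      theta <- theta_mstep(w, theta)
      # E-step
      lw <- log_pi(theta) + log_f(betas)
      m <- apply(lw, 1, max)
      lse <- m + log(rowSums(exp(lw - m)))
      ll <- sum(lse)
      if (ll < ll_prev - 1e-6 * (1 + abs(ll_prev))) {
        stop("EM log-likelihood decreased (", ll_prev, " -> ", ll, ")",
             call. = FALSE)
      }
      w <- exp(lw - lse)
      if (min(colSums(w)) < floor_frac * N) { degenerate <- TRUE; break }
      if (is.finite(ll_prev) &&
          abs(ll - ll_prev) < tol * (1 + abs(ll))) { converged <- TRUE; break }
      ll_prev <- ll
    }
    if (degenerate) next
    n_used <- n_used + 1L
    if (is.null(best) || ll > best$ll) {
      best <- list(ll = ll, betas = betas, theta = theta, w = w,
                   seed = start_seed, converged = converged)
    }
  }
  if (is.null(best)) stop("all EM starts degenerated: no class retained ",
                          floor_frac * 100, "% of respondents", call. = FALSE)

  # quasi-Newton polish of the full observed-data likelihood
  pack <- function(betas, theta) c(unlist(betas), as.vector(theta))
  unpack <- function(v) {
    betas <- lapply(seq_len(C), function(c)
      stats::setNames(v[((c - 1) * K + 1):(c * K)], colnames(X)))
    theta <- matrix(v[(C * K + 1):(C * K + (C - 1) * p)], C - 1L, p,
                    dimnames = list(NULL, colnames(Z)))
    list(betas = betas, theta = theta)
  }
  negll_full <- function(v) {
    par <- unpack(v)
    -obs_loglik(par$betas, par$theta)
  }
  grad_full <- function(v) {
    par <- unpack(v)
    lw <- log_pi(par$theta) + log_f(par$betas)
    m <- apply(lw, 1, max)
    lse <- m + log(rowSums(exp(lw - m)))
    w <- exp(lw - lse)
    g_beta <- unlist(lapply(seq_len(C), function(c) {
      pc <- stats::plogis(drop(X %*% par$betas[[c]]))
      -drop(crossprod(X, w[gi, c] * (y - pc)))
    }))
    pi_n <- exp(log_pi(par$theta))
    g_theta <- -as.vector(t(crossprod(Z, (w - pi_n)[, seq_len(C - 1L),
                                                    drop = FALSE])))
    c(g_beta, g_theta)
  }
  pol <- stats::optim(pack(best$betas, best$theta), negll_full, grad_full,
                      method = "BFGS", control = list(maxit = 300L))
  use_pol <- -pol$value >= best$ll - 1e-8
  par <- if (use_pol) unpack(pol$par) else list(betas = best$betas,
                                                theta = best$theta)
  ll_final <- if (use_pol) -pol$value else best$ll

  # posterior and label switching: descending share, ties by first coefficient
  lw <- log_pi(par$theta) + log_f(par$betas)
  m <- apply(lw, 1, max)
  lse <- m + log(rowSums(exp(lw - m)))
  post <- exp(lw - lse)
  shares <- colMeans(post)
  b1 <- vapply(par$betas, `[[`, numeric(1), 2L)
  ord <- order(-shares, b1)
  betas <- par$betas[ord]
  post <- post[, ord, drop = FALSE]
  shares <- shares[ord]
  theta_full <- rbind(par$theta, 0)[ord, , drop = FALSE]
  theta <- sweep(theta_full[-C, , drop = FALSE], 2, theta_full[C, ], "-")
  labels <- paste("class", seq_len(C))
  rownames(theta) <- labels[-C]
  dimnames(post) <- list(ids, labels)
  names(betas) <- labels

  H <- tryCatch(stats::optimHess(pack(betas, theta), negll_full, grad_full),
                error = function(e) NULL)
  n_params <- C * K + (C - 1L) * p
  structure(list(
    n_classes = C, class_betas = betas, theta = theta, shares = shares,
    posterior = post, loglik = ll_final, n_params = n_params,
    aic = -2 * ll_final + 2 * n_params,
    bic = -2 * ll_final + log(N) * n_params,
    converged = best$converged, n_starts_used = n_used,
    best_start_seed = best$seed, hessian = H,
    meta = coded$meta, attrs = coded$attrs, Z = Z, ids = ids,
    class_labels = labels), class = "dce_lc_fit")
}

#' @export
print.dce_lc_fit <- function(x, ...) {
  cat("Latent-class logit: ", x$n_classes, " classes, loglik ",
      sprintf("%.3f", x$loglik), ", BIC ", sprintf("%.1f", x$bic), "\n",
      sep = "")
  cat("shares:", paste(sprintf("%.3f", x$shares), collapse = " "), "\n")
  invisible(x)
}

#' Scan the number of latent classes
#'
#' Fits the latent-class model for each candidate class count and tabulates
#' fit and information criteria; the BIC-minimizing row is flagged. A class
#' count that fails to converge (or whose starts all degenerate) is recorded
#' with `converged = FALSE`, not dropped.
#'
#' @inheritParams fit_latent_class
#' @param C_range integer vector of class counts to try.
#' @return data.frame `C, loglik, n_params, aic, bic, converged, best_bic`.
#' @export
select_classes <- function(coded, covariates = NULL, C_range = 1:6,
                           n_starts = 20L, seed = 1L, ...) {
  if (length(C_range) == 0L) stop("C_range is empty", call. = FALSE)
  rows <- lapply(C_range, function(C) {
    fit <- tryCatch(fit_latent_class(coded, covariates, C = C,
                                     n_starts = n_starts, seed = seed, ...),
                    error = function(e) NULL)
    if (is.null(fit)) {
      data.frame(C = C, loglik = NA_real_, n_params = NA_integer_,
                 aic = NA_real_, bic = NA_real_, converged = FALSE)
    } else {
      data.frame(C = C, loglik = fit$loglik, n_params = fit$n_params,
                 aic = fit$aic, bic = fit$bic, converged = fit$converged)
    }
  })
  tab <- do.call(rbind, rows)
  tab$best_bic <- FALSE
  if (any(!is.na(tab$bic))) tab$best_bic[which.min(tab$bic)] <- TRUE
  tab
}

#' Covariate effects on class membership
#'
#' Reports the membership multinomial-logit coefficients (each class versus
#' the reference class, the last after share ordering) with standard errors
#' from the polished full-likelihood Hessian and Wald p-values; stars mark
#' significance at the 5% level without multiplicity correction. When the
#' Hessian is singular or unavailable the standard errors are reported as
#' NA, never fabricated.
#'
#' @param fit a `dce_lc_fit` with `C >= 2`.
#' @return data.frame `covariate, class, coefficient, se, p_value, sig`.
#' @export
membership_effects <- function(fit) {
  if (fit$n_classes < 2L) stop("membership effects need C >= 2", call. = FALSE)
  C <- fit$n_classes
  K <- length(fit$class_betas[[1]])
  p <- ncol(fit$theta)
  idx <- (C * K + 1L):(C * K + (C - 1L) * p)
  se <- matrix(NA_real_, C - 1L, p)
  if (!is.null(fit$hessian)) {
    V <- tryCatch(solve(fit$hessian), error = function(e) NULL)
    if (!is.null(V)) {
      dv <- diag(V)[idx]
      if (all(is.finite(dv)) && all(dv > 0)) se <- matrix(sqrt(dv), C - 1L, p)
    }
  }
  ref <- fit$class_labels[C]
  rows <- do.call(rbind, lapply(seq_len(C - 1L), function(c) {
    data.frame(covariate = colnames(fit$theta),
               class = paste(fit$class_labels[c], "vs", ref),
               coefficient = fit$theta[c, ], se = se[c, ],
               stringsAsFactors = FALSE)
  }))
  rows$p_value <- 2 * stats::pnorm(-abs(rows$coefficient / rows$se))
  rows$sig <- !is.na(rows$p_value) & rows$p_value < 0.05
  rownames(rows) <- NULL
  rows
}

#' Per-class relative-importance profiles
#'
#' Applies the range-based relative importance to each class's coefficient
#' vector; the equal-weighting benchmark (100 / number of attributes) is
#' attached to each table.
#'
#' @param fit a `dce_lc_fit`.
#' @return named list of `dce_ri` data.frames, one per class.
#' @export
class_ri_profiles <- function(fit) {
  out <- lapply(fit$class_betas, function(b)
    relative_importance(attribute_ranges(b, fit$meta)))
  names(out) <- fit$class_labels
  out
}
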