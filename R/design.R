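#' Choice design objects
#'
#' A `dce_design` is a long-format data.frame with one row per
#' task x alternative: `task_id`, `block_id`, `alternative` ("A"/"B"),
#' `task_type` (standard/warmup/dominance/repeat), `repeat_of`, and one
#' character column per attribute holding the level label. The attribute
#' configuration, block count, D-error and generating seed travel as
#' attributes of the object.
#'
#' @name dce_design
NULL

new_dce_design <- function(df, attrs, n_blocks, d_err = NA_real_, seed = NA_integer_) {
  structure(df, class = c("dce_design", "data.frame"),
            attributes_cfg = attrs, n_blocks = n_blocks,
            d_error = d_err, seed = seed)
}

#' @export
print.dce_design <- function(x, ...) {
  tt <- table(x$task_type[x$alternative == "A"])
  cat("Choice design: ", sum(tt), " tasks (",
      paste(names(tt), tt, sep = "=", collapse = ", "), ") in ",
      attr(x, "n_blocks"), " block(s)", sep = "")
  if (is.finite(attr(x, "d_error"))) cat(sprintf("; D-error %.5f", attr(x, "d_error")))
  cat("\n")
  invisible(x)
}

design_attrs <- function(design) attr(design, "attributes_cfg")

# split design rows into per-task profile data.frames (A and B)
design_profiles <- function(design, types = NULL) {
  d <- as.data.frame(design)
  if (!is.null(types)) d <- d[d$task_type %in% types, , drop = FALSE]
  a <- d[d$alternative == "A", , drop = FALSE]
  b <- d[d$alternative == "B", , drop = FALSE]
  b <- b[match(a$task_id, b$task_id), , drop = FALSE]
  list(meta = a[c("task_id", "block_id", "task_type", "repeat_of")],
       A = a[setdiff(names(d), c("task_id", "block_id", "alternative",
                                 "task_type", "repeat_of"))],
       B = b[setdiff(names(d), c("task_id", "block_id", "alternative",
                                 "task_type", "repeat_of"))])
}

# D-error from a matrix of coded profile differences (tasks x K)
d_error_from_diffs <- function(D, beta) {
  eta <- drop(D %*% beta)
  p <- stats::plogis(eta)
  w <- p * (1 - p)
  M <- crossprod(D * sqrt(w))
  K <- ncol(D)
  if (qr(M)$rank < K) {
    stop(structure(class = c("icudce_singular_design", "error", "condition"),
                   list(message = "singular Fisher information: design not identified",
                        call = NULL)))
  }
  ld <- determinant(M, logarithm = TRUE)
  exp(-as.numeric(ld$modulus) / K)
}

#' D-error of a paired-profile design
#'
#' The D-error is `det(M)^(-1/K)` where `M` is the Fisher information of the
#' paired conditional logit evaluated at `prior_beta`, summed over the
#' standard tasks, and `K` the coefficient dimension (one dummy per
#' non-reference level). Lower is better.
#'
#' @param design a `dce_design`.
#' @param prior_beta prior coefficient vector (default all zero,
#'   utility-neutral).
#' @return positive scalar D-error.
#' @export
d_error <- function(design, prior_beta = NULL) {
  attrs <- design_attrs(design)
  pr <- design_profiles(design, types = "standard")
  if (nrow(pr$A) == 0L) stop("design has no standard tasks", call. = FALSE)
  D <- code_profiles(pr$A, attrs) - code_profiles(pr$B, attrs)
  if (is.null(prior_beta)) prior_beta <- rep(0, ncol(D))
  if (length(prior_beta) != ncol(D)) {
    stop("prior_beta has length ", length(prior_beta), ", coding needs ", ncol(D),
         call. = FALSE)
  }
  d_error_from_diffs(D, prior_beta)
}

pair_key <- function(a, b) {
  ka <- paste(unlist(a), collapse = "\r")
  kb <- paste(unlist(b), collapse = "\r")
  paste(sort(c(ka, kb)), collapse = "\n")
}

valid_pair <- function(a, b, attrs) {
  a <- unlist(a); b <- unlist(b)
  if (identical(unname(a), unname(b))) return(FALSE)
  if (dominates(a, b, attrs) || dominates(b, a, attrs)) return(FALSE)
  TRUE
}

draw_valid_pair <- function(factorial, attrs, max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    idx <- sample.int(nrow(factorial), 2L, replace = TRUE)
    a <- factorial[idx[1L], , drop = FALSE]
    b <- factorial[idx[2L], , drop = FALSE]
    if (valid_pair(a, b, attrs)) return(list(a = a, b = b))
  }
  stop("attribute space too small to supply non-dominated distinct pairs",
       call. = FALSE)
}

#' Generate a D-efficient blocked choice design
#'
#' Builds `n_tasks` paired-profile tasks by coordinate exchange: starting
#' from a random valid design, each sweep visits every
#' (task, alternative, attribute) cell in a seed-randomized order and
#' accepts the first level swap that strictly lowers the D-error while
#' keeping the pair valid (profiles distinct, no ordinal dominance, no
#' duplicate task). Tasks are then split into `n_blocks` equal blocks.
#'
#' @param attrs a `dce_attributes` object.
#' @param n_tasks number of standard tasks (divisible by `n_blocks`).
#' @param n_blocks number of blocks.
#' @param prior_beta prior coefficients for the D-error (default zero).
#' @param n_sweeps maximum coordinate-exchange sweeps (default 10; a sweep
#'   with no accepted swap stops the search).
#' @param seed integer seed; identical inputs and seed give an identical
#'   design.
#' @return a `dce_design` of standard tasks.
#' @export
generate_design <- function(attrs, n_tasks = 24L, n_blocks = 2L,
                            prior_beta = NULL, n_sweeps = 10L, seed = 1L) {
  attrs <- as_dce_attributes(attrs)
  if (n_tasks %% n_blocks != 0L) {
    stop("n_tasks (", n_tasks, ") must be divisible by n_blocks (", n_blocks, ")",
         call. = FALSE)
  }
  if (n_sweeps < 1L) stop("n_sweeps must be >= 1", call. = FALSE)
  local_seed(seed)
  meta <- coding_metadata(attrs)
  if (is.null(prior_beta)) prior_beta <- rep(0, nrow(meta))

  # integer-level internals: profiles are rows of level indices, with a
  # per-attribute dummy lookup so candidate coding is a table lookup
  nA <- length(attrs)
  L <- vapply(attrs, function(a) length(a$levels), integer(1))
  ordinal <- vapply(attrs, `[[`, logical(1), "ordinal")
  lookup <- lapply(attrs, function(a) {
    n <- length(a$levels)
    m <- matrix(0, n, n - 1L)
    nonref <- setdiff(a$levels, a$reference)
    for (j in seq_along(nonref)) m[match(nonref[j], a$levels), j] <- 1
    m
  })
  code_row <- function(prof) unlist(lapply(seq_len(nA), function(k)
    lookup[[k]][prof[k], ]), use.names = FALSE)
  # a weakly dominates b on ordinal attributes (lower index = better)
  dom_int <- function(a, b) {
    da <- a[ordinal]; db <- b[ordinal]
    all(da <= db) && any(da < db)
  }
  valid_int <- function(a, b) {
    !identical(a, b) && !dom_int(a, b) && !dom_int(b, a)
  }
  key_int <- function(a, b) {
    ka <- paste(a, collapse = ","); kb <- paste(b, collapse = ",")
    if (ka < kb) paste(ka, kb) else paste(kb, ka)
  }
  draw_int <- function() vapply(L, function(l) sample.int(l, 1L), integer(1))

  A <- B <- matrix(0L, n_tasks, nA)
  keys <- character(n_tasks)
  for (t in seq_len(n_tasks)) {
    tries <- 0L
    repeat {
      a <- draw_int(); b <- draw_int()
      if (valid_int(a, b)) {
        k <- key_int(a, b)
        if (!k %in% keys[seq_len(t - 1L)]) { A[t, ] <- a; B[t, ] <- b; keys[t] <- k; break }
      }
      tries <- tries + 1L
      if (tries > 2000L) stop("attribute space too small to supply ", n_tasks,
                              " non-dominated distinct pairs", call. = FALSE)
    }
  }

  XA <- t(apply(A, 1, code_row)); XB <- t(apply(B, 1, code_row))
  cur <- tryCatch(d_error_from_diffs(XA - XB, prior_beta),
                  icudce_singular_design = function(e) Inf)

  for (sweep in seq_len(n_sweeps)) {
    cells <- expand.grid(task = seq_len(n_tasks), alt = 1:2, attr = seq_len(nA))
    cells <- cells[sample.int(nrow(cells)), , drop = FALSE]
    improved <- FALSE
    for (i in seq_len(nrow(cells))) {
      t <- cells$task[i]; alt <- cells$alt[i]; k_attr <- cells$attr[i]
      cur_lvl <- if (alt == 1L) A[t, k_attr] else B[t, k_attr]
      for (lvl in setdiff(seq_len(L[k_attr]), cur_lvl)) {
        a_new <- A[t, ]; b_new <- B[t, ]
        if (alt == 1L) a_new[k_attr] <- lvl else b_new[k_attr] <- lvl
        if (!valid_int(a_new, b_new)) next
        k <- key_int(a_new, b_new)
        if (k %in% keys[-t]) next
        XA2 <- XA; XB2 <- XB
        XA2[t, ] <- code_row(a_new); XB2[t, ] <- code_row(b_new)
        cand <- tryCatch(d_error_from_diffs(XA2 - XB2, prior_beta),
                         icudce_singular_design = function(e) Inf)
        if (cand < cur) {  # first strictly improving swap accepted
          A[t, ] <- a_new; B[t, ] <- b_new
          XA <- XA2; XB <- XB2; keys[t] <- k
          cur <- cand; improved <- TRUE
          break
        }
      }
    }
    if (!improved) break
  }

  to_labels <- function(M) {
    df <- as.data.frame(lapply(seq_len(nA), function(k)
      attrs[[k]]$levels[M[, k]]), stringsAsFactors = FALSE, optional = TRUE)
    names(df) <- names(attrs)
    df
  }
  Adf <- to_labels(A); Bdf <- to_labels(B)
  block <- sample(rep(seq_len(n_blocks), each = n_tasks / n_blocks))
  long <- rbind(
    data.frame(task_id = seq_len(n_tasks), block_id = block, alternative = "A",
               task_type = "standard", repeat_of = NA_integer_, Adf,
               stringsAsFactors = FALSE),
    data.frame(task_id = seq_len(n_tasks), block_id = block, alternative = "B",
               task_type = "standard", repeat_of = NA_integer_, Bdf,
               stringsAsFactors = FALSE))
  long <- long[order(long$task_id, long$alternative), , drop = FALSE]
  rownames(long) <- NULL
  new_dce_design(long, attrs, n_blocks, cur, as.integer(seed))
}

# build the two profiles of a dominance task: ordinal attributes set to their
# best/worst levels, non-ordinal attributes held equal at a random level
make_dominance_pair <- function(attrs, factorial) {
  base <- factorial[sample.int(nrow(factorial), 1L), , drop = FALSE]
  dom <- und <- base
  for (a in attrs) {
    if (a$ordinal) {
      dom[[a$name]] <- a$levels[1L]
      und[[a$name]] <- a$levels[length(a$levels)]
    }
  }
  list(a = dom, b = und)
}

#' Inject warm-up and quality-check tasks into each block
#'
#' Adds, per block: one warm-up task (a random valid pair, excluded from
#' estimation), one dominance task (one profile better on every ordinal
#' attribute, non-ordinal attributes held equal), and one repeat of a
#' randomly chosen standard task in that block. The presented order within
#' a block puts the warm-up first; quality tasks are appended.
#'
#' @param design a `dce_design` of standard tasks.
#' @param seed integer seed.
#' @return a `dce_design` with 3 extra tasks per block.
#' @export
inject_quality_tasks <- function(design, seed = 1L) {
  attrs <- design_attrs(design)
  if (any(design$task_type != "standard")) {
    stop("design already contains non-standard tasks; inject only once",
         call. = FALSE)
  }
  if (!any(vapply(attrs, `[[`, logical(1), "ordinal"))) {
    stop("no ordinal attribute configured: cannot build a dominance task",
         call. = FALSE)
  }
  local_seed(seed)
  factorial <- enumerate_full_factorial(attrs)
  acols <- names(attrs)
  out <- as.data.frame(design)
  next_id <- max(out$task_id)
  for (blk in sort(unique(out$block_id))) {
    std_ids <- unique(out$task_id[out$block_id == blk & out$task_type == "standard"])
    warm <- draw_valid_pair(factorial, attrs)
    dom <- make_dominance_pair(attrs, factorial)
    rep_id <- if (length(std_ids) == 1L) std_ids else sample(std_ids, 1L)
    rep_rows <- out[out$task_id == rep_id, , drop = FALSE]
    add <- function(id, type, repeat_of, pa, pb) {
      rbind(
        cbind(data.frame(task_id = id, block_id = blk, alternative = "A",
                         task_type = type, repeat_of = repeat_of,
                         stringsAsFactors = FALSE), pa[acols]),
        cbind(data.frame(task_id = id, block_id = blk, alternative = "B",
                         task_type = type, repeat_of = repeat_of,
                         stringsAsFactors = FALSE), pb[acols]))
    }
    out <- rbind(out,
      add(next_id + 1L, "warmup", NA_integer_, warm$a, warm$b),
      add(next_id + 2L, "dominance", NA_integer_, dom$a, dom$b),
      add(next_id + 3L, "repeat", rep_id,
          rep_rows[rep_rows$alternative == "A", acols, drop = FALSE],
          rep_rows[rep_rows$alternative == "B", acols, drop = FALSE]))
    next_id <- next_id + 3L
  }
  rownames(out) <- NULL
  new_dce_design(out, attrs, attr(design, "n_blocks"),
                 attr(design, "d_error"), attr(design, "seed"))
}

#' Level balance diagnostic
#'
#' Counts how often each level of each attribute appears among the standard
#' tasks (both alternatives pooled). Reported, not enforced.
#'
#' @param design a `dce_design`.
#' @return data.frame `attribute, level, count`.
#' @export
level_balance <- function(design) {
  attrs <- design_attrs(design)
  std <- as.data.frame(design)[design$task_type == "standard", , drop = FALSE]
  do.call(rbind, lapply(attrs, function(a) {
    cnt <- vapply(a$levels, function(l) sum(std[[a$name]] == l), numeric(1))
    data.frame(attribute = a$name, level = a$levels, count = as.integer(cnt),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}

#' Read / write a design CSV
#'
#' One row per task x alternative:
#' `task_id, block_id, alternative, task_type, repeat_of, <attribute columns>`.
#'
#' @param design a `dce_design`.
#' @param path file path.
#' @param attrs attribute configuration used to revalidate on read.
#' @export
write_design <- function(design, path) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path, attrs) {
  attrs <- as_dce_attributes(attrs)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(repeat_of = "integer"))
  for (a in attrs) df[[a$name]] <- as.character(df[[a$name]])
  code_profiles(df[names(attrs)], attrs)  # validates level labels
  n_blocks <- length(unique(df$block_id))
  new_dce_design(df, attrs, n_blocks)
}
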