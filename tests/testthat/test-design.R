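test_that("full factorial enumerates the product space deterministically", {
  a2 <- toy_attrs2()
  expect_equal(nrow(enumerate_full_factorial(a2)), 4L)

  a3 <- dce_attributes(list(
    list(name = "p", label = "p", levels = c("1", "2", "3"), reference = "1",
         ordinal = FALSE),
    list(name = "q", label = "q", levels = c("1", "2", "3", "4"),
         reference = "1", ordinal = FALSE),
    list(name = "r", label = "r", levels = c("1", "2"), reference = "1",
         ordinal = FALSE)))
  expect_equal(nrow(enumerate_full_factorial(a3)), 24L)

  # packaged default configuration against an independent counting loop
  attrs <- default_attributes()
  ff <- enumerate_full_factorial(attrs)
  count <- 1L
  for (a in attrs) count <- count * length(a$levels)
  expect_equal(nrow(ff), count)
  expect_equal(nrow(unique(ff)), count)
  # lexicographic: first attribute varies slowest
  expect_equal(unique(ff[[1]]), attrs[[1]]$levels)
  expect_equal(ff[[length(attrs)]][1:2],
               attrs[[length(attrs)]]$levels[1:2])
})

test_that("attribute configuration is validated", {
  expect_error(dce_attributes(list()), "empty")
  expect_error(dce_attributes(list(list(name = "a", label = "a",
                                        levels = "only", reference = "only",
                                        ordinal = FALSE))),
               "fewer than 2 levels")
  expect_error(dce_attributes(list(list(name = "a", label = "a",
                                        levels = c("x", "y"), reference = "z",
                                        ordinal = FALSE))),
               "reference level")
  cfg <- tempfile(fileext = ".yaml")
  write_attributes(default_attributes(), cfg)
  expect_equal(read_attributes(cfg), default_attributes())
})

test_that("D-error matches a hand-assembled information oracle", {
  attrs <- toy_attrs2()
  df <- rbind(
    data.frame(task_id = 1L, block_id = 1L, alternative = c("A", "B"),
               task_type = "standard", repeat_of = NA_integer_,
               a = c("hi", "lo"), b = c("x", "y")),
    data.frame(task_id = 2L, block_id = 1L, alternative = c("A", "B"),
               task_type = "standard", repeat_of = NA_integer_,
               a = c("lo", "hi"), b = c("y", "x")))
  des <- make_design(df, attrs)
  # oracle: assemble M element-by-element from closed-form logit information
  D <- rbind(c(1, -1), c(-1, 1))          # coded diffs (a.hi, b.y) per task
  beta0 <- c(0, 0)
  M <- matrix(0, 2, 2)
  for (t in 1:2) {
    p <- 1 / (1 + exp(-sum(D[t, ] * beta0)))
    for (j in 1:2) for (k in 1:2) {
      M[j, k] <- M[j, k] + p * (1 - p) * D[t, j] * D[t, k]
    }
  }
  expect_error(d_error(des), "singular")  # the two diffs are collinear

  df$b <- c("x", "y", "y", "y")           # break collinearity
  des <- make_design(df, attrs)
  D <- rbind(c(1, -1), c(-1, 0))
  M <- matrix(0, 2, 2)
  for (t in 1:2) {
    p <- 0.5
    for (j in 1:2) for (k in 1:2) {
      M[j, k] <- M[j, k] + p * (1 - p) * D[t, j] * D[t, k]
    }
  }
  expect_equal(d_error(des), det(M)^(-1 / 2), tolerance = 1e-12)
})

test_that("duplicating every task exactly halves the D-error", {
  des <- generate_design(toy_attrs3(), n_tasks = 6L, n_blocks = 1L, seed = 4L)
  base <- d_error(des)
  df <- as.data.frame(des)
  dup <- df
  dup$task_id <- dup$task_id + max(df$task_id)
  des2 <- make_design(rbind(df, dup), toy_attrs3())
  expect_equal(d_error(des2), base / 2, tolerance = 1e-12)
})

test_that("identical profiles in every task give a singular-information error", {
  attrs <- toy_attrs2()
  df <- data.frame(task_id = c(1L, 1L), block_id = 1L,
                   alternative = c("A", "B"), task_type = "standard",
                   repeat_of = NA_integer_, a = "hi", b = "x")
  expect_error(d_error(make_design(df, attrs)),
               class = "icudce_singular_design")
})

test_that("generate_design returns the requested blocked structure", {
  attrs <- default_attributes()
  des <- generate_design(attrs, n_tasks = 24L, n_blocks = 2L, seed = 1L,
                         n_sweeps = 2L)
  a_rows <- des[des$alternative == "A", ]
  expect_equal(nrow(a_rows), 24L)
  expect_true(all(a_rows$task_type == "standard"))
  expect_equal(as.vector(table(a_rows$block_id)), c(12L, 12L))
  # no identical pairs, no dominated pairs
  pr <- icudce:::design_profiles(des, "standard")
  for (t in seq_len(nrow(pr$A))) {
    expect_false(identical(unlist(pr$A[t, ]), unlist(pr$B[t, ])))
    expect_false(dominates(pr$A[t, ], pr$B[t, ], attrs))
    expect_false(dominates(pr$B[t, ], pr$A[t, ], attrs))
  }
  # level balance diagnostic: every level appears at least once
  expect_true(all(level_balance(des)$count >= 1L))

  toy <- generate_design(toy_attrs2(), n_tasks = 4L, n_blocks = 1L, seed = 2L)
  expect_equal(sum(toy$alternative == "A"), 4L)
  expect_true(all(toy$block_id == 1L))
})

test_that("coordinate exchange beats pure random search", {
  attrs <- toy_attrs_bin3()
  # oracle: best of 1000 random valid designs drawn independently
  ff <- enumerate_full_factorial(attrs)
  set.seed(10)
  best_random <- Inf
  for (r in 1:1000) {
    rows <- list()
    for (t in 1:4) {
      repeat {
        ij <- sample.int(nrow(ff), 2L, replace = TRUE)
        if (!identical(unlist(ff[ij[1], ]), unlist(ff[ij[2], ])) &&
            !dominates(ff[ij[1], ], ff[ij[2], ], attrs) &&
            !dominates(ff[ij[2], ], ff[ij[1], ], attrs)) break
      }
      rows[[t]] <- cbind(
        data.frame(task_id = t, block_id = 1L, alternative = c("A", "B"),
                   task_type = "standard", repeat_of = NA_integer_),
        rbind(ff[ij[1], ], ff[ij[2], ]))
    }
    d <- tryCatch(d_error(make_design(do.call(rbind, rows), attrs)),
                  error = function(e) Inf)
    best_random <- min(best_random, d)
  }
  opt <- generate_design(attrs, n_tasks = 4L, n_blocks = 1L, seed = 10L,
                         n_sweeps = 10L)
  expect_lte(d_error(opt), best_random)
})

test_that("design generation is deterministic in the seed", {
  attrs <- toy_attrs3()
  d1 <- generate_design(attrs, 8L, 2L, seed = 5L)
  d2 <- generate_design(attrs, 8L, 2L, seed = 5L)
  d3 <- generate_design(attrs, 8L, 2L, seed = 6L)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  expect_false(identical(as.data.frame(d1), as.data.frame(d3)))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_design(d1, f1); write_design(d2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  back <- read_design(f1, attrs)
  expect_equal(as.data.frame(back)$age, as.data.frame(d1)$age)
})

test_that("infeasibly small attribute spaces are rejected", {
  tiny <- dce_attributes(list(
    list(name = "u", label = "u", levels = c("good", "bad"),
         reference = "bad", ordinal = TRUE),
    list(name = "v", label = "v", levels = c("good", "bad"),
         reference = "bad", ordinal = TRUE)))
  expect_error(generate_design(tiny, n_tasks = 4L, n_blocks = 1L, seed = 1L),
               "too small")
})

test_that("quality-task injection adds warmup, dominance and repeat per block", {
  des <- study_design()
  for (blk in 1:2) {
    types <- des$task_type[des$block_id == blk & des$alternative == "A"]
    expect_equal(sum(types == "standard"), 12L)
    expect_equal(length(types), 15L)
    expect_equal(sum(types == "warmup"), 1L)
    expect_equal(sum(types == "dominance"), 1L)
    expect_equal(sum(types == "repeat"), 1L)
  }
  # repeats duplicate a standard task of the same block exactly
  attrs <- icudce:::design_attrs(des)
  df <- as.data.frame(des)
  reps <- df[df$task_type == "repeat" & df$alternative == "A", ]
  for (i in seq_len(nrow(reps))) {
    orig <- df[df$task_id == reps$repeat_of[i], ]
    copy <- df[df$task_id == reps$task_id[i], ]
    expect_equal(orig$block_id[1], copy$block_id[1])
    expect_equal(orig[names(attrs)], copy[names(attrs)],
                 ignore_attr = TRUE)
  }
  expect_error(inject_quality_tasks(des, seed = 1L), "only once")
})

test_that("the dominance task dominates on every ordinal attribute", {
  des <- study_design()
  attrs <- icudce:::design_attrs(des)
  df <- as.data.frame(des)
  for (tid in unique(df$task_id[df$task_type == "dominance"])) {
    a <- df[df$task_id == tid & df$alternative == "A", names(attrs)]
    b <- df[df$task_id == tid & df$alternative == "B", names(attrs)]
    # exhaustive per-attribute comparison oracle
    strict <- 0L
    for (at in attrs) {
      ia <- match(a[[at$name]], at$levels)
      ib <- match(b[[at$name]], at$levels)
      if (at$ordinal) {
        expect_lte(ia, ib)
        if (ia < ib) strict <- strict + 1L
      } else {
        expect_equal(ia, ib)  # non-ordinal attributes held equal
      }
    }
    expect_gte(strict, 1L)
    expect_true(dominates(a, b, attrs))
  }
})

test_that("dominance tasks need an ordinal attribute", {
  flat <- dce_attributes(list(
    list(name = "a", label = "a", levels = c("x", "y"), reference = "x",
         ordinal = FALSE),
    list(name = "b", label = "b", levels = c("x", "y", "z"), reference = "x",
         ordinal = FALSE)))
  des <- generate_design(flat, n_tasks = 4L, n_blocks = 1L, seed = 3L)
  expect_error(inject_quality_tasks(des, seed = 1L), "ordinal")
})
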