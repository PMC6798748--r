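# Dummy coding of level labels against per-attribute reference levels.
# Shared by the design search (Fisher information) and the estimators.

# seed the RNG for the rest of the calling function, restoring the caller's
# caller RNG state when that function exits
local_seed <- function(seed, envir = parent.frame()) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  expr <- if (had) bquote(assign(".Random.seed", .(old), globalenv()))
  else quote(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  do.call(on.exit, list(expr, add = TRUE), envir = envir)
  set.seed(as.integer(seed))
}

# run code under a local RNG seed, restoring the caller's RNG state after
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Column metadata for the dummy coding of an attribute configuration
#'
#' One row per non-reference level, in attribute order then level order.
#'
#' @param attrs a `dce_attributes` object.
#' @return data.frame with columns `column` (coded column name,
#'   `<attribute>.<level>`), `attribute`, `level`.
#' @export
coding_metadata <- function(attrs) {
  attrs <- as_dce_attributes(attrs)
  rows <- do.call(rbind, lapply(attrs, function(a) {
    nonref <- setdiff(a$levels, a$reference)
    data.frame(column = paste(a$name, nonref, sep = "."),
               attribute = a$name, level = nonref,
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  rows
}

# profiles: data.frame of level labels (one column per attribute)
# returns numeric matrix, one dummy column per non-reference level
code_profiles <- function(profiles, attrs, intercept = FALSE) {
  attrs <- as_dce_attributes(attrs)
  meta <- coding_metadata(attrs)
  missing_attr <- setdiff(names(attrs), names(profiles))
  if (length(missing_attr)) {
    stop("profiles lack attribute column(s): ", paste(missing_attr, collapse = ", "),
         call. = FALSE)
  }
  for (a in attrs) {
    bad <- !profiles[[a$name]] %in% a$levels
    if (any(bad)) {
      stop("unknown level '", profiles[[a$name]][which(bad)[1]],
           "' for attribute '", a$name, "' (row ", which(bad)[1], ")",
           call. = FALSE)
    }
  }
  X <- vapply(seq_len(nrow(meta)), function(j) {
    as.numeric(profiles[[meta$attribute[j]]] == meta$level[j])
  }, numeric(nrow(profiles)))
  X <- matrix(X, nrow = nrow(profiles), ncol = nrow(meta),
              dimnames = list(NULL, meta$column))
  if (intercept) X <- cbind(`(Intercept)` = 1, X)
  X
}

# decode a coded row set back to level labels (coding round-trip)
decode_profiles <- function(X, attrs) {
  attrs <- as_dce_attributes(attrs)
  out <- lapply(attrs, function(a) {
    nonref <- setdiff(a$levels, a$reference)
    cols <- paste(a$name, nonref, sep = ".")
    sub <- X[, cols, drop = FALSE]
    lab <- rep(a$reference, nrow(X))
    hit <- sub == 1
    for (j in seq_along(nonref)) lab[hit[, j]] <- nonref[j]
    lab
  })
  as.data.frame(out, stringsAsFactors = FALSE, optional = TRUE)
}
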