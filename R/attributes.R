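#' Attribute configuration for a choice experiment
#'
#' An attribute is one patient factor shown in a choice task (for example
#' patient age), with a fixed set of discrete levels, a designated reference
#' level (coefficient fixed at 0 in all models), and an `ordinal` flag.
#' Ordinal attributes have their levels listed from most to least desirable
#' for admission; the dominance quality task and the design search use this
#' ordering, non-ordinal attributes are never compared across profiles.
#'
#' @param specs a list; each element a list with fields `name`, `label`,
#'   `levels` (character, length >= 2, unique), `reference` (one of
#'   `levels`), `ordinal` (logical).
#' @return an object of class `dce_attributes` (the validated list).
#' @export
dce_attributes <- function(specs) {
  if (length(specs) == 0L) stop("attribute configuration is empty", call. = FALSE)
  for (a in specs) {
    for (f in c("name", "label", "levels", "reference", "ordinal")) {
      if (is.null(a[[f]])) stop("attribute missing field '", f, "'", call. = FALSE)
    }
    if (length(a$levels) < 2L) {
      stop("attribute '", a$name, "' has fewer than 2 levels", call. = FALSE)
    }
    if (anyDuplicated(a$levels)) {
      stop("attribute '", a$name, "' has duplicate level labels", call. = FALSE)
    }
    if (!a$reference %in% a$levels) {
      stop("reference level '", a$reference, "' is not a level of '", a$name, "'",
           call. = FALSE)
    }
  }
  nm <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate attribute names", call. = FALSE)
  names(specs) <- nm
  structure(specs, class = "dce_attributes")
}

#' @export
print.dce_attributes <- function(x, ...) {
  cat("Choice-experiment attributes (", length(x), "):\n", sep = "")
  for (a in x) {
    cat(sprintf("  %-16s [%s%s] levels: %s (ref: %s)\n", a$name,
                if (a$ordinal) "ordinal" else "nominal",
                "", paste(a$levels, collapse = " | "), a$reference))
  }
  invisible(x)
}

#' The packaged study attribute configuration
#'
#' Eight patient-related factors: age, type and severity of the main
#' comorbidity, the family's view on admission, functional status, acute
#' severity (NEWS band), the registrar's subjective report, and ward nursing
#' capacity. Reference levels: 89 yr, prostate cancer, severe comorbidity,
#' family view not known, and the less admission-favouring level of the
#' remaining attributes. Ordinal flags are set only where a desirability
#' ordering is defensible (younger, milder comorbidity, better functional
#' status, more supportive family).
#'
#' @return a `dce_attributes` object with 8 attributes.
#' @export
default_attributes <- function() {
  dce_attributes(list(
    list(name = "age", label = "Patient age (yr)",
         levels = c("39", "66", "89"), reference = "89", ordinal = TRUE),
    list(name = "comorb_type", label = "Type of main comorbidity",
         levels = c("prostate cancer", "COPD", "heart failure", "dementia"),
         reference = "prostate cancer", ordinal = FALSE),
    list(name = "comorb_severity", label = "Severity of main comorbidity",
         levels = c("mild", "moderate", "severe"), reference = "severe",
         ordinal = TRUE),
    list(name = "family_view", label = "Family's view on admission",
         levels = c("insists on admission", "not known", "against admission"),
         reference = "not known", ordinal = TRUE),
    list(name = "functional", label = "Functional status",
         levels = c("good", "limited"), reference = "limited", ordinal = TRUE),
    list(name = "news", label = "Acute severity (NEWS band)",
         levels = c("medium", "high", "very high"), reference = "medium",
         ordinal = FALSE),
    list(name = "registrar", label = "Registrar's subjective report",
         levels = c("not struggling", "struggling"),
         reference = "not struggling", ordinal = FALSE),
    list(name = "ward", label = "Ward nursing capacity",
         levels = c("normal", "reduced"), reference = "normal", ordinal = FALSE)
  ))
}

#' Read / write an attribute configuration
#'
#' YAML schema: `attributes: [{name, label, levels, reference, ordinal}]`.
#'
#' @param path file path.
#' @return `read_attributes` returns a `dce_attributes` object;
#'   `write_attributes` returns `path` invisibly.
#' @export
read_attributes <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$attributes)) stop("config has no 'attributes' key", call. = FALSE)
  specs <- lapply(cfg$attributes, function(a) {
    a$levels <- as.character(a$levels)
    a$reference <- as.character(a$reference)
    a$ordinal <- isTRUE(a$ordinal)
    a
  })
  dce_attributes(specs)
}

#' @rdname read_attributes
#' @param attrs a `dce_attributes` object.
#' @export
write_attributes <- function(attrs, path) {
  yaml::write_yaml(list(attributes = lapply(unname(attrs), function(a) {
    list(name = a$name, label = a$label, levels = as.list(a$levels),
         reference = a$reference, ordinal = a$ordinal)
  })), path)
  invisible(path)
}

#' Enumerate the full factorial of patient profiles
#'
#' Every combination of one level per attribute, in lexicographic order: the
#' first attribute varies slowest, levels in their configured order.
#'
#' @param attrs a `dce_attributes` object.
#' @return a data.frame with one column per attribute (character), one row
#'   per profile, `prod(level counts)` rows.
#' @export
enumerate_full_factorial <- function(attrs) {
  attrs <- as_dce_attributes(attrs)
  lv <- lapply(attrs, `[[`, "levels")
  # expand.grid varies the first factor fastest; reverse for lexicographic order
  g <- expand.grid(rev(lv), KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[, rev(seq_along(lv)), drop = FALSE]
  names(g) <- names(attrs)
  rownames(g) <- NULL
  g
}

as_dce_attributes <- function(attrs) {
  if (inherits(attrs, "dce_attributes")) return(attrs)
  dce_attributes(attrs)
}

# level index of each profile value within its attribute (1 = first listed)
level_index <- function(values, attr) match(values, attr$levels)

#' Pairwise profile dominance on ordinal attributes
#'
#' `a` weakly dominates `b` when, on every ordinal attribute, `a`'s level is
#' at least as desirable (earlier in the configured order), with strict
#' preference on at least one. Non-ordinal attributes are ignored.
#'
#' @param a,b named character vectors or one-row data.frames of levels.
#' @param attrs a `dce_attributes` object.
#' @return `TRUE` if `a` weakly dominates `b` with at least one strict
#'   ordinal advantage.
#' @export
dominates <- function(a, b, attrs) {
  attrs <- as_dce_attributes(attrs)
  a <- unlist(a)[names(attrs)]
  b <- unlist(b)[names(attrs)]
  strict <- FALSE
  for (at in attrs) {
    if (!at$ordinal) next
    ia <- level_index(a[[at$name]], at)
    ib <- level_index(b[[at$name]], at)
    if (ia > ib) return(FALSE)
    if (ia < ib) strict <- TRUE
  }
  strict
}
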