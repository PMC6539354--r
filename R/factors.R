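# Per-variable total-factor efficiency indices computed from optimal slacks:
# the ratio of the frontier target to the actual value (or its reciprocal for
# desirable outputs), one value per (dmu, period, variable).

#' Per-variable total-factor efficiency index formulas
#'
#' For an input (or an incoming link, which enters its receiving division as
#' an input) the target value is `actual - slack`, so the index is
#' `(actual - slack) / actual`. For a desirable output the target is
#' `actual + slack` and the index is `actual / (actual + slack)`. For an
#' undesirable output the target is `actual - slack`, index
#' `(actual - slack) / actual`. A good carry-over behaves like a desirable
#' output. An index of 1 means the variable is at its frontier target.
#'
#' @param actual Observed (positive) value.
#' @param slack Optimal slack (nonnegative; for inputs and bad outputs it
#'   cannot exceed `actual`).
#' @return Index in `(0, 1]`.
#' @export
input_factor_index <- function(actual, slack) {
  check_factor_args(actual, slack, bounded = TRUE)
  (actual - slack) / actual
}

#' @rdname input_factor_index
#' @export
good_output_factor_index <- function(actual, slack) {
  check_factor_args(actual, slack, bounded = FALSE)
  actual / (actual + slack)
}

#' @rdname input_factor_index
#' @export
bad_output_factor_index <- function(actual, slack) {
  check_factor_args(actual, slack, bounded = TRUE)
  (actual - slack) / actual
}

check_factor_args <- function(actual, slack, bounded) {
  if (any(actual <= 0))
    stop("`actual` must be strictly positive", call. = FALSE)
  if (any(slack < 0))
    stop("`slack` must be nonnegative", call. = FALSE)
  if (bounded && any(slack > actual * (1 + 1e-9)))
    stop("slack exceeds the actual value; inconsistent solution",
         call. = FALSE)
  invisible(NULL)
}

# map a slack table row role to its index formula
factor_index_value <- function(role, actual, slack) {
  switch(role,
         input = , link_in = input_factor_index(actual, pmin(slack, actual)),
         good_output = , carryover = good_output_factor_index(actual, slack),
         bad_output = bad_output_factor_index(actual, pmin(slack, actual)),
         stop("unknown role: ", role, call. = FALSE))
}

#' Tabulate total-factor efficiency indices for a set of solutions
#'
#' One row per `(dmu, period, division, variable)`, in deterministic order
#' (DMUs in panel order, then division, period, variable as declared).
#' Computed from the lexicographically-maximal slack solution when the
#' solves were run with `lex = TRUE` (the default), so the table is unique
#' among alternate optima. Link variables enter their receiving division as
#' inputs and are indexed with the input formula; they are tagged
#' `link_in` so downstream consumers can treat them as an extension.
#'
#' @param solutions List of `dndea_solution` (from [solve_all()]); `NULL`
#'   entries (failed units) are skipped.
#' @param spec The [dea_spec()] the solutions were computed under.
#' @return Data frame with columns `dmu`, `division`, `period`, `variable`,
#'   `role`, `actual`, `slack`, `index`.
#' @export
tabulate_indices <- function(solutions, spec) {
  spec <- validate_spec(spec)
  sv <- spec_variables(spec)
  out <- list()
  for (d in names(solutions)) {
    sol <- solutions[[d]]
    if (is.null(sol)) next
    sm <- sol$slacks
    # every declared variable must have a slack row in every period
    have <- paste(sm$division, sm$variable)
    want <- paste(sv$division, sv$variable)
    if (!all(want %in% have))
      stop("solution for DMU ", d, " lacks slacks for declared variable(s): ",
           paste(setdiff(want, have), collapse = ", "), call. = FALSE)
    sm$index <- vapply(seq_len(nrow(sm)), function(i)
      factor_index_value(sm$role[i], sm$obs[i], sm$slack[i]), 0)
    sm$dmu <- d
    out[[d]] <- sm[c("dmu", "division", "period", "variable", "role",
                     "obs", "slack", "index")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  names(res)[names(res) == "obs"] <- "actual"
  res
}
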