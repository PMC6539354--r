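#' Build and validate a panel dataset against a model specification
#'
#' A panel holds the observed nonnegative values of every declared variable
#' for every decision-making unit (DMU) and period. It is supplied in long
#' format with one row per `(dmu, period, division, variable)` cell. For a
#' carry-over variable, the period-\eqn{t} value is the stock carried from
#' period \eqn{t} into \eqn{t+1}.
#'
#' Validation checks completeness (every declared `(division, variable)`
#' pair present for every `(dmu, period)`), rejects negative values, and
#' replaces exact zeros by \eqn{10^{-6}} times the smallest positive value
#' of that variable across the panel (with a warning): the slacks-based
#' measure divides slacks by observed values, so strictly positive data are
#' required.
#'
#' @param data Data frame with columns `dmu`, `period`, `division`,
#'   `variable`, `value` (a `role` column, if present, is checked against
#'   the spec). Alternatively an existing `dndea_panel`.
#' @param spec A validated [dea_spec()].
#' @param periods Optional character vector fixing the period order;
#'   defaults to order of first appearance in `data`. Periods are opaque
#'   ordered labels (e.g. `"2013"`), never sorted lexically: carry-over
#'   continuity follows this order.
#' @return An object of class `dndea_panel`: the cleaned long data plus a
#'   `values` store of one DMU-by-period matrix per declared variable.
#' @examples
#' spec <- dea_spec(list(unit = list(inputs = "x", good_outputs = "y")))
#' df <- expand.grid(dmu = c("A", "B"), period = "p1",
#'                   stringsAsFactors = FALSE)
#' df <- rbind(transform(df, division = "unit", variable = "x", value = c(1, 2)),
#'             transform(df, division = "unit", variable = "y", value = c(1, 1)))
#' pan <- dea_panel(df, spec)
#' pan
#' @export
dea_panel <- function(data, spec, periods = NULL) {
  spec <- validate_spec(spec)
  if (inherits(data, "dndea_panel")) data <- data$data
  data <- as.data.frame(data)
  need <- c("dmu", "period", "division", "variable", "value")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("panel data lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  data$dmu <- as.character(data$dmu)
  data$period <- as.character(data$period)
  data$division <- as.character(data$division)
  data$variable <- as.character(data$variable)
  if (!is.numeric(data$value))
    stop("`value` must be numeric", call. = FALSE)

  sv <- spec_variables(spec)
  key <- function(d, v) paste(d, v, sep = "\r")
  role_of <- stats::setNames(sv$role, key(sv$division, sv$variable))

  dk <- key(data$division, data$variable)
  unknown <- !(dk %in% names(role_of))
  if (any(unknown))
    stop("panel contains undeclared (division, variable) pair(s): ",
         paste(unique(paste0(data$division[unknown], "/",
                             data$variable[unknown])), collapse = ", "),
         call. = FALSE)
  if ("role" %in% names(data)) {
    mismatch <- data$role != unname(role_of[dk])
    if (any(mismatch))
      stop("panel `role` column disagrees with the spec for: ",
           paste(unique(paste0(data$division[mismatch], "/",
                               data$variable[mismatch])), collapse = ", "),
           call. = FALSE)
  }
  data$role <- unname(role_of[dk])

  dup <- duplicated(data[c("dmu", "period", "division", "variable")])
  if (any(dup))
    stop("duplicated panel cell(s): ",
         paste(utils::head(unique(paste(data$dmu[dup], data$period[dup],
                                        data$division[dup], data$variable[dup],
                                        sep = "/")), 5L), collapse = ", "),
         call. = FALSE)

  dmus <- unique(data$dmu)
  if (is.null(periods)) periods <- unique(data$period)
  else if (!setequal(periods, unique(data$period)))
    stop("`periods` does not match the periods present in the data",
         call. = FALSE)

  if (any(!is.finite(data$value)))
    stop("panel contains non-finite value(s)", call. = FALSE)
  if (any(data$value < 0))
    stop("panel contains negative value(s); all quantities must be nonnegative",
         call. = FALSE)

  # zero replacement: eps * smallest positive value of that variable
  zero <- data$value == 0
  if (any(zero)) {
    for (v in unique(data$variable[zero])) {
      sel <- data$variable == v
      pos <- data$value[sel & data$value > 0]
      if (!length(pos))
        stop(sprintf("variable '%s' is zero everywhere; cannot rescale", v),
             call. = FALSE)
      data$value[sel & zero] <- 1e-6 * min(pos)
    }
    warning(sprintf("%d zero value(s) replaced by 1e-6 x the variable's smallest positive value",
                    sum(zero)), call. = FALSE)
  }

  # completeness + value store: one n x T matrix per (division, variable)
  values <- list()
  for (i in seq_len(nrow(sv))) {
    d <- sv$division[i]; v <- sv$variable[i]
    sel <- data$division == d & data$variable == v
    sub <- data[sel, ]
    M <- matrix(NA_real_, length(dmus), length(periods),
                dimnames = list(dmus, periods))
    M[cbind(match(sub$dmu, dmus), match(sub$period, periods))] <- sub$value
    if (anyNA(M)) {
      idx <- which(is.na(M), arr.ind = TRUE)
      stop(sprintf("incomplete panel: missing value for (%s, %s, %s, %s)%s",
                   dmus[idx[1, 1]], periods[idx[1, 2]], d, v,
                   if (nrow(idx) > 1) sprintf(" and %d more cell(s)", nrow(idx) - 1L) else ""),
           call. = FALSE)
    }
    if (is.null(values[[d]])) values[[d]] <- list()
    values[[d]][[v]] <- M
  }

  out <- data[c("dmu", "period", "division", "variable", "role", "value")]
  rownames(out) <- NULL
  structure(list(data = out,
                 dmus = dmus, periods = periods, values = values),
            class = "dndea_panel")
}

#' @export
print.dndea_panel <- function(x, ...) {
  cat(sprintf("Panel dataset: %d DMU(s) x %d period(s), %d variable cell(s)\n",
              length(x$dmus), length(x$periods), nrow(x$data)))
  cat(sprintf("  DMUs: %s\n", paste(utils::head(x$dmus, 8L), collapse = ", ")),
      if (length(x$dmus) > 8L) "  ...\n" else "", sep = "")
  cat(sprintf("  periods: %s\n", paste(x$periods, collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.dndea_panel <- function(x, ...) x$data

#' Read or write a panel as long-format CSV
#'
#' The CSV has the exact header `dmu,period,division,variable,role,value`
#' (the `role` column is written for readability and checked on read).
#' UTF-8, `.` decimal separator.
#'
#' @param path File path.
#' @param spec A validated [dea_spec()] used to validate on read.
#' @param panel A `dndea_panel` (or the long data frame).
#' @param periods Optional explicit period order (see [dea_panel()]).
#' @return `read_panel_csv()` returns a `dndea_panel`; `write_panel_csv()`
#'   returns `path` invisibly.
#' @export
read_panel_csv <- function(path, spec, periods = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  hdr <- names(utils::read.csv(path, nrows = 1L, check.names = FALSE))
  want <- c("dmu", "period", "division", "variable", "role", "value")
  if (!identical(hdr, want))
    stop(sprintf("panel CSV header must be exactly '%s' (got '%s')",
                 paste(want, collapse = ","), paste(hdr, collapse = ",")),
         call. = FALSE)
  df <- utils::read.csv(path, colClasses = c(dmu = "character",
                                             period = "character",
                                             division = "character",
                                             variable = "character",
                                             role = "character",
                                             value = "numeric"))
  dea_panel(df, spec, periods = periods)
}

#' @rdname read_panel_csv
#' @export
write_panel_csv <- function(panel, path) {
  df <- if (inherits(panel, "dndea_panel")) panel$data else as.data.frame(panel)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# value lookup helpers -------------------------------------------------------

# matrix n x T of a variable's values in a division
panel_matrix <- function(panel, division, variable) {
  M <- panel$values[[division]][[variable]]
  if (is.null(M))
    stop(sprintf("no values for variable '%s' in division '%s'",
                 variable, division), call. = FALSE)
  M
}
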