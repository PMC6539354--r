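#' Define a dynamic network DEA model specification
#'
#' A model specification declares the internal structure of the production
#' process under evaluation: its divisions, the role each observed variable
#' plays within a division (input, good output, bad output), the link
#' variables passed from one division to another within a period, and the
#' good carry-overs that connect a division's period \eqn{t} to period
#' \eqn{t+1}. Variable returns to scale (each intensity vector summing to
#' one) are hard-wired.
#'
#' @param divisions Named list, one element per division in evaluation order.
#'   Each element is itself a list with (any of) the character vectors
#'   `inputs`, `good_outputs` and `bad_outputs` naming the variables observed
#'   in that division.
#' @param links Optional data frame with columns `source`, `target`,
#'   `variable`: intermediate products generated by the `source` division and
#'   consumed as inputs by the `target` division within the same period. Link
#'   values are stored in the panel under the *target* division with role
#'   `"link_in"`.
#' @param carryovers Optional data frame with columns `division`, `variable`:
#'   good carry-overs (stocks such as fixed-asset investment) held by
#'   `division`, whose period-\eqn{t} value is the stock carried from
#'   \eqn{t} into \eqn{t+1}.
#' @param period_weights Optional positive numeric vector of per-period
#'   weights \eqn{W^t}; normalized to sum to one when the panel length is
#'   known. `NULL` means uniform.
#' @param division_weights Optional positive numeric vector (length = number
#'   of divisions) of division weights \eqn{W^k}; normalized to sum to one.
#'   `NULL` means uniform.
#'
#' @return An object of class `dndea_spec` with the derived per-division
#'   dimensions attached (see [validate_spec()]).
#' @seealso [two_stage_spec()] for the packaged two-stage configuration,
#'   [dea_panel()] for attaching data, [dndea()] for fitting.
#' @examples
#' spec <- dea_spec(divisions = list(
#'   farm = list(inputs = c("land", "labor"), good_outputs = "crop")))
#' spec
#' @export
dea_spec <- function(divisions, links = NULL, carryovers = NULL,
                     period_weights = NULL, division_weights = NULL) {
  spec <- structure(list(
    divisions = divisions,
    links = links,
    carryovers = carryovers,
    period_weights = period_weights,
    division_weights = division_weights
  ), class = "dndea_spec")
  validate_spec(spec)
}

#' Validate a model specification and attach derived dimensions
#'
#' Checks the declared topology (unique divisions, each variable in exactly
#' one role per division, link endpoints declared and distinct, positive
#' weights) and attaches the derived per-division dimensions: the number of
#' inputs \eqn{m_k}, good outputs \eqn{r1_k}, bad outputs \eqn{r2_k},
#' incoming links \eqn{linkin_k} and good carry-overs \eqn{ngood_k}.
#' Idempotent: validating a validated spec returns it unchanged.
#'
#' @param spec A `dndea_spec` (possibly hand-assembled).
#' @return The validated spec with a `dims` data frame attached.
#' @export
validate_spec <- function(spec) {
  if (!inherits(spec, "dndea_spec"))
    stop("`spec` must be a dndea_spec object", call. = FALSE)
  div <- spec$divisions
  if (!is.list(div) || length(div) < 1L)
    stop("at least one division is required", call. = FALSE)
  dnames <- names(div)
  if (is.null(dnames) || any(!nzchar(dnames)))
    stop("divisions must be a named list", call. = FALSE)
  if (anyDuplicated(dnames))
    stop("division identifiers must be unique", call. = FALSE)

  roles <- c("inputs", "good_outputs", "bad_outputs")
  for (k in dnames) {
    dk <- div[[k]]
    if (!is.list(dk))
      stop(sprintf("division '%s' must be a list", k), call. = FALSE)
    extra <- setdiff(names(dk), roles)
    if (length(extra))
      stop(sprintf("division '%s' has unknown role(s): %s", k,
                   paste(extra, collapse = ", ")), call. = FALSE)
    vars <- unlist(dk[roles], use.names = FALSE)
    if (anyDuplicated(vars))
      stop(sprintf("variable(s) %s appear in more than one role in division '%s'",
                   paste(unique(vars[duplicated(vars)]), collapse = ", "), k),
           call. = FALSE)
  }

  links <- spec$links
  if (!is.null(links) && nrow(links)) {
    req <- c("source", "target", "variable")
    if (!all(req %in% names(links)))
      stop("`links` needs columns source, target, variable", call. = FALSE)
    links <- as.data.frame(links)[req]
    bad <- !(links$source %in% dnames) | !(links$target %in% dnames)
    if (any(bad))
      stop("link refers to undeclared division(s): ",
           paste(unique(c(links$source[bad], links$target[bad])), collapse = ", "),
           call. = FALSE)
    if (any(links$source == links$target))
      stop("a link cannot connect a division to itself", call. = FALSE)
    # a link variable must not double as an ordinary role in its target
    for (i in seq_len(nrow(links))) {
      tv <- unlist(div[[links$target[i]]][roles], use.names = FALSE)
      if (links$variable[i] %in% tv)
        stop(sprintf("link variable '%s' already has a role in division '%s'",
                     links$variable[i], links$target[i]), call. = FALSE)
    }
  } else links <- data.frame(source = character(), target = character(),
                             variable = character(), stringsAsFactors = FALSE)

  co <- spec$carryovers
  if (!is.null(co) && nrow(co)) {
    if (!all(c("division", "variable") %in% names(co)))
      stop("`carryovers` needs columns division, variable", call. = FALSE)
    co <- as.data.frame(co)[c("division", "variable")]
    bad <- !(co$division %in% dnames)
    if (any(bad))
      stop("carry-over refers to undeclared division(s): ",
           paste(unique(co$division[bad]), collapse = ", "), call. = FALSE)
    for (i in seq_len(nrow(co))) {
      dv <- unlist(div[[co$division[i]]][roles], use.names = FALSE)
      if (co$variable[i] %in% dv)
        stop(sprintf("carry-over variable '%s' already has a role in division '%s'",
                     co$variable[i], co$division[i]), call. = FALSE)
    }
  } else co <- data.frame(division = character(), variable = character(),
                          stringsAsFactors = FALSE)

  dw <- spec$division_weights
  if (!is.null(dw)) {
    if (length(dw) != length(dnames) || any(!is.finite(dw)) || any(dw <= 0))
      stop("division weights must be strictly positive, one per division",
           call. = FALSE)
    dw <- dw / sum(dw)
    names(dw) <- dnames
  }
  pw <- spec$period_weights
  if (!is.null(pw)) {
    if (any(!is.finite(pw)) || any(pw <= 0))
      stop("period weights must be strictly positive", call. = FALSE)
    pw <- pw / sum(pw)
  }

  dims <- data.frame(
    division = dnames,
    m      = vapply(dnames, function(k) length(div[[k]]$inputs), 1L),
    r1     = vapply(dnames, function(k) length(div[[k]]$good_outputs), 1L),
    r2     = vapply(dnames, function(k) length(div[[k]]$bad_outputs), 1L),
    linkin = vapply(dnames, function(k) sum(links$target == k), 1L),
    ngood  = vapply(dnames, function(k) sum(co$division == k), 1L),
    row.names = NULL, stringsAsFactors = FALSE
  )

  structure(list(
    divisions = div, links = links, carryovers = co,
    period_weights = pw, division_weights = dw, dims = dims
  ), class = "dndea_spec")
}

# Long table of every variable the spec expects in the panel:
# (division, variable, role) with role in input/good_output/bad_output/
# link_in/carryover.  Link values live under the *target* division.
spec_variables <- function(spec) {
  rows <- list()
  role_map <- c(inputs = "input", good_outputs = "good_output",
                bad_outputs = "bad_output")
  for (k in names(spec$divisions)) {
    dk <- spec$divisions[[k]]
    for (r in names(role_map)) {
      for (v in dk[[r]])
        rows[[length(rows) + 1L]] <- data.frame(
          division = k, variable = v, role = role_map[[r]],
          stringsAsFactors = FALSE)
    }
  }
  lk <- spec$links
  for (i in seq_len(nrow(lk)))
    rows[[length(rows) + 1L]] <- data.frame(
      division = lk$target[i], variable = lk$variable[i], role = "link_in",
      stringsAsFactors = FALSE)
  co <- spec$carryovers
  for (i in seq_len(nrow(co)))
    rows[[length(rows) + 1L]] <- data.frame(
      division = co$division[i], variable = co$variable[i], role = "carryover",
      stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

# Resolve W^t and W^k for a panel with T periods; both normalized to sum 1.
resolve_weights <- function(spec, n_periods) {
  pw <- spec$period_weights
  if (is.null(pw)) pw <- rep(1 / n_periods, n_periods)
  if (length(pw) != n_periods)
    stop(sprintf("period weights have length %d but the panel has %d periods",
                 length(pw), n_periods), call. = FALSE)
  dw <- spec$division_weights
  if (is.null(dw)) {
    K <- length(spec$divisions)
    dw <- rep(1 / K, K)
    names(dw) <- names(spec$divisions)
  }
  list(period = pw / sum(pw), division = dw / sum(dw))
}

#' @export
print.dndea_spec <- function(x, ...) {
  cat("Dynamic network DEA model specification\n")
  cat(sprintf("  divisions: %s\n", paste(names(x$divisions), collapse = ", ")))
  d <- x$dims
  for (i in seq_len(nrow(d)))
    cat(sprintf("  %s: %d input(s), %d good / %d bad output(s), %d incoming link(s), %d carry-over(s)\n",
                d$division[i], d$m[i], d$r1[i], d$r2[i], d$linkin[i], d$ngood[i]))
  if (nrow(x$links))
    cat(sprintf("  links: %s\n",
                paste(sprintf("%s (%s->%s)", x$links$variable, x$links$source,
                              x$links$target), collapse = ", ")))
  if (nrow(x$carryovers))
    cat(sprintf("  carry-overs: %s\n",
                paste(sprintf("%s (%s)", x$carryovers$variable,
                              x$carryovers$division), collapse = ", ")))
  cat("  returns to scale: variable (e'lambda = 1)\n")
  invisible(x)
}

#' Read or write a model specification as JSON
#'
#' The JSON document mirrors the spec structure: keys `divisions` (per
#' division, per role), `links`, `carryovers` and `weights`. Round-trips
#' losslessly through [validate_spec()].
#'
#' @param path File path.
#' @param spec A validated `dndea_spec`.
#' @return `read_spec_json()` returns a validated `dndea_spec`;
#'   `write_spec_json()` returns `path` invisibly.
#' @export
read_spec_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$divisions))
    stop("spec JSON lacks a 'divisions' key", call. = FALSE)
  div <- lapply(doc$divisions, function(d)
    lapply(d, function(v) as.character(unlist(v))))
  links <- if (!is.null(doc$links) && length(doc$links))
    as.data.frame(doc$links, stringsAsFactors = FALSE) else NULL
  co <- if (!is.null(doc$carryovers) && length(doc$carryovers))
    as.data.frame(doc$carryovers, stringsAsFactors = FALSE) else NULL
  pw <- doc$weights$period
  dw <- doc$weights$division
  dea_spec(div, links = links, carryovers = co,
           period_weights = if (length(pw)) as.numeric(pw) else NULL,
           division_weights = if (length(dw)) as.numeric(dw) else NULL)
}

#' @rdname read_spec_json
#' @export
write_spec_json <- function(spec, path) {
  spec <- validate_spec(spec)
  doc <- list(
    divisions = spec$divisions,
    links = spec$links,
    carryovers = spec$carryovers,
    weights = list(period = spec$period_weights,
                   division = spec$division_weights)
  )
  jsonlite::write_json(doc, path, auto_unbox = FALSE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}
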