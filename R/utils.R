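# Shared low-level helpers: rate-expression evaluation, guard predicates,
# and deterministic RNG scoping.

# Allowed callables inside a rate expression. Only arithmetic and
# table-lookup are permitted so that every compiled system stays linear in
# the state vector x (rates are coefficients, never functions of x).
.rate_allowed_funs <- c("+", "-", "*", "/", "(", "[")

#' Parse a rate expression
#'
#' Rate expressions are written against the model's parameter table plus the
#' reserved generation index `i` (1-based position in the region named
#' `generation`, or 1 if the model has none). Only `+ - * /`, parentheses,
#' numeric literals, parameter names and per-generation table lookups
#' (`name[i]`) are allowed.
#'
#' @param text rate expression as a string (or a bare number).
#' @param params named list of declared parameters (for reference checking);
#'   `NULL` skips the check.
#' @return the parsed expression (a call or atomic), invisibly usable with
#'   [eval_rate()].
#' @keywords internal
parse_rate <- function(text, params = NULL) {
  if (is.numeric(text)) return(text)
  expr <- tryCatch(str2lang(as.character(text)),
                   error = function(e) stop("invalid rate expression: ", text, call. = FALSE))
  funs <- setdiff(all.names(expr), all.vars(expr))
  bad <- setdiff(funs, .rate_allowed_funs)
  if (length(bad) > 0)
    stop("nonlinear rate: disallowed operation '", bad[[1L]], "' in rate expression: ", text,
         call. = FALSE)
  if (!is.null(params)) {
    refs <- setdiff(all.vars(expr), c("i", "gamma"))
    missing <- setdiff(refs, names(params))
    if (length(missing) > 0)
      stop("unknown parameter: '", missing[[1L]], "' referenced by rate expression: ", text,
           call. = FALSE)
  }
  expr
}

#' Evaluate a rate expression at a generation index
#' @param expr parsed expression from [parse_rate()] (or a string/number).
#' @param params named list of parameter values (scalars or per-generation
#'   numeric vectors for `name[i]` lookups).
#' @param i generation index (1-based).
#' @return numeric scalar rate (1/time).
#' @keywords internal
eval_rate <- function(expr, params, i = 1L) {
  if (is.character(expr)) expr <- parse_rate(expr, params)
  v <- eval(expr, envir = c(params, list(i = i)), enclos = baseenv())
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
    stop("rate expression did not evaluate to a finite scalar", call. = FALSE)
  as.numeric(v)
}

# Substitute the numeric generation index into a rate expression and return
# deparsed text (used by the equation exporter so exported lines are
# self-contained R-parseable arithmetic over parameter names).
rate_text_at <- function(expr, i) {
  if (is.numeric(expr)) return(format(expr))
  if (is.character(expr)) expr <- str2lang(expr)
  if (!("i" %in% all.vars(expr))) return(paste(deparse(expr), collapse = ""))
  sub <- do.call(substitute, list(expr, list(i = as.numeric(i))))
  paste(deparse(sub), collapse = "")
}

#' Parse a guard / selector predicate
#'
#' Predicates are conjunctions of equality or inequality tests on region
#' states, e.g. `"cell_cycle == SM && differentiation != DP_late"`. The same
#' syntax is used for transition guards, exclusion selectors and source
#' target selectors.
#'
#' @param text predicate string, or `NULL`/`""` for the always-true guard.
#' @return data.frame with columns `region`, `op` (`==` or `!=`), `state`;
#'   zero rows mean "always true".
#' @keywords internal
parse_predicate <- function(text) {
  if (is.null(text) || !nzchar(trimws(text)))
    return(data.frame(region = character(), op = character(), state = character(),
                      stringsAsFactors = FALSE))
  clauses <- strsplit(text, "&&", fixed = TRUE)[[1L]]
  m <- regmatches(clauses, regexec("^\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*(==|!=)\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*$", clauses))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad))
    stop("invalid predicate clause: '", trimws(clauses[bad][[1L]]), "'", call. = FALSE)
  data.frame(region = vapply(m, `[[`, "", 2L),
             op = vapply(m, `[[`, "", 3L),
             state = vapply(m, `[[`, "", 4L),
             stringsAsFactors = FALSE)
}

# Evaluate a parsed predicate against a named character vector
# (region name -> current state).
eval_predicate <- function(pred, tuple) {
  if (nrow(pred) == 0L) return(TRUE)
  cur <- tuple[pred$region]
  eq <- cur == pred$state
  all(ifelse(pred$op == "==", eq, !eq))
}

# Run code with the global RNG seeded, restoring the previous RNG state on
# exit, so library calls stay deterministic without clobbering the caller.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
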