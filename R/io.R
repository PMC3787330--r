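# Timeseries writers/readers and the random-model fixture generator used
# by the property-test suite.

#' Write a trajectory or count series to CSV
#'
#' Header is `time,<flat-state names...>,<channel names...>`; values keep
#' 15 significant digits so a round-trip is lossless to well under 1e-12
#' relative.
#'
#' @param x a `statechart_trajectory`, an `abm_run`, or a data.frame whose
#'   first column is time.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(x, path) {
  df <- if (is.data.frame(x)) x else {
    d <- data.frame(time = x$time, check.names = FALSE)
    d <- cbind(d, as.data.frame(x$values, check.names = FALSE))
    if (!is.null(x$channels) && ncol(x$channels) > 0)
      d <- cbind(d, as.data.frame(x$channels, check.names = FALSE))
    d
  }
  stopifnot(all(vapply(df, function(col) all(is.finite(col)), TRUE)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

#' Generate a random valid statechart document
#'
#' Property-test fixture generator: a random model with up to `n_regions`
#' regions of up to `max_states` states each, chain-connected transitions
#' (so every state is reachable), non-negative rates, optional division
#' transitions (in a region named `generation`), optional guards,
#' generation-affine rates and a source. Deterministic per seed; the
#' output always parses with zero error diagnostics.
#'
#' @param seed integer.
#' @param n_regions maximum number of regions (<= 4).
#' @param max_states maximum states per region (<= 5).
#' @return the model document (YAML text).
#' @export
generate_fixture_model <- function(seed, n_regions = 3L, max_states = 4L) {
  stopifnot(n_regions <= 4L, max_states <= 5L)
  with_seed(seed, {
    nr <- sample.int(n_regions, 1L)
    has_gen <- stats::runif(1) < 0.6
    params <- list()
    new_param <- function(lo = 0, hi = 1) {
      nm <- paste0("p", length(params) + 1L)
      params[[nm]] <<- round(stats::runif(1, lo, hi), 4)
      nm
    }
    regions <- vector("list", nr)
    for (j in seq_len(nr)) {
      if (j == 1L && has_gen) {
        ns <- sample(2:max_states, 1L)
        states <- paste0("g", seq_len(ns))
        pdiv <- new_param(0.05, 0.8)
        trs <- lapply(seq_len(ns), function(i) {
          to <- if (i < ns) states[[i + 1L]] else states[[ns]]
          transition(states[[i]], to, pdiv, kind = "division")
        })
        if (stats::runif(1) < 0.5)
          trs <- c(trs, list(transition(states[[1L]], EXIT_STATE,
                                        new_param(0, 0.3), kind = "death")))
        regions[[j]] <- region("generation", states, transitions = trs)
      } else {
        ns <- sample.int(max_states, 1L)
        states <- paste0("r", j, letters[seq_len(ns)])
        trs <- list()
        if (ns > 1L) {
          for (i in seq_len(ns - 1L)) {
            rate <- if (has_gen && stats::runif(1) < 0.3)
              paste0(new_param(0.1, 0.5), " + ", new_param(0, 0.1), "*(i-1)")
            else new_param(0.05, 1)
            trs[[length(trs) + 1L]] <- transition(states[[i]], states[[i + 1L]], rate)
          }
          if (stats::runif(1) < 0.4)
            trs[[length(trs) + 1L]] <- transition(states[[ns]], states[[1L]],
                                                  new_param(0.05, 0.5))
        }
        if (stats::runif(1) < 0.4)
          trs[[length(trs) + 1L]] <- transition(states[[1L]], EXIT_STATE,
                                                new_param(0, 0.4), kind = "death")
        regions[[j]] <- region(paste0("reg", j), states, transitions = trs)
      }
    }
    # optional guard on a chain transition, referencing another region
    if (nr >= 2L && stats::runif(1) < 0.5) {
      gj <- sample.int(nr, 1L)
      other <- sample(setdiff(seq_len(nr), gj), 1L)
      trs <- regions[[gj]]$transitions
      if (length(trs) > 0) {
        ti <- sample.int(length(trs), 1L)
        tgt <- sample(regions[[other]]$states, 1L)
        op <- if (stats::runif(1) < 0.7) "==" else "!="
        trs[[ti]]$guard <- paste(regions[[other]]$name, op, tgt)
        regions[[gj]]$transitions <- trs
      }
    }
    sources <- list()
    if (stats::runif(1) < 0.7) {
      srate <- new_param(1, 20)
      into <- paste(vapply(regions, function(r)
        paste(r$name, "==", r$initial), ""), collapse = " && ")
      sources <- list(list(into = into, rate = srate))
    }
    model <- statechart_model(paste0("fixture_", seed), params, regions, sources)
    serialize_model(model)
  })
}
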