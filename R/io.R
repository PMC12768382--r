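# Model configs (JSON, with rationals as "num/den" strings to preserve
# exactness) and tabular export of iterate traces in the supporting-data
# layout: columns x, Gamma0, ..., GammaN, 12 significant digits.

#' Load a model from a JSON config
#'
#' The config either names a preset (with its parameters) or describes the
#' model explicitly:
#' \preformatted{
#' {"type": "integral", "preset": "example1"}
#' {"type": "discrete", "preset": "lyubich_shapiro", "a1": "3/10", "a2": "6/10"}
#' {"type": "integral", "weights": "pigeon",
#'  "operators": [{"slope": "1/4", "intercept": "1/4"},
#'                {"slope": "1/5", "intercept": "2/5"}]}
#' {"type": "integral", "weights": "four_outcome", "p": "1/2",
#'  "operators": [ ... four ... ]}
#' {"type": "integral",
#'  "weights": {"alpha": [{"xdeg": 0, "tdeg": 1, "coef": "1"}],
#'              "beta":  [{"xdeg": 0, "tdeg": 0, "coef": "1"},
#'                        {"xdeg": 0, "tdeg": 1, "coef": "-1"}]},
#'  "operators": [ ... ]}
#' {"type": "discrete",
#'  "operators": [{"slope": "7/10", "intercept": "3/10"},
#'                {"slope": "2/5", "intercept": "0"}]}
#' }
#' All rational values are strings \code{"num/den"} and are parsed exactly.
#'
#' @param path path to the JSON file.
#' @return an \code{integral_model} or \code{discrete_model}.
#' @export
load_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.null(cfg$preset)) {
    params <- cfg[setdiff(names(cfg), c("preset", "type", "operators"))]
    if (!is.null(cfg$operators)) params$ops <- lapply(cfg$operators, parse_op)
    return(do.call(preset_model, c(list(name = cfg$preset), params)))
  }
  type <- cfg$type %||% stop("config needs a 'type' or 'preset' field")
  ops <- lapply(cfg$operators %||% stop("config field 'operators' is required"),
                parse_op)
  if (type == "discrete") {
    if (length(ops) != 2L) stop("config field 'operators': discrete models need exactly 2")
    return(discrete_model(ops[[1]], ops[[2]], classical = FALSE))
  }
  if (type != "integral") stop("config field 'type' must be 'integral' or 'discrete'")
  ws <- cfg$weights %||% stop("config field 'weights' is required")
  if (is.character(ws) && length(ws) == 1L) {
    if (ws == "pigeon") {
      weights <- list(poly_weight(0, 1, "1"),
                      poly_weight(c(0, 0), c(0, 1), c("1", "-1")))
    } else if (ws == "four_outcome") {
      p <- q_from(cfg$p %||% "1/2")
      pm1 <- q_sub(q_one(), p)
      weights <- list(poly_weight(0, 1, list(p)),
                      poly_weight(0, 1, list(pm1)),
                      poly_weight(c(0, 0), c(0, 1), list(p, q_neg(p))),
                      poly_weight(c(0, 0), c(0, 1), list(pm1, q_neg(pm1))))
    } else stop("config field 'weights': unknown named layout '", ws, "'")
  } else {
    weights <- lapply(ws, parse_weight)
  }
  integral_model(weights, ops, p = cfg$p)
}

parse_op <- function(o) {
  if (is.null(o$slope) || is.null(o$intercept))
    stop("config field 'operators': each operator needs 'slope' and 'intercept'")
  make_affine_operator(o$slope, o$intercept)
}

parse_weight <- function(w) {
  terms <- if (!is.null(w$xdeg)) list(w) else w
  poly_weight(vapply(terms, function(t) as.integer(t$xdeg), integer(1)),
              vapply(terms, function(t) as.integer(t$tdeg), integer(1)),
              lapply(terms, `[[`, "coef"))
}

fmt12 <- function(x) sprintf("%.12g", x)

#' Write a Picard trace as a CSV iterate table
#'
#' Reproduces the supporting-data layout: header
#' \code{x,Gamma0,...,GammaN}, one row per node of a uniform grid on
#' \eqn{[0,1]}, values printed with 12 significant digits (lossless to that
#' precision on read-back).
#'
#' @param trace a \code{picard_trace} (or an \code{op_solution}, written as
#'   \code{x,value}).
#' @param n_grid number of grid rows.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_iterates_csv <- function(trace, n_grid = 101L, path) {
  if (inherits(trace, "op_solution")) {
    df <- as.data.frame(trace)
    lines <- c("x,value",
               paste(fmt12(df$x), fmt12(df$value), sep = ","))
    writeLines(lines, path)
    return(invisible(path))
  }
  stopifnot(inherits(trace, "picard_trace"))
  if (!length(trace$iterates)) stop("empty trace")
  df <- as.data.frame(trace, n_grid = n_grid)
  header <- paste(names(df), collapse = ",")
  body <- apply(vapply(df, fmt12, character(nrow(df))), 1L, paste, collapse = ",")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a fixation-summary table as CSV
#'
#' @param summaries a list of \code{fixation_summary} objects (or one).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_summary_csv <- function(summaries, path) {
  if (inherits(summaries, "fixation_summary")) summaries <- list(summaries)
  rows <- vapply(summaries, function(s)
    paste(fmt12(s$x0), fmt12(s$p_hat), fmt12(s$se), s$n_reps,
          s$censored_count, sep = ","), character(1))
  writeLines(c("x0,p_hat,se,n,censored", rows), path)
  invisible(path)
}
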