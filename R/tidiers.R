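#' Tidy a design verdict
#'
#' For a specificity verdict, returns the violations table (zero rows on a
#' pass); for an efficacy verdict, a one-row table of its measurements.
#'
#' @param x A `design_verdict`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy design_verdict
#' @export
tidy.design_verdict <- function(x, ...) {
  if (x$kind == "specificity") return(x$violations)
  tibble(intended_id = x$intended_id, pass = x$pass, coverage = x$coverage,
         exact_windows = x$exact_windows,
         longest_identical = x$longest_identical,
         warning = x$warning %||% NA_character_)
}

#' @rdname tidy.design_verdict
#' @method glance design_verdict
#' @export
glance.design_verdict <- function(x, ...) {
  if (x$kind == "specificity") {
    tibble(kind = x$kind, pass = x$pass,
           n_offtargets = length(x$per_offtarget_min),
           worst_min_mismatch = if (length(x$per_offtarget_min))
             min(x$per_offtarget_min) else NA_integer_,
           n_violations = nrow(x$violations))
  } else {
    tibble(kind = x$kind, pass = x$pass, coverage = x$coverage,
           longest_identical = x$longest_identical)
  }
}

#' Tidy a chimeric construct
#'
#' @param x A `chimeric_construct`.
#' @param what `"junctions"` (default), `"fragments"` or `"primers"`.
#' @param ... Unused.
#' @return The requested component as a tibble.
#' @method tidy chimeric_construct
#' @export
tidy.chimeric_construct <- function(x, what = c("junctions", "fragments",
                                                "primers"), ...) {
  what <- match.arg(what)
  if (what == "primers" && is.null(x$primers)) {
    abort("No primers designed yet; call design_overlap_primers() first.")
  }
  as_tibble(x[[what]])
}

#' @rdname tidy.chimeric_construct
#' @method glance chimeric_construct
#' @export
glance.chimeric_construct <- function(x, ...) {
  tibble(n_fragments = nrow(x$fragments), total_len = x$total_len,
         pass = x$pass, length_ok = x$length_ok,
         n_junction_windows = nrow(x$junctions),
         n_failing_junction_windows = sum(!x$junctions$pass))
}

#' One-row summary of a candidate search
#'
#' @param x A `fragment_candidates` tibble.
#' @param ... Unused.
#' @return A tibble with candidate counts and the best candidate's margins.
#' @method glance fragment_candidates
#' @export
glance.fragment_candidates <- function(x, ...) {
  tibble(n_candidates = nrow(x),
         best_min_offtarget_mismatch = if (nrow(x))
           x$min_offtarget_mismatch[[1]] else NA_integer_,
         best_length = if (nrow(x)) x$length[[1]] else NA_integer_,
         best_coverage = if (nrow(x)) x$mean_intended_coverage[[1]] else NA_real_)
}
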