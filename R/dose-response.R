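#' Combination dose-response surface
#'
#' Mean response of a cell culture over a full factorial dose grid of two
#' agents, each grid including dose 0 so the single-agent margins (row
#' `dose_b = 0`, column `dose_a = 0`) are available to the HSA reference
#' model. Responses are percentages, either inhibition (0 = no effect,
#' 100 = full kill) or viability (100 = untreated level).
#'
#' @param doses_a,doses_b Strictly ascending dose grids, each starting at 0.
#' @param response Numeric matrix `length(doses_a)` x `length(doses_b)`.
#' @param response_kind `"inhibition"` or `"viability"`.
#' @return An object of class `dose_response_surface`.
#' @export
dose_response_surface <- function(doses_a, doses_b, response,
                                  response_kind = c("inhibition", "viability")) {
  response_kind <- match.arg(response_kind)
  for (d in list(doses_a, doses_b)) {
    if (length(d) < 2L || any(diff(d) <= 0)) {
      abort_validation("dose grids must be strictly ascending with >= 2 doses")
    }
    if (d[[1L]] != 0) abort_validation("each dose grid must start at 0")
  }
  if (!is.matrix(response) ||
      nrow(response) != length(doses_a) || ncol(response) != length(doses_b)) {
    abort_validation("response must be a %d x %d matrix", length(doses_a), length(doses_b))
  }
  if (any(!is.finite(response))) abort_validation("response values must be finite")
  dimnames(response) <- list(format(doses_a, trim = TRUE), format(doses_b, trim = TRUE))
  structure(
    list(doses_a = as.numeric(doses_a), doses_b = as.numeric(doses_b),
         response = response, response_kind = response_kind),
    class = "dose_response_surface"
  )
}

#' @export
print.dose_response_surface <- function(x, ...) {
  cat(sprintf("<dose_response_surface> %d x %d grid (%s %%)\n",
              length(x$doses_a), length(x$doses_b), x$response_kind))
  invisible(x)
}

#' Read a dose-response surface from long-format CSV
#'
#' Expects columns `dose_a`, `dose_b`, `response_pct`; replicate rows for the
#' same dose pair are averaged. Every combination of the observed dose levels
#' must be present (full grid), and responses must lie in [-20, 120] — the
#' window admits modest assay noise beyond the nominal 0-100%.
#'
#' @param path CSV path.
#' @param response_kind How the assay reports: `"inhibition"` or `"viability"`.
#' @return A [dose_response_surface].
#' @export
read_dose_response <- function(path, response_kind = c("inhibition", "viability")) {
  response_kind <- match.arg(response_kind)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("dose_a", "dose_b", "response_pct")
  if (!all(req %in% names(df))) {
    abort_validation("dose-response CSV needs columns %s", paste(req, collapse = ", "))
  }
  if (any(df$dose_a < 0) || any(df$dose_b < 0)) abort_validation("doses must be >= 0")
  if (any(df$response_pct < -20 | df$response_pct > 120)) {
    abort_validation("response_pct outside [-20, 120]")
  }
  da <- sort(unique(df$dose_a)); db <- sort(unique(df$dose_b))
  mean_tab <- tapply(df$response_pct, list(factor(df$dose_a, levels = da),
                                           factor(df$dose_b, levels = db)), mean)
  miss <- which(is.na(mean_tab), arr.ind = TRUE)
  if (nrow(miss)) {
    abort_validation("missing grid cell (%s,%s)",
                     format(da[miss[1L, 1L]]), format(db[miss[1L, 2L]]))
  }
  dose_response_surface(da, db, unclass(mean_tab), response_kind = response_kind)
}

#' Convert a surface to the inhibition scale
#'
#' Viability percentages are mapped to inhibition by `100 - v`; a surface
#' already on the inhibition scale is returned unchanged (idempotent).
#'
#' @param surface A [dose_response_surface].
#' @return A [dose_response_surface] with `response_kind = "inhibition"`.
#' @export
to_inhibition <- function(surface) {
  stopifnot(inherits(surface, "dose_response_surface"))
  if (surface$response_kind == "inhibition") return(surface)
  dose_response_surface(surface$doses_a, surface$doses_b,
                        100 - surface$response, response_kind = "inhibition")
}
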