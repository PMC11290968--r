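#' HSA expected combination response
#'
#' Under the highest-single-agent reference model the expected inhibition at
#' a dose pair (a, b) with a, b > 0 is the larger of the two single-agent
#' inhibitions at those doses, read off the surface's margins (row
#' `dose_b = 0` and column `dose_a = 0`).
#'
#' @param surface A [dose_response_surface] on the inhibition scale.
#' @return Matrix of expected inhibition over the combination cells
#'   (doses_a > 0 x doses_b > 0).
#' @export
hsa_expected <- function(surface) {
  stopifnot(inherits(surface, "dose_response_surface"))
  if (surface$response_kind != "inhibition") {
    abort_validation("surface must be on the inhibition scale; see to_inhibition()")
  }
  if (surface$doses_a[[1L]] != 0 || surface$doses_b[[1L]] != 0) {
    abort_validation("single-agent margins (dose 0 row/column) are required")
  }
  ia <- surface$response[-1L, 1L]   # agent A alone at doses_a > 0
  ib <- surface$response[1L, -1L]   # agent B alone at doses_b > 0
  exp_mat <- outer(ia, ib, pmax)
  dimnames(exp_mat) <- list(rownames(surface$response)[-1L],
                            colnames(surface$response)[-1L])
  exp_mat
}

#' HSA synergy score of a combination surface
#'
#' Per combination cell, the excess of the observed inhibition over the HSA
#' expectation; the synergy score is the unweighted mean excess in
#' percentage points. Classification follows the conventional thresholds:
#' above +10 synergistic, below -10 antagonistic, otherwise additive.
#'
#' @param surface A [dose_response_surface] on the inhibition scale.
#' @param threshold Classification threshold in percentage points
#'   (default 10).
#' @return List of class `synergy_result` with `hsa_score`,
#'   `per_cell_excess` (matrix), `classification`.
#' @export
hsa_score <- function(surface, threshold = 10) {
  expected <- hsa_expected(surface)
  if (length(expected) == 0L) {
    abort_validation("surface has no combination cells")
  }
  observed <- surface$response[-1L, -1L, drop = FALSE]
  excess <- observed - expected
  score <- mean(excess)
  classification <- if (score > threshold) "synergistic"
                    else if (score < -threshold) "antagonistic"
                    else "additive"
  structure(
    list(hsa_score = score, per_cell_excess = excess,
         classification = classification, threshold = threshold),
    class = "synergy_result"
  )
}

#' @export
print.synergy_result <- function(x, ...) {
  cat(sprintf("<synergy_result> HSA score %.2f (%s; |threshold| = %.0f)\n",
              x$hsa_score, x$classification, x$threshold))
  invisible(x)
}
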