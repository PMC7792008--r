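#' Unit-cost edit distance
#'
#' Bit-parallel Levenshtein distance. `mode = "global"` is the full
#' Needleman-Wunsch distance; `mode = "infix"` leaves gaps at both ends of
#' `b` unpenalized (pattern `a` may match anywhere inside text `b`).
#'
#' @param a,b DNA (or any) strings
#' @param mode `"global"` or `"infix"`
#' @return integer distance
#' @export
edit_distance <- function(a, b, mode = c("global", "infix")) {
  mode <- match.arg(mode)
  cpp_edit_dist(a, b, mode == "global")
}

#' Global alignment with deterministic traceback
#'
#' Unit match/mismatch/gap costs; traceback prefers diagonal, then up
#' (consume `a`), then left (consume `b`). The expanded operation string uses
#' `M` (match/mismatch), `I` (base of `a` absent from `b`) and `D` (base of
#' `b` absent from `a`).
#'
#' @param a,b strings (`a` is the query)
#' @return list with `dist` and `ops` (one character per alignment column)
#' @export
align_global <- function(a, b) {
  cpp_align_global(a, b)
}
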