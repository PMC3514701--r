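#' Vertebral pattern classes and the ordinal severity scale
#'
#' The eight pattern classes encode which of the three investigated
#' boundaries of the vertebral column are shifted: cervico-thoracic (CT),
#' thoraco-lumbar (TL) and lumbo-sacral (LS). `R` is the regular column
#' (7 cervical + 12 thoracic + 5 lumbar, 24 presacral vertebrae).
#' The severity scale ranks the classes by the anteriority of the shifted
#' boundaries and by how many boundaries are involved: posterior-only
#' changes score 1-4, any cervico-thoracic change scores at least 6, and
#' values 2 and 5 are never assigned.
#'
#' @return `pattern_levels()` returns the eight class labels in severity
#'   order; `severity_scale()` returns the named integer lookup from class
#'   to severity score.
#' @examples
#' severity_scale()[["CT_TL_LS"]]
#' @export
pattern_levels <- function() {
  c("R", "LS", "TL", "TL_LS", "CT", "CT_LS", "CT_TL", "CT_TL_LS")
}

#' @rdname pattern_levels
#' @export
severity_scale <- function() {
  c(R = 0L, LS = 1L, TL = 3L, TL_LS = 4L,
    CT = 6L, CT_LS = 7L, CT_TL = 8L, CT_TL_LS = 9L)
}

#' Map a set of boundary shifts to its pattern class
#'
#' Deterministic bijection between the three boundary-shift flags and the
#' eight pattern classes.
#'
#' @param shifts a `boundary_shifts` object from [detect_shifts()], or any
#'   list with logical elements `ct`, `tl`, `ls`.
#' @return single character pattern class (one of [pattern_levels()]).
#' @examples
#' pattern_class(list(ct = TRUE, tl = TRUE, ls = FALSE))
#' @export
pattern_class <- function(shifts) {
  stopifnot(is.list(shifts),
            all(c("ct", "tl", "ls") %in% names(shifts)))
  ct <- isTRUE(shifts$ct); tl <- isTRUE(shifts$tl); ls <- isTRUE(shifts$ls)
  parts <- c(if (ct) "CT", if (tl) "TL", if (ls) "LS")
  if (length(parts) == 0L) "R" else paste(parts, collapse = "_")
}

#' Severity score of a pattern class
#'
#' @param pattern character vector of pattern classes.
#' @return integer vector of severity scores in \{0, 1, 3, 4, 6, 7, 8, 9\}.
#' @examples
#' severity_score(c("R", "CT_LS"))
#' @export
severity_score <- function(pattern) {
  scale <- severity_scale()
  bad <- setdiff(unique(pattern), names(scale))
  if (length(bad) > 0L) {
    stop("unknown pattern class: ", paste(bad, collapse = ", "))
  }
  unname(scale[pattern])
}

#' Collapse the eight pattern classes to the four-level grouping
#'
#' The four-level grouping ignores lumbo-sacral shifts, merging each class
#' with its `_LS` counterpart: \{R, LS\}, \{TL, TL_LS\}, \{CT, CT_LS\},
#' \{CT_TL, CT_TL_LS\}. This is the grouping used for the contingency table
#' that disregards changes in presacral number.
#'
#' @param pattern character vector of eight-level classes.
#' @return factor with levels `R.LS`, `TL.TL_LS`, `CT.CT_LS`,
#'   `CT_TL.CT_TL_LS`.
#' @export
pattern_group4 <- function(pattern) {
  map <- c(R = "R.LS", LS = "R.LS",
           TL = "TL.TL_LS", TL_LS = "TL.TL_LS",
           CT = "CT.CT_LS", CT_LS = "CT.CT_LS",
           CT_TL = "CT_TL.CT_TL_LS", CT_TL_LS = "CT_TL.CT_TL_LS")
  bad <- setdiff(unique(pattern), names(map))
  if (length(bad) > 0L) {
    stop("unknown pattern class: ", paste(bad, collapse = ", "))
  }
  factor(unname(map[pattern]),
         levels = c("R.LS", "TL.TL_LS", "CT.CT_LS", "CT_TL.CT_TL_LS"))
}
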