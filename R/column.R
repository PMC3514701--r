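#' Build a vertebral column object from long-format morphology rows
#'
#' A column holds the ordered presacral vertebrae of one subject, with one
#' rib observation per side. Rows with `sacral_attached = 1` (vertebrae
#' articulating or fusing with the sacrum/ilium) and everything caudal to
#' the first such vertebra are dropped: the presacral portion is the unit
#' of analysis.
#'
#' @param rows data frame of long-format morphology rows for one subject
#'   (see [read_morphology()] for the schema).
#' @return an object of class `vertebral_column`: a list with
#'   `subject_id`, `quality` and a `vertebrae` data frame with one row per
#'   ordinal and per-side state/ratio columns.
#' @export
as_vertebral_column <- function(rows) {
  rows <- as.data.frame(rows)
  req <- c("subject_id", "vertebra_ordinal", "side", "rib_state",
           "length_ratio", "tp_exceeds_t1", "sacral_attached",
           "ls_transitional_flag", "quality")
  miss <- setdiff(req, names(rows))
  if (length(miss) > 0L) {
    stop("morphology rows missing columns: ", paste(miss, collapse = ", "))
  }
  sid <- unique(rows$subject_id)
  if (length(sid) != 1L) stop("rows for exactly one subject expected")
  quality <- unique(rows$quality)
  if (length(quality) != 1L) {
    stop("inconsistent quality flag for subject ", sid)
  }
  if (anyDuplicated(rows[, c("vertebra_ordinal", "side")])) {
    stop("duplicate subject-vertebra-side rows for subject ", sid)
  }
  if (!all(rows$side %in% c("left", "right"))) {
    stop("side must be 'left' or 'right' (subject ", sid, ")")
  }
  states <- c("absent", "tp_enlarged", "present")
  if (!all(rows$rib_state %in% states)) {
    stop("invalid rib_state for subject ", sid)
  }
  if (any(!is.na(rows$length_ratio) & rows$length_ratio < 0)) {
    stop("negative length_ratio for subject ", sid)
  }

  # presacral portion: everything anterior to the first sacral vertebra
  if (any(rows$sacral_attached == 1)) {
    first_sacral <- min(rows$vertebra_ordinal[rows$sacral_attached == 1])
    rows <- rows[rows$vertebra_ordinal < first_sacral, , drop = FALSE]
  }

  ords <- sort(unique(rows$vertebra_ordinal))
  if (length(ords) > 0L &&
      !identical(as.integer(ords), seq_len(length(ords)))) {
    stop("vertebra ordinals must be contiguous from 1 (subject ", sid, ")")
  }
  left <- rows[rows$side == "left", , drop = FALSE]
  right <- rows[rows$side == "right", , drop = FALSE]
  if (!setequal(left$vertebra_ordinal, ords) ||
      !setequal(right$vertebra_ordinal, ords)) {
    stop("each vertebra needs exactly one observation per side (subject ",
         sid, ")")
  }
  left <- left[order(left$vertebra_ordinal), , drop = FALSE]
  right <- right[order(right$vertebra_ordinal), , drop = FALSE]

  vert <- data.frame(
    ordinal = as.integer(ords),
    left_state = left$rib_state,
    left_ratio = left$length_ratio,
    left_tp_exceeds_t1 = left$tp_exceeds_t1 == 1,
    right_state = right$rib_state,
    right_ratio = right$length_ratio,
    right_tp_exceeds_t1 = right$tp_exceeds_t1 == 1,
    ls_transitional = (left$ls_transitional_flag == 1) |
      (right$ls_transitional_flag == 1),
    stringsAsFactors = FALSE
  )
  structure(list(subject_id = sid, quality = quality, vertebrae = vert),
            class = "vertebral_column")
}

#' @export
print.vertebral_column <- function(x, ...) {
  cat("<vertebral_column> subject", x$subject_id,
      "-", nrow(x$vertebrae), "presacral vertebrae, quality:",
      x$quality, "\n")
  invisible(x)
}

#' Classify a single rib observation
#'
#' At the first and last thoracic positions a present rib is rudimentary
#' when its length is strictly less than half that of the rib of the
#' adjacent thoracic vertebra; at or above half it is full. Away from the
#' boundaries any present rib is full. An enlarged transverse process is
#' not a rib and classifies as absent here (its special role at the
#' seventh vertebra is handled by [classify_c7()]).
#'
#' @param state one of `"absent"`, `"tp_enlarged"`, `"present"`.
#' @param length_ratio length as a fraction of the adjacent thoracic rib
#'   (may be `NA` when `state != "present"`).
#' @param position `"first_thoracic"`, `"last_thoracic"` or `"other"`.
#' @return one of `"full"`, `"rudimentary"`, `"absent"`.
#' @examples
#' classify_rib("present", 0.4, "last_thoracic")
#' @export
classify_rib <- function(state,
                         length_ratio = NA_real_,
                         position = c("other", "first_thoracic",
                                      "last_thoracic")) {
  position <- match.arg(position)
  if (!state %in% c("absent", "tp_enlarged", "present")) {
    stop("invalid rib state: ", state)
  }
  if (state != "present") return("absent")
  if (position == "other") return("full")
  if (is.na(length_ratio)) {
    stop("length_ratio required for a present rib at a ", position,
         " boundary position")
  }
  if (length_ratio < 0.5) "rudimentary" else "full"
}

#' Classify the seventh vertebra
#'
#' A rib on the seventh vertebra marks a transitional cervico-thoracic
#' vertebra, except in the rare case of a rib longer than half the
#' adjacent thoracic rib, which gives the vertebra full thoracic identity.
#' An enlarged transverse process (apophysomegaly) counts as a rudimentary
#' cervical rib fused to the transverse process when it is longer than the
#' transverse process of the first thoracic vertebra. When the two sides
#' conflict (one thoracic identity, one normal) the more severe side wins
#' and a warning is raised.
#'
#' @param column a `vertebral_column`.
#' @return one of `"normal"`, `"transitional_cervicothoracic"`,
#'   `"thoracic_identity"`.
#' @export
classify_c7 <- function(column) {
  v <- column$vertebrae
  if (nrow(v) < 7L) return("normal")
  row <- v[v$ordinal == 7L, ]
  side_class <- function(state, ratio, tp_exceeds) {
    if (state == "present") {
      if (is.na(ratio)) {
        stop("length_ratio required for a present rib on vertebra 7 ",
             "(subject ", column$subject_id, ")")
      }
      if (ratio > 0.5) "thoracic_identity" else "transitional_cervicothoracic"
    } else if (state == "tp_enlarged" && isTRUE(tp_exceeds)) {
      "transitional_cervicothoracic"
    } else {
      "normal"
    }
  }
  lev <- c("normal", "transitional_cervicothoracic", "thoracic_identity")
  cl <- c(side_class(row$left_state, row$left_ratio, row$left_tp_exceeds_t1),
          side_class(row$right_state, row$right_ratio,
                     row$right_tp_exceeds_t1))
  ranks <- match(cl, lev)
  if (max(ranks) == 3L && min(ranks) == 1L) {
    warning("subject ", column$subject_id,
            ": conflicting sides at vertebra 7 (thoracic identity vs ",
            "normal); classified by the more severe side")
  }
  lev[max(ranks)]
}

# State of a boundary thoracic vertebra (8 = first thoracic position,
# 19 = twelfth thoracic position): "normal" (full rib on both sides),
# "transitional" (a rudimentary rib, or a rib on one side only) or
# "full_shift" (no rib on either side).
boundary_state <- function(column, ordinal, position) {
  v <- column$vertebrae
  if (!ordinal %in% v$ordinal) return(NA_character_)
  row <- v[v$ordinal == ordinal, ]
  cl <- c(classify_rib(row$left_state, row$left_ratio, position),
          classify_rib(row$right_state, row$right_ratio, position))
  if (all(cl == "absent")) return("full_shift")
  if (any(cl %in% c("rudimentary", "absent"))) return("transitional")
  "normal"
}

# Any rib (full or rudimentary) on the vertebra immediately caudal to the
# twelfth thoracic position marks a lumbar rib, i.e. a posterior
# thoraco-lumbar shift.
lumbar_rib_present <- function(column, ordinal = 20L) {
  v <- column$vertebrae
  if (!ordinal %in% v$ordinal) return(FALSE)
  row <- v[v$ordinal == ordinal, ]
  row$left_state == "present" || row$right_state == "present"
}

#' Detect boundary shifts in an evaluable column
#'
#' Applies the rib rules at the three investigated boundaries:
#' \itemize{
#'   \item cervico-thoracic: anterior shift when the seventh vertebra
#'     carries a cervical rib or qualifying enlarged transverse process;
#'     posterior shift when the first thoracic rib (eighth vertebra) is
#'     rudimentary or absent;
#'   \item thoraco-lumbar: anterior shift when the twelfth thoracic rib
#'     (nineteenth vertebra) is rudimentary or absent; posterior shift
#'     when a rib sits on the vertebra caudal to the twelve thoracic
#'     positions (a lumbar rib);
#'   \item lumbo-sacral: shifted when the presacral count differs from 24
#'     or a transitional lumbo-sacral vertebra was flagged by the
#'     observer.
#' }
#' When anterior and posterior evidence co-occur at one boundary the flag
#' is set once with direction `"anterior"`.
#'
#' @param column an evaluable `vertebral_column`.
#' @return an object of class `boundary_shifts`: list with logicals `ct`,
#'   `tl`, `ls` and directions `ct_direction`, `tl_direction` in
#'   `{"anterior", "posterior", "none"}`.
#' @export
detect_shifts <- function(column) {
  stopifnot(inherits(column, "vertebral_column"))
  if (!identical(column$quality, "evaluable")) {
    stop("column for subject ", column$subject_id, " is not evaluable")
  }
  n <- nrow(column$vertebrae)
  if (n == 0L) stop("empty column for subject ", column$subject_id)

  ct_anterior <- n >= 7L && classify_c7(column) != "normal"
  st8 <- if (n >= 8L) boundary_state(column, 8L, "first_thoracic") else NA
  ct_posterior <- !is.na(st8) && st8 != "normal"

  st19 <- if (n >= 19L) boundary_state(column, 19L, "last_thoracic") else NA
  tl_anterior <- !is.na(st19) && st19 != "normal"
  tl_posterior <- lumbar_rib_present(column, 20L)

  ls <- n != 24L || any(column$vertebrae$ls_transitional)

  structure(list(
    ct = ct_anterior || ct_posterior,
    tl = tl_anterior || tl_posterior,
    ls = ls,
    ct_direction = if (ct_anterior) "anterior"
                   else if (ct_posterior) "posterior" else "none",
    tl_direction = if (tl_anterior) "anterior"
                   else if (tl_posterior) "posterior" else "none"
  ), class = "boundary_shifts")
}

#' Regional vertebral counts with half-identity transitional vertebrae
#'
#' Each transitional vertebra contributes half a unit to each neighbouring
#' region: a transitional cervico-thoracic vertebra counts as half
#' cervical/half thoracic, a rudimentary twelfth rib as half thoracic/half
#' lumbar, and so on. Full identity shifts (e.g. a bilaterally absent
#' twelfth rib, or a full-length lumbar rib) move the whole unit. The
#' regional counts always sum exactly to the presacral count.
#'
#' @param column an evaluable `vertebral_column`.
#' @return one-row [tibble::tibble] with `cervical`, `thoracic`, `lumbar`
#'   (half-unit resolution) and integer `presacral`; attribute
#'   `segmentation_suspect` is `TRUE` when the rib-bearing block is
#'   non-contiguous (a warning is also raised).
#' @export
regional_counts <- function(column) {
  stopifnot(inherits(column, "vertebral_column"))
  v <- column$vertebrae
  n <- nrow(v)
  if (n == 0L) stop("empty column for subject ", column$subject_id)

  ribbed <- v$ordinal[v$left_state == "present" | v$right_state == "present"]
  suspect <- length(ribbed) > 1L && any(diff(sort(ribbed)) > 1L)
  # a cervical rib adjacent to the thoracic block is an expected gap source
  if (suspect && length(ribbed) > 1L) {
    core <- sort(ribbed[ribbed >= 8L])
    suspect <- length(core) > 1L && any(diff(core) > 1L)
    # an absent first thoracic rib leaves the block starting at 9; only
    # internal gaps are suspicious
  }
  if (suspect) {
    warning("subject ", column$subject_id,
            ": non-contiguous rib-bearing block; region assignment is ",
            "segmentation-suspect")
  }

  c7 <- if (n >= 7L) classify_c7(column) else "normal"
  st8 <- if (n >= 8L) boundary_state(column, 8L, "first_thoracic") else NA
  st19 <- if (n >= 19L) boundary_state(column, 19L, "last_thoracic") else NA

  w_c <- w_t <- w_l <- numeric(n)
  for (i in seq_len(n)) {
    if (i <= 6L) {
      w_c[i] <- 1
    } else if (i == 7L) {
      if (c7 == "normal") w_c[i] <- 1
      else if (c7 == "transitional_cervicothoracic") {
        w_c[i] <- 0.5; w_t[i] <- 0.5
      } else w_t[i] <- 1
    } else if (i == 8L) {
      if (is.na(st8) || st8 == "normal") w_t[i] <- 1
      else if (st8 == "transitional") { w_c[i] <- 0.5; w_t[i] <- 0.5 }
      else w_c[i] <- 1
    } else if (i <= 18L) {
      w_t[i] <- 1
    } else if (i == 19L) {
      if (is.na(st19) || st19 == "normal") w_t[i] <- 1
      else if (st19 == "transitional") { w_t[i] <- 0.5; w_l[i] <- 0.5 }
      else w_l[i] <- 1
    } else if (i == 20L) {
      row <- v[v$ordinal == 20L, ]
      cl <- c(classify_rib_lenient(row$left_state, row$left_ratio),
              classify_rib_lenient(row$right_state, row$right_ratio))
      if (all(cl == "full")) w_t[i] <- 1
      else if (any(cl != "absent")) { w_t[i] <- 0.5; w_l[i] <- 0.5 }
      else w_l[i] <- 1
    } else {
      w_l[i] <- 1
    }
  }
  out <- tibble::tibble(cervical = sum(w_c), thoracic = sum(w_t),
                        lumbar = sum(w_l), presacral = n)
  attr(out, "segmentation_suspect") <- suspect
  out
}

# Lumbar-rib classification: a present rib with a missing ratio is taken
# as full rather than rejected, since the half-length rule only formally
# applies at the thoracic boundary positions.
classify_rib_lenient <- function(state, ratio) {
  if (state != "present") return("absent")
  if (!is.na(ratio) && ratio < 0.5) "rudimentary" else "full"
}

#' Classify one column into pattern, severity and regional counts
#'
#' @param column a `vertebral_column`.
#' @return one-row tibble with subject id, quality, pattern class,
#'   severity score, shift flags and directions, regional counts, and an
#'   `extreme` flag for presacral counts outside 22-26 (absence-of-
#'   formation rather than patterning cases; they remain in all counts).
#'   Non-evaluable columns yield a row of `NA` results.
#' @export
classify_column <- function(column) {
  stopifnot(inherits(column, "vertebral_column"))
  if (!identical(column$quality, "evaluable")) {
    return(tibble::tibble(
      subject_id = column$subject_id, quality = column$quality,
      pattern = NA_character_, severity = NA_integer_,
      ct = NA, ct_direction = NA_character_,
      tl = NA, tl_direction = NA_character_, ls = NA,
      cervical = NA_real_, thoracic = NA_real_, lumbar = NA_real_,
      presacral = NA_integer_, extreme = NA
    ))
  }
  shifts <- detect_shifts(column)
  pat <- pattern_class(shifts)
  counts <- regional_counts(column)
  tibble::tibble(
    subject_id = column$subject_id, quality = column$quality,
    pattern = pat, severity = severity_score(pat),
    ct = shifts$ct, ct_direction = shifts$ct_direction,
    tl = shifts$tl, tl_direction = shifts$tl_direction, ls = shifts$ls,
    cervical = counts$cervical, thoracic = counts$thoracic,
    lumbar = counts$lumbar, presacral = as.integer(counts$presacral),
    extreme = counts$presacral < 22L | counts$presacral > 26L
  )
}

#' Read a long-format morphology CSV
#'
#' Schema (one row per subject-vertebra-side): `subject_id`,
#' `vertebra_ordinal`, `side` (`left`/`right`), `rib_state`
#' (`absent`/`tp_enlarged`/`present`), `length_ratio` (blank allowed),
#' `tp_exceeds_t1` (0/1), `sacral_attached` (0/1), `ls_transitional_flag`
#' (0/1), `quality` (`evaluable`/`insufficient_ossification`/
#' `uninterpretable`).
#'
#' @param path CSV file path.
#' @return validated tibble.
#' @export
read_morphology <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    vertebra_ordinal = readr::col_integer(),
    side = readr::col_character(),
    rib_state = readr::col_character(),
    length_ratio = readr::col_double(),
    tp_exceeds_t1 = readr::col_integer(),
    sacral_attached = readr::col_integer(),
    ls_transitional_flag = readr::col_integer(),
    quality = readr::col_character()
  ))
  if (anyDuplicated(tbl[, c("subject_id", "vertebra_ordinal", "side")])) {
    stop("duplicate subject-vertebra-side rows in ", path)
  }
  tbl
}

#' Classify every subject of a morphology table
#'
#' Splits the long-format morphology table by subject, builds each
#' [as_vertebral_column()] and runs [classify_column()]. Non-evaluable
#' subjects are retained with `NA` results so exclusions stay visible;
#' downstream analyses drop them.
#'
#' @param morphology long-format morphology tibble (see
#'   [read_morphology()]).
#' @return tibble with one row per subject, in first-appearance order.
#' @export
classify_cohort <- function(morphology) {
  morphology <- as.data.frame(morphology)
  if (nrow(morphology) == 0L) {
    return(classify_column(empty_column())[0, ])
  }
  ids <- unique(morphology$subject_id)
  pieces <- split(morphology,
                  factor(morphology$subject_id, levels = ids))
  rows <- lapply(pieces, function(df) classify_column(as_vertebral_column(df)))
  dplyr::bind_rows(rows)
}

# zero-row template helper
empty_column <- function() {
  structure(list(subject_id = "template", quality = "uninterpretable",
                 vertebrae = data.frame()),
            class = "vertebral_column")
}
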