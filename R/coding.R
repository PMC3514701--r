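#' Organ systems, germ layers and morphogenetic processes
#'
#' The ten organ-system codes used for malformation coding:
#' bronchopulmonary (BP), cardiovascular (CV), craniofacial (CF),
#' digestive system (DS), limb defects (LD), muscular system (MS),
#' nervous system (NS), skeletal (SK), urogenital (UG) and ventral body
#' wall (VBW).
#'
#' @return character vector of codes/labels.
#' @export
organ_systems <- function() {
  c("BP", "CV", "CF", "DS", "LD", "MS", "NS", "SK", "UG", "VBW")
}

#' @rdname organ_systems
#' @export
germ_layers <- function() c("endoderm", "mesoderm", "ectoderm")

#' @rdname organ_systems
#' @export
morphogenetic_processes <- function() {
  c("midline", "neural_crest", "left_right", "segmentation")
}

#' Default coding map from finding terms to systems, layers and processes
#'
#' Each controlled-vocabulary term maps to exactly one primary organ
#' system, optional secondary systems (not counted), the germ layers of
#' the malformed structure, and the morphogenetic processes whose
#' disturbance the finding indicates. The assignment ships as an editable
#' default (see also the YAML copy under `inst/extdata/coding_map.yaml`);
#' germ-layer and process analyses are relative to this map.
#'
#' @return tibble with columns `term`, `primary`, `secondary`, `layers`,
#'   `processes` (the last three semicolon-separated, possibly empty).
#' @export
default_coding_map <- function() {
  e <- function(term, primary, secondary = "", layers = "", processes = "") {
    data.frame(term = term, primary = primary, secondary = secondary,
               layers = layers, processes = processes,
               stringsAsFactors = FALSE)
  }
  tibble::as_tibble(dplyr::bind_rows(
    e("lung_hypoplasia", "BP", layers = "endoderm"),
    e("congenital_cystic_lung", "BP", layers = "endoderm"),
    e("ventricular_septal_defect", "CV", layers = "mesoderm"),
    e("hypoplastic_left_heart", "CV", layers = "mesoderm"),
    e("transposition_great_arteries", "CV", layers = "mesoderm",
      processes = "left_right"),
    e("dextrocardia", "CV", layers = "mesoderm", processes = "left_right"),
    e("common_arterial_trunk", "CV", layers = "mesoderm",
      processes = "neural_crest"),
    e("cleft_lip", "CF", layers = "ectoderm",
      processes = "neural_crest;midline"),
    e("cleft_palate", "CF", layers = "ectoderm", processes = "neural_crest"),
    e("micrognathia", "CF", layers = "ectoderm", processes = "neural_crest"),
    e("ear_tag", "CF", layers = "ectoderm", processes = "neural_crest"),
    e("TE_fistula", "DS", secondary = "BP", layers = "endoderm",
      processes = "midline"),
    e("duodenal_atresia", "DS", layers = "endoderm"),
    e("anal_atresia", "DS", layers = "endoderm"),
    e("intestinal_malrotation", "DS", layers = "endoderm",
      processes = "left_right"),
    e("limb_reduction", "LD", secondary = "SK", layers = "mesoderm"),
    e("polydactyly", "LD", secondary = "SK", layers = "mesoderm"),
    e("syndactyly", "LD", layers = "mesoderm"),
    e("club_foot", "LD", layers = "mesoderm"),
    e("diaphragmatic_hernia", "MS", layers = "mesoderm"),
    e("muscular_hypoplasia", "MS", layers = "mesoderm"),
    e("holoprosencephaly", "NS", secondary = "CF", layers = "ectoderm",
      processes = "midline;neural_crest"),
    e("anencephaly", "NS", layers = "ectoderm", processes = "midline"),
    e("spina_bifida", "NS", layers = "ectoderm", processes = "midline"),
    e("hydrocephalus", "NS", layers = "ectoderm"),
    e("skeletal_dysplasia", "SK", secondary = "LD;CF", layers = "mesoderm"),
    e("hemivertebrae", "SK", layers = "mesoderm", processes = "segmentation"),
    e("fused_ribs", "SK", layers = "mesoderm", processes = "segmentation"),
    e("fused_vertebrae", "SK", layers = "mesoderm",
      processes = "segmentation"),
    e("renal_agenesis", "UG", layers = "mesoderm"),
    e("hydronephrosis", "UG", layers = "mesoderm"),
    e("horseshoe_kidney", "UG", layers = "mesoderm"),
    e("hypospadias", "UG", layers = "endoderm"),
    e("omphalocele", "VBW", layers = "mesoderm", processes = "midline"),
    e("gastroschisis", "VBW", layers = "mesoderm"),
    e("bladder_exstrophy", "VBW", layers = "mesoderm", processes = "midline")
  ))
}

#' Read a coding map from a YAML config
#'
#' @param path YAML file with a `coding_map` list of entries
#'   (`term`, `primary`, optional `secondary`, `layers`, `processes`).
#' @return tibble in the [default_coding_map()] layout.
#' @export
read_coding_map <- function(path) {
  cfg <- yaml::read_yaml(path)
  entries <- cfg$coding_map
  if (is.null(entries)) stop("no 'coding_map' block in ", path)
  rows <- lapply(entries, function(x) {
    data.frame(
      term = x$term, primary = x$primary,
      secondary = paste(x$secondary %||% character(), collapse = ";"),
      layers = paste(x$layers %||% character(), collapse = ";"),
      processes = paste(x$processes %||% character(), collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  map <- tibble::as_tibble(dplyr::bind_rows(rows))
  validate_coding_map(map)
  map
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_coding_map <- function(map) {
  stopifnot(all(c("term", "primary", "secondary", "layers", "processes")
                %in% names(map)))
  if (anyDuplicated(map$term)) {
    stop("coding map has duplicate terms: every term must map to exactly ",
         "one primary system")
  }
  if (!all(map$primary %in% organ_systems())) {
    stop("coding map has primary systems outside the 10-code list")
  }
  invisible(map)
}

split_semi <- function(x) {
  if (is.na(x) || !nzchar(x)) character() else strsplit(x, ";")[[1]]
}

# secondary-cause contexts under which lung hypoplasia is not counted
lung_hypoplasia_secondary_contexts <- function() {
  c("skeletal_dysplasia", "diaphragmatic_hernia", "oligohydramnion")
}

#' Apply the primary/secondary causal rules to one subject's findings
#'
#' Encodes findings into per-system primary flags, counting each finding
#' in at most one organ system. A set of fixed causal rules takes
#' precedence over the map: tracheo-esophageal fistulas count for the
#' digestive system only (secondary for bronchopulmonary); skeletal
#' dysplasias for the skeleton (secondary for limbs and craniofacies);
#' holoprosencephaly for the nervous system (secondary for craniofacies);
#' limb reduction and polydactyly for the limbs (secondary for skeleton);
#' lung hypoplasia is secondary - not counted - when caused by skeletal
#' dysplasia, diaphragmatic hernia or oligohydramnion; and any finding
#' attributed to hypoxic stress is secondary.
#'
#' @param findings data frame of one subject's findings: columns
#'   `subject_id`, `term`, `raw_system`, `cause_context`
#'   (semicolon-separated, may be empty).
#' @param map coding map tibble ([default_coding_map()]).
#' @param availability named 0/1 (or logical) vector over
#'   [organ_systems()]; systems scored "non-available" (maceration, no
#'   autopsy) get no flag and never enter counts. Defaults to all
#'   available.
#' @param subject_id subject identifier, required when `findings` is
#'   empty.
#' @return one-row tibble: `subject_id`, one column per organ system with
#'   values `affected`/`unaffected`/`non_available`,
#'   `n_systems_affected`, `n_band`, and `all_non_available`.
#' @export
apply_primary_secondary <- function(findings, map = default_coding_map(),
                                    availability = NULL,
                                    subject_id = NULL) {
  validate_coding_map(map)
  systems <- organ_systems()
  if (is.null(availability)) {
    availability <- stats::setNames(rep(1L, length(systems)), systems)
  }
  avail <- as.logical(availability[systems])
  avail[is.na(avail)] <- TRUE

  findings <- as.data.frame(findings)
  if (nrow(findings) == 0L) {
    if (is.null(subject_id)) {
      stop("subject_id required for an empty findings list")
    }
    sid <- subject_id
  } else {
    sid <- unique(findings$subject_id)
    if (length(sid) != 1L) stop("findings for exactly one subject expected")
  }

  unknown <- setdiff(findings$term, map$term)
  if (length(unknown) > 0L) {
    stop("unknown finding term(s): ", paste(unknown, collapse = ", "))
  }

  primary_of <- function(term, context) {
    ctx <- split_semi(context)
    if ("hypoxic_stress" %in% ctx) return(NA_character_)
    if (term == "lung_hypoplasia" &&
        any(ctx %in% lung_hypoplasia_secondary_contexts())) {
      return(NA_character_)
    }
    # fixed causal rules (these agree with the shipped map but are
    # enforced regardless of map edits)
    fixed <- c(TE_fistula = "DS", skeletal_dysplasia = "SK",
               holoprosencephaly = "NS", limb_reduction = "LD",
               polydactyly = "LD", lung_hypoplasia = "BP")
    if (term %in% names(fixed)) return(unname(fixed[term]))
    map$primary[map$term == term]
  }

  prim <- character(nrow(findings))
  for (i in seq_len(nrow(findings))) {
    prim[i] <- primary_of(findings$term[i],
                          findings$cause_context[i] %||% "")
  }
  counted <- prim[!is.na(prim)]

  flags <- ifelse(avail,
                  ifelse(systems %in% counted, "affected", "unaffected"),
                  "non_available")
  n_aff <- sum(flags == "affected")

  out <- tibble::tibble(subject_id = sid)
  for (k in seq_along(systems)) out[[systems[k]]] <- flags[k]
  out$n_systems_affected <- n_aff
  out$n_band <- n_affected_band(n_aff)
  out$all_non_available <- all(!avail)
  attr(out, "primary_terms") <- findings$term[!is.na(prim)]
  out
}

#' Band the number of affected organ systems
#'
#' @param n integer vector of affected-system counts (over available
#'   systems only).
#' @return factor with levels `0`, `1`, `2`, `3`, `4plus`.
#' @export
n_affected_band <- function(n) {
  stopifnot(all(n >= 0))
  factor(ifelse(n >= 4, "4plus", as.character(n)),
         levels = c("0", "1", "2", "3", "4plus"))
}

#' Derive germ-layer and morphogenetic-process involvement
#'
#' Union over the subject's primary (counted) findings of the map's
#' germ-layer and process sets; secondary findings contribute nothing, so
#' layer/process attribution follows the primary cause only. A subject
#' can contribute to several layers and processes.
#'
#' @inheritParams apply_primary_secondary
#' @param record record row from [apply_primary_secondary()] (its
#'   `primary_terms` attribute identifies the counted findings).
#' @return `record` with added logical columns, one per germ layer and
#'   per process.
#' @export
derive_layers_processes <- function(record, findings,
                                    map = default_coding_map()) {
  terms <- attr(record, "primary_terms")
  if (is.null(terms)) {
    stop("record lacks primary findings; run apply_primary_secondary first")
  }
  layers <- unique(unlist(lapply(terms, function(tm) {
    split_semi(map$layers[map$term == tm])
  })))
  procs <- unique(unlist(lapply(terms, function(tm) {
    split_semi(map$processes[map$term == tm])
  })))
  for (l in germ_layers()) record[[l]] <- l %in% layers
  for (p in morphogenetic_processes()) record[[p]] <- p %in% procs
  record
}

#' Code a findings table into per-subject malformation records
#'
#' Runs [apply_primary_secondary()] and [derive_layers_processes()] for
#' every subject. Subjects present in `subjects` but absent from
#' `findings` are coded as having no findings (all available systems
#' unaffected); whether such subjects had only secondary findings or none
#' at all is not distinguished - both land in the no-malformation group.
#'
#' @param findings findings tibble (`subject_id`, `term`, `raw_system`,
#'   `cause_context`).
#' @param subjects optional tibble with `subject_id` and per-system
#'   availability columns `avail_<SYS>` (0/1); defaults to the subjects
#'   appearing in `findings`, all systems available.
#' @param map coding map.
#' @return tibble with one record row per subject.
#' @export
code_findings <- function(findings, subjects = NULL,
                          map = default_coding_map()) {
  findings <- as.data.frame(findings)
  if (is.null(subjects)) {
    subjects <- tibble::tibble(subject_id = unique(findings$subject_id))
  }
  subjects <- as.data.frame(subjects)
  avail_cols <- paste0("avail_", organ_systems())
  has_avail <- all(avail_cols %in% names(subjects))

  idx <- split(seq_len(nrow(findings)),
               factor(findings$subject_id,
                      levels = unique(subjects$subject_id)))
  rows <- vector("list", nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject_id[i]
    availability <- if (has_avail) {
      stats::setNames(as.integer(subjects[i, avail_cols]), organ_systems())
    } else NULL
    f <- findings[idx[[i]] %||% integer(), , drop = FALSE]
    rec <- apply_primary_secondary(f, map, availability, subject_id = sid)
    rows[[i]] <- derive_layers_processes(rec, f, map)
  }
  dplyr::bind_rows(rows)
}
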