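test_that("rib classification applies the strict half-length rule", {
  expect_equal(classify_rib("present", 0.4, "last_thoracic"), "rudimentary")
  expect_equal(classify_rib("present", 1.0, "other"), "full")
  # exactly half is not "less than half": full
  expect_equal(classify_rib("present", 0.5, "first_thoracic"), "full")
  expect_equal(classify_rib("present", 0.49, "first_thoracic"),
               "rudimentary")
  expect_equal(classify_rib("absent", position = "last_thoracic"), "absent")
  expect_equal(classify_rib("tp_enlarged", position = "other"), "absent")
  expect_error(classify_rib("present", NA_real_, "first_thoracic"),
               "length_ratio required")
  expect_error(classify_rib("gone", 1, "other"), "invalid rib state")
})

test_that("seventh-vertebra classification follows the cervical-rib rules", {
  bilat <- make_column("s", mods = list("7.left" = rib("present", 0.3),
                                        "7.right" = rib("present", 0.3)))
  expect_equal(classify_c7(bilat), "transitional_cervicothoracic")

  long <- make_column("s", mods = list("7.left" = rib("present", 0.7)))
  expect_warning(cls <- classify_c7(long), "conflicting sides")
  expect_equal(cls, "thoracic_identity")

  # exactly half the adjacent rib is still transitional, not thoracic
  half <- make_column("s", mods = list("7.left" = rib("present", 0.5),
                                       "7.right" = rib("present", 0.5)))
  expect_equal(classify_c7(half), "transitional_cervicothoracic")

  # enlarged transverse process only counts when longer than that of T1
  tp_no <- make_column("s", mods = list("7.left" = rib("tp_enlarged")))
  expect_equal(classify_c7(tp_no), "normal")
  tp_yes <- as_vertebral_column(make_column_rows(
    "s", mods = list("7.left" = rib("tp_enlarged")),
    tp_mods = list("7.left" = TRUE)))
  expect_equal(classify_c7(tp_yes), "transitional_cervicothoracic")

  expect_equal(classify_c7(make_column("s")), "normal")
})

test_that("boundary shifts are detected with their directions", {
  # cervical ribs only: anterior C-T shift
  ct <- make_column("s", mods = list("7.left" = rib("present", 0.3),
                                     "7.right" = rib("present", 0.3)))
  sh <- detect_shifts(ct)
  expect_true(sh$ct); expect_equal(sh$ct_direction, "anterior")
  expect_false(sh$tl); expect_false(sh$ls)

  # regular column: no shifts
  sh0 <- detect_shifts(make_column("s"))
  expect_false(sh0$ct); expect_false(sh0$tl); expect_false(sh0$ls)
  expect_equal(sh0$ct_direction, "none")

  # rudimentary first rib: posterior C-T shift
  sh_post <- detect_shifts(make_column(
    "s", mods = list("8.left" = rib("present", 0.3),
                     "8.right" = rib("present", 0.3))))
  expect_true(sh_post$ct); expect_equal(sh_post$ct_direction, "posterior")

  # rudimentary twelfth rib: anterior T-L shift
  sh_tl <- detect_shifts(make_column(
    "s", mods = list("19.left" = rib("present", 0.3))))
  expect_true(sh_tl$tl); expect_equal(sh_tl$tl_direction, "anterior")

  # lumbar rib: posterior T-L shift
  sh_lr <- detect_shifts(make_column(
    "s", mods = list("20.left" = rib("present", 0.9),
                     "20.right" = rib("present", 0.9))))
  expect_true(sh_lr$tl); expect_equal(sh_lr$tl_direction, "posterior")

  # cervical ribs + unilateral rudimentary twelfth + four lumbar:
  # all three boundaries shifted
  sh3 <- detect_shifts(make_column(
    "s", n = 23L, mods = list("7.left" = rib("present", 0.3),
                              "7.right" = rib("present", 0.4),
                              "19.left" = rib("present", 0.3))))
  expect_true(sh3$ct); expect_true(sh3$tl); expect_true(sh3$ls)

  # observer-flagged transitional lumbo-sacral vertebra at 24 presacral
  sh_flag <- detect_shifts(as_vertebral_column(
    make_column_rows("s", ls_flag_at = 24L)))
  expect_true(sh_flag$ls); expect_false(sh_flag$ct)

  expect_error(detect_shifts(make_column("s", quality = "uninterpretable")),
               "not evaluable")
})

test_that("pattern class is a bijection on the shift-flag triples", {
  seen <- character()
  for (ct in c(FALSE, TRUE)) for (tl in c(FALSE, TRUE))
    for (ls in c(FALSE, TRUE)) {
      pat <- pattern_class(list(ct = ct, tl = tl, ls = ls))
      seen <- c(seen, pat)
      parts <- strsplit(pat, "_")[[1]]
      expect_equal("CT" %in% parts, ct)
      expect_equal("TL" %in% parts, tl)
      expect_equal("LS" %in% parts, ls)
    }
  expect_setequal(seen, pattern_levels())
  expect_equal(pattern_class(list(ct = FALSE, tl = FALSE, ls = FALSE)), "R")
  expect_equal(pattern_class(list(ct = TRUE, tl = TRUE, ls = FALSE)),
               "CT_TL")
})

test_that("severity scores rank anteriority and number of boundaries", {
  expect_equal(severity_score("R"), 0L)
  expect_equal(severity_score("CT_LS"), 7L)
  expect_equal(severity_score("CT_TL_LS"), 9L)
  # 2 and 5 are never produced
  expect_setequal(severity_score(pattern_levels()),
                  c(0L, 1L, 3L, 4L, 6L, 7L, 8L, 9L))
  # any C-T shift scores at least 6; none scores at most 4
  for (pat in pattern_levels()) {
    has_ct <- "CT" %in% strsplit(pat, "_")[[1]]
    if (has_ct) expect_gte(severity_score(pat), 6L)
    else expect_lte(severity_score(pat), 4L)
  }
  expect_error(severity_score("XX"), "unknown pattern")
})

test_that("regional counts give transitional vertebrae half identities", {
  expect_equal(
    as.numeric(regional_counts(make_column("s"))[1, ]),
    c(7, 12, 5, 24))
  # transitional cervico-thoracic vertebra: half cervical / half thoracic
  ct <- make_column("s", mods = list("7.left" = rib("present", 0.3),
                                     "7.right" = rib("present", 0.3)))
  expect_equal(as.numeric(regional_counts(ct)[1, ]), c(6.5, 12.5, 5, 24))
  # bilaterally absent twelfth ribs: full lumbar identity of vertebra 19
  tl <- make_column("s", mods = list("19.left" = rib("absent"),
                                     "19.right" = rib("absent")))
  expect_equal(as.numeric(regional_counts(tl)[1, ]), c(7, 11, 6, 24))
  # full lumbar ribs: vertebra 20 takes thoracic identity
  lr <- make_column("s", mods = list("20.left" = rib("present", 0.9),
                                     "20.right" = rib("present", 0.9)))
  expect_equal(as.numeric(regional_counts(lr)[1, ]), c(7, 13, 4, 24))
  # non-contiguous rib block is flagged segmentation-suspect
  expect_warning(
    out <- regional_counts(make_column(
      "s", mods = list("12.left" = rib("absent"),
                       "12.right" = rib("absent")))),
    "segmentation-suspect")
  expect_equal(out$presacral, 24L)
})

test_that("laterality never changes the pattern class", {
  uni <- make_column("s", mods = list("7.left" = rib("present", 0.3)))
  bil <- make_column("s", mods = list("7.left" = rib("present", 0.3),
                                      "7.right" = rib("present", 0.3)))
  expect_equal(pattern_class(detect_shifts(uni)),
               pattern_class(detect_shifts(bil)))
  uni_tl <- make_column("s", mods = list("19.right" = rib("absent")))
  bil_tl <- make_column("s", mods = list("19.left" = rib("absent"),
                                         "19.right" = rib("absent")))
  expect_equal(pattern_class(detect_shifts(uni_tl)),
               pattern_class(detect_shifts(bil_tl)))
})

test_that("column construction validates its schema", {
  rows <- make_column_rows("s")
  expect_s3_class(as_vertebral_column(rows), "vertebral_column")
  expect_error(as_vertebral_column(rbind(rows, rows[1, ])),
               "duplicate subject-vertebra-side")
  bad <- rows; bad$length_ratio[15] <- -0.2
  expect_error(as_vertebral_column(bad), "negative length_ratio")
  gap <- rows[rows$vertebra_ordinal != 3, ]
  expect_error(as_vertebral_column(gap), "contiguous")
  # sacral-attached vertebrae are trimmed off the presacral list
  sac <- rows
  sac$sacral_attached[sac$vertebra_ordinal >= 24] <- 1L
  col <- as_vertebral_column(sac)
  expect_equal(nrow(col$vertebrae), 23L)
})

test_that("extreme presacral counts are flagged but still classified", {
  short_rows <- make_column_rows("s", n = 17L)
  cl <- classify_column(as_vertebral_column(short_rows))
  expect_true(cl$extreme)
  expect_true(cl$ls)  # presacral != 24
  expect_equal(cl$presacral, 17L)
  cl24 <- classify_column(make_column("s"))
  expect_false(cl24$extreme)
})

test_that("non-evaluable columns are retained with NA results", {
  rows <- rbind(make_column_rows("a"),
                make_column_rows("b", quality = "insufficient_ossification"))
  cl <- classify_cohort(rows)
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$pattern[cl$subject_id == "a"], "R")
  expect_true(is.na(cl$pattern[cl$subject_id == "b"]))
})
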