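test_that("the bundled caudal table parses with typed intervals", {
  tt <- tail_table()
  expect_s3_class(tt, "tail_records")
  expect_identical(nrow(tt), 31L)
  d <- tt[tt$taxon == "Deinonychus_antirrhopus", ]
  expect_identical(c(d$NC_lo, d$NC_hi), c(36, 40))   # 36 preserved (+4 est.)
  expect_identical(d$TP_lo, 10)
  expect_identical(d$E_lo, 9)
  expect_identical(d$PZ_lo, 11)                      # >10
  expect_true(is.infinite(d$PZ_hi))
  expect_identical(d$C_lo, 8)
  expect_false(d$twofold)
  expect_true(d$trpt)
  mz <- tt[tt$taxon == "Microraptor_zhaoianus", ]
  expect_identical(c(mz$NC_lo, mz$NC_hi), c(24, 26))
  expect_identical(c(mz$TP_lo, mz$E_lo, mz$PZ_lo, mz$C_lo), c(6, 6, 6, 3))
  expect_true(mz$twofold)
  # reversed range is normalized
  cp <- tt[tt$taxon == "Cryptovolans_pauli", ]
  expect_identical(c(cp$NC_lo, cp$NC_hi), c(20, 28))
  # inapplicable vs unknown are distinguished
  expect_identical(tt$PZ_status[tt$taxon == "Gorgosaurus_libratus"],
                   "inapplicable")
  expect_identical(tt$TP_status[tt$taxon == "Beipiaosaurus_inexpectus"],
                   "unknown")
})

test_that("empty tables and malformed tokens are handled explicitly", {
  expect_identical(nrow(parse_tail_table("taxon\tNC\tTP\tE\tPZ\tC\ttwofold\ttrpt")),
                   0L)
  expect_error(
    parse_tail_table(c("taxon\tNC\tTP\tE\tPZ\tC\ttwofold\ttrpt",
                       "X\tabc\t1\t1\t1\t1\tYes\tYes")),
    "malformed count token.*row 1.*NC")
})

test_that("tail conditions classify as the clades they diagnose", {
  tt <- tail_table()
  cls <- stats::setNames(classify_tail_condition(tt), tt$taxon)
  expect_identical(unname(cls["Microraptor_zhaoianus"]),
                   "microraptorian-pattern")
  expect_identical(unname(cls["Velociraptor_mongoliensis"]),
                   "eudromaeosaurian-pattern")
  # the new tail skeleton under the four-missing-caudals assumption
  expect_identical(unname(cls["UMNH_VP_20209"]), "eudromaeosaurian-pattern")
  expect_identical(unname(cls["Gorgosaurus_libratus"]), "acaudothecate")
  # every fully-known dromaeosaurid row matches its clade
  full <- tt$PZ_status == "known" & tt$C_status == "known" &
    tt$TP_status == "known" & is.finite(tt$PZ_hi) & is.finite(tt$C_hi)
  for (r in which(full & tt$group == "Microraptoria")) {
    expect_identical(unname(cls[tt$taxon[r]]), "microraptorian-pattern")
  }
  for (r in which(full & tt$group == "Eudromaeosauria")) {
    expect_identical(unname(cls[tt$taxon[r]]), "eudromaeosaurian-pattern")
  }
  # a boundary-straddling interval stays indeterminate
  amb <- tt[tt$taxon == "Deinonychus_antirrhopus", ]
  amb$C_lo <- 4; amb$C_hi <- 6
  expect_identical(classify_tail_condition(amb), "indeterminate")
})

test_that("encoding maps table semantics onto discrete characters", {
  tt <- tail_table()
  tm <- encode_tail_characters(tt)
  expect_s3_class(tm, "char_matrix")
  expect_identical(tm$n_char, 7L)
  # acaudothecate unenlagiine: caudotheca absent
  expect_identical(cell_states(tm, "Buitreraptor_gonzalezorum", 1), 0L)
  # hemicaudothecate taxa injected from the side table
  expect_identical(cell_states(tm, "Utahraptor_ostrommaysorum", 1), 1L)
  expect_identical(cell_states(tm, "Achillobator_giganticus", 1), 1L)
  # caudothecate eudromaeosaur
  expect_identical(cell_states(tm, "Deinonychus_antirrhopus", 1), 2L)
  # a record with all unknowns encodes as a missing row
  blank <- tt[tt$taxon == "UMNH_VP_20209", ]
  blank$PZ_status <- "unknown"; blank$C_status <- "unknown"
  blank$PZ_lo <- blank$PZ_hi <- blank$C_lo <- blank$C_hi <- NA
  tm2 <- encode_tail_characters(blank, hemicaudotheca_taxa = character(0))
  expect_true(all(tm2$flags[1, ] == 1L))
})

test_that("tail-character mapping expresses the inferred transitions", {
  tt <- tail_table()
  tm <- encode_tail_characters(tt)
  ch <- map_tail_changes(coelurosaur_tree(), tm)
  # change counts per character equal the parsimony length on the same tree
  tr <- attr(ch, "tree")
  pruned <- prune_taxa(tm, setdiff(tm$taxa, tr$tip.label))
  s <- tree_length(tr, pruned, per_character = TRUE)
  cn <- c("caudotheca", "transition", "elongation2x", "nc_class", "tp_class",
          "pz_class", "c_class")
  for (j in seq_along(cn)) {
    expect_identical(sum(ch$character == cn[j] & ch$acctran), s[j])
    expect_identical(sum(ch$character == cn[j] & ch$deltran), s[j])
  }
  caud <- ch[ch$character == "caudotheca", ]
  gain <- caud[caud$to == 2, ]
  hemi <- caud[caud$to == 1, ]
  expect_identical(nrow(gain), 1L)
  expect_identical(nrow(hemi), 1L)
  expect_identical(gain$from, 0L)  # caudotheca gained from the absent state
  expect_identical(hemi$from, 2L)  # hemicaudotheca replaces a full caudotheca
  # the hemicaudotheca arises INSIDE the caudothecate clade
  gain_tips <- strsplit(gain$clade, ",")[[1]]
  hemi_tips <- strsplit(hemi$clade, ",")[[1]]
  expect_true(all(hemi_tips %in% gain_tips))
  expect_lt(length(hemi_tips), length(gain_tips))
  expect_true(all(c("Microraptor_zhaoianus", "Deinonychus_antirrhopus") %in%
                    gain_tips))
  # twofold elongation: gained in Paraves, reversed within Eudromaeosauria
  el <- ch[ch$character == "elongation2x", ]
  gain2 <- el[el$from == 0 & el$to == 1, ]
  rev2 <- el[el$from == 1 & el$to == 0, ]
  expect_identical(nrow(gain2), 1L)
  expect_identical(nrow(rev2), 1L)
  gt <- strsplit(gain2$clade, ",")[[1]]
  expect_true(all(c("Archaeopteryx_sp", "Anchiornis_huxleyi",
                    "Buitreraptor_gonzalezorum", "Microraptor_zhaoianus") %in% gt))
  rt <- strsplit(rev2$clade, ",")[[1]]
  expect_true(all(c("Velociraptor_mongoliensis", "Deinonychus_antirrhopus") %in% rt))
  expect_true(all(rt %in% gt))
  # drops are logged, not silent
  expect_true("Dromaeosaurus_albertensis" %in% attr(ch, "dropped")$tree_only ||
                length(attr(ch, "dropped")$tree_only) == 0L)
})

test_that("constant characters map with zero changes", {
  tok <- matrix("0", 4, 1, dimnames = list(c(
    "Gorgosaurus_libratus", "Microraptor_zhaoianus",
    "Deinonychus_antirrhopus", "Velociraptor_mongoliensis"), NULL))
  m <- char_matrix(tok, symbols = c("0", "1"))
  ch <- map_tail_changes(coelurosaur_tree(), m)
  expect_identical(nrow(ch), 0L)
})

test_that("caudotheca position bounds follow the missing-count arithmetic", {
  pos <- infer_caudotheca_position(4, 3)
  expect_identical(pos[["first_contributing"]], 8L)
  expect_identical(pos[["cranial_extent"]], 7L)
  expect_identical(unname(infer_caudotheca_position(0, 1)),
                   c(2L, 1L))
  # strictly increasing in both arguments over a grid
  for (m in 0:6) {
    for (k in 1:5) {
      cur <- infer_caudotheca_position(m, k)[["cranial_extent"]]
      if (m > 0) {
        expect_lt(infer_caudotheca_position(m - 1, k)[["cranial_extent"]], cur)
      }
      if (k > 1) {
        expect_lt(infer_caudotheca_position(m, k - 1)[["cranial_extent"]], cur)
      }
    }
  }
})
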