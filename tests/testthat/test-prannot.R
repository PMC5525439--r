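test_that("spectral classification is total over the standard residues", {
  aa <- names(KD_SCALE)
  cls <- vapply(aa, function(a) classify_tuning(a)$class, character(1))
  # exactly M, L -> green and Q -> blue; all 17 others unknown
  expect_setequal(names(cls)[cls == "green"], c("M", "L"))
  expect_setequal(names(cls)[cls == "blue"], "Q")
  expect_equal(sum(cls == "unknown"), 17)

  expect_equal(classify_tuning("M")$wavelength_nm, c(518, 535))
  expect_equal(classify_tuning("L")$wavelength_nm, c(518, 535))
  expect_equal(classify_tuning("Q")$wavelength_nm, c(490, 490))
  expect_equal(classify_tuning("q")$class, "blue")
  expect_length(classify_tuning("A")$wavelength_nm, 0)
  expect_error(classify_tuning("Z"), "amino-acid")
  expect_error(classify_tuning("MQ"), "amino-acid")
  expect_error(classify_tuning(1), "amino-acid")
})

test_that("hydropathy prediction matches the brute-force window oracle", {
  # one strong hydrophobic block flanked by charged tails
  s <- paste0(strrep("D", 20), strrep("I", 30), strrep("D", 20))
  tm <- predict_tm(s)
  expect_equal(nrow(tm), 1)
  # recompute the above-cutoff centers independently
  means <- kd_window_oracle(s)
  centers <- which(means > 1.6) + 9      # center index offset (half window)
  expect_equal(tm$start, max(1, min(centers) - 9))
  expect_equal(tm$end, min(nchar(s), max(centers) + 9))

  # all-polar sequence: no helix
  expect_equal(nrow(predict_tm(strrep("D", 80))), 0)
  # intervals are disjoint and sorted for a two-block sequence
  s2 <- paste0(strrep("D", 15), strrep("L", 25), strrep("E", 25),
               strrep("V", 25), strrep("D", 15))
  tm2 <- predict_tm(s2)
  expect_equal(nrow(tm2), 2)
  expect_true(all(diff(as.vector(t(as.matrix(tm2)))) > 0))
  # short blocks (< 15 residues after expansion) are dropped
  expect_equal(nrow(predict_tm(paste0(strrep("D", 30), strrep("I", 2),
                                      strrep("D", 30)))), 0)
  expect_warning(predict_tm(strrep("I", 10)), "shorter")
  expect_error(predict_tm(s, window = 18), "odd")
})

test_that("the bundled reference scaffold has seven helices and its features", {
  ref <- pr_reference()
  tm <- predict_tm(ref)
  expect_equal(nrow(tm), 7)
  f <- attr(ref, "features")
  ch <- strsplit(unname(ref), "")[[1]]
  expect_identical(ch[f[["proton_acceptor"]]], "D")
  expect_identical(ch[f[["proton_donor"]]], "E")
  expect_identical(ch[f[["retinal_lysine"]]], "K")
  expect_equal(unname(f[["tuning"]]), 105)
  expect_equal(unname(f[["proton_acceptor"]]), 97)
  expect_equal(unname(f[["proton_donor"]]), 108)
  expect_equal(unname(f[["retinal_lysine"]]), 231)
})

test_that("feature mapping recovers generator truth positions", {
  for (res in c("M", "L", "Q")) {
    p <- gen_pr_protein(res, seed = 17)
    mf <- map_features(unname(p))
    expect_true(mf$mappable)
    ft <- mf$features
    truth <- attr(p, "features")
    for (nm in ft$feature)
      expect_equal(ft$query_pos[ft$feature == nm], unname(truth[[nm]]))
    expect_identical(ft$observed[ft$feature == "tuning"], res)
    expect_true(all(ft$present[ft$feature != "tuning"]))
  }
  expect_error(map_features(strrep("M", 49)), "fragment too short")
  # an unrelated protein is reported unmappable, not force-fitted
  junk <- paste(rep(c("G", "S", "P", "N"), 60), collapse = "")
  expect_false(map_features(junk)$mappable)
})

test_that("annotation integrates tuning, features and helices", {
  g <- annotate_rhodopsin(gen_pr_protein("M", seed = 18))
  expect_equal(g$spectral_class, "green")
  expect_equal(g$wavelength_nm, c(518, 535))
  expect_true(is.na(g$wavelength_note))
  expect_equal(g$n_helices, 7)

  b <- annotate_rhodopsin(gen_pr_protein("Q", seed = 18))
  expect_equal(b$spectral_class, "blue")
  expect_equal(b$wavelength_nm, c(490, 490))
  expect_match(b$wavelength_note, "490")

  u <- annotate_rhodopsin(gen_pr_protein("A", seed = 18))
  expect_equal(u$spectral_class, "unknown")
  expect_length(u$wavelength_nm, 0)
})

test_that("truncated and partial queries degrade gracefully", {
  p <- unname(gen_pr_protein("M", seed = 19))
  # C-terminal truncation before Lys231: retinal site reported absent
  trunc <- substr(p, 1, 200)
  mt <- map_features(trunc)
  expect_true(mt$mappable)
  expect_false(mt$features$present[mt$features$feature == "retinal_lysine"])
  expect_true(mt$features$present[mt$features$feature == "tuning"])

  # 167-residue internal fragment covering the tuning site still classifies
  frag <- substr(p, 50, 216)
  af <- annotate_rhodopsin(frag)
  expect_equal(af$spectral_class, "green")
  tun <- af$features[af$features$feature == "tuning", ]
  expect_equal(tun$query_pos, 105 - 49)

  # annotation is stable under a polar C-terminal extension
  ext <- paste0(p, strrep("GS", 10))
  a1 <- annotate_rhodopsin(p); a2 <- annotate_rhodopsin(ext)
  expect_equal(a2$features$query_pos, a1$features$query_pos)
  expect_equal(a2$spectral_class, a1$spectral_class)
  # and idempotent on repeated calls
  expect_equal(annotate_rhodopsin(p)$features, a1$features)
})

test_that("annotation reports round-trip to disk", {
  a <- annotate_rhodopsin(gen_pr_protein("Q", seed = 20))
  d <- file.path(tempdir(), "ann")
  write_annotation(a, d)
  js <- jsonlite::read_json(file.path(d, "annotation.json"))
  expect_equal(js$spectral_class, "blue")
  expect_equal(js$n_helices, 7)
  ft <- read.table(file.path(d, "features.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(ft), 4)
})
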