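test_that("rule tables match the published protocol structure", {
  adult <- slf_rules("adult")
  neo <- slf_rules("neonate")
  expect_identical(nrow(adult), 6L)
  expect_identical(nrow(neo), 6L)

  # adult SLF II includes the parietal ROI; the neonatal variant swaps in
  # the posterior middle-frontal ROI, and nothing else differs
  expect_setequal(adult$include[adult$name == "SLF II L"][[1]],
                  c("PaL", "MFgL"))
  expect_setequal(neo$include[neo$name == "SLF II L"][[1]],
                  c("MFgL-P", "MFgL"))
  expect_setequal(neo$include[neo$name == "SLF II R"][[1]],
                  c("MFgR-P", "MFgR"))
  same <- adult$name != "SLF II L" & adult$name != "SLF II R"
  expect_identical(adult$include[same], neo$include[same])
  expect_identical(adult$exclude, neo$exclude)

  # every rule excludes the appropriate temporal ROI and the mid-sagittal
  for (i in seq_len(nrow(adult))) {
    expect_true("Midsag" %in% adult$exclude[[i]])
    expect_true(paste0("Te", adult$hemisphere[i]) %in% adult$exclude[[i]])
  }
  expect_error(selection_rule("x", character(0)), "non-empty")
  expect_error(selection_rule("x", "PaL", c("PaL", "TeL")), "disjoint")
})

test_that("ROI membership uses nearest-voxel tests with supersampling", {
  lay <- make_phantom()
  ids <- lay$labels

  # vertex exactly at an ROI voxel centre -> inside
  b <- lay$rois$PaL
  centre <- voxel_to_world(lay$volume, matrix(b[c(1, 3, 5)], 1))
  two <- rbind(centre, centre + c(0, 0, 1))
  expect_true(streamline_in_roi(two, lay$volume, ids["PaL"]))

  # entirely outside the volume -> outside, not an error
  far <- rbind(c(500, 500, 500), c(510, 510, 510))
  expect_false(streamline_in_roi(far, lay$volume, ids["PaL"]))

  # two vertices straddling the 1-voxel mid-sagittal slab: missed without
  # supersampling, caught with it
  ms <- roi_centroid(lay, "Midsag")
  straddle <- rbind(ms - c(10, 0, 0), ms + c(10, 0, 0))
  expect_false(streamline_in_roi(straddle, lay$volume, ids["Midsag"],
                                 supersample = FALSE))
  expect_true(streamline_in_roi(straddle, lay$volume, ids["Midsag"],
                                supersample = TRUE))
})

test_that("selection equals the brute-force boolean oracle", {
  lay <- make_phantom()
  sim <- simulate_tractogram(lay, default_bundle_mix("neonate", 40, 25),
                             seed = 6)
  rules <- slf_rules("neonate")
  for (i in seq_len(nrow(rules))) {
    sel <- select_streamlines(sim$tractogram, rules[i, ], lay,
                              supersample = FALSE)
    oracle <- which(oracle_select(sim$tractogram, rules$include[[i]],
                                  rules$exclude[[i]], lay))
    expect_identical(sel$kept, oracle)
  }
})

test_that("selection is idempotent, monotone and partitions the input", {
  lay <- make_phantom()
  sim <- simulate_tractogram(lay, default_bundle_mix("neonate", 30, 20),
                             seed = 7)
  rule <- slf_rules("neonate")[1, ]
  sel <- select_streamlines(sim$tractogram, rule, lay)

  # idempotence
  again <- select_streamlines(sel$tractogram, rule, lay)
  expect_length(again$kept, length(sel$kept))

  # kept + rejected partition the input exactly
  expect_length(sel$kept, length(unique(sel$kept)))
  expect_true(all(sel$kept %in% seq_len(length(sim$tractogram))))

  # adding an exclude ROI never grows the kept set; nor does an include
  harsher <- rule
  harsher$exclude[[1]] <- c(rule$exclude[[1]], "MFgL")
  expect_true(all(select_streamlines(sim$tractogram, harsher, lay)$kept
                  %in% sel$kept))
  narrower <- rule
  narrower$include[[1]] <- c(rule$include[[1]], "PrgL")
  expect_true(all(select_streamlines(sim$tractogram, narrower, lay)$kept
                  %in% sel$kept))

  # include/exclude order is irrelevant
  flipped <- rule
  flipped$include[[1]] <- rev(rule$include[[1]])
  flipped$exclude[[1]] <- rev(rule$exclude[[1]])
  expect_identical(select_streamlines(sim$tractogram, flipped, lay)$kept,
                   sel$kept)
  expect_error(select_streamlines(sim$tractogram,
                                  selection_rule("x", "NoSuch"), lay),
               "unknown ROI")
})

test_that("full dissection recovers ground truth and handles edge cases", {
  lay <- make_phantom()
  sim <- simulate_tractogram(lay, seed = 8)
  dis <- dissect_slf(sim$tractogram, lay, "neonate")
  rep <- attr(dis, "report")
  expect_identical(names(dis), slf_rules("neonate")$name)

  for (i in seq_len(nrow(rep))) {
    truth <- sim$provenance$index[sim$provenance$bundle == rep$name[i]]
    expect_gte(mean(truth %in% rep$kept[[i]]), 0.99)
  }
  contaminants <- sim$provenance$index[sim$provenance$contaminant]
  expect_length(intersect(unlist(rep$kept), contaminants), 0)

  # empty tractogram -> six empty bundles
  empty <- dissect_slf(tractogram(), lay, "neonate")
  expect_true(all(vapply(empty, length, integer(1)) == 0))

  # a streamline satisfying two rules lands in both, with a warning
  pa <- roi_centroid(lay, "PaL")
  sfg <- roi_centroid(lay, "SFgL")
  prg <- roi_centroid(lay, "PrgL")
  multi <- tractogram(list(do.call(rbind, list(
    slfmature:::supersample_polyline(rbind(prg, pa), 1),
    slfmature:::supersample_polyline(rbind(pa, sfg), 1)))))
  expect_warning(both <- dissect_slf(multi, lay, "neonate"),
                 "more than one rule")
  expect_length(both[["SLF I L"]], 1)
  expect_length(both[["SLF III L"]], 1)
})
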