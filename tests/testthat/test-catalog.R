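test_that("location classification follows chromosome, strand and gap", {
  m <- toy_models()
  # A (chr1,+) with C (chr2,+): inter-chromosomal
  inter <- classify_location(toy_call("A", "C", chrom3 = "chr2", bp3 = 50L,
                                      strand3 = "+"), m)
  expect_equal(as.character(inter$location_category), "inter-chromosomal")
  # A (+) with B (-) on chr1: opposite strands can never be read-through
  opp <- classify_location(toy_call("A", "B"), m, readthrough_gap = 1e6)
  expect_equal(as.character(opp$location_category), "intra-chromosomal")
  # same-strand neighbours within the gap: read-through; beyond it: intra
  m2 <- gene_models(data.frame(
    gene_id = c("g1", "g2"), symbol = c("U", "D"), chrom = "chr1",
    strand = "+", start = c(100L, 1000L), end = c(500L, 1500L)))
  rt_call <- toy_call("U", "D", bp5 = 499L, bp3 = 1000L, strand3 = "+")
  expect_equal(as.character(
    classify_location(rt_call, m2, readthrough_gap = 600L)$location_category),
    "read-through")
  expect_equal(as.character(
    classify_location(rt_call, m2, readthrough_gap = 100L)$location_category),
    "intra-chromosomal")
  # transcription-order requirement: 3' partner upstream is never read-through
  wrong_order <- toy_call("D", "U", bp5 = 1499L, bp3 = 100L, strand3 = "+")
  expect_equal(as.character(
    classify_location(wrong_order, m2, readthrough_gap = 1e6)$location_category),
    "intra-chromosomal")
  # contradictory chromosomes are refused
  expect_error(classify_location(toy_call("A", "B", chrom5 = "chr9"), m),
               "contradict")
})

test_that("read-through set is monotone in the gap threshold", {
  ds <- shared_dataset()
  gaps <- c(0L, 500L, 2000L, 50000L, 1000000L)
  sets <- lapply(gaps, function(g) {
    cl <- classify_location(ds$calls, ds$models, readthrough_gap = g)
    cl$call_id[cl$location_category == "read-through"]
  })
  for (i in seq_len(length(sets) - 1))
    expect_true(all(sets[[i]] %in% sets[[i + 1]]))
})

test_that("junction sides use strand-aware donor/acceptor edges", {
  m <- toy_models()
  # + strand gene A, exon [100,200): donor edge (last transcribed base) = 199
  e5 <- classify_junction_site(toy_call("A", "B", bp5 = 199L, bp3 = 1100L), m)
  expect_equal(e5$junction_side5, "E")
  expect_equal(e5$junction_side3, "M")  # 1100 is inside B's exon [1000,1200)
  expect_equal(as.character(e5$junction_site_category), "EM")
  # 5 bases inside the exon at tolerance 0: M; within tolerance 5: E
  m5 <- classify_junction_site(toy_call("A", "B", bp5 = 194L, bp3 = 1100L), m)
  expect_equal(m5$junction_side5, "M")
  t5 <- classify_junction_site(toy_call("A", "B", bp5 = 194L, bp3 = 1100L), m,
                               edge_tolerance = 5L)
  expect_equal(t5$junction_side5, "E")
  # - strand gene B: donor edge is the genomic start; acceptor the end-1
  eB <- classify_junction_site(toy_call("B", "A", bp5 = 1400L, bp3 = 300L,
                                        strand5 = "-", strand3 = "+"), m)
  expect_equal(eB$junction_side5, "E")
  expect_equal(eB$junction_side3, "E")  # 300 = acceptor edge of A's 2nd exon
  aB <- classify_junction_site(toy_call("A", "B", bp5 = 199L, bp3 = 1599L), m)
  expect_equal(aB$junction_side3, "E")  # 1599 = end-1 of B exon, '-' acceptor
  # breakpoint outside the gene: flagged, categorised M
  out <- classify_junction_site(toy_call("A", "B", bp5 = 5000L, bp3 = 1100L), m)
  expect_equal(out$junction_side5, "M")
  expect_match(out$junction_flag, "outside-gene")
})

test_that("background filter removes exactly panel-key matches", {
  calls <- rbind(toy_call("A", "B", call_id = "c1"),
                 toy_call("B", "A", call_id = "c2", bp5 = 1400L, bp3 = 300L,
                          strand5 = "-", strand3 = "+"),
                 toy_call("A", "C", call_id = "c3", chrom3 = "chr2",
                          bp3 = 50L, strand3 = "+"))
  class(calls) <- c("chimera_calls", "data.frame")
  empty <- structure(data.frame(gene5 = character(), gene3 = character()),
                     class = c("background_panel", "data.frame"))
  res0 <- filter_background(calls, empty)
  expect_equal(nrow(res0$retained), 3L)  # empty panel is the identity
  panel <- structure(data.frame(gene5 = "A", gene3 = "B",
                                stringsAsFactors = FALSE),
                     class = c("background_panel", "data.frame"))
  res <- filter_background(calls, panel)
  expect_equal(res$retained$call_id, c("c2", "c3"))  # B->A kept: ordered pair
  expect_equal(res$report$n_removed_panel, 1L)
  expect_equal(res$report$n_input,
               res$report$n_retained + res$report$n_removed_panel +
                 res$report$n_removed_mm)
  # breakpoint mode requires coordinates to agree within tolerance
  panel_bp <- structure(data.frame(gene5 = "A", gene3 = "B",
                                   breakpoint5 = 500L, breakpoint3 = 5000L,
                                   stringsAsFactors = FALSE),
                        class = c("background_panel", "data.frame"))
  res_bp <- filter_background(calls, panel_bp, match_mode = "breakpoint")
  expect_equal(nrow(res_bp$retained), 3L)  # same pair, far breakpoints
})

test_that("MM filter drops exactly the MM category and needs classification", {
  m <- toy_models()
  calls <- rbind(toy_call("A", "B", bp5 = 199L, bp3 = 1599L, call_id = "ee"),
                 toy_call("A", "B", bp5 = 199L, bp3 = 1100L, call_id = "em"),
                 toy_call("A", "B", bp5 = 150L, bp3 = 1599L, call_id = "me"),
                 toy_call("A", "B", bp5 = 150L, bp3 = 1100L, call_id = "mm"))
  class(calls) <- c("chimera_calls", "data.frame")
  expect_error(filter_mm(calls), "classified")
  cl <- classify_junction_site(calls, m)
  expect_equal(as.character(cl$junction_site_category),
               c("EE", "EM", "ME", "MM"))
  res <- filter_mm(cl)
  expect_equal(res$retained$call_id, c("ee", "em", "me"))
  expect_equal(res$report$n_removed_mm, 1L)
  # all-EE input is the identity
  all_ee <- cl[cl$junction_site_category == "EE", ]
  expect_equal(nrow(filter_mm(all_ee)$retained), nrow(all_ee))
})

test_that("category summary proportions are exact and sum to 1 per axis", {
  ds <- shared_dataset()
  cl <- classify_junction_site(classify_location(ds$calls, ds$models),
                               ds$models)
  smry <- category_summary(cl)
  for (ax in unique(smry$axis)) {
    sub <- smry[smry$axis == ax, ]
    expect_equal(sum(sub$proportion), 1)
    expect_equal(sum(sub$n), nrow(cl))
  }
  loc <- smry[smry$axis == "location", ]
  expect_equal(stats::setNames(loc$n, loc$category)[
    c("inter-chromosomal", "intra-chromosomal", "read-through")],
    c("inter-chromosomal" = 15L, "intra-chromosomal" = 14L,
      "read-through" = 1L))
  one <- category_summary(cl[1, ])
  expect_equal(one$proportion[one$n > 0], c(1, 1))
  expect_warning(category_summary(cl[0, ]), "no calls")
})

test_that("screen_calls recovers the planted truth end-to-end", {
  ds <- shared_dataset()
  truth <- ds$truth
  res <- screen_calls(ds$calls, ds$models, ds$panel)
  rem <- res$report$removed
  expect_setequal(rem$call_id[rem$reason == "background-panel"],
                  truth$call_id[truth$in_panel])
  expect_setequal(rem$call_id[rem$reason == "MM-junction"],
                  truth$call_id[truth$junction_site_category == "MM" &
                                  !truth$in_panel])
  expect_equal(res$report$n_input,
               res$report$n_retained + res$report$n_removed_panel +
                 res$report$n_removed_mm)
  # every retained call keeps its truth categories
  mtch <- match(res$retained$call_id, truth$call_id)
  expect_equal(as.character(res$retained$location_category),
               truth$location_category[mtch])
  expect_equal(as.character(res$retained$junction_site_category),
               truth$junction_site_category[mtch])
  # no retained key is in the panel
  expect_false(any(paste(res$retained$gene5, res$retained$gene3) %in%
                     paste(ds$panel$gene5, ds$panel$gene3)))
})
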