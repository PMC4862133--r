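test_that("a standard .out record parses with coordinate conversion and taxonomy", {
  path <- write_rm_fixture(rm_record_gypsy)
  ann <- parse_repeatmasker_out(path, min_score = 250)
  expect_equal(nrow(ann), 1)
  expect_equal(ann$scaffold, "scaf1")
  expect_equal(ann$start, 100)   # 1-based inclusive 101..200 -> [100, 200)
  expect_equal(ann$end, 200)
  expect_equal(ann$order, "LTR")
  expect_equal(ann$superfamily, "Gypsy")
  expect_equal(ann$family, "FamA")
  expect_equal(ann$score, 1306)
  expect_equal(ann$divergence, 15.6)
  expect_equal(ann$strand, "+")
})

test_that("the score cutoff drops weak hits and keeps the rest", {
  low <- "120 10.0 0.0 0.0 scaf1 11 60 (100) + FamLow LTR/Gypsy 1 50 (0) 2"
  path <- write_rm_fixture(c(rm_record_gypsy, low))
  ann <- parse_repeatmasker_out(path, min_score = 250)
  expect_equal(ann$family, "FamA")
  ann0 <- parse_repeatmasker_out(path, min_score = 0)
  expect_setequal(ann0$family, c("FamA", "FamLow"))
})

test_that("simple/low-complexity/satellite classes are excluded at parse time", {
  recs <- c(rm_record_gypsy,
            "900 5.0 0.0 0.0 scaf1 301 400 (100) + (TA)n Simple_repeat 1 100 (0) 3",
            "900 5.0 0.0 0.0 scaf1 501 600 (100) + SAR Satellite 1 100 (0) 4",
            "900 5.0 0.0 0.0 scaf1 701 800 (100) + poly-A Low_complexity 1 100 (0) 5")
  ann <- parse_repeatmasker_out(write_rm_fixture(recs))
  expect_equal(ann$family, "FamA")
  ann_all <- parse_repeatmasker_out(write_rm_fixture(recs), drop_simple = FALSE)
  expect_equal(nrow(ann_all), 4)
})

test_that("records flagged * (overlapped by a better hit) are retained for explicit resolution", {
  starred <- "300 10.0 0.0 0.0 scaf1 151 250 (50) C FamB LTR/Copia 1 100 (0) 6 *"
  ann <- parse_repeatmasker_out(write_rm_fixture(c(rm_record_gypsy, starred)))
  expect_equal(nrow(ann), 2)
  expect_equal(ann$strand[ann$family == "FamB"], "-")
})

test_that("malformed and degenerate files are rejected distinctly from empty record sets", {
  bad_coord <- "500 1.0 0.0 0.0 scaf1 200 100 (0) + FamX LTR/Gypsy 1 100 (0) 1"
  expect_error(parse_repeatmasker_out(write_rm_fixture(bad_coord)), "line 4.*end < start")
  expect_error(parse_repeatmasker_out(tempfile()), "not found")
  empty <- tempfile(); file.create(empty)
  expect_error(parse_repeatmasker_out(empty), "empty")
  header_only <- write_rm_fixture(character(0))
  expect_equal(nrow(parse_repeatmasker_out(header_only)), 0)
})

test_that("classify resolves names, class/family strings and falls back to Unknown", {
  tax <- default_taxonomy()
  expect_equal(unlist(classify("Gypsy", tax)), c(order = "LTR", superfamily = "Gypsy"))
  expect_equal(classify("Helitron", tax)$order, "Helitron")
  expect_equal(classify("Helitron", tax)$superfamily, "Helitron")
  expect_equal(unlist(classify("LTR/Gypsy", tax)), c(order = "LTR", superfamily = "Gypsy"))
  expect_equal(unlist(classify("Gypsy/LTR", tax)), c(order = "LTR", superfamily = "Gypsy"))
  expect_equal(unlist(classify("DNA/TcMar-Tc1", tax)),
               c(order = "TIR", superfamily = "Tc1/mariner"))
  expect_equal(unlist(classify("RC/Helitron", tax)),
               c(order = "Helitron", superfamily = "Helitron"))
  expect_equal(unlist(classify("TotallyNovelRepeat", tax)),
               c(order = "Unknown", superfamily = "Unknown"))
  # known order, unknown superfamily
  expect_equal(unlist(classify("LTR/NovelFam", tax)),
               c(order = "LTR", superfamily = "Unknown"))
  # superfamily "Unknown" only when the order is Unknown or no family maps
  cl <- classify(c("P", "DNA/P", "SINE/Alu"), tax)
  expect_equal(cl$order, c("TIR", "TIR", "Others"))
})

test_that("every taxonomy superfamily maps to exactly one order", {
  tax <- default_taxonomy()
  per_sf <- tapply(tax$order, tax$superfamily, function(o) length(unique(o)))
  expect_true(all(per_sf == 1))
  expect_true(all(tax$order %in% c("LTR", "LINE", "TIR", "Helitron",
                                   "Maverick", "Others", "Unknown")))
})

test_that("annotations round-trip through the .out dialect", {
  set.seed(41)
  for (rep in 1:5) {
    ann <- random_annotations(12, scaffold_len = 500)
    ann$superfamily <- sample(c("Gypsy", "Copia"), 12, replace = TRUE)
    ann$order <- "LTR"
    ann$strand <- sample(c("+", "-"), 12, replace = TRUE)
    path <- tempfile(fileext = ".out")
    write_repeatmasker_out(ann, path)
    back <- parse_repeatmasker_out(path, min_score = 0)
    back <- back[order(back$family), ]
    ann <- ann[order(ann$family), ]
    rownames(back) <- rownames(ann) <- NULL
    expect_equal(back, ann)
  }
})

test_that("resolve_overlaps implements score-priority base assignment", {
  two <- data.frame(scaffold = "scaf1", start = c(0, 50), end = c(100, 150),
                    strand = "+", family = c("FamA", "FamB"),
                    superfamily = "Gypsy", order = "LTR",
                    score = c(500, 300), divergence = 1,
                    stringsAsFactors = FALSE)
  r <- resolve_overlaps(two)
  expect_equal(r$start[r$family == "FamA"], 0)
  expect_equal(r$end[r$family == "FamA"], 100)
  expect_equal(r$start[r$family == "FamB"], 100)
  expect_equal(r$end[r$family == "FamB"], 150)

  # disjoint input is unchanged
  disj <- two; disj$start <- c(0, 200); disj$end <- c(100, 300)
  expect_equal(resolve_overlaps(disj)[, c("start", "end")],
               disj[, c("start", "end")])

  # an identical interval listed twice leaves one survivor
  dup <- rbind(two[1, ], two[1, ])
  expect_equal(nrow(resolve_overlaps(dup)), 1)
  expect_equal(sum(with(resolve_overlaps(dup), end - start)), 100)
})

test_that("resolve_overlaps agrees with the per-base brute-force oracle", {
  set.seed(99)
  for (case in 1:200) {
    ann <- random_annotations(sample(2:10, 1))
    r <- resolve_overlaps(ann)
    got <- tapply(r$end - r$start, r$family, sum, default = 0)
    want <- oracle_overlap_bp(ann)
    names(want) <- ann$family
    want <- want[want > 0]
    expect_equal(as.numeric(got[names(want)]), as.numeric(want))
    # disjointness and conservation
    ir <- IRanges::IRanges(r$start + 1, r$end)
    expect_equal(length(IRanges::findOverlaps(ir, drop.self = TRUE)), 0)
    expect_lte(sum(r$end - r$start), sum(ann$end - ann$start))
    expect_lte(sum(r$end - r$start), 200)  # scaffold length bound
  }
})

test_that("union counting merges within family and never exceeds score-mode per family", {
  set.seed(7)
  ann <- random_annotations(10)
  ann$family <- rep(c("FamA", "FamB"), 5)
  u <- resolve_overlaps(ann, method = "union")
  for (f in c("FamA", "FamB")) {
    ir <- IRanges::IRanges(ann$start[ann$family == f] + 1, ann$end[ann$family == f])
    expect_equal(sum(u$end[u$family == f] - u$start[u$family == f]),
                 sum(IRanges::width(IRanges::reduce(ir))))
  }
})

test_that("category totals aggregate bp and shares per order and superfamily", {
  ann <- data.frame(scaffold = "s", start = c(0, 100, 300), end = c(50, 200, 400),
                    strand = "+", family = c("g1", "g2", "h1"),
                    superfamily = c("Gypsy", "Gypsy", "Helitron"),
                    order = c("LTR", "LTR", "Helitron"),
                    score = 500, divergence = 1, stringsAsFactors = FALSE)
  ct <- category_totals(ann)
  expect_equal(ct$bp[ct$level == "order" & ct$category == "LTR"], 150)
  expect_equal(ct$bp[ct$level == "superfamily" & ct$category == "Gypsy"], 150)
  expect_equal(ct$bp[ct$level == "total"], 250)
  expect_equal(ct$share_pct[ct$level == "order" & ct$category == "LTR"], 60)
  # shares over orders sum to 100
  expect_equal(sum(ct$share_pct[ct$level == "order"]), 100)
  # empty input: every category present with zero mass
  ct0 <- category_totals(ann[0, ])
  expect_equal(sum(ct0$bp), 0)
  expect_equal(sort(ct0$category[ct0$level == "order"]),
               sort(c("LTR", "LINE", "TIR", "Helitron", "Maverick",
                      "Others", "Unknown")))
  expect_true(all(ct0$share_pct == 0))
})

test_that("the transcribed contribution table reproduces the published order shares", {
  tab <- te_contribution_table()
  st1 <- order_shares(tab, "st1_kb")
  expect_equal(st1$share_pct[st1$order == "Helitron"], 40.61, tolerance = 0.01 / 40.61)
  expect_equal(st1$share_pct[st1$order == "LTR"], 17.38, tolerance = 0.01 / 17.38)
  expect_equal(st1$share_pct[st1$order == "LINE"], 18.66, tolerance = 0.01 / 18.66)
  expect_equal(st1$share_pct[st1$order == "TIR"], 14.81, tolerance = 0.01 / 14.81)
  j19 <- order_shares(tab, "j19_kb")
  expect_equal(j19$share_pct[j19$order == "LTR"], 19.54, tolerance = 0.01 / 19.54)
  expect_equal(j19$share_pct[j19$order == "Helitron"], 30.65, tolerance = 0.01 / 30.65)
  moj <- order_shares(tab, "moj_kb")
  expect_equal(moj$share_pct[moj$order == "LTR"], 33.46, tolerance = 0.01 / 33.46)
  expect_equal(moj$share_pct[moj$order == "Helitron"], 33.90, tolerance = 0.011 / 33.90)
})
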