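test_that("a world is byte-identical across rebuilds with the same seed", {
  w1 <- build_world(tiny_world_config())
  w2 <- build_world(tiny_world_config())
  expect_identical(w1, w2)
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- write_world(w1, d1); p2 <- write_world(w2, d2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  # and a different seed changes it
  w3 <- build_world(tiny_world_config(seed = 4))
  expect_false(identical(w1$assembly, w3$assembly))
})

test_that("a zero-family plan yields an empty annotation set and all-zero truth", {
  cfg <- sim_config(seed = 1,
                    scaffolds = data.frame(scaffold = "s1", length = 5000),
                    families = data.frame(family = character(),
                                          order = character(),
                                          superfamily = character(),
                                          unit_len = numeric(), n = integer(),
                                          m = integer(), identity = numeric()),
                    coverage = 5, genes = list(n = 2, len = 300))
  w <- build_world(cfg)
  expect_equal(nrow(w$annotations), 0)
  expect_equal(nrow(w$truth$families), 0)
  expect_equal(sum(truth_report(w$truth)$true_bp), 0)
})

test_that("collapse bookkeeping: n=4, m=1 gives multiplicity 4 and a 4x mass gap", {
  w <- build_world(tiny_world_config())
  famA <- w$truth$families[w$truth$families$family == "FamA", ]
  expect_equal(famA$true_bp, 4000)
  expect_equal(famA$assembled_bp, 1000)
  multA <- w$truth$retained$multiplicity[w$truth$retained$family == "FamA"]
  expect_equal(multA, 4L)
  # multiplicities of a family always sum to n
  for (f in w$truth$families$family) {
    expect_equal(sum(w$truth$retained$multiplicity[w$truth$retained$family == f]),
                 w$truth$families$n[w$truth$families$family == f])
  }
  # assembly lost exactly the excised bases
  lost <- sum((w$truth$families$n - w$truth$families$m) * w$truth$families$unit_len)
  expect_equal(sum(nchar(w$true_genome)) - sum(nchar(w$assembly)), lost)
})

test_that("truth report gives mass-weighted expected factors per level", {
  cfg <- sim_config(seed = 2,
                    scaffolds = data.frame(scaffold = "s1", length = 30000),
                    families = data.frame(
                      family = c("F1", "F2"), order = "LTR",
                      superfamily = c("Gypsy", "Gypsy"),
                      unit_len = c(1000, 1000), n = c(2, 1), m = c(1, 1),
                      identity = 0.99),
                    coverage = 5, genes = list(n = 0, len = 0))
  rep <- truth_report(build_world(cfg)$truth)
  expect_equal(rep$expected_factor[rep$level == "family" & rep$category == "F1"], 2)
  expect_equal(rep$expected_factor[rep$level == "family" & rep$category == "F2"], 1)
  # order pools mass: (2+1)/(1+1)
  expect_equal(rep$expected_factor[rep$level == "order" & rep$category == "LTR"], 1.5)
  # m = n everywhere gives factor 1
  cfg2 <- sim_config(seed = 2,
                     scaffolds = data.frame(scaffold = "s1", length = 30000),
                     families = data.frame(family = "F1", order = "LTR",
                                           superfamily = "Gypsy",
                                           unit_len = 1000, n = 3, m = 3,
                                           identity = 0.99),
                     coverage = 5, genes = list(n = 0, len = 0))
  rep2 <- truth_report(build_world(cfg2)$truth)
  expect_true(all(rep2$expected_factor == 1))
})

test_that("emitted annotations parse back to exactly the retained copies", {
  w <- build_world(tiny_world_config())
  d <- tempfile(); p <- write_world(w, d)
  back <- parse_repeatmasker_out(p["annotations"], min_score = 250)
  ret <- w$truth$retained[order(w$truth$retained$scaffold, w$truth$retained$start), ]
  expect_equal(back$scaffold, ret$scaffold)
  expect_equal(back$start, ret$start)
  expect_equal(back$end, ret$end)
  expect_equal(back$family, ret$family)
})

test_that("noiseless depth equals C x multiplicity on survivors and C elsewhere", {
  cfg <- tiny_world_config()
  w <- build_world(cfg)
  tr <- simulate_alignments(w, "depth")
  C <- cfg$coverage
  ret <- w$truth$retained
  for (i in seq_len(nrow(ret))) {
    seg <- tr[[ret$scaffold[i]]][(ret$start[i] + 1):ret$end[i]]
    expect_true(all(seg == C * ret$multiplicity[i]))
  }
  # gene (single-copy) positions sit exactly at C
  expect_equal(mean_feature_coverage(tr, w$genes)$value, C)
  # a collapse-free world is flat at C everywhere
  cfg1 <- sim_config(seed = 5,
                     scaffolds = data.frame(scaffold = "s1", length = 8000),
                     families = data.frame(family = "F", order = "LTR",
                                           superfamily = "Gypsy",
                                           unit_len = 500, n = 2, m = 2,
                                           identity = 0.99),
                     coverage = 4, genes = list(n = 2, len = 300))
  w1 <- build_world(cfg1)
  tr1 <- simulate_alignments(w1, "depth")
  expect_true(all(tr1$s1 == 4))
})

test_that("SAM and depth-TSV emissions agree base by base", {
  for (mode in c("noiseless", "poisson")) {
    w <- build_world(tiny_world_config(cov_mode = mode))
    lens <- vapply(w$assembly, nchar, 0L)
    tr_tsv <- simulate_alignments(w, "depth")
    tr_sam <- depth_track(simulate_alignments(w, "sam"), lens)
    expect_equal(lapply(tr_tsv, as.integer), lapply(tr_sam, as.integer),
                 ignore_attr = TRUE)
  }
})

test_that("poisson mode places the expected total read mass", {
  cfg <- tiny_world_config(seed = 9, cov_mode = "poisson")
  w <- build_world(cfg)
  tr <- simulate_alignments(w, "depth")
  # expected mass: C per true-genome base (collapsed survivors absorb their
  # sources' reads)
  expected <- cfg$coverage * sum(nchar(w$true_genome))
  n_reads_mean <- expected / cfg$read_len
  sd3 <- 3 * sqrt(n_reads_mean) * cfg$read_len
  expect_lt(abs(attr(tr, "aligned_bases") - expected), sd3)
})

test_that("an infeasible TE plan is rejected before emission", {
  expect_error(sim_config(seed = 1,
                          scaffolds = data.frame(scaffold = "s1", length = 2000),
                          families = data.frame(family = "F", order = "LTR",
                                                superfamily = "Gypsy",
                                                unit_len = 1000, n = 3, m = 1,
                                                identity = 0.99)),
               "exceeds genome")
})

test_that("the noiseless correction recovers true per-category mass exactly", {
  w <- build_world(tiny_world_config())
  tr <- simulate_alignments(w, "depth")
  cm <- corrected_mass(tr, resolve_overlaps(w$annotations),
                       mean_feature_coverage(tr, w$genes))
  rep <- truth_report(w$truth)
  for (f in w$truth$families$family) {
    got <- cm$corrected_bp[cm$level == "superfamily" &
             cm$category == w$truth$families$superfamily[w$truth$families$family == f]]
    want <- rep$true_bp[rep$level == "family" & rep$category == f]
    expect_equal(got, want)
  }
  expect_equal(cm$corrected_bp[cm$category == "Total"],
               rep$true_bp[rep$level == "total"])
})
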