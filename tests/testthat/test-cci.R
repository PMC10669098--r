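test_that("interaction score averages side summaries with gates and min rule", {
  # hand-built normalized layer: known means per side
  counts <- matrix(1L, 4, 40, dimnames = list(
    c("LIG", "RECA", "RECB", "OTHER"), sprintf("c%02d", 1:40)))
  m <- expression_matrix(counts)
  vals <- matrix(0, 4, 40, dimnames = dimnames(counts))
  vals["LIG", 1:20] <- 2 # sender mean 2.0
  vals["RECA", 21:40] <- 4 # receiver mean 4.0
  vals["RECB", 21:40] <- 1 # second complex component, mean 1.0
  m$normalized <- vals
  ann <- cell_annotation(data.frame(
    cell_id = colnames(counts), sample_id = "s1", tissue = "tumor",
    major_type = "M", subtype = rep(c("SND", "RCV"), each = 20)
  ), m)

  one <- interaction_score(m, ann, list(ligand = "LIG", receptor = "RECA"),
    "SND", "RCV")
  expect_equal(one$score, 3)

  # multi-component receptor: minimum over component means
  cplx <- interaction_score(m, ann,
    list(ligand = "LIG", receptor = c("RECA", "RECB")), "SND", "RCV")
  expect_equal(cplx$receptor_summary, 1)
  expect_equal(cplx$score, 1.5)

  # expression gate: receptor present in 5% < 10% of receiver cells
  vals2 <- vals
  vals2["RECA", ] <- 0
  vals2["RECA", 21] <- 4
  m2 <- m
  m2$normalized <- vals2
  gated <- interaction_score(m2, ann, list(ligand = "LIG", receptor = "RECA"),
    "SND", "RCV")
  expect_true(gated$gated)
  expect_equal(gated$score, 0)

  expect_error(interaction_score(m, ann, list(ligand = "NOPE", receptor = "RECA"),
    "SND", "RCV"), "absent")
})

test_that("permutation test is deterministic, add-one bounded, and gate-aware", {
  d <- planted_cci_data(101, n_cells = 60, fold = 3, n_bg = 6)
  db <- make_lr_db(c("PP", "B1"), c("PLIG", "BGX01"), c("PREC", "BGX02"))
  s1 <- permutation_test(d$matrix, d$annotation, db, n_perm = 200, seed = 5L)
  s2 <- permutation_test(d$matrix, d$annotation, db, n_perm = 200, seed = 5L)
  expect_identical(s1, s2)
  expect_true(all(s1$p >= 1 / 201))
  expect_true(all(s1$p <= 1))
  expect_equal(nrow(s1), 2 * 4) # 2 pairs x 2x2 ordered subtype pairs
  # planted pair most significant in its planted direction
  planted <- s1[s1$pair_id == "PP" & s1$sender == "SND" & s1$receiver == "RCV", ]
  expect_lt(planted$p, 0.05)

  # a gated (zero) observed score must carry p = 1
  d0 <- d
  x <- as.matrix(d0$matrix$normalized)
  x["PLIG", ] <- 0
  x["PLIG", 1] <- 5
  d0$matrix$normalized <- x
  s0 <- suppressWarnings(permutation_test(d0$matrix, d0$annotation,
    make_lr_db("PP", "PLIG", "PREC"), n_perm = 50, seed = 5L))
  expect_true(all(s0$p[s0$score == 0] == 1))
  expect_error(permutation_test(d$matrix, d$annotation, db, n_perm = 5), "at least 10")
})

test_that("interaction counting matches a brute-force tally", {
  set.seed(23)
  subtypes <- c("A", "B", "C")
  rec <- expand.grid(sender = subtypes, receiver = subtypes,
    pair_id = sprintf("p%02d", 1:12), stringsAsFactors = FALSE)
  rec$score <- runif(nrow(rec))
  rec$p <- runif(nrow(rec))
  rec$q <- rec$p
  class(rec) <- c("interaction_scores", "data.frame")
  cnt <- count_interactions(rec, alpha = 0.3)
  for (a in subtypes) {
    for (b in subtypes) {
      expect_equal(cnt[a, b],
        sum(rec$p < 0.3 & rec$sender == a & rec$receiver == b))
    }
  }
  tot <- attr(cnt, "total")
  expect_equal(tot["A", "B"], cnt["A", "B"] + cnt["B", "A"])
  expect_equal(tot["A", "A"], cnt["A", "A"])

  none <- rec
  none$p <- 1
  expect_true(all(count_interactions(none) == 0))
})

test_that("subsampling keeps small subtypes intact and is seed-stable", {
  ann <- cell_annotation(data.frame(
    cell_id = sprintf("c%04d", 1:600), sample_id = "s1", tissue = "tumor",
    major_type = "M", subtype = rep(c("BIG", "SMALL"), c(550, 50))
  ))
  sub <- subsample_cells(ann, per_subtype = 300, seed = 9L)
  expect_equal(sum(sub$subtype == "BIG"), 300L)
  expect_equal(sum(sub$subtype == "SMALL"), 50L)
  sub2 <- subsample_cells(ann, per_subtype = 300, seed = 9L)
  expect_identical(sub, sub2)
  expect_error(subsample_cells(ann, per_subtype = 5), "per_subtype")
})

test_that("specificity cv matches the one-hot closed form and orders records", {
  subtypes <- c("A", "B", "C")
  grid <- expand.grid(sender = subtypes, receiver = subtypes,
    stringsAsFactors = FALSE)
  m_pairs <- nrow(grid) # 9 subtype pairs
  rec <- do.call(rbind, lapply(c("HOT", "FLAT"), function(p) {
    g <- grid
    g$pair_id <- p
    g$score <- if (p == "HOT") c(5, rep(0, m_pairs - 1)) else rep(2, m_pairs)
    g$p <- 0.01
    g$q <- 0.01
    g
  }))
  class(rec) <- c("interaction_scores", "data.frame")
  spec <- specificity_filter(rec, top_n = 100)
  # score s in one pair, 0 in the m-1 others: cv = sqrt(m - 1)
  expect_equal(spec$cv[spec$pair_id == "HOT"], sqrt(m_pairs - 1))
  expect_equal(spec$cv[spec$pair_id == "FLAT"], 0)
  expect_equal(spec$pair_id[1], "HOT")
  expect_equal(spec$top_sender[spec$pair_id == "HOT"], "A")

  # invariant to record order
  spec2 <- specificity_filter(rec[sample(nrow(rec)), ], top_n = 100)
  expect_equal(spec, spec2)

  allzero <- rec
  allzero$score <- 0
  expect_error(suppressWarnings(specificity_filter(allzero)), "nonzero")
})
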