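test_that("expressing fractions use the in-subtype nonzero lower quartile", {
  # subtype nonzero normalized values {1,2,3,4}: t = 1.75, so 3 of 4 exceed...
  # values 2,3,4 > 1.75 -> Pgi counts cells *strictly above* among all 5
  counts <- matrix(0L, 2, 9, dimnames = list(c("GX", "GY"),
    sprintf("c%02d", 1:9)))
  m <- expression_matrix(counts)
  vals <- matrix(0, 2, 9, dimnames = dimnames(counts))
  vals["GX", 1:5] <- c(1, 2, 3, 4, 0) # subtype cells; one zero ignored for t
  vals["GX", 6:9] <- c(1.8, 1, 0, 0) # outside: one above t
  m$normalized <- vals
  ann <- cell_annotation(data.frame(
    cell_id = colnames(counts), sample_id = "s1", tissue = "tumor",
    major_type = "M", subtype = rep(c("IN", "OUT"), c(5, 4))
  ), m)
  ef <- expressing_fraction(m, ann, "GX", "IN")
  expect_equal(ef$threshold, 1.75)
  expect_equal(ef$Pgi, 3 / 5)
  expect_equal(ef$Qgi, 1 / 4)
  expect_true(ef$eligible)

  ef0 <- expressing_fraction(m, ann, "GY", "IN")
  expect_false(ef0$eligible)
  expect_equal(ef0$Pgi, 0)
  expect_error(expressing_fraction(m, ann, "NOPE", "IN"), "not present")
})

test_that("Sgi arithmetic, boundaries, and monotonicity", {
  expect_equal(signature_gene_score(0.8, 0.2), 0.75)
  expect_equal(signature_gene_score(0.3, 0), 1)
  expect_equal(signature_gene_score(0.5, 0.5), 0)
  expect_equal(signature_gene_score(0.2, 0.4), -1)
  expect_error(signature_gene_score(0, 0.1), "Pgi = 0")

  # strictly decreasing in Q, increasing in P
  q <- seq(0.05, 0.5, by = 0.05)
  expect_true(all(diff(signature_gene_score(rep(0.6, length(q)), q)) < 0))
  p <- seq(0.3, 0.9, by = 0.1)
  expect_true(all(diff(signature_gene_score(p, rep(0.2, length(p)))) > 0))
})

test_that("subtype signatures select planted markers and reject shared genes", {
  sim <- simulate_cohort(simulation_config(n_samples = 8,
    cells_per_sample = 500, seed = 13L))
  m <- normalize_counts(sim$matrix)
  sig <- build_subtype_signature(m, sim$annotation, "Treg")
  planted <- sim$truth$markers$gene[sim$truth$markers$subtype == "Treg"]
  expect_gte(sum(planted %in% sig$genes) / length(planted), 0.9)
  expect_false(any(startsWith(sig$genes, "BG")))
  # analytic expectation: Sgi ~ 1 - p_out/p_in for planted markers
  expect_lt(abs(sig$Ssubj - (1 - 0.05 / 0.8)), 0.08)

  tab <- sig$table
  bg <- tab[startsWith(tab$gene, "BG") & tab$eligible, ]
  expect_lt(stats::median(abs(bg$Sgi)), 0.3)

  expect_error(build_subtype_signature(m, sim$annotation, "Treg",
    min_cells = 1e6), "fewer than")
})

test_that("subTME scores combine Ssubj and abundance with missing handling", {
  sigs <- list(
    structure(list(subtype = "A", genes = "g", Ssubj = 0.8), class = "subtype_signature"),
    structure(list(subtype = "B", genes = "g", Ssubj = 0.6), class = "subtype_signature")
  )
  ab <- matrix(c(0.5, 0.2, NA, 0.5, NA, NA), nrow = 3,
    dimnames = list(c("s1", "s2", "s3"), c("A", "B")))
  sc <- subtme_score(sigs, ab, c("A", "B"))
  expect_equal(sc$score[sc$sample_id == "s1"], (0.8 * 0.5 + 0.6 * 0.5) / 2)
  # s2: B missing -> single-subtype mean, flagged incomplete
  expect_equal(sc$score[sc$sample_id == "s2"], 0.8 * 0.2)
  expect_true(sc$incomplete[sc$sample_id == "s2"])
  expect_true(is.na(sc$score[sc$sample_id == "s3"]))

  # raising the abundance of the higher-Ssubj subtype raises the score
  ab2 <- ab
  ab2["s1", "A"] <- 0.7
  sc2 <- subtme_score(sigs, ab2, c("A", "B"))
  expect_gt(sc2$score[1], sc$score[1])

  expect_error(subtme_score(sigs, ab, c("A", "C")), "signature")
})

test_that("ssGSEA scores rank-enrichment and matches the brute-force oracle", {
  set.seed(17)
  expr <- stats::setNames(rexp(200), sprintf("g%03d", 1:200))
  top_set <- names(sort(expr, decreasing = TRUE))[1:15]
  expect_gt(ssgsea_score(expr, top_set), 0)
  bottom_set <- names(sort(expr))[1:15]
  expect_lt(ssgsea_score(expr, bottom_set), 0)

  for (i in 1:10) {
    expr_i <- stats::setNames(rnorm(80), sprintf("h%02d", 1:80))
    set_i <- sample(names(expr_i), 12)
    expect_equal(ssgsea_score(expr_i, set_i),
      ssgsea_bruteforce(expr_i, set_i), tolerance = 1e-9)
    expect_equal(ssgsea_score(expr_i, set_i, normalization = "none"),
      ssgsea_bruteforce(expr_i, set_i, normalization = "none"),
      tolerance = 1e-9)
  }

  # invariance under strictly monotone transform
  expect_equal(ssgsea_score(expr, top_set), ssgsea_score(exp(expr), top_set))
  expect_error(ssgsea_score(expr, names(expr)), "whole gene universe")
  expect_error(ssgsea_score(expr, "ABSENT"), "no overlap")
})

test_that("bulk scoring averages signatures and warns on poor overlap", {
  set.seed(19)
  counts <- matrix(rpois(100 * 6, 5), 100,
    dimnames = list(sprintf("g%03d", 1:100), sprintf("s%d", 1:6)))
  bulk <- normalize_counts(expression_matrix(counts))
  sigA <- sprintf("g%03d", 1:10)
  one <- bulk_subtme_score(bulk, list(A = sigA))
  direct <- ssgsea_matrix(as.matrix(bulk$normalized), toupper(sigA))
  expect_equal(one$score, unname(direct))

  expect_warning(
    two <- bulk_subtme_score(bulk, list(A = sigA, BAD = c("NOPE1", "NOPE2"))),
    "BAD"
  )
  expect_equal(two$score, one$score)
  expect_error(
    suppressWarnings(bulk_subtme_score(bulk, list(BAD = c("NOPE1", "NOPE2")))),
    "no signature"
  )
})
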