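test_that("group means match a brute-force loop over samples", {
  m <- make_expression_matrix(n_genes = 20L,
                              groups = stats::setNames(c(3L, 3L, 3L),
                                                       c("g1", "g2", "g3")),
                              enriched_genes = 1:2, seed = 5)
  md <- compute_mean_data(m$expr, m$grouping)
  expect_equal(colnames(md), c("g1", "g2", "g3"))
  for (g in colnames(md)) {
    cols <- names(m$grouping)[m$grouping == g]
    for (i in seq_len(nrow(md))) {
      expect_equal(md[i, g], mean(m$expr[i, cols]))
    }
  }
  # triplicate (1,2,3) -> 2; singleton group passes values through
  e2 <- matrix(c(1, 2, 3, 7), nrow = 1,
               dimnames = list("g", c("a1", "a2", "a3", "b1")))
  md2 <- compute_mean_data(e2, c(a1 = "a", a2 = "a", a3 = "a", b1 = "b"))
  expect_equal(unname(md2[1, ]), c(2, 7))
  expect_error(compute_mean_data(e2, c(a1 = "a", a2 = "a", a3 = "a")),
               "unmapped")
})

test_that("specificity ratio is min(sc)/max(nsc) with an undefined flag at zero", {
  expect_equal(specificity_ratio(10, c(1, 2, 1)), 5)
  expect_equal(as.numeric(specificity_ratio(c(3, 3), c(3, 3, 3))), 1)
  z <- specificity_ratio(c(4, 5), c(0, 0))
  expect_true(is.infinite(z))
  expect_true(attr(z, "undefined"))
  expect_error(specificity_ratio(numeric(0), 1), "empty")

  # loop oracle on random matrices
  set.seed(11)
  for (k in 1:20) {
    sc <- matrix(stats::rlnorm(12), 4)
    nsc <- matrix(stats::rlnorm(20), 4)
    for (i in 1:4) {
      lo_min <- Inf; hi_max <- -Inf
      for (v in sc[i, ]) lo_min <- min(lo_min, v)
      for (v in nsc[i, ]) hi_max <- max(hi_max, v)
      expect_equal(as.numeric(specificity_ratio(sc[i, ], nsc[i, ])),
                   lo_min / hi_max)
    }
  }
})

test_that("sr is scale-invariant and sr > 1 iff every sc value beats every nsc value", {
  set.seed(21)
  for (k in 1:100) {
    sc <- stats::rlnorm(3); nsc <- stats::rlnorm(5)
    c0 <- stats::rlnorm(1)
    expect_equal(as.numeric(specificity_ratio(c0 * sc, c0 * nsc)),
                 as.numeric(specificity_ratio(sc, nsc)))
    expect_equal(as.numeric(specificity_ratio(sc, nsc)) > 1,
                 all(outer(sc, nsc, ">")))
  }
})

test_that("exact rank-sum p comes from full enumeration and matches wilcox.test", {
  # C(6,3) = 20 assignments; only one is as extreme: p = 1/20
  expect_equal(rank_sum_p(c(5, 6, 7), c(1, 2, 3), "greater"), 0.05)
  expect_equal(rank_sum_p(c(1, 1, 1), c(1, 1, 1)), 1)

  # cross-implementation oracle on random small untied cases
  set.seed(31)
  for (k in 1:50) {
    m <- sample(2:5, 1); n <- sample(2:5, 1)
    x <- sample.int(1000, m + n)  # untied
    p_pkg <- rank_sum_p(x[1:m], x[-(1:m)], "two-sided")
    p_ref <- stats::wilcox.test(x[1:m], x[-(1:m)], exact = TRUE,
                                correct = FALSE)$p.value
    expect_equal(p_pkg, p_ref, tolerance = 1e-9)
    p_pkg_g <- rank_sum_p(x[1:m], x[-(1:m)], "greater")
    p_ref_g <- stats::wilcox.test(x[1:m], x[-(1:m)], exact = TRUE,
                                  alternative = "greater")$p.value
    expect_equal(p_pkg_g, p_ref_g, tolerance = 1e-9)
  }

  # large-sample path: tie-corrected normal approximation
  set.seed(32)
  x <- round(stats::rnorm(20, 5), 1); y <- round(stats::rnorm(15, 6), 1)
  p_pkg <- rank_sum_p(x, y, "two-sided")
  p_ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = FALSE)$p.value)
  expect_equal(p_pkg, p_ref, tolerance = 1e-9)
})

test_that("rank-sum p is invariant under strictly monotone transforms", {
  set.seed(41)
  for (k in 1:100) {
    sc <- stats::rlnorm(3); nsc <- stats::rlnorm(4)
    p0 <- rank_sum_p(sc, nsc)
    expect_equal(rank_sum_p(log(sc), log(nsc)), p0)
    expect_equal(rank_sum_p(sc^3, nsc^3), p0)
    expect_equal(rank_sum_p(2 * sc + 1, 2 * nsc + 1), p0)
  }
})

test_that("heatmap normalization scales every nonzero row to max 1 and flags zero rows", {
  expect_equal(unname(heatmap_normalize(matrix(c(2, 4, 8), 1))[1, ]),
               c(0.25, 0.5, 1))
  z <- heatmap_normalize(matrix(c(0, 0, 0, 1, 2, 4), 2, byrow = TRUE))
  expect_equal(unname(z[1, ]), c(0, 0, 0))
  expect_equal(attr(z, "zero_rows"), 1L)
  set.seed(51)
  r <- heatmap_normalize(matrix(stats::rlnorm(60), 10))
  expect_equal(unname(apply(r, 1, max)), rep(1, 10))
  expect_true(all(r >= 0 & r <= 1))
})

test_that("specificity analysis ranks planted microglia genes first and validates groups", {
  m <- make_expression_matrix(seed = 61)
  md <- compute_mean_data(m$expr, m$grouping)
  res <- specificity_analysis(md, sc = "microglia")
  expect_equal(nrow(res), nrow(md))
  planted <- res$sr[m$enriched_genes]
  background <- res$sr[-m$enriched_genes]
  expect_gt(min(planted), stats::quantile(background, 0.9))
  expect_true(all(res$p > 0 & res$p <= 1))
  nm <- paste0("norm_", colnames(md))
  expect_true(all(nm %in% names(res)))
  expect_error(specificity_analysis(md, sc = "microglia",
                                    nsc = c("microglia", "cellgroup2")),
               "overlap")
  expect_error(specificity_analysis(md, sc = "nosuch"), "unknown")
})

test_that("expression TSV reader reproduces matrix and grouping", {
  m <- make_expression_matrix(n_genes = 10L, seed = 71)
  ed <- withr::local_tempfile(fileext = ".tsv")
  gd <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(data.frame(gene = rownames(m$expr), m$expr,
                                check.names = FALSE),
                     ed, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = names(m$grouping),
                                group = unname(m$grouping)),
                     gd, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_expression_tsv(ed, gd)
  expect_equal(back$expr, m$expr)
  expect_equal(back$grouping, m$grouping)
})
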