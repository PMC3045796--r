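test_that("redundancy is duplicates relative to unique documents", {
  expect_equal(round(redundancy(13355, 11022)), 21)
  expect_equal(round(redundancy(9005, 7523), 1), 19.7)
  expect_equal(redundancy(500, 500), 0)
  expect_error(redundancy(10, 0), "unique_ids")
  expect_error(redundancy(10, 11), "exceed")
  # strictly increasing in total for fixed unique
  expect_true(all(diff(redundancy(1000:1010, 1000)) > 0))
})

test_that("fold increase is the ratio of unique document counts", {
  expect_equal(round(fold_increase(7523, 2099), 1), 3.6)
  expect_equal(fold_increase(100, 100), 1)
  expect_equal(round(fold_increase(43, 28), 1), 1.5)
  expect_error(fold_increase(10, 0), "official_only")
})

test_that("official symbol occurrence is whole-token, case-insensitive", {
  coll <- make_collection("d5d", c(
    "polymorphisms of the FADS1 FADS2 gene cluster and fatty acids",
    "an unrelated abstract about membranes"))
  expect_true(official_occurrence(coll, "FADS1"))
  expect_true(official_occurrence(coll, "fads1"))
  expect_false(official_occurrence(abstract_collection("x"), "FADS1"))
  # embedded in a longer token: no whole-token match, though a substring
  # scan would hit
  embedded <- make_collection("x", "the FADS12 variant was sequenced")
  expect_true(grepl("FADS1", embedded$text[1], fixed = TRUE))
  expect_false(official_occurrence(embedded, "FADS1"))
  # short symbols are matchable (no 3-character minimum here)
  expect_true(official_occurrence(make_collection("x", "knockout of A2 gene"),
                                  "A2"))
  # multi-word symbols match as consecutive token runs
  multi <- make_collection("x", "encodes fatty acid desaturase 1 enzyme")
  expect_true(official_occurrence(multi, "fatty acid desaturase 1"))
  expect_false(official_occurrence(multi, "fatty acid desaturase 2"))
})

test_that("occurrence is monotone under adding documents", {
  base <- make_collection("x", "mentions GENE1 here")
  expect_true(official_occurrence(base, "GENE1"))
  grown <- make_collection("x", c("mentions GENE1 here", "nothing relevant",
                                  "more padding text"))
  expect_true(official_occurrence(grown, "GENE1"))
})

test_that("occurrence_report aggregates by label", {
  results <- data.frame(
    group_id = c("G1", "G1", "G2"),
    alias = c("a1", "a2", "b1"),
    label = c("synonym", "ambiguous", "synonym"),
    stringsAsFactors = FALSE)
  colls <- list(
    a1 = make_collection("a1", "about G1 biology"),
    a2 = make_collection("a2", "nothing related"),
    b1 = make_collection("b1", "no mention either"))
  rep <- occurrence_report(results, colls, c(G1 = "G1", G2 = "G2"))
  expect_equal(rep$per_alias$mentions_official, c(TRUE, FALSE, FALSE))
  agg <- rep$aggregate
  expect_equal(agg$fraction[agg$label == "synonym"], 0.5)
  expect_equal(agg$fraction[agg$label == "ambiguous"], 0)
})

test_that("pmid set stats compute exact unions and intersections", {
  a <- make_collection("A", rep("t", 3), ids = c("1", "2", "3"))
  b <- make_collection("B", rep("t", 3), ids = c("3", "4", "5"))
  d <- make_collection("D", rep("t", 2), ids = c("8", "9"))
  st <- pmid_set_stats(list(a, b, d))
  expect_equal(st$union_size, 7L)
  expect_equal(unname(st$sizes), c(3L, 3L, 2L))
  pw <- st$pairwise
  expect_equal(pw$intersection_size[pw$name_a == "A" & pw$name_b == "B"], 1L)
  expect_equal(pw$intersection_size[pw$name_a == "A" & pw$name_b == "D"], 0L)
  expect_equal(st$pairwise_ids[["A|B"]], "3")
})

test_that("pmid set stats obey inclusion-exclusion", {
  set.seed(13)
  for (i in 1:20) {
    a <- as.character(sample(100, sample(5:30, 1)))
    b <- as.character(sample(100, sample(5:30, 1)))
    st <- pmid_set_stats(list(A = a, B = b))
    expect_equal(st$union_size,
                 length(unique(a)) + length(unique(b)) -
                   st$pairwise$intersection_size[1])
  }
})

test_that("corpus_summary counts totals, uniques and redundancy", {
  colls <- list(
    G1 = make_collection("G1", rep("t", 3), ids = c("1", "2", "3")),
    a1 = make_collection("a1", rep("t", 2), ids = c("3", "4")),
    a2 = abstract_collection("a2"))
  term <- aliasprofiler:::new_terminology(data.frame(
    group_id = "G1", name = c("G1", "a1", "a2"),
    role = c("official", "alias", "alias"), stringsAsFactors = FALSE))
  cs <- corpus_summary(colls, term)
  expect_equal(cs$total_abstracts, 5L)
  expect_equal(cs$unique_ids, 4L)
  expect_equal(cs$redundancy_pct, 25)
  expect_equal(cs$n_official_symbols, 1L)
  expect_equal(cs$n_aliases, 1L)   # empty a2 not counted
})

# Permutation oracle for the Kruskal-Wallis decision on two samples.
perm_pvalue <- function(x, y, n_perm = 10000) {
  obs <- abs(mean(rank(c(x, y))[seq_along(x)]) -
             mean(rank(c(x, y))[-seq_along(x)]))
  pooled <- c(x, y)
  n <- length(x)
  hits <- 0
  for (i in seq_len(n_perm)) {
    r <- rank(pooled)[sample(length(pooled))]
    stat <- abs(mean(r[seq_len(n)]) - mean(r[-seq_len(n)]))
    if (stat >= obs - 1e-12) hits <- hits + 1
  }
  hits / n_perm
}

test_that("identical vocabulary sizes give a degenerate p = 1", {
  sizes <- list(`0.01` = rep(50, 5), `0.05` = rep(50, 5), `0.25` = rep(50, 5))
  expect_warning(out <- vocab_size_comparison(sizes), "identical")
  expect_equal(out$kw_p_value, 1)
  expect_true(all(out$dunn$p_value == 1))
})

test_that("well-separated vocabulary sizes are declared different", {
  set.seed(17)
  small <- rnorm(30, 50, 10)
  large <- rnorm(30, 500, 10)
  out <- vocab_size_comparison(list(strict = small, lax = large))
  expect_lt(out$kw_p_value, 0.05)
  expect_lt(out$dunn$p_value[1], 0.05)
  # the permutation oracle reaches the same decision at alpha = 0.05
  expect_lt(perm_pvalue(small, large, 2000), 0.05)
  # and on exchangeable samples both stay non-significant
  x <- rnorm(30, 100, 10)
  y <- rnorm(30, 100, 10)
  out2 <- vocab_size_comparison(list(a = x, b = y))
  p_perm <- perm_pvalue(x, y, 2000)
  expect_equal(out2$kw_p_value < 0.05, p_perm < 0.05)
})

test_that("two-level comparison agrees with the rank-sum decision", {
  set.seed(29)
  for (i in 1:10) {
    shift <- sample(c(0, 0, 8, 30), 1)
    x <- rnorm(15, 100, 10)
    y <- rnorm(15, 100 + shift, 10)
    out <- vocab_size_comparison(list(a = x, b = y))
    w <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
    expect_equal(out$kw_p_value < 0.05, w$p.value < 0.05,
                 info = paste("rep", i, "shift", shift))
  }
})

test_that("comparison inputs are validated", {
  expect_error(vocab_size_comparison(list(a = 1:5)), "two stringency")
  expect_error(vocab_size_comparison(list(a = 1:5, b = 2)),
               "two observations")
})
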