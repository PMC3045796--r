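# Brute-force document-frequency oracle: per-document membership scan over
# canonical terms, independent of term_frequencies' tabulation path.
brute_frequencies <- function(collection) {
  docs <- lapply(collection$text,
                 function(t) unique(singularize(tokenize(t))))
  terms <- sort(unique(unlist(docs)))
  freqs <- vapply(terms, function(tm) {
    mean(vapply(docs, function(d) tm %in% d, logical(1)))
  }, numeric(1))
  freqs[freqs > 0]
}

test_that("document frequencies use presence, not token counts", {
  coll <- make_collection("g", c("term term term term term other words",
                                 "unrelated words here"))
  tf <- term_frequencies(coll)
  expect_equal(unname(tf$freqs[["term"]]), 0.5)   # 1 of 2 docs
  expect_equal(tf$n, 2L)
  coll4 <- make_collection("g", c("aaa bbb", "aaa ccc", "aaa ddd", "eee fff"))
  expect_equal(unname(term_frequencies(coll4)$freqs[["aaa"]]), 0.75)
  expect_error(term_frequencies(abstract_collection("empty")), "empty")
})

test_that("frequencies match a brute-force membership scan", {
  set.seed(31)
  vocab <- c("alpha", "beta", "gamma", "delta", "cells", "cell", "genes")
  texts <- replicate(10, paste(sample(vocab, 12, replace = TRUE),
                               collapse = " "))
  coll <- make_collection("g", texts)
  tf <- term_frequencies(coll)
  oracle <- brute_frequencies(coll)
  expect_equal(tf$freqs, oracle[names(tf$freqs)])
  expect_setequal(names(tf$freqs), names(oracle))
  # invariance to document order
  perm <- make_collection("g", texts[sample(10)],
                          ids = as.character(101:110))
  expect_equal(term_frequencies(perm)$freqs, tf$freqs)
})

test_that("the difference cut-off follows t + k / max(n, n_floor)", {
  expect_equal(dynamic_cutoff(5), 0.45)
  expect_equal(dynamic_cutoff(100), 0.165)
  expect_equal(dynamic_cutoff(3), 0.45)    # clamped at n_floor = 5
  expect_equal(dynamic_cutoff(1), 0.45)
  expect_equal(dynamic_cutoff(10, filter_params(t = 0.2, k = 1)), 0.3)
  expect_error(dynamic_cutoff(-1), "n must be")
})

test_that("filter parameters are validated", {
  expect_error(filter_params(c = 0), "c must be")
  expect_error(filter_params(c = 1.5), "c must be")
  expect_error(filter_params(t = -0.1), "t must be")
  expect_error(filter_params(n_floor = 0), "n_floor")
})

test_that("the baseline filter excludes at frequency >= c", {
  baseline <- baseline_from(common = 0.30, borderline = 0.05,
                            rare = 0.001)
  terms <- c("common", "borderline", "rare", "unseen")
  expect_equal(apply_baseline_filter(terms, baseline, c = 0.05),
               c("rare", "unseen"))     # 0.05 >= c: excluded
  expect_equal(apply_baseline_filter(terms, baseline, c = 0.01),
               c("rare", "unseen"))     # 0.001 < c: still specific
  expect_equal(apply_baseline_filter("unseen", baseline, c = 0.001),
               "unseen")                # unseen terms always pass
  expect_equal(apply_baseline_filter(terms, baseline, c = 1.0), terms)
  # configurable strict comparison keeps the borderline term
  expect_equal(apply_baseline_filter(terms, baseline, c = 0.05,
                                     inclusive = FALSE),
               c("borderline", "rare", "unseen"))
})

# Exhaustive (term, name) scan oracle for the vocabulary selection.
brute_vocabulary <- function(group, baseline, params) {
  colls <- Filter(function(x) x$n >= 1,
                  c(list(group$official), group$aliases, group$controls))
  tfs <- lapply(colls, term_frequencies)
  all_terms <- sort(unique(unlist(lapply(tfs, function(x) names(x$freqs)))))
  keep <- character()
  for (tm in all_terms) {
    bf <- if (tm %in% names(baseline$freqs)) baseline$freqs[[tm]] else 0
    if (bf >= params$c) next
    for (tf in tfs) {
      f <- if (tm %in% names(tf$freqs)) tf$freqs[[tm]] else 0
      if (f - bf >= params$t + params$k / max(tf$n, params$n_floor)) {
        keep <- c(keep, tm)
        break
      }
    }
  }
  keep
}

test_that("vocabulary selection matches an exhaustive scan oracle", {
  for (seed in c(2, 9)) {
    p <- small_params(seed = seed)
    sim <- generate_corpus(p)
    baseline <- generate_baseline(p)
    ctrl <- assign_controls(sim$terminology, seed = seed)
    built <- build_name_groups(sim$terminology, sim$collections, ctrl)
    params <- filter_params()
    for (g in names(built$groups)[1:2]) {
      vocab <- select_group_vocabulary(built$groups[[g]], baseline, params)
      oracle <- brute_vocabulary(built$groups[[g]], baseline, params)
      expect_equal(vocab$terms, oracle, info = paste("seed", seed, g))
    }
  }
})

test_that("vocabulary selection applies the worked cut-off arithmetic", {
  # one name with 5 docs: cut-off 0.45, so a frequency-0.4 term is dropped
  # while a frequency-0.6 term is kept
  off <- make_collection("OFF", c("keep keep junk", "keep other junk",
                                  "keep third junk", "other junk drop",
                                  "drop other junk"))
  ali <- make_collection("ALI", "keep words", ids = "50")
  ctl <- make_collection("CTL", "unrelated stuff", ids = "60")
  group <- aliasprofiler:::new_name_group("G", off, list(ali), list(ctl))
  vocab <- select_group_vocabulary(group, empty_baseline(), filter_params())
  expect_true("keep" %in% vocab$terms)       # 0.6 >= 0.45 in OFF
  expect_false("drop" %in% vocab$terms)      # 0.4 < 0.45 everywhere
  # single-doc names have frequency 1 >= 0.45, so their terms enter:
  # the ANY-name quantifier lets controls contribute vocabulary
  expect_true(all(c("unrelated", "stuff") %in% vocab$terms))
  expect_equal(vocab$terms, sort(vocab$terms))
  expect_equal(colnames(vocab$freq), c("OFF", "ALI", "CTL"))
})

test_that("every retained term beats its baseline frequency somewhere", {
  p <- small_params(seed = 4)
  sim <- generate_corpus(p)
  baseline <- generate_baseline(p)
  ctrl <- assign_controls(sim$terminology, seed = 4)
  built <- build_name_groups(sim$terminology, sim$collections, ctrl)
  vocab <- select_group_vocabulary(built$groups[[1]], baseline)
  bf <- sapply(vocab$terms, function(tm) {
    if (tm %in% names(baseline$freqs)) baseline$freqs[[tm]] else 0
  })
  expect_true(all(apply(vocab$freq, 1, max) > bf))
})

test_that("vocabulary grows monotonically with the baseline cut-off", {
  p <- small_params(seed = 6)
  sim <- generate_corpus(p)
  baseline <- generate_baseline(p)
  ctrl <- assign_controls(sim$terminology, seed = 6)
  built <- build_name_groups(sim$terminology, sim$collections, ctrl)
  for (g in names(built$groups)) {
    vocabs <- lapply(c(0.01, 0.05, 0.25), function(cc) {
      v <- select_group_vocabulary(built$groups[[g]], baseline,
                                   filter_params(c = cc))
      if (is.null(v)) character() else v$terms
    })
    expect_true(all(vocabs[[1]] %in% vocabs[[2]]))
    expect_true(all(vocabs[[2]] %in% vocabs[[3]]))
  }
})

test_that("a group whose vocabulary fails every filter returns NULL", {
  # all terms ubiquitous in the baseline -> nothing survives
  baseline <- baseline_from(aaa = 0.9, bbb = 0.8, ccc = 0.7)
  off <- make_collection("O", "aaa bbb")
  ali <- make_collection("A", "bbb ccc", ids = "2")
  ctl <- make_collection("C", "aaa ccc", ids = "3")
  group <- aliasprofiler:::new_name_group("G", off, list(ali), list(ctl))
  expect_null(select_group_vocabulary(group, baseline, filter_params(c = 0.05)))
})

test_that("baseline frequencies cache to TSV and back", {
  p <- small_params(seed = 8)
  baseline <- generate_baseline(p)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_baseline(baseline, tf)
  back <- read_baseline(tf)
  expect_equal(back$n_docs, baseline$n_docs)
  expect_equal(back$freqs, baseline$freqs)
})
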