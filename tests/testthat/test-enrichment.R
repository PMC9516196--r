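test_that("the reported tail matches exhaustive hypergeometric sums", {
  universe <- sprintf("g%03d", 1:100)
  deg <- universe[1:10]
  term_hot <- c(universe[6:10], universe[90:94])   # overlap 5 of 10
  res <- fisher_term_test(deg, term_hot, universe)
  expect_equal(res$fisher_p, oracle_hyper_upper(5, 10, 10, 100))
  expect_equal(res$direction, "enriched")
  expect_equal(res$deg_in_term + res$deg_not_term + res$term_not_deg +
                 res$neither, 100)

  term_cold <- universe[40:69]                     # overlap 0 of 30
  res0 <- fisher_term_test(deg, term_cold, universe)
  expect_equal(res0$fisher_p, oracle_hyper_lower(0, 30, 10, 100))
  expect_equal(res0$direction, "depleted")

  expect_equal(fisher_term_test(deg, universe, universe)$fisher_p, 1)
  empty <- fisher_term_test(deg, character(0), universe)
  expect_true(empty$degenerate)
  expect_equal(empty$fisher_p, 1)
  expect_true(is.na(empty$direction))

  expect_error(fisher_term_test(deg, term_hot, character(0)),
               class = "mutmapr_parameter_error")
  expect_error(fisher_term_test(c(deg, "not_in_bg"), term_hot, universe),
               class = "mutmapr_parameter_error")
})

test_that("enrich_terms agrees with the per-term test across random annotation sets", {
  withr::with_seed(3, {
    universe <- sprintf("g%04d", 1:400)
    deg <- sample(universe, 40)
    ann <- lapply(1:20, function(i) sample(universe, sample(5:80, 1)))
    names(ann) <- sprintf("t%02d", 1:20)
    res <- enrich_terms(deg, ann, universe)
    for (i in seq_along(ann)) {
      single <- fisher_term_test(deg, ann[[i]], universe)
      expect_equal(res$fisher_p[i], single$fisher_p)
      expect_equal(res$direction[i], single$direction)
    }
    expect_true(all(res$deg_in_term + res$deg_not_term + res$term_not_deg +
                      res$neither == 400))
  })
})

test_that("permutation correction is add-one bounded, deterministic and seed-sensitive", {
  withr::with_seed(4, {
    universe <- sprintf("g%04d", 1:600)
    deg <- sample(universe, 60)
    ann <- lapply(1:15, function(i) sample(universe, 40))
    names(ann) <- sprintf("t%02d", 1:15)
    # one overwhelming term: almost all DEGs
    ann$planted <- c(deg[1:35], sample(setdiff(universe, deg), 5))
    obs <- enrich_terms(deg, ann, universe)

    res10 <- permutation_correct(obs, 60, universe, ann, n_perm = 10,
                                 seed = 5)
    expect_identical(res10$corrected_p,
                     permutation_correct(obs, 60, universe, ann,
                                         n_perm = 10, seed = 5)$corrected_p)
    expect_true(all(res10$corrected_p >= 1 / 11 & res10$corrected_p <= 1))

    res1k <- permutation_correct(obs, 60, universe, ann, n_perm = 1000,
                                 seed = 6)
    expect_equal(res1k$corrected_p[res1k$term_id == "planted"], 1 / 1001)
    expect_true(all(res1k$corrected_p >= 1 / 1001 & res1k$corrected_p <= 1))

    expect_error(permutation_correct(obs, 601, universe, ann),
                 class = "mutmapr_parameter_error")

    sig <- significant_terms(res1k)
    expect_true("planted" %in% sig$term_id)
    expect_true(all(diff(sig$corrected_p) >= 0))
    # strict threshold: corrected_p exactly at alpha is excluded
    fake <- data.frame(term_id = c("a", "b"), corrected_p = c(0.05, 0.049))
    expect_equal(significant_terms(fake)$term_id, "b")
    expect_equal(nrow(significant_terms(fake[0, ])), 0)
  })
})

test_that("the expressed-gene background applies the read-count floor", {
  counts <- data.frame(gene_id = c("a", "b", "c", "d"),
                       s1 = c(0, 1, 2, 5), s2 = c(0, 0, 3, 1))
  expect_equal(background_from_counts(counts), c("c", "d"))
  expect_equal(background_from_counts(counts, min_count = 1),
               c("b", "c", "d"))
})
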