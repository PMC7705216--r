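test_that("the initial posterior is uniform with entropy log2 N", {
  for (n in c(2, 7, 50)) {
    cat <- small_catalog(n = n, seed = n)
    st <- init_posterior(cat)
    expect_equal(st$probs, rep(1 / n, n))
    expect_identical(st$n_trials_absorbed, 0L)
    expect_equal(entropy(st), log2(n))
  }
})

test_that("entropy follows the usual definition", {
  expect_equal(entropy(c(0.5, 0.25, 0.25)), 1.5)
  expect_equal(entropy(c(1, 0, 0, 0)), 0)
  expect_equal(entropy(rep(1 / 8, 8)), 3)
  expect_error(entropy(c(0.7, 0.7)), "probability")
})

test_that("posterior updates renormalise likelihoods and leave input unchanged", {
  cat <- small_catalog(n = 4, seed = 1)
  st <- init_posterior(cat)
  # arithmetic normalisation on a hand-made weight vector
  expect_equal(clsmei:::posterior_update_vec(rep(0.25, 4),
                                             c(0.5, 0.25, 0.25, 0)),
               c(0.5, 0.25, 0.25, 0))
  st2 <- update_posterior(st, cat, 60, 25)
  expect_equal(sum(st2$probs), 1, tolerance = 1e-12)
  expect_identical(st2$n_trials_absorbed, 1L)
  # purity: the input state is untouched
  expect_equal(st$probs, rep(0.25, 4))
  expect_error(update_posterior(st, cat, 60, 3), "response_cu")
  expect_error(update_posterior(st, cat, 300, 25), "level")
})

test_that("update order does not matter (joint-likelihood equivalence)", {
  cat <- small_catalog(n = 6, seed = 2)
  trials <- list(c(40, 15), c(70, 35), c(55, 25))
  st_fwd <- init_posterior(cat)
  for (tr in trials) st_fwd <- update_posterior(st_fwd, cat, tr[1], tr[2])
  st_rev <- init_posterior(cat)
  for (tr in rev(trials)) st_rev <- update_posterior(st_rev, cat, tr[1], tr[2])
  expect_equal(st_fwd$probs, st_rev$probs, tolerance = 1e-12)
  # brute-force joint product over the catalog
  joint <- vapply(cat$entries, function(e) {
    prod(vapply(trials, function(tr) {
      max(category_probs(e, tr[1])[[as.character(tr[2])]], 1e-6)
    }, numeric(1)))
  }, numeric(1))
  expect_equal(st_fwd$probs, joint / sum(joint), tolerance = 1e-12)
})

test_that("uninformative trials leave the posterior unchanged", {
  # two copies of the same boundary structure: every level is uninformative
  e1 <- uniform_mcpf(10, 100, 5, id = "a")
  e2 <- uniform_mcpf(10, 100, 5, id = "b")
  cat <- clsmei:::new_catalog(list(e1, e2), 1000)
  st <- update_posterior(init_posterior(cat), cat, 55, 25)
  expect_equal(st$probs, c(0.5, 0.5), tolerance = 1e-12)
})

test_that("predictive response distribution is the posterior mixture", {
  cat <- small_catalog(n = 3, seed = 3)
  st <- init_posterior(cat)
  pr <- predictive_response_dist(st, cat, 60)
  expect_equal(sum(pr), 1, tolerance = 1e-9)
  # hand-computed weighted sum with the likelihood floor
  mix <- Reduce(`+`, lapply(cat$entries, function(e) {
    pmax(category_probs(e, 60), 1e-6)
  })) / 3
  expect_equal(unname(pr), unname(mix / sum(mix)), tolerance = 1e-12)
  # point mass recovers that entry's (floored, renormalised) categories
  pm <- clsmei:::new_posterior(c(1, 0, 0))
  one <- pmax(category_probs(cat$entries[[1]], 60), 1e-6)
  expect_equal(unname(predictive_response_dist(pm, cat, 60)),
               unname(one / sum(one)), tolerance = 1e-12)
})

test_that("probing is never expected to increase entropy", {
  cat <- small_catalog(n = 12, seed = 4)
  set.seed(7)
  for (rep in 1:50) {
    p <- rexp(12)
    st <- clsmei:::new_posterior(p / sum(p))
    lev <- sample(seq(0, 110, 5), 1)
    expect_lte(expected_posterior_entropy(st, cat, lev), entropy(st) + 1e-9)
  }
  # point mass: no uncertainty left to reduce, at any level
  pm <- clsmei:::new_posterior(c(rep(0, 11), 1))
  for (lev in c(0, 40, 80, 110)) {
    expect_equal(expected_posterior_entropy(pm, cat, lev), 0, tolerance = 1e-12)
  }
})

test_that("expected entropy at an uninformative level equals current entropy", {
  e1 <- uniform_mcpf(10, 100, 5, id = "a")
  e2 <- uniform_mcpf(10, 100, 5, id = "b")
  cat <- clsmei:::new_catalog(list(e1, e2), 1000)
  st <- init_posterior(cat)
  expect_equal(expected_posterior_entropy(st, cat, 55), entropy(st),
               tolerance = 1e-9)
})

test_that("MEI selection matches the brute-force oracle", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(2:10, 1)
    cat <- small_catalog(n = n, seed = 100 + rep)
    p <- rexp(n)
    st <- clsmei:::new_posterior(p / sum(p))
    cons <- selection_constraints(
      lower_limit = 10, upper_limit = 100,
      previous_level = if (rep %% 2 == 0) sample(seq(10, 100, 5), 1) else NULL)
    got <- select_mei_level(st, cat, cons)
    oracle <- brute_force_mei(st$probs, cat, cons)
    expect_equal(as.numeric(got), oracle$level)
    expect_equal(unname(attr(got, "expected_entropy")), oracle$epe,
                 tolerance = 1e-9)
  }
})

test_that("selection respects transition, repeat and limit constraints", {
  cat <- small_catalog(n = 5, seed = 6)
  st <- init_posterior(cat)
  cons <- selection_constraints(previous_level = 100)
  cand <- clsmei:::candidate_levels(cons)
  expect_true(all(cand >= 55))          # 45-dB transition cap
  expect_false(100 %in% cand)           # no immediate repeat
  # point-mass posterior: every level ties at 0, lowest candidate wins
  pm <- clsmei:::new_posterior(c(1, 0, 0, 0, 0))
  lev <- select_mei_level(pm, cat, selection_constraints(lower_limit = 20,
                                                         upper_limit = 90))
  expect_equal(as.numeric(lev), 20)
  expect_error(select_mei_level(st, cat,
                                selection_constraints(lower_limit = 110,
                                                      upper_limit = 110,
                                                      previous_level = 0)),
               "no admissible")
})

test_that("a discriminative region attracts the selected level", {
  # entries identical below 60 dB, divergent above
  e1 <- mcpf(c(seq(10, 55, length.out = 6), 70, 80, 90, 100), 5, entry_id = "a")
  e2 <- mcpf(c(seq(10, 55, length.out = 6), 60, 65, 70, 75), 5, entry_id = "b")
  cat <- clsmei:::new_catalog(list(e1, e2), 1000)
  st <- init_posterior(cat)
  lev <- select_mei_level(st, cat, selection_constraints())
  expect_gte(as.numeric(lev), 60)
})

test_that("precomputed likelihood grids give identical selections", {
  cat <- small_catalog(n = 8, seed = 8)
  lik <- catalog_likelihoods(cat, seq(0, 110, 5))
  p <- rexp(8); st <- clsmei:::new_posterior(p / sum(p))
  cons <- selection_constraints(lower_limit = 20, upper_limit = 95,
                                previous_level = 60)
  expect_equal(as.numeric(select_mei_level(st, cat, cons)),
               as.numeric(select_mei_level(st, cat, cons, lik = lik)))
})
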