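# Single finite-context model: alpha-smoothed estimator, counting,
# freezing, sparsity.

make_counts_model <- function(order, alpha, contexts, counts) {
  # arbitrary count state via the serialization container
  dump <- list(list(order = order, alpha = alpha, frozen = FALSE,
                    contexts = as.numeric(contexts),
                    counts = matrix(as.numeric(counts), ncol = 4)))
  obj <- list(ptr = infoprofile:::fcm_set_restore(dump),
              depths = as.integer(order), alphas = alpha)
  class(obj) <- "fcm_set"
  obj
}

test_that("estimator interpolates between counts and the uniform law", {
  m <- fcm(2, alpha = 1)
  expect_equal(unname(fcm_estimate(m, "AC")), rep(0.25, 4))

  # counts (2,0,1,1), alpha = 1 -> (3/8, 1/8, 2/8, 2/8)
  for (s in c("A", "A", "G", "T")) fcm_update(m, "AC", s)
  expect_equal(unname(fcm_estimate(m, "AC")), c(3, 1, 2, 2) / 8)
  expect_equal(sum(fcm_estimate(m, "AC")), 1, tolerance = 1e-12)

  # same counts, huge alpha -> approaches uniform
  big <- make_counts_model(2, 1e9, 1, c(2, 0, 1, 1))
  expect_equal(unname(fcm_estimate(big, "AC")), rep(0.25, 4),
               tolerance = 1e-8)

  # heavily skewed counts with the small-alpha setting used at k >= 14
  sk <- make_counts_model(2, 1 / 16, 1, c(1000, 0, 0, 0))
  expect_equal(unname(fcm_estimate(sk, "AC")),
               c(1000 + 1 / 16, 1 / 16, 1 / 16, 1 / 16) / (1000 + 4 / 16))
})

test_that("update counts one observation and preserves causality ordering", {
  m <- fcm(3)
  fcm_update(m, "ACG", "A")
  expect_equal(unname(fcm_estimate(m, "ACG")), c(2, 1, 1, 1) / 5)
  fcm_update(m, "ACG", "A")
  expect_equal(unname(fcm_counts(m, "ACG")), c(2, 0, 0, 0))
  # other contexts untouched
  expect_equal(unname(fcm_counts(m, "GGG")), rep(0, 4))
})

test_that("estimates always sum to one across random reachable states", {
  set.seed(42)
  m <- fcm(4, alpha = 1 / 16)
  for (i in 1:200) {
    ctx <- sample(c("A", "C", "G", "T"), 4, replace = TRUE)
    fcm_update(m, paste(ctx, collapse = ""),
               sample(c("A", "C", "G", "T"), 1))
  }
  for (i in 1:50) {
    ctx <- paste(sample(c("A", "C", "G", "T"), 4, replace = TRUE),
                 collapse = "")
    expect_equal(sum(fcm_estimate(m, ctx)), 1, tolerance = 1e-12)
  }
})

test_that("alpha = 1 reduces to the Laplace estimator on random counts", {
  set.seed(7)
  n <- 200
  keys <- sample(0:(4^6 - 1), n)
  counts <- matrix(rpois(4 * n, 30), ncol = 4)
  m <- make_counts_model(6, 1, keys, counts)
  idx <- sample(n, 25)
  for (i in idx) {
    ctx <- integer(6)
    v <- keys[i]
    for (j in 6:1) { ctx[j] <- v %% 4; v <- v %/% 4 }
    expect_equal(unname(fcm_estimate(m, ctx)),
                 (counts[i, ] + 1) / (sum(counts[i, ]) + 4))
  }
})

test_that("estimator converges to maximum-likelihood frequencies", {
  freqs <- c(0.5, 0.3, 0.15, 0.05)
  m <- make_counts_model(2, 1, 0, freqs * 1e6)
  expect_equal(unname(fcm_estimate(m, "AA")), freqs, tolerance = 1e-4)
})

test_that("frozen models answer identically but ignore updates", {
  set.seed(99)
  m <- fcm(5)
  for (i in 1:300) {
    ctx <- paste(sample(c("A", "C", "G", "T"), 5, replace = TRUE),
                 collapse = "")
    fcm_update(m, ctx, sample(c("A", "C", "G", "T"), 1))
  }
  frozen <- fcm_freeze(fcm_clone(m))
  ctxs <- replicate(1000, paste(sample(c("A", "C", "G", "T"), 5,
                                       replace = TRUE), collapse = ""))
  before <- t(vapply(ctxs, function(cc) fcm_estimate(frozen, cc),
                     numeric(4)))
  expect_equal(before,
               t(vapply(ctxs, function(cc) fcm_estimate(m, cc),
                        numeric(4))))
  for (i in 1:100) fcm_update(frozen, "ACGTA", "A")
  expect_equal(t(vapply(ctxs, function(cc) fcm_estimate(frozen, cc),
                        numeric(4))), before)
  # frozen empty model stays uniform
  fe <- fcm_freeze(fcm(2))
  fcm_update(fe, "AC", "A")
  expect_equal(unname(fcm_estimate(fe, "AC")), rep(0.25, 4))
})

test_that("stored contexts never exceed symbols processed or 4^k", {
  s <- random_dna(500, 21)
  tm <- train_models(s, profile_config(depths = c(2, 4, 8),
                                       direction = "direct"))
  sizes <- fcm_size(tm$direct)
  expect_true(all(sizes <= pmin(500, 4^c(2, 4, 8))))
  expect_true(all(sizes <= 500))
  # order 2 saturates: far fewer than 500 distinct dinucleotides exist
  expect_lte(sizes[1], 16)
})

test_that("contract violations are rejected", {
  m <- fcm(3)
  expect_error(fcm_estimate(m, "AC"), "order")
  expect_error(fcm_update(m, "ACGT", "A"), "order")
  expect_error(fcm_update(m, "ACG", "N"), "symbol")
  expect_error(fcm_estimate(m, "ANG"), "A, C, G, T")
  expect_error(fcm_set(c(4, 2)), "increasing")
  expect_error(fcm(2, alpha = 0), "alpha")
})
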