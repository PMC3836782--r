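# Profile engine: directional passes, min-combination, masking, Blackman
# smoothing, subsampling, conditional profiles.

raw_config <- function(...) profile_config(window = 1L, sample_step = 1L, ...)

make_profile <- function(values, valid = rep(TRUE, length(values)),
                         id = "s") {
  infoprofile:::new_information_profile(id, values, valid,
                                        profile_config(), "direct")
}

test_that("fresh models on unseen sequence emit the 2-bit baseline", {
  p <- profile_sequence("ACGT", raw_config())
  expect_equal(p$values, rep(2, 4))
})

test_that("homopolymers become near-perfectly predictable", {
  p <- profile_one_direction(strrep("A", 10000), raw_config())
  expect_lt(mean(p$values[9001:10000]), 0.1)
})

test_that("per-base information matches the naive oracle on full defaults", {
  s <- random_dna(1000, 17)
  substr(s, 400, 430) <- strrep("N", 31)  # masked run mid-sequence
  cfg <- raw_config()
  ref <- naive_profile(s, cfg$depths, cfg$alphas, cfg$gamma)
  eng <- profile_one_direction(s, cfg)
  expect_equal(is.na(eng$values), is.na(ref$info))
  expect_lt(max(abs(eng$values - ref$info), na.rm = TRUE), 1e-9)
})

test_that("reversed processing equals the direct profile of the reversed sequence", {
  s <- random_dna(700, 23)
  cfg <- raw_config(depths = c(2L, 4L, 8L))
  pr <- profile_one_direction(s, cfg, reversed = TRUE)
  flipped <- profile_one_direction(
    paste(rev(strsplit(s, "")[[1]]), collapse = ""), cfg)
  expect_equal(pr$values, rev(flipped$values), tolerance = 1e-12)
})

test_that("self-trained frozen statistics never hurt on the same sequence", {
  s <- random_dna(50000, 41)
  cfg <- raw_config(direction = "direct")
  trained <- train_models(s, cfg)
  fresh <- profile_one_direction(s, cfg)
  pre <- profile_one_direction(s, cfg, models = trained$direct)
  expect_lte(mean(pre$values), mean(fresh$values))
})

test_that("min-combination takes the element-wise minimum and ANDs masks", {
  a <- make_profile(c(1.0, 2.0, 3.0), c(TRUE, TRUE, FALSE))
  b <- make_profile(c(1.5, 0.5, 1.0), c(TRUE, TRUE, TRUE))
  cm <- combine_min(a, b)
  expect_equal(cm$values[1:2], c(1.0, 0.5))
  expect_true(is.na(cm$values[3]))
  expect_equal(cm$valid, c(TRUE, TRUE, FALSE))
  expect_equal(combine_min(b, b)$values, b$values)  # idempotent
  expect_error(combine_min(a, make_profile(1)), "length")
  set.seed(2)
  x <- make_profile(stats::runif(1000)); y <- make_profile(stats::runif(1000))
  cm <- combine_min(x, y)
  expect_true(all(cm$values <= x$values & cm$values <= y$values))
})

test_that("the full pipeline's combined profile never exceeds either pass", {
  s <- random_dna(5000, 57)
  cfg <- raw_config()
  pd <- profile_one_direction(s, cfg)
  pr <- profile_one_direction(s, cfg, reversed = TRUE)
  both <- profile_sequence(s, cfg)$unsmoothed
  expect_true(all(both$values <= pd$values + 1e-15))
  expect_true(all(both$values <= pr$values + 1e-15))
})

test_that("Blackman window has zero endpoints and the stated shape", {
  w <- blackman_window(5)
  expect_lt(abs(w[1]), 1e-12)   # 0.42 - 0.5 + 0.08
  expect_lt(abs(w[5]), 1e-12)
  expect_equal(w[3], 1)         # 0.42 + 0.5 + 0.08
  m <- 0:100
  expect_equal(blackman_window(101),
               0.42 - 0.5 * cos(2 * pi * m / 100) +
                 0.08 * cos(4 * pi * m / 100))
})

test_that("smoothing preserves constants, the identity window, and range", {
  const <- make_profile(rep(3.7, 500))
  expect_equal(smooth_profile(const, 101L)$values, rep(3.7, 500),
               tolerance = 1e-9)
  sig <- make_profile(stats::runif(500, 1, 3))
  expect_equal(smooth_profile(sig, 1L)$values, sig$values)
  sm <- smooth_profile(sig, 51L)$values
  expect_true(all(sm >= min(sig$values) - 1e-9 &
                    sm <= max(sig$values) + 1e-9))
  expect_error(smooth_profile(sig, 100L), "odd")
})

test_that("a unit impulse is smeared into the normalized Blackman taps", {
  x <- rep(0, 41); x[21] <- 1
  sm <- smooth_profile(make_profile(x), 5L)$values
  w <- blackman_window(5)
  expect_equal(sm[19:23], rev(w) / sum(w), tolerance = 1e-9)
  expect_lt(max(abs(sm[c(1:18, 24:41)])), 1e-9)
})

test_that("masked positions are excluded from smoothing and stay masked", {
  valid <- rep(TRUE, 200); valid[90:110] <- FALSE
  vals <- rep(1.5, 200); vals[90:110] <- NA
  sm <- smooth_profile(make_profile(vals, valid), 21L)
  expect_true(all(is.na(sm$values[90:110])))
  expect_equal(sm$values[valid], rep(1.5, sum(valid)), tolerance = 1e-9)
})

test_that("subsampling emits the fixed 1-based grid", {
  p <- make_profile(stats::runif(100))
  s20 <- subsample_profile(p, 20L)
  expect_equal(s20$pos, c(1L, 21L, 41L, 61L, 81L))
  expect_equal(s20$value, p$values[s20$pos])
  s1 <- subsample_profile(p, 1L)
  expect_equal(s1$value, p$values)
  expect_error(subsample_profile(p, 0L), "step")
})

test_that("non-ACGT positions are masked through the whole pipeline", {
  s <- paste0(random_dna(300, 3), strrep("N", 50), random_dna(300, 4))
  p <- profile_sequence(s, profile_config(window = 51L, sample_step = 10L))
  expect_true(all(is.na(p$values[301:350])))
  expect_true(all(!p$valid[301:350]))
  expect_true(all(!is.na(p$values[p$valid])))
  masked_samples <- p$samples$masked[p$samples$pos %in% 301:350]
  expect_true(all(masked_samples))
})

test_that("conditional profiles: perfect training beats fresh statistics", {
  s <- random_dna(30000, 13)
  cfg <- profile_config(window = 101L)
  cond <- conditional_profile(s, s, cfg)
  fresh <- profile_sequence(s, cfg)
  expect_lt(mean(cond$values), mean(fresh$values))
})

test_that("conditional profile of fully divergent target sits at the 2-bit ceiling", {
  # reference statistics contain no context of the target, so every model
  # answers uniformly: exactly 2 bits per base after warm-up
  cond <- conditional_profile(strrep("A", 3000), strrep("C", 3000),
                              raw_config(depths = c(2L, 4L)))
  expect_equal(cond$unsmoothed$values[5:3000], rep(2, 2996),
               tolerance = 1e-12)
})

test_that("conditional profiling localizes a planted divergent segment", {
  set.seed(19)
  ref <- random_dna(60000, 19)
  tgt <- ref
  substr(tgt, 30001, 33000) <- random_dna(3000, 77)
  cond <- conditional_profile(ref, tgt, profile_config(window = 1001L))
  expect_true(which.max(cond$values) %in% 30001:33000)
})

test_that("empty and invalid inputs are rejected", {
  expect_error(profile_sequence("", raw_config()), "empty")
  expect_error(conditional_profile(NULL, "ACGT", raw_config()), "reference")
  expect_error(profile_config(window = 1000L), "odd")
  expect_error(profile_config(gamma = 0), "gamma")
  expect_error(profile_config(sample_step = 0), "sample_step")
})

test_that("stored contexts are bounded by the depth-wise minimum", {
  s <- random_dna(2000, 67)
  cfg <- raw_config()
  tm <- train_models(s, cfg)
  for (set in list(tm$direct, tm$reversed)) {
    sizes <- fcm_size(set)
    expect_true(all(sizes <= pmin(2000, 4^cfg$depths)))
  }
})
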