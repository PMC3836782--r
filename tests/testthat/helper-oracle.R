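# Independent reference implementations used as oracles. Deliberately
# naive: explicit per-position loops, count tables in hash environments
# keyed by context strings, formulas written out verbatim. Nothing here
# touches the package's streaming C++ path.

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Per-position mixture information by brute force. Returns per-position
# info (NA at masked positions), the weight trajectory, and each model's
# plain running average information.
naive_profile <- function(sequence, depths, alphas, gamma) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  codes <- match(chars, c("A", "C", "G", "T")) - 1L
  K <- length(depths)
  tabs <- lapply(seq_len(K), function(i)
    new.env(hash = TRUE, parent = emptyenv()))
  w <- rep(1 / K, K)
  L <- length(codes)
  info <- rep(NA_real_, L)
  weights <- matrix(NA_real_, L, K)
  avg <- matrix(NA_real_, L, K)
  hsum <- rep(0, K)
  hist <- integer(0)
  nvalid <- 0L
  for (i in seq_len(L)) {
    s <- codes[i]
    if (is.na(s)) { hist <- integer(0); next }
    p <- numeric(K)
    for (m in seq_len(K)) {
      k <- depths[m]
      if (length(hist) >= k) {
        key <- paste(utils::tail(hist, k), collapse = "")
        cnt <- get0(key, envir = tabs[[m]], ifnotfound = rep(0, 4))
        p[m] <- (cnt[s + 1] + alphas[m]) / (sum(cnt) + 4 * alphas[m])
      } else p[m] <- 0.25
    }
    info[i] <- -log2(sum(w * p))
    nvalid <- nvalid + 1L
    hsum <- hsum - log2(p)
    avg[i, ] <- hsum / nvalid
    w <- w^gamma * p
    w <- w / sum(w)
    weights[i, ] <- w
    for (m in seq_len(K)) {
      k <- depths[m]
      if (length(hist) >= k) {
        key <- paste(utils::tail(hist, k), collapse = "")
        cnt <- get0(key, envir = tabs[[m]], ifnotfound = rep(0, 4))
        cnt[s + 1] <- cnt[s + 1] + 1
        assign(key, cnt, envir = tabs[[m]])
      }
    }
    hist <- c(hist, s)
  }
  list(info = info, weights = weights, avg_info = avg)
}

# Batch Bayesian posterior over models (no forgetting): for each model k,
# the log-likelihood of the sequence is accumulated with that model's own
# evolving counts; posterior = softmax(loglik) under a uniform prior,
# computed in log space.
naive_bayes_posterior <- function(sequence, depths, alphas) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  codes <- match(chars, c("A", "C", "G", "T")) - 1L
  K <- length(depths)
  loglik <- rep(0, K)
  for (m in seq_len(K)) {
    k <- depths[m]
    tab <- new.env(hash = TRUE, parent = emptyenv())
    hist <- integer(0)
    for (i in seq_along(codes)) {
      s <- codes[i]
      if (is.na(s)) { hist <- integer(0); next }
      if (length(hist) >= k) {
        key <- paste(utils::tail(hist, k), collapse = "")
        cnt <- get0(key, envir = tab, ifnotfound = rep(0, 4))
        loglik[m] <- loglik[m] +
          log((cnt[s + 1] + alphas[m]) / (sum(cnt) + 4 * alphas[m]))
        cnt[s + 1] <- cnt[s + 1] + 1
        assign(key, cnt, envir = tab)
      } else {
        loglik[m] <- loglik[m] + log(0.25)
      }
      hist <- c(hist, s)
    }
  }
  z <- loglik - max(loglik)
  exp(z) / sum(exp(z))
}
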