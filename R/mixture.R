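#' Mix per-model probability estimates
#'
#' The mixture's next-symbol distribution is the convex combination
#' \deqn{P(s) = \sum_k w_k P_k(s)}
#' of the `K` per-model estimates under the current weights.
#'
#' @param weights numeric vector of `K` non-negative weights summing to 1.
#' @param probs `K x 4` matrix; row `k` is model `k`'s probability vector.
#' @return numeric vector of 4 mixed probabilities (sums to 1).
#' @export
mix_probabilities <- function(weights, probs) {
  probs <- rbind(probs)
  if (length(weights) != nrow(probs))
    stop("number of weights does not match number of models")
  if (abs(sum(weights) - 1) > 1e-8)
    stop("weights must sum to 1")
  as.numeric(weights %*% probs)
}

#' Update mixture weights from an observed symbol
#'
#' Performance-weighted re-estimation with progressive forgetting: each
#' weight is raised to the power `gamma` (down-weighting accumulated past
#' evidence) and multiplied by the probability that model assigned to the
#' symbol actually observed, then the weights are renormalized:
#' \deqn{w_k \leftarrow \frac{w_k^\gamma \, P_k(x_n)}{\sum_j w_j^\gamma \, P_j(x_n)}}
#' With `gamma = 1` this recursion is exact Bayesian model averaging: after
#' `n` symbols the weights equal the posterior probability of each model
#' given the sequence (uniform prior over the `K` models). With
#' `gamma < 1` the distant past decays geometrically, letting the mixture
#' re-adapt inside non-stationary sequences — DNA alternates high-entropy
#' stretches with repeat-rich regions, and no single model order wins
#' everywhere.
#'
#' The per-model probabilities must be those computed *before* the observed
#' symbol was counted.
#'
#' @param weights current weights (sum to 1).
#' @param p_observed numeric vector of `K` probabilities each model
#'   assigned to the observed symbol.
#' @param gamma forgetting factor in (0, 1].
#' @return updated, renormalized weight vector.
#' @export
update_mixture_weights <- function(weights, p_observed, gamma = 0.99) {
  if (!(gamma > 0 && gamma <= 1)) stop("gamma must be in (0, 1]")
  if (length(weights) != length(p_observed))
    stop("number of weights does not match number of models")
  w <- weights^gamma * p_observed
  w / sum(w)
}

#' Information content of an observed probability
#'
#' The number of bits an ideal arithmetic coder would spend on a symbol
#' that was predicted with probability `p`: `-log2(p)`. A perfectly
#' predicted base costs 0 bits; a uniformly random DNA base costs 2 bits.
#'
#' @param p probability in (0, 1]; vectorized.
#' @return information in bits.
#' @export
information_content <- function(p) {
  if (any(p <= 0 | p > 1, na.rm = TRUE))
    stop("probabilities must lie in (0, 1]")
  -log2(p)
}

#' Update per-model running information averages
#'
#' Maintains, for each model, the average number of bits per symbol it
#' would have needed for the sequence so far:
#' \deqn{H_{k,n} = -\frac{1}{n}\sum_{i \le n} \log_2 P_k(x_i)}
#' computed incrementally. These averages measure each model's accumulated
#' performance and are exposed for diagnostics (the weight recursion itself
#' uses the forgetting form, not this plain average).
#'
#' @param avg_info numeric vector of `K` running averages after `n - 1`
#'   symbols (all zero for `n = 1`).
#' @param p_observed numeric vector of `K` probabilities assigned to the
#'   `n`-th observed symbol.
#' @param n number of symbols processed including the current one
#'   (`n >= 1`).
#' @return updated vector of `K` averages, bits/symbol.
#' @export
update_model_performance <- function(avg_info, p_observed, n) {
  if (n < 1) stop("n must be >= 1")
  if (length(avg_info) != length(p_observed))
    stop("number of averages does not match number of models")
  ((n - 1) * avg_info + information_content(p_observed)) / n
}
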