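#' Create a set of finite-context models
#'
#' A finite-context model (FCM) of order `k` estimates the probability of
#' the next base from counts `N(s|c)` accumulated for each length-`k`
#' context `c`:
#' \deqn{P(s|c) = \frac{N(s|c) + \alpha}{N(c) + 4\alpha}}
#' where `N(c)` is the total count for the context and the estimator
#' parameter `alpha` interpolates between the maximum-likelihood
#' frequencies (`alpha -> 0`, or `N(c)` large) and the uniform distribution
#' (`alpha -> Inf`). `alpha = 1` is the Laplace estimator. Counts are held
#' in a sparse hash table keyed by the 2-bit-packed context, so memory
#' grows with the number of distinct contexts seen, never with `4^k`
#' (`k = 16` alone would need ~4.3e9 dense states).
#'
#' Model sets have reference semantics (they wrap an external pointer):
#' [fcm_update()] and [fcm_freeze()] modify the set in place. Use
#' [fcm_clone()] for an independent copy.
#'
#' @param depths integer vector of context orders, strictly increasing,
#'   each in 1..31.
#' @param alphas numeric vector of per-model estimator parameters, recycled
#'   defaults from [default_alphas()].
#' @return an object of class `fcm_set`.
#' @examples
#' m <- fcm_set(c(2, 4))
#' fcm_estimate(m, "AC")
#' @export
fcm_set <- function(depths, alphas = default_alphas(depths)) {
  depths <- as.integer(depths)
  if (length(depths) == 0L) stop("at least one context depth is required")
  if (any(diff(depths) <= 0L) && length(depths) > 1L)
    stop("depths must be strictly increasing")
  alphas <- rep_len(as.numeric(alphas), length(depths))
  obj <- list(ptr = fcm_set_new(depths, alphas),
              depths = depths, alphas = alphas)
  class(obj) <- "fcm_set"
  obj
}

#' Default estimator parameters per context depth
#'
#' `alpha = 1` (Laplace) for shallow models; `alpha = 1/16` for the deep
#' models (`k >= 14`), whose count tables are sparse enough that heavy
#' smoothing toward uniform would drown the signal of previously seen
#' contexts.
#'
#' @param depths integer vector of context orders.
#' @return numeric vector of alphas, one per depth.
#' @export
default_alphas <- function(depths) {
  ifelse(depths >= 14, 1 / 16, 1)
}

#' Create a single finite-context model
#'
#' Convenience wrapper around [fcm_set()] for one order-`k` model.
#'
#' @param order context depth `k`.
#' @param alpha estimator parameter, default from [default_alphas()].
#' @return an `fcm_set` containing one model.
#' @export
fcm <- function(order, alpha = default_alphas(order)) {
  fcm_set(order, alpha)
}

parse_context <- function(model, context, which) {
  if (is.character(context)) context <- seq_encode(context)
  context <- as.integer(context)
  if (anyNA(context)) stop("context must contain only A, C, G, T")
  if (length(context) != model$depths[which])
    stop(sprintf("context length (%d) does not match model order (%d)",
                 length(context), model$depths[which]))
  context
}

parse_symbol <- function(symbol) {
  if (is.character(symbol)) symbol <- seq_encode(symbol)
  symbol <- as.integer(symbol)
  if (length(symbol) != 1L || is.na(symbol) || symbol < 0L || symbol > 3L)
    stop("symbol must be a single A, C, G or T (or code 0..3)")
  symbol
}

#' Next-symbol probability estimate for one context
#'
#' Returns the alpha-smoothed probability vector `P(A|c), P(C|c), P(G|c),
#' P(T|c)`. A context never seen yields the uniform vector; the components
#' always sum to 1.
#'
#' @param model an `fcm_set`.
#' @param context the conditioning context, as a DNA string (e.g. `"AC"`)
#'   or integer codes 0..3, oldest symbol first; its length must equal the
#'   model order.
#' @param which index of the model within the set (default 1).
#' @return named numeric vector of 4 probabilities.
#' @export
fcm_estimate <- function(model, context, which = 1L) {
  stopifnot(inherits(model, "fcm_set"))
  ctx <- parse_context(model, context, which)
  p <- fcm_estimate_ctx(model$ptr, which - 1L, ctx)
  names(p) <- c("A", "C", "G", "T")
  p
}

#' Observed counts for one context
#'
#' @inheritParams fcm_estimate
#' @return named numeric vector of 4 counts `N(s|c)`.
#' @export
fcm_counts <- function(model, context, which = 1L) {
  stopifnot(inherits(model, "fcm_set"))
  ctx <- parse_context(model, context, which)
  n <- fcm_counts_ctx(model$ptr, which - 1L, ctx)
  names(n) <- c("A", "C", "G", "T")
  n
}

#' Record one observation
#'
#' Increments `N(symbol|context)` by one. The caller is responsible for the
#' estimate-then-update ordering: the probability of a symbol must be taken
#' *before* that symbol is counted, or the model is no longer causal.
#' Frozen models silently ignore updates. The set is modified in place.
#'
#' @inheritParams fcm_estimate
#' @param symbol the observed base (`"A"`..`"T"` or code 0..3).
#' @return the model set, invisibly.
#' @export
fcm_update <- function(model, context, symbol, which = 1L) {
  stopifnot(inherits(model, "fcm_set"))
  ctx <- parse_context(model, context, which)
  fcm_update_ctx(model$ptr, which - 1L, ctx, parse_symbol(symbol))
  invisible(model)
}

#' Freeze a model set
#'
#' A frozen set answers [fcm_estimate()] exactly as before but ignores all
#' subsequent updates — this is how statistics trained on a reference
#' sequence are carried, unchanged, over a target sequence in conditional
#' profiling. Freezing is in place (reference semantics).
#'
#' @param model an `fcm_set`.
#' @return the model set, invisibly.
#' @export
fcm_freeze <- function(model) {
  stopifnot(inherits(model, "fcm_set"))
  fcm_set_freeze(model$ptr)
  invisible(model)
}

#' Deep-copy a model set
#'
#' @param model an `fcm_set`.
#' @return an independent `fcm_set` with identical counts, orders, alphas
#'   and frozen flags.
#' @export
fcm_clone <- function(model) {
  stopifnot(inherits(model, "fcm_set"))
  obj <- list(ptr = fcm_set_restore(fcm_set_dump(model$ptr)),
              depths = model$depths, alphas = model$alphas)
  class(obj) <- "fcm_set"
  obj
}

#' Number of stored contexts per model
#'
#' After processing `L` symbols the count for an order-`k` model is at most
#' `min(L, 4^k)` — the memory footprint depends on the sequence content and
#' the model depths, not on the sequence length kept around.
#'
#' @param model an `fcm_set`.
#' @return numeric vector, one entry per model.
#' @export
fcm_size <- function(model) {
  stopifnot(inherits(model, "fcm_set"))
  fcm_set_sizes(model$ptr)
}

#' @export
print.fcm_set <- function(x, ...) {
  fr <- fcm_set_frozen(x$ptr)
  cat(sprintf("<fcm_set: %d model(s)%s>\n", length(x$depths),
              if (all(fr)) ", frozen" else ""))
  cat(sprintf("  k = %s\n", paste(x$depths, collapse = ", ")))
  cat(sprintf("  alpha = %s\n", paste(format(x$alphas), collapse = ", ")))
  cat(sprintf("  stored contexts = %s\n",
              paste(format(fcm_size(x), big.mark = ","), collapse = ", ")))
  invisible(x)
}
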