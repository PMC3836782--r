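#' Profile engine configuration
#'
#' Bundles every tunable of the profiling pipeline. The defaults are the
#' parameterization used throughout the package: eight competitive
#' finite-context models of depths 2, 4, 6, 8, 10, 12, 14, 16 (`alpha = 1`
#' up to depth 12, `alpha = 1/16` for depths 14 and 16), forgetting factor
#' `gamma = 0.99`, minimum of the direct and reversed passes, Blackman
#' smoothing window of 1,001 bp and sampling every 20 bp.
#'
#' @param depths integer vector of context orders, strictly increasing.
#' @param alphas per-depth estimator parameters.
#' @param gamma forgetting factor in (0, 1]; 1 disables forgetting (pure
#'   Bayesian model averaging).
#' @param window odd positive integer, Blackman smoothing length in bp.
#'   Use 1 to disable smoothing. Larger windows (10,001 or 100,001 bp)
#'   suit chromosome-scale overviews.
#' @param sample_step positive integer, emit one value every this many bp.
#' @param direction `"both"` (min of direct and reversed passes, the
#'   default), `"direct"` or `"reversed"`.
#' @param revcomp if `TRUE` the reversed pass runs over the
#'   reverse-complement instead of the plain reversed character sequence.
#' @return an object of class `profile_config`.
#' @export
profile_config <- function(depths = c(2L, 4L, 6L, 8L, 10L, 12L, 14L, 16L),
                           alphas = default_alphas(depths),
                           gamma = 0.99,
                           window = 1001L,
                           sample_step = 20L,
                           direction = c("both", "direct", "reversed"),
                           revcomp = FALSE) {
  depths <- as.integer(depths)
  if (length(depths) == 0L || any(depths < 1L))
    stop("depths must be positive integers")
  if (length(depths) > 1L && any(diff(depths) <= 0L))
    stop("depths must be strictly increasing")
  alphas <- rep_len(as.numeric(alphas), length(depths))
  if (any(alphas <= 0)) stop("alphas must be > 0")
  if (!(gamma > 0 && gamma <= 1)) stop("gamma must be in (0, 1]")
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be an odd positive integer")
  sample_step <- as.integer(sample_step)
  if (sample_step < 1L) stop("sample_step must be >= 1")
  structure(list(depths = depths, alphas = alphas, gamma = gamma,
                 window = window, sample_step = sample_step,
                 direction = match.arg(direction),
                 revcomp = isTRUE(revcomp)),
            class = "profile_config")
}

#' @export
print.profile_config <- function(x, ...) {
  cat("<profile_config>\n")
  cat(sprintf("  depths: %s\n", paste(x$depths, collapse = ", ")))
  cat(sprintf("  alphas: %s\n", paste(format(x$alphas), collapse = ", ")))
  cat(sprintf("  gamma: %g | window: %d bp | step: %d bp | direction: %s%s\n",
              x$gamma, x$window, x$sample_step, x$direction,
              if (x$revcomp) " (revcomp)" else ""))
  invisible(x)
}

new_information_profile <- function(seq_id, values, valid, config,
                                    direction, window = NULL) {
  structure(list(seq_id = seq_id, values = values, valid = valid,
                 config = config, direction = direction, window = window),
            class = "information_profile")
}

#' @export
print.information_profile <- function(x, ...) {
  cat(sprintf("<information_profile '%s': %d bp, %s%s>\n", x$seq_id,
              length(x$values), x$direction,
              if (is.null(x$window)) ", unsmoothed"
              else sprintf(", smoothed (window %d bp)", x$window)))
  v <- x$values[x$valid]
  if (length(v))
    cat(sprintf("  valid: %d bp | mean %.4f bits | range [%.4f, %.4f]\n",
                length(v), mean(v), min(v), max(v)))
  invisible(x)
}

encode_input <- function(sequence) {
  if (is.integer(sequence)) sequence else seq_encode(sequence)
}

reverse_codes <- function(codes, revcomp = FALSE) {
  codes <- rev(codes)
  if (revcomp) 3L - codes else codes
}

#' Single-direction information profile
#'
#' Runs the mixture once, left to right, over the sequence (reversed first
#' if `reversed = TRUE`) and returns the per-base information content in
#' genomic coordinates (the reversed pass is flipped back). Model
#' statistics start empty unless a pretrained (typically frozen) set is
#' supplied. One pass is O(L) time; memory is bounded by the number of
#' distinct contexts.
#'
#' Non-ACGT positions are masked: they receive `NA`, contribute no counts,
#' and reset the context register so no context spans a masked run. Each
#' order-k model answers uniformly until k valid symbols have accumulated
#' since the start (or the last mask).
#'
#' @param sequence character string, `DNAString`, or an integer code
#'   vector from [seq_encode()].
#' @param config a [profile_config()].
#' @param models optional pretrained `fcm_set` (frozen for conditional
#'   profiling); depths/alphas must match `config`.
#' @param reversed process the sequence 3'->5' (plain reversal, or
#'   reverse-complement when `config$revcomp`).
#' @return an unsmoothed `information_profile`.
#' @export
profile_one_direction <- function(sequence, config = profile_config(),
                                  models = NULL, reversed = FALSE) {
  codes <- encode_input(sequence)
  if (length(codes) == 0L) stop("sequence is empty")
  id <- attr(sequence, "seq_id") %||% "seq"
  run_codes <- if (reversed) reverse_codes(codes, config$revcomp) else codes
  if (is.null(models)) {
    models <- fcm_set(config$depths, config$alphas)
  } else {
    stopifnot(inherits(models, "fcm_set"))
    if (!identical(models$depths, config$depths))
      stop("pretrained model depths do not match the configuration")
  }
  codes_int <- run_codes
  codes_int[is.na(codes_int)] <- -1L
  res <- ip_pass(models$ptr, codes_int, config$gamma, TRUE)
  info <- res$info
  if (reversed) info <- rev(info)
  prof <- new_information_profile(id, info, !is.na(codes), config,
                                  if (reversed) "reversed" else "direct")
  attr(prof, "model_avg_info") <- stats::setNames(res$model_avg_info,
                                                  paste0("k", config$depths))
  attr(prof, "final_weights") <- stats::setNames(res$final_weights,
                                                 paste0("k", config$depths))
  prof
}

#' Combine directional profiles by per-position minimum
#'
#' Eliminates the directionality bias of a single scan: the information
#' content of each base is the smaller of the values obtained in the
#' direct and reversed passes (a repeat copy is cheap to predict only
#' after its first occurrence has been seen, and which copy comes "first"
#' depends on the direction). The mask of the result is the AND of both
#' masks.
#'
#' @param direct,reversed_flipped two `information_profile`s of equal
#'   length, both in genomic coordinates.
#' @return an `information_profile` with `direction = "min_of_both"`.
#' @export
combine_min <- function(direct, reversed_flipped) {
  stopifnot(inherits(direct, "information_profile"),
            inherits(reversed_flipped, "information_profile"))
  if (length(direct$values) != length(reversed_flipped$values))
    stop("profiles have different lengths")
  valid <- direct$valid & reversed_flipped$valid
  vals <- pmin(direct$values, reversed_flipped$values)
  vals[!valid] <- NA_real_
  new_information_profile(direct$seq_id, vals, valid, direct$config,
                          "min_of_both")
}

#' Blackman window taps
#'
#' `w(m) = 0.42 - 0.5 cos(2 pi m / (M-1)) + 0.08 cos(4 pi m / (M-1))`,
#' `m = 0..M-1`. The endpoints are zero (0.42 - 0.5 + 0.08 = 0), so the
#' kernel tapers smoothly — much weaker spectral leakage than a boxcar.
#'
#' @param m window length (positive integer).
#' @return numeric vector of `m` taps (not normalized).
#' @export
blackman_window <- function(m) {
  m <- as.integer(m)
  if (m < 1L) stop("window length must be >= 1")
  if (m == 1L) return(1)
  i <- seq_len(m) - 1
  0.42 - 0.5 * cos(2 * pi * i / (m - 1)) + 0.08 * cos(4 * pi * i / (m - 1))
}

# centered linear convolution via zero-padded FFT (padded to a 2-3-5-smooth
# length so the transform stays O(n log n) for any input size)
conv_same <- function(x, w) {
  l <- length(x)
  m <- length(w)
  n <- stats::nextn(l + m - 1L, c(2L, 3L, 5L))
  fx <- stats::fft(c(x, rep(0, n - l)))
  fw <- stats::fft(c(w, rep(0, n - m)))
  r <- Re(stats::fft(fx * fw, inverse = TRUE)) / n
  half <- (m - 1L) %/% 2L
  r[(half + 1L):(half + l)]
}

#' Low-pass filter a profile with a Blackman window
#'
#' Each output value is the Blackman-weighted average of the input over a
#' centered window, with the taps renormalized to unit sum over the
#' positions actually available: masked positions are excluded from every
#' average (and stay masked in the output), and near the sequence edges
#' the truncated window is renormalized, so constants are preserved
#' everywhere and the output never leaves the input's range.
#'
#' @param profile an `information_profile`.
#' @param window odd positive integer; 1 returns the profile unchanged.
#' @return the smoothed `information_profile`.
#' @export
smooth_profile <- function(profile, window = profile$config$window) {
  stopifnot(inherits(profile, "information_profile"))
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be an odd positive integer")
  if (window == 1L) {
    out <- profile
    out$window <- 1L
    return(out)
  }
  w <- blackman_window(window)
  v <- profile$values
  v[!profile$valid] <- 0
  num <- conv_same(v, w)
  den <- conv_same(as.numeric(profile$valid), w)
  sm <- ifelse(profile$valid & den > 0, num / den, NA_real_)
  out <- new_information_profile(profile$seq_id, sm, profile$valid,
                                 profile$config, profile$direction,
                                 window = window)
  out
}

#' Subsample a profile on a fixed grid
#'
#' Emits 1-based positions `1, 1 + step, 1 + 2 step, ...` with their
#' (smoothed) values. Masked positions appear with `NA` value and
#' `masked = TRUE`.
#'
#' @param profile an `information_profile`.
#' @param step positive integer sampling step in bp.
#' @return a `data.frame` with columns `seq_id`, `pos`, `value`, `masked`.
#' @export
subsample_profile <- function(profile, step = profile$config$sample_step) {
  stopifnot(inherits(profile, "information_profile"))
  step <- as.integer(step)
  if (step < 1L) stop("step must be >= 1")
  pos <- seq.int(1L, length(profile$values), by = step)
  data.frame(seq_id = profile$seq_id, pos = pos,
             value = profile$values[pos],
             masked = !profile$valid[pos],
             stringsAsFactors = FALSE)
}

run_directions <- function(codes, config, models_direct = NULL,
                           models_reversed = NULL) {
  want_direct <- config$direction %in% c("both", "direct")
  want_reversed <- config$direction %in% c("both", "reversed")
  pd <- if (want_direct)
    profile_one_direction(codes, config, models = models_direct)
  pr <- if (want_reversed)
    profile_one_direction(codes, config, models = models_reversed,
                          reversed = TRUE)
  if (want_direct && want_reversed) combine_min(pd, pr)
  else if (want_direct) pd else pr
}

#' Full information profile of one sequence
#'
#' The complete pipeline: one mixture pass per configured direction with
#' fresh statistics each, flip of the reversed pass into genomic
#' coordinates, per-position minimum, Blackman smoothing, and subsampling.
#' Runtime is linear in the sequence length.
#'
#' @param sequence character string, `DNAString`, or integer codes.
#' @param config a [profile_config()].
#' @param id sequence identifier carried into outputs.
#' @return a smoothed `information_profile` with components `$samples`
#'   (the subsampled `data.frame`, see [subsample_profile()]) and
#'   `$unsmoothed` (the min-combined raw profile).
#' @examples
#' p <- profile_sequence(strrep("ACGT", 500), profile_config(window = 101L))
#' head(p$samples)
#' @export
profile_sequence <- function(sequence, config = profile_config(),
                             id = "seq") {
  codes <- encode_input(sequence)
  if (length(codes) == 0L) stop("sequence is empty")
  attr(codes, "seq_id") <- id
  raw <- run_directions(codes, config)
  raw$seq_id <- id
  sm <- smooth_profile(raw, config$window)
  sm$samples <- subsample_profile(sm, config$sample_step)
  sm$unsmoothed <- raw
  sm
}

#' Profile every record of a sequence set
#'
#' Each record is profiled independently (statistics never carry across
#' records).
#'
#' @param records named character vector or `DNAStringSet` (e.g. from
#'   [read_fasta()]).
#' @param config a [profile_config()].
#' @param verbose emit one progress line per record to standard error.
#' @return named list of `information_profile`s, in input order.
#' @export
profile_records <- function(records, config = profile_config(),
                            verbose = FALSE) {
  if (inherits(records, "DNAStringSet")) {
    nm <- names(records) %||% paste0("seq", seq_along(records))
    records <- stats::setNames(as.character(records), nm)
  }
  if (length(records) == 0L) stop("no sequence records supplied")
  if (is.null(names(records)))
    names(records) <- paste0("seq", seq_along(records))
  out <- vector("list", length(records))
  names(out) <- names(records)
  for (i in seq_along(records)) {
    if (verbose)
      message(sprintf("profiling %s (%d bp)", names(records)[i],
                      nchar(records[[i]])))
    out[[i]] <- profile_sequence(records[[i]], config, id = names(records)[i])
  }
  out
}

#' Train finite-context models on a reference sequence
#'
#' One counts-only pass per configured direction (direct models see the
#' reference 5'->3', reversed models see it reversed, or
#' reverse-complemented under `config$revcomp`). The returned sets are
#' frozen: applying them to a target leaves the reference statistics
#' untouched.
#'
#' @param sequence the reference sequence.
#' @param config a [profile_config()].
#' @return an object of class `trained_models`: a list with `$direct`
#'   and/or `$reversed` frozen `fcm_set`s plus the training parameters.
#' @export
train_models <- function(sequence, config = profile_config()) {
  codes <- encode_input(sequence)
  if (length(codes) == 0L) stop("reference sequence is empty")
  codes_int <- codes
  codes_int[is.na(codes_int)] <- -1L
  out <- list(direct = NULL, reversed = NULL,
              depths = config$depths, alphas = config$alphas,
              revcomp = config$revcomp)
  if (config$direction %in% c("both", "direct")) {
    m <- fcm_set(config$depths, config$alphas)
    fcm_set_train(m$ptr, codes_int)
    out$direct <- fcm_freeze(m)
  }
  if (config$direction %in% c("both", "reversed")) {
    rc <- reverse_codes(codes, config$revcomp)
    rc[is.na(rc)] <- -1L
    m <- fcm_set(config$depths, config$alphas)
    fcm_set_train(m$ptr, rc)
    out$reversed <- fcm_freeze(m)
  }
  class(out) <- "trained_models"
  out
}

#' Conditional information profile of a target given a reference
#'
#' Trains all models on the reference, freezes the counts, then profiles
#' the target with the frozen counts while the mixture weights stay live
#' (weight adaptation is what localizes divergence). Regions the target
#' shares with the reference are cheap to predict and sit near the
#' baseline; peaks mark sequence the reference never showed the models.
#' Smoothing, min-combination and subsampling follow the same
#' configuration as standalone profiles.
#'
#' @param reference reference sequence (or `NULL` if `models` is given).
#' @param target target sequence to be profiled.
#' @param config a [profile_config()].
#' @param id identifier for the target in outputs.
#' @param models optional pre-trained `trained_models` (e.g. from
#'   [load_models()]); skips the training pass.
#' @return a smoothed `information_profile` (as [profile_sequence()]).
#' @export
conditional_profile <- function(reference, target,
                                config = profile_config(), id = "target",
                                models = NULL) {
  if (is.null(models)) {
    if (is.null(reference)) stop("either a reference or trained models are required")
    models <- train_models(reference, config)
  }
  stopifnot(inherits(models, "trained_models"))
  if (!identical(as.integer(models$depths), config$depths))
    stop("trained model depths do not match the configuration")
  codes <- encode_input(target)
  if (length(codes) == 0L) stop("target sequence is empty")
  attr(codes, "seq_id") <- id
  raw <- run_directions(codes, config, models_direct = models$direct,
                        models_reversed = models$reversed)
  raw$seq_id <- id
  sm <- smooth_profile(raw, config$window)
  sm$samples <- subsample_profile(sm, config$sample_step)
  sm$unsmoothed <- raw
  sm
}
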