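open_out <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
}

#' Read a FASTA file
#'
#' Thin wrapper over `Biostrings::readDNAStringSet` that tolerates line
#' wrapping, CRLF endings and gzip compression, upper-cases residues and
#' returns plain character records (IUPAC ambiguity codes and `N` runs are
#' kept; the profile engine masks them).
#'
#' @param path path to a FASTA file (optionally gzipped).
#' @return named character vector, one element per record, in file order;
#'   names are the first whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e)
                    stop("failed to parse FASTA '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("FASTA file '", path, "' contains no records")
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop("FASTA file '", path, "' has an empty header")
  stats::setNames(toupper(as.character(set)), ids)
}

#' Write profile samples as a WIG (wiggle_0) custom track
#'
#' Emits `fixedStep` blocks (1-based starts, `step == span ==` the
#' sampling step). WIG has no missing-value record, so a run of masked
#' samples ends the current block and a new `fixedStep` line restarts
#' after the gap. Output is deterministic byte-for-byte for identical
#' input.
#'
#' @param samples a samples `data.frame` from [subsample_profile()]
#'   (columns `seq_id`, `pos`, `value`, `masked`), on a fixed-step grid.
#' @param path output path (`.gz` for gzip).
#' @param track_name name shown by the genome browser.
#' @param digits decimal places for values (default 4).
#' @return the path, invisibly.
#' @export
write_wig <- function(samples, path, track_name = "information_profile",
                      digits = 4L) {
  step <- infer_step(samples)
  con <- open_out(path)
  on.exit(close(con))
  lines <- c(sprintf(
    'track type=wiggle_0 name="%s" description="information profile (bits)"',
    track_name))
  keep <- !samples$masked & !is.na(samples$value)
  # split kept samples into runs of consecutive grid points
  if (any(keep)) {
    kept <- samples[keep, , drop = FALSE]
    brk <- cumsum(c(1L, as.integer(diff(kept$pos) != step |
                                     kept$seq_id[-1] != kept$seq_id[-nrow(kept)])))
    for (b in split(kept, brk)) {
      lines <- c(lines,
                 sprintf("fixedStep chrom=%s start=%d step=%d span=%d",
                         b$seq_id[1], b$pos[1], step, step),
                 formatC(b$value, format = "f", digits = digits))
    }
  }
  writeLines(lines, con)
  invisible(path)
}

infer_step <- function(samples) {
  stopifnot(is.data.frame(samples),
            all(c("seq_id", "pos", "value", "masked") %in% names(samples)))
  if (nrow(samples) < 2L) return(1L)
  d <- diff(samples$pos[samples$seq_id == samples$seq_id[1]])
  step <- unique(d[d > 0])
  if (length(step) > 1L)
    stop("samples are not on a fixed-step grid")
  as.integer(step[1] %||% 1L)
}

#' Write profile samples as bedGraph
#'
#' Each sample becomes a 0-based half-open interval of width equal to the
#' sampling step: a sample at 1-based position `p` covers
#' `[p - 1, p - 1 + step)`. Masked samples are omitted (bedGraph is
#' sparse by design).
#'
#' @inheritParams write_wig
#' @return the path, invisibly.
#' @export
write_bedgraph <- function(samples, path,
                           track_name = "information_profile",
                           digits = 4L) {
  step <- infer_step(samples)
  con <- open_out(path)
  on.exit(close(con))
  lines <- sprintf('track type=bedGraph name="%s"', track_name)
  keep <- !samples$masked & !is.na(samples$value)
  if (any(keep)) {
    b <- samples[keep, , drop = FALSE]
    lines <- c(lines, sprintf("%s\t%d\t%d\t%s", b$seq_id, b$pos - 1L,
                              b$pos - 1L + step,
                              formatC(b$value, format = "f",
                                      digits = digits)))
  }
  writeLines(lines, con)
  invisible(path)
}

#' Write profile samples as TSV
#'
#' Columns: `sequence_id`, `position` (1-based), `info_bits`, `masked`.
#' Masked samples are kept (with `NA` bits) so the grid stays complete.
#'
#' @inheritParams write_wig
#' @return the path, invisibly.
#' @export
write_tsv <- function(samples, path, digits = 4L) {
  stopifnot(is.data.frame(samples))
  con <- open_out(path)
  on.exit(close(con))
  vals <- ifelse(is.na(samples$value), "NA",
                 formatC(samples$value, format = "f", digits = digits))
  writeLines(c("sequence_id\tposition\tinfo_bits\tmasked",
               sprintf("%s\t%d\t%s\t%s", samples$seq_id, samples$pos, vals,
                       ifelse(samples$masked, "TRUE", "FALSE"))), con)
  invisible(path)
}

#' Read a profile TSV back
#'
#' @param path a file written by [write_tsv()].
#' @return a samples `data.frame` (columns as [subsample_profile()]).
#' @export
read_tsv_profile <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  data.frame(seq_id = as.character(df$sequence_id), pos = df$position,
             value = df$info_bits, masked = df$masked,
             stringsAsFactors = FALSE)
}

MODEL_CONTAINER_VERSION <- "infoprofile-models-1"

#' Save trained models
#'
#' Serializes a [train_models()] result (orders, alphas, frozen flags and
#' the full sparse count tables, context keys sorted) to a version-tagged
#' JSON container, losslessly. Gzip is applied for a `.gz` path.
#'
#' @param models a `trained_models` object.
#' @param path output path (conventionally `.json` or `.json.gz`).
#' @return the path, invisibly.
#' @export
save_models <- function(models, path) {
  stopifnot(inherits(models, "trained_models"))
  dump_one <- function(m) if (is.null(m)) NULL else fcm_set_dump(m$ptr)
  payload <- list(version = MODEL_CONTAINER_VERSION,
                  depths = models$depths, alphas = models$alphas,
                  revcomp = models$revcomp,
                  direct = dump_one(models$direct),
                  reversed = dump_one(models$reversed))
  json <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE,
                           null = "null")
  con <- open_out(path)
  on.exit(close(con))
  writeLines(json, con)
  invisible(path)
}

#' Load trained models
#'
#' @param path a container written by [save_models()].
#' @return a `trained_models` object equivalent to the one saved.
#' @export
load_models <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  payload <- tryCatch(
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                       simplifyMatrix = TRUE),
    error = function(e) stop("model container '", path,
                             "' is corrupt or truncated: ",
                             conditionMessage(e), call. = FALSE))
  if (!identical(payload$version, MODEL_CONTAINER_VERSION))
    stop("model container version mismatch: found '",
         payload$version %||% "<none>", "', expected '",
         MODEL_CONTAINER_VERSION, "'")
  restore_one <- function(d, depths, alphas) {
    if (is.null(d)) return(NULL)
    d <- lapply(d, function(m) {
      m$contexts <- as.numeric(m$contexts)
      m$counts <- matrix(as.numeric(m$counts), ncol = 4)
      m
    })
    obj <- list(ptr = fcm_set_restore(d), depths = as.integer(depths),
                alphas = as.numeric(alphas))
    class(obj) <- "fcm_set"
    obj
  }
  out <- list(direct = restore_one(payload$direct, payload$depths,
                                   payload$alphas),
              reversed = restore_one(payload$reversed, payload$depths,
                                     payload$alphas),
              depths = as.integer(payload$depths),
              alphas = as.numeric(payload$alphas),
              revcomp = isTRUE(payload$revcomp))
  class(out) <- "trained_models"
  out
}

#' Write a truth table of planted features as BED
#'
#' 0-based half-open intervals, as produced by [synth_generate()].
#'
#' @param truth `data.frame` with columns `chrom`, `start`, `end`, `name`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_truth_bed <- function(truth, path) {
  stopifnot(is.data.frame(truth))
  con <- open_out(path)
  on.exit(close(con))
  if (nrow(truth))
    writeLines(sprintf("%s\t%d\t%d\t%s", truth$chrom, truth$start,
                       truth$end, truth$name), con)
  else writeLines(character(0), con)
  invisible(path)
}
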