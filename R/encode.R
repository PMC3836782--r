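#' Encode a DNA sequence as 2-bit symbol codes
#'
#' Maps `A/a -> 0`, `C/c -> 1`, `G/g -> 2`, `T/t -> 3`. Every other
#' character (N runs, IUPAC ambiguity codes, gaps) becomes `NA`, which the
#' profile engine treats as a masked position: no model estimate, no count
#' update, and the context register is reset so no context ever spans a
#' masked run.
#'
#' @param x a single character string, or a `Biostrings::DNAString` /
#'   one-element `DNAStringSet`.
#' @return an integer vector of codes in `0:3` with `NA` at non-ACGT
#'   positions.
#' @examples
#' seq_encode("ACGTn")
#' @export
seq_encode <- function(x) {
  if (inherits(x, "DNAStringSet")) {
    if (length(x) != 1L) stop("expected a single sequence")
    x <- as.character(x)
  } else if (inherits(x, "XString")) {
    x <- as.character(x)
  }
  if (!is.character(x) || length(x) != 1L)
    stop("`x` must be a single character string or DNAString")
  code <- utf8ToInt(x)
  lut <- rep(NA_integer_, 128L)
  lut[utf8ToInt("A")] <- 0L; lut[utf8ToInt("a")] <- 0L
  lut[utf8ToInt("C")] <- 1L; lut[utf8ToInt("c")] <- 1L
  lut[utf8ToInt("G")] <- 2L; lut[utf8ToInt("g")] <- 2L
  lut[utf8ToInt("T")] <- 3L; lut[utf8ToInt("t")] <- 3L
  code[code > 127L | code < 1L] <- 1L  # exotic bytes -> index 1 -> NA
  lut[code]
}

#' Decode 2-bit symbol codes back to a DNA string
#'
#' Inverse of [seq_encode()]; `NA` codes become `N`.
#'
#' @param codes integer vector of codes in `0:3`, `NA` allowed.
#' @return a single character string.
#' @export
seq_decode <- function(codes) {
  chars <- c("A", "C", "G", "T")[codes + 1L]
  chars[is.na(chars)] <- "N"
  paste(chars, collapse = "")
}
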