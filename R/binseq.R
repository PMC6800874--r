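#' Binary sequences, weights and parity classes
#'
#' Binary sequences are represented as strings over `0`/`1`, written most
#' significant position first, with 1-based positions.  The weight of a
#' sequence is its number of 1s; a sequence of weight 0 has even parity.
#' The two parity classes of a given length each contain half of all
#' sequences, and flipping any fixed position is a bijection between them —
#' the combinatorial fact the counter-example families are built on.
#'
#' @param w a binary sequence string, e.g. `"1001"`.
#' @return `seq_weight()`: integer; `seq_parity()`: `"even"` or `"odd"`.
#' @examples
#' seq_weight("1011")        # 3
#' seq_parity("0000")        # "even"
#' flip_at("1001", 3)        # "1011"
#' mask_at("1001", 3)        # "10*1"
#' parity_sequences(2, "odd")  # "01" "10"
#' @export
seq_weight <- function(w) {
  check_binseq(w)
  sum(seq_bits(w))
}

#' @rdname seq_weight
#' @export
seq_parity <- function(w) {
  if (seq_weight(w) %% 2 == 0) "even" else "odd"
}

seq_bits <- function(w) {
  as.integer(strsplit(w, "", fixed = TRUE)[[1]])
}

check_binseq <- function(w) {
  stopifnot(is.character(w), length(w) == 1)
  if (nchar(w) < 1 || grepl("[^01]", w)) stop("not a binary sequence: ", w)
  invisible(w)
}

check_position <- function(w, i) {
  if (!(is.numeric(i) && length(i) == 1 && i == as.integer(i) &&
        i >= 1 && i <= nchar(w))) {
    stop("position out of range: i = ", i, " for length ", nchar(w))
  }
  as.integer(i)
}

#' Flip one position of a binary sequence
#'
#' Returns the sequence differing from `w` exactly at position `i`
#' (an involution that swaps the parity classes).
#'
#' @param w a binary sequence string.
#' @param i 1-based position.
#' @return A binary sequence string.
#' @export
flip_at <- function(w, i) {
  check_binseq(w)
  i <- check_position(w, i)
  bits <- seq_bits(w)
  bits[i] <- 1L - bits[i]
  paste(bits, collapse = "")
}

#' Mask one position of a binary sequence
#'
#' Replaces position `i` by `*`.  Masked sequences are what a deck member
#' retains of a sequence after the taxon at position `i` is removed: the two
#' parity classes become indistinguishable, since masking position `i` sends
#' both onto the same set of masked sequences.
#'
#' @param w a binary sequence string.
#' @param i 1-based position.
#' @return A string over `0`, `1`, `*` with exactly one `*`.
#' @export
mask_at <- function(w, i) {
  check_binseq(w)
  i <- check_position(w, i)
  paste0(substr(w, 1, i - 1), "*", substr(w, i + 1, nchar(w)))
}

#' Enumerate a parity class of binary sequences
#'
#' All `2^(r-1)` length-`r` binary sequences of the given parity, in
#' lexicographic order (`0 < 1`, stringwise).
#'
#' @param r sequence length, `r >= 1`.
#' @param parity `"even"` or `"odd"`.
#' @return Character vector of sequences.
#' @export
parity_sequences <- function(r, parity = c("even", "odd")) {
  parity <- match.arg(parity)
  stopifnot(r >= 1)
  grid <- expand.grid(rep(list(0:1), r))[, r:1, drop = FALSE]
  ws <- apply(grid, 1, paste, collapse = "")
  keep <- (rowSums(grid) %% 2 == 0) == (parity == "even")
  sort(ws[keep])
}

#' Restrict a sequence set by the value at one position
#'
#' @param S character vector of equal-length binary sequences.
#' @param i 1-based position.
#' @param h 0 or 1.
#' @return The subset of `S` with `h` at position `i`, in the original order.
#' @export
restrict_seqs <- function(S, i, h) {
  stopifnot(length(S) >= 1, h %in% c(0, 1))
  lens <- unique(nchar(S))
  if (length(lens) != 1) stop("sequences must have equal length")
  i <- check_position(S[1], i)
  S[substr(S, i, i) == as.character(h)]
}
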