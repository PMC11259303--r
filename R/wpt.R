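# Wavelet packet transform: db4 analysis/synthesis, frequency ordering
# of packet nodes, and band-limited reconstruction.

# Daubechies-4 (8-tap) decomposition low-pass filter; the high-pass is
# its quadrature mirror g[k] = (-1)^(k+1) h[L-1-k].
.db4_h <- c(-0.010597401785069032, 0.032883011666885206,
            0.030841381835560764, -0.18703481171909309,
            -0.027983769416859854, 0.63088076792985890,
            0.71484657055291570, 0.23037781330889650)

#' Wavelet filter pair
#'
#' Analysis filters of an orthogonal wavelet. Only `db4` (the 8-tap
#' Daubechies filter with 4 vanishing moments) is shipped; the synthesis
#' filters are implied by orthogonality (the inverse transform is the
#' transpose of the analysis transform).
#'
#' @param wavelet Filter name; only `"db4"`.
#' @return List with `h` (low-pass), `g` (high-pass) and `name`.
#' @export
wpt_filters <- function(wavelet = "db4") {
  if (!identical(wavelet, "db4")) {
    stop("only the db4 filter pair is shipped")
  }
  h <- .db4_h
  L <- length(h)
  g <- (-1)^(1:L) * rev(h)
  list(h = h, g = g, name = "db4")
}

#' Wavelet packet decomposition
#'
#' Recursively splits the signal `level` times: the child coefficients at
#' level j arise from the level j-1 parent by convolution with the
#' low-pass (`h`, even child `2i`) or high-pass (`g`, odd child `2i+1`)
#' filter followed by dyadic downsampling, with periodic boundary
#' handling (odd-length nodes are extended by repeating the last sample).
#'
#' @param x Numeric signal.
#' @param level Decomposition depth J >= 1; `length(x)` must be at least
#'   `2^level`.
#' @param filters A [wpt_filters()] pair.
#' @return A `wp_tree`: list with `nodes` (the `2^level` leaf coefficient
#'   vectors in natural filter-bank order), `lens` (node length per
#'   level), `level`, `n` (signal length) and `filters`.
#' @export
wpt_decompose <- function(x, level, filters = wpt_filters()) {
  stopifnot(level >= 1)
  if (length(x) < 2^level) {
    stop("signal too short for level ", level, ": need at least ",
         2^level, " samples, got ", length(x))
  }
  res <- cpp_wpt_decompose(as.numeric(x), as.integer(level),
                           filters$h, filters$g)
  structure(
    list(nodes = res$nodes, lens = res$lens, level = level,
         n = length(x), filters = filters),
    class = "wp_tree"
  )
}

#' @export
print.wp_tree <- function(x, ...) {
  cat(sprintf("<wp_tree> level %d, %d nodes of %d coefficients (n = %d)\n",
              x$level, 2^x$level, x$lens[x$level + 1], x$n))
  invisible(x)
}

#' Natural-to-frequency ordering of packet nodes
#'
#' Because each high-pass split mirrors the spectrum of its branch, the
#' filter-bank (natural) order of wavelet packet nodes is staggered with
#' respect to frequency. The passband centre rank of natural node `i` is
#' the inverse binary-reflected Gray code of `i`: the natural index of
#' the node with frequency rank `r` is `gray(r) = r xor (r >> 1)`.
#'
#' @param level Tree depth.
#' @param natural_index 0-based natural node index (vectorized), each in
#'   `[0, 2^level)`.
#' @return 0-based frequency rank(s); a bijection per level.
#' @export
natural_to_frequency_order <- function(level, natural_index) {
  nn <- 2^level
  if (any(natural_index < 0) || any(natural_index >= nn)) {
    stop("natural_index out of range [0, 2^level)")
  }
  vapply(as.integer(natural_index), function(g) {
    r <- 0L
    for (b in (level - 1):0) {
      bit <- bitwAnd(bitwShiftR(g, b), 1L)
      prev <- bitwAnd(r, 1L)
      r <- bitwOr(bitwShiftL(r, 1L), bitwXor(bit, prev))
    }
    r
  }, 0L)
}

# Natural indices sorted by ascending passband frequency: position r
# holds gray(r).
frequency_order <- function(level) {
  r <- 0:(2^level - 1)
  bitwXor(r, bitwShiftR(r, 1L))
}

# Passband centre frequency (Hz) of each natural node at `level`.
node_centres <- function(level, fs) {
  width <- (fs / 2) / 2^level
  rank <- natural_to_frequency_order(level, 0:(2^level - 1))
  (rank + 0.5) * width
}

# Natural indices of the nodes whose frequency-ordered passband centre
# lies in [low, high).
select_band_nodes <- function(level, fs, low_hz, high_hz) {
  centres <- node_centres(level, fs)
  idx <- which(centres >= low_hz & centres < high_hz) - 1L
  if (length(idx) == 0) {
    stop(sprintf("band [%g, %g) Hz selects no node at level %d (fs %g)",
                 low_hz, high_hz, level, fs))
  }
  idx
}

#' Reconstruct a signal from selected packet nodes
#'
#' Inverse wavelet packet transform keeping only the listed leaf nodes;
#' with all nodes kept this reproduces the original signal (perfect
#' reconstruction).
#'
#' @param tree A `wp_tree` from [wpt_decompose()].
#' @param keep 0-based natural node indices to retain.
#' @return Numeric signal of the original length.
#' @export
reconstruct_nodes <- function(tree, keep) {
  nn <- 2^tree$level
  mask <- logical(nn)
  mask[keep + 1L] <- TRUE
  cpp_wpt_reconstruct(tree$nodes, tree$level, tree$lens, mask,
                      tree$filters$h, tree$filters$g)
}

#' Reconstruct one EEG rhythm band
#'
#' Keeps exactly the nodes whose frequency-ordered passband centre lies
#' in the band's half-open range and inverts the transform.
#'
#' @param tree A `wp_tree`.
#' @param band Band name (`"delta"`, `"theta"`, `"alpha"`, `"beta"`) or a
#'   one-row data.frame with `low_hz` / `high_hz`.
#' @param fs Sampling rate of the decomposed signal, Hz.
#' @return Band-limited signal of the original length.
#' @export
reconstruct_band <- function(tree, band, fs) {
  if (is.character(band)) {
    bs <- band_specs()
    row <- bs[bs$band == band, ]
    if (nrow(row) != 1) stop("unknown band: ", band)
  } else {
    row <- band
  }
  if (row$high_hz > fs / 2 + 1e-9) stop("band exceeds the Nyquist frequency")
  keep <- select_band_nodes(tree$level, fs, row$low_hz, row$high_hz)
  reconstruct_nodes(tree, keep)
}
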