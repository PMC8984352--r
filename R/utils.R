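# Internal helpers shared across the package.

PHASES <- c("PRE", "FORCED", "POST")

#' @keywords internal
#' @noRd
substream_seed <- function(seed, k) {
  # LCG-style derivation of a child seed from (master seed, counter).
  # All arithmetic in doubles; results stay below 2^31.
  s <- (as.double(seed) %% 2147483629)
  as.integer(((s * 48271 + as.double(k) * 104729) %% 2147483629) + 1)
}

#' @keywords internal
#' @noRd
canonical_pair <- function(a, b) {
  list(a = pmin(a, b), b = pmax(a, b))
}

#' @keywords internal
#' @noRd
pair_key <- function(a, b) {
  p <- canonical_pair(a, b)
  paste(p$a, p$b, sep = "|")
}

# All unordered pairs of ids, canonically ordered (bat_a < bat_b).
#' @keywords internal
#' @noRd
all_pairs <- function(ids) {
  ids <- sort(ids)
  idx <- utils::combn(length(ids), 2)
  data.frame(bat_a = ids[idx[1, ]], bat_b = ids[idx[2, ]],
             stringsAsFactors = FALSE)
}

# All permutations of seq_len(n), as a matrix with one permutation per row.
# Used for exhaustive enumeration of small null spaces.
#' @keywords internal
#' @noRd
permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

# Midranks, the tie treatment used throughout the rank models.
#' @keywords internal
#' @noRd
midrank <- function(x) rank(x, ties.method = "average")

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
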