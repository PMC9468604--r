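#' Global sequence alignment (Needleman-Wunsch)
#'
#' Optimal global alignment under a fixed match/mismatch/gap scheme, used to
#' build the residue correspondence for cross-protein RMSD. Only aligned
#' (match or mismatch) columns enter the returned map; gap columns are
#' dropped. Traceback ties are broken deterministically: diagonal, then up
#' (gap in `seq_b`), then left (gap in `seq_a`).
#'
#' @param seq_a,seq_b strings over the 20-letter amino-acid alphabet.
#' @param match,mismatch,gap scoring scheme; defaults 2 / -1 / -2.
#' @return list with `map`, a tibble of 0-based aligned positions
#'   (`index_a`, `index_b`, strictly increasing in both columns), and
#'   `score`, the optimal global alignment score.
#' @export
#' @examples
#' align_sequences("ACD", "ACD", match = 1, mismatch = -1, gap = -2)
align_sequences <- function(seq_a, seq_b, match = 2, mismatch = -1, gap = -2) {
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  n <- length(a)
  m <- length(b)
  empty_map <- tibble(index_a = integer(), index_b = integer())
  if (n == 0 || m == 0) {
    return(list(map = empty_map, score = gap * (n + m)))
  }
  s <- matrix(0, n + 1, m + 1)
  s[, 1] <- gap * (0:n)
  s[1, ] <- gap * (0:m)
  sub <- outer(a, b, function(x, y) ifelse(x == y, match, mismatch))
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s[i + 1, j + 1] <- max(
        s[i, j] + sub[i, j],
        s[i, j + 1] + gap,
        s[i + 1, j] + gap
      )
    }
  }
  # traceback with diagonal > up > left tie preference
  ia <- integer(0)
  ib <- integer(0)
  i <- n
  j <- m
  while (i > 0 && j > 0) {
    cur <- s[i + 1, j + 1]
    if (cur == s[i, j] + sub[i, j]) {
      ia <- c(i - 1L, ia)
      ib <- c(j - 1L, ib)
      i <- i - 1
      j <- j - 1
    } else if (cur == s[i, j + 1] + gap) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  list(map = tibble(index_a = ia, index_b = ib), score = s[n + 1, m + 1])
}
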