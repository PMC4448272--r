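# Exhaustive in-band alignment oracle: recursively enumerates every
# monotone path through the (banded) alignment lattice and scores it with
# the same incremental rules as the DP, without any table reuse or
# memoization. Only feasible for short arms.
oracle_best_score <- function(st1, st2, params, dw, full = FALSE) {
  e1 <- enc(st1); e2 <- enc(st2)
  l1 <- length(e1); l2 <- length(e2)
  pid <- function(x, y) {
    if (x == 0 && y == 3) return(1L); if (x == 3 && y == 0) return(2L)
    if (x == 2 && y == 1) return(3L); if (x == 1 && y == 2) return(4L)
    if (x == 2 && y == 3) return(5L); if (x == 3 && y == 2) return(6L)
    0L
  }
  stk <- params$stacking
  s_mis <- -params$internal_init[2] / 2
  s_gap <- -params$bulge_init[1]
  inband <- function(i, j) full || abs(i - j) <= dw
  rec <- function(i, j, prev_pair) {
    if (i == l1 && j == l2) return(0)
    best <- -Inf
    if (i < l1 && j < l2 && inband(i + 1, j + 1)) {
      p <- pid(e1[i + 1], e2[j + 1])
      inc <- if (p > 0) {
        if (prev_pair > 0) -stk[prev_pair, p] else 0
      } else s_mis
      v <- inc + rec(i + 1, j + 1, if (p > 0) p else 0L)
      if (v > best) best <- v
    }
    if (i < l1 && inband(i + 1, j)) {
      v <- s_gap + rec(i + 1, j, 0L)
      if (v > best) best <- v
    }
    if (j < l2 && inband(i, j + 1)) {
      v <- s_gap + rec(i, j + 1, 0L)
      if (v > best) best <- v
    }
    best
  }
  rec(0L, 0L, 0L)
}
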