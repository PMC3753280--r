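# Independent oracles used to freeze expected values: these deliberately
# avoid the code paths they check.

# maximum-cardinality nested subset of a pair matching, by exhaustive
# enumeration over all subsets (use only for <= ~12 pairs)
oracle_max_nested <- function(pairs) {
  p <- NROW(pairs)
  if (p == 0L) return(0L)
  crossing <- function(a, b) {
    i <- pairs[a, 1L]; j <- pairs[a, 2L]
    k <- pairs[b, 1L]; l <- pairs[b, 2L]
    (i < k && k < j && j < l) || (k < i && i < l && l < j)
  }
  best <- 0L
  for (mask in 0:(2^p - 1L)) {
    sel <- which(bitwAnd(mask, 2^(0:(p - 1L))) > 0L)
    if (length(sel) <= best) next
    ok <- TRUE
    if (length(sel) > 1L) {
      for (a in seq_len(length(sel) - 1L)) {
        for (b in seq(a + 1L, length(sel))) {
          if (crossing(sel[a], sel[b])) { ok <- FALSE; break }
        }
        if (!ok) break
      }
    }
    if (ok) best <- length(sel)
  }
  best
}

euler_rot <- function(a, b, c) {
  Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0,
                             0, 0, 1), 3L, 3L)
  Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0,
                             sin(t), 0, cos(t)), 3L, 3L)
  Rz(a) %*% Ry(b) %*% Rz(c)
}

# brute-force minimum RMSD over rotations: coarse Euler grid then
# Nelder-Mead refinement; independent of the SVD path
oracle_min_rmsd <- function(Q, P, coarse_deg = 15) {
  Q0 <- sweep(Q, 2L, colMeans(Q))
  P0 <- sweep(P, 2L, colMeans(P))
  score <- function(ang) {
    R <- euler_rot(ang[1L], ang[2L], ang[3L])
    sqrt(mean(rowSums((P0 %*% t(R) - Q0)^2)))
  }
  step <- coarse_deg * pi / 180
  best <- c(0, 0, 0); bestv <- score(best)
  for (a in seq(0, 2 * pi - step / 2, by = step))
    for (b in seq(0, pi, by = step))
      for (c in seq(0, 2 * pi - step / 2, by = step)) {
        v <- score(c(a, b, c))
        if (v < bestv) { bestv <- v; best <- c(a, b, c) }
      }
  opt <- stats::optim(best, score, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  min(bestv, opt$value)
}

# random nested structure with optional crossing extras, for property tests
random_pair_structure <- function(len = 30L, npairs = 6L) {
  pairs <- matrix(integer(0), ncol = 2L)
  free <- seq_len(len)
  for (k in seq_len(npairs)) {
    if (length(free) < 2L) break
    ij <- sort(sample(free, 2L))
    if (ij[2L] - ij[1L] < 3L) next
    pairs <- rbind(pairs, ij)
    free <- setdiff(free, ij)
  }
  pairs
}

# sequence compatible with arbitrary pairs: G at 5' side, C at 3' side,
# A elsewhere
compatible_seq <- function(len, pairs) {
  ch <- rep("A", len)
  if (NROW(pairs)) {
    ch[pairs[, 1L]] <- "G"
    ch[pairs[, 2L]] <- "C"
  }
  paste(ch, collapse = "")
}

random_rotation <- function() {
  euler_rot(stats::runif(1, 0, 2 * pi), stats::runif(1, 0, pi),
            stats::runif(1, 0, 2 * pi))
}

rigid_move_graph <- function(g, R = random_rotation(),
                             t = stats::runif(3, -20, 20)) {
  apply_transform(g, list(rotation = R, translation = t))
}
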