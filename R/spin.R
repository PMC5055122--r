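#' SPIN parameters shared by BackSPIN
#'
#' @param numLevels maximum splitting depth (default 7).
#' @param runs_iters iterations per neighborhood width (default 12).
#' @param runs_step multiplicative width decay between batches (default
#'   0.1, in `(0, 1]`).
#' @param stop_const stopping threshold multiplier on the split objective
#'   (default 1.1); see [backspin()] for the normalization.
#' @return object of class `backspin_params`.
#' @export
backspin_params <- function(numLevels = 7, runs_iters = 12, runs_step = 0.1,
                            stop_const = 1.1) {
  if (numLevels < 1 || runs_iters < 1 || stop_const <= 0)
    stop("backspin_params: all parameters must be positive")
  if (runs_step <= 0 || runs_step > 1) stop("runs_step must be in (0, 1]")
  structure(list(numLevels = numLevels, runs_iters = runs_iters,
                 runs_step = runs_step, stop_const = stop_const),
            class = "backspin_params")
}

# Gaussian neighborhood weight matrix over positions 1..n with width sigma.
spin_weight_matrix <- function(n, sigma) {
  d <- outer(seq_len(n), seq_len(n), `-`)
  W <- exp(-(d^2) / (2 * sigma^2))
  W / sum(W)
}

# SPIN energy of order o: sum over pairs of dissimilarity x positional
# neighborhood weight.
spin_energy <- function(D, o, W) sum(D[o, o] * W)

#' Sort a correlation matrix with SPIN (neighborhood variant)
#'
#' Permutes the matrix to place similar elements at nearby positions. The
#' energy penalizing separation of similar elements is
#' `E(o) = sum(D[o, o] * W1)` with dissimilarity `D = 1 - C` and `W1` the
#' normalized unit-width Gaussian positional weight matrix (the
#' finest-resolution neighborhood, used to evaluate every candidate
#' order).
#'
#' The search anneals over a decreasing width schedule: `sigma` starts at
#' `n / 2` and is multiplied by `runs_step` after each width until it
#' falls below 1, with a final unit-width pass. At each width the
#' dynamics restart from the best order found so far and iterate (at most
#' `runs_iters` times) the center-of-mass reassignment: the shifted
#' non-negative similarity matrix is smoothed along positions,
#' `M = G[o, o] %*% W_sigma`, and elements are re-sorted by the weighted
#' positional center of mass of their similarity row (ties keep the
#' previous position) — each element moves toward the average position of
#' the elements it resembles. Every visited order is scored with `E`; the
#' best is kept, so the reported energy trace is non-increasing within
#' each width. The initial order is the average-linkage hierarchical
#' clustering seriation of `D`, making the whole procedure deterministic;
#' `seed` is accepted for interface stability and provenance.
#'
#' @param C symmetric correlation/similarity matrix.
#' @param params a [backspin_params()].
#' @param seed recorded in the result; the algorithm is deterministic.
#' @return object of class `spin_sorted`: `order` (permutation of
#'   indices), `C_sorted`, `energy_trace` (per width: running-best energy
#'   per iteration), `width_schedule`, `seed`.
#' @export
spin_sort <- function(C, params = backspin_params(), seed = 1L) {
  C <- as.matrix(C)
  n <- nrow(C)
  if (n != ncol(C) || max(abs(C - t(C))) > 1e-8)
    stop("C must be symmetric")
  if (any(!is.finite(C))) stop("C must be finite")
  if (n == 1) {
    return(structure(list(order = 1L, C_sorted = C,
                          energy_trace = list(), width_schedule = numeric(0),
                          seed = seed),
                     class = "spin_sorted"))
  }
  D <- 1 - C
  diag(D) <- 0
  G <- C - min(C)                       # non-negative similarity weights
  diag(G) <- 0
  pos <- seq_len(n)
  W1 <- exp(-outer(pos, pos, `-`)^2 / 2)
  W1 <- W1 / sum(W1)
  widths <- numeric(0)
  sigma <- n / 2
  while (sigma >= 1) {
    widths <- c(widths, sigma)
    sigma <- sigma * params$runs_step
  }
  if (length(widths) == 0 || widths[length(widths)] > 1)
    widths <- c(widths, 1)
  o_best <- stats::hclust(stats::as.dist(D), method = "average")$order
  e_best <- spin_energy(D, o_best, W1)
  trace <- list()
  for (sigma in widths) {
    W <- exp(-outer(pos, pos, `-`)^2 / (2 * sigma^2))
    o <- o_best
    etr <- e_best
    for (it in seq_len(params$runs_iters)) {
      M <- G[o, o] %*% W
      denom <- rowSums(M)
      cm <- ifelse(denom > 0, as.numeric(M %*% pos) / denom, pos)
      new_rank <- order(cm, pos)  # stable: ties keep the previous position
      if (all(new_rank == pos)) break   # fixed point of this width
      o <- o[new_rank]
      e <- spin_energy(D, o, W1)
      if (e < e_best - 1e-12) {
        e_best <- e
        o_best <- o
      }
      etr <- c(etr, e_best)
    }
    trace[[length(trace) + 1]] <- etr
  }
  structure(list(order = o_best, C_sorted = C[o_best, o_best],
                 energy_trace = trace, width_schedule = widths, seed = seed),
            class = "spin_sorted")
}

#' Objective value of splitting a sorted correlation matrix at x
#'
#' For a sorted symmetric matrix `C` of size `n`, the score of putting the
#' first `x` elements in the left block is
#' \deqn{f(x) = \frac{\sum_{i,j \le x, i \ne j} C_{ij} +
#'   \sum_{i,j > x, i \ne j} C_{ij}}{x^2 + (n - x)^2}.}
#' High within-block correlation relative to block sizes favors the split.
#'
#' @param C_sorted sorted symmetric matrix.
#' @param x left-block size, in `[1, n - 1]`.
#' @return the objective value.
#' @export
split_score <- function(C_sorted, x) {
  n <- nrow(C_sorted)
  if (x < 1 || x > n - 1) stop("x must be in [1, n - 1]")
  left <- seq_len(x)
  right <- (x + 1):n
  sl <- sum(C_sorted[left, left]) - sum(diag(C_sorted)[left])
  sr <- sum(C_sorted[right, right]) - sum(diag(C_sorted)[right])
  (sl + sr) / (x^2 + (n - x)^2)
}

#' Find the optimal split point of a sorted correlation matrix
#'
#' Exhaustively evaluates [split_score()] at every `x` in `[1, n - 1]` and
#' returns the argmax (smallest `x` on ties) with the full curve.
#'
#' @param sorted a `spin_sorted` object or a sorted symmetric matrix.
#' @return object of class `split_result`: `x_s`, `f`, `f_curve`, `n`.
#' @export
find_split <- function(sorted) {
  C <- if (inherits(sorted, "spin_sorted")) sorted$C_sorted else as.matrix(sorted)
  n <- nrow(C)
  if (n < 2) stop("need at least 2 elements to split")
  f_curve <- vapply(seq_len(n - 1), function(x) split_score(C, x), numeric(1))
  x_s <- which.max(f_curve)          # which.max returns the first maximum
  structure(list(x_s = x_s, f = f_curve[x_s], f_curve = f_curve, n = n),
            class = "split_result")
}
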