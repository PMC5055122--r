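#' Affinity propagation clustering
#'
#' Exemplar-based clustering by message passing between data points.
#' Responsibilities `R` and availabilities `A` are updated with damping
#' until the exemplar set is stable; each point is assigned to the
#' exemplar maximizing `A + S`.
#'
#' @param S square similarity matrix (higher = more similar).
#' @param preference self-similarity controlling the number of exemplars;
#'   default: median of the off-diagonal similarities.
#' @param damping damping factor in `[0.5, 1)` (default 0.9).
#' @param max_iter maximum iterations (default 500).
#' @param conv_iter stop after this many iterations without exemplar
#'   change (default 30).
#' @return list: `exemplars` (indices), `exemplar_of` (per point, the
#'   index of its exemplar), `iterations`, `converged`.
#' @export
affinity_propagation <- function(S, preference = NULL, damping = 0.9,
                                 max_iter = 500, conv_iter = 30) {
  S <- as.matrix(S)
  n <- nrow(S)
  if (n != ncol(S)) stop("S must be square")
  if (n == 1)
    return(list(exemplars = 1L, exemplar_of = 1L, iterations = 0L,
                converged = TRUE))
  if (is.null(preference))
    preference <- median(S[row(S) != col(S)])
  diag(S) <- preference
  # tiny deterministic jitter breaks exact ties without an RNG
  S <- S + S * 1e-12 * outer(seq_len(n), seq_len(n)) / n^2
  R <- matrix(0, n, n)
  A <- matrix(0, n, n)
  stable <- 0L
  last <- integer(0)
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # responsibilities
    AS <- A + S
    max1 <- apply(AS, 1, max)
    which1 <- max.col(AS, ties.method = "first")
    AS2 <- AS
    AS2[cbind(seq_len(n), which1)] <- -Inf
    max2 <- apply(AS2, 1, max)
    Rnew <- S - max1
    Rnew[cbind(seq_len(n), which1)] <- S[cbind(seq_len(n), which1)] - max2
    R <- damping * R + (1 - damping) * Rnew
    # availabilities
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    colsums <- colSums(Rp)
    Anew <- matrix(colsums, n, n, byrow = TRUE) - Rp
    dA <- diag(Anew)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dA
    A <- damping * A + (1 - damping) * Anew
    ex <- which(diag(A) + diag(R) > 0)
    if (identical(ex, last)) stable <- stable + 1L else stable <- 0L
    last <- ex
    if (stable >= conv_iter && length(ex) > 0) break
  }
  ex <- last
  if (length(ex) == 0) ex <- which.max(diag(A) + diag(R))
  assign_to <- ex[max.col(S[, ex, drop = FALSE], ties.method = "first")]
  assign_to[ex] <- ex
  list(exemplars = ex, exemplar_of = assign_to, iterations = it,
       converged = stable >= conv_iter)
}
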