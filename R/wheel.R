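# unit vectors to the vertices of a regular K-gon, one per prototype,
# in the given circular order (first vertex at angle 90 degrees)
wheel_vertices <- function(order_names) {
  K <- length(order_names)
  ang <- pi / 2 - 2 * pi * (seq_len(K) - 1) / K
  u <- cbind(cos(ang), sin(ang))
  rownames(u) <- order_names
  u
}

wheel_positions <- function(probabilities, u) {
  probabilities[, rownames(u), drop = FALSE] %*% u
}

# distinct circular orders up to rotation and reflection: fix the first
# element, permute the rest, keep one of each mirrored pair
circular_orders <- function(items) {
  rest <- items[-1]
  perms <- permutations_of(rest)
  keep <- vapply(perms, function(p) p[1] <= p[length(p)], logical(1))
  lapply(perms[keep], function(p) c(items[1], p))
}

permutations_of <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    out <- c(out, lapply(permutations_of(x[-i]), function(p) c(x[i], p)))
  out
}

#' Lay cells out on the prototype wheel
#'
#' Each cell sits at the probability-weighted combination of unit vectors
#' pointing to the vertices of a regular polygon, one vertex per
#' prototype: `x = sum_i p_i * u_i`. The vertex order is chosen to
#' minimize the number of cells inside the central area (radius `rho` of
#' the circumradius): exhaustively over circular orders for up to
#' `exhaustive_max` prototypes, otherwise greedily by placing the
#' most-confused prototype pairs adjacent.
#'
#' @param probabilities cells x prototypes matrix, rows summing to 1.
#' @param rho central-area radius as a fraction of the circumradius
#'   (default 0.2).
#' @param exhaustive_max exhaustive search bound (default 8).
#' @return list of class `wheel_layout`: `coords` (cells x 2),
#'   `vertex_order`, `vertices` (unit vectors), `n_central`, `rho`.
#' @export
wheel_layout <- function(probabilities, rho = 0.2, exhaustive_max = 8) {
  P <- as.matrix(probabilities)
  if (any(abs(rowSums(P) - 1) > 1e-6))
    stop("probability rows must sum to 1")
  protos <- colnames(P)
  K <- length(protos)
  count_central <- function(ord) {
    x <- wheel_positions(P, wheel_vertices(ord))
    sum(sqrt(rowSums(x^2)) < rho)
  }
  if (K <= 2) {
    best <- protos
  } else if (K <= exhaustive_max) {
    cands <- circular_orders(protos)
    scores <- vapply(cands, count_central, numeric(1))
    best <- cands[[which.min(scores)]]
  } else {
    # confusion weight: co-occurrence of probability mass between classes
    Wc <- crossprod(P)
    diag(Wc) <- 0
    best <- greedy_adjacency_order(Wc)
  }
  u <- wheel_vertices(best)
  coords <- wheel_positions(P, u)
  rownames(coords) <- rownames(P)
  structure(list(coords = coords, vertex_order = best, vertices = u,
                 n_central = count_central(best), rho = rho),
            class = "wheel_layout")
}

#' Coordinates of probability vectors on an existing wheel layout
#'
#' @param probabilities cells x prototypes matrix, rows summing to 1.
#' @param layout a [wheel_layout()] result.
#' @return cells x 2 coordinate matrix.
#' @export
wheel_coordinates <- function(probabilities, layout) {
  stopifnot(inherits(layout, "wheel_layout"))
  wheel_positions(as.matrix(probabilities), layout$vertices)
}

# build a cycle greedily: repeatedly append the unplaced prototype most
# confused with the current endpoint
greedy_adjacency_order <- function(W) {
  protos <- rownames(W)
  start <- protos[which.max(apply(W, 1, max))]
  ord <- start
  left <- setdiff(protos, start)
  while (length(left) > 0) {
    tail_p <- ord[length(ord)]
    nxt <- left[which.max(W[tail_p, left])]
    ord <- c(ord, nxt)
    left <- setdiff(left, nxt)
  }
  ord
}
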