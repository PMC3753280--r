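# Graph comparison: least-squares proper-rotation superposition (Kabsch via
# SVD, reflections excluded), RMSD over all 2n+1 matched vertices, and
# MaxAngle over corresponding helix edge vectors in the superposed frame.

match_vertices <- function(ref, pred) {
  lr <- sort(ref$vertices$label)
  lp <- sort(pred$vertices$label)
  if (!identical(lr, lp))
    stop("vertex label sets differ; graphs are not comparable")
  lr
}

#' Optimal proper-rotation superposition of two graphs
#'
#' Vertices are matched by label (never by proximity), both graphs are
#' centred on their vertex centroids, and the least-squares rotation is
#' obtained from the SVD of the covariance with determinant correction so a
#' reflection is never returned. The transform maps `pred` coordinates onto
#' the `ref` frame: `x' = R x + t`.
#'
#' @param ref,pred `tree_graph`s with identical vertex label sets.
#' @return List with `rotation` (3x3, det +1) and `translation` (length 3).
#' @export
superpose <- function(ref, pred) {
  labels <- match_vertices(ref, pred)
  kabsch(graph_coords(ref, labels), graph_coords(pred, labels))
}

#' Least-squares rigid superposition of two point sets (Kabsch)
#'
#' Rows of `P` are matched to rows of `Q`; both are centred, the optimal
#' proper rotation comes from the SVD of the covariance (smallest singular
#' direction flipped when the raw optimum is a reflection), and the RMSD of
#' the fit is returned alongside the transform `x' = R x + t` mapping `P`
#' onto `Q`.
#'
#' @param Q,P Matched coordinate matrices (m x 3).
#' @return List: `rotation`, `translation`, `rmsd`.
#' @export
kabsch <- function(Q, P) {
  stopifnot(nrow(Q) == nrow(P), ncol(Q) == 3L, ncol(P) == 3L)
  cq <- colMeans(Q); cp <- colMeans(P)
  Q0 <- sweep(Q, 2L, cq)
  P0 <- sweep(P, 2L, cp)
  H <- crossprod(P0, Q0)          # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)     # x' = R x, proper rotation
  t <- as.numeric(cq - R %*% cp)
  list(rotation = R, translation = t,
       rmsd = sqrt(mean(rowSums((P0 %*% t(R) - Q0)^2))))
}

#' Apply a rigid transform to a graph
#'
#' @param g A `tree_graph`.
#' @param transform List with `rotation` and `translation` (as returned by
#'   [superpose()]).
#' @return Transformed `tree_graph`.
#' @export
apply_transform <- function(g, transform) {
  xyz <- graph_coords(g)
  new <- t(transform$rotation %*% t(xyz) + transform$translation)
  g$vertices[, c("x", "y", "z")] <- new
  g
}

#' Compare two tree graphs with RMSD and MaxAngle
#'
#' RMSD is the root mean squared vertex distance over all 2n+1 matched
#' vertices after the RMSD-optimal superposition; MaxAngle is the largest
#' angle between corresponding helix edge vectors (oriented proximal to
#' distal) evaluated in that same superposed frame.
#'
#' @param ref,pred `tree_graph`s with identical vertex label sets.
#' @return Object of class `graph_comparison`: `rmsd` (Å), `max_angle`
#'   (degrees), `rotation`, `translation`, `correspondence`, and the
#'   per-edge `edge_angles`.
#' @export
compare_graphs <- function(ref, pred) {
  labels <- match_vertices(ref, pred)
  tf <- superpose(ref, pred)
  al <- apply_transform(pred, tf)
  Q <- graph_coords(ref, labels)
  P <- graph_coords(al, labels)
  rmsd <- sqrt(mean(rowSums((Q - P)^2)))
  er <- helix_edge_vectors(ref)
  ep <- helix_edge_vectors(al)
  ep <- ep[rownames(er), , drop = FALSE]
  nr <- sqrt(rowSums(er^2)); np <- sqrt(rowSums(ep^2))
  if (any(nr < 1e-12) || any(np < 1e-12))
    stop("zero-length helix edge; angle undefined")
  cosang <- pmin(1, pmax(-1, rowSums(er * ep) / (nr * np)))
  angles <- stats::setNames(acos(cosang) * 180 / pi, rownames(er))
  structure(list(rmsd = rmsd, max_angle = max(angles),
                 edge_angles = angles, rotation = tf$rotation,
                 translation = tf$translation, correspondence = labels),
            class = "graph_comparison")
}

#' @export
print.graph_comparison <- function(x, ...) {
  cat(sprintf("graph comparison: RMSD %.2f Å, MaxAngle %.2f°\n",
              x$rmsd, x$max_angle))
  invisible(x)
}

#' @rdname compare_graphs
#' @export
graph_rmsd <- function(ref, pred) compare_graphs(ref, pred)$rmsd

#' @rdname compare_graphs
#' @export
graph_max_angle <- function(ref, pred) compare_graphs(ref, pred)$max_angle
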