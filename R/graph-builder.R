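# Scaled planar tree graphs for junctions. An n-way junction graph has
# 2n+1 labeled vertices (proximal + distal per helix, one centroid) and 2n
# edges (n helix edges, n centroid connectors); model graphs are built in
# the z = 0 plane.

#' Knowledge-based scaling parameters
#'
#' Distance parameters derived from graphs of solved junction structures:
#' the coaxial-stack gap regression `s0 = 2.75 L + 3.91` (Å, L in nt), the
#' helix edge length `2.87 (b - 1)` (Å, b in bp, 2.87 Å = base rise), and
#' the mean separations of parallel (20.48 Å), perpendicular (19.95 Å) and
#' diagonal (21.17 Å) unstacked-helix arrangements from the stack axis.
#' Arrangement angles relative to the stack axis are 0, 90 and 45 degrees.
#'
#' @param ... Named overrides of the defaults.
#' @return List of class `scaling_parameters`.
#' @export
scaling_parameters <- function(...) {
  p <- list(s0_slope = 2.75, s0_intercept = 3.91, base_rise = 2.87,
            d_parallel = 20.48, d_perpendicular = 19.95, d_diagonal = 21.17,
            angle_parallel = 0, angle_perpendicular = 90, angle_diagonal = 45)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) stop("unknown parameter(s): ",
                            paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  dists <- unlist(p[c("s0_slope", "s0_intercept", "base_rise", "d_parallel",
                      "d_perpendicular", "d_diagonal")])
  if (any(dists <= 0)) stop("distance parameters must be positive")
  angs <- unlist(p[c("angle_parallel", "angle_perpendicular",
                     "angle_diagonal")])
  if (any(angs < 0 | angs > 180)) stop("angles must lie in [0, 180] degrees")
  structure(p, class = "scaling_parameters")
}

#' Gap between coaxially stacked helices
#'
#' `s0 = 2.75 L + 3.91` Å where `L` is the number of intervening loop
#' nucleotides between the two stacked helices.
#'
#' @param L Non-negative integer nucleotide count.
#' @param params A [scaling_parameters()] list.
#' @return Distance in Å.
#' @export
coaxial_spacing <- function(L, params = scaling_parameters()) {
  if (any(L < 0)) stop("L must be non-negative")
  params$s0_slope * L + params$s0_intercept
}

#' Helix edge length
#'
#' `2.87 (b - 1)` Å for a helix of `b` base pairs (2.87 Å per base-pair
#' step).
#'
#' @param b Base-pair count, at least 2 (a single pair is not a helix).
#' @inheritParams coaxial_spacing
#' @return Length in Å.
#' @export
helix_edge_length <- function(b, params = scaling_parameters()) {
  if (any(b < 2)) stop("a helix requires b >= 2 base pairs")
  params$base_rise * (b - 1)
}

#' Unstacked-helix arrangement distance
#'
#' Mean perpendicular distance from the unstacked helix's proximal vertex
#' to the coaxial-stack axis, by arrangement class.
#'
#' @param class `"parallel"`, `"perpendicular"` or `"diagonal"`.
#' @inheritParams coaxial_spacing
#' @return Distance in Å.
#' @export
arrangement_distance <- function(class, params = scaling_parameters()) {
  vapply(class, function(cl)
    switch(cl,
           parallel = params$d_parallel,
           perpendicular = params$d_perpendicular,
           diagonal = params$d_diagonal,
           stop("unknown arrangement class: ", cl)),
    0)
}

arrangement_angle <- function(class, params = scaling_parameters()) {
  vapply(class, function(cl)
    switch(cl,
           parallel = params$angle_parallel,
           perpendicular = params$angle_perpendicular,
           diagonal = params$angle_diagonal,
           stop("unknown arrangement class: ", cl)),
    0)
}

#' Construct a tree graph
#'
#' Validates the vertex/edge law (2n+1 vertices, 2n edges), label scheme
#' (`Hip`/`Hid` per helix plus centroid `C`) and, unless `recenter = FALSE`
#' recomputes the centroid as the mean of the proximal vertices.
#'
#' @param vertices Data frame with columns `label`, `role`
#'   (`proximal`/`distal`/`centroid`), `helix`, `x`, `y`, `z`.
#' @param edges Data frame with columns `from`, `to`, `type`
#'   (`helix`/`connector`), `helix`, `bp`.
#' @param recenter Recompute the centroid vertex from the proximal ones.
#' @return Object of class `tree_graph`.
#' @export
tree_graph <- function(vertices, edges, recenter = TRUE) {
  n <- sum(vertices$role == "proximal")
  if (n < 1L) stop("graph has no proximal vertices")
  if (nrow(vertices) != 2L * n + 1L)
    stop("an n-way graph needs 2n+1 vertices; got ", nrow(vertices),
         " for n = ", n)
  if (nrow(edges) != 2L * n)
    stop("an n-way graph needs 2n edges; got ", nrow(edges))
  if (sum(vertices$role == "centroid") != 1L)
    stop("exactly one centroid vertex required")
  if (anyDuplicated(vertices$label)) stop("duplicate vertex labels")
  if (!all(c(edges$from, edges$to) %in% vertices$label))
    stop("edge endpoint not among vertex labels")
  if (sum(edges$type == "helix") != n || sum(edges$type == "connector") != n)
    stop("expected n helix edges and n connector edges")
  if (recenter) {
    prox <- vertices[vertices$role == "proximal", c("x", "y", "z")]
    vertices[vertices$role == "centroid", c("x", "y", "z")] <-
      colMeans(prox)
  }
  rownames(vertices) <- rownames(edges) <- NULL
  structure(list(vertices = vertices, edges = edges, n = n),
            class = "tree_graph")
}

#' @export
print.tree_graph <- function(x, ...) {
  cat(sprintf("tree graph: %d-way junction, %d vertices, %d edges\n",
              x$n, nrow(x$vertices), nrow(x$edges)))
  invisible(x)
}

graph_coords <- function(g, labels = NULL) {
  v <- g$vertices
  if (!is.null(labels)) v <- v[match(labels, v$label), , drop = FALSE]
  m <- as.matrix(v[, c("x", "y", "z")])
  rownames(m) <- v$label
  m
}

#' Helix edge vectors (proximal to distal)
#'
#' @param g A `tree_graph`.
#' @return Matrix with one row per helix edge, rownames = helix labels.
#' @export
helix_edge_vectors <- function(g) {
  he <- g$edges[g$edges$type == "helix", , drop = FALSE]
  he <- he[order(he$helix), , drop = FALSE]
  from <- graph_coords(g, he$from)
  to <- graph_coords(g, he$to)
  m <- to - from
  rownames(m) <- he$helix
  m
}

# assemble a tree_graph from per-helix proximal/distal coordinate rows
assemble_graph <- function(prox, dist, bp, recenter = TRUE) {
  n <- nrow(prox)
  labels <- paste0("H", seq_len(n))
  vertices <- data.frame(
    label = c(paste0(labels, "p"), paste0(labels, "d"), "C"),
    role = c(rep("proximal", n), rep("distal", n), "centroid"),
    helix = c(labels, labels, NA),
    x = c(prox[, 1L], dist[, 1L], mean(prox[, 1L])),
    y = c(prox[, 2L], dist[, 2L], mean(prox[, 2L])),
    z = c(prox[, 3L], dist[, 3L], mean(prox[, 3L])),
    stringsAsFactors = FALSE)
  edges <- data.frame(
    from = c(paste0(labels, "p"), rep("C", n)),
    to = c(paste0(labels, "d"), paste0(labels, "p")),
    type = c(rep("helix", n), rep("connector", n)),
    helix = c(labels, labels),
    bp = c(bp, rep(NA, n)),
    stringsAsFactors = FALSE)
  tree_graph(vertices, edges, recenter = recenter)
}

#' Perpendicular distance from a helix's proximal vertex to a stack axis
#'
#' Measures, in a built or translated graph, the distance from the proximal
#' vertex of `helix` to the line through the two proximal vertices of the
#' stacked pair (the coaxial-stack axis). This is the geometric quantity
#' the arrangement-distance parameters describe.
#'
#' @param g A `tree_graph`.
#' @param stack Integer pair of stacked helix numbers, e.g. `c(1, 2)`, or a
#'   label like `"H1H2"`.
#' @param helix Helix number whose proximal vertex is measured.
#' @return Distance in Å.
#' @export
stack_axis_distance <- function(g, stack, helix) {
  if (is.character(stack)) stack <- parse_stack_label(stack)[1L, ]
  a <- graph_coords(g, paste0("H", stack[1L], "p"))[1L, ]
  b <- graph_coords(g, paste0("H", stack[2L], "p"))[1L, ]
  p <- graph_coords(g, paste0("H", helix, "p"))[1L, ]
  u <- b - a
  un <- sqrt(sum(u^2))
  if (un < 1e-12) stop("degenerate stack axis")
  u <- u / un
  w <- p - a
  sqrt(max(0, sum(w^2) - sum(w * u)^2))
}

rot2d <- function(deg) {
  th <- deg * pi / 180
  c(cos(th), sin(th))
}

#' Build a scaled planar model graph for a junction
#'
#' Coaxially stacked helices are laid antiparallel and collinear along the
#' x axis with a proximal-vertex gap of [coaxial_spacing()] over the
#' intervening loop; unstacked helices sit at their class's
#' [arrangement_distance()] from the stack axis with the helix edge at the
#' class angle (0/45/90 degrees); helix edge lengths follow
#' [helix_edge_length()]; the centroid is the mean of the proximal
#' vertices; everything lies in the z = 0 plane.
#'
#' @param j An `rna_junction`, or a list with `degree`, `bp` (helix
#'   base-pair counts) and `loop_lengths`.
#' @param topology A [junction_topology()] of matching degree.
#' @param params [scaling_parameters()].
#' @param side_sign +1 or -1: which side of the stack axis unstacked
#'   helices occupy (handedness convention matching the translation
#'   module).
#' @param template Optional [derive_family_template()] entry overriding the
#'   committed 4-way geometry.
#' @return A planar `tree_graph`.
#' @export
build_graph <- function(j, topology, params = scaling_parameters(),
                        side_sign = 1, template = NULL) {
  spec <- as_junction_spec(j)
  n <- spec$degree
  if (n != topology$degree)
    stop("topology degree ", topology$degree,
         " does not match junction degree ", n)
  if (NROW(topology$pairs) && any(topology$pairs > n))
    stop("topology names helices absent from the junction")
  if (!is.null(template)) return(build_from_template(spec, template))
  len <- helix_edge_length(spec$bp, params)
  prox <- matrix(0, n, 3L)
  dir <- matrix(0, n, 3L)
  place_stack <- function(pair, origin, axis) {
    # axis: unit 2D vector of the stack direction; first helix of `pair`
    # points along -axis, second along +axis
    L <- spec$loop_lengths[intervening_loop(pair[1L], pair[2L], n)]
    s0 <- coaxial_spacing(L, params)
    a <- pair[1L]; b <- pair[2L]
    prox[a, 1:2] <<- origin - axis * s0 / 2
    dir[a, 1:2] <<- -axis
    prox[b, 1:2] <<- origin + axis * s0 / 2
    dir[b, 1:2] <<- axis
  }
  place_unstacked <- function(h, class, sgn) {
    d <- arrangement_distance(class, params)
    ang <- arrangement_angle(class, params)
    prox[h, 1:2] <<- c(0, sgn * d)
    v <- rot2d(ang)
    dir[h, 1:2] <<- c(v[1L], sgn * v[2L])
  }
  prs <- topology$pairs
  nstack <- NROW(prs)
  if (n == 3L) {
    if (nstack == 1L) {
      place_stack(prs[1L, ], c(0, 0), c(1, 0))
      un <- setdiff(1:3, prs[1L, ])
      class <- THREEWAY_ARRANGEMENT[[topology$family]]
      place_unstacked(un, class, side_sign)
    } else {
      # no coaxial stack: radial placement at the perpendicular distance
      d <- params$d_perpendicular
      for (q in 1:3) {
        phi <- (90 + 120 * (q - 1)) * pi / 180
        u <- c(cos(phi), sin(phi))
        prox[q, 1:2] <- d * u
        dir[q, 1:2] <- u
      }
    }
  } else {
    entry <- FOURWAY_TABLE[[topology$family]]
    if (is.null(entry)) stop("unknown 4-way family: ", topology$family)
    if (nstack == 2L) {
      geo <- entry$geometry
      place_stack(prs[1L, ], c(0, 0), c(1, 0))
      if (geo == "parallel") {
        place_stack(prs[2L, ], c(0, side_sign * params$d_parallel), c(1, 0))
      } else {
        ang <- if (geo == "perpendicular") 90 else 45
        place_stack(prs[2L, ], c(0, 0),
                    { v <- rot2d(ang); c(v[1L], side_sign * v[2L]) })
      }
    } else if (nstack == 1L) {
      place_stack(prs[1L, ], c(0, 0), c(1, 0))
      un <- setdiff(1:4, prs[1L, ])
      classes <- entry$unstacked
      place_unstacked(un[1L], classes[1L], side_sign)
      place_unstacked(un[2L], classes[2L], -side_sign)
    } else {
      stop("a 4-way model graph requires at least one coaxial stack")
    }
  }
  dist <- prox + dir * len
  assemble_graph(prox, dist, spec$bp)
}

as_junction_spec <- function(j) {
  if (inherits(j, "rna_junction")) {
    list(degree = j$degree, bp = j$helices$bp,
         loop_lengths = vapply(j$loops, `[[`, 0L, "length"))
  } else {
    stopifnot(is.list(j), all(c("degree", "bp", "loop_lengths") %in% names(j)))
    j
  }
}

build_from_template <- function(spec, template) {
  n <- spec$degree
  if (nrow(template$directions) != n)
    stop("template degree does not match junction")
  len <- helix_edge_length(spec$bp)
  prox <- template$proximal
  dist <- prox + template$directions * len
  assemble_graph(prox, dist, spec$bp)
}

#' Derive empirical family templates from native graphs
#'
#' Superposes all graphs of a family onto the first one and averages the
#' proximal vertex positions and unit helix-edge directions per helix slot.
#' Slots whose averaged direction nearly cancels (mean vector shorter than
#' half a unit) are flagged degenerate with a warning.
#'
#' @param graphs List of `tree_graph`s.
#' @param families Character vector of family labels, one per graph.
#' @return Named list of templates: `proximal` (n x 3), `directions`
#'   (n x 3, unit rows), `degenerate` (logical per helix).
#' @export
derive_family_template <- function(graphs, families) {
  stopifnot(length(graphs) == length(families))
  if (length(graphs) == 0L) stop("no graphs supplied")
  out <- list()
  for (fam in unique(families)) {
    gs <- graphs[families == fam]
    ref <- gs[[1L]]
    pr_sum <- matrix(0, ref$n, 3L)
    dir_sum <- matrix(0, ref$n, 3L)
    for (g in gs) {
      tf <- superpose(ref, g)
      al <- apply_transform(g, tf)
      prox <- graph_coords(al)[paste0("H", seq_len(ref$n), "p"), , drop = FALSE]
      ev <- helix_edge_vectors(al)
      ev <- ev / sqrt(rowSums(ev^2))
      pr_sum <- pr_sum + prox
      dir_sum <- dir_sum + ev
    }
    prox <- pr_sum / length(gs)
    dirs <- dir_sum / length(gs)
    norms <- sqrt(rowSums(dirs^2))
    degen <- norms < 0.5
    if (any(degen))
      warning("family ", fam, ": degenerate mean direction for helix ",
              paste(which(degen), collapse = ","))
    dirs[!degen, ] <- dirs[!degen, , drop = FALSE] / norms[!degen]
    out[[fam]] <- list(family = fam, proximal = prox, directions = dirs,
                       degenerate = degen)
  }
  out
}

#' Write / read a tree graph as JSON
#'
#' @param g A `tree_graph`.
#' @param path File path.
#' @export
write_graph_json <- function(g, path) {
  obj <- list(vertices = g$vertices, edges = g$edges)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_graph_json
#' @export
read_graph_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  v <- obj$vertices
  e <- obj$edges
  v$helix[v$role == "centroid"] <- NA
  if (is.null(e$bp)) e$bp <- NA
  e$bp[e$type == "connector"] <- NA
  tree_graph(v, e, recenter = FALSE)
}

#' Write a pseudo-PDB rendering of a graph (one pseudo-atom per vertex)
#'
#' @param g A `tree_graph`.
#' @param path File path.
#' @export
write_graph_pdb <- function(g, path) {
  v <- g$vertices
  lines <- sprintf(
    "HETATM%5d  %-3s GRA A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
    seq_len(nrow(v)), ifelse(v$role == "centroid", "C", "P"),
    seq_len(nrow(v)), v$x, v$y, v$z)
  idx <- function(lab) match(lab, v$label)
  con <- sprintf("CONECT%5d%5d", idx(g$edges$from), idx(g$edges$to))
  writeLines(c(lines, con, "END"), path)
  invisible(path)
}
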