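# Junction topology: coaxial-stack sets and family labels, plus the
# committed family <-> stack/arrangement tables used by both the synthetic
# data generator and the graph builder.

THREEWAY_FAMILIES <- c("A", "B", "C", "none")
FOURWAY_FAMILIES <- c("H", "cH", "cL", "cK", "pi", "cW", "Psi", "cX", "X")

# Arrangement of the unstacked helix in a 3-way junction, per family.
# C is parallel (stated in the source analysis of family C packing);
# A = perpendicular and B = diagonal are committed here.
THREEWAY_ARRANGEMENT <- c(A = "perpendicular", B = "diagonal", C = "parallel")

# Committed 4-way table. Two-stack families carry the angle between the two
# stack axes; single-stack families carry the arrangement class of each of
# the two unstacked helices (in increasing helix order). The published
# schematics draw these families without numeric angles, so the geometry
# column is an implementation commitment (see the methods vignette).
FOURWAY_TABLE <- list(
  H   = list(stacks = c("H1H2", "H3H4"), geometry = "parallel"),
  cH  = list(stacks = c("H1H4", "H2H3"), geometry = "parallel"),
  cL  = list(stacks = c("H1H4", "H2H3"), geometry = "perpendicular"),
  cX  = list(stacks = c("H1H2", "H3H4"), geometry = "diagonal"),
  X   = list(stacks = c("H1H4", "H2H3"), geometry = "diagonal"),
  pi  = list(stacks = "H1H2", unstacked = c("parallel", "perpendicular")),
  cW  = list(stacks = "H2H3", unstacked = c("perpendicular", "perpendicular")),
  Psi = list(stacks = "H3H4", unstacked = c("parallel", "parallel")),
  cK  = list(stacks = "H1H4", unstacked = c("diagonal", "diagonal"))
)

#' Canonical label for a coaxial-stack set
#'
#' @param stacks Character vector of stacks (each like `"H1H2"` or
#'   `"H2H1"`), possibly empty.
#' @return Single string, e.g. `"H1H2"`, `"H1H4+H2H3"`, or `"none"`.
#' @export
stack_label <- function(stacks) {
  if (length(stacks) == 0L || identical(stacks, "none")) return("none")
  stacks <- unlist(strsplit(stacks, "+", fixed = TRUE))  # idempotent
  norm <- vapply(stacks, function(s) {
    h <- sort(as.integer(regmatches(s, gregexpr("[0-9]+", s))[[1]]))
    if (length(h) != 2L) stop("malformed stack label: ", s)
    paste0("H", h[1L], "H", h[2L])
  }, "")
  paste(sort(unname(norm)), collapse = "+")
}

parse_stack_label <- function(label) {
  if (label == "none" || label == "") return(matrix(integer(0), ncol = 2L))
  parts <- strsplit(label, "+", fixed = TRUE)[[1]]
  t(vapply(parts, function(s)
    as.integer(regmatches(s, gregexpr("[0-9]+", s))[[1]]), integer(2)))
}

#' Construct a junction topology (stack set + family)
#'
#' Validates the type invariants: stacks are disjoint helix pairs within the
#' junction degree; 3-way junctions carry at most one stack and a family in
#' A/B/C (or `"none"` for unstacked junctions), 4-way junctions at most two
#' stacks and one of the nine 4-way families.
#'
#' @param stacks Character vector of stacks or a single collapsed label.
#' @param family Family label.
#' @param degree Junction degree (3 or 4).
#' @return Object of class `junction_topology` with elements `stacks`
#'   (canonical label), `pairs` (matrix), `family`, `degree`.
#' @export
junction_topology <- function(stacks, family, degree) {
  degree <- as.integer(degree)
  if (!degree %in% c(3L, 4L)) stop("unsupported junction degree: ", degree)
  label <- stack_label(stacks)
  prs <- parse_stack_label(label)
  if (NROW(prs)) {
    if (any(prs < 1L | prs > degree))
      stop("stack names a helix outside H1..H", degree)
    if (anyDuplicated(c(prs)))
      stop("stacks are not disjoint: ", label)
  }
  maxstack <- if (degree == 3L) 1L else 2L
  if (NROW(prs) > maxstack)
    stop(degree, "-way junction admits at most ", maxstack, " stack(s)")
  fams <- if (degree == 3L) THREEWAY_FAMILIES else FOURWAY_FAMILIES
  if (!family %in% fams)
    stop("unknown ", degree, "-way family: ", family)
  if (degree == 3L && family == "none" && NROW(prs) > 0L)
    stop("family 'none' requires an empty stack set")
  structure(list(stacks = label, pairs = prs, family = family,
                 degree = degree),
            class = "junction_topology")
}

#' @export
print.junction_topology <- function(x, ...) {
  cat(sprintf("%d-way topology: stacks %s, family %s\n",
              x$degree, x$stacks, x$family))
  invisible(x)
}

#' Topology implied by a 4-way family under the committed table
#'
#' @param family One of the nine 4-way family labels.
#' @return `junction_topology` for degree 4.
#' @export
fourway_topology <- function(family) {
  entry <- FOURWAY_TABLE[[family]]
  if (is.null(entry)) stop("unknown 4-way family: ", family)
  junction_topology(entry$stacks, family, 4L)
}
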