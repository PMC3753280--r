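# Ideal-helix and composed-junction generators. Fixtures, not physical
# models: only the atoms the pipeline consumes are emitted (C1', purine
# C8/N1, pyrimidine C6/N3; plain C1' spacers for loop residues), laid out
# so that every base-pair vertex O' falls exactly on the helical axis and
# consecutive pairs are one base rise (2.87 Å, matching the helix edge
# parameterization) apart.

helix_frame <- function(origin, direction) {
  e3 <- direction / sqrt(sum(direction^2))
  tmp <- if (abs(e3[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- tmp - sum(tmp * e3) * e3
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(e3[2L] * e1[3L] - e3[3L] * e1[2L],
          e3[3L] * e1[1L] - e3[1L] * e1[3L],
          e3[1L] * e1[2L] - e3[2L] * e1[1L])
  list(R = cbind(e1, e2, e3), origin = origin)
}

frame_apply <- function(frame, xyz) {
  sweep(xyz %*% t(frame$R), 2L, frame$origin, `+`)
}

pair_is_purine_first <- function(letters2)
  substr(letters2, 1L, 1L) %in% PURINES

# atoms of one base pair in the local helix frame (axis = z through origin)
local_pair_atoms <- function(letters2, z, theta) {
  s <- if (pair_is_purine_first(letters2)) 1 else -1
  rot <- matrix(c(cos(theta), sin(theta), 0,
                  -sin(theta), cos(theta), 0, 0, 0, 1), 3L, 3L)
  pts <- rbind(c(4, 5.2, 0),          # C1' strand 1
               c(4, -5.2, 0),         # C1' strand 2
               c(1, 2.9 * s, 0),      # purine C8
               c(1, 1.4 * s, 0),      # purine N1
               c(1, -2.9 * s, 0),     # pyrimidine C6
               c(1, -1.4 * s, 0))     # pyrimidine N3
  pts <- pts %*% t(rot)
  pts[, 3L] <- z
  pts
}

pair_atom_rows <- function(letters2, res1, res2, chain1, chain2, pts) {
  l1 <- substr(letters2, 1L, 1L); l2 <- substr(letters2, 2L, 2L)
  pur_first <- pair_is_purine_first(letters2)
  prow <- function(chain, resnum, resname, atom, p)
    data.frame(chain = chain, resnum = resnum, icode = "", resname = resname,
               atom = atom, x = p[1L], y = p[2L], z = p[3L],
               stringsAsFactors = FALSE)
  base1 <- if (pur_first) list(c8n1 = TRUE) else list(c8n1 = FALSE)
  rows <- list(prow(chain1, res1, l1, "C1'", pts[1L, ]),
               prow(chain2, res2, l2, "C1'", pts[2L, ]))
  if (pur_first) {
    rows <- c(rows, list(prow(chain1, res1, l1, "C8", pts[3L, ]),
                         prow(chain1, res1, l1, "N1", pts[4L, ]),
                         prow(chain2, res2, l2, "C6", pts[5L, ]),
                         prow(chain2, res2, l2, "N3", pts[6L, ])))
  } else {
    rows <- c(rows, list(prow(chain2, res2, l2, "C8", pts[3L, ]),
                         prow(chain2, res2, l2, "N1", pts[4L, ]),
                         prow(chain1, res1, l1, "C6", pts[5L, ]),
                         prow(chain1, res1, l1, "N3", pts[6L, ])))
  }
  do.call(rbind, rows)
}

#' Generate an ideal duplex helix
#'
#' Builds `b` Watson-Crick pairs with the helical axis along the frame's
#' z direction, one base rise apart and twisted per step. The construction
#' places every base-pair vertex (as recovered by [basepair_vertex()])
#' exactly on the axis, so the graph edge of the helix has length
#' `rise * (b - 1)` and direction equal to the axis.
#'
#' @param b Number of base pairs (>= 2).
#' @param pair_letters Character vector of `b` two-letter pair codes
#'   (strand-1 letter first); defaults to a GC/CG alternation.
#' @param rise Axial displacement per pair step (Å).
#' @param twist Helical twist per step (degrees).
#' @param origin,direction Rigid placement of the axis.
#' @param chains Chain ids of the two strands.
#' @return An `atom_table`; pair k joins chain-1 residue k with chain-2
#'   residue `b - k + 1`.
#' @export
ideal_helix <- function(b, pair_letters = NULL, rise = 2.87, twist = 32.7,
                        origin = c(0, 0, 0), direction = c(0, 0, 1),
                        chains = c("A", "B")) {
  b <- as.integer(b)
  if (b < 2L) stop("a helix requires at least 2 base pairs")
  if (is.null(pair_letters))
    pair_letters <- rep_len(c("GC", "CG"), b)
  if (length(pair_letters) != b) stop("need one pair code per base pair")
  if (!all(pair_letters %in% CANONICAL_PAIRS))
    stop("pair codes must be canonical (AU/UA/GC/CG/GU/UG)")
  fr <- helix_frame(origin, direction)
  rows <- vector("list", b)
  for (m in 0:(b - 1L)) {
    pts <- local_pair_atoms(pair_letters[m + 1L], m * rise,
                            m * twist * pi / 180)
    pts <- frame_apply(fr, pts)
    rows[[m + 1L]] <- pair_atom_rows(pair_letters[m + 1L],
                                     res1 = m + 1L, res2 = b - m,
                                     chains[1L], chains[2L], pts)
  }
  at <- do.call(rbind, rows)
  at <- at[order(at$chain, at$resnum), , drop = FALSE]  # strand-wise order
  rownames(at) <- NULL
  class(at) <- c("atom_table", "data.frame")
  at
}

#' Terminal-pair vertices of a lone helix structure
#'
#' Convenience for geometry checks: detects (or accepts) the base pairs,
#' takes the maximal stacked run, and returns the two terminal vertices.
#'
#' @param atoms An `atom_table` containing one duplex.
#' @param pairs Optional annotation table.
#' @return 2 x 3 matrix (rows: first and last pair vertex).
#' @export
helix_vertices <- function(atoms, pairs = NULL) {
  sec <- structure_secondary(atoms, pairs)
  hx <- find_helices(sec$ss)
  if (nrow(hx) == 0L) stop("no helix (>= 2 stacked pairs) found")
  h <- hx[which.max(hx$bp), ]
  outer <- try_pair_vertex(atoms, sec$res, c(h$i1, h$j1))
  inner <- try_pair_vertex(atoms, sec$res,
                           c(h$i1 + h$bp - 1L, h$j1 - h$bp + 1L))
  if (is.null(outer) || is.null(inner)) stop("terminal pair atoms missing")
  rbind(outer, inner)
}

default_pair_letters <- function(b) rep_len(c("GC", "CG"), b)

#' Compose an atomic junction structure from a tree-graph blueprint
#'
#' Each helix of the blueprint is realized as an [ideal_helix()] rigidly
#' placed so its axis runs along the blueprint's helix edge (proximal
#' vertex to distal vertex); junction-loop and hairpin-cap residues are
#' emitted as plain C1' spacers. The residue numbering follows a single
#' chain laid out 5' to 3' through the junction (closing helix strand,
#' then branch hairpins and loops), and the ground-truth base-pair
#' annotation plus the implied secondary structure are returned alongside
#' the atoms.
#'
#' @param blueprint A `tree_graph` whose helix edges carry `bp` counts.
#' @param loop_lengths Integer vector of junction loop lengths (nt), one
#'   per helix (loop Li follows helix Hi).
#' @param pair_letters Optional list of per-helix pair-code vectors.
#' @param hairpin_len Spacer residues capping each branch helix.
#' @param rise,twist Helix geometry (defaults match the edge-length
#'   parameterization, so blueprint edges from [build_graph()] are
#'   compatible by construction).
#' @return List: `atoms`, `ss` (an `rna_ss`), `pairs` (annotation table),
#'   `blueprint`.
#' @export
synthesize_junction <- function(blueprint, loop_lengths,
                                pair_letters = NULL, hairpin_len = 4L,
                                rise = 2.87, twist = 32.7) {
  n <- blueprint$n
  stopifnot(length(loop_lengths) == n)
  he <- blueprint$edges[blueprint$edges$type == "helix", , drop = FALSE]
  he <- he[order(he$helix), , drop = FALSE]
  bp <- as.integer(he$bp)
  if (anyNA(bp)) stop("blueprint helix edges must carry bp counts")
  if (is.null(pair_letters))
    pair_letters <- lapply(bp, default_pair_letters)
  prox <- graph_coords(blueprint, paste0("H", seq_len(n), "p"))
  dist <- graph_coords(blueprint, paste0("H", seq_len(n), "d"))
  # consistency: blueprint edge length must match rise * (bp - 1)
  for (q in seq_len(n)) {
    elen <- sqrt(sum((dist[q, ] - prox[q, ])^2))
    want <- rise * (bp[q] - 1L)
    if (abs(elen - want) > 0.05 * max(want, 1))
      stop("blueprint edge H", q, " (", round(elen, 2),
           " Å) incompatible with ", bp[q], " bp at rise ", rise)
  }
  # --- sequence layout (single chain, 1-based positions) ---------------
  N <- sum(bp) * 2L + sum(loop_lengths) + (n - 1L) * hairpin_len
  seqletters <- rep("A", N)
  helix5 <- integer(n)   # start of 5' strand per helix
  helix3 <- integer(n)   # start of 3' strand (ascending) per helix
  pos <- 1L
  helix5[1L] <- pos; pos <- pos + bp[1L]
  loop_pos <- vector("list", n)
  hairpin_pos <- vector("list", n)
  for (i in seq_len(n)) {
    if (i > 1L) {
      helix5[i] <- pos; pos <- pos + bp[i]
      hairpin_pos[[i]] <- seq_len(hairpin_len) + pos - 1L
      pos <- pos + hairpin_len
      helix3[i] <- pos; pos <- pos + bp[i]
    }
    loop_pos[[i]] <- if (loop_lengths[i] > 0L)
      seq_len(loop_lengths[i]) + pos - 1L else integer(0)
    pos <- pos + loop_lengths[i]
  }
  helix3[1L] <- pos
  stopifnot(pos + bp[1L] - 1L == N)
  pair_idx <- vector("list", n)
  for (i in seq_len(n)) {
    k <- 0:(bp[i] - 1L)
    pair_idx[[i]] <- if (i == 1L)
      cbind(helix5[1L] + k, N - k)                      # outermost first
    else cbind(helix5[i] + k, helix3[i] + bp[i] - 1L - k)
    lets <- pair_letters[[i]]
    if (length(lets) != bp[i]) stop("pair_letters length mismatch, helix ", i)
    seqletters[pair_idx[[i]][, 1L]] <- substr(lets, 1L, 1L)
    seqletters[pair_idx[[i]][, 2L]] <- substr(lets, 2L, 2L)
  }
  # --- atoms ------------------------------------------------------------
  rows <- list()
  for (i in seq_len(n)) {
    u <- dist[i, ] - prox[i, ]
    fr <- helix_frame(prox[i, ], u)
    # order pairs proximal -> distal: closing helix H1 is entered from its
    # innermost pair, branch helices from their outermost pair
    ord <- if (i == 1L) rev(seq_len(bp[i])) else seq_len(bp[i])
    for (m in seq_along(ord)) {
      pr <- pair_idx[[i]][ord[m], ]
      lets <- pair_letters[[i]][ord[m]]
      pts <- frame_apply(fr, local_pair_atoms(lets, (m - 1L) * rise,
                                              (m - 1L) * twist * pi / 180))
      rows[[length(rows) + 1L]] <-
        pair_atom_rows(lets, pr[1L], pr[2L], "A", "A", pts)
    }
  }
  # loop + hairpin spacers: bare C1' beads on segments between anchors
  spacer <- function(positions, from, to) {
    if (!length(positions)) return(NULL)
    tfrac <- seq_along(positions) / (length(positions) + 1L)
    do.call(rbind, lapply(seq_along(positions), function(q) {
      p <- from + tfrac[q] * (to - from) + c(0, 0, 6)
      data.frame(chain = "A", resnum = positions[q], icode = "",
                 resname = seqletters[positions[q]], atom = "C1'",
                 x = p[1L], y = p[2L], z = p[3L], stringsAsFactors = FALSE)
    }))
  }
  for (i in seq_len(n)) {
    nxt <- if (i == n) 1L else i + 1L
    rows[[length(rows) + 1L]] <- spacer(loop_pos[[i]], prox[i, ], prox[nxt, ])
    rows[[length(rows) + 1L]] <-
      spacer(hairpin_pos[[i]], dist[i, ], dist[i, ] + c(4, 4, 4))
  }
  atoms <- do.call(rbind, Filter(Negate(is.null), rows))
  atoms <- atoms[order(atoms$resnum), , drop = FALSE]
  rownames(atoms) <- NULL
  class(atoms) <- c("atom_table", "data.frame")
  pm <- do.call(rbind, pair_idx)
  ann <- data.frame(chain_i = "A", resnum_i = pm[, 1L],
                    chain_j = "A", resnum_j = pm[, 2L],
                    class = vapply(paste0(seqletters[pm[, 1L]],
                                          seqletters[pm[, 2L]]),
                                   function(s) {
                                     s2 <- paste(sort(strsplit(s, "")[[1]]),
                                                 collapse = "")
                                     switch(s2, AU = "AU", CG = "GC",
                                            GU = "GU", s2)
                                   }, ""),
                    stringsAsFactors = FALSE)
  ss <- rna_ss(paste(seqletters, collapse = ""), pm)
  list(atoms = atoms, ss = ss, pairs = ann, blueprint = blueprint)
}
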