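# Translation of solved 3D structures into tree graphs: per terminal base
# pair, a vertex is placed by the three-step midpoint/projection/offset
# construction; helices become edges between their two terminal-pair
# vertices; the junction centroid is the mean of the proximal vertices.

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "U")

residue_key <- function(chain, resnum, icode) {
  paste(chain, resnum, ifelse(is.na(icode) | icode == "", ".", icode),
        sep = "|")
}

# residues in file appearance order, with their atom row indices
residue_table <- function(atoms) {
  key <- residue_key(atoms$chain, atoms$resnum, atoms$icode)
  first <- !duplicated(key)
  data.frame(key = key[first], chain = atoms$chain[first],
             resnum = atoms$resnum[first], icode = atoms$icode[first],
             resname = atoms$resname[first], stringsAsFactors = FALSE)
}

residue_atom <- function(atoms, key, name) {
  k <- residue_key(atoms$chain, atoms$resnum, atoms$icode)
  row <- which(k == key & atoms$atom == name)
  if (!length(row)) return(NULL)
  as.numeric(atoms[row[1L], c("x", "y", "z")])
}

#' Place a graph vertex from the atoms of one base pair
#'
#' Three steps: (1) the midpoint `M` of the two C1' atoms; (2) the
#' orthogonal projection `P` of `M` onto the line through the purine C8 and
#' pyrimidine C6 atoms; (3) the vertex `O' = M + 4 * unit(P - M)`, i.e. `M`
#' displaced exactly 4 Å toward the projection.
#'
#' @param c1p_a,c1p_b C1' coordinates of the two paired residues (length-3
#'   numerics).
#' @param c8 Purine C8 coordinate.
#' @param c6 Pyrimidine C6 coordinate.
#' @return Length-3 numeric vertex position.
#' @export
basepair_vertex <- function(c1p_a, c1p_b, c8, c6) {
  M <- (c1p_a + c1p_b) / 2
  d <- c6 - c8
  dn <- sqrt(sum(d^2))
  if (dn < 1e-9) stop("C8 and C6 atoms coincide; base-pair frame undefined")
  P <- c8 + sum((M - c8) * d) / dn^2 * d
  v <- P - M
  vn <- sqrt(sum(v^2))
  if (vn < 1e-9)
    stop("midpoint lies on the C8-C6 line; projection is degenerate")
  M + 4 * v / vn
}

#' Detect canonical Watson-Crick (and GU wobble) base pairs geometrically
#'
#' Built-in fallback when no external annotation is supplied: candidate
#' pairs must have a C1'-C1' distance of 10.4 +/- 1.5 Å, a purine
#' N1 - pyrimidine N3 distance below 3.5 Å, letters forming AU/GC/GU, and
#' a same-chain sequence separation of at least 3. Each residue keeps only
#' its best-scoring (shortest N1-N3) partner.
#'
#' @param atoms An `atom_table`.
#' @return Data frame with columns `chain_i`, `resnum_i`, `chain_j`,
#'   `resnum_j`, `class` (empty when nothing pairs).
#' @export
detect_wc_pairs <- function(atoms) {
  res <- residue_table(atoms)
  nr <- nrow(res)
  key <- residue_key(atoms$chain, atoms$resnum, atoms$icode)
  coord_of <- function(name) {
    out <- matrix(NA_real_, nr, 3L)
    sel <- atoms$atom == name
    idx <- match(key[sel], res$key)
    out[idx, ] <- as.matrix(atoms[sel, c("x", "y", "z")])
    out
  }
  c1 <- coord_of("C1'")
  n1 <- coord_of("N1")
  n3 <- coord_of("N3")
  empty <- data.frame(chain_i = character(0), resnum_i = integer(0),
                      chain_j = character(0), resnum_j = integer(0),
                      class = character(0))
  cand <- list()
  for (a in seq_len(nr - 1L)) {
    if (anyNA(c1[a, ])) next
    for (b in seq((a + 1L), nr)) {
      if (anyNA(c1[b, ])) next
      if (res$chain[a] == res$chain[b] &&
          abs(res$resnum[a] - res$resnum[b]) < 3L) next
      d11 <- sqrt(sum((c1[a, ] - c1[b, ])^2))
      if (d11 < 8.9 || d11 > 11.9) next
      ra <- res$resname[a]; rb <- res$resname[b]
      cls <- paste0(sort(c(ra, rb)), collapse = "")
      cls <- switch(cls, AU = "AU", CG = "GC", GU = "GU", NA_character_)
      if (is.na(cls)) next
      pur <- if (ra %in% PURINES) a else if (rb %in% PURINES) b else next
      pyr <- if (pur == a) b else a
      if (!res$resname[pyr] %in% PYRIMIDINES) next
      if (anyNA(n1[pur, ]) || anyNA(n3[pyr, ])) next
      hb <- sqrt(sum((n1[pur, ] - n3[pyr, ])^2))
      if (hb >= 3.5) next
      cand[[length(cand) + 1L]] <- c(a, b, hb, cls)
    }
  }
  if (!length(cand)) return(empty)
  cm <- do.call(rbind, cand)
  ord <- order(as.numeric(cm[, 3L]))
  used <- logical(nr)
  keep <- list()
  for (k in ord) {
    a <- as.integer(cm[k, 1L]); b <- as.integer(cm[k, 2L])
    if (used[a] || used[b]) next
    used[a] <- used[b] <- TRUE
    keep[[length(keep) + 1L]] <- data.frame(
      chain_i = res$chain[a], resnum_i = res$resnum[a],
      chain_j = res$chain[b], resnum_j = res$resnum[b],
      class = cm[k, 4L], stringsAsFactors = FALSE)
  }
  do.call(rbind, keep)
}

#' Secondary structure implied by an atom table plus base pairs
#'
#' Residues are ordered by file appearance; annotated pairs are mapped to
#' that ordering; crossing pairs (pseudoknots) are removed.
#'
#' @param atoms An `atom_table`.
#' @param pairs Base-pair annotation data frame (see
#'   [read_basepair_table()]); when NULL, [detect_wc_pairs()] is used.
#' @return List: `ss` (an `rna_ss`), `res` (residue table whose row k is
#'   sequence position k).
#' @export
structure_secondary <- function(atoms, pairs = NULL) {
  res <- residue_table(atoms)
  if (is.null(pairs)) pairs <- detect_wc_pairs(atoms)
  if (nrow(pairs)) {
    ki <- residue_key(pairs$chain_i, pairs$resnum_i,
                      if ("icode_i" %in% names(pairs)) pairs$icode_i else "")
    kj <- residue_key(pairs$chain_j, pairs$resnum_j,
                      if ("icode_j" %in% names(pairs)) pairs$icode_j else "")
    i <- match(ki, res$key); j <- match(kj, res$key)
    if (anyNA(i) || anyNA(j))
      stop("annotation names residues absent from the structure")
    pm <- cbind(i, j)
  } else pm <- NULL
  seqletters <- res$resname
  seqletters[!seqletters %in% c(PURINES, PYRIMIDINES)] <- "N"
  ss <- rna_ss(paste(seqletters, collapse = ""), pm)
  list(ss = remove_pseudoknots(ss), res = res)
}

#' Translate a junction of a solved structure into a tree graph
#'
#' For each junction helix the two terminal base pairs are converted to
#' vertices with [basepair_vertex()] (the proximal vertex comes from the
#' pair nearest the junction loop in sequence) and joined by a helix edge;
#' the centroid vertex is the mean of the n proximal vertices, with a
#' connector edge to each.
#'
#' @param atoms An `atom_table`.
#' @param pairs Optional base-pair annotation (else geometric detection).
#' @param junction Which junction to translate: an `rna_junction` from
#'   [structure_secondary()]'s structure, or an index into the junction
#'   list (default 1).
#' @return A `tree_graph` (typically non-planar, unlike model graphs).
#' @export
structure_to_graph <- function(atoms, pairs = NULL, junction = 1L) {
  sec <- structure_secondary(atoms, pairs)
  if (inherits(junction, "rna_junction")) {
    j <- junction
  } else {
    js <- find_junctions(sec$ss)
    if (length(js) < junction)
      stop("structure has ", length(js), " junction(s); index ", junction,
           " requested")
    j <- js[[junction]]
  }
  n <- j$degree
  prox <- matrix(NA_real_, n, 3L)
  dist <- matrix(NA_real_, n, 3L)
  for (q in seq_len(n)) {
    h <- j$helices[q, ]
    pair_list <- lapply(0:(h$bp - 1L), function(m)
      c(h$i1 + m, h$j1 - m))                     # outermost -> innermost
    # proximal terminal = pair nearest the junction loop in sequence: the
    # innermost pair for the closing helix, the outermost for branch helices
    if (h$closing) pair_list <- rev(pair_list)   # now [proximal ... distal]
    vprox <- usable_vertex(atoms, sec$res, pair_list, j, h$label)
    vdist <- usable_vertex(atoms, sec$res, rev(pair_list), j, h$label)
    prox[q, ] <- vprox
    dist[q, ] <- vdist
  }
  assemble_graph(prox, dist, j$helices$bp)
}

# walk pair_list from its head inward until a pair has all four atoms
usable_vertex <- function(atoms, res, pair_list, j, label) {
  for (pr in pair_list) {
    v <- try_pair_vertex(atoms, res, pr)
    if (!is.null(v)) return(v)
  }
  stop("helix ", label, ": fewer than 2 base pairs with usable atoms")
}

try_pair_vertex <- function(atoms, res, pr) {
  ra <- res[pr[1L], ]; rb <- res[pr[2L], ]
  if (ra$resname %in% PURINES && rb$resname %in% PYRIMIDINES) {
    pur <- ra; pyr <- rb
  } else if (rb$resname %in% PURINES && ra$resname %in% PYRIMIDINES) {
    pur <- rb; pyr <- ra
  } else return(NULL)
  c1a <- residue_atom(atoms, ra$key, "C1'")
  c1b <- residue_atom(atoms, rb$key, "C1'")
  c8 <- residue_atom(atoms, pur$key, "C8")
  c6 <- residue_atom(atoms, pyr$key, "C6")
  if (is.null(c1a) || is.null(c1b) || is.null(c8) || is.null(c6))
    return(NULL)
  basepair_vertex(c1a, c1b, c8, c6)
}

#' Translate every junction of a structure
#'
#' @inheritParams structure_to_graph
#' @return List of `tree_graph`s (empty when the structure has no
#'   junction).
#' @export
native_graphs <- function(atoms, pairs = NULL) {
  sec <- structure_secondary(atoms, pairs)
  js <- find_junctions(sec$ss)
  lapply(js, function(j) structure_to_graph(atoms, pairs, j))
}
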