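# Secondary-structure parsing and decomposition into helices, loops and
# n-way junctions. Indices are 1-based throughout (CT files are 1-based on
# disk already; dot-bracket positions are converted on input).

BRACKET_OPEN  <- c("(", "[", "{", "<")
BRACKET_CLOSE <- c(")", "]", "}", ">")
CANONICAL_PAIRS <- c("AU", "UA", "GC", "CG", "GU", "UG")

#' Construct a secondary-structure object
#'
#' @param sequence Single string over A/C/G/U (T is converted to U).
#' @param pairs Two-column integer matrix of base-pair indices (i < j,
#'   1-based), or NULL for no pairs.
#' @param noncanonical How to treat pairs whose letters are not one of
#'   AU/UA/GC/CG/GU/UG: `"drop"` removes them with a warning, `"error"`
#'   aborts. Only the three canonical pairing types are retained, mirroring
#'   the curation applied to annotated training structures.
#' @return An object of class `rna_ss` with elements `sequence` and `pairs`.
#' @export
rna_ss <- function(sequence, pairs = NULL, noncanonical = c("drop", "error")) {
  noncanonical <- match.arg(noncanonical)
  sequence <- toupper(gsub("\\s", "", sequence))
  sequence <- chartr("T", "U", sequence)
  n <- nchar(sequence)
  if (n > 0L && grepl("[^ACGUN-]", sequence))
    stop("sequence contains letters outside A/C/G/U/N")
  if (is.null(pairs) || NROW(pairs) == 0L) {
    pairs <- matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j")))
  } else {
    pairs <- matrix(as.integer(pairs), ncol = 2L)
    colnames(pairs) <- c("i", "j")
    swap <- pairs[, 1L] > pairs[, 2L]
    pairs[swap, ] <- pairs[swap, 2:1]
    if (any(pairs[, 1L] < 1L) || any(pairs[, 2L] > n))
      stop("pair index out of range")
    if (any(pairs[, 1L] == pairs[, 2L]))
      stop("residue paired with itself")
    idx <- c(pairs)
    if (anyDuplicated(idx))
      stop("a residue participates in more than one pair")
    letters2 <- ss_pair_letters(sequence, pairs)
    bad <- !(letters2 %in% CANONICAL_PAIRS)
    if (any(bad)) {
      if (noncanonical == "error")
        stop("non-canonical base pair(s): ",
             paste(unique(letters2[bad]), collapse = ", "))
      warning(sum(bad), " non-canonical pair(s) dropped")
      pairs <- pairs[!bad, , drop = FALSE]
    }
    pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  }
  structure(list(sequence = sequence, pairs = pairs), class = "rna_ss")
}

ss_pair_letters <- function(sequence, pairs) {
  if (NROW(pairs) == 0L) return(character(0))
  ch <- strsplit(sequence, "")[[1]]
  paste0(ch[pairs[, 1L]], ch[pairs[, 2L]])
}

#' @export
print.rna_ss <- function(x, ...) {
  cat("RNA secondary structure:", nchar(x$sequence), "nt,",
      nrow(x$pairs), "base pairs\n")
  invisible(x)
}

#' Parse a dot-bracket secondary structure
#'
#' Accepts two lines (sequence, bracket string) with an optional leading
#' `">"` header line. The four bracket families `()`, `[]`, `{}`, `<>` are
#' matched independently by per-family stacks, so simple pseudoknots survive
#' parsing and can be removed afterwards with [remove_pseudoknots()].
#'
#' @param text Character vector of lines, or one string with newlines, or a
#'   file path (when `file = TRUE`).
#' @param file Treat `text` as a path.
#' @inheritParams rna_ss
#' @return An `rna_ss` object.
#' @export
parse_dotbracket <- function(text, file = FALSE,
                             noncanonical = c("drop", "error")) {
  if (file) text <- readLines(text, warn = FALSE)
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  text <- trimws(text)
  text <- text[nzchar(text)]
  text <- text[!startsWith(text, ">")]
  if (length(text) == 0L) return(rna_ss("", NULL))
  if (length(text) < 2L)
    stop("dot-bracket input needs a sequence line and a structure line")
  seqline <- text[1L]
  dbline <- text[2L]
  if (nchar(seqline) != nchar(dbline))
    stop("sequence and structure lines differ in length (",
         nchar(seqline), " vs ", nchar(dbline), ")")
  ch <- strsplit(dbline, "")[[1]]
  bad <- setdiff(unique(ch), c(".", "-", ":", BRACKET_OPEN, BRACKET_CLOSE))
  if (length(bad))
    stop("unsupported structure character(s): ", paste(bad, collapse = " "))
  pairs <- vector("list", length(BRACKET_OPEN))
  for (f in seq_along(BRACKET_OPEN)) {
    stack <- integer(0)
    out <- list()
    op <- BRACKET_OPEN[f]; cl <- BRACKET_CLOSE[f]
    for (k in seq_along(ch)) {
      if (ch[k] == op) {
        stack <- c(stack, k)
      } else if (ch[k] == cl) {
        if (length(stack) == 0L)
          stop("unbalanced '", cl, "' at position ", k)
        out[[length(out) + 1L]] <- c(stack[length(stack)], k)
        stack <- stack[-length(stack)]
      }
    }
    if (length(stack))
      stop("unbalanced '", op, "' at position ", stack[1L])
    pairs[[f]] <- do.call(rbind, out)
  }
  rna_ss(seqline, do.call(rbind, pairs), noncanonical = noncanonical)
}

#' Write a dot-bracket string for a nested structure
#'
#' @param ss An `rna_ss` with non-crossing pairs.
#' @return Character vector of two lines (sequence, brackets).
#' @export
write_dotbracket <- function(ss) {
  stopifnot(inherits(ss, "rna_ss"))
  if (ss_has_crossings(ss$pairs))
    stop("structure contains pseudoknots; remove them first")
  ch <- rep(".", nchar(ss$sequence))
  ch[ss$pairs[, 1L]] <- "("
  ch[ss$pairs[, 2L]] <- ")"
  c(ss$sequence, paste(ch, collapse = ""))
}

#' Parse a CT-format secondary structure record
#'
#' Standard six-column CT: index, base, previous, next, pairing partner
#' (0 = unpaired), natural index. The header line (count + title) is
#' detected and skipped.
#'
#' @inheritParams parse_dotbracket
#' @return An `rna_ss` object.
#' @export
parse_ct <- function(text, file = FALSE, noncanonical = c("drop", "error")) {
  if (file) text <- readLines(text, warn = FALSE)
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  text <- trimws(text)
  text <- text[nzchar(text)]
  if (length(text) == 0L) return(rna_ss("", NULL))
  fields <- strsplit(text, "\\s+")
  # header: first token is the residue count and the line has <6 numeric cols
  first <- fields[[1L]]
  start <- if (length(first) < 6L || is.na(suppressWarnings(as.integer(first[5L])))) 2L else 1L
  fields <- fields[seq(start, length(fields))]
  n <- length(fields)
  base <- character(n); partner <- integer(n)
  for (k in seq_len(n)) {
    f <- fields[[k]]
    if (length(f) < 6L) stop("malformed CT line: ", paste(f, collapse = " "))
    idx <- as.integer(f[1L])
    if (idx != k) stop("CT indices not consecutive at line ", k)
    base[k] <- f[2L]
    partner[k] <- as.integer(f[5L])
  }
  if (any(partner < 0L | partner > n)) stop("CT pair index out of range")
  paired <- which(partner > 0L)
  if (any(partner[partner[paired]] != paired))
    stop("inconsistent reciprocal pairing in CT record")
  keep <- paired[paired < partner[paired]]
  pairs <- if (length(keep)) cbind(keep, partner[keep]) else NULL
  rna_ss(paste(base, collapse = ""), pairs, noncanonical = noncanonical)
}

#' Write a CT record
#'
#' @param ss An `rna_ss`.
#' @param title Title placed on the header line.
#' @return Character vector of CT lines.
#' @export
write_ct <- function(ss, title = "juncgraph") {
  stopifnot(inherits(ss, "rna_ss"))
  n <- nchar(ss$sequence)
  ch <- strsplit(ss$sequence, "")[[1]]
  partner <- integer(n)
  if (nrow(ss$pairs)) {
    partner[ss$pairs[, 1L]] <- ss$pairs[, 2L]
    partner[ss$pairs[, 2L]] <- ss$pairs[, 1L]
  }
  lines <- sprintf("%5d %s %7d %5d %5d %5d",
                   seq_len(n), ch, seq_len(n) - 1L,
                   ifelse(seq_len(n) == n, 0L, seq_len(n) + 1L),
                   partner, seq_len(n))
  c(sprintf("%5d  %s", n, title), lines)
}

ss_has_crossings <- function(pairs) {
  p <- NROW(pairs)
  if (p < 2L) return(FALSE)
  for (a in seq_len(p - 1L)) for (b in seq(a + 1L, p)) {
    i <- pairs[a, 1L]; j <- pairs[a, 2L]
    k <- pairs[b, 1L]; l <- pairs[b, 2L]
    if ((i < k && k < j && j < l) || (k < i && i < l && l < j))
      return(TRUE)
  }
  FALSE
}

#' Remove pseudoknots, keeping the maximum nested subset of pairs
#'
#' Crossing pairs are resolved by dynamic programming (Nussinov-style over
#' the fixed pairing partners): the returned structure carries the
#' maximum-cardinality non-crossing subset. Ties are broken toward keeping
#' the pair that opens at the smaller 5' index.
#'
#' @param ss An `rna_ss`, possibly with crossing pairs.
#' @return An `rna_ss` with a nested pair set.
#' @export
remove_pseudoknots <- function(ss) {
  stopifnot(inherits(ss, "rna_ss"))
  if (!ss_has_crossings(ss$pairs)) return(ss)
  n <- nchar(ss$sequence)
  partner <- integer(n)
  partner[ss$pairs[, 1L]] <- ss$pairs[, 2L]
  partner[ss$pairs[, 2L]] <- ss$pairs[, 1L]
  # M[i,j]: max retained pairs using pairs fully inside [i, j]
  M <- matrix(0L, n, n)
  for (span in 1:(n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- M[i + 1L, j]  # i unpaired inside this interval
      k <- partner[i]
      if (k > i && k <= j) {
        inner <- if (k - 1L >= i + 1L) M[i + 1L, k - 1L] else 0L
        outer <- if (k + 1L <= j) M[k + 1L, j] else 0L
        cand <- 1L + inner + outer
        if (cand >= best) best <- cand  # >= prefers pairing the 5'-most opener
      }
      M[i, j] <- best
    }
  }
  keep <- matrix(integer(0), ncol = 2L)
  stack <- list(c(1L, n))
  while (length(stack)) {
    iv <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- iv[1L]; j <- iv[2L]
    while (i < j) {
      k <- partner[i]
      if (k > i && k <= j) {
        inner <- if (k - 1L >= i + 1L) M[i + 1L, k - 1L] else 0L
        outer <- if (k + 1L <= j) M[k + 1L, j] else 0L
        if (1L + inner + outer >= M[i + 1L, j]) {
          keep <- rbind(keep, c(i, k))
          if (k + 1L <= j) stack[[length(stack) + 1L]] <- c(k + 1L, j)
          j <- k - 1L
          i <- i + 1L
          next
        }
      }
      i <- i + 1L
    }
  }
  rna_ss(ss$sequence, keep)
}

#' Find helices (maximal stacked runs of at least two pairs)
#'
#' A helix is a maximal run of consecutively stacked pairs
#' `(i,j), (i+1,j-1), ...` with at least two pairs. Isolated single pairs do
#' not qualify and are reported in the `isolated` attribute; for loop and
#' junction bookkeeping their residues count as unpaired.
#'
#' @param ss An `rna_ss` with nested pairs.
#' @return Data frame with one row per helix: `i1`, `j1` (outermost pair),
#'   `bp` (pair count). Attribute `isolated` holds the dissolved single
#'   pairs as a two-column matrix.
#' @export
find_helices <- function(ss) {
  stopifnot(inherits(ss, "rna_ss"))
  if (ss_has_crossings(ss$pairs))
    stop("structure contains pseudoknots; remove them first")
  p <- ss$pairs[order(ss$pairs[, 1L]), , drop = FALSE]
  runs <- list(); iso <- list()
  k <- 1L
  np <- nrow(p)
  while (k <= np) {
    len <- 1L
    while (k + len <= np &&
           p[k + len, 1L] == p[k, 1L] + len &&
           p[k + len, 2L] == p[k, 2L] - len) len <- len + 1L
    if (len >= 2L) runs[[length(runs) + 1L]] <- c(p[k, ], len)
    else iso[[length(iso) + 1L]] <- p[k, ]
    k <- k + len
  }
  out <- if (length(runs)) {
    m <- do.call(rbind, runs)
    data.frame(i1 = m[, 1L], j1 = m[, 2L], bp = m[, 3L])
  } else data.frame(i1 = integer(0), j1 = integer(0), bp = integer(0))
  attr(out, "isolated") <- if (length(iso)) do.call(rbind, iso) else
    matrix(integer(0), ncol = 2L)
  out
}

# Helix strand ranges: strand5 ascends i1..i2, strand3 ascends j2..j1.
helix_inner_pair <- function(h) c(h$i1 + h$bp - 1L, h$j1 - h$bp + 1L)

#' Find n-way junctions in a nested secondary structure
#'
#' Every loop bounded by three or more helices is returned. Helices are
#' labelled `H1..Hn` in 5'-to-3' encounter order; `H1` is the
#' junction-closing helix when the loop is closed by one (the exterior loop
#' of a multi-stem structure has none, and `H1` is then the first helix met
#' along the strand). Loop segment `Li` is the unpaired stretch between
#' `Hi` and `H(i+1)` (cyclically); residues of dissolved isolated pairs
#' count as loop nucleotides.
#'
#' @param ss An `rna_ss` with nested pairs.
#' @return List of `rna_junction` objects. Each has `degree`, `helices`
#'   (data frame: `label`, `i1`, `j1`, `bp`, `closing` flag, proximal pair
#'   columns `p5`, `p3`, and `closing_pair` letters), `loops` (list of
#'   `length`, `seq`, `positions`).
#' @export
find_junctions <- function(ss) {
  hx <- find_helices(ss)
  nh <- nrow(hx)
  if (nh == 0L) return(list())
  n <- nchar(ss$sequence)
  chs <- strsplit(ss$sequence, "")[[1]]
  # pairing map over helix pairs only (isolated pairs dissolved)
  partner <- integer(n)
  opens <- integer(n)   # position -> helix id whose outermost 5' residue this is
  for (h in seq_len(nh)) {
    for (k in 0:(hx$bp[h] - 1L)) {
      i <- hx$i1[h] + k; j <- hx$j1[h] - k
      partner[i] <- j; partner[j] <- i
    }
    opens[hx$i1[h]] <- h
  }
  walk_loop <- function(from, to) {
    # walk positions in (from, to): collect child helices and loop segments
    children <- integer(0)
    segs <- list()
    cur <- integer(0)
    k <- from
    while (k <= to) {
      h <- opens[k]
      if (h > 0L) {
        children <- c(children, h)
        segs[[length(segs) + 1L]] <- cur
        cur <- integer(0)
        k <- hx$j1[h] + 1L
      } else {
        cur <- c(cur, k)
        k <- k + 1L
      }
    }
    segs[[length(segs) + 1L]] <- cur
    list(children = children, segs = segs)
  }
  junctions <- list()
  add_junction <- function(closing, w) {
    helix_ids <- c(if (!is.na(closing)) closing, w$children)
    degree <- length(helix_ids)
    if (degree < 3L) return()
    # loop segments: for a closed junction segs are already L1..Ln
    # (seg before first child = L1 between H1(closing) and H2, ...,
    # last seg = Ln between Hn and H1). For an exterior junction, the
    # stretch before the first helix and after the last are tails wrapped
    # into Ln.
    if (!is.na(closing)) {
      segs <- w$segs
    } else {
      # exterior loop: flanking tails (before H1, after Hn) are ignored and
      # the wrap-around segment Ln is taken as empty
      segs <- w$segs[-1L]
      segs[[length(segs)]] <- integer(0)
    }
    loops <- lapply(segs, function(pos) {
      list(length = length(pos),
           seq = paste(chs[pos], collapse = ""),
           positions = pos)
    })
    hdf <- hx[helix_ids, , drop = FALSE]
    hdf$label <- paste0("H", seq_len(degree))
    hdf$closing <- !is.na(closing) & seq_len(degree) == 1L
    prox <- t(vapply(seq_len(degree), function(q) {
      h <- hdf[q, ]
      if (h$closing) helix_inner_pair(h) else c(h$i1, h$j1)
    }, integer(2)))
    hdf$p5 <- prox[, 1L]; hdf$p3 <- prox[, 2L]
    hdf$closing_pair <- paste0(chs[prox[, 1L]], chs[prox[, 2L]])
    rownames(hdf) <- NULL
    junctions[[length(junctions) + 1L]] <<- structure(
      list(degree = degree,
           helices = hdf[, c("label", "i1", "j1", "bp", "closing",
                             "p5", "p3", "closing_pair")],
           loops = loops),
      class = "rna_junction")
  }
  # interior loops: one per helix, bounded by its innermost pair
  for (h in seq_len(nh)) {
    ip <- helix_inner_pair(hx[h, ])
    w <- walk_loop(ip[1L] + 1L, ip[2L] - 1L)
    add_junction(h, w)
  }
  # exterior loop
  w <- walk_loop(1L, n)
  add_junction(NA_integer_, w)
  junctions
}

#' @export
print.rna_junction <- function(x, ...) {
  cat(sprintf("%d-way junction: helices %s (bp: %s), loop lengths (%s)\n",
              x$degree, paste(x$helices$label, collapse = " "),
              paste(x$helices$bp, collapse = ","),
              paste(vapply(x$loops, `[[`, 0L, "length"), collapse = ",")))
  invisible(x)
}

#' Summarise junctions of a structure as a JSON report
#'
#' @param ss An `rna_ss`.
#' @param path Optional file to write to.
#' @return JSON string (invisibly when written to a file).
#' @export
junction_report <- function(ss, path = NULL) {
  js <- find_junctions(remove_pseudoknots(ss))
  rep <- lapply(js, function(j) {
    list(degree = j$degree,
         helices = lapply(seq_len(j$degree), function(q) list(
           label = j$helices$label[q], bp = j$helices$bp[q],
           outer_pair = c(j$helices$i1[q], j$helices$j1[q]),
           closing = j$helices$closing[q])),
         loop_lengths = vapply(j$loops, `[[`, 0L, "length"),
         loop_sequences = vapply(j$loops, `[[`, "", "seq"))
  })
  json <- jsonlite::toJSON(rep, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
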