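# Shared fixtures built in code.

# 3-way junction: closing helix (4 bp) + two hairpin stems, loops (2,2,2)
threeway_db <- c("GGCCAAGGCCAAAGGCCAAGGCCAAAGGCCAAGGCC",
                 "((((..((((...))))..((((...))))..))))")

# tRNA-like 4-way: closing helix (2 bp) + three hairpin stems, loops 1 nt
fourway_db <- c("GGAGGAAACCAGGAAACCAGGAAACCACC",
                "((.((...)).((...)).((...)).))")

threeway_junction <- function() {
  find_junctions(parse_dotbracket(threeway_db))[[1L]]
}

fourway_junction <- function() {
  find_junctions(parse_dotbracket(fourway_db))[[1L]]
}

model_graph_3 <- function(family = "A", stacks = "H1H2",
                          bp = c(4L, 5L, 6L), loops = c(1L, 4L, 7L), ...) {
  build_graph(list(degree = 3L, bp = bp, loop_lengths = loops),
              junction_topology(stacks, family, 3L), ...)
}

model_graph_4 <- function(family = "cL", bp = c(5L, 4L, 4L, 5L),
                          loops = c(0L, 2L, 1L, 0L), ...) {
  build_graph(list(degree = 4L, bp = bp, loop_lengths = loops),
              fourway_topology(family), ...)
}

# random composed junction: closing stem + (degree-1) hairpin arms, all-GC
# stems so every pair is canonical
random_junction_db <- function(degree = 3L, bp = NULL, loops = NULL,
                               hairpin = 4L) {
  if (is.null(bp)) bp <- sample(2:4, degree, replace = TRUE)
  if (is.null(loops)) loops <- sample(0:4, degree, replace = TRUE)
  seq <- paste0(strrep("G", bp[1L]))
  db <- strrep("(", bp[1L])
  for (i in seq_len(degree)) {
    if (i > 1L) {
      seq <- paste0(seq, strrep("G", bp[i]), strrep("A", hairpin),
                    strrep("C", bp[i]))
      db <- paste0(db, strrep("(", bp[i]), strrep(".", hairpin),
                   strrep(")", bp[i]))
    }
    seq <- paste0(seq, strrep("A", loops[i]))
    db <- paste0(db, strrep(".", loops[i]))
  }
  seq <- paste0(seq, strrep("C", bp[1L]))
  db <- paste0(db, strrep(")", bp[1L]))
  c(seq, db)
}

# separable three-record dataset with three distinct stack and family
# labels (every LOOCV fold keeps two classes)
tiny_dataset <- function() {
  junction_dataset(
    c("a", "b", "c"),
    loop_seqs = list(c("", "AAAAAAAA", "AAAA"),
                     c("AAAAAAAA", "", "AAAA"),
                     c("AAAA", "AAAAAAAA", "")),
    helix_bp = list(c(4L, 4L, 4L), c(4L, 4L, 4L), c(4L, 4L, 4L)),
    closing_pairs = list(c("GC", "GC", "GC"), c("GC", "GC", "GC"),
                         c("GC", "GC", "GC")),
    stacks = c("H1H2", "H2H3", "H1H3"),
    family = c("A", "B", "C"))
}
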