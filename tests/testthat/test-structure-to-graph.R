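test_that("basepair_vertex follows the three-step construction exactly", {
  # frozen hand geometry: M = (0,0,0), projection onto the C8-C6 line
  # {y = 3} is (0,3,0), so O' = (0,4,0)
  o <- basepair_vertex(c(-5, 0, 0), c(5, 0, 0), c(-2, 3, 0), c(2, 3, 0))
  expect_equal(o, c(0, 4, 0))
  # |O' - M| = 4 for arbitrary valid geometry
  set.seed(3)
  for (rep in 1:20) {
    c1a <- stats::rnorm(3, sd = 5); c1b <- stats::rnorm(3, sd = 5)
    c8 <- stats::rnorm(3, sd = 5); c6 <- c8 + stats::rnorm(3)
    M <- (c1a + c1b) / 2
    o <- tryCatch(basepair_vertex(c1a, c1b, c8, c6),
                  error = function(e) NULL)
    if (is.null(o)) next  # degenerate draw
    expect_equal(sqrt(sum((o - M)^2)), 4, tolerance = 1e-12)
  }
  # rigid-motion equivariance
  R <- euler_rot(0.3, 1.1, 2.0); t <- c(3, -7, 11)
  mv <- function(x) as.numeric(R %*% x + t)
  o2 <- basepair_vertex(mv(c(-5, 0, 0)), mv(c(5, 0, 0)),
                        mv(c(-2, 3, 0)), mv(c(2, 3, 0)))
  expect_equal(o2, mv(c(0, 4, 0)), tolerance = 1e-12)
  # degenerate cases error
  expect_error(basepair_vertex(c(-5, 0, 0), c(5, 0, 0), c(0, 0, 0),
                               c(0, 0, 0)), "coincide")
  expect_error(basepair_vertex(c(-1, 0, 0), c(1, 0, 0), c(0, 0, 0),
                               c(0, 1, 0)), "degenerate")
})

test_that("geometric pair detection recovers an ideal duplex and drops flipped bases", {
  h <- ideal_helix(6)
  wc <- detect_wc_pairs(h)
  expect_identical(nrow(wc), 6L)
  expect_identical(wc$resnum_j, 6L:1L)   # A:k pairs B:(7-k)
  expect_true(all(wc$class == "GC"))
  # single strand: nothing pairs
  single <- h[h$chain == "A", ]
  expect_identical(nrow(detect_wc_pairs(single)), 0L)
  # displace one base 10 Å: its pair disappears
  broken <- h
  sel <- broken$chain == "B" & broken$resnum == 3L
  broken[sel, c("x", "y", "z")] <- broken[sel, c("x", "y", "z")] + 10
  wc2 <- detect_wc_pairs(broken)
  expect_identical(nrow(wc2), 5L)
  expect_false(any(wc2$chain_j == "B" & wc2$resnum_j == 3L))
})

test_that("PDB and mmCIF writing/parsing round-trips the generator output", {
  h <- ideal_helix(4, pair_letters = c("GC", "AU", "UA", "GU"))
  path <- tempfile(fileext = ".pdb")
  on.exit(unlink(path))
  write_structure_pdb(h, path)
  back <- read_structure(path)
  expect_identical(nrow(back), nrow(h))
  expect_equal(back$x, h$x, tolerance = 1e-3)
  expect_identical(back$atom, h$atom)
  expect_identical(back$resname, h$resname)
  # a C1* dialect name is normalized on read
  lines <- readLines(path)
  writeLines(gsub("C1'", "C1*", lines, fixed = TRUE), path)
  expect_identical(unique(read_structure(path)$atom[
    grepl("C1", read_structure(path)$atom)]), "C1'")
})

test_that("translated junction graphs obey the 2n+1 / 2n law and locate the centroid", {
  for (fam in c("A", "cL")) {
    g <- if (fam == "A") model_graph_3(fam) else model_graph_4(fam)
    loops <- if (fam == "A") c(1L, 4L, 7L) else c(0L, 2L, 1L, 0L)
    syn <- synthesize_junction(g, loops)
    nat <- structure_to_graph(syn$atoms, syn$pairs)
    n <- nat$n
    expect_identical(nrow(nat$vertices), 2L * n + 1L)
    expect_identical(nrow(nat$edges), 2L * n)
    prox <- nat$vertices[nat$vertices$role == "proximal", c("x", "y", "z")]
    cen <- unlist(nat$vertices[nat$vertices$role == "centroid",
                               c("x", "y", "z")])
    expect_equal(unname(cen), unname(colMeans(prox)), tolerance = 1e-9)
  }
})

test_that("translation is rigid-motion equivariant", {
  g <- model_graph_3("B")
  syn <- synthesize_junction(g, c(1L, 4L, 7L))
  R <- euler_rot(1.2, 0.5, 2.8); t <- c(10, -4, 6)
  moved <- syn$atoms
  xyz <- as.matrix(moved[, c("x", "y", "z")]) %*% t(R)
  moved$x <- xyz[, 1L] + t[1L]
  moved$y <- xyz[, 2L] + t[2L]
  moved$z <- xyz[, 3L] + t[3L]
  g1 <- structure_to_graph(syn$atoms, syn$pairs)
  g2 <- structure_to_graph(moved, syn$pairs)
  expect_equal(graph_rmsd(g1, g2), 0, tolerance = 1e-6)
})

test_that("helices with too few usable pairs raise a translation error", {
  g <- model_graph_3("A")
  syn <- synthesize_junction(g, c(1L, 4L, 7L))
  # strip the C8/C6 atoms of helix H2 so no pair can form a vertex
  j <- find_junctions(syn$ss)[[1L]]
  h2 <- j$helices[2L, ]
  res2 <- c(h2$i1:(h2$i1 + h2$bp - 1L), (h2$j1 - h2$bp + 1L):h2$j1)
  crippled <- syn$atoms[!(syn$atoms$resnum %in% res2 &
                            syn$atoms$atom %in% c("C8", "C6")), ]
  expect_error(structure_to_graph(crippled, syn$pairs), "H2")
})

test_that("an external annotation table overrides detection", {
  h <- ideal_helix(5)
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_basepair_table(detect_wc_pairs(h), path)
  back <- read_basepair_table(path)
  expect_identical(back, detect_wc_pairs(h))
})
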