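test_that("distance parameterizations evaluate the published formulas", {
  expect_equal(coaxial_spacing(0), 3.91)
  expect_equal(coaxial_spacing(4), 14.91)
  expect_gt(coaxial_spacing(5), coaxial_spacing(4))
  expect_error(coaxial_spacing(-1), "non-negative")
  expect_equal(helix_edge_length(2), 2.87)
  expect_equal(helix_edge_length(10), 25.83)
  expect_error(helix_edge_length(1), "b >= 2")
  expect_equal(unname(arrangement_distance("parallel")), 20.48)
  expect_equal(unname(arrangement_distance("perpendicular")), 19.95)
  expect_equal(unname(arrangement_distance("diagonal")), 21.17)
  expect_error(arrangement_distance("sideways"), "unknown")
  expect_error(scaling_parameters(base_rise = -1), "positive")
})

all_model_graphs <- function() {
  g3 <- lapply(c("A", "B", "C"), function(f) model_graph_3(family = f))
  g3n <- list(build_graph(list(degree = 3L, bp = c(4L, 4L, 4L),
                               loop_lengths = c(5L, 5L, 5L)),
                          junction_topology(character(0), "none", 3L)))
  g4 <- lapply(FOURWAY_FAMILIES, function(f) model_graph_4(family = f))
  c(g3, g3n, g4)
}

test_that("every built graph satisfies the 2n+1 / 2n law, centroid mean and planarity", {
  for (g in all_model_graphs()) {
    n <- g$n
    expect_identical(nrow(g$vertices), 2L * n + 1L)
    expect_identical(nrow(g$edges), 2L * n)
    prox <- g$vertices[g$vertices$role == "proximal", c("x", "y", "z")]
    cen <- unlist(g$vertices[g$vertices$role == "centroid",
                             c("x", "y", "z")])
    expect_equal(unname(cen), unname(colMeans(prox)), tolerance = 1e-12)
    expect_true(all(abs(g$vertices$z) < 1e-9))
  }
})

test_that("stacked helices are laid antiparallel, collinear, at the s0 gap", {
  params <- scaling_parameters()
  for (L in c(0L, 2L, 5L)) {
    g <- model_graph_3(loops = c(L, 4L, 7L))
    ev <- helix_edge_vectors(g)
    u1 <- ev["H1", ] / sqrt(sum(ev["H1", ]^2))
    u2 <- ev["H2", ] / sqrt(sum(ev["H2", ]^2))
    expect_equal(sum(u1 * u2), -1, tolerance = 1e-12)   # 180 degrees
    p1 <- unlist(g$vertices[g$vertices$label == "H1p", c("x", "y", "z")])
    p2 <- unlist(g$vertices[g$vertices$label == "H2p", c("x", "y", "z")])
    expect_equal(sqrt(sum((p1 - p2)^2)), coaxial_spacing(L, params))
    # collinear: lateral offset of H2p from the H1 axis is zero
    off <- p2 - p1
    expect_lt(sqrt(sum((off - sum(off * (-u1)) * (-u1))^2)), 1e-9)
  }
})

test_that("3-way arrangement classes realize distance and angle by family", {
  expect_arrangement <- function(family, class) {
    g <- model_graph_3(family = family)
    d <- stack_axis_distance(g, c(1L, 2L), 3L)
    expect_equal(d, unname(arrangement_distance(class)))
    ev <- helix_edge_vectors(g)
    u3 <- ev["H3", ] / sqrt(sum(ev["H3", ]^2))
    stack_axis <- c(1, 0, 0)
    ang <- acos(abs(sum(u3 * stack_axis))) * 180 / pi
    want <- switch(class, parallel = 0, perpendicular = 90, diagonal = 45)
    expect_equal(ang, want, tolerance = 1e-9)
  }
  expect_arrangement("C", "parallel")
  expect_arrangement("A", "perpendicular")
  expect_arrangement("B", "diagonal")
})

test_that("4-way two-stack families realize the committed inter-stack angles", {
  angle_between_stacks <- function(g, prs) {
    ev <- helix_edge_vectors(g)
    axis <- function(pair) {
      u <- ev[paste0("H", pair[2L]), ]
      u / sqrt(sum(u^2))
    }
    a1 <- axis(prs[1L, ]); a2 <- axis(prs[2L, ])
    acos(pmin(1, abs(sum(a1 * a2)))) * 180 / pi
  }
  for (fam in c("H", "cH")) {
    g <- model_graph_4(family = fam)
    expect_equal(angle_between_stacks(g, fourway_topology(fam)$pairs), 0,
                 tolerance = 1e-9)
  }
  g <- model_graph_4(family = "cL")
  expect_equal(angle_between_stacks(g, fourway_topology("cL")$pairs), 90,
               tolerance = 1e-9)
  for (fam in c("cX", "X")) {
    g <- model_graph_4(family = fam)
    expect_equal(angle_between_stacks(g, fourway_topology(fam)$pairs), 45,
                 tolerance = 1e-9)
  }
})

test_that("build_graph validates topology against the junction", {
  expect_error(build_graph(list(degree = 3L, bp = c(4L, 4L, 4L),
                                loop_lengths = c(1L, 1L, 1L)),
                           fourway_topology("cL")),
               "degree")
  # stacks must name cyclically adjacent helices for the gap loop
  expect_error(junction_topology("H1H5", "A", 3), "outside")
})

test_that("build_graph is deterministic and honours the side-sign flag", {
  a <- model_graph_3(family = "A")
  b <- model_graph_3(family = "A")
  expect_identical(a, b)
  flipped <- model_graph_3(family = "A", side_sign = -1)
  y <- flipped$vertices$y[flipped$vertices$label == "H3p"]
  expect_equal(y, -a$vertices$y[a$vertices$label == "H3p"])
})

test_that("graphs round-trip through JSON and export pseudo-PDB", {
  g <- model_graph_4(family = "cK")
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_graph_json(g, path)
  back <- read_graph_json(path)
  expect_equal(graph_coords(back), graph_coords(g))
  expect_identical(back$edges$type, g$edges$type)
  pdb <- tempfile(fileext = ".pdb")
  on.exit(unlink(pdb), add = TRUE)
  write_graph_pdb(g, pdb)
  lines <- readLines(pdb)
  expect_identical(sum(startsWith(lines, "HETATM")), 9L)
  expect_identical(sum(startsWith(lines, "CONECT")), 8L)
})

test_that("family templates average directions and flag degeneracy", {
  g <- model_graph_3(family = "A")
  tpl <- derive_family_template(list(g), "A")[["A"]]
  ev <- helix_edge_vectors(g)
  ev <- ev / sqrt(rowSums(ev^2))
  expect_equal(unname(tpl$directions), unname(ev), tolerance = 1e-9)
  expect_false(any(tpl$degenerate))
  # a rotated copy leaves the template congruent to the original
  g2 <- rigid_move_graph(g, euler_rot(0.4, 0.9, 1.7), c(3, -2, 8))
  tpl2 <- derive_family_template(list(g, g2), c("A", "A"))[["A"]]
  expect_equal(tpl2$directions, tpl$directions, tolerance = 1e-6)
  # opposed H3 directions cancel and get flagged
  g3 <- g
  i <- match(c("H3p", "H3d"), g3$vertices$label)
  p <- unlist(g3$vertices[i[1L], c("x", "y", "z")])
  d <- unlist(g3$vertices[i[2L], c("x", "y", "z")])
  g3$vertices[i[2L], c("x", "y", "z")] <- p - (d - p)
  expect_warning(tpl3 <- derive_family_template(list(g, g3), c("A", "A")),
                 "degenerate")
  expect_true(tpl3[["A"]]$degenerate[3L])
  # building from a template reproduces the source geometry
  gt <- build_graph(list(degree = 3L, bp = c(4L, 5L, 6L),
                         loop_lengths = c(1L, 4L, 7L)),
                    junction_topology("H1H2", "A", 3L), template = tpl)
  expect_lt(graph_rmsd(g, gt), 1e-6)
})
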