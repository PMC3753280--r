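test_that("dot-bracket parsing recovers hairpin pairs and handles empties", {
  ss <- parse_dotbracket(c("GGGAAACCC", "(((...)))"))
  expect_identical(unname(ss$pairs), matrix(c(1L, 9L, 2L, 8L, 3L, 7L),
                                            ncol = 2L, byrow = TRUE))
  empty <- parse_dotbracket("")
  expect_identical(nchar(empty$sequence), 0L)
  expect_identical(nrow(empty$pairs), 0L)
  # header lines are skipped
  withhdr <- parse_dotbracket(c("> test", "GGGAAACCC", "(((...)))"))
  expect_identical(withhdr$pairs, ss$pairs)
})

test_that("dot-bracket parse errors on malformed input", {
  expect_error(parse_dotbracket(c("GGGAAACCC", "(((...))")), "length")
  expect_error(parse_dotbracket(c("GGGAAACCC", "(((...).)")), "unbalanced")
  expect_error(parse_dotbracket(c("GGGAAACCC", ")((...)))")), "unbalanced")
  # non-canonical pairs: dropped with warning, or error on request
  expect_warning(ss <- parse_dotbracket(c("GAGAAACAC", "(((...)))")),
                 "non-canonical")
  expect_identical(nrow(ss$pairs), 2L)
  expect_error(parse_dotbracket(c("GAGAAACAC", "(((...)))"),
                                noncanonical = "error"), "non-canonical")
})

test_that("a multi-helix structure parses to three helices", {
  ss <- parse_dotbracket(threeway_db)
  hx <- find_helices(ss)
  expect_identical(nrow(hx), 3L)
  expect_identical(hx$bp, c(4L, 4L, 4L))
})

test_that("CT format round-trips sequence and pairs exactly", {
  for (db in list(c("GGGAAACCC", "(((...)))"), threeway_db, fourway_db)) {
    ss <- parse_dotbracket(db)
    back <- parse_ct(write_ct(ss))
    expect_identical(back$sequence, ss$sequence)
    expect_identical(back$pairs, ss$pairs)
    # and dot-bracket round trip
    again <- parse_dotbracket(write_dotbracket(ss))
    expect_identical(again$pairs, ss$pairs)
  }
})

test_that("CT parsing flags inconsistent reciprocal pairing", {
  lines <- write_ct(parse_dotbracket(c("GGGAAACCC", "(((...)))")))
  # residue 1 pairs 9; corrupt residue 9 to point at 3
  lines[10] <- sub(" 1 ", " 3 ", lines[10])
  expect_error(parse_ct(lines), "reciprocal")
  allzero <- parse_ct(write_ct(rna_ss("GGAACC")))
  expect_identical(nrow(allzero$pairs), 0L)
})

test_that("pseudoknot removal keeps the maximal nested set", {
  ss <- parse_dotbracket(c("GGGAACCAACCCAAGG", "(((..[[..)))..]]"))
  out <- remove_pseudoknots(ss)
  expect_identical(unname(out$pairs),
                   matrix(c(1L, 12L, 2L, 11L, 3L, 10L), ncol = 2L,
                          byrow = TRUE))
  # nested input is a fixed point
  nested <- parse_dotbracket(threeway_db)
  expect_identical(remove_pseudoknots(nested)$pairs, nested$pairs)
  # tie between two 2-pair families: 5'-opening family wins
  tie <- parse_dotbracket(c("GGAAGGCCCCAACC", "((..[[..))..]]"))
  kept <- remove_pseudoknots(tie)$pairs
  expect_identical(unname(kept), matrix(c(1L, 10L, 2L, 9L), ncol = 2L,
                                        byrow = TRUE))
})

test_that("pseudoknot removal matches the exhaustive oracle", {
  set.seed(7)
  for (rep in 1:25) {
    pairs <- random_pair_structure(len = 30L, npairs = 6L)
    ss <- rna_ss(compatible_seq(30L, pairs), pairs)
    out <- remove_pseudoknots(ss)
    expect_false(juncgraph:::ss_has_crossings(out$pairs))
    expect_identical(nrow(out$pairs), oracle_max_nested(ss$pairs))
    # retained pairs are a subset of the input
    expect_true(all(paste(out$pairs[, 1], out$pairs[, 2]) %in%
                      paste(ss$pairs[, 1], ss$pairs[, 2])))
  }
})

test_that("helix finding applies the b >= 2 rule and partitions pairs", {
  # isolated single pair inside a 2-bp helix loop
  ss <- parse_dotbracket(c("GGAAGAAAACAACC", "((..(....)..))"))
  hx <- find_helices(ss)
  expect_identical(nrow(hx), 1L)
  expect_identical(hx$bp, 2L)
  iso <- attr(hx, "isolated")
  expect_identical(unname(iso), matrix(c(5L, 10L), ncol = 2L))
  # 1-nt bulge breaks a stacked run into two helices
  ss2 <- parse_dotbracket(c("GGAGGAAACCCC", "((.((...))))"))
  hx2 <- find_helices(ss2)
  expect_identical(nrow(hx2), 2L)
  expect_identical(hx2$bp, c(2L, 2L))
  # partition property over random nested structures
  set.seed(11)
  for (rep in 1:20) {
    pairs <- random_pair_structure(26L, 5L)
    ss3 <- remove_pseudoknots(rna_ss(compatible_seq(26L, pairs), pairs))
    hx3 <- find_helices(ss3)
    covered <- attr(hx3, "isolated")
    if (nrow(hx3)) {
      for (q in seq_len(nrow(hx3)))
        covered <- rbind(covered, t(vapply(0:(hx3$bp[q] - 1L), function(m)
          c(hx3$i1[q] + m, hx3$j1[q] - m), integer(2))))
    }
    expect_setequal(paste(covered[, 1], covered[, 2]),
                    paste(ss3$pairs[, 1], ss3$pairs[, 2]))
  }
})

test_that("junction extraction finds 3- and 4-way loops with the naming convention", {
  j3 <- threeway_junction()
  expect_identical(j3$degree, 3L)
  expect_identical(vapply(j3$loops, `[[`, 0L, "length"), c(2L, 2L, 2L))
  expect_true(j3$helices$closing[1L])
  expect_identical(j3$helices$label, c("H1", "H2", "H3"))
  j4 <- fourway_junction()
  expect_identical(j4$degree, 4L)
  expect_identical(vapply(j4$loops, `[[`, 0L, "length"), c(1L, 1L, 1L, 1L))
  # single hairpin: no junction
  expect_length(find_junctions(parse_dotbracket(c("GGGAAACCC", "(((...)))"))),
                0L)
  # loop sequences attach correctly
  expect_identical(vapply(j3$loops, `[[`, "", "seq"), c("AA", "AA", "AA"))
})

test_that("junction degree equals helix ends on the loop", {
  set.seed(5)
  for (rep in 1:15) {
    db <- random_junction_db(degree = sample(3:5, 1L))
    ss <- parse_dotbracket(db)
    js <- find_junctions(ss)
    hx <- find_helices(ss)
    expect_gte(length(js), 1L)
    for (j in js) {
      expect_identical(j$degree, nrow(j$helices))
      expect_identical(j$degree, length(j$loops))
      expect_gte(j$degree, 3L)
    }
    expect_lte(sum(vapply(js, `[[`, 0L, "degree")), nrow(hx) + 1L)
  }
})

test_that("junction report serializes to JSON", {
  json <- junction_report(parse_dotbracket(threeway_db))
  parsed <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  expect_length(parsed, 1L)
  expect_identical(parsed[[1L]]$degree, 3L)
})
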