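# Classifier tests run with reduced tree counts (100-200 instead of the
# 500 default) to stay inside the suite's time budget; the learning
# problems here are easy enough that forest size is not the binding factor.

test_that("feature extraction reads off loop lengths, composition and symmetry", {
  f <- feature_vector(c("", "AA", "AAAAAAA"), c(4L, 4L, 4L),
                      c("GC", "GC", "GC"))
  expect_identical(unname(f[c("L1", "L2", "L3")]), c(0, 2, 7))
  expect_identical(unname(f[c("A2", "A3")]), c(1, 1))
  expect_identical(unname(f[c("pur2", "pur3")]), c(1, 1))
  expect_identical(unname(f["A1"]), 0)     # empty loop: all-zero composition
  expect_identical(unname(f["totL"]), 9)
  # same lengths, different sequence: lengths equal, composition differs
  g <- feature_vector(c("", "CC", "CCCCCCC"), c(4L, 4L, 4L),
                      c("GC", "GC", "GC"))
  expect_identical(f[c("L1", "L2", "L3")], g[c("L1", "L2", "L3")])
  expect_false(identical(f["A2"], g["A2"]))
  # symmetric junction: all pairwise ratio features zero
  s <- feature_vector(c("AAA", "AAA", "AAA"), c(4L, 4L, 4L),
                      c("GC", "GC", "GC"))
  expect_identical(unname(s[c("r12", "r13", "r23")]), c(0, 0, 0))
  # deterministic: same junction, same vector
  j <- threeway_junction()
  expect_identical(extract_features(j), extract_features(threeway_junction()))
})

test_that("degree outside 3/4 is rejected", {
  j5 <- find_junctions(parse_dotbracket(random_junction_db(5L)))[[1L]]
  expect_error(extract_features(j5), "degree")
})

test_that("training on a separable dataset reaches 100% training accuracy", {
  d <- synthetic_junction_dataset(60, 3, seed = 42)
  clf <- train_junction_classifier(d, ntree = 100, seed = 7)
  pred <- vapply(seq_len(nrow(d)), function(k)
    predict_topology(clf, d[k, , drop = FALSE])$stacks, "")
  expect_identical(pred, d$stacks)
})

test_that("training is deterministic under a fixed seed", {
  d <- synthetic_junction_dataset(40, 4, seed = 13)
  probe <- synthetic_junction_dataset(15, 4, seed = 99)
  pr <- function() {
    clf <- train_junction_classifier(d, ntree = 100, seed = 5)
    vapply(seq_len(nrow(probe)), function(k) {
      t <- predict_topology(clf, probe[k, , drop = FALSE])
      paste(t$stacks, t$family)
    }, "")
  }
  expect_identical(pr(), pr())
})

test_that("single-class data triggers a degenerate-training error", {
  d <- synthetic_junction_dataset(30, 3, seed = 1)
  d$stacks <- "H1H2"
  d$family <- "A"
  expect_error(train_junction_classifier(d, ntree = 20, seed = 1),
               "one class")
})

test_that("predicted topologies are always structurally valid", {
  d <- synthetic_junction_dataset(50, 4, seed = 3)
  clf <- train_junction_classifier(d, ntree = 100, seed = 3)
  probe <- synthetic_junction_dataset(30, 4, seed = 1234)
  for (k in seq_len(nrow(probe))) {
    top <- predict_topology(clf, probe[k, , drop = FALSE])
    # junction_topology() validates: disjoint pairs, count per degree,
    # admissible family; reaching here without error is the assertion
    expect_s3_class(top, "junction_topology")
    expect_lte(nrow(top$pairs), 2L)
  }
})

test_that("LOOCV runs one fold per record", {
  cv <- loocv(tiny_dataset(), ntree = 30, seed = 2)
  expect_identical(cv$n, 3L)
  expect_identical(nrow(cv$predictions), 3L)
  expect_error(loocv(tiny_dataset()[1:2, ], ntree = 10), "three")
})

test_that("shuffled labels give chance-level LOOCV accuracy", {
  set.seed(21)
  d <- synthetic_junction_dataset(40, 3, seed = 21)
  d$stacks <- sample(d$stacks)   # break the feature-label link
  # keep family consistent with nothing; only stack accuracy is examined
  cv <- loocv(d, ntree = 100, seed = 8)
  pmaj <- max(table(d$stacks)) / nrow(d)
  acc <- cv$stack_correct / cv$n
  halfwidth <- 1.96 * sqrt(pmaj * (1 - pmaj) / nrow(d))
  expect_lte(acc, pmaj + halfwidth)
})

test_that("degree mismatch between junction and classifier errors", {
  d <- synthetic_junction_dataset(30, 4, seed = 6)
  clf <- train_junction_classifier(d, ntree = 30, seed = 6)
  expect_error(predict_topology(clf, threeway_junction()), "degree")
})

test_that("dataset tables round-trip through TSV", {
  d <- synthetic_junction_dataset(20, 3, seed = 12)
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_junction_table(d, path)
  back <- read_junction_table(path)
  expect_identical(back$stacks, d$stacks)
  expect_identical(back$loop_seqs, d$loop_seqs)
  expect_identical(extract_features(back[1L, , drop = FALSE]),
                   extract_features(d[1L, , drop = FALSE]))
})

test_that("classifier serialization preserves predictions", {
  d <- synthetic_junction_dataset(40, 3, seed = 31)
  clf <- train_junction_classifier(d, ntree = 50, seed = 4)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_classifier(clf, path)
  clf2 <- read_classifier(path)
  probe <- synthetic_junction_dataset(15, 3, seed = 77)
  for (k in seq_len(nrow(probe))) {
    a <- predict_topology(clf, probe[k, , drop = FALSE])
    b <- predict_topology(clf2, probe[k, , drop = FALSE])
    expect_identical(a$stacks, b$stacks)
    expect_identical(a$family, b$family)
  }
})
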