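test_that("content pairing follows its precision/recall definitions", {
  truth <- cbind(c("a", "b", "c"), c("b", "c", "d"))
  # perfect prediction
  s <- contentPairing(truth, truth)
  expect_equal(unname(s), c(1, 1, 1))
  # 4 predicted, 2 correct, 3 annotated: LP = 0.5, LR = 2/3, CP = 4/7
  pred <- cbind(c("a", "b", "x", "y"), c("b", "c", "y", "z"))
  s <- contentPairing(pred, truth)
  expect_equal(unname(s["LP"]), 0.5)
  expect_equal(unname(s["LR"]), 2 / 3)
  expect_equal(unname(s["CP"]), 4 / 7)
  # no predictions, non-empty truth
  none <- matrix(character(0), 0, 2)
  expect_equal(unname(contentPairing(none, truth)["CP"]), 0)
  # both empty
  expect_equal(unname(contentPairing(none, none)), c(1, 1, 1))
  # links are unordered
  expect_equal(unname(contentPairing(cbind("b", "a"), cbind("a", "b"))["CP"]), 1)
})

test_that("content grouping matches groups greedily and averages overlaps", {
  truth <- list(G1 = c("a", "b", "c"), G2 = c("d", "e"))
  expect_equal(unname(contentGrouping(truth, truth)[c("NP", "NR", "CG")]),
               c(1, 1, 1))
  # a predicted group holding 7 of an 18-member category: NP 1, NR 7/18
  cat18 <- sprintf("w%02d", 1:18)
  got <- contentGrouping(list(cat18[1:7]), list(SWB1 = cat18))
  expect_equal(unname(got["NP"]), 1)
  expect_equal(unname(got["NR"]), 7 / 18)
  # overlapping predicted groups are invalid
  expect_error(contentGrouping(list(c("a", "b"), c("b", "c")), truth),
               "disjoint")
  # unmatched predicted groups and categories contribute zeros
  got <- contentGrouping(list(c("a", "b"), c("x", "y")), truth)
  expect_equal(unname(got["NP"]), mean(c(2 / 2, 0)))
  expect_equal(unname(got["NR"]), mean(c(2 / 3, 0)))
})

test_that("grouping equals an exhaustive assignment oracle on perturbed partitions", {
  exhaustive <- function(pred, truth) {
    nP <- length(pred); nT <- length(truth)
    ov <- matrix(0, nP, nT)
    for (i in seq_len(nP)) for (j in seq_len(nT))
      ov[i, j] <- length(intersect(pred[[i]], truth[[j]]))
    perms <- function(v, k) if (k == 0) list(integer(0)) else
      unlist(lapply(seq_along(v), function(i)
        lapply(perms(v[-i], k - 1), function(p) c(v[i], p))),
        recursive = FALSE)
    k <- min(nP, nT)
    best <- -1; bestAsn <- NULL
    for (sub in utils::combn(seq_len(nP), k, simplify = FALSE))
      for (p in perms(seq_len(nT), k)) {
        tot <- sum(ov[cbind(sub, p)])
        if (tot > best) { best <- tot; bestAsn <- cbind(sub, p) }
      }
    np <- numeric(nP); nr <- numeric(nT)
    for (r in seq_len(nrow(bestAsn))) {
      i <- bestAsn[r, 1]; j <- bestAsn[r, 2]
      np[i] <- ov[i, j] / length(pred[[i]])
      nr[j] <- ov[i, j] / length(truth[[j]])
    }
    c(NP = mean(np), NR = mean(nr))
  }
  set.seed(61)
  for (rep in 1:25) {
    n <- sample(8:14, 1)
    ids <- paste0("x", seq_len(n))
    ng <- sample(2:4, 1)
    lab <- sample(rep(seq_len(ng), length.out = n))
    truth <- split(ids, lab)
    lab2 <- lab
    for (k in sample(n, sample(0:2, 1))) lab2[k] <- sample(ng, 1)
    keep <- stats::runif(n) > 0.1
    pred <- split(ids[keep], lab2[keep])
    pred <- pred[lengths(pred) > 0]
    got <- contentGrouping(pred, truth)
    want <- exhaustive(pred, truth)
    expect_equal(unname(got[c("NP", "NR")]), unname(want), tolerance = 1e-12)
  }
})

test_that("content classification is standard set precision/recall", {
  truth <- sprintf("s%03d", 1:121)
  # perfect
  expect_equal(unname(contentClassification(truth, truth)["CC"]), 1)
  # 21 false alarms over a large clean pool, all 121 true positives found
  pred <- c(truth, sprintf("c%04d", 1:21))
  s <- contentClassification(pred, truth)
  expect_equal(unname(s["precision"]), 121 / 142)
  expect_equal(unname(s["recall"]), 1)
  expect_equal(unname(s["CC"]), 2 * (121 / 142) / (1 + 121 / 142))
  # empty prediction, non-empty truth
  expect_equal(unname(contentClassification(character(0), truth)["CC"]), 0)
})

test_that("harmonic means are zero when both arguments vanish", {
  expect_equal(panelprov:::harmonicMean(0, 0), 0)
  expect_equal(panelprov:::harmonicMean(1, 0), 0)
  expect_equal(panelprov:::harmonicMean(0.5, 0.5), 0.5)
  # harmonic mean lies between the minimum and the geometric mean
  set.seed(62)
  for (i in 1:20) {
    a <- runif(1); b <- runif(1)
    h <- panelprov:::harmonicMean(a, b)
    expect_gte(h, min(a, b) - 1e-12)
    expect_lte(h, sqrt(a * b) + 1e-12)
  }
})

test_that("metrics are invariant to id relabeling", {
  set.seed(63)
  ids <- sprintf("p%02d", 1:12)
  truth <- list(A = ids[1:5], B = ids[6:9])
  pred <- list(ids[c(1:4, 10)], ids[6:8])
  links <- cbind(ids[c(1, 2, 6)], ids[c(2, 3, 7)])
  tlinks <- cbind(ids[c(1, 2)], ids[c(2, 4)])
  relabel <- stats::setNames(sample(sprintf("q%02d", 1:12)), ids)
  g1 <- contentGrouping(pred, truth)
  g2 <- contentGrouping(lapply(pred, function(g) unname(relabel[g])),
                        lapply(truth, function(g) unname(relabel[g])))
  expect_equal(g1, g2)
  p1 <- contentPairing(links, tlinks)
  p2 <- contentPairing(cbind(relabel[links[, 1]], relabel[links[, 2]]),
                       cbind(relabel[tlinks[, 1]], relabel[tlinks[, 2]]))
  expect_equal(p1, p2)
})

test_that("ground truth derives links, groups and suspicious sets", {
  dir <- smallCorpusDir()
  truth <- readGroundTruth(file.path(dir, "truth.json"))
  # the small corpus plants one group of 3 panels in 3 documents
  expect_length(truth$imageGroups, 1)
  expect_length(truth$imageGroups[[1]], 3)
  expect_length(truth$imageLinks, 3)     # 3 choose 2 cross-document pairs
  expect_length(truth$suspiciousDocs, 3)
  expect_length(truth$docLinks, 3)
  expect_identical(truth$suspiciousPanels, sort(truth$imageGroups[[1]]))
  # no distractor-only document is suspicious
  expect_false(any(sprintf("doc%03d", 4:10) %in% truth$suspiciousDocs))
})

test_that("links referencing unknown ids raise a validation error", {
  expect_error(contentPairing(cbind("a", "zz"), cbind("a", "b"),
                              corpusIds = c("a", "b")), "absent")
})
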