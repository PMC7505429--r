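test_that("contingency matches hand-enumerable and brute-force cases", {
  # 2x2 OD case: truth = [1,1,0,0], pred = [1,0,0,0]
  truth <- matrix(c(1L, 1L, 0L, 0L), 2, 2)
  pred <- matrix(c(1L, 0L, 0L, 0L), 2, 2)
  t <- contingency(pred, truth, "OD")
  expect_identical(c(t$TP, t$FN, t$TN, t$FP), c(1L, 1L, 2L, 0L))
  expect_error(contingency(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
  set.seed(43)
  for (i in 1:50) {
    p <- random_mask(16); tr <- random_mask(16)
    for (reg in list(list("OD", c(1, 2)), list("OC", 2),
                     list("OD_rim", 1), list(0, 0))) {
      got <- contingency(p, tr, reg[[1]])
      want <- loop_contingency(p, tr, reg[[2]])
      expect_identical(got[c("TP", "TN", "FP", "FN")], want)
    }
  }
})

test_that("perfect prediction gives zero error counts and unit scores", {
  m <- random_mask(12)
  t <- contingency(m, m, "OD")
  expect_identical(c(t$FP, t$FN), c(0L, 0L))
  expect_equal(unname(sen_spc_acc(t)), c(1, 1, 1))
  expect_equal(unname(f1_precision_recall(t)["F1"]), 1)
})

test_that("sensitivity/specificity/accuracy follow the count definitions", {
  t <- list(TP = 3L, FN = 1L, TN = 5L, FP = 1L, P = 4L, N = 6L)
  class(t) <- "contingency"
  s <- sen_spc_acc(t)
  expect_equal(unname(s["SEN"]), 0.75)
  expect_equal(unname(s["SPC"]), 5 / 6)
  # prevalence-weighted form equals (TP+TN)/(P+N) = 0.8
  expect_equal(unname(s["ACC"]), 0.75 * 0.4 + (5 / 6) * 0.6)
  expect_equal(unname(s["ACC"]), 8 / 10)
})

test_that("the accuracy identity holds exactly on random tables", {
  set.seed(47)
  for (i in 1:100) {
    t <- list(TP = sample(0:50, 1), FN = sample(1:50, 1),
              TN = sample(1:50, 1), FP = sample(0:50, 1))
    t$P <- t$TP + t$FN; t$N <- t$TN + t$FP
    class(t) <- "contingency"
    s <- sen_spc_acc(t)
    expect_equal(unname(s["SEN"] * t$P / (t$P + t$N) + s["SPC"] * t$N / (t$P + t$N)),
                 (t$TP + t$TN) / (t$P + t$N), tolerance = 1e-14)
  }
})

test_that("F1 is the harmonic mean of precision and recall", {
  # precision 0.8 (TP=12, FP=3), recall 0.75 (FN=4)
  t <- list(TP = 12L, FP = 3L, FN = 4L, TN = 10L, P = 16L, N = 13L)
  class(t) <- "contingency"
  f <- f1_precision_recall(t)
  expect_equal(unname(f["Precision"]), 0.8)
  expect_equal(unname(f["Recall"]), 0.75)
  expect_equal(unname(f["F1"]), 2 * 0.8 * 0.75 / 1.55, tolerance = 1e-12)
  t0 <- list(TP = 0L, FP = 2L, FN = 3L, TN = 5L, P = 3L, N = 7L)
  class(t0) <- "contingency"
  expect_equal(unname(f1_precision_recall(t0)["F1"]), 0)
})

test_that("metrics agree with brute-force oracles on random masks", {
  set.seed(53)
  for (i in 1:100) {
    p <- random_mask(16); tr <- random_mask(16)
    lc <- loop_contingency(p, tr, c(1, 2))
    lc$P <- lc$TP + lc$FN; lc$N <- lc$TN + lc$FP
    t <- contingency(p, tr, "OD")
    if (t$P > 0 && t$N > 0) {
      s <- sen_spc_acc(t)
      expect_equal(unname(s["SEN"]), lc$TP / lc$P)
      expect_equal(unname(s["SPC"]), lc$TN / lc$N)
      expect_equal(unname(s["ACC"]), (lc$TP + lc$TN) / (lc$P + lc$N))
    }
    if (t$TP + t$FP > 0 && t$P > 0) {
      f <- f1_precision_recall(t)
      prec <- lc$TP / (lc$TP + lc$FP); rec <- lc$TP / lc$P
      want <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
      expect_equal(unname(f["F1"]), want)
    }
  }
})

test_that("radial contours recover analytic circle and square geometry", {
  ctr <- c(128, 128)
  circ <- circle_mask(256, ctr, 50)
  rc <- extract_radial_contour(circ, ctr, 24)
  expect_true(all(abs(rc$radii - 50) <= 0.75))
  # axis-aligned square of half-width a: radius a on axes, a*sqrt(2) diagonal
  sq <- matrix(FALSE, 256, 256)
  sq[98:158, 98:158] <- TRUE  # half-width 30 around (128,128)
  rs <- extract_radial_contour(sq, ctr, 8)
  expect_equal(rs$radii[c(1, 3, 5, 7)], rep(30, 4), tolerance = 0.7)
  expect_equal(rs$radii[c(2, 4, 6, 8)], rep(30 * sqrt(2), 4), tolerance = 1)
  expect_error(extract_radial_contour(matrix(FALSE, 8, 8), c(4, 4)),
               "empty region")
})

test_that("contours are invariant under joint translation of mask and centre", {
  m1 <- circle_mask(200, c(80, 90), 31)
  m2 <- circle_mask(200, c(110, 65), 31)
  r1 <- extract_radial_contour(m1, c(80, 90), 24)
  r2 <- extract_radial_contour(m2, c(110, 65), 24)
  expect_equal(r1$radii, r2$radii, tolerance = 1e-9)
})

test_that("BLE is zero on identical contours, symmetric, and exact on circles", {
  ctr <- c(128, 128)
  rc <- extract_radial_contour(circle_mask(256, ctr, 50), ctr, 24)
  expect_identical(ble(rc, rc), 0)
  r40 <- extract_radial_contour(circle_mask(256, ctr, 40), ctr, 24)
  expect_equal(ble(r40, rc), 10, tolerance = 0.3)
  expect_identical(ble(r40, rc), ble(rc, r40))
  bad <- rc; bad$angles <- bad$angles + 0.1
  expect_error(ble(rc, bad), "angle grids")
})

test_that("ROC-AUC handles separable, uninformative and degenerate scores", {
  truth <- c(rep(1, 5), rep(0, 5))
  expect_equal(roc_auc(10:1, truth), 1)
  expect_equal(roc_auc(rep(0.5, 10), truth), 0.5)
  expect_warning(a <- roc_auc(runif(6), rep(1, 6)), "single-class")
  expect_true(is.na(a))
})

test_that("ROC-AUC equals the rank (Mann-Whitney) statistic and pROC", {
  set.seed(59)
  for (i in 1:5) {
    n <- 30
    truth <- sample(0:1, n, replace = TRUE, prob = c(0.6, 0.4))
    if (length(unique(truth)) < 2) next
    sc <- rnorm(n) + truth
    got <- roc_auc(sc, truth)
    n1 <- sum(truth); n0 <- n - n1
    u <- (sum(rank(sc)[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    expect_equal(got, u, tolerance = 1e-12)
    p <- suppressMessages(pROC::auc(pROC::roc(truth, sc, quiet = TRUE)))
    expect_equal(got, as.numeric(p), tolerance = 1e-12)
  }
})
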