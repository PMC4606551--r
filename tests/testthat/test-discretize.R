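test_that("lowess normalization removes constant and linear trends", {
  withr::with_seed(1, {
    A <- runif(200, 6, 14)
    expect_true(all(abs(normalize_ma_lowess(rep(2.5, 200), A)) < 1e-6))

    M <- 2 * A + rnorm(200, sd = 0.01)
    out <- normalize_ma_lowess(M, A)
    slope <- coef(lm(out ~ A))[2]
    expect_lt(abs(slope), 0.01)

    # idempotence: renormalizing a normalized vector barely changes it
    again <- normalize_ma_lowess(out, A)
    expect_lt(sqrt(mean((again - out)^2)), 1e-3)
  })
})

test_that("lowess normalization validates its inputs", {
  expect_error(normalize_ma_lowess(1:5, 1:5), "at least 10")
  expect_error(normalize_ma_lowess(1:20, 1:10), "same length")
  expect_error(normalize_ma_lowess(rnorm(20), rnorm(20), span = 0), "span")
})

test_that("median/IQR scaling yields median 0 and IQR 1 per sample", {
  expr <- make_labels(matrix(c(1, 2, 3, 4, 5, 10, 20, 30, 40, 50), ncol = 2),
    gene_ids = paste0("g", 1:5), sample_ids = c("a", "b")
  )
  out <- normalize_median_iqr(expr)
  for (s in c("a", "b")) {
    expect_equal(median(out[[s]]), 0)
    expect_equal(unname(diff(quantile(out[[s]], c(.25, .75)))), 1)
  }
  withr::with_seed(2, {
    big <- make_labels(matrix(rnorm(1000), ncol = 1), sample_ids = "s1")
    scaled <- normalize_median_iqr(big)
    expect_lt(abs(median(scaled$s1)), 1e-12)
    expect_lt(abs(diff(quantile(scaled$s1, c(.25, .75))) - 1), 1e-12)
  })
  flat <- make_labels(matrix(c(1, 1, 1, 2, 3, 4), ncol = 2),
    sample_ids = c("flat", "ok")
  )
  expect_error(normalize_median_iqr(flat), "flat")
})

test_that("threshold labelling uses inclusive boundaries", {
  expr <- make_labels(matrix(c(1.2, -1.0, 0.0, 0.999), nrow = 1))
  out <- label_by_threshold(expr)
  expect_equal(unlist(out[1, -1], use.names = FALSE), c(1, -1, 0, 0))

  halves <- label_by_threshold(make_labels(matrix(c(0.5, -0.5), nrow = 1)),
    up = 0.5, down = -0.5
  )
  expect_equal(unlist(halves[1, -1], use.names = FALSE), c(1, -1))
  expect_error(label_by_threshold(expr, up = -1, down = 1), "exceed")
})

test_that("fold-change labelling is strict and baseline-relative", {
  expr <- make_labels(matrix(c(10, 10, 25, 20), nrow = 1),
    sample_ids = c("b1", "b2", "t1", "t2")
  )
  groups <- make_groups(c("ctrl", "ctrl", "case", "case"),
    sample_ids = c("b1", "b2", "t1", "t2")
  )
  out <- label_by_fold_change(expr, groups, "ctrl", 2, 0.5)
  expect_equal(out$t1, 1) # 25/10 > 2
  expect_equal(out$t2, 0) # 20/10 == 2, strict inequality
  expect_equal(out$b1, 0) # baseline sample at ratio 1
})

test_that("the 1.5-fold preset matches hand-evaluated boundaries", {
  expr <- make_labels(matrix(c(9, 9, 13.5, 13.6, 5.9), nrow = 1),
    sample_ids = c("c1", "c2", "k1", "k2", "k3")
  )
  groups <- make_groups(c("ctrl", "ctrl", "ko", "ko", "ko"),
    sample_ids = c("c1", "c2", "k1", "k2", "k3")
  )
  out <- discretize(expr, groups, preset = "fold1.5", baseline_group = "ctrl")
  expect_equal(out$k1, 0) # 13.5/9 = 1.5 exactly, strict
  expect_equal(out$k2, 1) # 13.6/9 > 1.5
  expect_equal(out$k3, -1) # 5.9/9 < 2/3
})

test_that("zero baselines error or skip as configured", {
  expr <- make_labels(matrix(c(0, 1, 5, 2.5), nrow = 2),
    gene_ids = c("zero", "fine"),
    sample_ids = c("b1", "t1")
  )
  groups <- make_groups(c("ctrl", "case"), sample_ids = c("b1", "t1"))
  expect_error(label_by_fold_change(expr, groups, "ctrl"), "zero")
  expect_warning(
    out <- label_by_fold_change(expr, groups, "ctrl",
      on_zero_baseline = "skip"
    ),
    "zero"
  )
  expect_equal(out$t1, c(0, 1)) # zero baseline skipped as 0; 2.5/1 > 2 -> +1
})

test_that("log-scale fold-change labelling compares differences", {
  expr <- make_labels(matrix(c(5, 5, 6.2, 3.9), nrow = 1),
    sample_ids = c("a1", "a2", "b1", "b2")
  )
  groups <- make_groups(c("A", "A", "B", "B"),
    sample_ids = c("a1", "a2", "b1", "b2")
  )
  out <- discretize(expr, groups, preset = "maqc-log", baseline_group = "A")
  expect_equal(out$b1, 1) # 6.2 - 5 > 1
  expect_equal(out$b2, -1) # 3.9 - 5 < -1
  expect_equal(out$a1, 0)
})

test_that("z-score labelling matches hand computations with sample sd", {
  out <- label_by_tsd(make_labels(matrix(c(0, 0, 10), nrow = 1)))
  expect_equal(unlist(out[1, -1], use.names = FALSE), c(0, 0, 1))

  sym <- label_by_tsd(make_labels(matrix(c(-3, 0, 3), nrow = 1)))
  expect_equal(unlist(sym[1, -1], use.names = FALSE), c(-1, 0, 1))

  flat <- label_by_tsd(make_labels(matrix(rep(4, 5), nrow = 1)))
  expect_equal(unlist(flat[1, -1], use.names = FALSE), rep(0, 5))
})

test_that("z-score labels are invariant to positive affine transforms", {
  withr::with_seed(3, {
    m <- matrix(rnorm(60), nrow = 5)
    base <- label_by_tsd(make_labels(m))
    for (i in 1:5) {
      a <- runif(1, 0.1, 10)
      b <- rnorm(1, sd = 5)
      shifted <- label_by_tsd(make_labels(a * m + b))
      expect_equal(shifted, base)
    }
  })
})

test_that("every labeller preserves within-gene value order", {
  withr::with_seed(8, {
    m <- matrix(rnorm(40, sd = 2), nrow = 4)
    expr <- make_labels(m)
    groups <- make_groups(rep(c("x", "y"), each = 5))
    labellers <- list(
      label_by_threshold(expr),
      label_by_tsd(expr),
      label_by_fold_change(
        make_labels(2^m), groups, "x",
        on_zero_baseline = "skip"
      )
    )
    for (lab in labellers) {
      for (i in 1:4) {
        v <- unlist(expr[i, -1])
        l <- unlist(lab[i, -1])
        expect_true(all(diff(l[order(v)]) >= 0))
      }
    }
  })
})

test_that("the tsd preset composes median/IQR scaling with z-score labels", {
  withr::with_seed(9, {
    expr <- make_labels(matrix(rnorm(80), nrow = 8))
    out <- discretize(expr, preset = "tsd")
    expect_equal(attr(out, "preset"), "tsd")
    expect_equal(out, {
      x <- label_by_tsd(normalize_median_iqr(expr))
      attr(x, "preset") <- "tsd"
      x
    })
    expect_true(all(unlist(out[-1]) %in% c(-1, 0, 1)))
  })
  expect_error(discretize(make_labels(matrix(1:20, nrow = 2)), preset = "fold2"),
    "baseline"
  )
})
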