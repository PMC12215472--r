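test_that("softmax normalizes, is shift-invariant, and matches the direct form", {
  expect_equal(softmax(c(0, 0, 0)), rep(1 / 3, 3))
  z <- c(-1.3, 0.4, 2.2, 0.0)
  expect_equal(softmax(z + 17.5), softmax(z), tolerance = 1e-12)
  # oracle: textbook form without max-subtraction, safe at this magnitude
  expect_equal(softmax(c(1, 2, 3)), exp(c(1, 2, 3)) / sum(exp(c(1, 2, 3))),
               tolerance = 1e-14)
  expect_equal(softmax(c(1, 2, 3)),
               c(0.09003057, 0.24472847, 0.66524096), tolerance = 1e-7)
  expect_error(softmax(c(1, NA, 2)), "index 2")
  expect_error(softmax(c(Inf, 0)), "index 1")
  expect_error(softmax(1), "length")
})

test_that("predict_label takes the lowest argmax index and its confidence", {
  expect_equal(predict_label(c(0.2, 0.5, 0.3)), list(index = 2L, confidence = 0.5))
  expect_equal(predict_label(c(0.5, 0.5))$index, 1L)
  set.seed(101)
  for (i in 1:50) {
    p <- as.numeric(random_panel_row(1, sample(3:8, 1)))
    # brute-force linear scan oracle
    best <- 1L
    for (j in seq_along(p)) if (p[j] > p[best]) best <- j
    expect_identical(predict_label(p)$index, best)
  }
})

test_that("weighted combination is the convex mixture of model beliefs", {
  k <- 4
  p <- random_panel_row(1, k)
  row <- rbind(p, p, p)
  res <- combine_weighted(row, c(0.2, 0.5, 0.3))
  expect_equal(unname(res$probs), as.numeric(p), tolerance = 1e-12)
  row2 <- random_panel_row(3, k)
  expect_equal(unname(combine_weighted(row2, c(1, 0, 0))$probs),
               unname(row2[1, ]), tolerance = 1e-12)
  # published fixed-weight configuration (0.3, 0.3, 0.4)
  row3 <- rbind(c(1, 0), c(1, 0), c(0, 1))
  colnames(row3) <- c("a", "b")
  expect_equal(unname(combine_weighted(row3, c(0.3, 0.3, 0.4))$probs),
               c(0.6, 0.4), tolerance = 1e-12)
  expect_error(combine_weighted(row3, c(0.5, 0.5)), "weights")
  expect_error(combine_weighted(row3, c(0.5, 0.4, 0.2)), "sum")
})

test_that("combine_weighted is permutation-equivariant", {
  set.seed(7)
  for (i in 1:20) {
    row <- random_panel_row(4, 5)
    w <- normalize_weights(stats::rexp(4))
    perm <- sample(4)
    r1 <- combine_weighted(row, w)
    r2 <- combine_weighted(row[perm, ], w[perm])
    expect_equal(unname(r1$probs), unname(r2$probs), tolerance = 1e-12)
    expect_identical(r1$predicted_index, r2$predicted_index)
  }
})

test_that("mean vote equals uniform weighted averaging exactly", {
  set.seed(12)
  for (i in 1:20) {
    m <- sample(2:5, 1)
    row <- random_panel_row(m, 3)
    expect_identical(mean_vote(row)$probs,
                     combine_weighted(row, rep(1 / m, m))$probs)
  }
  single <- random_panel_row(1, 3)
  expect_equal(unname(mean_vote(single)$probs), unname(single[1, ]))
  expect_equal(unname(mean_vote(rbind(c(.8, .2), c(.4, .6)))$probs), c(.6, .4))
})

test_that("majority vote picks the modal label with the stated tie rules", {
  row <- row_with_confidences(c(0.9, 0.8, 0.7), 3, top = c(1L, 1L, 2L))
  res <- majority_vote(row)
  expect_equal(res$predicted_index, 1L)
  expect_equal(unname(res$probs), c(2 / 3, 1 / 3, 0))
  # three-way tie: highest single-model confidence wins
  row2 <- row_with_confidences(c(0.5, 0.9, 0.6), 3, top = c(1L, 2L, 3L))
  expect_equal(majority_vote(row2)$predicted_index, 2L)
  # equal-confidence tie falls back to the lowest class index
  row3 <- row_with_confidences(c(0.6, 0.6), 4, top = c(3L, 2L))
  expect_equal(majority_vote(row3)$predicted_index, 2L)
  # counting oracle over random rows
  set.seed(33)
  for (i in 1:30) {
    r <- random_panel_row(5, 4)
    votes <- apply(r, 1, which.max)
    counts <- sapply(1:4, function(cl) sum(votes == cl))
    res <- majority_vote(r)
    expect_equal(unname(res$probs), counts / 5)
    expect_true(counts[res$predicted_index] == max(counts))
  }
})

test_that("fuzzy combination reduces to mean voting under equal confidences", {
  f <- build_default_fis(3)
  set.seed(91)
  for (i in 1:100) {
    conf <- runif(1, 0.4, 0.99)
    tops <- sample(4, 3, replace = TRUE)
    row <- row_with_confidences(rep(conf, 3), 4, top = tops)
    expect_equal(fuzzy_combine(row, f)$probs, mean_vote(row)$probs,
                 tolerance = 1e-9)
  }
})

test_that("fuzzy combination upweights the confident model and stays normalized", {
  f <- build_default_fis(3)
  row <- row_with_confidences(c(0.99, 0.60, 0.60), 5, top = c(1L, 2L, 2L))
  res <- fuzzy_combine(row, f)
  expect_gt(res$weights[1], res$weights[2])
  expect_equal(unname(res$weights[2]), unname(res$weights[3]),
               tolerance = 1e-12)
  expect_equal(sum(res$probs), 1, tolerance = 1e-9)
  expect_error(fuzzy_combine(random_panel_row(4, 3), f), "inputs")
})

test_that("every fusion strategy outputs a normalized convex combination", {
  f <- build_default_fis(3)
  set.seed(55)
  for (i in 1:25) {
    row <- random_panel_row(3, 6)
    for (res in list(mean_vote(row), majority_vote(row),
                     combine_weighted(row, normalize_weights(rexp(3))),
                     fuzzy_combine(row, f))) {
      expect_true(all(res$probs >= -1e-12))
      expect_equal(sum(res$probs), 1, tolerance = 1e-9)
      # convexity bound: ensemble confidence cannot exceed the largest
      # single-model mass on the chosen class (vote shares exempted)
      if (res$strategy != "majority") {
        expect_lte(res$confidence, max(row[, res$predicted_index]) + 1e-9)
      }
    }
  }
})

test_that("prediction panels round-trip through the CSV exchange format", {
  probs <- array(NA_real_, c(3, 3, 2))
  set.seed(4)
  for (j in 1:2) probs[, , j] <- random_panel_row(3, 3)
  panel <- prediction_panel(probs, c("finch", "oriole", "swallow"),
                            c("m1", "m2"),
                            sample_ids = c("a", "b", "c"),
                            true_labels = c("finch", "oriole", "swallow"))
  path <- tempfile(fileext = ".csv")
  write_predictions(panel, path)
  back <- read_predictions(path)
  expect_identical(back$classes, panel$classes)
  expect_identical(back$model_ids, panel$model_ids)
  expect_identical(back$sample_ids, panel$sample_ids)
  expect_identical(back$true_labels, panel$true_labels)
  expect_equal(back$probs, panel$probs, tolerance = 1e-11)

  jpath <- tempfile(fileext = ".json")
  write_predictions(panel, jpath)
  backj <- read_predictions(jpath)
  expect_equal(backj$probs, panel$probs, tolerance = 1e-11)
})

test_that("exchange-format violations are rejected with their line number", {
  lines <- c("sample_id,model_id,true_label,x,y",
             "s1,m1,x,0.500000,0.300000",
             "s2,m1,x,0.500000,0.500000")
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  expect_error(read_predictions(path), "line 2")
  # missing model block
  lines2 <- c("sample_id,model_id,true_label,x,y",
              "s1,m1,x,0.5,0.5", "s1,m2,x,0.5,0.5", "s2,m1,x,0.5,0.5")
  writeLines(lines2, path)
  expect_error(read_predictions(path), "rows")
  # unknown true label
  lines3 <- c("sample_id,model_id,true_label,x,y", "s1,m1,zz,0.5,0.5")
  writeLines(lines3, path)
  expect_error(read_predictions(path), "vocabulary")
})

test_that("an empty panel is valid and round-trips", {
  panel <- prediction_panel(array(numeric(0), c(0, 2, 1)),
                            c("x", "y"), "m1", sample_ids = character(0))
  path <- tempfile(fileext = ".csv")
  write_predictions(panel, path)
  back <- read_predictions(path)
  expect_equal(length(back$sample_ids), 0L)
  expect_identical(back$classes, c("x", "y"))
})

test_that("fuse_panel returns the combined-output contract for all strategies", {
  panel <- toy_panel()
  for (strat in c("fuzzy", "mean", "majority")) {
    out <- fuse_panel(panel, strat)
    expect_identical(attr(out, "strategy"), strat)
    expect_identical(names(out)[1:3],
                     c("sample_id", "predicted_label", "confidence"))
    expect_true(all(panel$classes %in% names(out)))
    expect_true(all(paste0("weight_", panel$model_ids) %in% names(out)))
    expect_equal(rowSums(out[, panel$classes]), rep(1, 6), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  outw <- fuse_panel(panel, "weighted", weights = c(0.7, 0.3))
  expect_equal(unname(unlist(outw[1, c("weight_densenet_a", "weight_resnet_b")])),
               c(0.7, 0.3))
  # average-confidence mode applies one shared weight vector
  outa <- fuse_panel(panel, "fuzzy", conf_mode = "average")
  w <- as.matrix(outa[, paste0("weight_", panel$model_ids)])
  expect_equal(max(apply(w, 2, function(col) diff(range(col)))), 0)
})
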