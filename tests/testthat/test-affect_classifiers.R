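test_that("network specifications enforce the family bounds", {
  expect_error(network_spec(5, c(64, 16)), "input_size")
  expect_error(network_spec(8, c(64)), "hidden layers")
  expect_error(network_spec(8, c(64, 16, 8, 8)), "hidden layers")
  expect_error(network_spec(8, c(300, 16)), "\\[8, 256\\]")
  expect_error(network_spec(8, c(64, 4)), "\\[8, 256\\]")
  expect_s3_class(network_spec(28, c(256, 8)), "network_spec")
})

test_that("parameter counts are deterministic functions of the spec", {
  # 8*64+64 + 64*16+16 + 16*1+1 = 1633
  expect_equal(n_params(network_spec(8, c(64, 16))), 1633)
  sp3 <- network_spec(6, c(16, 8, 8), output = "softmax")
  expect_equal(n_params(sp3, n_classes = 3),
               6 * 16 + 16 + 16 * 8 + 8 + 8 * 8 + 8 + 8 * 3 + 3)
  m <- build_network(network_spec(8, c(64, 16)), seed = 1)
  expect_equal(sum(vapply(m$par$W, length, 0)) +
                 sum(vapply(m$par$b, length, 0)), 1633)
})

test_that("task presets carry the tuned layouts and matching input sizes", {
  tk <- task_spec("NV+MV_vs_PV")
  expect_equal(tk$network$hidden_sizes, c(64L, 16L))
  expect_equal(tk$network$output, "sigmoid")
  expect_equal(tk$network$input_size, 8L)

  tk3 <- task_spec("HA_vs_MA_vs_LA")
  expect_equal(tk3$network$hidden_sizes, c(256L, 64L, 32L))
  expect_equal(tk3$network$output, "softmax")
  expect_equal(tk3$network$input_size, 6L)

  tkq <- task_spec("quadrant")
  expect_equal(tkq$network$hidden_sizes, c(128L, 64L, 16L))
  expect_equal(length(tkq$groups), 4)
  expect_equal(tkq$network$input_size, 7L)

  expect_equal(task_spec("PV_vs_NV")$network$hidden_sizes, c(32L, 8L))
  expect_equal(task_spec("MV_vs_NV")$network$hidden_sizes, c(64L, 32L))
  expect_equal(task_spec("LA+MA_vs_HA")$network$hidden_sizes,
               c(128L, 32L))
  expect_error(task_spec("nope"), "unknown task")
})

test_that("task class mapping partitions and excludes correctly", {
  labels <- data.frame(arousal = c("LA", "MA", "HA", "HA"),
                       valence = c("NV", "MV", "PV", "NV"),
                       quadrant = c("LANV", "MAMV", "LAPV", "HANV"))
  tk <- task_spec("LA+MA_vs_HA")
  expect_equal(oculaff:::task_classes(tk, labels),
               c("LA+MA", "LA+MA", "HA", "HA"))
  tk2 <- task_spec("PV_vs_NV")
  expect_equal(oculaff:::task_classes(tk2, labels),
               c("NV", NA, "PV", "NV"))
})

test_that("training and evaluation are reproducible given the seed", {
  d <- sample_feature_classes(40, separation = 1.5, seed = 19)
  lab <- data.frame(arousal = ifelse(d$y == "A", "HA", "LA"))
  r1 <- train_eval(d$X, lab, "HA_vs_LA", seed = 5, epochs = 15,
                   patience = 5)
  r2 <- train_eval(d$X, lab, "HA_vs_LA", seed = 5, epochs = 15,
                   patience = 5)
  expect_identical(r1$folds, r2$folds)
  expect_identical(r1$fold_assignment, r2$fold_assignment)
  expect_equal(nrow(r1$folds), 10)
  expect_true(all(r1$folds$accuracy >= 0 & r1$folds$accuracy <= 1))
  expect_true(all(r1$folds$auc >= 0 & r1$folds$auc <= 1))
})

test_that("architecture search returns the smallest equal-error network", {
  d <- sample_feature_classes(80, separation = 4, seed = 3)
  lab <- data.frame(arousal = ifelse(d$y == "A", "HA", "LA"))
  # grid of one -> that one
  one <- architecture_search(d$X, lab, "HA_vs_LA", grid = list(c(16, 8)),
                             seed = 2, epochs = 15, patience = 5)
  expect_equal(one$hidden_sizes, c(16L, 8L))
  # separable data: all near-zero error, smallest network wins
  g <- architecture_search(d$X, lab, "HA_vs_LA",
                           grid = list(c(128, 64), c(32, 8)), seed = 2,
                           epochs = 30, patience = 10)
  srch <- attr(g, "search")
  expect_true(all(srch$test_error <= 0.1))
  expect_equal(g$hidden_sizes, c(32L, 8L))
  expect_error(architecture_search(d$X, lab, "HA_vs_LA", grid = list()),
               "empty")
})

test_that("class imbalance below the stratification floor errors", {
  d <- sample_feature_classes(20, separation = 1, seed = 1)
  lab <- data.frame(arousal = c(rep("HA", 39), "LA"))
  expect_error(train_eval(d$X, lab, "HA_vs_LA", seed = 1, epochs = 5),
               "stratification error")
})
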