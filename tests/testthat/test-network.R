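test_that("the six presets reproduce the published layer stacks", {
  fmt <- function(name) {
    vapply(architecture_spec(name)$layers, function(l)
      paste(l$type, if (is.null(l$units)) l$rate else l$units), character(1))
  }
  expect_identical(fmt("M0"), c("embedding 64", "bilstm 128", "dropout 0.5",
                                "dense 64", "dropout 0.5", "dense 4"))
  expect_identical(fmt("M1")[2], "dense 128")
  expect_true(!any(grepl("bilstm", fmt("M1"))))
  expect_identical(fmt("M2"), c("embedding 64", "bilstm 128", "dropout 0.5",
                                "dense 64", "dropout 0.5", "dense 32",
                                "dropout 0.5", "dense 4"))
  expect_identical(fmt("M3"), c("embedding 64", "bilstm 128", "dropout 0.5",
                                "dense 4"))
  expect_identical(fmt("M4")[1:2], c("embedding 128", "bilstm 256"))
  expect_identical(fmt("M5")[1:2], c("embedding 32", "bilstm 64"))
  expect_error(architecture_spec("M9"), "unknown architecture")
})

test_that("parameter counts are monotone in the width scaling", {
  expect_gt(n_params(build_model("M4")), n_params(build_model("M0")))
  expect_gt(n_params(build_model("M0")), n_params(build_model("M5")))
})

test_that("untrained models emit row-stochastic outputs", {
  m <- build_model("M5", seed = 3)
  set.seed(3)
  fmat <- matrix(finding_vocabulary()$symbol[sample.int(10, 32, TRUE)],
                 nrow = 2)
  probs <- predict(m, fmat, type = "prob")
  expect_identical(dim(probs), c(2L, 16L, 4L))
  expect_true(all(abs(apply(probs, c(1, 2), sum) - 1) < 1e-5))
  expect_true(all(probs >= 0))
})

test_that("M1 predictions are position-wise independent, M0's are not", {
  base <- rep(".", 16)
  mod <- chart_at(`5` = "f")
  for (arch in c("M1", "M0")) {
    m <- build_model(arch, seed = 5)
    p1 <- predict(m, matrix(base, 1), type = "prob")
    p2 <- predict(m, matrix(mod, 1), type = "prob")
    other <- setdiff(1:16, 5)
    if (arch == "M1") {
      expect_identical(p1[1, other, ], p2[1, other, ])
      expect_false(identical(p1[1, 5, ], p2[1, 5, ]))
    } else {
      expect_false(identical(p1[1, other, ], p2[1, other, ]))
    }
  }
})

test_that("analytic gradients match central finite differences", {
  set.seed(1)
  layers <- tiny_arch()$layers
  # drop the dropout layers: the check runs the deterministic forward pass
  layers <- Filter(function(l) l$type != "dropout", layers)
  w <- dentplan:::cpp_init_weights(layers, 10L, 7L)
  X <- matrix(sample(0:9, 3 * 16, TRUE), 3, 16)
  Y <- matrix(sample(0:3, 3 * 16, TRUE), 3, 16)
  res <- dentplan:::cpp_loss_grad(layers, w, X, Y, 10L)
  eps <- 1e-6
  set.seed(2)
  for (k in seq_along(w)) for (j in seq_along(w[[k]])) {
    idxs <- sample.int(length(w[[k]][[j]]), min(12, length(w[[k]][[j]])))
    for (idx in idxs) {
      wp <- w; wp[[k]][[j]][idx] <- wp[[k]][[j]][idx] + eps
      wm <- w; wm[[k]][[j]][idx] <- wm[[k]][[j]][idx] - eps
      num <- (dentplan:::cpp_loss_grad(layers, wp, X, Y, 10L)$loss -
              dentplan:::cpp_loss_grad(layers, wm, X, Y, 10L)$loss) / (2 * eps)
      expect_equal(res$gradients[[k]][[j]][idx], num, tolerance = 1e-4)
    }
  }
})

test_that("training honours the protocol contracts", {
  col <- small_collection()
  cases <- draw_ncal(col, 60, seed = 21)
  cfg <- training_config(seed = 21, max_epochs = 60)
  m <- train_model(build_model(tiny_arch(), seed = 21), cases, cfg)

  h <- m$history
  expect_lte(m$stopped_epoch, cfg$max_epochs)
  expect_lte(m$best_epoch, m$stopped_epoch)
  expect_identical(nrow(h), m$stopped_epoch)

  # restored validation loss equals the curve minimum
  expect_equal(m$best_val_loss, min(h$val_loss), tolerance = 1e-12)
  expect_identical(m$best_epoch, which.min(h$val_loss))
  expect_lte(h$val_loss[m$best_epoch], h$val_loss[1])

  # learning-rate trace: non-increasing, floored, and halving-only
  expect_true(all(diff(h$lr) <= 0))
  expect_true(all(h$lr >= cfg$lr_floor))
  expect_true(all(h$lr <= cfg$initial_lr))

  # 80/20 inner split
  expect_identical(m$n_train, 48L)
  expect_identical(m$n_val, 12L)
})

test_that("training on the minimum viable set works; smaller errors", {
  col <- small_collection()
  cases <- draw_ncal(col, 10, seed = 31)
  m <- train_model(build_model(tiny_arch(), seed = 31), cases,
                   fast_config(seed = 31))
  expect_true(m$trained)
  expect_identical(m$n_train + m$n_val, 10L)
  too_few <- draw_ncal(col, 9, seed = 31)
  expect_error(train_model(build_model(tiny_arch()), too_few, fast_config()),
               "at least 10 cases")
})

test_that("training is reproducible from its seed", {
  col <- small_collection()
  cases <- draw_ncal(col, 40, seed = 13)
  cfg <- fast_config(seed = 13)
  m1 <- train_model(build_model(tiny_arch(), seed = 13), cases, cfg)
  m2 <- train_model(build_model(tiny_arch(), seed = 13), cases, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$weights, m2$weights)
  m3 <- train_model(build_model(tiny_arch(), seed = 14), cases,
                    fast_config(seed = 14))
  expect_false(identical(m1$history$loss, m3$history$loss))
})

test_that("evaluation arithmetic is exact on hand-built predictions", {
  truth <- matrix(sample(0:3, 3 * 16, TRUE), 3, 16)
  pred <- truth
  ev <- dentplan:::evaluate_predictions(pred, truth)
  expect_equal(ev$exact_set_accuracy, 100)
  expect_equal(ev$per_tooth_accuracy, 100)

  # one wrong tooth in one case: exact 2/3, per-tooth 47/48
  pred[2, 7] <- (truth[2, 7] + 1) %% 4
  ev <- dentplan:::evaluate_predictions(pred, truth)
  expect_equal(ev$exact_set_accuracy, 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(ev$per_tooth_accuracy, 100 * 47 / 48, tolerance = 1e-12)
  expect_identical(sum(ev$confusion), 48L)
  expect_lte(ev$exact_set_accuracy, ev$per_tooth_accuracy)

  # all-"-" predictor misses every case that needs treatment
  need <- matrix(1L, 2, 16)
  allnone <- matrix(0L, 2, 16)
  expect_equal(dentplan:::evaluate_predictions(allnone, need)$exact_set_accuracy, 0)
})

test_that("exact-set never exceeds per-tooth accuracy on real models", {
  col <- small_collection()
  m <- train_model(build_model("M5", seed = 17), draw_ncal(col, 80, 17),
                   fast_config(seed = 17))
  ev <- evaluate_model(m, collection_split(col, "test"))
  expect_lte(ev$exact_set_accuracy, ev$per_tooth_accuracy)
  expect_identical(sum(ev$confusion), 16L * ev$n_cases)

  pl <- predict_plan(m, rep(".", 16))
  expect_s3_class(pl, "plan_chart")
  expect_true(all(as.character(pl) %in% c("-", "K", "B", "E")))
})
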