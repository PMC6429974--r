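test_that("trailing moving average matches its closed form", {
  expect_equal(moving_average(rep(2.5, 50), 20), rep(2.5, 50))
  x <- rnorm(30)
  expect_equal(moving_average(x, 1), x)
  # unit step: value at step + j equals (j+1)/20 while the window fills
  step <- c(rep(0, 50), rep(1, 50))
  sm <- moving_average(step, 20)
  for (j in 0:19) expect_equal(sm[51 + j], (j + 1) / 20)
  expect_equal(sm[80], 1)
  # partial head windows average available history only
  expect_equal(moving_average(1:5, 3), c(1, 1.5, 2, 3, 4))
  expect_error(moving_average(numeric(0), 5), "empty")
})

test_that("smoothing then averaging equals averaging then smoothing", {
  set.seed(51)
  raw <- matrix(sample(0:3, 200 * 10, replace = TRUE), 200, 10)
  a <- rowMeans(apply(raw, 2, moving_average, window = 20))
  b <- moving_average(rowMeans(raw), 20)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("confusion matrices tally hand-built examples", {
  true <- c(0, 0, 0, 1, 1, 2, 2, 2, 3, 3, 3, 3)
  pred <- c(0, 0, 1, 1, 2, 2, 2, 3, 3, 3, 3, 0)
  cm <- confusion_matrix(true, pred)
  expect_equal(sum(cm), 12)
  expect_equal(unname(diag(cm)), c(2, 1, 2, 3))
  expect_equal(cm["3", "0"], 1L)
  expect_equal(cm["0", "1"], 1L)
  expect_error(confusion_matrix(c(0, 4), c(0, 0)), "0, 1, 2, 3")
  # perfect predictions give a diagonal matrix
  expect_equal(sum(confusion_matrix(true, true)) ,
               sum(diag(confusion_matrix(true, true))))
  # constant predictions give a single nonzero column
  cm0 <- confusion_matrix(true, rep(0, 12))
  expect_equal(unname(colSums(cm0)), c(12L, 0L, 0L, 0L))
})

test_that("kappa matches recomputation from expanded label pairs", {
  expect_equal(cohen_kappa(diag(c(5, 3, 8, 1))), 1)
  expect_equal(cohen_kappa(matrix(7, 4, 4)), 0)
  expect_equal(cohen_kappa(matrix(c(10, 0, 0, 0), 2, 2)), 0)  # degenerate
  set.seed(52)
  for (i in 1:200) {
    cm <- matrix(rpois(16, 5), 4, 4)
    if (sum(cm) == 0) next
    expect_equal(cohen_kappa(cm), kappa_pairs_oracle(cm), tolerance = 1e-12)
  }
})

test_that("kappa of randomly paired labels is near zero at large n", {
  set.seed(53)
  a <- sample(0:3, 20000, replace = TRUE)
  b <- sample(0:3, 20000, replace = TRUE)
  expect_lt(abs(cohen_kappa(confusion_matrix(a, b))), 0.05)
})

test_that("per-class metrics match hand arithmetic and the rounding tie rule", {
  # perfect continuous trace
  lab <- c(0, 0, 1, 1, 2, 2, 3, 3)
  m <- per_class_metrics(lab, as.numeric(lab))
  expect_true(all(m$per_class$accuracy == 100))
  expect_true(all(m$per_class$mse == 0))
  # class-0 beats at 0.5: MSE 0.25 but still accurate (0.5 rounds DOWN to 0)
  m2 <- per_class_metrics(rep(0, 4), rep(0.5, 4))
  expect_equal(m2$per_class$accuracy[1], 100)
  expect_equal(m2$per_class$mse[1], 0.25)
  # hand-computed 8-beat example
  lab3 <- c(0, 0, 1, 1, 2, 2, 3, 3)
  tr3 <- c(0.2, 0.8, 1.1, 2.0, 1.6, 2.4, 2.5, 3.0)
  m3 <- per_class_metrics(lab3, tr3)
  expect_equal(m3$per_class$accuracy, c(50, 50, 100, 50))
  expect_equal(m3$per_class$mse[1], mean(c(0.2^2, 0.8^2)))
  expect_equal(m3$per_class$mse[4], mean(c(0.5^2, 0)))
  expect_equal(m3$overall_accuracy, 100 * 5 / 8)
  # absent class reported as missing
  m4 <- per_class_metrics(c(0, 0, 1), c(0, 0, 1))
  expect_true(is.na(m4$per_class$accuracy[3]))
})

test_that("cohort aggregation uses median [IQR] and pooled (not averaged) kappa", {
  mk <- function(acc0) {
    list(per_class = data.frame(class = 0:3, n = 10,
                                accuracy = c(acc0, 50, 50, 50),
                                mse = c(0.1, 0.3, 0.3, 0.3)),
         overall_accuracy = acc0, overall_mse = 0.25)
  }
  agg <- aggregate_cohort(list(mk(90), mk(95), mk(100)))
  row <- agg$table[agg$table$metric == "accuracy" & agg$table$class == "0", ]
  expect_equal(row$median, 95)
  expect_equal(row$iqr, 10)
  # a single subject has zero IQR
  agg1 <- aggregate_cohort(list(mk(90)))
  expect_equal(agg1$table$iqr[agg1$table$class == "0" &
                                agg1$table$metric == "accuracy"], 0)
  # pooled kappa equals kappa of the summed matrices, not the mean of kappas
  set.seed(54)
  cms <- replicate(3, matrix(rpois(16, 4), 4, 4), simplify = FALSE)
  agg2 <- aggregate_cohort(list(mk(90), mk(95), mk(100)), cms)
  expect_equal(agg2$pooled_kappa, cohen_kappa(cms[[1]] + cms[[2]] + cms[[3]]))
  expect_false(isTRUE(all.equal(agg2$pooled_kappa,
                                mean(vapply(cms, cohen_kappa, numeric(1))))))
})

test_that("severity trend separates rising from stagnating traces", {
  marks <- protocol_marks(0, 100, 700, "presyncope")
  ons <- seq(0, 700, by = 1)
  rising <- pmax(0, (ons - 100) / 600) * 3
  expect_equal(severity_trend(rising, ons, marks), "increase")
  flat <- rep(1, length(ons))
  expect_equal(severity_trend(flat, ons, marks), "stagnation")
  # plateau reached early in LBNP: no further rise, hence stagnation
  plateau <- pmin(pmax(0, (ons - 100) / 150), 1) * 1.5
  expect_equal(severity_trend(plateau, ons, marks), "stagnation")
  expect_error(severity_trend(rising[ons >= 100], ons[ons >= 100], marks),
               "baseline")
})
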