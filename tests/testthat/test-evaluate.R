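toy_pred <- function() {
  # four ranked predictions: gold, non-gold, gold, non-gold
  grn_network(tibble::tibble(
    regulator = c("A", "A", "B", "B"), target = c("B", "C", "C", "A"),
    weight = c(0.9, 0.8, 0.7, 0.6)))
}
toy_gold <- tibble::tibble(regulator = c("A", "B"), target = c("B", "C"))
toy_universe4 <- tibble::tibble(regulator = c("A", "A", "B", "B"),
                                target = c("B", "C", "C", "A"))

test_that("confusion counts follow the four definitions over the universe", {
  genes <- c("A", "B", "C")
  # full universe of 6 ordered non-self pairs, threshold between ranks 2 and 3
  cm <- confusion_at_threshold(toy_pred(), toy_gold, tau = 0.75)
  expect_identical(as.integer(cm), c(1L, 1L, 1L, 3L))
  # tau = 0 predicts every pair in the universe
  cm0 <- confusion_at_threshold(toy_pred(), toy_gold, tau = 0)
  expect_identical(cm0$tp + cm0$fp, 6L)
  expect_identical(cm0$fn, 0L)
  # tau above the maximum weight predicts nothing
  cmx <- confusion_at_threshold(toy_pred(), toy_gold, tau = 0.95)
  expect_identical(as.integer(cmx), c(0L, 0L, 2L, 4L))
  # gold edges outside an explicit universe violate the contract
  expect_error(
    confusion_at_threshold(toy_pred(),
                           tibble::tibble(regulator = "C", target = "A"),
                           universe = toy_universe4, tau = 0.5),
    class = "bmanet_universe_error")
})

test_that("the hand-enumerated toy curve gives step-AUPR 5/6 and trapezoid AUROC 0.75", {
  ev <- evaluate_network(toy_pred(), toy_gold, universe = toy_universe4)
  # steps: recall 1/2 at precision 1, recall 1 at precision 2/3
  expect_equal(ev$aupr, 0.5 * 1 + 0.5 * (2 / 3), tolerance = 1e-12)
  expect_equal(ev$aupr, 0.8333, tolerance = 1e-4)
  expect_equal(ev$auroc, 0.75, tolerance = 1e-12)
  expect_equal(as.numeric(ev$points$tp), c(1, 1, 2, 2))
  expect_equal(glance(ev)$aupr, ev$aupr)
  expect_identical(nrow(tidy(ev)), 4L)
})

test_that("perfect rankings score 1 and curve invariants hold", {
  set.seed(1)
  genes <- paste0("G", 1:8)
  gold <- tibble::tibble(regulator = genes[1:5], target = genes[2:6])
  pred_w <- c(runif(5, 0.8, 1), runif(10, 0.01, 0.3))
  universe <- tidyr::expand_grid(regulator = genes, target = genes)
  universe <- universe[universe$regulator != universe$target, ]
  nongold <- dplyr::anti_join(universe, gold, by = c("regulator", "target"))
  pred <- grn_network(tibble::tibble(
    regulator = c(gold$regulator, nongold$regulator[1:10]),
    target = c(gold$target, nongold$target[1:10]),
    weight = pred_w))
  ev <- evaluate_network(pred, gold, universe)
  expect_equal(ev$aupr, 1)
  expect_equal(ev$auroc, 1)
  expect_true(all(diff(ev$points$recall) >= 0))
  expect_true(all(ev$points$tp + ev$points$fn == nrow(gold)))
  expect_true(all(ev$points$tp + ev$points$fp + ev$points$fn + ev$points$tn ==
                    nrow(universe)))
})

test_that("areas are invariant under strictly monotone weight transforms", {
  for (seed in 1:5) {
    set.seed(seed)
    genes <- paste0("G", 1:7)
    universe <- tidyr::expand_grid(regulator = genes, target = genes)
    universe <- universe[universe$regulator != universe$target, ]
    gold <- universe[sample(nrow(universe), 8), ]
    picks <- sample(nrow(universe), 20)
    pred <- tibble::tibble(regulator = universe$regulator[picks],
                           target = universe$target[picks],
                           weight = runif(20, 0.1, 0.9))
    ev1 <- evaluate_network(grn_network(pred), gold, universe)
    pred2 <- pred
    pred2$weight <- pred$weight^3  # strictly monotone on (0, 1]
    ev2 <- evaluate_network(grn_network(pred2), gold, universe)
    expect_equal(ev1$aupr, ev2$aupr, tolerance = 1e-12)
    expect_equal(ev1$auroc, ev2$auroc, tolerance = 1e-12)
  }
})

test_that("tie-grouped AUROC equals the pair-counting concordance formula", {
  # independent oracle: AUROC = P(gold > non-gold) + 0.5 P(tie) over all
  # gold x non-gold pairs of scores
  for (seed in 6:10) {
    set.seed(seed)
    genes <- paste0("G", 1:6)
    universe <- tidyr::expand_grid(regulator = genes, target = genes)
    universe <- universe[universe$regulator != universe$target, ]
    gold <- universe[sample(nrow(universe), 6), ]
    picks <- sample(nrow(universe), 15)
    # coarse weights force ties
    pred <- tibble::tibble(regulator = universe$regulator[picks],
                           target = universe$target[picks],
                           weight = sample(seq(0.1, 0.9, 0.2), 15, TRUE))
    ev <- evaluate_network(grn_network(pred), gold, universe)
    key <- paste(universe$regulator, universe$target)
    w <- setNames(rep(0, nrow(universe)), key)
    w[paste(pred$regulator, pred$target)] <- pred$weight
    is_gold <- key %in% paste(gold$regulator, gold$target)
    pos <- w[is_gold]; neg <- w[!is_gold]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(ev$auroc, mean(cmp), tolerance = 1e-12)
  }
})

test_that("random scores give AUROC near one half and empty gold errors", {
  set.seed(11)
  genes <- paste0("G", 1:12)
  universe <- tidyr::expand_grid(regulator = genes, target = genes)
  universe <- universe[universe$regulator != universe$target, ]
  aurocs <- vapply(1:20, function(i) {
    gold <- universe[sample(nrow(universe), 20), ]
    pred <- tibble::tibble(regulator = universe$regulator,
                           target = universe$target,
                           weight = runif(nrow(universe), 0.01, 1))
    evaluate_network(grn_network(pred), gold, universe)$auroc
  }, numeric(1))
  expect_lt(abs(mean(aurocs) - 0.5), 0.05)
  expect_error(evaluate_network(toy_pred(), toy_gold[0, ]),
               class = "bmanet_eval_error")
})

test_that("evaluation plots build for both curve types", {
  ev <- evaluate_network(toy_pred(), toy_gold, universe = toy_universe4)
  expect_s3_class(autoplot(ev, "pr"), "ggplot")
  expect_s3_class(autoplot(ev, "roc"), "ggplot")
})
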