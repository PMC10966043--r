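test_that("MAE loss matches its definition on vectors", {
  expect_equal(mae_loss(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_equal(mae_loss(c(1, 0), c(0.5, 0.5)), 0.5)
  expect_equal(mae_loss(c(1, 0, 0), c(0.7, 0.2, 0.1)), 0.2)
  expect_error(mae_loss(c(1, 0), c(1, 0, 0)), class = "specfuse_domain_error")
})

test_that("accuracy is 100 * trace / total of the confusion matrix", {
  cm <- matrix(c(3, 1, 2, 4), 2, 2)
  expect_equal(accuracy(cm), 70)
  expect_equal(accuracy(diag(c(5, 5, 7))), 100)
  # a 17-sample hold-out quantizes accuracy to multiples of 1/17
  cm17 <- matrix(0, 2, 2); cm17[1, 1] <- 9; cm17[2, 2] <- 5; cm17[1, 2] <- 3
  expect_equal(accuracy(cm17), 100 * 14 / 17, tolerance = 1e-12)
  expect_equal(round(accuracy(cm17), 1), 82.4)
  expect_error(accuracy(matrix(0, 2, 2)), class = "specfuse_domain_error")
  expect_error(accuracy(matrix(1, 2, 3)), class = "specfuse_domain_error")
})

test_that("confusion_matrix counts agree with raw predictions", {
  set.seed(13)
  truth <- sample(1:3, 50, replace = TRUE)
  pred <- sample(1:3, 50, replace = TRUE)
  cm <- confusion_matrix(truth, pred)
  expect_equal(sum(cm), 50)
  expect_equal(accuracy(cm), 100 * mean(truth == pred))
  expect_equal(cm["2", "3"], sum(truth == 2 & pred == 3))
})

test_that("stratified holdout hits the size and covers every class", {
  set.seed(77)
  year <- rep(1:7, c(17, 11, 12, 12, 8, 12, 12))
  sp <- specfuse:::stratified_holdout(year, 17)
  expect_length(sp$test, 17)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(sort(unique(year[sp$test])), 1:7)
  # proportionality: year 1 (17 of 84) contributes 3-4 of 17
  expect_true(sum(year[sp$test] == 1) %in% 3:4)
  expect_error(specfuse:::stratified_holdout(year, 0),
               class = "specfuse_split_error")
  expect_error(specfuse:::stratified_holdout(year, 84),
               class = "specfuse_split_error")
})

# small shared dataset for experiment-harness tests (4 year classes)
tiny_exp_data <- function(n_each = 6L, img = TRUE, seed = 3L) {
  set.seed(seed)
  year <- rep(c(2L, 4L, 6L, 7L), each = n_each)
  n <- length(year)
  x_spec <- matrix(rnorm(n * 10, mean = year / 2), n, 10)
  x_img <- NULL
  if (img) {
    x_img <- array(rnorm(n * 32 * 32 * 2, mean = 0.2 * year), c(n, 32, 32, 2))
  }
  list(x_spec = x_spec, x_img = x_img, year = year)
}

test_that("run_experiment returns consistent per-round results", {
  d <- tiny_exp_data()
  plan <- experiment_plan(task = "year7", channels = "toy", rounds = 2,
                          iterations = 4, test_size = 6, batch_size = 4,
                          seed = 5)
  fit <- run_experiment(plan, d)
  expect_length(fit$rounds, 2)
  for (r in fit$rounds) {
    expect_equal(sum(r$cm), 6)                       # hold-out size
    expect_equal(r$accuracy, accuracy(r$cm))         # accuracy from cm
    expect_length(r$loss, 4)
    expect_true(all(r$loss >= 0))
    expect_length(intersect(r$train, r$test), 0)
  }
  expect_equal(fit$mean_accuracy, mean(fit$accuracies))

  # deterministic: identical plan + data -> identical result
  fit2 <- run_experiment(plan, d)
  expect_identical(fit$accuracies, fit2$accuracies)
  expect_identical(lapply(fit$rounds, `[[`, "test"),
                   lapply(fit2$rounds, `[[`, "test"))
})

test_that("the three branch configurations run on identical splits", {
  d <- tiny_exp_data()
  base <- experiment_plan(task = "food_medicinal", rounds = 1, iterations = 3,
                          test_size = 6, batch_size = 4, seed = 9)
  fused <- run_experiment(base, d)
  fcnn <- run_experiment(base, list(x_spec = d$x_spec, x_img = NULL,
                                    year = d$year))
  cnn_plan <- experiment_plan(task = "food_medicinal", use_spectra = FALSE,
                              rounds = 1, iterations = 3, test_size = 6,
                              batch_size = 4, seed = 9)
  cnn <- run_experiment(cnn_plan, d)
  # same seed -> same split for the paired ablation comparison
  expect_identical(fused$rounds[[1]]$test, fcnn$rounds[[1]]$test)
  expect_identical(fused$rounds[[1]]$test, cnn$rounds[[1]]$test)
  expect_equal(dim(fused$rounds[[1]]$cm), c(2L, 2L))
})

test_that("degenerate label layouts raise split errors", {
  d <- tiny_exp_data()
  d$year[1] <- 1L   # class with a single sample
  plan <- experiment_plan(rounds = 1, iterations = 2, test_size = 4)
  expect_error(run_experiment(plan, d), class = "specfuse_split_error")
  expect_error(run_experiment(plan, d), "1")

  expect_error(run_experiment(
    experiment_plan(use_spectra = FALSE, rounds = 1, iterations = 2),
    list(x_spec = tiny_exp_data(img = FALSE)$x_spec, x_img = NULL,
         year = tiny_exp_data()$year)),
    class = "specfuse_domain_error")
})

test_that("food_medicinal_sweep builds the model ladder and baseline", {
  d <- tiny_exp_data()
  sw <- food_medicinal_sweep(d, m_values = 0:2, rgb_img = d$x_img[, , , c(1, 2, 1)],
                             rounds = 1, iterations = 3, test_size = 6,
                             batch_size = 4, seed = 4)
  expect_equal(nrow(sw), 4)
  expect_equal(sw$m, c(0L, 1L, 2L, NA))
  expect_match(sw$model[1], "FCNN")
  expect_match(sw$model[4], "RGB")
  expect_true(all(sw$mean_accuracy >= 0 & sw$mean_accuracy <= 100))
  fits <- attr(sw, "fits")
  expect_length(fits, 4)
  expect_error(food_medicinal_sweep(d, m_values = 0:5, rounds = 1,
                                    iterations = 2),
               class = "specfuse_domain_error")
})

test_that("year_test_report lays rounds out side by side", {
  d <- tiny_exp_data()
  plan <- function(s) experiment_plan(rounds = 2, iterations = 2,
                                      test_size = 6, batch_size = 4, seed = s)
  fits <- list("Test 1" = run_experiment(plan(1), d),
               "Test 2" = run_experiment(plan(2), d))
  rep_ <- year_test_report(fits)
  expect_equal(dim(rep_), c(3L, 3L))
  expect_equal(rep_$round, c("1", "2", "Average"))
  expect_equal(rep_[["Test 1"]][3],
               round(fits[["Test 1"]]$mean_accuracy, 1))
})
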