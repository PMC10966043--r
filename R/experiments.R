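#' Mean absolute error between a probability vector and its target
#'
#' The loss of the classification head: the mean absolute difference over
#' the entries of the predicted probability vector and the one-hot target
#' encoding. Also accepts matrices (row per sample).
#'
#' @param target numeric vector/matrix (one-hot class encoding).
#' @param predicted numeric vector/matrix of the same length (softmax
#'   output).
#' @return scalar loss.
#' @export
mae_loss <- function(target, predicted) {
  if (length(target) != length(predicted))
    abort_domain("target and predicted must have the same length")
  mean(abs(as.numeric(target) - as.numeric(predicted)))
}

#' Confusion matrix of predicted vs true classes
#'
#' @param truth,predicted class labels (factor, integer or character).
#' @param levels optional class levels fixing the matrix order.
#' @return A `confusion_matrix`: square counts matrix, rows = truth,
#'   cols = predicted.
#' @export
confusion_matrix <- function(truth, predicted, levels = NULL) {
  if (is.null(levels)) levels <- sort(unique(c(as.character(truth),
                                               as.character(predicted))))
  t_f <- factor(as.character(truth), levels = levels)
  p_f <- factor(as.character(predicted), levels = levels)
  cm <- unclass(table(truth = t_f, predicted = p_f))
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Classification accuracy from a confusion matrix
#'
#' The percentage of correct predictions: `100 * trace / total`. For the
#' binary one-vs-rest reduction this equals
#' `(TP + TN) / (TP + FP + FN + TN)` expressed as a percentage.
#'
#' @param cm a [confusion_matrix()] (any square counts matrix).
#' @return accuracy in percent.
#' @export
accuracy <- function(cm) {
  cm <- unclass(cm)
  if (!is.matrix(cm) || nrow(cm) != ncol(cm))
    abort_domain("accuracy expects a square confusion matrix")
  total <- sum(cm)
  if (total <= 0) abort_domain("confusion matrix is empty")
  100 * sum(diag(cm)) / total
}

#' Experiment plan: task, protocol and training settings
#'
#' @param task `"year7"` (7-class year-by-year) or `"food_medicinal"`
#'   (binary, years 1-5 vs 6-7).
#' @param channels free-text label of the image channel set (e.g.
#'   `"five-VNIR"`); informational.
#' @param use_spectra feed the spectral branch (default TRUE).
#' @param rounds repeated random train/validation rounds (default 10).
#' @param iterations gradient steps per round (default 1800).
#' @param test_size held-out samples per round (default 17).
#' @param batch_size,lr training settings.
#' @param seed integer seed; splits, initialization and training are
#'   deterministic given the seed.
#' @return An object of class `experiment_plan`.
#' @export
experiment_plan <- function(task = c("year7", "food_medicinal"),
                            channels = "five-VNIR", use_spectra = TRUE,
                            rounds = 10L, iterations = 1800L,
                            test_size = 17L, batch_size = 8L, lr = 1e-3,
                            seed = 1L) {
  task <- match.arg(task)
  rounds <- as.integer(rounds)
  if (rounds < 1L) abort_domain("rounds must be >= 1")
  structure(
    list(task = task, channels = channels, use_spectra = isTRUE(use_spectra),
         rounds = rounds, iterations = as.integer(iterations),
         test_size = as.integer(test_size), batch_size = as.integer(batch_size),
         lr = lr, seed = as.integer(seed)),
    class = "experiment_plan")
}

#' Train and evaluate a model under a plan
#'
#' Per round: draw a seeded stratified split (stratified by growth year so
#' every round's validation set covers the year classes), build the model
#' the plan calls for (fusion network when both inputs are present,
#' spectral-only when `x_img` is NULL or `use_spectra` only, image-only
#' when `use_spectra = FALSE`), train with MAE loss, and evaluate on the
#' held-out samples. Accuracy is always derived from the round's confusion
#' matrix.
#'
#' @param plan an [experiment_plan()].
#' @param data list with `x_spec` (n x p matrix or NULL), `x_img`
#'   (n x H x W x C array or NULL), `year` (integer vector), and optionally
#'   `use` (derived from `year` when absent).
#' @param dropout_spectral,dropout_head dropout rates passed to the
#'   architecture.
#' @return An object of class `fit_result`: per-round results (split,
#'   loss trajectory, confusion matrix, accuracy), `accuracies`, and
#'   `mean_accuracy`.
#' @export
run_experiment <- function(plan, data, dropout_spectral = 0.25,
                           dropout_head = 0.25) {
  stopifnot(inherits(plan, "experiment_plan"))
  year <- as.integer(data$year)
  n <- length(year)
  use <- if (!is.null(data$use)) data$use
         else ifelse(year <= 5L, "food", "medicinal")
  y <- if (plan$task == "year7") factor(year)
       else factor(use, levels = c("food", "medicinal"))
  lev <- levels(y)
  k <- nlevels(y)
  small <- names(which(table(year) < 2L))
  if (length(small))
    abort_split(sprintf("year class(es) %s have fewer than 2 samples",
                        paste(small, collapse = ", ")))

  use_spec <- plan$use_spectra && !is.null(data$x_spec)
  use_img <- !is.null(data$x_img)
  if (!use_spec && !use_img)
    abort_domain("plan disables the spectral branch but no images supplied")
  if (use_img) di <- dim(data$x_img)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(plan$seed)
  round_seeds <- sample.int(.Machine$integer.max %/% 2L, plan$rounds)

  rounds <- vector("list", plan$rounds)
  for (r in seq_len(plan$rounds)) {
    set.seed(round_seeds[r])
    sp <- stratified_holdout(year, plan$test_size)
    spec <- fccnn_spec(
      spectral_input_len = if (use_spec) ncol(data$x_spec) else 0L,
      image_rows = if (use_img) di[2] else 256L,
      image_cols = if (use_img) di[3] else 1024L,
      image_channels = if (use_img) di[4] else 0L,
      n_classes = k,
      dropout_spectral = dropout_spectral, dropout_head = dropout_head)
    net <- build_fccnn(spec)
    fit <- train_fccnn(
      net,
      x_spec = if (use_spec) data$x_spec[sp$train, , drop = FALSE],
      x_img = if (use_img) data$x_img[sp$train, , , , drop = FALSE],
      y = as.integer(y[sp$train]),
      iterations = plan$iterations, batch_size = plan$batch_size,
      lr = plan$lr)
    pred <- predict_fccnn(
      fit$net,
      x_spec = if (use_spec) data$x_spec[sp$test, , drop = FALSE],
      x_img = if (use_img) data$x_img[sp$test, , , , drop = FALSE],
      type = "class")
    cm <- confusion_matrix(y[sp$test], factor(lev[pred], levels = lev),
                           levels = lev)
    rounds[[r]] <- list(train = sp$train, test = sp$test, loss = fit$loss,
                        cm = cm, accuracy = accuracy(cm))
  }
  acc <- vapply(rounds, `[[`, numeric(1), "accuracy")
  structure(
    list(plan = plan, rounds = rounds, accuracies = acc,
         mean_accuracy = mean(acc)),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> task=%s channels=%s (%d rounds x %d iterations)\n",
              x$plan$task, x$plan$channels, x$plan$rounds, x$plan$iterations))
  cat("Round  Accuracy/%\n")
  for (r in seq_along(x$accuracies))
    cat(sprintf("%5d  %10.1f\n", r, x$accuracies[r]))
  cat(sprintf("Mean accuracy: %.1f%%\n", x$mean_accuracy))
  invisible(x)
}

#' Food-vs-medicinal model comparison sweep
#'
#' Runs the binary (years 1-5 vs 6-7) classification for a family of
#' models: Model 1 is the spectral-only network (m = 0 image bands);
#' Models 2..(max m + 1) add the optimal m VNIR band images to the fusion
#' network; an optional RGB-image-only baseline (no spectral branch) is run
#' when `rgb_img` is supplied.
#'
#' @param data as in [run_experiment()], where `x_img` is an
#'   n x H x W x B array whose channels are the optimal VNIR band images
#'   in descending importance order (so model m uses channels `1:m`).
#' @param m_values numbers of optimal VNIR bands to try (default 0:6).
#' @param rgb_img optional n x H x W x 3 array of band images nearest
#'   622/546/443 nm for the image-only baseline.
#' @param rounds,iterations,test_size,batch_size,lr,seed protocol settings
#'   shared by all models.
#' @return An object of class `sweep_result`: data.frame with one row per
#'   model (`model`, `m`, `mean_accuracy`), with the per-model
#'   `fit_result`s in attribute `fits`.
#' @export
food_medicinal_sweep <- function(data, m_values = 0:6, rgb_img = NULL,
                                 rounds = 10L, iterations = 1800L,
                                 test_size = 17L, batch_size = 8L,
                                 lr = 1e-3, seed = 1L) {
  nb <- if (!is.null(data$x_img)) dim(data$x_img)[4] else 0L
  if (max(m_values) > nb)
    abort_domain(sprintf("m = %d requested but only %d optimal band images supplied",
                         max(m_values), nb))
  fits <- list()
  rows <- list()
  for (m in m_values) {
    plan <- experiment_plan(
      task = "food_medicinal",
      channels = if (m == 0L) "none (spectra only)" else sprintf("optimal %d VNIR", m),
      use_spectra = TRUE, rounds = rounds, iterations = iterations,
      test_size = test_size, batch_size = batch_size, lr = lr, seed = seed)
    d <- list(x_spec = data$x_spec,
              x_img = if (m > 0L) data$x_img[, , , seq_len(m), drop = FALSE],
              year = data$year, use = data$use)
    fit <- run_experiment(plan, d)
    name <- if (m == 0L) "Full spectra + FCNN"
            else sprintf("Full spectra + optimal %d VNIR + FC-CNN", m)
    fits[[name]] <- fit
    rows[[length(rows) + 1L]] <-
      data.frame(model = name, m = m, mean_accuracy = fit$mean_accuracy)
  }
  if (!is.null(rgb_img)) {
    plan <- experiment_plan(
      task = "food_medicinal", channels = "RGB 622/546/443",
      use_spectra = FALSE, rounds = rounds, iterations = iterations,
      test_size = test_size, batch_size = batch_size, lr = lr, seed = seed)
    fit <- run_experiment(plan, list(x_spec = NULL, x_img = rgb_img,
                                     year = data$year, use = data$use))
    fits[["RGB image + CNN"]] <- fit
    rows[[length(rows) + 1L]] <-
      data.frame(model = "RGB image + CNN", m = NA_integer_,
                 mean_accuracy = fit$mean_accuracy)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("sweep_result", "data.frame"), fits = fits)
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("Models                                              Accuracy/%\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("%-50s %10.1f\n", x$model[i], x$mean_accuracy[i]))
  invisible(x)
}

#' Side-by-side report of year-by-year identification tests
#'
#' Combines several [run_experiment()] results into one table with a row
#' per validation round and a final mean-accuracy row, mirroring the usual
#' presentation of repeated random-split results.
#'
#' @param fits named list of `fit_result` objects run with the same number
#'   of rounds.
#' @return data.frame with column `round` plus one accuracy column per fit.
#' @export
year_test_report <- function(fits) {
  if (length(fits) < 1L) abort_domain("need at least one fit_result")
  rounds <- vapply(fits, function(f) length(f$accuracies), integer(1))
  if (length(unique(rounds)) != 1L)
    abort_consistency("fit_results have different round counts")
  if (is.null(names(fits)))
    names(fits) <- paste("Test", seq_along(fits))
  out <- data.frame(round = c(as.character(seq_len(rounds[1])), "Average"))
  for (nm in names(fits))
    out[[nm]] <- round(c(fits[[nm]]$accuracies, fits[[nm]]$mean_accuracy), 1)
  out
}
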