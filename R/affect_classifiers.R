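#' Deep multilayer perceptron specification
#'
#' The classifier family: a fully connected network whose input layer has
#' N in \{6, 7, 8, 28\} units (the size of the chosen feature set),
#' followed by m in \{2, 3\} hidden ReLU layers of 8-256 units, each
#' followed by dropout at rate 0.25, and a sigmoid (binary) or softmax
#' (multiclass) output head trained with Adam on (categorical) binary
#' cross-entropy.
#'
#' @param input_size Number of input features (6, 7, 8 or 28).
#' @param hidden_sizes Integer vector of 2 or 3 hidden-layer widths, each
#'   in \[8, 256\].
#' @param dropout_rate Dropout rate after every hidden layer.
#' @param output `"sigmoid"` for binary tasks, `"softmax"` for multiclass.
#' @return A `network_spec` object.
#' @export
network_spec <- function(input_size, hidden_sizes, dropout_rate = 0.25,
                         output = c("sigmoid", "softmax")) {
  output <- match.arg(output)
  if (!input_size %in% c(6, 7, 8, 28))
    stop("input_size must be one of 6, 7, 8, 28")
  m <- length(hidden_sizes)
  if (!m %in% c(2, 3))
    stop("the network family uses 2 or 3 hidden layers")
  if (any(hidden_sizes < 8 | hidden_sizes > 256))
    stop("hidden layer widths must lie in [8, 256]")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must lie in [0, 1)")
  structure(list(input_size = as.integer(input_size),
                 hidden_sizes = as.integer(hidden_sizes),
                 dropout_rate = dropout_rate, output = output),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec> %d -> %s -> %s (dropout %.2f)\n",
              x$input_size, paste(x$hidden_sizes, collapse = " -> "),
              x$output, x$dropout_rate))
  invisible(x)
}

#' Number of trainable parameters of a network
#'
#' @param spec A [network_spec()].
#' @param n_classes Number of classes (determines output units: 1 for a
#'   sigmoid head, one per class for softmax).
#' @return Integer parameter count (weights + biases).
#' @export
n_params <- function(spec, n_classes = 2) {
  out_units <- if (spec$output == "sigmoid") 1L else as.integer(n_classes)
  dims <- c(spec$input_size, spec$hidden_sizes, out_units)
  sum(dims[-length(dims)] * dims[-1]) + sum(dims[-1])
}

#' Instantiate a trainable network
#'
#' Builds the weight matrices (He initialization) and bias vectors for a
#' specification; the parameter count is a deterministic function of the
#' spec and class count.
#'
#' @param spec A [network_spec()].
#' @param n_classes Number of classes.
#' @param seed Optional seed for reproducible initialization.
#' @return A `dmlp_model` handle (untrained).
#' @export
build_network <- function(spec, n_classes = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out_units <- if (spec$output == "sigmoid") 1L else as.integer(n_classes)
  par <- mlp_init(c(spec$input_size, spec$hidden_sizes), out_units)
  structure(list(par = par, levels = NULL,
                 output = if (spec$output == "sigmoid") "sigmoid"
                          else "softmax",
                 spec = spec),
            class = "dmlp_model")
}

.task_table <- function() {
  list(
    "LA+MA_vs_HA" = list(column = "arousal", set = "arousal",
                         groups = list("LA+MA" = c("LA", "MA"),
                                       "HA" = "HA"),
                         hidden = c(128, 32)),
    "HA_vs_LA" = list(column = "arousal", set = "arousal",
                      groups = list(HA = "HA", LA = "LA"),
                      hidden = c(128, 64)),
    "HA_vs_MA" = list(column = "arousal", set = "arousal",
                      groups = list(HA = "HA", MA = "MA"),
                      hidden = c(128, 64)),
    "MA_vs_LA" = list(column = "arousal", set = "arousal",
                      groups = list(MA = "MA", LA = "LA"),
                      hidden = c(128, 64)),
    "HA_vs_MA_vs_LA" = list(column = "arousal", set = "arousal",
                            groups = list(HA = "HA", MA = "MA", LA = "LA"),
                            hidden = c(256, 64, 32)),
    "NV+MV_vs_PV" = list(column = "valence", set = "valence",
                         groups = list("NV+MV" = c("NV", "MV"),
                                       "PV" = "PV"),
                         hidden = c(64, 16)),
    "PV_vs_NV" = list(column = "valence", set = "valence",
                      groups = list(PV = "PV", NV = "NV"),
                      hidden = c(32, 8)),
    "PV_vs_MV" = list(column = "valence", set = "valence",
                      groups = list(PV = "PV", MV = "MV"),
                      hidden = c(32, 8)),
    "MV_vs_NV" = list(column = "valence", set = "valence",
                      groups = list(MV = "MV", NV = "NV"),
                      hidden = c(64, 32)),
    "PV_vs_MV_vs_NV" = list(column = "valence", set = "valence",
                            groups = list(PV = "PV", MV = "MV", NV = "NV"),
                            hidden = c(128, 64, 32)),
    "quadrant" = list(column = "quadrant", set = "combined",
                      groups = list(MAMV = "MAMV", HANV = "HANV",
                                    LANV = "LANV", LAPV = "LAPV"),
                      hidden = c(128, 64, 16)))
}

#' Classification task presets
#'
#' The preset arousal, valence and joint-quadrant tasks with their class
#' definitions, predictor sets and tuned hidden-layer sizes. Binary tasks
#' use a sigmoid head, multiclass tasks softmax.
#'
#' @param name Task name: `"LA+MA_vs_HA"`, `"HA_vs_LA"`, `"HA_vs_MA"`,
#'   `"MA_vs_LA"`, `"HA_vs_MA_vs_LA"`, `"NV+MV_vs_PV"`, `"PV_vs_NV"`,
#'   `"PV_vs_MV"`, `"MV_vs_NV"`, `"PV_vs_MV_vs_NV"` or `"quadrant"`.
#' @return A `task_spec` list: `name`, `column` (label column used),
#'   `groups` (class definition), `feature_set` ([feature_set_spec()]) and
#'   `network` ([network_spec()]).
#' @export
task_spec <- function(name) {
  tab <- .task_table()
  if (!name %in% names(tab))
    stop("unknown task '", name, "'; available: ",
         paste(names(tab), collapse = ", "))
  tk <- tab[[name]]
  fs <- feature_set(tk$set)
  structure(list(name = name, column = tk$column, groups = tk$groups,
                 feature_set = fs,
                 network = network_spec(
                   length(fs$members), tk$hidden,
                   output = if (length(tk$groups) == 2) "sigmoid"
                            else "softmax")),
            class = "task_spec")
}

#' @export
print.task_spec <- function(x, ...) {
  cat(sprintf("<task_spec> %s: %s over %s [%d features, hidden %s]\n",
              x$name, paste(names(x$groups), collapse = "/"), x$column,
              length(x$feature_set$members),
              paste(x$network$hidden_sizes, collapse = ", ")))
  invisible(x)
}

# Map a label data.frame onto task classes; NA for rows outside the task.
task_classes <- function(task, labels) {
  src <- labels[[task$column]]
  out <- rep(NA_character_, length(src))
  for (cls in names(task$groups)) out[src %in% task$groups[[cls]]] <- cls
  out
}

#' Train and evaluate a task with 10-fold cross-validation
#'
#' Restricts the feature table to the task's predictor set, maps labels to
#' task classes, and runs stratified k-fold cross-validation. Inside each
#' fold, features are z-scored and missing values are imputed with
#' statistics fitted on the training folds only; the network is trained
#' with Adam on (categorical) cross-entropy with early stopping on an
#' internal validation split. Reported metrics are accuracy, macro
#' f1-score and AUC (macro one-vs-rest for multiclass) per fold and
#' averaged. Fully reproducible given `seed`.
#'
#' @param features Feature data.frame (schema columns).
#' @param labels Data.frame with the task's label column (`arousal`,
#'   `valence` or `quadrant`), as produced by [annotate_session()].
#' @param task A [task_spec()] (or task name).
#' @param seed Integer seed.
#' @param k Number of folds.
#' @param epochs,batch_size,lr,patience Training budget.
#' @param spec Optional [network_spec()] overriding the preset.
#' @return An `eval_report`: per-fold metric data.frame, means, fold
#'   assignment and seed.
#' @export
train_eval <- function(features, labels, task, seed = 1, k = 10,
                       epochs = 200, batch_size = 32, lr = 1e-3,
                       patience = 20, spec = NULL) {
  if (is.character(task)) task <- task_spec(task)
  set.seed(seed)
  y_all <- task_classes(task, labels)
  keep <- !is.na(y_all)
  X <- as.matrix(features[keep, task$feature_set$members, drop = FALSE])
  y <- y_all[keep]
  spec <- spec %||% task$network
  if (ncol(X) != spec$input_size)
    stop("feature set size does not match the network input size")
  counts <- table(y)
  if (length(counts) < 2) stop("task needs at least 2 classes present")
  if (any(counts < 2))
    stop("stratification error: class(es) with fewer than 2 observations: ",
         paste(names(counts)[counts < 2], collapse = ", "))

  folds <- stratified_folds(y, k)
  per_fold <- NULL
  for (f in seq_len(k)) {
    te <- folds == f
    prep <- fit_preprocessor(X[!te, , drop = FALSE])
    model <- mlp_fit(apply_preprocessor(prep, X[!te, , drop = FALSE]),
                     y[!te], spec, epochs = epochs,
                     batch_size = batch_size, lr = lr, patience = patience)
    pr <- mlp_predict_proba(model, apply_preprocessor(prep,
                                                      X[te, , drop = FALSE]))
    met <- classification_metrics(y[te], pr, model$levels)
    per_fold <- rbind(per_fold,
                      data.frame(fold = f, auc = met$auc, f1 = met$f1,
                                 accuracy = met$accuracy))
  }
  structure(list(task = task$name, folds = per_fold,
                 mean_auc = mean(per_fold$auc, na.rm = TRUE),
                 mean_f1 = mean(per_fold$f1, na.rm = TRUE),
                 mean_accuracy = mean(per_fold$accuracy),
                 fold_assignment = folds, seed = seed),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s (10-fold CV): AUC %.2f, f1 %.2f, acc %.2f\n",
              x$task, x$mean_auc, x$mean_f1, x$mean_accuracy))
  invisible(x)
}

# Stratified fold assignment: shuffle within class, deal folds round-robin.
stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# Per-feature z-scoring + median imputation fitted on training data only.
fit_preprocessor <- function(X) {
  med <- apply(X, 2, stats::median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  mu <- apply(X, 2, mean, na.rm = TRUE)
  mu[!is.finite(mu)] <- 0
  sd_ <- apply(X, 2, stats::sd, na.rm = TRUE)
  sd_[!is.finite(sd_) | sd_ == 0] <- 1
  list(median = med, mean = mu, sd = sd_)
}

apply_preprocessor <- function(prep, X) {
  for (j in seq_len(ncol(X)))
    X[is.na(X[, j]), j] <- prep$median[j]
  sweep(sweep(X, 2, prep$mean, "-"), 2, prep$sd, "/")
}

# Accuracy, macro f1 and AUC (macro one-vs-rest for multiclass).
classification_metrics <- function(y_true, proba, levels) {
  pred <- levels[apply(proba, 1, which.max)]
  accuracy <- mean(pred == y_true)
  f1s <- vapply(levels, function(cls) {
    tp <- sum(pred == cls & y_true == cls)
    fp <- sum(pred == cls & y_true != cls)
    fn <- sum(pred != cls & y_true == cls)
    if (tp + fp + fn == 0) return(NA_real_)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  f1 <- mean(f1s, na.rm = TRUE)
  aucs <- vapply(seq_along(levels), function(j) {
    resp <- y_true == levels[j]
    if (length(unique(resp)) < 2) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(resp, proba[, j], quiet = TRUE,
                                   direction = "<", levels = c(FALSE, TRUE))))
  }, numeric(1))
  auc <- if (length(levels) == 2) aucs[2] else mean(aucs, na.rm = TRUE)
  list(accuracy = accuracy, f1 = f1, auc = auc)
}

#' Architecture search over candidate hidden-layer layouts
#'
#' Trains each candidate on a stratified 80/20 train/test split and
#' returns the specification with the smallest test error; ties are broken
#' in favour of the fewest total hidden neurons.
#'
#' @param features,labels,task As in [train_eval()].
#' @param grid List of hidden-size integer vectors to try.
#' @param seed Seed (the split and training are reproducible).
#' @param epochs,batch_size,lr,patience Training budget per candidate.
#' @return The winning [network_spec()], with the candidate error table in
#'   attribute `"search"`.
#' @export
architecture_search <- function(features, labels, task, grid, seed = 1,
                                epochs = 200, batch_size = 32, lr = 1e-3,
                                patience = 20) {
  if (length(grid) == 0) stop("empty architecture grid")
  if (is.character(task)) task <- task_spec(task)
  set.seed(seed)
  y_all <- task_classes(task, labels)
  keep <- !is.na(y_all)
  X <- as.matrix(features[keep, task$feature_set$members, drop = FALSE])
  y <- y_all[keep]
  te <- stratified_folds(y, 5) == 1      # stratified 80/20 split
  prep <- fit_preprocessor(X[!te, , drop = FALSE])
  Xtr <- apply_preprocessor(prep, X[!te, , drop = FALSE])
  Xte <- apply_preprocessor(prep, X[te, , drop = FALSE])
  errs <- vapply(grid, function(h) {
    sp <- network_spec(length(task$feature_set$members), h,
                       output = task$network$output)
    model <- mlp_fit(Xtr, y[!te], sp, epochs = epochs,
                     batch_size = batch_size, lr = lr, patience = patience)
    pr <- mlp_predict_proba(model, Xte)
    pred <- model$levels[apply(pr, 1, which.max)]
    mean(pred != y[te])
  }, numeric(1))
  sizes <- vapply(grid, sum, numeric(1))
  best <- order(round(errs, 9), sizes)[1]
  out <- network_spec(length(task$feature_set$members), grid[[best]],
                      output = task$network$output)
  attr(out, "search") <- data.frame(
    hidden = vapply(grid, paste, "", collapse = ","),
    test_error = errs, hidden_neurons = sizes)
  out
}
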