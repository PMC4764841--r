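#' Decoder specification for nested cross-validation
#'
#' Defines the RBF-kernel SVM search space and fold structure. Model
#' selection (candidate time window and the `gamma`/`cost` hyperparameters)
#' happens only inside the inner folds of each training set; outer test
#' trials never influence it.
#'
#' @param gamma,cost Numeric hyperparameter grids; defaults are the
#'   conventional log2-spaced RBF grids `2^(-15..3)` and `2^(-5..15)`
#'   (step 2 in the exponent).
#' @param outer_folds,inner_folds Stratified fold counts (defaults 10 and 5).
#' @param windows Candidate window ends in ms relative to the cue for
#'   type classification (default 0..1000 by 100, i.e. 500-ms windows
#'   starting -500..+500 ms).
#' @param seed Seed for the stratified fold shuffling.
#' @return A list of class `decoder_spec`.
#' @export
decoder_spec <- function(gamma = 2^seq(-15, 3, by = 2),
                         cost = 2^seq(-5, 15, by = 2),
                         outer_folds = 10, inner_folds = 5,
                         windows = seq(0, 1000, by = 100),
                         seed = 1) {
  if (!length(gamma) || !length(cost)) {
    stop_smf("invalid_config", "hyperparameter grids must be non-empty")
  }
  if (outer_folds < 2 || inner_folds < 2) {
    stop_smf("invalid_config", "fold counts must be >= 2")
  }
  structure(as.list(environment()), class = "decoder_spec")
}

# Stratified fold assignment: shuffles within class, deals round-robin.
stratified_folds <- function(labels, k, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

check_stratification <- function(labels, fold) {
  for (f in unique(fold)) {
    tr <- labels[fold != f]
    if (length(unique(tr)) < length(unique(labels)) ||
        min(table(tr)) < 1 || sum(fold == f) < 1) {
      stop_smf("stratification_error",
               "a class is absent from a fold; reduce fold count")
    }
  }
}

svm_fit_predict <- function(x_tr, y_tr, x_te, gamma, cost) {
  fit <- e1071::svm(x_tr, factor(y_tr), kernel = "radial",
                    gamma = gamma, cost = cost, scale = apply(x_tr, 2, sd) > 0)
  as.character(predict(fit, x_te))
}

# Inner-CV accuracy for every (window, gamma, cost) on the training trials.
inner_grid_accuracy <- function(X, labels, spec, fold_seed) {
  n_w <- dim(X)[2]
  ifold <- stratified_folds(labels, spec$inner_folds, fold_seed)
  check_stratification(labels, ifold)
  acc <- array(0, c(n_w, length(spec$gamma), length(spec$cost)))
  for (f in seq_len(spec$inner_folds)) {
    tr <- ifold != f
    te <- !tr
    if (!any(te)) next
    for (w in seq_len(n_w)) {
      x_tr <- X[tr, w, , drop = TRUE]
      x_te <- X[te, w, , drop = FALSE]
      dim(x_te) <- dim(x_te)[c(1, 3)]
      for (g in seq_along(spec$gamma)) {
        for (cc in seq_along(spec$cost)) {
          pred <- svm_fit_predict(x_tr, labels[tr], x_te,
                                  spec$gamma[g], spec$cost[cc])
          acc[w, g, cc] <- acc[w, g, cc] + sum(pred == labels[te])
        }
      }
    }
  }
  acc / length(labels)
}

# Deterministic arg-max with the tie-break: smaller cost, then smaller
# gamma, then earlier window. Grids are ascending, so iterate accordingly.
select_best <- function(acc, spec) {
  best <- c(w = 1L, g = 1L, c = 1L)
  best_acc <- -Inf
  for (cc in seq_along(spec$cost)) {
    for (g in seq_along(spec$gamma)) {
      for (w in seq_len(dim(acc)[1])) {
        if (acc[w, g, cc] > best_acc + 1e-12) {
          best_acc <- acc[w, g, cc]
          best <- c(w = w, g = g, c = cc)
        }
      }
    }
  }
  list(window = best[["w"]], gamma = spec$gamma[best[["g"]]],
       cost = spec$cost[best[["c"]]], inner_accuracy = best_acc)
}

binom_ci <- function(k, n) {
  ci <- binom.test(k, n)$conf.int
  100 * c(lower = ci[1], upper = ci[2])
}

#' Nested cross-validated movement-type classification
#'
#' Classifies grasp vs open from cue-locked features. For each outer fold,
#' an inner cross-validation over the training trials selects the candidate
#' time window and the SVM `gamma`/`cost` jointly (ties broken toward
#' smaller cost, then smaller gamma, then earlier window); the outer test
#' trials are scored once with that selection. Chance level is 50%.
#'
#' @param features A [extract_features()] result whose grid covers
#'   `spec$windows`.
#' @param spec A [decoder_spec()].
#' @param kind Which feature kind to decode from (default `"smf"`).
#' @return List of class `accuracy_curve`: `accuracy` (%, model-selected,
#'   pooled over outer test trials), `ci` (binomial 95%), `curve` (data frame
#'   of per-window outer accuracies with CIs), `folds` (per-fold selections,
#'   for audit), `n`.
#' @export
nested_cv_type_accuracy <- function(features, spec = decoder_spec(),
                                    kind = "smf") {
  X_all <- features$features[[kind]]
  if (is.null(X_all)) stop_smf("invalid_config", "kind '%s' not extracted", kind)
  widx <- match(spec$windows, features$window_end_ms)
  if (anyNA(widx)) {
    stop_smf("window_bounds", "spec windows missing from the feature grid")
  }
  X <- X_all[, widx, , drop = FALSE]
  labels <- features$labels
  ofold <- stratified_folds(labels, spec$outer_folds, spec$seed)
  check_stratification(labels, ofold)

  n_w <- length(widx)
  correct <- 0L
  curve_correct <- integer(n_w)
  fold_info <- vector("list", spec$outer_folds)
  for (f in seq_len(spec$outer_folds)) {
    tr <- ofold != f
    te <- !tr
    if (min(table(labels[tr])) < 2 || !any(te)) {
      stop_smf("stratification_error", "need >= 2 trials per class per fold")
    }
    acc <- inner_grid_accuracy(X[tr, , , drop = FALSE], labels[tr], spec,
                               fold_seed = spec$seed + 1000L + f)
    sel <- select_best(acc, spec)
    x_tr <- X[tr, sel$window, , drop = TRUE]
    x_te <- X[te, sel$window, , drop = FALSE]
    dim(x_te) <- dim(x_te)[c(1, 3)]
    pred <- svm_fit_predict(x_tr, labels[tr], x_te, sel$gamma, sel$cost)
    correct <- correct + sum(pred == labels[te])

    # per-window curve: hyperparameters re-selected per window from the same
    # inner-CV table, test trials scored at every candidate window
    for (w in seq_len(n_w)) {
      sw <- select_best(acc[w, , , drop = FALSE], spec)
      x_trw <- X[tr, w, , drop = TRUE]
      x_tew <- X[te, w, , drop = FALSE]
      dim(x_tew) <- dim(x_tew)[c(1, 3)]
      pw <- svm_fit_predict(x_trw, labels[tr], x_tew, sw$gamma, sw$cost)
      curve_correct[w] <- curve_correct[w] + sum(pw == labels[te])
    }
    fold_info[[f]] <- c(list(fold = f), sel,
                        list(window_end_ms = spec$windows[sel$window]))
  }
  n <- length(labels)
  curve <- data.frame(
    window_end_ms = spec$windows,
    accuracy = 100 * curve_correct / n,
    ci_lower = NA_real_, ci_upper = NA_real_
  )
  for (w in seq_len(n_w)) {
    ci <- binom_ci(curve_correct[w], n)
    curve$ci_lower[w] <- ci[1]
    curve$ci_upper[w] <- ci[2]
  }
  structure(
    list(accuracy = 100 * correct / n, ci = binom_ci(correct, n),
         curve = curve, folds = fold_info, n = n, kind = kind,
         chance = 50),
    class = "accuracy_curve"
  )
}

#' @export
print.accuracy_curve <- function(x, ...) {
  cat(sprintf(
    "<accuracy_curve> %s: %.1f%% (95%% CI %.1f-%.1f, n = %d, chance 50%%)\n",
    x$kind, x$accuracy, x$ci[1], x$ci[2], x$n
  ))
  invisible(x)
}

# Build rest/intention examples: concatenate the 11 windows of each epoch.
intention_examples <- function(features, kind,
                               rest_ends = seq(-2000, -1000, by = 100),
                               intent_ends = seq(0, 1000, by = 100)) {
  if (length(intersect(rest_ends, intent_ends))) {
    stop_smf("window_bounds", "rest and intention epochs must not overlap")
  }
  ridx <- match(rest_ends, features$window_end_ms)
  iidx <- match(intent_ends, features$window_end_ms)
  if (anyNA(ridx) || anyNA(iidx)) {
    stop_smf("window_bounds",
             "feature grid does not cover the rest/intention epochs")
  }
  X <- features$features[[kind]]
  n_tr <- dim(X)[1]
  flat <- function(idx) {
    m <- X[, idx, , drop = FALSE]
    dim(m) <- c(n_tr, length(idx) * dim(X)[3])
    m
  }
  list(
    x = rbind(flat(ridx), flat(iidx)),
    y = rep(c("rest", "intention"), each = n_tr),
    trial = rep(seq_len(n_tr), 2)
  )
}

#' Nested cross-validated movement-intention classification
#'
#' Rest vs intention decoding: each trial contributes one resting example
#' (features of the 11 windows covering -2500..-1000 ms concatenated) and one
#' intention example (the 11 windows covering -500..1000 ms). Folds are
#' formed over trials so the two examples of a trial never straddle a fold
#' boundary; the inner CV selects `gamma`/`cost`. Chance level is 50%.
#'
#' @inheritParams nested_cv_type_accuracy
#' @return List of class `accuracy_curve` (no per-window curve; `curve` is
#'   `NULL`).
#' @export
nested_cv_intention_accuracy <- function(features, spec = decoder_spec(),
                                         kind = "smf") {
  ex <- intention_examples(features, kind)
  n_tr <- max(ex$trial)
  tfold <- stratified_folds(features$labels, spec$outer_folds, spec$seed)
  ofold <- tfold[ex$trial]

  correct <- 0L
  fold_info <- vector("list", spec$outer_folds)
  for (f in seq_len(spec$outer_folds)) {
    tr <- ofold != f
    te <- !tr
    # inner CV over gamma x cost (single "window")
    Xtr <- ex$x[tr, , drop = FALSE]
    ytr <- ex$y[tr]
    trial_tr <- ex$trial[tr]
    ifold_tr <- stratified_folds(features$labels[unique(trial_tr)],
                                 spec$inner_folds,
                                 spec$seed + 2000L + f)[match(trial_tr, unique(trial_tr))]
    acc <- array(0, c(1, length(spec$gamma), length(spec$cost)))
    for (g in seq_along(spec$gamma)) {
      for (cc in seq_along(spec$cost)) {
        hits <- 0L
        for (fi in seq_len(spec$inner_folds)) {
          itr <- ifold_tr != fi
          ite <- !itr
          if (!any(ite) || length(unique(ytr[itr])) < 2) next
          pred <- svm_fit_predict(Xtr[itr, , drop = FALSE], ytr[itr],
                                  Xtr[ite, , drop = FALSE],
                                  spec$gamma[g], spec$cost[cc])
          hits <- hits + sum(pred == ytr[ite])
        }
        acc[1, g, cc] <- hits / length(ytr)
      }
    }
    sel <- select_best(acc, spec)
    pred <- svm_fit_predict(Xtr, ytr, ex$x[te, , drop = FALSE],
                            sel$gamma, sel$cost)
    correct <- correct + sum(pred == ex$y[te])
    fold_info[[f]] <- c(list(fold = f), sel[c("gamma", "cost", "inner_accuracy")])
  }
  n <- length(ex$y)
  structure(
    list(accuracy = 100 * correct / n, ci = binom_ci(correct, n),
         curve = NULL, folds = fold_info, n = n, kind = kind, chance = 50),
    class = "accuracy_curve"
  )
}

#' Compare decoding accuracies across feature kinds
#'
#' One-way ANOVA across feature kinds (groups = kinds, observations =
#' subjects), Tukey-Kramer adjusted pairwise comparisons, and a paired
#' two-tailed t-test between two designated kinds.
#'
#' @param table Numeric matrix or data frame, subjects x feature kinds
#'   (column names are the kind labels); no missing cells.
#' @param paired_cols Length-2 character or index vector naming the columns
#'   for the paired t-test (default the first two).
#' @return List with `F`, `df` (numerator, denominator), `p`, `tukey` (data
#'   frame of adjusted pairwise p-values), and `paired_t` (list with
#'   `t`, `df`, `p`).
#' @export
compare_feature_accuracies <- function(table, paired_cols = c(1, 2)) {
  table <- as.matrix(table)
  if (nrow(table) < 2) stop_smf("incomplete_table", "need >= 2 subjects")
  if (anyNA(table)) stop_smf("incomplete_table", "accuracy table has missing cells")
  if (is.null(colnames(table))) {
    colnames(table) <- paste0("kind", seq_len(ncol(table)))
  }
  long <- data.frame(
    acc = as.vector(table),
    kind = factor(rep(colnames(table), each = nrow(table)))
  )
  fit <- aov(acc ~ kind, data = long)
  an <- anova(fit)
  tk <- TukeyHSD(fit)$kind
  tukey <- data.frame(
    comparison = rownames(tk), diff = tk[, "diff"], p_adj = tk[, "p adj"],
    row.names = NULL
  )
  pt <- t.test(table[, paired_cols[1]], table[, paired_cols[2]], paired = TRUE)
  list(
    F = unname(an$`F value`[1]),
    df = c(an$Df[1], an$Df[2]),
    p = unname(an$`Pr(>F)`[1]),
    tukey = tukey,
    paired_t = list(t = unname(pt$statistic), df = unname(pt$parameter),
                    p = pt$p.value)
  )
}
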