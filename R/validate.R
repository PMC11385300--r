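# Chronological holdout and decade-block K-fold validation: confusion
# matrices, error rates and the three proper scoring rules (logarithmic,
# quadratic/Brier, spherical).

#' Chronological split plans
#'
#' Cases are always partitioned by calendar year — chronological, never
#' random. The default holdout plan trains on 1975-2011 (75%) and tests
#' on 2012-2022 (25%); the default K-fold plan uses the five decade
#' blocks K1 1975-1984, K2 1985-1994, K3 1995-2004, K4 2005-2014,
#' K5 2015-2022.
#'
#' @param name `"holdout"` or `"kfold"`.
#' @param train_years,test_years year vectors (holdout).
#' @param folds named list of year vectors (kfold); must be disjoint.
#' @return object of class `"split_plan"`.
#' @export
split_plan <- function(name = c("holdout", "kfold"),
                       train_years = 1975:2011, test_years = 2012:2022,
                       folds = list(K1 = 1975:1984, K2 = 1985:1994,
                                    K3 = 1995:2004, K4 = 2005:2014,
                                    K5 = 2015:2022)) {
  name <- match.arg(name)
  if (name == "holdout") {
    if (!length(train_years) || !length(test_years))
      stop_bbn("train and test year sets must be non-empty",
               "bbn_validation_error")
    if (length(intersect(train_years, test_years)))
      stop_bbn("train and test years overlap", "bbn_validation_error")
    plan <- list(name = name, train_years = as.integer(train_years),
                 test_years = as.integer(test_years))
  } else {
    yrs <- unlist(folds)
    if (anyDuplicated(yrs))
      stop_bbn("fold year sets overlap", "bbn_validation_error")
    plan <- list(name = name, folds = lapply(folds, as.integer))
  }
  structure(plan, class = "split_plan")
}

#' @keywords internal
plan_years <- function(plan) {
  if (plan$name == "holdout") c(plan$train_years, plan$test_years)
  else unlist(plan$folds, use.names = FALSE)
}

#' Partition discretized cases by a split plan
#'
#' @param cases data.frame with a `year` column (e.g. from
#'   [cases_to_states()] or raw records).
#' @param plan a [split_plan()].
#' @return for a holdout plan, `list(train = ..., test = ...)`; for a
#'   kfold plan, a named list of fold data.frames.
#' @export
split_cases <- function(cases, plan) {
  stopifnot(inherits(plan, "split_plan"))
  if (!"year" %in% names(cases))
    stop_bbn("cases lack a 'year' column", "bbn_data_error")
  outside <- setdiff(unique(cases$year), plan_years(plan))
  if (length(outside))
    stop_bbn(sprintf("case year(s) outside the split plan: %s",
                     paste(sort(outside), collapse = ", ")),
             "bbn_data_error")
  if (plan$name == "holdout") {
    list(train = cases[cases$year %in% plan$train_years, , drop = FALSE],
         test = cases[cases$year %in% plan$test_years, , drop = FALSE])
  } else {
    lapply(plan$folds, function(yrs)
      cases[cases$year %in% yrs, , drop = FALSE])
  }
}

#' Error rate of a confusion matrix, in percent
#'
#' `100 * (1 - trace / total)`, reported to two decimals.
#'
#' @param cm square confusion matrix (actual in rows, predicted in
#'   columns) or a `"bbn_evaluation"` object.
#' @return percentage, rounded to 2 decimals.
#' @examples
#' cm <- matrix(c(8, 2, 1, 9), 2, byrow = TRUE)
#' error_rate(cm)   # 15
#' @export
error_rate <- function(cm) {
  if (inherits(cm, "bbn_evaluation")) cm <- cm$confusion
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm))
    stop_bbn("confusion matrix must be square", "bbn_validation_error")
  total <- sum(cm)
  if (total <= 0)
    stop_bbn("confusion matrix is empty", "bbn_validation_error")
  round(100 * (1 - sum(diag(cm)) / total), 2)
}

# Scoring rules from a matrix of posteriors (rows = cases) and the index
# of the actual state per case. The logarithmic rule floors the actual
# state's probability at `floor` to keep the mean finite; floored cases
# are counted and flagged in the report.
#' @keywords internal
scoring_rules <- function(probs, actual_idx, floor = 1e-12) {
  n <- nrow(probs)
  pc <- probs[cbind(seq_len(n), actual_idx)]
  floored <- sum(pc < floor)
  sumsq <- rowSums(probs^2)
  list(logarithmic_loss = mean(-log(pmax(pc, floor))),
       quadratic_loss = mean(1 - 2 * pc + sumsq),
       spherical_payoff = mean(pc / sqrt(sumsq)),
       n_floored = floored)
}

#' Evaluate a fitted network on test cases
#'
#' For every test case the posterior of `target` is computed given the
#' chosen evidence (all other variables by default), the argmax state is
#' crossed against the actual band in a confusion matrix, and the three
#' proper scoring rules are accumulated from the full posterior: with
#' \eqn{P_c} the posterior probability of the actual state and
#' \eqn{P_j} the posterior vector,
#' logarithmic loss = mean\eqn{(-\ln P_c)} (nats, \eqn{[0,\infty)}),
#' quadratic (Brier) loss = mean\eqn{(1 - 2P_c + \sum_j P_j^2)}
#' (\eqn{[0,2]}), spherical payoff =
#' mean\eqn{(P_c / \sqrt{\sum_j P_j^2})} (\eqn{[0,1]}).
#'
#' The network and the banding schemes must have been fitted on training
#' data only; this function does not refit anything.
#'
#' @param fit a fitted `"bbn"`.
#' @param test_cases data.frame of discretized test cases.
#' @param target output node to score.
#' @param evidence_policy `"all"` (every non-target node observed, the
#'   default) or `"inputs"` (input nodes only).
#' @param floor lower bound applied to the actual-state probability in
#'   the logarithmic rule.
#' @return object of class `"bbn_evaluation"`: list with `target`, `n`,
#'   `confusion` (actual x predicted table in declared state order),
#'   `error_rate`, `logarithmic_loss`, `quadratic_loss`,
#'   `spherical_payoff`, `n_floored`.
#' @export
evaluate_network <- function(fit, test_cases, target,
                             evidence_policy = c("all", "inputs"),
                             floor = 1e-12) {
  evidence_policy <- match.arg(evidence_policy)
  stopifnot(inherits(fit, "bbn"))
  states <- fit$spec$nodes[[target]]$states
  if (!nrow(test_cases))
    stop_bbn("no test cases", "bbn_validation_error")
  probs <- predict(fit, test_cases, target, type = "prob",
                   evidence_policy = evidence_policy)
  predicted <- factor(states[max.col(probs, ties.method = "first")],
                      levels = states)
  actual <- factor(as.character(test_cases[[target]]), levels = states)
  if (anyNA(actual))
    stop_bbn(sprintf("test cases contain states outside node '%s'", target),
             "bbn_data_error")
  cm <- table(actual = actual, predicted = predicted)
  sc <- scoring_rules(probs, as.integer(actual), floor = floor)
  structure(c(list(target = target, n = nrow(test_cases), confusion = cm,
                   error_rate = error_rate(cm)), sc),
            class = "bbn_evaluation")
}

#' @export
print.bbn_evaluation <- function(x, ...) {
  cat(sprintf("Evaluation of '%s' on %d test cases\n", x$target, x$n))
  print(x$confusion)
  cat(sprintf("\nError rate: %.2f%%\n", x$error_rate))
  cat(sprintf("Logarithmic loss: %.4f   Quadratic loss: %.4f   Spherical payoff: %.4f\n",
              x$logarithmic_loss, x$quadratic_loss, x$spherical_payoff))
  if (x$n_floored > 0)
    cat(sprintf("Note: %d case(s) had zero posterior mass on the actual state (floored).\n",
                x$n_floored))
  invisible(x)
}

#' Decade-block K-fold cross-validation report
#'
#' For each of the first `K - 1` folds, the model (banding schemes and
#' CPTs) is refitted on all other folds' years and tested on the fold;
#' the final row retrains on folds 1..K-1 and tests on the last fold.
#' Everything data-dependent — schemes and CPTs — is refit inside each
#' fold, so no test information leaks into training.
#'
#' @param records raw (undiscretized) seasonal case records.
#' @param target output node to score.
#' @param plan a kfold [split_plan()].
#' @param spec network structure (default [tillage_network()]).
#' @param prior_weight CPT pseudo-count.
#' @param n_bands bands for non-output variables.
#' @param evidence_policy passed to [evaluate_network()].
#' @return data.frame with one row per fold (fold name, train/test sizes,
#'   error rate), an `Average` row over the cross-validation folds, and a
#'   `Final test` row.
#' @export
kfold_report <- function(records, target, plan = split_plan("kfold"),
                         spec = tillage_network(), prior_weight = 1,
                         n_bands = 5L,
                         evidence_policy = c("all", "inputs")) {
  evidence_policy <- match.arg(evidence_policy)
  if (plan$name != "kfold")
    stop_bbn("'plan' must be a kfold split plan", "bbn_validation_error")
  fold_names <- names(plan$folds)
  K <- length(fold_names)
  run_one <- function(train_years, test_years, label) {
    train <- records[records$year %in% train_years, , drop = FALSE]
    test <- records[records$year %in% test_years, , drop = FALSE]
    schemes <- fit_tillage_schemes(train, n_bands = n_bands)
    fit <- bbn_fit(spec, cases_to_states(train, schemes), prior_weight)
    ev <- evaluate_network(fit, cases_to_states(test, schemes), target,
                           evidence_policy = evidence_policy)
    data.frame(fold = label, n_train = nrow(train), n_test = nrow(test),
               error_rate = ev$error_rate, stringsAsFactors = FALSE)
  }
  outside <- setdiff(unique(records$year), plan_years(plan))
  if (length(outside))
    stop_bbn(sprintf("case year(s) outside the split plan: %s",
                     paste(sort(outside), collapse = ", ")),
             "bbn_data_error")
  cv <- lapply(fold_names[-K], function(f)
    run_one(unlist(plan$folds[setdiff(fold_names, f)]), plan$folds[[f]], f))
  cv <- do.call(rbind, cv)
  avg <- data.frame(fold = "Average", n_train = NA_integer_,
                    n_test = NA_integer_,
                    error_rate = round(mean(cv$error_rate), 2))
  fin <- run_one(unlist(plan$folds[fold_names[-K]]),
                 plan$folds[[fold_names[K]]], "Final test")
  rbind(cv, avg, fin)
}
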