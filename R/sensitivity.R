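# Sensitivity-to-findings and scenario influence analysis on a fitted
# network: how much would observing each variable reduce the variance or
# entropy of a target, and how do evidence presets move the posterior
# bands of the outputs.

# Posterior of `node` given evidence, as a plain numeric vector.
#' @keywords internal
post_vec <- function(fit, node, evidence = NULL) {
  as.numeric(posterior(fit, node, evidence))
}

#' @keywords internal
dist_variance <- function(p, m) sum(p * m^2) - sum(p * m)^2

#' Variance reduction of a target from observing a finding node
#'
#' \eqn{V(Q) - \sum_f P(f)\, V(Q \mid f)}, where the variance of the
#' discrete target \eqn{Q} uses its state midpoints as real values
#' (units of the target squared) and every distribution comes from exact
#' inference. By the law of total variance this is non-negative, and it
#' is zero when target and finding are independent. Observing the target
#' itself removes all of its variance, so the self-finding returns the
#' full \eqn{V(Q)}.
#'
#' @param fit a fitted `"bbn"` whose target node carries midpoints
#'   (see [attach_midpoints()]).
#' @param target node whose variance is reduced.
#' @param finding node assumed observed.
#' @param evidence optional baseline evidence conditioning the whole
#'   computation.
#' @return variance reduction (target units squared).
#' @export
variance_reduction <- function(fit, target, finding, evidence = NULL) {
  m <- fit$spec$nodes[[target]]$midpoints
  if (is.null(m))
    stop_bbn(sprintf("target '%s' has no state midpoints; attach fitted binning schemes first",
                     target), "bbn_config_error")
  pq <- post_vec(fit, target, evidence)
  v0 <- dist_variance(pq, m)
  if (identical(finding, target)) return(v0)
  pf <- post_vec(fit, finding, evidence)
  states_f <- fit$spec$nodes[[finding]]$states
  vcond <- 0
  for (i in seq_along(states_f)) {
    if (pf[i] <= 0) next
    ev <- c(evidence, stats::setNames(states_f[i], finding))
    vcond <- vcond + pf[i] * dist_variance(post_vec(fit, target, ev), m)
  }
  v0 - vcond
}

#' Mutual information between two nodes of a fitted network, in bits
#'
#' \eqn{\sum_{q,f} P(q,f) \log_2 \frac{P(q,f)}{P(q)P(f)}} over the exact
#' joint obtained by inference; symmetric in its arguments. The
#' self-information of a node is its entropy.
#'
#' @inheritParams variance_reduction
#' @return mutual information in bits.
#' @export
mutual_information <- function(fit, target, finding, evidence = NULL) {
  pq <- post_vec(fit, target, evidence)
  if (identical(finding, target))
    return(-sum(ifelse(pq > 0, pq * log2(pq), 0)))
  pf <- post_vec(fit, finding, evidence)
  states_f <- fit$spec$nodes[[finding]]$states
  mi <- 0
  for (i in seq_along(states_f)) {
    if (pf[i] <= 0) next
    ev <- c(evidence, stats::setNames(states_f[i], finding))
    pqf <- post_vec(fit, target, ev)
    nz <- pqf > 0 & pq > 0
    mi <- mi + pf[i] * sum(pqf[nz] * log2(pqf[nz] / pq[nz]))
  }
  max(mi, 0)
}

#' Variance of beliefs of a target with respect to a finding
#'
#' \eqn{\sum_f P(f) \sum_q (P(q \mid f) - P(q))^2}: the expected squared
#' displacement of the target's belief vector when the finding is
#' observed. This reconstructs the third column of Netica-style
#' sensitivity reports, whose exact formula is not published; it is
#' isolated here so it can be swapped out if a definition surfaces.
#'
#' @inheritParams variance_reduction
#' @return non-negative scalar.
#' @export
variance_of_beliefs <- function(fit, target, finding, evidence = NULL) {
  pq <- post_vec(fit, target, evidence)
  if (identical(finding, target)) {
    # observing the target collapses its belief vector to an indicator
    return(sum(vapply(seq_along(pq), function(f) {
      d <- -pq; d[f] <- 1 - pq[f]
      pq[f] * sum(d^2)
    }, 0)))
  }
  pf <- post_vec(fit, finding, evidence)
  states_f <- fit$spec$nodes[[finding]]$states
  vb <- 0
  for (i in seq_along(states_f)) {
    if (pf[i] <= 0) next
    ev <- c(evidence, stats::setNames(states_f[i], finding))
    vb <- vb + pf[i] * sum((post_vec(fit, target, ev) - pq)^2)
  }
  vb
}

#' Rank all other nodes by their sensitivity on a target
#'
#' One row per non-target node, sorted by variance reduction (descending;
#' ties broken by mutual information, then by node name), the layout of a
#' sensitivity-to-findings report.
#'
#' @inheritParams variance_reduction
#' @return data.frame with columns `node`, `variance_reduction`,
#'   `mutual_information`, `variance_of_beliefs`.
#' @export
rank_findings <- function(fit, target, evidence = NULL) {
  others <- setdiff(names(fit$spec$nodes), target)
  rows <- lapply(others, function(f) data.frame(
    node = f,
    variance_reduction = variance_reduction(fit, target, f, evidence),
    mutual_information = mutual_information(fit, target, f, evidence),
    variance_of_beliefs = variance_of_beliefs(fit, target, f, evidence),
    stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(-out$variance_reduction, -out$mutual_information,
                   out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Posterior band shifts under evidence presets
#'
#' For each preset and each target, the posterior band distribution under
#' the preset evidence is compared with the no-evidence baseline; the
#' change is reported in percentage points per band — the form in which
#' scenario comparisons such as no-till versus conventional till are
#' quoted.
#'
#' @param fit a fitted `"bbn"`.
#' @param presets named list of evidence sets (default
#'   [scenario_presets()]).
#' @param targets nodes to report (default: the output-kind nodes).
#' @return data.frame with columns `preset`, `target`, `state`,
#'   `baseline`, `scenario` (probabilities) and `change_pp`
#'   (percentage points, scenario minus baseline).
#' @export
scenario_influence <- function(fit, presets = scenario_presets(),
                               targets = NULL) {
  stopifnot(inherits(fit, "bbn"))
  if (is.null(targets)) {
    kinds <- vapply(fit$spec$nodes, `[[`, "", "kind")
    targets <- names(kinds)[kinds == "output"]
  }
  if (is.null(names(presets)))
    stop_bbn("'presets' must be a named list", "bbn_validation_error")
  rows <- list()
  for (pn in names(presets)) {
    for (tg in targets) {
      ev <- presets[[pn]]
      ev <- ev[setdiff(names(ev), tg)]
      base <- post_vec(fit, tg, NULL)
      scen <- post_vec(fit, tg, ev)
      rows[[length(rows) + 1L]] <- data.frame(
        preset = pn, target = tg, state = fit$spec$nodes[[tg]]$states,
        baseline = base, scenario = scen,
        change_pp = 100 * (scen - base), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
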