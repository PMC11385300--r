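# Discrete factor algebra supporting exact variable-elimination inference.
# A factor is list(vars = character, levels = named list of state labels,
# v = numeric vector in column-major order over vars).

#' @keywords internal
make_factor <- function(vars, levels, v) {
  list(vars = vars, levels = levels[vars], v = v)
}

#' @keywords internal
cpt_factor <- function(fit, node) {
  cpt <- fit$cpts[[node]]
  vars <- names(dimnames(cpt))
  make_factor(vars, dimnames(cpt), as.vector(cpt))
}

# Index vector (1-based) of variable k over the full column-major grid.
#' @keywords internal
grid_index <- function(dims, k) {
  rep(rep.int(seq_len(dims[k]), rep.int(prod(dims[seq_len(k - 1L)]), dims[k])),
      times = prod(dims[-seq_len(k)]))
}

#' @keywords internal
factor_multiply <- function(f1, f2) {
  vars <- union(f1$vars, f2$vars)
  levels <- c(f1$levels, f2$levels)[vars]
  dims <- lengths(levels)
  idx <- lapply(seq_along(vars), function(k) grid_index(dims, k))
  names(idx) <- vars
  lin <- function(f) {
    if (!length(f$vars)) return(rep.int(1L, prod(dims)))
    out <- rep.int(1L, prod(dims)); stride <- 1L
    for (v in f$vars) {
      out <- out + (idx[[v]] - 1L) * stride
      stride <- stride * length(f$levels[[v]])
    }
    out
  }
  make_factor(vars, levels, f1$v[lin(f1)] * f2$v[lin(f2)])
}

# Drop 'var' by slicing at 'state' (evidence conditioning).
#' @keywords internal
factor_reduce <- function(f, var, state) {
  if (!var %in% f$vars) return(f)
  dims <- lengths(f$levels)
  k <- match(var, f$vars)
  keep <- grid_index(dims, k) == match(state, f$levels[[var]])
  make_factor(f$vars[-k], f$levels[-k], f$v[keep])
}

# Sum 'var' out of the factor.
#' @keywords internal
factor_marginalize <- function(f, var) {
  k <- match(var, f$vars)
  dims <- lengths(f$levels)
  if (length(dims) == 1L)
    return(make_factor(character(0), list(), sum(f$v)))
  arr <- array(f$v, dims)
  out <- apply(arr, seq_along(dims)[-k], sum)
  make_factor(f$vars[-k], f$levels[-k], as.vector(out))
}

# Eliminate hidden variables in min-degree order, return product factor.
#' @keywords internal
eliminate <- function(factors, hidden) {
  while (length(hidden)) {
    # min-degree: variable whose elimination creates the smallest factor
    sizes <- vapply(hidden, function(h) {
      nb <- character(0)
      for (f in factors) if (h %in% f$vars) nb <- union(nb, f$vars)
      nb <- setdiff(nb, h)
      prod(vapply(nb, function(v) {
        for (f in factors) if (v %in% f$vars) return(length(f$levels[[v]]))
        1L
      }, 1L))
    }, 0)
    h <- hidden[which.min(sizes)]
    hidden <- setdiff(hidden, h)
    touch <- vapply(factors, function(f) h %in% f$vars, TRUE)
    prod_f <- Reduce(factor_multiply, factors[touch])
    factors <- c(factors[!touch], list(factor_marginalize(prod_f, h)))
  }
  Reduce(factor_multiply, factors)
}

#' Exact posterior distribution of a node given evidence
#'
#' Computes the marginal of `target` conditional on `evidence` by variable
#' elimination with a min-degree elimination order, and renormalizes the
#' result to absorb floating-point drift.
#'
#' @param fit a fitted `"bbn"` from [bbn_fit()].
#' @param target node name; must not appear in `evidence`.
#' @param evidence named character vector/list of observed `node = state`
#'   pairs (may be empty or `NULL`).
#' @return object of class `"posterior"`: named numeric vector of
#'   probabilities over the target's declared states (attributes `node`).
#' @examples
#' spec <- network_spec(
#'   list(node_spec("A", c("a1", "a2"), "input"),
#'        node_spec("B", c("b1", "b2"), "output")),
#'   rbind(c("A", "B")))
#' d <- data.frame(A = c("a1", "a1", "a2", "a2"), B = c("b1", "b1", "b2", "b1"))
#' fit <- bbn_fit(spec, d, prior_weight = 0)
#' posterior(fit, "A", c(B = "b1"))
#' @export
posterior <- function(fit, target, evidence = NULL) {
  stopifnot(inherits(fit, "bbn"))
  spec <- fit$spec
  if (!target %in% names(spec$nodes))
    stop_bbn(sprintf("unknown target node '%s'", target), "bbn_validation_error")
  evidence <- check_evidence(spec, evidence)
  if (target %in% names(evidence))
    stop_bbn("target node must not be part of the evidence",
             "bbn_validation_error")

  factors <- lapply(names(spec$nodes), function(v) cpt_factor(fit, v))
  for (v in names(evidence))
    factors <- lapply(factors, factor_reduce, var = v, state = evidence[[v]])
  factors <- factors[vapply(factors, function(f) length(f$v) > 0, TRUE)]
  hidden <- setdiff(names(spec$nodes), c(target, names(evidence)))
  res <- eliminate(factors, hidden)
  # res is a factor over target only (possibly with scalar factors folded in)
  p <- if (length(res$vars)) {
    stats::setNames(res$v, res$levels[[res$vars]])[spec$nodes[[target]]$states]
  } else stop_bbn("internal error: target eliminated", "bbn_error")
  z <- sum(p)
  if (!is.finite(z) || z <= 0)
    stop_bbn("evidence has probability zero under the fitted model",
             "bbn_impossible_evidence")
  structure(p / z, class = "posterior", node = target)
}

#' @export
print.posterior <- function(x, digits = 4, ...) {
  cat(sprintf("Posterior distribution of '%s':\n", attr(x, "node")))
  v <- round(as.numeric(x), digits)
  names(v) <- names(x)
  print(v)
  invisible(x)
}

#' Joint probability of a complete assignment
#'
#' Chain-rule factorization: the product over nodes of
#' \eqn{P(\mathrm{state} \mid \mathrm{parent\ states})}.
#'
#' @param fit a fitted `"bbn"`.
#' @param assignment named character vector/list assigning a state to
#'   every node.
#' @return a single probability.
#' @export
joint_probability <- function(fit, assignment) {
  stopifnot(inherits(fit, "bbn"))
  assignment <- check_evidence(fit$spec, assignment)
  missing <- setdiff(names(fit$spec$nodes), names(assignment))
  if (length(missing))
    stop_bbn(sprintf("assignment must cover every node; missing: %s",
                     paste(missing, collapse = ", ")),
             "bbn_validation_error")
  prob <- 1
  for (v in names(fit$spec$nodes)) {
    cpt <- fit$cpts[[v]]
    idx <- lapply(names(dimnames(cpt)), function(u)
      match(assignment[[u]], fit$spec$nodes[[u]]$states))
    prob <- prob * do.call(`[`, c(list(cpt), idx))
  }
  unname(prob)
}

#' Most probable state of a node given evidence
#'
#' Argmax of [posterior()]; ties are broken deterministically in favour of
#' the state declared first in the node's state order.
#'
#' @inheritParams posterior
#' @return a single state label.
#' @export
predict_state <- function(fit, target, evidence = NULL) {
  p <- posterior(fit, target, evidence)
  names(p)[which.max(p)]   # which.max returns the first maximum
}

#' Predict target states or posteriors for a table of cases
#'
#' For each row of `newdata`, evidence is assembled from the network's
#' node columns (all nodes except `target` by default, or inputs only)
#' and the posterior of `target` is computed by exact inference.
#'
#' @param object a fitted `"bbn"`.
#' @param newdata data.frame of discretized cases.
#' @param target node to predict.
#' @param type `"state"` for argmax labels, `"prob"` for the full
#'   posterior matrix (rows = cases, columns = target states).
#' @param evidence_policy `"all"` observes every non-target node present
#'   in `newdata`; `"inputs"` observes input-kind nodes only.
#' @param ... unused.
#' @export
predict.bbn <- function(object, newdata, target,
                        type = c("state", "prob"),
                        evidence_policy = c("all", "inputs"), ...) {
  type <- match.arg(type)
  evidence_policy <- match.arg(evidence_policy)
  spec <- object$spec
  kinds <- vapply(spec$nodes, `[[`, "", "kind")
  ev_nodes <- setdiff(names(spec$nodes), target)
  if (evidence_policy == "inputs")
    ev_nodes <- intersect(ev_nodes, names(kinds)[kinds == "input"])
  ev_nodes <- intersect(ev_nodes, names(newdata))
  states <- spec$nodes[[target]]$states
  probs <- matrix(NA_real_, nrow(newdata), length(states),
                  dimnames = list(NULL, states))
  for (i in seq_len(nrow(newdata))) {
    ev <- stats::setNames(vapply(ev_nodes, function(v)
      as.character(newdata[[v]][i]), ""), ev_nodes)
    probs[i, ] <- as.numeric(posterior(object, target, ev))
  }
  if (type == "prob") return(probs)
  factor(states[max.col(probs, ties.method = "first")], levels = states)
}
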