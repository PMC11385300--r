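#' Fit a discrete belief network to complete discretized case data
#'
#' Learns every conditional probability table (CPT) by Dirichlet/Laplace
#' counting: for a node with states \eqn{s_1,\dots,s_k} and a given parent
#' configuration with row total \eqn{N},
#' \deqn{\hat P(s_i \mid \mathrm{parents}) = \frac{n_i + w}{N + w k},}
#' where \eqn{w \ge 0} is `prior_weight`, a uniform pseudo-count added to
#' every cell. With `prior_weight = 0`, parent configurations never
#' observed fall back to a uniform distribution.
#'
#' Cases must be complete: every node of the structure must have a legal
#' state in every row (missing values are rejected, there is no EM here).
#' Extra columns (e.g. `year`, `experiment`) are ignored.
#'
#' @param spec a [network_spec()] (e.g. [tillage_network()]).
#' @param data data.frame of discretized cases, one column per node,
#'   character or factor; see [cases_to_states()].
#' @param prior_weight non-negative pseudo-count (default 1).
#' @return an object of class `"bbn"`: list with `spec`, `cpts` (one
#'   array per node; first dimension indexes the node's states, remaining
#'   dimensions its parents), `prior_weight`, `nobs`.
#' @examples
#' spec <- network_spec(
#'   list(node_spec("A", c("a1", "a2"), "input"),
#'        node_spec("B", c("b1", "b2"), "output")),
#'   rbind(c("A", "B")))
#' d <- data.frame(A = c("a1", "a1", "a2"), B = c("b1", "b2", "b1"))
#' fit <- bbn_fit(spec, d, prior_weight = 0)
#' coef(fit)
#' @seealso [posterior()], [predict.bbn()], [simulate.bbn()]
#' @export
bbn_fit <- function(spec, data, prior_weight = 1) {
  stopifnot(inherits(spec, "network_spec"))
  if (!is.numeric(prior_weight) || length(prior_weight) != 1L ||
      is.na(prior_weight) || prior_weight < 0)
    stop_bbn("'prior_weight' must be a single non-negative number",
             "bbn_validation_error")
  missing_cols <- setdiff(names(spec$nodes), names(data))
  if (length(missing_cols))
    stop_bbn(sprintf("data lacks column(s) for node(s): %s",
                     paste(missing_cols, collapse = ", ")),
             "bbn_data_error")
  n <- nrow(data)
  cols <- list()
  for (v in names(spec$nodes)) {
    x <- as.character(data[[v]])
    bad <- which(is.na(x) | !(x %in% spec$nodes[[v]]$states))
    if (length(bad))
      stop_bbn(sprintf("row %d: '%s' is not a legal state of node '%s'",
                       bad[1L], as.character(data[[v]][bad[1L]]), v),
               "bbn_data_error")
    cols[[v]] <- factor(x, levels = spec$nodes[[v]]$states)
  }

  cpts <- list()
  for (v in names(spec$nodes)) {
    pa <- parents(spec, v)
    counts <- table(cols[c(v, pa)])       # dim: node states x parent states
    counts <- array(as.numeric(counts), dim = dim(counts),
                    dimnames = dimnames(counts))
    k <- dim(counts)[1L]
    post <- counts + prior_weight
    # normalize each column (parent configuration) over the node dimension
    m <- matrix(post, nrow = k)
    tot <- colSums(m)
    zero <- tot == 0                       # only possible when prior_weight == 0
    m <- sweep(m, 2L, ifelse(zero, 1, tot), "/")
    m[, zero] <- 1 / k
    cpt <- array(m, dim = dim(counts), dimnames = dimnames(counts))
    names(dimnames(cpt)) <- c(v, pa)
    cpts[[v]] <- cpt
  }

  structure(list(spec = spec, cpts = cpts, prior_weight = prior_weight,
                 nobs = n),
            class = "bbn")
}

#' @export
print.bbn <- function(x, ...) {
  cat(sprintf("Fitted belief network: %d nodes, %d links, %d training cases, prior weight %g\n",
              length(x$spec$nodes), nrow(x$spec$links), x$nobs, x$prior_weight))
  cat(sprintf("  total CPT entries: %d\n",
              sum(vapply(x$cpts, length, 1L))))
  invisible(x)
}

#' @export
summary.bbn <- function(object, ...) {
  rows <- lapply(names(object$spec$nodes), function(v) {
    cpt <- object$cpts[[v]]
    data.frame(node = v,
               kind = object$spec$nodes[[v]]$kind,
               n_states = dim(cpt)[1L],
               n_parents = length(dim(cpt)) - 1L,
               n_rows = prod(dim(cpt)) / dim(cpt)[1L],
               n_entries = length(cpt))
  })
  out <- do.call(rbind, rows)
  structure(list(table = out, nobs = object$nobs,
                 prior_weight = object$prior_weight),
            class = "summary.bbn")
}

#' @export
print.summary.bbn <- function(x, ...) {
  cat(sprintf("Belief network fitted to %d cases (prior weight %g)\n\n",
              x$nobs, x$prior_weight))
  print(x$table, row.names = FALSE)
  cat(sprintf("\nTotal conditional probabilities: %d\n", sum(x$table$n_entries)))
  invisible(x)
}

#' Flat table of fitted conditional probabilities
#'
#' @param object a fitted `"bbn"`.
#' @param ... unused.
#' @return data.frame with columns `node`, `parents` (comma-separated
#'   `parent=state` tuple, empty for root nodes), `state`, `probability`.
#' @export
coef.bbn <- function(object, ...) {
  out <- lapply(names(object$cpts), function(v) {
    cpt <- object$cpts[[v]]
    dn <- dimnames(cpt)
    g <- expand.grid(dn, stringsAsFactors = FALSE)
    pa <- names(dn)[-1L]
    tup <- if (length(pa)) {
      apply(g[, pa, drop = FALSE], 1L, function(r)
        paste(paste0(pa, "=", r), collapse = ","))
    } else rep("", nrow(g))
    data.frame(node = v, parents = tup, state = g[[1L]],
               probability = as.vector(cpt), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Log-likelihood of complete cases under a fitted belief network
#' @param object a fitted `"bbn"`.
#' @param data data.frame of complete discretized cases.
#' @param ... unused.
#' @export
logLik.bbn <- function(object, data, ...) {
  ll <- sum(vapply(seq_len(nrow(data)), function(i) {
    log(joint_probability(object, lapply(data[i, names(object$spec$nodes)],
                                         as.character)))
  }, 0))
  structure(ll, df = sum(vapply(object$cpts, function(cpt)
    prod(dim(cpt)) - prod(dim(cpt)) / dim(cpt)[1L], 0)),
    nobs = nrow(data), class = "logLik")
}

#' Ancestral (forward) sampling from a fitted belief network
#'
#' @param object a fitted `"bbn"`.
#' @param nsim number of cases to draw.
#' @param seed optional integer passed to [set.seed()].
#' @param ... unused.
#' @return data.frame of sampled states, one column per node, columns in
#'   topological order.
#' @export
simulate.bbn <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  ord <- object$spec$order
  out <- as.data.frame(stats::setNames(
    rep(list(character(nsim)), length(ord)), ord),
    stringsAsFactors = FALSE)
  for (v in ord) {
    cpt <- object$cpts[[v]]
    states <- object$spec$nodes[[v]]$states
    pa <- parents(object$spec, v)
    if (!length(pa)) {
      out[[v]] <- sample(states, nsim, replace = TRUE, prob = as.vector(cpt))
    } else {
      # linear index of each case's parent configuration into the CPT columns
      m <- matrix(cpt, nrow = length(states))
      cfg <- rep(1L, nsim); stride <- 1L
      for (p in pa) {
        pi <- match(out[[p]], object$spec$nodes[[p]]$states)
        cfg <- cfg + (pi - 1L) * stride
        stride <- stride * length(object$spec$nodes[[p]]$states)
      }
      for (cc in unique(cfg)) {
        rows <- which(cfg == cc)
        out[[v]][rows] <- sample(states, length(rows), replace = TRUE,
                                 prob = m[, cc])
      }
    }
  }
  out
}
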