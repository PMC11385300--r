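#' @keywords internal
stop_bbn <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "bbn_error", "error"),
                      call = call))
}

#' Declare a node of a discrete belief network
#'
#' A node has a name, an ordered set of at least two state labels, a role
#' (`kind`) in the network, and optionally a numeric midpoint per state.
#' Midpoints carry the real-valued interpretation of ordered bands (in the
#' units of the underlying variable) and are required by variance-based
#' sensitivity analysis; categorical nodes can leave them unset.
#'
#' @param name node identifier (single string).
#' @param states ordered character vector of state labels (length >= 2,
#'   no duplicates). The declared order is authoritative throughout the
#'   package: CPT rows, confusion-matrix axes and argmax tie-breaking all
#'   follow it.
#' @param kind one of `"input"`, `"intermediary"`, `"output"`.
#' @param midpoints optional numeric vector, one value per state, strictly
#'   increasing for ordered bands.
#' @return an object of class `"node_spec"`.
#' @seealso [network_spec()], [tillage_network()]
#' @export
node_spec <- function(name, states, kind = c("input", "intermediary", "output"),
                      midpoints = NULL) {
  kind <- match.arg(kind)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_bbn("node 'name' must be a single non-empty string",
             "bbn_validation_error")
  states <- as.character(states)
  if (length(states) < 2L)
    stop_bbn(sprintf("node '%s' needs at least 2 states", name),
             "bbn_validation_error")
  if (anyDuplicated(states))
    stop_bbn(sprintf("node '%s' has duplicated state labels", name),
             "bbn_validation_error")
  if (!is.null(midpoints)) {
    midpoints <- as.numeric(midpoints)
    if (length(midpoints) != length(states))
      stop_bbn(sprintf("node '%s': midpoints length (%d) != number of states (%d)",
                       name, length(midpoints), length(states)),
               "bbn_validation_error")
    if (any(diff(midpoints) <= 0))
      stop_bbn(sprintf("node '%s': midpoints must be strictly increasing", name),
               "bbn_validation_error")
  }
  structure(list(name = name, states = states, kind = kind,
                 midpoints = midpoints),
            class = "node_spec")
}

#' Declare the structure of a discrete belief network
#'
#' Assembles node declarations and directed links into a validated
#' directed acyclic graph (DAG). Link endpoints must name declared nodes,
#' self-links and duplicate links are rejected, and a cycle anywhere in
#' the graph raises a structural error naming one offending cycle.
#'
#' @param nodes list of [node_spec()] objects.
#' @param links two-column character matrix or data.frame
#'   (parent, child), one row per directed link.
#' @return an object of class `"network_spec"` with components `nodes`
#'   (named list), `links` (2-column character matrix) and `order`
#'   (a topological order of the node names).
#' @examples
#' spec <- network_spec(
#'   list(node_spec("A", c("a1", "a2"), "input"),
#'        node_spec("B", c("b1", "b2"), "output")),
#'   rbind(c("A", "B")))
#' spec$order
#' @export
network_spec <- function(nodes, links) {
  if (inherits(nodes, "node_spec")) nodes <- list(nodes)
  if (!length(nodes) || !all(vapply(nodes, inherits, TRUE, "node_spec")))
    stop_bbn("'nodes' must be a list of node_spec objects",
             "bbn_validation_error")
  names(nodes) <- vapply(nodes, `[[`, "", "name")
  if (anyDuplicated(names(nodes)))
    stop_bbn("duplicated node names", "bbn_validation_error")

  links <- as.matrix(links)
  if (length(links) == 0L) {
    links <- matrix(character(), ncol = 2L)
  }
  if (ncol(links) != 2L)
    stop_bbn("'links' must have two columns (parent, child)",
             "bbn_validation_error")
  mode(links) <- "character"
  colnames(links) <- c("parent", "child")
  unknown <- setdiff(c(links), names(nodes))
  if (length(unknown))
    stop_bbn(sprintf("link endpoint(s) not declared as nodes: %s",
                     paste(unknown, collapse = ", ")),
             "bbn_validation_error")
  if (any(links[, 1L] == links[, 2L]))
    stop_bbn("self-links are not allowed", "bbn_validation_error")
  if (anyDuplicated(paste(links[, 1L], links[, 2L])))
    stop_bbn("duplicated links", "bbn_validation_error")

  ord <- topological_order(names(nodes), links)

  structure(list(nodes = nodes, links = links, order = ord),
            class = "network_spec")
}

# Kahn's algorithm; on failure, reports one cycle found by DFS.
topological_order <- function(node_names, links) {
  indeg <- stats::setNames(integer(length(node_names)), node_names)
  kids <- lapply(stats::setNames(node_names, node_names),
                 function(p) links[links[, 1L] == p, 2L])
  for (ch in links[, 2L]) indeg[ch] <- indeg[ch] + 1L
  queue <- node_names[indeg == 0L]
  ord <- character(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, v)
    for (ch in kids[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) != length(node_names)) {
    stop_bbn(sprintf("network contains a cycle: %s",
                     paste(find_cycle(node_names, links), collapse = " -> ")),
             "bbn_cycle_error")
  }
  ord
}

# DFS with colouring; returns the node sequence of one directed cycle.
find_cycle <- function(node_names, links) {
  kids <- lapply(stats::setNames(node_names, node_names),
                 function(p) links[links[, 1L] == p, 2L])
  colour <- stats::setNames(rep("white", length(node_names)), node_names)
  stack <- character(0)
  cycle <- NULL
  visit <- function(v) {
    if (!is.null(cycle)) return(invisible())
    colour[v] <<- "grey"
    stack <<- c(stack, v)
    for (ch in kids[[v]]) {
      if (!is.null(cycle)) return(invisible())
      if (colour[ch] == "grey") {
        i <- match(ch, stack)
        cycle <<- c(stack[i:length(stack)], ch)
      } else if (colour[ch] == "white") visit(ch)
    }
    colour[v] <<- "black"
    stack <<- stack[-length(stack)]
    invisible()
  }
  for (v in node_names) if (colour[v] == "white") visit(v)
  cycle
}

#' @export
print.network_spec <- function(x, ...) {
  kinds <- vapply(x$nodes, `[[`, "", "kind")
  cat(sprintf("Belief network structure: %d nodes, %d links\n",
              length(x$nodes), nrow(x$links)))
  cat(sprintf("  inputs: %s\n",
              paste(names(x$nodes)[kinds == "input"], collapse = ", ")))
  cat(sprintf("  intermediaries: %s\n",
              paste(names(x$nodes)[kinds == "intermediary"], collapse = ", ")))
  cat(sprintf("  outputs: %s\n",
              paste(names(x$nodes)[kinds == "output"], collapse = ", ")))
  invisible(x)
}

#' Parents of a node in a network structure
#' @param spec a `network_spec` (or fitted `bbn`).
#' @param node node name.
#' @return character vector of parent names, in link declaration order.
#' @export
parents <- function(spec, node) {
  if (inherits(spec, "bbn")) spec <- spec$spec
  stopifnot(inherits(spec, "network_spec"))
  if (!node %in% names(spec$nodes))
    stop_bbn(sprintf("unknown node '%s'", node), "bbn_validation_error")
  unname(spec$links[spec$links[, 2L] == node, 1L])
}

#' Children of a node in a network structure
#' @inheritParams parents
#' @return character vector of child names.
#' @export
children <- function(spec, node) {
  if (inherits(spec, "bbn")) spec <- spec$spec
  stopifnot(inherits(spec, "network_spec"))
  if (!node %in% names(spec$nodes))
    stop_bbn(sprintf("unknown node '%s'", node), "bbn_validation_error")
  unname(spec$links[spec$links[, 1L] == node, 2L])
}

#' @keywords internal
node_states <- function(spec, node) spec$nodes[[node]]$states

# Validate an evidence set: named character vector/list of node = state.
#' @keywords internal
check_evidence <- function(spec, evidence) {
  if (is.null(evidence) || !length(evidence)) return(stats::setNames(character(0), character(0)))
  evidence <- unlist(evidence)
  if (is.null(names(evidence)) || any(!nzchar(names(evidence))))
    stop_bbn("evidence must be a named set of node = state", "bbn_validation_error")
  bad <- setdiff(names(evidence), names(spec$nodes))
  if (length(bad))
    stop_bbn(sprintf("evidence names unknown node(s): %s",
                     paste(bad, collapse = ", ")), "bbn_validation_error")
  for (v in names(evidence)) {
    if (!evidence[[v]] %in% spec$nodes[[v]]$states)
      stop_bbn(sprintf("'%s' is not a legal state of node '%s'",
                       evidence[[v]], v), "bbn_validation_error")
  }
  evidence
}

#' Attach band midpoints from fitted binning schemes to a network structure
#'
#' Sensitivity analysis treats ordered bands as real values through their
#' midpoints; those midpoints are a property of the fitted discretization,
#' so this helper copies them from a list of [fit_bins()] schemes onto the
#' matching nodes.
#'
#' @param spec a `network_spec`.
#' @param schemes named list of `bin_scheme` objects (names = node names).
#' @return the updated `network_spec`.
#' @export
attach_midpoints <- function(spec, schemes) {
  stopifnot(inherits(spec, "network_spec"))
  for (v in names(schemes)) {
    if (!v %in% names(spec$nodes)) next
    sc <- schemes[[v]]
    nd <- spec$nodes[[v]]
    if (length(sc$labels) == length(nd$states) && all(sc$labels == nd$states)) {
      spec$nodes[[v]] <- node_spec(nd$name, nd$states, nd$kind,
                                   midpoints = sc$midpoints)
    } else {
      # scheme collapsed to fewer bands than declared: re-declare states
      spec$nodes[[v]] <- node_spec(nd$name, sc$labels, nd$kind,
                                   midpoints = sc$midpoints)
    }
  }
  spec
}
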