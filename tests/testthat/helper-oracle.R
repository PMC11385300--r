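# Independent oracles used across the suite.
#
# The enumeration oracle computes posteriors from the full joint built by
# brute-force chain-rule multiplication over an expand.grid of all
# assignments; it shares no code with the package's factor algebra.

enum_joint <- function(fit) {
  spec <- fit$spec
  states <- lapply(spec$nodes, `[[`, "states")
  grid <- expand.grid(states, stringsAsFactors = FALSE)
  p <- rep(1, nrow(grid))
  for (v in names(spec$nodes)) {
    cpt <- fit$cpts[[v]]
    fam <- names(dimnames(cpt))
    idx <- vapply(fam, function(u) match(grid[[u]], spec$nodes[[u]]$states),
                  integer(nrow(grid)))
    idx <- matrix(idx, nrow = nrow(grid))
    dims <- dim(cpt)
    stride <- cumprod(c(1, dims[-length(dims)]))
    lin <- 1 + as.vector((idx - 1) %*% stride)
    p <- p * cpt[lin]
  }
  cbind(grid, joint = p)
}

enum_posterior <- function(fit, target, evidence = NULL) {
  j <- enum_joint(fit)
  if (length(evidence))
    for (v in names(evidence)) j <- j[j[[v]] == evidence[[v]], , drop = FALSE]
  states <- fit$spec$nodes[[target]]$states
  p <- vapply(states, function(s) sum(j$joint[j[[target]] == s]), 0)
  p / sum(p)
}

# Random DAG over n nodes (edges only forward in a fixed order) with
# random strictly-positive CPTs; returns a "bbn" built by hand.
random_bbn <- function(n_nodes, max_states = 4, edge_prob = 0.4) {
  nms <- paste0("N", seq_len(n_nodes))
  nstates <- sample(2:max_states, n_nodes, replace = TRUE)
  nodes <- lapply(seq_len(n_nodes), function(i)
    node_spec(nms[i], paste0("s", seq_len(nstates[i]))))
  links <- matrix(character(0), ncol = 2)
  if (n_nodes > 1)
    for (i in seq_len(n_nodes - 1))
      for (k in (i + 1):n_nodes)
        if (stats::runif(1) < edge_prob) links <- rbind(links, c(nms[i], nms[k]))
  spec <- network_spec(nodes, links)
  cpts <- lapply(names(spec$nodes), function(v) {
    pa <- parents(spec, v)
    dims <- c(length(spec$nodes[[v]]$states),
              vapply(pa, function(p) length(spec$nodes[[p]]$states), 1L))
    dn <- c(list(spec$nodes[[v]]$states),
            lapply(pa, function(p) spec$nodes[[p]]$states))
    names(dn) <- c(v, pa)
    m <- matrix(stats::rgamma(prod(dims), 1) + 1e-3, nrow = dims[1L])
    m <- sweep(m, 2L, colSums(m), "/")
    array(m, dims, dn)
  })
  names(cpts) <- names(spec$nodes)
  structure(list(spec = spec, cpts = cpts, prior_weight = NA_real_, nobs = 0L),
            class = "bbn")
}

# Build a fitted bbn directly from hand-specified CPT arrays.
manual_bbn <- function(spec, cpts) {
  structure(list(spec = spec, cpts = cpts, prior_weight = NA_real_, nobs = 0L),
            class = "bbn")
}

# Two-node helper: P(A), P(B|A) as matrices/vectors.
chain_ab <- function(pa1 = 0.5, pb1_a1 = 0.9, pb1_a2 = 0.1) {
  spec <- network_spec(
    list(node_spec("A", c("a1", "a2"), "input"),
         node_spec("B", c("b1", "b2"), "output")),
    rbind(c("A", "B")))
  cpts <- list(
    A = array(c(pa1, 1 - pa1), 2L, dimnames = list(A = c("a1", "a2"))),
    B = array(c(pb1_a1, 1 - pb1_a1, pb1_a2, 1 - pb1_a2), c(2L, 2L),
              dimnames = list(B = c("b1", "b2"), A = c("a1", "a2"))))
  manual_bbn(spec, cpts)
}

# Small raw-records fixture with the full case-column roster, generated
# from a reduced configuration (and memoised, since several files use it).
.fixture_cache <- new.env(parent = emptyenv())
small_records <- function(years = 1975:1994, seed = 7L) {
  key <- paste("rec", min(years), max(years), seed, sep = "_")
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <-
      simulate_tillage_data(sim_config(years = years, seed = seed))
  .fixture_cache[[key]]
}
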