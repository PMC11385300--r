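# Hand-checkable fixtures: a disconnected pair, a noisy two-node chain
# with midpoints, and a three-node chain for the data-processing check.

disconnected_pair <- function() {
  spec <- network_spec(
    list(node_spec("X", c("x1", "x2"), midpoints = c(0, 1)),
         node_spec("Y", c("y1", "y2"), midpoints = c(0, 1))),
    matrix(character(0), ncol = 2))
  manual_bbn(spec, list(
    X = array(c(0.3, 0.7), 2, dimnames = list(X = c("x1", "x2"))),
    Y = array(c(0.6, 0.4), 2, dimnames = list(Y = c("y1", "y2")))))
}

noisy_chain <- function(eps = 0.2) {
  spec <- network_spec(
    list(node_spec("A", c("a1", "a2"), midpoints = c(0, 10)),
         node_spec("B", c("b1", "b2"), midpoints = c(0, 1))),
    rbind(c("A", "B")))
  manual_bbn(spec, list(
    A = array(c(0.5, 0.5), 2, dimnames = list(A = c("a1", "a2"))),
    B = array(c(1 - eps, eps, eps, 1 - eps), c(2, 2),
              dimnames = list(B = c("b1", "b2"), A = c("a1", "a2")))))
}

test_that("independent nodes yield zero variance reduction and zero mutual information", {
  fit <- disconnected_pair()
  expect_equal(variance_reduction(fit, "X", "Y"), 0, tolerance = 1e-12)
  expect_equal(mutual_information(fit, "X", "Y"), 0, tolerance = 1e-12)
  expect_equal(variance_of_beliefs(fit, "X", "Y"), 0, tolerance = 1e-12)
})

test_that("observing the target itself removes its full variance and entropy", {
  fit <- noisy_chain()
  # V(A) with midpoints (0, 10) and P = (1/2, 1/2): 100/2 - 25 = 25
  expect_equal(variance_reduction(fit, "A", "A"), 25)
  expect_equal(mutual_information(fit, "A", "A"), 1)  # H(A) = 1 bit
})

test_that("variance reduction on a two-node toy equals arithmetic over the joint", {
  eps <- 0.2
  fit <- noisy_chain(eps)
  # P(B=b1) = 1/2; P(A=a1|b1) = 0.8, so V(A|b1) = 100*0.8*0.2 = 16 = V(A|b2)
  # VR = V(A) - 16 = 25 - 16 = 9
  expect_equal(variance_reduction(fit, "A", "B"), 9, tolerance = 1e-9)
  # mutual information: 1 - H(0.8) bits
  h <- -(0.8 * log2(0.8) + 0.2 * log2(0.2))
  expect_equal(mutual_information(fit, "A", "B"), 1 - h, tolerance = 1e-9)
  # variance of beliefs: sum_f P(f) * sum_q (P(q|f) - P(q))^2 = 2*(0.3^2)*... by hand:
  # P(A|b1) = (0.8, 0.2) vs prior (0.5, 0.5): squared displacement 2*0.09 = 0.18
  expect_equal(variance_of_beliefs(fit, "A", "B"), 0.18, tolerance = 1e-9)
})

test_that("mutual information is symmetric and reaches 1 bit on a uniform bijection", {
  fit <- noisy_chain(0.25)
  expect_equal(mutual_information(fit, "A", "B"),
               mutual_information(fit, "B", "A"), tolerance = 1e-9)
  det <- noisy_chain(0)   # deterministic copy of a fair coin
  expect_equal(mutual_information(det, "A", "B"), 1, tolerance = 1e-9)
})

test_that("sensitivity statistics match brute-force enumeration on random networks", {
  set.seed(404)
  for (rep in 1:5) {
    fit <- random_bbn(sample(3:5, 1), max_states = 3)
    # attach midpoints so variance-based sensitivity is defined
    for (v in names(fit$spec$nodes)) {
      nd <- fit$spec$nodes[[v]]
      fit$spec$nodes[[v]] <- node_spec(nd$name, nd$states, nd$kind,
                                       midpoints = seq_along(nd$states))
    }
    nodes <- names(fit$spec$nodes)
    target <- sample(nodes, 1)
    finding <- sample(setdiff(nodes, target), 1)
    j <- enum_joint(fit)
    # oracle: joint table of (target, finding) by direct summation
    ts <- fit$spec$nodes[[target]]$states
    fs <- fit$spec$nodes[[finding]]$states
    jt <- outer(ts, fs, Vectorize(function(q, f)
      sum(j$joint[j[[target]] == q & j[[finding]] == f])))
    pq <- rowSums(jt); pf <- colSums(jt)
    m <- seq_along(ts)
    v0 <- sum(pq * m^2) - sum(pq * m)^2
    vr_oracle <- v0 - sum(vapply(seq_along(fs), function(k) {
      pc <- jt[, k] / pf[k]
      pf[k] * (sum(pc * m^2) - sum(pc * m)^2)
    }, 0))
    mi_oracle <- sum(ifelse(jt > 0, jt * log2(jt / outer(pq, pf)), 0))
    expect_equal(variance_reduction(fit, target, finding), vr_oracle,
                 tolerance = 1e-9)
    expect_equal(mutual_information(fit, target, finding), mi_oracle,
                 tolerance = 1e-9)
    expect_gte(variance_reduction(fit, target, finding), -1e-9)
    # MI bounded by both entropies
    h <- function(p) -sum(ifelse(p > 0, p * log2(p), 0))
    expect_lte(mi_oracle, min(h(pq), h(pf)) + 1e-9)
  }
})

test_that("information decays along a chain (data-processing inequality)", {
  spec <- network_spec(
    list(node_spec("A", c("a1", "a2")), node_spec("B", c("b1", "b2")),
         node_spec("C", c("c1", "c2"), "output")),
    rbind(c("A", "B"), c("B", "C")))
  noisy <- function(nm, pa, eps) array(c(1 - eps, eps, eps, 1 - eps), c(2, 2),
                                       dimnames = stats::setNames(
                                         list(c(paste0(tolower(nm), 1:2)),
                                              paste0(tolower(pa), 1:2)),
                                         c(nm, pa)))
  fit <- manual_bbn(spec, list(
    A = array(c(0.5, 0.5), 2, dimnames = list(A = c("a1", "a2"))),
    B = noisy("B", "A", 0.15),
    C = noisy("C", "B", 0.15)))
  expect_lt(mutual_information(fit, "C", "A"),
            mutual_information(fit, "C", "B"))
})

test_that("the findings ranking is complete, sorted, and led by informative parents", {
  rec <- small_records()
  schemes <- fit_tillage_schemes(rec)
  spec <- attach_midpoints(tillage_network(), schemes)
  fit <- bbn_fit(spec, cases_to_states(rec, schemes), 1)
  rk <- rank_findings(fit, "yield")
  expect_equal(nrow(rk), 10)
  expect_true(all(diff(rk$variance_reduction) <= 1e-9))
  expect_true(all(rk$variance_reduction >= -1e-9))
  expect_true(all(rk$mutual_information >= -1e-12))
  expect_true(all(rk$variance_of_beliefs >= -1e-12))
  # the direct biomass parent must outrank nodes two links away from yield
  expect_lt(match("biomass", rk$node), match("temperature", rk$node))
  expect_lt(match("biomass", rk$node), match("tillage", rk$node))
})

test_that("a target without midpoints is a configuration error", {
  fit <- bbn_fit(tillage_network(),
                 cases_to_states(small_records(),
                                 fit_tillage_schemes(small_records())), 1)
  expect_error(variance_reduction(fit, "yield", "biomass"),
               class = "bbn_config_error")
})

test_that("scenario influence reports baseline-vs-preset shifts per band", {
  rec <- small_records()
  schemes <- fit_tillage_schemes(rec)
  fit <- bbn_fit(tillage_network(), cases_to_states(rec, schemes), 1)
  si <- scenario_influence(fit, list(none = character(0), NT = c(tillage = "NT")))
  expect_equal(nrow(si), 2 * 3 * 5)   # presets x output targets x bands
  empty <- si[si$preset == "none", ]
  expect_true(all(abs(empty$change_pp) < 1e-9))   # baseline vs itself
  nt <- si[si$preset == "NT", ]
  expect_equal(sum(nt$scenario[nt$target == "runoff"]), 1, tolerance = 1e-9)
})
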