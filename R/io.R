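# Case-file and configuration I/O plus the end-to-end pipeline driver.

CASE_COLUMNS <- c("experiment", "year", "tillage", "soil", "rainfall",
                  "temperature", "csom", "aws", "interception", "biomass",
                  "yield", "runoff", "ghg")

#' Write seasonal case records to a delimited text file
#'
#' Numeric columns are written with enough digits to round-trip exactly
#' through [read_cases()].
#'
#' @param records data.frame of case records.
#' @param path output file.
#' @param sep field delimiter, tab (default) or comma.
#' @param comment optional comment line written first, prefixed `// `.
#' @return `path`, invisibly.
#' @export
write_cases <- function(records, path, sep = "\t", comment = NULL) {
  out <- records
  for (v in names(out))
    if (is.double(out[[v]])) out[[v]] <- formatC(out[[v]], digits = 17,
                                                 format = "g")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("// ", comment), con)
  utils::write.table(out, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read seasonal case records from a delimited text file
#'
#' Accepts tab- or comma-delimited files (auto-detected from the header
#' unless `sep` is given) with a header row; a leading case-file style
#' comment line (`// ...`) is tolerated. Columns are validated against
#' the 11-variable roster plus `experiment` and `year`; numeric columns
#' must parse, and errors name the file, row and column.
#'
#' @param path input file.
#' @param sep optional explicit delimiter.
#' @return data.frame of typed case records.
#' @export
read_cases <- function(path, sep = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) && startsWith(lines[1L], "//")) lines <- lines[-1L]
  if (!length(lines))
    stop_bbn(sprintf("%s: empty case file", path), "bbn_data_error")
  if (is.null(sep))
    sep <- if (grepl("\t", lines[1L], fixed = TRUE)) "\t" else ","
  d <- utils::read.table(text = lines, header = TRUE, sep = sep,
                         colClasses = "character",
                         stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(CASE_COLUMNS, names(d))
  if (length(missing))
    stop_bbn(sprintf("%s: missing column(s): %s", path,
                     paste(missing, collapse = ", ")), "bbn_data_error")
  numeric_cols <- setdiff(CASE_COLUMNS, c("experiment", "tillage", "soil"))
  for (v in names(d)) {
    if (!(v %in% numeric_cols || v == "oc_percent")) next
    x <- suppressWarnings(as.numeric(d[[v]]))
    bad <- which(is.na(x))
    if (length(bad))
      stop_bbn(sprintf("%s: row %d, column '%s': cannot parse '%s' as a number",
                       path, bad[1L], v, d[[v]][bad[1L]]),
               "bbn_data_error")
    d[[v]] <- x
  }
  d$year <- as.integer(d$year)
  d
}

#' Write a network structure to a YAML configuration file
#' @param spec a [network_spec()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network_spec <- function(spec, path) {
  stopifnot(inherits(spec, "network_spec"))
  nodes <- lapply(spec$nodes, function(nd) {
    l <- list(states = as.list(nd$states), kind = nd$kind)
    if (!is.null(nd$midpoints)) l$midpoints <- as.numeric(nd$midpoints)
    l
  })
  links <- apply(spec$links, 1L, function(r) paste(r[1L], "->", r[2L]))
  yaml::write_yaml(list(nodes = nodes, links = as.list(links)), path,
                   precision = 17L)
  invisible(path)
}

#' Read a network structure from a YAML configuration file
#' @param path input file.
#' @return a validated [network_spec()]; the read/write round trip is
#'   lossless.
#' @export
read_network_spec <- function(path) {
  l <- yaml::read_yaml(path)
  nodes <- lapply(names(l$nodes), function(nm) {
    nd <- l$nodes[[nm]]
    node_spec(nm, unlist(nd$states), nd$kind,
              midpoints = if (!is.null(nd$midpoints)) as.numeric(nd$midpoints))
  })
  links <- do.call(rbind, lapply(l$links, function(s) {
    parts <- strsplit(s, "->", fixed = TRUE)[[1L]]
    if (length(parts) != 2L)
      stop_bbn(sprintf("%s: malformed link '%s'", path, s), "bbn_data_error")
    trimws(parts)
  }))
  network_spec(nodes, links)
}

#' Write / read banding schemes as YAML
#' @param schemes named list of `bin_scheme` objects.
#' @param path file path.
#' @return `path` (write) or the named scheme list (read); band
#'   assignments are identical before and after the round trip.
#' @export
write_schemes <- function(schemes, path) {
  yaml::write_yaml(lapply(schemes, scheme_to_list), path, precision = 17L)
  invisible(path)
}

#' @rdname write_schemes
#' @export
read_schemes <- function(path) {
  lapply(yaml::read_yaml(path), scheme_from_list)
}

#' Export fitted CPTs as a flat delimited table
#' @param fit a fitted `"bbn"`.
#' @param path output file (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_cpts <- function(fit, path) {
  tab <- coef(fit)
  tab$probability <- formatC(tab$probability, digits = 17, format = "g")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Tiny polynomial hash over a character vector; used to stamp reports
# with a fingerprint of the run manifest without external dependencies.
# Arithmetic stays below 2^53, so it is exact in doubles.
#' @keywords internal
manifest_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n")) %% 256
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full analysis pipeline
#'
#' Simulate the seasonal dataset, fit banding schemes on the training
#' years only, discretize, learn the CPTs, evaluate every output node on
#' the chronological holdout, run the decade-block K-fold report for each
#' output, rank sensitivity findings, compute scenario influence, and
#' write every report as a delimited text file under `out_dir`. All
#' randomness flows from `config$seed`: two runs with the same
#' configuration produce byte-identical report files (the manifest's
#' timestamp field excepted).
#'
#' @param config a [sim_config()].
#' @param out_dir output directory, created if needed. `NULL` skips all
#'   file output.
#' @param plan holdout [split_plan()].
#' @param kfold_plan kfold [split_plan()] (NULL skips the K-fold stage).
#' @param prior_weight CPT pseudo-count.
#' @param n_bands bands for non-output variables.
#' @param evidence_policy passed to [evaluate_network()].
#' @return (invisibly) list with `records`, `schemes`, `fit`,
#'   `evaluations`, `kfold`, `sensitivity`, `scenarios`, `calibration`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         plan = split_plan("holdout"),
                         kfold_plan = split_plan("kfold"),
                         prior_weight = 1, n_bands = 5L,
                         evidence_policy = c("all", "inputs")) {
  evidence_policy <- match.arg(evidence_policy)
  t0 <- proc.time()[["elapsed"]]
  stage <- function(msg) message(sprintf("[%6.1fs] %s",
                                         proc.time()[["elapsed"]] - t0, msg))

  stage("simulating seasonal dataset")
  records <- simulate_tillage_data(config)

  stage("fitting banding schemes on training years")
  splits <- split_cases(records, plan)
  schemes <- fit_tillage_schemes(splits$train, n_bands = n_bands)

  stage("learning conditional probability tables")
  spec <- attach_midpoints(tillage_network(n_bands = n_bands), schemes)
  train_states <- cases_to_states(splits$train, schemes)
  test_states <- cases_to_states(splits$test, schemes)
  fit <- bbn_fit(spec, train_states, prior_weight = prior_weight)

  kinds <- vapply(spec$nodes, `[[`, "", "kind")
  outputs <- names(kinds)[kinds == "output"]

  stage("holdout evaluation")
  evaluations <- lapply(stats::setNames(outputs, outputs), function(tg)
    evaluate_network(fit, test_states, tg, evidence_policy = evidence_policy))

  kf <- NULL
  if (!is.null(kfold_plan)) {
    stage("K-fold cross-validation")
    kf <- lapply(stats::setNames(outputs, outputs), function(tg)
      kfold_report(records, tg, plan = kfold_plan, spec = tillage_network(n_bands = n_bands),
                   prior_weight = prior_weight, n_bands = n_bands,
                   evidence_policy = evidence_policy))
  }

  stage("sensitivity to findings")
  sens <- lapply(stats::setNames(outputs, outputs), function(tg)
    rank_findings(fit, tg))

  stage("scenario influence")
  scen <- scenario_influence(fit)

  calib <- calibration_report(records)

  manifest <- list(
    package = "tillagebbn",
    version = as.character(utils::packageVersion("tillagebbn")),
    seed = config$seed,
    years = range(config$years),
    n_experiments = nrow(config$soils) * length(config$tillage_systems),
    n_cases = nrow(records),
    prior_weight = prior_weight, n_bands = n_bands,
    evidence_policy = evidence_policy,
    holdout_train = range(plan$train_years),
    holdout_test = range(plan$test_years))
  hash <- manifest_hash(vapply(manifest, function(x)
    paste(format(x), collapse = ","), ""))
  manifest$hash <- hash

  if (!is.null(out_dir)) {
    stage(sprintf("writing reports to %s", out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    stamp <- sprintf("# run %s", hash)
    wt <- function(df, file) {
      p <- file.path(out_dir, file)
      writeLines(stamp, p)
      suppressWarnings(utils::write.table(df, p, sep = "\t", quote = FALSE,
                                          row.names = FALSE, append = TRUE))
    }
    write_cases(records, file.path(out_dir, "cases.tsv"),
                comment = paste("run", hash))
    write_cpts(fit, file.path(out_dir, "cpts.tsv"))
    write_schemes(schemes, file.path(out_dir, "schemes.yaml"))
    for (tg in outputs) {
      cm <- as.data.frame.matrix(evaluations[[tg]]$confusion)
      wt(cbind(actual = rownames(cm), cm),
         sprintf("confusion_%s.tsv", tg))
      if (!is.null(kf)) wt(kf[[tg]], sprintf("kfold_%s.tsv", tg))
      wt(sens[[tg]], sprintf("sensitivity_%s.tsv", tg))
    }
    score_tab <- do.call(rbind, lapply(outputs, function(tg) {
      e <- evaluations[[tg]]
      data.frame(target = tg, n = e$n, error_rate = e$error_rate,
                 logarithmic_loss = e$logarithmic_loss,
                 quadratic_loss = e$quadratic_loss,
                 spherical_payoff = e$spherical_payoff)
    }))
    wt(score_tab, "scores.tsv")
    wt(scen, "scenarios.tsv")
    wt(cbind(statistic = rownames(calib$yield), calib$yield),
       "calibration_yield.tsv")
    wt(cbind(statistic = rownames(calib$runoff), calib$runoff),
       "calibration_runoff.tsv")
    manifest_out <- c(manifest, list(timestamp = format(Sys.time(), tz = "UTC")))
    yaml::write_yaml(manifest_out, file.path(out_dir, "manifest.yaml"))
    summary_lines <- c(
      stamp,
      sprintf("Seasonal cases: %d (seed %d)", nrow(records), config$seed),
      sprintf("Holdout: train %d-%d (%d cases), test %d-%d (%d cases)",
              min(plan$train_years), max(plan$train_years), nrow(splits$train),
              min(plan$test_years), max(plan$test_years), nrow(splits$test)),
      "",
      "Holdout error rates and scoring rules:",
      vapply(outputs, function(tg) {
        e <- evaluations[[tg]]
        sprintf("  %-7s error %6.2f%%  log %.4f  quadratic %.4f  spherical %.4f",
                tg, e$error_rate, e$logarithmic_loss, e$quadratic_loss,
                e$spherical_payoff)
      }, ""))
    writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  }

  stage("done")
  invisible(list(records = records, schemes = schemes, fit = fit,
                 evaluations = evaluations, kfold = kf, sensitivity = sens,
                 scenarios = scen, calibration = calib, manifest = manifest))
}
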