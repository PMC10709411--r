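# End-to-end orchestration: preprocessing, eigenloci, then a grid search
# over the integrative factor mu with network construction, module
# detection, eigengene computation, and survival analysis at each grid
# point; plus patient-level bootstrap stability at a fixed mu.

#' Build a run configuration
#'
#' Collects every tunable of the pipeline with its default. `muGrid` must
#' be sorted, unique, and within `[0, 1]`.
#'
#' @param muGrid integrative-factor grid (default 0 to 1 in steps of 0.1).
#' @param corCutoff feature-election absolute-correlation cutoff.
#' @param offset log-normalization offset.
#' @param maxMissingFrac methylation missingness tolerance per locus.
#' @param maxLoci locus-count threshold for the eigenloci core step.
#' @param rsqCut scale-free fit requirement for the soft power.
#' @param candidatePowers soft powers to scan.
#' @param minModuleSize smallest allowed module.
#' @param mergeCorCutoff module-merge first-PC |correlation| threshold.
#' @param kCandidates number of lasso-selected eigengenes.
#' @param minRecallLow,minRecallHigh recall floors for the risk cutoffs.
#' @param goldStandard clinical gold-standard rule (see
#'   [prepare_survival()]).
#' @param aftDist AFT error distribution.
#' @param normalizeExpression log10-normalize the expression input first?
#' @param seed seed for the oversampling draw (and bootstrap).
#' @return List of class `run_config`.
#' @export
run_config <- function(muGrid = seq(0, 1, by = 0.1), corCutoff = 0.2,
                       offset = 1, maxMissingFrac = 0.5, maxLoci = 6,
                       rsqCut = 0.75, candidatePowers = 1:20,
                       minModuleSize = 5, mergeCorCutoff = 0.85,
                       kCandidates = 3, minRecallLow = 0.2,
                       minRecallHigh = 0.05, goldStandard = "precomputed",
                       aftDist = "weibull", normalizeExpression = TRUE,
                       seed = 1) {
  muGrid <- as.numeric(muGrid)
  if (any(muGrid < 0 | muGrid > 1) || is.unsorted(muGrid, strictly = TRUE)) {
    stop("`muGrid` must be strictly increasing within [0, 1]")
  }
  structure(list(muGrid = muGrid, corCutoff = corCutoff, offset = offset,
                 maxMissingFrac = maxMissingFrac, maxLoci = maxLoci,
                 rsqCut = rsqCut, candidatePowers = candidatePowers,
                 minModuleSize = minModuleSize,
                 mergeCorCutoff = mergeCorCutoff, kCandidates = kCandidates,
                 minRecallLow = minRecallLow, minRecallHigh = minRecallHigh,
                 goldStandard = goldStandard, aftDist = aftDist,
                 normalizeExpression = normalizeExpression, seed = seed),
            class = "run_config")
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(unclass(config), tf, version = 2L)
  unname(tools::md5sum(tf))
}

# mu-independent stages: normalization, cleaning, survival labels, feature
# election + union, eigenloci, balanced sample multiset.
.preprocess_stage <- function(expr, meth, map, clinical, config) {
  if (isTRUE(config$normalizeExpression)) {
    expr <- normalize_expression(expr, config$offset)
  }
  meth <- clean_methylation(meth, config$maxMissingFrac)
  surv <- prepare_survival(clinical, config$goldStandard)
  election <- elect_features(expr, meth, surv, config$corCutoff)
  election <- compute_union(election, map)
  exprSel <- expr[intersect(rownames(expr), election$selectedGenes), ,
                  drop = FALSE]
  methSel <- meth[intersect(rownames(meth), election$selectedLoci), ,
                  drop = FALSE]
  if (nrow(exprSel) == 0L) stop("feature election removed every gene")
  eigenloci <- compute_eigenloci(methSel, map, config$maxLoci)
  shared <- intersect(colnames(exprSel), colnames(eigenloci$values))
  balSurv <- surv[surv$ID %in% shared, , drop = FALSE]
  balanced <- balance_by_oversampling(balSurv$ID, balSurv$goldRisk,
                                      config$seed)
  list(expr = exprSel, eigenloci = eigenloci, surv = surv,
       election = election, balanced = balanced)
}

# One mu grid point: network -> soft power -> modules -> eigengenes ->
# survival analysis. Raises on stage failure; the caller records NA.
.run_single_mu <- function(expr, eigenloci, surv, balanced, mu, config) {
  net <- integrated_adjacency(expr, eigenloci, mu)
  net$softPower <- pick_soft_power(net, config$rsqCut, config$candidatePowers)
  modules <- detect_modules(net, config$minModuleSize,
                            mergeData = expr,
                            mergeCorCutoff = config$mergeCorCutoff)
  eg <- compute_module_eigengenes(expr, eigenloci, modules, balanced, mu)
  stacked <- stack_eigengenes(eg)
  candidates <- lasso_select_eigengenes(stacked, surv, config$kCandidates)
  model <- select_best_subset(candidates, stacked, surv,
                              config$minRecallLow, config$minRecallHigh,
                              config$aftDist)
  list(mu = mu, softPower = as.integer(net$softPower), modules = modules,
       nModules = sum(names(modules$sizes) != "0"), eigengenes = eg,
       candidates = candidates, model = model, logRankP = model$logRankP)
}

#' Run the full integration pipeline over a mu grid
#'
#' Preprocesses once (normalization, cleaning, clinical labeling, feature
#' election with union expansion, eigenloci, risk-balanced oversampling),
#' then at every `mu` in the grid builds the integrated network, picks the
#' soft power, detects modules, computes eigengenes, and runs the survival
#' analysis. The best `mu` minimizes the low-vs-high log-rank p-value
#' (ties toward smaller `mu`). Deterministic given the config seed.
#'
#' @param expr gene x sample expression matrix (raw unless
#'   `config$normalizeExpression` is `FALSE`).
#' @param meth locus x sample beta matrix (missing entries allowed).
#' @param map locus-gene map data.frame.
#' @param clinical clinical table (see [prepare_survival()]).
#' @param config a [run_config()].
#' @param outDir optional directory; when given, results are written there
#'   via [write_run_result()].
#' @param force overwrite an `outDir` holding results from a different
#'   configuration.
#' @return List of class `run_result`: `perMu` (data.frame of per-grid-point
#'   summaries), `bestMu`, `best` (full record at the best grid point),
#'   `survivalTable`, `config`, `configHash`.
#' @export
run_pipeline <- function(expr, meth, map, clinical, config = run_config(),
                         outDir = NULL, force = FALSE) {
  t0 <- Sys.time()
  pre <- .preprocess_stage(expr, meth, map, clinical, config)
  records <- vector("list", length(config$muGrid))
  for (i in seq_along(config$muGrid)) {
    mu <- config$muGrid[i]
    rec <- tryCatch(
      .run_single_mu(pre$expr, pre$eigenloci, pre$surv, pre$balanced, mu,
                     config),
      error = function(e) {
        omix_log("mu = ", mu, " failed: ", conditionMessage(e))
        NULL
      })
    records[i] <- list(rec)  # [[<- would drop NULL records
    omix_log("mu = ", format(mu), ": ",
             if (is.null(rec)) "failed" else
               paste0(rec$nModules, " modules, p = ",
                      signif(rec$logRankP, 3)))
  }
  ps <- vapply(records, function(r) if (is.null(r)) NA_real_ else r$logRankP,
               numeric(1))
  if (all(is.na(ps))) stop("every mu grid point failed")
  bestIdx <- which(ps == min(ps, na.rm = TRUE))[1L]
  best <- records[[bestIdx]]
  perMu <- data.frame(
    mu = config$muGrid,
    nModules = vapply(records, function(r) if (is.null(r)) NA_integer_ else
      as.integer(r$nModules), integer(1)),
    softPower = vapply(records, function(r) if (is.null(r)) NA_integer_ else
      r$softPower, integer(1)),
    candidates = vapply(records, function(r) if (is.null(r)) NA_character_ else
      paste(r$candidates, collapse = "+"), character(1)),
    chosenSubset = vapply(records, function(r) if (is.null(r)) NA_character_ else
      paste(r$model$chosenSubset, collapse = "+"), character(1)),
    logRankP = ps,
    nLow = vapply(records, function(r) if (is.null(r)) NA_integer_ else
      as.integer(r$model$groupSizes[["low"]]), integer(1)),
    nIntermediate = vapply(records, function(r) if (is.null(r)) NA_integer_ else
      as.integer(r$model$groupSizes[["intermediate"]]), integer(1)),
    nHigh = vapply(records, function(r) if (is.null(r)) NA_integer_ else
      as.integer(r$model$groupSizes[["high"]]), integer(1)),
    stringsAsFactors = FALSE)
  result <- structure(
    list(perMu = perMu, bestMu = config$muGrid[bestIdx], best = best,
         survivalTable = pre$surv, election = pre$election, config = config,
         configHash = config_hash(config)),
    class = "run_result")
  omix_log("best mu = ", result$bestMu, " (p = ", signif(ps[bestIdx], 3),
           "); total ", round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1),
           " s")
  if (!is.null(outDir)) write_run_result(result, outDir, force = force)
  result
}

#' Kaplan-Meier curve coordinates per risk group
#'
#' @param time,event survival outcomes.
#' @param group risk-group labels.
#' @return data.frame with `group`, `time`, `nRisk`, `nEvent`, `survival`.
#' @export
km_curve_data <- function(time, event, group) {
  out <- lapply(sort(unique(as.character(group))), function(g) {
    sel <- group == g
    sf <- survival::survfit(survival::Surv(time[sel], event[sel]) ~ 1)
    data.frame(group = g, time = sf$time, nRisk = sf$n.risk,
               nEvent = sf$n.event, survival = sf$surv,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write pipeline results to a directory
#'
#' Emits `result.json` (per-mu summaries, best model, config, config hash),
#' `modules.tsv`, `eigengenes.tsv`, `stratification.tsv`, and
#' `km_curves.tsv` for the best grid point. Refuses to overwrite a
#' directory holding results from a different configuration unless
#' `force = TRUE`. Outputs contain no timestamps, so reruns with the same
#' config and seed are byte-identical.
#'
#' @param result a `run_result`.
#' @param outDir output directory (created if needed).
#' @param force overwrite results from a different config hash.
#' @return `outDir`, invisibly.
#' @export
write_run_result <- function(result, outDir, force = FALSE) {
  jsonPath <- file.path(outDir, "result.json")
  if (file.exists(jsonPath) && !force) {
    prev <- jsonlite::read_json(jsonPath)
    if (!identical(prev$configHash, result$configHash)) {
      stop(outDir, " holds results from a different configuration; ",
           "use force = TRUE to overwrite")
    }
  }
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  best <- result$best
  payload <- list(
    bestMu = result$bestMu,
    perMu = result$perMu,
    best = list(mu = best$mu, softPower = best$softPower,
                nModules = best$nModules, candidates = best$candidates,
                chosenSubset = best$model$chosenSubset,
                aftCoefficients = as.list(best$model$aft$coefficients),
                aftScale = best$model$aft$scale,
                lowCutoff = best$model$lowCutoff,
                highCutoff = best$model$highCutoff,
                logRankP = best$model$logRankP,
                groupSizes = as.list(best$model$groupSizes)),
    config = unclass(result$config),
    configHash = result$configHash)
  jsonlite::write_json(payload, jsonPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  mod <- best$modules$moduleOf
  utils::write.table(data.frame(gene = names(mod), module = as.integer(mod)),
                     file.path(outDir, "modules.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_matrix(stack_eigengenes(best$eigengenes),
               file.path(outDir, "eigengenes.tsv"))
  groupOf <- best$model$groupOf
  lp <- best$model$aft$linearPredictor
  utils::write.table(
    data.frame(ID = names(groupOf), group = unname(groupOf),
               predictedLogTime = sprintf("%.17g", unname(lp[names(groupOf)]))),
    file.path(outDir, "stratification.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  surv <- result$survivalTable
  idx <- match(names(groupOf), surv$ID)
  km <- km_curve_data(surv$time[idx], surv$event[idx], unname(groupOf))
  km$survival <- sprintf("%.17g", km$survival)
  utils::write.table(km, file.path(outDir, "km_curves.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(outDir)
}

#' Patient-level bootstrap stability of the survival result
#'
#' Resamples patients with replacement (same n), reruns the mu-dependent
#' stages (network, modules, eigengenes, survival) at a fixed `mu`, and
#' summarizes the per-iteration low-vs-high log-rank p-values. The gene and
#' locus universe, preprocessing, and eigenloci are shared across
#' iterations. Aborts when more than 20% of iterations fail.
#'
#' @param expr,meth,map,clinical cohort inputs as in [run_pipeline()].
#' @param mu the integrative factor to hold fixed (typically `bestMu`).
#' @param nIterations number of bootstrap iterations.
#' @param config a [run_config()].
#' @param seed master seed for the resampling.
#' @return List of class `bootstrap_result` with `meanP`, `varP`,
#'   `pValues`, `nIterations`, `nFailed`, `mu`, `seed`.
#' @export
bootstrap_stability <- function(expr, meth, map, clinical, mu,
                                nIterations = 100, config = run_config(),
                                seed = 1) {
  pre <- .preprocess_stage(expr, meth, map, clinical, config)
  el <- pre$eigenloci$values
  shared <- intersect(colnames(pre$expr), colnames(el))
  pool <- pre$surv$ID[pre$surv$ID %in% shared]
  iterSeeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                          nIterations))
  ps <- rep(NA_real_, nIterations)
  for (it in seq_len(nIterations)) {
    ps[it] <- tryCatch({
      ids <- with_seed(iterSeeds[it], sample(pool, length(pool),
                                             replace = TRUE))
      newIDs <- sprintf("%s.b%03d", ids, seq_along(ids))
      exprB <- pre$expr[, ids, drop = FALSE]
      colnames(exprB) <- newIDs
      elB <- el[, ids, drop = FALSE]
      colnames(elB) <- newIDs
      survB <- pre$surv[match(ids, pre$surv$ID), , drop = FALSE]
      survB$ID <- newIDs
      balancedB <- balance_by_oversampling(survB$ID, survB$goldRisk,
                                           iterSeeds[it])
      rec <- .run_single_mu(exprB, elB, survB, balancedB, mu, config)
      rec$logRankP
    }, error = function(e) NA_real_)
  }
  nFailed <- sum(is.na(ps))
  if (nFailed > 0.2 * nIterations) {
    stop("bootstrap aborted: ", nFailed, " of ", nIterations,
         " iterations failed")
  }
  structure(list(meanP = mean(ps, na.rm = TRUE),
                 varP = stats::var(ps[!is.na(ps)]),
                 pValues = ps, nIterations = nIterations, nFailed = nFailed,
                 mu = mu, seed = seed),
            class = "bootstrap_result")
}
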