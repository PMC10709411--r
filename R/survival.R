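# Survival modeling on eigengenes: lasso-Cox screening of the three most
# prognostic eigengenes, Weibull accelerated failure time (AFT) fits over
# every non-empty subset, recall-constrained precision-maximizing cutoffs on
# the AFT predictions, three-group stratification, and the low-vs-high
# log-rank test.

# Align an eigengene feature matrix (features x samples) with a survival
# table; returns the design (patients x features) and the matching rows.
.align_design <- function(eigengenes, survival) {
  ids <- intersect(colnames(eigengenes), survival$ID)
  s <- survival[match(ids, survival$ID), , drop = FALSE]
  keep <- !is.na(s$time) & !is.na(s$event)
  s <- s[keep, , drop = FALSE]
  if (nrow(s) == 0L) stop("no patients with both eigengenes and survival data")
  list(x = t(eigengenes[, s$ID, drop = FALSE]), surv = s)
}

#' Select the most prognostic eigengenes by lasso Cox regression
#'
#' Fits an L1-penalized Cox path over a decreasing penalty grid and returns
#' the first `k` distinct eigengenes to enter the path (entry-order ties
#' broken by the larger absolute coefficient at entry, then feature order).
#' If fewer than `k` ever enter, those that do are returned.
#'
#' @param eigengenes feature x sample matrix (all variants stacked, see
#'   [stack_eigengenes()]).
#' @param survival data.frame with `ID`, `time`, `event`.
#' @param k number of eigengenes to keep (default 3).
#' @return Character vector of up to `k` eigengene IDs.
#' @export
lasso_select_eigengenes <- function(eigengenes, survival, k = 3) {
  al <- .align_design(eigengenes, survival)
  if (sum(al$surv$event) == 0L) stop("no events in the survival data")
  if (k >= nrow(eigengenes)) return(rownames(eigengenes))
  y <- survival::Surv(al$surv$time, al$surv$event)
  fit <- glmnet::glmnet(al$x, y, family = "cox", alpha = 1, standardize = TRUE,
                        nlambda = 100L)
  beta <- as.matrix(fit$beta)  # features x lambdas, lambda decreasing
  entered <- apply(beta != 0, 1L, function(z) if (any(z)) which(z)[1L] else NA_integer_)
  entryCoef <- vapply(seq_len(nrow(beta)), function(i) {
    if (is.na(entered[i])) 0 else abs(beta[i, entered[i]])
  }, numeric(1))
  ord <- order(entered, -entryCoef, seq_along(entered), na.last = NA)
  sel <- rownames(beta)[ord]
  if (length(sel) < k) {
    omix_log("only ", length(sel), " eigengenes entered the lasso path")
  }
  utils::head(sel, k)
}

#' Fit a Weibull accelerated failure time model
#'
#' `log T = b0 + sum_j b_j x_j + sigma * eps` with extreme-value error.
#' Zero-variance covariates are dropped before fitting and reported with
#' coefficient 0. The linear predictor is the predicted log survival time.
#'
#' @param design patients x eigengene matrix (rownames = patient IDs).
#' @param survival data.frame with `ID`, `time` (> 0), `event`; rows are
#'   matched to `design` by ID.
#' @param dist AFT error distribution passed to [survival::survreg()]
#'   (default `"weibull"`).
#' @return List of class `aft_fit` with `coefficients`, `scale`,
#'   `linearPredictor` (named by patient), and the underlying `fit`.
#' @export
fit_aft <- function(design, survival, dist = "weibull") {
  if (is.null(dim(design))) stop("`design` must be a matrix")
  s <- survival[match(rownames(design), survival$ID), , drop = FALSE]
  if (anyNA(s$time) || anyNA(s$event)) stop("design rows lack survival data")
  if (nrow(design) < 10L) stop("need at least 10 patients for the AFT fit")
  if (sum(s$event) < 1L) stop("need at least 1 event for the AFT fit")
  if (any(s$time <= 0)) stop("AFT models need strictly positive times")
  sds <- apply(design, 2L, stats::sd)
  active <- colnames(design)[sds > 0]
  df <- data.frame(time = s$time, event = s$event,
                   design[, active, drop = FALSE], check.names = FALSE)
  form <- if (length(active) > 0L) {
    stats::reformulate(sprintf("`%s`", active),
                       response = quote(survival::Surv(time, event)))
  } else {
    survival::Surv(time, event) ~ 1
  }
  fit <- tryCatch(
    survival::survreg(form, data = df, dist = dist),
    error = function(e) stop("AFT fit failed: ", conditionMessage(e)),
    warning = function(w) {
      suppressWarnings(survival::survreg(form, data = df, dist = dist))
    })
  coefs <- stats::setNames(rep(0, ncol(design) + 1L), c("(Intercept)", colnames(design)))
  got <- stats::coef(fit)
  names(got) <- sub("^`(.*)`$", "\\1", names(got))
  coefs[names(got)] <- got
  lp <- stats::setNames(drop(cbind(1, design) %*% coefs), rownames(design))
  structure(list(coefficients = coefs, scale = fit$scale,
                 linearPredictor = lp, dist = dist, fit = fit),
            class = "aft_fit")
}

#' Recall-constrained precision-maximizing cutoff on AFT predictions
#'
#' Scans the midpoints of sorted unique predictions. For `direction =
#' "high"` the positive class is the deceased and the implied group is
#' `prediction < cutoff`; for `"low"` the positive class is the alive
#' (censored) and the group is `prediction > cutoff`. Among cutoffs whose
#' group reaches `minRecall` for the positive class, the one maximizing
#' precision is returned; precision ties break toward the smaller group.
#'
#' @param predictions per-patient predicted log survival times.
#' @param outcomes per-patient vital status (1 = deceased, 0 = alive).
#' @param direction `"high"` or `"low"` risk group.
#' @param minRecall minimum recall for the positive class (defaults in the
#'   pipeline: 0.2 for low, 0.05 for high).
#' @return The chosen cutoff (scalar), with attributes `precision`,
#'   `recall`, `groupSize`.
#' @export
find_alive_cutoff <- function(predictions, outcomes,
                              direction = c("high", "low"), minRecall) {
  direction <- match.arg(direction)
  if (length(predictions) != length(outcomes)) stop("length mismatch")
  if (any(!is.finite(predictions))) stop("predictions must be finite")
  if (!all(outcomes %in% c(0, 1))) stop("outcomes must be 0/1")
  positive <- if (direction == "high") outcomes == 1 else outcomes == 0
  if (sum(positive) == 0L) stop("no positive-class patients for direction ", direction)
  u <- sort(unique(predictions))
  if (length(u) < 2L) stop("predictions are constant; no cutoff exists")
  cands <- (u[-1L] + u[-length(u)]) / 2
  best <- NULL
  for (cut in cands) {
    sel <- if (direction == "high") predictions < cut else predictions > cut
    n <- sum(sel)
    if (n == 0L) next
    tp <- sum(sel & positive)
    recall <- tp / sum(positive)
    if (recall < minRecall) next
    precision <- tp / n
    if (is.null(best) || precision > best$precision ||
        (precision == best$precision && n < best$n)) {
      best <- list(cut = cut, precision = precision, recall = recall, n = n)
    }
  }
  if (is.null(best)) {
    stop("no cutoff reaches recall ", minRecall, " for the ", direction,
         "-risk group; lower `minRecall`")
  }
  structure(best$cut, precision = best$precision, recall = best$recall,
            groupSize = best$n)
}

#' Stratify patients by AFT-predicted survival
#'
#' Predicted time below `highCutoff` is high risk, above `lowCutoff` low
#' risk, otherwise intermediate. Requires `highCutoff <= lowCutoff`.
#'
#' @param predictions named per-patient predicted log survival times.
#' @param lowCutoff,highCutoff cutoffs on the prediction scale.
#' @return Named character vector in `{low, intermediate, high}`.
#' @export
stratify_risk <- function(predictions, lowCutoff, highCutoff) {
  if (lowCutoff < highCutoff) {
    stop("overlapping cutoffs: lowCutoff must be >= highCutoff")
  }
  out <- ifelse(predictions < highCutoff, "high",
                ifelse(predictions > lowCutoff, "low", "intermediate"))
  stats::setNames(out, names(predictions))
}

#' Two-group log-rank test p-value
#'
#' Standard log-rank chi-square with 1 degree of freedom between the low-
#' and high-risk groups.
#'
#' @param time,event survival outcome vectors.
#' @param group two-level grouping vector (e.g. `"low"` / `"high"`).
#' @return P-value in `(0, 1]`.
#' @export
logrank_pvalue <- function(time, event, group) {
  group <- as.factor(as.character(group))
  if (nlevels(group) != 2L || any(table(group) == 0L)) {
    stop("need exactly two non-empty groups")
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  unname(stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE))
}

# All non-empty subsets of candidate IDs ordered by size then
# lexicographically; determines the subset-selection tie-break.
.subsets_of <- function(ids) {
  ids <- sort(ids)
  out <- list()
  for (size in seq_along(ids)) {
    cmb <- utils::combn(ids, size, simplify = FALSE)
    out <- c(out, cmb[order(vapply(cmb, paste, character(1), collapse = "|"))])
  }
  out
}

#' Choose the best eigengene subset for risk stratification
#'
#' For each non-empty subset of the lasso candidates: fit the AFT model,
#' derive the high- and low-risk cutoffs with [find_alive_cutoff()],
#' stratify, and compute the low-vs-high log-rank p-value. Returns the
#' subset with the smallest p-value (ties toward fewer eigengenes, then
#' lexicographic order). Subsets whose cutoff search fails or whose cutoffs
#' overlap are skipped.
#'
#' @param candidates eigengene IDs from [lasso_select_eigengenes()].
#' @param eigengenes stacked feature x sample matrix.
#' @param survival data.frame with `ID`, `time`, `event`.
#' @param minRecallLow,minRecallHigh recall floors for the two cutoffs.
#' @param dist AFT error distribution.
#' @return List of class `risk_model`: `candidates`, `chosenSubset`, `aft`,
#'   `lowCutoff`, `highCutoff`, `minRecallLow`, `minRecallHigh`, `groupOf`,
#'   `logRankP`, `groupSizes`, and `perSubset` (subset, p) bookkeeping.
#' @export
select_best_subset <- function(candidates, eigengenes, survival,
                               minRecallLow = 0.2, minRecallHigh = 0.05,
                               dist = "weibull") {
  al <- .align_design(eigengenes[candidates, , drop = FALSE], survival)
  best <- NULL
  perSubset <- list()
  for (subset in .subsets_of(candidates)) {
    res <- tryCatch({
      aft <- fit_aft(al$x[, subset, drop = FALSE], al$surv, dist = dist)
      lp <- aft$linearPredictor
      highCut <- find_alive_cutoff(lp, al$surv$event, "high", minRecallHigh)
      lowCut <- find_alive_cutoff(lp, al$surv$event, "low", minRecallLow)
      groupOf <- stratify_risk(lp, as.numeric(lowCut), as.numeric(highCut))
      two <- groupOf %in% c("low", "high")
      p <- logrank_pvalue(al$surv$time[two], al$surv$event[two], groupOf[two])
      list(aft = aft, lowCutoff = as.numeric(lowCut),
           highCutoff = as.numeric(highCut), groupOf = groupOf, p = p)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      perSubset[[paste(subset, collapse = "+")]] <- NA_real_
      next
    }
    perSubset[[paste(subset, collapse = "+")]] <- res$p
    if (is.null(best) || res$p < best$p) {
      best <- c(res, list(subset = subset))
    }
  }
  if (is.null(best)) {
    stop("no eigengene subset admits both cutoffs; lower the recall floors")
  }
  sizes <- table(factor(best$groupOf, levels = c("low", "intermediate", "high")))
  structure(list(candidates = candidates, chosenSubset = best$subset,
                 aft = best$aft, lowCutoff = best$lowCutoff,
                 highCutoff = best$highCutoff, minRecallLow = minRecallLow,
                 minRecallHigh = minRecallHigh, groupOf = best$groupOf,
                 logRankP = best$p, groupSizes = sizes,
                 perSubset = unlist(perSubset)),
            class = "risk_model")
}
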