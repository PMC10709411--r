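# Module eigengenes: each module is summarized into one expression feature
# (Ee), one methylation feature (Em), and their mu-combination
# Eem = (1 - mu) Ee + mu Em. PCA weights are learned on a risk-balanced
# (oversampled) low/high subset and applied to every sample, so
# intermediate-risk patients get eigengene values without influencing the
# weights.

#' Balance low- and high-risk samples by oversampling
#'
#' Excludes intermediate-risk (and unlabeled) samples, then duplicates the
#' minority class — whole-class replication plus a seeded draw of the
#' remainder without replacement — until the two classes have equal counts.
#'
#' @param sampleIDs character vector of sample IDs.
#' @param goldRisk parallel vector of labels in
#'   `{low, intermediate, high, NA}`.
#' @param seed integer seed making the draw reproducible.
#' @return Character multiset of sample IDs (each ID may repeat).
#' @export
balance_by_oversampling <- function(sampleIDs, goldRisk, seed = 1) {
  stopifnot(length(sampleIDs) == length(goldRisk))
  low <- sort(sampleIDs[!is.na(goldRisk) & goldRisk == "low"])
  high <- sort(sampleIDs[!is.na(goldRisk) & goldRisk == "high"])
  if (length(low) == 0L || length(high) == 0L) {
    stop("need at least one low- and one high-risk sample to balance; ",
         "use unbalanced PCA instead")
  }
  minority <- if (length(low) <= length(high)) low else high
  majority <- if (length(low) <= length(high)) high else low
  reps <- length(majority) %/% length(minority)
  rem <- length(majority) - reps * length(minority)
  extra <- if (rem > 0L) {
    with_seed(seed, sample(minority, rem, replace = FALSE))
  } else {
    character(0)
  }
  c(majority, rep(minority, reps), extra)
}

#' Combine expression and methylation eigengenes
#'
#' Elementwise `Eem = (1 - mu) * Ee + mu * Em` over matched module x sample
#' grids.
#'
#' @param Ee,Em module x sample matrices with identical dimnames (up to the
#'   `e`/`m` row suffix).
#' @param mu integrative factor in `[0, 1]`.
#' @return Module x sample matrix.
#' @export
combine_eigengenes <- function(Ee, Em, mu) {
  if (!identical(dim(Ee), dim(Em)) || !identical(colnames(Ee), colnames(Em))) {
    stop("`Ee` and `Em` grids do not match")
  }
  if (!is.numeric(mu) || length(mu) != 1L || mu < 0 || mu > 1) {
    stop("`mu` must be a single value in [0, 1]")
  }
  (1 - mu) * Ee + mu * Em
}

# PCA weights on the balanced columns of a standardized matrix, then the
# weighted average over all columns. Standardization statistics come from
# the balanced multiset.
.module_pca <- function(m, members, balancedIDs) {
  rows <- intersect(members, rownames(m))
  if (length(rows) == 0L) return(NULL)
  B <- m[rows, balancedIDs, drop = FALSE]
  mu <- rowMeans(B)
  sds <- apply(B, 1L, stats::sd)
  keep <- sds > 0
  if (!any(keep)) return(NULL)
  if (any(!keep)) {
    omix_log("dropped ", sum(!keep), " constant genes from a module PCA")
  }
  rows <- rows[keep]
  Zall <- (m[rows, , drop = FALSE] - mu[keep]) / sds[keep]
  pd <- principal_direction(Zall[, balancedIDs, drop = FALSE])
  list(weights = pd$weights, values = drop(crossprod(pd$weights, Zall)))
}

#' Compute module eigengenes from expression and gene-level methylation
#'
#' Per non-zero module: genes are standardized (statistics from the balanced
#' samples), PCA weights are learned on the balanced columns, and the
#' weighted average is evaluated for all samples, giving `Ee` from
#' expression, `Em` from eigenloci, and `Eem` as their mu-combination.
#' Module 0 (unassigned outliers) gets no eigengene. A module with no gene
#' in the methylation data gets an all-zero `Em` row (logged), so `Eem`
#' stays well defined.
#'
#' PCA signs are arbitrary; `Ee` is oriented toward the module's mean
#' standardized expression profile, and `Em` is then oriented to correlate
#' non-negatively with `Ee`. Without the second step, widespread
#' methylation-expression anticorrelation would make the sign of `Em`
#' relative to `Ee` a coin flip, and the mu-combination could cancel the
#' two signals instead of blending them.
#'
#' @param expr normalized gene x sample expression matrix.
#' @param eigenloci gene x sample methylation matrix or
#'   [compute_eigenloci()] result.
#' @param modules a `module_assignment`.
#' @param balancedIDs sample multiset from [balance_by_oversampling()];
#'   must be drawn from the shared samples.
#' @param mu integrative factor in `[0, 1]`.
#' @return List of class `eigengene_set` with `Ee`, `Em`, `Eem` (module x
#'   sample, rownames `<module><e|m|em>`), `alphaE`, `alphaM` (per-module
#'   gene weights), `mu`, `balancedIDs`.
#' @export
compute_module_eigengenes <- function(expr, eigenloci, modules, balancedIDs,
                                      mu) {
  el <- eigenloci_values(eigenloci)
  samples <- intersect(colnames(expr), colnames(el))
  if (length(samples) < 3L) stop("need >= 3 samples shared by both data types")
  if (!all(balancedIDs %in% samples)) {
    stop("balanced sample IDs must be present in both data types")
  }
  expr <- expr[, samples, drop = FALSE]
  el <- el[, samples, drop = FALSE]
  moduleOf <- modules$moduleOf
  mods <- sort(unique(moduleOf[moduleOf != 0L]))
  if (length(mods) == 0L) stop("no non-zero modules to summarize")

  Ee <- Em <- matrix(NA_real_, length(mods), length(samples),
                     dimnames = list(mods, samples))
  alphaE <- alphaM <- stats::setNames(vector("list", length(mods)),
                                      as.character(mods))
  dropE <- integer(0)
  for (i in seq_along(mods)) {
    members <- names(moduleOf)[moduleOf == mods[i]]
    pe <- .module_pca(expr, members, balancedIDs)
    if (is.null(pe)) {
      dropE <- c(dropE, i)
      next
    }
    Ee[i, ] <- pe$values
    alphaE[[i]] <- pe$weights
    pm <- .module_pca(el, members, balancedIDs)
    if (is.null(pm)) {
      omix_log("module ", mods[i], " has no usable methylation; Em row is 0")
      Em[i, ] <- 0
    } else {
      flip <- cor0(pm$values, pe$values) < 0
      Em[i, ] <- if (flip) -pm$values else pm$values
      alphaM[[i]] <- if (flip) -pm$weights else pm$weights
    }
  }
  if (length(dropE) > 0L) {
    omix_log("omitted ", length(dropE), " modules with no usable expression")
    keep <- setdiff(seq_along(mods), dropE)
    Ee <- Ee[keep, , drop = FALSE]
    Em <- Em[keep, , drop = FALSE]
    alphaE <- alphaE[keep]
    alphaM <- alphaM[keep]
    mods <- mods[keep]
  }
  Eem <- combine_eigengenes(Ee, Em, mu)
  rownames(Ee) <- paste0(mods, "e")
  rownames(Em) <- paste0(mods, "m")
  rownames(Eem) <- paste0(mods, "em")
  structure(list(Ee = Ee, Em = Em, Eem = Eem, alphaE = alphaE,
                 alphaM = alphaM, mu = mu, balancedIDs = balancedIDs),
            class = "eigengene_set")
}

#' Stack the three eigengene variants into one feature matrix
#'
#' @param eg an `eigengene_set`.
#' @return Matrix with rows `<module>e`, `<module>m`, `<module>em`.
#' @export
stack_eigengenes <- function(eg) {
  rbind(eg$Ee, eg$Em, eg$Eem)
}
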