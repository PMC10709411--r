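# The integrated gene network: edge weights blend absolute expression
# correlation and absolute gene-level methylation correlation through the
# integrative factor mu, W(i,j) = (1 - mu)|corE(i,j)| + mu|corM(i,j)|.
# Soft-thresholding and topological-overlap module detection follow the
# weighted co-expression network methodology.

# |cor| block over a feature matrix, with undefined correlations set to 0
# and pairs sharing < minShared samples zeroed out.
.abs_cor <- function(m, minShared = 3L) {
  if (ncol(m) < minShared) return(matrix(0, nrow(m), nrow(m),
                                         dimnames = list(rownames(m), rownames(m))))
  ac <- abs(cor0(t(m), t(m)))
  if (anyNA(m)) {
    shared <- crossprod(!is.na(t(m)))
    ac[shared < minShared] <- 0
  }
  pmin(ac, 1)
}

#' Build the mu-integrated gene similarity network
#'
#' Every gene present in either data type becomes a node. The edge weight is
#' `(1 - mu) * |corE| + mu * |corM|`, each correlation computed over all
#' samples carrying that data type; a gene missing one data type contributes
#' 0 for the missing term. The diagonal is set to 0.
#'
#' @param expr normalized gene x sample expression matrix.
#' @param eigenloci gene x sample methylation matrix, or the result of
#'   [compute_eigenloci()].
#' @param mu integrative factor in `[0, 1]`; 0 = expression only,
#'   1 = methylation only.
#' @return List of class `integrated_network` with `W` (symmetric gene x
#'   gene matrix in `[0, 1]`), `mu`, `softPower` (`NA` until chosen),
#'   `genes`.
#' @export
integrated_adjacency <- function(expr, eigenloci, mu) {
  if (!is.numeric(mu) || length(mu) != 1L || mu < 0 || mu > 1) {
    stop("`mu` must be a single value in [0, 1]")
  }
  el <- eigenloci_values(eigenloci)
  assert_matrix(expr, "`expr`")
  assert_matrix(el, "`eigenloci`")
  genes <- sort(union(rownames(expr), rownames(el)))
  W <- matrix(0, length(genes), length(genes), dimnames = list(genes, genes))
  gE <- intersect(genes, rownames(expr))
  gM <- intersect(genes, rownames(el))
  if (length(setdiff(genes, gE)) > 0L || length(setdiff(genes, gM)) > 0L) {
    omix_log(length(setdiff(genes, gM)), " genes lack methylation and ",
             length(setdiff(genes, gE)), " lack expression; ",
             "their missing similarity term is 0")
  }
  if (mu < 1 && length(gE) > 0L) {
    W[gE, gE] <- W[gE, gE] + (1 - mu) * .abs_cor(expr[gE, , drop = FALSE])
  }
  if (mu > 0 && length(gM) > 0L) {
    W[gM, gM] <- W[gM, gM] + mu * .abs_cor(el[gM, , drop = FALSE])
  }
  diag(W) <- 0
  W <- (W + t(W)) / 2  # guard against asymmetric rounding
  structure(list(W = W, mu = mu, softPower = NA_integer_, genes = genes),
            class = "integrated_network")
}

# Signed scale-free topology fit for a connectivity vector: bin log10(k)
# into ~10 equal-occupancy bins, regress log10(frequency) on log10(mean k),
# return r-squared signed by the negated slope.
scale_free_fit <- function(k) {
  k <- k[k > 0]
  if (length(unique(k)) < 3L) return(NA_real_)
  breaks <- unique(stats::quantile(k, probs = seq(0, 1, length.out = 11L)))
  if (length(breaks) < 4L) return(NA_real_)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  freq <- tabulate(bin, nbins = nlevels(bin)) / length(k)
  meanK <- tapply(k, bin, mean)
  ok <- freq > 0 & !is.na(meanK)
  if (sum(ok) < 3L) return(NA_real_)
  fit <- stats::lm(log10(freq[ok]) ~ log10(meanK[ok]))
  # summary() warns on near-perfect fits, which are routine on 10 bins
  r2 <- suppressWarnings(summary(fit)$r.squared)
  slope <- stats::coef(fit)[2L]
  unname(r2 * sign(-slope))
}

#' Choose the soft-thresholding power
#'
#' For each candidate power, raises the similarity matrix elementwise,
#' computes node connectivity, and measures how well the degree distribution
#' follows a power law (signed scale-free fit index). Returns the smallest
#' power whose fit reaches `rsqCut`; if none does, the power with the best
#' fit (logged as non-converged).
#'
#' @param net an `integrated_network`.
#' @param rsqCut required scale-free fit index (default 0.75).
#' @param candidatePowers powers to scan (default 1..20).
#' @return Integer power. The per-power fits are attached as attribute
#'   `fits`.
#' @export
pick_soft_power <- function(net, rsqCut = 0.75, candidatePowers = 1:20) {
  W <- net$W
  fits <- vapply(candidatePowers, function(beta) {
    A <- W^beta
    diag(A) <- 0
    scale_free_fit(rowSums(A))
  }, numeric(1))
  names(fits) <- candidatePowers
  ok <- which(!is.na(fits) & fits >= rsqCut)
  power <- if (length(ok) > 0L) {
    candidatePowers[ok[1L]]
  } else {
    if (all(is.na(fits))) stop("scale-free fit undefined at every candidate power")
    omix_log("no power reaches fit ", rsqCut, "; using best fit ",
             round(max(fits, na.rm = TRUE), 3))
    candidatePowers[which.max(fits)]
  }
  structure(as.integer(power), fits = fits)
}

#' Topological overlap matrix
#'
#' `TOM(i,j) = (sum_u A(i,u) A(u,j) + A(i,j)) / (min(k_i, k_j) + 1 - A(i,j))`
#' with zero diagonal adjacency; the diagonal of the result is 1.
#'
#' @param A symmetric adjacency matrix in `[0, 1]` with zero diagonal.
#' @return Symmetric matrix in `[0, 1]`.
#' @export
tom_similarity <- function(A) {
  diag(A) <- 0
  k <- rowSums(A)
  L <- A %*% A
  denom <- outer(k, k, pmin) + 1 - A
  TOM <- (L + A) / denom
  diag(TOM) <- 1
  pmin(pmax((TOM + t(TOM)) / 2, 0), 1)
}

# First PC profile per module over standardized rows of `data`; used only
# for merging similar modules.
.module_profiles <- function(data, moduleOf) {
  mods <- sort(unique(moduleOf[moduleOf != 0L]))
  profs <- lapply(mods, function(m) {
    rows <- names(moduleOf)[moduleOf == m]
    rows <- intersect(rows, rownames(data))
    if (length(rows) == 0L) return(rep(NA_real_, ncol(data)))
    Z <- data[rows, , drop = FALSE]
    sds <- apply(Z, 1L, stats::sd)
    Z <- Z[sds > 0, , drop = FALSE]
    if (nrow(Z) == 0L) return(rep(NA_real_, ncol(data)))
    Z <- (Z - rowMeans(Z)) / apply(Z, 1L, stats::sd)
    principal_direction(Z)$scores
  })
  names(profs) <- mods
  profs
}

#' Detect gene modules in the integrated network
#'
#' Raises the similarity to `softPower`, converts to topological overlap,
#' clusters genes by average-linkage hierarchical clustering on `1 - TOM`,
#' and cuts the dendrogram at 99% of its maximum merge height. Clusters
#' smaller than `minModuleSize`, and clusters whose mean within-cluster
#' topological overlap does not exceed `cohesionFactor` times their mean
#' overlap with the rest of the network (unstructured networks otherwise
#' congeal into one spurious giant cluster just below the cut), fall into
#' module 0 (unassigned outliers).
#' When `mergeData` is supplied, modules whose first-PC profiles correlate
#' above `mergeCorCutoff` in absolute value are merged iteratively. Modules
#' are relabeled 1..K by decreasing size (ties broken by the smallest member
#' gene symbol).
#'
#' @param net an `integrated_network`.
#' @param minModuleSize smallest allowed module (default 5).
#' @param softPower adjacency exponent; defaults to `net$softPower`.
#' @param mergeData optional gene x sample matrix for eigengene-based module
#'   merging (typically the normalized expression matrix).
#' @param mergeCorCutoff merge modules with first-PC |correlation| above
#'   this (default 0.85).
#' @param cohesionFactor required ratio of within-module to module-to-rest
#'   mean topological overlap (default 2).
#' @return List of class `module_assignment` with `moduleOf` (named integer
#'   vector, 0 = unassigned) and `sizes`.
#' @export
detect_modules <- function(net, minModuleSize = 5, softPower = net$softPower,
                           mergeData = NULL, mergeCorCutoff = 0.85,
                           cohesionFactor = 2) {
  W <- net$W
  genes <- net$genes
  if (is.na(softPower)) stop("choose `softPower` first (pick_soft_power)")
  if (length(genes) < minModuleSize) {
    warning("fewer genes than minModuleSize; all genes unassigned (module 0)")
    moduleOf <- stats::setNames(rep(0L, length(genes)), genes)
    return(structure(list(moduleOf = moduleOf, sizes = table(moduleOf)),
                     class = "module_assignment"))
  }
  A <- W^softPower
  TOM <- tom_similarity(A)
  tree <- stats::hclust(stats::as.dist(1 - TOM), method = "average")
  cutH <- 0.99 * max(tree$height)
  raw <- if (cutH <= 0) {
    stats::setNames(rep(1L, length(genes)), genes)
  } else {
    stats::cutree(tree, h = cutH)
  }
  moduleOf <- raw
  small <- names(which(table(raw) < minModuleSize))
  moduleOf[raw %in% as.integer(small)] <- 0L

  # confidence filter: a real module coheres well above its background, or
  # is strongly correlated in absolute terms (a near-homogeneous network
  # has no meaningful background to compare against)
  if (length(genes) > 1L) {
    for (m in setdiff(unique(moduleOf), 0L)) {
      inside <- moduleOf == m
      if (sum(!inside) == 0L) break  # single all-gene cluster: heights ~ 0
      block <- TOM[inside, inside]
      within <- mean(block[upper.tri(block)])
      cross <- mean(TOM[inside, !inside])
      wblock <- W[inside, inside]
      strong <- mean(wblock[upper.tri(wblock)]) >= 0.35
      if (within < cohesionFactor * cross && !strong) {
        omix_log("demoted a ", sum(inside), "-gene cluster to module 0 ",
                 "(within/cross overlap ", round(within / cross, 2), ")")
        moduleOf[inside] <- 0L
      }
    }
  }

  if (!is.null(mergeData) && length(unique(moduleOf[moduleOf != 0L])) > 1L) {
    repeat {
      profs <- .module_profiles(mergeData, moduleOf)
      mods <- as.integer(names(profs))
      if (length(mods) < 2L) break
      P <- do.call(cbind, profs)
      C <- abs(cor0(P, P))
      diag(C) <- 0
      if (max(C) <= mergeCorCutoff) break
      idx <- which(C == max(C), arr.ind = TRUE)[1L, ]
      keep <- min(mods[idx]); drop <- max(mods[idx])
      moduleOf[moduleOf == drop] <- keep
      omix_log("merged modules with first-PC |cor| ",
               round(max(C), 3), " > ", mergeCorCutoff)
    }
  }

  # deterministic relabeling: 1..K by decreasing size, ties by first member
  mods <- unique(moduleOf[moduleOf != 0L])
  if (length(mods) > 0L) {
    info <- data.frame(
      mod = mods,
      size = vapply(mods, function(m) sum(moduleOf == m), integer(1)),
      first = vapply(mods, function(m) min(names(moduleOf)[moduleOf == m]),
                     character(1)),
      stringsAsFactors = FALSE)
    info <- info[order(-info$size, info$first), ]
    relabel <- stats::setNames(seq_len(nrow(info)), info$mod)
    moduleOf[moduleOf != 0L] <- relabel[as.character(moduleOf[moduleOf != 0L])]
  }
  moduleOf <- stats::setNames(as.integer(moduleOf), genes)
  structure(list(moduleOf = moduleOf, sizes = table(moduleOf)),
            class = "module_assignment")
}
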