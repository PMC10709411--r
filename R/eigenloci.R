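# Gene-level methylation: summarize each gene's CpG loci into one value per
# sample via the first principal component ("eigenloci"), restricting genes
# with many loci to their most densely co-methylated core first.

#' First principal direction of a feature-by-sample matrix
#'
#' Rows are centered (not scaled) internally; the first left singular vector
#' gives the feature weights and its projection the per-sample scores. The
#' sign is fixed so scores correlate non-negatively with the mean feature
#' profile (falling back to a non-negative weight sum when that correlation
#' is undefined), making outputs reproducible.
#'
#' @param X numeric matrix, features x samples (>= 1 feature, >= 2 samples).
#' @return List with `weights` (unit vector over features) and `scores`
#'   (vector over samples).
#' @export
principal_direction <- function(X) {
  if (!is.matrix(X) || !is.numeric(X)) stop("`X` must be a numeric matrix")
  if (nrow(X) < 1L || ncol(X) < 2L) stop("need >= 1 feature and >= 2 samples")
  if (anyNA(X)) stop("`X` must not contain missing values")
  Xc <- X - rowMeans(X)
  if (max(abs(Xc)) < .Machine$double.eps^0.5) stop("zero variance: all features constant")
  sv <- svd(Xc, nu = 1L, nv = 1L)
  w <- drop(sv$u)
  scores <- drop(crossprod(w, Xc))
  meanProfile <- colMeans(X)
  orient <- suppressWarnings(stats::cor(scores, meanProfile))
  if (is.na(orient) || orient == 0) orient <- sum(w)
  if (orient < 0) {
    w <- -w
    scores <- -scores
  }
  names(w) <- rownames(X)
  names(scores) <- colnames(X)
  list(weights = w, scores = scores)
}

#' Find the densest co-methylated core of a gene's loci
#'
#' Builds a complete graph on the loci weighted by absolute pairwise Pearson
#' correlation, detects communities by weighted fast-greedy modularity, and
#' returns the community with the highest mean pairwise absolute correlation.
#' Singleton communities are ignored unless every community is a singleton,
#' in which case the full locus set is returned. Constant locus rows are
#' removed before graph construction.
#'
#' @param betaSub locus x sample beta matrix for one gene.
#' @return Character vector of locus IDs forming the core.
#' @export
find_core <- function(betaSub) {
  assert_matrix(betaSub, "`betaSub`")
  sds <- apply(betaSub, 1L, stats::sd)
  betaSub <- betaSub[sds > 0, , drop = FALSE]
  if (nrow(betaSub) < 2L) return(rownames(betaSub))
  A <- abs(stats::cor(t(betaSub)))
  diag(A) <- 0
  off <- A[upper.tri(A)]
  # a uniform complete graph has no community structure to exploit
  if (max(off) - min(off) < 1e-12) return(rownames(betaSub))
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  comm <- igraph::membership(igraph::cluster_fast_greedy(g))
  groups <- split(rownames(betaSub), comm)
  meanCor <- vapply(groups, function(loci) {
    if (length(loci) < 2L) return(NA_real_)
    block <- A[loci, loci]
    mean(block[upper.tri(block)])
  }, numeric(1))
  if (all(is.na(meanCor))) {
    omix_log("all communities are singletons; keeping all loci")
    return(rownames(betaSub))
  }
  groups[[which.max(meanCor)]]
}

#' Compute gene-level methylation (eigenloci) for every mapped gene
#'
#' For each gene with at least one locus in `meth`: when the gene has fewer
#' than `maxLoci` loci, the eigenloci is the first principal component of
#' all its loci; otherwise the loci are first reduced to their densest
#' co-methylated core by [find_core()]. Genes with no mapped loci, or whose
#' loci are all constant, are omitted (and counted in the log).
#'
#' @param meth cleaned locus x sample beta matrix (no missing values).
#' @param map locus-gene map (`data.frame` with `locus`, `gene`).
#' @param maxLoci genes with at least this many loci go through the core
#'   step first (default 6).
#' @return List of class `eigenloci` with `values` (gene x sample matrix),
#'   `weights` (per gene, named locus weights of unit norm), and `coreLoci`
#'   (per gene, the locus subset used).
#' @export
compute_eigenloci <- function(meth, map, maxLoci = 6) {
  assert_matrix(meth, "`meth`")
  if (anyNA(meth)) stop("`meth` must be cleaned first (no missing betas)")
  lociByGene <- split(map$locus, map$gene)
  lociByGene <- lapply(lociByGene, intersect, rownames(meth))
  lociByGene <- lociByGene[lengths(lociByGene) > 0L]
  if (length(lociByGene) == 0L) stop("no gene has a mapped locus in `meth`")

  values <- matrix(NA_real_, length(lociByGene), ncol(meth),
                   dimnames = list(names(lociByGene), colnames(meth)))
  weights <- coreLoci <- stats::setNames(vector("list", length(lociByGene)),
                                         names(lociByGene))
  dropped <- character(0)
  for (gene in names(lociByGene)) {
    loci <- lociByGene[[gene]]
    B <- meth[loci, , drop = FALSE]
    core <- if (length(loci) >= maxLoci) find_core(B) else loci
    pd <- tryCatch(principal_direction(meth[core, , drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(pd)) {
      dropped <- c(dropped, gene)
      next
    }
    values[gene, ] <- pd$scores
    weights[[gene]] <- pd$weights
    coreLoci[[gene]] <- core
  }
  if (length(dropped) > 0L) {
    omix_log("omitted ", length(dropped), " genes with constant loci: ",
             paste(utils::head(dropped, 5L), collapse = ", "))
    values <- values[!rownames(values) %in% dropped, , drop = FALSE]
    weights <- weights[!names(weights) %in% dropped]
    coreLoci <- coreLoci[!names(coreLoci) %in% dropped]
  }
  structure(list(values = values, weights = weights, coreLoci = coreLoci),
            class = "eigenloci")
}
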