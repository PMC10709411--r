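# Preprocessing: expression normalization, methylation cleaning, clinical
# gold-standard risk labeling, survival-correlated feature election, and the
# gene/locus union expansion.

#' Log-normalize a raw expression matrix
#'
#' Applies `log10(x + offset)` entrywise. The offset keeps zero counts finite;
#' it defaults to 1 so a zero count maps to 0.
#'
#' @param raw nonnegative gene x sample matrix.
#' @param offset positive real added before the log.
#' @return Matrix of the same shape with attribute `normalized = TRUE`.
#' @export
normalize_expression <- function(raw, offset = 1) {
  assert_matrix(raw, "`raw`")
  if (!is.numeric(offset) || length(offset) != 1L || offset <= 0) {
    stop("`offset` must be a single positive number")
  }
  if (any(raw < 0, na.rm = TRUE)) stop("expression values must be nonnegative")
  out <- log10(raw + offset)
  attr(out, "normalized") <- TRUE
  out
}

#' Clean a beta-value methylation matrix
#'
#' Drops loci whose missing fraction exceeds `maxMissingFrac` (loci with all
#' values missing are always dropped, never imputed) and imputes each
#' remaining missing beta with that locus's mean over observed samples.
#'
#' @param meth locus x sample matrix of beta values in `[0, 1]`, `NA` allowed.
#' @param maxMissingFrac loci missing more than this fraction are removed.
#' @return Locus x sample matrix with no missing entries.
#' @export
clean_methylation <- function(meth, maxMissingFrac = 0.5) {
  assert_matrix(meth, "`meth`")
  rng <- range(meth, na.rm = TRUE)
  if (rng[1L] < 0 || rng[2L] > 1) stop("beta values must lie in [0, 1]")
  missFrac <- rowMeans(is.na(meth))
  drop <- missFrac > maxMissingFrac | missFrac == 1
  if (any(drop)) {
    omix_log("dropped ", sum(drop), " of ", nrow(meth),
             " loci with > ", round(100 * maxMissingFrac), "% missing betas",
             " (", sum(missFrac == 1), " entirely missing)")
  }
  out <- meth[!drop, , drop = FALSE]
  nImp <- sum(is.na(out))
  if (nImp > 0L) {
    rm <- rowMeans(out, na.rm = TRUE)
    idx <- which(is.na(out), arr.ind = TRUE)
    out[idx] <- rm[idx[, 1L]]
    omix_log("imputed ", nImp, " missing betas with locus means")
  }
  out
}

# Token tables for the clinical gold standards.
.lung_low <- c("I", "IA", "IB", "II", "IIA")
.lung_high <- c("IIIB", "IV")
.lung_known <- c(.lung_low, "IIB", "III", "IIIA", .lung_high)
.cyto_map <- c(favorable = "low", intermediate = "intermediate", poor = "high",
               low = "low", high = "high")

#' Clean survival data and assign gold-standard risk labels
#'
#' Removes patients with missing survival time or vital status, then
#' populates a three-level `goldRisk` label (low / intermediate / high) from
#' the requested cohort-specific rule:
#' \describe{
#'   \item{lungStage}{tumor stages I, IA, IB, II, IIA are low risk; IIIB and
#'     IV high risk; the remaining stages intermediate.}
#'   \item{afpIshak}{high risk if AFP > 500 or Ishak fibrosis score = 6; low
#'     risk if AFP < 250 and Ishak is 0, 1, or 2; otherwise intermediate.}
#'   \item{braak}{Braak 0-2 low, 5-6 high, 3-4 intermediate.}
#'   \item{cytogenetics}{passes through a favorable/intermediate/poor column.}
#'   \item{precomputed}{passes through a low/intermediate/high `risk` column.}
#' }
#'
#' @param clinical data.frame with columns `ID`, `time`, `event`, plus the
#'   rule-specific column(s) (`stage`, `AFP` and `Ishak`, `braak`, or `risk`).
#' @param goldStandard which labeling rule to apply.
#' @return data.frame with columns `ID`, `time`, `event`, `goldRisk`.
#' @export
prepare_survival <- function(clinical,
                             goldStandard = c("precomputed", "lungStage",
                                              "afpIshak", "braak",
                                              "cytogenetics")) {
  goldStandard <- match.arg(goldStandard)
  need <- c("ID", "time", "event")
  missCol <- setdiff(need, names(clinical))
  if (length(missCol) > 0L) {
    stop("clinical table lacks column(s): ", paste(missCol, collapse = ", "))
  }
  keep <- !is.na(clinical$time) & !is.na(clinical$event)
  if (any(!keep)) {
    omix_log("removed ", sum(!keep), " patients with missing time or status")
  }
  cl <- clinical[keep, , drop = FALSE]
  if (!all(cl$event %in% c(0, 1))) stop("`event` must be 0 (censored) or 1 (event)")
  if (any(cl$time < 0)) stop("`time` must be nonnegative")

  require_col <- function(col) {
    if (!col %in% names(cl)) {
      stop("gold standard '", goldStandard, "' needs column `", col, "`")
    }
    cl[[col]]
  }

  goldRisk <- switch(goldStandard,
    lungStage = {
      stage <- toupper(trimws(as.character(require_col("stage"))))
      stage <- sub("^STAGE\\s*", "", stage)
      bad <- stats::na.omit(setdiff(stage, .lung_known))
      if (length(bad) > 0L) stop("unknown tumor stage: ", paste(bad, collapse = ", "))
      ifelse(is.na(stage), NA_character_,
             ifelse(stage %in% .lung_low, "low",
                    ifelse(stage %in% .lung_high, "high", "intermediate")))
    },
    afpIshak = {
      afp <- as.numeric(require_col("AFP"))
      ishak <- as.numeric(require_col("Ishak"))
      bad <- stats::na.omit(setdiff(ishak, 0:6))
      if (length(bad) > 0L) stop("unknown Ishak score: ", paste(bad, collapse = ", "))
      high <- (!is.na(afp) & afp > 500) | (!is.na(ishak) & ishak == 6)
      low <- !is.na(afp) & afp < 250 & !is.na(ishak) & ishak %in% 0:2
      out <- ifelse(high, "high", ifelse(low, "low", "intermediate"))
      out[!high & (is.na(afp) | is.na(ishak))] <- NA_character_
      out
    },
    braak = {
      braak <- as.numeric(require_col("braak"))
      bad <- stats::na.omit(setdiff(braak, 0:6))
      if (length(bad) > 0L) stop("unknown Braak score: ", paste(bad, collapse = ", "))
      ifelse(is.na(braak), NA_character_,
             ifelse(braak <= 2, "low", ifelse(braak >= 5, "high", "intermediate")))
    },
    cytogenetics = {
      lab <- tolower(trimws(as.character(require_col("cytogenetics"))))
      bad <- stats::na.omit(setdiff(lab, names(.cyto_map)))
      if (length(bad) > 0L) stop("unknown cytogenetic class: ", paste(bad, collapse = ", "))
      unname(.cyto_map[lab])
    },
    precomputed = {
      lab <- tolower(trimws(as.character(require_col("risk"))))
      bad <- stats::na.omit(setdiff(lab, c("low", "intermediate", "high")))
      if (length(bad) > 0L) stop("unknown risk label: ", paste(bad, collapse = ", "))
      lab
    }
  )

  data.frame(ID = as.character(cl$ID), time = as.numeric(cl$time),
             event = as.numeric(cl$event), goldRisk = goldRisk,
             stringsAsFactors = FALSE)
}

# Max of |cor(feature, time)| and |cor(feature, event)| per feature row,
# over the samples shared between the matrix and the survival table.
.survival_cor <- function(m, surv) {
  ids <- intersect(colnames(m), surv$ID)
  if (length(ids) < 3L) stop("need at least 3 samples shared with survival data")
  s <- surv[match(ids, surv$ID), ]
  cc <- cor0(t(m[, ids, drop = FALSE]), cbind(time = s$time, event = s$event))
  apply(abs(cc), 1L, max)
}

#' Elect survival-correlated genes and loci
#'
#' Keeps a feature when the larger of its absolute Pearson correlations with
#' survival time and with vital status reaches `corCutoff` (either-exceeds
#' rule; zero-variance features count as correlation 0). Correlations for
#' each data type use all samples carrying that data type plus survival.
#'
#' @param expr normalized gene x sample matrix.
#' @param meth cleaned locus x sample beta matrix.
#' @param survival output of [prepare_survival()].
#' @param corCutoff absolute-correlation threshold (0.2 in the TCGA-scale
#'   default).
#' @return List of class `feature_election` with `selectedGenes`,
#'   `selectedLoci`, `corCutoff`.
#' @export
elect_features <- function(expr, meth, survival, corCutoff = 0.2) {
  if (!is.numeric(corCutoff) || corCutoff < 0 || corCutoff > 1) {
    stop("`corCutoff` must be in [0, 1]")
  }
  geneCor <- .survival_cor(expr, survival)
  lociCor <- .survival_cor(meth, survival)
  out <- list(selectedGenes = names(geneCor)[geneCor >= corCutoff],
              selectedLoci = names(lociCor)[lociCor >= corCutoff],
              corCutoff = corCutoff)
  omix_log("elected ", length(out$selectedGenes), "/", nrow(expr), " genes and ",
           length(out$selectedLoci), "/", nrow(meth), " loci at |cor| >= ",
           corCutoff)
  class(out) <- "feature_election"
  out
}

#' Expand an election by the gene/locus union
#'
#' Adds the loci of every selected gene and the genes of every selected
#' locus, iterating to a fixed point so that the operation is idempotent
#' even for many-to-many maps. Features absent from the map pass through.
#'
#' @param election a `feature_election`.
#' @param map locus-gene map from [read_locus_gene_map()].
#' @return Expanded `feature_election` (never removes features).
#' @export
compute_union <- function(election, map) {
  genes <- election$selectedGenes
  loci <- election$selectedLoci
  repeat {
    g2 <- union(genes, map$gene[map$locus %in% loci])
    l2 <- union(loci, map$locus[map$gene %in% genes])
    if (length(g2) == length(genes) && length(l2) == length(loci)) break
    genes <- g2
    loci <- l2
  }
  out <- election
  out$selectedGenes <- sort(genes)
  out$selectedLoci <- sort(loci)
  out
}
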