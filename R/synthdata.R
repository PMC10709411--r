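# Seeded generator of coupled expression/methylation/survival cohorts with
# planted module, latent-factor, and hazard structure, plus a scorer that
# compares a pipeline run against the planted truth. Every stage of the
# package is testable on these cohorts without any external download.

#' Simulate a coupled expression/methylation/survival cohort
#'
#' Plants `nModules` latent factors (one per module, standard normal across
#' samples). Each module gene loads on its factor in expression (loading
#' drawn from `[0.5, 1]` with random sign) and, independently signed, in a
#' gene-level methylation latent; an `anticorFraction` of genes flips the
#' methylation sign relative to expression. Noise genes are independent.
#' Each gene's CpG loci are inverse-logit transforms of its methylation
#' latent plus a per-locus offset and noise, so betas stay in `(0, 1)`;
#' locus counts follow `1 + min(Poisson(1.5), 11)`, keeping most genes
#' under 6 loci. Survival follows a Weibull accelerated failure time law
#' `log T = b0 + b1 * z_prognostic + scale * eps` with uniform censoring
#' calibrated to `censoringRate`; gold-standard risk labels are tertiles of
#' the prognostic factor with a fraction of labels flipped. Betas are
#' masked missing completely at random at `missingRate`.
#'
#' `signalChannel` restricts where the survival-linked factors live. With
#' `"both"` (default) the same factors drive both data types. With
#' `"expression"` only expression carries them; methylation still has
#' co-methylation module structure, but built from independent factors over
#' a shuffled gene grouping, so it is uninformative about both the planted
#' modules and survival. `"methylation"` is the mirror image.
#'
#' @param nSamples number of patients.
#' @param nModules number of planted modules.
#' @param genesPerModule genes per planted module.
#' @param nNoiseGenes unstructured genes appended after the module genes.
#' @param withinModuleCor target mean pairwise expression correlation
#'   within a module.
#' @param prognosticEffect AFT coefficient `b1` on the prognostic factor.
#' @param aftIntercept,aftScale AFT intercept `b0` and scale `sigma`.
#' @param censoringRate expected fraction of censored patients.
#' @param missingRate fraction of betas masked missing at random.
#' @param anticorFraction fraction of module genes whose methylation latent
#'   is anti-coupled to their expression loading.
#' @param labelNoise fraction of gold-risk labels flipped at random.
#' @param prognosticModule which planted module drives survival.
#' @param signalChannel `"both"`, `"expression"`, or `"methylation"`.
#' @param lociPerGene function(n) returning n locus counts (default
#'   `1 + min(Poisson(1.5), 11)`).
#' @param seed integer seed; the generator is deterministic given it.
#' @return List with `expr` (raw positive gene x sample matrix), `meth`
#'   (locus x sample betas with missing values), `map` (locus-gene
#'   data.frame), `clinical` (ID/time/event/risk data.frame), and `truth`
#'   (`synthetic_truth`: planted labels, latent factors, prognostic module,
#'   AFT parameters, coupling signs, rates).
#' @export
simulate_cohort <- function(nSamples = 150, nModules = 3, genesPerModule = 30,
                            nNoiseGenes = 60, withinModuleCor = 0.8,
                            prognosticEffect = 1, aftIntercept = 3,
                            aftScale = 0.5, censoringRate = 0.3,
                            missingRate = 0.05, anticorFraction = 0.5,
                            labelNoise = 0.1, prognosticModule = 1,
                            signalChannel = c("both", "expression", "methylation"),
                            lociPerGene = NULL, seed = 1) {
  signalChannel <- match.arg(signalChannel)
  stopifnot(nSamples > 0, nModules > 0, genesPerModule > 0, nNoiseGenes >= 0,
            withinModuleCor > 0, withinModuleCor < 1,
            censoringRate >= 0, censoringRate < 1,
            missingRate >= 0, missingRate < 1,
            prognosticModule %in% seq_len(nModules))
  if (is.null(lociPerGene)) {
    lociPerGene <- function(n) 1L + pmin(stats::rpois(n, 1.5), 11L)
  }
  with_seed(seed, {
    samples <- sprintf("S%04d", seq_len(nSamples))
    nGenes <- nModules * genesPerModule + nNoiseGenes
    genes <- sprintf("G%04d", seq_len(nGenes))
    moduleOf <- stats::setNames(
      c(rep(seq_len(nModules), each = genesPerModule), rep(0L, nNoiseGenes)),
      genes)

    z <- matrix(stats::rnorm(nModules * nSamples), nModules, nSamples,
                dimnames = list(paste0("module", seq_len(nModules)), samples))

    # noise SD calibrated so the mean within-module correlation is near the
    # target given loadings uniform on [0.5, 1] (E[a^2] = 7/12).
    noiseSD <- sqrt((7 / 12) * (1 / withinModuleCor - 1))
    loadE <- stats::runif(nGenes, 0.5, 1) * sample(c(-1, 1), nGenes, replace = TRUE)
    loadM <- stats::runif(nGenes, 0.5, 1) *
      sign(loadE) * ifelse(stats::runif(nGenes) < anticorFraction, -1, 1)

    # an inert channel keeps co-feature module structure, but from
    # independent factors over a shuffled gene grouping, so it carries no
    # information about the planted modules or survival
    latent_for <- function(load, active) {
      if (active) {
        grouping <- moduleOf
        factors <- z
      } else {
        grouping <- moduleOf
        planted <- which(moduleOf > 0)
        grouping[planted] <- sample(moduleOf[planted])
        factors <- matrix(stats::rnorm(nModules * nSamples), nModules,
                          nSamples)
      }
      t(vapply(seq_len(nGenes), function(g) {
        noise <- stats::rnorm(nSamples, sd = if (grouping[g] > 0) noiseSD else 1)
        if (grouping[g] > 0) load[g] * factors[grouping[g], ] + noise else noise
      }, numeric(nSamples)))
    }
    exprLatent <- latent_for(loadE, signalChannel != "methylation")
    methLatent <- latent_for(loadM, signalChannel != "expression")
    dimnames(exprLatent) <- dimnames(methLatent) <- list(genes, samples)

    # raw expression on a positive count-like scale; log10(x + 1) in the
    # pipeline recovers the latent up to a near-affine map
    expr <- 10^(exprLatent + 2)

    nLoci <- lociPerGene(nGenes)
    locusGene <- rep(genes, nLoci)
    loci <- sprintf("cg%06d", seq_len(sum(nLoci)))
    map <- data.frame(locus = loci, gene = locusGene, stringsAsFactors = FALSE)
    offsets <- stats::rnorm(length(loci))
    meth <- stats::plogis(
      methLatent[locusGene, , drop = FALSE] + offsets +
        matrix(stats::rnorm(length(loci) * nSamples, sd = 0.4),
               length(loci), nSamples))
    dimnames(meth) <- list(loci, samples)

    # Weibull AFT survival: log T = b0 + b1 z + sigma * log(Exp(1))
    zProg <- z[prognosticModule, ]
    logT <- aftIntercept + prognosticEffect * zProg +
      aftScale * log(stats::rexp(nSamples))
    T <- exp(logT)
    if (censoringRate > 0) {
      cmax <- stats::uniroot(function(cm) mean(pmin(T, cm)) / cm - censoringRate,
                             interval = c(min(T) * 1e-6, max(T) * 1e6),
                             tol = 1e-10)$root
      C <- stats::runif(nSamples, 0, cmax)
      event <- as.numeric(T <= C)
      time <- pmin(T, C)
    } else {
      event <- rep(1, nSamples)
      time <- T
    }

    # gold risk from prognostic-factor tertiles (higher factor with b1 > 0
    # means longer predicted survival, hence low risk), plus label flips
    qs <- stats::quantile(zProg, c(1, 2) / 3)
    dirn <- if (prognosticEffect >= 0) 1 else -1
    risk <- ifelse(dirn * zProg <= min(dirn * qs), "high",
                   ifelse(dirn * zProg > max(dirn * qs), "low", "intermediate"))
    flip <- which(stats::runif(nSamples) < labelNoise)
    risk[flip] <- vapply(risk[flip], function(r) {
      sample(setdiff(c("low", "intermediate", "high"), r), 1L)
    }, character(1))

    if (missingRate > 0) {
      mask <- matrix(stats::runif(length(meth)) < missingRate,
                     nrow(meth), ncol(meth))
      meth[mask] <- NA_real_
    }

    clinical <- data.frame(ID = samples, time = time, event = event,
                           risk = risk, stringsAsFactors = FALSE)
    truth <- structure(
      list(moduleOfGene = moduleOf, latentFactors = z,
           prognosticModule = prognosticModule,
           aftParams = c(b0 = aftIntercept, b1 = prognosticEffect,
                         scale = aftScale),
           couplingSigns = cbind(expression = sign(loadE),
                                 methylation = sign(loadM)),
           missingRate = missingRate, censoringRate = censoringRate,
           signalChannel = signalChannel, seed = seed),
      class = "synthetic_truth")
    list(expr = expr, meth = meth, map = map, clinical = clinical,
         truth = truth)
  })
}

#' Score a pipeline run against the planted truth
#'
#' Computes the adjusted Rand index between planted and detected module
#' labels, the best absolute correlation between each planted factor and
#' the detected eigengenes of its best-overlapping module, the error of an
#' oracle AFT fit on the true prognostic factor, and the selection rank of
#' the prognostic module's eigengenes among the lasso candidates.
#'
#' @param truth a `synthetic_truth`.
#' @param result a `run_result` from [run_pipeline()] on the same cohort.
#' @return List with `moduleARI`, `eigengeneCor` (per planted module),
#'   `prognosticSelectionRank` (`NA` when no candidate maps to the
#'   prognostic module), and `aftB1Error`.
#' @export
truth_report <- function(truth, result) {
  best <- result$best
  moduleOf <- best$modules$moduleOf
  common <- intersect(names(truth$moduleOfGene), names(moduleOf))
  if (length(common) == 0L) stop("no genes shared between truth and result")
  ari <- mclust::adjustedRandIndex(truth$moduleOfGene[common], moduleOf[common])

  stacked <- stack_eigengenes(best$eigengenes)
  samples <- intersect(colnames(stacked), colnames(truth$latentFactors))
  planted <- setdiff(unique(truth$moduleOfGene), 0L)
  egCor <- stats::setNames(rep(NA_real_, length(planted)),
                           rownames(truth$latentFactors)[planted])
  matched <- stats::setNames(rep(NA_integer_, length(planted)), names(egCor))
  for (i in seq_along(planted)) {
    members <- names(truth$moduleOfGene)[truth$moduleOfGene == planted[i]]
    hits <- moduleOf[intersect(members, names(moduleOf))]
    hits <- hits[hits != 0L]
    if (length(hits) == 0L) next
    det <- as.integer(names(sort(table(hits), decreasing = TRUE))[1L])
    matched[i] <- det
    rows <- paste0(det, c("e", "m", "em"))
    rows <- intersect(rows, rownames(stacked))
    egCor[i] <- max(abs(cor0(t(stacked[rows, samples, drop = FALSE]),
                             truth$latentFactors[planted[i], samples])))
  }

  rank <- NA_integer_
  progDet <- matched[match(truth$prognosticModule, planted)]
  if (!is.na(progDet)) {
    hit <- grepl(sprintf("^%d(e|m|em)$", progDet), best$candidates)
    if (any(hit)) rank <- which(hit)[1L]
  }

  oracle <- tryCatch({
    x <- matrix(truth$latentFactors[truth$prognosticModule, ], ncol = 1,
                dimnames = list(colnames(truth$latentFactors), "zProg"))
    surv <- result$survivalTable
    fit <- fit_aft(x[surv$ID, , drop = FALSE], surv)
    abs(fit$coefficients["zProg"] - truth$aftParams["b1"])
  }, error = function(e) NA_real_)

  list(moduleARI = ari, eigengeneCor = egCor,
       prognosticSelectionRank = rank, aftB1Error = unname(oracle))
}
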