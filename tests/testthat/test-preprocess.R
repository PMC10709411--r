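test_that("log10 normalization maps counts as expected and flags output", {
  m <- matrix(c(0, 9, 99, 999), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  out <- normalize_expression(m, offset = 1)
  expect_equal(unname(out[1, 1]), 0)
  expect_equal(unname(out[2, 1]), 1)
  expect_equal(unname(out[1, 2]), 2)
  expect_equal(unname(out[2, 2]), 3)
  expect_true(attr(out, "normalized"))
  m[1, 1] <- -1
  expect_error(normalize_expression(m), "nonnegative")
})

test_that("methylation cleaning drops >50%-missing loci and imputes the rest", {
  meth <- rbind(
    mostly_missing = c(NA, NA, NA, 0.5, 0.5),   # 60% -> dropped
    some_missing = c(NA, NA, 0.2, 0.4, 0.6),    # 40% -> imputed to 0.4
    all_missing = c(NA, NA, NA, NA, NA),        # never imputed
    complete = c(0.1, 0.2, 0.3, 0.4, 0.5))
  colnames(meth) <- sprintf("s%d", 1:5)
  out <- clean_methylation(meth, maxMissingFrac = 0.5)
  expect_setequal(rownames(out), c("some_missing", "complete"))
  expect_false(anyNA(out))
  expect_equal(unname(out["some_missing", 1:2]), c(0.4, 0.4))
  # imputation preserves the observed mean
  expect_equal(mean(out["some_missing", ]), 0.4)
  expect_error(clean_methylation(meth * 3), "\\[0, 1\\]")
})

test_that("a locus row mean survives imputation exactly", {
  meth <- rbind(l1 = c(0.2, NA, 0.4))
  colnames(meth) <- sprintf("s%d", 1:3)
  out <- clean_methylation(meth)
  expect_equal(unname(out["l1", 2]), 0.3)
})

clin <- function(...) {
  base <- data.frame(ID = NA, time = 10, event = 1, stringsAsFactors = FALSE)
  extra <- list(...)
  n <- max(lengths(extra))
  df <- base[rep(1, n), , drop = FALSE]
  df$ID <- sprintf("P%02d", seq_len(n))
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  df
}

test_that("lung-stage gold standard follows the stage tables", {
  got <- prepare_survival(
    clin(stage = c("I", "IA", "IB", "II", "IIA", "IIB", "III", "IIIA", "IIIB", "IV")),
    "lungStage")$goldRisk
  expect_identical(got, c(rep("low", 5), rep("intermediate", 3), rep("high", 2)))
  expect_error(prepare_survival(clin(stage = "V"), "lungStage"), "V")
})

test_that("AFP/Ishak gold standard encodes the liver thresholds", {
  got <- prepare_survival(
    clin(AFP = c(600, 100, 100, 300, 501), Ishak = c(3, 1, 3, 1, 0)),
    "afpIshak")$goldRisk
  expect_identical(got, c("high", "low", "intermediate", "intermediate", "high"))
  got2 <- prepare_survival(clin(AFP = 100, Ishak = 6), "afpIshak")$goldRisk
  expect_identical(got2, "high")
  expect_error(prepare_survival(clin(AFP = 100, Ishak = 9), "afpIshak"), "9")
})

test_that("Braak gold standard maps 0-2 low, 5-6 high, 3-4 intermediate", {
  got <- prepare_survival(clin(braak = c(0, 2, 3, 4, 5, 6)), "braak")$goldRisk
  expect_identical(got, c("low", "low", "intermediate", "intermediate",
                          "high", "high"))
})

test_that("pass-through standards validate tokens and required columns", {
  got <- prepare_survival(clin(cytogenetics = c("favorable", "poor", "Intermediate")),
                          "cytogenetics")$goldRisk
  expect_identical(got, c("low", "high", "intermediate"))
  expect_error(prepare_survival(clin(cytogenetics = "odd"), "cytogenetics"), "odd")
  expect_error(prepare_survival(clin(risk = "low"), "lungStage"), "stage")
})

test_that("patients with missing time or status are removed", {
  df <- clin(risk = c("low", "high", "low"))
  df$time[2] <- NA
  df$event[3] <- NA
  out <- prepare_survival(df, "precomputed")
  expect_identical(out$ID, "P01")
  df$event <- 2
  expect_error(prepare_survival(clin(risk = "low", event = 2), "precomputed"))
})

make_election_inputs <- function(n = 40, seed = 1) {
  set.seed(seed)
  time <- stats::rexp(n, 1 / 10)
  surv <- data.frame(ID = sprintf("s%02d", 1:n), time = time,
                     event = stats::rbinom(n, 1, 0.5),
                     goldRisk = "low", stringsAsFactors = FALSE)
  expr <- rbind(coupled = time + stats::rnorm(n, sd = 2),
                null = stats::rnorm(n),
                flat = rep(1, n))
  colnames(expr) <- surv$ID
  meth <- rbind(lcoupled = stats::plogis(scale(time)[, 1] + stats::rnorm(n, sd = 1)),
                lnull = stats::runif(n))
  colnames(meth) <- surv$ID
  list(expr = expr, meth = meth, surv = surv)
}

test_that("feature election keeps either-correlated features, drops the rest", {
  d <- make_election_inputs()
  el <- elect_features(d$expr, d$meth, d$surv, corCutoff = 0.2)
  expect_true("coupled" %in% el$selectedGenes)
  expect_false("flat" %in% el$selectedGenes)    # zero variance counts as 0
  expect_true("lcoupled" %in% el$selectedLoci)
})

test_that("raising the election cutoff never adds features", {
  d <- make_election_inputs(seed = 3)
  prev <- NULL
  for (cutoff in c(0.1, 0.3, 0.6, 0.9)) {
    el <- elect_features(d$expr, d$meth, d$surv, cutoff)
    if (!is.null(prev)) {
      expect_true(all(el$selectedGenes %in% prev$selectedGenes))
      expect_true(all(el$selectedLoci %in% prev$selectedLoci))
    }
    prev <- el
  }
})

test_that("election separates survival-coupled from null genes as the null distribution predicts", {
  # 50 coupled and 450 null genes; with n samples the null |cor| is roughly
  # normal with sd 1/sqrt(n - 1), giving an exact false-keep expectation
  n <- 60
  nullKeep <- coupledKeep <- numeric(20)
  for (r in 1:20) {
    set.seed(r)
    z <- stats::rnorm(n)
    time <- exp(1 + 1.2 * z + stats::rnorm(n, sd = 0.3))
    expr <- rbind(
      matrix(rep(z, each = 50), 50, n) * 0.8 +
        matrix(stats::rnorm(50 * n, sd = 0.6), 50, n),
      matrix(stats::rnorm(450 * n), 450, n))
    dimnames(expr) <- list(sprintf("g%03d", 1:500), sprintf("s%02d", 1:n))
    surv <- data.frame(ID = colnames(expr), time = time, event = 1,
                       goldRisk = "low", stringsAsFactors = FALSE)
    meth <- expr[1:2, , drop = FALSE]
    rownames(meth) <- c("cgA", "cgB")
    el <- elect_features(expr, stats::plogis(meth), surv, 0.2)
    coupledKeep[r] <- mean(sprintf("g%03d", 1:50) %in% el$selectedGenes)
    nullKeep[r] <- mean(sprintf("g%03d", 51:500) %in% el$selectedGenes)
  }
  expect_gte(mean(coupledKeep), 0.8)
  # two chances (time, status) to clear 0.2; null rate must stay near the
  # analytic single-test rate 2*P(|N(0,1/sqrt(n-1))| > 0.2) ~ 0.25
  pNull <- 2 * stats::pnorm(0.2 * sqrt(n - 1), lower.tail = FALSE)
  expect_lt(mean(nullKeep), 2.5 * pNull)
})

test_that("gene/locus union expansion matches the definition and is idempotent", {
  map <- data.frame(locus = c("cg1", "cg2"), gene = c("A", "B"))
  el <- structure(list(selectedGenes = "A", selectedLoci = "cg2",
                       corCutoff = 0.2), class = "feature_election")
  out <- compute_union(el, map)
  expect_setequal(out$selectedGenes, c("A", "B"))
  expect_setequal(out$selectedLoci, c("cg1", "cg2"))
  expect_identical(compute_union(out, map), out)
})

test_that("union expansion is idempotent under many-to-many maps and monotone", {
  map <- data.frame(locus = c("cg1", "cg1", "cg2", "cg3"),
                    gene = c("A", "B", "B", "C"))
  el <- structure(list(selectedGenes = "A", selectedLoci = character(0),
                       corCutoff = 0.2), class = "feature_election")
  out <- compute_union(el, map)
  expect_identical(compute_union(out, map), out)
  expect_true(all(el$selectedGenes %in% out$selectedGenes))
  empty <- structure(list(selectedGenes = character(0),
                          selectedLoci = character(0), corCutoff = 0.2),
                     class = "feature_election")
  got <- compute_union(empty, map)
  expect_length(got$selectedGenes, 0)
  expect_length(got$selectedLoci, 0)
})
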