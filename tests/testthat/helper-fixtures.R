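# Shared fixtures and independent oracles for the test suite.

options(omixnet.verbose = FALSE)

# Small labeled matrix with optional missing entries.
make_matrix <- function(nr = 3, nc = 4, seed = 1, na = 0) {
  m <- matrix(round(stats::rnorm(nr * nc), 6), nr, nc,
              dimnames = list(sprintf("f%02d", seq_len(nr)),
                              sprintf("s%02d", seq_len(nc))))
  set.seed(seed)
  m[] <- stats::rnorm(nr * nc)
  if (na > 0) m[sample(length(m), na)] <- NA
  m
}

# A small cohort processed up to the eigenloci stage, cached per call set.
processed_cohort <- local({
  cache <- new.env()
  function(seed = 1, ...) {
    key <- paste(seed, paste(deparse(list(...)), collapse = ""), sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    co <- simulate_cohort(seed = seed, ...)
    expr <- normalize_expression(co$expr)
    meth <- clean_methylation(co$meth)
    el <- compute_eigenloci(meth, co$map)
    out <- list(cohort = co, expr = expr, meth = meth, eigenloci = el)
    cache[[key]] <- out
    out
  }
})

# Independent log-rank oracle: the observed-minus-expected over variance
# chi-square, accumulated over distinct event times.
logrank_oracle <- function(time, event, group) {
  group <- as.character(group)
  g1 <- sort(unique(group))[1L]
  OminusE <- 0
  V <- 0
  for (t in sort(unique(time[event == 1]))) {
    atRisk <- time >= t
    n <- sum(atRisk)
    n1 <- sum(atRisk & group == g1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group == g1)
    OminusE <- OminusE + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- OminusE^2 / V
  list(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

# Exhaustive oracle for the recall-constrained precision-maximizing cutoff.
cutoff_oracle <- function(pred, outcome, direction, minRecall) {
  positive <- if (direction == "high") outcome == 1 else outcome == 0
  u <- sort(unique(pred))
  cands <- (u[-1] + u[-length(u)]) / 2
  best <- NULL
  for (cut in cands) {
    sel <- if (direction == "high") pred < cut else pred > cut
    if (!any(sel)) next
    tp <- sum(sel & positive)
    if (tp / sum(positive) < minRecall) next
    prec <- tp / sum(sel)
    if (is.null(best) || prec > best$prec ||
        (prec == best$prec && sum(sel) < best$n)) {
      best <- list(cut = cut, prec = prec, n = sum(sel))
    }
  }
  best
}

# Brute-force first principal direction through the feature covariance.
pca_oracle <- function(X) {
  Xc <- X - rowMeans(X)
  S <- Xc %*% t(Xc) / (ncol(X) - 1)
  w <- eigen(S, symmetric = TRUE)$vectors[, 1L]
  list(weights = unname(w), scores = unname(drop(crossprod(w, Xc))))
}

# Correlation up to sign.
abs_cor <- function(x, y) abs(stats::cor(x, y))

# Loci x sample matrix with two planted correlation blocks.
make_blocks <- function(seed = 1, sizes = c(5, 3), rs = c(0.9, 0.6), n = 40) {
  set.seed(seed)
  rows <- list()
  for (b in seq_along(sizes)) {
    z <- stats::rnorm(n)
    lam <- sqrt(rs[b])
    for (i in seq_len(sizes[b])) {
      rows[[length(rows) + 1]] <- lam * z + sqrt(1 - lam^2) * stats::rnorm(n)
    }
  }
  X <- do.call(rbind, rows)
  dimnames(X) <- list(sprintf("cg%02d", seq_len(nrow(X))),
                      sprintf("s%02d", seq_len(n)))
  X
}
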