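# Independent brute-force oracles used to cross-check the vectorized
# implementations, plus small fixture builders. Oracles deliberately use
# naive enumeration, not the package's code paths.

# co-occurrence counts by looping over every pixel pair
bruteGLCM <- function(grid, ng, d = 1, angles = c(0, 45, 90, 135),
                      symmetric = TRUE) {
  offs <- list("0" = c(0, d), "45" = c(-d, d), "90" = c(-d, 0),
               "135" = c(-d, -d))
  cnt <- matrix(0, ng, ng)
  for (ang in angles) {
    o <- offs[[as.character(ang)]]
    for (r in seq_len(nrow(grid))) for (c in seq_len(ncol(grid))) {
      r2 <- r + o[1]; c2 <- c + o[2]
      if (r2 >= 1 && r2 <= nrow(grid) && c2 >= 1 && c2 <= ncol(grid))
        cnt[grid[r, c] + 1, grid[r2, c2] + 1] <-
          cnt[grid[r, c] + 1, grid[r2, c2] + 1] + 1
    }
  }
  if (symmetric) cnt <- cnt + t(cnt)
  cnt / sum(cnt)
}

# run counts by walking every scan line pixel by pixel
bruteRLM <- function(grid, ng, angles = c(0, 45, 90, 135)) {
  h <- nrow(grid); w <- ncol(grid)
  lmax <- max(h, w)
  cnt <- matrix(0, ng, lmax)
  addLine <- function(v) {
    i <- 1
    while (i <= length(v)) {
      j <- i
      while (j < length(v) && v[j + 1] == v[i]) j <- j + 1
      cnt[v[i] + 1, j - i + 1] <<- cnt[v[i] + 1, j - i + 1] + 1
      i <- j + 1
    }
  }
  for (ang in angles) {
    if (ang == 0) for (r in seq_len(h)) addLine(grid[r, ])
    if (ang == 90) for (c in seq_len(w)) addLine(grid[, c])
    if (ang == 45) for (s in 2:(h + w)) {
      rs <- pmax(1, s - w):pmin(h, s - 1)
      addLine(grid[cbind(rev(rs), s - rev(rs))])
    }
    if (ang == 135) for (s in (1 - w):(h - 1)) {
      rs <- max(1, 1 + s):min(h, w + s)
      addLine(grid[cbind(rs, rs - s)])
    }
  }
  cnt
}

# AUC by exhaustive pair comparison, ties half-weighted
bruteAUC <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Welch two-sample t-test from the textbook formulas
welchOracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- var(x); v2 <- var(y)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# small random quantized region
randomQROI <- function(h, w, ng, seed) {
  g <- withr::with_seed(seed, matrix(sample(0:(ng - 1), h * w, TRUE), h, w))
  storage.mode(g) <- "integer"
  new("QuantizedROI", levels = as.integer(ng), grid = g,
      nPixels = as.integer(h * w))
}

# plain Gaussian two-class feature table (no images involved) for
# classifier/evaluation tests: p features, standardized class separation
# `sep` on every feature
gaussianTable <- function(n0, n1, p = 2, sep = 2, seed = 1) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n0 * p), n0),
               matrix(rnorm(n1 * p, mean = sep), n1))
    colnames(X) <- paste0("f", seq_len(p))
    df <- as.data.frame(X)
    df$label <- rep(c(0L, 1L), c(n0, n1))
    df
  })
}

# feature-table SummarizedExperiment straight from a matrix
seFromMatrix <- function(m, labels, subjects = NULL) {
  ids <- sprintf("img%03d", seq_len(ncol(m)))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = m),
    colData = S4Vectors::DataFrame(
      image_id = ids,
      subject_id = if (is.null(subjects)) ids else subjects,
      label = as.integer(labels)))
}

# tiny synthetic cohort cached per session (used by several test files)
.tinyCohortEnv <- new.env()
tinyCohort <- function() {
  if (is.null(.tinyCohortEnv$co)) {
    cfg <- simulationConfig(imageHeight = 160L, imageWidth = 160L,
                            nRois = 2L, roiSize = 64L)
    .tinyCohortEnv$co <- generateCohort(cfg, 4, 4, 2, seed = 42)
    .tinyCohortEnv$ft <- extractFeatureTable(.tinyCohortEnv$co)
  }
  list(cohort = .tinyCohortEnv$co, ft = .tinyCohortEnv$ft)
}
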