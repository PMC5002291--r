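#' Retrain an ensemble of maps under different seeds
#'
#' Re-runs initialization, training, cluster delineation and assignment
#' with identical hyperparameters for each seed; only the codebook
#' initialization and the sample presentation order vary. This is the
#' protocol for probing whether the clustering is an artifact of a
#' particular random start.
#'
#' @param data samples x dimension matrix of all components to assign.
#' @param config list of hyperparameters: \code{rows, cols}, \code{radii}
#'   (per-epoch schedule), \code{mode}, \code{kernel}, \code{delineate}
#'   (\code{list(method, q, tol)}); missing entries take the package
#'   defaults (12 x 10 lattice, radii 4 to 1, batch, gaussian, threshold
#'   at the median).
#' @param seeds integer vector of length >= 2.
#' @param trainIndex row indices of \code{data} used for training
#'   (default: all rows).
#' @return list with one entry per seed, each
#'   \code{list(model, clustermap, assignments, seed)}.
#' @export
retrainEnsemble <- function(data, config = list(), seeds,
                            trainIndex = seq_len(nrow(data))) {
  if (length(seeds) < 2L) stop("supply at least 2 seeds")
  X <- as.matrix(data)
  rows <- config$rows %||% 12L
  cols <- config$cols %||% 10L
  radii <- config$radii %||% twoPhaseSchedule()
  mode <- config$mode %||% "batch"
  kernel <- config$kernel %||% "gaussian"
  del <- config$delineate %||% list(method = "threshold", q = 0.5)
  lapply(seeds, function(s) {
    model <- sofmInit(rows, cols, data = X[trainIndex, , drop = FALSE],
                      mode = "sample", seed = s, kernel = kernel)
    model <- sofmTrain(model, X[trainIndex, , drop = FALSE], radii = radii,
                       mode = mode, seed = s)
    cmap <- delineateClusters(uMatrix(model), method = del$method,
                              q = del$q %||% 0.5, tol = del$tol)
    list(model = model, clustermap = cmap,
         assignments = assignCluster(model, cmap, X), seed = s)
  })
}

#' Pairwise co-membership indicators of a partition
#'
#' For every unordered pair of components, 1 if the two share a cluster
#' and 0 otherwise. Co-membership is invariant under relabeling of
#' cluster ids, which makes it the natural unit for comparing partitions
#' from independently trained maps.
#'
#' @param assignments integer cluster ids, one per component.
#' @return integer vector over the \code{choose(n, 2)} unordered pairs, in
#'   column order of \code{combn(n, 2)}.
#' @export
comembership <- function(assignments) {
  n <- length(assignments)
  if (n < 2L) stop("need at least 2 components")
  eq <- outer(assignments, assignments, "==")
  as.integer(eq[upper.tri(eq)])
}

#' Per-component clustering consistency between two runs
#'
#' For each component, the fraction of its cluster-mates in run A that are
#' again its cluster-mates in run B; a component with no cluster-mates in
#' run A contributes 1 by convention. The summary (mean, SD over
#' components) answers "what share of each component's neighbors
#' survived the retraining".
#'
#' @param runA,runB integer cluster assignments over the same components.
#' @return \code{list(fractions, mean, sd)}.
#' @export
consistencyFraction <- function(runA, runB) {
  if (length(runA) != length(runB))
    stop("runs cover different component sets")
  n <- length(runA)
  fr <- vapply(seq_len(n), function(i) {
    mates <- which(runA == runA[i])
    mates <- mates[mates != i]
    if (length(mates) == 0L) return(1)
    mean(runB[mates] == runB[i])
  }, numeric(1L))
  list(fractions = fr, mean = mean(fr), sd = stats::sd(fr))
}

#' Cohen's kappa between two binary indicator series
#'
#' Chance-corrected agreement \code{kappa = (p_o - p_e) / (1 - p_e)} with
#' \code{p_o} the observed agreement and \code{p_e} the chance agreement
#' computed from the marginal rates. The 95% CI uses the large-sample
#' standard error \code{sqrt(p_o (1 - p_o) / (n (1 - p_e)^2))}; the
#' p-value tests kappa = 0 with the null-hypothesis standard error.
#' Intended use: the two series are pairwise co-membership indicators from
#' two independently trained maps (see [comembership()]), which makes the
#' statistic label-invariant.
#'
#' @param a,b equal-length binary vectors.
#' @param conf confidence level (default 0.95).
#' @return list with \code{kappa, ciLow, ciHigh, se, z, p, pObserved,
#'   pExpected, n}.
#' @export
cohensKappa <- function(a, b, conf = 0.95) {
  stopifnot(length(a) == length(b), length(a) >= 1L,
            all(a %in% c(0, 1)), all(b %in% c(0, 1)))
  n <- length(a)
  po <- mean(a == b)
  pa1 <- mean(a == 1); pb1 <- mean(b == 1)
  marg <- rbind(c(pa1, 1 - pa1), c(pb1, 1 - pb1))
  pe <- pa1 * pb1 + (1 - pa1) * (1 - pb1)
  if (pe >= 1 - .Machine$double.eps^0.5)
    stop("kappa is undefined: both series are constant and identical (chance agreement = 1)")
  kappa <- (po - pe) / (1 - pe)
  se <- sqrt(po * (1 - po) / (n * (1 - pe)^2))
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  # null SE (Fleiss, Levin & Paik) for the test of kappa = 0
  pi_ <- c(pa1, 1 - pa1); pj_ <- c(pb1, 1 - pb1)
  se0 <- sqrt((pe + pe^2 - sum(pi_ * pj_ * (pi_ + pj_))) / n) / (1 - pe)
  z <- if (se0 > 0) kappa / se0 else Inf
  list(kappa = kappa, ciLow = kappa - zq * se, ciHigh = kappa + zq * se,
       se = se, z = z, p = 2 * stats::pnorm(-abs(z)),
       pObserved = po, pExpected = pe, n = n)
}

#' Intraclass correlation, two-way random effects, absolute agreement
#'
#' ICC(A,1): single-measure, absolute-agreement ICC from the two-way
#' random-effects mean-squares decomposition,
#' \code{(MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))}, with the
#' McGraw-Wong confidence interval. Here rows are components and columns
#' are training runs; the rated quantity is a per-run numeric summary of
#' each component's clustering (the package convention uses the
#' consistency fraction against a baseline run).
#'
#' @param ratings numeric matrix, components x runs (>= 2 of each).
#' @param conf confidence level.
#' @return list with \code{icc, ciLow, ciHigh, msr, msc, mse}.
#' @export
iccAbsolute <- function(ratings, conf = 0.95) {
  m <- as.matrix(ratings)
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) stop("need >= 2 components and >= 2 runs")
  if (anyNA(m)) stop("ratings must be complete")
  grand <- mean(m)
  if (sum((m - grand)^2) < .Machine$double.eps)
    stop("ICC is undefined: total variance is zero")
  rm_ <- rowMeans(m); cm_ <- colMeans(m)
  ssr <- k * sum((rm_ - grand)^2)
  ssc <- n * sum((cm_ - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- max(sst - ssr - ssc, 0)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  alpha <- 1 - conf
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  fl <- stats::qf(1 - alpha / 2, n - 1, v)
  fu <- stats::qf(1 - alpha / 2, v, n - 1)
  ciLow <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  ciHigh <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  list(icc = icc, ciLow = ciLow, ciHigh = ciHigh,
       msr = msr, msc = msc, mse = mse)
}

#' Summarize clustering robustness of a retrained ensemble
#'
#' Computes, over all run pairs, Cohen's kappa on co-membership
#' indicators (mean and range), the per-component consistency fractions
#' of every run against the first (baseline) run, and the ICC(A,1) of
#' that component x run consistency matrix.
#'
#' @param ensemble result of [retrainEnsemble()].
#' @param csvPath optional path for the per-component consistency CSV.
#' @param jsonPath optional path for the JSON summary.
#' @return list with \code{kappaMean, kappaRange, kappaPairs,
#'   meanConsistency, sdConsistency, icc, consistency} (components x runs
#'   matrix, baseline column included as 1s).
#' @export
robustnessReport <- function(ensemble, csvPath = NULL, jsonPath = NULL) {
  stopifnot(length(ensemble) >= 2L)
  assigns <- lapply(ensemble, `[[`, "assignments")
  nRuns <- length(assigns)
  pairs <- utils::combn(nRuns, 2L)
  kres <- lapply(seq_len(ncol(pairs)), function(j) {
    cohensKappa(comembership(assigns[[pairs[1L, j]]]),
                comembership(assigns[[pairs[2L, j]]]))
  })
  kappas <- vapply(kres, `[[`, numeric(1L), "kappa")
  cons <- vapply(seq_len(nRuns), function(r)
    consistencyFraction(assigns[[1L]], assigns[[r]])$fractions,
    numeric(length(assigns[[1L]])))
  perComp <- rowMeans(cons[, -1L, drop = FALSE])
  icc <- tryCatch(iccAbsolute(cons), error = function(e) NULL)
  out <- list(kappaMean = mean(kappas), kappaRange = range(kappas),
              kappaPairs = kres,
              meanConsistency = mean(perComp),
              sdConsistency = stats::sd(perComp),
              icc = icc, consistency = cons)
  if (!is.null(csvPath)) {
    df <- data.frame(component = seq_along(perComp), cons)
    names(df) <- c("component", paste0("run", seq_len(nRuns)))
    df$mean_consistency <- perComp
    utils::write.csv(df, csvPath, row.names = FALSE)
  }
  if (!is.null(jsonPath)) {
    jsonlite::write_json(list(
      kappa_mean = out$kappaMean, kappa_range = out$kappaRange,
      kappa_ci = if (length(kres) == 1L)
        c(kres[[1L]]$ciLow, kres[[1L]]$ciHigh) else NULL,
      mean_consistency = out$meanConsistency,
      sd_consistency = out$sdConsistency,
      icc = if (!is.null(icc)) icc$icc else NULL),
      jsonPath, auto_unbox = TRUE, digits = NA)
  }
  out
}
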