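#' Train a labelled-line ensemble of one-vs-one linear classifiers
#'
#' ITDs are discretised into `n_bins` equal bins over the response grid's
#' ITD range; for every pair of bins a linear soft-margin maximum-margin
#' classifier (cost 1) is trained on standardised population rate patterns,
#' pooling all stimulus frequencies (the readout is frequency-blind). A
#' pattern's predicted bin is the one with most pairwise votes; ties are
#' broken by the summed signed decision values, then by the lower bin
#' index.
#'
#' @param responses a [simulatePopulation()] result used as the training
#'   pool.
#' @param n_bins number of ITD bins M (>= 2); M(M-1)/2 classifiers are
#'   trained.
#' @param n_train training patterns drawn per bin (without replacement from
#'   the pool).
#' @param seed integer seed for the draw.
#' @return object of class `classifier_ensemble`: bin edges/centers,
#'   standardisation statistics, pair table and oriented weight matrix, and
#'   the training-set indices.
#' @export
trainClassifier <- function(responses, n_bins, n_train, seed = 1L) {
  if (n_bins < 2L) stop("n_bins must be >= 2")
  pat <- responsePatterns(responses)
  edges <- binEdges(responses$conditions$itd_us, n_bins)
  lab <- findInterval(pat$tau, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(lab, n_bins)
  if (any(counts == 0L))
    stop("ITD bin(s) without training patterns: ",
         paste(which(counts == 0L), collapse = ", "))
  if (any(counts < n_train))
    stop("fewer than n_train patterns available in bin(s) ",
         paste(which(counts < n_train), collapse = ", "))
  train_idx <- withr::with_seed(seed, {
    unlist(lapply(seq_len(n_bins), function(b) {
      sample(which(lab == b), n_train)
    }))
  })
  X <- pat$X[train_idx, , drop = FALSE]
  y <- lab[train_idx]
  ctr <- colMeans(X)
  scl <- pmax(apply(X, 2, stats::sd), 1e-12)
  Xs <- scale(X, center = ctr, scale = scl)

  pairs <- t(utils::combn(n_bins, 2L))
  W <- matrix(0, nrow(pairs), ncol(X))
  rho <- numeric(nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    a <- pairs[p, 1]; b <- pairs[p, 2]
    sel <- y == a | y == b
    yy <- factor(y[sel], levels = c(a, b))
    m <- e1071::svm(Xs[sel, , drop = FALSE], yy, kernel = "linear",
                    cost = 1, scale = FALSE)
    w <- as.numeric(t(m$coefs) %*% m$SV)
    r <- m$rho
    # orient the hyperplane so that decision > 0 votes for bin a
    dec <- as.numeric(Xs[sel, , drop = FALSE] %*% w) - r
    pred_a <- stats::predict(m, Xs[sel, , drop = FALSE]) == as.character(a)
    if (all(pred_a) || all(!pred_a)) pred_a <- yy == as.character(a)
    if (mean(dec[pred_a]) < mean(dec[!pred_a])) {
      w <- -w
      r <- -r
    }
    W[p, ] <- w
    rho[p] <- r
  }
  structure(list(n_bins = n_bins, bin_edges = edges,
                 bin_centers = (edges[-1] + edges[-length(edges)]) / 2,
                 pairs = pairs, W = W, rho = rho,
                 center = ctr, scale = scl,
                 n_train = n_train, seed = seed,
                 train_idx = train_idx),
            class = "classifier_ensemble")
}

#' @export
print.classifier_ensemble <- function(x, ...) {
  cat(sprintf(
    "Labelled-line ensemble: %d ITD bins, %d pairwise linear classifiers, %d training patterns/bin\n",
    x$n_bins, nrow(x$pairs), x$n_train))
  invisible(x)
}

# flatten a population_response into (pattern matrix, true ITD per pattern)
responsePatterns <- function(responses) {
  d <- dim(responses$rates)
  X <- t(matrix(responses$rates, d[1], d[2] * d[3]))
  list(X = X, tau = rep(responses$conditions$itd_us, d[3]),
       frequency = rep(responses$conditions$frequency_hz, d[3]))
}

binEdges <- function(itd_us, n_bins) {
  r <- range(itd_us)
  seq(r[1] - 1e-9, r[2] + 1e-9, length.out = n_bins + 1L)
}

#' Predict ITD bins with a trained ensemble
#'
#' @param ensemble a [trainClassifier()] result.
#' @param X pattern matrix (patterns x cells), raw rates in Hz.
#' @return integer vector of predicted bin indices.
#' @export
predictBins <- function(ensemble, X) {
  Xs <- scale(X, center = ensemble$center, scale = ensemble$scale)
  D <- Xs %*% t(ensemble$W) -
    matrix(ensemble$rho, nrow(Xs), length(ensemble$rho), byrow = TRUE)
  M <- ensemble$n_bins
  votes <- matrix(0L, nrow(Xs), M)
  score <- matrix(0, nrow(Xs), M)
  for (p in seq_len(nrow(ensemble$pairs))) {
    a <- ensemble$pairs[p, 1]; b <- ensemble$pairs[p, 2]
    va <- D[, p] > 0
    votes[, a] <- votes[, a] + va
    votes[, b] <- votes[, b] + !va
    score[, a] <- score[, a] + D[, p]
    score[, b] <- score[, b] - D[, p]
  }
  vapply(seq_len(nrow(Xs)), function(i) {
    cand <- which(votes[i, ] == max(votes[i, ]))
    if (length(cand) > 1L)
      cand <- cand[score[i, cand] == max(score[i, cand])]
    cand[1]
  }, integer(1))
}

#' Test error of the labelled-line decoder
#'
#' Root-mean-square difference, in microseconds, between the centre of the
#' predicted ITD bin and the true stimulus ITD, over an independent test
#' response set.
#'
#' @param ensemble a [trainClassifier()] result.
#' @param responses test [simulatePopulation()] result (generate with a
#'   fresh seed, disjoint from training).
#' @return list with `rms_us`, `confusion` (true bin x predicted bin
#'   counts) and `n_test`.
#' @export
classifierTestError <- function(ensemble, responses) {
  pat <- responsePatterns(responses)
  if (nrow(pat$X) == 0L) stop("empty test set")
  pred <- predictBins(ensemble, pat$X)
  true_bin <- findInterval(pat$tau, ensemble$bin_edges,
                           rightmost.closed = TRUE, all.inside = TRUE)
  err <- ensemble$bin_centers[pred] - pat$tau
  conf <- table(factor(true_bin, levels = seq_len(ensemble$n_bins)),
                factor(pred, levels = seq_len(ensemble$n_bins)))
  list(rms_us = sqrt(mean(err^2)), confusion = conf, n_test = length(pred))
}

#' Training error of the ensemble on its own training patterns
#'
#' @param ensemble a [trainClassifier()] result.
#' @param responses the training pool the ensemble was drawn from.
#' @return RMS error in microseconds on the training patterns.
#' @export
classifierTrainError <- function(ensemble, responses) {
  pat <- responsePatterns(responses)
  idx <- ensemble$train_idx
  pred <- predictBins(ensemble, pat$X[idx, , drop = FALSE])
  sqrt(mean((ensemble$bin_centers[pred] - pat$tau[idx])^2))
}

#' Decoding acuity as a function of population subset size
#'
#' Cells are ranked by single-cell mutual information; for each subset size
#' the top-ranked cells are kept, the ensemble retrained and the test error
#' recomputed. Saturation size is the smallest subset whose acuity is
#' within 5 percent of the full-population acuity.
#'
#' @param train_responses,test_responses [simulatePopulation()] results on
#'   the same cells and condition grid (different seeds).
#' @param mi_per_cell single-cell MI values (bits), one per cell, as
#'   returned by [mutualInformation()].
#' @param subset_sizes subset sizes to evaluate (each <= number of cells).
#' @param n_bins,n_train,seed passed to [trainClassifier()].
#' @return list with `curve` (data.frame size, rms_us) and
#'   `saturation_size`.
#' @export
subsetAcuity <- function(train_responses, test_responses, mi_per_cell,
                         subset_sizes, n_bins, n_train, seed = 1L) {
  n_cells <- dim(train_responses$rates)[1]
  if (any(subset_sizes > n_cells)) stop("subset larger than population")
  stopifnot(length(mi_per_cell) == n_cells)
  ranking <- order(mi_per_cell, decreasing = TRUE)
  rms <- vapply(subset_sizes, function(k) {
    keep <- ranking[seq_len(k)]
    tr <- subsetResponses(train_responses, keep)
    te <- subsetResponses(test_responses, keep)
    ens <- trainClassifier(tr, n_bins, n_train, seed = seed)
    classifierTestError(ens, te)$rms_us
  }, numeric(1))
  curve <- data.frame(size = subset_sizes, rms_us = rms)
  full <- rms[which.max(subset_sizes)]
  ok <- curve$size[curve$rms_us <= 1.05 * full]
  list(curve = curve, saturation_size = if (length(ok)) min(ok) else NA)
}

subsetResponses <- function(responses, keep) {
  out <- responses
  out$cells <- responses$cells[keep, , drop = FALSE]
  out$rates <- responses$rates[keep, , , drop = FALSE]
  out
}

#' Bilateral hemispheric rate-difference signal
#'
#' Per condition and trial, the mean firing rate across the population in
#' one hemisphere minus the mean rate of the mirrored population in the
#' other hemisphere. In expectation the difference is an odd function of
#' ITD and vanishes at the midline.
#'
#' @param responses [simulatePopulation()] for the cells of one hemisphere.
#' @param mirrored_responses independent [simulatePopulation()] for
#'   [mirrorPopulation()] of the same cells on the identical condition
#'   grid.
#' @return data.frame with `itd_us`, `frequency_hz`, `trial` and the
#'   difference signal `D` in Hz.
#' @export
bilateralDifferenceSignal <- function(responses, mirrored_responses) {
  if (!isTRUE(all.equal(responses$conditions,
                        mirrored_responses$conditions)))
    stop("condition grids differ between hemispheres")
  m1 <- apply(responses$rates, c(2, 3), mean)
  m2 <- apply(mirrored_responses$rates, c(2, 3), mean)
  D <- m1 - m2
  n_trial <- ncol(D)
  data.frame(
    itd_us = rep(responses$conditions$itd_us, n_trial),
    frequency_hz = rep(responses$conditions$frequency_hz, n_trial),
    trial = rep(seq_len(n_trial), each = nrow(responses$conditions)),
    D = as.vector(D))
}

#' Fit the linear ITD estimator on the difference signal
#'
#' Ordinary least squares of the true ITD on the bilateral difference
#' signal, pooled over all stimulus frequencies (the readout is
#' frequency-blind); per-frequency fits are reported for diagnostics.
#'
#' @param diff_signal data.frame from [bilateralDifferenceSignal()].
#' @return object of class `difference_decoder` with `gain` (us per Hz),
#'   `intercept` (us), `r_squared` and `per_frequency` diagnostics.
#' @export
fitDifferenceDecoder <- function(diff_signal) {
  if (stats::sd(diff_signal$D) == 0)
    stop("degenerate difference signal (constant D)")
  r2 <- function(f, y) 1 - sum(stats::resid(f)^2) / sum((y - mean(y))^2)
  fit <- stats::lm(itd_us ~ D, data = diff_signal)
  per_f <- do.call(rbind, lapply(
    split(diff_signal, diff_signal$frequency_hz), function(d) {
      f <- stats::lm(itd_us ~ D, data = d)
      data.frame(frequency_hz = d$frequency_hz[1],
                 gain = unname(stats::coef(f)[2]),
                 r_squared = r2(f, d$itd_us))
    }))
  rownames(per_f) <- NULL
  structure(list(gain = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2(fit, diff_signal$itd_us),
                 per_frequency = per_f),
            class = "difference_decoder")
}

#' @export
print.difference_decoder <- function(x, ...) {
  cat(sprintf(
    "Bilateral difference decoder: tau-hat = %.3f us/Hz * D %+.2f us (R^2 = %.4f)\n",
    x$gain, x$intercept, x$r_squared))
  invisible(x)
}

#' Estimate ITD from a difference signal
#'
#' @param decoder a [fitDifferenceDecoder()].
#' @param D difference-signal values in Hz.
#' @return ITD estimates in microseconds.
#' @export
predictItd <- function(decoder, D) {
  decoder$gain * D + decoder$intercept
}

#' Test error of the bilateral difference decoder
#'
#' @param decoder a [fitDifferenceDecoder()].
#' @param diff_signal independent test data.frame from
#'   [bilateralDifferenceSignal()] (fresh simulation seeds).
#' @return list with `by_frequency` and `by_itd` (data.frames holding RMS
#'   and maximal absolute error in us), plus overall `rms_us` and `max_us`.
#' @export
differenceDecoderError <- function(decoder, diff_signal) {
  if (nrow(diff_signal) == 0L) stop("empty test set")
  err <- predictItd(decoder, diff_signal$D) - diff_signal$itd_us
  agg <- function(key) {
    do.call(rbind, lapply(split(seq_along(err), key), function(i) {
      data.frame(key = key[i[1]], rms_us = sqrt(mean(err[i]^2)),
                 max_us = max(abs(err[i])))
    }))
  }
  by_f <- agg(diff_signal$frequency_hz)
  names(by_f)[1] <- "frequency_hz"
  by_t <- agg(diff_signal$itd_us)
  names(by_t)[1] <- "itd_us"
  rownames(by_f) <- rownames(by_t) <- NULL
  list(by_frequency = by_f, by_itd = by_t,
       rms_us = sqrt(mean(err^2)), max_us = max(abs(err)))
}
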