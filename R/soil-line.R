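# Soil-line analysis: logistic classification of bare-soil pixels into clean
# soil-line pixels versus vegetation-contaminated mixels on the four band
# DNs, and the red-NIR soil line fitted on the clean class.

.asBandMatrix <- function(pixels) {
  if (is.data.frame(pixels)) pixels <- as.matrix(pixels[, .BANDS])
  if (is.null(colnames(pixels))) colnames(pixels) <- .BANDS
  stopifnot(ncol(pixels) == 4L)
  pixels[, .BANDS, drop = FALSE]
}

#' Fit the soil-line logistic classifier
#'
#' Maximum-likelihood logistic regression of the clean/mixel label on the
#' four band DNs, p = 1 / (1 + exp(-(alpha + sum beta_i X_i))), fitted by
#' iteratively reweighted least squares on standardized predictors (zero
#' initial coefficients, tolerance 1e-8 on the coefficient change, at most
#' 100 iterations, 1e-6 ridge jitter on a singular weighted system) and
#' reported on the original DN scale. Complete separation — the expected good
#' case when the two pixel groups are visually distinct — is detected by
#' coefficient-norm divergence and reported rather than treated as failure.
#'
#' @param pixels matrix or data.frame of band DNs with columns green, red,
#'   red_edge, nir (one row per pixel)
#' @param labels 0/1 per pixel; 1 = clean soil-line pixel
#' @param tol,maxIter IRLS stopping controls
#' @return a \linkS4class{SoilLineClassifier}
#' @export
fitLogistic <- function(pixels, labels, tol = 1e-8, maxIter = 100L) {
  X <- .asBandMatrix(pixels)
  yv <- as.numeric(labels)
  if (nrow(X) < 5L) stop("need >= 5 pixels", call. = FALSE)
  if (length(unique(yv)) < 2L)
    stop("both classes must be present", call. = FALSE)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Z <- cbind(1, sweep(sweep(X, 2, ctr), 2, scl, "/"))
  beta <- numeric(5L)
  ll <- -Inf
  llTrace <- numeric()
  separated <- FALSE
  converged <- FALSE
  it <- 0L
  for (it in seq_len(maxIter)) {
    eta <- drop(Z %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    A <- crossprod(Z, Z * w)
    b <- A %*% beta + crossprod(Z, yv - p)
    newBeta <- tryCatch(drop(solve(A, b)), error = function(e)
      drop(solve(A + diag(1e-6, ncol(Z)), b)))
    step <- sqrt(sum((newBeta - beta)^2))
    beta <- newBeta
    ll <- sum(yv * stats::plogis(drop(Z %*% beta), log.p = TRUE) +
              (1 - yv) * stats::plogis(-drop(Z %*% beta), log.p = TRUE))
    llTrace <- c(llTrace, ll)
    if (sqrt(sum(beta^2)) > 1e4) { separated <- TRUE; break }
    if (step < tol) { converged <- TRUE; break }
  }
  if (!converged && !separated) {
    pFinal <- stats::plogis(drop(Z %*% beta))
    if (max(pmin(pFinal, 1 - pFinal)) < 1e-6) separated <- TRUE
  }
  betasOrig <- beta[-1] / scl
  alphaOrig <- beta[1] - sum(betasOrig * ctr)
  names(betasOrig) <- .BANDS
  if (!converged && !separated)
    warning("IRLS did not converge in ", maxIter,
            " iterations; partial result returned")
  new("SoilLineClassifier", alpha = alphaOrig, betas = betasOrig,
      converged = converged, nIter = it, separated = separated,
      logLik = ll, llTrace = llTrace)
}

#' Classify pixels with a fitted soil-line model
#'
#' @param model a \linkS4class{SoilLineClassifier}
#' @param pixels band-DN matrix/data.frame (columns green, red, red_edge,
#'   nir)
#' @param threshold probability cut for the soil-line label (default 0.5)
#' @return data.frame: p (probability of clean soil-line pixel), soil_line
#'   (logical)
#' @export
classifyPixels <- function(model, pixels, threshold = 0.5) {
  X <- .asBandMatrix(pixels)
  p <- stats::plogis(model@alpha + drop(X %*% model@betas))
  data.frame(p = p, soil_line = p >= threshold)
}

#' Provisional clean/mixel labels from soil-line residuals
#'
#' When no training labels are supplied, a provisional red-NIR line is fitted
#' on all pixels and the NIR residuals are split by 2-means (centres
#' initialised at the residual extremes, so the split is deterministic); the
#' lower-residual cluster is labelled clean. These labels seed the logistic
#' refit.
#'
#' @param pixels band-DN matrix/data.frame
#' @return integer 0/1 vector, 1 = clean soil-line pixel
#' @export
provisionalLabels <- function(pixels) {
  X <- .asBandMatrix(pixels)
  fit <- stats::lm(X[, "nir"] ~ X[, "red"])
  res <- stats::residuals(fit)
  km <- stats::kmeans(res, centers = matrix(range(res), 2, 1))
  clean <- which.min(km$centers)
  as.integer(km$cluster == clean)
}

#' Fit the red-NIR soil line on the clean class
#'
#' Ordinary least squares of NIR on red DN over clean bare-soil pixels; the
#' residual RMSE quantifies how tightly the pixels sit on the line.
#'
#' @param red,nir DN vectors of the clean pixels
#' @return a \linkS4class{SoilLine}
#' @export
fitSoilLine <- function(red, nir) {
  stopifnot(length(red) == length(nir))
  if (length(red) < 3L) stop("need >= 3 clean pixels", call. = FALSE)
  if (stats::sd(red) == 0)
    stop("singular fit: red DN is constant", call. = FALSE)
  fit <- stats::lm(nir ~ red)
  new("SoilLine", intercept = unname(stats::coef(fit)[1]),
      slope = unname(stats::coef(fit)[2]),
      rmse = sqrt(mean(stats::residuals(fit)^2)), n = length(red))
}

#' Full soil-line analysis of the bare-soil bands
#'
#' Draws a pixel sample from the band rasters, derives provisional labels
#' (unless given), fits the logistic classifier, classifies every sampled
#' pixel, and fits the soil line on the clean class.
#'
#' @param bands named list of band FieldRasters
#' @param labels optional 0/1 training labels for the sampled pixels
#' @param nPixels number of pixels to sample (all pixels if fewer)
#' @param seed sampling seed
#' @return list: model (\linkS4class{SoilLineClassifier}), soilLine
#'   (\linkS4class{SoilLine}), pixels (data.frame with bands, p, soil_line),
#'   mixelFraction (estimated share of mixels)
#' @export
soilLineAnalysis <- function(bands, labels = NULL, nPixels = 5000,
                             seed = 1) {
  stopifnot(all(.BANDS %in% names(bands)))
  npx <- length(bands$red@values)
  idx <- if (npx > nPixels)
    .withSeed(seed + 505, sample.int(npx, nPixels)) else seq_len(npx)
  X <- vapply(.BANDS, function(b) bands[[b]]@values[idx],
              numeric(length(idx)))
  keep <- stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]
  if (is.null(labels)) labels <- provisionalLabels(X)
  model <- fitLogistic(X, labels)
  cls <- classifyPixels(model, X)
  clean <- cls$soil_line
  line <- fitSoilLine(X[clean, "red"], X[clean, "nir"])
  list(model = model,
       soilLine = line,
       pixels = data.frame(X, p = cls$p, soil_line = cls$soil_line),
       mixelFraction = mean(!clean))
}
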