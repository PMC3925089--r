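## Spectral density at frequency zero, estimated from an autoregressive fit
## with AIC order selection (order bounded by N/20). For an AR(p) fit,
## s(0) = sigma^2 / (1 - sum(phi))^2.
.spectrum0ar <- function(x, maxOrderCap = 50L) {
  n <- length(x)
  if (stats::var(x) == 0) return(0)
  ord <- max(1L, min(as.integer(n / 20), maxOrderCap))
  fit <- tryCatch(stats::ar(x, aic = TRUE, order.max = ord),
                  error = function(e) NULL)
  if (is.null(fit)) return(stats::var(x))
  if (fit$order == 0L) return(fit$var.pred)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Geweke convergence z-scores
#'
#' Compares the mean of an early window of the chain with the mean of a late
#' window, per reaction. Under stationarity
#' \deqn{z = \frac{\bar x_A - \bar x_B}{\sqrt{\hat s_A/N_A + \hat s_B/N_B}}}
#' is approximately standard normal, where \eqn{\hat s} is the spectral
#' density at frequency zero (autoregressive estimate), which accounts for
#' chain autocorrelation. Large |z| flags non-stationarity; the conventional
#' criterion is |z| < 1.96.
#'
#' @param chain N x n matrix (or [FluxSamples-class]), N >= 100.
#' @param fracFirst,fracLast fractions of the chain used for the early and
#'   late windows; defaults 0.1 and 0.5, with
#'   \code{fracFirst + fracLast <= 1}.
#' @return named numeric vector of z-scores with attribute
#'   \code{"degenerate"} marking zero-variance reactions (reported as z = 0).
#' @export
gewekeDiagnostic <- function(chain, fracFirst = 0.1, fracLast = 0.5) {
  m <- .runMatrix(chain)
  N <- nrow(m)
  if (N < 100) stop("chain too short for the Geweke test (N >= 100 required)")
  if (fracFirst + fracLast > 1)
    stop("fracFirst + fracLast must be <= 1 (non-overlapping windows)")
  nA <- floor(fracFirst * N)
  nB <- floor(fracLast * N)
  z <- numeric(ncol(m))
  degenerate <- logical(ncol(m))
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    if (stats::var(x) == 0) {
      z[j] <- 0
      degenerate[j] <- TRUE
      next
    }
    a <- x[seq_len(nA)]
    b <- x[seq.int(N - nB + 1L, N)]
    sA <- .spectrum0ar(a)
    sB <- .spectrum0ar(b)
    denom <- sqrt(sA / nA + sB / nB)
    z[j] <- if (denom == 0) 0 else (mean(a) - mean(b)) / denom
    if (denom == 0) degenerate[j] <- TRUE
  }
  if (is(chain, "FluxSamples")) names(z) <- chain@reactionIds
  attr(z, "degenerate") <- degenerate
  z
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Compares within-chain and between-chain variability over M >= 2 chains of
#' N samples. Per reaction,
#' \deqn{\hat R = \sqrt{\frac{(N-1)/N\, W + B/N}{W}}}
#' with W the mean within-chain variance and B = N times the variance of the
#' chain means. The multivariate statistic generalises the ratio through the
#' largest eigenvalue of \eqn{W^{-1} B/N} on the within/between covariance
#' matrices; because network fluxes are linearly dependent the pooled
#' within-chain covariance is regularised with \code{1e-10 I} before the
#' eigenproblem. Values below 1.2 are conventionally read as convergence,
#' values near 1.0 as better.
#'
#' @param chains list of >= 2 N x n matrices (or [FluxSamples-class]
#'   objects), equal N >= 10.
#' @return list with \code{mpsrf} (scalar multivariate R) and \code{psrf}
#'   (per-reaction R, zero-variance reactions flagged via attribute
#'   \code{"degenerate"} and reported as 1).
#' @export
gelmanRubin <- function(chains) {
  if (length(chains) < 2L)
    stop("the Gelman-Rubin diagnostic needs at least 2 chains")
  mats <- lapply(chains, .runMatrix)
  Ns <- vapply(mats, nrow, integer(1))
  if (length(unique(Ns)) != 1L) stop("chains must have equal length")
  N <- Ns[1]
  if (N < 10) stop("chains too short (N >= 10 required)")
  M <- length(mats)
  n <- ncol(mats[[1]])

  means <- do.call(rbind, lapply(mats, colMeans))      # M x n
  vars <- do.call(rbind, lapply(mats, function(m) apply(m, 2, stats::var)))
  W <- colMeans(vars)
  B <- N * apply(means, 2, stats::var)
  degenerate <- W == 0
  psrf <- rep(1, n)
  ok <- !degenerate
  psrf[ok] <- sqrt(((N - 1) / N * W[ok] + B[ok] / N) / W[ok])
  if (is(chains[[1]], "FluxSamples")) names(psrf) <- chains[[1]]@reactionIds
  attr(psrf, "degenerate") <- degenerate

  Wmat <- Reduce(`+`, lapply(mats, stats::cov)) / M
  Bn <- stats::cov(means)                               # = B-matrix / N
  Wreg <- Wmat + diag(1e-10, n)
  lambda <- tryCatch({
    ev <- eigen(solve(Wreg, Bn), only.values = TRUE)$values
    max(Re(ev))
  }, error = function(e) NA_real_)
  mpsrf <- sqrt((N - 1) / N + lambda)
  list(mpsrf = mpsrf, psrf = psrf)
}

## CDF of the asymptotic Cramer-von Mises distribution (Brownian-bridge
## integral), via the classical Bessel-K series.
.pcramer <- function(q, eps = 1e-5) {
  if (q >= 10) return(1)   # series truncation degrades; CDF is 1 to ~1e-10
  logEps <- log(eps)
  total <- 0
  for (k in 0:3) {
    z <- gamma(k + 0.5) * sqrt(4 * k + 1) / (gamma(k + 1) * pi^1.5 * sqrt(q))
    u <- (4 * k + 1)^2 / (16 * q)
    total <- total + if (u > -logEps) 0 else z * exp(-u) * besselK(u, 0.25)
  }
  total
}

#' Heidelberger-Welch stationarity test
#'
#' Per reaction, tests the null hypothesis that the chain is a stationary
#' sequence using a Cramer-von Mises statistic on the standardised
#' cumulative-sum (Brownian bridge) process, with the spectral density at
#' zero estimated from the second half of the chain. The test is first run
#' on the full chain; on rejection the first 10%, 20%, ... up to 50% of the
#' chain is discarded and the test repeated, passing at the first
#' non-rejected stage. Reactions failing at every stage are reported as
#' non-converged.
#'
#' @param chain N x n matrix (or [FluxSamples-class]), N >= 100.
#' @param alpha significance level of the stationarity test; default 0.05.
#' @return named numeric vector of 0/1 pass indicators with attributes
#'   \code{"startFraction"} (fraction of the chain discarded at the passing
#'   stage; NA on failure), \code{"usableLength"} and \code{"degenerate"}
#'   (zero-variance reactions, reported as failures).
#' @export
heidelbergerWelch <- function(chain, alpha = 0.05) {
  m <- .runMatrix(chain)
  N <- nrow(m)
  if (N < 100)
    stop("chain too short for the Heidelberger-Welch test (N >= 100 required)")
  fracs <- seq(0, 0.5, by = 0.1)
  pass <- numeric(ncol(m))
  startFrac <- rep(NA_real_, ncol(m))
  usable <- rep(NA_integer_, ncol(m))
  degenerate <- logical(ncol(m))
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    if (stats::var(x) == 0) {
      degenerate[j] <- TRUE
      next
    }
    s0 <- .spectrum0ar(x[seq.int(floor(N / 2) + 1L, N)])
    if (s0 <= 0) {
      degenerate[j] <- TRUE
      next
    }
    for (f in fracs) {
      y <- x[seq.int(floor(f * N) + 1L, N)]
      nn <- length(y)
      bridge <- cumsum(y) - mean(y) * seq_len(nn)
      cvm <- sum(bridge^2 / (nn * s0)) / nn
      if (is.finite(cvm) && .pcramer(cvm) < 1 - alpha) {
        pass[j] <- 1
        startFrac[j] <- f
        usable[j] <- nn
        break
      }
    }
  }
  if (is(chain, "FluxSamples")) names(pass) <- chain@reactionIds
  attr(pass, "startFraction") <- startFrac
  attr(pass, "usableLength") <- usable
  attr(pass, "degenerate") <- degenerate
  pass
}

#' Combined convergence diagnostics for a run group
#'
#' Applies the three empirical convergence diagnostics the way they are used
#' to assess flux samplers: Geweke z-scores and Heidelberger-Welch pass
#' indicators are computed per run and averaged across runs, the
#' Gelman-Rubin factors are computed across the runs treated as parallel
#' chains. The three results are reported side by side; no single aggregated
#' verdict is produced because the tests are known to disagree.
#'
#' @param runs list of >= 2 [FluxSamples-class] objects (or matrices) with
#'   equal sample counts.
#' @param alpha Heidelberger-Welch significance level.
#' @return a [DiagnosticsReport-class].
#' @export
convergenceDiagnostics <- function(runs, alpha = 0.05) {
  if (length(runs) < 2L)
    stop("need >= 2 runs (the Gelman-Rubin diagnostic requires them)")
  gw <- Reduce(`+`, lapply(runs, function(r)
    as.numeric(gewekeDiagnostic(r)))) / length(runs)
  hw <- Reduce(`+`, lapply(runs, function(r)
    as.numeric(heidelbergerWelch(r, alpha)))) / length(runs)
  gr <- gelmanRubin(runs)
  rids <- if (is(runs[[1]], "FluxSamples")) runs[[1]]@reactionIds
          else paste0("R", seq_along(gw))
  names(gw) <- rids
  names(hw) <- rids
  psrf <- as.numeric(gr$psrf)
  names(psrf) <- rids
  new("DiagnosticsReport",
      gewekeZ = gw, gelmanR = gr$mpsrf, gelmanRPerReaction = psrf,
      hwPass = hw, hwFraction = mean(hw),
      thresholds = list(R_crit = 1.2, z_crit = 1.96, hw_alpha = alpha))
}
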