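#' FOSS pin ranges retained for methane prediction
#'
#' The informative mid-infrared regions, expressed as 1-based FOSS pin
#' indices: 260-402 (~1,000-1,550 cm-1), 442-472 (~1,705-1,820 cm-1) and
#' 701-767 (~2,700-2,955 cm-1), totalling 241 points. Uninformative
#' regions and the high water-absorption bands fall outside these ranges.
#'
#' @return Integer vector of 241 pin indices.
#' @export
mir_informative_pins <- function() {
  c(260:402, 442:472, 701:767)
}

#' Select the informative spectral points from raw FOSS spectra
#'
#' Extracts the 241 informative pins from full-length (1,060-pin) raw
#' absorbance vectors, preserving order. The selection is a projection:
#' re-applying it to a vector padded back into pin space re-extracts the
#' same values.
#'
#' @param spectra numeric vector (one spectrum) or matrix (rows =
#'   spectra) of at least 767 pins.
#' @return A 241-point vector, or a matrix with 241 columns.
#' @export
select_informative_pins <- function(spectra) {
  pins <- mir_informative_pins()
  if (is.matrix(spectra)) {
    if (ncol(spectra) < max(pins)) {
      stop("raw spectra must have at least ", max(pins), " pins")
    }
    spectra[, pins, drop = FALSE]
  } else {
    if (length(spectra) < max(pins)) {
      stop("raw spectrum must have at least ", max(pins), " pins")
    }
    spectra[pins]
  }
}

scale_nonconstant <- function(x) {
  s <- apply(x, 2, stats::sd)
  s[s == 0 | !is.finite(s)] <- 1
  scale(x, center = TRUE, scale = s)
}

#' Detect homogeneous spectra subsets over time
#'
#' Principal components are computed on the scaled spectra of one
#' laboratory; every component explaining more than `variance_threshold`
#' of the variance is monitored for shifts over time. A shift is declared
#' where the standardized CUSUM of a monitored component's scores (in
#' date order) exceeds `cusum_threshold`; split dates from all monitored
#' components are pooled and define the homogeneous subsets.
#'
#' @param spectra matrix of processed spectra (rows = samples).
#' @param dates sample dates (sortable; one per row).
#' @param variance_threshold minimum explained-variance share for a
#'   component to be monitored (default 1%).
#' @param cusum_threshold standardized CUSUM statistic above which a
#'   changepoint is declared.
#' @param min_segment minimum samples per segment.
#' @return Tibble with `index`, `date`, `subset` (integer label, in date
#'   order).
#' @export
detect_homogeneous_subsets <- function(spectra, dates,
                                       variance_threshold = 0.01,
                                       cusum_threshold = 3,
                                       min_segment = 10) {
  n <- nrow(spectra)
  out <- tibble::tibble(index = seq_len(n), date = dates)
  if (n < 2) {
    warning("fewer than 2 spectra; a single subset is returned")
    out$subset <- 1L
    return(out)
  }
  ord <- order(dates)
  sc <- scale_nonconstant(spectra)
  pc <- stats::prcomp(sc, center = FALSE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  monitored <- which(expl > variance_threshold)
  splits <- integer(0)
  for (comp in monitored) {
    z <- pc$x[ord, comp]
    s <- stats::sd(z)
    if (s == 0) next
    zc <- (z - mean(z)) / s
    cus <- cumsum(zc)
    k <- seq_len(n - 1)
    stat <- abs(cus[k]) / sqrt(n)
    ok <- k >= min_segment & k <= n - min_segment
    if (any(ok) && max(stat[ok]) > cusum_threshold) {
      splits <- c(splits, k[ok][which.max(stat[ok])])
    }
  }
  subset_ord <- integer(n)
  bounds <- sort(unique(splits))
  lab <- 1L
  prev <- 0L
  for (b in c(bounds, n)) {
    subset_ord[(prev + 1L):b] <- lab
    lab <- lab + 1L
    prev <- b
  }
  out$subset <- subset_ord[order(ord)]
  out
}

#' Standardize a spectra subset to reference statistics
#'
#' Per-pin affine alignment: each pin of the subset is mapped so its mean
#' and standard deviation equal those of the reference laboratory/period
#' (`slope = sd_ref / sd_subset`, `offset = mean_ref - slope *
#' mean_subset`). Pins with zero variance in the subset get an offset-only
#' map with a warning. The applied map is returned for audit.
#'
#' @param spectra subset spectra matrix (rows = samples).
#' @param reference reference spectra matrix, or a list with `mean` and
#'   `sd` vectors per pin.
#' @return List with `spectra` (standardized matrix) and `map` (tibble:
#'   `pin`, `slope`, `offset`).
#' @export
standardize_subset <- function(spectra, reference) {
  if (is.list(reference) && !is.data.frame(reference)) {
    m_ref <- reference$mean; s_ref <- reference$sd
  } else {
    m_ref <- colMeans(reference)
    s_ref <- apply(reference, 2, stats::sd)
  }
  m_sub <- colMeans(spectra)
  s_sub <- apply(spectra, 2, stats::sd)
  zero <- s_sub == 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance pin(s): offset-only map applied")
  }
  slope <- ifelse(zero, 1, s_ref / s_sub)
  offset <- m_ref - slope * m_sub
  std <- sweep(sweep(spectra, 2, slope, `*`), 2, offset, `+`)
  list(spectra = std,
       map = tibble::tibble(pin = seq_along(slope), slope = slope,
                            offset = offset))
}

pseudo_solve <- function(S, tol = 1e-10) {
  sv <- svd(S)
  pos <- sv$d > tol * max(sv$d)
  sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
}

#' Mahalanobis-distance quality control of spectra
#'
#' Squared Mahalanobis distances are computed in the score space of the
#' principal components explaining more than `variance_threshold` of the
#' variance; a spectrum is flagged when its squared distance exceeds the
#' chi-squared quantile at `p_threshold` with degrees of freedom equal to
#' the number of retained components.
#'
#' @param spectra matrix of spectra (rows = samples).
#' @param p_threshold chi-squared tail probability for flagging (default
#'   0.001).
#' @param variance_threshold explained-variance share for retaining a
#'   component.
#' @return Tibble with `index`, `distance2`, `df`, `qc_pass`.
#' @export
mahalanobis_qc <- function(spectra, p_threshold = 0.001,
                           variance_threshold = 0.01) {
  sc <- scale_nonconstant(spectra)
  pc <- stats::prcomp(sc, center = FALSE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  keep <- which(expl > variance_threshold)
  if (length(keep) == 0) keep <- 1L
  scores <- pc$x[, keep, drop = FALSE]
  S <- stats::cov(scores)
  Sinv <- tryCatch(solve(S), error = function(e) {
    warning("singular score covariance; using a pseudo-inverse")
    pseudo_solve(S)
  })
  ctr <- colMeans(scores)
  d2 <- stats::mahalanobis(scores, center = ctr, cov = Sinv, inverted = TRUE)
  cutoff <- stats::qchisq(1 - p_threshold, df = length(keep))
  tibble::tibble(index = seq_len(nrow(spectra)), distance2 = d2,
                 df = length(keep), qc_pass = d2 <= cutoff)
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing with a third-order polynomial
#' and filter width 11 by default, applied per spectrum. Interior points
#' reproduce any polynomial of degree up to the order exactly; edges use
#' the off-center rows of the projection matrix (a full-window polynomial
#' fit evaluated at the edge positions).
#'
#' @param spectra numeric vector or matrix (rows = spectra).
#' @param order polynomial order.
#' @param width odd filter width, greater than `order`.
#' @return Smoothed vector or matrix of the same shape.
#' @export
savitzky_golay <- function(spectra, order = 3, width = 11) {
  if (width %% 2 == 0 || width <= order) {
    stop("filter width must be odd and greater than the polynomial order")
  }
  one <- function(x) {
    if (length(x) < width) stop("spectrum shorter than the filter width")
    as.numeric(signal::sgolayfilt(x, p = order, n = width))
  }
  if (is.matrix(spectra)) {
    t(apply(spectra, 1, one))
  } else {
    one(spectra)
  }
}
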