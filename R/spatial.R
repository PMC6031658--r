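#' Spectral band of interest
#'
#' @param center center frequency, Hz.
#' @param half_width half width, Hz (band = center +/- half_width).
#' @return A list of class `spectral_band`.
#' @export
spectral_band <- function(center = 10, half_width = 3) {
  if (center - half_width <= 0)
    stop("spectral_band: band must stay above 0 Hz")
  structure(list(center = center, half_width = half_width,
                 low = center - half_width, high = center + half_width),
            class = "spectral_band")
}

# mean periodogram power of an epoch_set in [lo, hi) Hz, per channel,
# averaged over epochs
band_power <- function(epochs, lo, hi) {
  d <- epochs$data
  n <- dim(d)[3L]
  f <- (seq_len(n) - 1L) * epochs$sfreq / n
  sel <- which(f >= lo & f < hi & f <= epochs$sfreq / 2)
  pw <- matrix(0, dim(d)[1L], dim(d)[2L])
  for (e in seq_len(dim(d)[1L])) {
    X <- stats::mvfft(t(d[e, , , drop = TRUE]))
    pw[e, ] <- colMeans(abs(X[sel, , drop = FALSE])^2)
  }
  colMeans(pw)
}

#' Select the reactive frequency band from rest vs. active power
#'
#' Scans 1-Hz bins centred on 8..30 Hz, computes the relative decrease
#' (rest - active) / rest of the channel-averaged band power, and returns
#' the bin with the largest decrease as `center +/- 3 Hz`. Averaging power
#' over channels before forming the ratio keeps channels that carry no
#' signal from flooding the estimate with noise. If no bin shows a decrease
#' the canonical mu band 10 +/- 3 Hz is returned with a warning.
#'
#' @param rest,active two [epoch_set()]s sharing channels and sampling rate.
#' @param half_width band half width, Hz.
#' @return A [spectral_band()].
#' @export
select_band <- function(rest, active, half_width = 3) {
  stopifnot(rest$sfreq == active$sfreq,
            dim(rest$data)[2L] == dim(active$data)[2L])
  centers <- 8:30
  dec <- vapply(centers, function(fc) {
    pr <- mean(band_power(rest, fc - 0.5, fc + 0.5))
    pa <- mean(band_power(active, fc - 0.5, fc + 0.5))
    (pr - pa) / max(pr, .Machine$double.eps)
  }, numeric(1))
  if (all(dec <= 0)) {
    warning("select_band: no power decrease found in 8-30 Hz; using default 10 +/- 3 Hz")
    return(spectral_band(10, half_width))
  }
  spectral_band(centers[which.max(dec)], half_width)
}

# trace-normalized average of per-epoch sample covariances; optionally on a
# subset of epochs. Data enter as epochs x channels x samples.
epoch_covariance <- function(data, idx = seq_len(dim(data)[1L])) {
  C <- dim(data)[2L]
  acc <- matrix(0, C, C)
  for (e in idx) {
    x <- data[e, , , drop = TRUE]
    cc <- tcrossprod(x) / ncol(x)
    tr <- sum(diag(cc))
    if (tr > 0) acc <- acc + cc / tr
  }
  acc / length(idx)
}

# symmetric whitening W s.t. W' A W = I; rank-deficient A gets a logged
# shrinkage ridge
whitener <- function(A, tol = 1e-10) {
  eg <- eigen((A + t(A)) / 2, symmetric = TRUE)
  lam <- eg$values
  if (min(lam) < tol * max(lam)) {
    log_msg("whitener: rank-deficient covariance, applying shrinkage ridge")
    lam <- lam + max(lam) * 1e-8
  }
  eg$vectors %*% diag(1 / sqrt(lam), length(lam))
}

# inverse of a symmetric Gram matrix with a tiny ridge so that patterns of
# numerically degenerate (zero-power) components stay finite
ridged_inverse <- function(G, rel = 1e-10) {
  solve(G + diag(nrow(G)) * rel * max(mean(abs(diag(G))), .Machine$double.xmin))
}

new_spatial_filter <- function(kind, filters, patterns, eigenvalues, band = NULL) {
  structure(list(kind = kind, filters = filters, patterns = patterns,
                 eigenvalues = eigenvalues,
                 n_components = ncol(filters), band = band),
            class = "spatial_filter")
}

#' @export
print.spatial_filter <- function(x, ...) {
  cat(sprintf("<spatial_filter> %s: %d x %d, eigenvalues [%s]\n", x$kind,
              nrow(x$filters), x$n_components,
              paste(sprintf("%.3f", x$eigenvalues), collapse = ", ")))
  invisible(x)
}

#' Spatio-spectral decomposition (SSD)
#'
#' Finds spatial filters maximizing power in the signal band against the
#' flanking bands, by the generalized eigenproblem of the band-filtered
#' covariance versus the flanking-band covariance. Flanking bands are the
#' 2-Hz strips directly below and above the signal band. Components are
#' ordered by descending eigenvalue (in-band to flank power ratio) and the
#' top `n_keep` retained.
#'
#' @param epochs a broadband [epoch_set()].
#' @param band a [spectral_band()].
#' @param n_keep number of components to retain (at most the channel count).
#' @return A `spatial_filter` of kind `"SSD"`.
#' @export
fit_ssd <- function(epochs, band = spectral_band(10, 3), n_keep = 20L) {
  C <- dim(epochs$data)[2L]
  if (n_keep > C) stop("fit_ssd: n_keep exceeds channel count")
  sig <- bandpass(epochs, c(band$low, band$high))
  lo_edge <- max(band$low - 2, 0.5)
  flank_lo <- bandpass(epochs, c(lo_edge, band$low))
  flank_hi <- bandpass(epochs, c(band$high, band$high + 2))
  Cs <- epoch_covariance(sig$data)
  Cn <- (epoch_covariance(flank_lo$data) + epoch_covariance(flank_hi$data)) / 2
  W <- whitener(Cn)
  eg <- eigen(t(W) %*% Cs %*% W, symmetric = TRUE)
  keep <- seq_len(n_keep)
  filters <- (W %*% eg$vectors)[, keep, drop = FALSE]
  patterns <- Cs %*% filters %*% ridged_inverse(t(filters) %*% Cs %*% filters)
  new_spatial_filter("SSD", filters, patterns, eg$values[keep], band)
}

#' Common spatial patterns (CSP)
#'
#' Solves the generalized eigenproblem of the class `+1` covariance against
#' the summed class covariance: eigenvalues lie in `[0, 1]` and measure the
#' class `+1` share of variance in each component. `n_components / 2`
#' filters are taken from each end of the spectrum (most left-lateralized
#' and most right-lateralized variance ratios). The filters `W` satisfy the
#' whitening identity `W' (C1 + C2) W = I`.
#'
#' @param x an [epoch_set()], or a 3D array `epochs x dims x samples` of
#'   already-projected data (e.g. SSD components).
#' @param labels per-epoch labels in `{+1, -1}`; taken from `x` when it is
#'   an [epoch_set()].
#' @param n_components even number of components to extract.
#' @return A `spatial_filter` of kind `"CSP"`; `eigenvalues` are stored in
#'   selection order (high end first, then low end).
#' @export
fit_csp <- function(x, labels = NULL, n_components = 10L) {
  if (inherits(x, "epoch_set")) {
    labels <- labels %||% x$labels
    x <- x$data
  }
  if (is.null(labels)) stop("fit_csp: labels required for array input")
  if (length(unique(labels)) < 2L)
    stop("fit_csp: both classes must be present")
  if (n_components %% 2L != 0L) stop("fit_csp: n_components must be even")
  C <- dim(x)[2L]
  if (n_components > C) stop("fit_csp: n_components exceeds dimension")
  C1 <- epoch_covariance(x, which(labels == 1L))
  C2 <- epoch_covariance(x, which(labels == -1L))
  csp_from_covariances(C1, C2, n_components)
}

# shared GEVD core: filters of C1 against C1 + C2, both-ends selection
csp_from_covariances <- function(C1, C2, n_components) {
  W <- whitener(C1 + C2)
  eg <- eigen(t(W) %*% C1 %*% W, symmetric = TRUE)   # descending eigenvalues
  C <- ncol(W)
  half <- n_components / 2
  sel <- c(seq_len(half), seq(C, by = -1L, length.out = half))
  filters <- (W %*% eg$vectors)[, sel, drop = FALSE]
  Ctot <- C1 + C2
  patterns <- Ctot %*% filters %*% ridged_inverse(t(filters) %*% Ctot %*% filters)
  new_spatial_filter("CSP", filters, patterns, eg$values[sel])
}

#' Log band-power features from SSD + CSP projections
#'
#' Projects each epoch through the SSD filters (if given) and then the CSP
#' filters, computes per component the time-averaged squared amplitude
#' (variance proxy) and takes the natural log. A numerical floor guards
#' zero-variance components.
#'
#' @param epochs an [epoch_set()] (band-filtered as appropriate).
#' @param csp a CSP `spatial_filter`.
#' @param ssd optional SSD `spatial_filter` applied before CSP.
#' @return A `feature_matrix`: list with `values` (epochs x components),
#'   `labels`, `subject_id`, `feature_kind`.
#' @export
csp_logpower_features <- function(epochs, csp, ssd = NULL) {
  proj <- t(csp$filters)
  if (!is.null(ssd)) proj <- proj %*% t(ssd$filters)
  d <- epochs$data
  vals <- matrix(0, dim(d)[1L], nrow(proj))
  floor_hit <- FALSE
  for (e in seq_len(dim(d)[1L])) {
    z <- proj %*% d[e, , , drop = TRUE]
    pw <- rowMeans(z^2)
    if (any(pw < 1e-300)) floor_hit <- TRUE
    vals[e, ] <- log(pmax(pw, 1e-300))
  }
  if (floor_hit)
    log_msg("csp_logpower_features: zero-variance component floored")
  feature_matrix(vals, epochs$labels, epochs$subject_id, "csp_logpower")
}

#' @rdname csp_logpower_features
#' @param values numeric matrix, samples x features.
#' @param labels per-sample class labels.
#' @param subject_id subject identifier.
#' @param feature_kind `"csp_logpower"` or `"flattened_timecourse"`.
#' @export
feature_matrix <- function(values, labels, subject_id = NA_integer_,
                           feature_kind = "csp_logpower") {
  stopifnot(nrow(values) == length(labels), all(is.finite(values)))
  structure(list(values = values, labels = labels,
                 subject_id = subject_id, feature_kind = feature_kind),
            class = "feature_matrix")
}
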