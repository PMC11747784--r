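hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n)

#' One-sided periodogram of a single segment
#'
#' With `scaling = "density"` (default) the standard windowed density
#' estimator is returned: `|X(k)|^2 / (fs * sum(w^2))` with interior bins
#' doubled, so units are genuinely microvolts^2/Hz. `scaling = "raw"` gives
#' the unscaled textbook form `|X(k)|^2 / M` (no window correction, no
#' doubling).
#'
#' @param x Numeric vector of M >= 2 samples.
#' @param fs Sampling rate, Hz.
#' @param window `"hann"` or `"rectangular"`.
#' @param detrend Subtract the segment mean before windowing (default
#'   `TRUE`; prevents DC leakage into the low bins).
#' @param scaling `"density"` or `"raw"` (see Details).
#' @return A list with `freqs` (Hz, length `floor(M/2) + 1`) and `psd`.
#' @export
periodogram_segment <- function(x, fs, window = c("hann", "rectangular"),
                                detrend = TRUE,
                                scaling = c("density", "raw")) {
  window <- match.arg(window)
  scaling <- match.arg(scaling)
  m <- length(x)
  if (m < 2L) stop("segment must contain at least 2 samples", call. = FALSE)
  w <- if (window == "hann") hann_window(m) else rep(1, m)
  if (detrend) x <- x - mean(x)
  X <- stats::fft(x * w)
  half <- seq_len(m %/% 2 + 1L)
  p <- Mod(X[half])^2
  if (scaling == "density") {
    p <- p / (fs * sum(w^2))
    interior <- half > 1 & (half < m %/% 2 + 1L | m %% 2 == 1L)
    p[interior] <- 2 * p[interior]
  } else {
    p <- p / m
  }
  list(freqs = (half - 1) * fs / m, psd = p)
}

#' Welch power spectral density estimate
#'
#' Averages one-sided periodograms of `nperseg`-sample segments taken at
#' `overlap` fractional overlap (Hann window by default). At the study
#' defaults — 2,500-sample trials, 250-sample segments, 50% overlap — this
#' yields 19 segments and a 1 Hz bin spacing, so the 15 and 18 Hz targets
#' fall exactly on bins.
#'
#' @param x Numeric vector, or a channels x samples matrix (one estimate per
#'   row).
#' @param fs Sampling rate, Hz.
#' @param nperseg Samples per segment (L).
#' @param overlap Fractional overlap in `[0, 1)`.
#' @inheritParams periodogram_segment
#' @return An object of class `eeg_psd`: `freqs` (Hz), `psd` (channels x
#'   bins matrix, microvolts^2/Hz), `nperseg`, `n_segments`, `window`, `fs`,
#'   `channel_names`.
#' @export
#'
#' @examples
#' x <- sin(2 * pi * 15 * seq(0, 10, by = 1 / 250))
#' spec <- welch_psd(x, fs = 250)
#' spec$freqs[which.max(spec$psd[1, ])]
welch_psd <- function(x, fs, nperseg = 250, overlap = 0.5,
                      window = c("hann", "rectangular"), detrend = TRUE,
                      scaling = c("density", "raw")) {
  window <- match.arg(window)
  scaling <- match.arg(scaling)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  len <- ncol(x)
  if (nperseg > len) {
    stop("`nperseg` (", nperseg, ") exceeds the signal length (", len, ")",
         call. = FALSE)
  }
  step <- nperseg * (1 - overlap)
  if (step <= 0) stop("`overlap` must be below 1", call. = FALSE)
  starts <- round(seq(0, len - nperseg, by = step))
  n_seg <- length(starts)
  psd <- NULL
  for (ch in seq_len(nrow(x))) {
    acc <- 0
    for (s0 in starts) {
      pg <- periodogram_segment(x[ch, (s0 + 1):(s0 + nperseg)], fs,
                                window = window, detrend = detrend,
                                scaling = scaling)
      acc <- acc + pg$psd
    }
    if (is.null(psd)) psd <- matrix(0, nrow(x), length(acc))
    psd[ch, ] <- acc / n_seg
  }
  structure(list(freqs = (seq_len(nperseg %/% 2 + 1L) - 1) * fs / nperseg,
                 psd = psd, nperseg = nperseg, n_segments = n_seg,
                 window = window, fs = fs,
                 channel_names = rownames(x) %||% paste0("ch", seq_len(nrow(x)))),
            class = "eeg_psd")
}

#' @export
print.eeg_psd <- function(x, ...) {
  cat("<eeg_psd> ", nrow(x$psd), " channel(s), ", length(x$freqs),
      " bins (", x$freqs[1], "-", x$freqs[length(x$freqs)], " Hz, ",
      x$freqs[2] - x$freqs[1], " Hz spacing), ", x$n_segments,
      " Welch segment(s), ", x$window, " window\n", sep = "")
  invisible(x)
}

#' Read a PSD value at (nearest bin to) a frequency
#'
#' @param spec An `eeg_psd` from [welch_psd()].
#' @param f Frequency, Hz; must lie within the spectrum's range. Ties
#'   between bins break toward the lower frequency.
#' @param channel Channel index or name (default 1).
#' @return PSD at the nearest bin, microvolts^2/Hz.
#' @export
psd_feature <- function(spec, f, channel = 1L) {
  rng <- range(spec$freqs)
  if (f < rng[1] || f > rng[2]) {
    stop("frequency ", f, " Hz outside the spectrum range [",
         rng[1], ", ", rng[2], "] Hz", call. = FALSE)
  }
  if (is.character(channel)) channel <- match(channel, spec$channel_names)
  spec$psd[channel, which.min(abs(spec$freqs - f))]
}

#' Harmonic sine/cosine reference bank for SSVEP decoding
#'
#' Builds the 2H-row reference set for candidate frequency `f`: rows
#' `sin(2*pi*h*f*t)`, `cos(2*pi*h*f*t)` for harmonics `h = 1..H`, sampled at
#' `t = m / fs`, `m = 0..n-1`.
#'
#' @param f Candidate stimulation frequency, Hz.
#' @param H Number of harmonics (3 captures the strongest SSVEP components;
#'   higher harmonics mostly add noise).
#' @param fs Sampling rate, Hz.
#' @param n Number of samples.
#' @return An object of class `ssvep_reference` with fields `frequency`,
#'   `n_harmonics`, `fs` and `matrix` (2H x n).
#' @export
build_reference <- function(f, H = 3, fs = 250, n = 2500) {
  for (h in seq_len(H)) {
    if (h * f >= fs / 2) {
      stop("harmonic ", h, " (", h * f, " Hz) is at or above Nyquist (",
           fs / 2, " Hz)", call. = FALSE)
    }
  }
  t <- (seq_len(n) - 1) / fs
  mat <- matrix(0, 2 * H, n)
  for (h in seq_len(H)) {
    mat[2 * h - 1, ] <- sin(2 * pi * h * f * t)
    mat[2 * h, ] <- cos(2 * pi * h * f * t)
  }
  rownames(mat) <- paste0(rep(c("sin", "cos"), H), rep(seq_len(H), each = 2))
  structure(list(frequency = f, n_harmonics = H, fs = fs, matrix = mat),
            class = "ssvep_reference")
}

#' Maximum canonical correlation with a harmonic reference set
#'
#' For a single channel the maximum canonical correlation with the reference
#' bank reduces to the multiple correlation coefficient of the centered
#' signal on the centered reference rows; it is computed from the
#' reference-side normal equations with a small ridge (`1e-10` relative) on
#' the Gram matrix for stability. For a channels x samples matrix the full
#' multivariate CCA is solved via orthonormal bases and the leading singular
#' value. Only the largest coefficient is returned, matching how SSVEP
#' decoding uses CCA.
#'
#' @param x Numeric vector (one channel) or channels x samples matrix.
#' @param ref An [build_reference()] object (or a 2H x n matrix).
#' @return The maximum canonical correlation, in `[0, 1]`. Invariant to
#'   affine rescaling of `x`.
#' @export
cca_max_correlation <- function(x, ref) {
  Y <- if (inherits(ref, "ssvep_reference")) ref$matrix else ref
  if (is.matrix(x) && nrow(x) > 1L) {
    if (ncol(x) != ncol(Y)) stop("length mismatch with reference",
                                 call. = FALSE)
    Xc <- t(x) - rep(rowMeans(x), each = ncol(x))
    Yc <- t(Y) - rep(rowMeans(Y), each = ncol(Y))
    qx <- qr.Q(qr(Xc))
    qy <- qr.Q(qr(Yc))
    return(min(1, max(0, svd(crossprod(qx, qy))$d[1])))
  }
  x <- as.numeric(x)
  if (length(x) != ncol(Y)) stop("length mismatch with reference",
                                 call. = FALSE)
  xc <- x - mean(x)
  ss_tot <- sum(xc^2)
  if (ss_tot == 0) {
    stop("correlation undefined for a constant signal", call. = FALSE)
  }
  Yc <- Y - rowMeans(Y)
  G <- tcrossprod(Yc)                      # 2H x 2H Gram matrix
  ridge <- 1e-10 * mean(diag(G))
  if (rcond(G) < 1e-12) {
    warning("rank-deficient reference Gram matrix; ridge-regularized solve",
            call. = FALSE)
  }
  beta <- solve(G + diag(ridge, nrow(G)), Yc %*% xc)
  fitted <- drop(crossprod(Yc, beta))
  rho2 <- sum(fitted * xc) / ss_tot
  sqrt(min(1, max(0, rho2)))
}

canonical_feature_names <- function(channels = c("O1", "O2", "Pz", "Cz"),
                                    freqs = c(15, 18)) {
  c(paste0("psd_", rep(channels, times = length(freqs)), "_",
           rep(freqs, each = length(channels))),
    paste0("cca_", rep(channels, times = length(freqs)), "_",
           rep(freqs, each = length(channels))))
}

# Average the per-session averaged segments belonging to one target
# frequency; avgs is the `averages` tibble from preprocess_recording().
group_average_by_target <- function(avgs, plans) {
  merged <- dplyr::left_join(avgs, plans[, c("session_id", "target_frequency")],
                             by = "session_id")
  merged |>
    dplyr::group_by(.data$target_frequency) |>
    dplyr::summarise(
      data = list(Reduce(`+`, .data$data) / length(.data$data)),
      fs = .data$fs[1], .groups = "drop")
}

#' Assemble the 16-entry PSD + CCA feature vector for one subject
#'
#' The canonical feature order is: PSD at 15 Hz for O1, O2, Pz, Cz; PSD at
#' 18 Hz for the same channels; then the CCA coefficients in the same
#' channel-within-frequency order (16 values: 4 channels x 2 frequencies x
#' {PSD, CCA}). Features indexed by frequency `f` are computed from the
#' average of the session averages whose *target* frequency is `f`, which is
#' the grouping that separates the conditions (a grand average over all
#' sessions is symmetric between them — see the package vignette). PSD
#' entries come from [welch_psd()] + [psd_feature()]; CCA entries from
#' [cca_max_correlation()] with an H-harmonic reference.
#'
#' @param averages The `averages` tibble from [preprocess_recording()] (one
#'   averaged stimulation segment per session).
#' @param plans Session plans (for the session-to-target-frequency map).
#' @param channels Channel names, all of which must be present.
#' @param freqs The two candidate frequencies, Hz.
#' @param H Harmonics in the CCA reference.
#' @param nperseg,overlap Welch parameters.
#' @return A one-row tibble with the 16 canonical feature columns.
#' @export
extract_feature_vector <- function(averages, plans = default_session_plans(),
                                   channels = c("O1", "O2", "Pz", "Cz"),
                                   freqs = c(15, 18), H = 3,
                                   nperseg = 250, overlap = 0.5) {
  groups <- group_average_by_target(averages, plans)
  ch_names <- rownames(groups$data[[1]])
  missing <- setdiff(channels, ch_names)
  if (length(missing)) {
    stop("missing channel(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  psd_vals <- c()
  cca_vals <- c()
  for (f in freqs) {
    gi <- match(f, groups$target_frequency)
    if (is.na(gi)) stop("no sessions with target frequency ", f, call. = FALSE)
    m <- groups$data[[gi]][channels, , drop = FALSE]
    fs <- groups$fs[gi]
    spec <- welch_psd(m, fs, nperseg = nperseg, overlap = overlap)
    ref <- build_reference(f, H = H, fs = fs, n = ncol(m))
    psd_vals <- c(psd_vals,
                  vapply(channels, function(ch) psd_feature(spec, f, ch),
                         numeric(1)))
    cca_vals <- c(cca_vals,
                  vapply(channels,
                         function(ch) cca_max_correlation(m[ch, ], ref),
                         numeric(1)))
  }
  out <- tibble::as_tibble(as.list(stats::setNames(
    c(psd_vals, cca_vals), canonical_feature_names(channels, freqs))))
  out
}

#' Extract a feature matrix for a set of preprocessed subjects
#'
#' `mode = "combined"` gives the 16-feature-per-subject matrix used for
#' classification. `mode = "per_frequency"` instead emits, for each target
#' frequency, the 8 features (4 channels x {PSD, CCA}) evaluated at that
#' frequency on its own session group, with a `target_frequency` column —
#' mirroring separate per-frequency analyses.
#'
#' @param preprocessed A named list (names = subject ids) of
#'   [preprocess_recording()] results, or a cohort tibble from
#'   [simulate_cohort()] whose recordings are preprocessed internally.
#' @param labels Optional character vector of class labels aligned with the
#'   subjects (taken from the cohort tibble when available).
#' @param mode `"combined"` or `"per_frequency"`.
#' @inheritParams extract_feature_vector
#' @param ... Passed to [preprocess_recording()] when `preprocessed` is a
#'   cohort tibble.
#' @return A tibble with `subject_id`, `label`, and feature columns (16 for
#'   combined; 8 plus `target_frequency` for per-frequency).
#' @export
extract_features <- function(preprocessed, plans = default_session_plans(),
                             labels = NULL,
                             mode = c("combined", "per_frequency"),
                             channels = c("O1", "O2", "Pz", "Cz"),
                             freqs = c(15, 18), H = 3,
                             nperseg = 250, overlap = 0.5, ...) {
  mode <- match.arg(mode)
  if (tibble::is_tibble(preprocessed) && "recording" %in% names(preprocessed)) {
    labels <- labels %||% preprocessed$condition
    ids <- preprocessed$subject_id
    preprocessed <- purrr::map(preprocessed$recording,
                               preprocess_recording, ...)
    names(preprocessed) <- ids
  }
  ids <- names(preprocessed) %||% sprintf("S%02d", seq_along(preprocessed))
  labels <- labels %||% rep(NA_character_, length(preprocessed))
  rows <- purrr::map(seq_along(preprocessed), function(i) {
    avgs <- preprocessed[[i]]$averages
    if (mode == "combined") {
      fv <- extract_feature_vector(avgs, plans, channels, freqs, H,
                                   nperseg, overlap)
      dplyr::bind_cols(tibble::tibble(subject_id = ids[i], label = labels[i]),
                       fv)
    } else {
      groups <- group_average_by_target(avgs, plans)
      purrr::map(freqs, function(f) {
        gi <- match(f, groups$target_frequency)
        m <- groups$data[[gi]][channels, , drop = FALSE]
        fs <- groups$fs[gi]
        spec <- welch_psd(m, fs, nperseg = nperseg, overlap = overlap)
        ref <- build_reference(f, H = H, fs = fs, n = ncol(m))
        vals <- c(vapply(channels, function(ch) psd_feature(spec, f, ch),
                         numeric(1)),
                  vapply(channels,
                         function(ch) cca_max_correlation(m[ch, ], ref),
                         numeric(1)))
        names(vals) <- c(paste0("psd_", channels), paste0("cca_", channels))
        dplyr::bind_cols(
          tibble::tibble(subject_id = ids[i], label = labels[i],
                         target_frequency = f),
          tibble::as_tibble(as.list(vals)))
      }) |> dplyr::bind_rows()
    }
  })
  dplyr::bind_rows(rows)
}

#' Group PSD ratio (normal / CVD)
#'
#' Mean PSD of the normal-vision group over a frequency band divided by that
#' of the CVD group: ratios above 1 signify higher power in normal-vision
#' subjects, below 1 higher power in CVD subjects. With 15 Hz-target
#' sessions, the expected pattern is a ratio above 1 in the 14-16 Hz band
#' and below 1 in the 17-19 Hz band.
#'
#' @param spec_normal,spec_cvd `eeg_psd` objects on the same frequency grid
#'   (group-averaged spectra).
#' @param band Length-2 numeric, band edges in Hz (inclusive).
#' @return The unitless PSD ratio.
#' @export
psd_group_ratio <- function(spec_normal, spec_cvd, band) {
  if (!isTRUE(all.equal(spec_normal$freqs, spec_cvd$freqs))) {
    stop("spectra must share one frequency grid", call. = FALSE)
  }
  sel <- spec_normal$freqs >= band[1] & spec_normal$freqs <= band[2]
  if (!any(sel)) stop("empty band", call. = FALSE)
  num <- mean(spec_normal$psd[, sel])
  den <- mean(spec_cvd$psd[, sel])
  if (den == 0) stop("zero denominator: CVD group PSD is zero in the band",
                     call. = FALSE)
  num / den
}
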