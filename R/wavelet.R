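#' Orthonormal filters for the Daubechies-4 wavelet
#'
#' Scaling (lowpass) filter with 4 vanishing moments (8 taps, sum sqrt(2))
#' and its conjugate quadrature mirror highpass. These are the analysis
#' filters of the periodized, orthogonal packet transform used throughout.
#'
#' @return List with elements `h` (lowpass) and `g` (highpass).
#' @keywords internal
db4_filters <- function() {
  h <- c(0.230377813308855230, 0.714846570552541500,
         0.630880767929590400, -0.027983769416983850,
         -0.187034811718881140, 0.030841381835986965,
         0.032883011666982945, -0.010597401784997278)
  g <- rev(h) * (-1)^(seq_along(h) - 1)
  list(h = h, g = g)
}

# One periodized analysis step: correlate x with filter f and keep every
# second output. Circular indexing keeps the transform orthogonal at any
# even length.
wpt_analysis_step <- function(x, f) {
  n <- length(x)
  k <- n %/% 2L
  idx0 <- 2L * (0:(k - 1L))
  out <- numeric(k)
  for (m in seq_along(f)) {
    out <- out + f[m] * x[(idx0 + (m - 1L)) %% n + 1L]
  }
  out
}

# Adjoint (= inverse, by orthogonality) of one analysis step for an
# approximation/detail pair.
wpt_synthesis_step <- function(a, d, filters) {
  k <- length(a)
  n <- 2L * k
  x <- numeric(n)
  idx0 <- 2L * (0:(k - 1L))
  for (m in seq_along(filters$h)) {
    pos <- (idx0 + (m - 1L)) %% n + 1L
    x[pos] <- x[pos] + a * filters$h[m] + d * filters$g[m]
  }
  x
}

# Natural (Paley) index of the node holding frequency-ordered index f at a
# given level: the binary-reflected Gray code of f. The frequency content
# of packet children flips in every highpass branch, and the Gray code is
# exactly the bookkeeping that undoes the flips.
natural_from_freq <- function(f) {
  bitwXor(f, f %/% 2L)
}

freq_from_natural <- function(n) {
  f <- 0L
  while (n > 0L) {
    f <- bitwXor(f, n)
    n <- n %/% 2L
  }
  f
}

#' Level-5 discrete wavelet packet decomposition
#'
#' Recursively splits both the approximation and detail branches with the
#' db4 conjugate-mirror pair, giving the full binary tree of sub-band
#' packets down to `max_level`. Periodized (circular) convolution keeps the
#' transform orthogonal, so coefficient energy equals signal energy at
#' every level (Parseval). Nodes are addressable by frequency-ordered
#' index; the band of frequency index i at level L spans
#' `[(fs/2) * i / 2^L, (fs/2) * (i+1) / 2^L)` Hz.
#'
#' @param x Numeric signal; its length must be divisible by `2^max_level`
#'   and at least `2^max_level`.
#' @param fs Sampling rate in Hz.
#' @param wavelet Mother wavelet; only `"db4"` is provided.
#' @param max_level Decomposition depth (default 5).
#' @return An object of class `wpt_tree`: per-level lists of coefficient
#'   vectors in natural order plus `fs` and `max_level`.
#' @export
wpt_decompose <- function(x, fs, wavelet = "db4", max_level = 5) {
  if (!identical(wavelet, "db4")) {
    stop("unknown wavelet '", wavelet, "': only db4 is available")
  }
  n <- length(x)
  if (n < 2^max_level) {
    stop(sprintf("signal too short: %d samples cannot support level %d",
                 n, max_level))
  }
  if (n %% 2^max_level != 0) {
    stop(sprintf("signal length %d not divisible by 2^%d", n, max_level))
  }
  filt <- db4_filters()
  levels <- vector("list", max_level + 1L)
  levels[[1]] <- list(x)
  for (l in seq_len(max_level)) {
    parents <- levels[[l]]
    children <- vector("list", 2L * length(parents))
    for (p in seq_along(parents)) {
      children[[2L * p - 1L]] <- wpt_analysis_step(parents[[p]], filt$h)
      children[[2L * p]] <- wpt_analysis_step(parents[[p]], filt$g)
    }
    levels[[l + 1L]] <- children
  }
  structure(list(levels = levels, fs = fs, max_level = max_level,
                 n = n, wavelet = wavelet),
            class = "wpt_tree")
}

#' Fetch one packet node by level and frequency-ordered index
#'
#' @param tree A [wpt_decompose()] result.
#' @param level Level 0..`max_level`.
#' @param freq_index Frequency-ordered position at that level
#'   (0-based, 0 = lowest band).
#' @return List with `level`, `freq_index`, `natural_index`, `band`
#'   (`c(lo, hi)` in Hz) and `coefficients`.
#' @export
wpt_node <- function(tree, level, freq_index) {
  stopifnot(inherits(tree, "wpt_tree"),
            level >= 0, level <= tree$max_level,
            freq_index >= 0, freq_index < 2^level)
  nat <- natural_from_freq(as.integer(freq_index))
  width <- (tree$fs / 2) / 2^level
  list(level = level, freq_index = as.integer(freq_index),
       natural_index = nat,
       band = c(freq_index * width, (freq_index + 1) * width),
       coefficients = tree$levels[[level + 1L]][[nat + 1L]])
}

#' Select the five band packets used by the hybrid feature pool
#'
#' Picks, from one packet tree, the nodes whose bands are exactly
#' theta 4-8 Hz and alpha 8-12 Hz (level 4), low beta 14-16 Hz (level 5),
#' high beta 16-32 Hz (level 2) and gamma 32-40 Hz (level 3). The delta
#' region (0-4 Hz) is excluded: 4-45 Hz bandpassed input carries no delta.
#'
#' @param tree A [wpt_decompose()] result (depth >= 5).
#' @param fs Sampling rate; bands must align with the dyadic grid
#'   (they do at 128 Hz).
#' @return Ordered list of five nodes (class `band_selection`), in the
#'   band order above.
#' @export
select_band_nodes <- function(tree, fs = tree$fs) {
  stopifnot(inherits(tree, "wpt_tree"))
  if (tree$max_level < 5) stop("tree depth must be at least 5")
  bands <- eeg_bands()
  nodes <- vector("list", length(bands))
  names(nodes) <- names(bands)
  for (b in names(bands)) {
    lo <- bands[[b]][1]; hi <- bands[[b]][2]
    width <- hi - lo
    found <- NULL
    for (l in 0:tree$max_level) {
      node_width <- (fs / 2) / 2^l
      if (abs(node_width - width) < 1e-9 && abs(lo %% width) < 1e-9) {
        found <- wpt_node(tree, l, as.integer(round(lo / width)))
        break
      }
    }
    if (is.null(found)) {
      stop(sprintf("band %s [%g, %g) Hz not representable on the dyadic grid at fs = %g",
                   b, lo, hi, fs))
    }
    nodes[[b]] <- found
  }
  structure(nodes, class = "band_selection")
}

#' Reconstruct the band-limited signal of a single packet node
#'
#' Inverts the packet transform with every other node zeroed, yielding the
#' node's contribution at the original length and sampling rate.
#'
#' @param tree A [wpt_decompose()] result.
#' @param node A node from [wpt_node()] or [select_band_nodes()].
#' @return Numeric vector of length `tree$n`.
#' @export
wpt_reconstruct_node <- function(tree, node) {
  filt <- db4_filters()
  v <- node$coefficients
  nat <- node$natural_index
  for (l in seq(node$level, 1L)) {
    zero <- numeric(length(v))
    v <- if (nat %% 2L == 0L) {
      wpt_synthesis_step(v, zero, filt)
    } else {
      wpt_synthesis_step(zero, v, filt)
    }
    nat <- nat %/% 2L
  }
  v
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodogram: Hann-windowed segments of `nperseg`
#' samples with `overlap` fractional overlap, one-sided density scaling
#' (integral of the PSD over frequency equals the signal's mean square).
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param nperseg Segment length (clipped to `length(x)`).
#' @param overlap Fractional overlap between segments in \[0, 1).
#' @return List with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs, nperseg = 256, overlap = 0.5) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  step <- max(1L, floor(nperseg * (1 - overlap)))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (0:(nperseg - 1)) / nperseg))
  u <- sum(w^2)
  nfreq <- nperseg %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)] * w
    sp <- abs(stats::fft(seg))^2 / (fs * u)
    half <- sp[1:nfreq]
    # one-sided: double everything except DC and (for even n) Nyquist
    dbl <- rep(2, nfreq)
    dbl[1] <- 1
    if (nperseg %% 2L == 0L) dbl[nfreq] <- 1
    acc <- acc + half * dbl
  }
  list(freq = (0:(nfreq - 1L)) * fs / nperseg, psd = acc / length(starts))
}

# Trapezoidal integral of a PSD over [lo, hi] on its native grid.
band_integral <- function(freq, psd, lo, hi) {
  i <- which(freq >= lo - 1e-9 & freq <= hi + 1e-9)
  if (length(i) < 2) return(0)
  sum(diff(freq[i]) * (psd[i][-1] + psd[i][-length(i)]) / 2)
}

#' Wavelet-domain features F12-F19 of a signal
#'
#' From the five selected band packets: F12 is the total coefficient
#' energy and F13 the population standard deviation, both over the
#' concatenated coefficient vector; F14 is the sum over packets of the
#' Shannon entropy (natural log) of each packet's normalized
#' squared-coefficient distribution (an all-zero packet contributes 0);
#' F15-F19 are per-band powers, the Welch-PSD integral of each packet's
#' band-limited reconstruction over its own band, in band order (theta,
#' alpha, low beta, high beta, gamma).
#'
#' @param tree A [wpt_decompose()] result for the signal.
#' @param selection A [select_band_nodes()] result from the same tree.
#' @param nperseg,overlap Welch parameters (defaults: 256-sample Hann
#'   segments, 50% overlap).
#' @return Named numeric vector `F12`..`F19`.
#' @export
wavelet_features <- function(tree, selection, nperseg = 256, overlap = 0.5) {
  stopifnot(inherits(selection, "band_selection"))
  coefs <- lapply(selection, `[[`, "coefficients")
  if (any(vapply(coefs, length, integer(1)) == 0L)) {
    stop("internal error: empty coefficient vector in band selection")
  }
  all_c <- unlist(coefs, use.names = FALSE)
  entropy <- vapply(coefs, function(cc) {
    e <- cc^2
    tot <- sum(e)
    if (tot == 0) return(0)
    p <- e[e > 0] / tot
    -sum(p * log(p))
  }, numeric(1))
  powers <- vapply(seq_along(selection), function(i) {
    node <- selection[[i]]
    rec <- wpt_reconstruct_node(tree, node)
    ps <- welch_psd(rec, tree$fs, nperseg = nperseg, overlap = overlap)
    band_integral(ps$freq, ps$psd, node$band[1], node$band[2])
  }, numeric(1))
  out <- c(sum(all_c^2),
           sqrt(mean((all_c - mean(all_c))^2)),
           sum(entropy),
           powers)
  names(out) <- paste0("F", 12:19)
  out
}
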