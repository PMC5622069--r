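## Peak-list input/output and centroiding.

#' Read a peak list or spectrum from disk
#'
#' Text dialects (`tsv`, `csv`) are two numeric columns, m/z then intensity,
#' whitespace or comma separated; a single leading header line is skipped
#' automatically when its first token is non-numeric. The `mzml` dialect
#' reads the first spectrum of an mzML file through Bioconductor's mzR.
#'
#' Intensities are never renormalised on read; any normalisation downstream
#' (abundance classes, occupancy fractions) is explicit, because abundance
#' classes depend on raw intensity ratios.
#'
#' @param path file path
#' @param dialect one of `"tsv"`, `"csv"`, `"mzml"`
#' @return a [MassSpectrum] with points sorted ascending by m/z; metadata
#'   records `source` and `dialect`
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("mz\tintensity", "100\t5", "200\t7"), f)
#' readPeakList(f)
#' @export
readPeakList <- function(path, dialect = c("tsv", "csv", "mzml")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    qmStop(sprintf("cannot read '%s': no such file", path), "qmIOError")
  if (dialect == "mzml") {
    if (!requireNamespace("mzR", quietly = TRUE))
      qmStop("reading mzML requires the mzR package", "qmIOError")
    h <- mzR::openMSfile(path)
    on.exit(mzR::close(h))
    pk <- mzR::peaks(h, 1L)
    if (NROW(pk) == 0L) qmStop(sprintf("'%s' is empty", path), "qmEmptyInput")
    return(MassSpectrum(pk[, 1], pk[, 2],
                        metadata = list(source = path, dialect = "mzml")))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) qmStop(sprintf("'%s' is empty", path), "qmEmptyInput")
  splitRow <- function(x) strsplit(trimws(x), "[,\t ]+")[[1]]
  first <- splitRow(lines[1])
  start <- 1L
  if (is.na(suppressWarnings(as.numeric(first[1])))) start <- 2L
  if (start > length(lines))
    qmStop(sprintf("'%s' has a header but no data rows", path), "qmEmptyInput")
  n <- length(lines) - start + 1L
  mzv <- numeric(n); iv <- numeric(n)
  for (i in seq_len(n)) {
    tok <- splitRow(lines[start + i - 1L])
    vals <- suppressWarnings(as.numeric(tok))
    if (length(vals) < 2L || any(is.na(vals[1:2])))
      qmStop(sprintf("non-numeric row at line %d of '%s'",
                     start + i - 1L, path), "qmParseError")
    mzv[i] <- vals[1]; iv[i] <- vals[2]
  }
  MassSpectrum(mzv, iv, metadata = list(source = path, dialect = dialect))
}

#' Write a peak list or spectrum as tab-separated text
#'
#' Values are written with enough digits to round-trip through
#' [readPeakList()] to better than six significant figures.
#'
#' @param x a [PeakList] or [MassSpectrum]
#' @param path output path
#' @param header write the `mz intensity` header line?
#' @return `path`, invisibly
#' @export
writePeakList <- function(x, path, header = TRUE) {
  stopifnot(is(x, "PeakList") || is(x, "MassSpectrum"))
  lines <- sprintf("%.10g\t%.10g", mz(x), intensity(x))
  if (header) lines <- c("mz\tintensity", lines)
  writeLines(lines, path)
  invisible(path)
}

#' Is a spectrum centroided?
#'
#' Heuristic: profile data live on a near-uniform sampling grid (spacing
#' coefficient of variation below 1%) or on a dense axis (5% or more of
#' adjacent spacings below 0.05 Th); anything else is treated as
#' centroided. Centroid lists have irregular, feature-driven spacings, so
#' neither test fires on them.
#'
#' @param spectrum a [MassSpectrum]
#' @return logical
#' @export
isCentroided <- function(spectrum) {
  d <- diff(mz(spectrum))
  if (length(d) < 2L) return(TRUE)
  uniformGrid <- stats::sd(d) / mean(d) < 0.01
  dense <- mean(d < 0.05) >= 0.05
  !uniformGrid && !dense
}

#' Centroid a spectrum
#'
#' Finds local maxima exceeding both an intensity and a prominence threshold
#' (both expressed as fractions of the base peak). Peak positions are refined
#' by parabolic interpolation through the apex and its neighbours; the FWHM
#' is estimated by linear interpolation to half maximum on both flanks and
#' reported as 0 when a flank is truncated (by the spectrum edge or by an
#' overlapping neighbour). On input already recognised as centroided (see
#' [isCentroided()]) the points above the intensity threshold are returned
#' as-is with zero widths.
#'
#' @param spectrum a [MassSpectrum]
#' @param minRelIntensity minimum apex intensity, fraction of base peak
#' @param minProminence minimum prominence, fraction of base peak
#' @param profile force profile (`TRUE`) or centroid (`FALSE`) handling;
#'   `NULL` auto-detects
#' @return a [PeakList] (empty when all intensities are zero)
#' @examples
#' x <- seq(990, 1010, 0.1)
#' sp <- MassSpectrum(x, exp(-(x - 1000)^2 / (2 * 4)))
#' pickPeaks(sp)
#' @export
pickPeaks <- function(spectrum, minRelIntensity = 0.01, minProminence = 0,
                      profile = NULL) {
  stopifnot(minRelIntensity >= 0, minRelIntensity < 1,
            minProminence >= 0, minProminence < 1)
  x <- mz(spectrum); y <- intensity(spectrum)
  base <- max(y)
  if (base <= 0) return(PeakList(numeric(), numeric(), numeric()))
  if (is.null(profile)) profile <- !isCentroided(spectrum)
  if (!profile) {
    keep <- y >= minRelIntensity * base & y > 0
    return(PeakList(x[keep], y[keep], rep(0, sum(keep))))
  }
  n <- length(y)
  if (n < 3L) return(PeakList(numeric(), numeric(), numeric()))
  apex <- which(diff(sign(diff(y))) < 0) + 1L
  if (y[1] > y[2]) apex <- c(1L, apex)
  if (y[n] > y[n - 1L]) apex <- c(apex, n)
  # keep plateau starts: rising then flat then falling
  out <- list()
  for (i in apex) {
    h <- y[i]
    if (h < minRelIntensity * base) next
    # prominence: descend each side until terrain higher than h (or edge)
    lmin <- h
    j <- i - 1L
    while (j >= 1L && y[j] <= h) { lmin <- min(lmin, y[j]); j <- j - 1L }
    if (j < 1L) lmin <- min(lmin, y[1])
    rmin <- h
    j <- i + 1L
    while (j <= n && y[j] <= h) { rmin <- min(rmin, y[j]); j <- j + 1L }
    if (j > n) rmin <- min(rmin, y[n])
    prom <- h - max(lmin, rmin)
    if (prom < minProminence * base) next
    # apex refinement: weighted quadratic fit to log intensity over the
    # peak top (exact for a Gaussian profile independent of grid
    # alignment, and noise-averaging); 3-point parabola as fallback
    mzApex <- x[i]; iApex <- h
    lo <- i; while (lo > 1L && y[lo - 1L] > 0.3 * h && y[lo - 1L] <= y[lo]) lo <- lo - 1L
    hi <- i; while (hi < n && y[hi + 1L] > 0.3 * h && y[hi + 1L] <= y[hi]) hi <- hi + 1L
    if (hi - lo >= 4L) {
      idx <- lo:hi
      xs <- x[idx] - x[i]
      fit <- stats::lm.wfit(cbind(1, xs, xs^2), log(y[idx]), y[idx]^2)
      a <- fit$coefficients
      if (!anyNA(a) && a[3] < 0) {
        v <- -a[2] / (2 * a[3])
        if (abs(v) <= (x[hi] - x[lo]) / 2) {
          mzApex <- x[i] + v
          iApex <- exp(a[1] - a[2]^2 / (4 * a[3]))
        }
      }
    } else if (i > 1L && i < n) {
      y1 <- y[i - 1L]; y2 <- y[i]; y3 <- y[i + 1L]
      den <- y1 - 2 * y2 + y3
      if (den < 0) {
        d <- 0.5 * (y1 - y3) / den
        if (abs(d) <= 0.5) {
          mzApex <- x[i] + d * (x[i + 1L] - x[i - 1L]) / 2
          iApex <- y2 - 0.25 * (y1 - y3) * d
        }
      }
    }
    out[[length(out) + 1L]] <-
      c(mzApex, iApex, .fwhmInterp(x, y, i, max(h, iApex) / 2))
  }
  if (!length(out)) return(PeakList(numeric(), numeric(), numeric()))
  m <- do.call(rbind, out)
  m <- m[!duplicated(round(m[, 1], 6)), , drop = FALSE]
  PeakList(m[, 1], m[, 2], m[, 3])
}

## Linear interpolation to the half-maximum crossing on both flanks of the
## apex at index i; returns 0 when either flank never descends to half max
## before rising again or hitting the spectrum edge.
.fwhmInterp <- function(x, y, i, half) {
  n <- length(y)
  left <- NA_real_
  j <- i
  while (j > 1L) {
    if (y[j - 1L] > y[j] && y[j] > half) break  # flank rises again
    if (y[j - 1L] <= half) {
      f <- (y[j] - half) / (y[j] - y[j - 1L])
      left <- x[j] - f * (x[j] - x[j - 1L])
      break
    }
    j <- j - 1L
  }
  right <- NA_real_
  j <- i
  while (j < n) {
    if (y[j + 1L] > y[j] && y[j] > half) break
    if (y[j + 1L] <= half) {
      f <- (y[j] - half) / (y[j] - y[j + 1L])
      right <- x[j] + f * (x[j + 1L] - x[j])
      break
    }
    j <- j + 1L
  }
  if (is.na(left) || is.na(right)) 0 else right - left
}
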