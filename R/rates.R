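## Binned firing rates, Gaussian smoothing, the active-electrode filter, and
## Pearson correlation analysis of binned rates. Conventions: 100 ms bins,
## half-open [a, a + w), smoothing with a normalized 5-bin discrete Gaussian,
## electrodes enter correlation analyses only when their mean firing rate
## exceeds 0.05 Hz (strictly).

#' Bin a spike train into a rate histogram
#'
#' Counts spikes in consecutive half-open bins of width \code{binWidth}
#' starting at the train's \code{tStart} and divides by the bin width, giving
#' rates in Hz. The histogram has \code{floor(duration / binWidth)} bins;
#' spikes past the last full bin (only possible when the duration is not a
#' bin multiple) are not counted.
#'
#' @param train a [SpikeTrain-class].
#' @param binWidth bin width in seconds (default 0.1).
#' @return a [RateHistogram-class].
#' @export
binRates <- function(train, binWidth = 0.1) {
  if (binWidth <= 0) stop("binWidth must be positive")
  dur <- duration(train)
  if (binWidth > dur) stop("binWidth exceeds the recording duration")
  nbins <- floor(dur / binWidth + 1e-9)
  idx <- floor((train@times - train@tStart) / binWidth) + 1L
  counts <- tabulate(idx[idx >= 1L & idx <= nbins], nbins)
  new("RateHistogram", electrodeId = train@electrodeId, binWidth = binWidth,
      rates = counts / binWidth, tStart = train@tStart)
}

#' Discrete Gaussian smoothing kernel
#'
#' Gaussian weights evaluated at integer bin offsets over an odd support,
#' normalized to sum to one.
#'
#' @param kernelBins odd kernel support in bins (default 5).
#' @param sigmaBins Gaussian SD in bins (default 1.25, i.e. the 5-bin support
#'   covers +/- 2 SD).
#' @return numeric vector of length \code{kernelBins} summing to 1.
#' @export
gaussianKernel <- function(kernelBins = 5, sigmaBins = 1.25) {
  if (kernelBins < 1 || kernelBins %% 2 == 0)
    stop("kernelBins must be odd and >= 1")
  if (kernelBins == 1) return(1)
  h <- (kernelBins - 1) / 2
  k <- stats::dnorm(seq(-h, h), sd = sigmaBins)
  k / sum(k)
}

#' Smooth a rate histogram with a Gaussian kernel
#'
#' Convolves the per-bin rates with the normalized discrete Gaussian of
#' [gaussianKernel()]. At the histogram edges the kernel mass that would fall
#' outside the histogram is renormalized over the in-range bins (each input
#' bin's count is fully redistributed, never zero-padded away), so the total
#' spike count is conserved exactly.
#'
#' @param hist a [RateHistogram-class].
#' @param kernelBins odd kernel support in bins (default 5).
#' @param sigmaBins Gaussian SD in bins (default 1.25).
#' @return a smoothed [RateHistogram-class].
#' @export
smoothRates <- function(hist, kernelBins = 5, sigmaBins = 1.25) {
  k <- gaussianKernel(kernelBins, sigmaBins)
  x <- hist@rates
  n <- length(x)
  h <- (kernelBins - 1) / 2
  if (h == 0 || n == 0)
    return(initialize(hist, smoothed = TRUE, kernelBins = as.integer(kernelBins)))
  offsets <- seq(-h, h)
  ## weight actually available to each source bin (kernel clipped at edges)
  avail <- numeric(n)
  for (j in seq_along(offsets)) {
    dest <- seq_len(n) + offsets[j]
    ok <- dest >= 1L & dest <= n
    avail[ok] <- avail[ok] + k[j]
  }
  out <- numeric(n)
  src <- x / avail
  for (j in seq_along(offsets)) {
    dest <- seq_len(n) + offsets[j]
    ok <- dest >= 1L & dest <= n
    out[dest[ok]] <- out[dest[ok]] + src[ok] * k[j]
  }
  initialize(hist, rates = out, smoothed = TRUE,
             kernelBins = as.integer(kernelBins))
}

#' Filter electrodes by minimum firing rate
#'
#' An electrode is active when its session-wide mean firing rate
#' (spike count / duration) is strictly greater than \code{minRate}.
#' Correlation analyses operate on active electrodes only.
#'
#' @param session a [RecordingSession-class].
#' @param minRate threshold in Hz (default 0.05).
#' @return character vector of active electrode ids.
#' @export
activeFilter <- function(session, minRate = 0.05) {
  dur <- duration(session)
  ids <- electrodeIds(session)
  counts <- vapply(session@trains, function(t) length(t@times), integer(1L))
  ids[counts / dur > minRate]
}

#' Matrix of binned (optionally smoothed) rates for a session
#'
#' Convenience builder: bins every requested electrode on the common grid and
#' optionally applies Gaussian smoothing, returning a bins x electrodes
#' matrix ready for [pearsonMatrix()].
#'
#' @param session a [RecordingSession-class].
#' @param electrodes electrode ids (default: all).
#' @param binWidth bin width in seconds (default 0.1).
#' @param smooth apply [smoothRates()] (default TRUE).
#' @param kernelBins,sigmaBins smoothing parameters.
#' @return numeric matrix, bins x electrodes, colnames = electrode ids.
#' @export
sessionRates <- function(session, electrodes = electrodeIds(session),
                         binWidth = 0.1, smooth = TRUE, kernelBins = 5,
                         sigmaBins = 1.25) {
  cols <- lapply(electrodes, function(id) {
    h <- binRates(session@trains[[id]], binWidth)
    if (smooth) h <- smoothRates(h, kernelBins, sigmaBins)
    h@rates
  })
  m <- do.call(cbind, cols)
  colnames(m) <- electrodes
  m
}

#' Pairwise Pearson correlation of binned rates
#'
#' Standard Pearson coefficients between all pairs of rate histograms on a
#' common bin grid. Channels with zero variance yield undefined coefficients,
#' returned as NA (their diagonal entry included) and excluded from
#' [ccSummary()] means rather than set to zero.
#'
#' @param rateMatrix bins x electrodes matrix as from [sessionRates()], or a
#'   list of [RateHistogram-class] objects on identical grids.
#' @return symmetric correlation matrix with electrode dimnames.
#' @export
pearsonMatrix <- function(rateMatrix) {
  if (is.list(rateMatrix) && !is.matrix(rateMatrix)) {
    bw <- vapply(rateMatrix, function(h) h@binWidth, numeric(1L))
    nb <- vapply(rateMatrix, function(h) length(h@rates), integer(1L))
    if (length(unique(bw)) > 1L || length(unique(nb)) > 1L)
      stop("histograms must share one bin grid")
    ids <- vapply(rateMatrix, function(h) h@electrodeId, character(1L))
    rateMatrix <- vapply(rateMatrix, function(h) h@rates,
                         numeric(nb[[1L]]))
    colnames(rateMatrix) <- ids
  }
  if (nrow(rateMatrix) < 2L) stop("need at least 2 bins")
  cc <- suppressWarnings(stats::cor(rateMatrix))
  degenerate <- apply(rateMatrix, 2L, stats::sd) == 0
  cc[degenerate, ] <- NA_real_
  cc[, degenerate] <- NA_real_
  diag(cc)[!degenerate] <- 1
  cc
}

#' Intra-/inter-network correlation summary
#'
#' Averages the off-diagonal Pearson coefficients by module membership:
#' intra-CC over unordered within-module pairs (per module and pooled),
#' inter-CC over between-module pairs (per module pair and pooled). Pairs
#' involving control electrodes are summarized separately and never enter
#' intra/inter means; undefined (NA) coefficients are dropped from every
#' mean. A module with fewer than two electrodes in the matrix has undefined
#' intra-CC and is flagged.
#'
#' @param mat correlation matrix from [pearsonMatrix()] (electrode dimnames
#'   required and covered by \code{map}).
#' @param map a [ModuleMap-class].
#' @return a [CCSummary-class].
#' @export
ccSummary <- function(mat, map) {
  ids <- colnames(mat)
  if (is.null(ids)) stop("correlation matrix must carry electrode dimnames")
  unknown <- setdiff(ids, names(map@assignment))
  if (length(unknown))
    stop("electrodes not covered by the module map: ",
         paste(unknown, collapse = ", "))
  mod <- unname(map@assignment[ids])
  ctrl <- mod == map@controlLabel
  n <- length(ids)
  intra_vals <- list()
  inter_vals <- list()
  control_vals <- numeric()
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in seq.int(i + 1L, n)) {
      v <- mat[i, j]
      if (is.na(v)) next
      if (ctrl[i] || ctrl[j]) {
        control_vals <- c(control_vals, v)
      } else if (mod[i] == mod[j]) {
        intra_vals[[mod[i]]] <- c(intra_vals[[mod[i]]], v)
      } else {
        key <- paste(sort(c(mod[i], mod[j])), collapse = "\r")
        inter_vals[[key]] <- c(inter_vals[[key]], v)
      }
    }
  }
  mods <- intersect(moduleLabels(map), unique(mod))
  intraModule <- vapply(mods, function(m) {
    if (is.null(intra_vals[[m]])) NA_real_ else mean(intra_vals[[m]])
  }, numeric(1L))
  flagged <- mods[vapply(mods, function(m) sum(mod == m) < 2L, logical(1L))]
  ip <- names(inter_vals)
  interPairs <- if (length(ip)) {
    parts <- strsplit(ip, "\r", fixed = TRUE)
    data.frame(module1 = vapply(parts, `[`, character(1L), 1L),
               module2 = vapply(parts, `[`, character(1L), 2L),
               cc = vapply(inter_vals, mean, numeric(1L)),
               n_pairs = lengths(inter_vals), row.names = NULL)
  } else {
    data.frame(module1 = character(), module2 = character(), cc = numeric(),
               n_pairs = integer())
  }
  all_intra <- unlist(intra_vals, use.names = FALSE)
  all_inter <- unlist(inter_vals, use.names = FALSE)
  new("CCSummary",
      intraModule = intraModule,
      intraOverall = if (length(all_intra)) mean(all_intra) else NA_real_,
      interPairs = interPairs,
      interOverall = if (length(all_inter)) mean(all_inter) else NA_real_,
      control = if (length(control_vals)) mean(control_vals) else NA_real_,
      nPairs = c(intra = length(all_intra), inter = length(all_inter),
                 control = length(control_vals)),
      flagged = flagged)
}

#' Full connectivity analysis of one session
#'
#' Applies the active-electrode filter, builds smoothed rate histograms on
#' the standard grid, and returns the correlation matrix plus its module
#' summary.
#'
#' @param session a [RecordingSession-class].
#' @param map a [ModuleMap-class] covering the session.
#' @param binWidth,kernelBins,sigmaBins,minRate analysis parameters; defaults
#'   are the package conventions (0.1 s bins, 5-bin Gaussian, 0.05 Hz filter).
#' @param smooth correlate smoothed (default) or raw histograms.
#' @return list with elements \code{matrix} (correlation matrix over active,
#'   mapped electrodes), \code{summary} (a [CCSummary-class]) and
#'   \code{active} (the active electrode ids).
#' @export
connectivity <- function(session, map, binWidth = 0.1, kernelBins = 5,
                         sigmaBins = 1.25, minRate = 0.05, smooth = TRUE) {
  active <- activeFilter(session, minRate)
  active <- intersect(active, names(map@assignment))
  if (length(active) < 2L)
    stop("fewer than two active mapped electrodes")
  rm <- sessionRates(session, active, binWidth, smooth, kernelBins, sigmaBins)
  mat <- pearsonMatrix(rm)
  list(matrix = mat, summary = ccSummary(mat, map), active = active)
}
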