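#' Parameters for the nucleosome summit caller
#'
#' The caller smooths the extended-dyad coverage with a Gaussian kernel
#' and greedily selects height-ranked strict local maxima subject to a
#' minimum inter-summit distance. `max_height_cap` clips per-base coverage
#' before smoothing so clonal pile-ups cannot dominate (default 200, the
#' conventional clonal cap). `min_height` defaults to 5% of the smoothed
#' track mean over nonzero bases, making the threshold depth-invariant; an
#' absolute value may be supplied instead.
#'
#' @param bandwidth Gaussian kernel sd in bp
#' @param min_distance minimum distance between accepted summits, bp
#' @param min_height absolute smoothed-coverage threshold, or NULL for the
#'   relative default
#' @param min_height_frac fraction of the nonzero-base mean used when
#'   `min_height` is NULL
#' @param max_height_cap per-base coverage cap applied before smoothing,
#'   or NULL to disable
#' @return an object of class `CallerParams`
#' @export
caller_params <- function(bandwidth = 15, min_distance = 110L,
                          min_height = NULL, min_height_frac = 0.05,
                          max_height_cap = 200) {
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  if (min_distance < 1) stop("min_distance must be >= 1")
  if (!is.null(max_height_cap) && max_height_cap <= 0)
    stop("max_height_cap must be > 0 if set")
  structure(list(bandwidth = bandwidth,
                 min_distance = as.integer(min_distance),
                 min_height = min_height,
                 min_height_frac = min_height_frac,
                 max_height_cap = max_height_cap),
            class = "CallerParams")
}

#' Smooth a dyad track with a Gaussian kernel
#'
#' Discrete Gaussian convolution, kernel truncated at +/- 4 sd and
#' renormalized to sum 1, zero-padded at chromosome edges. The per-base
#' cap, if configured, is applied before smoothing.
#'
#' @param track a `DyadTrack`
#' @param bandwidth kernel sd in bp
#' @param cap optional per-base coverage cap
#' @return named list of numeric vectors, one per chromosome
#' @export
smooth_track <- function(track, bandwidth = 15, cap = NULL) {
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  h <- as.integer(ceiling(4 * bandwidth))
  k <- stats::dnorm(seq(-h, h), sd = bandwidth)
  k <- k / sum(k)
  out <- lapply(names(track$coverage), function(ch) {
    x <- as.numeric(track$coverage[[ch]])
    if (!is.null(cap)) x <- pmin(x, cap)
    n <- length(x)
    if (n == 0 || all(x == 0)) return(numeric(n))
    y <- stats::convolve(x, rev(k), type = "open")
    y[(h + 1):(h + n)]
  })
  names(out) <- names(track$coverage)
  out
}

# Strict local maxima of one smoothed vector via run-length encoding:
# a run is a maximum iff its value exceeds both neighbouring runs;
# plateaus resolve to the leftmost base. Returns 0-based positions.
.local_maxima <- function(y) {
  r <- rle(y)
  nr <- length(r$values)
  if (nr < 3) return(list(pos = integer(0), height = numeric(0)))
  i <- 2:(nr - 1)
  is_max <- r$values[i] > r$values[i - 1] & r$values[i] > r$values[i + 1]
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- i[is_max]
  list(pos = starts[idx] - 1L, height = r$values[idx])
}

#' Call nucleosome summits from a smoothed track
#'
#' All strict local maxima above the height threshold are ranked by height
#' (ties broken by smaller coordinate, then chromosome name) and accepted
#' greedily provided they lie at least `min_distance` bp from every summit
#' already accepted on the same chromosome. Calls are returned sorted by
#' coordinate.
#'
#' @param smoothed result of [smooth_track()]
#' @param params a `CallerParams`
#' @param dyad_counts optional `RleList` of raw per-base dyad counts; when
#'   given, each call reports the raw dyads within summit +/- bandwidth
#' @return data.frame (chrom, summit, height, raw_dyads); summit is 0-based
#' @export
call_summits <- function(smoothed, params = caller_params(),
                         dyad_counts = NULL) {
  min_height <- params$min_height
  if (is.null(min_height)) {
    nz <- unlist(lapply(smoothed, function(y) y[y > 1e-12]),
                 use.names = FALSE)
    min_height <- if (length(nz)) params$min_height_frac * mean(nz) else Inf
  }
  cand <- lapply(sort(names(smoothed)), function(ch) {
    lm <- .local_maxima(smoothed[[ch]])
    keep <- lm$height >= min_height
    if (!any(keep)) return(NULL)
    data.frame(chrom = ch, summit = lm$pos[keep],
               height = lm$height[keep], stringsAsFactors = FALSE)
  })
  cand <- do.call(rbind, cand)
  empty <- data.frame(chrom = character(), summit = integer(),
                      height = numeric(), raw_dyads = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(cand) || nrow(cand) == 0) return(empty)
  ord <- order(-cand$height, cand$summit, cand$chrom)
  cand <- cand[ord, ]
  d <- params$min_distance
  acc <- vector("list", length(smoothed))
  names(acc) <- names(smoothed)
  blocked <- lapply(smoothed, function(y) logical(length(y)))
  take <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ch <- cand$chrom[i]; p <- cand$summit[i]
    if (blocked[[ch]][p + 1L]) next
    take[i] <- TRUE
    lo <- max(p - d + 1L, 0L) + 1L
    hi <- min(p + d - 1L, length(blocked[[ch]]) - 1L) + 1L
    blocked[[ch]][lo:hi] <- TRUE
  }
  calls <- cand[take, ]
  calls <- calls[order(calls$chrom, calls$summit), ]
  rownames(calls) <- NULL
  calls$raw_dyads <- NA_integer_
  if (!is.null(dyad_counts)) {
    bw <- as.integer(ceiling(params$bandwidth))
    calls$raw_dyads <- vapply(seq_len(nrow(calls)), function(i) {
      r <- dyad_counts[[calls$chrom[i]]]
      lo <- max(calls$summit[i] - bw, 0L) + 1L
      hi <- min(calls$summit[i] + bw, length(r) - 1L) + 1L
      as.integer(sum(as.numeric(r[lo:hi])))
    }, integer(1))
  }
  calls
}

#' Smooth a track and call nucleosome summits
#'
#' @param track a `DyadTrack`
#' @param params a `CallerParams`
#' @return data.frame of calls, as [call_summits()]
#' @export
call_nucleosomes <- function(track, params = caller_params()) {
  sm <- smooth_track(track, bandwidth = params$bandwidth,
                     cap = params$max_height_cap)
  call_summits(sm, params, dyad_counts = track$dyad_counts)
}

#' Write nucleosome calls
#'
#' TSV keeps all columns; BED6 represents each summit as a 3 bp feature
#' centred on the summit with the smoothed height as score.
#'
#' @param calls data.frame from [call_summits()]
#' @param path output path
#' @param format "tsv" or "bed"
#' @export
write_calls <- function(calls, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(calls, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    df <- data.frame(calls$chrom, pmax(calls$summit - 1L, 0L),
                     calls$summit + 2L,
                     sprintf("nuc_%05d", seq_len(nrow(calls))),
                     calls$height, ".")
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read nucleosome calls written by [write_calls()] (TSV form)
#' @param path TSV path
#' @return data.frame of calls
#' @export
read_calls <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
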