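#' Sliding-window smoothing of a per-base signal
#'
#' Averages a per-base signal in sliding windows, the standard preprocessing
#' applied to tiling-array enrichment profiles (defaults: 1-kb window sliding
#' by 500 bp). Window means ignore missing values, weighting by the defined
#' bases actually covered; a window with no defined bases propagates `NA`
#' rather than fabricating a zero.
#'
#' @param raw either a numeric vector of per-base values starting at
#'   `region_start`, or a data frame with columns `pos` (0-based base
#'   position) and `value` (bases absent from the table are treated as
#'   missing).
#' @param window window size in bp (> 0).
#' @param step slide in bp (> 0); `window < step` is allowed.
#' @param region_start 0-based start of the signal (default 0).
#' @param chrom chromosome name carried on the output.
#' @return a signal-track tibble with columns `chrom`, `start`, `end`
#'   (the window footprint, half-open) and `value`; the number of windows is
#'   `floor((L - window) / step) + 1` for a signal of length `L`.
#' @examples
#' sliding_window_smooth(rep(1, 3000))           # every window value 1
#' @export
sliding_window_smooth <- function(raw, window = 1000, step = 500,
                                  region_start = 0, chrom = "chrX") {
  if (window <= 0) rlang::abort("window must be > 0")
  if (step <= 0) rlang::abort("step must be > 0")
  if (is.data.frame(raw)) {
    stopifnot(all(c("pos", "value") %in% names(raw)))
    if (nrow(raw) == 0) rlang::abort("empty signal")
    region_start <- min(raw$pos)
    L <- max(raw$pos) - region_start + 1
    values <- rep(NA_real_, L)
    values[raw$pos - region_start + 1] <- raw$value
  } else {
    values <- as.double(raw)
    L <- length(values)
  }
  if (L < window) rlang::abort("signal shorter than one window")
  n <- floor((L - window) / step) + 1
  starts <- region_start + (seq_len(n) - 1) * step
  vals <- vapply(starts, function(s) {
    w <- values[(s - region_start + 1):(s - region_start + window)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
  out <- tibble::tibble(chrom = chrom, start = as.double(starts),
                        end = as.double(starts + window), value = vals)
  attr(out, "window") <- window
  attr(out, "step") <- step
  out
}

#' Transposon insertion density
#'
#' Counts insertion sites in fixed genomic intervals and reports density as
#' insertions per `per` bases in an `interval`-sized bin (default: per 1 kb
#' in a 10-kb interval). Insertions outside the region are ignored with a
#' message reporting how many were dropped. Positions on a bin boundary
#' count to the bin starting there (half-open tiling).
#'
#' @param positions integer vector of 0-based insertion positions; duplicate
#'   positions are independent insertions and all count.
#' @param region the region to tile (single-row interval table or list).
#' @param interval bin size in bp, a multiple of `per`.
#' @param per density denominator unit in bp.
#' @return a signal-track tibble (`chrom`, `start`, `end`, `value`); the last
#'   bin is clipped to the region end but densities keep the nominal
#'   `interval / per` denominator, so `sum(value) * interval / per` equals
#'   the number of in-region insertions.
#' @export
insertion_density <- function(positions, region, interval = 10000, per = 1000) {
  region <- as_region(region)
  if (interval <= 0 || per <= 0) rlang::abort("interval and per must be > 0")
  if (interval %% per != 0) rlang::abort("interval must be a multiple of per")
  positions <- as.double(positions)
  inside <- positions >= region$start & positions < region$end
  if (any(!inside)) {
    message(sum(!inside), " insertion(s) outside the region ignored")
    positions <- positions[inside]
  }
  starts <- seq(region$start, region$end - 1, by = interval)
  idx <- floor((positions - region$start) / interval) + 1
  counts <- tabulate(idx, nbins = length(starts))
  tibble::tibble(chrom = region$chrom,
                 start = as.double(starts),
                 end = pmin(starts + interval, region$end),
                 value = counts / (interval / per))
}

#' Threshold a signal track into enrichment intervals
#'
#' Converts a windowed enrichment histogram into interval calls: maximal runs
#' of windows with `value >= cutoff` become intervals (the union of the
#' qualifying window footprints); runs whose footprint is shorter than
#' `min_run` bp are dropped. Missing-value windows never qualify.
#'
#' @param track a signal-track tibble (`chrom`, `start`, `end`, `value`).
#' @param cutoff enrichment threshold (same units as `value`).
#' @param min_run minimum footprint length in bp to keep (default 0).
#' @return an interval table of enriched regions.
#' @export
threshold_enrichment <- function(track, cutoff, min_run = 0) {
  validate_intervals(track, one_chrom = TRUE, arg = "track")
  if (nrow(track) == 0) rlang::abort("empty track")
  if (!"value" %in% names(track)) rlang::abort("track must have a value column")
  if (all(is.na(track$value))) rlang::abort("track is all missing values")
  hits <- track[!is.na(track$value) & track$value >= cutoff, ]
  out <- merge_intervals(hits[c("chrom", "start", "end")])
  out[interval_length(out) >= min_run, ]
}
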