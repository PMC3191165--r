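#' Construct a tidy interval table
#'
#' Interval tables are the package's common currency: ordinary tibbles with at
#' least `chrom`, `start`, `end` columns, in 0-based half-open coordinates
#' (`start` inclusive, `end` exclusive), so that the genomic length of an
#' interval is exactly `end - start`. Extra columns (`label`, scores,
#' metadata) pass through every operation untouched unless documented
#' otherwise.
#'
#' @param chrom chromosome name, recycled to the length of `start`.
#' @param start,end integer base positions, `end >= start`. `end == start`
#'   denotes an empty interval (length 0), allowed internally but never
#'   written to BED.
#' @param label optional free-text label per interval.
#' @param ... further columns, tidyr-style (each recycled to length).
#' @return a tibble with columns `chrom`, `start`, `end` (+ extras), sorted
#'   by `start`.
#' @examples
#' interval_tbl("chrX", c(0, 100), c(50, 200), label = c("a", "b"))
#' @export
interval_tbl <- function(chrom = "chrX", start = integer(), end = integer(),
                         label = NULL, ...) {
  out <- tibble::tibble(chrom = chrom, start = as.double(start),
                        end = as.double(end), ...)
  if (!is.null(label)) out$label <- label
  validate_intervals(out)
  dplyr::arrange(out, .data$start, .data$end)
}

#' @keywords internal
validate_intervals <- function(x, one_chrom = FALSE, arg = "intervals") {
  stopifnot(is.data.frame(x))
  missing <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(missing) > 0) {
    rlang::abort(sprintf("%s must have columns chrom/start/end (missing: %s)",
                         arg, paste(missing, collapse = ", ")))
  }
  if (nrow(x) == 0) return(invisible(x))
  if (any(!is.finite(x$start)) || any(!is.finite(x$end))) {
    rlang::abort(sprintf("%s has non-finite coordinates", arg))
  }
  if (any(x$start < 0)) rlang::abort(sprintf("%s has negative start", arg))
  bad <- which(x$end < x$start)
  if (length(bad) > 0) {
    rlang::abort(sprintf("%s row %d: end (%s) < start (%s)", arg, bad[1],
                         format(x$end[bad[1]], scientific = FALSE),
                         format(x$start[bad[1]], scientific = FALSE)))
  }
  if (one_chrom && length(unique(x$chrom)) > 1) {
    rlang::abort(sprintf("%s spans multiple chromosomes: %s", arg,
                         paste(unique(x$chrom), collapse = ", ")))
  }
  invisible(x)
}

## half-open [start, end) <-> IRanges closed [start+1, end]; width 0 preserved
as_iranges <- function(x) {
  IRanges::IRanges(start = x$start + 1, end = x$end)
}

iranges_tbl <- function(ir, chrom = "chrX") {
  tibble::tibble(chrom = chrom,
                 start = as.double(IRanges::start(ir) - 1),
                 end = as.double(IRanges::end(ir)))
}

chrom_of <- function(x, default = "chrX") {
  if (nrow(x) == 0) default else x$chrom[[1]]
}

#' Interval lengths in base pairs
#'
#' Length under the half-open convention is `end - start`; an empty interval
#' has length 0.
#'
#' @param x an interval table (or any data frame with `start`/`end`).
#' @return a numeric vector of lengths, one per row.
#' @examples
#' interval_length(interval_tbl("chrX", 10793400, 10984198)) # 190798
#' @export
interval_length <- function(x) {
  validate_intervals(x)
  x$end - x$start
}

total_length <- function(x) sum(interval_length(x))

#' Merge overlapping or nearby intervals
#'
#' Unions intervals that overlap, abut, or are separated by at most
#' `max_gap` bases, bedtools-merge style. The result is sorted and pairwise
#' disjoint; covered bases never decrease. Metadata columns are dropped
#' (merged intervals have no unique provenance).
#'
#' @param x interval table on a single chromosome.
#' @param max_gap merge across gaps of up to this many bases (default 0:
#'   only overlapping or adjacent intervals are united).
#' @return a normalized interval table.
#' @examples
#' merge_intervals(interval_tbl("chrX", c(0, 10), c(10, 20))) # [0, 20)
#' @export
merge_intervals <- function(x, max_gap = 0) {
  validate_intervals(x, one_chrom = TRUE)
  stopifnot(max_gap >= 0)
  if (nrow(x) == 0) return(interval_tbl(character(), integer(), integer()))
  ir <- IRanges::reduce(as_iranges(x), min.gapwidth = max_gap + 1,
                        drop.empty.ranges = TRUE)
  iranges_tbl(ir, chrom_of(x))
}

#' Complement of an interval set within a region
#'
#' Returns the maximal sub-intervals of `region` not covered by `x`; the
#' complement and the (normalized) set tile the region exactly. This is how
#' bands are derived from called interbands: the gaps between interband
#' borders are the bands.
#'
#' @param x interval table; must lie within `region`.
#' @param region a single-row interval table (or list with
#'   `chrom`/`start`/`end`) delimiting the universe.
#' @return interval table of the uncovered gaps.
#' @export
complement_intervals <- function(x, region) {
  region <- as_region(region)
  validate_intervals(x, one_chrom = TRUE)
  if (nrow(x) > 0) {
    if (any(x$chrom != region$chrom)) {
      rlang::abort("intervals and region are on different chromosomes")
    }
    if (min(x$start) < region$start || max(x$end) > region$end) {
      rlang::abort("intervals extend outside the region")
    }
  }
  merged <- merge_intervals(x)
  ir <- IRanges::setdiff(as_iranges(region), as_iranges(merged))
  iranges_tbl(ir, region$chrom)
}

#' @keywords internal
as_region <- function(region) {
  if (is.data.frame(region)) {
    validate_intervals(region, arg = "region")
    stopifnot(nrow(region) == 1)
    list(chrom = region$chrom[[1]], start = region$start[[1]],
         end = region$end[[1]])
  } else {
    stopifnot(is.list(region), all(c("chrom", "start", "end") %in% names(region)))
    region
  }
}

region_tbl <- function(region) {
  region <- as_region(region)
  interval_tbl(region$chrom, region$start, region$end)
}

#' Read and write interval files
#'
#' `read_intervals()` reads BED (3-6 columns, no header, 0-based half-open)
#' or headered TSV (columns `chrom`, `start`, `end`, any extras; coordinates
#' taken as already 0-based half-open). `write_intervals()` is its inverse;
#' `read_intervals(write_intervals(x))` is the identity on
#' chrom/start/end/label.
#'
#' @param path file path.
#' @param format `"bed"` or `"tsv"`; default guessed from the extension.
#' @return an interval table.
#' @export
read_intervals <- function(path, format = c("guess", "bed", "tsv")) {
  format <- match.arg(format)
  if (format == "guess") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "tsv"
  }
  if (format == "bed") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    n <- lengths(fields)
    bad <- which(n < 3)
    if (length(bad) > 0) {
      rlang::abort(sprintf("malformed BED line %d in %s: fewer than 3 fields",
                           bad[1], path))
    }
    start <- suppressWarnings(as.double(vapply(fields, `[[`, "", 2)))
    end <- suppressWarnings(as.double(vapply(fields, `[[`, "", 3)))
    bad <- which(!is.finite(start) | !is.finite(end))
    if (length(bad) > 0) {
      rlang::abort(sprintf("malformed BED line %d in %s: non-numeric coordinates",
                           bad[1], path))
    }
    bad <- which(end < start)
    if (length(bad) > 0) {
      rlang::abort(sprintf("BED line %d in %s: start > end", bad[1], path))
    }
    out <- tibble::tibble(chrom = vapply(fields, `[[`, "", 1),
                          start = start, end = end)
    if (all(n >= 4)) out$label <- vapply(fields, `[[`, "", 4)
    if (all(n >= 5)) out$score <- suppressWarnings(
      as.double(vapply(fields, `[[`, "", 5)))
    if (all(n >= 6)) out$strand <- vapply(fields, `[[`, "", 6)
  } else {
    out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    validate_intervals(out, arg = path)
  }
  bad <- which(out$end < out$start)
  if (length(bad) > 0) {
    rlang::abort(sprintf("line %d in %s: start > end", bad[1], path))
  }
  dplyr::arrange(tibble::as_tibble(out), .data$start, .data$end)
}

#' @rdname read_intervals
#' @param x interval table to write.
#' @export
write_intervals <- function(x, path, format = c("guess", "bed", "tsv")) {
  format <- match.arg(format)
  if (format == "guess") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "tsv"
  }
  validate_intervals(x)
  if (format == "bed") {
    x <- dplyr::filter(x, .data$end > .data$start)  # empty intervals not representable
    cols <- c("chrom", "start", "end",
              intersect(c("label", "score", "strand"), names(x)))
    readr::write_tsv(format_coords(x[cols]), path, col_names = FALSE,
                     progress = FALSE)
  } else {
    readr::write_tsv(format_coords(x), path, progress = FALSE)
  }
  invisible(path)
}

## keep large coordinates out of scientific notation on disk
format_coords <- function(x) {
  dplyr::mutate(x, dplyr::across(
    dplyr::any_of(c("start", "end")),
    ~ format(.x, scientific = FALSE, trim = TRUE)))
}

#' Read a printed band/interband coordinate table
#'
#' Reads a headered TSV with columns `name`, `type` (`IB` or `B`), `start`,
#' `end` holding coordinate pairs as printed in the literature: 1-based pairs
#' `s..e` whose *printed* length equals `e - s`. Each pair is converted to
#' the internal half-open interval `[s - 1, e - 1)`, so `interval_length()`
#' reproduces the printed length column exactly. (Under this arithmetic,
#' consecutive printed rows with `next_start = end + 1` leave one unassigned
#' base per boundary; the printed tables are internally inconsistent by that
#' one base and the conversion is faithful to their own length column.)
#'
#' @param path TSV path.
#' @param chrom chromosome to assign (the printed tables omit it).
#' @return an interval table with `name`, `type` columns, sorted by start.
#' @export
read_band_table <- function(path, chrom = "chrX") {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("name", "type", "start", "end")
  if (!all(need %in% names(raw))) {
    rlang::abort(sprintf("%s must have columns %s", path,
                         paste(need, collapse = ", ")))
  }
  out <- tibble::tibble(chrom = chrom,
                        start = raw$start - 1,
                        end = raw$end - 1,
                        name = raw$name,
                        type = ifelse(raw$type == "IB", "interband", "band"))
  validate_intervals(out, arg = path)
  dplyr::arrange(out, .data$start)
}

#' Read a printed FISH-probe coordinate table
#'
#' TSV with columns `name`, `interband` (the structure each probe was
#' designed against) and printed 1-based `start`/`end` pairs, converted with
#' the same arithmetic as [read_band_table()].
#'
#' @param path TSV path.
#' @param chrom chromosome to assign.
#' @return an interval table with `label` (probe name) and
#'   `target_interband` columns.
#' @export
read_probe_table <- function(path, chrom = "chrX") {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  out <- tibble::tibble(chrom = chrom, start = raw$start - 1,
                        end = raw$end - 1, label = raw$name,
                        target_interband = raw$interband)
  validate_intervals(out, arg = path)
  dplyr::arrange(out, .data$start)
}
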