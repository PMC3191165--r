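#' Build a banding map from interband calls
#'
#' Interbands are mapped first; the regions in between are then filled in as
#' bands. The result tiles the region exactly: interbands are the calls
#' (clipped to the region) and bands are their complement, in strict
#' alternation.
#'
#' @param calls interval table of disjoint interband calls inside `region`.
#' @param region single-row interval table (or list) delimiting the map.
#' @param labels optional interval table with a `name` column; elements
#'   overlapping a labeled interval take its name (cytological names are
#'   fixture data, not code). Unlabeled elements are auto-numbered
#'   `IB1..`/`B1..`.
#' @return a tibble of class `banding_map` with columns `chrom`, `start`,
#'   `end`, `type` (`"interband"`/`"band"`), `name`, and the region stored
#'   as an attribute.
#' @export
build_banding_map <- function(calls, region, labels = NULL) {
  region <- as_region(region)
  validate_intervals(calls, arg = "calls")
  calls <- dplyr::arrange(tibble::as_tibble(calls), .data$start)
  if (nrow(calls) > 1 && any(calls$start[-1] < calls$end[-nrow(calls)])) {
    rlang::abort("interband calls overlap")
  }
  ib <- calls[calls$end > calls$start, c("chrom", "start", "end")]
  ib$type <- "interband"
  bands <- complement_intervals(ib[c("chrom", "start", "end")], region)
  bands$type <- "band"
  map <- dplyr::arrange(dplyr::bind_rows(ib, bands), .data$start)
  map$name <- NA_character_
  if (!is.null(labels)) {
    validate_intervals(labels, arg = "labels")
    stopifnot("name" %in% names(labels))
    ovl <- IRanges::findOverlaps(as_iranges(map), as_iranges(labels),
                                 select = "first")
    map$name <- labels$name[ovl]
  }
  auto <- is.na(map$name)
  for (tp in c("interband", "band")) {
    idx <- which(map$type == tp & auto)
    ord <- which(map$type == tp)
    map$name[idx] <- paste0(ifelse(tp == "interband", "IB", "B"),
                            match(idx, ord))
  }
  new_banding_map(map, region)
}

new_banding_map <- function(map, region) {
  structure(tibble::as_tibble(map), region = region,
            class = c("banding_map", class(tibble::tibble())))
}

#' Assemble a banding map from an explicit element table
#'
#' For maps transcribed from printed coordinate tables (see
#' [read_band_table()]). Checks sortedness and strict band/interband
#' alternation; with `strict = TRUE` also requires exact tiling. Printed
#' tables whose arithmetic leaves one unassigned base per boundary can be
#' loaded with `strict = FALSE`; the total unassigned bases are recorded in
#' `attr(, "boundary_gap_bp")`.
#'
#' @param elements interval table with a `type` column
#'   (`"interband"`/`"band"`) and optionally `name`.
#' @param strict require exact tiling (default `TRUE`).
#' @return a `banding_map` tibble.
#' @export
banding_map_from_elements <- function(elements, strict = TRUE) {
  validate_intervals(elements, one_chrom = TRUE, arg = "elements")
  stopifnot("type" %in% names(elements))
  map <- dplyr::arrange(tibble::as_tibble(elements), .data$start)
  if (!all(map$type %in% c("interband", "band"))) {
    rlang::abort("type must be 'interband' or 'band'")
  }
  if (any(map$type[-1] == map$type[-nrow(map)])) {
    rlang::abort("elements do not alternate band/interband")
  }
  gaps <- map$start[-1] - map$end[-nrow(map)]
  if (any(gaps < 0)) rlang::abort("elements overlap")
  if (strict && any(gaps > 0)) {
    rlang::abort("elements do not tile the region (use strict = FALSE for printed tables with boundary gaps)")
  }
  if (!"name" %in% names(map)) map$name <- NA_character_
  region <- list(chrom = chrom_of(map), start = min(map$start),
                 end = max(map$end))
  out <- new_banding_map(map, region)
  attr(out, "boundary_gap_bp") <- sum(gaps)
  out
}

#' @export
print.banding_map <- function(x, ...) {
  r <- attr(x, "region")
  cat(sprintf("<banding_map> %s:%s-%s  %d interbands / %d bands\n",
              r$chrom, format(r$start, scientific = FALSE),
              format(r$end, scientific = FALSE),
              sum(x$type == "interband"), sum(x$type == "band")))
  NextMethod()
}

#' Extract the interbands or bands of a map
#' @param map a `banding_map`.
#' @return an interval table of the selected elements.
#' @export
interbands <- function(map) {
  as_plain_tbl(map)[map$type == "interband", , drop = FALSE]
}

#' @rdname interbands
#' @export
bands <- function(map) {
  as_plain_tbl(map)[map$type == "band", , drop = FALSE]
}

as_plain_tbl <- function(x) {
  x <- tibble::as_tibble(x)
  class(x) <- class(tibble::tibble())
  attr(x, "region") <- NULL
  attr(x, "params") <- NULL
  x
}

coverage_fraction <- function(element, features) {
  if (is.null(features) || nrow(features) == 0) return(0)
  merged <- merge_intervals(features[c("chrom", "start", "end")])
  ir <- IRanges::intersect(as_iranges(merged),
                           IRanges::IRanges(element$start + 1, element$end))
  sum(IRanges::width(ir)) / (element$end - element$start)
}

#' Classify bands as late-replicating IH or faint early-replicating
#'
#' Two band types occur: large, dense, late-replicating intercalary
#' heterochromatin (IH) bands enriched for SUUR, D1 and lamin, and thin
#' early-replicating "faint" bands. A band is called `IH_late` when it is
#' substantially late-replicating (`late_fraction >= t_late`) or jointly
#' SUUR- and lamin-covered (`>= t_black` each, the BLACK-chromatin
#' signature), and carries no open-chromatin evidence; otherwise
#' `faint_early`.
#'
#' @param map a `banding_map`.
#' @param late interval table of late-replication calls (required).
#' @param suur,lamin optional interval tables of SUUR / lamin domains.
#' @param open optional interval table of open-chromatin features (e.g. the
#'   pooled interband-protein/DHS features); any feature whose midpoint
#'   falls inside the band vetoes `IH_late` (midpoint containment, so
#'   features of a flanking interband that merely graze the border do not
#'   count as open chromatin in the band).
#' @param t_late late-replication coverage threshold (default 0.4: one
#'   canonical IH band is late-replicating over only its distal 40%).
#' @param t_black SUUR/lamin coverage threshold (default 0.5).
#' @return the map with band rows annotated: `late_fraction`,
#'   `suur_fraction`, `lamin_fraction`, `open_overlap_bp`, `band_class`
#'   (`NA` for interbands).
#' @export
classify_bands <- function(map, late, suur = NULL, lamin = NULL, open = NULL,
                           t_late = 0.4, t_black = 0.5) {
  stopifnot(inherits(map, "banding_map"))
  if (is.null(late)) rlang::abort("missing required track: late replication")
  validate_intervals(late, arg = "late")
  out <- tibble::as_tibble(map)
  n <- nrow(out)
  out$late_fraction <- NA_real_
  out$suur_fraction <- NA_real_
  out$lamin_fraction <- NA_real_
  out$open_features <- NA_integer_
  out$band_class <- NA_character_
  open_mid <- if (is.null(open) || nrow(open) == 0) double() else
    floor((open$start + open$end) / 2)
  for (i in which(out$type == "band")) {
    el <- out[i, ]
    lf <- coverage_fraction(el, late)
    sf <- coverage_fraction(el, suur)
    mf <- coverage_fraction(el, lamin)
    nopen <- sum(open_mid >= el$start & open_mid < el$end)
    ih <- (lf >= t_late || (sf >= t_black && mf >= t_black)) && nopen == 0
    out$late_fraction[i] <- lf
    out$suur_fraction[i] <- sf
    out$lamin_fraction[i] <- mf
    out$open_features[i] <- nopen
    out$band_class[i] <- if (ih) "IH_late" else "faint_early"
  }
  new_banding_map(out, attr(map, "region"))
}

#' Summarize a banding map
#'
#' @param map a `banding_map`.
#' @return a one-row tibble: element counts, total bp per type, the
#'   interband fraction of the region in percent, and per-type size
#'   min/max/mean.
#' @export
summarize_region <- function(map) {
  stopifnot(inherits(map, "banding_map"))
  r <- attr(map, "region")
  ib <- interbands(map); bd <- bands(map)
  ib_bp <- total_length(ib); bd_bp <- total_length(bd)
  stat <- function(x, f) if (nrow(x) == 0) NA_real_ else f(interval_length(x))
  tibble::tibble(
    region_bp = r$end - r$start,
    n_interbands = nrow(ib), n_bands = nrow(bd),
    interband_bp = ib_bp, band_bp = bd_bp,
    interband_fraction = interband_fraction(ib_bp, r$end - r$start),
    interband_min = stat(ib, min), interband_max = stat(ib, max),
    interband_mean = stat(ib, mean),
    band_min = stat(bd, min), band_max = stat(bd, max),
    band_mean = stat(bd, mean))
}

#' Interband DNA fraction of a region, in percent
#'
#' The textbook quantity "interbands account for x% of the DNA": `100 *
#' interband_bp / region_bp`, rounded to 2 decimals.
#'
#' @param interband_bp total interband DNA in bp.
#' @param region_bp region length in bp.
#' @export
interband_fraction <- function(interband_bp, region_bp) {
  stopifnot(region_bp > 0, interband_bp >= 0)
  round(100 * interband_bp / region_bp, 2)
}

#' @method glance banding_map
#' @export
glance.banding_map <- function(x, ...) summarize_region(x)

#' @method tidy banding_map
#' @export
tidy.banding_map <- function(x, ...) as_plain_tbl(x)

#' Compare two banding maps of the same region
#'
#' For each band of `a`, finds the band of `b` with maximal overlap and
#' reports the overlap in bp and the Jaccard index; also computes the global
#' Jaccard of the two interband base sets (symmetric). Agreement between
#' independently drawn maps of the same region is typically summarized by
#' the latter.
#'
#' @param a,b `banding_map`s on the same region.
#' @return a list of class `map_comparison`: `$elements` (per-band table)
#'   and `$interband_jaccard`.
#' @export
compare_maps <- function(a, b) {
  stopifnot(inherits(a, "banding_map"), inherits(b, "banding_map"))
  ra <- attr(a, "region"); rb <- attr(b, "region")
  if (ra$chrom != rb$chrom || ra$start != rb$start || ra$end != rb$end) {
    rlang::abort("maps cover different regions")
  }
  ba <- bands(a); bb <- bands(b)
  rows <- purrr::map_dfr(seq_len(nrow(ba)), function(i) {
    x <- ba[i, ]
    ov <- pmax(0, pmin(x$end, bb$end) - pmax(x$start, bb$start))
    j <- if (nrow(bb) == 0) NA_integer_ else which.max(ov)
    if (is.na(j) || ov[j] == 0) {
      tibble::tibble(name = x$name, start = x$start, end = x$end,
                     best_match = NA_character_, overlap_bp = 0, jaccard = 0)
    } else {
      uni <- (x$end - x$start) + (bb$end[j] - bb$start[j]) - ov[j]
      tibble::tibble(name = x$name, start = x$start, end = x$end,
                     best_match = bb$name[j], overlap_bp = ov[j],
                     jaccard = ov[j] / uni)
    }
  })
  structure(list(elements = rows,
                 interband_jaccard = jaccard_sets(interbands(a), interbands(b))),
            class = "map_comparison")
}

#' Jaccard index of two interval sets' base coverage
#' @param x,y interval tables on one chromosome.
#' @export
jaccard_sets <- function(x, y) {
  xm <- merge_intervals(x[c("chrom", "start", "end")])
  ym <- merge_intervals(y[c("chrom", "start", "end")])
  inter <- sum(IRanges::width(IRanges::intersect(as_iranges(xm), as_iranges(ym))))
  uni <- sum(IRanges::width(IRanges::union(as_iranges(xm), as_iranges(ym))))
  if (uni == 0) return(1)
  inter / uni
}

#' @export
print.map_comparison <- function(x, ...) {
  cat(sprintf("<map_comparison> global interband Jaccard %.3f\n",
              x$interband_jaccard))
  print(x$elements, n = Inf)
  invisible(x)
}

#' @method tidy map_comparison
#' @export
tidy.map_comparison <- function(x, ...) x$elements

#' @method glance map_comparison
#' @export
glance.map_comparison <- function(x, ...) {
  tibble::tibble(interband_jaccard = x$interband_jaccard,
                 n_bands_compared = nrow(x$elements),
                 mean_band_jaccard = mean(x$elements$jaccard))
}
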