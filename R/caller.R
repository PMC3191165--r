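#' Evidence classes recognized by the interband caller
#'
#' Open-chromatin evidence is grouped into classes so that several redundant
#' tracks of the same kind (e.g. five interband-associated proteins) count
#' as one line of evidence: `interband_protein` (Chriz/CHRO, BEAF-32, WDS,
#' BRE1, RNA Pol II, NURF, TRX, GAF), `dhs` (DNase I hypersensitive sites),
#' `h1_dip` (local depletions of linker histone H1), `orc` (origin
#' recognition complex binding), `active_state` (active chromatin-state
#' segments), `histone_variant` (e.g. H3.3).
#'
#' @export
evidence_classes <- c("interband_protein", "dhs", "h1_dip", "orc",
                      "active_state", "histone_variant")

#' Assemble a marker panel
#'
#' A marker panel bundles the evidence tracks for one region: a tibble with
#' one row per (marker, cell type) track, each carrying its evidence class
#' and an interval table of enriched features.
#'
#' @param region single-row interval table (or list) for the analyzed span.
#' @param tracks tibble with columns `marker`, `cell_type`, `class`,
#'   `features` (list-column of interval tables). Build incrementally with
#'   [add_track()].
#' @return an object of class `marker_panel`.
#' @export
marker_panel <- function(region, tracks = NULL) {
  region <- as_region(region)
  if (is.null(tracks)) {
    tracks <- tibble::tibble(marker = character(), cell_type = character(),
                             class = character(), features = list())
  }
  stopifnot(all(c("marker", "cell_type", "class", "features") %in% names(tracks)))
  bad <- setdiff(unique(tracks$class), evidence_classes)
  if (length(bad) > 0) {
    rlang::abort(sprintf("unknown evidence class(es): %s",
                         paste(bad, collapse = ", ")))
  }
  purrr::walk(tracks$features, validate_intervals)
  structure(list(region = region, tracks = tibble::as_tibble(tracks)),
            class = "marker_panel")
}

#' @rdname marker_panel
#' @param panel a `marker_panel`.
#' @param marker marker name (e.g. `"Chriz"`).
#' @param class evidence class, one of [evidence_classes].
#' @param features interval table of enriched regions for this track.
#' @param cell_type cell line the track was measured in.
#' @export
add_track <- function(panel, marker, class, features, cell_type = "Kc") {
  stopifnot(inherits(panel, "marker_panel"))
  class <- match.arg(class, evidence_classes)
  validate_intervals(features)
  panel$tracks <- dplyr::bind_rows(
    panel$tracks,
    tibble::tibble(marker = marker, cell_type = cell_type, class = class,
                   features = list(tibble::as_tibble(features))))
  panel
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("<marker_panel> %s:%s-%s\n", x$region$chrom,
              format(x$region$start, scientific = FALSE),
              format(x$region$end, scientific = FALSE)))
  if (nrow(x$tracks) == 0) {
    cat("  (no tracks)\n")
  } else {
    smry <- dplyr::summarise(
      dplyr::group_by(x$tracks, .data$class, .data$marker),
      cells = paste(.data$cell_type, collapse = ","),
      n_features = sum(vapply(.data$features, nrow, integer(1))),
      .groups = "drop")
    print(smry, n = Inf)
  }
  invisible(x)
}

#' @method tidy marker_panel
#' @export
tidy.marker_panel <- function(x, ...) {
  tidyr::unnest(x$tracks, "features")
}

#' Combine a marker's tracks across cell types
#'
#' The same marker is often profiled in several cell lines (S2, BG3, Kc);
#' this pools one marker's interval sets into a single set by per-base
#' union, intersection, or majority vote (covered in at least half of the
#' available cell types).
#'
#' @param panel a `marker_panel`.
#' @param marker marker name present in the panel.
#' @param mode `"union"` (default), `"intersection"`, or `"majority"`.
#' @return a normalized interval table.
#' @export
combine_cell_types <- function(panel, marker, mode = c("union", "intersection",
                                                       "majority")) {
  stopifnot(inherits(panel, "marker_panel"))
  mode <- match.arg(mode)
  rows <- panel$tracks[panel$tracks$marker == marker, ]
  if (nrow(rows) == 0) rlang::abort(sprintf("unknown marker: %s", marker))
  sets <- purrr::map(rows$features, ~ merge_intervals(
    .x[.x$end > .x$start, c("chrom", "start", "end")]))
  combine_interval_sets(sets, mode, chrom = panel$region$chrom)
}

combine_interval_sets <- function(sets, mode, chrom = "chrX") {
  k <- length(sets)
  if (k == 1) return(sets[[1]])
  need <- switch(mode, union = 1, intersection = k, majority = ceiling(k / 2))
  width <- max(1, vapply(sets, function(s) if (nrow(s)) max(s$end) else 0,
                         numeric(1)))
  cvg <- Reduce(`+`, purrr::map(sets, function(s) {
    IRanges::coverage(as_iranges(s), width = width)
  }))
  ir <- IRanges::slice(cvg, lower = need, rangesOnly = TRUE)
  iranges_tbl(ir, chrom)
}

#' Interband caller parameters
#'
#' @param min_support minimum number of distinct evidence classes that must
#'   co-localize for a base to be part of an interband candidate (default 2:
#'   redundant tracks of one class cannot outvote the absence of a second
#'   line of evidence).
#' @param combine_cells how to pool a marker across cell types
#'   (see [combine_cell_types()]); default `"union"`.
#' @param merge_gap candidate runs separated by at most this many bases are
#'   merged (default 500 bp, one smoothing step).
#' @param min_size,max_size size limits in bp for retained calls (defaults
#'   300 and 10000; mapped interbands span roughly 600-3000 bp).
#' @return a list of class `caller_params`.
#' @export
caller_params <- function(min_support = 2,
                          combine_cells = c("union", "intersection", "majority"),
                          merge_gap = 500, min_size = 300, max_size = 10000) {
  stopifnot(min_support >= 1, merge_gap >= 0, min_size < max_size)
  structure(list(min_support = min_support,
                 combine_cells = match.arg(combine_cells),
                 merge_gap = merge_gap, min_size = min_size,
                 max_size = max_size),
            class = "caller_params")
}

## one merged interval set per evidence class (cell types pooled per marker,
## then markers of a class pooled by union)
class_sets <- function(panel, combine_cells) {
  classes <- unique(panel$tracks$class)
  purrr::map(rlang::set_names(classes), function(cl) {
    markers <- unique(panel$tracks$marker[panel$tracks$class == cl])
    per_marker <- purrr::map(markers, ~ combine_cell_types(panel, .x,
                                                           combine_cells))
    merge_intervals(dplyr::bind_rows(per_marker))
  })
}

## summed binary coverage across evidence classes, as an Rle over [1, end]
class_count_coverage <- function(sets, region_end) {
  width <- region_end
  covs <- purrr::map(sets, function(s) {
    IRanges::coverage(as_iranges(s), width = width)
  })
  if (length(covs) == 0) return(S4Vectors::Rle(0L, width))
  Reduce(`+`, covs)
}

#' Call interbands from a marker panel
#'
#' The core demarcation procedure: every base of the region is scored by the
#' number of distinct open-chromatin evidence classes covering it; maximal
#' runs with at least `min_support` classes become candidates; candidates
#' separated by at most `merge_gap` bp are merged and those outside
#' `[min_size, max_size]` are dropped; each surviving call is annotated
#' with its supporting evidence classes and a consensus peak. Call
#' intervals are exactly the consensus runs (so the caller agrees base for
#' base with a per-base voting oracle); [refine_borders()] widens them to
#' the edge-to-edge extent of the supporting feature distributions when
#' that view is wanted.
#'
#' @param panel a `marker_panel`.
#' @param params a [caller_params()] list.
#' @param refine widen call borders to supporting-feature extents as
#'   [refine_borders()] does (default `FALSE`: intervals are the consensus
#'   runs).
#' @return a tibble of class `interband_calls`, sorted and disjoint, with
#'   columns `chrom`, `start`, `end`, `peak`, `support` (comma-joined
#'   evidence classes), `n_classes`, `cell_types`. Candidates dropped by the
#'   size filter are kept in `attr(, "dropped")` with a reason column.
#' @export
call_interbands <- function(panel, params = caller_params(), refine = FALSE) {
  stopifnot(inherits(panel, "marker_panel"), inherits(params, "caller_params"))
  region <- panel$region
  if ((region$end - region$start) < params$min_size) {
    rlang::abort("region is shorter than min_size")
  }
  empty <- tibble::tibble(chrom = character(), start = double(),
                          end = double(), peak = double(),
                          support = character(), n_classes = integer(),
                          cell_types = character())
  if (nrow(panel$tracks) == 0 ||
      all(vapply(panel$tracks$features, nrow, integer(1)) == 0)) {
    return(new_interband_calls(empty, params))
  }
  sets <- class_sets(panel, params$combine_cells)
  cvg <- class_count_coverage(sets, region$end)
  cand <- IRanges::slice(cvg, lower = params$min_support, rangesOnly = TRUE)
  cand <- IRanges::reduce(cand, min.gapwidth = params$merge_gap + 1)
  cand_tbl <- iranges_tbl(cand, region$chrom)
  ## clip to region
  cand_tbl <- dplyr::mutate(cand_tbl,
                            start = pmax(.data$start, region$start),
                            end = pmin(.data$end, region$end))
  cand_tbl <- cand_tbl[cand_tbl$end > cand_tbl$start, ]
  len <- interval_length(cand_tbl)
  keep <- len >= params$min_size & len <= params$max_size
  dropped <- cand_tbl[!keep, ]
  if (nrow(dropped) > 0) {
    dropped$reason <- ifelse(interval_length(dropped) < params$min_size,
                             "below min_size", "above max_size")
  }
  calls <- cand_tbl[keep, ]
  out <- annotate_calls(calls, sets, cvg, panel, region,
                        refine = refine, min_support = params$min_support)
  out <- new_interband_calls(out, params)
  attr(out, "dropped") <- dropped
  out
}

new_interband_calls <- function(x, params) {
  structure(tibble::as_tibble(x),
            params = params,
            class = c("interband_calls", class(tibble::tibble())))
}

## peak, support annotation and (optionally) edge refinement for candidate
## intervals; clipping keeps refined calls disjoint and inside the region
annotate_calls <- function(calls, sets, cvg, panel, region, refine,
                           min_support) {
  n <- nrow(calls)
  if (n == 0) {
    return(tibble::tibble(chrom = character(), start = double(),
                          end = double(), peak = double(),
                          support = character(), n_classes = integer(),
                          cell_types = character()))
  }
  all_feats <- tidyr::unnest(panel$tracks, "features")
  all_feats <- all_feats[all_feats$end > all_feats$start, ]
  fir <- as_iranges(all_feats)
  ## clip limits: midpoints between neighboring candidates, region ends
  lim_lo <- c(region$start,
              floor((calls$end[-n] + calls$start[-1]) / 2))
  lim_hi <- c(floor((calls$end[-n] + calls$start[-1]) / 2),
              region$end)
  rows <- purrr::map(seq_len(n), function(i) {
    ci <- IRanges::IRanges(calls$start[i] + 1, calls$end[i])
    hit <- as.logical(IRanges::countOverlaps(fir, ci) > 0)
    sup_feats <- all_feats[hit, ]
    sup_classes <- sort(unique(sup_feats$class))
    cells <- sort(unique(sup_feats$cell_type))
    if (refine && nrow(sup_feats) > 0) {
      s <- max(lim_lo[i], min(sup_feats$start))
      e <- min(lim_hi[i], max(sup_feats$end))
      s <- min(s, calls$start[i])  # never shrink below the consensus run
      e <- max(e, calls$end[i])
    } else {
      s <- calls$start[i]; e <- calls$end[i]
    }
    tibble::tibble(chrom = region$chrom, start = s, end = e,
                   peak = peak_position(cvg, calls$start[i], calls$end[i]),
                   support = paste(sup_classes, collapse = ","),
                   n_classes = length(sup_classes),
                   cell_types = paste(cells, collapse = ","))
  })
  dplyr::bind_rows(rows)
}

## midpoint of the leftmost maximal-count run inside [start, end)
peak_position <- function(cvg, start, end) {
  w <- S4Vectors::window(cvg, start + 1, end)
  v <- S4Vectors::runValue(w)
  l <- S4Vectors::runLength(w)
  stops <- cumsum(l)
  starts1 <- c(1, utils::head(stops, -1) + 1)
  i <- which(v == max(v))[1]
  ## run occupies half-open [start + starts1[i] - 1, start + stops[i])
  floor((2 * start + starts1[i] - 1 + stops[i]) / 2)
}

#' Refine call borders against the evidence
#'
#' Re-annotates interband calls on a panel: the consensus `peak` is the
#' midpoint of the maximal evidence-count run inside the call (ties broken
#' leftmost), and the call's edges are widened to the outermost bases of the
#' union of supporting features overlapping it (the "edges of
#' distributions"), clipped at the midpoint to any neighboring call so calls
#' stay disjoint.
#'
#' @param calls an interval table of candidate calls (sorted, disjoint).
#' @param panel the `marker_panel` the calls were derived from.
#' @param params the [caller_params()] used (for `combine_cells`).
#' @return an `interband_calls` tibble.
#' @export
refine_borders <- function(calls, panel, params = caller_params()) {
  stopifnot(inherits(panel, "marker_panel"))
  validate_intervals(calls, arg = "calls")
  calls <- dplyr::arrange(tibble::as_tibble(calls), .data$start)
  sets <- class_sets(panel, params$combine_cells)
  cvg <- class_count_coverage(sets, panel$region$end)
  out <- annotate_calls(calls[c("chrom", "start", "end")], sets, cvg, panel,
                        panel$region, refine = TRUE,
                        min_support = params$min_support)
  new_interband_calls(out, params)
}

#' Concordance of FISH probes with interband calls
#'
#' For each probe, reports the call it overlaps (distance 0), or the nearest
#' call with a signed distance (positive when the probe lies proximal/right
#' of the call, negative when distal/left). A probe equidistant from two
#' calls is assigned to the left one and flagged.
#'
#' @param calls interval table of interband calls.
#' @param probes interval table of probes (a `label` column is carried
#'   through as the probe name).
#' @return a tibble with one row per probe: `probe`, `probe_start`,
#'   `probe_end`, `call_start`, `call_end`, `distance`, `tie`.
#' @export
probe_concordance <- function(calls, probes) {
  validate_intervals(calls, arg = "calls")
  validate_intervals(probes, arg = "probes")
  calls <- dplyr::arrange(tibble::as_tibble(calls), .data$start)
  purrr::map_dfr(seq_len(nrow(probes)), function(i) {
    p <- probes[i, ]
    ## gap between probe and each call (0 when overlapping)
    gap_left <- calls$start - p$end    # call right of probe
    gap_right <- p$start - calls$end   # call left of probe
    gap <- pmax(gap_left, gap_right, 0)
    j <- which(gap == min(gap))
    tie <- length(j) > 1 && min(gap) > 0
    j <- j[1]
    d <- if (gap[j] == 0) 0 else if (gap_right[j] > 0) gap_right[j] else -gap_left[j]
    tibble::tibble(probe = if ("label" %in% names(p)) p$label else paste0("probe", i),
                   probe_start = p$start, probe_end = p$end,
                   call_start = calls$start[j], call_end = calls$end[j],
                   distance = d, tie = tie)
  })
}
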