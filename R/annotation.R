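#' Construct a gene-model table
#'
#' A minimal flat gene model: one row per gene with its span, strand, TSS
#' (the strand-appropriate end), first exon and optional 5'UTR. This is the
#' level of annotation needed to place interbands in genomic context;
#' isoforms are out of scope.
#'
#' @param id gene identifiers.
#' @param chrom,start,end gene span, 0-based half-open.
#' @param strand `"+"` or `"-"`.
#' @param first_exon_start,first_exon_end first-exon span (within the gene;
#'   defaults to the first kilobase at the TSS end).
#' @param utr5_start,utr5_end optional 5'UTR span.
#' @return a tibble with a computed `tss` column.
#' @export
gene_models <- function(id, chrom = "chrX", start, end, strand = "+",
                        first_exon_start = NULL, first_exon_end = NULL,
                        utr5_start = NA_real_, utr5_end = NA_real_) {
  g <- tibble::tibble(id = id, chrom = chrom, start = as.double(start),
                      end = as.double(end), strand = strand)
  validate_intervals(g, arg = "genes")
  if (!all(g$strand %in% c("+", "-"))) rlang::abort("strand must be + or -")
  g$tss <- ifelse(g$strand == "+", g$start, g$end - 1)
  if (is.null(first_exon_start)) {
    w <- pmin(1000, g$end - g$start)
    first_exon_start <- ifelse(g$strand == "+", g$start, g$end - w)
    first_exon_end <- ifelse(g$strand == "+", g$start + w, g$end)
  }
  g$first_exon_start <- as.double(first_exon_start)
  g$first_exon_end <- as.double(first_exon_end)
  if (any(g$first_exon_start < g$start | g$first_exon_end > g$end)) {
    rlang::abort("first exon must lie within the gene")
  }
  g$utr5_start <- as.double(utr5_start)
  g$utr5_end <- as.double(utr5_end)
  dplyr::arrange(g, .data$start)
}

#' Read gene models from a headered TSV
#'
#' Expected columns: `id`, `chrom`, `start`, `end`, `strand`,
#' `first_exon_start`, `first_exon_end` (+ optional `utr5_start`,
#' `utr5_end`); coordinates 0-based half-open.
#'
#' @param path TSV path.
#' @export
read_gene_models <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  gene_models(id = raw$id, chrom = raw$chrom, start = raw$start,
              end = raw$end, strand = raw$strand,
              first_exon_start = raw$first_exon_start,
              first_exon_end = raw$first_exon_end,
              utr5_start = raw$utr5_start %||% NA_real_,
              utr5_end = raw$utr5_end %||% NA_real_)
}

overlaps <- function(s1, e1, s2, e2) pmax(s1, s2) < pmin(e1, e2)

#' Genomic context of interbands
#'
#' Classifies each interband against gene models with the precedence
#' `five_prime > first_exon > intergenic > internal`: an interband touching
#' any TSS (+- `tss_slop`) or 5'UTR is `five_prime`; otherwise one touching
#' a first exon is `first_exon`; otherwise one touching no gene body at all
#' is `intergenic`; anything else (inside a gene away from its 5' end) is
#' `internal`. Interbands characteristically fall at 5' gene ends,
#' intergenic gaps, or first exons.
#'
#' @param ib interval table of interbands.
#' @param genes a [gene_models()] table.
#' @param tss_slop bp window around the TSS counted as 5' (default 250;
#'   interbands are sub-kilobase structures).
#' @return a tibble with one row per interband: `start`, `end`, `context`,
#'   `genes` (comma-joined ids involved).
#' @export
interband_context <- function(ib, genes, tss_slop = 250) {
  validate_intervals(ib, arg = "ib")
  if (tss_slop < 0) rlang::abort("tss_slop must be >= 0")
  purrr::map_dfr(seq_len(nrow(ib)), function(i) {
    s <- ib$start[i]; e <- ib$end[i]
    at_tss <- overlaps(s, e, genes$tss - tss_slop, genes$tss + tss_slop + 1) |
      (!is.na(genes$utr5_start) &
         overlaps(s, e, genes$utr5_start, genes$utr5_end))
    at_fe <- overlaps(s, e, genes$first_exon_start, genes$first_exon_end)
    in_body <- overlaps(s, e, genes$start, genes$end)
    if (any(at_tss)) {
      ctx <- "five_prime"; ids <- genes$id[at_tss]
    } else if (any(at_fe)) {
      ctx <- "first_exon"; ids <- genes$id[at_fe]
    } else if (!any(in_body)) {
      ctx <- "intergenic"
      left <- genes$id[genes$end <= s]
      right <- genes$id[genes$start >= e]
      ids <- c(utils::tail(left, 1), utils::head(right, 1))
    } else {
      ctx <- "internal"; ids <- genes$id[in_body]
    }
    tibble::tibble(start = s, end = e,
                   name = if ("name" %in% names(ib)) ib$name[i] else NA_character_,
                   context = ctx, genes = paste(ids, collapse = ","))
  })
}

#' ORC spacing within a span
#'
#' Kilobases of DNA per origin-recognition-complex binding site, reported to
#' one decimal. A span with no sites is reported with status `"absent"`
#' rather than an infinite spacing.
#'
#' @param n_sites number of ORC binding sites (>= 0).
#' @param span_kb span length in kb (> 0).
#' @return a one-row tibble: `n_sites`, `span_kb`, `kb_per_site` (`NA` when
#'   absent), `status`.
#' @examples
#' orc_spacing(7, 68)   # 9.7 kb per site
#' orc_spacing(4, 170)  # 42.5 kb per site
#' @export
orc_spacing <- function(n_sites, span_kb) {
  if (n_sites < 0 || span_kb <= 0) rlang::abort("invalid inputs")
  if (n_sites == 0) {
    tibble::tibble(n_sites = 0L, span_kb = span_kb,
                   kb_per_site = NA_real_, status = "absent")
  } else {
    tibble::tibble(n_sites = as.integer(n_sites), span_kb = span_kb,
                   kb_per_site = round(span_kb / n_sites, 1), status = "ok")
  }
}

#' Fraction of features falling in interbands
#'
#' Quantifies claims of the form "these features are located almost totally
#' in the interbands": returns both the fraction of feature *bases* inside
#' interbands and the fraction of *whole features* assigned to interbands by
#' the midpoint rule (point-like features relative to interband size).
#'
#' @param features interval table (e.g. ORC binding sites).
#' @param map a `banding_map`.
#' @return a one-row tibble: `base_fraction`, `feature_fraction`,
#'   `n_features`, `feature_bp`.
#' @export
feature_in_interband_fraction <- function(features, map) {
  validate_intervals(features, arg = "features")
  stopifnot(inherits(map, "banding_map"))
  ib <- interbands(map)
  ibr <- as_iranges(merge_intervals(ib[c("chrom", "start", "end")]))
  feat <- features[features$end > features$start, ]
  if (nrow(feat) == 0) {
    return(tibble::tibble(base_fraction = NA_real_, feature_fraction = NA_real_,
                          n_features = 0L, feature_bp = 0))
  }
  fir <- as_iranges(feat)
  inter_bp <- sum(IRanges::width(IRanges::pintersect(
    IRanges::findOverlapPairs(fir, ibr))))
  mid <- floor((feat$start + feat$end) / 2)
  midr <- IRanges::IRanges(mid + 1, mid + 1)
  in_ib <- IRanges::countOverlaps(midr, ibr) > 0
  tibble::tibble(base_fraction = inter_bp / sum(interval_length(feat)),
                 feature_fraction = mean(in_ib),
                 n_features = nrow(feat),
                 feature_bp = sum(interval_length(feat)))
}

#' Chromatin-state composition of an element
#'
#' Fraction of an element covered by each label of a chromatin-state (or
#' chromatin-color) segmentation; any uncovered remainder is reported under
#' `"none"`. Fractions sum to 1.
#'
#' @param element single-row interval table (or list with
#'   `chrom`/`start`/`end`).
#' @param states interval table with a `label` column; segments may tile or
#'   partially cover the element but segments with different labels must not
#'   overlap.
#' @return a tibble with columns `label`, `bp`, `fraction`.
#' @export
state_composition <- function(element, states) {
  el <- as_region(element)
  validate_intervals(states, arg = "states")
  stopifnot("label" %in% names(states))
  st <- dplyr::arrange(states[states$end > states$start, ], .data$start)
  if (nrow(st) > 1) {
    ov <- st$start[-1] < st$end[-nrow(st)]
    if (any(ov & st$label[-1] != st$label[-nrow(st)])) {
      rlang::abort("state segments with different labels overlap")
    }
  }
  el_len <- el$end - el$start
  elr <- IRanges::IRanges(el$start + 1, el$end)
  per <- dplyr::group_by(st, .data$label)
  per <- dplyr::summarise(per, bp = {
    m <- merge_intervals(dplyr::pick(dplyr::everything())[c("chrom", "start", "end")])
    sum(IRanges::width(IRanges::intersect(as_iranges(m), elr)))
  }, .groups = "drop")
  per <- per[per$bp > 0, ]
  covered <- sum(per$bp)
  if (covered < el_len) {
    per <- dplyr::bind_rows(per, tibble::tibble(label = "none",
                                                bp = el_len - covered))
  }
  dplyr::mutate(dplyr::arrange(per, dplyr::desc(.data$bp)),
                fraction = .data$bp / el_len)
}
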