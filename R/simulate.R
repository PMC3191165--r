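#' Simulation parameters for synthetic banding regions
#'
#' Defaults emulate a well-characterized X-chromosome region: nine
#' interbands of 600-3000 bp separating eight bands, the two flanking bands
#' being large (150-200 kb) late-replicating intercalary-heterochromatin
#' (IH) bands and the six in between thin (2-17 kb) early-replicating faint
#' bands. Open-chromatin evidence (interband proteins, DHS, H1 dips, ORC)
#' co-localizes in the interbands; IH bands carry late-replication, SUUR and
#' lamin cover and repressive chromatin labels; faint bands carry active
#' chromatin without open-chromatin features.
#'
#' @param n_interbands number of planted interbands (>= 1).
#' @param interband_size_range,ih_band_size_range,faint_band_size_range size
#'   ranges in bp to draw element lengths from (uniform).
#' @param ih_band_count how many bands are IH type; they occupy the
#'   outermost band slots.
#' @param ih_late_fraction fraction of each IH band (from its distal/left
#'   end) covered by late-replication and SUUR calls, recycled across IH
#'   bands; default 1 (fully late).
#' @param marker_classes evidence classes to simulate (default: all six —
#'   interband proteins, DHS, H1 dips, ORC, active chromatin state, histone
#'   variant — the full open-chromatin ensemble observed at interbands); the
#'   `interband_protein` class carries markers Chriz, BEAF-32 and WDS, the
#'   others one track each.
#' @param cell_types cell types per marker (tracks are duplicated with
#'   independent jitter).
#' @param snr signal-to-noise odds of feature enrichment inside versus
#'   outside the true interbands: each interband receives each marker class
#'   with probability `snr / (1 + snr)`, and spurious features are planted
#'   outside interbands at the matching expected count
#'   `n_interbands / (1 + snr)` per class, so that the expected fraction of
#'   a class's features with midpoint in a true interband is
#'   `snr / (1 + snr)`.
#' @param false_feature_rate additional spurious features per kb per class
#'   on top of the snr-determined load (default 0; raise it, or use
#'   [corrupt_panel()], for robustness experiments).
#' @param border_jitter_sd Gaussian jitter (bp) on feature borders; default
#'   50 bp, the resolution at which tiling-array enrichment borders are
#'   defined.
#' @param flank `"interband"` (region starts and ends with an interband,
#'   printed-map style: n bands = n_interbands - 1) or `"band"`
#'   (n bands = n_interbands + 1).
#' @param ins_rate_ib,ins_rate_band transposon insertions per kb inside
#'   interbands / bands.
#' @param region_length optional total length; `NULL` (default) lets the
#'   drawn element sizes determine it.
#' @param seed integer seed driving every draw through one generator stream.
#' @return a list of class `sim_params`.
#' @export
sim_params <- function(n_interbands = 9,
                       interband_size_range = c(600, 3000),
                       ih_band_count = 2,
                       ih_band_size_range = c(150000, 200000),
                       faint_band_size_range = c(2000, 17000),
                       ih_late_fraction = 1,
                       marker_classes = c("interband_protein", "dhs",
                                          "h1_dip", "orc", "active_state",
                                          "histone_variant"),
                       cell_types = "Kc",
                       snr = 5,
                       false_feature_rate = 0,
                       border_jitter_sd = 50,
                       flank = c("interband", "band"),
                       ins_rate_ib = 5, ins_rate_band = 0.5,
                       region_length = NULL,
                       seed = 1L) {
  stopifnot(n_interbands >= 1, snr > 0, border_jitter_sd >= 0,
            false_feature_rate >= 0, ih_band_count >= 0,
            all(interband_size_range > 0), all(ih_band_size_range > 0),
            all(faint_band_size_range > 0))
  flank <- match.arg(flank)
  n_bands <- if (flank == "interband") n_interbands - 1 else n_interbands + 1
  if (ih_band_count > n_bands) rlang::abort("more IH bands than band slots")
  marker_classes <- match.arg(marker_classes, evidence_classes,
                              several.ok = TRUE)
  structure(as.list(environment()), class = "sim_params")
}

## marker names per simulated evidence class
sim_markers <- function(classes) {
  defaults <- list(interband_protein = c("Chriz", "BEAF-32", "WDS"),
                   dhs = "DHS", h1_dip = "H1_dip", orc = "ORC2",
                   active_state = "state1", histone_variant = "H3.3")
  defaults[classes]
}

#' Generate a synthetic region with planted ground truth
#'
#' Deterministic given `params$seed` (one generator stream; draws occur in
#' the order: element sizes, per-class marker presence and jitter, spurious
#' features, insertions, axial lengths, gene placement). Returns the planted
#' banding map together with every input the pipeline consumes, so that
#' calls, classifications and summaries can be scored against truth.
#'
#' @param params a [sim_params()] list.
#' @return a list of class `synthetic_truth`: `map` (planted `banding_map`
#'   with `band_class` on bands), `panel` (`marker_panel`; features carry an
#'   `origin` column `"true"`/`"spurious"`), `late`, `suur`, `lamin`
#'   (interval tables), `states` (labeled interval table: BLACK for IH,
#'   YELLOW for faint bands, RED for interbands), `genes`, `insertions`
#'   (position vector), `axial` (name/a_um/a_sd), and `params`.
#' @export
generate_region <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(p$seed)

  ## --- planted element sizes and layout -------------------------------
  n_bands <- if (p$flank == "interband") p$n_interbands - 1 else p$n_interbands + 1
  band_type <- rep("faint_early", n_bands)
  if (p$ih_band_count > 0) {
    ## IH bands take the outermost slots, alternating left/right
    slots <- integer(0)
    lo <- 1; hi <- n_bands
    for (i in seq_len(p$ih_band_count)) {
      if (i %% 2 == 1) { slots <- c(slots, lo); lo <- lo + 1 }
      else { slots <- c(slots, hi); hi <- hi - 1 }
    }
    band_type[slots] <- "IH_late"
  }
  ib_size <- round(stats::runif(p$n_interbands, p$interband_size_range[1],
                                p$interband_size_range[2]))
  band_size <- ifelse(
    band_type == "IH_late",
    round(stats::runif(n_bands, p$ih_band_size_range[1], p$ih_band_size_range[2])),
    round(stats::runif(n_bands, p$faint_band_size_range[1],
                       p$faint_band_size_range[2])))
  ## interleave
  if (p$flank == "interband") {
    types <- c(rbind("interband", c(band_type, NA)))[seq_len(2 * p$n_interbands - 1)]
    sizes <- c(rbind(ib_size, c(band_size, NA)))[seq_len(2 * p$n_interbands - 1)]
  } else {
    types <- c(rbind(band_type,
                     rep("interband", n_bands)))[seq_len(2 * n_bands - 1)]
    sizes <- c(rbind(band_size, c(ib_size, NA)))[seq_len(2 * n_bands - 1)]
  }
  total <- sum(sizes)
  if (!is.null(p$region_length)) {
    if (p$region_length < total) {
      rlang::abort("region_length too short for the drawn element sizes")
    }
    total <- p$region_length  # trailing slack becomes part of the last band
  }
  starts <- cumsum(c(0, utils::head(sizes, -1)))
  elements <- tibble::tibble(
    chrom = "chrX", start = starts, end = starts + sizes,
    type = ifelse(types == "interband", "interband", "band"),
    band_class = ifelse(types == "interband", NA_character_, types))
  region <- list(chrom = "chrX", start = 0, end = total)
  if (!is.null(p$region_length)) elements$end[nrow(elements)] <- total
  ib <- elements[elements$type == "interband", ]
  bd <- elements[elements$type == "band", ]
  map <- new_banding_map(
    dplyr::mutate(elements,
                  name = element_names(elements$type, elements$band_class)),
    region)

  ## --- marker panel ----------------------------------------------------
  markers <- sim_markers(p$marker_classes)
  p_present <- p$snr / (1 + p$snr)
  tracks <- list()
  for (cl in names(markers)) {
    present <- stats::runif(nrow(ib)) < p_present
    for (m in markers[[cl]]) {
      for (ct in p$cell_types) {
        feats <- true_features(ib[present, ], cl, p$border_jitter_sd, region)
        n_spur <- stats::rpois(1, nrow(ib) / (1 + p$snr) +
                                 p$false_feature_rate *
                                   (region$end - region$start) / 1000)
        spur <- spurious_features(region, ib, n_spur)
        tracks[[length(tracks) + 1]] <- tibble::tibble(
          marker = m, cell_type = ct, class = cl,
          features = list(dplyr::bind_rows(feats, spur)))
      }
    }
  }
  panel <- marker_panel(region, dplyr::bind_rows(tracks))

  ## --- replication / repressive-domain tracks -------------------------
  ihb <- bd[bd$band_class == "IH_late", ]
  frac <- rep_len(p$ih_late_fraction, nrow(ihb))
  late <- tibble::tibble(chrom = "chrX", start = ihb$start,
                         end = ihb$start + ceiling(frac * (ihb$end - ihb$start)))
  suur <- late
  lamin <- tibble::tibble(chrom = "chrX", start = ihb$start, end = ihb$end)

  ## --- chromatin-state labels ------------------------------------------
  states <- dplyr::mutate(
    elements[c("chrom", "start", "end")],
    label = dplyr::case_when(elements$type == "interband" ~ "RED",
                             elements$band_class == "IH_late" ~ "BLACK",
                             TRUE ~ "YELLOW"))

  ## --- transposon insertions -------------------------------------------
  lens <- interval_length(elements)
  rate <- ifelse(elements$type == "interband", p$ins_rate_ib, p$ins_rate_band)
  n_ins <- stats::rpois(nrow(elements), rate * lens / 1000)
  insertions <- sort(unlist(purrr::map(seq_len(nrow(elements)), function(i) {
    floor(stats::runif(n_ins[i], elements$start[i], elements$end[i]))
  })))

  ## --- axial lengths (EM emulation) ------------------------------------
  ratio_range <- function(type, class) {
    if (type == "interband") c(3, 15)
    else if (class == "IH_late") c(150, 210)
    else c(10, 75)
  }
  ratios <- purrr::map2_dbl(elements$type, elements$band_class, function(t, cl) {
    r <- ratio_range(t, cl); stats::runif(1, r[1], r[2])
  })
  a_um <- (interval_length(map) * 0.34 / 1000) / ratios
  axial <- tibble::tibble(name = map$name, a_um = a_um, a_sd = 0.1 * a_um,
                          true_ratio = ratios)

  ## --- gene models mimicking interband contexts ------------------------
  genes <- sim_genes(ib, bd, region)

  structure(list(map = map, panel = panel, late = late, suur = suur,
                 lamin = lamin, states = states, genes = genes,
                 insertions = insertions, axial = axial, params = p),
            class = "synthetic_truth")
}

element_names <- function(type, band_class) {
  nm <- character(length(type))
  nm[type == "interband"] <- paste0("IB", seq_len(sum(type == "interband")))
  nm[type == "band"] <- paste0("B", seq_len(sum(type == "band")))
  nm
}

## jittered copies of the truth interbands for one evidence class; every
## class emulates smoothed enrichment regions, so features span the
## interband with border jitter (ORC binding sites are point-like, but the
## tracks that report them are kilobase-scale enrichment regions)
true_features <- function(ib, class, jitter_sd, region) {
  if (nrow(ib) == 0) {
    return(tibble::tibble(chrom = character(), start = double(),
                          end = double(), origin = character()))
  }
  s <- round(ib$start + stats::rnorm(nrow(ib), 0, jitter_sd))
  e <- round(ib$end + stats::rnorm(nrow(ib), 0, jitter_sd))
  e <- pmax(e, s + 50)  # keep a sensible minimum feature width
  tibble::tibble(chrom = ib$chrom,
                 start = pmax(region$start, s),
                 end = pmin(region$end, e),
                 origin = "true")
}

## n spurious features with midpoints outside true interbands
spurious_features <- function(region, ib, n) {
  if (n == 0) {
    return(tibble::tibble(chrom = character(), start = double(),
                          end = double(), origin = character()))
  }
  w <- round(stats::runif(n, 400, 1500))
  mid <- floor(stats::runif(n, region$start, region$end))
  in_ib <- rep(FALSE, n)
  if (nrow(ib) > 0) {
    for (i in seq_len(nrow(ib))) {
      in_ib <- in_ib | (mid >= ib$start[i] & mid < ib$end[i])
    }
  }
  w <- w[!in_ib]; mid <- mid[!in_ib]
  tibble::tibble(chrom = region$chrom,
                 start = pmax(region$start, mid - floor(w / 2)),
                 end = pmin(region$end, mid + ceiling(w / 2)),
                 origin = "spurious")
}

## one gene layout per interband, cycling through the contexts observed at
## real interbands: mostly divergent 5' pairs, plus an intergenic gap, a
## first-exon overlap and one internal exception
sim_genes <- function(ib, bd, region) {
  n <- nrow(ib)
  plan <- rep("five_prime_pair", n)
  if (n >= 3) plan[3] <- "intergenic"
  if (n >= 5) plan[5] <- "first_exon"
  if (n >= 2) plan[2] <- "five_prime"
  if (n >= 1) plan[n] <- "internal"
  rows <- list()
  gid <- 0
  nextid <- function() { gid <<- gid + 1; sprintf("gene%02d", gid) }
  for (i in seq_len(n)) {
    s <- ib$start[i]; e <- ib$end[i]; mid <- floor((s + e) / 2)
    glen <- 4000
    ## genes are sized to the local layout: they never cross the midline of
    ## a flanking band, so one interband's genes cannot invade the next
    left_band <- bd[bd$end == s, ]
    right_band <- bd[bd$start == e, ]
    lb <- if (nrow(left_band)) s - floor(0.45 * (s - left_band$start[1])) else region$start
    rb <- if (nrow(right_band)) e + floor(0.45 * (right_band$end[1] - e)) else region$end
    add <- function(start, end, strand, fe_len = 500) {
      start <- max(region$start, lb, start); end <- min(region$end, rb, end)
      if (end - start < 100) return(invisible())  # clipped away at the flank
      fe_len <- min(fe_len, end - start)
      rows[[length(rows) + 1]] <<- gene_models(
        id = nextid(), chrom = ib$chrom[i], start = start, end = end,
        strand = strand,
        first_exon_start = if (strand == "+") start else end - fe_len,
        first_exon_end = if (strand == "+") start + fe_len else end)
    }
    switch(plan[i],
      five_prime_pair = {    # divergent promoters inside the interband
        add(mid - 100 - glen, mid - 100, "-")
        add(mid + 100, mid + 100 + glen, "+")
      },
      five_prime = {         # single gene starting in the interband
        add(mid, mid + glen, "+")
      },
      intergenic = {         # genes kept well clear of the interband
        add(s - 2000 - glen, s - 2000, "-")
        add(e + 2000, e + 2000 + glen, "+")
      },
      first_exon = {         # interband inside a long first exon, TSS distant
        add(s - 1500, s - 1500 + glen + (e - s), "+",
            fe_len = 1500 + (e - s))
      },
      internal = {           # interband mid-gene, far from the 5' end
        add(s - 3000, e + 3000, "+", fe_len = 400)
      })
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$start)
}

#' Corrupt a synthetic panel
#'
#' Deletes true features and/or adds spurious ones at given per-feature /
#' per-kb rates, leaving the stored ground truth untouched so recovery can
#' still be scored.
#'
#' @param truth a `synthetic_truth`.
#' @param delete_rate probability in `[0, 1]` of deleting each true feature.
#' @param add_rate spurious features per kb per track, in `[0, 1]`.
#' @param seed seed for the corruption draws.
#' @return a `marker_panel`.
#' @export
corrupt_panel <- function(truth, delete_rate = 0, add_rate = 0, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (delete_rate < 0 || delete_rate > 1 || add_rate < 0 || add_rate > 1) {
    rlang::abort("rates must be in [0, 1]")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  panel <- truth$panel
  ib <- interbands(truth$map)
  panel$tracks$features <- purrr::map(panel$tracks$features, function(f) {
    is_true <- f$origin == "true"
    drop <- is_true & stats::runif(nrow(f)) < delete_rate
    f <- f[!drop, ]
    L_kb <- (panel$region$end - panel$region$start) / 1000
    extra <- spurious_features(panel$region, ib, stats::rpois(1, add_rate * L_kb))
    dplyr::bind_rows(f, extra)
  })
  panel
}

#' Score interband calls against a planted map
#'
#' Each call is matched to the planted interband it maximally overlaps.
#' Precision is the fraction of calls matched to some planted interband,
#' recall the fraction of planted interbands recovered by at least one call,
#' mean Jaccard is averaged over recovered interbands (against their
#' best-overlapping call), and border error is the mean absolute edge
#' displacement of those pairs.
#'
#' @param calls interval table of calls.
#' @param truth_map the planted `banding_map`.
#' @return a one-row tibble: `n_calls`, `n_truth`, `precision`, `recall`,
#'   `mean_jaccard`, `border_error_bp`.
#' @export
evaluate_calls <- function(calls, truth_map) {
  stopifnot(inherits(truth_map, "banding_map"))
  validate_intervals(calls, arg = "calls")
  truth <- interbands(truth_map)
  n_calls <- nrow(calls); n_truth <- nrow(truth)
  if (n_calls == 0) {
    return(tibble::tibble(n_calls = 0L, n_truth = n_truth, precision = NA_real_,
                          recall = 0, mean_jaccard = NA_real_,
                          border_error_bp = NA_real_))
  }
  ov <- function(i, j) max(0, min(calls$end[i], truth$end[j]) -
                              max(calls$start[i], truth$start[j]))
  ovmat <- outer(seq_len(n_calls), seq_len(n_truth), Vectorize(ov))
  matched_call <- apply(ovmat, 1, max) > 0
  recovered <- apply(ovmat, 2, max) > 0
  jac <- border <- rep(NA_real_, n_truth)
  for (j in which(recovered)) {
    i <- which.max(ovmat[, j])
    uni <- (calls$end[i] - calls$start[i]) + (truth$end[j] - truth$start[j]) -
      ovmat[i, j]
    jac[j] <- ovmat[i, j] / uni
    border[j] <- mean(c(abs(calls$start[i] - truth$start[j]),
                        abs(calls$end[i] - truth$end[j])))
  }
  tibble::tibble(n_calls = as.integer(n_calls), n_truth = as.integer(n_truth),
                 precision = mean(matched_call), recall = mean(recovered),
                 mean_jaccard = mean(jac, na.rm = TRUE),
                 border_error_bp = mean(border, na.rm = TRUE))
}

#' @export
print.synthetic_truth <- function(x, ...) {
  r <- attr(x$map, "region")
  cat(sprintf("<synthetic_truth> %s:%s-%s  %d interbands / %d bands, %d tracks\n",
              r$chrom, format(r$start, scientific = FALSE),
              format(r$end, scientific = FALSE),
              sum(x$map$type == "interband"), sum(x$map$type == "band"),
              nrow(x$panel$tracks)))
  invisible(x)
}
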