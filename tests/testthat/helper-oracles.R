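# Brute-force per-base oracles. Every oracle works on an explicit logical or
# integer vector over the region's bases, independently of the interval
# arithmetic used by the package.

# logical coverage vector for [region_start, region_end)
base_cover <- function(df, region_start, region_end) {
  v <- rep(FALSE, region_end - region_start)
  for (i in seq_len(nrow(df))) {
    s <- max(df$start[i], region_start); e <- min(df$end[i], region_end)
    if (e > s) v[(s - region_start + 1):(e - region_start)] <- TRUE
  }
  v
}

# runs of TRUE as an interval tibble
runs_tbl <- function(v, region_start, chrom = "chrX") {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  tibble::tibble(chrom = chrom,
                 start = region_start + starts[keep] - 1,
                 end = region_start + ends[keep])
}

# union with gap closing, per-base
oracle_merge <- function(df, max_gap, region_start, region_end) {
  v <- base_cover(df, region_start, region_end)
  runs <- runs_tbl(v, region_start, chrom = df$chrom[1] %||% "chrX")
  if (nrow(runs) <= 1) return(runs)
  out <- runs[1, ]
  for (i in 2:nrow(runs)) {
    if (runs$start[i] - out$end[nrow(out)] <= max_gap) {
      out$end[nrow(out)] <- runs$end[i]
    } else {
      out <- rbind(out, runs[i, ])
    }
  }
  out
}

oracle_complement <- function(df, region_start, region_end, chrom = "chrX") {
  v <- base_cover(df, region_start, region_end)
  runs_tbl(!v, region_start, chrom)
}

# per-base evidence-class voting caller (candidate runs only, no refinement)
oracle_vote <- function(panel, min_support, merge_gap, min_size, max_size) {
  region <- panel$region
  L <- region$end - region$start
  counts <- rep(0L, L)
  for (cl in unique(panel$tracks$class)) {
    feats <- dplyr::bind_rows(
      panel$tracks$features[panel$tracks$class == cl])
    counts <- counts + base_cover(feats, region$start, region$end)
  }
  cand <- runs_tbl(counts >= min_support, region$start, region$chrom)
  # close gaps <= merge_gap
  if (nrow(cand) > 1) {
    merged <- cand[1, ]
    for (i in 2:nrow(cand)) {
      if (cand$start[i] - merged$end[nrow(merged)] <= merge_gap) {
        merged$end[nrow(merged)] <- cand$end[i]
      } else merged <- rbind(merged, cand[i, ])
    }
    cand <- merged
  }
  len <- cand$end - cand$start
  cand[len >= min_size & len <= max_size, ]
}

# per-base Jaccard of two interval tables
oracle_jaccard <- function(a, b, region_start, region_end) {
  va <- base_cover(a, region_start, region_end)
  vb <- base_cover(b, region_start, region_end)
  if (sum(va | vb) == 0) return(1)
  sum(va & vb) / sum(va | vb)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# small panel builder: features given as list(class = list(c(start, end), ...))
toy_panel <- function(features_by_class, region_end = 10000, cell = "Kc") {
  region <- list(chrom = "chrX", start = 0, end = region_end)
  p <- marker_panel(region)
  markers <- c(interband_protein = "Chriz", dhs = "DHS", h1_dip = "H1_dip",
               orc = "ORC2", active_state = "state1", histone_variant = "H3.3")
  for (cl in names(features_by_class)) {
    ivs <- features_by_class[[cl]]
    df <- tibble::tibble(chrom = "chrX",
                         start = vapply(ivs, `[`, 0, 1),
                         end = vapply(ivs, `[`, 0, 2))
    p <- add_track(p, markers[[cl]], cl, df, cell_type = cell)
  }
  p
}

# random interval table within [0, max_end)
random_intervals <- function(n, max_end, max_len = NULL, chrom = "chrX") {
  max_len <- max_len %||% max_end
  s <- sample.int(max_end, n, replace = TRUE) - 1
  len <- sample.int(max_len, n, replace = TRUE)
  tibble::tibble(chrom = chrom, start = s, end = pmin(s + len, max_end))
}

table1_path <- function() chromoband_example("bands")
table2_path <- function() chromoband_example("axial")
table3_path <- function() chromoband_example("probes")

table1_region <- function(tbl) {
  list(chrom = "chrX", start = min(tbl$start), end = max(tbl$end))
}
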