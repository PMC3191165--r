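test_that("banding maps tile the region with strict alternation", {
  tbl <- read_band_table(table1_path())
  region <- table1_region(tbl)
  ib <- tbl[tbl$type == "interband", ]
  map <- build_banding_map(ib, region, labels = tbl[c("chrom", "start", "end", "name")])
  expect_equal(sum(map$type == "interband"), 9)
  expect_equal(sum(map$type == "band"), 8)   # nine interband borders -> eight bands
  expect_equal(map$name[map$type == "band"][1], "10A1-2")
  # zero calls -> one band spanning the region
  one <- build_banding_map(interval_tbl(), region)
  expect_equal(nrow(one), 1)
  expect_equal(interval_length(one), region$end - region$start)
  # random disjoint calls: per-base tiling oracle + conservation
  set.seed(17)
  for (rep in 1:8) {
    calls <- merge_intervals(random_intervals(10, 50000, max_len = 3000))
    m <- build_banding_map(calls, list(chrom = "chrX", start = 0, end = 50000))
    expect_true(all(m$type[-1] != m$type[-nrow(m)]))
    expect_equal(m$start[-1], m$end[-nrow(m)])  # no gaps, no overlaps
    s <- summarize_region(m)
    expect_equal(s$interband_bp + s$band_bp, 50000)
    got_ib <- interbands(m)
    expect_equal(base_cover(got_ib, 0, 50000), base_cover(calls, 0, 50000))
    # rebuilding from the extracted interbands is the identity
    m2 <- build_banding_map(got_ib, list(chrom = "chrX", start = 0, end = 50000))
    expect_equal(m2$start, m$start)
    expect_equal(m2$end, m$end)
  }
  expect_error(build_banding_map(
    interval_tbl("chrX", c(0, 50), c(100, 150)), region), "overlap")
})

test_that("printed element tables load as maps only in lenient mode", {
  tbl <- read_band_table(table1_path())
  expect_error(banding_map_from_elements(tbl), "tile")
  map <- banding_map_from_elements(tbl, strict = FALSE)
  expect_equal(attr(map, "boundary_gap_bp"), 16)  # one base per printed boundary
  expect_equal(nrow(map), 17)
})

test_that("band classification separates IH from faint bands", {
  region <- list(chrom = "chrX", start = 0, end = 10000)
  map <- build_banding_map(interval_tbl("chrX", c(0, 4000), c(1000, 5000)),
                           region)
  full <- interval_tbl("chrX", 1000, 4000)
  # fully late + SUUR + lamin, no open markers -> IH_late
  cl <- classify_bands(map, late = full, suur = full, lamin = full)
  expect_equal(bands(cl)$band_class, c("IH_late", "faint_early"))
  # no late/SUUR cover -> faint_early
  cl0 <- classify_bands(map, late = interval_tbl())
  expect_true(all(bands(cl0)$band_class == "faint_early"))
  # threshold monotonicity: raising t_late never converts faint to IH
  part <- interval_tbl("chrX", 1000, 2200)  # 40% of the 3000-bp band
  for (t1 in c(0.2, 0.4, 0.6)) {
    a <- bands(classify_bands(map, late = part, t_late = t1))$band_class
    b <- bands(classify_bands(map, late = part, t_late = t1 + 0.2))$band_class
    expect_true(all(!(a == "faint_early" & b == "IH_late")))
  }
  expect_error(classify_bands(map, late = NULL), "late")
})

test_that("two IH and six faint bands are recovered from a realistic fixture", {
  # two flanking dense bands: one fully late-replicating, one late over only
  # its distal 40%, plus six faint bands carrying no repressive cover
  tr <- generate_region(sim_params(seed = 5, ih_late_fraction = c(1, 0.4)))
  open_feats <- dplyr::filter(tidy(tr$panel), .data$origin == "true")
  cl <- classify_bands(tr$map, late = tr$late, suur = tr$suur,
                       lamin = tr$lamin, open = open_feats)
  got <- bands(cl)
  expect_equal(sum(got$band_class == "IH_late"), 2)
  expect_equal(sum(got$band_class == "faint_early"), 6)
  # the classes land on the planted ones
  expect_equal(got$band_class, bands(tr$map)$band_class)
})

test_that("region summaries report counts, totals and fractions", {
  tbl <- read_band_table(table1_path())
  map <- build_banding_map(tbl[tbl$type == "interband", ], table1_region(tbl))
  s <- summarize_region(map)
  expect_equal(s$n_interbands, 9)
  expect_equal(s$n_bands, 8)
  expect_equal(s$interband_bp + s$band_bp, s$region_bp)
  # worked example from stated totals: 20,100 bp of 428,307 bp = 4.69%
  expect_equal(interband_fraction(20100, 428307), 4.69)
  # single-band map has interband fraction 0
  single <- build_banding_map(interval_tbl(),
                              list(chrom = "chrX", start = 0, end = 1000))
  expect_equal(summarize_region(single)$interband_fraction, 0)
  expect_equal(glance(map), s)
})

test_that("map comparison reports per-band overlap and interband Jaccard", {
  region <- list(chrom = "chrX", start = 0, end = 20000)
  a <- build_banding_map(interval_tbl("chrX", c(2000, 9000), c(3000, 10000)),
                         region)
  expect_equal(compare_maps(a, a)$interband_jaccard, 1)
  expect_true(all(compare_maps(a, a)$elements$jaccard == 1))
  # disjoint interband sets -> global interband Jaccard 0
  b <- build_banding_map(interval_tbl("chrX", c(5000, 14000), c(6000, 15000)),
                         region)
  expect_equal(compare_maps(a, b)$interband_jaccard, 0)
  # random maps vs brute-force base counting
  set.seed(23)
  for (rep in 1:5) {
    x <- build_banding_map(merge_intervals(random_intervals(4, 10000, max_len = 800)),
                           list(chrom = "chrX", start = 0, end = 10000))
    y <- build_banding_map(merge_intervals(random_intervals(4, 10000, max_len = 800)),
                           list(chrom = "chrX", start = 0, end = 10000))
    cmp <- compare_maps(x, y)
    expect_equal(cmp$interband_jaccard,
                 oracle_jaccard(interbands(x), interbands(y), 0, 10000))
    for (i in seq_len(nrow(cmp$elements))) {
      el <- cmp$elements[i, ]
      ov <- vapply(seq_len(nrow(bands(y))), function(j) {
        bj <- bands(y)[j, ]
        max(0, min(el$end, bj$end) - max(el$start, bj$start))
      }, numeric(1))
      expect_equal(el$overlap_bp, max(ov))
    }
  }
  short <- build_banding_map(interval_tbl(),
                             list(chrom = "chrX", start = 0, end = 500))
  expect_error(compare_maps(a, short), "different regions")
})
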