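test_that("cell-type combination modes match per-base voting", {
  region <- list(chrom = "chrX", start = 0, end = 2000)
  p <- marker_panel(region)
  p <- add_track(p, "Chriz", "interband_protein",
                 interval_tbl("chrX", 100, 400), cell_type = "S2")
  # single cell type: any mode returns the set unchanged
  for (m in c("union", "intersection", "majority")) {
    got <- combine_cell_types(p, "Chriz", m)
    expect_equal(got$start, 100)
    expect_equal(got$end, 400)
  }
  # two disjoint cell types: intersection empty, union both
  p <- add_track(p, "Chriz", "interband_protein",
                 interval_tbl("chrX", 600, 900), cell_type = "BG3")
  expect_equal(nrow(combine_cell_types(p, "Chriz", "intersection")), 0)
  expect_equal(nrow(combine_cell_types(p, "Chriz", "union")), 2)
  expect_error(combine_cell_types(p, "nope"), "unknown marker")
  # three random cell types: majority = per-base 2-of-3 vote
  set.seed(21)
  for (rep in 1:5) {
    q <- marker_panel(region)
    sets <- list()
    for (ct in c("S2", "BG3", "Kc")) {
      x <- merge_intervals(random_intervals(6, 2000, max_len = 300))
      sets[[ct]] <- x
      q <- add_track(q, "DHS", "dhs", x, cell_type = ct)
    }
    got <- combine_cell_types(q, "DHS", "majority")
    votes <- Reduce(`+`, lapply(sets, base_cover, 0, 2000))
    want <- runs_tbl(votes >= 2, 0)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("interband calling equals the per-base voting oracle exactly", {
  # hand-built panel, 3 evidence classes over 10 kb
  p <- toy_panel(list(
    interband_protein = list(c(1000, 1800), c(4000, 4900), c(8000, 8700)),
    dhs = list(c(1100, 1700), c(4200, 5100)),
    h1_dip = list(c(950, 1850), c(8100, 8600))))
  prm <- caller_params(min_support = 2, merge_gap = 0)
  calls <- call_interbands(p, prm)
  want <- oracle_vote(p, 2, 0, prm$min_size, prm$max_size)
  expect_equal(calls$start, want$start)
  expect_equal(calls$end, want$end)
  expect_equal(calls$support,
               c("dhs,h1_dip,interband_protein", "dhs,interband_protein",
                 "h1_dip,interband_protein"))
  # random panels across parameter settings
  set.seed(31)
  for (rep in 1:8) {
    q <- toy_panel(list(
      interband_protein = lapply(1:6, function(i) sort(sample.int(20000, 2))),
      dhs = lapply(1:5, function(i) sort(sample.int(20000, 2))),
      orc = lapply(1:4, function(i) sort(sample.int(20000, 2))),
      h1_dip = lapply(1:4, function(i) sort(sample.int(20000, 2)))),
      region_end = 20000)
    for (ms in 1:3) {
      prm <- caller_params(min_support = ms, merge_gap = 100, min_size = 300,
                           max_size = 20000 - 1)
      got <- call_interbands(q, prm)
      want <- oracle_vote(q, ms, 100, 300, 20000 - 1)
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_true(all(got$n_classes >= pmin(ms, 4)))
      # calls sorted and disjoint
      if (nrow(got) > 1) {
        expect_true(all(diff(got$start) > 0))
        expect_true(all(got$start[-1] >= got$end[-nrow(got)]))
      }
    }
  }
  # empty panel -> empty call list
  empty <- marker_panel(list(chrom = "chrX", start = 0, end = 10000))
  expect_equal(nrow(call_interbands(empty)), 0)
  small <- marker_panel(list(chrom = "chrX", start = 0, end = 100))
  expect_error(call_interbands(small), "min_size")
})

test_that("raising min_support never increases called bases", {
  set.seed(41)
  for (rep in 1:5) {
    tr <- generate_region(sim_params(seed = 500 + rep))
    bp <- vapply(1:4, function(ms) {
      calls <- call_interbands(tr$panel, caller_params(min_support = ms))
      sum(interval_length(calls))
    }, numeric(1))
    expect_true(all(diff(bp) <= 0))
  }
})

test_that("border refinement finds evidence peaks and distribution edges", {
  # single rectangular feature: peak at its midpoint, edges at its ends
  p <- toy_panel(list(dhs = list(c(2000, 3000))))
  calls <- call_interbands(p, caller_params(min_support = 1), refine = TRUE)
  expect_equal(calls$start, 2000)
  expect_equal(calls$end, 3000)
  expect_equal(calls$peak, 2500)
  # two offset equal-height features: peak at the intersection midpoint,
  # edges spanning the union
  p2 <- toy_panel(list(dhs = list(c(1000, 3000)),
                       h1_dip = list(c(2000, 4000))))
  calls2 <- call_interbands(p2, caller_params(min_support = 1), refine = TRUE)
  expect_equal(calls2$start, 1000)
  expect_equal(calls2$end, 4000)
  expect_equal(calls2$peak, 2500)
  expect_equal(calls2$n_classes, 2L)
  # random stacked features: peak lies in the argmax run of per-base counts
  set.seed(51)
  for (rep in 1:5) {
    q <- toy_panel(list(
      dhs = lapply(1:3, function(i) 3000 + sort(sample.int(2000, 2))),
      h1_dip = lapply(1:3, function(i) 3000 + sort(sample.int(2000, 2))),
      orc = lapply(1:2, function(i) 3000 + sort(sample.int(2000, 2)))))
    calls <- call_interbands(q, caller_params(min_support = 1,
                                              merge_gap = 2000), refine = TRUE)
    counts <- rep(0, 10000)
    for (cl in unique(q$tracks$class)) {
      feats <- dplyr::bind_rows(q$tracks$features[q$tracks$class == cl])
      counts <- counts + base_cover(feats, 0, 10000)
    }
    for (i in seq_len(nrow(calls))) {
      inside <- counts[(calls$start[i] + 1):calls$end[i]]
      expect_equal(counts[calls$peak[i] + 1], max(inside))
    }
  }
})

test_that("probe concordance reports overlaps, signed distances and ties", {
  calls <- interval_tbl("chrX", c(1000, 5000), c(2000, 6000))
  # probe inside a call
  inside <- probe_concordance(calls, interval_tbl("chrX", 1200, 1400))
  expect_equal(inside$distance, 0)
  # probe equidistant from two calls -> left call, flagged
  tie <- probe_concordance(calls, interval_tbl("chrX", 3400, 3600))
  expect_equal(tie$call_start, 1000)
  expect_true(tie$tie)
  # printed FISH probes vs the printed interband set: distances by direct
  # interval arithmetic (several probes fall just outside the printed
  # interband extents; they are reported, not asserted inside)
  tbl <- read_band_table(table1_path())
  probes <- read_probe_table(table3_path())
  pc <- probe_concordance(tbl[tbl$type == "interband", ], probes)
  expect_equal(pc$distance[pc$probe == "spas_9F_10A"], 137)
  expect_equal(pc$distance[pc$probe == "CG15208"], 1463)
  expect_equal(pc$distance[pc$probe == "CG1582"], -806)
  expect_equal(pc$distance[pc$probe == "Vago"], -213)
  expect_equal(pc$distance[pc$probe == "CG2076"], 0)
  expect_equal(pc$distance[pc$probe == "l(1)10Bb"], 0)
})
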