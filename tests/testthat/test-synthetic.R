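test_that("generation is deterministic and lays out the planted map", {
  a <- generate_region(sim_params(seed = 7))
  b <- generate_region(sim_params(seed = 7))
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  expect_false(identical(serialize(a, NULL),
                         serialize(generate_region(sim_params(seed = 8)), NULL)))
  # printed-map layout: region starts and ends with an interband
  expect_equal(sum(a$map$type == "interband"), 9)
  expect_equal(sum(a$map$type == "band"), 8)
  expect_equal(a$map$type[1], "interband")
  expect_equal(a$map$type[nrow(a$map)], "interband")
  # band-flanked layout
  fl <- generate_region(sim_params(seed = 7, flank = "band"))
  expect_equal(sum(fl$map$type == "band"), 10)
  expect_equal(fl$map$type[1], "band")
  # two IH bands at the outermost slots
  bd <- bands(a$map)
  expect_equal(which(bd$band_class == "IH_late"), c(1L, 8L))
  # map tiles its region
  expect_equal(bd$start, interbands(a$map)$end[-9])
  # element sizes respect the configured ranges
  expect_true(all(interval_length(interbands(a$map)) >= 600 &
                  interval_length(interbands(a$map)) <= 3000))
  # infeasible packing
  expect_error(generate_region(sim_params(seed = 1, region_length = 1000)),
               "too short")
})

test_that("marker features land in interbands at the configured odds", {
  # midpoint-in-interband fraction across seeds within 3 binomial SDs of
  # snr/(1+snr), per evidence class
  n_in <- 0; n_tot <- 0
  for (s in 1:20) {
    tr <- generate_region(sim_params(seed = 200 + s))
    f <- tidy(tr$panel)
    mids <- floor((f$start + f$end) / 2)
    ibv <- interbands(tr$map)
    inib <- vapply(mids, function(m) any(m >= ibv$start & m < ibv$end),
                   logical(1))
    n_in <- n_in + sum(inib); n_tot <- n_tot + length(inib)
  }
  p <- 5 / 6
  expect_lt(abs(n_in / n_tot - p), 3 * sqrt(p * (1 - p) / n_tot))
})

test_that("panel corruption respects its rates and preserves truth", {
  tr <- generate_region(sim_params(seed = 9))
  # zero rates: identity
  same <- corrupt_panel(tr, delete_rate = 0, add_rate = 0)
  expect_identical(same$tracks$features, tr$panel$tracks$features)
  # delete rate 1: only spurious features remain
  gone <- corrupt_panel(tr, delete_rate = 1)
  remaining <- dplyr::bind_rows(gone$tracks$features)
  expect_true(all(remaining$origin == "spurious"))
  expect_error(corrupt_panel(tr, delete_rate = 1.2), "rates")
  # realized deletion fraction within 3 binomial SDs over many draws
  n_true <- sum(dplyr::bind_rows(tr$panel$tracks$features)$origin == "true")
  deleted <- 0; total <- 0
  for (s in 1:50) {
    cp <- corrupt_panel(tr, delete_rate = 0.3, seed = s)
    left <- sum(dplyr::bind_rows(cp$tracks$features)$origin == "true")
    deleted <- deleted + (n_true - left); total <- total + n_true
  }
  expect_lt(abs(deleted / total - 0.3), 3 * sqrt(0.3 * 0.7 / total))
})

test_that("call scoring matches a brute-force matching oracle", {
  tr <- generate_region(sim_params(seed = 10))
  truth <- interbands(tr$map)
  # calls identical to truth: perfect scores
  perfect <- evaluate_calls(truth, tr$map)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$mean_jaccard, 1)
  expect_equal(perfect$border_error_bp, 0)
  # no calls: zero recall
  expect_equal(evaluate_calls(interval_tbl(), tr$map)$recall, 0)
  # perturbed calls vs direct recomputation
  set.seed(61)
  for (rep in 1:5) {
    shift <- sample(-300:300, nrow(truth), replace = TRUE)
    calls <- dplyr::mutate(truth, start = pmax(0, start + shift),
                           end = end + shift)
    keep <- sort(sample.int(nrow(calls), 6))
    calls <- calls[keep, ]
    ev <- evaluate_calls(calls, tr$map)
    jac <- vapply(seq_len(nrow(truth)), function(j) {
      ov <- pmax(0, pmin(calls$end, truth$end[j]) - pmax(calls$start, truth$start[j]))
      if (max(ov) == 0) return(NA_real_)
      i <- which.max(ov)
      ov[i] / (calls$end[i] - calls$start[i] +
                 truth$end[j] - truth$start[j] - ov[i])
    }, numeric(1))
    expect_equal(ev$recall, mean(!is.na(jac)))
    expect_equal(ev$mean_jaccard, mean(jac, na.rm = TRUE))
    expect_equal(ev$n_calls, 6L)
  }
})

test_that("synthetic axial lengths encode the planted compaction ranges", {
  tr <- generate_region(sim_params(seed = 12))
  ct <- compaction_table(tr$map, tr$axial, mode = "exact")
  ranges <- list(interband = c(3, 15), faint_early = c(10, 75),
                 IH_late = c(150, 210))
  for (i in seq_len(nrow(ct))) {
    key <- if (ct$type[i] == "interband") "interband" else
      bands(tr$map)$band_class[match(ct$name[i], bands(tr$map)$name)]
    expect_gte(ct$ratio_exact[i], ranges[[key]][1] * 0.99)
    expect_lte(ct$ratio_exact[i], ranges[[key]][2] * 1.01)
  }
})

test_that("insertions are enriched in interbands", {
  tr <- generate_region(sim_params(seed = 13))
  ibv <- interbands(tr$map)
  inib <- vapply(tr$insertions, function(m) any(m >= ibv$start & m < ibv$end),
                 logical(1))
  ib_kb <- sum(interval_length(ibv)) / 1000
  band_kb <- sum(interval_length(bands(tr$map))) / 1000
  rate_in <- sum(inib) / ib_kb
  rate_out <- sum(!inib) / band_kb
  expect_gt(rate_in, 3 * rate_out)
})
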