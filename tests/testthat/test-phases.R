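test_that("interval grid arithmetic: five equal intervals tiling each period", {
  cyc <- regular_cycles(3, period = 4, insp_fraction = 0.3)  # insp 0-1.2 s
  g <- build_interval_grid(cyc)
  expect_equal(nrow(g), 30)  # 10 intervals per breath
  i1 <- g[g$breath == 1 & g$period == "insp", ]
  expect_equal(i1$duration, rep(0.24, 5))
  expect_equal(i1$t_start[4], 0.72)
  expect_equal(i1$t_end[4], 0.96)
  # tiling: total grid time equals total breath time
  expect_equal(sum(g$duration), sum(cyc$t_trough_next - cyc$t_trough))
})

test_that("a degenerate breath is excluded but leaves the grid valid", {
  cyc <- regular_cycles(3)
  cyc$t_peak[2] <- cyc$t_trough[2]  # zero-length inspiration
  g <- build_interval_grid(cyc)
  expect_true(all(g$excluded[g$breath == 2]))
  expect_equal(unique(g$reason[g$breath == 2]), "zero_length_period")
  expect_false(any(g$excluded[g$breath != 2]))
})

test_that("composite phases follow the 60-100% / 0-60% definitions", {
  cyc <- regular_cycles(5, period = 4, insp_fraction = 0.4)  # insp 1.6 s, exp 2.4 s
  ph <- assemble_phases(build_interval_grid(cyc))
  # breath 2 spans [4, 8): inspiration [4, 5.6), expiration [5.6, 8)
  at <- function(t) respmsna:::assign_phase(t, ph)
  expect_equal(at(4 + 0.7 * 1.6), "inspiration_postinspiration")   # 70% of insp
  expect_equal(at(5.6 + 0.3 * 2.4), "inspiration_postinspiration") # 30% of exp
  expect_equal(at(5.6 + 0.8 * 2.4), "mid_late_expiration")         # 80% of exp
  expect_equal(at(4 + 0.3 * 1.6), "mid_late_expiration")           # 30% of insp
})

test_that("phase windows partition non-excluded grid time", {
  set.seed(41)
  for (rep in 1:5) {
    n <- sample(5:12, 1)
    tr <- cumsum(c(0, stats::runif(n, 2, 6)))
    f <- stats::runif(n, 0.2, 0.6)
    cyc <- tibble::tibble(
      breath = seq_len(n),
      t_trough = tr[-length(tr)],
      t_peak = tr[-length(tr)] + f * diff(tr),
      t_trough_next = tr[-1]
    )
    g <- build_interval_grid(cyc)
    ph <- assemble_phases(g)
    # member intervals are disjoint
    o <- ph[order(ph$t_start), ]
    expect_true(all(diff(o$t_start) >= o$duration[-nrow(o)] - 1e-9))
    # each complete phase instance has 5 members totalling half a breath's span
    dur <- tapply(ph$duration, ph$phase_id, sum)
    expect_true(all(tapply(ph$phase_id, ph$phase_id, length) == 5))
    # phases jointly tile the time they cover: compare against the grid
    # restricted to the covered span
    covered <- range(c(ph$t_start, ph$t_end))
    gin <- g[g$t_start >= covered[1] - 1e-9 & g$t_end <= covered[2] + 1e-9, ]
    expect_equal(sum(ph$duration), sum(gin$duration), tolerance = 1e-9)
  }
})

test_that("boundary phase instances missing cross-breath partners are dropped", {
  cyc <- regular_cycles(4)
  ph <- assemble_phases(build_interval_grid(cyc))
  # the last breath's mid-late expiration needs the next breath's inspiration
  expect_false("mid_late_exp_0004" %in% ph$phase_id)
  expect_true("insp_post_0004" %in% ph$phase_id)
  # the 'same-breath' pairing keeps it
  ph2 <- assemble_phases(build_interval_grid(cyc),
                         expiration_pairing = "same")
  expect_true("mid_late_exp_0004" %in% ph2$phase_id)
})

test_that("artifact exclusion removes whole phase instances", {
  cyc <- regular_cycles(5, period = 4)
  ph <- assemble_phases(build_interval_grid(cyc))
  ng <- const_neurogram(10, 20)
  clean <- exclude_artifact_phases(ph, ng)
  expect_false(any(clean$excluded))

  ng$samples[round(9.0 * ng$fs)] <- 200  # spike at 9 s
  hit <- exclude_artifact_phases(ph, ng)
  spiked <- unique(hit$phase_id[hit$t_start <= 9 & hit$t_end > 9])
  expect_true(all(hit$excluded[hit$phase_id %in% spiked]))
  expect_false(any(hit$excluded[!hit$phase_id %in% spiked]))

  masked <- exclude_artifact_phases(ph, const_neurogram(10, 20),
                                    mask = tibble::tibble(t_start = 4,
                                                          t_end = 8))
  touching <- unique(masked$phase_id[masked$t_start < 8 & masked$t_end > 4])
  expect_gte(length(touching), 2)
  expect_true(all(masked$excluded[masked$phase_id %in% touching]))
})

test_that("phase metric counting and change formulas", {
  cyc <- regular_cycles(6, period = 4, insp_fraction = 0.4)
  ph <- assemble_phases(build_interval_grid(cyc))
  ng <- const_neurogram(10, 24)
  # heartbeats every 0.5 s; bursts placed at known phase times
  r_times <- seq(0.25, 23.75, by = 0.5)
  insp_times <- 4 * (1:4) + 0.4 * 4 * 0.7          # 70% of inspiration
  exp_times <- 4 * (1:4) + 1.6 + 2.4 * 0.8         # 80% of expiration
  bursts <- tibble::tibble(peak_time = c(insp_times, exp_times))
  pm <- phase_metrics(ph, bursts, r_times, ng)
  expect_equal(sort(pm$n_bursts), c(4, 4))
  # constant neurogram: area rates equal the level everywhere
  expect_equal(pm$total_area_per_s, c(10, 10), tolerance = 0.05)
  expect_equal(pm$mean_area_per_s, c(10, 10), tolerance = 0.05)

  fake <- pm
  fake$incidence <- c(40, 80)   # insp first (alphabetical label order)
  chg <- modulation_change(fake)
  inc <- chg[chg$metric == "incidence", ]
  expect_equal(inc$abs_change, -40)
  expect_equal(inc$pct_change, -50)
  fake$incidence <- c(55, 50)
  inc2 <- modulation_change(fake)[1, ]
  expect_equal(inc2$abs_change, 5)
  expect_equal(inc2$pct_change, 10)
  fake$incidence <- c(50, 50)
  expect_equal(modulation_change(fake)$pct_change[1], 0)
  fake$incidence <- c(10, 0)
  expect_true(is.na(modulation_change(fake)$pct_change[1]))
})

test_that("with no exclusions phase counts conserve totals on synthetic data", {
  p <- quick_params(duration_s = 150, seed = 42)
  sub <- generate_subject(p)
  pl <- run_phase_pipeline(sub)
  ph <- pl$phases
  covered <- range(c(ph$t_start, ph$t_end))
  shift <- pl$shifted$shift_applied
  bt <- pl$bursts$peak_time - shift
  expect_equal(sum(pl$metrics$n_bursts),
               sum(bt >= covered[1] & bt < covered[2]))
  r_in <- pl$r[pl$r >= covered[1] & pl$r < covered[2]]
  # R times inside the covered span but in a gap between phase instances
  # (none here: instances tile the span)
  expect_equal(sum(pl$metrics$n_heartbeats), length(r_in))
  expect_equal(sum(pl$metrics$duration_s), diff(covered), tolerance = 1e-6)
})
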