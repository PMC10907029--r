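test_that("subject_params validates its invariants", {
  expect_s3_class(subject_params(), "subject_params")
  expect_error(subject_params(duration_s = -1), "duration_s")
  expect_error(subject_params(insp_fraction = 1), "insp_fraction")
  expect_error(subject_params(burst_prob_exp = 1.2), "probabilities")
  expect_error(subject_params(burst_latency_s = -0.1), "burst_latency_s")
  expect_error(subject_params(sbp_base = 70, dbp_base = 80), "sbp_base")
})

test_that("zero-variance respiration gives identical breaths at exact multiples", {
  p <- subject_params(duration_s = 60, fs = 100, breath_period_mean = 4,
                      breath_period_cv = 0, breath_amp_cv = 0,
                      insp_fraction = 0.3, seed = 1)
  resp <- generate_respiration(p)
  lm <- resp$landmarks
  expect_equal(nrow(lm), 15)
  expect_equal(lm$t_trough, seq(0, 56, by = 4))
  expect_equal(lm$t_trough_next, seq(4, 60, by = 4))
  # inspiration lasts insp_fraction of the period
  expect_equal(lm$t_peak - lm$t_trough, rep(1.2, 15))
  expect_equal(length(resp$respiration), 6000)
})

test_that("respiration generation is deterministic under a seed and errors on degenerate duration", {
  p <- quick_params(duration_s = 30)
  a <- generate_respiration(p, seed = 7)
  b <- generate_respiration(p, seed = 7)
  expect_identical(a$respiration, b$respiration)
  expect_identical(a$landmarks, b$landmarks)
  p_short <- subject_params(duration_s = 1, breath_period_mean = 4,
                            breath_period_cv = 0)
  expect_error(generate_respiration(p_short), "shorter than one breath")
})

test_that("zero cardiac modulation gives constant RR and constant per-beat MAP", {
  p <- subject_params(duration_s = 60, fs = 100, rsa_amp = 0, th_amp = 0,
                      seed = 2)
  resp <- generate_respiration(p)
  card <- generate_cardiac(p, resp$landmarks)
  expect_lt(diff(range(card$beats$rr)), 1e-6)
  expect_lt(diff(range(card$beats$map)), 1e-9)
  expect_true(all(card$beats$sbp > card$beats$dbp))
})

test_that("Traube-Hering modulation has the configured peak-to-peak MAP depth", {
  p <- subject_params(duration_s = 120, fs = 100, th_amp = 6, rsa_amp = 0,
                      noise_sd = 0, breath_period_cv = 0, seed = 3)
  resp <- generate_respiration(p)
  card <- generate_cardiac(p, resp$landmarks)
  dev <- card$beats$map - (p$dbp_base + p$sbp_base) / 2
  # continuous modulation depth is th_amp/2; beats sample it densely
  expect_lte(max(abs(dev)), 3 + 1e-9)
  expect_gt(diff(range(dev)), 0.9 * 6)
})

test_that("extreme phase probabilities confine bursts to the expiratory window", {
  p <- subject_params(duration_s = 120, fs = 100, burst_prob_insp = 0,
                      burst_prob_exp = 1, baro_slope = 0, seed = 4)
  sub <- generate_subject(p)
  tb <- sub$truth$bursts[!is.na(sub$truth$bursts$window), ]
  expect_true(all(tb$occurred[tb$window == "mid_late_expiration"]))
  expect_false(any(tb$occurred[tb$window == "inspiration_postinspiration"]))
})

test_that("a noise-free burst peaks at its drawn amplitude", {
  p <- subject_params(duration_s = 30, fs = 250, noise_sd = 0,
                      burst_prob_exp = 1, burst_prob_insp = 1,
                      baro_slope = 0, seed = 5)
  sub <- generate_subject(p)
  tb <- sub$truth$bursts[which(sub$truth$bursts$occurred), ]
  # channel max equals the tallest drawn amplitude (bursts do not overlap;
  # sub-sample offset of the pulse centre permits a half-sample error)
  expect_equal(max(sub$record$data$msna), max(tb$amplitude), tolerance = 1e-3)
})

test_that("ground truth is self-consistent and channels have the contracted length", {
  p <- quick_params(duration_s = 60, seed = 6)
  sub <- generate_subject(p)
  expect_identical(sub$truth$params, p)
  n <- round(p$duration_s * p$fs)
  expect_equal(nrow(sub$record$data), n)
  tb <- sub$truth$bursts[which(sub$truth$bursts$occurred), ]
  # every true burst centre sits exactly one latency after its cycle's R wave
  expect_equal(tb$center_time - tb$r_time,
               rep(p$burst_latency_s, nrow(tb)))
  # landmark triples strictly increase
  lmk <- sub$truth$resp_landmarks
  expect_true(all(lmk$t_trough < lmk$t_peak & lmk$t_peak < lmk$t_trough_next))
  # identical seeds give identical records
  sub2 <- generate_subject(p)
  expect_identical(sub$record$data, sub2$record$data)
})

test_that("binned burst occurrence in the truth table recovers the baroreflex slope", {
  slopes <- vapply(8:11, function(s) {
    p <- subject_params(duration_s = 620, fs = 50, burst_prob_exp = 0.5,
                        burst_prob_insp = 0.5, baro_slope = -5, seed = s)
    sub <- generate_subject(p)
    tb <- sub$truth$bursts
    # gating DBP is the previous cycle's true diastolic pressure
    dbp_at_r <- c(sub$truth$beats$dbp,
                  sub$truth$beats$dbp[nrow(sub$truth$beats)])
    gate <- c(dbp_at_r[1], dbp_at_r[-length(dbp_at_r)])
    keep <- !is.na(tb$window)
    d <- data.frame(dbp = gate[keep], occ = tb$occurred[keep])
    bins <- aggregate(occ ~ floor(dbp), data = d, FUN = mean)
    names(bins) <- c("bin", "p")
    wts <- as.numeric(table(floor(d$dbp)))
    unname(coef(lm(100 * p ~ bin, data = bins, weights = wts))[2])
  }, numeric(1))
  expect_lt(abs(mean(slopes) - (-5)), 0.8)
})

test_that("generate_cohort draws labelled subjects deterministically", {
  spec <- list(list(label = "A", n = 3,
                    params = quick_params(duration_s = 20)),
               list(label = "B", n = 2,
                    params = quick_params(duration_s = 20),
                    sd = c(hr_base = 3)))
  co <- generate_cohort(spec, seed = 11)
  expect_equal(nrow(co), 5)
  expect_equal(co$group, c("A", "A", "A", "B", "B"))
  # distinct subject seeds give distinct noise realisations
  expect_false(identical(co$record[[1]]$data$msna, co$record[[2]]$data$msna))
  # per-subject parameter jitter is applied in group B only
  hrs <- vapply(co$params, function(p) p$hr_base, numeric(1))
  expect_true(all(hrs[1:3] == hrs[1]))
  expect_false(hrs[4] == hrs[5])
  co2 <- generate_cohort(spec, seed = 11)
  expect_identical(co$record[[3]]$data, co2$record[[3]]$data)
  expect_error(generate_cohort(list(), seed = 1), "nonempty")
})
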