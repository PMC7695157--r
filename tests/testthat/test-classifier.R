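# features, slow-eye-movement detection and the stage decision ladder

feat_row <- function(ant = 0, post = 0, slow = 0, sem = FALSE,
                     marker = "none", artifact = FALSE) {
  data.frame(epoch = 1, alpha_anterior = ant, alpha_posterior = post,
             slowwave = slow, sem = sem, marker = marker,
             artifact = artifact)
}

test_cfg <- function() classifier_config(alpha_threshold = 25,
                                         slowwave_threshold = 100)

test_that("the decision ladder follows marker > B2/3 > A-branch > B1 > 0", {
  cfg <- test_cfg()
  # markers force C regardless of spectral content
  expect_equal(classify_epoch(feat_row(ant = 500, post = 500,
                                       marker = "spindle"), cfg), "C")
  expect_equal(classify_epoch(feat_row(slow = 1e4, marker = "kcomplex"),
                              cfg), "C")
  # slow-wave dominance with suppressed alpha
  expect_equal(classify_epoch(feat_row(slow = 150), cfg), "B2/3")
  # alpha branch by frontalization ratio
  expect_equal(classify_epoch(feat_row(ant = 20, post = 100), cfg), "A1")
  expect_equal(classify_epoch(feat_row(ant = 70, post = 100), cfg), "A2")
  expect_equal(classify_epoch(feat_row(ant = 60, post = 40), cfg), "A3")
  # surviving alpha beats slow waves (precedence rule 2 needs alpha low)
  expect_equal(classify_epoch(feat_row(ant = 10, post = 200, slow = 500),
                              cfg), "A1")
  # SEM evidence without alpha: B1; nothing at all: 0
  expect_equal(classify_epoch(feat_row(sem = TRUE), cfg), "B1")
  expect_equal(classify_epoch(feat_row(), cfg), "0")
  expect_error(classify_epoch(feat_row(artifact = TRUE), cfg), "artifact")
  expect_error(classifier_config(alpha_threshold = 1,
                                 slowwave_threshold = 1, r1 = 2, r2 = 1),
               "r1 < r2")
})

test_that("a planted occipital tone yields posterior-dominant alpha power", {
  fs <- 200
  t <- seq_len(10 * fs) / fs
  labs <- c("Fz", "F3", "Pz", "O1", "O2", "EOGL", "EOGR")
  samples <- matrix(0, length(labs), length(t),
                    dimnames = list(labs, NULL))
  for (ch in c("Pz", "O1", "O2")) {
    samples[ch, ] <- 30 * sin(2 * pi * 10 * t)
  }
  rec <- recording(samples, fs = fs, channel_labels = labs)
  feats <- extract_features(rec, segment_epochs(rec))
  expect_true(all(feats$alpha_posterior > 50 * pmax(feats$alpha_anterior,
                                                    1e-12)))
})

test_that("white-noise band powers scale with bandwidth", {
  set.seed(801)
  fs <- 200
  labs <- c("Fz", "Pz", "O1", "EOGL", "EOGR")
  sdev <- 10
  samples <- matrix(rnorm(length(labs) * 60 * fs, 0, sdev), length(labs))
  rec <- recording(samples, fs = fs, channel_labels = labs)
  feats <- extract_features(rec, segment_epochs(rec))
  # alpha band: 5 of 100 one-sided bins; slow band: 6 of 100
  expect_lt(abs(mean(feats$alpha_posterior) / (sdev^2 * 5 / 100) - 1), 0.5)
  expect_lt(abs(mean(feats$slowwave) / (sdev^2 * 6 / 100) - 1), 0.5)
  # and every single epoch within 3x of the expectation
  expect_true(all(feats$alpha_posterior < 3 * sdev^2 * 5 / 100 * 3))
})

test_that("epochs overlapping a marker are flagged with its type", {
  sim <- simulate_recording(stage_sequence(rep("0", 8)), seed = 802)
  rec <- sim$recording
  mk <- data.frame(sample_index = c(250, 1100),
                   marker_type = c("SPINDLE", "KCOMPLEX"))
  feats <- extract_features(rec, segment_epochs(rec), markers = mk)
  expect_equal(feats$marker[2], "spindle")
  expect_equal(feats$marker[6], "kcomplex")
  expect_equal(sum(feats$marker != "none"), 2)
})

test_that("SEM detection needs amplitude, anti-phase and slowness", {
  fs <- 200
  t <- seq_len(6 * fs) / fs
  wave <- 80 * sin(2 * pi * 0.3 * t)
  noise1 <- rnorm(length(t), 0, 2)
  noise2 <- rnorm(length(t), 0, 2)
  cfg <- test_cfg()
  # anti-phase 0.3 Hz, 80 uV: detected
  expect_true(any(detect_sem(wave + noise1, -wave + noise2, fs, cfg)))
  # in-phase drift (non-ocular): rejected
  expect_false(any(detect_sem(wave + noise1, wave + noise2, fs, cfg)))
  # too small: rejected
  expect_false(any(detect_sem(0.2 * wave + noise1, -0.2 * wave + noise2,
                              fs, cfg)))
  # anti-phase but fast (2 Hz): rejected
  fastw <- 80 * sin(2 * pi * 2 * t)
  expect_false(any(detect_sem(fastw + noise1, -fastw + noise2, fs, cfg)))
})

test_that("SEM sensitivity and specificity reach 0.9 on planted epochs", {
  sem_sim <- simulate_recording(stage_sequence(rep("B1", 200)), seed = 803)
  clean_sim <- simulate_recording(stage_sequence(rep("0", 200)), seed = 804)
  cfg <- test_cfg()
  hit <- detect_sem(sem_sim$recording$samples["EOGL", ],
                    sem_sim$recording$samples["EOGR", ],
                    sem_sim$recording$fs, cfg)
  fa <- detect_sem(clean_sim$recording$samples["EOGL", ],
                   clean_sim$recording$samples["EOGR", ],
                   clean_sim$recording$fs, cfg)
  expect_gte(mean(hit), 0.9)  # sensitivity
  expect_gte(mean(!fa), 0.9)  # specificity
})

test_that("classification is deterministic and threshold-self-consistent", {
  calib <- shared_calib()
  sim <- simulate_recording(stage_sequence(rep(c("A1", "B2/3", "0"),
                                               each = 20)), seed = 805)
  s1 <- classify_recording(sim$recording, calib, markers = sim$markers)
  s2 <- classify_recording(sim$recording, calib, markers = sim$markers)
  expect_identical(s1$stages, s2$stages)
  # scaling all channels and recalibrating from scaled data changes nothing
  # (absolute-amplitude screens scale alongside)
  k <- 2
  rec2 <- sim$recording
  rec2$samples <- rec2$samples * k
  cal_rec <- simulate_calibration_segment(30, seed = 901)
  cal_rec$samples <- cal_rec$samples * k
  calib2 <- calibrate(filter_recording(cal_rec),
                      low_voltage_floor = 10 * k^2)
  cfg2 <- classifier_config(calib2, sem_min_amp = 40 * k)
  s3 <- classify_recording(rec2, calib2, config = cfg2,
                           markers = sim$markers, amp_limit = 200 * k)
  expect_identical(s3$stages, s1$stages)
})

test_that("an all-A1 recording is classified A1 in at least 95% of epochs", {
  calib <- shared_calib()
  sim <- simulate_recording(stage_sequence(rep("A1", 40)), seed = 806)
  s <- classify_recording(sim$recording, calib)
  expect_gte(mean(s$stages == "A1", na.rm = TRUE), 0.95)
})

test_that("an all-0 recording never crosses the alpha-dominance threshold", {
  calib <- shared_calib()
  sim <- simulate_recording(stage_sequence(rep("0", 40)), seed = 807)
  rec <- filter_recording(sim$recording)
  feats <- extract_features(rec, segment_epochs(rec),
                            config = classifier_config(calib))
  expect_true(all(pmax(feats$alpha_anterior, feats$alpha_posterior) <
                    calib$alpha_threshold))
})

test_that("a fully artifact-flagged recording yields no stages and metrics refuse", {
  calib <- shared_calib()
  sim <- simulate_recording(stage_sequence(rep("A1", 60)), seed = 808)
  rec <- sim$recording
  rec$samples[2, seq(1, ncol(rec$samples), by = 50)] <- 1e4 # spikes everywhere
  s <- classify_recording(rec, calib)
  expect_true(all(is.na(s$stages)))
  expect_error(stage_amounts(s), "artifact")
  expect_error(mean_vigilance_value(s), "artifact")
})

test_that("the non-canonical event detector finds planted events only", {
  calib <- shared_calib()
  one_c <- stage_sequence(c(rep("0", 10), "C", rep("0", 9)))
  sim <- simulate_recording(one_c, seed = 809)
  expect_equal(nrow(sim$markers), 1)
  det <- detect_events(sim$recording)
  expect_gte(nrow(det), 1)
  # detected onset close to the planted one (within half a second)
  expect_lt(min(abs(det$sample_index - sim$markers$sample_index)), 100)
  clean <- simulate_recording(stage_sequence(rep("0", 20)), seed = 810)
  expect_equal(nrow(detect_events(clean$recording)), 0)
})
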