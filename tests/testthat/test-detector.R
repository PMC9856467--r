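# Hand-built feature series for threshold/detector arithmetic.
fake_feats <- function(avg, std = avg, hop = 0.2, duration_s = NULL) {
  structure(list(times = hop * seq_along(avg), per_pair_cc = rbind(avg),
                 pairs = mscdetect:::as_pair_matrix(rbind(c(1, 2))),
                 duration_s = if (is.null(duration_s)) hop * (length(avg) + 1)
                              else duration_s,
                 avg = avg, std = std), class = "cc_features")
}

test_that("thresholds follow Th = u + 3*sd with population sd", {
  th <- thresholds(u_avg = 0.5, sd_avg = 0.1, u_std = 0.2, sd_std = 0.05)
  expect_equal(th$th_avg, 0.8, tolerance = 1e-9)
  expect_equal(th$th_std, 0.35, tolerance = 1e-9)

  f <- fake_feats(rep(c(0, 1), 50))
  th2 <- init_thresholds(f)
  expect_equal(th2$u_avg, 0.5)
  expect_equal(th2$sd_avg, 0.5)                 # population sd of 0/1
  expect_equal(th2$th_avg, 2.0)

  f3 <- fake_feats(rep(0.3, 40))
  th3 <- init_thresholds(f3)
  expect_equal(th3$th_avg, 0.3)                 # sd = 0

  # permutation invariance of the training statistics
  set.seed(1)
  v <- runif(100)
  expect_equal(init_thresholds(fake_feats(v))$th_avg,
               init_thresholds(fake_feats(sample(v)))$th_avg)
})

test_that("the training span runs through the n-th seizure offset", {
  avg <- c(rep(0.2, 50), rep(0.9, 50))          # later windows are hotter
  f <- fake_feats(avg)
  ann <- annotations(c(2, 30), c(4, 32))
  th <- init_thresholds(f, ann, n_train = 1)    # spans times <= 4 s (20 windows)
  expect_equal(th$u_avg, 0.2)
  expect_error(init_thresholds(f, ann[0, ]), "training seizure")
})

test_that("detection needs both features above threshold and is refractory", {
  th <- thresholds(0.2, 0.05, 0.1, 0.02)        # th_avg 0.35, th_std 0.16
  base <- rep(0.2, 100)
  f_none <- fake_feats(base, rep(0.1, 100))
  expect_equal(nrow(detect_events(f_none, th)), 0L)

  avg <- base; avg[50:60] <- 0.9
  f_and <- fake_feats(avg, rep(0.1, 100))       # std never crosses
  expect_equal(nrow(detect_events(f_and, th)), 0L)

  std <- rep(0.1, 100); std[50:60] <- 0.5
  f_both <- fake_feats(avg, std)
  ev <- detect_events(f_both, th)
  expect_equal(ev$time_s, 0.2 * 50)             # absorbed into one event

  # two qualifying bursts closer than the refractory period merge
  avg2 <- base; avg2[c(50, 52)] <- 0.9
  std2 <- rep(0.5, 100)
  ev2 <- detect_events(fake_feats(avg2, std2), th, refractory_s = 30)
  expect_equal(nrow(ev2), 1L)
  ev3 <- detect_events(fake_feats(avg2, std2), th, refractory_s = 0.3)
  expect_equal(nrow(ev3), 2L)
})

test_that("raising the AVG threshold never adds events", {
  set.seed(2)
  avg <- runif(500); std <- runif(500)
  counts <- vapply(c(0.3, 0.5, 0.7, 0.9), function(ta)
    nrow(detect_events(fake_feats(avg, std),
                       thresholds(ta, 0, 0.2, 0), refractory_s = 1)),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("evaluation counts matches, misses and false alarms", {
  ann <- annotations(c(100, 500, 900), c(120, 520, 920))
  ev <- structure(data.frame(time_s = c(101, 503, 1500, 1600)),
                  class = c("detection_events", "data.frame"))
  rep <- evaluate_detections(ev, ann, duration_s = 3600)
  expect_equal(rep$detection_rate, 2 / 3 * 100, tolerance = 1e-9)
  expect_equal(rep$n_false_alarms, 2L)
  expect_equal(rep$false_alarm_rate_per_h, 2)
  expect_equal(rep$delays_s, c(1, 3))
  # conservation: matched + missed = seizures; matched + FA = events
  expect_equal(rep$n_detected + rep$n_missed, rep$n_seizures)
  expect_equal(rep$n_detected + rep$n_false_alarms, nrow(ev))

  perfect <- structure(data.frame(time_s = c(100.5, 500.5, 900.5)),
                       class = c("detection_events", "data.frame"))
  rep2 <- evaluate_detections(perfect, ann, 3600)
  expect_equal(rep2$detection_rate, 100)
  expect_equal(rep2$false_alarm_rate_per_h, 0)

  none <- structure(data.frame(time_s = numeric(0)),
                    class = c("detection_events", "data.frame"))
  rep3 <- evaluate_detections(none, ann, 3600)
  expect_equal(rep3$detection_rate, 0)
  expect_equal(rep3$false_alarm_rate_per_h, 0)
  expect_error(evaluate_detections(none, ann, 0), "positive")
})

test_that("threshold iteration keeps, recomputes, or flags per block", {
  th0 <- thresholds(0.2, 0.05, 0.1, 0.02)       # th_avg 0.35, th_std 0.16
  mk_block <- function(peak) {
    avg <- rep(0.2, 300); std <- rep(0.1, 300)
    avg[150:160] <- peak; std[150:160] <- 0.5
    list(features = fake_feats(avg, std), annotations = annotations(29, 33))
  }
  good <- mk_block(0.9)
  hist1 <- iterate_thresholds(list(good, good), th0)
  expect_true(all(hist1$history$action == "keep"))
  expect_equal(hist1$thresholds[[2]]$th_avg, th0$th_avg)

  # seizure too weak for th0 but separable: recomputation recovers it
  weak <- mk_block(0.35)                        # below th_avg = 0.35
  hist2 <- iterate_thresholds(list(weak), th0)
  expect_equal(hist2$history$action, "recomputed")
  expect_equal(hist2$history$detection_rate, 100)

  # nothing separates the seizure: recomputation fails, thresholds retained
  flat <- list(features = fake_feats(rep(0.2, 300), rep(0.1, 300)),
               annotations = annotations(29, 33))
  hist3 <- iterate_thresholds(list(flat), th0)
  expect_equal(hist3$history$action, "flagged")
  expect_equal(hist3$thresholds[[1]]$th_avg, th0$th_avg)

  # check cadence: only every 3rd block verified
  hist4 <- iterate_thresholds(list(good, good, good, good), th0, check_every = 3)
  expect_equal(hist4$history$checked, c(FALSE, FALSE, TRUE, FALSE))
})

test_that("a mid-record coupling drop triggers recomputation that restores detection", {
  mk <- function(seed, gain) {
    sim <- synth_lfp(synth_config(
      n_channels = 4, duration_s = 360,
      seizures = data.frame(onset_s = c(60, 180, 300), duration_s = 8),
      coupled_pairs = rbind(c(1, 2)), coupling_gain = gain, seed = seed))
    feats <- avg_std(cc_curves(sim$recording, rbind(c(1, 2), c(3, 4)),
                               band = c(150, 250)),
                     rbind(c(1, 2)), rbind(c(3, 4)))
    list(features = feats, annotations = sim$annotations)
  }
  pre1 <- mk(41, 4); pre2 <- mk(42, 4)
  post1 <- mk(43, 0.45); post2 <- mk(44, 0.45)
  th0 <- init_thresholds(pre1$features, pre1$annotations, n_train = 3)

  # the strong-coupling thresholds miss the weakened seizures
  miss <- evaluate_detections(detect_events(post1$features, th0),
                              post1$annotations, post1$features$duration_s)
  expect_lt(miss$detection_rate, 100)

  hist <- iterate_thresholds(list(pre2, post1, post2), th0)
  expect_equal(hist$history$action[1], "keep")
  expect_equal(hist$history$action[2], "recomputed")
  # post-drift blocks are fully detected with the updated thresholds
  expect_equal(hist$history$detection_rate[2], 100)
  rep3 <- evaluate_detections(
    detect_events(post2$features, hist$thresholds[[2]]),
    post2$annotations, post2$features$duration_s)
  expect_equal(rep3$detection_rate, 100)
  expect_lt(rep3$false_alarm_rate_per_h, 10)
})
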