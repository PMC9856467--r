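# A small map with a hand-set grid for window/score arithmetic.
toy_map <- function(vals = NULL, n_f = 6, n_t = 40, hop = 0.2) {
  if (is.null(vals)) vals <- matrix(0.5, n_f, n_t)
  mscdetect:::msc_map_obj(vals, freqs = seq(0, 500, length.out = nrow(vals)),
                          times = hop * seq_len(ncol(vals)), pair = c(1L, 2L))
}

test_that("onset_window selects the 5 s of columns around the onset", {
  m <- toy_map()
  win <- onset_window(m, 4.0)
  expect_length(win, 25L)                       # 5 s / 0.2 s hop
  expect_equal(range(m$times[win]), c(1.6, 6.4))

  expect_gte(length(onset_window(m, m$times[1])), 1L)  # clipped at the start
  expect_error(onset_window(m, 99), "outside")
})

test_that("edge strength sums map pixels at edge pixels inside the window", {
  m <- toy_map(matrix(0, 6, 40))
  e <- matrix(0L, 6, 40)
  m$values[2, 10] <- 0.5; m$values[3, 11] <- 0.6; m$values[4, 12] <- 0.7
  e[2, 10] <- 1L; e[3, 11] <- 1L; e[4, 12] <- 1L
  m$values[5, 39] <- 0.9; e[5, 39] <- 1L        # edge outside the window
  win <- onset_window(m, 2.2)
  expect_equal(edge_strength(m, e, win), 1.8)
  expect_equal(edge_strength(m, matrix(0L, 6, 40), win), 0)
})

test_that("qccs integrates all pixels in the +/-2.5 s, <=500 Hz box", {
  m <- toy_map(matrix(1, 6, 40))
  expect_equal(qccs(m, 4.0), 6 * 25)
  m0 <- toy_map(matrix(0, 6, 40))
  expect_equal(qccs(m0, 4.0), 0)
  m2 <- toy_map(matrix(2, 6, 40))
  expect_equal(qccs(m2, 4.0), 2 * qccs(toy_map(matrix(1, 6, 40)), 4.0))
  expect_error(qccs(m, 1e6), "outside")
})

test_that("rank_pairs orders by strength with deterministic tie-breaks", {
  set.seed(1)
  pairs <- t(combn(12, 2))
  sc <- data.frame(i = pairs[, 1], j = pairs[, 2],
                   edge_strength = runif(nrow(pairs)))
  r <- rank_pairs(sc)
  expect_equal(nrow(r$selected), 10L)
  expect_equal(nrow(r$background), 10L)
  o <- order(-sc$edge_strength)
  expect_equal(pair_keys <- paste(r$selected[, 1], r$selected[, 2]),
               paste(sc$i[o][1:10], sc$j[o][1:10]))
  expect_equal(paste(r$background[, 1], r$background[, 2]),
               paste(sc$i[o][57:66], sc$j[o][57:66]))
  expect_length(intersect(pair_keys, paste(r$background[, 1], r$background[, 2])), 0L)

  ties <- data.frame(i = pairs[1:12, 1], j = pairs[1:12, 2], edge_strength = 1)
  r2 <- rank_pairs(ties)
  expect_equal(r2$selected, mscdetect:::as_pair_matrix(pairs[1:10, ]))
  expect_equal(nrow(r2$background), 2L)         # floor(12/2) minus overlap rule
  expect_error(rank_pairs(sc[0, ]), "no pair scores")
})

test_that("band_from_edges returns the strongest component's extent", {
  m <- toy_map(matrix(0.1, 10, 40))
  m$freqs <- seq(0, 450, by = 50)
  e <- matrix(0L, 10, 40)
  e[4:6, 15] <- 1L                               # component A, rows 150-250 Hz
  m$values[4:6, 15] <- 0.9                       # strength 2.7
  e[9, 20:21] <- 1L                              # component B, strength 0.2
  win <- onset_window(m, 3.5)
  b <- band_from_edges(e, m, win)
  expect_equal(c(b$f_lo, b$f_hi), c(150, 250))
  expect_equal(b$edge_time_s, 3.0)
  expect_null(band_from_edges(matrix(0L, 10, 40), m, win))
})

test_that("common_band intersects, falls back to the majority band, or fails", {
  expect_equal(common_band(list(c(100, 300), c(150, 400))), c(150, 300))
  expect_equal(common_band(list(c(10, 30), c(10, 30))), c(10, 30))
  expect_equal(common_band(list(c(1, 30), c(1, 30), c(200, 400))), c(1, 30),
               tolerance = 1)
  expect_error(common_band(list(c(1, 2), c(100, 101), c(300, 301))), "manually")
})

test_that("selection recovers coupled pairs and band on a compact recording", {
  sim <- synth_lfp(synth_config(
    n_channels = 4, duration_s = 150,
    seizures = data.frame(onset_s = c(20, 60, 100), duration_s = 10),
    coupled_pairs = rbind(c(1, 2)), coupling_gain = 4, seed = 12))
  sel <- select_pairs(sim$recording, sim$annotations,
                      spectral_config(f_max = 500), n_train = 3)
  expect_equal(c(sel$scores$i[1], sel$scores$j[1]), c(1, 2))
  expect_gt(band_jaccard(sel$band, c(150, 250)), 0.5)
  expect_equal(nrow(sel$selected), 6L)
  expect_true(all(sel$scores$edge_strength >= 0))

  json <- withr::local_tempfile(fileext = ".json")
  write_selection(sel, json)
  back <- read_selection(json)
  expect_equal(back$selected, sel$selected)
  expect_equal(back$band, sel$band)
})

test_that("qccs_matrix is symmetric with a dominant coupled entry", {
  sim <- synth_lfp(synth_config(
    n_channels = 4, duration_s = 60,
    seizures = data.frame(onset_s = 25, duration_s = 10),
    coupled_pairs = rbind(c(1, 2)), coupling_gain = 4, seed = 13))
  M <- qccs_matrix(sim$recording, 25, spectral_config(f_max = 500))
  expect_equal(M, t(M))
  expect_equal(diag(M), rep(0, 4), ignore_attr = TRUE)
  off <- M[upper.tri(M)]
  expect_equal(max(off), M[1, 2])
})
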