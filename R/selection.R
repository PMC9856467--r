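#' Columns of an MSC map around a seizure onset
#'
#' Returns the indices of map columns whose center times lie within
#' `±half_width_s` of the onset (default a 5 s window: 2.5 s either side).
#' Ranges extending past the map are clipped; an onset outside the map's
#' time span is an error.
#'
#' @param map an `msc_map`.
#' @param onset_s onset time, seconds (absolute, same clock as `map$times`).
#' @param half_width_s half-width of the window, seconds (default 2.5).
#' @return An integer vector of column indices (non-empty).
#' @export
onset_window <- function(map, onset_s, half_width_s = 2.5) {
  if (onset_s < min(map$times) - 1e-9 || onset_s > max(map$times) + 1e-9)
    stop("onset at ", onset_s, " s lies outside the map time span [",
         round(min(map$times), 3), ", ", round(max(map$times), 3), "]")
  cols <- which(map$times >= onset_s - half_width_s &
                map$times <= onset_s + half_width_s)
  if (length(cols) == 0L) stop("no map columns near onset")
  cols
}

#' Edge strength of a channel pair around an onset
#'
#' Sum of MSC-map pixel values at the pixels flagged by the edge detector,
#' restricted to the given window columns. This is the quantity used to rank
#' channel pairs: pairs whose coherence rises sharply at onset accumulate
#' large sums, pairs without a detectable coherence change score near zero.
#'
#' @param map an `msc_map`.
#' @param edges an `edge_map` of matching shape (see [canny_edges()]).
#' @param window integer column indices (see [onset_window()]).
#' @return A non-negative scalar.
#' @export
edge_strength <- function(map, edges, window) {
  e <- if (inherits(edges, "edge_map")) edges$edges else as.matrix(edges)
  if (!all(dim(e) == dim(map$values))) stop("edge/map shape mismatch")
  sub_v <- map$values[, window, drop = FALSE]
  sub_e <- e[, window, drop = FALSE]
  sum(sub_v[sub_e == 1L])
}

#' Quantified cross-correlation strength (QCCS)
#'
#' Sum of all MSC-map pixel values over the columns within `±2.5` s of the
#' detected edge time and the frequency rows from 0 up to `f_max_hz`
#' (default 500 Hz), clipped to the rows present in the map. Linear in the
#' pixel values; used to build channel-by-channel synchronization matrices.
#'
#' @param map an `msc_map`.
#' @param edge_time_s time of the detected edge, seconds.
#' @param half_width_s half-width of the integration window (default 2.5 s).
#' @param f_max_hz upper frequency bound in Hz (default 500).
#' @return A non-negative scalar.
#' @export
qccs <- function(map, edge_time_s, half_width_s = 2.5, f_max_hz = 500) {
  cols <- onset_window(map, edge_time_s, half_width_s)
  rows <- which(map$freqs >= 0 & map$freqs <= f_max_hz)
  sum(map$values[rows, cols])
}

#' Rank channel pairs by edge strength
#'
#' Sorts pairs by `edge_strength` descending (ties broken by smaller channel
#' indices), takes the top `n_select` as the selected (detection) pairs and
#' the bottom `n_background` as the background pairs used only to stabilize
#' the STD feature. With fewer than `n_select + n_background` pairs, the
#' background takes the lowest `floor(n/2)` pairs not already selected.
#'
#' @param scores data frame with columns `i`, `j`, `edge_strength` (one row
#'   per pair); extra columns are carried along.
#' @param n_select,n_background target counts (default 10 each).
#' @return A list of class `pair_selection` with `selected`, `background`
#'   (pair matrices) and the sorted `scores`.
#' @export
rank_pairs <- function(scores, n_select = 10L, n_background = 10L) {
  scores <- as.data.frame(scores)
  if (nrow(scores) == 0L) stop("no pair scores to rank")
  o <- order(-scores$edge_strength, scores$i, scores$j)
  scores <- scores[o, , drop = FALSE]
  rownames(scores) <- NULL
  n <- nrow(scores)
  sel_idx <- seq_len(min(n_select, n))
  if (n >= n_select + n_background) {
    bg_idx <- seq.int(n - n_background + 1L, n)
  } else {
    pool <- setdiff(seq_len(n), sel_idx)
    take <- min(length(pool), floor(n / 2))
    bg_idx <- if (take > 0) utils::tail(seq_len(n), take) else integer(0)
    bg_idx <- setdiff(bg_idx, sel_idx)
  }
  structure(list(
    selected = as_pair_matrix(scores[sel_idx, c("i", "j")]),
    background = as_pair_matrix(scores[bg_idx, c("i", "j")]),
    scores = scores), class = "pair_selection")
}

#' Frequency band of the principal edge component
#'
#' Among the 8-connected edge components intersecting the onset window, picks
#' the one contributing the largest edge strength and returns the frequency
#' extent `[f_lo, f_hi]` of its rows, together with the component's earliest
#' column time (the detected edge time). Returns `NULL` when the window
#' contains no edge pixels.
#'
#' @param edges an `edge_map`.
#' @param map the source `msc_map`.
#' @param window integer column indices (see [onset_window()]).
#' @return `NULL`, or a list with `f_lo`, `f_hi`, `edge_time_s`, `strength`.
#' @export
band_from_edges <- function(edges, map, window) {
  e <- if (inherits(edges, "edge_map")) edges$edges else as.matrix(edges)
  sub <- matrix(0L, nrow(e), ncol(e))
  sub[, window] <- e[, window]
  if (!any(sub == 1L)) return(NULL)
  lab <- label_components8(sub)
  comps <- setdiff(unique(as.vector(lab)), 0L)
  best <- NULL
  for (cmp in comps) {
    idx <- which(lab == cmp, arr.ind = TRUE)
    strength <- sum(map$values[idx])
    if (is.null(best) || strength > best$strength) {
      best <- list(
        f_lo = min(map$freqs[idx[, 1]]), f_hi = max(map$freqs[idx[, 1]]),
        edge_time_s = min(map$times[idx[, 2]]), strength = strength)
    }
  }
  best
}

#' Common frequency band of several pairs
#'
#' Strict intersection of the per-pair bands; when the intersection is empty,
#' falls back to the majority band: the longest contiguous run of frequency
#' bins covered by at least half of the bands. Errors only when no majority
#' band exists either.
#'
#' @param bands list of `c(f_lo, f_hi)` pairs (or lists with `f_lo`/`f_hi`).
#' @param resolution_hz bin width used for the majority fallback (default 1).
#' @return `c(f_lo, f_hi)` in Hz.
#' @export
common_band <- function(bands, resolution_hz = 1) {
  bands <- lapply(bands, function(b) {
    if (is.list(b)) c(b$f_lo, b$f_hi) else as.numeric(b[1:2])
  })
  if (length(bands) == 0L) stop("no bands to intersect")
  lo <- max(vapply(bands, `[`, numeric(1), 1L))
  hi <- min(vapply(bands, `[`, numeric(1), 2L))
  if (lo < hi) return(c(lo, hi))
  # majority fallback on a bin grid
  grid_lo <- min(vapply(bands, `[`, numeric(1), 1L))
  grid_hi <- max(vapply(bands, `[`, numeric(1), 2L))
  centers <- seq(grid_lo + resolution_hz / 2, grid_hi, by = resolution_hz)
  cover <- rowSums(vapply(bands, function(b)
    centers >= b[1] & centers <= b[2], logical(length(centers))))
  maj <- cover >= length(bands) / 2
  if (!any(maj))
    stop("pair bands share no common frequency range; supply the band manually")
  runs <- rle(maj)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  best <- which(runs$values)[which.max(runs$lengths[runs$values])]
  c(centers[starts[best]] - resolution_hz / 2,
    centers[ends[best]] + resolution_hz / 2)
}

# Per-onset pair scores: maps around each onset, edges, strengths, bands.
# Returns a list with the score table (summed over onsets) and per-pair
# strongest band info.
score_pairs_at_onsets <- function(rec, onsets, cfg, canny_cfg,
                                  span_s = 10, pairs = NULL) {
  nc <- n_channels(rec)
  if (is.null(pairs)) pairs <- t(utils::combn(nc, 2L))
  pairs <- as_pair_matrix(pairs)
  keys <- pair_key(pairs)
  strength <- stats::setNames(numeric(nrow(pairs)), keys)
  qc <- stats::setNames(numeric(nrow(pairs)), keys)
  band_best <- stats::setNames(vector("list", nrow(pairs)), keys)
  for (onset in onsets) {
    slice <- crop_recording(rec, onset - span_s, onset + span_s)
    maps <- all_pairs_maps(slice, cfg, pairs = pairs)
    for (k in seq_len(nrow(pairs))) {
      map <- maps[[keys[k]]]
      win <- onset_window(map, onset)
      em <- canny_edges(map, canny_cfg)
      strength[k] <- strength[k] + edge_strength(map, em, win)
      b <- band_from_edges(em, map, win)
      if (!is.null(b)) {
        qc[k] <- qc[k] + qccs(map, b$edge_time_s)
        if (is.null(band_best[[k]])) {
          band_best[[k]] <- b
        } else {
          # pool the principal components across training onsets: the pair's
          # band is the frequency extent they jointly cover
          band_best[[k]]$f_lo <- min(band_best[[k]]$f_lo, b$f_lo)
          band_best[[k]]$f_hi <- max(band_best[[k]]$f_hi, b$f_hi)
          if (b$strength > band_best[[k]]$strength) {
            band_best[[k]]$strength <- b$strength
            band_best[[k]]$edge_time_s <- b$edge_time_s
          }
        }
      } else {
        qc[k] <- qc[k] + qccs(map, onset)
      }
    }
  }
  list(scores = data.frame(i = pairs[, 1], j = pairs[, 2],
                           edge_strength = as.numeric(strength),
                           qccs = as.numeric(qc) / length(onsets)),
       bands = band_best)
}

#' Select detection channel pairs and the common frequency band
#'
#' The preprocessing pipeline: for each training onset, compute all-pairs MSC
#' maps on a slice around the onset, run the edge detector, and accumulate
#' per-pair edge strengths over onsets. Pairs are ranked ([rank_pairs()]):
#' the top 10 become the detection pairs, the bottom 10 the background pairs.
#' The common band is the intersection ([common_band()]) of the bands of
#' those selected pairs whose edge strength reaches at least
#' `band_min_frac` of the top score — pairs without a pronounced edge carry
#' no band information and are excluded from the intersection.
#'
#' @param rec an [recording()].
#' @param ann a [annotations()] data frame; the first `n_train` onsets are
#'   used (default 5).
#' @param cfg a [spectral_config()].
#' @param canny_cfg a [canny_config()].
#' @param n_train number of training seizures (default 5).
#' @param span_s half-width of the per-onset analysis slice, seconds.
#' @param band_min_frac minimum edge strength (fraction of the top score)
#'   for a pair's band to enter the intersection (default 0.5).
#' @return A list of class `selection_result`: `selected`, `background`
#'   (pair matrices), `band` (`c(f_lo, f_hi)` Hz), `scores`, `pair_bands`.
#' @export
select_pairs <- function(rec, ann, cfg = spectral_config(),
                         canny_cfg = canny_config(), n_train = 5L,
                         span_s = 10, band_min_frac = 0.5) {
  onsets <- utils::head(ann$onset_s, n_train)
  if (length(onsets) == 0L) stop("no training seizures")
  sc <- score_pairs_at_onsets(rec, onsets, cfg, canny_cfg, span_s)
  ranked <- rank_pairs(sc$scores)
  top <- max(sc$scores$edge_strength)
  strengths <- stats::setNames(sc$scores$edge_strength,
                               pair_key(as_pair_matrix(sc$scores[, c("i", "j")])))
  sel_keys <- pair_key(ranked$selected)
  keep <- sel_keys[strengths[sel_keys] >= band_min_frac * top]
  cand <- sc$bands[keep]
  cand <- cand[!vapply(cand, is.null, logical(1))]
  if (length(cand) == 0L)
    stop("no selected pair produced a usable edge band; supply the band manually")
  band <- common_band(cand)
  structure(list(selected = ranked$selected, background = ranked$background,
                 band = band, scores = ranked$scores, pair_bands = sc$bands),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> band %.1f-%.1f Hz; %d selected, %d background pairs\n",
              x$band[1], x$band[2], nrow(x$selected), nrow(x$background)))
  cat("  top pairs:", paste(utils::head(pair_key(x$selected), 5), collapse = " "), "\n")
  invisible(x)
}

#' Save / load a selection result as JSON
#' @param sel a `selection_result`.
#' @param path JSON file path.
#' @return `path` invisibly; `read_selection` returns a `selection_result`.
#' @export
write_selection <- function(sel, path) {
  jsonlite::write_json(list(
    selected = unclass(sel$selected), background = unclass(sel$background),
    band = sel$band, scores = sel$scores), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_selection
#' @export
read_selection <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(selected = as_pair_matrix(obj$selected),
                 background = as_pair_matrix(obj$background),
                 band = as.numeric(obj$band),
                 scores = as.data.frame(obj$scores),
                 pair_bands = NULL),
            class = "selection_result")
}

#' QCCS matrix over all channel pairs
#'
#' Builds the symmetric channel-by-channel matrix whose entry `(i, j)` is the
#' mean (over onsets) QCCS of pair `(i, j)`, using the per-onset detected
#' edge time where an edge is found and the annotated onset time otherwise.
#' The diagonal is 0. Large entries mark the site pairs whose coherence
#' strengthens at seizure onset.
#'
#' @param rec an [recording()].
#' @param onsets numeric vector of onset times, seconds.
#' @param cfg a [spectral_config()].
#' @param canny_cfg a [canny_config()].
#' @param span_s half-width of the per-onset analysis slice, seconds.
#' @return A symmetric numeric matrix with channel labels as dimnames.
#' @export
qccs_matrix <- function(rec, onsets, cfg = spectral_config(),
                        canny_cfg = canny_config(), span_s = 10) {
  if (length(onsets) == 0L) stop("need at least one onset")
  nc <- n_channels(rec)
  sc <- score_pairs_at_onsets(rec, onsets, cfg, canny_cfg, span_s)
  M <- matrix(0, nc, nc, dimnames = list(rec$channel_labels, rec$channel_labels))
  for (k in seq_len(nrow(sc$scores))) {
    i <- sc$scores$i[k]; j <- sc$scores$j[k]
    M[i, j] <- M[j, i] <- sc$scores$qccs[k]
  }
  M
}
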