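#' Canny edge-detector configuration
#'
#' Parameters of the edge detector applied to MSC maps: Gaussian smoothing
#' scale `sigma` (in map pixels), the high hysteresis threshold as a fraction
#' of the maximal normalized gradient magnitude, and the low/high threshold
#' ratio. Defaults follow the values used for coherence maps: `sigma = 2`,
#' `high_threshold = 0.90`, `low_ratio = 0.4` (so the effective low threshold
#' is 0.36 of the maximal gradient).
#'
#' @param sigma Gaussian scale in pixels (> 0).
#' @param high_threshold high threshold, fraction of max gradient in (0, 1].
#' @param low_ratio low/high threshold ratio in (0, 1).
#' @return A list of class `canny_config`.
#' @export
canny_config <- function(sigma = 2, high_threshold = 0.90, low_ratio = 0.4) {
  if (sigma <= 0) stop("sigma must be positive")
  if (!(high_threshold > 0 && high_threshold <= 1)) stop("high_threshold must be in (0, 1]")
  if (!(low_ratio > 0 && low_ratio < 1)) stop("low_ratio must be in (0, 1)")
  structure(list(sigma = sigma, high_threshold = high_threshold,
                 low_ratio = low_ratio), class = "canny_config")
}

# Pad a matrix symmetrically (mirror with edge duplication) by r rows/cols.
pad_symmetric <- function(img, r) {
  n <- nrow(img); m <- ncol(img)
  ri <- c(pmin(r:1, n), 1:n, pmax(n - (1:r) + 1L, 1L))
  ci <- c(pmin(r:1, m), 1:m, pmax(m - (1:r) + 1L, 1L))
  img[ri, ci, drop = FALSE]
}

#' Gaussian smoothing of a matrix
#'
#' Convolves with a sampled, normalized 2-D Gaussian kernel truncated at
#' `±ceiling(4*sigma)` pixels, using symmetric (reflected) border padding.
#' Separable, so applied as two 1-D passes.
#'
#' @param img numeric matrix with finite entries.
#' @param sigma Gaussian standard deviation in pixels (> 0).
#' @return A matrix of the same shape.
#' @export
gaussian_smooth <- function(img, sigma = 2) {
  if (sigma <= 0) stop("sigma must be positive")
  img <- as.matrix(img)
  if (!all(is.finite(img))) stop("img must have finite entries")
  r <- ceiling(4 * sigma)
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  p <- pad_symmetric(img, r)
  n <- nrow(img); m <- ncol(img)
  # vertical pass
  acc <- matrix(0, n, m + 2L * r)
  for (d in -r:r) acc <- acc + k[d + r + 1L] * p[(1L + r + d):(n + r + d), , drop = FALSE]
  # horizontal pass
  out <- matrix(0, n, m)
  for (d in -r:r) out <- out + k[d + r + 1L] * acc[, (1L + r + d):(m + r + d), drop = FALSE]
  out
}

#' Gradient magnitude and direction (2x2 finite differences)
#'
#' First-order partial derivatives by 2x2 averaged finite differences:
#' `Gx(i,j) = (f(i+1,j) - f(i,j) + f(i+1,j+1) - f(i,j+1)) / 2` along the first
#' index and symmetrically for `Gy` along the second; magnitude
#' `M = sqrt(Gx^2 + Gy^2)` and direction `atan2(Gy, Gx)`. The derivative
#' lives on the inter-pixel grid; the last row/column is replicated so the
#' output keeps the input shape.
#'
#' @param img numeric matrix, at least 2x2.
#' @return A list with matrices `magnitude`, `direction`, `gx`, `gy`.
#' @export
grad_finite_diff <- function(img) {
  img <- as.matrix(img)
  n <- nrow(img); m <- ncol(img)
  if (n < 2L || m < 2L) stop("img must be at least 2x2")
  a <- img[1:(n - 1), 1:(m - 1)]; b <- img[2:n, 1:(m - 1)]
  c_ <- img[1:(n - 1), 2:m];      d <- img[2:n, 2:m]
  gx <- (b - a + d - c_) / 2
  gy <- (c_ - a + d - b) / 2
  gx <- gx[c(1:(n - 1), n - 1), c(1:(m - 1), m - 1), drop = FALSE]
  gy <- gy[c(1:(n - 1), n - 1), c(1:(m - 1), m - 1), drop = FALSE]
  list(magnitude = sqrt(gx^2 + gy^2), direction = atan2(gy, gx),
       gx = gx, gy = gy)
}

# Neighbor matrix shifted by (di, dj); out-of-range entries filled with `fill`.
shift_matrix <- function(M, di, dj, fill = -Inf) {
  n <- nrow(M); m <- ncol(M)
  out <- matrix(fill, n, m)
  si <- max(1L, 1L - di):min(n, n - di)
  sj <- max(1L, 1L - dj):min(m, m - dj)
  out[si, sj] <- M[si + di, sj + dj]
  out
}

#' Non-maximum suppression along the gradient direction
#'
#' Keeps a pixel's gradient magnitude only when it is `>=` both of its
#' neighbors along the gradient direction quantized to one of four axes
#' (0°, 45°, 90°, 135°); otherwise the magnitude is set to 0. Ties are kept
#' so plateau edges survive. Out-of-range neighbors never suppress.
#'
#' @param magnitude,direction matrices of matching shape (radians direction).
#' @return The suppressed magnitude matrix.
#' @export
nonmax_suppress <- function(magnitude, direction) {
  magnitude <- as.matrix(magnitude); direction <- as.matrix(direction)
  if (!all(dim(magnitude) == dim(direction))) stop("shape mismatch")
  sector <- (round(direction / (pi / 4)) %% 4)
  # sector 0: gradient along first index; 1: (+1,+1) diagonal;
  # 2: along second index; 3: (+1,-1) diagonal.
  nb <- list(
    `0` = list(c(1L, 0L), c(-1L, 0L)),
    `1` = list(c(1L, 1L), c(-1L, -1L)),
    `2` = list(c(0L, 1L), c(0L, -1L)),
    `3` = list(c(1L, -1L), c(-1L, 1L)))
  out <- magnitude
  for (s in 0:3) {
    mask <- sector == s
    if (!any(mask)) next
    n1 <- shift_matrix(magnitude, nb[[s + 1]][[1]][1], nb[[s + 1]][[1]][2])
    n2 <- shift_matrix(magnitude, nb[[s + 1]][[2]][1], nb[[s + 1]][[2]][2])
    suppress <- mask & (magnitude < n1 | magnitude < n2)
    out[suppress] <- 0
  }
  out
}

neighbor8_any <- function(mask) {
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    out <- out | shift_matrix(mask, di, dj, fill = FALSE)
  }
  out
}

#' Dual-threshold hysteresis edge linking
#'
#' Normalizes the suppressed gradient by its maximum; pixels at or above
#' `high_threshold` are strong edges, pixels at or above
#' `low_ratio * high_threshold` are weak candidates, and the output marks
#' strong pixels plus every weak pixel transitively 8-connected to a strong
#' one. An all-zero input yields an all-zero output.
#'
#' @param suppressed non-negative matrix (NMS output).
#' @param cfg a [canny_config()].
#' @return A binary (0/1) integer matrix.
#' @export
hysteresis_threshold <- function(suppressed, cfg = canny_config()) {
  suppressed <- as.matrix(suppressed)
  if (any(suppressed < 0)) stop("suppressed magnitudes must be >= 0")
  mx <- max(suppressed)
  if (mx == 0) return(matrix(0L, nrow(suppressed), ncol(suppressed)))
  nrm <- suppressed / mx
  strong <- nrm >= cfg$high_threshold
  weak <- nrm >= cfg$low_ratio * cfg$high_threshold
  marked <- strong
  repeat {
    grow <- weak & !marked & neighbor8_any(marked)
    if (!any(grow)) break
    marked <- marked | grow
  }
  out <- matrix(0L, nrow(suppressed), ncol(suppressed))
  out[marked] <- 1L
  out
}

#' Canny edge detection on an MSC map
#'
#' Full pipeline: Gaussian smoothing ([gaussian_smooth()]), 2x2
#' finite-difference gradient ([grad_finite_diff()]), non-maximum suppression
#' ([nonmax_suppress()]) and dual-threshold hysteresis
#' ([hysteresis_threshold()]). On a coherence map, the surviving edges trace
#' the time-frequency locations where synchronization changes abruptly —
#' at seizure onset, a near-vertical edge spanning the reactive frequency
#' band.
#'
#' @param map an `msc_map` (see [build_msc_map()]) or a plain matrix.
#' @param cfg a [canny_config()].
#' @return An object of class `edge_map` with binary `edges`, `magnitude`,
#'   `direction`, and the source `freqs`/`times` axes when available.
#' @export
canny_edges <- function(map, cfg = canny_config()) {
  vals <- if (inherits(map, "msc_map")) map$values else as.matrix(map)
  sm <- gaussian_smooth(vals, cfg$sigma)
  g <- grad_finite_diff(sm)
  nms <- nonmax_suppress(g$magnitude, g$direction)
  edges <- hysteresis_threshold(nms, cfg)
  structure(list(edges = edges, magnitude = g$magnitude,
                 direction = g$direction,
                 freqs = if (inherits(map, "msc_map")) map$freqs else NULL,
                 times = if (inherits(map, "msc_map")) map$times else NULL),
            class = "edge_map")
}

#' @export
print.edge_map <- function(x, ...) {
  cat(sprintf("<edge_map> %d x %d, %d edge pixels\n",
              nrow(x$edges), ncol(x$edges), sum(x$edges)))
  invisible(x)
}

# Label 8-connected components of a logical/0-1 matrix; returns an integer
# matrix (0 = background).
label_components8 <- function(mask) {
  mask <- mask > 0
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  todo <- which(mask & lab == 0L)
  while (length(todo)) {
    cur <- cur + 1L
    seed <- matrix(FALSE, nrow(mask), ncol(mask))
    seed[todo[1]] <- TRUE
    repeat {
      grow <- mask & !seed & neighbor8_any(seed)
      if (!any(grow)) break
      seed <- seed | grow
    }
    lab[seed] <- cur
    todo <- which(mask & lab == 0L)
  }
  lab
}
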