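# Shared fixture builders: tiny images and masks constructed in code.

# random RGB array (H, W, 3) in [0, 1]
random_rgb <- function(h, w = h) {
  array(stats::runif(h * w * 3), dim = c(h, w, 3L))
}

# random logical mask with roughly `p` coverage
random_mask <- function(h, w = h, p = 0.3) {
  matrix(stats::runif(h * w) < p, h, w)
}

# a filled axis-aligned rectangle mask
rect_mask <- function(h, w, r1, r2, c1, c2) {
  m <- matrix(FALSE, h, w)
  m[r1:r2, c1:c2] <- TRUE
  m
}

# independent exhaustive Otsu oracle: search all 256 candidate levels for
# the split maximising between-class variance (lowest level among ties)
otsu_oracle <- function(gray) {
  g8 <- as.vector(round(gray * 255))
  best_t <- NA_integer_
  best_v <- -Inf
  n <- length(g8)
  for (t in 0:255) {
    lo <- g8 <= t
    n0 <- sum(lo)
    if (n0 == 0L || n0 == n) next
    w0 <- n0 / n
    v <- w0 * (1 - w0) * (mean(g8[lo]) - mean(g8[!lo]))^2
    if (v > best_v + 1e-12) {
      best_v <- v
      best_t <- t
    }
  }
  best_t
}

# independent per-pixel HSV interval check (scalar arithmetic, no
# vectorised shortcuts shared with the implementation)
hsv_gate_oracle <- function(img, range) {
  h <- dim(img)[1]
  w <- dim(img)[2]
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      r <- img[i, j, 1]; g <- img[i, j, 2]; b <- img[i, j, 3]
      mx <- max(r, g, b); mn <- min(r, g, b)
      v <- mx
      s <- if (mx > 0) (mx - mn) / mx else 0
      hue <- if (mx == mn) 0 else if (mx == r) {
        (60 * (g - b) / (mx - mn) + 360) %% 360
      } else if (mx == g) {
        60 * (b - r) / (mx - mn) + 120
      } else {
        60 * (r - g) / (mx - mn) + 240
      }
      h8 <- round(hue / 2) %% 180
      s8 <- round(s * 255)
      v8 <- round(v * 255)
      out[i, j] <- h8 >= range$h_lo && h8 <= range$h_hi &&
        s8 >= range$s_lo && s8 <= range$s_hi &&
        v8 >= range$v_lo && v8 <= range$v_hi
    }
  }
  out
}

# Mann-Whitney U-statistic AUC oracle: exhaustive double loop over
# (positive, negative) pairs, ties counted half
auc_oracle <- function(scores, truth) {
  s <- as.vector(scores)
  y <- as.vector(truth)
  pos <- s[y]
  neg <- s[!y]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}
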