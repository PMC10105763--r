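# Standard acquisition time grid: 118 frames over 4 s.
lsfg_times <- function(n = 118, duration = 4) (seq_len(n) - 1) * duration / n

# Pure-tone MBR series with mean m and peak-to-peak 2 * a.
tone_series <- function(m = 20, a = 2, f = 1.5, phase = 0,
                        t = lsfg_times()) {
  lsfg_series(m + a * sin(2 * pi * f * t + phase), t)
}

# Independent oracle: least-squares amplitude of a centered series at one
# known frequency (2-column sin/cos fit), no shared code with the package.
ls_amplitude_oracle <- function(y, t, f) {
  D <- cbind(sin(2 * pi * f * t), cos(2 * pi * f * t))
  x <- solve(crossprod(D), crossprod(D, y))
  sqrt(sum(x^2))
}

# Independent 4-connectivity oracle: flood fill over linear indices.
is_4_connected <- function(mask) {
  n <- sum(mask)
  if (n <= 1) return(TRUE)
  H <- nrow(mask)
  W <- ncol(mask)
  start <- which(mask)[1]
  visited <- logical(H * W)
  stack <- integer(n)
  stack[1] <- start
  top <- 1L
  visited[start] <- TRUE
  seen <- 1L
  while (top > 0L) {
    p <- stack[top]
    top <- top - 1L
    r <- (p - 1L) %% H + 1L
    c <- (p - 1L) %/% H + 1L
    for (q in c(if (r > 1) p - 1L, if (r < H) p + 1L,
                if (c > 1) p - H, if (c < W) p + H)) {
      if (mask[q] && !visited[q]) {
        visited[q] <- TRUE
        seen <- seen + 1L
        top <- top + 1L
        stack[top] <- q
      }
    }
  }
  seen == n
}

# Independent Otsu oracle: exhaustive search over all candidate thresholds
# maximizing the between-class variance.
otsu_oracle <- function(values) {
  v <- sort(unique(values))
  cuts <- (v[-1] + v[-length(v)]) / 2
  bcv <- vapply(cuts, function(th) {
    lo <- values[values <= th]
    hi <- values[values > th]
    (length(lo) * length(hi) / length(values)^2) * (mean(hi) - mean(lo))^2
  }, numeric(1))
  cuts[which.max(bcv)]
}
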