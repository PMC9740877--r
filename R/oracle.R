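#' Batch re-computation of the detection trace
#'
#' Independent, non-streaming route to the same trace as [run_detector()]:
#' rather than carrying a ring buffer through the samples, it reconstructs
#' the gap window at every sample index from the glance structure of the
#' whole stream (which gap occupies which slot follows in closed form from
#' the glance count). Used as a cross-check of the streaming detector; the
#' two must agree element-wise.
#'
#' @param stream A [gaze_stream()].
#' @param config A [detector_config()] with a finite `threshold`.
#' @return A tibble with columns `t, sigma, sigma_smooth, delta, cum,
#'   distracted` — the same contract as the trace of [run_detector()].
#' @export
batch_oracle <- function(stream, config = detector_config()) {
  if (is.null(config$threshold)) {
    stop_usage("detector threshold is uncalibrated; set `threshold` in detector_config()")
  }
  if (!inherits(stream, "gaze_stream")) stream <- gaze_stream(stream)
  t <- stream$t
  on <- effective_on(stream, config)
  N <- length(t)
  empty <- tibble(t = numeric(), sigma = numeric(), sigma_smooth = numeric(),
                  delta = numeric(), cum = numeric(), distracted = logical())
  if (N == 0L) return(empty)
  n <- config$n
  rate <- rate_hz(stream)
  m <- smoothing_m(config, rate)

  # Glance structure: g(i) = index of the most recent glance started at or
  # before sample i; gap k is the off-target interval following glance k.
  onset <- on & !c(FALSE, on[-N])
  g <- cumsum(onset)
  last_on_idx <- cummax(ifelse(on, seq_len(N), 0L))
  gaze_time <- ifelse(last_on_idx > 0L, t[pmax(last_on_idx, 1L)], NA_real_)
  live_val <- t - gaze_time # meaningful at off samples with g >= 1

  # Frozen value of gap k: its last per-sample update, i.e. the live value
  # at the final off-target sample before glance k + 1 begins.
  G <- g[N]
  frozen <- rep(NA_real_, max(G, 1L))
  off <- !on & g >= 1L
  if (any(off)) {
    off_idx <- which(off)
    last_update <- vapply(split(off_idx, g[off_idx]), max, integer(1))
    frozen[as.integer(names(last_update))] <- live_val[last_update]
  }

  pop_sd <- function(v) {
    if (length(v) < 2L) return(0)
    mu <- sum(v) / length(v)
    sqrt(sum((v - mu)^2) / length(v))
  }

  if (config$live_gap == "include") {
    # Slot s (0-based) at sample i holds the frozen gap with the largest
    # index k <= K(i) = g(i) - 1 such that (k - 1) mod n == s, unless the
    # live gap g(i) currently occupies that slot.
    K <- pmax(g - 1L, 0L)
    W <- matrix(NA_real_, nrow = N, ncol = n)
    for (s in 0L:(n - 1L)) {
      k_s <- K - ((K - (s + 1L)) %% n)
      k_s[K < s + 1L] <- NA_integer_
      W[, s + 1L] <- frozen[k_s]
    }
    live_rows <- which(off)
    if (length(live_rows) > 0) {
      W[cbind(live_rows, ((g[live_rows] - 1L) %% n) + 1L)] <- live_val[live_rows]
    }
    cnt <- rowSums(!is.na(W))
    mu <- rowSums(W, na.rm = TRUE) / pmax(cnt, 1L)
    sigma <- sqrt(rowSums((W - mu)^2, na.rm = TRUE) / pmax(cnt, 1L))
    sigma[cnt < 2L] <- 0
  } else {
    # Completed-gaps window: while glance gg is the latest, the window spans
    # gaps max(1, gg - n)..gg - 1 during the glance and loses its oldest gap
    # (evicted by the live overwrite) once the driver looks away again.
    sigma_on <- vapply(seq_len(max(G, 1L)), function(gg) {
      if (gg < 3L) return(0)
      pop_sd(frozen[max(1L, gg - n):(gg - 1L)])
    }, numeric(1))
    sigma_off <- vapply(seq_len(max(G, 1L)), function(gg) {
      if (gg < 3L) return(0)
      pop_sd(frozen[max(1L, gg - n + 1L):(gg - 1L)])
    }, numeric(1))
    sigma <- numeric(N)
    has_g <- g >= 1L
    sigma[has_g & on] <- sigma_on[g[has_g & on]]
    sigma[has_g & !on] <- sigma_off[g[has_g & !on]]
  }

  trace <- finish_trace(t, sigma, m, rate, config)
  trace$distracted <- trace$cum > config$threshold
  trace
}
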