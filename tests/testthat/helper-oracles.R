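# Independent brute-force oracles used to freeze expected values.

# per-pixel dynamic-programming LHI oracle: explicit loops, no vectorisation
lhi_oracle <- function(stack, threshold, tau) {
  S <- dim(stack)[1]; H <- dim(stack)[2]; W <- dim(stack)[3]
  f <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    v <- 0
    for (s in 2:S) {
      if (abs(stack[s, i, j] - stack[s - 1, i, j]) > threshold) v <- tau
      else v <- max(0, v - 1)
    }
    f[i, j] <- v
  }
  f
}

# exhaustive FROC oracle: enumerate every score cut point, recount TP/FP
froc_oracle <- function(cands, truths, n_scans, fp_levels) {
  hit_of <- rep(NA_integer_, nrow(cands))
  # per-truth best hit (highest score, ties by candidate order)
  tp_score <- rep(NA_real_, nrow(truths))
  ignored <- logical(nrow(cands))
  is_tp <- logical(nrow(cands))
  for (t in seq_len(nrow(truths))) {
    same <- which(cands$seriesuid == truths$seriesuid[t])
    if (!length(same)) next
    d <- sqrt((cands$coordX[same] - truths$coordX[t])^2 +
              (cands$coordY[same] - truths$coordY[t])^2 +
              (cands$coordZ[same] - truths$coordZ[t])^2)
    hits <- same[d < truths$diameter_mm[t] / 2]
    if (!length(hits)) next
    best <- hits[order(-cands$score[hits], hits)][1]
    is_tp[best] <- TRUE
    ignored[setdiff(hits, best)] <- TRUE
    tp_score[t] <- cands$score[best]
  }
  ignored <- ignored & !is_tp
  fp_scores <- cands$score[!is_tp & !ignored]
  cuts <- c(Inf, sort(unique(cands$score), decreasing = TRUE))
  sens <- vapply(fp_levels, function(L) {
    best <- 0
    for (t in cuts) {
      fp <- sum(fp_scores >= t)
      if (fp / n_scans <= L) {
        s <- sum(tp_score >= t, na.rm = TRUE) / nrow(truths)
        best <- max(best, s)
      }
    }
    best
  }, numeric(1))
  sens
}

# centre of mass of a non-negative image, 0-based (x, y)
com2d <- function(img) {
  tot <- sum(img)
  if (tot == 0) return(c(NA_real_, NA_real_))
  ys <- seq_len(nrow(img)) - 1
  xs <- seq_len(ncol(img)) - 1
  c(sum(colSums(img) * xs) / tot, sum(rowSums(img) * ys) / tot)
}

random_toy_matchset <- function(seed) {
  # small candidate/truth sets over 2-5 scans for FROC oracle comparison
  set.seed(seed)
  n_scans <- sample(2:5, 1)
  scans <- sprintf("s%02d", seq_len(n_scans))
  n_truths <- sample(2:10, 1)
  truths <- data.frame(seriesuid = sample(scans, n_truths, replace = TRUE),
                       coordX = runif(n_truths, -40, 40),
                       coordY = runif(n_truths, -40, 40),
                       coordZ = runif(n_truths, -40, 40),
                       diameter_mm = runif(n_truths, 4, 14))
  n_c <- sample(5:50, 1)
  near <- sample(seq_len(n_truths), n_c, replace = TRUE)
  jitter <- matrix(rnorm(3 * n_c, 0, 6), n_c, 3)
  cands <- data.frame(seriesuid = truths$seriesuid[near],
                      coordX = truths$coordX[near] + jitter[, 1],
                      coordY = truths$coordY[near] + jitter[, 2],
                      coordZ = truths$coordZ[near] + jitter[, 3],
                      diameter_mm = runif(n_c, 4, 14),
                      score = round(runif(n_c), 3),
                      label = "unfiltered")
  list(cands = cands, truths = truths, n_scans = n_scans, scans = scans)
}
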