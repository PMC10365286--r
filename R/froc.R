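#' Match candidates to ground-truth nodules
#'
#' LUNA16-style hit criterion: a candidate hits a truth if the Euclidean
#' distance between their world centres is smaller than the truth radius
#' (`diameter_mm / 2`). Per truth, the highest-scoring hitting candidate is
#' the true positive (ties broken by input order); further hits on an
#' already-hit truth are ignored (neither TP nor FP); candidates hitting
#' nothing are false positives.
#'
#' @param cands candidate data.frame (world mm, `score`).
#' @param truths annotation data.frame (world mm, `diameter_mm`).
#' @param scans character vector of scan ids under evaluation; defaults to
#'   the union of the ids present in `truths` and unannotated scans must be
#'   listed explicitly. Candidates on unknown scans raise an error.
#' @return list with `candidates` (input plus `match` in
#'   `{"TP","FP","ignored"}` and `truth_row`), `truths` (plus `hit`,
#'   `hit_score`), and `scans`.
#' @export
match_candidates <- function(cands, truths, scans = NULL) {
  scans <- scans %||% unique(truths$seriesuid)
  unknown <- setdiff(unique(cands$seriesuid), scans)
  if (length(unknown))
    stop("match_candidates: candidate scan id(s) not under evaluation: ",
         paste(unknown, collapse = ", "))
  cands$match <- rep("FP", nrow(cands))
  cands$truth_row <- rep(NA_integer_, nrow(cands))
  truths$hit <- rep(FALSE, nrow(truths))
  truths$hit_score <- rep(NA_real_, nrow(truths))
  for (sid in scans) {
    ci <- which(cands$seriesuid == sid)
    ti <- which(truths$seriesuid == sid)
    if (!length(ci) || !length(ti)) next
    cxyz <- as.matrix(cands[ci, c("coordX", "coordY", "coordZ")])
    hit_any <- logical(length(ci))
    top_any <- logical(length(ci))
    for (t in ti) {
      d <- sqrt(colSums((t(cxyz) -
                         as.numeric(truths[t, c("coordX", "coordY",
                                                "coordZ")]))^2))
      hits <- which(d < truths$diameter_mm[t] / 2)
      if (!length(hits)) next
      hit_any[hits] <- TRUE
      best <- hits[order(-cands$score[ci[hits]], hits)[1]]
      top_any[best] <- TRUE
      truths$hit[t] <- TRUE
      truths$hit_score[t] <- cands$score[ci[best]]
      cands$truth_row[ci[best]] <- t
    }
    cands$match[ci[top_any]] <- "TP"
    cands$match[ci[hit_any & !top_any]] <- "ignored"
    cands$match[ci[!hit_any]] <- "FP"
  }
  list(candidates = cands, truths = truths, scans = scans)
}

#' FROC sensitivities at fixed false-positive rates
#'
#' Sweeps the candidate score threshold and reports, for each
#' false-positives-per-scan level, the best achievable sensitivity among
#' operating points with `FP/scan <= level` (step-function reading, no
#' interpolation; 0 if no threshold qualifies).
#'
#' @param matched result of [match_candidates()].
#' @param n_scans number of scans (must be positive).
#' @param fp_levels false-positive-per-scan levels; default the seven
#'   canonical levels `1/8 ... 8`.
#' @param interpolate linearly interpolate the FROC curve between
#'   adjacent operating points instead of the default step-function
#'   reading.
#' @return a `froc_result`: `fp_levels`, `sensitivities`, `cpm` (mean
#'   sensitivity, 3 decimals, when seven levels are used), `n_truths`,
#'   `n_scans`.
#' @export
froc_sensitivities <- function(matched, n_scans,
                               fp_levels = c(1/8, 1/4, 1/2, 1, 2, 4, 8),
                               interpolate = FALSE) {
  if (n_scans <= 0) stop("froc_sensitivities: n_scans must be positive")
  cands <- matched$candidates
  truths <- matched$truths
  n_truths <- nrow(truths)
  hit_scores <- truths$hit_score[truths$hit]
  fp_scores <- cands$score[cands$match == "FP"]
  thr <- c(Inf, sort(unique(cands$score[cands$match != "ignored"]),
                     decreasing = TRUE))
  tp_at <- vapply(thr, function(t) sum(hit_scores >= t), numeric(1))
  fp_at <- vapply(thr, function(t) sum(fp_scores >= t), numeric(1))
  sens <- vapply(fp_levels, function(L) {
    ok <- fp_at / n_scans <= L
    if (!any(ok) || n_truths == 0) return(0)
    best <- max(tp_at[ok]) / n_truths
    if (interpolate && any(!ok)) {
      # linear interpolation towards the next (higher-FP) operating point
      i_hi <- which(!ok)[which.min(fp_at[!ok])]
      f0 <- max(fp_at[ok][tp_at[ok] == max(tp_at[ok])]) / n_scans
      f1 <- fp_at[i_hi] / n_scans
      s1 <- tp_at[i_hi] / n_truths
      if (f1 > f0 && s1 > best)
        best <- best + (s1 - best) * (L - f0) / (f1 - f0)
    }
    best
  }, numeric(1))
  structure(list(fp_levels = fp_levels, sensitivities = sens,
                 cpm = if (length(fp_levels) == 7) cpm_score(sens) else
                   round(mean(sens), 3),
                 n_truths = n_truths, n_scans = n_scans),
            class = "froc_result")
}

#' @export
print.froc_result <- function(x, ...) {
  cat("FROC analysis:", x$n_truths, "nodules over", x$n_scans, "scans\n")
  lev <- format(x$fp_levels, digits = 3)
  cat("  FP/scan:     ", paste(sprintf("%6s", lev), collapse = " "), "\n")
  cat("  sensitivity: ",
      paste(sprintf("%6.3f", x$sensitivities), collapse = " "), "\n")
  cat(sprintf("  CPM: %.3f\n", x$cpm))
  invisible(x)
}

#' Competition Performance Metric
#'
#' The arithmetic mean of the seven sensitivities at 1/8, 1/4, 1/2, 1, 2,
#' 4 and 8 false positives per scan, reported at 3 decimals.
#'
#' @param sensitivities exactly seven values in `[0, 1]`.
#' @return scalar CPM.
#' @export
cpm_score <- function(sensitivities) {
  if (length(sensitivities) != 7)
    stop("cpm_score: exactly seven sensitivities required")
  if (any(sensitivities < 0 | sensitivities > 1))
    stop("cpm_score: sensitivities must lie in [0, 1]")
  round(mean(sensitivities), 3)
}

#' Nodule size strata
#'
#' Diameter partition used for size-stratified CPM: small `[3, 5)` mm,
#' medium `[5, 10]` mm, large `(10, Inf)` mm.
#'
#' @param d numeric diameters (mm), all `>= 3`.
#' @return factor with levels small/medium/large.
#' @export
size_strata <- function(d) {
  factor(ifelse(d < 5, "small", ifelse(d <= 10, "medium", "large")),
         levels = c("small", "medium", "large"))
}

#' Size-stratified CPM
#'
#' Computes per-stratum FROC sensitivities: the stratum's truths define the
#' sensitivity numerator/denominator while the false-positive rate at each
#' operating point is computed over all candidates. Empty strata are
#' reported as `NA` and flagged.
#'
#' @param matched result of [match_candidates()].
#' @param n_scans number of scans.
#' @param fp_levels FP/scan levels (default the canonical seven).
#' @return list with per-stratum `froc_result`s (`NA` CPM for empty
#'   strata) and a `cpm` named vector.
#' @export
stratified_cpm <- function(matched, n_scans,
                           fp_levels = c(1/8, 1/4, 1/2, 1, 2, 4, 8)) {
  truths <- matched$truths
  strata <- size_strata(truths$diameter_mm)
  cands <- matched$candidates
  fp_scores <- cands$score[cands$match == "FP"]
  thr <- c(Inf, sort(unique(cands$score[cands$match != "ignored"]),
                     decreasing = TRUE))
  fp_at <- vapply(thr, function(t) sum(fp_scores >= t), numeric(1))
  out <- list()
  cpms <- c(small = NA_real_, medium = NA_real_, large = NA_real_)
  for (s in levels(strata)) {
    ti <- which(strata == s)
    if (!length(ti)) {
      out[[s]] <- list(empty = TRUE)
      next
    }
    hs <- truths$hit_score[ti][truths$hit[ti]]
    tp_at <- vapply(thr, function(t) sum(hs >= t), numeric(1))
    sens <- vapply(fp_levels, function(L) {
      ok <- fp_at / n_scans <= L
      if (!any(ok)) return(0)
      max(tp_at[ok]) / length(ti)
    }, numeric(1))
    cpmv <- if (length(fp_levels) == 7) cpm_score(sens) else
      round(mean(sens), 3)
    out[[s]] <- structure(list(fp_levels = fp_levels,
                               sensitivities = sens, cpm = cpmv,
                               n_truths = length(ti), n_scans = n_scans),
                          class = "froc_result")
    cpms[s] <- cpmv
  }
  list(strata = out, cpm = cpms)
}

#' Candidate-level confusion counts for filtered candidates
#'
#' Treats the HS2 label as the decision (`nodule` = positive) and the
#' matching result as the reference: sensitivity `TP/(TP+FN)` and
#' specificity `TN/(TN+FP)` over candidate decisions.
#'
#' @param matched result of [match_candidates()] on candidates carrying
#'   HS2 labels.
#' @return named vector `c(tp, fp, tn, fn, sensitivity, specificity)`.
#' @export
candidate_confusion <- function(matched) {
  cands <- matched$candidates
  used <- cands$match != "ignored"
  is_true <- cands$match[used] == "TP"
  called <- cands$label[used] != "tissue"
  tp <- sum(is_true & called)
  fn <- sum(is_true & !called)
  fp <- sum(!is_true & called)
  tn <- sum(!is_true & !called)
  c(tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}
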