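#' Match a sort result to ground truth
#'
#' Greedy one-to-one matching per unit: each reported spike is matched to the
#' nearest not-yet-matched truth spike of the same unit within `tol_samples`
#' (reported spikes processed in order of their distance to the nearest
#' candidate, so close pairs claim each other first). Matched reported spikes
#' are correct; unmatched reported spikes are false positives; unmatched
#' truth spikes are misses. When the result's unit numbering does not
#' correspond to the truth's, the unit correspondence maximizing the total
#' number of matches is found first (exhaustively for up to 6 units, greedily
#' above).
#'
#' @param result A sort result from [run_sort()] (or any list with a `units`
#'   element: one data frame with a `time` column per unit).
#' @param truth Ground truth from [simulate_recording()] (`$truth`).
#' @param tol_samples Matching tolerance in samples (default 15, i.e. half
#'   the 1-ms refractory period at 30 kHz, which prevents double matching).
#' @return List of class `truth_outcomes`: `per_unit` (data frame per truth
#'   unit: `matched` flag and `overlap` flag per truth spike),
#'   `false_positives` (count per result unit), `unit_map` (result unit ->
#'   truth unit), `tol_samples`.
#' @export
match_to_truth <- function(result, truth, tol_samples = 15L) {
  res_times <- lapply(result$units, function(df) {
    if (is.data.frame(df)) sort(df$time) else sort(df)
  })
  true_times <- truth$unit_times
  nr <- length(res_times); nt <- length(true_times)
  count_matches <- function(rt, tt) {
    if (length(rt) == 0L || length(tt) == 0L) return(0L)
    length(greedy_match(rt, tt, tol_samples)$matched_truth)
  }
  # unit correspondence maximizing total matches
  if (nr == 0L) {
    map <- integer(0)
  } else if (max(nr, nt) <= 6L) {
    cnt <- outer(seq_len(nr), seq_len(nt),
                 Vectorize(function(i, j) count_matches(res_times[[i]],
                                                        true_times[[j]])))
    perms <- all_assignments(nr, nt)
    scores <- vapply(perms, function(p) {
      sum(cnt[cbind(which(!is.na(p)), p[!is.na(p)])])
    }, 0L)
    map <- perms[[which.max(scores)]]
  } else {
    cnt <- outer(seq_len(nr), seq_len(nt),
                 Vectorize(function(i, j) count_matches(res_times[[i]],
                                                        true_times[[j]])))
    map <- rep(NA_integer_, nr)
    for (k in seq_len(min(nr, nt))) {
      best <- arrayInd(which.max(cnt), dim(cnt))
      map[best[1L]] <- best[2L]
      cnt[best[1L], ] <- -1L
      cnt[, best[2L]] <- -1L
    }
  }
  per_unit <- vector("list", nt)
  fp <- integer(nr)
  for (j in seq_len(nt)) {
    tt <- true_times[[j]]
    matched <- rep(FALSE, length(tt))
    i <- match(j, map)
    if (!is.na(i)) {
      gm <- greedy_match(res_times[[i]], tt, tol_samples)
      matched[gm$matched_truth] <- TRUE
      fp[i] <- length(res_times[[i]]) - length(gm$matched_truth)
    }
    per_unit[[j]] <- data.frame(
      time = tt, matched = matched,
      overlap = truth$overlap_flags[[j]]
    )
  }
  # result units mapped to no truth unit: everything they report is false
  for (i in seq_len(nr)) {
    if (nr > 0L && is.na(map[i])) fp[i] <- length(res_times[[i]])
  }
  structure(
    list(per_unit = per_unit, false_positives = fp, unit_map = map,
         tol_samples = tol_samples),
    class = "truth_outcomes"
  )
}

# one-to-one nearest matching of sorted reported times rt to truth times tt
greedy_match <- function(rt, tt, tol) {
  if (length(rt) == 0L || length(tt) == 0L) {
    return(list(matched_truth = integer(0), matched_reported = integer(0)))
  }
  pos <- findInterval(rt, tt)
  cand_lo <- pmax(pos, 1L)
  cand_hi <- pmin(pos + 1L, length(tt))
  d_lo <- abs(rt - tt[cand_lo])
  d_hi <- abs(rt - tt[cand_hi])
  nearest <- ifelse(d_lo <= d_hi, cand_lo, cand_hi)
  nd <- pmin(d_lo, d_hi)
  ord <- order(nd)
  used <- rep(FALSE, length(tt))
  matched_truth <- integer(0); matched_reported <- integer(0)
  for (i in ord) {
    if (nd[i] > tol) break
    j <- nearest[i]
    if (!used[j]) {
      used[j] <- TRUE
    } else {
      # nearest taken: try the other neighbour
      j2 <- if (j == cand_lo[i]) cand_hi[i] else cand_lo[i]
      if (j2 != j && !used[j2] && abs(rt[i] - tt[j2]) <= tol) j <- j2
      else next
      used[j] <- TRUE
    }
    matched_truth <- c(matched_truth, j)
    matched_reported <- c(matched_reported, i)
  }
  list(matched_truth = matched_truth, matched_reported = matched_reported)
}

# all injective (partial) assignments of result units to truth units
all_assignments <- function(nr, nt) {
  if (nr == 0L) return(list(integer(0)))
  cols <- c(seq_len(nt), rep(NA_integer_, max(0L, nr - nt)))
  perms <- unique(combinat_permn(cols, nr))
  perms
}

# all length-k arrangements of v (with NA padding allowed), small k only
combinat_permn <- function(v, k) {
  if (k == 0L) return(list(integer(0)))
  out <- list()
  for (i in seq_along(v)) {
    rest <- combinat_permn(v[-i], k - 1L)
    for (r in rest) {
      cand <- c(v[i], r)
      if (anyDuplicated(cand[!is.na(cand)]) == 0L) {
        out[[length(out) + 1L]] <- cand
      }
    }
  }
  out
}

#' Score matched outcomes
#'
#' Aggregates [match_to_truth()] outcomes into the standard report: total
#' truth spikes (with the overlap subset in parentheses when printed),
#' correctly sorted counts, false positives, and the three percentages -
#' sorted, overlap-sorted, and false-positive rate (false positives divided
#' by total truth spikes). Percentages are reported raw and truncated to
#' integer (the tabulated convention; the FP percentage is conventionally
#' shown with 2 decimals).
#'
#' @param outcomes A [match_to_truth()] result.
#' @return A list of class `score_report` with fields `total_true`,
#'   `total_true_overlaps`, `sorted_correct`, `sorted_correct_overlaps`,
#'   `false_positives`, `sorted_pct`, `overlap_sorted_pct`, `fp_pct`,
#'   truncated variants `sorted_pct_int` / `overlap_sorted_pct_int`, and
#'   `per_unit` counts.
#' @export
score_sort <- function(outcomes) {
  pu <- outcomes$per_unit
  total_true <- sum(vapply(pu, nrow, 0L))
  if (total_true == 0L) stop("ground truth contains no spikes")
  total_ov <- sum(vapply(pu, function(d) sum(d$overlap), 0L))
  sorted <- sum(vapply(pu, function(d) sum(d$matched), 0L))
  sorted_ov <- sum(vapply(pu, function(d) sum(d$matched & d$overlap), 0L))
  fp <- sum(outcomes$false_positives)
  per_unit <- data.frame(
    unit = seq_along(pu),
    true = vapply(pu, nrow, 0L),
    true_overlaps = vapply(pu, function(d) sum(d$overlap), 0L),
    sorted = vapply(pu, function(d) sum(d$matched), 0L),
    sorted_overlaps = vapply(pu, function(d) sum(d$matched & d$overlap), 0L)
  )
  structure(
    list(
      total_true = total_true,
      total_true_overlaps = total_ov,
      sorted_correct = sorted,
      sorted_correct_overlaps = sorted_ov,
      false_positives = fp,
      sorted_pct = 100 * sorted / total_true,
      overlap_sorted_pct = if (total_ov > 0) 100 * sorted_ov / total_ov
                           else NA_real_,
      fp_pct = 100 * fp / total_true,
      sorted_pct_int = trunc(100 * sorted / total_true),
      overlap_sorted_pct_int = if (total_ov > 0)
        trunc(100 * sorted_ov / total_ov) else NA_integer_,
      per_unit = per_unit,
      tol_samples = outcomes$tol_samples
    ),
    class = "score_report"
  )
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf(
    "<score_report> %d (%d) true spikes (overlaps); sorted %d (%d) = %d%% (%s%%); FP %d (%.2f%%)\n",
    x$total_true, x$total_true_overlaps, x$sorted_correct,
    x$sorted_correct_overlaps, x$sorted_pct_int,
    ifelse(is.na(x$overlap_sorted_pct_int), "-", x$overlap_sorted_pct_int),
    x$false_positives, x$fp_pct
  ))
  invisible(x)
}
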