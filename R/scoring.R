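# Scoring pipeline output against synthetic ground truth.

#' Match detected spike times to ground truth
#'
#' Greedy one-to-one matching within `+/- tol` seconds: detections are
#' swept in time order and each takes the earliest unmatched truth spike
#' within tolerance.
#'
#' @param truth_times,detected_times ascending times, seconds.
#' @param tol matching tolerance, seconds (default 0.5 ms).
#' @return list `precision`, `recall`, `f1`, `n_matched`, and
#'   `matches` (two-column matrix of matched truth/detected indices).
#' @export
score_detection <- function(truth_times, detected_times, tol = 5e-4) {
  truth_times <- sort(truth_times)
  detected_times <- sort(detected_times)
  nt <- length(truth_times)
  nd <- length(detected_times)
  matches <- matrix(integer(0), ncol = 2,
                    dimnames = list(NULL, c("truth", "detected")))
  i <- 1L
  for (j in seq_len(nd)) {
    while (i <= nt && truth_times[i] < detected_times[j] - tol) i <- i + 1L
    if (i <= nt && abs(truth_times[i] - detected_times[j]) <= tol) {
      matches <- rbind(matches, c(i, j))
      i <- i + 1L
    }
  }
  tp <- nrow(matches)
  precision <- if (nd > 0) tp / nd else NA_real_
  recall <- if (nt > 0) tp / nt else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(precision = precision, recall = recall, f1 = f1, n_matched = tp,
       matches = matches)
}

## all permutations of 1..m (m <= 7 in practice)
all_perms <- function(m) {
  if (m == 1) return(list(1L))
  out <- list()
  for (p in all_perms(m - 1L)) {
    for (pos in seq_len(m)) {
      out[[length(out) + 1]] <- append(p, m, after = pos - 1L)
    }
  }
  out
}

#' Sorting accuracy under optimal cluster-to-unit matching
#'
#' Builds the contingency table of true versus predicted labels (over the
#' same matched spikes) and finds the one-to-one cluster/unit assignment
#' maximizing agreement by exhaustive permutation search.
#'
#' @param truth_labels,pred_labels equal-length label vectors.
#' @return list `accuracy`, `assignment` (named vector: for each predicted
#'   label, the matched truth label or NA), `table`.
#' @export
score_sorting <- function(truth_labels, pred_labels) {
  stopifnot(length(truth_labels) == length(pred_labels))
  n <- length(truth_labels)
  if (n == 0) return(list(accuracy = NA_real_, assignment = NULL,
                          table = NULL))
  tab <- table(truth = truth_labels, pred = pred_labels)
  r <- nrow(tab); c <- ncol(tab)
  m <- max(r, c)
  sq <- matrix(0, m, m)
  sq[seq_len(r), seq_len(c)] <- tab
  best <- -1; best_perm <- NULL
  for (p in all_perms(m)) {
    agree <- sum(sq[cbind(seq_len(m), unlist(p))])
    if (agree > best) {
      best <- agree
      best_perm <- unlist(p)
    }
  }
  assignment <- stats::setNames(rep(NA_character_, c), colnames(tab))
  for (ti in seq_len(r)) {
    ci <- best_perm[ti]
    if (ci <= c) assignment[ci] <- rownames(tab)[ti]
  }
  list(accuracy = best / n, assignment = assignment, table = tab)
}

#' Confusion counts for responsiveness classification
#'
#' @param truth_flags,pred_flags logical vectors over the same (matched)
#'   units.
#' @return named vector `TP, FP, FN, TN` plus `sensitivity` and
#'   `specificity` (NA when undefined).
#' @export
score_response <- function(truth_flags, pred_flags) {
  stopifnot(length(truth_flags) == length(pred_flags))
  tp <- sum(truth_flags & pred_flags)
  fp <- sum(!truth_flags & pred_flags)
  fn <- sum(truth_flags & !pred_flags)
  tn <- sum(!truth_flags & !pred_flags)
  c(TP = tp, FP = fp, FN = fn, TN = tn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Match predicted units to true units
#'
#' Per channel, matches detected spikes to true spikes in time
#' ([score_detection()]) and assigns each predicted unit the true unit it
#' best agrees with ([score_sorting()] on the matched spikes).  True units
#' with no matched predicted unit appear with `pred_unit = NA`.
#'
#' @param truth a `synth_ground_truth`.
#' @param unit_table pipeline unit table: `channel, unit, spike_time_s`.
#' @param tol spike-time matching tolerance, seconds.
#' @return data frame `channel, true_unit, pred_unit`.
#' @export
match_units <- function(truth, unit_table, tol = 5e-4) {
  out <- list()
  for (ch in unique(truth$units$channel)) {
    tsp <- truth$spikes[truth$spikes$channel == ch, ]
    psp <- unit_table[unit_table$channel == ch, ]
    true_units <- truth$units$unit[truth$units$channel == ch]
    assigned <- stats::setNames(rep(NA_integer_, length(true_units)),
                                true_units)
    if (nrow(tsp) > 0 && nrow(psp) > 0) {
      tsp <- tsp[order(tsp$time_s), ]
      psp <- psp[order(psp$spike_time_s), ]
      sc <- score_detection(tsp$time_s, psp$spike_time_s, tol)
      if (nrow(sc$matches) > 0) {
        tl <- tsp$unit[sc$matches[, "truth"]]
        pl <- psp$unit[sc$matches[, "detected"]]
        srt <- score_sorting(tl, pl)
        for (pu in names(srt$assignment)) {
          tu <- srt$assignment[[pu]]
          if (!is.na(tu)) assigned[tu] <- as.integer(pu)
        }
      }
    }
    out[[length(out) + 1]] <- data.frame(
      channel = ch, true_unit = as.integer(names(assigned)),
      pred_unit = unname(assigned))
  }
  do.call(rbind, out)
}

#' Score a full pipeline run against synthetic ground truth
#'
#' Convenience wrapper combining [match_units()], [score_sorting()] and
#' [score_response()]: matches predicted units to true units, compares
#' responsiveness verdicts (a true unit with no matched predicted unit
#' counts as a miss), and pools per-channel sorting accuracy weighted by
#' matched spike count.
#'
#' @param truth a `synth_ground_truth`.
#' @param result a [run_pipeline()] result bundle.
#' @param tol spike matching tolerance, seconds.
#' @return list `response` (output of [score_response()]),
#'   `sorting_accuracy` (pooled), `unit_matching` (the [match_units()]
#'   table with truth/predicted responsive flags).
#' @export
score_pipeline <- function(truth, result, tol = 5e-4) {
  mu <- match_units(truth, result$units, tol)
  key_t <- paste(truth$units$channel, truth$units$unit)
  truth_flag <- truth$units$responsive[match(paste(mu$channel, mu$true_unit),
                                             key_t)]
  pred_flag <- rep(FALSE, nrow(mu))
  for (i in seq_len(nrow(mu))) {
    if (!is.na(mu$pred_unit[i])) {
      uid <- paste0("ch", mu$channel[i], "u", mu$pred_unit[i])
      hit <- result$unit_summary$responsive[result$unit_summary$unit_id == uid]
      if (length(hit) == 1) pred_flag[i] <- hit
    }
  }
  mu$truth_responsive <- truth_flag
  mu$pred_responsive <- pred_flag

  accs <- numeric(0); wts <- numeric(0)
  for (ch in unique(truth$spikes$channel)) {
    tsp <- truth$spikes[truth$spikes$channel == ch, ]
    psp <- result$units[result$units$channel == ch, ]
    if (nrow(tsp) < 2 || nrow(psp) < 2) next
    tsp <- tsp[order(tsp$time_s), ]
    psp <- psp[order(psp$spike_time_s), ]
    sc <- score_detection(tsp$time_s, psp$spike_time_s, tol)
    if (nrow(sc$matches) < 2) next
    srt <- score_sorting(tsp$unit[sc$matches[, "truth"]],
                         psp$unit[sc$matches[, "detected"]])
    accs <- c(accs, srt$accuracy)
    wts <- c(wts, nrow(sc$matches))
  }
  list(response = score_response(truth_flag, pred_flag),
       sorting_accuracy = if (length(accs)) sum(accs * wts) / sum(wts) else
         NA_real_,
       unit_matching = mu)
}
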