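#' Match a predicted segmentation against a gold standard
#'
#' Object-level bookkeeping with over/under-segmentation accounting.
#' From the pairwise overlap matrix:
#' \itemize{
#'   \item a predicted object covering the majority (>= 50% of area) of
#'     two or more gold objects marks those gold objects
#'     \emph{undersegmented} (`Nunder`, one count per gold object);
#'   \item two or more remaining predicted objects lying mostly (>= 50%
#'     of their own area) inside one gold object mark it oversegmented,
#'     counting one `Nover` per \emph{extra} predicted object;
#'   \item a remaining gold object overlapped by exactly one remaining
#'     predicted object at Jaccard >= `overlap_threshold` is correct
#'     (`Nt`);
#'   \item leftover predicted objects are false positives (`NFP`),
#'     leftover gold objects false negatives (`NFN`).
#' }
#' Every gold object contributes to at most one of
#' `Nt`/`Nunder`/`NFN`/oversegmented.
#'
#' @param pred,gold integer label matrices of identical shape.
#' @param overlap_threshold qualifying Jaccard index for a correct match
#'   (default 0.5).
#' @return object of class `MatchCounts`: list with `Nt`, `Nunder`,
#'   `Nover`, `NFP`, `NFN`, and `pairs` (data.frame of Nt-matched
#'   pred/gold label pairs, used for shape fidelity).
#' @export
match_segments <- function(pred, gold, overlap_threshold = 0.5) {
  pred <- as_label_matrix(pred); gold <- as_label_matrix(gold)
  if (!all(dim(pred) == dim(gold))) stop("shape mismatch")
  p_labs <- sort(unique(pred[pred > 0L]))
  g_labs <- sort(unique(gold[gold > 0L]))
  p_area <- tabulate(pred[pred > 0L], nbins = max(pred, 1L))
  g_area <- tabulate(gold[gold > 0L], nbins = max(gold, 1L))
  both <- pred > 0L & gold > 0L
  ov <- if (any(both))
    as.data.frame(table(p = pred[both], g = gold[both]),
                  stringsAsFactors = FALSE) else
    data.frame(p = character(), g = character(), Freq = integer())
  ov <- ov[ov$Freq > 0, , drop = FALSE]
  ov$p <- as.integer(as.character(ov$p))
  ov$g <- as.integer(as.character(ov$g))
  ov$frac_of_gold <- ov$Freq / g_area[ov$g]
  ov$frac_of_pred <- ov$Freq / p_area[ov$p]
  ov$jaccard <- ov$Freq / (p_area[ov$p] + g_area[ov$g] - ov$Freq)

  gold_state <- setNames(rep("open", length(g_labs)), g_labs)
  pred_used <- setNames(rep(FALSE, length(p_labs)), p_labs)
  Nt <- 0L; Nunder <- 0L; Nover <- 0L

  # undersegmentation: one pred covers the majority of >= 2 gold objects
  for (p in p_labs) {
    covered <- ov$g[ov$p == p & ov$frac_of_gold >= 0.5]
    covered <- covered[gold_state[as.character(covered)] == "open"]
    if (length(covered) >= 2L) {
      Nunder <- Nunder + length(covered)
      gold_state[as.character(covered)] <- "under"
      pred_used[as.character(p)] <- TRUE
    }
  }
  # oversegmentation: >= 2 remaining preds mostly inside one gold object
  for (g in g_labs) {
    if (gold_state[as.character(g)] != "open") next
    inside <- ov$p[ov$g == g & ov$frac_of_pred >= 0.5]
    inside <- inside[!pred_used[as.character(inside)]]
    if (length(inside) >= 2L) {
      Nover <- Nover + (length(inside) - 1L)
      gold_state[as.character(g)] <- "over"
      pred_used[as.character(inside)] <- TRUE
    }
  }
  # correct matches at qualifying Jaccard
  pairs <- data.frame(pred = integer(), gold = integer())
  for (g in g_labs) {
    if (gold_state[as.character(g)] != "open") next
    cand <- ov[ov$g == g & ov$jaccard >= overlap_threshold, , drop = FALSE]
    cand <- cand[!pred_used[as.character(cand$p)], , drop = FALSE]
    if (nrow(cand) == 1L) {
      Nt <- Nt + 1L
      gold_state[as.character(g)] <- "matched"
      pred_used[as.character(cand$p)] <- TRUE
      pairs <- rbind(pairs, data.frame(pred = cand$p, gold = g))
    }
  }
  NFN <- sum(gold_state == "open")
  NFP <- sum(!pred_used)
  structure(list(Nt = Nt, Nunder = Nunder, Nover = Nover,
                 NFP = as.integer(NFP), NFN = as.integer(NFN),
                 pairs = pairs),
            class = "MatchCounts")
}

#' @export
print.MatchCounts <- function(x, ...) {
  cat(sprintf("MatchCounts: Nt=%d Nunder=%d Nover=%d NFP=%d NFN=%d\n",
              x$Nt, x$Nunder, x$Nover, x$NFP, x$NFN))
  invisible(x)
}

#' Object-level precision, recall and F-score
#'
#' `P = Nt / (Nt + NFP + Nover)`, `R = Nt / (Nt + NFN + Nunder)`,
#' `F = 2PR / (P + R)`. A zero denominator makes the metric undefined
#' (`NA`), not zero.
#'
#' @param c a `MatchCounts` (or a list with the five count fields).
#' @return named numeric vector `c(P =, R =, F =)`.
#' @export
precision_recall_f <- function(c) {
  stopifnot(all(c(c$Nt, c$Nunder, c$Nover, c$NFP, c$NFN) >= 0))
  dp <- c$Nt + c$NFP + c$Nover
  dr <- c$Nt + c$NFN + c$Nunder
  P <- if (dp > 0) c$Nt / dp else NA_real_
  R <- if (dr > 0) c$Nt / dr else NA_real_
  Fs <- if (!is.na(P) && !is.na(R) && (P + R) > 0) 2 * P * R / (P + R)
        else NA_real_
  c(P = P, R = R, F = Fs)
}

#' Shape fidelity of matched objects
#'
#' For every correctly matched pair, the quotient of perimeter--area
#' ratios, `(P/A)_pred / (P/A)_gold`; 1 indicates identical morphology,
#' and the quotient halves when linear size doubles. Perimeter is the
#' exposed pixel-face count.
#'
#' @param pred,gold label matrices.
#' @param matches a `MatchCounts` from [match_segments()].
#' @return list with `per_object` (data.frame pred, gold, quotient) and
#'   `mean` (image-level mean quotient); empty with no matches.
#' @export
shape_fidelity <- function(pred, gold, matches) {
  stopifnot(inherits(matches, "MatchCounts"))
  if (nrow(matches$pairs) == 0L)
    return(list(per_object = data.frame(pred = integer(), gold = integer(),
                                        quotient = numeric()),
                mean = NA_real_))
  pred <- as_label_matrix(pred); gold <- as_label_matrix(gold)
  per_p <- face_perimeter(pred); per_g <- face_perimeter(gold)
  area_p <- tabulate(pred[pred > 0L], nbins = max(pred))
  area_g <- tabulate(gold[gold > 0L], nbins = max(gold))
  q <- vapply(seq_len(nrow(matches$pairs)), function(i) {
    p <- matches$pairs$pred[i]; g <- matches$pairs$gold[i]
    (per_p[p] / area_p[p]) / (per_g[g] / area_g[g])
  }, numeric(1))
  list(per_object = data.frame(pred = matches$pairs$pred,
                               gold = matches$pairs$gold, quotient = q),
       mean = mean(q))
}
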