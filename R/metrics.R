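#' Pairwise object overlaps between two label maps
#'
#' For every reference object r_i, lists the target objects sharing at least
#' one pixel with it, with intersection pixel counts and both object sizes.
#'
#' @param reference,target [label_map]s (or integer matrices) of one shape.
#' @return A list with `pairs` (tibble: ref, tgt, intersection, ref_size,
#'   tgt_size, dice), `ref_sizes`, `tgt_sizes` (named integer vectors) and
#'   the label vectors `ref_labels`, `tgt_labels`.
#' @export
overlap_sets <- function(reference, target) {
  R <- label_matrix(reference); T_ <- label_matrix(target)
  if (!identical(dim(R), dim(T_))) stop("label maps differ in shape")
  ref_labels <- setdiff(sort(unique(as.vector(R))), 0L)
  tgt_labels <- setdiff(sort(unique(as.vector(T_))), 0L)
  ref_sizes <- tabulate(factor(R[R > 0], levels = ref_labels),
                        length(ref_labels))
  names(ref_sizes) <- ref_labels
  tgt_sizes <- tabulate(factor(T_[T_ > 0], levels = tgt_labels),
                        length(tgt_labels))
  names(tgt_sizes) <- tgt_labels
  both <- which(R > 0 & T_ > 0)
  if (length(both)) {
    key <- paste(R[both], T_[both])
    cnt <- table(key)
    parts <- do.call(rbind, strsplit(names(cnt), " ", fixed = TRUE))
    pairs <- tibble::tibble(ref = as.integer(parts[, 1]),
                            tgt = as.integer(parts[, 2]),
                            intersection = as.integer(cnt))
    pairs <- pairs[order(pairs$ref, pairs$tgt), ]
    pairs$ref_size <- ref_sizes[as.character(pairs$ref)]
    pairs$tgt_size <- tgt_sizes[as.character(pairs$tgt)]
    pairs$dice <- 2 * pairs$intersection / (pairs$ref_size + pairs$tgt_size)
  } else {
    pairs <- tibble::tibble(ref = integer(), tgt = integer(),
                            intersection = integer(), ref_size = integer(),
                            tgt_size = integer(), dice = numeric())
  }
  list(pairs = pairs, ref_sizes = ref_sizes, tgt_sizes = tgt_sizes,
       ref_labels = ref_labels, tgt_labels = tgt_labels)
}

#' One-to-one object matches by mutual best overlap
#'
#' A reference object and a target object are matched when each is the
#' other's largest-intersection partner (mutual best overlap); the result
#' is one-to-one by construction. Intersection ties are broken toward the
#' smaller partner label id.
#'
#' @param overlaps result of [overlap_sets()].
#' @return A tibble with columns `ref`, `tgt` (one row per matched pair).
#' @export
one_to_one_matches <- function(overlaps) {
  p <- overlaps$pairs
  if (nrow(p) == 0) return(tibble::tibble(ref = integer(), tgt = integer()))
  # rows sorted by (ref, tgt): the first maximum is the smallest partner id
  best_t_for_r <- vapply(split(seq_len(nrow(p)), p$ref), function(i)
    p$tgt[i[which.max(p$intersection[i])]], integer(1))
  best_r_for_t <- vapply(split(seq_len(nrow(p)), p$tgt), function(i)
    p$ref[i[which.max(p$intersection[i])]], integer(1))
  r <- as.integer(names(best_t_for_r))
  mutual <- best_r_for_t[as.character(best_t_for_r)] == r
  tibble::tibble(ref = r[mutual], tgt = unname(best_t_for_r[mutual]))
}

#' Object-level segmentation similarity (SM)
#'
#' Compares a target segmentation to a reference segmentation at the object
#' level:
#' \deqn{SM(R,T) = k \frac{1}{N}\sum_i \max_{t_j \in T^{r_i}}
#'   \frac{2|r_i \cap t_j|}{|r_i| + |t_j|} +
#'   (1-k) \frac{2|P^R_T|}{N+M}}
#' the weighted sum of (first term) the mean best Dice overlap of each of
#' the N reference objects with any overlapping target object, and (second
#' term) the fraction of objects in a one-to-one (mutual best overlap)
#' matching P among all N + M objects. A reference object overlapping
#' nothing contributes 0 to the first term.
#'
#' @param reference,target [label_map]s (or integer matrices) of one shape;
#'   the reference must contain at least one object. An empty target yields
#'   SM = 0 with a warning.
#' @param k weighting factor in \[0, 1\] (default 0.6).
#' @return An object of class `sm_report`: fields `sm`, `term1`, `term2`,
#'   `k`, `n_ref` (N), `n_target` (M), `matched` (pair tibble),
#'   `per_reference` (tibble of per-reference best matches and Dice).
#' @examples
#' m <- matrix(0L, 8, 8); m[2:4, 2:4] <- 1L; m[6:8, 5:7] <- 2L
#' sm_score(m, m)$sm  # identical maps score 1
#' @export
sm_score <- function(reference, target, k = 0.6) {
  if (k < 0 || k > 1) stop("`k` must lie in [0, 1]")
  ov <- overlap_sets(reference, target)
  N <- length(ov$ref_labels); M <- length(ov$tgt_labels)
  if (N == 0) stop("reference has no objects")
  per_ref <- tibble::tibble(ref = ov$ref_labels, best_tgt = NA_integer_,
                            best_dice = 0)
  if (nrow(ov$pairs)) {
    by_ref <- split(seq_len(nrow(ov$pairs)), ov$pairs$ref)
    hit <- match(as.integer(names(by_ref)), per_ref$ref)
    picks <- vapply(by_ref, function(i) i[which.max(ov$pairs$dice[i])],
                    integer(1))
    per_ref$best_tgt[hit] <- ov$pairs$tgt[picks]
    per_ref$best_dice[hit] <- ov$pairs$dice[picks]
  }
  matched <- one_to_one_matches(ov)
  term1 <- mean(per_ref$best_dice)
  term2 <- 2 * nrow(matched) / (N + M)
  if (M == 0) {
    warning("target has no objects; SM = 0")
    term1 <- 0; term2 <- 0
  }
  structure(list(sm = k * term1 + (1 - k) * term2, term1 = term1,
                 term2 = term2, k = k, n_ref = N, n_target = M,
                 n_matched = nrow(matched), matched = matched,
                 per_reference = per_ref),
            class = "sm_report")
}

#' @export
print.sm_report <- function(x, ...) {
  cat(sprintf(paste0("<sm_report> SM = %.4f (k = %.2f)\n",
                     "  mean best Dice over %d reference object(s): %.4f\n",
                     "  one-to-one matches: %d of (N + M) = %d -> %.4f\n"),
              x$sm, x$k, x$n_ref, x$term1, x$n_matched,
              x$n_ref + x$n_target, x$term2))
  invisible(x)
}

#' Per-object segmentation quality scores
#'
#' The best Dice overlap of each reference object with any overlapping
#' target object — the per-cell quality values whose histogram and
#' image-level mean summarize segmentation quality.
#'
#' @inheritParams sm_score
#' @return A tibble with columns `ref`, `best_tgt`, `best_dice`.
#' @export
per_cell_scores <- function(reference, target) {
  sm_score(reference, target)$per_reference
}

#' Pixel-level ROC / AUC / accuracy of a probability map
#'
#' Thresholds the map at 101 levels spanning \[0, 1\] (rule: positive when
#' `prob >= t`), recording sensitivity and specificity at each level; the
#' AUC is the trapezoidal area under the resulting ROC curve and the
#' accuracy is the fraction of correctly classified pixels at threshold
#' 0.50. Object identity is ignored: the truth is a single binary mask.
#'
#' @param prob probability map (matrix in \[0, 1\]).
#' @param truth binary matrix of the same shape.
#' @return An object of class `class_eval`: `roc` (tibble of threshold,
#'   sensitivity, specificity), `auc`, `acc`. If the truth is all one
#'   class the AUC is NA (with a warning) and only the accuracy is
#'   meaningful.
#' @export
classification_eval <- function(prob, truth) {
  if (!identical(dim(prob), dim(truth))) stop("shapes differ")
  if (!all(truth %in% c(0, 1, FALSE, TRUE))) stop("`truth` must be binary")
  tr <- as.logical(truth)
  npos <- sum(tr); nneg <- sum(!tr)
  th <- seq(0, 1, by = 0.01)
  pv <- as.vector(prob)
  sens <- vapply(th, function(t) if (npos) sum(pv >= t & tr) / npos else NA_real_,
                 numeric(1))
  spec <- vapply(th, function(t) if (nneg) sum(pv < t & !tr) / nneg else NA_real_,
                 numeric(1))
  acc <- sum((pv >= 0.5) == tr) / length(pv)
  if (npos == 0 || nneg == 0) {
    warning("truth contains a single class; AUC is undefined")
    auc <- NA_real_
  } else {
    fpr <- 1 - spec; tpr <- sens
    o <- order(fpr, tpr)
    fpr <- c(0, fpr[o], 1); tpr <- c(0, tpr[o], 1)
    auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  }
  structure(list(roc = tibble::tibble(threshold = th, sensitivity = sens,
                                      specificity = spec),
                 auc = auc, acc = acc),
            class = "class_eval")
}

#' @export
print.class_eval <- function(x, ...) {
  cat(sprintf("<class_eval> AUC = %s, ACC@0.50 = %.4f\n",
              ifelse(is.na(x$auc), "NA", sprintf("%.4f", x$auc)), x$acc))
  invisible(x)
}

#' Tidiers for evaluation objects
#'
#' `tidy()` returns the per-object (or per-threshold) table; `glance()`
#' returns a one-row summary.
#'
#' @param x an `sm_report` or `class_eval`.
#' @param ... unused.
#' @return A tibble.
#' @exportS3Method generics::tidy sm_report
#' @name tidiers
tidy.sm_report <- function(x, ...) x$per_reference

#' @exportS3Method generics::glance sm_report
#' @rdname tidiers
glance.sm_report <- function(x, ...) {
  tibble::tibble(sm = x$sm, term1 = x$term1, term2 = x$term2, k = x$k,
                 n_ref = x$n_ref, n_target = x$n_target,
                 n_matched = x$n_matched)
}

#' @exportS3Method generics::tidy class_eval
#' @rdname tidiers
tidy.class_eval <- function(x, ...) x$roc

#' @exportS3Method generics::glance class_eval
#' @rdname tidiers
glance.class_eval <- function(x, ...) tibble::tibble(auc = x$auc, acc = x$acc)
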