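#' Per-position confusion counts between two structures
#'
#' Each position contributes exactly one count, so
#' `tp + tn + fp + fn == length`:
#' \itemize{
#'   \item `tp` — paired to the same partner in prediction and reference;
#'   \item `tn` — unpaired in both;
#'   \item `fn` — paired in the reference but unpaired in the prediction;
#'   \item `fp` — predicted paired while the reference is unpaired, or
#'     paired to the wrong partner.
#' }
#'
#' @param pred,ref [rna_structure()] objects of equal length.
#' @return object of class `pk_confusion` with fields `tp`, `tn`, `fp`,
#'   `fn`.
#' @export
confusion_counts <- function(pred, ref) {
  stopifnot(inherits(pred, "rna_structure"), inherits(ref, "rna_structure"))
  if (pred$length != ref$length)
    stop(sprintf("length mismatch: prediction %d vs reference %d",
                 pred$length, ref$length), call. = FALSE)
  pv <- partner_vector(pred); rv <- partner_vector(ref)
  tp <- sum(!is.na(pv) & !is.na(rv) & pv == rv)
  tn <- sum(is.na(pv) & is.na(rv))
  fn <- sum(is.na(pv) & !is.na(rv))
  fp <- pred$length - tp - tn - fn
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn), class = "pk_confusion")
}

#' @export
print.pk_confusion <- function(x, ...) {
  cat(sprintf("confusion counts: tp = %d, tn = %d, fp = %d, fn = %d (n = %d)\n",
              x$tp, x$tn, x$fp, x$fn, x$tp + x$tn + x$fp + x$fn))
  invisible(x)
}

#' Prediction metrics from confusion counts
#'
#' Computes PPV (precision) `tp / (tp + fp)`, recall `tp / (tp + fn)`,
#' their harmonic mean F1, and the Matthews correlation coefficient
#' `(tp * tn - fp * fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`. A zero
#' denominator makes the affected metric `NaN` with a warning, never a
#' silent 0.
#'
#' @param counts a `pk_confusion` object, or a list/vector with fields
#'   `tp`, `tn`, `fp`, `fn`.
#' @return object of class `pk_metrics` with fields `ppv`, `recall`, `f1`,
#'   `mcc`, kept at full precision (the print method rounds to 3
#'   decimals).
#' @examples
#' compute_metrics(list(tp = 4342, tn = 3975, fp = 1306, fn = 1053))
#' @export
compute_metrics <- function(counts) {
  c <- lapply(counts[c("tp", "tn", "fp", "fn")], as.numeric)
  stopifnot(!anyNA(unlist(c)), all(unlist(c) >= 0))
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined: zero denominator", what), call. = FALSE)
      return(NaN)
    }
    num / den
  }
  ppv <- safe_div(c$tp, c$tp + c$fp, "PPV")
  recall <- safe_div(c$tp, c$tp + c$fn, "recall")
  f1 <- if (is.nan(ppv) || is.nan(recall)) {
    warning("F1 undefined: PPV or recall undefined", call. = FALSE)
    NaN
  } else safe_div(2 * ppv * recall, ppv + recall, "F1")
  den2 <- (c$tp + c$fp) * (c$tp + c$fn) * (c$tn + c$fp) * (c$tn + c$fn)
  mcc <- if (den2 == 0) {
    warning("MCC undefined: zero denominator", call. = FALSE)
    NaN
  } else (c$tp * c$tn - c$fp * c$fn) / sqrt(den2)
  structure(list(ppv = ppv, recall = recall, f1 = f1, mcc = mcc),
            class = "pk_metrics")
}

#' @export
print.pk_metrics <- function(x, digits = 3, ...) {
  cat(sprintf("PPV = %s, recall = %s, F1 = %s, MCC = %s\n",
              format(round(x$ppv, digits), nsmall = digits),
              format(round(x$recall, digits), nsmall = digits),
              format(round(x$f1, digits), nsmall = digits),
              format(round(x$mcc, digits), nsmall = digits)))
  invisible(x)
}

#' Slip-tolerant core-stem matching
#'
#' Counts how many of the reference pseudoknot's two core pairs are
#' matched by a predicted core pair, where a pair `(k, l)` is treated as
#' equivalent to `(k ± slip, l)` or `(k, l ± slip)` — one coordinate may
#' slip, not both. Each predicted pair may satisfy at most one reference
#' pair; the maximum matching over the 2 x 2 assignment is returned.
#'
#' @param pred predicted core pairs: a `pk_prediction`,
#'   `structure_candidate`, [rna_structure()] (reduced via
#'   [core_pairs()]), or a 2-column matrix / list of `c(p, q)` pairs.
#' @param ref_core reference core pairs in any of the same forms.
#' @param slip maximum one-coordinate slip (default 1).
#' @return integer in 0, 1, 2.
#' @examples
#' core_stem_matches(list(c(5, 12), c(10, 17)), list(c(5, 11), c(10, 17)))
#' @export
core_stem_matches <- function(pred, ref_core, slip = 1L) {
  pm <- as_core_matrix(pred)
  rm <- as_core_matrix(ref_core)
  ok <- function(a, b) {
    if (anyNA(a) || anyNA(b)) return(FALSE)
    dk <- abs(a[1L] - b[1L]); dl <- abs(a[2L] - b[2L])
    (dk == 0L && dl <= slip) || (dl == 0L && dk <= slip)
  }
  m <- matrix(FALSE, nrow(pm), nrow(rm))
  for (a in seq_len(nrow(pm))) for (b in seq_len(nrow(rm)))
    m[a, b] <- ok(pm[a, ], rm[b, ])
  # max bipartite matching on a (at most) 2 x 2 grid
  if (nrow(m) >= 2L && ncol(m) >= 2L &&
      ((m[1L, 1L] && m[2L, 2L]) || (m[1L, 2L] && m[2L, 1L]))) return(2L)
  if (any(m)) 1L else 0L
}

as_core_matrix <- function(x) {
  if (inherits(x, c("pk_prediction", "structure_candidate", "rna_structure")))
    return(core_pairs(x))
  if (is.list(x) && !is.data.frame(x)) x <- do.call(rbind, x)
  x <- as.matrix(x)
  stopifnot(ncol(x) == 2L, nrow(x) >= 1L, nrow(x) <= 2L)
  x
}

#' Evaluate predicted structures against references
#'
#' Per-sequence confusion counts and metrics plus an aggregated row
#' (counts summed, metrics recomputed from the summed counts), as used
#' for whole-dataset reporting.
#'
#' @param pred,ref lists of [rna_structure()] objects (or single
#'   structures), matched by position.
#' @param ids optional sequence identifiers.
#' @return data frame with columns `id`, `tp`, `tn`, `fp`, `fn`, `ppv`,
#'   `recall`, `f1`, `mcc`; the last row (`id == "TOTAL"`) aggregates.
#' @export
evaluate_structures <- function(pred, ref, ids = NULL) {
  if (inherits(pred, "rna_structure")) pred <- list(pred)
  if (inherits(ref, "rna_structure")) ref <- list(ref)
  if (length(pred) != length(ref))
    stop(sprintf("record count mismatch: %d predictions vs %d references",
                 length(pred), length(ref)), call. = FALSE)
  if (is.null(ids)) ids <- paste0("seq", seq_along(pred))
  one <- function(i) {
    cc <- tryCatch(confusion_counts(pred[[i]], ref[[i]]), error = function(e)
      stop(sprintf("record '%s': %s", ids[i], conditionMessage(e)), call. = FALSE))
    mm <- suppressWarnings(compute_metrics(cc))
    data.frame(id = ids[i], tp = cc$tp, tn = cc$tn, fp = cc$fp, fn = cc$fn,
               ppv = mm$ppv, recall = mm$recall, f1 = mm$f1, mcc = mm$mcc)
  }
  d <- do.call(rbind, lapply(seq_along(pred), one))
  tot <- list(tp = sum(d$tp), tn = sum(d$tn), fp = sum(d$fp), fn = sum(d$fn))
  mm <- suppressWarnings(compute_metrics(tot))
  rbind(d, data.frame(id = "TOTAL", tp = tot$tp, tn = tot$tn, fp = tot$fp,
                      fn = tot$fn, ppv = mm$ppv, recall = mm$recall,
                      f1 = mm$f1, mcc = mm$mcc))
}
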