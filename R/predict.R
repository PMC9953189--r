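#' Predict an H-type pseudoknot in an RNA sequence
#'
#' End-to-end pipeline: enumerate all candidate core-stem quadruples,
#' extend each contiguously, keep the quadruples achieving the maximal
#' stem pairing, enumerate their bulge/internal-loop gap continuations,
#' and select the final structure by minimum energy among the
#' maximally-paired candidates (see [select_optimal()]). Gap-mediated
#' pairs never enter the first-stage pairing count, so restricting the
#' gap search to the top-ranked quadruples is exact.
#'
#' If no candidate quadruple exists the sequence is reported all-unpaired
#' with a warning rather than as an error.
#'
#' @param seq RNA sequence (raw string; normalized with [normalize_rna()]).
#' @param maximum_bulge_size maximum bulge/internal-loop gap length
#'   (default 3).
#' @param allow_gu admit G-U wobble pairs (default `FALSE`).
#' @param beta1,beta2,beta3 pseudoknot penalty parameters in kcal/mol
#'   (defaults 9.6, 0.1, 0.1); see [energy_params()].
#' @param use_stacking add nearest-neighbor stacking terms to the
#'   selection energy (default `FALSE`: penalty-only ranking).
#' @param min_left_loop,min_right_loop minimum loop sizes (default 1).
#' @param trace print a per-stage decoration trace (dot-bracket after the
#'   core stems and after each contiguous extension step) for the selected
#'   quadruple.
#' @return object of class `pk_prediction`: list with `seq`, `id`,
#'   `structure` ([rna_structure()]), `dotbracket`, `quad` (selected
#'   core-stem quadruple or `NULL`), `candidate` (the winning
#'   `structure_candidate` or `NULL`), `no_pseudoknot` flag, and counters
#'   `n_quads` / `n_candidates`.
#' @examples
#' p <- predict_pseudoknot("ACAUCCGCCUGAUUUGAGCACA")
#' p$dotbracket
#' @export
predict_pseudoknot <- function(seq, maximum_bulge_size = 3L, allow_gu = FALSE,
                               beta1 = 9.6, beta2 = 0.1, beta3 = 0.1,
                               use_stacking = FALSE,
                               min_left_loop = 1L, min_right_loop = 1L,
                               trace = FALSE) {
  id <- if (!is.null(names(seq))) names(seq)[1L] else "<sequence>"
  seq <- normalize_rna(unname(seq)[1L], id)
  rules <- pair_rules(allow_gu)
  eparams <- energy_params(beta1, beta2, beta3, use_stacking = use_stacking)
  dparams <- decoration_params(maximum_bulge_size, rules)
  quads <- enumerate_core_stems(seq, rules, min_left_loop, min_right_loop)
  if (nrow(quads) == 0L) {
    warning(sprintf("sequence '%s': no pseudoknot candidate; reporting all unpaired", id),
            call. = FALSE)
    s <- rna_structure(nchar(seq))
    return(new_pk_prediction(seq, id, s, NULL, NULL, nrow(quads), 0L))
  }
  # stage 1 on contiguous decorations only (gap pairs never change the rank)
  counts <- integer(nrow(quads))
  exts <- vector("list", nrow(quads))
  for (r in seq_len(nrow(quads))) {
    dc <- extend_stems(seq, unlist(quads[r, ]), rules)
    exts[[r]] <- dc
    counts[r] <- nrow(dc$left_stem) + nrow(dc$right_stem)
  }
  top <- which(counts == max(counts))
  candidates <- unlist(lapply(top, function(r)
    decorate(seq, unlist(quads[r, ]), dparams, eparams)), recursive = FALSE)
  best <- select_optimal(candidates)
  if (trace) {
    sel <- top[vapply(top, function(r) all(exts[[r]]$quad == best$quad),
                      logical(1L))][1L]
    print_decoration_trace(seq, exts[[sel]], best)
  }
  new_pk_prediction(seq, id, best$structure, best$quad, best,
                    nrow(quads), length(candidates))
}

new_pk_prediction <- function(seq, id, structure, quad, candidate,
                              n_quads, n_candidates) {
  structure(list(seq = seq, id = id, structure = structure,
                 dotbracket = write_structure(structure), quad = quad,
                 candidate = candidate,
                 no_pseudoknot = is.null(quad),
                 n_quads = n_quads, n_candidates = n_candidates),
            class = "pk_prediction")
}

# Table-style trace: one dot-bracket row per decoration stage.
print_decoration_trace <- function(seq, dc, best) {
  n <- nchar(seq)
  row <- function(label, p, q, layer, gap = rep(FALSE, length(p))) {
    cat(sprintf("%-12s %s\n", label,
                write_structure(rna_structure(n, p, q, layer, gap))))
  }
  cat(sprintf("%-12s %s\n", "sequence", seq))
  q <- dc$quad
  row("core stems", c(q[["i"]], q[["j"]]), c(q[["k"]], q[["l"]]),
      c("square", "round"))
  p_acc <- c(q[["i"]], q[["j"]]); q_acc <- c(q[["k"]], q[["l"]])
  ly_acc <- c("square", "round")
  stage <- 1L
  for (m in list(dc$right_stem, dc$left_stem)) {
    ly <- if (identical(m, dc$right_stem)) "round" else "square"
    if (nrow(m) > 1L) for (r in 2:nrow(m)) {
      p_acc <- c(p_acc, m[r, "p"]); q_acc <- c(q_acc, m[r, "q"])
      ly_acc <- c(ly_acc, ly)
      row(sprintf("stage %d", stage), p_acc, q_acc, ly_acc)
      stage <- stage + 1L
    }
  }
  cat(sprintf("%-12s %s\n", "selected", write_structure(best$structure)))
}

#' @export
print.pk_prediction <- function(x, ...) {
  cat(sprintf("H-type pseudoknot prediction for '%s' (%d nt)\n", x$id,
              nchar(x$seq)))
  cat(x$seq, "\n")
  cat(x$dotbracket, "\n")
  if (x$no_pseudoknot) {
    cat("no pseudoknot candidate found\n")
  } else {
    cat(sprintf("core-stem quadruple (i, j, k, l) = (%s); %d candidate quadruples, %d decorated candidates\n",
                paste(x$quad, collapse = ", "), x$n_quads, x$n_candidates))
    cat(sprintf("stem pairs %d, gap-mediated pairs %d, total energy %.2f kcal/mol\n",
                x$candidate$nongap_pair_count,
                sum(x$structure$pairs$gap), x$candidate$total_energy))
  }
  invisible(x)
}

#' @export
summary.pk_prediction <- function(object, ...) {
  print(object)
  if (!object$no_pseudoknot) {
    lr <- loop_regions(object$quad)
    cat(sprintf("left loop %d..%d, right loop %d..%d; Bp = %d, Up = %d\n",
                lr$left[1L], lr$left[2L], lr$right[1L], lr$right[2L],
                object$candidate$Bp, object$candidate$Up))
    cp <- core_pairs(object)
    cat(sprintf("outermost stem pairs: square (%d, %d), round (%d, %d)\n",
                cp[1L, 1L], cp[1L, 2L], cp[2L, 1L], cp[2L, 2L]))
  }
  invisible(object)
}

#' Arc-diagram plot of a predicted or reference structure
#'
#' Draws the sequence on a line with one arc per base pair; square-layer
#' pairs above in one colour, round-layer pairs in another, gap-mediated
#' pairs dashed.
#'
#' @param x a `pk_prediction` or [rna_structure()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.pk_prediction <- function(x, ...) plot(x$structure, main = x$id, ...)

#' @export
plot.rna_structure <- function(x, main = "", ...) {
  n <- x$length
  graphics::plot(NULL, xlim = c(0.5, n + 0.5), ylim = c(-0.5, n / 2 + 1),
                 xlab = "position", ylab = "", yaxt = "n", bty = "n",
                 main = main, ...)
  graphics::segments(1, 0, n, 0)
  graphics::points(seq_len(n), rep(0, n), pch = 16, cex = 0.5)
  if (nrow(x$pairs)) {
    cols <- ifelse(x$pairs$layer == "square", "#1b6ca8", "#c0392b")
    for (r in seq_len(nrow(x$pairs))) {
      p <- x$pairs$p[r]; q <- x$pairs$q[r]
      t <- seq(0, pi, length.out = 50)
      graphics::lines((p + q) / 2 + (q - p) / 2 * cos(t), (q - p) / 2 * sin(t),
                      col = cols[r], lty = if (x$pairs$gap[r]) 2 else 1)
    }
  }
  invisible(x)
}

#' Structure-level core stems of a prediction
#'
#' Summarizes each predicted crossing helix by its outermost non-gap pair
#' (smallest `p`, largest `q` per bracket layer). This is the
#' representation used for slip-tolerant core-stem matching against a
#' reference, where single-base differences in helix extent are absorbed
#' by the slip rule.
#'
#' @param x a `pk_prediction`, `structure_candidate`, or [rna_structure()].
#' @return 2 x 2 integer matrix, rows = (square stem, round stem),
#'   columns = (p, q); rows of `NA` for absent layers.
#' @export
core_pairs <- function(x) {
  s <- if (inherits(x, "rna_structure")) x
       else if (inherits(x, "pk_prediction")) x$structure
       else if (inherits(x, "structure_candidate")) x$structure
       else stop("cannot extract core pairs from this object", call. = FALSE)
  out <- matrix(NA_integer_, 2L, 2L,
                dimnames = list(c("square", "round"), c("p", "q")))
  for (ly in c("square", "round")) {
    pr <- s$pairs[s$pairs$layer == ly & !s$pairs$gap, , drop = FALSE]
    if (nrow(pr)) out[ly, ] <- c(min(pr$p), max(pr$q))
  }
  out
}
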