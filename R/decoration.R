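#' Decoration parameters
#'
#' @param maximum_bulge_size maximum gap length tried on each side of a
#'   gap-mediated extension (`B`); `0` disables bulges and internal loops.
#'   Default 3.
#' @param rules a [pair_rules()] object.
#' @return object of class `decoration_params`.
#' @export
decoration_params <- function(maximum_bulge_size = 3L, rules = pair_rules()) {
  maximum_bulge_size <- as.integer(maximum_bulge_size)
  stopifnot(maximum_bulge_size >= 0L, inherits(rules, "pair_rules"))
  structure(list(maximum_bulge_size = maximum_bulge_size, rules = rules),
            class = "decoration_params")
}

#' Extend core stems with contiguous stacked pairs
#'
#' Starting from the two crossing core pairs, each stem is grown outward to
#' maximality: the right (round-layer) stem adds `(j - t, l + t)` for
#' t = 1, 2, ... drawing on left-loop and 3'-tail bases, and the left
#' (square-layer) stem adds `(i - t, k + t)` drawing on 5'-head and
#' right-loop bases, while the positions are free, in range, and
#' complementary. The two stems consume disjoint position sets, so the
#' result does not depend on extension order.
#'
#' @param seq RNA sequence string.
#' @param quad core-stem quadruple `c(i, j, k, l)`.
#' @param rules a [pair_rules()] object.
#' @return object of class `decorated_candidate`: list with the `quad`, and
#'   `left_stem` / `right_stem` integer matrices (columns `p`, `q`; first
#'   row is the core pair, then outward extensions in order).
#' @examples
#' extend_stems("ACAUCCGCCUGAUUUGAGCACA", c(5, 10, 11, 17))
#' @export
extend_stems <- function(seq, quad, rules = pair_rules()) {
  quad <- as_quad(quad)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(bases)
  if (quad[["l"]] > n) stop("quadruple exceeds sequence length", call. = FALSE)
  if (!is_complementary(bases[quad[["i"]]], bases[quad[["k"]]], rules) ||
      !is_complementary(bases[quad[["j"]]], bases[quad[["l"]]], rules))
    stop("core pairs are not complementary under the active rules", call. = FALSE)
  used <- rep(FALSE, n)
  used[quad] <- TRUE
  grow <- function(p0, q0, pmin_ok, qmax_ok) {
    ps <- p0; qs <- q0
    p <- p0 - 1L; q <- q0 + 1L
    while (p >= pmin_ok && q <= qmax_ok && !used[p] && !used[q] &&
           is_complementary(bases[p], bases[q], rules)) {
      used[p] <<- TRUE; used[q] <<- TRUE
      ps <- c(ps, p); qs <- c(qs, q)
      p <- p - 1L; q <- q + 1L
    }
    cbind(p = ps, q = qs)
  }
  # right stem first (order is immaterial; sets are disjoint)
  right <- grow(quad[["j"]], quad[["l"]], 1L, n)
  left  <- grow(quad[["i"]], quad[["k"]], 1L, n)
  structure(list(quad = quad, left_stem = left, right_stem = right,
                 seq = seq, rules = rules),
            class = "decorated_candidate")
}

#' @export
print.decorated_candidate <- function(x, ...) {
  cat(sprintf("decorated candidate: quad (%d, %d, %d, %d), %d + %d contiguous pairs\n",
              x$quad[1L], x$quad[2L], x$quad[3L], x$quad[4L],
              nrow(x$left_stem), nrow(x$right_stem)))
  invisible(x)
}

# Free-position run downward from p (inclusive), bounded below by bound_lo.
free_run_down <- function(used, p, bound_lo) {
  lo <- p
  while (lo >= bound_lo && !used[lo]) lo <- lo - 1L
  if (lo + 1L > p) integer() else (lo + 1L):p
}

free_run_up <- function(used, q, bound_hi) {
  hi <- q
  while (hi <= bound_hi && !used[hi]) hi <- hi + 1L
  if (hi - 1L < q) integer() else q:(hi - 1L)
}

#' Enumerate gap-mediated stem continuations (bulges and internal loops)
#'
#' After contiguous extension stalls, each stem may continue across one gap
#' event. For the stem's outermost pair `(p0, q0)` every gap combination
#' `(b_inner, b_outer)` in `[0, B]^2` except `(0, 0)` is tried: the pair
#' `(p0 - 1 - b_inner, q0 + 1 + b_outer)` is formed if both positions are
#' free, inside their respective unpaired runs, and complementary, after
#' which stacking continues contiguously to maximality. A gap on one side
#' only is a bulge; gaps on both sides form an internal loop.
#'
#' Sides follow the pair-of-sets terminology: `"left_pair_of_sets"`
#' continues the right (round) stem across remaining left-loop bases
#' (inner) and 3'-tail bases (outer); `"right_pair_of_sets"` continues the
#' left (square) stem across 5'-head bases (inner) and remaining
#' right-loop bases (outer).
#'
#' @param dc a [extend_stems()] result.
#' @param side `"left_pair_of_sets"` or `"right_pair_of_sets"`.
#' @param params a [decoration_params()] object.
#' @return list of gap choices, each a list with `b_inner`, `b_outer`, and
#'   `pairs` (integer matrix of the gap-mediated pairs, outermost last).
#'   Distinct gap combinations yielding identical pair sets are
#'   deduplicated. Empty list if no continuation exists.
#' @export
enumerate_gap_extensions <- function(dc, side = c("left_pair_of_sets",
                                                  "right_pair_of_sets"),
                                     params = decoration_params()) {
  stopifnot(inherits(dc, "decorated_candidate"), inherits(params, "decoration_params"))
  side <- match.arg(side)
  B <- params$maximum_bulge_size
  if (B == 0L) return(list())
  bases <- strsplit(dc$seq, "", fixed = TRUE)[[1]]
  n <- length(bases)
  used <- rep(FALSE, n)
  used[c(dc$left_stem, dc$right_stem)] <- TRUE
  stem <- if (side == "left_pair_of_sets") dc$right_stem else dc$left_stem
  p0 <- stem[nrow(stem), "p"]; q0 <- stem[nrow(stem), "q"]
  inner_set <- free_run_down(used, p0 - 1L, 1L)
  outer_set <- free_run_up(used, q0 + 1L, n)
  if (!length(inner_set) || !length(outer_set)) return(list())
  choices <- list(); seen <- character()
  for (bi in 0:B) for (bo in 0:B) {
    if (bi == 0L && bo == 0L) next
    p <- p0 - 1L - bi; q <- q0 + 1L + bo
    if (!(p %in% inner_set) || !(q %in% outer_set)) next
    if (!is_complementary(bases[p], bases[q], params$rules)) next
    ps <- p; qs <- q
    pp <- p - 1L; qq <- q + 1L
    while (pp %in% inner_set && qq %in% outer_set &&
           is_complementary(bases[pp], bases[qq], params$rules)) {
      ps <- c(ps, pp); qs <- c(qs, qq)
      pp <- pp - 1L; qq <- qq + 1L
    }
    key <- paste(ps, qs, collapse = ";")
    if (key %in% seen) next
    seen <- c(seen, key)
    choices[[length(choices) + 1L]] <-
      list(b_inner = bi, b_outer = bo, pairs = cbind(p = ps, q = qs))
  }
  choices
}

#' Decorate a core-stem quadruple into full structure candidates
#'
#' Runs contiguous extension, enumerates gap-mediated continuations on both
#' pairs of sets, and emits one structure candidate per element of the
#' Cartesian product (no-gap option included on each side). Gap-mediated
#' pairs carry gap flags and are excluded from the first-stage pairing
#' count used for candidate ranking.
#'
#' @param seq RNA sequence string.
#' @param quad core-stem quadruple `c(i, j, k, l)`.
#' @param params a [decoration_params()] object.
#' @param energy a [energy_params()] object used to score each candidate.
#' @return list of `structure_candidate` objects (see [total_energy()]).
#' @export
decorate <- function(seq, quad, params = decoration_params(),
                     energy = energy_params()) {
  dc <- extend_stems(seq, quad, params$rules)
  left_choices <- c(list(NULL),
                    enumerate_gap_extensions(dc, "left_pair_of_sets", params))
  right_choices <- c(list(NULL),
                     enumerate_gap_extensions(dc, "right_pair_of_sets", params))
  out <- vector("list", length(left_choices) * length(right_choices))
  idx <- 1L
  for (lc in left_choices) for (rc in right_choices) {
    # left/right pair of sets extend the round/square stems respectively
    round_p <- dc$right_stem[, "p"]; round_q <- dc$right_stem[, "q"]
    square_p <- dc$left_stem[, "p"]; square_q <- dc$left_stem[, "q"]
    gap_round <- rep(FALSE, length(round_p))
    gap_square <- rep(FALSE, length(square_p))
    if (!is.null(lc)) {
      round_p <- c(round_p, lc$pairs[, "p"]); round_q <- c(round_q, lc$pairs[, "q"])
      gap_round <- c(gap_round, rep(TRUE, nrow(lc$pairs)))
    }
    if (!is.null(rc)) {
      square_p <- c(square_p, rc$pairs[, "p"]); square_q <- c(square_q, rc$pairs[, "q"])
      gap_square <- c(gap_square, rep(TRUE, nrow(rc$pairs)))
    }
    out[[idx]] <- structure_candidate(
      seq = seq, quad = dc$quad,
      p = c(square_p, round_p), q = c(square_q, round_q),
      layer = c(rep("square", length(square_p)), rep("round", length(round_p))),
      gap = c(gap_square, gap_round),
      params = energy)
    idx <- idx + 1L
  }
  out
}
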