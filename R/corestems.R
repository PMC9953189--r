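#' Base-pairing rules
#'
#' A–U and C–G (Watson–Crick) pairs are always admissible; the G–U wobble
#' pair is admitted only when `allow_gu = TRUE` (opt-in, mirroring the
#' command-line switch).
#'
#' @param allow_gu logical, admit the G–U wobble pair.
#' @return object of class `pair_rules`.
#' @export
pair_rules <- function(allow_gu = FALSE) {
  stopifnot(is.logical(allow_gu), length(allow_gu) == 1L, !is.na(allow_gu))
  structure(list(allow_gu = allow_gu), class = "pair_rules")
}

#' Test base complementarity
#'
#' Symmetric in its arguments; vectorized over `a` and `b`.
#'
#' @param a,b character vectors of bases in `A`, `C`, `G`, `U`.
#' @param rules a [pair_rules()] object.
#' @return logical vector.
#' @examples
#' is_complementary("A", "U")                       # TRUE
#' is_complementary("G", "U")                       # FALSE
#' is_complementary("G", "U", pair_rules(TRUE))     # TRUE (wobble)
#' @export
is_complementary <- function(a, b, rules = pair_rules()) {
  stopifnot(inherits(rules, "pair_rules"))
  key <- paste0(pmin(a, b), pmax(a, b))
  out <- key %in% c("AU", "CG")
  if (rules$allow_gu) out <- out | key == "GU"
  out
}

# n x n logical complementarity matrix for a split sequence
comp_matrix <- function(bases, rules) {
  n <- length(bases)
  m <- outer(bases, bases, function(x, y) is_complementary(x, y, rules))
  dim(m) <- c(n, n)
  m
}

#' Enumerate candidate core-stem quadruples
#'
#' A core-stem quadruple `(i, j, k, l)` holds the two crossing base pairs
#' that establish an H-type pseudoknot: the left core pair `(i, k)` and the
#' right core pair `(j, l)` with `i < j < k < l`. This returns exactly the
#' set of quadruples whose two pairs are complementary under `rules` and
#' whose loops meet the minimum sizes (left loop `j - i - 1`, right loop
#' `l - k - 1`). This candidate set is what a parse forest of a pseudoknot
#' grammar over the sequence would contain; it is computed by direct
#' enumeration.
#'
#' @param seq RNA sequence string (normalized; see [normalize_rna()]).
#' @param rules a [pair_rules()] object.
#' @param min_left_loop,min_right_loop minimum loop sizes (default 1: both
#'   connecting loops must be nonempty).
#' @return data frame with integer columns `i`, `j`, `k`, `l`, sorted
#'   lexicographically; zero rows if no candidate exists.
#' @examples
#' enumerate_core_stems("ACGUACGU")
#' @export
enumerate_core_stems <- function(seq, rules = pair_rules(),
                                 min_left_loop = 1L, min_right_loop = 1L) {
  stopifnot(min_left_loop >= 0L, min_right_loop >= 0L)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(bases)
  empty <- data.frame(i = integer(), j = integer(), k = integer(), l = integer())
  if (n < 4L) return(empty)
  m <- comp_matrix(bases, rules)
  # all complementary ordered pairs (p, q), p < q
  idx <- which(m & upper.tri(m), arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  P <- idx[, 1L]; Q <- idx[, 2L]
  res <- vector("list", length(P))
  # left pair (i, k) = (P[a], Q[a]); right pairs (j, l) must satisfy
  # i + min_left_loop < j < k and l > k + min_right_loop
  for (a in seq_along(P)) {
    i <- P[a]; k <- Q[a]
    sel <- P > i + min_left_loop & P < k & Q > k + min_right_loop
    if (any(sel))
      res[[a]] <- cbind(i = i, j = P[sel], k = k, l = Q[sel])
  }
  res <- do.call(rbind, res)
  if (is.null(res)) return(empty)
  res <- as.data.frame(res)
  res[order(res$i, res$j, res$k, res$l), , drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}

#' Loop regions delimited by a core-stem quadruple
#'
#' The left loop connects the two 5' core bases (positions `i+1 .. j-1`);
#' the right loop connects the two 3' core bases (positions `k+1 .. l-1`).
#' Bounds are exclusive of the core bases themselves.
#'
#' @param quad numeric vector `c(i, j, k, l)` or a one-row data frame from
#'   [enumerate_core_stems()].
#' @return list with integer vectors `left = c(first, last)` and
#'   `right = c(first, last)`; a zero-length loop is reported as
#'   `c(first, last)` with `last < first`.
#' @examples
#' loop_regions(c(5, 10, 11, 17))  # left 6..9, right 12..16
#' @export
loop_regions <- function(quad) {
  quad <- as_quad(quad)
  list(left = c(quad[["i"]] + 1L, quad[["j"]] - 1L),
       right = c(quad[["k"]] + 1L, quad[["l"]] - 1L))
}

as_quad <- function(quad) {
  if (is.data.frame(quad)) quad <- unlist(quad[1L, c("i", "j", "k", "l")])
  quad <- as.integer(quad)
  stopifnot(length(quad) == 4L)
  names(quad) <- c("i", "j", "k", "l")
  if (!(quad[1L] < quad[2L] && quad[2L] < quad[3L] && quad[3L] < quad[4L]))
    stop("core-stem quadruple must satisfy i < j < k < l", call. = FALSE)
  quad
}

#' Write candidate quadruples as a debug TSV
#'
#' @param quads data frame from [enumerate_core_stems()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_quads_tsv <- function(quads, path) {
  utils::write.table(quads, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
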