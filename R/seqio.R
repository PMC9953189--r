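RNA_ALPHABET <- c("A", "C", "G", "U")

#' Normalize and validate an RNA sequence string
#'
#' Uppercases the input and maps T to U (DNA-style input is tolerated).
#' Any other character is an error: the prediction algorithm has no
#' ambiguity handling, so `N` and IUPAC codes are rejected.
#'
#' @param x character scalar, the raw sequence.
#' @param id identifier used in error messages.
#' @return the normalized sequence (uppercase, over A/C/G/U).
#' @examples
#' normalize_rna("acgt")  # "ACGU"
#' @export
normalize_rna <- function(x, id = "<sequence>") {
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  s <- chartr("t", "u", toupper(x))
  s <- chartr("T", "U", s)
  bad <- which(!strsplit(s, "", fixed = TRUE)[[1]] %in% RNA_ALPHABET)
  if (length(bad) > 0L) {
    ch <- substr(s, bad[1L], bad[1L])
    stop(sprintf("sequence '%s': illegal character '%s' at position %d",
                 id, ch, bad[1L]), call. = FALSE)
  }
  if (nchar(s) == 0L)
    stop(sprintf("sequence '%s' is empty", id), call. = FALSE)
  s
}

#' Read RNA sequences from FASTA or plain text
#'
#' Accepts multi-record FASTA (leading `>` on the first non-blank line) or
#' plain text with one raw sequence per line. Records are normalized with
#' [normalize_rna()] and returned in input order.
#'
#' @param path file path, or a character vector of lines (treated as the
#'   file content, useful for tests).
#' @return named character vector of normalized sequences; names are FASTA
#'   identifiers (first word of the header) or `seq1`, `seq2`, ... for
#'   plain-text input.
#' @export
read_rna_sequences <- function(path) {
  is_file <- length(path) == 1L && file.exists(path)
  lines <- if (is_file) readLines(path, warn = FALSE) else path
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no sequences found in input", call. = FALSE)
  if (startsWith(trimws(lines[1L]), ">")) {
    fa <- if (is_file) path else {
      tmp <- tempfile(fileext = ".fasta"); writeLines(path, tmp); tmp
    }
    set <- tryCatch(Biostrings::readBStringSet(fa, format = "fasta"),
                    error = function(e)
                      stop("malformed FASTA: ", conditionMessage(e), call. = FALSE))
    ss <- as.character(set)
    ids <- vapply(strsplit(names(set), "\\s+"),
                  function(w) if (length(w)) w[1L] else "", character(1L))
    if (any(!nzchar(ids)))
      stop("malformed FASTA header: empty identifier", call. = FALSE)
    if (any(!nzchar(ss)))
      stop("malformed FASTA: record with no sequence", call. = FALSE)
    names(ss) <- ids
  } else {
    if (any(startsWith(trimws(lines), ">")))
      stop("malformed input: FASTA header '>' after plain sequence lines", call. = FALSE)
    ss <- trimws(lines)
    names(ss) <- paste0("seq", seq_along(ss))
  }
  vapply(seq_along(ss), function(i) normalize_rna(ss[[i]], names(ss)[i]),
         character(1L), USE.NAMES = FALSE) |> stats::setNames(names(ss))
}

#' Two-layer RNA secondary structure
#'
#' Container for a (possibly pseudoknotted) secondary structure over two
#' bracket layers: `square` (`[ ]`, the 5'-opening core stem and its
#' extensions) and `round` (`( )`, the right core stem and its extensions).
#' Invariants checked on construction: positions in range, each position in
#' at most one pair, each layer internally nested (non-crossing), and if
#' both layers are occupied at least one square pair crosses a round pair.
#'
#' @param length sequence length (positive integer).
#' @param p,q integer vectors of 5' and 3' pair positions (1-based, p < q).
#' @param layer character vector, `"square"` or `"round"` per pair.
#' @param gap logical vector flagging gap-mediated pairs (formed after a
#'   bulge or internal loop); defaults to all `FALSE`.
#' @return an object of class `rna_structure`: a list with elements
#'   `length` and `pairs` (data frame with columns `p`, `q`, `layer`,
#'   `gap`, sorted by `p`).
#' @export
rna_structure <- function(length, p = integer(), q = integer(),
                          layer = character(), gap = logical(length(p))) {
  length <- as.integer(length)
  p <- as.integer(p); q <- as.integer(q)
  layer <- as.character(layer); gap <- as.logical(gap)
  stopifnot(length >= 1L, base::length(q) == base::length(p),
            base::length(layer) == base::length(p),
            base::length(gap) == base::length(p))
  if (any(!layer %in% c("square", "round")))
    stop("layer must be 'square' or 'round'", call. = FALSE)
  if (any(p < 1L) || any(q > length) || any(p >= q))
    stop("invalid pair: need 1 <= p < q <= length", call. = FALSE)
  pos <- c(p, q)
  if (anyDuplicated(pos))
    stop(sprintf("position %d occurs in more than one pair",
                 pos[anyDuplicated(pos)]), call. = FALSE)
  for (ly in c("square", "round")) {
    sel <- layer == ly
    if (crossing_exists(p[sel], q[sel]))
      stop(sprintf("pairs within the %s layer must be nested", ly), call. = FALSE)
  }
  sq <- layer == "square"
  if (any(sq) && any(!sq) && !layers_cross(p[sq], q[sq], p[!sq], q[!sq]))
    stop("both layers occupied but no square pair crosses a round pair",
         call. = FALSE)
  o <- order(p)
  structure(list(length = length,
                 pairs = data.frame(p = p[o], q = q[o], layer = layer[o],
                                    gap = gap[o])),
            class = "rna_structure")
}

# TRUE if any two pairs of the set cross (i < j < k < l for (i,k),(j,l))
crossing_exists <- function(p, q) {
  n <- length(p)
  if (n < 2L) return(FALSE)
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    i <- min(p[a], p[b]); k <- if (i == p[a]) q[a] else q[b]
    j <- max(p[a], p[b]); l <- if (j == p[a]) q[a] else q[b]
    if (i < j && j < k && k < l) return(TRUE)
  }
  FALSE
}

layers_cross <- function(p1, q1, p2, q2) {
  for (a in seq_along(p1)) for (b in seq_along(p2)) {
    if ((p1[a] < p2[b] && p2[b] < q1[a] && q1[a] < q2[b]) ||
        (p2[b] < p1[a] && p1[a] < q2[b] && q2[b] < q1[a])) return(TRUE)
  }
  FALSE
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(sprintf("rna_structure: length %d, %d pairs (%d square, %d round, %d gap-mediated)\n",
              x$length, nrow(x$pairs), sum(x$pairs$layer == "square"),
              sum(x$pairs$layer == "round"), sum(x$pairs$gap)))
  cat(write_structure(x), "\n")
  invisible(x)
}

#' Parse extended dot-bracket notation
#'
#' Reads a two-layer extended dot-bracket string: square brackets `[ ]`
#' form one nesting layer, round brackets `( )` the other; `.` is unpaired.
#' Each layer is matched independently by a stack.
#'
#' @param text dot-bracket string over `. ( ) [ ]`.
#' @param expected_length if given, the string length must equal it.
#' @return an [rna_structure()] (gap flags all `FALSE`; the notation does
#'   not record them).
#' @examples
#' parse_dotbracket("[.[[[.((((]]].].))).).")
#' @export
parse_dotbracket <- function(text, expected_length = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  n <- nchar(text)
  if (!is.null(expected_length) && n != expected_length)
    stop(sprintf("dot-bracket length %d does not match expected length %d",
                 n, expected_length), call. = FALSE)
  ch <- strsplit(text, "", fixed = TRUE)[[1]]
  bad <- which(!ch %in% c(".", "(", ")", "[", "]"))
  if (length(bad))
    stop(sprintf("illegal character '%s' at position %d in dot-bracket string",
                 ch[bad[1L]], bad[1L]), call. = FALSE)
  p <- integer(); q <- integer(); layer <- character()
  for (ly in list(c("[", "]", "square"), c("(", ")", "round"))) {
    stack <- integer()
    for (i in seq_len(n)) {
      if (ch[i] == ly[1L]) stack <- c(stack, i)
      else if (ch[i] == ly[2L]) {
        if (!length(stack))
          stop(sprintf("unbalanced '%s' at position %d", ly[2L], i), call. = FALSE)
        p <- c(p, stack[length(stack)]); q <- c(q, i); layer <- c(layer, ly[3L])
        stack <- stack[-length(stack)]
      }
    }
    if (length(stack))
      stop(sprintf("unbalanced '%s' at position %d", ly[1L], stack[1L]), call. = FALSE)
  }
  rna_structure(n, p, q, layer)
}

#' Write a structure as an extended dot-bracket string
#'
#' Inverse of [parse_dotbracket()]: square-layer pairs become `[ ]`,
#' round-layer pairs `( )`, unpaired positions `.`.
#'
#' @param s an [rna_structure()].
#' @param seq optional sequence whose length must match `s$length`.
#' @return single dot-bracket string.
#' @export
write_structure <- function(s, seq = NULL) {
  stopifnot(inherits(s, "rna_structure"))
  if (!is.null(seq) && nchar(seq) != s$length)
    stop("sequence length does not match structure length", call. = FALSE)
  out <- rep(".", s$length)
  sq <- s$pairs$layer == "square"
  out[s$pairs$p[sq]] <- "["; out[s$pairs$q[sq]] <- "]"
  out[s$pairs$p[!sq]] <- "("; out[s$pairs$q[!sq]] <- ")"
  paste0(out, collapse = "")
}

#' Partner vector of a structure
#'
#' @param s an [rna_structure()].
#' @return integer vector `v` of length `s$length`; `v[i]` is the partner
#'   of position `i`, or `NA` if unpaired.
#' @export
partner_vector <- function(s) {
  stopifnot(inherits(s, "rna_structure"))
  v <- rep(NA_integer_, s$length)
  v[s$pairs$p] <- s$pairs$q
  v[s$pairs$q] <- s$pairs$p
  v
}

#' Read dot-bracket structures, one per line
#'
#' Lines starting with `>` or containing only sequence letters are skipped,
#' so files interleaving FASTA-style headers, sequences and structures are
#' accepted.
#'
#' @param path file path or character vector of lines.
#' @return list of [rna_structure()] objects.
#' @export
read_dotbracket_file <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path, warn = FALSE) else path
  lines <- trimws(lines)
  keep <- nzchar(lines) & !startsWith(lines, ">") &
    grepl("^[][().]+$", lines)
  lapply(lines[keep], parse_dotbracket)
}
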