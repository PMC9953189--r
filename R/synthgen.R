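#' Specification of a planted H-type pseudoknot
#'
#' Describes the geometry of a synthetic benchmark instance:
#' `head | left stem 5' | left loop | right stem 5' | left stem 3' |
#' right loop | right stem 3' | tail`, with the left stem pairs in the
#' square layer and the right stem pairs in the round layer (the two
#' helices cross). Optionally one gap-mediated continuation (bulge or
#' internal loop) is planted beyond one stem.
#'
#' @param left_stem_len,right_stem_len helix lengths in base pairs (>= 2).
#' @param left_loop_len,right_loop_len connecting loop lengths (>= 1).
#' @param head_len,tail_len flanking unpaired region lengths (>= 0).
#' @param bulge optional list `list(side, inner_gap, outer_gap,
#'   pairs_after_gap)`; `side` is `"left"` (continue the round stem across
#'   left-loop and tail bases) or `"right"` (continue the square stem
#'   across head and right-loop bases). Gaps of 0/0 are not allowed and at
#'   least one pair must follow the gap.
#' @param seed integer RNG seed; identical specs give identical instances.
#' @return object of class `plant_spec`.
#' @export
plant_spec <- function(left_stem_len = 4L, right_stem_len = 4L,
                       left_loop_len = 4L, right_loop_len = 5L,
                       head_len = 2L, tail_len = 2L, bulge = NULL,
                       seed = 1L) {
  spec <- list(left_stem_len = as.integer(left_stem_len),
               right_stem_len = as.integer(right_stem_len),
               left_loop_len = as.integer(left_loop_len),
               right_loop_len = as.integer(right_loop_len),
               head_len = as.integer(head_len),
               tail_len = as.integer(tail_len),
               bulge = bulge, seed = as.integer(seed))
  stopifnot(spec$left_stem_len >= 2L, spec$right_stem_len >= 2L,
            spec$left_loop_len >= 1L, spec$right_loop_len >= 1L,
            spec$head_len >= 0L, spec$tail_len >= 0L)
  if (!is.null(bulge)) {
    stopifnot(is.list(bulge),
              all(c("side", "inner_gap", "outer_gap", "pairs_after_gap")
                  %in% names(bulge)))
    stopifnot(bulge$side %in% c("left", "right"),
              bulge$inner_gap >= 0L, bulge$outer_gap >= 0L,
              bulge$inner_gap + bulge$outer_gap >= 1L,
              bulge$pairs_after_gap >= 1L)
    need_in <- bulge$inner_gap + bulge$pairs_after_gap
    need_out <- bulge$outer_gap + bulge$pairs_after_gap
    if (bulge$side == "left") {
      if (need_in > spec$left_loop_len || need_out > spec$tail_len)
        stop("infeasible bulge: left loop or tail too short", call. = FALSE)
    } else {
      if (need_in > spec$head_len || need_out > spec$right_loop_len)
        stop("infeasible bulge: head or right loop too short", call. = FALSE)
    }
  }
  structure(spec, class = "plant_spec")
}

COMPLEMENT <- c(A = "U", U = "A", C = "G", G = "C")

#' Generate a sequence with a planted H-type pseudoknot
#'
#' Builds the ground-truth structure from a [plant_spec()], samples stem
#' bases uniformly, and fills unpaired regions by rejection so that the
#' planted helices dominate: fills creating a competing helix of 3 or more
#' consecutive complementary pairs between unpaired regions are rejected
#' (up to `max_attempts` resamples), and the bases immediately flanking
#' each helix are kept non-complementary so neither stem can extend past
#' its planted length. RNG state is restored on exit; identical seeds give
#' identical output.
#'
#' @param spec a [plant_spec()].
#' @param max_attempts resampling bound for the rejection filter.
#' @return list with `seq` (sequence string), `structure` (ground-truth
#'   [rna_structure()] including gap flags), `core` (2 x 2 matrix of the
#'   outermost pair of each planted helix, the convention of
#'   [core_pairs()]), `spec`, and `seed`.
#' @examples
#' inst <- generate_pseudoknot(plant_spec(seed = 42))
#' inst$seq
#' write_structure(inst$structure)
#' @export
generate_pseudoknot <- function(spec, max_attempts = 50L) {
  stopifnot(inherits(spec, "plant_spec"))
  a <- spec$left_stem_len; b <- spec$right_stem_len
  p <- spec$left_loop_len; q <- spec$right_loop_len
  h <- spec$head_len; t <- spec$tail_len
  n <- h + 2L * a + 2L * b + p + q + t
  # region index ranges
  head_r <- if (h) 1:h else integer()
  A_r <- (h + 1L):(h + a)
  lloop_r <- (h + a + 1L):(h + a + p)
  B_r <- (h + a + p + 1L):(h + a + p + b)
  A2_r <- (h + a + p + b + 1L):(h + 2L * a + p + b)
  rloop_r <- (h + 2L * a + p + b + 1L):(h + 2L * a + p + b + q)
  B2_r <- (h + 2L * a + p + b + q + 1L):(n - t)
  tail_r <- if (t) (n - t + 1L):n else integer()

  # planted pairs: A with A2 (square), B with B2 (round), outermost first
  sq_p <- A_r; sq_q <- rev(A2_r)
  rd_p <- B_r; rd_q <- rev(B2_r)
  gp_p <- integer(); gp_q <- integer(); gp_layer <- character()
  if (!is.null(spec$bulge)) {
    bg <- spec$bulge
    npg <- bg$pairs_after_gap
    if (bg$side == "left") {
      # round stem continues: outermost round pair is (B_r[1], B2_r[b])
      p0 <- B_r[1L]; q0 <- B2_r[b]
      gp_p <- (p0 - 1L - bg$inner_gap) - (seq_len(npg) - 1L)
      gp_q <- (q0 + 1L + bg$outer_gap) + (seq_len(npg) - 1L)
      gp_layer <- rep("round", npg)
    } else {
      # square stem continues: outermost square pair is (A_r[1], A2_r[a])
      q0 <- A2_r[a]
      gp_p <- (A_r[1L] - 1L - bg$inner_gap) - (seq_len(npg) - 1L)
      gp_q <- (q0 + 1L + bg$outer_gap) + (seq_len(npg) - 1L)
      gp_layer <- rep("square", npg)
    }
  }

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  paired_p <- c(sq_p, rd_p, gp_p); paired_q <- c(sq_q, rd_q, gp_q)
  free_pos <- setdiff(seq_len(n), c(paired_p, paired_q))
  # planted pair membership: partner[i] = planted partner or 0
  partner <- integer(n)
  partner[paired_p] <- paired_q; partner[paired_q] <- paired_p

  bases <- character(n)
  for (s in seq_along(paired_p)) {
    x <- sample(names(COMPLEMENT), 1L)
    bases[paired_p[s]] <- x
    bases[paired_q[s]] <- COMPLEMENT[[x]]
  }
  bases[free_pos] <- sample(names(COMPLEMENT), length(free_pos), replace = TRUE)

  wc <- function(x, y) COMPLEMENT[[x]] == y
  # Any antiparallel run of >= 3 consecutive Watson-Crick pairs that is not
  # a run of planted pairs could seed or join a competing helix; the same
  # holds for a single complementary pair flanking a planted helix (it
  # would extend the stem outward and shift its outermost pair). Both are
  # repaired by resampling an involved base (planted pairs are resampled
  # together so the ground truth never changes).
  find_bad_triple <- function() {
    for (x in seq_len(n - 2L)) for (y in seq(n, x + 5L)) {
      if (y > n || y - 2L <= x + 2L) next
      xs <- x + 0:2; ys <- y - 0:2
      if (all(vapply(1:3, function(a) wc(bases[xs[a]], bases[ys[a]]), logical(1L))) &&
          !all(partner[xs] == ys))
        return(c(xs, ys))
    }
    NULL
  }
  flank_pairs <- rbind(c(min(sq_p) - 1L, max(sq_q) + 1L),
                       c(min(rd_p) - 1L, max(rd_q) + 1L))
  find_bad_flank <- function() {
    for (r in 1:2) {
      fp <- flank_pairs[r, ]
      if (fp[1L] < 1L || fp[2L] > n) next
      if (wc(bases[fp[1L]], bases[fp[2L]]) ||
          paste0(bases[fp[1L]], bases[fp[2L]]) %in% c("GU", "UG"))
        return(fp)
    }
    NULL
  }
  resample_at <- function(pos) {
    bases[pos] <<- sample(names(COMPLEMENT), 1L)
    if (partner[pos] > 0L) bases[partner[pos]] <<- COMPLEMENT[[bases[pos]]]
  }
  ok <- FALSE
  for (attempt in seq_len(max_attempts * 10L)) {
    bad <- find_bad_triple()
    if (!is.null(bad)) {
      xs <- bad[1:3]; ys <- bad[4:6]
      # resample an end of a non-planted pair of the run: resampling a
      # planted pair moves its partner with it and can never break it.
      # The pair and end are chosen at random so that a position pinned by
      # several overlapping constraints does not capture every repair.
      cand <- which(partner[xs] != ys)
      w <- cand[sample.int(length(cand), 1L)]
      ends <- c(xs[w], ys[w])
      fe <- ends[partner[ends] == 0L]
      resample_at(if (length(fe)) fe[sample.int(length(fe), 1L)]
                  else ends[sample.int(2L, 1L)])
      next
    }
    fl <- find_bad_flank()
    if (!is.null(fl)) {
      fe <- fl[partner[fl] == 0L]
      resample_at(if (length(fe)) fe[sample.int(length(fe), 1L)] else fl[1L])
      next
    }
    ok <- TRUE
    break
  }
  if (!ok)
    warning("repair loop exhausted; instance may contain competing helices",
            call. = FALSE)
  seqstr <- paste0(bases, collapse = "")
  st <- rna_structure(n,
                      p = c(sq_p, rd_p, gp_p),
                      q = c(sq_q, rd_q, gp_q),
                      layer = c(rep("square", a), rep("round", b), gp_layer),
                      gap = c(rep(FALSE, a + b), rep(TRUE, length(gp_p))))
  core <- rbind(square = c(p = min(sq_p), q = max(sq_q)),
                round = c(p = min(rd_p), q = max(rd_q)))
  list(seq = seqstr, structure = st, core = core, spec = spec,
       seed = spec$seed)
}

#' Write synthetic instances as paired FASTA + dot-bracket files
#'
#' @param instances list of [generate_pseudoknot()] results.
#' @param prefix output path prefix; writes `<prefix>.fasta` and
#'   `<prefix>.db` (dot-bracket, one header + sequence + structure per
#'   record). Headers record the seed.
#' @return character vector of the two paths, invisibly.
#' @export
write_synthetic <- function(instances, prefix) {
  if (!is.null(instances$seq)) instances <- list(instances)
  fa <- paste0(prefix, ".fasta"); db <- paste0(prefix, ".db")
  falines <- dblines <- character()
  for (i in seq_along(instances)) {
    inst <- instances[[i]]
    hdr <- sprintf(">synth%d seed=%d", i, inst$seed)
    falines <- c(falines, hdr, inst$seq)
    dblines <- c(dblines, hdr, inst$seq, write_structure(inst$structure))
  }
  writeLines(falines, fa)
  writeLines(dblines, db)
  invisible(c(fa, db))
}
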