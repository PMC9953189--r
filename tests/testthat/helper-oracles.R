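# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: complementarity is a lookup table, enumeration
# scans all position quadruples, and decoration is reconstructed by a
# direct pair scan rather than the gap-grid walk.

oracle_comp <- function(a, b, gu = FALSE) {
  key <- paste0(sort(c(a, b)), collapse = "")
  key == "AU" || key == "CG" || (gu && key == "GU")
}

# every (i, j, k, l) with i < j < k < l, complementary core pairs, and
# minimum loop sizes, by scanning all 4-subsets of positions
oracle_quads <- function(seq, gu = FALSE, min_left = 1L, min_right = 1L) {
  bases <- strsplit(seq, "")[[1]]
  n <- length(bases)
  if (n < 4L) return(matrix(integer(), ncol = 4L))
  combs <- t(utils::combn(n, 4L))
  keep <- logical(nrow(combs))
  for (r in seq_len(nrow(combs))) {
    i <- combs[r, 1L]; j <- combs[r, 2L]; k <- combs[r, 3L]; l <- combs[r, 4L]
    keep[r] <- oracle_comp(bases[i], bases[k], gu) &&
      oracle_comp(bases[j], bases[l], gu) &&
      (j - i - 1L) >= min_left && (l - k - 1L) >= min_right
  }
  combs[keep, , drop = FALSE]
}

random_rna <- function(n) paste0(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                                 collapse = "")

as_quad_matrix <- function(x) matrix(as.integer(as.matrix(x)), ncol = 4L)

# pair-set signature of a structure candidate, for set comparisons
cand_signature <- function(cand) {
  pr <- cand$structure$pairs
  paste(sort(paste0(pr$p, "-", pr$q)), collapse = ";")
}

# Decoration oracle: reconstructs the candidate set for one quadruple by a
# direct scan. Contiguous extension by naive stepping; gap continuations by
# scanning all (p, q) with p in the free run below the stem end, q in the
# free run above it, gap lengths within B and not both zero, then stacking
# naively; candidates are the cross product of side choices.
oracle_decorate_signatures <- function(seq, quad, B, gu = FALSE) {
  bases <- strsplit(seq, "")[[1]]
  n <- length(bases)
  i <- quad[1L]; j <- quad[2L]; k <- quad[3L]; l <- quad[4L]
  used <- rep(FALSE, n); used[c(i, j, k, l)] <- TRUE
  step_out <- function(p, q) {
    ps <- integer(); qs <- integer()
    repeat {
      p <- p - 1L; q <- q + 1L
      if (p < 1L || q > n || used[p] || used[q] ||
          !oracle_comp(bases[p], bases[q], gu)) break
      used[p] <<- TRUE; used[q] <<- TRUE
      ps <- c(ps, p); qs <- c(qs, q)
    }
    cbind(ps, qs)
  }
  right_ext <- step_out(j, l)   # round stem first
  left_ext <- step_out(i, k)
  round_pairs <- rbind(c(j, l), right_ext)
  square_pairs <- rbind(c(i, k), left_ext)
  run_down <- function(p) { out <- integer(); while (p >= 1L && !used[p]) { out <- c(out, p); p <- p - 1L }; out }
  run_up <- function(q) { out <- integer(); while (q <= n && !used[q]) { out <- c(out, q); q <- q + 1L }; out }
  side_choices <- function(stem) {
    p0 <- stem[nrow(stem), 1L]; q0 <- stem[nrow(stem), 2L]
    inner <- run_down(p0 - 1L); outer <- run_up(q0 + 1L)
    sigs <- list()
    for (p in inner) for (q in outer) {
      bi <- (p0 - 1L) - p; bo <- q - (q0 + 1L)
      if (bi > B || bo > B || (bi == 0L && bo == 0L)) next
      if (!oracle_comp(bases[p], bases[q], gu)) next
      ps <- p; qs <- q
      pp <- p - 1L; qq <- q + 1L
      while (pp %in% inner && qq %in% outer && oracle_comp(bases[pp], bases[qq], gu)) {
        ps <- c(ps, pp); qs <- c(qs, qq); pp <- pp - 1L; qq <- qq + 1L
      }
      sig <- paste(sort(paste0(ps, "-", qs)), collapse = ";")
      sigs[[sig]] <- cbind(ps, qs)
    }
    sigs
  }
  left_set_choices <- side_choices(round_pairs)    # continues the round stem
  right_set_choices <- side_choices(square_pairs)  # continues the square stem
  base_pairs <- rbind(square_pairs, round_pairs)
  sigs <- character()
  for (lc in c(list(NULL), unname(left_set_choices)))
    for (rc in c(list(NULL), unname(right_set_choices))) {
      all_p <- rbind(base_pairs, lc, rc)
      sigs <- c(sigs, paste(sort(paste0(all_p[, 1L], "-", all_p[, 2L])),
                            collapse = ";"))
    }
  sort(unique(sigs))
}

# reference structure with known pairing, no partner mismatches possible in
# the derived prediction: pred keeps a random subset of ref pairs and adds
# random extra pairs among ref-unpaired positions
random_ref_pred_pair <- function(n, n_ref_pairs, n_extra) {
  pos <- sample(n)
  ref_p <- pmin(pos[seq_len(n_ref_pairs) * 2 - 1], pos[seq_len(n_ref_pairs) * 2])
  ref_q <- pmax(pos[seq_len(n_ref_pairs) * 2 - 1], pos[seq_len(n_ref_pairs) * 2])
  used <- 2L * n_ref_pairs
  keep <- sample(c(TRUE, FALSE), n_ref_pairs, replace = TRUE)
  extra_idx <- pos[(used + 1):(used + 2 * n_extra)]
  ex_p <- pmin(extra_idx[seq_len(n_extra) * 2 - 1], extra_idx[seq_len(n_extra) * 2])
  ex_q <- pmax(extra_idx[seq_len(n_extra) * 2 - 1], extra_idx[seq_len(n_extra) * 2])
  list(ref = list(p = ref_p, q = ref_q),
       pred = list(p = c(ref_p[keep], ex_p), q = c(ref_q[keep], ex_q)))
}

# partner vectors -> per-position confusion counts, straight from the
# definitions (used to cross-check confusion_counts)
oracle_confusion <- function(pv, rv) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(pv)) {
    if (is.na(pv[i]) && is.na(rv[i])) tn <- tn + 1L
    else if (is.na(pv[i])) fn <- fn + 1L
    else if (!is.na(rv[i]) && pv[i] == rv[i]) tp <- tp + 1L
    else fp <- fp + 1L
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

WORKED_SEQ <- "ACAUCCGCCUGAUUUGAGCACA"
WORKED_FULL_DB <- "[.[[[.((((]]].].))).)."
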