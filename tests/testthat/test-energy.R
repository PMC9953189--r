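test_that("pseudoknot penalty evaluates the affine relation exactly", {
  expect_equal(pseudoknot_penalty(0, 0), 9.6)
  expect_equal(pseudoknot_penalty(2, 9), 10.7)
  expect_equal(pseudoknot_penalty(5, 7, energy_params(0, 0, 0)), 0)
  # affine and monotone nondecreasing in both arguments
  p <- energy_params()
  expect_true(pseudoknot_penalty(3, 4, p) >= pseudoknot_penalty(2, 4, p))
  expect_true(pseudoknot_penalty(3, 5, p) >= pseudoknot_penalty(3, 4, p))
  d1 <- pseudoknot_penalty(4, 0, p) - pseudoknot_penalty(3, 0, p)
  d2 <- pseudoknot_penalty(9, 0, p) - pseudoknot_penalty(8, 0, p)
  expect_equal(d1, d2)
})

test_that("the bundled stacking table loads, is complete, and is symmetric", {
  tab <- default_stack_table()
  expect_length(tab, 36L)
  pairs <- c("AU", "UA", "CG", "GC", "GU", "UG")
  for (p1 in pairs) for (p2 in pairs) {
    key <- paste0(substr(p1, 1, 1), substr(p2, 1, 1), "/",
                  substr(p1, 2, 2), substr(p2, 2, 2))
    rev_key <- paste0(substr(p2, 2, 2), substr(p1, 2, 2), "/",
                      substr(p2, 1, 1), substr(p1, 1, 1))
    expect_false(is.na(tab[key]))
    expect_equal(unname(tab[key]), unname(tab[rev_key]),
                 info = paste(key, rev_key))
  }
})

test_that("stack energy sums within-layer adjacent stacks only", {
  tab <- default_stack_table()
  expect_equal(stack_energy("ACGU", rna_structure(4L)), 0)
  expect_equal(stack_energy("ACGU", rna_structure(4L, 1, 4, "round")), 0)
  s <- rna_structure(6L, p = c(1, 2), q = c(6, 5), layer = c("round", "round"))
  expect_equal(stack_energy("GCAAGC", s), unname(tab["GC/CG"]))
  # non-adjacent pairs in one layer contribute nothing
  s2 <- rna_structure(8L, p = c(1, 3), q = c(8, 6), layer = c("round", "round"))
  expect_equal(stack_energy("GAGACACC", s2), 0)
})

test_that("total energy combines penalty and optional stacking", {
  # candidate with two isolated crossing pairs: no stacks, Bp = 2, Up = 0
  cand <- structure_candidate("ACGUACGU", c(1, 3, 4, 6),
                              p = c(1, 3), q = c(4, 6),
                              layer = c("square", "round"),
                              gap = c(FALSE, FALSE))
  expect_equal(cand$Bp, 2L)
  expect_equal(cand$Up, 2L)  # positions 2 and 5 inside span 1..6
  expect_equal(cand$total_energy, 9.6 + 0.2 + 0.2)
  expect_equal(total_energy(cand, energy_params(0, 0, 0)), 0)

  # with stacking enabled the stacked-step sum is added
  seq <- "GGAACCAAU"
  cs <- structure_candidate(seq, c(2, 3, 5, 9),
                            p = c(1, 2, 3), q = c(6, 5, 9),
                            layer = c("square", "square", "round"),
                            gap = rep(FALSE, 3),
                            params = energy_params(use_stacking = TRUE))
  tab <- default_stack_table()
  expect_equal(cs$stack, unname(tab["GG/CC"]))
  expect_equal(cs$total_energy,
               unname(tab["GG/CC"]) + pseudoknot_penalty(3, cs$Up))
  expect_lt(cs$total_energy,
            total_energy(cs, energy_params(use_stacking = FALSE)))
})

test_that("selection maximizes non-gap pairing before minimizing energy", {
  mk <- function(p, q, layer, gap = rep(FALSE, length(p)), seq, quad,
                 eps = energy_params())
    structure_candidate(seq, quad, p, q, layer, gap, eps)
  seq <- WORKED_SEQ
  cands <- decorate(seq, c(5, 10, 11, 17))
  ng <- vapply(cands, `[[`, numeric(1), "nongap_pair_count")
  en <- vapply(cands, `[[`, numeric(1), "total_energy")
  best <- select_optimal(cands)
  expect_equal(best$nongap_pair_count, max(ng))
  expect_equal(best$total_energy, min(en[ng == max(ng)]))

  # a higher non-gap count wins regardless of energy
  lo <- mk(p = c(5, 10), q = c(11, 17), layer = c("square", "round"), seq = seq,
           quad = c(5, 10, 11, 17))
  expect_equal(select_optimal(c(cands, list(lo)))$nongap_pair_count, max(ng))

  # permutation invariance
  set.seed(11)
  for (rep in 1:5) {
    perm <- sample(length(cands))
    expect_identical(cand_signature(select_optimal(cands[perm])),
                     cand_signature(best))
  }
  expect_error(select_optimal(list()), "no pseudoknot")
})

test_that("equal-count, equal-energy ties fall to total pairs then smallest quadruple", {
  # two single-pair-stem candidates, same counts, same (zero-beta) energy
  seq <- "AAAAAUAUAAAAU"
  eps <- energy_params(0, 0, 0)
  a <- structure_candidate(seq, c(3, 6, 8, 11), p = c(3, 6), q = c(8, 11),
                           layer = c("square", "round"), gap = c(FALSE, FALSE),
                           params = eps)
  b <- structure_candidate(seq, c(2, 6, 8, 12), p = c(2, 6), q = c(8, 12),
                           layer = c("square", "round"), gap = c(FALSE, FALSE),
                           params = eps)
  expect_equal(a$total_energy, b$total_energy)
  # same energy, same counts: lexicographically smaller quad (b) wins
  expect_equal(unname(select_optimal(list(a, b))$quad), c(2L, 6L, 8L, 12L))
  expect_equal(unname(select_optimal(list(b, a))$quad), c(2L, 6L, 8L, 12L))
  # more total pairs (via a gap-mediated pair) beats the quad tie-break
  a2 <- structure_candidate(seq, c(3, 6, 8, 11),
                            p = c(3, 6, 1), q = c(8, 11, 13),
                            layer = c("square", "round", "square"),
                            gap = c(FALSE, FALSE, TRUE), params = eps)
  expect_equal(unname(select_optimal(list(a2, b))$quad), c(3L, 6L, 8L, 11L))
})

test_that("gap-mediated pairs change energy but never the stage-1 count", {
  cands <- decorate(WORKED_SEQ, c(5, 10, 11, 17))
  ng <- vapply(cands, `[[`, numeric(1), "nongap_pair_count")
  expect_equal(unique(ng), 5)
  npairs <- vapply(cands, function(c) nrow(c$structure$pairs), numeric(1))
  en <- vapply(cands, `[[`, numeric(1), "total_energy")
  # candidates differing only by gap pairs differ in energy (Up shrinks)
  expect_gt(max(npairs), min(npairs))
  expect_gt(max(en), min(en))
})
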