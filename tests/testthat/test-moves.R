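test_that("move classification matches a hand-enumerated table on a 2x2 genome", {
  g <- tiny_genome(c(2, 2))  # chromosomes (1 2) and (3 4), gaps 0..2 each
  cls <- function(k1, g1, k2, g2, r)
    classify_move(g, list(chrom1 = k1, gap1 = g1, chrom2 = k2, gap2 = g2, rejoin = r))
  # same chromosome, internal cuts
  expect_identical(cls(1, 0, 1, 1, 0), "inversion")
  expect_identical(cls(1, 0, 1, 1, 1), "excision")
  expect_identical(cls(1, 0, 1, 2, 1), "excision")  # whole-chromosome circularization
  # two linear chromosomes, internal cuts: both rejoins translocate
  expect_identical(cls(1, 1, 2, 1, 0), "translocation")
  expect_identical(cls(1, 1, 2, 1, 1), "translocation")
  # telomere + internal: still a translocation (one exchanged fragment empty)
  expect_identical(cls(1, 2, 2, 1, 0), "translocation")
  # telomere + telomere: the single non-identity rejoin is a fusion
  expect_identical(cls(1, 2, 2, 0, 0), "fusion")
  expect_identical(cls(1, 2, 2, 0, 1), "fusion")
  expect_identical(cls(1, 0, 2, 0, 0), "fusion")  # identity rejoin swapped out
})

test_that("moves involving circular fragments classify as fission/fusion/reintegration", {
  g <- new_dcj_genome(list(1:4, 5:8), c(FALSE, TRUE))
  expect_identical(classify_move(g, list(chrom1 = 2, gap1 = 0, chrom2 = 2,
                                         gap2 = 2, rejoin = 0)), "inversion")
  expect_identical(classify_move(g, list(chrom1 = 2, gap1 = 0, chrom2 = 2,
                                         gap2 = 2, rejoin = 1)), "fission")
  expect_identical(classify_move(g, list(chrom1 = 1, gap1 = 2, chrom2 = 2,
                                         gap2 = 1, rejoin = 0)), "reintegration")
  h <- new_dcj_genome(list(1:4, 5:8), c(TRUE, TRUE))
  expect_identical(classify_move(h, list(chrom1 = 1, gap1 = 1, chrom2 = 2,
                                         gap2 = 1, rejoin = 0)), "fusion")
})

test_that("every move conserves gene content and is undone by its inverse", {
  set.seed(5)
  g <- tiny_genome(c(6, 5, 4), mu = 0.3)
  ids <- gene_multiset(g)
  for (mv in all_moves(g)) {
    move <- dcjsim:::build_move(g, mv$k1, mv$g1, mv$k2, mv$g2, mv$r)
    if (move$identity) next
    h <- apply_move(g, move)
    expect_identical(gene_multiset(h), ids)
    # inverse: an inversion undoes itself; an excision is undone by
    # reintegrating the fragment at its source; translocations by repeating
    # the same cuts and rejoin.
    whole_chrom_excision <- move$class == "excision" && move$gap1 == 0L &&
      move$gap2 == length(g$chromosomes[[move$chrom1]])
    inv <- switch(move$class,
      inversion = move,
      excision = if (whole_chrom_excision) NULL else
        dcjsim:::build_move(h, length(h$chromosomes), 0L,
                            move$chrom1, move$gap1, 0L),
      translocation = {
        # rejoin 0 is self-inverse at the same cuts; rejoin 1 reverses the
        # exchanged prefixes, so the second cut sits after the old suffix
        gap2 <- if (move$rejoin == 0L) move$gap2
                else length(g$chromosomes[[move$chrom1]]) - move$gap1
        dcjsim:::build_move(h, move$chrom1, move$gap1,
                            move$chrom2, gap2, move$rejoin)
      },
      NULL)
    if (!is.null(inv)) {
      # reintegration of an excised fragment can need the opposite orientation
      g2 <- apply_move(h, inv)
      if (move$class == "excision" && !genomes_identical(g2, g)) {
        inv$rejoin <- 1L
        g2 <- apply_move(h, inv)
      }
      expect_true(genomes_identical(g2, g))
    }
  }
})

test_that("inverting a whole chromosome leaves the genome unchanged up to reversal", {
  g <- tiny_genome(c(5, 5))
  move <- dcjsim:::build_move(g, 1L, 0L, 1L, 5L, 0L)
  expect_true(genomes_identical(apply_move(g, move), g))
})

test_that("proposals use every cut point uniformly", {
  set.seed(99)
  g <- tiny_genome(c(10, 10))
  hits <- integer(22)  # 11 gaps per linear chromosome of 10 genes
  n <- 20000
  for (i in seq_len(n)) {
    mv <- propose_move(g)
    i1 <- (mv$chrom1 - 1L) * 11L + mv$gap1 + 1L
    i2 <- (mv$chrom2 - 1L) * 11L + mv$gap2 + 1L
    hits[i1] <- hits[i1] + 1L
    hits[i2] <- hits[i2] + 1L
  }
  p <- stats::chisq.test(hits)$p.value
  expect_gt(p, 1e-4)
  # single-chromosome genome: every proposal intra-chromosomal
  g1 <- tiny_genome(10)
  for (i in 1:50) {
    mv <- propose_move(g1)
    expect_identical(mv$chrom1, mv$chrom2)
  }
})

test_that("same-chromosome cut-pair frequency matches the combinatorial ratio", {
  set.seed(7)
  g <- tiny_genome(c(50, 50))
  K <- 102  # 51 positions per chromosome
  exp_frac <- 2 * choose(51, 2) / choose(K, 2)
  same <- vapply(1:4000, function(i) {
    mv <- propose_move(g)
    mv$chrom1 == mv$chrom2
  }, TRUE)
  se <- sqrt(exp_frac * (1 - exp_frac) / 4000)
  expect_lt(abs(mean(same) - exp_frac), 4 * se)
})
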