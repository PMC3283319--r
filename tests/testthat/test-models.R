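test_that("dosage-sensitivity rule matches the fragment-freedom conditions", {
  # genome with zero sensitive genes: everything passes
  g0 <- tiny_genome(c(5, 5))
  for (mv in all_moves(g0)) {
    move <- dcjsim:::build_move(g0, mv$k1, mv$g1, mv$k2, mv$g2, mv$r)
    if (!move$identity) expect_true(accept_ds(g0, move))
  }
  # sensitive genes on both sides of both cuts: translocation rejected
  illegal <- make_fixture("ds-illegal-rejoin")
  expect_false(accept_ds(illegal$genome, illegal$move))
  # exchanged fragments free of sensitive genes: accepted
  legal <- make_fixture("ds-legal-rejoin")
  expect_true(accept_ds(legal$genome, legal$move))
  # inversions always pass, excisions need a sensitive-free fragment
  sens <- rep(FALSE, 20); sens[7] <- TRUE
  g <- new_dcj_genome(list(1:10, 11:20), sensitive = sens)
  inv <- dcjsim:::build_move(g, 1L, 4L, 1L, 8L, 0L)
  exc_bad <- dcjsim:::build_move(g, 1L, 4L, 1L, 8L, 1L)
  exc_ok <- dcjsim:::build_move(g, 2L, 2L, 2L, 8L, 1L)
  expect_true(accept_ds(g, inv))
  expect_false(accept_ds(g, exc_bad))
  expect_true(accept_ds(g, exc_ok))
  # fusion of two chromosomes that both carry sensitive genes is rejected
  sens2 <- rep(FALSE, 20); sens2[c(3, 13)] <- TRUE
  g2 <- new_dcj_genome(list(1:10, 11:20), sensitive = sens2)
  fus <- dcjsim:::build_move(g2, 1L, 10L, 2L, 0L, 0L)
  expect_identical(fus$class, "fusion")
  expect_false(accept_ds(g2, fus))
  sens3 <- rep(FALSE, 20); sens3[3] <- TRUE
  g3 <- new_dcj_genome(list(1:10, 11:20), sensitive = sens3)
  expect_true(accept_ds(g3, dcjsim:::build_move(g3, 1L, 10L, 2L, 0L, 0L)))
})

test_that("the sensitive-gene partition is invariant along a DCJ-DS run", {
  m <- model_config("ds", mu = 0.15)
  run <- run_simulation(m, 300, n_chrom = 6, n_genes = 600, seed = 17,
                        checkpoints = 1:300)
  part0 <- sensitive_partition(run$start)
  for (snap in run$snapshots)
    expect_identical(sensitive_partition(snap), part0)
})

test_that("maxT accepts/rejects by exchanged-fragment size, exhaustively on a small genome", {
  set.seed(3)
  g <- tiny_genome(c(12, 12), mu = 0)
  Tm <- 4
  for (mv in all_moves(g)) {
    move <- dcjsim:::build_move(g, mv$k1, mv$g1, mv$k2, mv$g2, mv$r)
    if (move$identity) next
    got <- accept_maxT(g, move, T_max = Tm)
    # brute-force evaluation of the published rule
    want <- if (move$class == "inversion") TRUE
    else if (move$class == "excision") (move$gap2 - move$gap1) <= Tm
    else {
      la <- move$gap1; lb <- 12 - move$gap1
      lc <- move$gap2; ld <- 12 - move$gap2
      if (move$rejoin == 0) (la <= Tm && lc <= Tm) || (lb <= Tm && ld <= Tm)
      else (lb <= Tm && lc <= Tm) || (la <= Tm && ld <= Tm)
    }
    expect_identical(got, want)
  }
})

test_that("maxL is the conjunction of maxT and the inversion-length cap", {
  set.seed(4)
  g <- tiny_genome(c(10, 10))
  Lm <- 3
  for (mv in all_moves(g)) {
    move <- dcjsim:::build_move(g, mv$k1, mv$g1, mv$k2, mv$g2, mv$r)
    if (move$identity) next
    want <- accept_maxT(g, move, T_max = Lm) &&
      (move$class != "inversion" || (move$gap2 - move$gap1) <= Lm)
    expect_identical(accept_maxL(g, move, L_max = Lm), want)
  }
  # boundary: inversion of exactly L_max accepted, L_max + 1 rejected
  g2 <- tiny_genome(20)
  at_cap <- dcjsim:::build_move(g2, 1L, 2L, 1L, 5L, 0L)
  over <- dcjsim:::build_move(g2, 1L, 2L, 1L, 6L, 0L)
  expect_true(accept_maxL(g2, at_cap, L_max = 3))
  expect_false(accept_maxL(g2, over, L_max = 3))
})

test_that("pfix limits behave: p_fix = 0 blocks all gated moves; empirical rate matches", {
  m0 <- model_config("pfix", p_fix = 0, pfix_scope = "all")
  r <- run_simulation(m0, 200, n_chrom = 4, n_genes = 400, seed = 5)
  expect_identical(as.integer(r$log$n_t), 0L)
  # empirical acceptance of gated proposals at p_fix = 0.3
  set.seed(8)
  g <- tiny_genome(c(30, 30))
  mv <- dcjsim:::build_move(g, 1L, 10L, 2L, 10L, 0L)
  acc <- vapply(1:2000, function(i) accept_pfix(g, mv, p_fix = 0.3), TRUE)
  se <- sqrt(0.3 * 0.7 / 2000)
  expect_lt(abs(mean(acc) - 0.3), 4 * se)
})

test_that("each model reduces to plain DCJ at its limiting parameter, draw-for-draw", {
  base <- run_simulation(model_config("dcj"), 300, n_chrom = 5, n_genes = 500,
                         seed = 23)
  limits <- list(model_config("ds", mu = 0),
                 model_config("maxT", T_max = Inf),
                 model_config("maxL", L_max = Inf),
                 model_config("pfix", p_fix = 1))
  for (m in limits) {
    r <- run_simulation(m, 300, n_chrom = 5, n_genes = 500, seed = 23)
    expect_identical(r$end$chromosomes, base$end$chromosomes)
    expect_identical(r$log$by_class, base$log$by_class)
  }
})

test_that("macro-synteny decay under DS slows with mu while micro-synteny barely moves", {
  mus <- c(0, 0.08, 0.2)
  stats <- lapply(mus, function(mu) {
    reps <- lapply(1:3, function(i) {
      r <- run_simulation(model_config("ds", mu = mu), 1500, n_chrom = 10,
                          n_genes = 2000, seed = 100 * i + round(1000 * mu))
      mk <- sample_markers(r$start, 800)
      synteny_compare(r$start, r$end, mk)
    })
    c(p = mean(vapply(reps, `[[`, 1, "p")), s = mean(vapply(reps, `[[`, 1, "s")))
  })
  p <- vapply(stats, `[`, 1, "p")
  s <- vapply(stats, `[`, 1, "s")
  expect_true(all(diff(p) > 0))          # p non-decreasing in mu at fixed n
  expect_lt(diff(range(s)) / mean(s), 0.5)  # s depends only weakly on mu
})
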