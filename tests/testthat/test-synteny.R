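test_that("marker sampling is uniform and validates its arguments", {
  g <- init_genome(4, 400, seed = 1)
  expect_error(sample_markers(g, 401), "exceeds")
  expect_identical(sample_markers(g, 400), 1:400)
  set.seed(2)
  counts <- integer(4)
  for (i in 1:300) {
    mk <- sample_markers(g, 40)
    counts <- counts + tabulate(g$ancestral[mk], 4)
  }
  expect_gt(stats::chisq.test(counts)$p.value, 1e-4)
})

test_that("identical genomes give s = 1, p = 1, identity best-match, diagonal dots", {
  g <- init_genome(5, 500, seed = 3)
  mk <- sample_markers(g, 200)
  st <- synteny_compare(g, g, mk)
  expect_equal(st$s, 1)
  expect_equal(st$p, 1)
  hom <- pal_homology(g, g, mk)
  expect_identical(unname(hom$best_ab), as.integer(names(hom$best_ab)))
  expect_true(all(diag(hom$z_ab) > 0))
  dp <- dot_plot_matrix(g, g, mk)
  expect_identical(nrow(dp), length(mk))
  expect_identical(dp$pos_a, dp$pos_b)
})

test_that("one reciprocal translocation on a 2x10 genome gives the hand-counted s", {
  fx <- make_fixture("single-translocation")
  mk <- 1:20
  # 18 adjacencies in a; the two cut adjacencies (5,6) and (15,16) are broken
  expect_equal(micro_synteny_s(fx$a, fx$b, mk), 16 / 18)
  expect_equal(micro_synteny_s(fx$a, fx$b, mk, signed = TRUE), 16 / 18)
})

test_that("signed adjacency counts orientation: an inversion's interior is conserved only unsigned", {
  g <- new_dcj_genome(list(1:6))
  h <- apply_move(g, dcjsim:::build_move(g, 1L, 1L, 1L, 4L, 0L))  # invert genes 2..4
  # unsigned: interior adjacencies of the inverted block survive, the two
  # breakpoints (1,2) and (4,5) are lost: s = 3/5
  expect_equal(micro_synteny_s(g, h, 1:6), 3 / 5)
  # signed: the boundary adjacencies flip orientation too, same count here
  expect_equal(micro_synteny_s(g, h, 1:6, signed = TRUE), 3 / 5)
})

test_that("z-scores and best matches follow the closed formula on a 3-PAL toy", {
  # 3 PALs of 10 markers each; O matrix [[10,0,0],[0,8,2],[0,2,8]]
  chrom_a <- list(1:10, 11:20, 21:30)
  perm <- c(1:10, 11:18, 29:30, 19:20, 21:28)
  chrom_b <- list(perm[1:10], perm[11:20], perm[21:30])
  a <- new_dcj_genome(chrom_a)
  b <- new_dcj_genome(chrom_b)
  hom <- pal_homology(a, b, 1:30)
  O <- matrix(c(10, 0, 0, 0, 8, 2, 0, 2, 8), 3, byrow = TRUE)
  E <- matrix(10 * 10 / 30, 3, 3)
  V <- 10 * (10 / 30) * (1 - 10 / 30)
  expect_equal(unname(hom$O), O)
  expect_equal(unname(hom$E), E)
  expect_equal(unname(hom$z_ab), (O - E) / sqrt(V))
  expect_identical(unname(hom$best_ab), c(1L, 2L, 3L))
  expect_identical(unname(hom$best_ba), c(1L, 2L, 3L))
  expect_equal(macro_synteny_p(a, b, 1:30), 26 / 30)
})

test_that("directional p saturates near 1/c under long unconstrained DCJ runs", {
  # saturation is measured with the directional best-match map; argmax
  # selection over finitely many noisy cells biases it upward of 1/c, more so
  # when the per-cell marker counts are small (c = 20 case)
  sat <- function(cc, n_genes) {
    mean(vapply(1:3, function(i) {
      r <- run_simulation(model_config("dcj"), 3 * n_genes, n_chrom = cc,
                          n_genes = n_genes, seed = 40 + i)
      macro_synteny_p(r$start, r$end, 1:n_genes, direction = "a_to_b")
    }, 1))
  }
  p5 <- sat(5L, 2000)
  expect_lt(abs(p5 - 0.2), 0.06)
  p20 <- sat(20L, 4000)
  expect_gt(p20, 0.05)
  expect_lt(p20, 0.12)
})

test_that("p from a marker subsample is an unbiased estimate of the full-set value", {
  r <- run_simulation(model_config("ds", mu = 0.1), 1200, n_chrom = 10,
                      n_genes = 2000, seed = 55)
  p_full <- macro_synteny_p(r$start, r$end, 1:2000)
  set.seed(9)
  p_sub <- mean(vapply(1:20, function(i) {
    macro_synteny_p(r$start, r$end, sample_markers(r$start, 400))
  }, 1))
  expect_lt(abs(p_sub - p_full), 0.03)
})

test_that("p_ab and p_ba may differ but stay close for simulated pairs", {
  r <- run_simulation(model_config("ds", mu = 0.1), 800, n_chrom = 8,
                      n_genes = 1600, seed = 77)
  mk <- sample_markers(r$start, 800)
  p_ab <- macro_synteny_p(r$start, r$end, mk)
  p_ba <- macro_synteny_p(r$end, r$start, mk)
  expect_lt(abs(p_ab - p_ba), 0.1)
})

test_that("markers on circular fragments count as non-conserved but keep their adjacencies", {
  g <- new_dcj_genome(list(1:12))
  # excise genes 4..9 as a circular fragment
  h <- apply_move(g, dcjsim:::build_move(g, 1L, 3L, 1L, 9L, 1L))
  expect_true(any(h$circular))
  p <- macro_synteny_p(g, h, 1:12)
  expect_equal(p, 6 / 12)  # the six excised genes lose chromosomal context
  s <- micro_synteny_s(g, h, 1:12)
  # adjacencies within the fragment survive (4-5 ... 8-9), plus the circular
  # closure creates (4,9); of 11 original adjacencies, (3,4) and (9,10) break
  expect_equal(s, 9 / 11)
})
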