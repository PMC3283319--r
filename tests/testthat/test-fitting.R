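test_that("chi-square arithmetic matches a hand computation", {
  # toy replicate table: s = (.10, .12, .14), p = (.50, .55, .60)
  mean_s <- mean(c(.10, .12, .14)); sd_s <- sd(c(.10, .12, .14))
  mean_p <- mean(c(.50, .55, .60)); sd_p <- sd(c(.50, .55, .60))
  got <- dcjsim:::chi2_from_stats(mean_s, mean_p, sd_s, sd_p,
                                  s_obs = .09, p_obs = .48)
  want <- ((mean_s - .09) / sd_s)^2 + ((mean_p - .48) / sd_p)^2
  expect_equal(got, want)
  # symmetric in the two terms
  got_swapped <- dcjsim:::chi2_from_stats(mean_p, mean_s, sd_p, sd_s,
                                          s_obs = .48, p_obs = .09)
  expect_equal(got, got_swapped)
  # sigma floor guards degenerate deviations
  expect_true(is.finite(dcjsim:::chi2_from_stats(.1, .5, 0, 0, .2, .5)))
})

test_that("chi_square is deterministic given a seed and ~zero at self-generated targets", {
  m <- model_config("ds", mu = 0.1)
  st1 <- chi_square(m, 300, list(p = .5, s = .5, markers = 500),
                    replicates = 3, seed = 5, n_chrom = 5, n_genes = 1000)
  st2 <- chi_square(m, 300, list(p = .5, s = .5, markers = 500),
                    replicates = 3, seed = 5, n_chrom = 5, n_genes = 1000)
  expect_identical(st1, st2)
  # using the replicate means as the observed target zeroes the objective
  st3 <- chi_square(m, 300, list(p = st1$mean_p, s = st1$mean_s, markers = 500),
                    replicates = 3, seed = 5, n_chrom = 5, n_genes = 1000)
  expect_equal(st3$chi2, 0)
})

test_that("quadratic surface fit recovers an exact paraboloid vertex to machine precision", {
  g <- expand.grid(x = seq(-1, 1, length.out = 7), y = seq(-1, 1, length.out = 7))
  z <- 3 + 2 * (g$x - 0.3)^2 + 5 * (g$y + 0.2)^2 + 1.5 * (g$x - 0.3) * (g$y + 0.2)
  qf <- fit_quadratic_surface(g$x, g$y, z)
  expect_true(qf$minimum)
  expect_equal(unname(qf$vertex), c(0.3, -0.2), tolerance = 1e-10)
  # saddle detected
  qs <- fit_quadratic_surface(g$x, g$y, g$x^2 - g$y^2)
  expect_false(qs$minimum)
})

test_that("fit_parameters recovers known parameters from a synthetic target", {
  # generate the "observed" statistics at known (n*, mu*) on a reduced genome
  m_true <- model_config("ds", mu = 0.08)
  truth <- dcjsim:::sim_stats(m_true, 1200, n_markers = 800, replicates = 10,
                              seed = 99, n_chrom = 10, n_genes = 2000)
  obs <- list(p = truth$mean_p, s = truth$mean_s, markers = 800)
  # the noisy surface can make the parabolic refinement fall back to the grid
  # argmin (with a warning); either path must recover the truth
  fit <- suppressWarnings(
    fit_parameters("ds", obs, seed = 31, replicates = 5,
                   n_interval = c(100, 5000), param_interval = c(0, 0.3),
                   n_chrom = 10, n_genes = 2000))
  expect_lt(abs(fit$n_hat - 1200) / 1200, 0.15)
  expect_lt(abs(fit$param_hat - 0.08) / 0.08, 0.25)
  expect_identical(nrow(fit$grid), 49L)
  # grid spans +/-15% of the phase-one optimum
  expect_equal(max(fit$grid$n) / fit$phase1["n"], 1.15, tolerance = 0.01,
               ignore_attr = TRUE)
})

test_that("neighbor joining solves the 3-taxon case exactly and recovers additive trees", {
  D <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D)
  # three-point formulas: a = (dAB + dAC - dBC)/2, etc.
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(bl[c("A", "B", "C")]), c(2, 3, 7))
  fx <- make_fixture("additive-tree")
  rec <- nj_tree(fx$distances)
  expect_equal(ape::dist.topo(ape::unroot(fx$tree), rec)[1], 0)
  # recovered branch lengths reproduce the additive distances
  Dr <- ape::cophenetic.phylo(rec)
  expect_equal(Dr[rownames(fx$distances), colnames(fx$distances)],
               fx$distances, tolerance = 1e-8)
})

test_that("NJ on ultrametric star distances returns near-equal branch lengths", {
  D <- matrix(8, 4, 4) - diag(8, 4)
  dimnames(D) <- list(letters[1:4], letters[1:4])
  tr <- nj_tree(D)
  tips <- tr$edge.length[tr$edge[, 2] <= 4]
  expect_lt(diff(range(tips)), 1e-8)
})

test_that("nj_tree validates its input", {
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2)), "symmetric|three")
  D <- matrix(c(0, -1, -1, 0), 2)
  expect_error(nj_tree(D), "non-negative|three")
})

test_that("PHYLIP square matrices round-trip", {
  D <- pairwise_matrix(observed_pairs(), "n")
  path <- tempfile()
  write_phylip_square(D, path)
  D2 <- read_phylip_square(path)
  expect_equal(D, D2)
  expect_error(read_phylip_square(textConnection("x")), "malformed|cannot")
})
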