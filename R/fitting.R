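#' Observed pairwise synteny conservation among five metazoan genomes
#'
#' Shared single-copy marker counts, macro-synteny conservation \code{p},
#' micro-synteny conservation \code{s}, and the fitted dosage-sensitivity model
#' parameters (rearrangement count \code{n}, sensitive fraction \code{mu},
#' inter-chromosomal count \code{n_t}) for the ten pairwise comparisons of
#' human (Hs), lancelet (Bf), sea anemone (Nv), placozoan (Ta) and sponge (Aq).
#' These values serve as fitting targets and as the distance inputs for
#' tree construction.
#'
#' @return data.frame with columns \code{pair}, \code{taxon1}, \code{taxon2},
#'   \code{markers}, \code{p}, \code{s}, \code{n}, \code{mu}, \code{n_t}.
#' @export
observed_pairs <- function() {
  df <- data.frame(
    pair = c("Hs-Bf", "Hs-Nv", "Hs-Ta", "Hs-Aq", "Bf-Nv",
             "Bf-Ta", "Bf-Aq", "Nv-Ta", "Nv-Aq", "Ta-Aq"),
    markers = c(4408L, 3451L, 3557L, 2400L, 3972L,
                3970L, 2690L, 2664L, 3972L, 2953L),
    p = c(.58, .45, .51, .35, .51, .59, .42, .39, .57, .44),
    s = c(.0218, .0038, .0138, .0038, .0055,
          .0229, .0082, .0141, .0049, .0152),
    n = c(26441, 49650, 30122, 49550, 42970,
          25492, 35917, 30652, 43878, 27394),
    mu = c(.0727, .0793, .0696, .0689, .0817,
           .0739, .0662, .0775, .0690, .0596),
    n_t = c(1712, 2931, 2115, 3328, 2431,
            1637, 2602, 1868, 3092, 2232),
    stringsAsFactors = FALSE)
  parts <- strsplit(df$pair, "-", fixed = TRUE)
  df$taxon1 <- vapply(parts, `[`, "", 1)
  df$taxon2 <- vapply(parts, `[`, "", 2)
  df[c("pair", "taxon1", "taxon2", "markers", "p", "s", "n", "mu", "n_t")]
}

# chi-square objective from replicate summaries (pure arithmetic, testable)
chi2_from_stats <- function(mean_s, mean_p, sigma_s, sigma_p, s_obs, p_obs,
                            sigma_floor = 1e-6) {
  ss <- max(sigma_s, sigma_floor)
  sp <- max(sigma_p, sigma_floor)
  ((mean_s - s_obs) / ss)^2 + ((mean_p - p_obs) / sp)^2
}

# replicate seeds derived from a base seed; kept below 2^31
replicate_seeds <- function(seed, replicates) {
  (as.double(seed) * 1009 + 9973 * seq_len(replicates)) %% 2147483647 + 1
}

# run `replicates` seeded simulations and summarize s, p, n_t (internal)
sim_stats <- function(model, n, n_markers, replicates, seed,
                      n_chrom = 20, n_genes = 20000, engine = "fast") {
  seeds <- replicate_seeds(seed, replicates)
  one <- function(sd) {
    run <- run_simulation(model, n = round(n), n_chrom = n_chrom,
                          n_genes = n_genes, seed = sd, engine = engine)
    markers <- sample_markers(run$start, min(n_markers, n_genes))
    st <- synteny_compare(run$start, run$end, markers)
    c(s = st$s, p = st$p, n_t = as.double(run$log$n_t))
  }
  reps <- vapply(seeds, one, c(s = 0, p = 0, n_t = 0))
  list(mean_s = mean(reps["s", ]), mean_p = mean(reps["p", ]),
       sigma_s = stats::sd(reps["s", ]), sigma_p = stats::sd(reps["p", ]),
       mean_nt = mean(reps["n_t", ]), replicates = replicates)
}

#' Chi-square comparison of a model to observed synteny conservation
#'
#' Runs seeded replicate simulations and returns the chi-square objective:
#' the squared normalized deviations of the replicate means of \code{s} and
#' \code{p} from their observed values, each normalized by the replicate
#' standard deviation. A small floor guards degenerate deviations (for example
#' at n = 0 every replicate is identical).
#'
#' @param model a \code{dcj_model}.
#' @param n accepted-move count per run.
#' @param observed list or one-row data.frame with \code{p}, \code{s},
#'   \code{markers}.
#' @param replicates number of simulation runs (>= 2).
#' @param seed base seed; replicate seeds derive from it deterministically.
#' @param n_chrom,n_genes genome dimensions.
#' @param sigma_floor lower bound for the replicate standard deviations.
#' @return List: \code{chi2}, \code{mean_s}, \code{mean_p}, \code{sigma_s},
#'   \code{sigma_p}, \code{mean_nt}.
#' @export
chi_square <- function(model, n, observed, replicates = 10, seed = 1,
                       n_chrom = 20, n_genes = 20000, sigma_floor = 1e-6) {
  if (replicates < 2) stop("need at least two replicates")
  st <- sim_stats(model, n, observed$markers, replicates, seed,
                  n_chrom, n_genes)
  st$chi2 <- chi2_from_stats(st$mean_s, st$mean_p, st$sigma_s, st$sigma_p,
                             observed$s, observed$p, sigma_floor)
  st
}

#' Least-squares quadratic surface and its stationary point
#'
#' Fits \code{chi2 ~ a + b x + c y + d x^2 + e y^2 + f x y} by least squares
#' and returns the stationary point. Used for the refinement phase of
#' \code{\link{fit_parameters}}; exact on a sampled paraboloid.
#'
#' @param x,y,z numeric vectors (grid coordinates and objective values).
#' @return List: \code{vertex} (c(x, y)), \code{coef}, \code{minimum} (TRUE if
#'   the Hessian is positive definite).
#' @export
fit_quadratic_surface <- function(x, y, z) {
  X <- cbind(1, x, y, x^2, y^2, x * y)
  cf <- qr.solve(X, z)
  H <- matrix(c(2 * cf[4], cf[6], cf[6], 2 * cf[5]), 2, 2)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  minimum <- all(ev > 0)
  vertex <- tryCatch(solve(H, -c(cf[2], cf[3])), error = function(e) c(NA, NA))
  list(vertex = vertex, coef = cf, minimum = minimum)
}

#' Fit model parameters to observed synteny conservation
#'
#' Estimates the accepted-move count n and the model parameter (sensitive
#' fraction mu, fragment cap, or acceptance probability) in three stages.
#' A coarse localization pass evaluates the chi-square objective on a
#' log-spaced grid over the search brackets (at reduced replication) to find
#' the right valley — the objective's sublevel sets are curved, so coordinate
#' descent started far away can stall on a ridge. Phase one then alternates
#' one-dimensional Brent minimizations in n and in the parameter, each over a
#' local bracket around the current point, until the optimum moves by less
#' than 2% or \code{sweeps} is exhausted. The objective at a given
#' (n, parameter) is made deterministic by deriving all replicate seeds from
#' \code{seed} (common random numbers), which Brent needs to behave on a noisy
#' surface; evaluations are memoized. Phase two evaluates the objective on a
#' \code{grid_dim} x \code{grid_dim} grid spanning \code{grid_span} of the
#' phase-one optimum on each axis and fits a quadratic surface by least
#' squares; its stationary point is reported as the fitted value (falling back
#' to the grid argmin when the surface is not convex).
#'
#' @param model_name one of "ds", "maxT", "maxL", "pfix".
#' @param observed list or one-row data.frame with \code{p}, \code{s},
#'   \code{markers}.
#' @param seed base seed for the common-random-number scheme.
#' @param replicates simulation runs per objective evaluation.
#' @param n_interval search bracket for n.
#' @param param_interval search bracket for the model parameter (defaults:
#'   mu in [0, 0.5]; T_max/L_max in [2, 500]; p_fix in [1e-7, 1e-2]).
#' @param sweeps maximum coordinate-descent sweeps in phase one.
#' @param grid_dim,grid_span refinement grid size and half-width (fraction of
#'   the phase-one optimum).
#' @param coarse_dim,coarse_replicates size and replication of the coarse
#'   localization grid.
#' @param n_chrom,n_genes genome dimensions.
#' @return A \code{dcj_fit} list: \code{n_hat}, \code{param_hat}, \code{chi2},
#'   \code{mean_s}, \code{mean_p}, \code{sigma_s}, \code{sigma_p},
#'   \code{n_t_hat}, \code{grid} (data.frame of phase-two evaluations),
#'   \code{phase1} (the phase-one optimum), \code{evaluations}.
#' @export
fit_parameters <- function(model_name = c("ds", "maxT", "maxL", "pfix"),
                           observed, seed = 1, replicates = 10,
                           n_interval = c(100, 1e5), param_interval = NULL,
                           sweeps = 4, grid_dim = 7, grid_span = 0.15,
                           coarse_dim = 5, coarse_replicates = 3,
                           n_chrom = 20, n_genes = 20000) {
  model_name <- match.arg(model_name)
  if (is.null(param_interval))
    param_interval <- switch(model_name, ds = c(0, 0.5), maxT = c(2, 500),
                             maxL = c(2, 500), pfix = c(1e-7, 1e-2))

  make_model <- function(param) {
    switch(model_name,
           ds = model_config("ds", mu = param),
           maxT = model_config("maxT", T_max = param),
           maxL = model_config("maxL", L_max = param),
           pfix = model_config("pfix", p_fix = param))
  }
  cache <- new.env(parent = emptyenv())
  evals <- 0L
  objective <- function(n, param, reps = replicates) {
    key <- paste(round(n), signif(param, 10), reps)
    if (!is.null(cache[[key]])) return(cache[[key]]$chi2)
    st <- chi_square(make_model(param), round(n), observed,
                     replicates = reps, seed = seed,
                     n_chrom = n_chrom, n_genes = n_genes)
    evals <<- evals + 1L
    cache[[key]] <- st
    st$chi2
  }

  # coarse localization: log-spaced grid over the brackets
  logseq <- function(lo, hi, k) exp(seq(log(lo), log(hi), length.out = k))
  n_pts <- logseq(max(n_interval[1], 1), n_interval[2], coarse_dim)
  p_lo <- if (param_interval[1] > 0) param_interval[1] else param_interval[2] / 100
  p_pts <- logseq(p_lo, param_interval[2], coarse_dim)
  coarse <- expand.grid(n = n_pts, param = p_pts)
  coarse$chi2 <- mapply(function(n, p) objective(n, p, coarse_replicates),
                        coarse$n, coarse$param)
  best <- which.min(coarse$chi2)
  n_hat <- coarse$n[best]
  param_hat <- coarse$param[best]

  # phase one: alternating Brent line minimizations over local brackets
  clamp <- function(x, iv) pmax(pmin(x, iv[2]), iv[1])
  for (sw in seq_len(sweeps)) {
    n_prev <- n_hat; p_prev <- param_hat
    n_br <- clamp(c(n_hat / 2.5, n_hat * 2.5), n_interval)
    n_hat <- stats::optimize(function(n) objective(n, param_hat),
                             n_br, tol = 0.01 * n_hat)$minimum
    p_br <- clamp(c(param_hat / 2.5, param_hat * 2.5), param_interval)
    param_hat <- stats::optimize(function(p) objective(n_hat, p),
                                 p_br, tol = 0.01 * param_hat)$minimum
    if (abs(n_hat - n_prev) < 0.02 * n_prev &&
        abs(param_hat - p_prev) < 0.02 * p_prev) break
  }
  phase1 <- c(n = round(n_hat), param = param_hat)

  ns <- round(seq(n_hat * (1 - grid_span), n_hat * (1 + grid_span),
                  length.out = grid_dim))
  ps <- seq(param_hat * (1 - grid_span), param_hat * (1 + grid_span),
            length.out = grid_dim)
  ps <- pmax(pmin(ps, param_interval[2]), param_interval[1])
  grid <- expand.grid(n = ns, param = ps)
  grid$chi2 <- mapply(objective, grid$n, grid$param)

  # fit in scaled coordinates for numerical balance
  sx <- (grid$n - n_hat) / max(n_hat, 1)
  sy <- (grid$param - param_hat) / max(abs(param_hat), 1e-12)
  qf <- fit_quadratic_surface(sx, sy, grid$chi2)
  if (qf$minimum && all(is.finite(qf$vertex)) &&
      all(abs(qf$vertex) <= 2 * grid_span)) {
    n_fit <- n_hat + qf$vertex[1] * max(n_hat, 1)
    param_fit <- param_hat + qf$vertex[2] * max(abs(param_hat), 1e-12)
  } else {
    warning("quadratic surface is not a local minimum; using grid argmin")
    best <- which.min(grid$chi2)
    n_fit <- grid$n[best]
    param_fit <- grid$param[best]
  }
  st <- cache[[paste(round(n_fit), signif(param_fit, 10), replicates)]]
  if (is.null(st))
    st <- chi_square(make_model(param_fit), round(n_fit), observed,
                     replicates = replicates, seed = seed,
                     n_chrom = n_chrom, n_genes = n_genes)
  structure(list(n_hat = round(n_fit), param_hat = param_fit,
                 chi2 = st$chi2, mean_s = st$mean_s, mean_p = st$mean_p,
                 sigma_s = st$sigma_s, sigma_p = st$sigma_p,
                 n_t_hat = st$mean_nt, grid = grid, phase1 = phase1,
                 evaluations = evals, model_name = model_name),
            class = "dcj_fit")
}

#' @export
print.dcj_fit <- function(x, ...) {
  cat(sprintf("dcj_fit (%s): n_hat = %d, param_hat = %.4g, chi2 = %.3g\n",
              x$model_name, x$n_hat, x$param_hat, x$chi2))
  cat(sprintf("  mean s = %.4g (sd %.2g), mean p = %.4g (sd %.2g), n_t = %.0f\n",
              x$mean_s, x$sigma_s, x$mean_p, x$sigma_p, x$n_t_hat))
  invisible(x)
}
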