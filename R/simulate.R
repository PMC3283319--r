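#' Configure a DCJ-[C] model
#'
#' The plain DCJ model accepts every proposed move. Each extension adds one
#' parameter: \code{ds} rejects moves that change the partition of sensitive
#' genes among chromosomes (the sensitive fraction \code{mu} is a property of
#' the starting genome, recorded here for fitting); \code{maxT} caps the size
#' of exchanged/excised fragments of inter-chromosomal moves at \code{T_max}
#' genes; \code{maxL} additionally caps inversion length at \code{L_max}
#' (and uses \code{L_max} for the inter-chromosomal caps); \code{pfix} accepts
#' gated inter-chromosomal moves with probability \code{p_fix}. Each model
#' reduces to plain DCJ at its limiting parameter value (\code{mu = 0},
#' \code{T_max = Inf}, \code{L_max = Inf}, \code{p_fix = 1}).
#'
#' @param name one of "dcj", "ds", "maxT", "maxL", "pfix".
#' @param mu sensitive-gene fraction used when initializing genomes for this
#'   model (meaningful for "ds"; kept for all models so that seeded runs are
#'   comparable).
#' @param T_max maximum exchanged/excised fragment size in genes ("maxT").
#' @param L_max maximum rearranged fragment size in genes ("maxL").
#' @param p_fix acceptance probability for gated moves ("pfix").
#' @param pfix_scope which classes the Bernoulli gate covers: "literal"
#'   (translocations and excisions) or "all" (every inter-chromosomal class).
#' @param telomeres are telomeric cut points proposable?
#' @param allow_fusion is the fusion of two linear chromosomes allowed? The
#'   default (FALSE) treats chromosome fusion as outside the model repertoire;
#'   circular-fragment fusions are always part of the repertoire.
#' @return A \code{dcj_model} list.
#' @examples
#' model_config("ds", mu = 0.07)
#' model_config("maxT", T_max = 20)
#' @export
model_config <- function(name = c("dcj", "ds", "maxT", "maxL", "pfix"),
                         mu = 0, T_max = Inf, L_max = Inf, p_fix = 1,
                         pfix_scope = c("literal", "all"),
                         telomeres = TRUE, allow_fusion = FALSE) {
  name <- match.arg(name)
  pfix_scope <- match.arg(pfix_scope)
  if (mu < 0 || mu > 1) stop("mu must be in [0, 1]")
  if (p_fix < 0 || p_fix > 1) stop("p_fix must be in [0, 1]")
  if (T_max < 0 || L_max < 0) stop("fragment-size caps must be non-negative")
  structure(list(name = name, mu = mu, T_max = T_max, L_max = L_max,
                 p_fix = p_fix, pfix_scope = pfix_scope,
                 telomeres = telomeres, allow_fusion = allow_fusion),
            class = "dcj_model")
}

#' @export
print.dcj_model <- function(x, ...) {
  param <- switch(x$name, dcj = "", ds = sprintf(", mu = %g", x$mu),
                  maxT = sprintf(", T_max = %g", x$T_max),
                  maxL = sprintf(", L_max = %g", x$L_max),
                  pfix = sprintf(", p_fix = %g (%s scope)", x$p_fix, x$pfix_scope))
  cat(sprintf("dcj_model: DCJ-%s%s\n",
              switch(x$name, dcj = "(plain)", ds = "DS", maxT = "maxT",
                     maxL = "maxL", pfix = "pfix"), param))
  invisible(x)
}

model_code <- function(model) {
  switch(model$name, dcj = 0L, ds = 1L, maxT = 2L, maxL = 3L, pfix = 4L)
}

model_param <- function(model) {
  switch(model$name, dcj = 0, ds = 0, maxT = model$T_max,
         maxL = model$L_max, pfix = model$p_fix)
}

#' Run a DCJ-[C] simulation
#'
#' Proposes DCJ moves by uniform cut-point sampling and accepts or rejects them
#' under the rules of \code{model} until \code{n} moves have been accepted and
#' applied. The starting genome is either given or initialized with
#' \code{init_genome(n_chrom, n_genes, model$mu)}. Runs are reproducible: with
#' the same seed, model and engine, results are bit-identical, and the "fast"
#' (order-statistic tree) and "naive" (plain list) engines consume the RNG
#' identically so they produce identical runs.
#'
#' @param model a \code{dcj_model} from \code{\link{model_config}}.
#' @param n number of accepted moves to apply.
#' @param n_chrom,n_genes starting genome dimensions (used when \code{genome}
#'   is NULL).
#' @param genome optional starting \code{dcj_genome}.
#' @param seed optional integer seed, applied before genome initialization.
#' @param engine "fast" (C++ order-statistic trees) or "naive" (reference R
#'   implementation).
#' @param checkpoints optional increasing vector of accepted-move counts at
#'   which genome snapshots are recorded.
#' @param max_proposals watchdog: abort if this many proposals fail to yield
#'   \code{n} acceptances (dead configurations, e.g. p_fix = 0 with no
#'   intra-chromosomal moves possible).
#' @return A \code{dcj_run} list: \code{start} and \code{end} genomes,
#'   \code{log} (accepted count \code{n}, inter-chromosomal count \code{n_t},
#'   per-class counts, proposal and rejection counts, and for the fast engine
#'   the mean/max depth of the chromosome trees), \code{snapshots} (list of
#'   \code{dcj_genome} at the checkpoints), and \code{model}.
#' @examples
#' run <- run_simulation(model_config("dcj"), n = 50, n_chrom = 4,
#'                       n_genes = 200, seed = 1)
#' run$log$n_t
#' @export
run_simulation <- function(model, n, n_chrom = 20, n_genes = 20000,
                           genome = NULL, seed = NULL,
                           engine = c("fast", "naive"),
                           checkpoints = NULL, max_proposals = 1e9) {
  engine <- match.arg(engine)
  if (n < 0) stop("n must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(genome)) genome <- init_genome(n_chrom, n_genes, model$mu)
  start <- genome
  checkpoints <- as.integer(sort(unique(checkpoints)))
  checkpoints <- checkpoints[checkpoints >= 1 & checkpoints <= n]
  if (engine == "fast") {
    res <- .dcj_run_cpp(genome$chromosomes, genome$circular, genome$sensitive,
                        model_code(model), model_param(model), n,
                        checkpoints, model$telomeres, model$allow_fusion,
                        model$pfix_scope == "all", max_proposals)
    end <- new_dcj_genome(res$genome$chromosomes, res$genome$circular,
                          genome$sensitive, genome$ancestral)
    snaps <- lapply(res$snapshots, function(s) {
      if (is.null(s)) return(NULL)
      new_dcj_genome(s$chromosomes, s$circular, genome$sensitive,
                     genome$ancestral)
    })
    log <- res$log
    log$by_class <- stats::setNames(as.integer(log$by_class),
                                    names(log$by_class))
  } else {
    res <- run_naive_engine(genome, model, n, checkpoints, max_proposals)
    end <- res$genome
    snaps <- res$snapshots
    log <- res$log
  }
  names(snaps) <- as.character(checkpoints)
  structure(list(start = start, end = end, log = log, snapshots = snaps,
                 model = model),
            class = "dcj_run")
}

#' @export
print.dcj_run <- function(x, ...) {
  cat(sprintf("dcj_run: %s, %d accepted moves (%d inter-chromosomal) in %s proposals\n",
              x$model$name, as.integer(x$log$n), as.integer(x$log$n_t),
              format(x$log$proposed, big.mark = ",")))
  print(x$log$by_class)
  invisible(x)
}
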