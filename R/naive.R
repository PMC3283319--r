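# Naive list-based DCJ engine. This is the reference implementation: every
# operation works directly on the dcj_genome list structure with ordinary
# vector splicing, so its behaviour can be read off the code. The fast
# order-statistic tree engine (src/dcj.cpp) must reproduce it draw-for-draw:
# both consume the RNG in the order documented in propose_move().

#' Propose a DCJ move by uniform cut-point sampling
#'
#' Draws two distinct cut points uniformly from all cut positions of the
#' genome and a rejoin choice uniformly from the two non-identity
#' reconnections. Cut positions are the gaps between consecutive genes of each
#' chromosome; for linear chromosomes the two telomeric ends are included when
#' \code{telomeres = TRUE}. RNG draw order: position 1, position 2 (redrawn
#' until distinct from position 1), rejoin bit. If the drawn rejoin is the
#' identity reconnection (possible when cuts are telomeric), the other rejoin
#' is used.
#'
#' @param genome a \code{dcj_genome}.
#' @param telomeres are telomeric cut points proposable?
#' @return A \code{dcj_move}: list with \code{chrom1}, \code{gap1},
#'   \code{chrom2}, \code{gap2} (gap indices are 0-based; on a linear
#'   chromosome of L genes, gap 0 and gap L are the telomeres; on a circular
#'   fragment gap 0 sits between the last and first gene), \code{rejoin}
#'   (0 or 1) and \code{class}.
#' @export
propose_move <- function(genome, telomeres = TRUE) {
  counts <- cut_position_counts(genome, telomeres)
  K <- sum(counts)
  if (K < 2) stop("genome has fewer than two cut points")
  cum <- cumsum(counts)
  p1 <- floor(stats::runif(1) * K)
  repeat {
    p2 <- floor(stats::runif(1) * K)
    if (p2 != p1) break
  }
  if (p2 < p1) { tmp <- p1; p1 <- p2; p2 <- tmp }
  loc1 <- locate_position(genome, p1, cum, telomeres)
  loc2 <- locate_position(genome, p2, cum, telomeres)
  r <- if (stats::runif(1) < 0.5) 0L else 1L
  build_move(genome, loc1$k, loc1$g, loc2$k, loc2$g, r)
}

cut_position_counts <- function(genome, telomeres = TRUE) {
  lens <- lengths(genome$chromosomes)
  ifelse(genome$circular, lens, if (telomeres) lens + 1L else lens - 1L)
}

locate_position <- function(genome, pos, cum, telomeres) {
  k <- findInterval(pos, cum) + 1L
  g <- as.integer(pos - (if (k > 1L) cum[k - 1L] else 0L))
  if (!genome$circular[k] && !telomeres) g <- g + 1L
  list(k = k, g = g)
}

# Resolve a raw (chrom, gap, chrom, gap, rejoin) tuple into a classified move.
# Swaps the identity rejoin for the other reconnection where applicable.
build_move <- function(genome, k1, g1, k2, g2, rejoin) {
  if (k1 > k2 || (k1 == k2 && g1 > g2)) {
    tmp <- k1; k1 <- k2; k2 <- tmp
    tmp <- g1; g1 <- g2; g2 <- tmp
  }
  lens <- lengths(genome$chromosomes)
  circ <- genome$circular
  cls <- NULL
  identity_move <- FALSE
  if (k1 == k2) {
    if (g1 == g2) stop("cut points coincide")
    if (rejoin == 0L) cls <- "inversion"
    else cls <- if (circ[k1]) "fission" else "excision"
  } else if (!circ[k1] && !circ[k2]) {
    ea <- g1 == 0L; eb <- g1 == lens[k1]
    ec <- g2 == 0L; ed <- g2 == lens[k2]
    id0 <- (ea && ec) || (eb && ed)
    id1 <- (ea && ed) || (eb && ec)
    if (rejoin == 0L && id0) rejoin <- 1L
    else if (rejoin == 1L && id1) rejoin <- 0L
    identity_move <- (rejoin == 0L && id0) || (rejoin == 1L && id1)
    is_fusion <- if (rejoin == 0L) (ea && ed) || (eb && ec)
                 else (ea && ec) || (eb && ed)
    cls <- if (is_fusion) "fusion" else "translocation"
  } else if (circ[k1] && circ[k2]) {
    cls <- "fusion"
  } else {
    cls <- "reintegration"
  }
  structure(list(chrom1 = k1, gap1 = g1, chrom2 = k2, gap2 = g2,
                 rejoin = as.integer(rejoin), class = cls,
                 identity = identity_move),
            class = "dcj_move")
}

#' Classify a DCJ move
#'
#' The move class is a pure function of the two cut points, the rejoin choice
#' and chromosome topology: \code{inversion} (two cuts on one chromosome,
#' reversing rejoin), \code{excision} (two cuts on one linear chromosome,
#' circularizing rejoin), \code{fission} (circular fragment split in two),
#' \code{translocation} (cuts on two linear chromosomes), \code{fusion} (two
#' telomeric cuts joining two linear chromosomes, or two circular fragments
#' merging), \code{reintegration} (circular fragment inserted into a linear
#' chromosome).
#'
#' @param genome a \code{dcj_genome}.
#' @param move a \code{dcj_move}, or the raw fields via \code{...}.
#' @return character scalar, the move class.
#' @export
classify_move <- function(genome, move) {
  build_move(genome, move$chrom1, move$gap1, move$chrom2, move$gap2,
             move$rejoin)$class
}

#' Acceptance rules of the constrained DCJ models
#'
#' \code{accept_move} evaluates whether \code{model} accepts \code{move} on
#' \code{genome}. \code{accept_ds}, \code{accept_maxT}, \code{accept_maxL} and
#' \code{accept_pfix} are convenience wrappers for single rules.
#'
#' Under the dosage-sensitivity rule the partition of sensitive genes among
#' (linear) chromosomes must be unchanged: inversions always pass; a
#' translocation passes if the fragment pair staying together on each product
#' chromosome isolates all sensitive genes (one side of each breakpoint free of
#' sensitive genes before and after); an excision passes if the excised
#' fragment carries no sensitive gene; a reintegration passes if the circular
#' fragment carries none. Under the maximum-fragment rules, a translocation
#' passes if one exchanged-fragment pair is at most \code{T_max} genes and an
#' excision if the excised fragment is; the inversion-length cap applies only
#' to \code{maxL}. Under Bernoulli thinning, gated classes pass a trial with
#' success probability \code{p_fix} (one RNG draw, made only when
#' \code{p_fix < 1}).
#'
#' @param genome a \code{dcj_genome}.
#' @param move a \code{dcj_move}.
#' @param model a \code{dcj_model} from \code{\link{model_config}}.
#' @param T_max,L_max,p_fix single-rule parameters for the wrappers.
#' @return TRUE or FALSE.
#' @export
accept_move <- function(genome, move, model) {
  lens <- lengths(genome$chromosomes)
  k1 <- move$chrom1; g1 <- move$gap1
  k2 <- move$chrom2; g2 <- move$gap2
  cls <- move$class
  sens_in <- function(k, i, j) {
    if (j <= i) return(0L)
    sum(genome$sensitive[abs(genome$chromosomes[[k]][(i + 1L):j])])
  }
  switch(model$name,
    dcj = TRUE,
    ds = {
      if (cls == "inversion" || cls == "fission") TRUE
      else if (cls == "excision") sens_in(k1, g1, g2) == 0L
      else if (cls == "reintegration") {
        kc <- if (genome$circular[k1]) k1 else k2
        sens_in(kc, 0L, lens[kc]) == 0L
      } else if (cls == "fusion" && genome$circular[k1]) TRUE
      else { # translocation or linear fusion
        af <- sens_in(k1, 0L, g1) == 0L
        bf <- sens_in(k1, g1, lens[k1]) == 0L
        cf <- sens_in(k2, 0L, g2) == 0L
        df <- sens_in(k2, g2, lens[k2]) == 0L
        if (move$rejoin == 0L) (af && cf) || (bf && df)
        else (bf && cf) || (af && df)
      }
    },
    maxT = ,
    maxL = {
      Tm <- if (model$name == "maxT") model$T_max else model$L_max
      if (cls == "inversion")
        model$name == "maxT" || (g2 - g1) <= Tm
      else if (cls == "excision") (g2 - g1) <= Tm
      else if (cls %in% c("fission", "reintegration")) TRUE
      else if (cls == "fusion" && genome$circular[k1]) TRUE
      else {
        la <- g1; lb <- lens[k1] - g1; lc <- g2; ld <- lens[k2] - g2
        if (move$rejoin == 0L) (la <= Tm && lc <= Tm) || (lb <= Tm && ld <= Tm)
        else (lb <= Tm && lc <= Tm) || (la <= Tm && ld <= Tm)
      }
    },
    pfix = {
      gated <- if (model$pfix_scope == "all") cls != "inversion"
               else cls %in% c("translocation", "excision")
      if (!gated || model$p_fix >= 1) TRUE
      else stats::runif(1) < model$p_fix
    },
    stop("unknown model: ", model$name))
}

#' @rdname accept_move
#' @export
accept_ds <- function(genome, move)
  accept_move(genome, move, model_config("ds"))

#' @rdname accept_move
#' @export
accept_maxT <- function(genome, move, T_max)
  accept_move(genome, move, model_config("maxT", T_max = T_max))

#' @rdname accept_move
#' @export
accept_maxL <- function(genome, move, L_max)
  accept_move(genome, move, model_config("maxL", L_max = L_max))

#' @rdname accept_move
#' @export
accept_pfix <- function(genome, move, p_fix)
  accept_move(genome, move, model_config("pfix", p_fix = p_fix))

#' Apply a DCJ move to a genome
#'
#' Returns the rearranged genome. Gene content is conserved; only adjacencies
#' at the two cut points change. Empty chromosomes are dropped; a newly excised
#' circular fragment is appended after the existing chromosomes.
#'
#' @param genome a \code{dcj_genome}.
#' @param move a \code{dcj_move} (see \code{\link{propose_move}}).
#' @return The rearranged \code{dcj_genome}.
#' @export
apply_move <- function(genome, move) {
  chrom <- genome$chromosomes
  circ <- genome$circular
  k1 <- move$chrom1; g1 <- move$gap1
  k2 <- move$chrom2; g2 <- move$gap2
  r <- move$rejoin
  rc <- function(v) if (length(v)) -rev(v) else integer(0)
  slice <- function(v, i, j) if (j > i) v[(i + 1L):j] else integer(0)
  open_circ <- function(v, g) if (g == 0L) v else c(slice(v, g, length(v)), v[seq_len(g)])
  switch(move$class,
    inversion = {
      v <- chrom[[k1]]
      chrom[[k1]] <- c(slice(v, 0L, g1), rc(slice(v, g1, g2)),
                       slice(v, g2, length(v)))
    },
    excision = ,
    fission = {
      v <- chrom[[k1]]
      chrom[[k1]] <- c(slice(v, 0L, g1), slice(v, g2, length(v)))
      chrom[[length(chrom) + 1L]] <- slice(v, g1, g2)
      circ <- c(circ, TRUE)
    },
    translocation = ,
    fusion = {
      if (circ[k1] && circ[k2]) {
        e1 <- open_circ(chrom[[k1]], g1)
        e2 <- open_circ(chrom[[k2]], g2)
        if (r == 1L) e2 <- rc(e2)
        chrom[[k1]] <- c(e1, e2)
        chrom[[k2]] <- integer(0)
      } else {
        v1 <- chrom[[k1]]; v2 <- chrom[[k2]]
        a <- slice(v1, 0L, g1); b <- slice(v1, g1, length(v1))
        cc <- slice(v2, 0L, g2); d <- slice(v2, g2, length(v2))
        if (r == 0L) { chrom[[k1]] <- c(a, d); chrom[[k2]] <- c(cc, b) }
        else { chrom[[k1]] <- c(a, rc(cc)); chrom[[k2]] <- c(rc(b), d) }
      }
    },
    reintegration = {
      kc <- if (circ[k1]) k1 else k2
      kl <- if (circ[k1]) k2 else k1
      gc_ <- if (circ[k1]) g1 else g2
      gl <- if (circ[k1]) g2 else g1
      e <- open_circ(chrom[[kc]], gc_)
      if (r == 1L) e <- rc(e)
      vl <- chrom[[kl]]
      chrom[[kl]] <- c(slice(vl, 0L, gl), e, slice(vl, gl, length(vl)))
      chrom[[kc]] <- integer(0)
    },
    stop("unknown move class: ", move$class))
  keep <- lengths(chrom) > 0L
  new_dcj_genome(chrom[keep], circ[keep], genome$sensitive, genome$ancestral)
}

# Naive simulation loop: proposes, gates, applies, mirroring the RNG draw
# order of the fast engine exactly. Used as the oracle in tests.
run_naive_engine <- function(genome, model, n, checkpoints = integer(0),
                             max_proposals = 1e9) {
  acc <- 0
  prop <- 0
  classes <- c("inversion", "translocation", "excision", "reintegration",
               "fission", "fusion")
  by_class <- stats::setNames(integer(6), classes)
  rej_model <- 0; rej_fusion <- 0
  snaps <- vector("list", length(checkpoints))
  cp_i <- 1L
  while (acc < n) {
    prop <- prop + 1
    if (prop > max_proposals)
      stop("proposal budget exceeded: acceptance may be impossible")
    move <- propose_move(genome, telomeres = model$telomeres)
    if (move$identity) next
    if (move$class == "fusion" && !genome$circular[move$chrom1] &&
        !model$allow_fusion) {
      rej_fusion <- rej_fusion + 1
      next
    }
    if (!accept_move(genome, move, model)) {
      rej_model <- rej_model + 1
      next
    }
    genome <- apply_move(genome, move)
    acc <- acc + 1
    by_class[move$class] <- by_class[move$class] + 1L
    if (cp_i <= length(checkpoints) && acc == checkpoints[cp_i]) {
      snaps[[cp_i]] <- genome
      cp_i <- cp_i + 1L
    }
  }
  nt <- sum(by_class[classes != "inversion"])
  list(genome = genome,
       log = list(n = acc, n_t = nt, by_class = by_class, proposed = prop,
                  rejected_model = rej_model,
                  rejected_fusion_disabled = rej_fusion),
       snapshots = snaps)
}
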