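#' Simulate genome evolution on a star phylogeny
#'
#' Evolves \code{leaves} independent lineages from one shared root genome, each
#' for \code{n_branch} accepted moves (so any two leaves are separated by
#' \code{2 * n_branch} moves). For the dosage-sensitivity model the sensitive
#' gene set can be shared across branches (the model's defining correlation
#' mechanism) or redrawn independently per branch at the same fraction, which
#' preserves the per-branch rearrangement dynamics but destroys the
#' between-lineage correlation.
#'
#' @param model a \code{dcj_model}.
#' @param n_branch accepted moves per branch.
#' @param leaves number of lineages.
#' @param shared_sensitive share one sensitive-gene set across branches?
#' @param n_chrom,n_genes root genome dimensions.
#' @param seed optional integer seed.
#' @param engine simulation engine.
#' @return List with \code{root} (\code{dcj_genome}) and \code{leaves} (list of
#'   \code{dcj_genome}).
#' @export
simulate_star <- function(model, n_branch, leaves = 5, shared_sensitive = TRUE,
                          n_chrom = 20, n_genes = 20000, seed = NULL,
                          engine = "fast") {
  if (!is.null(seed)) set.seed(seed)
  root <- init_genome(n_chrom, n_genes, model$mu)
  leaf_list <- vector("list", leaves)
  for (i in seq_len(leaves)) {
    g <- root
    if (!shared_sensitive)
      g$sensitive <- stats::runif(g$N) < model$mu
    run <- run_simulation(model, n = n_branch, genome = g, engine = engine)
    leaf_list[[i]] <- run$end
  }
  list(root = root, leaves = leaf_list)
}

#' Simulate genome evolution along a phylogenetic tree
#'
#' Recursively evolves a root genome along every branch of a rooted tree; each
#' internal node passes its genome to its child branches. Branch lengths are
#' accepted-move counts (rounded).
#'
#' @param tree an \code{ape::phylo} tree with edge lengths in accepted moves.
#' @param model a \code{dcj_model}.
#' @param shared_sensitive share one sensitive set across the whole tree, or
#'   redraw independently for each branch?
#' @param n_chrom,n_genes root genome dimensions.
#' @param seed optional integer seed.
#' @param engine simulation engine.
#' @return List with \code{root} and \code{leaves} (named by tip labels).
#' @export
simulate_along_tree <- function(tree, model, shared_sensitive = TRUE,
                                n_chrom = 20, n_genes = 20000, seed = NULL,
                                engine = "fast") {
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (!is.null(seed)) set.seed(seed)
  root_genome <- init_genome(n_chrom, n_genes, model$mu)
  ntip <- length(tree$tip.label)
  root_node <- ntip + 1L
  leaves <- vector("list", ntip)
  evolve <- function(node, genome) {
    kids <- which(tree$edge[, 1] == node)
    for (e in kids) {
      child <- tree$edge[e, 2]
      g <- genome
      if (!shared_sensitive)
        g$sensitive <- stats::runif(g$N) < model$mu
      run <- run_simulation(model, n = round(tree$edge.length[e]),
                            genome = g, engine = engine)
      if (child <= ntip) leaves[[child]] <<- run$end
      else evolve(child, run$end)
    }
  }
  evolve(root_node, root_genome)
  names(leaves) <- tree$tip.label
  list(root = root_genome, leaves = leaves)
}

#' Count marker families with conserved macro-synteny in all leaves
#'
#' Samples \code{n_families} marker genes and counts how many retain conserved
#' chromosomal context in every leaf. In simulation the ancestral truth is
#' known, so conservation in a leaf is judged exactly as in
#' \code{\link{macro_synteny_p}} for the root-leaf pair: the marker's (root
#' chromosome, leaf PAL) pair must be a homologous pair under the z-score best
#' match. With \code{reference = "pairwise"} a marker instead counts as
#' conserved when all leaf-leaf pairs agree, which is the criterion available
#' for real data without ancestral truth.
#'
#' @param root the ancestral \code{dcj_genome}.
#' @param leaves list of leaf \code{dcj_genome}s.
#' @param n_families number of marker families to sample.
#' @param seed optional integer seed for the marker sample.
#' @param markers optional explicit marker ids (overrides sampling).
#' @param reference "root" (default) or "pairwise".
#' @param direction homology direction, see \code{\link{macro_synteny_p}}.
#' @return List: \code{k_conserved}, \code{n_families}, \code{markers},
#'   \code{per_leaf} (conserved fraction per leaf).
#' @export
count_multiway_conserved <- function(root, leaves, n_families = 1144,
                                     seed = NULL, markers = NULL,
                                     reference = c("root", "pairwise"),
                                     direction = "union") {
  reference <- match.arg(reference)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(markers)) markers <- sample_markers(root, n_families)
  n_fam <- length(markers)
  conserved_pair <- function(a, b) {
    hom <- pal_homology(a, b, markers)
    pal_a <- hom$pal_a; pal_b <- hom$pal_b
    keep <- !is.na(pal_a) & !is.na(pal_b)
    ca <- as.character(pal_a)
    cons <- keep & !is.na(hom$best_ab[ca]) & (pal_b == hom$best_ab[ca])
    if (direction == "union") {
      cb <- as.character(pal_b)
      cons <- cons | (keep & !is.na(hom$best_ba[cb]) & (pal_a == hom$best_ba[cb]))
    }
    cons & !is.na(cons)
  }
  if (reference == "root") {
    per <- vapply(leaves, function(lf) conserved_pair(root, lf),
                  logical(n_fam))
  } else {
    combos <- utils::combn(length(leaves), 2)
    per <- apply(combos, 2, function(ij)
      conserved_pair(leaves[[ij[1]]], leaves[[ij[2]]]))
  }
  all_cons <- rowSums(per) == ncol(per)
  list(k_conserved = sum(all_cons), n_families = n_fam, markers = markers,
       per_leaf = colMeans(per))
}

#' Expected multi-way conservation under independent gene movement
#'
#' Under a star phylogeny in which each gene is retained on its homologous
#' chromosome independently along each of \code{k} branches with probability
#' q, a pairwise comparison conserves a gene with probability q^2; reading q
#' from the mean observed pairwise conservation \code{q = sqrt(mean(p))}, the
#' expected number of families conserved in all \code{k} leaves is
#' \code{n_families * q^k}.
#'
#' @param p_values pairwise macro-synteny conservation values in (0, 1].
#' @param k number of leaves.
#' @param n_families total family count.
#' @return Expected count (not rounded).
#' @examples
#' expected_independent(observed_pairs()$p, k = 5, n_families = 1144)
#' @export
expected_independent <- function(p_values, k = 5, n_families = 1144) {
  if (length(p_values) == 0) stop("no p values given")
  if (any(p_values <= 0 | p_values > 1)) stop("p values must be in (0, 1]")
  q <- sqrt(mean(p_values))
  n_families * q^k
}

#' Replicate distribution of multi-way conserved families
#'
#' Repeats a star-phylogeny experiment and returns the per-replicate conserved
#' counts for the shared and/or independent sensitive-set conditions. With
#' \code{pool_realizations} set, a pool of that many branch realizations is
#' simulated once from a common root, and each replicate draws \code{leaves}
#' of them at random without replacement — an economical protocol for models
#' whose branches are exchangeable given the root (all models in the shared
#' condition; for "independent" the sensitive set is redrawn per realization).
#'
#' @param model a \code{dcj_model} (typically "ds").
#' @param n_branch accepted moves per branch.
#' @param replicates replicate experiments per condition.
#' @param conditions subset of c("shared", "independent").
#' @param leaves,n_families,n_chrom,n_genes experiment dimensions.
#' @param seed base seed.
#' @param engine simulation engine.
#' @param pool_realizations optional pool size (e.g. 100); NULL simulates
#'   fresh leaves for every replicate.
#' @return data.frame with columns \code{condition}, \code{replicate},
#'   \code{k_conserved}.
#' @export
multiway_distribution <- function(model, n_branch, replicates = 20,
                                  conditions = c("shared", "independent"),
                                  leaves = 5, n_families = 1144,
                                  n_chrom = 20, n_genes = 20000, seed = 1,
                                  engine = "fast", pool_realizations = NULL) {
  out <- list()
  i <- 0L
  if (is.null(pool_realizations)) {
    seeds <- replicate_seeds(seed, replicates * length(conditions))
    for (cond in conditions) {
      for (r in seq_len(replicates)) {
        i <- i + 1L
        sim <- simulate_star(model, n_branch, leaves = leaves,
                             shared_sensitive = (cond == "shared"),
                             n_chrom = n_chrom, n_genes = n_genes,
                             seed = seeds[i], engine = engine)
        cnt <- count_multiway_conserved(sim$root, sim$leaves,
                                        n_families = min(n_families, n_genes))
        out[[i]] <- data.frame(condition = cond, replicate = r,
                               k_conserved = cnt$k_conserved)
      }
    }
  } else {
    seeds <- replicate_seeds(seed, length(conditions))
    for (ci in seq_along(conditions)) {
      cond <- conditions[ci]
      sim <- simulate_star(model, n_branch, leaves = pool_realizations,
                           shared_sensitive = (cond == "shared"),
                           n_chrom = n_chrom, n_genes = n_genes,
                           seed = seeds[ci], engine = engine)
      for (r in seq_len(replicates)) {
        i <- i + 1L
        pick <- sample.int(pool_realizations, leaves)
        cnt <- count_multiway_conserved(sim$root, sim$leaves[pick],
                                        n_families = min(n_families, n_genes))
        out[[i]] <- data.frame(condition = cond, replicate = r,
                               k_conserved = cnt$k_conserved)
      }
    }
  }
  do.call(rbind, out)
}
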