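#' Rarefy an ASV table to a common depth
#'
#' Subsamples each sample's reads without replacement so every retained
#' sample sums exactly to `depth`. Samples with fewer total reads than
#' `depth` are dropped with a warning (rather than erroring), since the
#' intended use rarefies to the minimum observed depth. Seeded and
#' deterministic.
#'
#' @param counts samples x ASVs integer matrix
#' @param depth target depth; the protocol default is 1,604 reads
#' @param seed integer seed
#' @return rarefied integer matrix (possibly with fewer rows)
#' @export
rarefy <- function(counts, depth = 1604, seed = 1) {
  if (depth <= 0) stop("depth must be positive")
  stop_if_not_count_matrix(counts)
  tot <- rowSums(counts)
  drop <- tot < depth
  if (any(drop))
    warning(sprintf("dropping %d sample(s) below depth %d: %s",
                    sum(drop), depth,
                    paste(rownames(counts)[drop], collapse = ", ")))
  keep <- counts[!drop, , drop = FALSE]
  set.seed(derive_seed(seed, "rarefy"))
  out <- keep
  for (s in seq_len(nrow(keep))) {
    row <- keep[s, ]
    if (sum(row) == depth) next
    pool <- rep.int(seq_along(row), row)
    sel <- sample(pool, depth, replace = FALSE)
    out[s, ] <- tabulate(sel, nbins = length(row))
  }
  storage.mode(out) <- "integer"
  out
}

#' Alpha diversity: observed ASVs, Shannon, Pielou, Faith's PD
#'
#' Shannon entropy uses natural logarithms (nats), so Pielou's evenness is
#' H / ln(observed); it is defined as 0 for single-ASV samples. Faith's PD
#' is the total branch length of the subtree spanning the root and all
#' present tips (rooted convention: the path to the root is included).
#'
#' @param counts samples x ASVs matrix
#' @param tree rooted `phylo`; required for `faith_pd`, may be NULL to skip
#' @return data.frame with columns observed, shannon, pielou, faith_pd
#' @export
alpha_diversity <- function(counts, tree = NULL) {
  if (any(rowSums(counts) == 0))
    stop("empty sample(s): ",
         paste(rownames(counts)[rowSums(counts) == 0], collapse = ", "))
  p <- relative_abundance(counts)
  observed <- rowSums(counts > 0)
  shannon <- apply(p, 1L, function(v) { v <- v[v > 0]; -sum(v * log(v)) })
  pielou <- ifelse(observed > 1, shannon / log(observed), 0)
  fpd <- rep(NA_real_, nrow(counts))
  if (!is.null(tree)) {
    et <- .edge_tip_matrix(tree, colnames(counts))
    obs_edges <- (et$M %*% .presence_by_tip(counts, et)) > 0  # edges x samples
    fpd <- as.numeric(crossprod(obs_edges, et$len))
  }
  data.frame(observed = observed, shannon = shannon, pielou = pielou,
             faith_pd = fpd, row.names = rownames(counts))
}

# edge x tip incidence of a rooted tree, restricted/ordered to asv_ids;
# M[e, t] is TRUE when tip t descends through edge e
.edge_tip_matrix <- function(tree, asv_ids) {
  miss <- setdiff(asv_ids, tree$tip.label)
  if (length(miss))
    stop("tree lacks tips for: ", paste(utils::head(miss, 5), collapse = ", "))
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  below <- matrix(FALSE, nnode, ntip)
  below[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
    below[par, ] <- below[par, ] | below[child, ]
  }
  M <- below[tr$edge[, 2L], , drop = FALSE]
  len <- tr$edge.length
  if (is.null(len)) stop("tree has no branch lengths")
  list(M = M, len = len, tip_index = match(asv_ids, tr$tip.label),
       tree = tr)
}

# tips x samples presence indicator in tree-tip order; tips without a
# matching ASV column count as absent
.presence_by_tip <- function(counts, et) {
  pres <- matrix(FALSE, ncol(et$M), nrow(counts))
  pres[et$tip_index, ] <- t(counts > 0)
  pres
}

#' Jaccard distance on presence/absence
#'
#' d = 1 - |A intersect B| / |A union B| over the presence sets of each
#' sample pair; intended for rarefied tables.
#'
#' @param counts samples x ASVs matrix (rarefied)
#' @return symmetric distance matrix with zero diagonal
#' @export
beta_jaccard <- function(counts) {
  pres <- counts > 0
  if (any(rowSums(pres) == 0)) stop("sample(s) with empty presence set")
  shared <- tcrossprod(pres * 1)
  sizes <- rowSums(pres)
  union <- outer(sizes, sizes, "+") - shared
  d <- 1 - shared / union
  diag(d) <- 0
  dimnames(d) <- list(rownames(counts), rownames(counts))
  validate_distance_matrix(d)
}

#' Unweighted UniFrac distance
#'
#' For each sample pair, the fraction of observed branch length (branches
#' lying on a root-to-tip path of at least one present tip in either
#' sample) that is unique to one of the two samples.
#'
#' @param counts samples x ASVs matrix (rarefied)
#' @param tree rooted `phylo` covering the ASVs
#' @return symmetric distance matrix in [0, 1]
#' @export
beta_unifrac_unweighted <- function(counts, tree) {
  pres <- counts > 0
  if (any(rowSums(pres) == 0)) stop("sample(s) with empty presence set")
  et <- .edge_tip_matrix(tree, colnames(counts))
  obs <- (et$M %*% .presence_by_tip(counts, et)) > 0  # edges x samples
  n <- nrow(counts)
  d <- matrix(0, n, n, dimnames = list(rownames(counts), rownames(counts)))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    u <- obs[, i] | obs[, j]
    s <- obs[, i] & obs[, j]
    d[i, j] <- d[j, i] <- sum(et$len[u & !s]) / sum(et$len[u])
  }
  validate_distance_matrix(d)
}

#' Centered log-ratio transform
#'
#' @param counts samples x features matrix
#' @param pseudocount added to every count before closure (default 1)
#' @return matrix of CLR coordinates (rows sum to 0)
#' @export
clr_transform <- function(counts, pseudocount = 1) {
  x <- counts + pseudocount
  if (any(x <= 0)) stop("matrix not strictly positive after pseudocount")
  lx <- log(x)
  lx - rowMeans(lx)
}

#' Aitchison distance
#'
#' Euclidean distance between CLR-transformed compositions of the
#' unrarefied table; invariant to per-sample total count scaling.
#'
#' @inheritParams clr_transform
#' @return symmetric distance matrix
#' @export
beta_aitchison <- function(counts, pseudocount = 1) {
  z <- clr_transform(counts, pseudocount)
  d <- as.matrix(stats::dist(z))
  diag(d) <- 0
  validate_distance_matrix(d)
}

#' PhILR-transformed Euclidean distance
#'
#' Builds isometric log-ratio balances from the rooted tree's sequential
#' binary partition (one balance per internal node, contrasting the
#' geometric means of the two child clades; unit taxon and branch weights)
#' and returns Euclidean distances between samples in balance space.
#' Non-bifurcating trees are resolved internally with zero-length edges
#' and reported via a message.
#'
#' @param counts samples x ASVs matrix (unrarefied)
#' @param tree rooted `phylo` whose tips cover the ASVs
#' @param pseudocount added before closure
#' @return symmetric distance matrix
#' @export
philr_euclidean <- function(counts, tree, pseudocount = 1) {
  b <- philr_balances(counts, tree, pseudocount)
  d <- as.matrix(stats::dist(b))
  diag(d) <- 0
  validate_distance_matrix(d)
}

#' @rdname philr_euclidean
#' @return `philr_balances`: samples x internal-node matrix of ILR balances
#' @export
philr_balances <- function(counts, tree, pseudocount = 1) {
  if (!ape::is.binary(tree)) {
    message("resolving multifurcations with zero-length edges for PhILR")
    tree <- ape::multi2di(tree, random = FALSE)
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  tree <- ape::drop.tip(tree, setdiff(tree$tip.label, colnames(counts)))
  x <- counts[, tree$tip.label, drop = FALSE] + pseudocount
  if (any(x <= 0)) stop("matrix not strictly positive after pseudocount")
  p <- x / rowSums(x)
  lp <- log(p)
  ntip <- length(tree$tip.label)
  below <- .edge_tip_matrix(tree, tree$tip.label)
  tr <- below$tree
  # children of each internal node in the postorder-edge representation
  balances <- matrix(0, nrow(counts), tr$Nnode,
                     dimnames = list(rownames(counts), NULL))
  node_tips <- matrix(FALSE, ntip + tr$Nnode, ntip)
  node_tips[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  for (e in seq_len(nrow(tr$edge)))
    node_tips[tr$edge[e, 1L], ] <- node_tips[tr$edge[e, 1L], ] |
      node_tips[tr$edge[e, 2L], ]
  lp <- lp[, tr$tip.label, drop = FALSE]
  for (v in seq_len(tr$Nnode)) {
    node <- ntip + v
    ch <- tr$edge[tr$edge[, 1L] == node, 2L]
    L <- node_tips[ch[1L], ]; R <- node_tips[ch[2L], ]
    r <- sum(L); s <- sum(R)
    gl <- if (r > 1) rowMeans(lp[, L, drop = FALSE]) else lp[, L]
    gr <- if (s > 1) rowMeans(lp[, R, drop = FALSE]) else lp[, R]
    balances[, v] <- sqrt(r * s / (r + s)) * (gl - gr)
  }
  balances
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers the squared distance matrix and eigendecomposes it.
#' Negative eigenvalues (from non-Euclidean distances) are reported but
#' their axes are excluded; proportions of inertia are computed over the
#' positive eigenvalues only.
#'
#' @param dm symmetric distance matrix
#' @return list with `coordinates` (samples x axes), `eigenvalues`
#'   (all, sorted descending), `proportion` (per retained axis)
#' @export
pcoa <- function(dm) {
  validate_distance_matrix(dm)
  n <- nrow(dm)
  d2 <- dm^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% d2 %*% J
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  ev <- eg$values
  pos <- which(ev > max(ev, 0) * 1e-10)
  coords <- eg$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(ev[pos]), nrow = length(pos))
  rownames(coords) <- rownames(dm)
  colnames(coords) <- if (length(pos)) sprintf("Axis%d", seq_along(pos))
    else character(0)
  prop <- if (length(pos)) ev[pos] / sum(ev[pos]) else numeric(0)
  list(coordinates = coords, eigenvalues = ev, proportion = prop,
       negative_eigenvalues = sum(ev < 0))
}
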