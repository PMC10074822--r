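# Independent brute-force oracles used across the suite. These stay naive
# on purpose: enumeration and double loops, no shared code with R/.

# unweighted UniFrac via root-to-tip path enumeration with ape::nodepath
oracle_unifrac <- function(tree, tips1, tips2) {
  root <- length(tree$tip.label) + 1L
  path_edges <- function(tips) {
    edges <- character(0)
    for (tp in tips) {
      nodes <- ape::nodepath(tree, root, match(tp, tree$tip.label))
      for (k in seq_len(length(nodes) - 1L))
        edges <- c(edges, paste(nodes[k], nodes[k + 1L]))
    }
    unique(edges)
  }
  key <- paste(tree$edge[, 1L], tree$edge[, 2L])
  e1 <- path_edges(tips1); e2 <- path_edges(tips2)
  u <- union(e1, e2)
  uniq <- setdiff(u, intersect(e1, e2))
  sum(tree$edge.length[match(uniq, key)]) /
    sum(tree$edge.length[match(u, key)])
}

# Faith's PD via the same path enumeration (rooted convention)
oracle_faith_pd <- function(tree, tips) {
  root <- length(tree$tip.label) + 1L
  key <- paste(tree$edge[, 1L], tree$edge[, 2L])
  edges <- character(0)
  for (tp in tips) {
    nodes <- ape::nodepath(tree, root, match(tp, tree$tip.label))
    for (k in seq_len(length(nodes) - 1L))
      edges <- c(edges, paste(nodes[k], nodes[k + 1L]))
  }
  sum(tree$edge.length[match(unique(edges), key)])
}

# literal step-up BH: sort, scale, enforce monotonicity by explicit loop
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  if (m > 1L) for (i in (m - 1L):1L) adj[i] <- min(adj[i], adj[i + 1L])
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

# one-sided Fisher p as an explicit sum of hypergeometric point masses
# written from choose() products, not phyper
oracle_fisher_greater <- function(a, b, c_, d) {
  n_draw <- a + b          # set size
  n_white <- a + c_        # category size
  N <- a + b + c_ + d
  ks <- seq(a, min(n_draw, n_white))
  if (!length(ks)) return(1)
  sum(choose(n_white, ks) * choose(N - n_white, n_draw - ks)) /
    choose(N, n_draw)
}

# a_r(i) by the double loop over mapped ASVs, straight from the definition
oracle_reaction_abundance <- function(counts, E) {
  asvs <- rownames(E)
  out <- matrix(NA_real_, nrow(counts), ncol(E),
                dimnames = list(rownames(counts), colnames(E)))
  for (s in seq_len(nrow(counts))) {
    for (r in seq_len(ncol(E))) {
      num <- 0; den <- 0
      for (a in asvs) {
        num <- num + counts[s, a] * E[a, r]
        den <- den + counts[s, a]
      }
      out[s, r] <- num / den
    }
  }
  out
}

# random rooted bifurcating tree over n tips (independent of the package
# generator: ape::rtree, which is rooted and binary)
oracle_random_tree <- function(n, labels = sprintf("t%d", seq_len(n))) {
  tr <- ape::rtree(n, tip.label = labels)
  tr$edge.length <- round(tr$edge.length + 0.01, 4)
  tr
}

# Procrustes distance after optimal translation + rotation/reflection
procrustes_error <- function(X, Y) {
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  s <- svd(crossprod(Xc, Yc))
  R <- s$u %*% t(s$v)
  sqrt(sum((Yc - Xc %*% R)^2))
}

# small fixture: toy GSMM collection with known structure
toy_collection <- function() {
  subsystems <- c(R1 = "glycolysis", R2 = "glycolysis", R3 = "mucin",
                  R4 = "mucin", R5 = "valerate")
  models <- list(
    gA1 = list(rank = "genus", taxon = "Pediococcus",
               reactions = c("R1", "R3", "R4")),
    gA2 = list(rank = "genus", taxon = "Pediococcus",
               reactions = c("R1", "R2", "R3", "R4")),
    gA3 = list(rank = "genus", taxon = "Pediococcus",
               reactions = c("R1", "R3")),
    gA4 = list(rank = "genus", taxon = "Pediococcus",
               reactions = c("R1", "R2")),
    gB1 = list(rank = "genus", taxon = "Lactobacillus",
               reactions = c("R1", "R5")),
    fC1 = list(rank = "family", taxon = "Lactobacillaceae",
               reactions = c("R1", "R2", "R5")),
    sD1 = list(rank = "species", taxon = "Pediococcus acidilactici",
               reactions = c("R1", "R4")))
  new_gsmm_collection(models, subsystems)
}

toy_taxonomy <- function(asv_ids, ...) {
  rows <- list(...)
  n <- length(asv_ids)
  tax <- data.frame(domain = rep("Bacteria", n),
                    phylum = rep("Firmicutes", n),
                    class = rep("Bacilli", n),
                    order = rep("Lactobacillales", n),
                    family = rep("", n), genus = rep("", n),
                    species = rep("", n),
                    row.names = asv_ids, stringsAsFactors = FALSE)
  for (a in names(rows)) for (r in names(rows[[a]]))
    tax[a, r] <- rows[[a]][[r]]
  tax
}
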