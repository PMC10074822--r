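#' Benjamini-Hochberg step-up adjustment
#'
#' Sorts p ascending, multiplies by m/rank, enforces monotonicity from the
#' largest p down, caps at 1, and restores the original order.
#'
#' @param p numeric vector of p-values in [0, 1]; NaN is rejected
#' @return adjusted p-values, same order as input
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' Kruskal-Wallis rank test across groups
#'
#' Rank-based H statistic with tie correction and a chi-squared reference
#' distribution; the conventional global test before pairwise rank-sum
#' comparisons.
#'
#' @param values numeric vector of observations
#' @param groups group label per observation (>= 2 groups, each >= 2 obs)
#' @return list with `statistic` (H), `df`, `p_value`
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.character(groups)
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least 2 groups")
  if (any(sizes < 2)) stop("each group needs at least 2 observations")
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  H <- 12 / (N * (N + 1)) * sum(sizes * (rbar - (N + 1) / 2)^2)
  ties <- table(values)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (C > 0) H <- H / C
  df <- length(sizes) - 1L
  list(statistic = H, df = df,
       p_value = stats::pchisq(H, df, lower.tail = FALSE))
}

# exact two-sided rank-sum p by subset enumeration (handles ties)
.wilcox_exact_enum <- function(x, y) {
  N <- length(x) + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_along(x)])
  subsets <- utils::combn(N, length(x))
  W <- apply(subsets, 2L, function(idx) sum(r[idx]))
  lo <- mean(W <= w_obs + 1e-9)
  hi <- mean(W >= w_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

# normal approximation with tie-corrected variance and continuity correction
.wilcox_normal <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(c(x, y))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Pairwise two-sample Wilcoxon rank-sum tests with BH adjustment
#'
#' Exact enumeration is used when both groups have at most `exact_max`
#' observations (default 8), a tie- and continuity-corrected normal
#' approximation otherwise. Adjustment is BH across all pairs.
#'
#' @inheritParams kruskal_wallis
#' @param exact_max largest group size for exact enumeration
#' @param alpha significance threshold on the adjusted p (default 0.05,
#'   strict: significant means adjusted p < alpha)
#' @return data.frame: group1, group2, statistic (rank sum of group1),
#'   p, p_adj, significant
#' @export
pairwise_wilcoxon <- function(values, groups, exact_max = 8, alpha = 0.05) {
  groups <- as.character(groups)
  gs <- split(values, groups)
  if (any(lengths(gs) == 0)) stop("group with zero observations")
  nm <- names(gs)
  pairs <- utils::combn(length(nm), 2)
  res <- data.frame(group1 = nm[pairs[1L, ]], group2 = nm[pairs[2L, ]],
                    statistic = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pairs))) {
    x <- gs[[pairs[1L, k]]]; y <- gs[[pairs[2L, k]]]
    res$statistic[k] <- sum(rank(c(x, y))[seq_along(x)])
    res$p[k] <- if (length(x) <= exact_max && length(y) <= exact_max)
      .wilcox_exact_enum(x, y) else .wilcox_normal(x, y)
  }
  res$p_adj <- bh_adjust(res$p)
  res$significant <- res$p_adj < alpha
  res
}

#' Kruskal-Wallis followed by pairwise Wilcoxon
#'
#' @inheritParams pairwise_wilcoxon
#' @return list with `statistic`, `p_value`, and `pairwise` table
#' @export
group_test <- function(values, groups, alpha = 0.05) {
  kw <- kruskal_wallis(values, groups)
  kw$pairwise <- pairwise_wilcoxon(values, groups, alpha = alpha)
  kw
}

# within-group sum of squared distances for a label vector
.ss_within <- function(d2, groups) {
  ss <- 0
  for (idx in split(seq_along(groups), groups))
    ss <- ss + sum(d2[idx, idx]) / (2 * length(idx))
  ss
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' Partitions the sum of squared inter-point distances into among- and
#' within-group components and tests the pseudo-F statistic by permuting
#' sample labels. The p-value uses the (1 + b) / (1 + n_perm) convention
#' and therefore never returns 0.
#'
#' @param dm symmetric distance matrix with sample ids
#' @param groups group label per sample (same order as `dm` rows); each
#'   group needs >= 2 samples
#' @param n_perm number of permutations (protocol default 999)
#' @param seed integer seed
#' @return list with `statistic` (pseudo-F), `p_value`, `n_perm`, `seed`,
#'   `ss_among`, `ss_within`, `df`
#' @export
permanova <- function(dm, groups, n_perm = 999, seed = 1) {
  validate_distance_matrix(dm)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(dm))
  sizes <- table(groups)
  if (any(sizes < 2)) stop("singleton group")
  a <- length(sizes); N <- nrow(dm)
  d2 <- dm^2
  sst <- sum(d2) / (2 * N)
  ssw <- .ss_within(d2, groups)
  ssa <- sst - ssw
  f_obs <- (ssa / (a - 1)) / (ssw / (N - a))
  set.seed(derive_seed(seed, "permanova"))
  b <- 0L
  for (i in seq_len(n_perm)) {
    gp <- groups[sample.int(N)]
    ssw_p <- .ss_within(d2, gp)
    f_p <- ((sst - ssw_p) / (a - 1)) / (ssw_p / (N - a))
    if (f_p >= f_obs - 1e-12) b <- b + 1L
  }
  list(statistic = f_obs, p_value = (1 + b) / (1 + n_perm),
       n_perm = n_perm, seed = seed, ss_among = ssa, ss_within = ssw,
       df = c(a - 1L, N - a))
}

#' Pairwise PERMANOVA with BH adjustment
#'
#' Recomputes the pseudo-F on the two-group submatrix for every group pair
#' and BH-adjusts across pairs.
#'
#' @inheritParams permanova
#' @return data.frame: group1, group2, statistic, p, p_adj
#' @export
pairwise_permanova <- function(dm, groups, n_perm = 999, seed = 1) {
  groups <- as.character(groups)
  nm <- sort(unique(groups))
  pairs <- utils::combn(length(nm), 2)
  res <- data.frame(group1 = nm[pairs[1L, ]], group2 = nm[pairs[2L, ]],
                    statistic = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pairs))) {
    sel <- groups %in% nm[pairs[, k]]
    r <- permanova(dm[sel, sel, drop = FALSE], groups[sel], n_perm,
                   seed = derive_seed(seed, paste0("pair", k)))
    res$statistic[k] <- r$statistic
    res$p[k] <- r$p_value
  }
  res$p_adj <- bh_adjust(res$p)
  res
}

# geometric (spatial) median by Weiszfeld iteration
.spatial_median <- function(x, tol = 1e-9, max_iter = 200) {
  m <- colMeans(x)
  for (i in seq_len(max_iter)) {
    d <- sqrt(rowSums(sweep(x, 2L, m)^2))
    if (any(d < tol)) return(m)
    w <- 1 / d
    m_new <- colSums(x * w) / sum(w)
    if (sqrt(sum((m_new - m)^2)) < tol) return(m_new)
    m <- m_new
  }
  m
}

.permdisp_f <- function(coords, groups) {
  z <- numeric(nrow(coords))
  for (idx in split(seq_len(nrow(coords)), groups)) {
    med <- .spatial_median(coords[idx, , drop = FALSE])
    z[idx] <- sqrt(rowSums(sweep(coords[idx, , drop = FALSE], 2L, med)^2))
  }
  sizes <- table(groups)
  a <- length(sizes); N <- length(z)
  zbar <- tapply(z, groups, mean)
  ssa <- sum(sizes * (zbar - mean(z))^2)
  ssw <- sum((z - zbar[groups])^2)
  list(f = (ssa / (a - 1)) / (ssw / (N - a)), z = z)
}

#' PERMDISP: homogeneity of multivariate dispersions
#'
#' Embeds the distance matrix by PCoA (axes with negative eigenvalues are
#' discarded and reported), computes each sample's distance to its group's
#' spatial median, and tests the ANOVA F of those distances by permuting
#' labels.
#'
#' @inheritParams permanova
#' @return list with `statistic`, `p_value`, `n_perm`, `seed`,
#'   `dispersion` (per-sample distance to group median, for boxplots),
#'   `group_means`, `negative_eigenvalues`
#' @export
permdisp <- function(dm, groups, n_perm = 999, seed = 1) {
  validate_distance_matrix(dm)
  groups <- as.character(groups)
  if (any(table(groups) < 2)) stop("singleton group")
  ord <- pcoa(dm)
  coords <- ord$coordinates
  obs <- .permdisp_f(coords, groups)
  set.seed(derive_seed(seed, "permdisp"))
  b <- 0L
  N <- nrow(coords)
  for (i in seq_len(n_perm)) {
    f_p <- .permdisp_f(coords, groups[sample.int(N)])$f
    if (f_p >= obs$f - 1e-12) b <- b + 1L
  }
  list(statistic = obs$f, p_value = (1 + b) / (1 + n_perm),
       n_perm = n_perm, seed = seed,
       dispersion = stats::setNames(obs$z, rownames(dm)),
       group_means = tapply(obs$z, groups, mean),
       negative_eigenvalues = ord$negative_eigenvalues)
}

#' Pearson correlation between expected and observed mock profiles
#'
#' @param expected named composition of the community standard
#' @param observed matrix (replicates x taxa) or single named vector of
#'   observed compositions over the same taxa
#' @return list with `r` (per replicate), `mean_r`, and
#'   `observed_vs_observed` (mean pairwise r among replicates, NA if < 2)
#' @export
mock_pearson <- function(expected, observed) {
  if (is.null(dim(observed))) observed <- matrix(observed, nrow = 1,
                                                 dimnames = list(NULL, names(observed)))
  observed <- observed[, names(expected), drop = FALSE]
  if (stats::sd(expected) == 0) stop("zero-variance expected profile")
  if (any(apply(observed, 1L, stats::sd) == 0))
    stop("zero-variance observed profile")
  r <- apply(observed, 1L, function(o) stats::cor(expected, o))
  ovo <- NA_real_
  if (nrow(observed) >= 2) {
    cc <- stats::cor(t(observed))
    ovo <- mean(cc[upper.tri(cc)])
  }
  list(r = r, mean_r = mean(r), observed_vs_observed = ovo)
}

#' PCA on standardized features
#'
#' Features are z-scored (zero-variance features dropped and reported)
#' before the eigendecomposition, so every feature contributes equal
#' variance — the convention for ASV and reaction-abundance score plots.
#'
#' @param x samples x features numeric matrix (>= 2 samples)
#' @return list with `scores`, `loadings`, `sdev`, `proportion`,
#'   `dropped` (zero-variance feature names)
#' @export
pca_standardized <- function(x) {
  if (nrow(x) < 2) stop("need at least 2 samples")
  v <- apply(x, 2L, stats::var)
  dropped <- colnames(x)[v == 0 | is.na(v)]
  keep <- x[, v > 0 & !is.na(v), drop = FALSE]
  if (ncol(keep) < 2) stop("fewer than 2 non-constant features")
  z <- scale(keep)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  prop <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, loadings = pc$rotation, sdev = pc$sdev,
       proportion = prop, dropped = dropped)
}
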