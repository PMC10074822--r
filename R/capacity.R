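#' Map ASVs to genome-scale metabolic models
#'
#' For each ASV, the taxonomy is searched from species up through genus to
#' family for the lowest assigned rank at which the taxon name matches at
#' least one model label of that rank (exact, case-sensitive match after
#' whitespace trimming; no fuzzy matching). ASVs assigned only above family
#' level, or whose names match no model, are excluded with a reason rather
#' than erroring.
#'
#' @param taxonomy taxonomy data.frame over the ASVs of interest
#' @param collection a `gsmm_collection`
#' @return list with `mapping` (data.frame: asv_id, rank, taxon, n_models),
#'   `models` (named list: asv_id -> model ids), `unmapped` (data.frame:
#'   asv_id, reason), and `summary` (counts per rank, mean models per
#'   mapped ASV)
#' @export
map_asvs <- function(taxonomy, collection) {
  stopifnot(inherits(collection, "gsmm_collection"))
  model_rank <- vapply(collection$models, `[[`, "", "rank")
  model_taxon <- trimws(vapply(collection$models, `[[`, "", "taxon"))
  by_rank <- lapply(c(species = "species", genus = "genus",
                      family = "family"),
                    function(r) split(names(collection$models)[model_rank == r],
                                      model_taxon[model_rank == r]))
  asvs <- rownames(taxonomy)
  rows <- vector("list", length(asvs))
  models <- list()
  unmapped <- list()
  for (i in seq_along(asvs)) {
    a <- asvs[i]
    found <- FALSE
    any_named <- FALSE
    for (r in c("species", "genus", "family")) {
      nm <- trimws(taxonomy[a, r])
      if (is.na(nm) || nm == "") next
      any_named <- TRUE
      hit <- by_rank[[r]][[nm]]
      if (length(hit)) {
        rows[[i]] <- data.frame(asv_id = a, rank = r, taxon = nm,
                                n_models = length(hit),
                                stringsAsFactors = FALSE)
        models[[a]] <- hit
        found <- TRUE
        break
      }
    }
    if (!found)
      unmapped[[a]] <- data.frame(
        asv_id = a,
        reason = if (any_named) "no model for taxon" else "rank above family",
        stringsAsFactors = FALSE)
  }
  mapping <- do.call(rbind, rows) %||%
    data.frame(asv_id = character(), rank = character(),
               taxon = character(), n_models = integer())
  unmapped <- do.call(rbind, c(unmapped, list(stringsAsFactors = FALSE))) %||%
    data.frame(asv_id = character(), reason = character())
  rownames(unmapped) <- NULL
  per_rank <- table(factor(mapping$rank,
                           levels = c("family", "genus", "species")))
  list(mapping = mapping, models = models, unmapped = unmapped,
       summary = list(n_mapped = nrow(mapping),
                      n_unmapped = nrow(unmapped),
                      per_rank = per_rank,
                      mean_models = if (nrow(mapping))
                        mean(mapping$n_models) else NA_real_,
                      mean_models_per_rank = if (nrow(mapping))
                        tapply(mapping$n_models, mapping$rank, mean)
                      else NULL))
}

#' Per-ASV reaction occurrence probabilities
#'
#' E(i, j) is the fraction of ASV j's mapped models that contain reaction
#' i — the expected probability that the organism behind the ASV carries
#' the reaction.
#'
#' @param mapping result of [map_asvs()]
#' @param collection the `gsmm_collection` used for the mapping
#' @return matrix, mapped ASVs x reactions, values in [0, 1]
#' @export
reaction_probabilities <- function(mapping, collection) {
  if (!nrow(mapping$mapping)) stop("empty mapping")
  rxn_ids <- names(collection$subsystems)
  asvs <- mapping$mapping$asv_id
  E <- matrix(0, length(asvs), length(rxn_ids),
              dimnames = list(asvs, rxn_ids))
  for (a in asvs) {
    mods <- mapping$models[[a]]
    cnt <- table(unlist(lapply(mods, function(m)
      unique(collection$models[[m]]$reactions))))
    E[a, names(cnt)] <- as.numeric(cnt) / length(mods)
  }
  E
}

#' Normalized reaction abundance per sample
#'
#' For each sample and reaction, the abundance-weighted mean of E(i, j)
#' over the mapped ASVs:
#' a_r(i) = sum_j a_ASV(j) E(i, j) / sum_j a_ASV(j),
#' where the sums run over the mapped (included) ASVs only — unmapped ASVs
#' enter neither numerator nor denominator by default. Setting
#' `denominator = "all"` uses the total sample count instead, for
#' sensitivity analysis.
#'
#' @param counts samples x ASVs matrix (e.g. the digesta subset)
#' @param E mapped-ASVs x reactions probability matrix from
#'   [reaction_probabilities()]
#' @param denominator "mapped" (default) or "all"
#' @return list with `abundance` (samples x reactions matrix in [0, 1])
#'   and `prevalence` (fraction of reactions present in all samples,
#'   fraction of samples containing > 90% of reactions)
#' @export
reaction_abundance <- function(counts, E, denominator = c("mapped", "all")) {
  denominator <- match.arg(denominator)
  mapped <- intersect(colnames(counts), rownames(E))
  W <- counts[, mapped, drop = FALSE]
  wsum <- rowSums(W)
  if (any(wsum == 0))
    stop("sample(s) with zero mapped counts: ",
         paste(rownames(counts)[wsum == 0], collapse = ", "))
  denom <- if (denominator == "mapped") wsum else rowSums(counts)
  ram <- (W %*% E[mapped, , drop = FALSE]) / denom
  present <- ram > 0
  prevalence <- list(
    frac_reactions_in_all_samples = mean(colSums(present) == nrow(ram)),
    frac_samples_over_90pct_reactions =
      mean(rowSums(present) > 0.9 * ncol(ram)))
  list(abundance = ram, prevalence = prevalence)
}

#' Differential reaction abundance between two diets
#'
#' Two-sample t-test per reaction (pooled-variance Student form by
#' default; Welch by flag) comparing mean a_r between the two diets.
#' Reactions with zero variance in both groups and equal means carry no
#' information and are skipped (reported). BH adjustment across tested
#' reactions; significant at adjusted p <= 0.05. The sign of t (group1
#' minus group2) is recorded as the direction.
#'
#' @param ram samples x reactions abundance matrix
#' @param groups diet label per sample (same order as rows)
#' @param diet_pair character vector of the two diets to compare
#' @param welch use Welch's unequal-variance form
#' @param alpha significance threshold on adjusted p (inclusive)
#' @return data.frame: reaction, mean_diff, statistic, df, p, p_adj,
#'   significant, direction; skipped reactions in attribute "skipped"
#' @export
differential_reactions <- function(ram, groups, diet_pair, welch = FALSE,
                                   alpha = 0.05) {
  stopifnot(length(diet_pair) == 2)
  groups <- as.character(groups)
  i1 <- which(groups == diet_pair[1L]); i2 <- which(groups == diet_pair[2L])
  if (length(i1) < 2 || length(i2) < 2)
    stop("each diet needs at least 2 samples")
  x <- ram[i1, , drop = FALSE]; y <- ram[i2, , drop = FALSE]
  n1 <- nrow(x); n2 <- nrow(y)
  m1 <- colMeans(x); m2 <- colMeans(y)
  v1 <- apply(x, 2L, stats::var); v2 <- apply(y, 2L, stats::var)
  skipped <- colnames(ram)[v1 == 0 & v2 == 0 & m1 == m2]
  test <- setdiff(colnames(ram), skipped)
  m1 <- m1[test]; m2 <- m2[test]; v1 <- v1[test]; v2 <- v2[test]
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    tstat <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(test))
  }
  p <- 2 * stats::pt(-abs(tstat), df)
  res <- data.frame(reaction = test, mean_diff = m1 - m2,
                    statistic = tstat, df = df, p = p,
                    p_adj = bh_adjust(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  res$significant <- res$p_adj <= alpha
  res$direction <- ifelse(res$statistic > 0, diet_pair[1L], diet_pair[2L])
  attr(res, "skipped") <- skipped
  attr(res, "diet_pair") <- diet_pair
  res
}

#' One-sided Fisher's exact test for over-representation
#'
#' p = P(X >= x) for X hypergeometric with the table's margins, i.e. the
#' upper hypergeometric tail of the 2x2 table
#' \code{rbind(c(x, b), c(c, d))}.
#'
#' @param x,b,c_,d_ cell counts: x = in-set and in-category, b = in-set
#'   not in category, c_ = out-of-set in category, d_ = neither
#' @return p-value
#' @export
fisher_exact_greater <- function(x, b, c_, d_) {
  stopifnot(x >= 0, b >= 0, c_ >= 0, d_ >= 0)
  # white balls = category column total, draws = set row total
  stats::phyper(x - 1, x + c_, b + d_, x + b, lower.tail = FALSE)
}

#' Direction-aware subsystem enrichment among differential reactions
#'
#' For each direction (reactions significantly higher in diet 1, resp.
#' diet 2), tests every subsystem for over-representation within that
#' direction's significant set against the remaining tested reactions,
#' using a one-sided Fisher's exact test, BH-adjusted across subsystems
#' and directions within the diet pair. The enrichment universe is the
#' set of tested reactions (zero-variance reactions were never tested).
#'
#' @param diff result of [differential_reactions()]
#' @param subsystems named character vector, reaction -> subsystem
#' @param alpha enrichment threshold on adjusted p (inclusive)
#' @param two_sided use the two-sided Fisher test instead
#' @return data.frame: subsystem, direction (diet label), a, b, c, d
#'   (contingency counts), p, p_adj, enriched
#' @export
subsystem_enrichment <- function(diff, subsystems, alpha = 0.05,
                                 two_sided = FALSE) {
  diet_pair <- attr(diff, "diet_pair")
  orphan <- setdiff(diff$reaction, names(subsystems))
  if (length(orphan))
    stop("reaction(s) absent from subsystem map: ",
         paste(utils::head(orphan, 5), collapse = ", "))
  ss <- subsystems[diff$reaction]
  rows <- list()
  for (dir in diet_pair) {
    sig <- diff$significant & diff$direction == dir
    for (s in sort(unique(ss))) {
      in_ss <- ss == s
      a <- sum(sig & in_ss); b <- sum(sig & !in_ss)
      c_ <- sum(!sig & in_ss); d <- sum(!sig & !in_ss)
      p <- if (two_sided)
        stats::fisher.test(matrix(c(a, c_, b, d), 2))$p.value
      else fisher_exact_greater(a, b, c_, d)
      rows[[length(rows) + 1L]] <- data.frame(
        subsystem = s, direction = dir, a = a, b = b, c = c_, d = d,
        p = p, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$p_adj <- bh_adjust(res$p)
  res$enriched <- res$p_adj <= alpha
  attr(res, "diet_pair") <- diet_pair
  res
}

#' Enrichment heat-table across diet pairs
#'
#' Combines per-pair enrichment results into a long-format table and a
#' pair x subsystem matrix of signed calls: +1 when the subsystem is
#' enriched in the pair's first diet, -1 when enriched in the second,
#' 0 otherwise.
#'
#' @param enrichments named list of [subsystem_enrichment()] results; names
#'   like "FM_vs_SBM" (used as row labels)
#' @return list with `long` (pair, subsystem, direction, p, p_adj,
#'   enriched) and `signed` (pairs x subsystems numeric matrix)
#' @export
capacity_report <- function(enrichments) {
  stopifnot(length(enrichments) >= 1, !is.null(names(enrichments)))
  long <- do.call(rbind, lapply(names(enrichments), function(pr) {
    e <- enrichments[[pr]]
    data.frame(pair = pr, e[, c("subsystem", "direction", "p", "p_adj",
                                "enriched")],
               stringsAsFactors = FALSE)
  }))
  subsys <- sort(unique(long$subsystem))
  signed <- matrix(0, length(enrichments), length(subsys),
                   dimnames = list(names(enrichments), subsys))
  for (pr in names(enrichments)) {
    e <- enrichments[[pr]]
    dp <- attr(e, "diet_pair")
    hit <- e[e$enriched, , drop = FALSE]
    for (k in seq_len(nrow(hit)))
      signed[pr, hit$subsystem[k]] <-
        if (hit$direction[k] == dp[1L]) 1 else -1
  }
  list(long = long, signed = signed)
}
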