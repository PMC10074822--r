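#' Filter an ASV table on taxonomy and prevalence
#'
#' Retains exactly the ASVs that (a) are not annotated as chloroplast or
#' mitochondria at any rank (case-insensitive), (b) carry a phylum-level
#' assignment, and (c) occur with count > 0 in at least `min_samples`
#' samples. ASVs absent from the taxonomy are treated as phylum-unassigned
#' and removed. The prevalence filter is computed over all samples of the
#' supplied table (one merged table of biological samples); pass a
#' pre-subset table to restrict it.
#'
#' @param counts samples x ASVs integer matrix
#' @param taxonomy taxonomy data.frame (see [read_taxonomy()])
#' @param min_samples minimum number of samples an ASV must occur in
#' @return list with `counts` (the filtered table) and `removed`
#'   (data.frame of removed ASVs with a `reason` column)
#' @export
filter_asvs <- function(counts, taxonomy, min_samples = 3) {
  stop_if_not_count_matrix(counts)
  asvs <- colnames(counts)
  reason <- stats::setNames(rep(NA_character_, length(asvs)), asvs)

  tax <- taxonomy[match(asvs, rownames(taxonomy)), , drop = FALSE]
  organelle <- apply(tax, 1L, function(v)
    any(grepl("chloroplast|mitochondria", v, ignore.case = TRUE)))
  organelle[is.na(organelle)] <- FALSE
  no_phylum <- is.na(tax$phylum) | tax$phylum == ""
  prevalence <- colSums(counts > 0)
  rare <- prevalence < min_samples

  reason[rare] <- sprintf("present in %d < %d samples",
                          prevalence[rare], min_samples)
  reason[no_phylum] <- "no phylum-level assignment"
  reason[organelle] <- "chloroplast/mitochondria"

  keep <- is.na(reason)
  removed <- data.frame(asv_id = asvs[!keep], reason = reason[!keep],
                        row.names = NULL, stringsAsFactors = FALSE)
  list(counts = counts[, keep, drop = FALSE], removed = removed)
}

#' Convert counts to relative abundances
#'
#' @param counts samples x features matrix; every sample total must be > 0
#' @return matrix of the same shape with rows summing to 1
#' @export
relative_abundance <- function(counts) {
  tot <- rowSums(counts)
  if (any(tot <= 0))
    stop("sample(s) with zero total count: ",
         paste(rownames(counts)[tot <= 0], collapse = ", "))
  counts / tot
}

#' Aggregate ASV abundances at genus or lowest assigned rank
#'
#' Each ASV is labelled by its assigned name at `target_rank` if present,
#' otherwise by its lowest assigned rank above it (e.g. a family name for a
#' genus-unassigned ASV); abundances are summed per label. The returned
#' matrix carries a `ranks` attribute recording the rank each label came
#' from, disambiguating e.g. a family name used as a genus-or-lowest label.
#'
#' @param rel samples x ASVs relative abundance matrix
#' @param taxonomy taxonomy data.frame covering the ASVs
#' @param target_rank rank to aggregate at (default "genus")
#' @return samples x taxa matrix of summed relative abundances
#' @export
aggregate_lowest_rank <- function(rel, taxonomy, target_rank = "genus") {
  stopifnot(target_rank %in% TAXONOMY_RANKS)
  ranks_upto <- TAXONOMY_RANKS[seq_len(match(target_rank, TAXONOMY_RANKS))]
  tax <- taxonomy[match(colnames(rel), rownames(taxonomy)),
                  ranks_upto, drop = FALSE]
  label <- character(ncol(rel))
  label_rank <- character(ncol(rel))
  for (i in seq_len(ncol(rel))) {
    v <- as.character(tax[i, ])
    assigned <- which(!is.na(v) & v != "")
    if (!length(assigned))
      stop(sprintf("ASV '%s' has no assigned rank at all (filter first)",
                   colnames(rel)[i]))
    j <- max(assigned)
    label[i] <- v[j]
    label_rank[i] <- ranks_upto[j]
  }
  out <- t(rowsum(t(rel), group = label))
  ranks <- tapply(label_rank, label, function(x) x[[1L]])
  attr(out, "ranks") <- ranks[colnames(out)]
  out
}

#' Rank taxa by overall mean relative abundance, with per-group means
#'
#' Taxa beyond the top `n` are pooled into an `"Other"` row, so per-group
#' means always sum to 1.
#'
#' @param comp samples x taxa relative abundance matrix
#' @param n number of top taxa to report
#' @param metadata metadata data.frame with a `group` column
#' @return list with `taxa` (ranked names), `overall_mean`, and
#'   `group_means` (taxa+Other x groups matrix)
#' @export
top_n_taxa <- function(comp, n, metadata) {
  stopifnot(n >= 1)
  groups <- metadata[rownames(comp), "group"]
  overall <- sort(colMeans(comp), decreasing = TRUE)
  top <- names(overall)[seq_len(min(n, length(overall)))]
  gm <- t(rowsum(comp, groups) / as.vector(table(groups)[sort(unique(groups))]))
  gm <- gm[top, , drop = FALSE]
  other <- 1 - colSums(gm)
  gm <- rbind(gm, Other = pmax(other, 0))
  list(taxa = top, overall_mean = overall[top], group_means = gm)
}

#' Core ASV detection by prevalence
#'
#' An ASV is core if it occurs (count > 0) in at least
#' `prevalence_threshold` of the selected samples. Also computes per-group
#' core sets and their all-group intersection (the Venn-diagram center).
#'
#' @param counts samples x ASVs matrix
#' @param metadata metadata with a `group` column (needed for per-group sets)
#' @param samples optional character vector restricting the sample set
#' @param prevalence_threshold fraction in (0, 1], default 0.80
#' @return list with `core` (character vector), `per_group` (named list of
#'   character vectors), and `intersection`
#' @export
core_asvs <- function(counts, metadata = NULL, samples = rownames(counts),
                      prevalence_threshold = 0.80) {
  if (prevalence_threshold <= 0 || prevalence_threshold > 1)
    stop("prevalence_threshold must lie in (0, 1]")
  if (!length(samples)) stop("empty sample subset")
  sub <- counts[samples, , drop = FALSE]
  prev <- colMeans(sub > 0)
  core <- colnames(sub)[prev >= prevalence_threshold]
  per_group <- NULL
  intersection <- NULL
  if (!is.null(metadata)) {
    grp <- metadata[samples, "group"]
    per_group <- lapply(split(samples, grp), function(s) {
      p <- colMeans(counts[s, , drop = FALSE] > 0)
      colnames(counts)[p >= prevalence_threshold]
    })
    intersection <- Reduce(intersect, per_group)
  }
  list(core = core, per_group = per_group, intersection = intersection)
}

#' Shared ASVs between two sample compartments
#'
#' An ASV counts as present in a compartment if its relative abundance
#' reaches `min_presence` (default 0.05%) in at least one sample of that
#' compartment. Reports the shared (intersection) ASV count and, for each
#' compartment, the summed mean relative abundance of the shared ASVs.
#'
#' @param relA,relB samples x ASVs relative abundance matrices for the two
#'   compartments (e.g. digesta vs feed), over a common ASV universe
#' @param min_presence presence threshold on relative abundance
#' @return list with `shared` (ids), `n_shared`, `presentA`, `presentB`,
#'   `shared_abundance_A`, `shared_abundance_B`
#' @export
shared_asvs <- function(relA, relB, min_presence = 0.0005) {
  presentA <- colnames(relA)[apply(relA >= min_presence, 2L, any)]
  presentB <- colnames(relB)[apply(relB >= min_presence, 2L, any)]
  shared <- intersect(presentA, presentB)
  list(shared = shared, n_shared = length(shared),
       presentA = presentA, presentB = presentB,
       shared_abundance_A = sum(colMeans(relA[, shared, drop = FALSE])),
       shared_abundance_B = sum(colMeans(relB[, shared, drop = FALSE])))
}
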