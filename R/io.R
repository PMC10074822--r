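#' Read an ASV count table
#'
#' Counts are stored as a tab-separated table with sample ids in the first
#' column and ASV ids in the header (samples in rows). The transposed
#' dialect (ASVs in rows) is accepted via `transpose = TRUE`. Validation
#' rejects rather than repairs: duplicate ids, negative, non-integer or
#' non-finite counts, and ragged rows are errors.
#'
#' @param path file path
#' @param transpose set TRUE if the file stores ASVs in rows
#' @return integer matrix, samples x ASVs, with dimnames
#' @export
read_asv_table <- function(path, transpose = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = NULL,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[-1L])
  if (!is.numeric(m)) stop("non-numeric entries in count table")
  rownames(m) <- ids
  if (transpose) m <- t(m)
  stop_if_not_count_matrix(m)
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_asv_table
#' @param counts samples x ASVs integer matrix
#' @export
write_asv_table <- function(counts, path) {
  stop_if_not_count_matrix(counts)
  df <- data.frame(sample_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy table
#'
#' TSV with an `asv_id` column and up to seven rank columns (domain,
#' phylum, class, order, family, genus, species). Empty cells mean
#' unassigned; the common sentinels "NA", "unclassified", "unassigned"
#' (any case) are normalized to empty. Lineages must fill top-down: an
#' assigned rank below an unassigned one is an error.
#'
#' @param path file path
#' @return data.frame with the 7 rank columns, row names = ASV ids
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL)
  if (!"asv_id" %in% names(df)) stop("taxonomy file needs an 'asv_id' column")
  if (anyDuplicated(df$asv_id)) stop("duplicate ASV ids in taxonomy")
  rn <- df$asv_id
  df$asv_id <- NULL
  missing_ranks <- setdiff(TAXONOMY_RANKS, names(df))
  for (r in missing_ranks) df[[r]] <- ""
  extra <- setdiff(names(df), TAXONOMY_RANKS)
  if (length(extra))
    stop("unknown taxonomy columns: ", paste(extra, collapse = ", "))
  df <- df[TAXONOMY_RANKS]
  rownames(df) <- rn
  for (r in TAXONOMY_RANKS) {
    v <- trimws(df[[r]])
    v[tolower(v) %in% c("na", "unclassified", "unassigned", "n/a")] <- ""
    df[[r]] <- v
  }
  validate_taxonomy(df)
  df
}

validate_taxonomy <- function(tax) {
  m <- as.matrix(tax[TAXONOMY_RANKS]) != ""
  for (i in seq_len(nrow(m))) {
    assigned <- which(m[i, ])
    if (length(assigned) && any(diff(assigned) > 1L))
      stop(sprintf(
        "ASV '%s': rank '%s' assigned below an unassigned rank",
        rownames(tax)[i],
        TAXONOMY_RANKS[assigned[which(diff(assigned) > 1L)[1L] + 1L]]))
  }
  invisible(tax)
}

#' @rdname read_taxonomy
#' @param tax taxonomy data.frame
#' @export
write_taxonomy <- function(tax, path) {
  df <- data.frame(asv_id = rownames(tax), tax, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogeny in newick format
#'
#' @param path file path
#' @param asv_ids optional ASV ids to cross-check against tip labels;
#'   mismatches are reported as a warning, not an error
#' @return an `ape::phylo` tree
#' @export
read_tree <- function(path, asv_ids = NULL) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick tree")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  if (!is.null(asv_ids)) {
    miss <- setdiff(asv_ids, tree$tip.label)
    if (length(miss))
      warning("ASVs missing from tree: ", paste(miss, collapse = ", "))
  }
  tree
}

#' @rdname read_tree
#' @param tree a `phylo` object
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read sample metadata
#'
#' TSV with `sample_id`, `group`, `sample_type`, `tank`, `run` columns.
#' `sample_type` must be one of digesta, feed, water, control.
#'
#' @param path file path
#' @param sample_ids optional sample ids that must all have a metadata row
#' @return data.frame, row names = sample ids
#' @export
read_metadata <- function(path, sample_ids = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  req <- c("sample_id", "group", "sample_type")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in metadata")
  bad <- setdiff(unique(df$sample_type),
                 c("digesta", "feed", "water", "control"))
  if (length(bad))
    stop("unknown sample_type value(s): ", paste(bad, collapse = ", "))
  rownames(df) <- df$sample_id
  df$sample_id <- NULL
  if (!is.null(sample_ids)) {
    absent <- setdiff(sample_ids, rownames(df))
    if (length(absent))
      stop("samples without metadata: ", paste(absent, collapse = ", "))
  }
  df
}

#' @rdname read_metadata
#' @param metadata metadata data.frame
#' @export
write_metadata <- function(metadata, path) {
  df <- data.frame(sample_id = rownames(metadata), metadata,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' GSMM collection container
#'
#' A collection of genome-scale metabolic models reduced to what the
#' reaction-capacity analysis needs: per model a taxonomic label
#' (rank + name) and a reaction id set, plus a map assigning every
#' reaction to exactly one subsystem.
#'
#' @param models named list; each element `list(rank=, taxon=, reactions=)`
#' @param subsystems named character vector, reaction id -> subsystem name
#' @return a validated `gsmm_collection`
#' @export
new_gsmm_collection <- function(models, subsystems) {
  if (!length(models) || is.null(names(models)))
    stop("models must be a non-empty named list")
  if (anyDuplicated(names(models))) stop("duplicate model ids")
  for (id in names(models)) {
    m <- models[[id]]
    if (is.null(m$rank) || is.null(m$taxon))
      stop(sprintf("model '%s' lacks a taxonomic label", id))
    if (!m$rank %in% c("species", "genus", "family"))
      stop(sprintf("model '%s': rank must be species/genus/family", id))
    if (!length(m$reactions))
      stop(sprintf("model '%s' has an empty reaction set", id))
    orphan <- setdiff(m$reactions, names(subsystems))
    if (length(orphan))
      stop(sprintf("model '%s': reaction(s) without subsystem: %s",
                   id, paste(utils::head(orphan, 5), collapse = ", ")))
  }
  structure(list(models = models, subsystems = subsystems),
            class = "gsmm_collection")
}

#' Read / write a GSMM collection as JSON
#'
#' The exchange format is a project-defined JSON document with two
#' objects: `"models"` (model id -> `{rank, taxon, reactions: [...]}`)
#' and `"subsystems"` (reaction id -> subsystem name). SBML is out of
#' scope; only reaction presence and subsystem labels are represented.
#'
#' @param path file path
#' @return a `gsmm_collection`
#' @export
read_gsmms <- function(path) {
  x <- jsonlite::read_json(path)
  if (is.null(x$models) || is.null(x$subsystems))
    stop("GSMM JSON needs 'models' and 'subsystems' objects")
  subsystems <- unlist(x$subsystems)
  models <- lapply(x$models, function(m)
    list(rank = m$rank, taxon = m$taxon,
         reactions = as.character(unlist(m$reactions))))
  new_gsmm_collection(models, subsystems)
}

#' @rdname read_gsmms
#' @param collection a `gsmm_collection`
#' @export
write_gsmms <- function(collection, path) {
  stopifnot(inherits(collection, "gsmm_collection"))
  jsonlite::write_json(
    list(models = collection$models,
         subsystems = as.list(collection$subsystems)),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' @export
print.gsmm_collection <- function(x, ...) {
  cat(sprintf("GSMM collection: %d models over %d taxa, %d reactions, %d subsystems\n",
              length(x$models),
              length(unique(vapply(x$models, `[[`, "", "taxon"))),
              length(x$subsystems),
              length(unique(x$subsystems))))
  invisible(x)
}

#' Write a square labelled distance matrix as TSV
#' @param dm symmetric matrix with dimnames
#' @param path file path
#' @export
write_distance_matrix <- function(dm, path) {
  df <- data.frame(sample_id = rownames(dm), dm, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[-1L])
  rownames(m) <- as.character(df[[1L]])
  validate_distance_matrix(m)
  m
}

#' Validate a labelled distance matrix
#'
#' Checks symmetry (to 1e-12), an exactly-zero diagonal, finiteness and
#' non-negativity; returns the matrix invisibly.
#' @param m matrix to validate
#' @export
validate_distance_matrix <- function(m) {
  if (any(!is.finite(m))) stop("distance matrix has non-finite entries")
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-12)
    stop("distance matrix must be symmetric")
  if (any(diag(m) != 0)) stop("distance matrix diagonal must be exactly 0")
  if (any(m < 0)) stop("distances must be non-negative")
  invisible(m)
}
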