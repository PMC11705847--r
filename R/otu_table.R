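#' Construct and validate an OTU count table
#'
#' The `otu_table` is the substrate of every analysis in this package: a
#' non-negative integer matrix of read counts with taxa as rows and samples
#' as columns, plus an optional taxonomy lookup.  All-zero taxon rows are
#' dropped on construction (with a warning) so that downstream relative
#' abundances are always well defined.
#'
#' @param counts numeric matrix, taxa x samples, non-negative integers;
#'   rownames are taxon identifiers, colnames are sample identifiers.
#' @param taxonomy optional named character vector mapping taxon id to a
#'   semicolon-delimited lineage string.
#' @return An object of class `otu_table`: a list with elements `counts`
#'   (integer matrix) and `taxonomy` (named character vector or `NULL`).
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 2L, 1L, 4L), nrow = 3,
#'             dimnames = list(paste0("OTU_", 1:3), c("s1", "s2")))
#' tab <- otu_table(m)
#' n_taxa(tab)
#' @export
otu_table <- function(counts, taxonomy = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("OTU_%04d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("S%03d", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts)))
    stop("duplicated taxon identifiers: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicated sample identifiers: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (any(!is.finite(counts)))
    stop("counts must be finite")
  if (any(counts < 0))
    stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integers")
  storage.mode(counts) <- "integer"
  zero <- rowSums(counts) == 0L
  if (any(zero)) {
    warning(sum(zero), " all-zero taxon row(s) dropped: ",
            paste(utils::head(rownames(counts)[zero], 5), collapse = ", "),
            if (sum(zero) > 5) ", ..." else "")
    counts <- counts[!zero, , drop = FALSE]
  }
  if (nrow(counts) == 0L) stop("table has no taxa with positive counts")
  if (!is.null(taxonomy)) {
    taxonomy <- taxonomy[intersect(names(taxonomy), rownames(counts))]
    if (length(taxonomy) == 0L) taxonomy <- NULL
  }
  structure(list(counts = counts, taxonomy = taxonomy), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat("otu_table: ", nrow(x$counts), " taxa x ", ncol(x$counts),
      " samples\n", sep = "")
  cat("  total reads: ", sum(x$counts),
      "; sample depths: ", min(colSums(x$counts)), "-",
      max(colSums(x$counts)), "\n", sep = "")
  if (!is.null(x$taxonomy))
    cat("  taxonomy present for ", length(x$taxonomy), " taxa\n", sep = "")
  invisible(x)
}

#' @rdname otu_table
#' @param x an `otu_table`.
#' @export
n_taxa <- function(x) nrow(x$counts)

#' @rdname otu_table
#' @export
n_samples <- function(x) ncol(x$counts)

#' @rdname otu_table
#' @export
taxon_ids <- function(x) rownames(x$counts)

#' @rdname otu_table
#' @export
sample_ids <- function(x) colnames(x$counts)

#' @rdname otu_table
#' @export
sample_depths <- function(x) colSums(x$counts)

#' Per-sample relative abundances
#'
#' Derived view: each column (sample) of the count matrix divided by its
#' total.  Counts themselves are never stored normalized.
#'
#' @param x an `otu_table`.
#' @return taxa x samples numeric matrix with unit column sums.
#' @export
rel_abund <- function(x) {
  sweep(x$counts, 2, colSums(x$counts), "/")
}

#' Read an OTU table from TSV (or BIOM JSON)
#'
#' The TSV layout is the common amplicon-export one: first column holds
#' identifiers (header typically `#OTU_ID`), one column per sample, and an
#' optional final `taxonomy` column with a semicolon-delimited lineage.
#' A BIOM-format JSON file is accepted through the same entry point (the
#' file is sniffed; requires the `biomformat` package).
#'
#' @param path path to the file.
#' @param orientation `"taxa_rows"` (default) if rows are taxa,
#'   `"samples_rows"` if rows are samples (the table is transposed).
#' @return an [otu_table].
#' @export
read_otu_table <- function(path, orientation = c("taxa_rows", "samples_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readChar(path, nchars = 1L, useBytes = TRUE)
  if (identical(first, "{")) {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM JSON requires the 'biomformat' package")
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    if (orientation == "samples_rows") m <- t(m)
    return(otu_table(m))
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("malformed table: fewer than 2 columns")
  ids <- as.character(df[[1L]])
  df <- df[, -1L, drop = FALSE]
  taxonomy <- NULL
  if (tolower(names(df)[ncol(df)]) == "taxonomy") {
    taxonomy <- stats::setNames(as.character(df[[ncol(df)]]), ids)
    df <- df[, -ncol(df), drop = FALSE]
  }
  m <- matrix(NA_real_, nrow(df), ncol(df),
              dimnames = list(ids, names(df)))
  for (j in seq_len(ncol(df))) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) | v < 0 | abs(v - round(v)) > 1e-8)
    if (length(bad))
      stop("malformed count in row '", ids[bad[1L]], "', column '",
           names(df)[j], "': ", df[bad[1L], j])
    m[, j] <- v
  }
  if (orientation == "samples_rows") {
    m <- t(m)
    taxonomy <- NULL
  }
  otu_table(m, taxonomy = taxonomy)
}

#' Write an OTU table as TSV
#'
#' @param x an [otu_table].
#' @param path output path.
#' @export
write_otu_table <- function(x, path) {
  df <- data.frame(`#OTU_ID` = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(x$taxonomy))
    df$taxonomy <- unname(x$taxonomy[rownames(x$counts)])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Tab-separated with a header containing at least `sample_id`; typical
#' columns are `site` (collection location) and `niche`
#' (endophytic / epiphytic).
#'
#' @param path path to the TSV.
#' @return a data.frame with one row per sample.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(md)) stop("metadata must have a sample_id column")
  if (anyDuplicated(md$sample_id))
    stop("duplicated sample_id in metadata")
  md
}

#' Write sample metadata as TSV
#' @param md metadata data.frame.
#' @param path output path.
#' @export
write_metadata <- function(md, path) {
  utils::write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check that metadata covers a table
#'
#' Every analyzed sample must have exactly one metadata row.
#'
#' @param x an [otu_table].
#' @param md metadata data.frame with a `sample_id` column.
#' @return invisibly, `md` reordered to the table's samples.
#' @export
validate_metadata <- function(x, md) {
  missing <- setdiff(sample_ids(x), md$sample_id)
  if (length(missing))
    stop("samples without metadata: ", paste(missing, collapse = ", "))
  invisible(md[match(sample_ids(x), md$sample_id), , drop = FALSE])
}

#' Remove singleton and ultra-rare taxa
#'
#' Reproduces the standard amplicon cleaning step: taxa whose total count
#' across all samples is 1 (singletons) are removed, as are taxa whose total
#' relative abundance (taxon total divided by the pre-filter grand total) is
#' below `min_rel_abund` (default 0.005%).
#'
#' @param x an [otu_table].
#' @param min_rel_abund minimum total relative abundance, default `5e-5`.
#' @param drop_singletons remove taxa with total count 1 (default `TRUE`).
#' @return filtered [otu_table]; attributes `n_singletons_removed` and
#'   `n_rare_removed` report counts removed per rule.
#' @export
filter_otus <- function(x, min_rel_abund = 5e-5, drop_singletons = TRUE) {
  stopifnot(min_rel_abund >= 0, min_rel_abund < 1)
  tot <- rowSums(x$counts)
  grand <- sum(tot)
  singleton <- drop_singletons & (tot == 1L)
  rare <- (tot / grand) < min_rel_abund
  keep <- !(singleton | rare)
  if (!any(keep)) stop("all taxa filtered; nothing left")
  out <- otu_table(x$counts[keep, , drop = FALSE], taxonomy = x$taxonomy)
  attr(out, "n_singletons_removed") <- sum(singleton)
  attr(out, "n_rare_removed") <- sum(rare & !singleton)
  out
}

#' Rarefy (subsample) every sample to a common depth
#'
#' Subsampling is without replacement, so a sample already at `depth`
#' is returned unchanged (up to taxon order) and taxa absent before
#' rarefaction stay absent.
#'
#' @param x an [otu_table].
#' @param depth target reads per sample; default the minimum sample depth.
#' @param seed integer seed for reproducibility.
#' @param drop_shallow if `TRUE`, samples shallower than `depth` are dropped
#'   with a warning instead of raising an error.
#' @return rarefied [otu_table].
#' @export
rarefy <- function(x, depth = NULL, seed = 1L, drop_shallow = FALSE) {
  depths <- sample_depths(x)
  if (is.null(depth)) depth <- min(depths)
  stopifnot(depth >= 1)
  if (all(depths < depth)) stop("depth exceeds every sample total")
  shallow <- depths < depth
  if (any(shallow)) {
    if (!drop_shallow)
      stop("samples shallower than depth: ",
           paste(names(depths)[shallow], collapse = ", "),
           " (use drop_shallow = TRUE to drop them)")
    warning("dropping ", sum(shallow), " sample(s) shallower than ", depth)
  }
  counts <- x$counts[, !shallow, drop = FALSE]
  set.seed(as.integer(seed))
  out <- counts
  for (j in seq_len(ncol(counts))) {
    cj <- counts[, j]
    if (sum(cj) == depth) next
    reads <- rep.int(seq_along(cj), cj)
    keep <- sample(reads, depth, replace = FALSE)
    out[, j] <- tabulate(keep, nbins = length(cj))
  }
  suppressWarnings(otu_table(out, taxonomy = x$taxonomy))
}

#' Total-sum scaling (relative abundance) view
#'
#' Alternative to rarefaction: returns per-sample proportions.  Kept as a
#' plain numeric matrix because counts in an `otu_table` are always integer.
#'
#' @param x an [otu_table].
#' @return taxa x samples matrix of proportions.
#' @export
total_sum_scale <- function(x) rel_abund(x)

#' Aggregate counts at a taxonomic rank
#'
#' Sums counts over taxa sharing the lineage prefix down to `rank` (1-based
#' index into the semicolon-delimited lineage, e.g. 3 = class for a
#' kingdom;phylum;class;... string).
#'
#' @param x an [otu_table] carrying taxonomy.
#' @param rank integer lineage position.
#' @return an [otu_table] whose rows are lineage groups.
#' @export
aggregate_rank <- function(x, rank) {
  if (is.null(x$taxonomy)) stop("table carries no taxonomy")
  lin <- strsplit(unname(x$taxonomy[rownames(x$counts)]), ";", fixed = TRUE)
  key <- vapply(lin, function(v)
    if (length(v) >= rank) trimws(v[[rank]]) else "unclassified", character(1))
  key[is.na(key) | key == ""] <- "unclassified"
  agg <- rowsum(x$counts, group = key)
  otu_table(agg)
}
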