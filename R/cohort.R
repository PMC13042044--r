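#' Cohort table container
#'
#' Bundles a species-by-sample relative-abundance matrix with per-sample
#' metadata.  Every model in the package consumes this unit.  Column sums of
#' the abundance matrix are 1 (up to numerical tolerance); metadata has one
#' row per sample column, keyed by `sample_id`.
#'
#' @param abundance numeric matrix, rows = species, columns = samples, values
#'   relative abundances in `[0, 1]`.
#' @param metadata data.frame with a `sample_id` column covering every
#'   abundance column.
#' @return An object of class `cohort_table`: a list with elements
#'   `abundance` and `metadata`.
#' @export
cohort_table <- function(abundance, metadata) {
  if (!is.matrix(abundance) || !is.numeric(abundance))
    stopf("abundance must be a numeric matrix")
  if (is.null(rownames(abundance)) || is.null(colnames(abundance)))
    stopf("abundance matrix needs species rownames and sample colnames")
  if (anyDuplicated(rownames(abundance)))
    stopf("duplicate species identifiers in abundance matrix")
  if (anyDuplicated(colnames(abundance)))
    stopf("duplicate sample identifiers in abundance matrix")
  if (!"sample_id" %in% names(metadata))
    stopf("metadata lacks a sample_id column")
  missing <- setdiff(colnames(abundance), metadata$sample_id)
  if (length(missing))
    stopf("metadata does not cover samples: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  nonzero <- colSums(abundance) > 0
  bad <- abs(colSums(abundance)[nonzero] - 1) > 1e-6
  if (any(bad))
    stopf("abundance columns do not sum to 1: %s",
          paste(utils::head(colnames(abundance)[nonzero][bad], 5),
                collapse = ", "))
  metadata <- metadata[match(colnames(abundance), metadata$sample_id), ,
                       drop = FALSE]
  rownames(metadata) <- NULL
  structure(list(abundance = abundance, metadata = metadata),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("cohort_table: %d species x %d samples",
              nrow(x$abundance), ncol(x$abundance)))
  if ("study_id" %in% names(x$metadata))
    cat(sprintf(" (%d studies)", length(unique(x$metadata$study_id))))
  cat("\n")
  invisible(x)
}

#' Write a cohort table to a directory as two TSV files
#'
#' `abundance.tsv` holds the species-by-sample matrix (first column
#' `species_id`); `metadata.tsv` holds one row per sample.
#'
#' @param cohort a [cohort_table()].
#' @param dir output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ab <- data.frame(species_id = rownames(cohort$abundance),
                   cohort$abundance, check.names = FALSE)
  p1 <- file.path(dir, "abundance.tsv")
  p2 <- file.path(dir, "metadata.tsv")
  utils::write.table(ab, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$metadata, p2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(abundance = p1, metadata = p2))
}

#' Read a cohort table written by [write_cohort()]
#'
#' @param dir directory containing `abundance.tsv` and `metadata.tsv`.
#' @return A [cohort_table()].
#' @export
read_cohort <- function(dir) {
  ab <- utils::read.delim(file.path(dir, "abundance.tsv"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  md <- utils::read.delim(file.path(dir, "metadata.tsv"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(ab[, -1, drop = FALSE])
  rownames(m) <- ab$species_id
  cohort_table(m, md)
}
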