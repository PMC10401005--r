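#' Construct a PAV matrix
#'
#' The central container of the pipeline: a genes-by-accessions binary
#' presence matrix (1 = present, 0 = absent) together with per-accession
#' metadata profiles.
#'
#' @param presence Integer or logical matrix, genes in rows and accessions
#'   in columns, with complete `dimnames`. Entries must be 0/1.
#' @param profiles Data frame of accession metadata with at least an
#'   `accession_id` column matching `colnames(presence)`. Conventional
#'   columns are `mean_depth` (reads), `group` (one of `"wild"`,
#'   `"landrace"`, `"cultivar"`), `clade`, `ploidy` (2--5) and `in_vitro`
#'   (logical).
#'
#' @return An object of class `pav_matrix`: a list with elements
#'   `presence` (integer matrix) and `profiles` (data frame, rows ordered
#'   as the matrix columns).
#' @export
#'
#' @examples
#' m <- matrix(c(1L, 0L, 1L, 1L), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("acc1", "acc2")))
#' prof <- data.frame(accession_id = c("acc1", "acc2"), group = "wild")
#' pav <- pav_matrix(m, prof)
#' gene_ids(pav)
pav_matrix <- function(presence, profiles = NULL) {
  if (!is.matrix(presence)) {
    stop("`presence` must be a matrix")
  }
  if (is.logical(presence)) {
    storage.mode(presence) <- "integer"
  }
  if (!all(presence %in% c(0L, 1L))) {
    stop("`presence` entries must be 0 or 1")
  }
  if (is.null(rownames(presence)) || is.null(colnames(presence))) {
    stop("`presence` must carry gene row names and accession column names")
  }
  if (anyDuplicated(rownames(presence)) || anyDuplicated(colnames(presence))) {
    stop("gene and accession identifiers must be unique")
  }
  storage.mode(presence) <- "integer"
  if (is.null(profiles)) {
    profiles <- data.frame(accession_id = colnames(presence),
                           stringsAsFactors = FALSE)
  }
  if (!"accession_id" %in% names(profiles)) {
    stop("`profiles` must have an `accession_id` column")
  }
  missing <- setdiff(colnames(presence), profiles$accession_id)
  if (length(missing) > 0) {
    stop("profiles missing for accession(s): ",
         paste(head(missing, 5), collapse = ", "))
  }
  profiles <- profiles[match(colnames(presence), profiles$accession_id), ,
                       drop = FALSE]
  rownames(profiles) <- NULL
  structure(list(presence = presence, profiles = profiles),
            class = "pav_matrix")
}

#' @export
print.pav_matrix <- function(x, ...) {
  cat(sprintf("pav_matrix: %d genes x %d accessions\n",
              nrow(x$presence), ncol(x$presence)))
  freq <- mean(x$presence)
  cat(sprintf("  overall presence rate: %.3f\n", freq))
  if ("group" %in% names(x$profiles)) {
    tab <- table(x$profiles$group)
    cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @rdname pav_matrix
#' @param pav A `pav_matrix`.
#' @export
gene_ids <- function(pav) rownames(pav$presence)

#' @rdname pav_matrix
#' @export
accession_ids <- function(pav) colnames(pav$presence)

#' Per-accession gene counts
#'
#' Number of genes called present in each accession.
#'
#' @param pav A `pav_matrix`.
#' @return Named integer vector, one entry per accession.
#' @export
accession_gene_counts <- function(pav) {
  colSums(pav$presence)
}

stopifnot_pav <- function(pav) {
  if (!inherits(pav, "pav_matrix")) stop("expected a `pav_matrix` object")
  invisible(pav)
}

match_accessions <- function(pav, ids, what = "accession") {
  unknown <- setdiff(ids, accession_ids(pav))
  if (length(unknown) > 0) {
    stop("unknown ", what, "(s): ", paste(head(unknown, 5), collapse = ", "))
  }
  match(ids, accession_ids(pav))
}
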