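#' Beta value from methylated/unmethylated signal intensities
#'
#' Converts Illumina array signal intensities to the methylation beta
#' value `M / (U + M + 100)`, the standard offset-stabilised ratio of
#' methylated signal to total signal. Vectorised over `M` and `U`.
#'
#' @param M Methylated signal intensity (non-negative; vectorised).
#' @param U Unmethylated signal intensity (non-negative; vectorised).
#' @return Beta values in \[0, 1). `NA` inputs give `NA`.
#' @examples
#' beta_value(300, 100) # 0.6
#' @export
beta_value <- function(M, U) {
  if (any(M < 0, na.rm = TRUE) || any(U < 0, na.rm = TRUE))
    stop("signal intensities must be non-negative", call. = FALSE)
  M / (U + M + 100)
}

#' Restrict beta matrices to their common CpG sites
#'
#' Mirrors the cross-platform design in which only probes measured by
#' every array involved are analysed: all matrices are restricted to the
#' sorted intersection of their site ids, so downstream pair mining and
#' concordance work on an identical ordered site universe.
#'
#' @param matrices A list of two or more [beta_matrix()] objects.
#' @return A list of beta matrices, each restricted to the common sites
#'   in the same (sorted) order; sample columns are untouched.
#' @export
intersect_probes <- function(matrices) {
  if (!is.list(matrices) || length(matrices) < 2)
    stop("`matrices` must be a list of at least two beta matrices",
         call. = FALSE)
  common <- Reduce(intersect, lapply(matrices, site_ids))
  if (length(common) == 0) {
    nms <- names(matrices)
    if (is.null(nms)) nms <- paste0("matrix", seq_along(matrices))
    stop("no CpG sites shared by: ", paste(nms, collapse = ", "),
         call. = FALSE)
  }
  common <- sort(common)
  lapply(matrices, bm_subset, sites = common)
}

#' Read / write a beta matrix as TSV
#'
#' The TSV dialect is: a header row of sample ids, first column
#' `probe_id`, tab-separated, `NA` for missing cells. Values outside
#' \[0, 1\] or duplicated probe ids are rejected with the offending line
#' number.
#'
#' @param path File path.
#' @param group Optional group labels for the samples (see
#'   [beta_matrix()]).
#' @return `read_beta_matrix` returns a [beta_matrix()];
#'   `write_beta_matrix` returns `path` invisibly.
#' @export
read_beta_matrix <- function(path, group = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c("character"))
  if (names(df)[1] != "probe_id")
    stop("first column must be `probe_id` in ", path, call. = FALSE)
  ids <- df[[1]]
  dup <- which(duplicated(ids))
  if (length(dup))
    stop(sprintf("duplicate probe_id '%s' at line %d of %s",
                 ids[dup[1]], dup[1] + 1L, path), call. = FALSE)
  raw <- as.matrix(df[-1])
  vals <- suppressWarnings(
    matrix(as.numeric(raw), nrow(raw), ncol(raw),
           dimnames = list(NULL, colnames(raw))))
  nonnum <- which(is.na(vals) & !is.na(raw) & !(raw %in% c("NA", "")),
                  arr.ind = TRUE)
  if (nrow(nonnum))
    stop(sprintf("non-numeric value at line %d of %s",
                 nonnum[1, 1] + 1L, path), call. = FALSE)
  bad <- which(!is.na(vals) & (vals < 0 | vals > 1), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("beta value out of [0,1] at line %d of %s",
                 bad[1, 1] + 1L, path), call. = FALSE)
  rownames(vals) <- ids
  beta_matrix(vals, group = group)
}

#' @rdname read_beta_matrix
#' @param x A [beta_matrix()].
#' @export
write_beta_matrix <- function(x, path) {
  df <- data.frame(probe_id = site_ids(x), unclass(x)[, , drop = FALSE],
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe-to-gene promoter annotation table
#'
#' Expects TSV columns `probe_id` and `gene_symbol`. If a probe appears
#' on several rows only the first listed gene is kept, with a warning
#' (the annotation convention of taking the primary promoter
#' association).
#'
#' @param path File path.
#' @return A data.frame with columns `probe_id`, `gene_symbol`, one row
#'   per probe.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  if (!all(c("probe_id", "gene_symbol") %in% names(df)))
    stop("annotation TSV needs columns probe_id, gene_symbol", call. = FALSE)
  df <- df[, c("probe_id", "gene_symbol")]
  if (anyDuplicated(df$probe_id)) {
    warning(sum(duplicated(df$probe_id)),
            " probes annotated to multiple genes; keeping first listed gene")
    df <- df[!duplicated(df$probe_id), ]
  }
  rownames(df) <- NULL
  df
}

#' Read / write pathway gene sets in GMT format
#'
#' @param path File path to a standard GMT file (name, description,
#'   tab-separated gene symbols).
#' @return `read_gmt` returns a named list of character vectors of gene
#'   symbols.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @param pathways Named list of character vectors of gene symbols.
#' @param descriptions Optional character vector of descriptions (second
#'   GMT column); defaults to the pathway names.
#' @export
write_gmt <- function(pathways, path, descriptions = NULL) {
  if (is.null(names(pathways)) || any(names(pathways) == ""))
    stop("pathways must be a named list", call. = FALSE)
  if (is.null(descriptions)) descriptions <- names(pathways)
  lines <- vapply(seq_along(pathways), function(i) {
    paste(c(names(pathways)[i], descriptions[i], pathways[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
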