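#' Methylation beta-value matrix
#'
#' A `beta_matrix` is a numeric matrix of methylation beta values in
#' \[0, 1\] with CpG sites as rows and samples as columns, plus an
#' optional per-sample group label (`"normal"`, `"tumor"` or
#' `"adjacent_normal"`). Missing values (`NA`) are allowed and are
#' treated downstream as "no information".
#'
#' @param values Numeric matrix, sites x samples, with unique rownames
#'   (CpG/probe identifiers) and unique colnames (sample identifiers).
#' @param group Optional character vector of group labels, one per
#'   sample (recycled from a single value). Must be one of `"normal"`,
#'   `"tumor"`, `"adjacent_normal"`.
#' @return An object of class `beta_matrix`: the value matrix with a
#'   `group` attribute.
#' @export
beta_matrix <- function(values, group = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values))))
    stop("`values` must have rownames (site ids) and colnames (sample ids)",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate site ids in beta matrix", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in beta matrix", call. = FALSE)
  ok <- values[!is.na(values)]
  if (any(!is.finite(ok)))
    stop("non-finite beta values", call. = FALSE)
  if (any(ok < 0 | ok > 1))
    stop("beta values must lie in [0, 1]", call. = FALSE)
  if (!is.null(group)) {
    group <- rep_len(as.character(group), ncol(values))
    bad <- setdiff(unique(group), c("normal", "tumor", "adjacent_normal"))
    if (length(bad))
      stop("unknown group label(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    names(group) <- colnames(values)
  }
  structure(values, group = group, class = c("beta_matrix", "matrix", "array"))
}

#' @export
print.beta_matrix <- function(x, ...) {
  grp <- attr(x, "group")
  cat(sprintf("beta_matrix: %d CpG sites x %d samples\n", nrow(x), ncol(x)))
  if (!is.null(grp)) {
    tab <- table(grp)
    cat("groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}

site_ids <- function(x) rownames(x)
sample_ids <- function(x) colnames(x)
sample_groups <- function(x) attr(x, "group")

#' Subset a beta matrix keeping its class and group labels
#' @noRd
bm_subset <- function(x, sites = NULL, samples = NULL) {
  grp <- attr(x, "group")
  v <- unclass(x)
  attr(v, "group") <- NULL
  if (!is.null(sites)) v <- v[sites, , drop = FALSE]
  if (!is.null(samples)) {
    v <- v[, samples, drop = FALSE]
    if (!is.null(grp)) grp <- grp[colnames(v)]
  }
  beta_matrix(v, group = grp)
}
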