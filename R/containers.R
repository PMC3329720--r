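#' Construct an omics intensity matrix
#'
#' An `omics_matrix` is a numeric element-by-sample intensity matrix for one
#' measurement platform. Rows are molecular elements (genes or metabolites),
#' columns are samples; both must carry unique identifiers and every value
#' must be finite.
#'
#' @param values numeric matrix, elements in rows, samples in columns.
#' @param platform `"gene"` or `"metabolite"`.
#' @param element_ids,sample_ids optional identifier vectors; taken from
#'   `dimnames(values)` when omitted.
#'
#' @return A numeric matrix of class `omics_matrix` with a `platform`
#'   attribute.
#' @export
omics_matrix <- function(values, platform = c("gene", "metabolite"),
                         element_ids = rownames(values),
                         sample_ids = colnames(values)) {
  platform <- match.arg(platform)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(element_ids) || is.null(sample_ids))
    stop("omics_matrix requires element and sample identifiers", call. = FALSE)
  element_ids <- as.character(element_ids)
  sample_ids <- as.character(sample_ids)
  if (length(element_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  if (anyDuplicated(element_ids))
    stop("duplicate element ids: ",
         paste(unique(element_ids[duplicated(element_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  if (!all(is.finite(values)))
    stop("omics_matrix values must all be finite", call. = FALSE)
  dimnames(values) <- list(element_ids, sample_ids)
  structure(values, platform = platform, class = c("omics_matrix", "matrix", "array"))
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix [%s]: %d elements x %d samples\n",
              attr(x, "platform"), nrow(x), ncol(x)))
  if (nrow(x) > 0 && ncol(x) > 0) {
    show <- x[seq_len(min(5L, nrow(x))), seq_len(min(5L, ncol(x))), drop = FALSE]
    print(unclass(show))
    if (nrow(x) > 5L || ncol(x) > 5L) cat("...\n")
  }
  invisible(x)
}

#' Construct a binary phenotype vector
#'
#' Case/control labels for the samples of an [omics_matrix()]: 1 = case,
#' 0 = control. Both groups must be non-empty.
#'
#' @param sample_ids character sample identifiers.
#' @param group integer/logical vector of the same length; coerced to 0/1.
#'
#' @return Named integer vector of class `phenotype_vector`.
#' @export
phenotype_vector <- function(sample_ids, group) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids in phenotype", call. = FALSE)
  if (length(group) != length(sample_ids))
    stop("sample_ids and group lengths differ", call. = FALSE)
  group <- as.integer(group)
  if (anyNA(group) || !all(group %in% c(0L, 1L)))
    stop("group must be binary 0/1", call. = FALSE)
  if (!any(group == 1L) || !any(group == 0L))
    stop("both case and control groups must be non-empty", call. = FALSE)
  structure(stats::setNames(group, sample_ids), class = "phenotype_vector")
}

#' @export
print.phenotype_vector <- function(x, ...) {
  cat(sprintf("phenotype_vector: %d samples (%d cases, %d controls)\n",
              length(x), sum(x == 1L), sum(x == 0L)))
  invisible(x)
}

# align a phenotype vector to a matrix's samples; errors on mismatch
align_phenotype <- function(mat, labels) {
  if (!inherits(labels, "phenotype_vector"))
    stop("labels must be a phenotype_vector", call. = FALSE)
  missing <- setdiff(names(labels), colnames(mat))
  if (length(missing))
    stop("phenotype references samples absent from the matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  missing2 <- setdiff(colnames(mat), names(labels))
  if (length(missing2))
    stop("matrix samples missing from the phenotype: ",
         paste(missing2, collapse = ", "), call. = FALSE)
  as.integer(labels[colnames(mat)])
}

#' Construct a named collection of element sets
#'
#' Holds, per platform, the membership of molecular elements in named sets
#' (the \eqn{g_{jS}} / \eqn{m_{kS}} indicators). Sets are stored as named
#' lists of element-identifier vectors, the in-memory form of a GMT file; a
#' set name shared across the two platforms links its gene and metabolite
#' members into one cross-platform set.
#'
#' @param gene,metabolite named lists of character vectors (element ids per
#'   set). Either may be `NULL`, but every set must have at least one member
#'   on at least one platform.
#'
#' @return List of class `set_collection` with fields `gene`, `metabolite`,
#'   `set_names`.
#' @export
set_collection <- function(gene = NULL, metabolite = NULL) {
  check_platform_sets <- function(x, what) {
    if (is.null(x)) return(list())
    if (!is.list(x) || is.null(names(x)) || any(names(x) == ""))
      stop(what, " sets must be a named list", call. = FALSE)
    if (anyDuplicated(names(x)))
      stop("duplicate set names in ", what, " sets", call. = FALSE)
    lapply(x, function(v) unique(as.character(v)))
  }
  gene <- check_platform_sets(gene, "gene")
  metabolite <- check_platform_sets(metabolite, "metabolite")
  set_names <- union(names(gene), names(metabolite))
  if (!length(set_names)) stop("set_collection is empty", call. = FALSE)
  sizes <- vapply(set_names, function(s)
    length(gene[[s]]) + length(metabolite[[s]]), integer(1))
  if (any(sizes == 0L))
    stop("sets with no members on any platform: ",
         paste(set_names[sizes == 0L], collapse = ", "), call. = FALSE)
  structure(list(gene = gene, metabolite = metabolite, set_names = set_names),
            class = "set_collection")
}

#' @export
print.set_collection <- function(x, ...) {
  cat(sprintf("set_collection: %d sets (%d with gene members, %d with metabolite members)\n",
              length(x$set_names), length(x$gene), length(x$metabolite)))
  invisible(x)
}

#' Binary set-membership matrix for one platform
#'
#' @param sets a [set_collection()].
#' @param element_ids identifiers of the measured elements (membership is
#'   restricted to these).
#' @param platform `"gene"` or `"metabolite"`.
#'
#' @return Integer 0/1 matrix, sets in rows (all `sets$set_names`), measured
#'   elements in columns.
#' @export
membership_matrix <- function(sets, element_ids, platform = c("gene", "metabolite")) {
  platform <- match.arg(platform)
  stopifnot(inherits(sets, "set_collection"))
  element_ids <- as.character(element_ids)
  m <- matrix(0L, nrow = length(sets$set_names), ncol = length(element_ids),
              dimnames = list(sets$set_names, element_ids))
  plat <- sets[[platform]]
  for (s in names(plat)) {
    hit <- element_ids %in% plat[[s]]
    if (any(hit)) m[s, hit] <- 1L
  }
  m
}
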