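#' Read an intensity matrix from TSV
#'
#' Dialect: UTF-8 tab-separated values, '.' decimal separator, a header
#' row of sample ids, first column the element id; every value numeric and
#' finite (NA is not accepted). Malformed or ragged lines are reported
#' with their line numbers.
#'
#' @param path file path.
#' @param platform `"gene"` or `"metabolite"`.
#' @return An [omics_matrix()].
#' @export
read_matrix <- function(path, platform = c("gene", "metabolite")) {
  platform <- match.arg(platform)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) != 1L)
    stop("ragged rows in ", path, " at line(s): ",
         paste(which(nf != nf[1]), collapse = ", "), call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("matrix TSV needs an id column plus samples",
                          call. = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m) || anyNA(m) || !all(is.finite(m))) {
    bad <- which(apply(df[, -1L, drop = FALSE], 1L,
                       function(r) anyNA(suppressWarnings(as.numeric(r)))))
    stop("non-numeric or missing values in ", path, " at data line(s): ",
         paste(utils::head(bad + 1L, 10L), collapse = ", "), call. = FALSE)
  }
  rownames(m) <- ids
  omics_matrix(m, platform)
}

#' Write an intensity matrix to TSV
#'
#' @param mat an [omics_matrix()] (or plain named matrix).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(mat, path) {
  df <- data.frame(element_id = rownames(mat), unclass(mat),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read one platform's sets from a GMT file
#'
#' One set per line: `set_name <TAB> description <TAB> member ids...`.
#' A line without at least one member id is a parse error naming the line.
#'
#' @param path file path.
#' @return Named list of character member vectors (feed to
#'   [set_collection()]).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short))
    stop("GMT line(s) without members in ", path, ": line ",
         paste(short, collapse = ", "), call. = FALSE)
  out <- lapply(parts, function(p) p[-(1:2)])
  names(out) <- vapply(parts, `[`, "", 1L)
  if (anyDuplicated(names(out)))
    stop("duplicate set names in ", path, call. = FALSE)
  out
}

#' Write one platform's sets to a GMT file
#'
#' @param sets named list of member-id vectors, or a [set_collection()]
#'   with `platform` naming which side to write.
#' @param path output file.
#' @param platform used when `sets` is a `set_collection`.
#' @param description description field (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, platform = c("gene", "metabolite"),
                      description = "na") {
  if (inherits(sets, "set_collection")) {
    platform <- match.arg(platform)
    sets <- sets[[platform]]
  }
  lines <- vapply(names(sets), function(s)
    paste(c(s, description, sets[[s]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read case/control labels from TSV
#'
#' Two columns with a header: `sample_id`, `group` (0 = control,
#' 1 = case).
#'
#' @param path file path.
#' @return A [phenotype_vector()].
#' @export
read_phenotype <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group")
  if (!all(need %in% names(df)))
    stop("phenotype TSV must have header columns 'sample_id' and 'group'",
         call. = FALSE)
  phenotype_vector(df$sample_id, df$group)
}

#' Write case/control labels to TSV
#'
#' @param labels a [phenotype_vector()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_phenotype <- function(labels, path) {
  utils::write.table(
    data.frame(sample_id = names(labels), group = as.integer(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an enrichment results table to TSV
#'
#' Columns: `set_name`, `method`, `statistic`, `p_value`, `direction`,
#' `n_genes`, `n_metabolites` - one row per set x method. Permutation
#' p-values below resolution are written as 0; the permutation count is
#' recorded in the run log.
#'
#' @param results an `intenrich` fit or its results data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  if (inherits(results, "intenrich")) results <- results$results
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an enrichment results table written by [write_results()]
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write simulation ground truth to TSV
#'
#' Two files: `<stem>_elements.tsv` (element_id, platform, diff_flag) and
#' `<stem>_sets.tsv` (set_name, associated_flag, null_flag).
#'
#' @param truth a `sim_truth`.
#' @param stem output path stem.
#' @return Character vector of the two paths, invisibly.
#' @export
write_truth <- function(truth, stem) {
  stopifnot(inherits(truth, "sim_truth"))
  p1 <- paste0(stem, "_elements.tsv")
  p2 <- paste0(stem, "_sets.tsv")
  el <- rbind(
    data.frame(element_id = names(truth$diff_gene), platform = "gene",
               diff_flag = as.integer(truth$diff_gene)),
    data.frame(element_id = names(truth$diff_metab), platform = "metabolite",
               diff_flag = as.integer(truth$diff_metab)))
  utils::write.table(el, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  si <- truth$set_info
  utils::write.table(
    data.frame(set_name = si$set_name,
               associated_flag = as.integer(si$set_name %in%
                                              truth$associated_sets),
               null_flag = as.integer(si$null)),
    p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}
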