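#' Validate a gene x sample expression matrix
#'
#' Expression matrices are plain numeric matrices with genes in rows
#' (rownames = gene ids, possibly duplicated before duplication handling)
#' and samples in columns (colnames = unique sample ids). All values must
#' be finite.
#'
#' @param x numeric matrix, genes in rows.
#' @param allow_duplicate_genes if `FALSE`, duplicated gene ids are an error.
#' @return `x`, invisibly, after validation.
#' @export
validate_expression_matrix <- function(x, allow_duplicate_genes = TRUE) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression matrix must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(colnames(x)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (!allow_duplicate_genes && anyDuplicated(rownames(x)))
    stop("duplicate gene ids present")
  if (!all(is.finite(x)))
    stop("expression matrix contains non-finite values")
  invisible(x)
}

#' Construct a cell-line screen
#'
#' Bundles a gene x cell-line expression matrix with a drug x cell-line
#' table of ln(IC50) values (lower = more sensitive), tissue labels and the
#' landmark / housekeeping gene sets used by feature filtering and RUV-type
#' homogenization.
#'
#' @param expression gene x cell-line numeric matrix.
#' @param response drug x cell-line numeric matrix of ln(IC50); `NA` marks
#'   unscreened combinations. Rownames are drug names.
#' @param tissues named character vector, one tissue label per cell line.
#' @param landmark_genes,housekeeping_genes character vectors of gene ids.
#' @return an object of class `cell_screen`.
#' @export
cell_screen <- function(expression, response, tissues = NULL,
                        landmark_genes = character(),
                        housekeeping_genes = character()) {
  validate_expression_matrix(expression)
  if (!is.matrix(response) || is.null(rownames(response)))
    stop("response must be a drug x cell-line matrix with drug rownames")
  if (!all(colnames(response) %in% colnames(expression)))
    stop("response columns must be a subset of expression sample ids")
  n_ok <- rowSums(!is.na(response))
  if (any(n_ok < 2))
    stop("every drug needs >= 2 non-missing responses; offending: ",
         paste(rownames(response)[n_ok < 2], collapse = ", "))
  if (is.null(tissues))
    tissues <- stats::setNames(rep("unspecified", ncol(expression)),
                               colnames(expression))
  universe <- unique(rownames(expression))
  if (!all(landmark_genes %in% universe))
    stop("landmark genes outside the gene universe")
  if (!all(housekeeping_genes %in% universe))
    stop("housekeeping genes outside the gene universe")
  structure(list(expression = expression, response = response,
                 tissues = tissues,
                 landmark_genes = landmark_genes,
                 housekeeping_genes = housekeeping_genes),
            class = "cell_screen")
}

#' @exportS3Method base::print
print.cell_screen <- function(x, ...) {
  cat("cell_screen:", nrow(x$expression), "genes x",
      ncol(x$expression), "cell lines;",
      nrow(x$response), "drug(s);",
      length(x$landmark_genes), "landmark,",
      length(x$housekeeping_genes), "housekeeping genes\n")
  invisible(x)
}

#' Construct a patient cohort
#'
#' @param expression gene x patient numeric matrix.
#' @param response named 0/1 vector (1 = responder), one entry per patient.
#' @param raw_labels optional named character vector of clinical categories.
#' @param survival_months optional named numeric vector.
#' @return an object of class `patient_cohort`.
#' @export
patient_cohort <- function(expression, response, raw_labels = NULL,
                           survival_months = NULL) {
  validate_expression_matrix(expression)
  samples <- colnames(expression)
  if (!all(samples %in% names(response)))
    stop("response must be defined for every expression sample")
  response <- response[samples]
  if (!all(response %in% c(0, 1)))
    stop("response must be binary 0/1")
  structure(list(expression = expression, response = response,
                 raw_labels = raw_labels,
                 survival_months = survival_months),
            class = "patient_cohort")
}

#' @exportS3Method base::print
print.patient_cohort <- function(x, ...) {
  cat("patient_cohort:", nrow(x$expression), "genes x",
      ncol(x$expression), "patients;",
      sum(x$response == 1), "responders /", sum(x$response == 0),
      "non-responders\n")
  invisible(x)
}

#' Read a delimited expression matrix
#'
#' Expects one header row of sample ids and a first column of gene ids.
#' Parsing is strict: any cell that does not coerce to a finite number is an
#' error naming its row and column.
#'
#' @param path file path (TSV by default).
#' @param orientation `"genes_in_rows"` (default) or `"samples_in_rows"`;
#'   the returned matrix is always genes in rows.
#' @param sep field separator.
#' @return numeric gene x sample matrix.
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("genes_in_rows",
                                                   "samples_in_rows"),
                                   sep = "\t") {
  orientation <- match.arg(orientation)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           row.names = NULL, check.names = FALSE,
                           colClasses = "character", quote = "\"")
  ids <- raw[[1L]]
  sample_ids <- colnames(raw)[-1L]   # before subsetting uniquifies them
  body <- as.matrix(raw[, -1L, drop = FALSE])
  colnames(body) <- sample_ids
  suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(!is.finite(num) & body != "", arr.ind = TRUE)
  if (length(bad) == 0 && any(!is.finite(num)))
    bad <- which(!is.finite(num), arr.ind = TRUE)
  if (length(bad) > 0) {
    stop(sprintf("non-numeric cell at row '%s', column '%s' in %s",
                 ids[bad[1, 1]], colnames(body)[bad[1, 2]], path))
  }
  dimnames(num) <- list(ids, colnames(body))
  if (orientation == "samples_in_rows") num <- t(num)
  validate_expression_matrix(num)
  num
}

#' Write an expression matrix (genes in rows) to a delimited file
#'
#' Round-trips with [read_expression_matrix()].
#'
#' @param x gene x sample matrix.
#' @param path output path.
#' @param sep field separator.
#' @export
write_expression_matrix <- function(x, path, sep = "\t") {
  validate_expression_matrix(x)
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove duplicated gene names from a train/test matrix pair
#'
#' Every gene id occurring more than once in either matrix is removed from
#' both, entirely (all of its rows; duplicated names are never collapsed).
#'
#' @param train,test gene x sample matrices.
#' @return list with elements `train` and `test`, both with unique gene ids.
#' @export
remove_duplicate_genes <- function(train, test) {
  g1 <- rownames(train); g2 <- rownames(test)
  dups <- union(unique(g1[duplicated(g1)]), unique(g2[duplicated(g2)]))
  out_train <- train[!(g1 %in% dups), , drop = FALSE]
  out_test <- test[!(g2 %in% dups), , drop = FALSE]
  if (nrow(out_train) == 0 || nrow(out_test) == 0)
    stop("duplication handling removed all genes")
  list(train = out_train, test = out_test)
}

#' Ordered train/test gene intersection
#'
#' @param train,test gene x sample matrices with unique gene ids
#'   (duplication handling already applied).
#' @return character vector of shared gene ids in training order.
#' @export
intersect_features <- function(train, test) {
  if (anyDuplicated(rownames(train)) || anyDuplicated(rownames(test)))
    stop("apply remove_duplicate_genes() before intersecting features")
  shared <- rownames(train)[rownames(train) %in% rownames(test)]
  if (length(shared) == 0)
    stop("train and test share no genes")
  shared
}

#' Binarize clinical response categories
#'
#' @param labels named character vector of clinical categories.
#' @param responder_set categories counted as responders (e.g. `c("cCR",
#'   "cPR")` or `c("CR", "PR", "MR")`).
#' @param nonresponder_set categories counted as non-responders; every label
#'   must fall in one of the two sets.
#' @return named 0/1 vector (1 = responder).
#' @export
binarize_clinical_labels <- function(labels, responder_set,
                                     nonresponder_set) {
  known <- c(responder_set, nonresponder_set)
  unknown <- setdiff(unique(labels), known)
  if (length(unknown) > 0)
    stop("unknown clinical label(s): ", paste(unknown, collapse = ", "))
  stats::setNames(as.integer(labels %in% responder_set), names(labels))
}

#' Binarize progression-free survival at the median
#'
#' Patients with survival strictly above the cohort median are responders;
#' values equal to the median go to the non-responder class (deterministic,
#' conservative tie rule).
#'
#' @param months named numeric vector of progression-free survival.
#' @return named 0/1 vector.
#' @export
median_split_survival <- function(months) {
  if (length(months) < 2) stop("need >= 2 samples")
  if (length(unique(months)) == 1)
    stop("all survival values identical; no median split possible")
  med <- stats::median(months)
  stats::setNames(as.integer(months > med), names(months))
}
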