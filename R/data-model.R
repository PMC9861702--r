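REGRESSION_TASKS <- c("loewe", "bliss", "zip", "hsa", "s")
CLASSIFICATION_TASKS <- c("synergy", "ddi")

#' Feature store for drug descriptors and cell-line expression profiles
#'
#' Bundles the two feature lookup tables used as model input: one row per
#' drug of continuous chemical descriptors and one row per cell line of
#' normalized landmark-gene expression values. All drug vectors must share
#' a common length \code{p_d} and all cell-line vectors a common length
#' \code{p_c}; no non-finite values are allowed.
#'
#' @param drug numeric matrix of drug descriptors, rownames are drug ids.
#' @param cell numeric matrix of cell-line expression values, rownames are
#'   cell-line ids.
#' @return An object of class \code{"feature_store"} with elements
#'   \code{drug}, \code{cell}, \code{p_d}, \code{p_c}.
#' @export
feature_store <- function(drug, cell) {
  drug <- as.matrix(drug)
  cell <- as.matrix(cell)
  for (nm in c("drug", "cell")) {
    m <- if (nm == "drug") drug else cell
    if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
      stop(sprintf("%s feature matrix needs unique rownames (ids)", nm))
    if (!is.numeric(m) || any(!is.finite(m)))
      stop(sprintf("%s feature matrix contains non-finite or non-numeric values", nm))
  }
  structure(
    list(drug = drug, cell = cell, p_d = ncol(drug), p_c = ncol(cell)),
    class = "feature_store"
  )
}

#' @export
print.feature_store <- function(x, ...) {
  cat(sprintf("Feature store: %d drugs x %d descriptors, %d cell lines x %d genes\n",
              nrow(x$drug), x$p_d, nrow(x$cell), x$p_c))
  invisible(x)
}

#' Read a drug or cell-line feature table
#'
#' Reads a delimited text table whose first column is the entity id and whose
#' remaining columns are numeric features. A header row is required.
#'
#' @param path file path.
#' @param kind \code{"drug"} or \code{"cell"}; informational, used in error
#'   messages only.
#' @param sep field delimiter, \code{","} (default) or \code{"\t"}.
#' @return numeric matrix with ids as rownames.
#' @export
load_feature_table <- function(path, kind = c("drug", "cell"), sep = ",") {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop(sprintf("%s feature table not found: %s", kind, path))
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = NA, stringsAsFactors = FALSE,
                          comment.char = "", quote = "\"")
  if (ncol(df) < 2) stop(sprintf("%s table must have an id column plus features", kind))
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop(sprintf("duplicate id in %s table: '%s'", kind, dup))
  }
  feat <- df[, -1, drop = FALSE]
  for (j in seq_along(feat)) {
    if (!is.numeric(feat[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(feat[[j]]))))[1]
      stop(sprintf("non-numeric value in %s table at row %d, column '%s'",
                   kind, bad, names(feat)[j]))
    }
  }
  m <- as.matrix(feat)
  rownames(m) <- ids
  m
}

#' Write a feature table as CSV
#'
#' @param m numeric matrix with ids as rownames.
#' @param path output file path.
#' @param id_col name of the id column in the header.
#' @export
write_feature_table <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Binary synergy label from a Loewe score
#'
#' A combination is called synergistic when its Loewe score strictly exceeds
#' the threshold (default 5); a score exactly at the threshold is negative,
#' keeping the positive set conservative.
#'
#' @param loewe numeric vector of Loewe synergy scores.
#' @param threshold decision threshold (default 5).
#' @return integer vector of 0/1 labels.
#' @export
assign_synergy_label <- function(loewe, threshold = 5) {
  if (any(!is.finite(loewe))) stop("non-finite Loewe score")
  as.integer(loewe > threshold)
}

#' Binary adverse-DDI label from an interaction category
#'
#' Drug pairs whose recorded interaction category is adverse are positive;
#' pairs with a non-harmful category, and pairs with no recorded category,
#' are negative.
#'
#' @param category character vector of category names (NA = no record).
#' @param adverse_categories character vector of category names considered
#'   adverse.
#' @return integer vector of 0/1 labels.
#' @export
assign_ddi_label <- function(category, adverse_categories) {
  ifelse(!is.na(category) & category %in% adverse_categories, 1L, 0L)
}

#' Default drug-drug-interaction category set
#'
#' Eighteen interaction categories of which sixteen are adverse, mirroring
#' the structure of curated interaction databases where only a few recorded
#' interaction types are non-harmful.
#'
#' @return data.frame with columns \code{name} and \code{adverse}.
#' @export
default_ddi_categories <- function() {
  adverse <- c(
    "increased_cardiotoxicity", "increased_hepatotoxicity",
    "increased_nephrotoxicity", "increased_neurotoxicity",
    "increased_myelosuppression", "increased_qt_prolongation",
    "increased_bleeding_risk", "increased_hypotension",
    "increased_serotonergic_effect", "increased_cns_depression",
    "decreased_therapeutic_efficacy", "increased_serum_concentration",
    "decreased_serum_concentration", "increased_gastrointestinal_toxicity",
    "increased_skeletal_muscle_toxicity", "increased_immunosuppression"
  )
  benign <- c("improved_absorption", "therapeutic_additivity")
  data.frame(name = c(adverse, benign),
             adverse = c(rep(TRUE, length(adverse)), rep(FALSE, length(benign))),
             stringsAsFactors = FALSE)
}

unordered_pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Average replicate synergy measurements
#'
#' Replicates are rows sharing the same unordered drug pair and cell line.
#' Each synergy score is replaced by its arithmetic mean over the replicates,
#' the synergy label is re-derived from the averaged Loewe score, and the DDI
#' label is carried through (replicates with conflicting DDI labels are an
#' error, since DDI status is a property of the drug pair).
#'
#' @param samples combination data.frame (see \code{\link{read_combination_table}}).
#' @param threshold synergy-label threshold applied to the averaged Loewe score.
#' @return combination data.frame with one row per (unordered pair, cell line).
#' @export
average_replicates <- function(samples, threshold = 5) {
  key <- paste(unordered_pair_key(samples$drug_x, samples$drug_y),
               samples$cell_line, sep = "\r")
  idx <- split(seq_len(nrow(samples)), key)
  first <- vapply(idx, `[`, integer(1), 1L)
  ord <- order(first)  # preserve first-appearance order
  idx <- idx[ord]
  out <- samples[vapply(idx, `[`, integer(1), 1L), , drop = FALSE]
  for (task in REGRESSION_TASKS) {
    out[[task]] <- vapply(idx, function(i) mean(samples[[task]][i]), numeric(1))
  }
  if (!is.null(samples$ddi_label)) {
    conflict <- vapply(idx, function(i) length(unique(samples$ddi_label[i])) > 1, logical(1))
    if (any(conflict)) {
      stop(sprintf("conflicting DDI labels among replicates of pair (%s, %s)",
                   out$drug_x[which(conflict)[1]], out$drug_y[which(conflict)[1]]))
    }
  }
  out$synergy_label <- assign_synergy_label(out$loewe, threshold)
  rownames(out) <- NULL
  out
}

#' Remove zero-variance feature columns
#'
#' Chemical-descriptor dimensions that never vary across the sample set carry
#' no information and are dropped before training.
#'
#' @param m numeric matrix (samples x features).
#' @return list with \code{matrix} (reduced) and \code{kept} (strictly
#'   increasing indices of retained columns).
#' @export
drop_constant_features <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) == 0 || ncol(m) == 0) stop("empty feature matrix")
  rng <- apply(m, 2, function(col) diff(range(col)))
  kept <- which(rng > 0)
  list(matrix = m[, kept, drop = FALSE], kept = as.integer(kept))
}

#' Resolve model input vectors for one combination sample
#'
#' @param drug_x,drug_y drug ids.
#' @param cell_line cell-line id.
#' @param store a \code{\link{feature_store}}.
#' @return list with numeric vectors \code{dx}, \code{dy}, \code{cr}.
#' @export
build_model_input <- function(drug_x, drug_y, cell_line, store) {
  for (id in c(drug_x, drug_y)) {
    if (!id %in% rownames(store$drug)) stop(sprintf("unknown drug id: '%s'", id))
  }
  if (!cell_line %in% rownames(store$cell))
    stop(sprintf("unknown cell-line id: '%s'", cell_line))
  list(dx = store$drug[drug_x, ], dy = store$drug[drug_y, ],
       cr = store$cell[cell_line, ])
}

#' Read a combination table
#'
#' Expects columns \code{drug_x}, \code{drug_y}, \code{cell_line}, the five
#' synergy scores \code{loewe}, \code{bliss}, \code{zip}, \code{hsa}, \code{s},
#' and either a 0/1 \code{ddi_label} column or a textual \code{ddi_category}
#' column (mapped through \code{\link{assign_ddi_label}}). A
#' \code{synergy_label} column is derived from the Loewe score when absent.
#'
#' @param path file path.
#' @param sep field delimiter.
#' @param threshold synergy-label threshold.
#' @param adverse_categories category names treated as adverse when a
#'   \code{ddi_category} column is present.
#' @return data.frame of combination samples.
#' @export
read_combination_table <- function(path, sep = ",", threshold = 5,
                                   adverse_categories = default_ddi_categories()$name[default_ddi_categories()$adverse]) {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "", quote = "\"")
  need <- c("drug_x", "drug_y", "cell_line", REGRESSION_TASKS)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("combination table missing columns: ", paste(miss, collapse = ", "))
  if (is.null(df$ddi_label)) {
    if (is.null(df$ddi_category))
      stop("combination table needs a ddi_label or ddi_category column")
    df$ddi_label <- assign_ddi_label(df$ddi_category, adverse_categories)
  }
  if (is.null(df$synergy_label)) df$synergy_label <- assign_synergy_label(df$loewe, threshold)
  if (any(df$drug_x == df$drug_y)) stop("self-combinations (drug_x == drug_y) are invalid")
  df
}

#' Assemble a dataset of combination samples and their feature store
#'
#' @param samples combination data.frame.
#' @param store a \code{\link{feature_store}}.
#' @return object of class \code{"deml_dataset"}.
#' @export
deml_dataset <- function(samples, store) {
  unknown_d <- setdiff(unique(c(samples$drug_x, samples$drug_y)), rownames(store$drug))
  if (length(unknown_d)) stop("drug ids not in store: ", paste(utils::head(unknown_d, 3), collapse = ", "))
  unknown_c <- setdiff(unique(samples$cell_line), rownames(store$cell))
  if (length(unknown_c)) stop("cell-line ids not in store: ", paste(utils::head(unknown_c, 3), collapse = ", "))
  structure(list(samples = samples, store = store), class = "deml_dataset")
}

#' @export
print.deml_dataset <- function(x, ...) {
  cat(sprintf("Drug-combination dataset: %d samples, %d drugs, %d cell lines\n",
              nrow(x$samples), nrow(x$store$drug), nrow(x$store$cell)))
  cat(sprintf("  synergy positives: %d (%.1f%%), adverse-DDI positives: %d (%.1f%%)\n",
              sum(x$samples$synergy_label), 100 * mean(x$samples$synergy_label),
              sum(x$samples$ddi_label), 100 * mean(x$samples$ddi_label)))
  invisible(x)
}

# Batched feature lookup: returns list(Dx, Dy, Cr) matrices for sample rows.
batch_inputs <- function(samples, store) {
  list(Dx = store$drug[samples$drug_x, , drop = FALSE],
       Dy = store$drug[samples$drug_y, , drop = FALSE],
       Cr = store$cell[samples$cell_line, , drop = FALSE])
}
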