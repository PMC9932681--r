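## Thematic-map accuracy: confusion matrix (rows = predicted, columns =
## reference), overall accuracy, kappa, and per-class producer / user
## accuracy. The layout mirrors the standard remote-sensing accuracy table:
## column sums are the labeled reference totals per class.

#' Confusion matrix of a predicted class map against reference labels
#'
#' Only pixels with a reference label >= 0 are counted;
#' `counts[i, j]` = number of pixels predicted class i with reference class j.
#'
#' @param pred predicted class ids (vector or matrix, -1 ignored).
#' @param reference a [label_map()] or integer vector/matrix (-1 = unlabeled).
#' @param class_names class names (taken from `reference` when it is a
#'   [label_map()]).
#' @return K x K integer matrix of class `confusion_matrix` with dimnames
#'   `predicted` x `reference`.
#' @export
confusion_matrix <- function(pred, reference,
                             class_names = NULL) {
  ref <- if (inherits(reference, "label_map")) reference$labels else reference
  if (is.null(class_names)) {
    class_names <- if (inherits(reference, "label_map")) reference$class_names
    else as.character(seq_len(max(c(ref, pred)) + 1L) - 1L)
  }
  pred <- as.integer(pred); ref <- as.integer(ref)
  if (length(pred) != length(ref)) stop("disjoint extents")
  sel <- ref >= 0L
  if (!any(sel)) stop("no labeled reference pixels")
  k <- length(class_names)
  cm <- table(factor(pred[sel], levels = 0:(k - 1L)),
              factor(ref[sel], levels = 0:(k - 1L)))
  cm <- matrix(as.integer(cm), k, k,
               dimnames = list(predicted = class_names,
                               reference = class_names))
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Assemble a confusion matrix from counts
#'
#' @param counts K x K non-negative counts, rows = predicted.
#' @param class_names class names.
#' @return a `confusion_matrix`.
#' @export
as_confusion_matrix <- function(counts,
                                class_names = c("healthy", "infected",
                                                "ground")) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || sum(counts) <= 0)
    stop("counts must be non-negative with positive total")
  dimnames(counts) <- list(predicted = class_names, reference = class_names)
  structure(counts, class = c("confusion_matrix", "matrix"))
}

#' Overall accuracy: correctly labeled fraction
#'
#' @param cm a confusion matrix (rows = predicted).
#' @return scalar in \[0, 1\].
#' @export
overall_accuracy <- function(cm) {
  n <- sum(cm)
  if (n <= 0) stop("empty confusion matrix")
  sum(diag(as.matrix(cm))) / n
}

#' Cohen's kappa: chance-corrected map agreement
#'
#' `(Po - Pe) / (1 - Pe)` with `Pe = sum_k row_k * col_k / N^2`.
#'
#' @param cm a confusion matrix.
#' @return scalar in \[-1, 1\]; 1 iff the matrix is diagonal.
#' @export
kappa_coefficient <- function(cm) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  if (n <= 0) stop("empty confusion matrix")
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (pe >= 1) stop("degenerate matrix: chance agreement Pe = 1")
  (po - pe) / (1 - pe)
}

#' Producer and user accuracy per class
#'
#' Producer accuracy (column-wise recall): fraction of reference pixels of a
#' class that were predicted as it. User accuracy (row-wise precision):
#' fraction of pixels predicted as a class that really are it. Empty
#' rows/columns give NA.
#'
#' @param cm a confusion matrix.
#' @return list with numeric vectors `producer` and `user`.
#' @export
producer_user_accuracy <- function(cm) {
  cm <- as.matrix(cm)
  if (sum(cm) <= 0) stop("empty confusion matrix")
  dg <- diag(cm)
  cs <- colSums(cm); rs <- rowSums(cm)
  list(producer = ifelse(cs > 0, dg / cs, NA_real_),
       user = ifelse(rs > 0, dg / rs, NA_real_))
}

#' Pool confusion matrices entrywise
#'
#' Summing counts across models pools their accuracy assessments: the overall
#' accuracy of the pooled matrix equals the count-weighted mean accuracy of
#' the parts.
#'
#' @param cms list of confusion matrices with identical layout.
#' @return a pooled `confusion_matrix`.
#' @export
pool_confusions <- function(cms) {
  out <- Reduce(`+`, lapply(cms, as.matrix))
  structure(out, class = c("confusion_matrix", "matrix"))
}

#' Accuracy report in the standard thematic-map layout
#'
#' @param cm a confusion matrix.
#' @return a list (`counts`, `oa`, `kappa`, `producer`, `user`) of class
#'   `accuracy_report`; its print method shows counts, row sums, U(%), P(%),
#'   OA(%) and kappa.
#' @export
accuracy_report <- function(cm) {
  pu <- producer_user_accuracy(cm)
  structure(list(counts = as.matrix(cm), oa = overall_accuracy(cm),
                 kappa = kappa_coefficient(cm),
                 producer = pu$producer, user = pu$user),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  m <- x$counts
  tab <- cbind(m, Sum = rowSums(m), `U(%)` = round(100 * x$user, 1))
  tab <- rbind(tab, Sum = c(colSums(m), sum(m), NA),
               `P(%)` = c(round(100 * x$producer, 1), NA, NA))
  print(tab, na.print = "")
  cat(sprintf("OA = %.2f%%   kappa = %.3f\n", 100 * x$oa, x$kappa))
  invisible(x)
}

#' Benchmark confusion matrices from a UAV mite-infestation survey
#'
#' Published per-model confusion matrices for the twelve feature x clusterer
#' recognition models (features: pca, lle, ss, bc; clusterers: kmeans, fcm,
#' dp) evaluated on a spider-mite-infested jujube orchard against reference
#' regions of 5,036 healthy, 2,438 infected and 11,213 ground pixels, plus
#' the pooled per-feature and per-clusterer matrices as published. Shipped as
#' plain CSV in `extdata`; used to validate the accuracy arithmetic and the
#' pooling identity.
#'
#' @return named list of `confusion_matrix` objects with attributes `group`
#'   (`"model"`, `"by_feature"`, `"by_clusterer"`), `feature`, `clusterer`.
#' @export
benchmark_matrices <- function() {
  path <- system.file("extdata", "benchmark_confusion.csv",
                      package = "specmite", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cls <- c("healthy", "infected", "ground")
  out <- list()
  for (id in unique(df$id)) {
    rows <- df[df$id == id, ]
    rows <- rows[match(cls, rows$predicted), ]
    cm <- as_confusion_matrix(as.matrix(rows[, cls]), cls)
    attr(cm, "group") <- rows$group[1]
    attr(cm, "feature") <- rows$feature[1]
    attr(cm, "clusterer") <- rows$clusterer[1]
    out[[id]] <- cm
  }
  out
}
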