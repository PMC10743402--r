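#' Fit a ConStruct pathogenicity classifier
#'
#' Trains the ConStruct model: a random forest (bagged ensemble of decision
#' trees with random feature subsetting) over the nine protein-centric
#' predictors computed by [encode_features()]. Labels must contain both
#' classes (`pathogenic` and `benign`). Fits are reproducible: the RNG is
#' seeded from `seed` immediately before the forest is grown, so the same
#' data and hyperparameters always give the same model.
#'
#' @param data labelled variant data frame (columns of
#'   [read_variant_table()], `label` in `pathogenic`/`benign`), or an
#'   already-encoded feature data frame if `labels` is given
#' @param labels optional explicit label vector when `data` is a feature
#'   data frame
#' @param map annotation map used for encoding
#' @param matrix substitution matrix used for encoding
#' @param ntree number of trees (default 500)
#' @param mtry features tried per split; default `floor(sqrt(p))`
#' @param nodesize minimum terminal-node size (default 1)
#' @param seed integer RNG seed (default 17)
#' @return object of class `construct_model` with elements `forest`
#'   (the fitted ensemble), `feature_names`, `hyperparameters`, `training`
#'   (class counts and data fingerprint) and `call`
#' @seealso [predict.construct_model()], [construct_cv()]
#' @examples
#' map <- otoferlin_annotation()
#' set.seed(1)
#' toy <- simulate_training_set(simulation_config(n_pathogenic = 30,
#'                                                n_benign = 30, seed = 1))
#' fit <- construct_fit(toy, ntree = 50)
#' fit
#' @export
construct_fit <- function(data, labels = NULL, map = otoferlin_annotation(),
                          matrix = blosum80(), ntree = 500, mtry = NULL,
                          nodesize = 1, seed = 17) {
  if (is.null(labels)) {
    data <- as.data.frame(data)
    if (!"label" %in% names(data)) stop("data has no 'label' column")
    keep <- data$label %in% c("pathogenic", "benign")
    if (!all(keep)) stop("labels must be 'pathogenic' or 'benign'")
    labels <- data$label
    features <- encode_features(data, map, matrix)
  } else {
    features <- as.data.frame(data)[FEATURE_NAMES]
  }
  if (anyNA(features) || any(!is.finite(as.matrix(features))))
    stop("features contain missing or non-finite values")
  y <- factor(labels, levels = c("benign", "pathogenic"))
  if (anyNA(y)) stop("labels must be 'pathogenic' or 'benign'")
  if (nlevels(droplevels(y)) < 2L)
    stop("training data must contain both classes")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(features))))
  set.seed(seed)
  forest <- randomForest::randomForest(x = features, y = y, ntree = ntree,
                                       mtry = mtry, nodesize = nodesize)
  structure(list(
    forest = forest,
    feature_names = names(features),
    hyperparameters = list(ntree = ntree, mtry = mtry,
                           nodesize = nodesize, seed = seed),
    training = list(n = length(y),
                    n_pathogenic = sum(y == "pathogenic"),
                    n_benign = sum(y == "benign"),
                    fingerprint = feature_fingerprint(features, y)),
    call = match.call()
  ), class = "construct_model")
}

# cheap content fingerprint recorded in model metadata
feature_fingerprint <- function(features, y) {
  sprintf("n=%d;p=%d;sum=%.6g;pos=%d", nrow(features), ncol(features),
          sum(as.matrix(features)), sum(y == "pathogenic"))
}

#' Predict pathogenicity probabilities
#'
#' Returns the ensemble vote fraction for the pathogenic class (in
#' `[0, 1]`), or the class call at a probability threshold. `newdata` may
#' be a variant data frame (encoded on the fly) or an already-encoded
#' feature data frame; its feature schema must match the training one.
#'
#' @param object a [construct_fit()] model
#' @param newdata variant or feature data frame
#' @param type `"prob"` (default) for probabilities, `"class"` for
#'   `pathogenic`/`benign` calls
#' @param threshold probability cutoff for `type = "class"`; a variant is
#'   called pathogenic when its probability is strictly greater (default 0.5)
#' @param map,matrix annotation map and matrix for on-the-fly encoding
#' @param ... unused
#' @return numeric probabilities or a character vector of calls
#' @export
predict.construct_model <- function(object, newdata,
                                    type = c("prob", "class"),
                                    threshold = 0.5,
                                    map = otoferlin_annotation(),
                                    matrix = blosum80(), ...) {
  type <- match.arg(type)
  newdata <- as.data.frame(newdata)
  features <- if (all(object$feature_names %in% names(newdata)))
    newdata[object$feature_names] else encode_features(newdata, map, matrix)
  if (!identical(names(features), object$feature_names))
    stop("feature schema mismatch: expected ",
         paste(object$feature_names, collapse = ", "))
  p <- unname(stats::predict(object$forest, features,
                             type = "prob")[, "pathogenic"])
  if (type == "prob") p else ifelse(p > threshold, "pathogenic", "benign")
}

#' @export
print.construct_model <- function(x, ...) {
  hp <- x$hyperparameters
  cat("ConStruct pathogenicity model (random forest)\n")
  cat(sprintf("  training: %d variants (%d pathogenic, %d benign)\n",
              x$training$n, x$training$n_pathogenic, x$training$n_benign))
  cat(sprintf("  trees: %d, mtry: %d, nodesize: %d, seed: %d\n",
              hp$ntree, hp$mtry, hp$nodesize, hp$seed))
  invisible(x)
}

#' @export
summary.construct_model <- function(object, ...) {
  print(object)
  cat("  predictors:", paste(object$feature_names, collapse = ", "), "\n")
  cat("  fingerprint:", object$training$fingerprint, "\n")
  invisible(object)
}
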