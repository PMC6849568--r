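#' Build a two-class training table from detection reports
#'
#' Regions labeled `correct_cell`, `merged` or `split` become class
#' `"cell"` (merged and split objects look like cells and their count
#' effects largely cancel); `noise` regions become class `"noise"`; `ppi`
#' regions are excluded (they still satisfy the one-to-one condition and
#' are never candidates for removal).
#'
#' @param reports a [classify_detections()] report or list of them.
#' @param features matching [region_feature_table()] data.frame or list of
#'   them (row order = region label order).
#' @return data.frame of features plus a `class` factor
#'   (levels `cell`, `noise`).
#' @export
build_training_set <- function(reports, features) {
  if (inherits(reports, "DetectionReport")) reports <- list(reports)
  if (is.data.frame(features)) features <- list(features)
  if (length(reports) != length(features))
    stop("`reports` and `features` must be paired", call. = FALSE)
  out <- list()
  for (i in seq_along(reports)) {
    lab <- reports[[i]]$region_labels
    ft <- features[[i]]
    if (nrow(ft) != length(lab))
      stop("feature table ", i, " does not cover every region", call. = FALSE)
    cls <- ifelse(lab %in% c("correct_cell", "merged", "split"), "cell",
                  ifelse(lab == "noise", "noise", NA))
    keep <- !is.na(cls)
    df <- ft[keep, setdiff(names(ft), "region"), drop = FALSE]
    df$class <- cls[keep]
    out[[i]] <- df
  }
  tab <- do.call(rbind, out)
  tab$class <- factor(tab$class, levels = c("cell", "noise"))
  if (any(table(tab$class) == 0L))
    stop("degenerate training set: a class has no members", call. = FALSE)
  rownames(tab) <- NULL
  tab
}

#' Train the linear discriminant noise filter
#'
#' Fisher's two-class linear discriminant on standardised features with a
#' ridge-regularised pooled within-class covariance (`ridge` added to the
#' diagonal). The decision threshold on the discriminant score is placed
#' where the two class posteriors are equal under empirical priors and a
#' shared projected variance.
#'
#' @param table training data.frame from [build_training_set()]: feature
#'   columns plus a `class` factor with levels `cell` and `noise`.
#' @param ridge diagonal regularisation added to the pooled covariance.
#' @return A list of class `LDAModel` with the weight vector, threshold,
#'   standardisation constants, priors and resubstitution accuracy.
#' @export
train_lda <- function(table, ridge = 1e-6) {
  if (!"class" %in% names(table)) stop("`table` needs a `class` column",
                                       call. = FALSE)
  cls <- factor(table$class, levels = c("cell", "noise"))
  X <- as.matrix(table[, setdiff(names(table), "class"), drop = FALSE])
  storage.mode(X) <- "double"
  if (any(table(cls) < 2L))
    stop("each class needs at least 2 samples", call. = FALSE)

  mu <- colMeans(X)
  sdev <- apply(X, 2L, stats::sd)
  sdev[!is.finite(sdev) | sdev == 0] <- 1
  Z <- sweep(sweep(X, 2L, mu), 2L, sdev, "/")

  zc <- Z[cls == "cell", , drop = FALSE]
  zn <- Z[cls == "noise", , drop = FALSE]
  n1 <- nrow(zc); n0 <- nrow(zn)
  s_pool <- ((n1 - 1L) * stats::cov(zc) + (n0 - 1L) * stats::cov(zn)) /
            (n1 + n0 - 2L)
  diag(s_pool) <- diag(s_pool) + ridge
  m1 <- colMeans(zc); m0 <- colMeans(zn)
  w <- tryCatch(solve(s_pool, m1 - m0),
                error = function(e)
                  stop("singular pooled covariance after regularisation",
                       call. = FALSE))
  if (any(!is.finite(w)))
    stop("non-finite discriminant weights", call. = FALSE)

  s1 <- sum(w * m1); s0 <- sum(w * m0)    # class means on the score axis
  sigma2 <- drop(t(w) %*% s_pool %*% w)   # shared score variance
  prior1 <- n1 / (n1 + n0); prior0 <- 1 - prior1
  # equal posteriors: midpoint shifted by the prior log-odds
  thr <- (s1 + s0) / 2 - sigma2 * log(prior1 / prior0) / (s1 - s0)

  model <- structure(list(
    features = colnames(X), weights = w, threshold = thr,
    center = mu, scale = sdev,
    priors = c(cell = prior1, noise = prior0),
    score_means = c(cell = s1, noise = s0)
  ), class = "LDAModel")
  model$training_accuracy <- mean(predict_lda(model, table) == cls)
  model
}

#' Classify regions with a trained discriminant
#'
#' @param model an [train_lda()] model.
#' @param newdata data.frame containing the model's feature columns.
#' @return factor of predicted classes (`cell`/`noise`).
#' @export
predict_lda <- function(model, newdata) {
  if (!inherits(model, "LDAModel")) stop("untrained model", call. = FALSE)
  X <- as.matrix(newdata[, model$features, drop = FALSE])
  storage.mode(X) <- "double"
  Z <- sweep(sweep(X, 2L, model$center), 2L, model$scale, "/")
  s <- drop(Z %*% model$weights)
  cell_high <- model$score_means["cell"] > model$score_means["noise"]
  lab <- if (cell_high) ifelse(s > model$threshold, "cell", "noise")
         else ifelse(s < model$threshold, "cell", "noise")
  factor(lab, levels = c("cell", "noise"))
}

#' @export
print.LDAModel <- function(x, ...) {
  cat(sprintf("<LDAModel> %d features, training accuracy %.3f\n",
              length(x$features), x$training_accuracy))
  invisible(x)
}

#' Remove noise regions using a trained discriminant
#'
#' Extracts features for every region, classifies them, deletes regions
#' classified as noise, and relabels the survivors contiguously in their
#' original order. Filtering twice is identical to filtering once.
#'
#' @param regions a [labeled_regions()].
#' @param source the matching [image8()] (defaults to `regions$source`).
#' @param model an [train_lda()] model.
#' @return A filtered [labeled_regions()].
#' @export
apply_noise_filter <- function(regions, source = NULL, model) {
  if (!inherits(model, "LDAModel")) stop("untrained model", call. = FALSE)
  src <- if (is.null(source)) regions$source else source
  if (length(regions$regions) == 0L) return(regions)
  ft <- region_feature_table(regions, src)
  keep <- predict_lda(model, ft) == "cell"
  lab <- regions$labels
  lab[lab %in% which(!keep)] <- 0L
  u <- sort(unique(lab[lab > 0L]))
  if (length(u)) lab[lab > 0L] <- match(lab[lab > 0L], u)
  out <- labeled_regions(lab, source = src, role = regions$role)
  out$params <- regions$params
  out
}

#' Serialise / restore an LDA model as JSON
#'
#' @param model an [train_lda()] model.
#' @param path JSON file path.
#' @export
write_lda_model <- function(model, path) {
  jsonlite::write_json(
    list(features = model$features, weights = unname(model$weights),
         threshold = model$threshold, center = unname(model$center),
         scale = unname(model$scale), priors = as.list(model$priors),
         score_means = as.list(model$score_means),
         training_accuracy = model$training_accuracy),
    path, auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' @rdname write_lda_model
#' @param path JSON file path.
#' @return `read_lda_model()` returns the restored `LDAModel`.
#' @export
read_lda_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    features = j$features,
    weights = stats::setNames(as.numeric(j$weights), j$features),
    threshold = j$threshold,
    center = stats::setNames(as.numeric(j$center), j$features),
    scale = stats::setNames(as.numeric(j$scale), j$features),
    priors = unlist(j$priors),
    score_means = unlist(j$score_means),
    training_accuracy = j$training_accuracy
  ), class = "LDAModel")
}

#' Confusion-matrix classification metrics
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, `F1 = 2pr/(p+r)` and
#' overall accuracy, counting `positive_class` as positive.
#'
#' @param predicted,truth label vectors of equal length.
#' @param positive_class the positive class label (default `"cell"`).
#' @return A list of class `ClassifierMetrics`: `TP`, `TN`, `FP`, `FN`,
#'   `precision`, `recall`, `F1`, `overall_accuracy`.
#' @export
classification_metrics <- function(predicted, truth, positive_class = "cell") {
  if (length(predicted) != length(truth))
    stop("label vectors differ in length", call. = FALSE)
  p_pos <- predicted == positive_class
  t_pos <- truth == positive_class
  TP <- sum(p_pos & t_pos); TN <- sum(!p_pos & !t_pos)
  FP <- sum(p_pos & !t_pos); FN <- sum(!p_pos & t_pos)
  metrics_from_counts(TP, TN, FP, FN)
}

#' Metrics from explicit confusion counts
#' @param TP,TN,FP,FN confusion-matrix counts.
#' @return As [classification_metrics()].
#' @export
metrics_from_counts <- function(TP, TN, FP, FN) {
  if (TP + FP == 0L) stop("precision undefined: TP + FP = 0", call. = FALSE)
  if (TP + FN == 0L) stop("recall undefined: TP + FN = 0", call. = FALSE)
  p <- TP / (TP + FP); r <- TP / (TP + FN)
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN,
                 precision = p, recall = r,
                 F1 = 2 * p * r / (p + r),
                 overall_accuracy = (TP + TN) / (TP + TN + FP + FN)),
            class = "ClassifierMetrics")
}

#' @export
print.ClassifierMetrics <- function(x, ...) {
  cat(sprintf(
    "<ClassifierMetrics> TP %d TN %d FP %d FN %d | p %.3f r %.3f F1 %.3f acc %.3f\n",
    x$TP, x$TN, x$FP, x$FN, x$precision, x$recall, x$F1, x$overall_accuracy))
  invisible(x)
}
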