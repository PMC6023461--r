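# Three-class mitotic phenotype scoring. The default classifier is a
# Gaussian class-conditional (quadratic discriminant) model on standardised
# features -- the minimal model trainable from tens of labelled nuclei and
# fully auditable. A rule-based fallback thresholding area and extent is
# available as classifier = "rules".

PHENOTYPE_CLASSES <- c("normal", "spindle", "cytokinesis")

#' Phenotype-model configuration
#'
#' @param features feature subset used by the classifier. The default
#'   excludes texture features, whose synthetic rendering is simplistic.
#' @param n_min minimum labelled examples per class.
#' @param ridge covariance ridge: `epsilon * trace/d` is added to the
#'   diagonal of each class covariance.
#' @param classifier `"qda"` (Gaussian class-conditional) or `"rules"`
#'   (area/extent/intensity thresholds).
#' @return A list of class `"phenotype_config"`.
#' @export
phenotype_config <- function(features = c("num_pix", "extend", "circularity",
                                          "mean_intensity"),
                             n_min = 10, ridge = 1e-6,
                             classifier = c("qda", "rules")) {
  structure(list(features = features, n_min = n_min, ridge = ridge,
                 classifier = match.arg(classifier)),
            class = "phenotype_config")
}

#' Fit the phenotype classifier
#'
#' @param features data.frame of nucleus features with a `class` column in
#'   `{normal, spindle, cytokinesis}`.
#' @param config a [phenotype_config()].
#' @return A list of class `"phenotype_model"`: feature subset,
#'   standardisation parameters, per-class means and (regularised)
#'   covariances, class priors.
#' @export
fit_phenotype_model <- function(features, config = phenotype_config()) {
  if (!"class" %in% names(features))
    stop("training features need a 'class' column")
  miss_f <- setdiff(config$features, names(features))
  if (length(miss_f) > 0)
    stop("missing feature column(s): ", paste(miss_f, collapse = ", "))
  cls <- as.character(features$class)
  bad <- setdiff(unique(cls), PHENOTYPE_CLASSES)
  if (length(bad) > 0)
    stop("unknown class label(s): ", paste(bad, collapse = ", "))
  counts <- table(factor(cls, PHENOTYPE_CLASSES))
  missing_cls <- names(counts)[counts == 0]
  if (length(missing_cls) > 0)
    stop("no training examples for class: ",
         paste(missing_cls, collapse = ", "))
  if (any(counts < config$n_min))
    stop("need at least ", config$n_min, " examples per class (got ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "), ")")

  # maximum-likelihood (divide-by-n) moments throughout, so the model is
  # invariant under duplication of the training set
  X <- as.matrix(features[, config$features, drop = FALSE])
  center <- colMeans(X)
  scale_ <- sqrt(colMeans(sweep(X, 2, center)^2))
  if (any(scale_ == 0))
    stop("feature(s) with zero variance in training data: ",
         paste(config$features[scale_ == 0], collapse = ", "))
  Z <- sweep(sweep(X, 2, center), 2, scale_, "/")
  d <- ncol(Z)

  means <- covs <- list()
  for (cl in PHENOTYPE_CLASSES) {
    Zi <- Z[cls == cl, , drop = FALSE]
    mu <- colMeans(Zi)
    Zc <- sweep(Zi, 2, mu)
    S <- crossprod(Zc) / nrow(Zc)
    S <- S + diag(config$ridge * sum(diag(S)) / d, d)
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch))
      stop("singular covariance for class '", cl,
           "' even after regularization")
    means[[cl]] <- mu
    covs[[cl]] <- S
  }
  priors <- as.numeric(counts) / sum(counts)
  names(priors) <- PHENOTYPE_CLASSES

  model <- structure(list(classifier = config$classifier,
                          classes = PHENOTYPE_CLASSES,
                          features = config$features, center = center,
                          scale = scale_, means = means, covs = covs,
                          priors = priors), class = "phenotype_model")
  if (config$classifier == "rules")
    model$rules <- fit_rules(features, cls)
  model
}

# Threshold rules on raw num_pix / extend / mean_intensity: midpoints of the
# class means, mimicking a manual two-feature gate.
fit_rules <- function(features, cls) {
  m <- function(col, cl) mean(features[[col]][cls == cl])
  list(area_small = (m("num_pix", "spindle") + m("num_pix", "normal")) / 2,
       area_large = (m("num_pix", "normal") + m("num_pix", "cytokinesis")) / 2,
       extend_cut = (m("extend", "cytokinesis") + m("extend", "normal")) / 2,
       int_cut = (m("mean_intensity", "normal") +
                    m("mean_intensity", "spindle")) / 2)
}

#' Classify nuclei
#'
#' Assigns each nucleus the maximum-posterior class; exact posterior ties
#' break in class order (normal < spindle < cytokinesis).
#'
#' @param model a fitted [fit_phenotype_model()].
#' @param features data.frame carrying the model's feature columns.
#' @return Character vector of class labels (empty for empty input).
#' @export
classify_nuclei <- function(model, features) {
  stopifnot(inherits(model, "phenotype_model"))
  miss <- setdiff(model$features, names(features))
  if (length(miss) > 0)
    stop("missing feature column(s): ", paste(miss, collapse = ", "))
  if (nrow(features) == 0) return(character(0))
  if (model$classifier == "rules") {
    r <- model$rules
    out <- rep("normal", nrow(features))
    out[features$num_pix >= r$area_large &
          features$extend < r$extend_cut] <- "cytokinesis"
    out[features$num_pix < r$area_small &
          features$mean_intensity > r$int_cut] <- "spindle"
    return(out)
  }
  X <- as.matrix(features[, model$features, drop = FALSE])
  Z <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  scores <- sapply(model$classes, function(cl) {
    S <- model$covs[[cl]]
    ch <- chol(S)
    diff <- sweep(Z, 2, model$means[[cl]])
    y <- backsolve(ch, t(diff), transpose = TRUE)
    log(model$priors[[cl]]) - sum(log(diag(ch))) - 0.5 * colSums(y^2)
  })
  if (nrow(features) == 1) scores <- matrix(scores, nrow = 1,
                                            dimnames = list(NULL,
                                                            model$classes))
  model$classes[apply(scores, 1, which.max)]
}

#' Per-field phenotype fractions
#'
#' @param labels character vector of per-nucleus class labels.
#' @return One-row data.frame: `n_cells`, `frac_normal`, `frac_spindle`,
#'   `frac_cytokinesis`, `defined`. With zero cells the fractions are `NA`
#'   and `defined` is `FALSE` (undefined-marked rather than NaN).
#' @export
phenotype_fractions <- function(labels) {
  n <- length(labels)
  if (n == 0)
    return(data.frame(n_cells = 0L, frac_normal = NA_real_,
                      frac_spindle = NA_real_, frac_cytokinesis = NA_real_,
                      defined = FALSE))
  counts <- table(factor(labels, PHENOTYPE_CLASSES))
  data.frame(n_cells = n, frac_normal = as.numeric(counts["normal"]) / n,
             frac_spindle = as.numeric(counts["spindle"]) / n,
             frac_cytokinesis = as.numeric(counts["cytokinesis"]) / n,
             defined = TRUE)
}

#' Serialise / load a phenotype model as JSON
#'
#' @param model a `phenotype_model`.
#' @param path JSON file path.
#' @return `read_phenotype_model()` returns the model; the writer returns
#'   `path` invisibly.
#' @export
write_phenotype_model <- function(model, path) {
  obj <- list(classifier = model$classifier, classes = model$classes,
              features = model$features, center = as.list(model$center),
              scale = as.list(model$scale),
              means = lapply(model$means, as.list),
              covs = lapply(model$covs, function(S) as.data.frame(S)),
              priors = as.list(model$priors), rules = model$rules)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_phenotype_model
#' @export
read_phenotype_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- list(classifier = obj$classifier, classes = obj$classes,
                features = obj$features,
                center = unlist(obj$center)[obj$features],
                scale = unlist(obj$scale)[obj$features],
                means = lapply(obj$means, function(m)
                  unlist(m)[obj$features]),
                covs = lapply(obj$covs, function(S) {
                  M <- as.matrix(S)
                  dimnames(M) <- list(obj$features, obj$features)
                  M
                }),
                priors = unlist(obj$priors)[obj$classes])
  if (!is.null(obj$rules)) model$rules <- obj$rules
  structure(model, class = "phenotype_model")
}

#' Read a user-labelled training CSV
#'
#' Expects one row per nucleus with feature columns and a `class` column in
#' `{normal, spindle, cytokinesis}`.
#'
#' @param path CSV path.
#' @return A validated data.frame.
#' @export
read_training_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"class" %in% names(df))
    stop("training CSV '", path, "' has no 'class' column")
  bad <- which(!df$class %in% PHENOTYPE_CLASSES)
  if (length(bad) > 0)
    stop("training CSV '", path, "' row ", bad[1], ": unknown class '",
         df$class[bad[1]], "'")
  df
}

#' Generate a labelled training set from the synthetic generator
#'
#' Renders fields with a balanced phenotype mixture, segments them, matches
#' detected nuclei to ground-truth cells (true centroid falling inside a
#' detected footprint), and returns the matched features labelled with the
#' true class. This is the bundled stand-in for the original (unavailable)
#' manually labelled training data.
#'
#' @param seed integer seed.
#' @param n_fields number of training fields.
#' @param cells_per_field expected cells per field.
#' @param base a [scene_spec()] template (marker and cargo are removed).
#' @param params a [seg_params()].
#' @return Features data.frame with a `class` column.
#' @export
generate_training_features <- function(seed = 99L, n_fields = 3,
                                       cells_per_field = 120,
                                       base = scene_spec(),
                                       params = seg_params()) {
  out <- list()
  for (i in seq_len(n_fields)) {
    spec <- base
    spec$platform <- "well384"
    spec$marker <- NULL
    spec$cargo <- NULL
    spec$expected_cells <- cells_per_field
    spec$phenotype_mix <- c(normal = 1 / 3, spindle = 1 / 3,
                            cytokinesis = 1 / 3)
    spec$seed <- field_seed(seed, 1L, i, 1L)
    fr <- render_field(spec)
    seg <- segment_field(fr$field$channels$nuclei, params)
    m <- match_truth_to_labels(fr$truth, seg$labels)
    ok <- !is.na(m)
    lab_once <- names(which(table(m[ok]) == 1))
    ok <- ok & m %in% as.integer(lab_once)
    if (!any(ok)) next
    f <- seg$features[m[ok], ]
    f$class <- fr$truth$cells$class[ok]
    out[[i]] <- f
  }
  do.call(rbind, out)
}

#' Match ground-truth cells to detected labels
#'
#' A truth cell matches the detected label whose footprint contains its
#' (rounded) true centroid; `NA` when the centroid falls on background.
#'
#' @param truth a `ground_truth`.
#' @param labels detected label matrix.
#' @return Integer vector (length = number of truth cells) of label ids.
#' @export
match_truth_to_labels <- function(truth, labels) {
  if (nrow(truth$cells) == 0) return(integer(0))
  r <- pmin(pmax(round(truth$cells$centroid_row) + 1, 1), nrow(labels))
  c_ <- pmin(pmax(round(truth$cells$centroid_col) + 1, 1), ncol(labels))
  m <- labels[cbind(r, c_)]
  ifelse(m == 0, NA_integer_, m)
}
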