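# Singlet/multiplet discrimination: an L2-regularised logistic (linear)
# classifier on standardised nuclear-morphology features, trained from a
# small set of annotated examples (~150 per class suffices).

default_classifier_features <- function() {
  c("axial_ratio", "symmetry", "axial_small", "roundness")
}

classifier_scores <- function(model, records) {
  missing <- setdiff(model$features, names(records))
  if (length(missing))
    stop("records lack classifier features: ", paste(missing, collapse = ", "))
  x <- as.matrix(records[model$features])
  z <- sweep(sweep(x, 2, model$center), 2, model$scale, `/`)
  drop(z %*% model$weights) + model$bias
}

#' Train the singlet/multiplet linear classifier
#'
#' Fits an L2-regularised logistic regression on standardised morphology
#' features (default: axial length ratio, symmetry, axial small length,
#' roundness; optionally add `"phh3_mean"` to improve retention of
#' mitotic singlets, whose condensed chromatin mimics clump morphology).
#' The regularisation strength is chosen by 5-fold cross-validation over
#' a fixed grid; folds derive from `seed`, so training is deterministic.
#' Positive decision scores mean singlet.
#'
#' @param records Feature tibble from [nucleus_features()].
#' @param labels Character/factor vector, one of `"singlet"`/`"multiplet"`
#'   per record (multiplet = clump or debris).
#' @param features Feature columns to use.
#' @param seed Integer seed controlling the cross-validation folds.
#' @return Object of class `singlet_classifier`: feature names, weights,
#'   bias, standardisation parameters, training metadata and the
#'   `goodness` separation index (see [classifier_goodness()]).
#' @export
train_singlet_classifier <- function(records, labels,
                                     features = default_classifier_features(),
                                     seed = 1L) {
  labels <- as.character(labels)
  if (!all(labels %in% c("singlet", "multiplet")))
    stop("labels must be 'singlet' or 'multiplet'")
  tab <- table(factor(labels, c("singlet", "multiplet")))
  if (any(tab == 0)) stop("both classes must be present")
  if (any(tab < 10)) stop("need at least 10 examples per class")
  missing <- setdiff(features, names(records))
  if (length(missing)) stop("missing feature columns: ",
                            paste(missing, collapse = ", "))
  x <- as.matrix(records[features])
  keep <- apply(x, 2, function(v) sd(v) > 0)
  if (!all(keep)) {
    warning("dropping zero-variance feature(s): ",
            paste(features[!keep], collapse = ", "))
    features <- features[keep]
    x <- x[, keep, drop = FALSE]
  }
  if (!ncol(x)) stop("no usable features left")
  center <- colMeans(x)
  scale <- apply(x, 2, sd)
  z <- sweep(sweep(x, 2, center), 2, scale, `/`)
  y <- as.integer(labels == "singlet")

  # glmnet needs >= 2 columns; a duplicated column under ridge splits the
  # weight evenly, so the effective single-feature weight is the sum
  dup <- ncol(z) == 1
  zfit <- if (dup) cbind(z, z) else z
  set.seed(as.integer(seed))
  foldid <- sample(rep_len(1:5, nrow(zfit)))
  grid <- 10^seq(1, -4, length.out = 30)
  cv <- glmnet::cv.glmnet(zfit, y, family = "binomial", alpha = 0,
                          lambda = grid, foldid = foldid,
                          standardize = FALSE)
  beta <- as.numeric(coef(cv, s = "lambda.min"))
  bias <- beta[1]
  w <- if (dup) sum(beta[-1]) else beta[-1]
  names(w) <- features

  model <- structure(list(
    features = features, weights = w, bias = bias,
    center = center, scale = scale,
    lambda = cv$lambda.min, seed = as.integer(seed),
    n_singlet = unname(tab["singlet"]), n_multiplet = unname(tab["multiplet"])
  ), class = "singlet_classifier")
  scores <- classifier_scores(model, records)
  model$training_accuracy <- mean((scores >= 0) == (y == 1))
  model$goodness <- classifier_goodness(model, records, labels)
  model
}

#' Separation quality ("goodness") of a trained classifier
#'
#' A d-prime-style index: the absolute difference of the mean decision
#' scores of the two classes divided by their pooled score SD.  Higher is
#' better separation; 0 means the score distributions coincide.  This is
#' this package's own definition of the training-quality figure reported
#' by commercial linear-classifier trainers.
#'
#' @param model A `singlet_classifier`.
#' @param records Feature tibble.
#' @param labels `"singlet"`/`"multiplet"` per record.
#' @return Non-negative scalar (`Inf`, with a warning, if the pooled SD
#'   is zero).
#' @export
classifier_goodness <- function(model, records, labels) {
  labels <- as.character(labels)
  s <- classifier_scores(model, records)
  a <- s[labels == "singlet"]; b <- s[labels == "multiplet"]
  if (!length(a) || !length(b)) stop("both classes must be present")
  pooled <- sqrt(((length(a) - 1) * stats::var(a) +
                  (length(b) - 1) * stats::var(b)) /
                 (length(a) + length(b) - 2))
  if (!is.finite(pooled) || pooled == 0) {
    warning("zero pooled score SD; goodness is infinite")
    return(Inf)
  }
  abs(mean(a) - mean(b)) / pooled
}

#' Apply the singlet classifier to nucleus records
#'
#' Flags every record as singlet (`TRUE`) or multiplet/debris (`FALSE`)
#' and attaches the decision score.  Downstream gating consumes singlets
#' only; this also filters out fluorescent debris.  Idempotent.
#'
#' @param records Feature tibble.
#' @param model A `singlet_classifier`.
#' @return `records` with `singlet_score` and logical `singlet` columns.
#' @export
classify_singlets <- function(records, model) {
  stopifnot(inherits(model, "singlet_classifier"))
  if (!nrow(records)) {
    records$singlet_score <- numeric(0)
    records$singlet <- logical(0)
    return(records)
  }
  s <- classifier_scores(model, records)
  dplyr::mutate(records, singlet_score = s, singlet = s >= 0)
}

#' Derive singlet/multiplet training labels from simulator ground truth
#'
#' Matches each segmented object to the simulated nuclei whose true
#' centres fall inside it: exactly one centre = singlet, two or more =
#' multiplet (objects containing no centre are dropped as unmatchable).
#'
#' @param labels Segmentation label matrix.
#' @param truth Ground-truth tibble from [render_field()] (needs `row`,
#'   `col`).
#' @return Tibble with `nucleus_id` (segmentation label) and `class`.
#' @export
training_labels_from_truth <- function(labels, truth) {
  hit <- labels[cbind(pmin(pmax(round(truth$row), 1), nrow(labels)),
                      pmin(pmax(round(truth$col), 1), ncol(labels)))]
  counts <- table(hit[hit > 0])
  tibble(nucleus_id = as.integer(names(counts)),
         class = ifelse(as.integer(counts) >= 2, "multiplet", "singlet"))
}

#' Serialise / restore a singlet classifier
#'
#' The model (feature names, weights, bias, standardisation, metadata)
#' is written as JSON so it can be versioned alongside gate configs.
#'
#' @param model A `singlet_classifier`.
#' @param path File path.
#' @return `write_classifier` returns `path` invisibly; `read_classifier`
#'   returns the model.
#' @export
write_classifier <- function(model, path) {
  stopifnot(inherits(model, "singlet_classifier"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$features <- as.character(m$features)
  for (f in c("weights", "center", "scale"))
    m[[f]] <- setNames(as.numeric(m[[f]]), m$features)
  structure(m, class = "singlet_classifier")
}

#' @export
print.singlet_classifier <- function(x, ...) {
  cat("Singlet/multiplet linear classifier\n")
  cat("  features:", paste(x$features, collapse = ", "), "\n")
  cat(sprintf("  trained on %d singlets / %d multiplets; goodness %.2f\n",
              x$n_singlet, x$n_multiplet, x$goodness))
  invisible(x)
}

#' @describeIn train_singlet_classifier Tidy the fitted weights
#'   (broom-style): one row per feature plus the bias term.
#' @param x A `singlet_classifier`.
#' @param ... Unused.
#' @export
tidy.singlet_classifier <- function(x, ...) {
  tibble(term = c(x$features, "(bias)"),
         estimate = c(unname(x$weights), x$bias))
}

#' @describeIn train_singlet_classifier One-row model summary
#'   (broom-style).
#' @export
glance.singlet_classifier <- function(x, ...) {
  tibble(goodness = x$goodness, training_accuracy = x$training_accuracy,
         lambda = x$lambda, n_singlet = x$n_singlet,
         n_multiplet = x$n_multiplet, seed = x$seed)
}
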