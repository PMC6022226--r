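# Activity transforms, ordinary-least-squares model fitting and the
# validation statistics used throughout QSAR work: r2, adjusted r2,
# leave-one-out q2 via PRESS, and the mean squared residual ("least-squared
# error") reported with the published models.

#' Convert IC50 (micromolar) to pIC50
#'
#' pIC50 is defined here as -log10 of the IC50 expressed in micromolar,
#' the scale on which all printed activities in the compound series are
#' reported (e.g. 35.48 uM -> -1.5500).
#'
#' @param ic50_um positive IC50 value(s) in micromolar.
#' @return -log10(ic50_um).
#' @export
#' @examples
#' pic50(3.48)    # -0.5416
#' pic50(1)       #  0
pic50 <- function(ic50_um) {
  if (any(is.na(ic50_um)))
    stop("censored or missing IC50 has no pIC50")
  if (any(ic50_um <= 0))
    stop("IC50 must be positive")
  -log10(ic50_um)
}

#' Construct a fixed-coefficient linear QSAR model
#'
#' @param endpoint label of the modelled activity (e.g. a cell line).
#' @param intercept model intercept.
#' @param terms named numeric vector of coefficients; names are descriptor
#'   column names.
#' @return object of class `qsar_model`.
#' @export
qsar_model <- function(endpoint, intercept, terms) {
  stopifnot(is.numeric(terms), length(terms) >= 1,
            !is.null(names(terms)), all(nzchar(names(terms))))
  structure(list(endpoint = endpoint, intercept = unname(intercept),
                 terms = terms),
            class = "qsar_model")
}

#' @export
print.qsar_model <- function(x, ...) {
  cat(sprintf("<qsar_model> %s: pIC50 = %.5g %s\n", x$endpoint, x$intercept,
              paste(sprintf("%+.5g*%s", x$terms, names(x$terms)),
                    collapse = " ")))
  invisible(x)
}

#' Predict activity from a linear QSAR model
#'
#' @param object a `qsar_model`.
#' @param newdata data frame (or named vector) of descriptor values; must
#'   contain every descriptor named by the model.
#' @param ... unused.
#' @return numeric vector of predicted activities.
#' @export
predict.qsar_model <- function(object, newdata, ...) {
  if (is.numeric(newdata)) newdata <- as.data.frame(as.list(newdata))
  miss <- setdiff(names(object$terms), colnames(newdata))
  if (length(miss))
    stop("descriptor(s) missing from input: ", paste(miss, collapse = ", "))
  X <- as.matrix(newdata[, names(object$terms), drop = FALSE])
  drop(object$intercept + X %*% object$terms)
}

#' Adjusted r-squared
#'
#' @param r2 coefficient of determination.
#' @param n number of samples.
#' @param p number of model terms (excluding the intercept).
#' @return 1 - (1 - r2) (n - 1) / (n - p - 1).
#' @export
adjusted_r2 <- function(r2, n, p) 1 - (1 - r2) * (n - 1) / (n - p - 1)

#' Fit a multiple linear regression QSAR model
#'
#' Ordinary least squares with intercept, fitted through [stats::lm()].
#' Leave-one-out PRESS and q2 are computed exactly from the hat-matrix
#' leverages (algebraically identical to refitting n times).
#'
#' @param X numeric matrix or data frame of descriptors (columns named).
#' @param y numeric response vector.
#' @return list of class `qsar_fit` with elements `model` (a
#'   [qsar_model()]), `stats` (n, p, sse, lse, r2, r2_adj, press, q2_loo),
#'   `fitted` and `residuals`.
#' @export
fit_mlr <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("X", seq_len(ncol(X)))
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  if (n <= p + 1)
    stop("need more samples than terms plus intercept (n = ", n,
         ", p = ", p, ")")
  const <- apply(X, 2, function(v) diff(range(v)) == 0)
  if (any(const))
    stop("constant descriptor column(s): ",
         paste(colnames(X)[const], collapse = ", "))
  qrX <- qr(cbind(1, X))
  if (qrX$rank < p + 1) {
    dep <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, p + 1)] - 1]
    stop("rank-deficient descriptor matrix; collinear column(s): ",
         paste(dep, collapse = ", "))
  }
  d <- data.frame(.y = y, X, check.names = FALSE)
  fit <- lm(.y ~ ., data = d)
  res <- stats::residuals(fit)
  h <- lm.influence(fit, do.coef = FALSE)$hat
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  press <- sum((res / (1 - h))^2)
  stats <- list(n = n, p = p, sse = sse, lse = sse / n,
                r2 = 1 - sse / sst,
                r2_adj = adjusted_r2(1 - sse / sst, n, p),
                press = press, q2_loo = 1 - press / sst)
  cf <- coef(fit)
  model <- qsar_model(endpoint = "fitted", intercept = cf[1],
                      terms = setNames(cf[-1], colnames(X)))
  structure(list(model = model, stats = stats,
                 fitted = unname(stats::fitted(fit)),
                 residuals = unname(res)),
            class = "qsar_fit")
}

#' @export
print.qsar_fit <- function(x, ...) {
  print(x$model)
  s <- x$stats
  cat(sprintf("  n = %d, p = %d, r2 = %.3f, r2_adj = %.3f, q2_loo = %.3f, lse = %.4f\n",
              s$n, s$p, s$r2, s$r2_adj, s$q2_loo, s$lse))
  invisible(x)
}

#' Residuals between experimental and predicted activities
#'
#' @param experimental named (by compound) numeric vector of experimental
#'   activities.
#' @param predicted named numeric vector of predicted activities over the
#'   same compounds.
#' @return data frame `compound`, `experimental`, `predicted`, `residual`
#'   with attributes `sse` and `lse` (mean squared residual).
#' @export
residual_table <- function(experimental, predicted) {
  if (is.null(names(experimental)) || is.null(names(predicted)))
    stop("activities must be named by compound")
  if (!setequal(names(experimental), names(predicted)))
    stop("compound labels differ between experimental and predicted")
  predicted <- predicted[names(experimental)]
  r <- experimental - predicted
  out <- data.frame(compound = names(experimental),
                    experimental = unname(experimental),
                    predicted = unname(predicted),
                    residual = unname(r))
  attr(out, "sse") <- sum(r^2)
  attr(out, "lse") <- mean(r^2)
  out
}

#' Selectivity index
#'
#' Ratio of the IC50 in a normal cell line to the IC50 in a tumour line;
#' larger values indicate a safer compound.  Reported rounded to the
#' nearest integer in the study tables.
#'
#' @param ic50_normal,ic50_tumor positive IC50 values (same unit).
#' @return the ratio (unrounded).
#' @export
selectivity_index <- function(ic50_normal, ic50_tumor) {
  if (any(c(ic50_normal, ic50_tumor) <= 0, na.rm = FALSE) ||
      any(is.na(c(ic50_normal, ic50_tumor))))
    stop("IC50 values must be positive")
  ic50_normal / ic50_tumor
}

#' Fold change of a marker level over control
#'
#' @param treated,control marker levels; `control` must be positive.
#' @return treated / control (unrounded; reported to 1 decimal in tables).
#' @export
fold_change <- function(treated, control) {
  if (any(is.na(control)) || any(control <= 0))
    stop("control level must be positive")
  treated / control
}

#' Apply a fixed model to held-out compounds
#'
#' Predicts the activity of external (test) compounds with an already-fitted
#' model -- no refitting -- and tabulates residuals.
#'
#' @param model a `qsar_model`.
#' @param descriptors data frame of descriptor values with row names (or a
#'   `compound` column) identifying the compounds.
#' @param activities named numeric vector of experimental activities for
#'   the same compounds.
#' @param train_labels compound labels used to train `model`; overlap with
#'   the test compounds is an error.
#' @return residual table as from [residual_table()].
#' @export
external_validate <- function(model, descriptors, activities,
                              train_labels = character()) {
  labs <- if (!is.null(descriptors$compound)) descriptors$compound
          else rownames(descriptors)
  if (is.null(labs)) stop("descriptor rows must be labelled")
  overlap <- intersect(labs, train_labels)
  if (length(overlap))
    stop("test compounds overlap training set: ",
         paste(overlap, collapse = ", "))
  pred <- setNames(predict(model, descriptors), labs)
  residual_table(activities[labs], pred)
}

#' Read / write linear model files
#'
#' Models are stored as JSON with fields `endpoint`, `intercept` and
#' `terms` (descriptor/coefficient pairs).
#'
#' @param file path to a model JSON file.
#' @return a `qsar_model`.
#' @export
read_model <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = TRUE)
  qsar_model(j$endpoint, j$intercept,
             setNames(j$terms$coefficient, j$terms$descriptor))
}

#' @rdname read_model
#' @param model a `qsar_model` to serialise.
#' @export
write_model <- function(model, file) {
  jsonlite::write_json(
    list(endpoint = model$endpoint, intercept = model$intercept,
         terms = data.frame(descriptor = names(model$terms),
                            coefficient = unname(model$terms))),
    file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}

#' The two published regression models
#'
#' The fixed-coefficient linear models for HepG2 and Caco-2 anti-
#' proliferative activity, as packaged model files.
#'
#' @return named list of two `qsar_model` objects (`HepG2`, `Caco-2`).
#' @export
published_models <- function() {
  dir <- system.file("models", package = "coumarinQSAR")
  if (!nzchar(dir)) dir <- file.path("inst", "models")
  list("HepG2" = read_model(file.path(dir, "eq1_hepg2.json")),
       "Caco-2" = read_model(file.path(dir, "eq2_caco2.json")))
}
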