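# One-class predictive models for proximal mis-splicing SNVs. Three model
# classes, one per mutation site group with a high abnormal-splicing rate:
# donor intronic (+3..+6), donor exonic (-2..-1), acceptor intronic (+3).
# Each variant is summarised by two splice-strength differences computed at
# the authentic site: donor models use (donor_mut - donor_wt,
# donor_mut - acceptor_wt); the acceptor model uses (acceptor_mut -
# acceptor_wt, acceptor_mut - donor_wt). A linear-kernel one-class SVM
# (nu = 0.05) learns the boundary of the mis-splicing feature cloud.
#
# Features are scaled by the training standard deviation but NOT centred:
# a linear one-class SVM separates its training cloud from the origin, and
# the signal here is precisely the coherent offset of mis-splicing strength
# losses from zero; centring would erase it.

MODEL_CLASS_POSITIONS <- list(
  donor_intronic = list(side = "donor", region = "intronic", range = c(3L, 6L)),
  donor_exonic = list(side = "donor", region = "exonic", range = c(1L, 2L)),
  acceptor_intronic = list(side = "acceptor", region = "intronic",
                           range = c(3L, 3L)))

#' Model class of a variant position, if any
#'
#' @param location Location call from [classify_variant_location()].
#' @return `"donor_intronic"`, `"donor_exonic"`, `"acceptor_intronic"`, or
#'   `NA` when the position belongs to no model class.
#' @export
feature_model_class <- function(location) {
  d <- location$distance_bp
  if (is.na(d)) return(NA_character_)
  if (location$side == "donor" && d >= 3L && d <= 6L) return("donor_intronic")
  if (location$side == "donor" && d <= -1L && d >= -2L) return("donor_exonic")
  if (location$side == "acceptor" && d == 3L) return("acceptor_intronic")
  NA_character_
}

#' Strength-difference feature pair of a variant
#'
#' @param variant List `pos`, `ref`, `alt` (0-based position).
#' @param location Location call (determines the model class).
#' @param donor_site,acceptor_site Genomic anchors of the authentic donor
#'   and acceptor of the variant's intron (see [splice_site_window()]).
#' @param genome_seq Chromosome sequence.
#' @param donor_model,acceptor_model `splice_strength_model`s.
#' @param strand `"+"` or `"-"`.
#' @return List `model_class`, `f1`, `f2`.
#' @export
make_features <- function(variant, location, donor_site, acceptor_site,
                          genome_seq, donor_model, acceptor_model,
                          strand = "+") {
  mc <- feature_model_class(location)
  if (is.na(mc)) stop("variant position is not eligible for any model class")
  don_wt <- score_splice_site(
    splice_site_window(genome_seq, donor_site, "donor", strand), donor_model)
  acc_wt <- score_splice_site(
    splice_site_window(genome_seq, acceptor_site, "acceptor", strand),
    acceptor_model)
  if (startsWith(mc, "donor")) {
    sd_ <- strength_delta(variant, donor_site, genome_seq, donor_model, strand)
    f1 <- sd_$score_mut - sd_$score_wt
    f2 <- sd_$score_mut - acc_wt
  } else {
    sd_ <- strength_delta(variant, acceptor_site, genome_seq, acceptor_model,
                          strand)
    f1 <- sd_$score_mut - sd_$score_wt
    f2 <- sd_$score_mut - don_wt
  }
  list(model_class = mc, f1 = f1, f2 = f2)
}

#' Train a one-class SVM on mis-splicing feature pairs
#'
#' @param features Numeric matrix (or data.frame) with columns `f1`, `f2`.
#' @param nu Upper bound on the training-error fraction / lower bound on
#'   the support-vector fraction (default 0.05).
#' @param seed RNG seed recorded with the model (training itself is
#'   deterministic).
#' @return Object of class `oneclass_model` carrying the fitted boundary
#'   and the training scale.
#' @export
train_one_class <- function(features, nu = 0.05, seed = 1L) {
  X <- as.matrix(features)[, c("f1", "f2"), drop = FALSE]
  if (nrow(X) < 10L) stop("at least 10 training vectors required")
  sdv <- apply(X, 2L, sd)
  if (all(sdv == 0)) warning("degenerate training set: all feature vectors identical")
  sdv[sdv == 0] <- 1
  Xs <- sweep(X, 2L, sdv, "/")
  set.seed(seed)
  fit <- e1071::svm(Xs, y = NULL, type = "one-classification",
                    kernel = "linear", nu = nu, scale = FALSE)
  structure(list(fit = fit, scale_sd = sdv, nu = nu, seed = seed,
                 n_train = nrow(X)), class = "oneclass_model")
}

#' @export
print.oneclass_model <- function(x, ...) {
  cat(sprintf("<oneclass_model> linear one-class SVM, nu=%.2f, n=%d\n",
              x$nu, x$n_train))
  invisible(x)
}

#' Predict inlier (predicted mis-splicing) status
#'
#' @param object A `oneclass_model`.
#' @param newdata Matrix/data.frame with `f1`, `f2`.
#' @param ... Unused.
#' @return Logical vector: `TRUE` = inlier = predicted mis-splicing.
#' @export
predict.oneclass_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, c("f1", "f2"), drop = FALSE]
  if (!nrow(X)) return(logical(0))
  Xs <- sweep(X, 2L, object$scale_sd, "/")
  # threshold on the decision value with a tolerance proportional to its
  # scale: duplicated training points form margin clusters whose decision
  # values land within libsvm's termination tolerance of zero, and those
  # boundary points must not flip to outliers
  dv <- attr(predict(object$fit, Xs, decision.values = TRUE),
             "decision.values")
  as.vector(dv >= -1e-6 * (1 + max(abs(dv))))
}

#' Cross-validated accuracy of a one-class model
#'
#' Repeated k-fold cross-validation; for a one-class model trained on
#' positives only, fold accuracy is the held-out inlier rate (sensitivity),
#' the only label available. Means are reported both over all folds and
#' over per-iteration means (identical in expectation; SDs differ).
#'
#' @param features Matrix/data.frame with `f1`, `f2`.
#' @param folds,iterations CV protocol (defaults 3, 1000).
#' @param nu One-class nu.
#' @param seed RNG seed for the fold assignments.
#' @return List `mean_accuracy`, `sd_accuracy` (over folds),
#'   `mean_by_iteration`, `sd_by_iteration`, `n`.
#' @export
cross_validate <- function(features, folds = 3L, iterations = 1000L,
                           nu = 0.05, seed = 1L) {
  X <- as.matrix(features)[, c("f1", "f2"), drop = FALSE]
  if (nrow(X) < folds) stop("fewer vectors than folds")
  set.seed(seed)
  fold_acc <- matrix(NA_real_, iterations, folds)
  for (it in seq_len(iterations)) {
    fold <- sample(rep(seq_len(folds), length.out = nrow(X)))
    for (f in seq_len(folds)) {
      tr <- X[fold != f, , drop = FALSE]
      te <- X[fold == f, , drop = FALSE]
      m <- train_one_class(tr, nu = nu, seed = seed)
      fold_acc[it, f] <- mean(predict(m, te))
    }
  }
  list(mean_accuracy = mean(fold_acc), sd_accuracy = sd(as.vector(fold_acc)),
       mean_by_iteration = mean(rowMeans(fold_acc)),
       sd_by_iteration = sd(rowMeans(fold_acc)), n = nrow(X))
}

#' Label candidate variants with a trained one-class model
#'
#' @param model A `oneclass_model`.
#' @param candidates `data.table` with columns `f1`, `f2` (from
#'   [make_features()]) plus any id columns.
#' @return The table with a `predicted_missplicing` column appended.
#' @export
predict_candidates <- function(model, candidates) {
  dt <- as.data.table(candidates)
  if (!nrow(dt)) { dt[, predicted_missplicing := logical(0)]; return(dt) }
  dt[, predicted_missplicing := predict(model, dt[, .(f1, f2)])]
  dt
}
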