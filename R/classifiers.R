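#' Fit a Gaussian discriminant voxel classifier
#'
#' Estimates the parameters of one of the four base classifiers used by the
#' positive-unanimous-voting detector, for the two voxel classes lesional
#' (`w1`, positive) and non-lesional (`w2`):
#'
#' * `NB` — naive Bayes: per-feature, per-class univariate Gaussians
#'   (means and SDs), product likelihood.
#' * `LDA` — linear discriminant: class means with pooled within-class
#'   covariance.
#' * `QDA` — quadratic discriminant: class means with per-class covariances.
#' * `MDA` — Mahalanobis discriminant: nearest class mean in pooled-covariance
#'   Mahalanobis distance (priors are ignored at decision time).
#'
#' Every covariance receives a ridge `epsilon * trace(Sigma)/d` on the
#' diagonal for numerical conditioning. Priors default to class frequencies
#' of the training set.
#'
#' @param X numeric matrix, n x d feature matrix.
#' @param y labels: logical/0-1 vector, `TRUE`/1 = lesional (`w1`).
#' @param kind `"NB"`, `"LDA"`, `"QDA"` or `"MDA"`.
#' @param ridge relative ridge `epsilon` (0 disables regularization).
#' @param priors optional length-2 numeric `c(p_w1, p_w2)`, must sum to 1.
#' @param qda_variant `"full"` (standard QDA discriminant, default) or
#'   `"printed"` (linear-only form without the quadratic and log-determinant
#'   terms).
#' @return An object of class `gda`.
#' @export
gda_fit <- function(X, y, kind = c("NB", "LDA", "QDA", "MDA"),
                    ridge = 1e-6, priors = NULL,
                    qda_variant = c("full", "printed")) {
  kind <- match.arg(kind)
  qda_variant <- match.arg(qda_variant)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.logical(y)
  if (length(y) != nrow(X)) stop("length(y) != nrow(X)")
  if (!any(y) || all(y)) stop("both classes must be present in y")
  d <- ncol(X)
  if (nrow(X) <= d) stop("need more samples than features")
  feats <- colnames(X) %||% paste0("x", seq_len(d))
  X1 <- X[y, , drop = FALSE]; X2 <- X[!y, , drop = FALSE]
  n1 <- nrow(X1); n2 <- nrow(X2)
  mu1 <- colMeans(X1); mu2 <- colMeans(X2)
  sd1 <- apply(X1, 2, sd); sd2 <- apply(X2, 2, sd)
  zero_var <- feats[sd1 == 0 | sd2 == 0]
  if (length(zero_var) && ridge == 0)
    stop("zero-variance feature(s): ", paste(zero_var, collapse = ", "))
  S1 <- cov(X1); S2 <- cov(X2)
  Sp <- ((n1 - 1) * S1 + (n2 - 1) * S2) / (n1 + n2 - 2)
  regularize <- function(S) {
    eps <- ridge * sum(diag(S)) / d
    S + diag(eps, d)
  }
  if (ridge > 0) {
    S1 <- regularize(S1); S2 <- regularize(S2); Sp <- regularize(Sp)
    floor_sd <- sqrt(ridge) * pmax(sd1 + sd2, .Machine$double.eps)
    sd1 <- pmax(sd1, floor_sd); sd2 <- pmax(sd2, floor_sd)
  }
  if (any(sd1 <= 0) || any(sd2 <= 0))
    stop("zero-variance feature(s): ", paste(zero_var, collapse = ", "))
  if (is.null(priors)) priors <- c(n1, n2) / (n1 + n2)
  if (length(priors) != 2L || any(priors <= 0) || abs(sum(priors) - 1) > 1e-8)
    stop("priors must be two positive numbers summing to 1")
  chol_or_stop <- function(S, what) {
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) stop("singular ", what, " covariance")
    ch
  }
  model <- list(kind = kind, d = d, feature_names = feats,
                mu = rbind(w1 = mu1, w2 = mu2),
                nb_sds = rbind(w1 = sd1, w2 = sd2),
                pooled_cov = Sp, class_covs = list(w1 = S1, w2 = S2),
                priors = c(w1 = priors[1], w2 = priors[2]),
                n = c(w1 = n1, w2 = n2),
                ridge = ridge, qda_variant = qda_variant)
  # cache inverses used by the decision rules, failing fast when singular
  if (kind %in% c("LDA", "MDA"))
    model$pooled_inv <- chol2inv(chol_or_stop(Sp, "pooled"))
  if (kind == "QDA") {
    ch1 <- chol_or_stop(S1, "class w1"); ch2 <- chol_or_stop(S2, "class w2")
    model$class_invs <- list(w1 = chol2inv(ch1), w2 = chol2inv(ch2))
    model$logdet <- c(w1 = 2 * sum(log(diag(ch1))), w2 = 2 * sum(log(diag(ch2))))
  }
  structure(model, class = "gda")
}

#' @export
print.gda <- function(x, ...) {
  cat(sprintf("<gda> %s classifier, %d features (%s), n = %d + %d, priors %.3f/%.3f\n",
              x$kind, x$d, paste(x$feature_names, collapse = ", "),
              x$n[1], x$n[2], x$priors[1], x$priors[2]))
  invisible(x)
}

#' @export
coef.gda <- function(object, ...) {
  list(means = object$mu, nb_sds = object$nb_sds,
       pooled_cov = object$pooled_cov, class_covs = object$class_covs,
       priors = object$priors)
}

check_newdata <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$d)
    stop("newdata has ", ncol(X), " features; model expects ", model$d)
  storage.mode(X) <- "double"
  X
}

# Decision scores: positive score means "lesional wins". NB: log posterior
# ratio; LDA/QDA: g1(x) - g2(x); MDA: D(w2,x) - D(w1,x).
gda_score <- function(model, X) {
  X <- check_newdata(model, X)
  switch(model$kind,
    NB = {
      loglik <- function(w) {
        ll <- dnorm(as.vector(X), rep(model$mu[w, ], each = nrow(X)),
                    rep(model$nb_sds[w, ], each = nrow(X)), log = TRUE)
        rowSums(matrix(ll, nrow = nrow(X)))
      }
      unname((loglik("w1") + log(model$priors[["w1"]])) -
             (loglik("w2") + log(model$priors[["w2"]])))
    },
    LDA = {
      Si <- model$pooled_inv
      g <- function(mu, p) X %*% (Si %*% mu) - 0.5 * drop(mu %*% Si %*% mu) + log(p)
      drop(g(model$mu["w1", ], model$priors["w1"]) -
           g(model$mu["w2", ], model$priors["w2"]))
    },
    QDA = {
      if (model$qda_variant == "printed") {
        g <- function(w) {
          Si <- model$class_invs[[w]]; mu <- model$mu[w, ]
          X %*% (Si %*% mu) - 0.5 * drop(mu %*% Si %*% mu) +
            log(model$priors[w])
        }
        drop(g("w1") - g("w2"))
      } else {
        g <- function(w) {
          Si <- model$class_invs[[w]]; mu <- model$mu[w, ]
          Xc <- sweep(X, 2, mu)
          -0.5 * rowSums((Xc %*% Si) * Xc) - 0.5 * model$logdet[w] +
            log(model$priors[w])
        }
        g("w1") - g("w2")
      }
    },
    MDA = {
      Si <- model$pooled_inv
      D <- function(w) {
        Xc <- sweep(X, 2, model$mu[w, ])
        rowSums((Xc %*% Si) * Xc)
      }
      D("w2") - D("w1")
    })
}

#' Predict voxel labels or decision scores
#'
#' Labels follow the classifier's decision rule with score ties resolved to
#' the negative (non-lesional) class — conservative for a lesion detector.
#'
#' @param object a fitted [gda_fit()] model.
#' @param newdata numeric matrix with the model's features as columns.
#' @param type `"label"` for 0/1 labels, `"score"` for the signed decision
#'   score (positive = lesional).
#' @param ... unused.
#' @return numeric vector of labels or scores.
#' @export
predict.gda <- function(object, newdata, type = c("label", "score"), ...) {
  type <- match.arg(type)
  s <- gda_score(object, newdata)
  if (type == "score") s else as.integer(s > 0)
}
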