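#' Combine classifier label volumes by positive unanimous voting
#'
#' `L_PUV(v) = prod_j L_j(v)`: a voxel is lesional only when every classifier
#' labels it lesional — the intersection of the positive sets. The PUV
#' positive set is therefore contained in each classifier's positive set, so
#' both false and true positive counts can only shrink.
#'
#' @param label_volumes list of 0/1 3D arrays (or [fcd_volume]s) on one grid.
#' @return 0/1 3D array of the unanimous labels.
#' @export
puv_combine <- function(label_volumes) {
  stopifnot(length(label_volumes) >= 1L)
  arrs <- lapply(label_volumes, function(v) {
    a <- if (inherits(v, "fcd_volume")) v$data else v
    if (!all(a %in% c(0, 1))) stop("label volumes must be binary")
    a
  })
  dims <- dim(arrs[[1L]])
  for (a in arrs[-1L])
    if (!identical(dim(a), dims)) stop("label volume grid mismatch")
  Reduce(`*`, arrs)
}

#' Closed-form PUV decision from the four fitted classifiers
#'
#' Evaluates the unanimous-voting decision directly from the classifier
#' parameters as the product of four decision indicators: the naive-Bayes
#' posterior ratio `p(w1|x)/p(w2|x) > 1` (computed from the per-feature
#' Gaussian likelihood ratio product), the LDA and QDA discriminant
#' differences `g1(x) - g2(x) > 0`, and the Mahalanobis distance comparison
#' `D(w2,x) > D(w1,x)`. Ties vote negative. The result is identical, voxel
#' for voxel, to [puv_combine()] applied to the four single-classifier label
#' volumes.
#'
#' @param models list of four fitted [gda_fit()] models, one per kind
#'   (NB, LDA, QDA, MDA, any order).
#' @param x numeric matrix of feature vectors (rows).
#' @return integer 0/1 vector, one entry per row of `x`.
#' @export
puv_decision <- function(models, x) {
  kinds <- vapply(models, function(m) m$kind, character(1))
  if (!setequal(kinds, c("NB", "LDA", "QDA", "MDA")) || length(models) != 4L)
    stop("need exactly one model of each kind NB, LDA, QDA, MDA")
  names(models) <- kinds
  x <- as.matrix(x)
  nbm <- models$NB
  # log of the expanded product form: prod_f (s2/s1) exp((x-mu2)^2/(2 s2^2)
  # - (x-mu1)^2/(2 s1^2)), plus the prior ratio of the posterior quotient
  term <- function(w, sgn) {
    mu <- rep(nbm$mu[w, ], each = nrow(x))
    s <- rep(nbm$nb_sds[w, ], each = nrow(x))
    m <- matrix(sgn * (log(s) + (as.vector(x) - mu)^2 / (2 * s^2)),
                nrow = nrow(x))
    rowSums(m)
  }
  log_ratio_nb <- term("w2", 1) + term("w1", -1) +
    log(nbm$priors[["w1"]] / nbm$priors[["w2"]])
  ind_nb <- log_ratio_nb > 0

  ldam <- models$LDA
  Si <- ldam$pooled_inv
  dmu <- ldam$mu["w1", ] - ldam$mu["w2", ]
  lin <- drop(x %*% (Si %*% dmu))
  const <- 0.5 * (drop(ldam$mu["w1", ] %*% Si %*% ldam$mu["w1", ]) -
                  drop(ldam$mu["w2", ] %*% Si %*% ldam$mu["w2", ]))
  ind_lda <- (lin - const + log(ldam$priors[["w1"]] / ldam$priors[["w2"]])) > 0

  ind_qda <- gda_score(models$QDA, x) > 0

  mdam <- models$MDA
  Sim <- mdam$pooled_inv
  D <- function(w) {
    xc <- sweep(x, 2, mdam$mu[w, ])
    rowSums((xc %*% Sim) * xc)
  }
  ind_mda <- D("w2") > D("w1")

  as.integer(ind_nb & ind_lda & ind_qda & ind_mda)
}
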