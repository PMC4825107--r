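#' Pipeline configuration
#'
#' Collects the tunable parameters of the PUV detector with the working
#' defaults: a 3^3-voxel normative window (N = 27), feature group FG6
#' (normative differences of thickness, relative intensity and boundary
#' width), all four base classifiers, opening window `Lw = 3`, region size
#' threshold `Ts = 112.5` mm^3, 26-connectivity.
#'
#' @param feature_group `"FG1"`..`"FG6"`.
#' @param window_edge odd normative window edge in voxels.
#' @param Lw morphological opening window edge (odd).
#' @param Ts_mm3 region size threshold in mm^3.
#' @param connectivity 6, 18 or 26.
#' @param qda_variant `"full"` or `"printed"` QDA discriminant.
#' @param ridge covariance ridge epsilon.
#' @param neg_per_pos training subsampling: at most this many negatives per
#'   positive voxel.
#' @param zscore z-score features with training-set statistics before
#'   classifier fitting.
#' @param priors optional fixed class priors `c(p_w1, p_w2)`.
#' @param boundary_intensity optional fixed `Bg` for the relative-intensity
#'   map (`NULL`: GM/WM histogram peak midpoint per subject).
#' @param seed RNG seed for training subsampling.
#' @return An object of class `puv_config` (a list).
#' @export
puv_config <- function(feature_group = "FG6", window_edge = 3L, Lw = 3L,
                       Ts_mm3 = 112.5, connectivity = 26L,
                       qda_variant = c("full", "printed"), ridge = 1e-6,
                       neg_per_pos = 10, zscore = TRUE, priors = NULL,
                       boundary_intensity = NULL, seed = 1L) {
  stopifnot(feature_group %in% names(feature_groups))
  structure(list(feature_group = feature_group,
                 window_edge = as.integer(window_edge), Lw = as.integer(Lw),
                 Ts_mm3 = Ts_mm3, connectivity = as.integer(connectivity),
                 qda_variant = match.arg(qda_variant), ridge = ridge,
                 neg_per_pos = neg_per_pos, zscore = isTRUE(zscore),
                 priors = priors, boundary_intensity = boundary_intensity,
                 seed = as.integer(seed)),
            class = "puv_config")
}

cohort_features <- function(subjects, config) {
  lapply(subjects, compute_features,
         boundary_intensity = config$boundary_intensity)
}

# Pooled, optionally subsampled and z-scored training matrix across subjects.
build_training_set <- function(subjects, features, normative, config,
                               stream = 0L) {
  xs <- list(); ys <- list()
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    fm <- assemble_feature_matrix(features[[i]], normative,
                                  group = config$feature_group)
    lab <- if (is.null(s$lesion_mask)) rep(0L, length(fm$voxels)) else
      as.integer(s$lesion_mask$data[fm$voxels] != 0)
    xs[[i]] <- fm$x; ys[[i]] <- lab
  }
  X <- do.call(rbind, xs); y <- unlist(ys)
  n_pos <- sum(y == 1)
  if (n_pos == 0) stop("no lesional voxels in the training set")
  neg <- which(y == 0)
  cap <- ceiling(config$neg_per_pos * n_pos)
  if (length(neg) > cap) {
    keep_neg <- with_seed(child_seed(config$seed, 1000L + stream),
                          sample(neg, cap))
    sel <- sort(c(which(y == 1), keep_neg))
    X <- X[sel, , drop = FALSE]; y <- y[sel]
  }
  scaling <- NULL
  if (config$zscore) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, sd)
    scl[scl == 0] <- 1
    X <- sweep(sweep(X, 2, ctr), 2, scl, `/`)
    scaling <- list(center = ctr, scale = scl)
  }
  list(X = X, y = y, scaling = scaling)
}

apply_scaling <- function(X, scaling) {
  if (is.null(scaling)) return(X)
  sweep(sweep(X, 2, scaling$center), 2, scaling$scale, `/`)
}

#' Fit the positive-unanimous-voting FCD detector
#'
#' Builds the full detector from a cohort of pre-aligned subjects: computes
#' the four feature maps per subject, fits the normative local-mean model on
#' the healthy controls, assembles the pooled voxel training set (ground-truth
#' lesion voxels positive, everything else negative, negatives subsampled to
#' `neg_per_pos` per positive), and fits the four Gaussian discriminant
#' classifiers on the configured feature group.
#'
#' @param subjects list of [fcd_subject]s (at least one control and one
#'   patient with a lesion mask).
#' @param config a [puv_config()].
#' @param features optional precomputed list of `fcd_features` matching
#'   `subjects` (to avoid recomputation).
#' @return An object of class `puv_model` with elements `normative`,
#'   `models` (NB/LDA/QDA/MDA), `scaling`, `config`.
#' @export
puv_fit <- function(subjects, config = puv_config(), features = NULL) {
  stopifnot(length(subjects) >= 2L)
  controls <- Filter(function(s) !s$is_patient, subjects)
  if (length(controls) == 0L) stop("need at least one healthy control")
  if (!any(vapply(subjects, `[[`, logical(1), "is_patient")))
    stop("need at least one patient in the training cohort")
  features <- features %||% cohort_features(subjects, config)
  is_ctrl <- !vapply(subjects, `[[`, logical(1), "is_patient")
  normative <- fit_normative(features[is_ctrl], config$window_edge)
  train <- build_training_set(subjects, features, normative, config)
  models <- lapply(c("NB", "LDA", "QDA", "MDA"), function(k)
    gda_fit(train$X, train$y, kind = k, ridge = config$ridge,
            priors = config$priors, qda_variant = config$qda_variant))
  names(models) <- c("NB", "LDA", "QDA", "MDA")
  structure(list(normative = normative, models = models,
                 scaling = train$scaling, config = config,
                 n_train = c(pos = sum(train$y == 1), neg = sum(train$y == 0)),
                 control_ids = vapply(controls, `[[`, character(1), "id")),
            class = "puv_model")
}

#' @export
print.puv_model <- function(x, ...) {
  cat(sprintf("<puv_model> PUV detector on %s (%s)\n", x$config$feature_group,
              paste(feature_groups[[x$config$feature_group]], collapse = ", ")))
  cat(sprintf("  normative: %d controls, N = %d; training voxels: %d pos / %d neg\n",
              x$normative$K, x$normative$N, x$n_train["pos"], x$n_train["neg"]))
  cat(sprintf("  classifiers: %s; Lw = %d, Ts = %g mm^3, %d-connectivity\n",
              paste(names(x$models), collapse = " + "), x$config$Lw,
              x$config$Ts_mm3, x$config$connectivity))
  invisible(x)
}

#' @export
summary.puv_model <- function(object, ...) {
  print(object)
  for (m in object$models) print(m)
  invisible(object)
}

#' @export
coef.puv_model <- function(object, ...) lapply(object$models, coef)

#' Detect lesions in one subject with a fitted PUV model
#'
#' Runs the voxel classification and region refinement for a new subject:
#' assembles the subject's feature matrix against the model's normative maps,
#' labels every domain voxel with each of the four classifiers, combines the
#' labels by positive unanimous voting, and refines the PUV volume by opening,
#' connected-component labelling and the size filter, yielding the
#' subject-level call.
#'
#' @param object a fitted [puv_fit()] model.
#' @param subject an [fcd_subject].
#' @param features optional precomputed `fcd_features` for the subject.
#' @param ... unused.
#' @return An object of class `puv_detection`: per-classifier raw label
#'   volumes, the PUV volume at raw/opened/filtered stages, the surviving
#'   regions, the subject call, and the classification domain mask.
#' @export
predict.puv_model <- function(object, subject, features = NULL, ...) {
  stopifnot(inherits(subject, "fcd_subject"))
  config <- object$config
  features <- features %||% compute_features(subject,
                                             config$boundary_intensity)
  fm <- assemble_feature_matrix(features, object$normative,
                                group = config$feature_group)
  X <- apply_scaling(fm$x, object$scaling)
  dims <- dim(subject$volume$data)
  label_vol <- function(bits) {
    a <- array(0, dim = dims)
    a[fm$voxels] <- bits
    a
  }
  labels <- lapply(object$models, function(m) label_vol(predict(m, X)))
  puv_raw <- puv_combine(labels)
  ref <- refine_labels(puv_raw, subject$volume$spacing, subject$id,
                       Lw = config$Lw, Ts_mm3 = config$Ts_mm3,
                       connectivity = config$connectivity)
  structure(list(subject_id = subject$id, labels = labels, puv = puv_raw,
                 opened = ref$opened, filtered = ref$filtered,
                 regions = ref$regions, surviving = ref$surviving,
                 call = ref$call, domain_mask = features$domain_mask,
                 spacing = subject$volume$spacing,
                 truth = if (is.null(subject$lesion_mask)) NULL else
                   subject$lesion_mask$data),
            class = "puv_detection")
}

#' @export
print.puv_detection <- function(x, ...) {
  cat(sprintf("<puv_detection> subject %s\n", x$subject_id))
  for (k in names(x$labels))
    cat(sprintf("  %-4s positives: %d\n", k, sum(x$labels[[k]])))
  cat(sprintf("  PUV  positives: %d (opened %d, filtered %d)\n",
              sum(x$puv), sum(x$opened), sum(x$filtered)))
  cat(sprintf("  call: %s\n", if (x$call$is_patient_pred) "patient" else "control"))
  invisible(x)
}

#' Voxel metrics of a detection at a chosen stage
#'
#' @param detection a `puv_detection`.
#' @param stage `"raw"`, `"opened"` or `"filtered"` (PUV volume stage) or a
#'   classifier id `"NB"`, `"LDA"`, `"QDA"`, `"MDA"` (raw labels).
#' @param truth optional 0/1 truth array; defaults to the subject's lesion
#'   mask (all-zero if the subject had none).
#' @return `puv_metrics` computed within the classification domain mask.
#' @export
detection_voxel_metrics <- function(detection, stage = "filtered",
                                    truth = NULL) {
  pred <- switch(stage,
                 raw = detection$puv, opened = detection$opened,
                 filtered = detection$filtered,
                 detection$labels[[stage]])
  if (is.null(pred)) stop("unknown stage ", stage)
  truth <- truth %||% detection$truth %||% array(0, dim = dim(pred))
  detection_metrics(confusion_counts(pred, truth, detection$domain_mask))
}

#' @export
plot.puv_detection <- function(x, z = NULL, ...) {
  d <- dim(x$puv)
  z <- z %||% if (!is.null(x$truth) && any(x$truth != 0))
    round(mean(arrayInd(which(x$truth != 0), d)[, 3])) else d[3] %/% 2L
  sl <- x$filtered[, , z]
  image(seq_len(d[1]), seq_len(d[2]), sl, col = c("white", "red"),
        xlab = "x", ylab = "y",
        main = sprintf("%s: filtered PUV labels, slice z = %d", x$subject_id, z),
        ...)
  if (!is.null(x$truth)) {
    tr <- x$truth[, , z]
    if (any(tr != 0))
      contour(seq_len(d[1]), seq_len(d[2]), tr, levels = 0.5, add = TRUE,
              drawlabels = FALSE, col = "blue")
  }
  invisible(x)
}

#' Leave-one-out cross-validation of the PUV detector
#'
#' Each subject is held out in turn; the normative model is fitted on the
#' remaining controls and the classifiers on all remaining subjects, the held
#' -out subject is classified and refined, and voxel metrics are recorded for
#' every classifier (raw) and for PUV at the raw/opened/filtered stages.
#' Feature maps are computed once per subject; they do not depend on the fold.
#'
#' @param subjects list of [fcd_subject]s (every training fold must retain at
#'   least one control and one patient).
#' @param config a [puv_config()].
#' @return An object of class `puv_loocv`: data frame `voxel` (per subject x
#'   classifier x stage metrics), list `detections`, list `calls`,
#'   `subject_metrics`, and `summary` (mean/SD of each metric by classifier
#'   and stage).
#' @export
puv_loocv <- function(subjects, config = puv_config()) {
  n <- length(subjects)
  stopifnot(n >= 2L)
  is_pat <- vapply(subjects, `[[`, logical(1), "is_patient")
  ids <- vapply(subjects, `[[`, character(1), "id")
  features <- cohort_features(subjects, config)
  rows <- list(); detections <- vector("list", n); calls <- vector("list", n)
  for (i in seq_len(n)) {
    train_idx <- setdiff(seq_len(n), i)
    if (!any(is_pat[train_idx])) stop("training fold without a patient")
    ctrl_idx <- train_idx[!is_pat[train_idx]]
    if (length(ctrl_idx) == 0L) stop("training fold without a control")
    normative <- fit_normative(features[ctrl_idx], config$window_edge)
    train <- build_training_set(subjects[train_idx], features[train_idx],
                                normative, config, stream = i)
    models <- lapply(c("NB", "LDA", "QDA", "MDA"), function(k)
      gda_fit(train$X, train$y, kind = k, ridge = config$ridge,
              priors = config$priors, qda_variant = config$qda_variant))
    names(models) <- c("NB", "LDA", "QDA", "MDA")
    model <- structure(list(normative = normative, models = models,
                            scaling = train$scaling, config = config,
                            n_train = c(pos = sum(train$y == 1),
                                        neg = sum(train$y == 0)),
                            control_ids = ids[ctrl_idx]),
                       class = "puv_model")
    det <- predict(model, subjects[[i]], features = features[[i]])
    detections[[i]] <- det
    calls[[i]] <- det$call
    truth <- det$truth %||% array(0, dim = dim(det$puv))
    stages <- c(names(det$labels), "raw", "opened", "filtered")
    for (st in stages) {
      m <- detection_voxel_metrics(det, st, truth)
      cls <- if (st %in% names(det$labels)) st else "PUV"
      stg <- if (st %in% names(det$labels)) "raw" else st
      rows[[length(rows) + 1L]] <-
        data.frame(subject = ids[i], is_patient = is_pat[i], classifier = cls,
                   stage = stg, tp = m$counts$tp, fp = m$counts$fp,
                   fn = m$counts$fn, tn = m$counts$tn, tpr = m$tpr,
                   fpr = m$fpr, precision = m$precision, f_score = m$f_score)
    }
  }
  voxel <- do.call(rbind, rows)
  truth_flags <- stats::setNames(is_pat, ids)
  subj <- subject_metrics(calls, truth_flags)
  agg <- stats::aggregate(cbind(f_score, tpr, fpr) ~ classifier + stage,
                          data = voxel,
                          FUN = function(v) c(mean = mean(v, na.rm = TRUE),
                                              sd = sd(v, na.rm = TRUE)),
                          na.action = stats::na.pass)
  structure(list(voxel = voxel, detections = detections, calls = calls,
                 subject_metrics = subj, summary = agg, config = config),
            class = "puv_loocv")
}

#' @export
print.puv_loocv <- function(x, ...) {
  cat(sprintf("<puv_loocv> %d subjects\n", length(x$calls)))
  cat("subject level: "); print(x$subject_metrics)
  puv <- x$voxel[x$voxel$classifier == "PUV" & x$voxel$stage == "filtered", ]
  cat(sprintf("voxel level (PUV filtered): mean F = %.3f, mean FPR = %.5f\n",
              mean(puv$f_score), mean(puv$fpr, na.rm = TRUE)))
  invisible(x)
}

#' Fit on a whole cohort and detect on every subject
#'
#' Convenience orchestration of the five framework steps for a cohort read
#' from a manifest or supplied as subjects. Intended for quick runs and the
#' command-line wrapper; use [puv_loocv()] for unbiased evaluation.
#'
#' @param cohort list of [fcd_subject]s or path to a manifest CSV.
#' @param config a [puv_config()].
#' @param out_dir optional directory; when given, label volumes (per
#'   classifier and PUV), region tables and subject calls are written there.
#' @return list with the fitted `puv_model` and per-subject `puv_detection`s.
#' @export
run_detect <- function(cohort, config = puv_config(), out_dir = NULL) {
  subjects <- if (is.character(cohort)) read_cohort(cohort) else cohort
  features <- cohort_features(subjects, config)
  model <- puv_fit(subjects, config, features = features)
  detections <- lapply(seq_along(subjects), function(i)
    predict(model, subjects[[i]], features = features[[i]]))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    calls <- list(); regions <- list()
    for (det in detections) {
      sp <- det$spacing
      for (k in names(det$labels))
        write_volume(fcd_volume(det$labels[[k]], sp),
                     file.path(out_dir, sprintf("%s_label_%s.nii.gz",
                                                det$subject_id, k)),
                     mask = TRUE)
      write_volume(fcd_volume(det$filtered, sp),
                   file.path(out_dir, sprintf("%s_label_PUV_filtered.nii.gz",
                                              det$subject_id)), mask = TRUE)
      if (nrow(det$regions$regions))
        regions[[det$subject_id]] <- cbind(subject_id = det$subject_id,
                                           det$regions$regions)
      calls[[det$subject_id]] <- data.frame(
        subject_id = det$subject_id,
        is_patient_pred = det$call$is_patient_pred)
    }
    write.csv(do.call(rbind, c(calls, make.row.names = FALSE)),
              file.path(out_dir, "subject_calls.csv"), row.names = FALSE)
    if (length(regions))
      write.csv(do.call(rbind, c(regions, make.row.names = FALSE)),
                file.path(out_dir, "regions.csv"), row.names = FALSE)
  }
  list(model = model, detections = detections)
}
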