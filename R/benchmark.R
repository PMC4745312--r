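#' Match segmented objects against ground-truth masks
#'
#' For each ground-truth object, finds the segmented record with the
#' largest intersection-over-union (IoU) of the pixel masks, in full-frame
#' coordinates.
#'
#' @param records object records from [segment_slidemap()].
#' @param truth ground-truth list from [generate_slide_scene()].
#' @param dim scene dimensions `(h, w)`.
#' @return data.frame with `truth_id`, `label`, `phenotype`, `record_id`
#'   (NA if nothing overlaps), `iou`.
#' @export
match_truth_objects <- function(records, truth, dim) {
  H <- dim[1]
  rec_pix <- lapply(records, function(r) {
    loc <- which(r$mask, arr.ind = TRUE)
    (loc[, 2] + r$bbox[["col0"]] - 2L) * H + loc[, 1] + r$bbox[["row0"]] - 1L
  })
  out <- lapply(truth, function(tr) {
    loc <- which(tr$mask, arr.ind = TRUE)
    tp <- (loc[, 2] + tr$bbox[["col"]] - 2L) * H + loc[, 1] + tr$bbox[["row"]] - 1L
    ious <- vapply(rec_pix, function(rp) {
      inter <- length(intersect(tp, rp))
      if (inter == 0) 0 else inter / (length(tp) + length(rp) - inter)
    }, numeric(1))
    best <- if (length(ious) && max(ious) > 0) which.max(ious) else NA_integer_
    data.frame(truth_id = tr$object_id, label = tr$label,
               phenotype = tr$phenotype, record_id = best,
               iou = if (is.na(best)) 0 else ious[best])
  })
  do.call(rbind, out)
}

# render a labeled object set straight from ground truth (no segmentation)
.render_object_set <- function(n, spec, seed) {
  with_seed(seed, {
    n_suit <- n %/% 2
    counts <- .apportion(n - n_suit, spec$unsuitable_mix)
    phenos <- c(rep("suitable", n_suit), rep(names(counts), counts))
    radii <- runif(n, spec$cell_radius_range[1], spec$cell_radius_range[2])
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    lapply(seq_len(n), function(i) {
      tsd <- if (phenos[i] == "suitable") spec$texture_noise_sd_suitable
             else spec$texture_noise_sd_unsuitable
      cell <- render_cell(phenos[i], radii[i], tsd, spec$stain_color,
                          spec$background_level, seed = seeds[i])
      list(object_id = i, mask = cell$mask, crop = cell$crop,
           label = if (phenos[i] == "suitable") "suitable" else "unsuitable",
           phenotype = phenos[i])
    })
  })
}

#' Run the reproducible synthetic benchmark
#'
#' End-to-end surrogate of the cell-selection experiment: generate labeled
#' synthetic objects (1000 training and 360 testing by default, half
#' suitable in each set), extract the feature registry, select
#' `n_features` features with the floating nonparametric-criterion search,
#' train the classifier (RBF-kernel SVM tuned by 10-fold CV by default),
#' and evaluate on the held-out objects.
#'
#' Two modes: `"objects"` (default) renders objects straight from ground
#' truth, isolating the feature/selection/classification stages from
#' segmentation noise; `"scene"` runs the full image pipeline on generated
#' slide scenes and labels segmented objects by best-IoU truth match
#' (practical for small object counts).
#'
#' @param n_train,n_test object counts (half suitable each).
#' @param n_features selected-subset size (default 7).
#' @param method,kernel,folds classifier settings, see [train_classifier()].
#' @param registry feature registry, see [feature_registry()].
#' @param spec a [scene_spec()] providing rendering parameters.
#' @param B bootstrap resamples for the report CIs.
#' @param shuffle_labels permute the training labels (negative control).
#' @param seed integer master seed.
#' @return list with `report` (an `eval_report`), `trace`
#'   (`selection_trace`), `model`, `train`, `test` (feature tables), and
#'   `config`.
#' @export
run_benchmark <- function(n_train = 1000, n_test = 360, n_features = 7,
                          method = "svm", kernel = "rbf", folds = 10,
                          registry = feature_registry("full"),
                          spec = scene_spec(), B = 1000,
                          shuffle_labels = FALSE, seed = 1L,
                          mode = c("objects", "scene")) {
  mode <- match.arg(mode)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 5))
  if (mode == "objects") {
    train_obj <- .render_object_set(n_train, spec, seeds[1])
    test_obj <- .render_object_set(n_test, spec, seeds[2])
  } else {
    collect <- function(want, sd0) {
      objs <- list(); s <- sd0
      while (length(objs) < want) {
        sc_spec <- spec
        sc_spec$seed <- s
        sc <- generate_slide_scene(sc_spec)
        map <- stitch_tiles(sc$tiles, sc_spec$tile_grid)
        recs <- segment_slidemap(map, sc$background)
        m <- match_truth_objects(recs, sc$truth, dim(sc$scene))
        ok <- !is.na(m$record_id) & m$iou >= 0.5
        for (i in which(ok)) {
          r <- recs[[m$record_id[i]]]
          r$label <- m$label[i]
          objs[[length(objs) + 1]] <- r
        }
        s <- s + 1L
      }
      objs[seq_len(want)]
    }
    train_obj <- collect(n_train, seeds[1])
    test_obj <- collect(n_test, seeds[2])
  }
  train <- compute_feature_table(train_obj, registry)
  test <- compute_feature_table(test_obj, registry)
  if (shuffle_labels)
    train$labels <- with_seed(seeds[3], sample(train$labels))
  trace <- stepwise_select(train, n_features)
  train_sel <- subset_features(train, features = trace$selected)
  test_sel <- subset_features(test, features = trace$selected)
  model <- train_classifier(train_sel, method = method, kernel = kernel,
                            folds = folds, seed = seeds[4])
  report <- evaluate_classifier(model, test_sel, B = B, seed = seeds[5])
  list(report = report, trace = trace, model = model,
       train = train, test = test,
       config = list(n_train = n_train, n_test = n_test,
                     n_features = n_features, method = method,
                     kernel = kernel, folds = folds, seed = seed,
                     mode = mode, shuffle_labels = shuffle_labels))
}
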