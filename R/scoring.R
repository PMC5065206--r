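#' Batch scoring and the full pipeline
#'
#' @name scoring
#' @keywords internal
NULL

#' Run configuration
#'
#' Collects which scores to compute and the statistical settings.
#' Score columns are named `pd_s{span}_{penalty}` (e.g. `pd_s3_linear`),
#' `resid_{type}_mu` / `resid_{type}_sigma`, and `ra`, `sf`, `rd`.
#'
#' @param spans subset of the moving-average spans (default `c(3,5,7,9)`).
#' @param penalties subset of `c("linear","quadratic","cubic")`.
#' @param residual_types subset of `c("mean","median")`.
#' @param classic include RA, SF, RD (default TRUE).
#' @param alpha significance level for the statistics stage.
#' @param seed seed for block pairing and any simulation.
#' @param boundary smoothing boundary rule, see [smooth_profile()].
#' @return object of class `run_config`.
#' @export
run_config <- function(spans = c(3, 5, 7, 9),
                       penalties = c("linear", "quadratic", "cubic"),
                       residual_types = c("mean", "median"),
                       classic = TRUE, alpha = 0.05, seed = 1L,
                       boundary = "wrap") {
  penalties <- match.arg(penalties, several.ok = TRUE)
  if (length(residual_types))
    residual_types <- match.arg(residual_types, c("mean", "median"), several.ok = TRUE)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (length(spans) && any(spans %% 2 == 0 | spans < 3))
    stop("spans must be odd integers >= 3")
  n_metrics <- length(spans) * length(penalties) + length(residual_types) * 2 +
    if (classic) 3 else 0
  if (n_metrics == 0) stop("config enables no metric")
  structure(list(spans = as.integer(spans), penalties = penalties,
                 residual_types = residual_types, classic = classic,
                 alpha = alpha, seed = as.integer(seed), boundary = boundary),
            class = "run_config")
}

#' Metric column names implied by a configuration
#' @param config a [run_config()].
#' @return character vector of score column names.
#' @export
metric_names <- function(config = run_config()) {
  c(as.vector(t(outer(config$spans, config$penalties,
                      function(s, p) sprintf("pd_s%d_%s", s, p)))),
    as.vector(vapply(config$residual_types,
                     function(t) sprintf("resid_%s_%s", t, c("mu", "sigma")),
                     character(2))),
    if (config$classic) c("ra", "sf", "rd"))
}

#' Score a single nucleus
#'
#' Computes every enabled score for one nucleus given as a mask, a contour,
#' or both. A missing contour is traced from the mask; a missing mask (needed
#' only for the classic metrics) is filled from the contour.
#'
#' @param mask binary nucleus mask, or NULL.
#' @param contour ordered contour matrix, or NULL.
#' @param config a [run_config()].
#' @return named numeric vector with one element per metric column.
#' @export
score_nucleus <- function(mask = NULL, contour = NULL, config = run_config()) {
  if (is.null(mask) && is.null(contour)) stop("need a mask or a contour")
  if (is.null(contour)) contour <- extract_contour(mask)
  if (is.null(mask) && config$classic) mask <- fill_contour(contour)
  d <- radial_distances(contour)
  out <- numeric(0)
  for (s in config$spans) for (p in config$penalties) {
    cfg <- penalty_config(span = s, penalty = p, boundary = config$boundary)
    out[sprintf("pd_s%d_%s", s, p)] <- penalty_driven_score(contour, cfg)$pd
  }
  for (t in config$residual_types) {
    res <- residual_analysis(d, t)
    out[sprintf("resid_%s_mu", t)] <- res$mu
    out[sprintf("resid_%s_sigma", t)] <- res$sigma
  }
  if (config$classic) {
    cm <- classic_metrics(mask)
    out["ra"] <- cm$ra; out["sf"] <- cm$sf; out["rd"] <- cm$rd
  }
  out
}

#' Score every nucleus of a synthetic cohort
#'
#' @param cohort result of [generate_cohort()].
#' @param config a [run_config()].
#' @param segment if TRUE, re-segment each rendered image instead of using
#'   the ground-truth mask (the cohort must have been generated with
#'   `render = TRUE`).
#' @return data frame with `image_id`, `class`, and one column per metric.
#' @export
score_cohort <- function(cohort, config = run_config(), segment = FALSE) {
  rows <- lapply(cohort$items, function(it) {
    if (segment) {
      mask <- segment_nucleus(it$image)
      sc <- score_nucleus(mask = mask, config = config)
    } else {
      sc <- score_nucleus(mask = it$nucleus$mask, contour = it$nucleus$contour,
                          config = config)
    }
    cbind(data.frame(image_id = it$id, class = it$class), as.data.frame(t(sc)))
  })
  do.call(rbind, rows)
}

#' Score a directory of images, masks, or contours
#'
#' Input detection per file: `.csv` files are read as ordered contours
#' (columns `x`, `y`); `.png`/`.tif(f)` files are read as images — a
#' two-valued single-channel image is taken as a pre-segmented binary mask,
#' anything else is run through [segment_nucleus()]. Class labels come from
#' a `manifest.csv` (columns `image_id`, `class`) in the directory, or,
#' failing that, from immediate subdirectory names. Per-item failures are
#' recorded, not fatal.
#'
#' @param input_dir directory to scan (recursively).
#' @param config a [run_config()].
#' @param out optional path for the scores CSV.
#' @return list with `scores` (data frame) and `errors` (data frame of
#'   failed items with messages).
#' @export
score_batch <- function(input_dir, config = run_config(), out = NULL) {
  files <- sort(list.files(input_dir, pattern = "\\.(png|tif|tiff|csv)$",
                           recursive = TRUE, full.names = TRUE,
                           ignore.case = TRUE))
  files <- files[basename(files) != "manifest.csv"]
  if (!length(files)) stop("no readable inputs in ", input_dir)
  manifest_path <- file.path(input_dir, "manifest.csv")
  labels <- NULL
  if (file.exists(manifest_path)) {
    man <- read.csv(manifest_path, stringsAsFactors = FALSE)
    labels <- setNames(as.character(man$class), man$image_id)
  }
  scores <- list(); errors <- list()
  for (f in files) {
    id <- sub("\\.[^.]*$", "", basename(f))
    cl <- if (!is.null(labels) && id %in% names(labels)) labels[[id]]
          else basename(dirname(f))
    res <- tryCatch({
      if (grepl("\\.csv$", f, ignore.case = TRUE)) {
        sc <- score_nucleus(contour = validate_contour(read_contour(f)),
                            config = config)
      } else {
        img <- read_image(f)
        if (is.matrix(img) && length(unique(as.vector(img))) <= 2L) {
          sc <- score_nucleus(mask = img > max(img) / 2, config = config)
        } else {
          sc <- score_nucleus(mask = segment_nucleus(img), config = config)
        }
      }
      cbind(data.frame(image_id = id, class = cl), as.data.frame(t(sc)))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[length(errors) + 1L]] <- data.frame(image_id = id, file = f,
                                                  message = conditionMessage(res))
    } else {
      scores[[length(scores) + 1L]] <- res
    }
  }
  if (!length(scores)) stop("no inputs could be scored in ", input_dir)
  list(scores = do.call(rbind, scores),
       errors = if (length(errors)) do.call(rbind, errors)
                else data.frame(image_id = character(0), file = character(0),
                                message = character(0)),
       out = if (!is.null(out)) {
         write.csv(do.call(rbind, scores), out, row.names = FALSE); out
       })
}

#' Simulate, score, and test in one call
#'
#' Generates a synthetic cohort (or scores an input directory), computes all
#' enabled metrics, and runs the Friedman + post-hoc report.
#'
#' @param config a [run_config()].
#' @param n_per_class cohort size per class (ignored with `input_dir`).
#' @param master_seed cohort master seed (defaults to `config$seed`).
#' @param input_dir optional directory of existing inputs (see
#'   [score_batch()]).
#' @param segment if TRUE render images and push them through the
#'   segmentation pipeline instead of using ground-truth masks.
#' @return list with `manifest` (synthetic runs), `scores`, and `report`
#'   (an `irr_significance`).
#' @export
full_pipeline <- function(config = run_config(), n_per_class = 200,
                          master_seed = NULL, input_dir = NULL,
                          segment = FALSE) {
  if (is.null(master_seed)) master_seed <- config$seed
  if (is.null(input_dir)) {
    cohort <- generate_cohort(n_per_class, master_seed, render = segment)
    scores <- score_cohort(cohort, config, segment = segment)
    manifest <- cohort$manifest
  } else {
    batch <- score_batch(input_dir, config)
    scores <- batch$scores
    manifest <- NULL
  }
  report <- significance_table(scores, metrics = metric_names(config),
                               alpha = config$alpha, seed = config$seed)
  list(manifest = manifest, scores = scores, report = report)
}

#' Boxplots of a score by diagnostic class
#'
#' Minimal plotting helper for cohort score tables.
#'
#' @param scores data frame from [score_cohort()] / [score_batch()].
#' @param metric score column to plot.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot_scores <- function(scores, metric, ...) {
  boxplot(scores[[metric]] ~ factor(scores$class, levels = unique(scores$class)),
          xlab = "class", ylab = metric, ...)
  invisible(NULL)
}
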