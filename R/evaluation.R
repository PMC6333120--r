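# Evaluation: mean absolute error (HU) by tissue region against a reference
# CT on the MR grid, with the background excluded by a body mask, plus the
# leave-one-out and train/test drivers.

#' Region masks for evaluation
#'
#' `entire` is the body mask; `bone`, `fat` and `muscle` are the
#' corresponding label regions intersected with it, so every tissue mask is
#' a subset of `entire` and outside-body air is excluded everywhere.
#'
#' @param reference_labels [label_volume()] on the evaluation grid.
#' @param body_mask `masct_volume` mask aligned with the labels.
#' @return named list of logical arrays (`entire`, `bone`, `fat`, `muscle`).
#' @export
region_masks <- function(reference_labels, body_mask) {
  if (!identical(dim(reference_labels$labels), dim(body_mask$data)))
    stop("labels and body mask must be aligned", call. = FALSE)
  body <- body_mask$data != 0
  if (!any(body)) stop("empty body mask", call. = FALSE)
  lab <- reference_labels$labels
  list(entire = body,
       bone = (lab == 4L) & body,
       fat = (lab == 2L) & body,
       muscle = (lab == 3L) & body)
}

#' Mean absolute error over a masked region
#'
#' @param reference,test `masct_volume`s on one grid.
#' @param mask logical/binary array or `masct_volume` mask; must select at
#'   least one voxel.
#' @return MAE in the images' units (HU for CT).
#' @export
mae <- function(reference, test, mask = NULL) {
  a <- if (inherits(reference, "masct_volume")) reference$data else reference
  b <- if (inherits(test, "masct_volume")) test$data else test
  if (!identical(dim(a), dim(b)))
    stop("images must share one grid", call. = FALSE)
  m <- if (is.null(mask)) array(TRUE, dim(a))
       else if (inherits(mask, "masct_volume")) mask$data != 0
       else mask != 0
  if (!any(m)) stop("empty evaluation mask", call. = FALSE)
  mean(abs(a[m] - b[m]))
}

evaluate_sct <- function(sct, reference_ct, reference_labels, body) {
  rm <- region_masks(reference_labels, body)
  vapply(rm, function(m) if (any(m)) mae(reference_ct, sct, m) else NA_real_,
         double(1))
}

#' Leave-one-out evaluation over a cohort
#'
#' Each subject is synthesized from an atlas of all remaining subjects and
#' scored against its own reference CT on the MR grid. Atlas pairs are
#' subject-local (a pair depends only on its own subject), so each pair is
#' built once and reused across folds. Per subject, the fused result and the
#' per-single-atlas MAEs are reported.
#'
#' @param cohort list of subjects (see [build_atlas()]); each additionally
#'   needs `labels` (a [label_volume()] of reference tissue regions; for
#'   phantom cohorts the generator's ground truth, for real data e.g.
#'   [classify_tissues_ct()] on the reference CT).
#' @param cfg [masct_config()].
#' @return object of class `masct_report`: `per_subject` data frame,
#'   `aggregate` (mean and population SD per region), `single_atlas_mae`
#'   (per subject, entire region, one value per atlas pair), `config`.
#' @export
leave_one_out <- function(cohort, cfg = masct_config()) {
  if (length(cohort) < 2)
    stop("leave-one-out needs a cohort of >= 2 subjects", call. = FALSE)
  ids <- vapply(cohort, function(s) s$id, character(1))
  if (anyDuplicated(ids)) stop("subject ids must be unique", call. = FALSE)
  pairs <- lapply(cohort, build_atlas_pair, cfg = cfg)
  rows <- list(); singles <- list()
  for (i in seq_along(cohort)) {
    a <- structure(list(pairs = pairs[-i],
                        standard_scale = config_scale(cfg),
                        build_config = unclass(cfg)),
                   class = "masct_atlas")
    rep_i <- evaluate_one(a, cohort[[i]], cfg)
    rows[[i]] <- rep_i$row
    singles[[ids[i]]] <- rep_i$single_mae
  }
  finish_report(do.call(rbind, rows), singles, cfg)
}

#' Train/test evaluation
#'
#' One atlas is built from the training subjects and applied to every test
#' subject; train and test ids must be disjoint.
#'
#' @param train,test subject lists (see [leave_one_out()]).
#' @param cfg [masct_config()].
#' @return a `masct_report` (one row per test subject).
#' @export
train_test_eval <- function(train, test, cfg = masct_config()) {
  tr_ids <- vapply(train, function(s) s$id, character(1))
  te_ids <- vapply(test, function(s) s$id, character(1))
  if (length(intersect(tr_ids, te_ids)) > 0)
    stop("train and test subject ids overlap", call. = FALSE)
  a <- build_atlas(train, cfg)
  rows <- list(); singles <- list()
  for (i in seq_along(test)) {
    rep_i <- evaluate_one(a, test[[i]], cfg)
    rows[[i]] <- rep_i$row
    singles[[te_ids[i]]] <- rep_i$single_mae
  }
  finish_report(do.call(rbind, rows), singles, cfg)
}

evaluate_one <- function(a, subject, cfg) {
  body <- body_mask(subject$ct, cfg$air_threshold_hu)
  syn <- synthesize_sct(a, subject$water, subject$fat,
                        as.matrix(subject$landmarks$mr),
                        body_mask = body, cfg = cfg)
  labels <- subject$labels
  maes <- evaluate_sct(syn$sct, subject$ct, labels, body)
  rm <- region_masks(labels, body)
  single <- vapply(syn$prop$entries, function(e)
    mae(subject$ct, e$ct_reg, rm$entire), double(1))
  names(single) <- vapply(syn$prop$entries, function(e) e$id, character(1))
  row <- data.frame(subject = subject$id,
                    mae_entire = maes[["entire"]], mae_bone = maes[["bone"]],
                    mae_fat = maes[["fat"]], mae_muscle = maes[["muscle"]],
                    n_entire = sum(rm$entire), n_bone = sum(rm$bone),
                    n_fat = sum(rm$fat), n_muscle = sum(rm$muscle),
                    stringsAsFactors = FALSE)
  list(row = row, single_mae = single)
}

finish_report <- function(per_subject, singles, cfg) {
  regions <- c("mae_entire", "mae_bone", "mae_fat", "mae_muscle")
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  agg <- data.frame(region = sub("mae_", "", regions),
                    mean = vapply(regions, function(r) mean(per_subject[[r]]),
                                  double(1)),
                    sd = vapply(regions, function(r) pop_sd(per_subject[[r]]),
                                double(1)),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(per_subject = per_subject, aggregate = agg,
                 single_atlas_mae = singles, config = unclass(cfg)),
            class = "masct_report")
}

#' @export
print.masct_report <- function(x, ...) {
  cat("<masct_report>", nrow(x$per_subject), "subject(s)\n")
  a <- x$aggregate
  for (i in seq_len(nrow(a)))
    cat(sprintf("  MAE %-7s %6.1f +/- %.1f HU\n", a$region[i], a$mean[i],
                a$sd[i]))
  invisible(x)
}
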