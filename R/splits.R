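# Cross-validation split plans: stratified image-level folds and
# subject-independent folds.

new_split_plan <- function(strategy, folds, seed) {
  structure(list(strategy = strategy, n_folds = length(folds), folds = folds,
                 seed = seed),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan %s> %d folds\n", x$strategy, x$n_folds))
  for (i in seq_along(x$folds))
    cat(sprintf("  fold %d: train %d / val %d / test %d\n", i,
                length(x$folds[[i]]$train), length(x$folds[[i]]$val),
                length(x$folds[[i]]$test)))
  invisible(x)
}

# split ids of one class into n_folds chunks as evenly as possible,
# larger chunks first
class_chunks <- function(ids, n_folds) {
  n <- length(ids)
  sizes <- rep(n %/% n_folds, n_folds)
  extra <- n %% n_folds
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  split(ids, rep(seq_len(n_folds), times = sizes))
}

# stratified two-way split of ids by label with a given fraction in part 2
strat_holdout <- function(ids, labels, frac2) {
  p1 <- character(); p2 <- character()
  for (cl in unique(labels)) {
    cl_ids <- ids[labels == cl]
    n2 <- max(1L, round(frac2 * length(cl_ids)))
    if (n2 >= length(cl_ids)) n2 <- length(cl_ids) - 1L
    if (n2 < 1L) { p1 <- c(p1, cl_ids); next }
    take <- sample(cl_ids, n2)
    p2 <- c(p2, take)
    p1 <- c(p1, setdiff(cl_ids, take))
  }
  # guarantee a non-empty holdout whenever there is anything to spare
  if (length(p2) == 0L && length(p1) >= 2L) {
    move <- sample(p1, 1L)
    p2 <- move
    p1 <- setdiff(p1, move)
  }
  list(part1 = p1, part2 = p2)
}

#' Stratified image-level cross-validation folds
#'
#' Pools all images and partitions them into `n_folds` stratified test folds
#' (class ratio preserved within one image per fold). Within each fold the
#' non-test images are split 90/10 (stratified) into training and validation.
#' Images from one subject may appear on both sides of a fold, so this
#' strategy upper-bounds image-level discrimination.
#'
#' @param image_ids Character vector of unique image identifiers.
#' @param labels Class label (`"R"`/`"NR"`) per image.
#' @param n_folds Number of folds (default 6).
#' @param val_frac Validation fraction of the non-test images (default 0.10).
#' @param seed Integer seed.
#' @return A `split_plan` with per-fold `train`, `val`, `test` id sets.
#' @export
make_image_folds <- function(image_ids, labels, n_folds = 6L, val_frac = 0.10,
                             seed = 1L) {
  assert_count(n_folds, "n_folds", min = 2L)
  image_ids <- as.character(image_ids)
  if (anyDuplicated(image_ids)) stop("`image_ids` must be unique", call. = FALSE)
  labels <- as.character(labels)
  for (cl in unique(labels))
    if (sum(labels == cl) < n_folds)
      stop(sprintf("class '%s' has fewer images (%d) than folds (%d)",
                   cl, sum(labels == cl), n_folds), call. = FALSE)
  set.seed(seed)
  test_sets <- rep(list(character()), n_folds)
  for (cl in unique(labels)) {
    shuffled <- sample(image_ids[labels == cl])
    ch <- class_chunks(shuffled, n_folds)
    for (i in seq_len(n_folds)) test_sets[[i]] <- c(test_sets[[i]], ch[[i]])
  }
  names(labels) <- image_ids
  folds <- lapply(seq_len(n_folds), function(i) {
    rest <- setdiff(image_ids, test_sets[[i]])
    hv <- strat_holdout(rest, labels[rest], val_frac)
    list(train = hv$part1, val = hv$part2, test = test_sets[[i]])
  })
  new_split_plan("image_level", folds, seed)
}

#' Subject-independent cross-validation folds
#'
#' Partitions subjects (never images) into `n_folds` test folds with class
#' counts as even as possible, so that every subject is tested exactly once
#' and no subject contributes images to both the training and the test side
#' of any fold. For a 12R/18NR cohort this yields six folds of (2R, 3NR); for
#' 23R/23NR, five folds of (4R, 4NR) and a sixth of (3R, 3NR). Remaining
#' subjects are split 90/10 into train/validation at subject granularity.
#'
#' @param subject_ids Unique subject identifiers.
#' @param labels Class label (`"R"`/`"NR"`) per subject.
#' @param n_folds Number of folds (default 6).
#' @param val_frac Validation fraction of non-test subjects (default 0.10).
#' @param seed Integer seed.
#' @return A `split_plan` whose `train`, `val`, `test` sets hold subject ids.
#' @export
make_subject_folds <- function(subject_ids, labels, n_folds = 6L,
                               val_frac = 0.10, seed = 1L) {
  assert_count(n_folds, "n_folds", min = 2L)
  subject_ids <- as.character(subject_ids)
  if (anyDuplicated(subject_ids)) stop("`subject_ids` must be unique", call. = FALSE)
  labels <- as.character(labels)
  counts <- table(labels)
  if (any(counts < n_folds / 2) || length(subject_ids) < n_folds)
    stop(sprintf(
      "cohort (%s) too small for %d subject-level folds; reduce n_folds to <= %d",
      paste(sprintf("%s=%d", names(counts), counts), collapse = ", "),
      n_folds, max(2L, min(counts))), call. = FALSE)
  set.seed(seed)
  test_sets <- rep(list(character()), n_folds)
  for (cl in unique(labels)) {
    shuffled <- sample(subject_ids[labels == cl])
    ch <- class_chunks(shuffled, n_folds)
    for (i in seq_len(n_folds)) test_sets[[i]] <- c(test_sets[[i]], ch[[i]])
  }
  names(labels) <- subject_ids
  folds <- lapply(seq_len(n_folds), function(i) {
    rest <- setdiff(subject_ids, test_sets[[i]])
    hv <- strat_holdout(rest, labels[rest], val_frac)
    list(train = hv$part1, val = hv$part2, test = test_sets[[i]])
  })
  new_split_plan("subject_level", folds, seed)
}
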