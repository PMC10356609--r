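# ROI category labelling: programmatic counterpart of interactive ROI
# annotation. At most 10 distinct categories may be used; the reserved
# category "unlabelled" marks untouched objects and does not count toward
# the limit.

MAX_CATEGORIES <- 10L
UNLABELLED <- "unlabelled"

check_categories <- function(categories) {
  cats <- setdiff(unique(as.character(categories)), c(UNLABELLED, NA_character_))
  if (length(cats) > MAX_CATEGORIES) {
    stopf("%d distinct categories supplied; at most %d are allowed",
          length(cats), MAX_CATEGORIES)
  }
  cats
}

#' Assign ROI categories from a table
#'
#' Fills the `category` column of a results table from an assignment table
#' (`roi_id`, `category`). Objects not mentioned get the reserved category
#' `"unlabelled"`. At most 10 distinct categories are allowed; unknown
#' `roi_id`s are an error listing the offending ids.
#'
#' @param records Output of [measure_rois()].
#' @param assignment Data frame with columns `roi_id` and `category`.
#' @return `records` with `category` filled.
#' @export
#' @examples
#' rec <- data.frame(roi_id = 1:3, category = NA_character_)
#' assign_by_table(rec, data.frame(roi_id = 1:2, category = c("EZ", "DZ")))
assign_by_table <- function(records, assignment) {
  if (!all(c("roi_id", "category") %in% names(assignment))) {
    stopf("`assignment` needs columns roi_id and category")
  }
  check_categories(assignment$category)
  unknown <- setdiff(assignment$roi_id, records$roi_id)
  if (length(unknown)) {
    stopf("assignment refers to unknown roi_id(s): %s",
          paste(sort(unknown), collapse = ", "))
  }
  m <- match(records$roi_id, assignment$roi_id)
  records$category <- ifelse(is.na(m), UNLABELLED,
                             as.character(assignment$category)[m])
  records
}

#' Assign ROI categories from region masks
#'
#' Each object is assigned to the category whose mask covers the majority of
#' its voxels (ties resolve to the alphabetically first category name);
#' objects covered by no mask are `"unlabelled"`. Mirrors drawing named
#' regions (for example root zones) over a maximum Z projection.
#'
#' @param labels Integer 3D label array.
#' @param masks Named list of logical 3D arrays, same shape as `labels`; at
#'   most 10 entries.
#' @return Data frame with columns `roi_id` and `category`.
#' @export
assign_by_mask <- function(labels, masks) {
  labels <- as_volume(labels, "labels")
  if (!is.list(masks) || is.null(names(masks)) || any(names(masks) == "")) {
    stopf("`masks` must be a named list of logical arrays")
  }
  check_categories(names(masks))
  nlab <- max(labels, 0L)
  cover <- matrix(0L, nlab, length(masks),
                  dimnames = list(NULL, names(masks)))
  for (nm in names(masks)) {
    m <- as_mask(masks[[nm]], nm)
    if (!same_dim(m, labels)) stopf("mask '%s' dim does not match `labels`", nm)
    inside <- labels[m]
    inside <- inside[inside > 0L]
    if (length(inside)) cover[, nm] <- tabulate(inside, nbins = nlab)
  }
  ord <- order(colnames(cover))  # alphabetic tie-break
  cover <- cover[, ord, drop = FALSE]
  category <- rep(UNLABELLED, nlab)
  if (nlab > 0L) {
    best <- apply(cover, 1L, function(r) {
      if (all(r == 0L)) return(NA_integer_)
      which.max(r)  # first maximum in alphabetic order
    })
    hit <- !is.na(best)
    category[hit] <- colnames(cover)[best[hit]]
  }
  data.frame(roi_id = seq_len(nlab), category = category)
}

#' Remeasure a label map on a new stack, keeping categories
#'
#' Runs [measure_rois()] against a (possibly different) stack and carries
#' category assignments over by `roi_id`. Assignment rows whose id is absent
#' from the label map are reported as orphaned (attribute `orphaned_ids`,
#' plus a warning) rather than silently dropped.
#'
#' @param labels Integer 3D label array.
#' @param assignment Data frame (`roi_id`, `category`), e.g. from
#'   [assign_by_mask()].
#' @param stack An [multichannel_stack()] matching `labels` in shape.
#' @param mask Optional exclusion mask (see [measure_rois()]).
#' @return Annotated records; attribute `orphaned_ids` lists assignment ids
#'   not present in the label map.
#' @export
remeasure <- function(labels, assignment, stack, mask = NULL) {
  records <- measure_rois(labels, stack, mask)
  orphaned <- sort(setdiff(assignment$roi_id, records$roi_id))
  if (length(orphaned)) {
    warning(sprintf("assignment roi_id(s) absent from label map (orphaned): %s",
                    paste(orphaned, collapse = ", ")), call. = FALSE)
    assignment <- assignment[!assignment$roi_id %in% orphaned, , drop = FALSE]
  }
  out <- assign_by_table(records, assignment)
  attr(out, "orphaned_ids") <- orphaned
  out
}

#' Per-category summary of emission ratios
#'
#' @param records Annotated records (with a `category` column).
#' @return Data frame with `category`, `n` and `median_ratio`.
#' @export
summarize_categories <- function(records) {
  cat_f <- factor(records$category)
  n <- as.integer(table(cat_f))
  med <- as.numeric(tapply(records$emission_ratio, cat_f, median, na.rm = TRUE))
  data.frame(category = levels(cat_f), n = n, median_ratio = med)
}
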