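#' Item specifications for the PHQ-9 / GAD-7 / TSQ symptom battery
#'
#' Builds the table of item specifications the rest of the package works
#' with: nine PHQ-9 depression items and seven GAD-7 anxiety items scored
#' 0 ("not at all") to 3 ("nearly every day"), and ten Trauma Screening
#' Questionnaire (TSQ) PTSD items with a binary yes/no (0/1) format.
#'
#' Non-default block sizes produce a reduced battery (the first `p_dep`
#' PHQ items, etc.) and are intended for simulation studies on smaller
#' networks; labels then fall back to the item code.
#'
#' @param p_dep,p_anx,p_ptsd number of items taken from each instrument.
#' @return A data.frame with one row per item and columns `name`,
#'   `instrument` (`"PHQ9"`, `"GAD7"`, `"TSQ"`), `level_min`, `level_max`
#'   and `label`.
#' @export
#' @examples
#' items <- phq_gad_tsq_items()
#' table(items$instrument)
phq_gad_tsq_items <- function(p_dep = 9L, p_anx = 7L, p_ptsd = 10L) {
  stopifnot(p_dep >= 0, p_anx >= 0, p_ptsd >= 0, p_dep <= 9, p_anx <= 7,
            p_ptsd <= 10)
  phq_labels <- c("Anhedonia", "Sad mood", "Sleep", "Fatigue", "Appetite",
                  "Guilt", "Concentration", "Motor", "Suicide")
  gad_labels <- c("Nervousness", "Uncontrollable worry", "Excessive worry",
                  "Trouble relaxing", "Restlessness", "Irritability",
                  "Afraid something awful might happen")
  tsq_labels <- c("Upsetting memories", "Upsetting dreams", "Flashbacks",
                  "Emotional cue activity", "Bodily reactions",
                  "Sleep disturbance", "Irritability",
                  "Difficulty concentrating", "Hypervigilance",
                  "Exaggerated startle response")
  spec <- rbind(
    data.frame(name = paste0("PHQ.", seq_len(9)), instrument = "PHQ9",
               level_min = 0L, level_max = 3L, label = phq_labels)[seq_len(p_dep), ],
    data.frame(name = paste0("GAD.", seq_len(7)), instrument = "GAD7",
               level_min = 0L, level_max = 3L, label = gad_labels)[seq_len(p_anx), ],
    data.frame(name = paste0("PTSD.", seq_len(10)), instrument = "TSQ",
               level_min = 0L, level_max = 1L, label = tsq_labels)[seq_len(p_ptsd), ])
  rownames(spec) <- NULL
  if (p_dep < 9L || p_anx < 7L || p_ptsd < 10L) spec$label <- spec$name
  spec
}

validate_items <- function(items) {
  need <- c("name", "instrument", "level_min", "level_max", "label")
  if (!is.data.frame(items) || !all(need %in% names(items)))
    sn_stop("sn_schema_error", "item table must have columns %s",
            paste(need, collapse = ", "))
  if (anyDuplicated(items$name))
    sn_stop("sn_schema_error", "duplicated item names")
  bad <- !items$instrument %in% c("PHQ9", "GAD7", "TSQ")
  if (any(bad))
    sn_stop("sn_schema_error", "unknown instrument: %s",
            items$instrument[bad][1])
  ord <- items$instrument %in% c("PHQ9", "GAD7")
  if (any(items$level_min[ord] != 0L) || any(items$level_max[ord] != 3L))
    sn_stop("sn_schema_error", "PHQ9/GAD7 items must be scored 0..3")
  if (any(items$level_min[!ord] != 0L) || any(items$level_max[!ord] != 1L))
    sn_stop("sn_schema_error", "TSQ items must be scored 0/1")
  items
}

#' Construct a validated symptom dataset
#'
#' The container every estimation stage consumes: an integer score matrix
#' (respondents by items), a group label per respondent and the item
#' specification table.  Scores are checked against each item's level
#' range; no missing values are allowed (see [read_dataset()] for the
#' listwise-deletion policy applied to files).
#'
#' @param scores integer matrix, `n` respondents by `p` items; column
#'   names must match `items$name` (unnamed columns are assigned them).
#' @param group character or factor of length `n`.
#' @param items item specification table, see [phq_gad_tsq_items()].
#' @return An object of class `symptom_dataset` with elements `scores`,
#'   `group` (factor), `items`, `n` and `p`.
#' @export
symptom_dataset <- function(scores, group, items = phq_gad_tsq_items()) {
  items <- validate_items(items)
  scores <- as.matrix(scores)
  if (is.null(colnames(scores))) colnames(scores) <- items$name
  if (!identical(colnames(scores), items$name))
    sn_stop("sn_schema_error", "score columns do not match item names")
  if (length(group) != nrow(scores))
    sn_stop("sn_schema_error", "group has length %d, need %d",
            length(group), nrow(scores))
  if (anyNA(scores))
    sn_stop("sn_validation_error", "missing scores after validation")
  if (any(scores != round(scores)))
    sn_stop("sn_validation_error", "non-integer score values")
  storage.mode(scores) <- "integer"
  for (j in seq_len(ncol(scores))) {
    bad <- which(scores[, j] < items$level_min[j] |
                 scores[, j] > items$level_max[j])
    if (length(bad))
      sn_stop("sn_validation_error",
              "item %s: score %d out of range [%d, %d] at row %d",
              items$name[j], scores[bad[1], j], items$level_min[j],
              items$level_max[j], bad[1])
  }
  structure(list(scores = scores, group = factor(group), items = items,
                 n = nrow(scores), p = ncol(scores)),
            class = "symptom_dataset")
}

#' @export
print.symptom_dataset <- function(x, ...) {
  cat(sprintf("symptom_dataset: %d respondents x %d items\n", x$n, x$p))
  print(table(group = x$group))
  invisible(x)
}

#' Subset a symptom dataset by group or row index
#'
#' @param data a [symptom_dataset()].
#' @param group group labels to keep (default all).
#' @param rows integer row indices to keep (applied after group filter).
#' @return A `symptom_dataset` with the selected respondents.
#' @export
subset_dataset <- function(data, group = NULL, rows = NULL) {
  stopifnot(inherits(data, "symptom_dataset"))
  keep <- seq_len(data$n)
  if (!is.null(group)) keep <- keep[data$group[keep] %in% group]
  if (!is.null(rows)) keep <- keep[rows]
  symptom_dataset(data$scores[keep, , drop = FALSE],
                  droplevels(data$group[keep]), data$items)
}

#' Read a wide item-level CSV into a symptom dataset
#'
#' Expects a header row, one integer column per declared item and a group
#' column.  Unknown columns raise a schema error naming the column.  Rows
#' containing any missing item value are dropped (listwise deletion) with
#' a message stating how many; out-of-range values raise a validation
#' error citing the first offending row.  Row order is preserved.
#'
#' @param path CSV file path.
#' @param group_column name of the group-label column (default `"group"`).
#' @param items item specification table.
#' @return A [symptom_dataset()].
#' @export
read_dataset <- function(path, group_column = "group",
                         items = phq_gad_tsq_items()) {
  items <- validate_items(items)
  df <- read.csv(path, check.names = FALSE)
  if (!group_column %in% names(df))
    sn_stop("sn_schema_error", "missing group column '%s'", group_column)
  unknown <- setdiff(names(df), c(items$name, group_column))
  if (length(unknown))
    sn_stop("sn_schema_error", "unknown column '%s'", unknown[1])
  missing_items <- setdiff(items$name, names(df))
  if (length(missing_items))
    sn_stop("sn_schema_error", "missing item column '%s'", missing_items[1])
  scores <- as.matrix(df[, items$name, drop = FALSE])
  keep <- !apply(is.na(scores), 1, any) & !is.na(df[[group_column]])
  if (any(!keep))
    message(sprintf("read_dataset: dropped %d of %d rows with missing values",
                    sum(!keep), nrow(scores)))
  symptom_dataset(scores[keep, , drop = FALSE], df[[group_column]][keep],
                  items)
}

#' Write a symptom dataset to CSV
#'
#' Inverse of [read_dataset()]: one row per respondent, one column per
#' item plus the group column.
#'
#' @param data a [symptom_dataset()].
#' @param path output CSV path.
#' @param group_column name for the group column.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path, group_column = "group") {
  stopifnot(inherits(data, "symptom_dataset"))
  df <- as.data.frame(data$scores)
  df[[group_column]] <- as.character(data$group)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Flag childhood-trauma subgroups from CTQ-SF abuse subscale scores
#'
#' Applies the moderate-severe CTQ-SF cutoffs: emotional abuse (EA) at a
#' subscale score of 13 or more, physical abuse (PA) at 10 or more,
#' sexual abuse (SA) at 8 or more.  Each 5-item subscale score ranges
#' 5-25.  The three flags are independent: a respondent can carry
#' several, and allocating multi-positive respondents to disjoint
#' analysis groups is deliberately left to the caller.
#'
#' @param ea_score,pa_score,sa_score integer vectors of subscale sums
#'   (each in 5..25), recycled to a common length.
#' @return A data.frame with logical columns `EA`, `PA`, `SA`.
#' @export
#' @examples
#' assign_ct_subgroup(13, 9, 7)   # EA only
assign_ct_subgroup <- function(ea_score, pa_score, sa_score) {
  n <- max(length(ea_score), length(pa_score), length(sa_score))
  ea <- rep_len(ea_score, n); pa <- rep_len(pa_score, n)
  sa <- rep_len(sa_score, n)
  for (s in list(ea, pa, sa)) {
    if (anyNA(s) || any(s != round(s)) || any(s < 5) || any(s > 25))
      sn_stop("sn_validation_error",
              "CTQ-SF subscale scores must be integers in 5..25")
  }
  data.frame(EA = ea >= 13, PA = pa >= 10, SA = sa >= 8)
}
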