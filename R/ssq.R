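# Simulator Sickness Questionnaire scoring: 16 items on a 0-3 scale,
# three weighted subscales (Nausea, Oculomotor, Disorientation) and the
# weighted total.

#' SSQ item-to-subscale mapping
#'
#' The standard Kennedy 16-item table: each subscale sums 7 designated
#' items and items may contribute to two subscales. Shipped as an
#' editable data.frame so alternative mappings can be substituted.
#'
#' @return data.frame with columns `item`, `symptom`, `nausea`,
#'   `oculomotor`, `disorientation` (0/1 membership).
#' @export
ssq_item_table <- function() {
  data.frame(
    item = 1:16,
    symptom = c("general discomfort", "fatigue", "headache", "eye strain",
                "difficulty focusing", "increased salivation", "sweating",
                "nausea", "difficulty concentrating", "fullness of head",
                "blurred vision", "dizzy (eyes open)", "dizzy (eyes closed)",
                "vertigo", "stomach awareness", "burping"),
    nausea = c(1, 0, 0, 0, 0, 1, 1, 1, 1, 0, 0, 0, 0, 0, 1, 1),
    oculomotor = c(1, 1, 1, 1, 1, 0, 0, 0, 1, 0, 1, 0, 0, 0, 0, 0),
    disorientation = c(0, 0, 0, 0, 1, 0, 0, 1, 0, 1, 1, 1, 1, 1, 0, 0),
    stringsAsFactors = FALSE
  )
}

.ssq_weights <- c(nausea = 9.54, oculomotor = 7.58, disorientation = 13.92)
.ssq_total_factor <- 3.74

check_ssq_items <- function(items) {
  items <- as.numeric(items)
  if (length(items) != 16) stop("an SSQ response has exactly 16 items")
  if (any(is.na(items)) || any(items < 0) || any(items > 3) ||
      any(items != round(items))) {
    stop("SSQ items must be integers in 0..3")
  }
  items
}

#' SSQ subscale scores
#'
#' Raw subscale scores are the sums of the 7 contributing items; weighted
#' scores multiply the raws by 9.54 (Nausea), 7.58 (Oculomotor) and
#' 13.92 (Disorientation).
#'
#' @param items 16 integer item scores in 0..3.
#' @param mapping Item-subscale table, see [ssq_item_table()].
#' @return List with `raw` and `weighted` (each named nausea/oculomotor/
#'   disorientation) and `total` (see [ssq_total()]).
#' @export
ssq_subscale_scores <- function(items, mapping = ssq_item_table()) {
  items <- check_ssq_items(items)
  raw <- c(
    nausea = sum(items * mapping$nausea),
    oculomotor = sum(items * mapping$oculomotor),
    disorientation = sum(items * mapping$disorientation)
  )
  weighted <- raw * .ssq_weights
  list(raw = raw, weighted = weighted,
       total = .ssq_total_factor * sum(raw))
}

#' SSQ total score
#'
#' `total = 3.74 x (raw_N + raw_O + raw_D)`. The printed reciprocal-weight
#' form (dividing each weighted subscale by its own weight before the
#' 3.74 factor) is available via `form = "as_printed"` and is
#' algebraically identical.
#'
#' @param items 16 integer item scores in 0..3.
#' @param form `"standard"` or `"as_printed"`.
#' @param mapping Item-subscale table.
#' @return Total score in `[0, 235.62]`.
#' @export
ssq_total <- function(items, form = c("standard", "as_printed"),
                      mapping = ssq_item_table()) {
  form <- match.arg(form)
  sc <- ssq_subscale_scores(items, mapping)
  if (form == "standard") {
    .ssq_total_factor * sum(sc$raw)
  } else {
    .ssq_total_factor * (sc$weighted[["nausea"]] / .ssq_weights[["nausea"]] +
                           sc$weighted[["oculomotor"]] /
                             .ssq_weights[["oculomotor"]] +
                           sc$weighted[["disorientation"]] /
                             .ssq_weights[["disorientation"]])
  }
}

#' Maximum attainable SSQ total
#' @return `3.74 * 63 = 235.62`, the total when all 16 items are 3.
#' @export
ssq_max_total <- function() .ssq_total_factor * 3 * 3 * 7

#' Score an SSQ response table
#'
#' @param responses data.frame with columns `subject_id`, `video_id`,
#'   `item_1` .. `item_16`.
#' @return The input with added columns `raw_n`, `raw_o`, `raw_d`,
#'   `weighted_n`, `weighted_o`, `weighted_d`, `total`, `total_norm`
#'   (total / 235.62).
#' @export
score_ssq_table <- function(responses) {
  item_cols <- paste0("item_", 1:16)
  if (!all(item_cols %in% names(responses))) {
    stop("responses must have columns item_1 .. item_16")
  }
  out <- responses
  for (i in seq_len(nrow(responses))) {
    sc <- ssq_subscale_scores(as.numeric(responses[i, item_cols]))
    out$raw_n[i] <- sc$raw[["nausea"]]
    out$raw_o[i] <- sc$raw[["oculomotor"]]
    out$raw_d[i] <- sc$raw[["disorientation"]]
    out$weighted_n[i] <- sc$weighted[["nausea"]]
    out$weighted_o[i] <- sc$weighted[["oculomotor"]]
    out$weighted_d[i] <- sc$weighted[["disorientation"]]
    out$total[i] <- sc$total
  }
  out$total_norm <- out$total / ssq_max_total()
  out
}

#' Average SSQ totals by video
#'
#' Mean total per video across subjects, plus the per-item mean and
#' standard deviation (across all responses).
#'
#' @param responses data.frame with `subject_id`, `video_id`,
#'   `item_1` .. `item_16`.
#' @return List with `by_video` (video_id, mean_total, n) and `items`
#'   (item, mean, sd).
#' @export
ssq_average_by_video <- function(responses) {
  if (nrow(responses) == 0) stop("no responses")
  scored <- score_ssq_table(responses)
  agg <- aggregate(scored$total, by = list(video_id = scored$video_id),
                   FUN = mean)
  names(agg)[2] <- "mean_total"
  agg$n <- as.vector(table(scored$video_id)[as.character(agg$video_id)])
  item_cols <- paste0("item_", 1:16)
  items <- data.frame(
    item = 1:16,
    mean = vapply(item_cols, function(cc) mean(scored[[cc]]), 0),
    sd = vapply(item_cols, function(cc) sd(scored[[cc]]), 0)
  )
  rownames(items) <- NULL
  list(by_video = agg, items = items)
}
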