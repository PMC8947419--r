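#' Cross-tabulate setae calls against eclosion outcomes
#'
#' Builds the contingency table of per-pupa setae calls versus observed
#' eclosion outcomes and derives the three accuracies:
#' * setae-positive accuracy: males among the setae-positive pupae that
#'   emerged;
#' * setae-negative accuracy: females among the setae-negative pupae that
#'   emerged;
#' * overall accuracy: correctly sexed among all pupae that emerged.
#'
#' Unfledged pupae (those that died without emerging) appear in the counts
#' but are excluded from every accuracy denominator, since they provide no
#' sex label. Percentages are reported rounded half up to one decimal.
#'
#' @param calls data frame with columns `pupa_id` and `call`
#'   (`"male_setae_detected"` / `"no_setae_detected"`), one row per pupa.
#' @param manifest data frame with columns `pupa_id` and `outcome`
#'   (`"male"`, `"female"`, `"unfledged"`).
#' @return a `pupa_eval` object: group totals, per-outcome counts, and
#'   `acc_setae_pos`, `acc_setae_neg`, `acc_overall` in percent (NA with a
#'   warning when a denominator is empty).
#' @export
build_table <- function(calls, manifest) {
  if (!all(c("pupa_id", "call") %in% names(calls)) ||
      !all(c("pupa_id", "outcome") %in% names(manifest)))
    pv_stop("pv_config_error",
            "calls need pupa_id+call, manifest needs pupa_id+outcome")
  bad_outcome <- setdiff(unique(manifest$outcome),
                         c("male", "female", "unfledged"))
  if (length(bad_outcome))
    pv_stop("pv_config_error",
            paste("unknown outcome value(s):",
                  paste(bad_outcome, collapse = ", ")))
  unmatched <- setdiff(calls$pupa_id, manifest$pupa_id)
  if (length(unmatched))
    pv_stop("pv_unmatched_pupae",
            paste("no outcome for pupa id(s):",
                  paste(sort(unmatched), collapse = ", ")),
            pupa_ids = unmatched)
  outcome <- manifest$outcome[match(calls$pupa_id, manifest$pupa_id)]
  pos <- calls$call == "male_setae_detected"
  cnt <- function(sel, what) sum(sel & outcome == what)
  pos_counts <- c(female = cnt(pos, "female"), male = cnt(pos, "male"),
                  unfledged = cnt(pos, "unfledged"))
  neg_counts <- c(female = cnt(!pos, "female"), male = cnt(!pos, "male"),
                  unfledged = cnt(!pos, "unfledged"))
  pct <- function(num, den) {
    if (den == 0) {
      warning("empty accuracy denominator (no emerged pupae in group); ",
              "reporting NA")
      return(NA_real_)
    }
    round_half_up(1000 * num / den) / 10
  }
  pos_emerged <- pos_counts[["female"]] + pos_counts[["male"]]
  neg_emerged <- neg_counts[["female"]] + neg_counts[["male"]]
  structure(list(
    n_setae_pos = sum(pos), n_setae_neg = sum(!pos),
    setae_pos_outcomes = pos_counts, setae_neg_outcomes = neg_counts,
    acc_setae_pos = pct(pos_counts[["male"]], pos_emerged),
    acc_setae_neg = pct(neg_counts[["female"]], neg_emerged),
    acc_overall = pct(pos_counts[["male"]] + neg_counts[["female"]],
                      pos_emerged + neg_emerged)
  ), class = "pupa_eval")
}

#' Tabular report of an evaluation
#'
#' One row per call group mirroring the contingency-table layout:
#' `type, observed, female, male, unfledged, accuracy`.
#'
#' @param table a `pupa_eval` from [build_table()].
#' @return data frame with two rows (`no_setae`, `setae`).
#' @export
summarize_evaluation <- function(table) {
  stopifnot(inherits(table, "pupa_eval"))
  if (table$n_setae_pos + table$n_setae_neg == 0) {
    return(data.frame(type = character(), observed = integer(),
                      female = integer(), male = integer(),
                      unfledged = integer(), accuracy = numeric()))
  }
  data.frame(
    type = c("no_setae", "setae"),
    observed = c(table$n_setae_neg, table$n_setae_pos),
    female = c(table$setae_neg_outcomes[["female"]],
               table$setae_pos_outcomes[["female"]]),
    male = c(table$setae_neg_outcomes[["male"]],
             table$setae_pos_outcomes[["male"]]),
    unfledged = c(table$setae_neg_outcomes[["unfledged"]],
                  table$setae_pos_outcomes[["unfledged"]]),
    accuracy = c(table$acc_setae_neg, table$acc_setae_pos)
  )
}

#' @export
print.pupa_eval <- function(x, ...) {
  cat("Pupal sex identification vs. eclosion outcome\n")
  df <- summarize_evaluation(x)
  if (!nrow(df)) {
    cat("  (empty cohort)\n")
    return(invisible(x))
  }
  print(df, row.names = FALSE)
  cat(sprintf("Overall accuracy (emerged pupae only): %s%%\n",
              format(x$acc_overall, nsmall = 1)))
  invisible(x)
}

#' JSON-ready representation of an evaluation
#' @param table a `pupa_eval`.
#' @return a plain list suitable for [jsonlite::toJSON()].
#' @export
evaluation_as_list <- function(table) {
  stopifnot(inherits(table, "pupa_eval"))
  list(
    n_setae_pos = table$n_setae_pos,
    n_setae_neg = table$n_setae_neg,
    setae_pos_outcomes = as.list(table$setae_pos_outcomes),
    setae_neg_outcomes = as.list(table$setae_neg_outcomes),
    acc_setae_pos = table$acc_setae_pos,
    acc_setae_neg = table$acc_setae_neg,
    acc_overall = table$acc_overall
  )
}
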