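# Named ablation presets: task-roster variants, the one-gate variant, and
# expert-roster variants with a fixed total of six experts.

reg_task <- function(nm) task_spec(nm, "regression")
cls_task <- function(nm) task_spec(nm, "classification")

variant_task_presets <- function() {
  list(
    onlyDDS = list(tasks = list(cls_task("synergy"))),
    Loewe = list(tasks = list(reg_task("loewe"), cls_task("synergy"))),
    removeLoewe = list(tasks = c(lapply(c("zip", "bliss", "hsa", "s"), reg_task),
                                 list(cls_task("synergy")))),
    nonLoewe = list(tasks = c(lapply(c("zip", "bliss", "hsa", "s"), reg_task),
                              list(cls_task("synergy")))),
    REG = list(tasks = c(lapply(REGRESSION_TASKS, reg_task),
                         list(cls_task("synergy")))),
    DDI = list(tasks = list(cls_task("ddi"), cls_task("synergy"))),
    full = list(tasks = default_tasks()),
    DEML = list(tasks = default_tasks()),
    onegate = list(tasks = default_tasks(), share_one_gate = TRUE)
  )
}

expert_kind_codes <- c(DCE = "dense", BAE = "bi_additive", BIE = "bi_interaction")

#' Build a named model variant
#'
#' Task-roster presets: \code{"onlyDDS"} (synergy classification only),
#' \code{"Loewe"} (Loewe regression + synergy classification),
#' \code{"removeLoewe"}/\code{"nonLoewe"} (the four non-Loewe regressions +
#' synergy classification), \code{"REG"} (all five regressions + synergy
#' classification), \code{"DDI"} (DDI + synergy classification),
#' \code{"full"}/\code{"DEML"} (all seven tasks) and \code{"onegate"} (all
#' seven tasks with one task-common gating network).
#'
#' Expert-roster presets keep the total at six experts split evenly across
#' the included kinds: \code{"DCE"}, \code{"BAE"}, \code{"BIE"} (six of one
#' kind), the pairwise combinations \code{"DCE+BAE"}, \code{"DCE+BIE"},
#' \code{"BAE+BIE"} (three of each) and \code{"DCE+BAE+BIE"} (two of each).
#'
#' @param name preset name.
#' @param ... further arguments forwarded to \code{\link{deml_config}} (e.g.
#'   \code{p_d}, \code{p_c}, reduced widths).
#' @return a \code{\link{deml_config}} for the variant.
#' @export
build_variant <- function(name, ...) {
  tp <- variant_task_presets()
  if (name %in% names(tp)) {
    p <- tp[[name]]
    return(deml_config(tasks = p$tasks,
                       share_one_gate = isTRUE(p$share_one_gate), ...))
  }
  codes <- strsplit(name, "+", fixed = TRUE)[[1]]
  if (all(codes %in% names(expert_kind_codes)) && !anyDuplicated(codes)) {
    kinds <- expert_kind_codes[codes]
    count <- 6L %/% length(kinds)
    ek <- stats::setNames(rep(count, length(kinds)), kinds)
    return(deml_config(expert_kinds = ek, ...))
  }
  stop(sprintf("unknown variant '%s'; available: %s and expert combos of %s",
               name, paste(names(tp), collapse = ", "),
               paste(names(expert_kind_codes), collapse = "/")))
}
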