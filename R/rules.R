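#' Decision-rule features and conditions
#'
#' A condition compares one lesion feature (`SUVpeak`, `TBRpeak` or `SUVbg`)
#' to a threshold with a strict comparator (`greater` or `less`).
#'
#' @param feature one of `"SUVpeak"`, `"TBRpeak"`, `"SUVbg"`.
#' @param comparator `"greater"` or `"less"` (strict inequalities).
#' @param threshold numeric threshold in the feature's units.
#' @return a `rule_condition` list.
#' @export
rule_condition <- function(feature = c("SUVpeak", "TBRpeak", "SUVbg"),
                           comparator = c("greater", "less"), threshold) {
  feature <- match.arg(feature)
  comparator <- match.arg(comparator)
  stopifnot(is.numeric(threshold), length(threshold) == 1L, is.finite(threshold))
  structure(list(feature = feature, comparator = comparator,
                 threshold = threshold),
            class = "rule_condition")
}

rule_features <- function() c("SUVpeak", "TBRpeak", "SUVbg")

feature_column <- function(feature) {
  c(SUVpeak = "suvpeak", TBRpeak = "tbrpeak", SUVbg = "suvbg")[[feature]]
}

cond_holds <- function(cond, values) {
  if (cond$comparator == "greater") values > cond$threshold else values < cond$threshold
}

#' Prioritised two-condition decision rule
#'
#' A decision rule reads: if `cond1` holds use `method1`; else if `cond2`
#' holds use `method2`; otherwise use `default_method`. The two conditions
#' must test different features and the three output methods must be
#' pairwise distinct members of [pet_methods()].
#'
#' @param cond1,cond2 [rule_condition] objects on distinct features.
#' @param method1,method2,default_method distinct method names.
#' @return an object of class `decision_rule`.
#' @seealso [default_decision_rule()], [apply_rule()], [rule_search()]
#' @export
decision_rule <- function(cond1, method1, cond2, method2, default_method) {
  stopifnot(inherits(cond1, "rule_condition"), inherits(cond2, "rule_condition"))
  if (cond1$feature == cond2$feature)
    stop("the two conditions must test different features", call. = FALSE)
  methods <- c(method1, method2, default_method)
  if (!all(methods %in% pet_methods()))
    stop("methods must be drawn from pet_methods()", call. = FALSE)
  if (anyDuplicated(methods))
    stop("the three output methods must be pairwise distinct", call. = FALSE)
  structure(list(cond1 = cond1, method1 = method1,
                 cond2 = cond2, method2 = method2,
                 default_method = default_method),
            class = "decision_rule")
}

#' The shipped lesion-adaptive decision rule
#'
#' The rule found to select the preferred segmentation method most accurately:
#' if SUVpeak > 8 use SUV4.0; else if SUVbg > 0.8 use MV3; otherwise use MV2.
#'
#' @return a [decision_rule].
#' @export
default_decision_rule <- function() {
  decision_rule(
    rule_condition("SUVpeak", "greater", 8), "SUV4.0",
    rule_condition("SUVbg", "greater", 0.8), "MV3",
    "MV2"
  )
}

#' @export
format.decision_rule <- function(x, ...) {
  cmp <- function(cond) if (cond$comparator == "greater") ">" else "<"
  sprintf("if %s %s %g use %s; else if %s %s %g use %s; else use %s",
          x$cond1$feature, cmp(x$cond1), x$cond1$threshold, x$method1,
          x$cond2$feature, cmp(x$cond2), x$cond2$threshold, x$method2,
          x$default_method)
}

#' @export
print.decision_rule <- function(x, ...) {
  cat("Decision rule:", format(x), "\n")
  invisible(x)
}

#' Apply a decision rule to lesion features
#'
#' Evaluates the rule's strict comparisons on each lesion's features and
#' returns the selected method per lesion.
#'
#' @param rule a [decision_rule].
#' @param features data frame with numeric columns `suvpeak`, `tbrpeak`,
#'   `suvbg` (only the two features the rule uses are required).
#' @return character vector of selected method names.
#' @export
apply_rule <- function(rule, features) {
  stopifnot(inherits(rule, "decision_rule"), is.data.frame(features))
  get_feature <- function(cond) {
    col <- feature_column(cond$feature)
    if (is.null(features[[col]]))
      stop(sprintf("feature column '%s' is missing", col), call. = FALSE)
    v <- features[[col]]
    if (any(is.na(v)))
      stop(sprintf("feature '%s' has missing values", cond$feature), call. = FALSE)
    v
  }
  c1 <- cond_holds(rule$cond1, get_feature(rule$cond1))
  c2 <- cond_holds(rule$cond2, get_feature(rule$cond2))
  ifelse(c1, rule$method1, ifelse(c2, rule$method2, rule$default_method))
}

#' @rdname apply_rule
#' @param object,newdata,... `predict` method arguments (`newdata` as
#'   `features` above).
#' @export
predict.decision_rule <- function(object, newdata, ...) {
  apply_rule(object, newdata)
}

#' Threshold grids for rule enumeration
#'
#' Default grids: SUVpeak and TBRpeak from 1 to 12 in steps of 0.5
#' (23 values each); SUVbg in steps of 0.2 within 0.5–2, anchored at 2.0
#' (0.6, 0.8, ..., 2.0; 8 values) so that the shipped rule's SUVbg
#' threshold of 0.8 is a grid point.
#'
#' @param suvpeak,tbrpeak,suvbg numeric threshold vectors.
#' @return a `threshold_grid` list.
#' @export
threshold_grid <- function(suvpeak = seq(1, 12, by = 0.5),
                           tbrpeak = seq(1, 12, by = 0.5),
                           suvbg = seq(0.6, 2.0, by = 0.2)) {
  structure(list(SUVpeak = as.numeric(suvpeak),
                 TBRpeak = as.numeric(tbrpeak),
                 SUVbg = as.numeric(suvbg)),
            class = "threshold_grid")
}

#' Closed-form size of the rule space
#'
#' The number of enumerable rules is the sum over ordered pairs of distinct
#' features of the product of their grid sizes, times 4 comparator
#' combinations, times the number of ordered method triples (120 distinct
#' triples from 6 methods, or 216 when repeated methods are allowed).
#'
#' @param grid a [threshold_grid].
#' @param distinct_methods logical; require the three output methods to be
#'   pairwise distinct (the default convention).
#' @param n_methods size of the method pool.
#' @return integer rule count.
#' @export
count_rules <- function(grid = threshold_grid(), distinct_methods = TRUE,
                        n_methods = 6L) {
  sizes <- lengths(grid)
  pairs <- 0
  for (f1 in seq_along(sizes)) for (f2 in seq_along(sizes))
    if (f1 != f2) pairs <- pairs + sizes[[f1]] * sizes[[f2]]
  triples <- if (distinct_methods)
    n_methods * (n_methods - 1L) * (n_methods - 2L)
  else n_methods^3
  as.integer(pairs * 4L * triples)
}

# Integer-coded condition table: one row per (feature, comparator, threshold).
condition_table <- function(grid) {
  rows <- list()
  for (f in seq_along(rule_features()))
    for (cmp in 1:2)
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, comparator = cmp,
        threshold = grid[[rule_features()[f]]])
  out <- do.call(rbind, rows)
  out$cond_id <- seq_len(nrow(out))
  out
}

#' Enumerate every decision rule over a threshold grid
#'
#' Generates the full rule space in a deterministic order: every ordered
#' pair of distinct features, every grid threshold per feature, both strict
#' comparators per condition, and every ordered triple of methods from the
#' pool (distinct by default). Rules are returned in integer-coded compact
#' form; use [rule_from_row()] to materialise one row as a [decision_rule].
#'
#' @inheritParams count_rules
#' @param methods the method pool (default [pet_methods()]).
#' @return data frame with one row per rule: `cond1`, `cond2` (indices into
#'   the attached `conditions` attribute), `m1`, `m2`, `m3` (method indices),
#'   plus attribute `conditions` (the condition table) and `methods`.
#' @export
enumerate_rules <- function(grid = threshold_grid(), methods = pet_methods(),
                            distinct_methods = TRUE) {
  ct <- condition_table(grid)
  nc <- nrow(ct)
  # ordered condition pairs on distinct features
  c1 <- rep(seq_len(nc), each = nc)
  c2 <- rep(seq_len(nc), times = nc)
  ok <- ct$feature[c1] != ct$feature[c2]
  c1 <- c1[ok]; c2 <- c2[ok]
  nm <- length(methods)
  tg <- expand.grid(m3 = seq_len(nm), m2 = seq_len(nm), m1 = seq_len(nm))
  tg <- tg[, c("m1", "m2", "m3")]
  if (distinct_methods)
    tg <- tg[tg$m1 != tg$m2 & tg$m1 != tg$m3 & tg$m2 != tg$m3, , drop = FALSE]
  np <- length(c1); nt <- nrow(tg)
  rules <- data.frame(
    cond1 = rep(c1, each = nt),
    cond2 = rep(c2, each = nt),
    m1 = rep.int(tg$m1, np),
    m2 = rep.int(tg$m2, np),
    m3 = rep.int(tg$m3, np)
  )
  attr(rules, "conditions") <- ct
  attr(rules, "methods") <- methods
  rules
}

#' Materialise one enumerated rule as a decision_rule object
#'
#' @param rules the data frame returned by [enumerate_rules()].
#' @param i row index.
#' @return a [decision_rule].
#' @export
rule_from_row <- function(rules, i) {
  ct <- attr(rules, "conditions")
  methods <- attr(rules, "methods")
  mk <- function(cid) rule_condition(
    rule_features()[ct$feature[cid]],
    c("greater", "less")[ct$comparator[cid]],
    ct$threshold[cid])
  decision_rule(mk(rules$cond1[i]), methods[rules$m1[i]],
                mk(rules$cond2[i]), methods[rules$m2[i]],
                methods[rules$m3[i]])
}

#' Accuracy of a decision rule on a rated lesion table
#'
#' The fraction of lesions for which the rule-selected segmentation method
#' was rated 3 ("preferred"). Lesions with no method rated 3 necessarily
#' count as failures; the denominator is all lesions in the table.
#'
#' @param rule a [decision_rule].
#' @param table data frame with feature columns `suvpeak`, `tbrpeak`,
#'   `suvbg` and rating columns `rating_<method>` for all six methods.
#' @return accuracy in \[0, 1\].
#' @export
rule_accuracy <- function(rule, table) {
  sel <- apply_rule(rule, table)
  rm <- rating_matrix(table)
  idx <- match(sel, colnames(rm))
  r <- rm[cbind(seq_len(nrow(rm)), idx)]
  mean(r == 3L)
}

#' Extract the lesion-by-method rating matrix from a rated table
#'
#' @param table data frame with columns `rating_<method>` for each of the
#'   six methods; ratings must be integers 1–5 with no missing values.
#' @return integer matrix, one column per method in [pet_methods()] order.
#' @export
rating_matrix <- function(table) {
  cols <- paste0("rating_", pet_methods())
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols))
    stop("missing rating columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  rm <- as.matrix(table[cols])
  colnames(rm) <- pet_methods()
  if (any(is.na(rm))) {
    bad <- which(is.na(rm), arr.ind = TRUE)[1, ]
    stop(sprintf("missing rating for lesion %s, method %s",
                 rownames(rm)[bad[1]] %||% bad[1], pet_methods()[bad[2]]),
         call. = FALSE)
  }
  if (!all(rm %in% 1:5))
    stop("ratings must be integers between 1 and 5", call. = FALSE)
  storage.mode(rm) <- "integer"
  rm
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialise / deserialise a decision rule as JSON
#'
#' @param rule a [decision_rule].
#' @param path optional file path; when omitted the JSON string is returned.
#' @return `rule_to_json`: JSON string (invisibly when written to a file);
#'   `rule_from_json`: a [decision_rule].
#' @export
rule_to_json <- function(rule, path = NULL) {
  stopifnot(inherits(rule, "decision_rule"))
  x <- list(
    conditions = list(
      c(rule$cond1[c("feature", "comparator", "threshold")], list(method = rule$method1)),
      c(rule$cond2[c("feature", "comparator", "threshold")], list(method = rule$method2))
    ),
    default_method = rule$default_method
  )
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname rule_to_json
#' @param json JSON string or file path.
#' @export
rule_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  mk <- function(c) rule_condition(c$feature, c$comparator, c$threshold)
  decision_rule(mk(x$conditions[[1]]), x$conditions[[1]]$method,
                mk(x$conditions[[2]]), x$conditions[[2]]$method,
                x$default_method)
}
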