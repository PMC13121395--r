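# Vectorised evaluation engine for the exhaustive decision-rule search.
#
# Every rule is "condition 1 -> method 1, else condition 2 -> method 2, else
# method 3". For a fixed lesion subset the number of correct selections of a
# rule decomposes over its three branches:
#
#   correct = #(C1 & rated3[m1]) + #(!C1 & C2 & rated3[m2])
#           + #(!C1 & !C2 & rated3[m3])
#
# With Z[c, m] = #(C_c & rated3[m]) and W[c1, c2, m] = #(C_c1 & C_c2 &
# rated3[m]) precomputed by matrix products, each of the ~10^6 rules costs a
# handful of vectorised gathers per fold, so the full default grid runs in
# minutes on one CPU. No model fitting happens anywhere: rules are fixed and
# cross-validation only re-estimates the same population accuracy.

# condition truth matrix: n lesions x n conditions, numeric 0/1
condition_matrix <- function(table, ct) {
  feats <- cbind(table$suvpeak, table$tbrpeak, table$suvbg)
  if (any(is.na(feats)))
    stop("feature columns suvpeak/tbrpeak/suvbg must be complete", call. = FALSE)
  C <- matrix(0, nrow(feats), nrow(ct))
  for (cid in seq_len(nrow(ct))) {
    v <- feats[, ct$feature[cid]]
    C[, cid] <- if (ct$comparator[cid] == 1L) v > ct$threshold[cid]
                else v < ct$threshold[cid]
  }
  C
}

# per-subset branch count tables; r3 is the numeric 0/1 rated-3 matrix
branch_tables <- function(C, r3) {
  nc <- ncol(C); nm <- ncol(r3)
  Z <- crossprod(C, r3)                      # nc x nm
  W <- array(0, c(nc, nc, nm))
  for (m in seq_len(nm))
    W[, , m] <- crossprod(C * r3[, m], C)
  list(Z = Z, W = W, tot = unname(colSums(r3)))
}

# linear gather indices into Z (nc x nm) and W (nc x nc x nm) for all rules
rule_gather_index <- function(rules, nc) {
  list(
    z1 = rules$cond1 + (rules$m1 - 1L) * nc,
    z2 = rules$cond2 + (rules$m2 - 1L) * nc,
    z3 = rules$cond1 + (rules$m3 - 1L) * nc,
    z4 = rules$cond2 + (rules$m3 - 1L) * nc,
    w2 = rules$cond1 + (rules$cond2 - 1L) * nc + (rules$m2 - 1L) * nc * nc,
    w3 = rules$cond1 + (rules$cond2 - 1L) * nc + (rules$m3 - 1L) * nc * nc,
    m3 = rules$m3
  )
}

rule_correct_counts <- function(bt, gi) {
  bt$Z[gi$z1] +
    (bt$Z[gi$z2] - bt$W[gi$w2]) +
    (bt$tot[gi$m3] - bt$Z[gi$z3] - bt$Z[gi$z4] + bt$W[gi$w3])
}

#' Full-table accuracy of every enumerated rule
#'
#' Vectorised equivalent of calling [rule_accuracy()] on each rule: the
#' fraction of lesions whose rule-selected method is rated 3.
#'
#' @param rules integer-coded rule table from [enumerate_rules()].
#' @param table rated lesion table (see [rule_accuracy()]).
#' @return numeric vector of accuracies, one per rule row.
#' @export
evaluate_rules <- function(rules, table) {
  ct <- attr(rules, "conditions")
  methods <- attr(rules, "methods")
  C <- condition_matrix(table, ct)
  rm3 <- rating_matrix(table)[, methods, drop = FALSE] == 3L
  storage.mode(rm3) <- "double"
  bt <- branch_tables(C, rm3)
  gi <- rule_gather_index(rules, nrow(ct))
  rule_correct_counts(bt, gi) / nrow(table)
}

#' Exhaustive cross-validated decision-rule search
#'
#' Evaluates every rule of the threshold grid on a rated lesion table using
#' repeated k-fold cross-validation: in each iteration the lesions are
#' shuffled and partitioned into `n_folds` folds, each fold serves once as
#' the held-out set, and every rule's accuracy (selected method rated 3) is
#' recorded on it. Because the rules are predefined there is no fitting;
#' the mean and dispersion of each rule's accuracy are compiled across all
#' `n_folds * n_iterations` held-out evaluations. Rules are ranked by mean
#' accuracy (descending), ties broken by smaller SD and then by enumeration
#' order.
#'
#' @param table rated lesion table with feature columns `suvpeak`,
#'   `tbrpeak`, `suvbg` and rating columns `rating_<method>`.
#' @param grid a [threshold_grid()] (ignored when `rules` is supplied).
#' @param rules optional precomputed rule table from [enumerate_rules()].
#' @param n_folds number of cross-validation folds.
#' @param n_iterations number of shuffled repetitions.
#' @param rng_seed integer seed governing all iterations.
#' @return an object of class `rule_search`: the ranked results (integer
#'   coded, with `mean_accuracy`, `accuracy_sd` across all fold evaluations
#'   and `accuracy_sd_within`, the mean of per-iteration across-fold SDs),
#'   the winning rule as `best_rule`, and the search settings. Methods:
#'   `print`, `summary`, `coef` (the best rule), `predict` (apply the best
#'   rule to new lesions), `plot` (accuracy distribution).
#' @export
rule_search <- function(table, grid = threshold_grid(), rules = NULL,
                        n_folds = 5L, n_iterations = 50L, rng_seed = 1L) {
  if (is.null(rules)) rules <- enumerate_rules(grid)
  n <- nrow(table)
  if (n < n_folds)
    stop("need at least as many lesions as folds", call. = FALSE)
  ct <- attr(rules, "conditions")
  methods <- attr(rules, "methods")
  C <- condition_matrix(table, ct)
  rm3 <- rating_matrix(table)[, methods, drop = FALSE] == 3L
  storage.mode(rm3) <- "double"
  gi <- rule_gather_index(rules, nrow(ct))
  nr <- nrow(rules)
  s <- numeric(nr); ss <- numeric(nr); sd_within_sum <- numeric(nr)
  n_evals <- n_folds * n_iterations
  # near-equal contiguous fold sizes over the shuffled order
  bounds <- round(seq(0, n, length.out = n_folds + 1))
  set.seed(rng_seed)
  for (it in seq_len(n_iterations)) {
    perm <- sample.int(n)
    it_s <- numeric(nr); it_ss <- numeric(nr)
    for (f in seq_len(n_folds)) {
      idx <- perm[(bounds[f] + 1L):bounds[f + 1L]]
      bt <- branch_tables(C[idx, , drop = FALSE], rm3[idx, , drop = FALSE])
      acc <- rule_correct_counts(bt, gi) / length(idx)
      s <- s + acc; ss <- ss + acc * acc
      it_s <- it_s + acc; it_ss <- it_ss + acc * acc
    }
    v <- (it_ss - it_s * it_s / n_folds) / (n_folds - 1)
    sd_within_sum <- sd_within_sum + sqrt(pmax(v, 0))
  }
  mean_acc <- s / n_evals
  sd_all <- sqrt(pmax((ss - s * s / n_evals) / (n_evals - 1), 0))
  ord <- order(-mean_acc, sd_all, seq_len(nr))
  results <- rules[ord, , drop = FALSE]
  results$mean_accuracy <- mean_acc[ord]
  results$accuracy_sd <- sd_all[ord]
  results$accuracy_sd_within <- sd_within_sum[ord] / n_iterations
  results$enum_order <- ord
  rownames(results) <- NULL
  attr(results, "conditions") <- ct
  attr(results, "methods") <- methods
  structure(list(results = results,
                 best_rule = rule_from_row(results, 1L),
                 n_rules = nr, n_lesions = n,
                 n_folds = n_folds, n_iterations = n_iterations,
                 rng_seed = rng_seed),
            class = "rule_search")
}

#' Decode integer-coded rules into a readable table
#'
#' @param rules rule table from [enumerate_rules()] or the `results` element
#'   of a [rule_search] object.
#' @param i row indices to decode (default all).
#' @return data frame with feature/comparator/threshold/method columns.
#' @export
decode_rules <- function(rules, i = seq_len(nrow(rules))) {
  ct <- attr(rules, "conditions")
  methods <- attr(rules, "methods")
  cmps <- c("greater", "less")
  out <- data.frame(
    feature1 = rule_features()[ct$feature[rules$cond1[i]]],
    comparator1 = cmps[ct$comparator[rules$cond1[i]]],
    threshold1 = ct$threshold[rules$cond1[i]],
    method1 = methods[rules$m1[i]],
    feature2 = rule_features()[ct$feature[rules$cond2[i]]],
    comparator2 = cmps[ct$comparator[rules$cond2[i]]],
    threshold2 = ct$threshold[rules$cond2[i]],
    method2 = methods[rules$m2[i]],
    default_method = methods[rules$m3[i]],
    stringsAsFactors = FALSE
  )
  extra <- intersect(c("mean_accuracy", "accuracy_sd", "accuracy_sd_within"),
                     names(rules))
  for (col in extra) out[[col]] <- rules[[col]][i]
  out
}

#' Locate a decision rule in an enumerated/ranked rule table
#'
#' @param rules rule table (possibly ranked search results).
#' @param rule a [decision_rule].
#' @return integer row index, or `NA` if the rule is not in the table.
#' @export
match_rule <- function(rules, rule) {
  ct <- attr(rules, "conditions")
  methods <- attr(rules, "methods")
  find_cond <- function(cond) {
    f <- match(cond$feature, rule_features())
    cmp <- match(cond$comparator, c("greater", "less"))
    hit <- which(ct$feature == f & ct$comparator == cmp &
                   abs(ct$threshold - cond$threshold) < 1e-9)
    if (length(hit) != 1L) NA_integer_ else hit
  }
  c1 <- find_cond(rule$cond1); c2 <- find_cond(rule$cond2)
  m1 <- match(rule$method1, methods); m2 <- match(rule$method2, methods)
  m3 <- match(rule$default_method, methods)
  if (anyNA(c(c1, c2, m1, m2, m3))) return(NA_integer_)
  hit <- which(rules$cond1 == c1 & rules$cond2 == c2 &
                 rules$m1 == m1 & rules$m2 == m2 & rules$m3 == m3)
  if (length(hit)) hit[1] else NA_integer_
}

#' @export
print.rule_search <- function(x, ...) {
  cat(sprintf("Decision-rule search: %d rules on %d lesions (%d-fold CV x %d iterations)\n",
              x$n_rules, x$n_lesions, x$n_folds, x$n_iterations))
  cat("Best rule:", format(x$best_rule), "\n")
  cat(sprintf("  mean accuracy %.4f (SD %.4f across %d held-out folds)\n",
              x$results$mean_accuracy[1], x$results$accuracy_sd[1],
              x$n_folds * x$n_iterations))
  invisible(x)
}

#' @export
summary.rule_search <- function(object, n = 10L, ...) {
  top <- decode_rules(object$results, seq_len(min(n, nrow(object$results))))
  structure(list(top = top, n_rules = object$n_rules,
                 n_lesions = object$n_lesions,
                 n_folds = object$n_folds,
                 n_iterations = object$n_iterations),
            class = "summary.rule_search")
}

#' @export
print.summary.rule_search <- function(x, ...) {
  cat(sprintf("Top rules of %d evaluated on %d lesions:\n", x$n_rules, x$n_lesions))
  print(x$top, digits = 4)
  invisible(x)
}

#' @export
coef.rule_search <- function(object, ...) object$best_rule

#' @export
predict.rule_search <- function(object, newdata, ...) {
  apply_rule(object$best_rule, newdata)
}

#' @export
plot.rule_search <- function(x, ...) {
  graphics::hist(x$results$mean_accuracy, breaks = 50,
                 main = "Cross-validated rule accuracies",
                 xlab = "mean accuracy", col = "grey80", border = "white", ...)
  graphics::abline(v = x$results$mean_accuracy[1], col = "red", lwd = 2)
  invisible(x)
}
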