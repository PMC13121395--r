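#' Reference MTV: mean volume of preferred-rated segmentations
#'
#' For each lesion, the arithmetic mean MTV across the methods rated 3.
#' Lesions with no method rated 3 have no reference and are excluded; their
#' ids are attached as attribute `excluded`.
#'
#' @param table rated lesion table with `rating_<method>` and `mtv_<method>`
#'   columns (and optionally `lesion_id`).
#' @return data frame with `lesion_id`, `ref_mtv_ml` and `n_rate3`.
#' @export
reference_mtv <- function(table) {
  rm3 <- rating_matrix(table) == 3L
  mm <- mtv_matrix(table)
  n_rate3 <- rowSums(rm3)
  ref <- rowSums(mm * rm3) / n_rate3
  ids <- table$lesion_id %||% as.character(seq_len(nrow(table)))
  keep <- n_rate3 >= 1L
  out <- data.frame(lesion_id = ids[keep], ref_mtv_ml = ref[keep],
                    n_rate3 = n_rate3[keep], stringsAsFactors = FALSE)
  attr(out, "excluded") <- ids[!keep]
  out
}

#' Spearman rank correlation with tie handling
#'
#' Rank correlation using average ranks for ties, with a two-sided p value
#' (asymptotic, as appropriate in the presence of ties). Constant input has
#' no defined rank correlation and is flagged rather than silently returned.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho`, `p`, `n` and `constant` (TRUE when either input
#'   is constant, in which case `rho` and `p` are `NA`).
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    return(list(rho = NA_real_, p = NA_real_, n = length(x), constant = TRUE))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x), constant = FALSE)
}

#' Flag discrepant volumes against a reference
#'
#' A volume is relatively discrepant when it differs from the reference by
#' more than `rel_threshold` (fraction of the reference) and absolutely
#' discrepant when the difference exceeds `abs_threshold` mL. The signed
#' direction (over/under-estimation) is recorded. When the reference is 0
#' the relative flag is undefined (`NA`) but the absolute flag is still
#' computed.
#'
#' @param mtv numeric vector of candidate volumes (mL).
#' @param ref_mtv numeric vector of reference volumes (mL).
#' @param rel_threshold relative threshold (default 0.10, i.e. 10%).
#' @param abs_threshold absolute threshold in mL (default 3).
#' @return data frame with `rel_exceeded`, `abs_exceeded`, `flag`
#'   (`"within"`, `"rel_exceeded"`, `"abs_exceeded"`, `"both"`) and
#'   `direction` (`"over"`, `"under"`, `"equal"`).
#' @export
deviation_flags <- function(mtv, ref_mtv, rel_threshold = 0.10, abs_threshold = 3.0) {
  stopifnot(length(mtv) == length(ref_mtv),
            rel_threshold > 0, abs_threshold > 0)
  diff <- mtv - ref_mtv
  rel <- ifelse(ref_mtv > 0, abs(diff) / ref_mtv > rel_threshold, NA)
  abs_ex <- abs(diff) > abs_threshold
  flag <- ifelse(is.na(rel) | !rel,
                 ifelse(abs_ex, "abs_exceeded", "within"),
                 ifelse(abs_ex, "both", "rel_exceeded"))
  direction <- ifelse(diff > 0, "over", ifelse(diff < 0, "under", "equal"))
  data.frame(rel_exceeded = rel, abs_exceeded = abs_ex,
             flag = flag, direction = direction, stringsAsFactors = FALSE)
}

#' Total metabolic tumour volume per scan
#'
#' Sums lesion MTVs within each scan.
#'
#' @param scan_id character/factor vector of scan identifiers, one per lesion.
#' @param mtv_ml numeric vector of lesion MTVs (mL).
#' @return data frame with `scan_id` and `tmtv_ml`, one row per scan.
#' @export
tmtv <- function(scan_id, mtv_ml) {
  stopifnot(length(scan_id) == length(mtv_ml))
  agg <- tapply(mtv_ml, scan_id, sum)
  data.frame(scan_id = names(agg), tmtv_ml = as.numeric(agg),
             stringsAsFactors = FALSE, row.names = NULL)
}

# resolve a selection strategy into one method name per lesion
resolve_strategy <- function(strategy, table) {
  if (inherits(strategy, "decision_rule")) return(apply_rule(strategy, table))
  if (inherits(strategy, "rule_search")) return(predict(strategy, table))
  if (inherits(strategy, "method_selector")) return(select_method(strategy, table))
  if (is.character(strategy) && length(strategy) == 1L) {
    if (strategy == "oracle") {
      rm3 <- rating_matrix(table) == 3L
      pr <- selector_priority()
      return(apply(rm3[, pr, drop = FALSE], 1L, function(z) {
        w <- which(z); if (length(w)) pr[w[1]] else pr[1]
      }))
    }
    if (strategy %in% pet_methods()) return(rep(strategy, nrow(table)))
  }
  stop("strategy must be a decision rule, a method selector, 'oracle', or a method name",
       call. = FALSE)
}

#' Agreement of a selection strategy with the preferred-rating reference
#'
#' Applies a selection strategy (a fixed single method, a [decision_rule] or
#' [rule_search] fit, a trained [method_selector][train_selector], or the
#' `"oracle"` that always picks a rate-3 method when one exists) to every
#' lesion, takes the selected method's MTV, and quantifies agreement with
#' the reference (mean MTV of rate-3 segmentations): Spearman correlation at
#' lesion level (overall and per timepoint) and at scan level (TMTV),
#' fractions of lesions beyond the relative/absolute deviation thresholds,
#' and signed over/under-estimation counts. Lesions without any rate-3
#' method have no reference and are excluded (reported in `n_excluded`).
#'
#' @param table rated lesion table with features, ratings, MTVs, `scan_id`
#'   and `timepoint` columns.
#' @param strategy the selection strategy (see above).
#' @param rel_threshold,abs_threshold deviation thresholds (fraction / mL).
#' @return an object of class `agreement_report`.
#' @export
strategy_report <- function(table, strategy, rel_threshold = 0.10, abs_threshold = 3.0) {
  sel <- resolve_strategy(strategy, table)
  mm <- mtv_matrix(table)
  mtv_sel <- mm[cbind(seq_len(nrow(mm)), match(sel, colnames(mm)))]
  ref <- reference_mtv(table)
  ids <- table$lesion_id %||% as.character(seq_len(nrow(table)))
  keep <- match(ref$lesion_id, ids)
  lesion <- data.frame(lesion_id = ref$lesion_id,
                       scan_id = table$scan_id[keep],
                       timepoint = table$timepoint[keep],
                       method = sel[keep],
                       mtv_ml = mtv_sel[keep],
                       ref_mtv_ml = ref$ref_mtv_ml,
                       stringsAsFactors = FALSE)
  lesion <- cbind(lesion, deviation_flags(lesion$mtv_ml, lesion$ref_mtv_ml,
                                          rel_threshold, abs_threshold))
  per_tp <- function(f) {
    tps <- sort(unique(lesion$timepoint))
    out <- lapply(tps, function(tp) f(lesion[lesion$timepoint == tp, , drop = FALSE]))
    stats::setNames(out, tps)
  }
  rho_lesion <- spearman_rho(lesion$mtv_ml, lesion$ref_mtv_ml)
  rho_lesion_tp <- per_tp(function(d)
    if (nrow(d) >= 3) spearman_rho(d$mtv_ml, d$ref_mtv_ml)
    else list(rho = NA_real_, p = NA_real_, n = nrow(d), constant = NA))
  scans <- merge(tmtv(lesion$scan_id, lesion$mtv_ml),
                 stats::setNames(tmtv(lesion$scan_id, lesion$ref_mtv_ml),
                                 c("scan_id", "ref_tmtv_ml")),
                 by = "scan_id")
  tp_of_scan <- tapply(lesion$timepoint, lesion$scan_id, function(z) z[1])
  scans$timepoint <- as.character(tp_of_scan[scans$scan_id])
  rho_scan <- spearman_rho(scans$tmtv_ml, scans$ref_tmtv_ml)
  structure(list(
    strategy = if (is.character(strategy)) strategy else class(strategy)[1],
    lesion = lesion,
    scan = scans,
    rho_lesion = rho_lesion,
    rho_lesion_by_timepoint = rho_lesion_tp,
    rho_scan = rho_scan,
    frac_rel_exceeded = mean(lesion$rel_exceeded, na.rm = TRUE),
    frac_abs_exceeded = mean(lesion$abs_exceeded),
    n_over = sum(lesion$direction == "over"),
    n_under = sum(lesion$direction == "under"),
    n_lesions = nrow(lesion),
    n_excluded = length(attr(ref, "excluded")),
    excluded = attr(ref, "excluded"),
    rel_threshold = rel_threshold, abs_threshold = abs_threshold),
    class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement report (%s strategy), %d lesions (%d without reference excluded)\n",
              x$strategy, x$n_lesions, x$n_excluded))
  cat(sprintf("  lesion-level Spearman rho = %.3f; scan-level (TMTV) rho = %.3f\n",
              x$rho_lesion$rho, x$rho_scan$rho))
  cat(sprintf("  > %.0f%% deviation: %.1f%% of lesions; > %g mL: %.1f%%\n",
              100 * x$rel_threshold, 100 * x$frac_rel_exceeded,
              x$abs_threshold, 100 * x$frac_abs_exceeded))
  cat(sprintf("  over-estimated: %d lesions, under-estimated: %d\n",
              x$n_over, x$n_under))
  invisible(x)
}

#' @export
plot.agreement_report <- function(x, level = c("lesion", "scan"), ...) {
  level <- match.arg(level)
  d <- if (level == "lesion")
    data.frame(ref = x$lesion$ref_mtv_ml, val = x$lesion$mtv_ml,
               tp = x$lesion$timepoint)
  else
    data.frame(ref = x$scan$ref_tmtv_ml, val = x$scan$tmtv_ml,
               tp = x$scan$timepoint)
  cols <- c(baseline = "#1f77b4", interim = "#2ca02c", eot = "#d62728")
  eps <- 1e-3
  graphics::plot(pmax(d$ref, eps), pmax(d$val, eps), log = "xy",
                 col = cols[d$tp], pch = 19, cex = 0.6,
                 xlab = "reference MTV (mL)",
                 ylab = sprintf("%s MTV (mL)", x$strategy),
                 main = sprintf("%s-level agreement", level), ...)
  graphics::abline(0, 1, untf = TRUE)
  rng <- range(pmax(d$ref, eps))
  xs <- exp(seq(log(rng[1]), log(rng[2]), length.out = 100))
  graphics::lines(xs, xs * (1 + x$rel_threshold), lty = 2, col = "red")
  graphics::lines(xs, xs * (1 - x$rel_threshold), lty = 2, col = "red")
  graphics::lines(xs, pmax(xs + x$abs_threshold, eps), lty = 3, col = "blue")
  graphics::lines(xs, pmax(xs - x$abs_threshold, eps), lty = 3, col = "blue")
  graphics::legend("topleft", legend = names(cols), col = cols, pch = 19, bty = "n")
  invisible(x)
}
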