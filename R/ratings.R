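#' Specify a simulated rated-lesion cohort
#'
#' Describes the statistical structure of a simulated cohort of lesions with
#' uptake features and per-method quality ratings, built around a planted
#' selection rule: the method the rule picks for a lesion is rated 3
#' ("preferred"), other methods are co-acceptable (also rated 3) with a
#' fixed probability and otherwise rated on the under/over-estimation side
#' of the scale according to their relative strictness, and with probability
#' `rating_noise` the planted method's rating is flipped away from 3.
#'
#' @param n_lesions_per_timepoint named or ordered integer triple
#'   (baseline, interim, end-of-treatment); defaults to the 409/67/122 split
#'   of a three-timepoint lymphoma cohort (598 lesions).
#' @param suvpeak_range SUVpeak is drawn log-uniformly within this range.
#' @param suvbg_range SUVbg is drawn uniformly within this range; TBRpeak is
#'   derived as SUVpeak/SUVbg.
#' @param planted_rule the [decision_rule] generating the preferred method.
#' @param co_acceptability probability that a non-preferred method is also
#'   rated 3.
#' @param rating_noise probability in \[0, 1\] that the planted method's
#'   rating is perturbed away from 3.
#' @param n_patients number of patients the lesions are spread over (each
#'   patient contributes one scan per timepoint).
#' @param rng_seed integer seed.
#' @return a `rating_sim_spec` list.
#' @export
rating_sim_spec <- function(n_lesions_per_timepoint = c(baseline = 409, interim = 67, eot = 122),
                            suvpeak_range = c(2, 20),
                            suvbg_range = c(0.3, 2.5),
                            planted_rule = default_decision_rule(),
                            co_acceptability = 0.2,
                            rating_noise = 0,
                            n_patients = 33L,
                            rng_seed = 1L) {
  n <- as.integer(n_lesions_per_timepoint)
  stopifnot(length(n) == 3L, all(n >= 0L),
            rating_noise >= 0, rating_noise <= 1,
            co_acceptability >= 0, co_acceptability <= 1,
            inherits(planted_rule, "decision_rule"))
  if (sum(n) == 0L) stop("the simulated cohort must contain lesions", call. = FALSE)
  structure(list(n_lesions_per_timepoint = stats::setNames(n, c("baseline", "interim", "eot")),
                 suvpeak_range = suvpeak_range, suvbg_range = suvbg_range,
                 planted_rule = planted_rule,
                 co_acceptability = co_acceptability,
                 rating_noise = rating_noise,
                 n_patients = as.integer(n_patients),
                 rng_seed = as.integer(rng_seed)),
            class = "rating_sim_spec")
}

# Nominal strictness of each operator's effective threshold, most permissive
# first. Non-preferred methods stricter than the planted method tend to
# under-segment (ratings 1-2); more permissive ones over-segment (4-5).
method_strictness <- function() {
  stats::setNames(c(1, 6, 2, 5, 3, 4), pet_methods())
}

#' Simulate a rated lesion table from a planted selection rule
#'
#' Draws lesion features (SUVpeak log-uniform, SUVbg uniform, TBRpeak their
#' ratio), assigns each lesion to a patient scan at its timepoint, applies
#' the planted rule to fix the preferred (rate-3) method, and fills in the
#' remaining ratings by the co-acceptability/strictness scheme of
#' [rating_sim_spec]. Per-method metabolic tumour volumes are synthesised
#' from a log-normal true volume with rating-dependent multiplicative bias
#' (under-estimating ratings shrink the volume, over-estimating ratings —
#' especially 5, "flooding" — inflate it), so the agreement stage can be
#' exercised end to end.
#'
#' @param spec a [rating_sim_spec].
#' @return data frame with one row per lesion: identifiers (`lesion_id`,
#'   `patient_id`, `scan_id`), `timepoint`, `location`, features (`suvpeak`,
#'   `suvbg`, `tbrpeak`), the planted `preferred_method`, and per-method
#'   `rating_<method>` and `mtv_<method>` columns.
#' @export
simulate_rating_table <- function(spec) {
  stopifnot(inherits(spec, "rating_sim_spec"))
  set.seed(spec$rng_seed)
  counts <- spec$n_lesions_per_timepoint
  n <- sum(counts)
  timepoint <- rep(names(counts), counts)
  patient_id <- sample.int(spec$n_patients, n, replace = TRUE)
  scan_id <- paste0("P", formatC(patient_id, width = 2, flag = "0"), "_", timepoint)
  location <- sample(c("nodal_above", "nodal_below", "extranodal"), n,
                     replace = TRUE, prob = c(0.45, 0.30, 0.25))
  lsp <- log(spec$suvpeak_range)
  suvpeak <- exp(stats::runif(n, lsp[1], lsp[2]))
  suvbg <- stats::runif(n, spec$suvbg_range[1], spec$suvbg_range[2])
  tbrpeak <- suvpeak / suvbg
  tab <- data.frame(lesion_id = sprintf("L%04d", seq_len(n)),
                    patient_id = patient_id, scan_id = scan_id,
                    timepoint = timepoint, location = location,
                    suvpeak = suvpeak, suvbg = suvbg, tbrpeak = tbrpeak,
                    stringsAsFactors = FALSE)
  preferred <- apply_rule(spec$planted_rule, tab)
  tab$preferred_method <- preferred
  strict <- method_strictness()
  ratings <- matrix(NA_integer_, n, 6, dimnames = list(NULL, pet_methods()))
  for (m in pet_methods()) {
    is_pref <- preferred == m
    ratings[is_pref, m] <- 3L
    other <- !is_pref
    co <- other & stats::runif(n) < spec$co_acceptability
    ratings[co, m] <- 3L
    rest <- other & !co
    stricter <- strict[m] > strict[preferred]
    under <- rest & stricter
    over <- rest & !stricter
    ratings[under, m] <- sample(1:2, sum(under), replace = TRUE)
    ratings[over, m] <- sample(4:5, sum(over), replace = TRUE)
  }
  if (spec$rating_noise > 0) {
    flip <- stats::runif(n) < spec$rating_noise
    idx <- cbind(which(flip), match(preferred[flip], pet_methods()))
    ratings[idx] <- sample(c(2L, 4L), sum(flip), replace = TRUE)
  }
  # synthetic per-method MTVs: log-normal true volume, rating-dependent bias
  true_vol <- exp(stats::rnorm(n, mean = log(3), sd = 1))
  mtvs <- matrix(NA_real_, n, 6, dimnames = list(NULL, pet_methods()))
  for (m in pet_methods()) {
    r <- ratings[, m]
    bias <- numeric(n)
    bias[r == 1L] <- stats::runif(sum(r == 1L), 0.05, 0.5)
    bias[r == 2L] <- stats::runif(sum(r == 2L), 0.6, 0.9)
    bias[r == 3L] <- exp(stats::rnorm(sum(r == 3L), 0, 0.15))
    bias[r == 4L] <- stats::runif(sum(r == 4L), 1.1, 1.5)
    bias[r == 5L] <- stats::runif(sum(r == 5L), 2, 8)
    mtvs[, m] <- true_vol * bias
  }
  for (m in pet_methods()) tab[[paste0("rating_", m)]] <- ratings[, m]
  for (m in pet_methods()) tab[[paste0("mtv_", m)]] <- mtvs[, m]
  tab
}

#' Extract the lesion-by-method MTV matrix from a simulated/loaded table
#'
#' @param table data frame with `mtv_<method>` columns.
#' @return numeric matrix with one column per method.
#' @export
mtv_matrix <- function(table) {
  cols <- paste0("mtv_", pet_methods())
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols))
    stop("missing MTV columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  mm <- as.matrix(table[cols])
  colnames(mm) <- pet_methods()
  mm
}
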