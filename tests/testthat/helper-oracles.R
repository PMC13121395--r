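# Independent brute-force oracles used to validate the vectorised
# implementations. These deliberately use the simplest possible algorithms
# (scalar stack-based flood fill, per-voxel tallies, explicit rank formula)
# and share no code with the package internals.

# scalar stack-based 26-connected flood fill from a seed
flood_fill_oracle <- function(candidate, seed) {
  d <- dim(candidate)
  out <- array(FALSE, d)
  if (!candidate[seed[1], seed[2], seed[3]]) return(out)
  stack <- list(seed)
  out[seed[1], seed[2], seed[3]] <- TRUE
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      if (di == 0 && dj == 0 && dk == 0) next
      i <- v[1] + di; j <- v[2] + dj; k <- v[3] + dk
      if (i < 1 || i > d[1] || j < 1 || j > d[2] || k < 1 || k > d[3]) next
      if (candidate[i, j, k] && !out[i, j, k]) {
        out[i, j, k] <- TRUE
        stack[[length(stack) + 1L]] <- c(i, j, k)
      }
    }
  }
  out
}

# per-voxel majority-vote tally (no connectivity restriction)
mv_count_oracle <- function(masks, k) {
  d <- dim(masks[[1]])
  out <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (kk in seq_len(d[3])) {
    votes <- 0L
    for (m in masks) if (m[i, j, kk]) votes <- votes + 1L
    out[i, j, kk] <- votes >= k
  }
  out
}

# average ranks computed from scratch (no call to rank())
average_ranks <- function(x) {
  ord <- order(x)
  r <- numeric(length(x))
  pos <- 1L
  while (pos <= length(x)) {
    run <- pos
    while (run < length(x) && x[ord[run + 1L]] == x[ord[pos]]) run <- run + 1L
    r[ord[pos:run]] <- mean(pos:run)
    pos <- run + 1L
  }
  r
}

# Spearman rho via the explicit Pearson-on-ranks formula
spearman_oracle <- function(x, y) {
  rx <- average_ranks(x); ry <- average_ranks(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# per-lesion scalar rule application + rating lookup
rule_accuracy_oracle <- function(rule, table) {
  hits <- 0L
  for (i in seq_len(nrow(table))) {
    feat <- function(cond) switch(cond$feature,
                                  SUVpeak = table$suvpeak[i],
                                  TBRpeak = table$tbrpeak[i],
                                  SUVbg = table$suvbg[i])
    test <- function(cond) if (cond$comparator == "greater")
      feat(cond) > cond$threshold else feat(cond) < cond$threshold
    m <- if (test(rule$cond1)) rule$method1
         else if (test(rule$cond2)) rule$method2
         else rule$default_method
    if (table[[paste0("rating_", m)]][i] == 3L) hits <- hits + 1L
  }
  hits / nrow(table)
}

# small random phantom with one blurred lesion; returns volume + seed
random_phantom <- function(seed, grid = 16L, spacing = 2) {
  set.seed(seed)
  bg <- runif(1, 0.2, 1.2)
  peak <- runif(1, 3, 12)
  extent <- (grid - 1) * spacing
  r <- runif(1, 4, 7)
  centre <- runif(3, r + spacing, extent - r - spacing)
  ps <- phantom_spec(grid, spacing, background_suv = bg,
                     noise_sd = runif(1, 0, 0.15),
                     psf_fwhm = sample(c(0, 4, 6), 1),
                     lesions = list(lesion_spec(centre, r, peak)),
                     rng_seed = seed)
  g <- generate_volume(ps)
  list(vol = g$volume, seed = as.integer(g$seeds[1, c("i", "j", "k")]),
       background = bg, peak = peak)
}

# rating table with fully random ratings (no planted structure)
random_rating_table <- function(n, seed) {
  set.seed(seed)
  tab <- data.frame(lesion_id = sprintf("R%03d", seq_len(n)),
                    suvpeak = exp(runif(n, log(1.5), log(25))),
                    suvbg = runif(n, 0.2, 2.6))
  tab$tbrpeak <- tab$suvpeak / tab$suvbg
  for (m in pet_methods())
    tab[[paste0("rating_", m)]] <- sample(1:5, n, replace = TRUE)
  for (m in pet_methods())
    tab[[paste0("mtv_", m)]] <- exp(rnorm(n, log(2), 1))
  tab
}

# a random valid decision rule (grid-free thresholds)
random_rule <- function(seed) {
  set.seed(seed)
  feats <- sample(c("SUVpeak", "TBRpeak", "SUVbg"), 2)
  thr <- function(f) switch(f, SUVpeak = runif(1, 1, 12),
                            TBRpeak = runif(1, 1, 12),
                            SUVbg = runif(1, 0.5, 2))
  ms <- sample(pet_methods(), 3)
  decision_rule(
    rule_condition(feats[1], sample(c("greater", "less"), 1), thr(feats[1])), ms[1],
    rule_condition(feats[2], sample(c("greater", "less"), 1), thr(feats[2])), ms[2],
    ms[3])
}

# uniform cubic block of given SUV planted in a zero volume
block_volume <- function(block_suv = 5, grid = 9L, spacing = 2,
                         from = 4L, to = 6L, background = 0) {
  v <- array(background, rep(grid, 3L))
  v[from:to, from:to, from:to] <- block_suv
  suv_volume(v, rep(spacing, 3L))
}

# drop mask attributes (threshold, convergence) for voxel-set comparison
bare <- function(m) array(as.logical(m), dim(m))
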