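# Build the flat entry table used by the permutation engine: one row per
# (bin curve, grid cell) with positive mass. Bin curves are the cell-wise
# means of their member densities, laid on the analysis grid.
.bin_entries <- function(densities, bins, window, step) {
  grid <- seq(ceiling(min(window) / step) * step,
              floor(max(window) / step) * step, by = step)
  bin_ids <- unique(bins$bin_id)
  size <- table(bins$bin_id)
  idx_list <- vector("list", nrow(bins))
  w_list <- vector("list", nrow(bins))
  b_list <- vector("list", nrow(bins))
  bin_index <- match(bins$bin_id, bin_ids)
  for (k in seq_len(nrow(bins))) {
    d <- densities[[bins$lab_id[k]]]
    if (is.null(d)) stop("no calibrated density for ", bins$lab_id[k])
    if (d$step != step) stop("density grid step != analysis step")
    pos <- round((d$calbp - grid[1]) / step) + 1
    ok <- pos >= 1 & pos <= length(grid)
    idx_list[[k]] <- pos[ok]
    w_list[[k]] <- d$mass[ok] / size[[bins$bin_id[k]]]
    b_list[[k]] <- rep(bin_index[k], sum(ok))
  }
  list(grid = grid,
       idx = unlist(idx_list), w = unlist(w_list), bin = unlist(b_list),
       bin_ids = bin_ids, n_bins = length(bin_ids))
}

# Sum per-label SPDs for one label assignment. labels: integer vector over
# bins (1..L). Returns L x ncell matrix.
.label_spds <- function(entries, labels, n_labels) {
  ncell <- length(entries$grid)
  group <- entries$idx + ncell * (labels[entries$bin] - 1L)
  acc <- rowsum(entries$w, group, reorder = FALSE)
  out <- matrix(0, nrow = n_labels, ncol = ncell)
  g <- as.integer(rownames(acc))
  out[cbind((g - 1L) %/% ncell + 1L, (g - 1L) %% ncell + 1L)] <- acc[, 1]
  out
}

#' Regional mark permutation test
#'
#' Tests whether each labelled subset of the dates deviates from the pooled
#' trend by randomly permuting the region labels (marks) and recomputing
#' per-label SPDs from the already-calibrated densities. Label counts are
#' preserved exactly in every permutation, and the observed assignment is
#' included as one permutation (plus-one convention): each label's
#' observed SPD joins its permuted set for the z-transform and the
#' pointwise 2.5/97.5% bands, exactly as in [model_test()], so the test is
#' exchangeable under the null.
#'
#' Labels are permuted at the bin level by default, so that several dates
#' from one site never leak label information across a permutation; set
#' `level = "date"` to permute individual dates as marks instead.
#'
#' @param densities named list of `cal_density` (keys = lab_id).
#' @param bins bin table from [bin_dates()].
#' @param labels region label per date, aligned with `bins` rows (or a
#'   named vector keyed by lab_id). Within a bin, labels must agree.
#' @param runs Monte Carlo permutations (default 1000).
#' @param seed mandatory RNG seed.
#' @param window,step analysis grid.
#' @param level `"bin"` (default) or `"date"` permutation granularity.
#' @return object of class `permutation_test`: per-label list of results
#'   (`region`, `segments`, `global_p`, `observed_stat`, `zobs`, `lo`,
#'   `hi`, `obs_spd`), plus `calbp`, `runs`, `seed`.
#' @export
permutation_test <- function(densities, bins, labels, runs = 1000, seed,
                             window = c(2000, 12000), step = 5,
                             level = c("bin", "date")) {
  if (missing(seed) || is.null(seed)) stop("permutation_test: a seed is required")
  level <- match.arg(level)
  if (!is.null(names(labels))) labels <- labels[bins$lab_id]
  if (length(labels) != nrow(bins)) stop("labels must align with bins rows")
  if (anyNA(labels)) stop("missing region label(s)")
  lab_f <- factor(labels)
  if (nlevels(lab_f) < 2) stop("need at least 2 distinct labels")
  entries <- .bin_entries(densities, bins, window, step)
  # observed per-bin labels; within-bin consistency required at bin level
  bf <- factor(bins$bin_id, levels = entries$bin_ids)
  mixed <- tapply(as.integer(lab_f), bf, function(v) length(unique(v)) > 1)
  if (level == "bin" && any(mixed)) {
    stop("bins with mixed labels; use level = \"date\" to permute dates")
  }
  bin_lab <- tapply(as.integer(lab_f), bf, function(v) v[1])
  L <- nlevels(lab_f)
  ncell <- length(entries$grid)
  counts <- tabulate(as.integer(lab_f), L)
  if (any(tabulate(bin_lab, L) < 1)) stop("a label has no bins")
  obs <- .label_spds(entries, as.integer(bin_lab), L)
  sims <- array(0, dim = c(runs, L, ncell))
  withr::with_seed(seed, {
    for (r in seq_len(runs)) {
      perm <- if (level == "bin") sample(as.integer(bin_lab)) else {
        pl <- sample(as.integer(lab_f))          # permute date marks
        as.integer(tapply(pl, factor(bins$bin_id, levels = entries$bin_ids),
                          function(v) v[1]))     # bin takes its first date's mark
      }
      sims[r, , ] <- .label_spds(entries, perm, L)
    }
  })
  results <- lapply(seq_len(L), function(l) {
    rt <- mc_rank_test(obs[l, ], sims[, l, ])
    segs <- exceed_segments(entries$grid, rt$zobs, rt$lo, rt$hi)
    list(region = levels(lab_f)[l], segments = segs, global_p = rt$p,
         observed_stat = rt$obs_stat, sim_stats = rt$sim_stats,
         zobs = rt$zobs, lo = rt$lo, hi = rt$hi, obs_spd = obs[l, ])
  })
  names(results) <- levels(lab_f)
  structure(list(results = results, calbp = entries$grid, runs = runs,
                 seed = seed, level = level, counts = counts),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("Mark permutation test (%d runs, %s-level):\n", x$runs, x$level))
  for (r in x$results) {
    cat(sprintf("  %s: global p = %.4g, %d deviation segment(s)\n",
                r$region, r$global_p, nrow(r$segments)))
  }
  invisible(x)
}

#' Pairwise permutation comparison of two date sets
#'
#' Two-set special case of [permutation_test()]: the two sets are pooled,
#' labels permuted, and a symmetric two-sided global p-value returned. The
#' pairwise statistic is the sum of both labels' band-exceedance
#' statistics, which makes the result invariant to swapping the sets.
#'
#' @param densities_a,densities_b named `cal_density` lists for the two sets.
#' @param bins_a,bins_b their bin tables.
#' @param runs,seed,window,step,level as in [permutation_test()].
#' @return list with `global_p`, `observed_stat` and the underlying
#'   `permutation_test` object.
#' @export
pairwise_permutation <- function(densities_a, bins_a, densities_b, bins_b,
                                 runs = 1000, seed, window = c(2000, 12000),
                                 step = 5, level = c("bin", "date")) {
  if (!length(densities_a) || !length(densities_b)) stop("empty date set")
  bins_a$bin_id <- paste0("A:", bins_a$bin_id)
  bins_b$bin_id <- paste0("B:", bins_b$bin_id)
  densities <- c(densities_a, densities_b)
  bins <- rbind(bins_a, bins_b)
  labels <- c(rep("A", nrow(bins_a)), rep("B", nrow(bins_b)))
  pt <- permutation_test(densities, bins, labels, runs = runs, seed = seed,
                         window = window, step = step, level = level)
  obs <- pt$results$A$observed_stat + pt$results$B$observed_stat
  sim <- pt$results$A$sim_stats + pt$results$B$sim_stats
  p <- (1 + sum(sim >= obs)) / (runs + 1)
  list(global_p = p, observed_stat = obs, test = pt)
}
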